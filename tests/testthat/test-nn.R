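# Correctness of the hand-written recurrent engine: analytic gradients
# against central differences, initialisation-time loss, determinism.

numeric_grad_check <- function(net, inputs, yg, yz, paths, eps = 1e-5,
                               n_per = 4L) {
  loss_fn <- function(par) {
    net$par <- par
    fw <- haplosnp:::net_forward(net, inputs)
    haplosnp:::smoothed_ce(fw$pg, yg, 0.1)$loss +
      haplosnp:::smoothed_ce(fw$pz, yz, 0.1)$loss
  }
  fw <- haplosnp:::net_forward(net, inputs)
  lg <- haplosnp:::smoothed_ce(fw$pg, yg, 0.1)
  lz <- haplosnp:::smoothed_ce(fw$pz, yz, 0.1)
  gr <- haplosnp:::net_backward(net, fw$cache, lg$dlogits, lz$dlogits)
  getp <- function(l, pth) { for (p in pth) l <- l[[p]]; l }
  setp <- function(l, pth, v) {
    if (length(pth) == 1L) { l[[pth]] <- v; l }
    else { l[[pth[1]]] <- setp(l[[pth[1]]], pth[-1], v); l }
  }
  worst <- 0
  for (pth in paths) {
    P <- getp(net$par, pth); G <- getp(gr, pth)
    for (r in seq_len(n_per)) {
      k <- sample(length(P), 1L)
      P2 <- P; P2[k] <- P[k] + eps
      lp <- loss_fn(setp(net$par, pth, P2))
      P2[k] <- P[k] - eps
      lm <- loss_fn(setp(net$par, pth, P2))
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - G[k]) / max(abs(num), abs(G[k]), 1e-6))
    }
  }
  worst
}

test_that("pileup-network gradients match central differences", {
  set.seed(11)
  net <- build_pileup_network(list(hidden = 4L, fc = 6L, w = 2L), seed = 2)
  X <- array(abs(rnorm(3 * 5 * 16)), c(3, 5, 16))
  worst <- numeric_grad_check(net, X, c(1L, 5L, 21L), c(1L, 2L, 3L),
                              list(c("l1f", "Wx"), c("l1b", "Wh"),
                                   c("l2f", "Wx"), c("l2b", "b"),
                                   c("fc", "W"), c("hg", "W"), c("hz", "b")))
  expect_lt(worst, 1e-3)
})

test_that("haplotype-network gradients match central differences", {
  set.seed(12)
  net <- build_haplotype_network(list(hidden = 3L, fc = 5L, comb = 4L,
                                      w = 2L, t = 1L), seed = 3)
  X <- list(short = array(abs(rnorm(3 * 5 * 104)), c(3, 5, 104)),
            long = array(abs(rnorm(3 * 3 * 104)), c(3, 3, 104)))
  worst <- numeric_grad_check(net, X, c(1L, 5L, 10L), c(1L, 2L, 3L),
                              list(c("short", "l1f", "Wx"),
                                   c("short", "l2b", "Wh"),
                                   c("short", "fc", "W"),
                                   c("long", "l1b", "Wx"),
                                   c("long", "l2f", "b"),
                                   c("comb", "W"), c("hg", "W"), c("hz", "b")))
  expect_lt(worst, 1e-3)
})

test_that("untrained heads are near-uniform so the loss starts near log K", {
  net <- build_pileup_network(list(hidden = 16L, fc = 32L, w = 16L), seed = 5)
  X <- array(abs(rnorm(20 * 33 * 16)), c(20, 33, 16))
  fw <- haplosnp:::net_forward(net, X)
  expect_equal(rowSums(fw$pg), rep(1, 20), tolerance = 1e-9)
  expect_equal(rowSums(fw$pz), rep(1, 20), tolerance = 1e-9)
  l <- haplosnp:::smoothed_ce(fw$pg, sample(21, 20, TRUE), 0.1)$loss +
    haplosnp:::smoothed_ce(fw$pz, sample(3, 20, TRUE), 0.1)$loss
  expect_equal(l, log(21) + log(3), tolerance = 0.15)
})

test_that("training is deterministic and can overfit a separable toy set", {
  set.seed(6)
  N <- 200L
  X <- array(0, c(N, 33, 16))
  yg <- sample(c(1L, 2L, 5L, 8L), N, replace = TRUE)
  for (i in seq_len(N)) X[i, , yg[i]] <- 10 + rnorm(33)
  yz <- ifelse(yg == 1L, 1L, ifelse(yg %in% c(5L, 8L), 2L, 3L))
  cfg <- list(batch = 16L, epochs = 60L, lr = 8e-3, smoothing = 0.01,
              lookahead = FALSE, augment = FALSE)
  net <- build_pileup_network(list(hidden = 12L, fc = 24L, w = 16L), seed = 1)
  tr1 <- train_pileup(net, X, yg, yz, cfg, seed = 9)
  pr <- net_predict(tr1, X)
  expect_gte(mean(max.col(pr$pg) == yg), 0.99)
  expect_gte(mean(max.col(pr$pz) == yz), 0.99)
  tr2 <- train_pileup(net, X, yg, yz, cfg, seed = 9)
  expect_identical(tr1$par, tr2$par)
  expect_identical(tr1$loss_history, tr2$loss_history)
  # degenerate training sets are rejected
  expect_error(train_pileup(net, X[1, , , drop = FALSE], yg[1], yz[1], cfg),
               "training set")
})

test_that("lookahead wrapper trains and differs from plain Adam", {
  set.seed(7)
  N <- 40L
  X <- array(0, c(N, 33, 16))
  yg <- sample(c(1L, 5L), N, replace = TRUE)
  for (i in seq_len(N)) X[i, , yg[i]] <- 8
  yz <- ifelse(yg == 1L, 1L, 2L)
  net <- build_pileup_network(list(hidden = 8L, fc = 16L, w = 16L), seed = 2)
  cfg <- list(batch = 8L, epochs = 5L, lr = 5e-3, smoothing = 0.01,
              lookahead = TRUE, lookahead_k = 5L, lookahead_alpha = 0.5,
              augment = FALSE)
  tr_la <- train_pileup(net, X, yg, yz, cfg, seed = 3)
  cfg$lookahead <- FALSE
  tr_ad <- train_pileup(net, X, yg, yz, cfg, seed = 3)
  expect_false(identical(tr_la$par, tr_ad$par))
  expect_lt(tail(tr_la$loss_history, 1), tr_la$loss_history[1])
})

test_that("allele-relabeling augmentation is self-consistent", {
  # label map: applying a permutation then its inverse is the identity
  perms <- haplosnp:::all_base_perms()
  for (p in perms[c(2, 7, 13, 24)]) {
    inv <- order(p)
    m1 <- haplosnp:::geno_label_map(p, TRUE)
    m2 <- haplosnp:::geno_label_map(inv, TRUE)
    expect_equal(m2[m1], seq_len(21L))
  }
  # channel permutation composes consistently with the label map:
  # predictions on permuted images equal permuted-class predictions
  net <- build_pileup_network(list(hidden = 6L, fc = 8L, w = 2L), seed = 4)
  X <- array(abs(rnorm(4 * 5 * 16)), c(4, 5, 16))
  p <- c(2L, 3L, 1L, 4L)
  Xp <- haplosnp:::net_augment(net, X, p)
  inv <- order(p)
  Xpp <- haplosnp:::net_augment(net, Xp, inv)
  expect_equal(X, Xpp)
})

test_that("quality score follows the clipped log-odds law", {
  expect_equal(quality_score(0.5), 0)
  expect_equal(quality_score(0.9), 10 * log10(9), tolerance = 1e-9)
  expect_equal(quality_score(1 - 1e-12), 60)
  expect_equal(quality_score(1e-12), 0)
  # antisymmetry of the raw transform
  p <- runif(50, 0.01, 0.99)
  expect_equal(quality_score(p, clip = FALSE),
               -quality_score(1 - p, clip = FALSE), tolerance = 1e-9)
  # strict monotonicity on a fine grid
  grid <- seq(1e-6, 1 - 1e-6, length.out = 1000)
  expect_true(all(diff(quality_score(grid, clip = FALSE)) > 0))
})

test_that("model checkpoints round-trip through save/load", {
  net <- build_pileup_network(list(hidden = 6L, fc = 8L, w = 2L), seed = 4)
  f <- tempfile(fileext = ".rds")
  save_model(net, f)
  net2 <- load_model(f)
  expect_identical(net$par, net2$par)
  expect_identical(class(net), class(net2))
  X <- array(abs(rnorm(2 * 5 * 16)), c(2, 5, 16))
  expect_equal(haplosnp:::net_forward(net, X)$pg,
               haplosnp:::net_forward(net2, X)$pg)
})
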