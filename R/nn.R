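# Recurrent-network engine.
#
# Bidirectional LSTM stacks with exact backpropagation-through-time,
# dense layers, label-smoothed softmax cross-entropy, and Adam with an
# optional lookahead wrapper. The per-time-step recurrences run in
# compiled code (src/lstm.cpp); batches are numeric arrays with
# dimensions N (batch) x D (channels) x T (time). All parameters live in
# nested named lists of matrices/vectors so the optimizer can walk them
# generically. Gradient correctness is pinned by numerical-difference
# tests.

#' @useDynLib haplosnp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_rand <- function(nr, nc, scale) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

init_lstm <- function(input, hidden) {
  sc <- 1 / sqrt(hidden)
  b <- stats::runif(4L * hidden, -sc, sc)
  b[(hidden + 1L):(2L * hidden)] <- 1          # forget-gate bias
  list(Wx = nn_rand(input, 4L * hidden, sc),
       Wh = nn_rand(hidden, 4L * hidden, sc), b = b)
}

init_dense <- function(input, output) {
  sc <- 1 / sqrt(input)
  list(W = nn_rand(input, output, sc), b = stats::runif(output, -sc, sc))
}

rev_time <- function(X) {
  X[, , dim(X)[3]:1, drop = FALSE]
}

lstm_forward <- function(X, p) {
  lstm_forward_cpp(X, p$Wx, p$Wh, p$b)
}

lstm_backward <- function(X, p, cache, dH) {
  r <- lstm_backward_cpp(X, p$Wx, p$Wh, cache$i, cache$f, cache$g, cache$o,
                         cache$cprev, cache$tc, cache$h, dH)
  list(dX = r$dX, grads = list(Wx = r$dWx, Wh = r$dWh, b = as.numeric(r$db)))
}

bilstm_forward <- function(X, pf, pb) {
  N <- dim(X)[1]; T_ <- dim(X)[3]; H <- nrow(pf$Wh)
  fw <- lstm_forward(X, pf)
  bw <- lstm_forward(rev_time(X), pb)
  out <- array(0, c(N, 2L * H, T_))
  out[, 1:H, ] <- fw$h
  out[, (H + 1L):(2L * H), ] <- rev_time(bw$h)
  list(out = out, fw = fw, bw = bw)
}

bilstm_backward <- function(X, pf, pb, fwd, dOut) {
  H <- nrow(pf$Wh)
  bf <- lstm_backward(X, pf, fwd$fw, dOut[, 1:H, , drop = FALSE])
  bb <- lstm_backward(rev_time(X), pb, fwd$bw,
                      rev_time(dOut[, (H + 1L):(2L * H), , drop = FALSE]))
  list(dX = bf$dX + rev_time(bb$dX), gf = bf$grads, gb = bb$grads)
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Label-smoothed cross entropy. y: 1-based class indices. Returns the
# mean loss and the gradient w.r.t. logits (already divided by N).
smoothed_ce <- function(p, y, smoothing) {
  N <- nrow(p); K <- ncol(p)
  tgt <- matrix(smoothing / K, N, K)
  tgt[cbind(seq_len(N), y)] <- tgt[cbind(seq_len(N), y)] + (1 - smoothing)
  lp <- log(pmax(p, 1e-12))
  list(loss = -sum(tgt * lp) / N, dlogits = (p - tgt) / N)
}

# ---- nested-parameter-tree utilities -------------------------------------

tree_map <- function(a, f) {
  if (is.list(a)) lapply(a, tree_map, f = f) else f(a)
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(k) tree_map2(a[[k]], b[[k]], f))
    names(out) <- names(a)
    out
  } else f(a, b)
}

adam_init <- function(par) {
  list(m = tree_map(par, function(x) x * 0),
       v = tree_map(par, function(x) x * 0), t = 0L)
}

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map2(st$m, grad, function(m, g) beta1 * m + (1 - beta1) * g)
  st$v <- tree_map2(st$v, grad, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  upd <- tree_map2(st$m, st$v, function(m, v)
    lr * (m / c1) / (sqrt(v / c2) + eps))
  list(par = tree_map2(par, upd, `-`), state = st)
}

# ---- model building blocks -----------------------------------------------

# N x T x C image batch to a scaled N x C x T cube.
as_input_cube <- function(X3, scale = NULL) {
  X <- aperm(X3, c(1L, 3L, 2L))
  if (!is.null(scale)) X <- sweep(X, 2L, scale, "/")
  X
}

# Shared branch: 2 BiLSTM layers -> middle time step -> tanh -> dense(+relu)
branch_forward <- function(par, X, mid) {
  N <- dim(X)[1]
  L1 <- bilstm_forward(X, par$l1f, par$l1b)
  L2 <- bilstm_forward(L1$out, par$l2f, par$l2b)
  m <- matrix(L2$out[, , mid], N)
  a <- tanh(m)
  z <- a %*% par$fc$W + matrix(par$fc$b, N, length(par$fc$b), byrow = TRUE)
  r <- pmax(z, 0)
  list(out = r, X = X, L1 = L1, L2 = L2, a = a, z = z, mid = mid)
}

branch_backward <- function(par, cache, dOut) {
  dz <- dOut * (cache$z > 0)
  gfc <- list(W = crossprod(cache$a, dz), b = colSums(dz))
  da <- dz %*% t(par$fc$W)
  dm <- da * (1 - cache$a^2)
  d2 <- dim(cache$L2$out)
  dL2 <- array(0, d2)
  dL2[, , cache$mid] <- dm
  b2 <- bilstm_backward(cache$L1$out, par$l2f, par$l2b, cache$L2, dL2)
  b1 <- bilstm_backward(cache$X, par$l1f, par$l1b, cache$L1, b2$dX)
  list(grads = list(l1f = b1$gf, l1b = b1$gb, l2f = b2$gf, l2b = b2$gb,
                    fc = gfc))
}

head_forward <- function(par, r) {
  lg <- r %*% par$hg$W + matrix(par$hg$b, nrow(r), length(par$hg$b), byrow = TRUE)
  lz <- r %*% par$hz$W + matrix(par$hz$b, nrow(r), length(par$hz$b), byrow = TRUE)
  list(pg = softmax(lg), pz = softmax(lz))
}

head_backward <- function(par, r, dlg, dlz) {
  list(grads = list(hg = list(W = crossprod(r, dlg), b = colSums(dlg)),
                    hz = list(W = crossprod(r, dlz), b = colSums(dlz))),
       dr = dlg %*% t(par$hg$W) + dlz %*% t(par$hz$W))
}
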