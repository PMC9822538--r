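# Shared training machinery for the two genotyper networks.
#
# Internal S3 generics: `net_forward` (inputs -> head probabilities +
# cache), `net_backward` (head logit grads -> parameter gradient tree),
# `net_slice` (index a batch out of the input container) and
# `net_augment` (allele-relabeling augmentation). The loop below is Adam
# with an optional lookahead wrapper (slow weights synchronised every k
# steps), summed label-smoothed cross-entropy over the genotype and
# zygosity heads.

net_forward <- function(net, inputs, ...) UseMethod("net_forward")
net_backward <- function(net, cache, dlg, dlz) UseMethod("net_backward")
net_slice <- function(net, inputs, idx) UseMethod("net_slice")
net_augment <- function(net, inputs, perm) UseMethod("net_augment")
net_bind <- function(net, input_list) UseMethod("net_bind")

bind_arrays1 <- function(lst) {
  d <- dim(lst[[1]])
  n <- vapply(lst, function(x) dim(x)[1], 1L)
  out <- array(0, c(sum(n), d[2], d[3]))
  at <- 0L
  for (x in lst) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

# Permuted genotype-class index map for a base permutation `perm`
# (perm[b] = new identity of base b); I and D are fixed points.
geno_label_map <- function(perm, round1 = TRUE) {
  cls <- genotype_classes(round1)
  relabel <- function(a) {
    b <- match(a, BASES)
    ifelse(is.na(b), a, BASES[perm[b]])
  }
  p <- class_to_pair(cls)
  match(pair_to_class(relabel(p[, 1]), relabel(p[, 2])), cls)
}

# New-channel <- old-channel index vector for base-channel blocks.
base_channel_idx <- function(perm) match(1:4, perm)

#' @keywords internal
train_network <- function(net, inputs, yg, yz, tcfg, seed = 1L) {
  set.seed(as.integer(seed))
  if (length(yg) < 2L || length(unique(yg)) < 2L)
    stop("training set must contain at least two examples and two classes")
  # static allele-relabeling expansion: `augment` = total copies of the
  # training set (the original plus augment-1 randomly drawn base
  # permutations, fixed for the whole run)
  n_copies <- if (isTRUE(tcfg$augment)) 4L
              else if (is.numeric(tcfg$augment)) as.integer(tcfg$augment)
              else 1L
  if (n_copies > 1L) {
    perms <- all_base_perms()
    picks <- sample(2:length(perms), n_copies - 1L)   # perms[[1]] = identity
    aug_in <- list(inputs); aug_yg <- list(yg)
    for (p in perms[picks]) {
      aug_in[[length(aug_in) + 1L]] <- net_augment(net, inputs, p)
      aug_yg[[length(aug_yg) + 1L]] <-
        geno_label_map(p, net$cfg$n_geno == 21L)[yg]
    }
    inputs <- net_bind(net, aug_in)
    yg <- unlist(aug_yg)
    yz <- rep(yz, n_copies)
  }
  n <- length(yg)
  par <- net$par
  st <- adam_init(par)
  slow <- if (isTRUE(tcfg$lookahead)) par else NULL
  k_la <- tcfg$lookahead_k %||% 5L
  a_la <- tcfg$lookahead_alpha %||% 0.5
  history <- numeric(0)
  step <- 0L

  decay <- tcfg$lr_decay %||% 1
  decay_at <- ceiling((tcfg$lr_decay_at %||% 0.7) * tcfg$epochs)
  for (ep in seq_len(tcfg$epochs)) {
    lr_ep <- if (ep > decay_at) tcfg$lr * decay else tcfg$lr
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = tcfg$batch)) {
      idx <- ord[b0:min(b0 + tcfg$batch - 1L, n)]
      if (length(idx) < 2L) next
      xb <- net_slice(net, inputs, idx)
      ygb <- yg[idx]; yzb <- yz[idx]
      net$par <- par
      fw <- net_forward(net, xb)
      lg <- smoothed_ce(fw$pg, ygb, tcfg$smoothing)
      lz <- smoothed_ce(fw$pz, yzb, tcfg$smoothing)
      grads <- net_backward(net, fw$cache, lg$dlogits, lz$dlogits)
      up <- adam_step(par, grads, st, lr_ep)
      par <- up$par; st <- up$state
      step <- step + 1L
      if (!is.null(slow) && step %% k_la == 0L) {
        slow <- tree_map2(slow, par, function(s, f) s + a_la * (f - s))
        par <- slow
      }
      ep_loss <- ep_loss + lg$loss + lz$loss; nb <- nb + 1L
    }
    history <- c(history, ep_loss / max(nb, 1L))
  }
  net$par <- par
  net$loss_history <- history
  net
}

all_base_perms <- function() {
  p <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b)))
    p[[length(p) + 1L]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initial mean training loss of an untrained model
#'
#' With near-zero logits both heads are near-uniform, so the summed
#' smoothed cross entropy starts near `log(K_genotype) + log(3)`.
#' @keywords internal
uniform_loss <- function(n_geno) log(n_geno) + log(3)

#' Predict head probabilities in batches
#' @param net a trained network.
#' @param inputs the network's input container.
#' @param batch batch size for chunked forward passes.
#' @return list with matrices `pg`, `pz`.
#' @export
net_predict <- function(net, inputs, batch = 512L) {
  n <- net_n(net, inputs)
  pg <- NULL; pz <- NULL
  for (b0 in seq(1L, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, n)
    fw <- net_forward(net, net_slice(net, inputs, idx))
    pg <- rbind(pg, fw$pg); pz <- rbind(pz, fw$pz)
  }
  list(pg = pg, pz = pz)
}

net_n <- function(net, inputs) {
  if (is.array(inputs)) dim(inputs)[1] else dim(inputs$short)[1]
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with a versioned header recording the model
#' class and configuration.
#' @param net network object.
#' @param path checkpoint file path.
#' @export
save_model <- function(net, path) {
  saveRDS(list(format = "haplosnp-model-v1", class = class(net),
               cfg = net$cfg, par = net$par), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "haplosnp-model-v1")) stop("not a model checkpoint")
  structure(list(par = x$par, cfg = x$cfg), class = x$class)
}
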