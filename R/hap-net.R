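#' Second-round (haplotype) genotyper network
#'
#' Two recurrent branches — one over the `(2w+1) x 104` short-range
#' pileup image, one over the `(2t+1) x 104` long-range haplotype image —
#' each a two-layer bidirectional LSTM reduced at its middle time step
#' (the same convention as the pileup network), followed by a combining
#' fully connected layer and two heads: genotype (10 base pairs) and
#' zygosity (3 classes). Profiles as in [pileup_net_config()]; the
#' published full profile trains with batch 512, lr 1e-5, 30 epochs.
#'
#' @param profile `"desk"` or `"full"`.
#' @export
hap_net_config <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "full")
    list(net = list(hidden = 128L, fc = 512L, comb = 512L, w = 16L, t = 5L),
         train = list(batch = 512L, epochs = 30L, lr = 1e-5,
                      smoothing = 0.1, lookahead = TRUE, augment = FALSE,
                      neg_ratio = 3))
  else
    list(net = list(hidden = 32L, fc = 64L, comb = 64L, w = 16L, t = 5L),
         train = list(batch = 16L, epochs = 30L, lr = 1e-2,
                      lr_decay = 0.1, lr_decay_at = 0.5,
                      smoothing = 0.01, lookahead = FALSE, augment = 6L,
                      neg_ratio = 1.5))
}

# Per-channel scaling for one 26-feature block, repeated over the four
# alignment-subset blocks: counts, frequencies, quality sums/means,
# mapping-quality sums/means.
hap_scale <- function() {
  rep(c(rep(25, 5), rep(1, 5), rep(750, 4), rep(40, 4),
        rep(1500, 4), rep(60, 4)), 4)
}

#' Build an untrained haplotype network
#'
#' @param config the `net` element of [hap_net_config()].
#' @param seed seed for parameter initialisation.
#' @return object of class `hap_net`.
#' @export
build_haplotype_network <- function(config = hap_net_config()$net, seed = 1L) {
  set.seed(as.integer(seed))
  H <- config$hidden; FC <- config$fc; CB <- config$comb
  branch <- function() list(l1f = init_lstm(104L, H), l1b = init_lstm(104L, H),
                            l2f = init_lstm(2L * H, H), l2b = init_lstm(2L * H, H),
                            fc = init_dense(2L * H, FC))
  par <- list(short = branch(), long = branch(),
              comb = init_dense(2L * FC, CB),
              hg = init_dense(CB, 10L), hz = init_dense(CB, 3L))
  structure(list(par = par,
                 cfg = list(hidden = H, fc = FC, comb = CB,
                            w = config$w, t = config$t,
                            seq_short = 2L * config$w + 1L,
                            seq_long = 2L * config$t + 1L,
                            channels = 104L, n_geno = 10L,
                            scale = hap_scale())),
            class = "hap_net")
}

#' @export
net_forward.hap_net <- function(net, inputs, ...) {
  ds <- dim(inputs$short); dl <- dim(inputs$long)
  if (ds[2] != net$cfg$seq_short || ds[3] != 104L ||
      dl[2] != net$cfg$seq_long || dl[3] != 104L)
    stop("haplotype-net input shapes must be N x (2w+1) x 104 and N x (2t+1) x 104")
  Xs <- as_input_cube(inputs$short, net$cfg$scale)
  Xl <- as_input_cube(inputs$long, net$cfg$scale)
  bs <- branch_forward(net$par$short, Xs, mid = net$cfg$w + 1L)
  bl <- branch_forward(net$par$long, Xl, mid = net$cfg$t + 1L)
  cc <- cbind(bs$out, bl$out)
  z <- cc %*% net$par$comb$W +
    matrix(net$par$comb$b, nrow(cc), length(net$par$comb$b), byrow = TRUE)
  r <- pmax(z, 0)
  hd <- head_forward(net$par, r)
  list(pg = hd$pg, pz = hd$pz,
       cache = list(bs = bs, bl = bl, cc = cc, z = z, r = r))
}

#' @export
net_backward.hap_net <- function(net, cache, dlg, dlz) {
  hb <- head_backward(net$par, cache$r, dlg, dlz)
  dz <- hb$dr * (cache$z > 0)
  gcomb <- list(W = crossprod(cache$cc, dz), b = colSums(dz))
  dcc <- dz %*% t(net$par$comb$W)
  FC <- net$cfg$fc
  gs <- branch_backward(net$par$short, cache$bs, dcc[, 1:FC, drop = FALSE])
  gl <- branch_backward(net$par$long, cache$bl,
                        dcc[, (FC + 1L):(2L * FC), drop = FALSE])
  c(list(short = gs$grads, long = gl$grads, comb = gcomb), hb$grads)
}

#' @export
net_slice.hap_net <- function(net, inputs, idx) {
  list(short = inputs$short[idx, , , drop = FALSE],
       long = inputs$long[idx, , , drop = FALSE])
}

#' @export
net_bind.hap_net <- function(net, input_list) {
  list(short = bind_arrays1(lapply(input_list, `[[`, "short")),
       long = bind_arrays1(lapply(input_list, `[[`, "long")))
}

#' @export
net_augment.hap_net <- function(net, inputs, perm) {
  bi <- base_channel_idx(perm)
  blk <- c(bi, 5L, bi + 5L, 10L, bi + 10L, bi + 14L, bi + 18L, bi + 22L)
  idx <- as.integer(outer(blk, c(0L, 26L, 52L, 78L), `+`))
  list(short = inputs$short[, , idx, drop = FALSE],
       long = inputs$long[, , idx, drop = FALSE])
}

#' Train the haplotype network
#'
#' @param net a [build_haplotype_network()] result.
#' @param images list of arrays `short`, `long` from [haplotype_images()].
#' @param yg,yz 1-based genotype (10-class) and zygosity labels.
#' @param train_cfg the `train` element of [hap_net_config()].
#' @param seed integer seed.
#' @export
train_haplotype <- function(net, images, yg, yz,
                            train_cfg = hap_net_config()$train, seed = 1L) {
  stopifnot(inherits(net, "hap_net"))
  train_network(net, images, yg, yz, train_cfg, seed)
}

#' Call candidate sites with a trained haplotype network
#'
#' @param net a trained `hap_net`.
#' @param sites candidate data.frame (`contig`, `pos0`, `ref`).
#' @param images list of arrays `short`, `long`.
#' @return data.frame of call records (quality = min of head scores).
#' @export
call_haplotype <- function(net, sites, images) {
  stopifnot(inherits(net, "hap_net"), nrow(sites) == dim(images$short)[1])
  records_from_heads(sites, net_predict(net, images), genotype_classes(FALSE))
}
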