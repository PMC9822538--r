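#' First-round (pileup) genotyper network
#'
#' A two-layer bidirectional LSTM over the `(2w+1) x 16` strand-split
#' pileup image. The middle time step of the second layer's output is
#' passed through a tanh, a fully connected layer, and two softmax heads:
#' genotype (21 unordered symbol pairs) and zygosity (3 classes). The
#' "full" profile mirrors the published configuration (hidden 128, fully
#' connected 512, batch 2000, learning rate 1e-4, 200 epochs, label
#' smoothing 0.1); the "desk" profile is the scaled-down configuration
#' the test suite trains in minutes on one CPU (hidden 32, fc 64, batch
#' 16, 30 epochs, lr 1e-2 with late decay, smoothing 0.01, plain Adam,
#' sixfold allele-permutation expansion of the training set).
#'
#' @param profile `"desk"` or `"full"`.
#' @return list with `net` (architecture) and `train` (optimisation)
#'   settings; pass to [build_pileup_network()] / [train_pileup()].
#' @export
pileup_net_config <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "full")
    list(net = list(hidden = 128L, fc = 512L, w = 16L),
         train = list(batch = 2000L, epochs = 200L, lr = 1e-4,
                      smoothing = 0.1, lookahead = TRUE, augment = FALSE,
                      neg_ratio = 3))
  else
    list(net = list(hidden = 32L, fc = 64L, w = 16L),
         train = list(batch = 16L, epochs = 30L, lr = 1e-2,
                      lr_decay = 0.1, lr_decay_at = 0.5,
                      smoothing = 0.01, lookahead = FALSE, augment = 6L,
                      neg_ratio = 1.5))
}

# Fixed per-channel input scaling (counts ~ depth, indel maxima ~ bases).
pileup_scale <- function() rep(c(rep(25, 6), 10, 10), 2)

#' Build an untrained pileup network
#'
#' @param config the `net` element of [pileup_net_config()] (or a
#'   compatible list with `hidden`, `fc`, `w`).
#' @param seed seed for parameter initialisation.
#' @return object of class `pileup_net`.
#' @export
build_pileup_network <- function(config = pileup_net_config()$net, seed = 1L) {
  set.seed(as.integer(seed))
  H <- config$hidden; FC <- config$fc; w <- config$w
  par <- list(l1f = init_lstm(16L, H), l1b = init_lstm(16L, H),
              l2f = init_lstm(2L * H, H), l2b = init_lstm(2L * H, H),
              fc = init_dense(2L * H, FC),
              hg = init_dense(FC, 21L), hz = init_dense(FC, 3L))
  structure(list(par = par,
                 cfg = list(hidden = H, fc = FC, w = w, seq_len = 2L * w + 1L,
                            channels = 16L, n_geno = 21L,
                            scale = pileup_scale())),
            class = "pileup_net")
}

#' @export
net_forward.pileup_net <- function(net, inputs, ...) {
  d <- dim(inputs)
  if (length(d) != 3L || d[2] != net$cfg$seq_len || d[3] != 16L)
    stop(sprintf("expected input of shape N x %d x 16", net$cfg$seq_len))
  X <- as_input_cube(inputs, net$cfg$scale)
  br <- branch_forward(net$par, X, mid = net$cfg$w + 1L)
  hd <- head_forward(net$par, br$out)
  list(pg = hd$pg, pz = hd$pz, cache = list(br = br, r = br$out))
}

#' @export
net_backward.pileup_net <- function(net, cache, dlg, dlz) {
  hb <- head_backward(net$par, cache$r, dlg, dlz)
  bb <- branch_backward(net$par, cache$br, hb$dr)
  c(bb$grads, hb$grads)
}

#' @export
net_slice.pileup_net <- function(net, inputs, idx) {
  inputs[idx, , , drop = FALSE]
}

#' @export
net_bind.pileup_net <- function(net, input_list) {
  bind_arrays1(input_list)
}

#' @export
net_augment.pileup_net <- function(net, inputs, perm) {
  bi <- base_channel_idx(perm)
  inputs[, , c(bi, 5:8, bi + 8L, 13:16), drop = FALSE]
}

#' Train the pileup network
#'
#' Summed label-smoothed cross-entropy over the two heads, Adam with a
#' lookahead wrapper, deterministic under a fixed seed.
#'
#' @param net a [build_pileup_network()] result.
#' @param images `N x (2w+1) x 16` array of pileup images.
#' @param yg,yz 1-based genotype (21-class) and zygosity (3-class) labels.
#' @param train_cfg the `train` element of [pileup_net_config()].
#' @param seed integer seed.
#' @return the trained network, with `$loss_history`.
#' @export
train_pileup <- function(net, images, yg, yz,
                         train_cfg = pileup_net_config()$train, seed = 1L) {
  stopifnot(inherits(net, "pileup_net"))
  train_network(net, images, yg, yz, train_cfg, seed)
}

#' Phred-like quality score of a class probability
#'
#' The log-odds transform `q(P) = (10/ln 10) * ln(P / (1 - P))`, clipped
#' to \[0, 60\]; probabilities are clipped to `(1e-10, 1 - 1e-10)` first.
#' `q(0.5) = 0`; the transform is strictly monotone. A call record's
#' quality is the smaller of its genotype-head and zygosity-head scores.
#'
#' @param P probability (vectorised).
#' @param clip clip the score into \[0, 60\] (default); `FALSE` returns
#'   the raw antisymmetric log-odds value.
#' @return quality score(s) in \[0, 60\] (when clipped).
#' @export
quality_score <- function(P, clip = TRUE) {
  P <- pmin(pmax(P, 1e-10), 1 - 1e-10)
  q <- 10 / log(10) * log(P / (1 - P))
  if (clip) pmin(pmax(q, 0), 60) else q
}

# Shared head-to-record logic for both genotypers.
records_from_heads <- function(sites, pred, classes) {
  gi <- max.col(pred$pg, ties.method = "first")
  zi <- max.col(pred$pz, ties.method = "first")
  cls <- classes[gi]
  pg <- pred$pg[cbind(seq_along(gi), gi)]
  pz <- pred$pz[cbind(seq_along(zi), zi)]
  pair <- class_to_pair(cls)
  zyg <- zygosity_of(cls, sites$ref)
  data.frame(contig = sites$contig, pos0 = sites$pos0, ref = sites$ref,
             genotype = cls, a1 = pair[, 1], a2 = pair[, 2],
             zygosity = zyg, zygosity_head = zygosity_classes()[zi],
             head_conflict = zyg != zygosity_classes()[zi],
             pg = pg, pz = pz,
             qual = pmin(quality_score(pg), quality_score(pz)))
}

#' Call candidate sites with a trained pileup network
#'
#' One call record per candidate: head probabilities, argmax classes, and
#' the Phred-like record quality (min of the two head scores). When the
#' zygosity head disagrees with the zygosity implied by the genotype
#' head, the genotype head wins and the conflict is flagged.
#'
#' @param net a trained `pileup_net`.
#' @param sites candidate data.frame (`contig`, `pos0`, `ref`).
#' @param images matching image array.
#' @return data.frame of call records.
#' @export
call_pileup <- function(net, sites, images) {
  stopifnot(inherits(net, "pileup_net"), nrow(sites) == dim(images)[1])
  records_from_heads(sites, net_predict(net, images), genotype_classes(TRUE))
}

#' Genotype/zygosity training labels for candidate sites
#'
#' Joins candidates against the simulator truth: SNPs label the allele
#' pair, insertion anchors label base+I pairs, positions inside a
#' deletion label base+D pairs, everything else is labelled homozygous
#' reference. Truth-indel sites can be excluded (second-round training,
#' whose class space has no I/D).
#'
#' @param sites candidate data.frame (`pos0`, `ref`).
#' @param truth `truth_variants` data.frame from [generate_diploid()].
#' @param round1 if `FALSE`, indel-truth candidates get `NA` labels.
#' @return list with `yg`, `yz` (1-based indices), `class` strings.
#' @export
label_candidates <- function(sites, truth, round1 = TRUE) {
  cls <- character(nrow(sites))
  snp <- truth[truth$class == "SNP", ]
  ins <- truth[truth$class == "INS", ]
  del <- truth[truth$class == "DEL", ]
  del_pos <- if (nrow(del))
    data.frame(pos0 = unlist(mapply(function(p, l) (p + 1L):(p + l),
                                    del$pos0, del$len, SIMPLIFY = FALSE)),
               zyg = rep(del$zyg, del$len))
  else data.frame(pos0 = integer(), zyg = character())
  for (k in seq_len(nrow(sites))) {
    p <- sites$pos0[k]; r <- sites$ref[k]
    i <- match(p, snp$pos0)
    if (!is.na(i)) {
      cls[k] <- if (snp$zyg[i] == "het") pair_to_class(r, snp$alt[i])
                else pair_to_class(snp$alt[i], snp$alt[i])
      next
    }
    i <- match(p, ins$pos0)
    if (!is.na(i)) {
      cls[k] <- if (ins$zyg[i] == "het") pair_to_class(r, "I")
                else pair_to_class("I", "I")
      next
    }
    i <- match(p, del_pos$pos0)
    if (!is.na(i)) {
      cls[k] <- if (del_pos$zyg[i] == "het") pair_to_class(r, "D")
                else pair_to_class("D", "D")
      next
    }
    cls[k] <- pair_to_class(r, r)
  }
  is_indel <- grepl("[ID]", cls)
  if (!round1) cls[is_indel] <- NA
  yg <- match(cls, genotype_classes(round1))
  yz <- match(zygosity_of(ifelse(is.na(cls), "AA", cls),
                          ifelse(is.na(cls), "A", sites$ref)),
              zygosity_classes())
  yz[is.na(cls)] <- NA
  list(yg = yg, yz = yz, class = cls)
}
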