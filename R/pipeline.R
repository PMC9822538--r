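#' Full pipeline configuration
#'
#' All tunables of the two-round caller in one object: candidate search
#' (depth d, allele frequency e), image flanking sizes (w, t), the
#' het-site quality threshold for phasing, the merge threshold delta,
#' and the two network profiles.
#'
#' @param profile `"desk"` (scaled-down training; the test default) or
#'   `"full"` (published configuration).
#' @export
snp_call_config <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  list(min_depth = 6L, min_af = 0.12, w = 16L, t = 5L,
       het_qual = 14, delta = 14,
       # training draws examples from the alignments at these coverage
       # fractions (1 = as sequenced); adding a downsampled copy (e.g.
       # c(1, 0.55)) exposes the models to shallow coverage pockets, in
       # the spirit of multi-coverage training mixtures, at the price of
       # longer training and more conservative calls
       coverage_mix = 1,
       pileup = pileup_net_config(profile),
       hap = hap_net_config(profile))
}

#' Train the pileup and haplotype models on simulated truth
#'
#' Runs the full training protocol: candidate search, pileup-image
#' labelling from the truth set (candidates absent from the truth are
#' homozygous-reference negatives, downsampled to `neg_ratio` negatives
#' per positive), first-round training; then first-round calling,
#' het-site selection, phasing, haplotagging, haplotype-image generation
#' and second-round training (truth-indel candidates excluded from round
#' two, whose class space has no I/D).
#'
#' @param rs a `read_set`.
#' @param genome the matching [generate_diploid()] genome.
#' @param config a [snp_call_config()].
#' @param seed integer seed (training shuffles, negative downsampling).
#' @param region optional `c(start, end)`: only candidates inside this
#'   0-based half-open interval are used for training.
#' @return list with `pileup_model`, `hap_model`, and stage counts.
#' @export
train_snp_models <- function(rs, genome, config = snp_call_config(),
                             seed = 1L, region = NULL) {
  ref <- genome$ref_vec
  truth <- genome$truth_variants
  set.seed(as.integer(seed))

  # training copies of the alignments at the configured coverage
  # fractions (seeded read subsampling); the first, full-coverage copy
  # also drives first-round calling and phasing
  mixes <- config$coverage_mix %||% 1
  copies <- lapply(mixes, function(f) {
    rsf <- if (f >= 1) rs else subset_reads(rs, stats::runif(n_reads(rs)) < f)
    pilef <- build_pileup(rsf)
    candsf <- find_candidates(pilef, ref, config$min_depth, config$min_af)
    candsf_t <- if (is.null(region)) candsf
                else candsf[candsf$pos0 >= region[1] & candsf$pos0 < region[2], ,
                            drop = FALSE]
    list(rs = rsf, mat = pilef$mat, cands = candsf, train_cands = candsf_t,
         lab = label_candidates(candsf_t, truth, round1 = TRUE),
         lab2 = label_candidates(candsf_t, truth, round1 = FALSE))
  })

  pick_train <- function(y_z, valid, neg_ratio) {
    pos <- intersect(which(y_z != 1L), valid)
    neg <- intersect(which(y_z == 1L), valid)
    n_neg <- min(length(neg), ceiling(neg_ratio * max(length(pos), 1L)))
    sort(c(pos, sample(neg, n_neg)))
  }

  img_list <- list(); yg <- integer(0); yz <- integer(0); n1 <- 0L
  for (cp in copies) {
    keep <- pick_train(cp$lab$yz, seq_along(cp$lab$yz),
                       config$pileup$train$neg_ratio)
    img_list[[length(img_list) + 1L]] <-
      pileup_images(cp$rs, cp$train_cands$pos0[keep], config$w, mat = cp$mat)
    yg <- c(yg, cp$lab$yg[keep]); yz <- c(yz, cp$lab$yz[keep])
    n1 <- n1 + length(keep)
  }
  imgs <- bind_arrays1(img_list)
  pnet <- build_pileup_network(config$pileup$net, seed = seed)
  pnet <- train_pileup(pnet, imgs, yg, yz, config$pileup$train, seed = seed)

  # round-one calls over ALL full-coverage candidates drive phasing
  # (no truth used)
  all_cands <- copies[[1]]$cands
  all_imgs <- pileup_images(rs, all_cands$pos0, config$w,
                            mat = copies[[1]]$mat)
  calls1 <- call_pileup(pnet, all_cands, all_imgs)
  het <- select_het_sites(calls1, config$het_qual)
  phased <- phase_sites(rs, het)

  short_l <- list(); long_l <- list()
  yg2 <- integer(0); yz2 <- integer(0); n2 <- 0L
  for (cp in copies) {
    valid <- which(!is.na(cp$lab2$yg))
    keep2 <- pick_train(cp$lab2$yz, valid, config$hap$train$neg_ratio)
    rsf <- set_haplotags(cp$rs, haplotag_reads(cp$rs, phased))
    hi <- haplotype_images(rsf, cp$train_cands$pos0[keep2], phased$pos0,
                           config$w, config$t)
    short_l[[length(short_l) + 1L]] <- hi$short
    long_l[[length(long_l) + 1L]] <- hi$long
    yg2 <- c(yg2, cp$lab2$yg[keep2]); yz2 <- c(yz2, cp$lab2$yz[keep2])
    n2 <- n2 + length(keep2)
  }
  himgs <- list(short = bind_arrays1(short_l), long = bind_arrays1(long_l))
  hnet <- build_haplotype_network(config$hap$net, seed = seed)
  hnet <- train_haplotype(hnet, himgs, yg2, yz2, config$hap$train, seed = seed)

  list(pileup_model = pnet, hap_model = hnet,
       counts = list(candidates = nrow(all_cands),
                     train_round1 = n1, train_round2 = n2,
                     het_sites = nrow(het),
                     phase_blocks = length(unique(phased$block))))
}

#' Run the two-round SNP caller
#'
#' Candidate search, first-round pileup calling, phasing and
#' haplotagging of high-quality heterozygous calls, second-round
#' haplotype-model calling of all candidates over the four alignment
#' subsets, and the quality-threshold merge. Optionally writes the final
#' VCF.
#'
#' @param rs a `read_set` (or BAM path).
#' @param ref reference base vector or a [generate_diploid()] genome.
#' @param pileup_model,hap_model trained networks.
#' @param config a [snp_call_config()].
#' @param second_round which candidates the haplotype model re-examines:
#'   `"all"` (default; required for the merge to see two scores per
#'   site) or `"low-qual-only"` (only first-round calls below `delta`).
#' @param vcf_path if non-`NULL`, write the final VCF here.
#' @return list with `candidates`, `calls_round1`, `calls_round2`,
#'   `phased`, `haplotags`, `final` (merged calls) and per-stage counts.
#' @export
call_snps <- function(rs, ref, pileup_model, hap_model,
                      config = snp_call_config(),
                      second_round = c("all", "low-qual-only"),
                      vcf_path = NULL) {
  second_round <- match.arg(second_round)
  if (is.character(rs)) rs <- read_alignments(rs)
  if (inherits(ref, "diploid_genome")) ref <- ref$ref_vec
  pile <- build_pileup(rs)
  cands <- find_candidates(pile, ref, config$min_depth, config$min_af)
  imgs <- pileup_images(rs, cands$pos0, config$w, mat = pile$mat)
  calls1 <- call_pileup(pileup_model, cands, imgs)

  het <- select_het_sites(calls1, config$het_qual)
  phased <- phase_sites(rs, het)
  tags <- haplotag_reads(rs, phased)
  rs <- set_haplotags(rs, tags)

  cands2 <- if (second_round == "all") cands
            else cands[calls1$qual < config$delta, , drop = FALSE]
  himgs <- haplotype_images(rs, cands2$pos0, phased$pos0, config$w, config$t)
  calls2 <- call_haplotype(hap_model, cands2, himgs)

  final <- merge_calls(calls2, calls1, config$delta)
  if (!is.null(vcf_path))
    write_vcf(final, rs$contig, rs$contig_length, vcf_path)
  list(candidates = cands, calls_round1 = calls1, calls_round2 = calls2,
       phased = phased, haplotags = tags, final = final,
       counts = list(candidates = nrow(cands), het_sites = nrow(het),
                     phase_blocks = length(unique(phased$block)),
                     tagged = sum(tags > 0L), final_calls = nrow(final)))
}

#' Model-level calls thresholded at delta (for evaluation)
#'
#' Variant records from a single round with quality strictly above
#' `delta`, SNP alleles only — the per-model call sets compared when
#' contrasting the two rounds.
#'
#' @param calls call records from [call_pileup()] or [call_haplotype()].
#' @param delta quality threshold.
#' @return data.frame in [merge_calls()] output form.
#' @export
model_calls <- function(calls, delta = 14) {
  sel <- calls$qual > delta & calls$zygosity != "hom_ref" &
    calls$a1 %in% BASES & calls$a2 %in% BASES
  rows <- which(sel)
  out <- do.call(rbind, lapply(rows, function(i)
    finalize_call(cbind(calls[i, ], source = "model"))))
  if (is.null(out))
    out <- data.frame(contig = character(), pos0 = integer(),
                      ref = character(), alt = character(), gt = character(),
                      qual = numeric(), source = character())
  out
}
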