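#' Simulate a synthetic diploid genome with truth variants
#'
#' Generates a random reference contig and plants homozygous/heterozygous
#' SNPs and short (1-5 bp) indels onto two haplotype copies. Variant
#' counts follow Binomial(length, rate); heterozygous variants are placed
#' on one haplotype chosen at random, homozygous variants on both.
#' Variants are spaced so alleles never overlap (at least 2 reference
#' bases between the end of one variant's span and the next). The default
#' SNP density of 1 per kilobase matches the human genome-wide average;
#' indels only exercise the first-round model's I/D label classes.
#'
#' @param length contig length in bases (>= 1000).
#' @param snp_rate per-base SNP rate in \[0, 0.1\].
#' @param het_fraction fraction of variants that are heterozygous.
#' @param indel_rate per-base indel rate in \[0, 0.1\].
#' @param seed integer seed; regeneration with the same arguments is
#'   bit-identical.
#' @param contig contig name.
#' @return object of class `diploid_genome`: `reference` (string),
#'   `hap1`, `hap2` (haplotype sequences), `truth_variants` (data.frame
#'   with 0-based anchor `pos0`, VCF-style `ref`/`alt` allele strings,
#'   `zyg` in \{het, hom_alt\}, `class` in \{SNP, INS, DEL\}, `hap`
#'   carrying the haplotype of het variants, `len` indel length), and the
#'   generating parameters.
#' @export
generate_diploid <- function(length, snp_rate = 1e-3, het_fraction = 2/3,
                             indel_rate = 2e-4, seed = 1L, contig = "chrS") {
  rates <- c(snp_rate, indel_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 0.1))
    stop("snp_rate and indel_rate must be finite and in [0, 0.1]")
  if (!is.finite(het_fraction) || het_fraction < 0 || het_fraction > 1)
    stop("het_fraction must be in [0, 1]")
  if (length < 1000) stop("length must be >= 1000")
  set.seed(as.integer(seed))

  ref <- sample(BASES, length, replace = TRUE)

  n_snp <- stats::rbinom(1L, length, snp_rate)
  n_ind <- stats::rbinom(1L, length, indel_rate)
  cand <- data.frame(
    pos0 = c(sample.int(length, n_snp) - 1L, sample.int(length, n_ind) - 1L),
    class = rep(c("SNP", "INDEL"), c(n_snp, n_ind)))
  cand$len <- ifelse(cand$class == "SNP", 0L,
                     sample(1:5, nrow(cand), replace = TRUE))
  cand$class[cand$class == "INDEL"] <-
    sample(c("INS", "DEL"), sum(cand$class == "INDEL"), replace = TRUE)
  # span on the reference: SNP/INS occupy the anchor base, DEL also deletes
  # `len` following bases
  cand$span <- ifelse(cand$class == "DEL", 1L + cand$len, 1L)
  cand <- cand[order(cand$pos0), , drop = FALSE]
  keep <- logical(nrow(cand)); prev_end <- 10L
  for (k in seq_len(nrow(cand))) {
    if (cand$pos0[k] >= prev_end + 2L &&
        cand$pos0[k] + cand$span[k] <= length - 10L) {
      keep[k] <- TRUE
      prev_end <- cand$pos0[k] + cand$span[k]
    }
  }
  v <- cand[keep, , drop = FALSE]
  n <- nrow(v)
  v$zyg <- ifelse(stats::runif(n) < het_fraction, "het", "hom_alt")
  v$hap <- ifelse(v$zyg == "het", sample(1:2, n, replace = TRUE), 0L)

  v$ref <- v$alt <- character(n)
  for (k in seq_len(n)) {
    p <- v$pos0[k]
    if (v$class[k] == "SNP") {
      v$ref[k] <- ref[p + 1L]
      v$alt[k] <- sample(setdiff(BASES, ref[p + 1L]), 1L)
    } else if (v$class[k] == "INS") {
      v$ref[k] <- ref[p + 1L]
      v$alt[k] <- paste0(ref[p + 1L],
                         paste0(sample(BASES, v$len[k], replace = TRUE),
                                collapse = ""))
    } else {
      v$ref[k] <- paste0(ref[(p + 1L):(p + 1L + v$len[k])], collapse = "")
      v$alt[k] <- ref[p + 1L]
    }
  }
  v <- v[, c("pos0", "ref", "alt", "zyg", "class", "hap", "len")]
  rownames(v) <- NULL

  structure(list(contig = contig, reference = paste0(ref, collapse = ""),
                 ref_vec = ref,
                 hap1 = apply_variants(ref, v, 1L),
                 hap2 = apply_variants(ref, v, 2L),
                 truth_variants = v, seed = as.integer(seed),
                 params = list(length = length, snp_rate = snp_rate,
                               het_fraction = het_fraction,
                               indel_rate = indel_rate)),
            class = "diploid_genome")
}

# Apply the variants carried by haplotype `h` to the reference base vector,
# returning the haplotype sequence as a single string.
apply_variants <- function(ref, v, h) {
  on_h <- v$zyg == "hom_alt" | v$hap == h
  vv <- v[on_h, , drop = FALSE]
  out <- as.list(ref)
  for (k in seq_len(nrow(vv))) {
    p <- vv$pos0[k] + 1L
    if (vv$class[k] == "SNP") out[[p]] <- vv$alt[k]
    else if (vv$class[k] == "INS") out[[p]] <- vv$alt[k]
    else out[(p + 1L):(p + vv$len[k])] <- list("")
  }
  paste0(unlist(out), collapse = "")
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat(sprintf("<diploid_genome> %s: %d bp, %d truth variants (%d het, %d SNP)\n",
              x$contig, nchar(x$reference), nrow(x$truth_variants),
              sum(x$truth_variants$zyg == "het"),
              sum(x$truth_variants$class == "SNP")))
  invisible(x)
}

beta_phred <- function(n, shape1, shape2) {
  pmax(2L, pmin(40L, as.integer(round(stats::rbeta(n, shape1, shape2) * 40))))
}

#' Simulate error-perturbed long reads from a diploid genome
#'
#' Reads are drawn alternately from the two haplotypes, placed uniformly
#' on the reference at their true coordinates (alignments are emitted
#' directly; no aligner is involved), and perturbed with per-base
#' substitution, insertion and deletion errors. Base qualities are drawn
#' from two Beta-scaled Phred bands so that erroneous bases carry lower
#' qualities than correct bases (correct band mean about Q30, error band
#' about Q13). Each read records its true haplotype of origin.
#'
#' @param genome a [generate_diploid()] result.
#' @param coverage target mean depth (> 0).
#' @param error_model list with per-base rates `sub`, `ins`, `del`.
#' @param read_length list `meanlog`, `sdlog` of the log-normal read
#'   length distribution (default mean about 9 kb).
#' @param seed integer seed.
#' @return a [new_read_set()] object with truth haplotype labels.
#' @export
simulate_reads <- function(genome, coverage,
                           error_model = list(sub = 0.04, ins = 0.01, del = 0.01),
                           read_length = list(meanlog = log(9000), sdlog = 0.35),
                           seed = 1L) {
  stopifnot(inherits(genome, "diploid_genome"))
  if (!is.finite(coverage) || coverage <= 0) stop("coverage must be > 0")
  em <- error_model
  if (any(!is.finite(c(em$sub, em$ins, em$del))) ||
      any(c(em$sub, em$ins, em$del) < 0))
    stop("error rates must be finite and >= 0")
  set.seed(as.integer(seed))
  L <- nchar(genome$reference)
  ref <- genome$ref_vec

  # The contig is treated as a window of a larger genome: reads may
  # overhang either edge and are clipped to the window, so the mean depth
  # is uniform across the whole contig (no finite-window coverage ramp).
  target <- coverage * L
  lens <- integer(0); starts <- integer(0)
  repeat {
    more <- as.integer(round(stats::rlnorm(64, read_length$meanlog,
                                           read_length$sdlog)))
    more <- pmax(500L, pmin(more, L))
    s <- as.integer(floor(stats::runif(64, -(more - 1), L)))
    e2 <- pmin(L, s + more); s2 <- pmax(0L, s)
    keep <- (e2 - s2) >= 200L
    lens <- c(lens, (e2 - s2)[keep]); starts <- c(starts, s2[keep])
    if (sum(as.numeric(lens)) >= target) break
  }
  cum <- cumsum(as.numeric(lens))
  k <- which(cum >= target)[1]
  lens <- lens[seq_len(k)]; starts <- starts[seq_len(k)]
  # stochastic rounding of the final read keeps the expected total at the
  # target; very low coverage can therefore yield zero reads
  excess_prob <- (cum[k] - target) / lens[k]
  if (stats::runif(1) < excess_prob) { lens <- lens[-k]; starts <- starts[-k] }
  n <- length(lens)
  if (n == 0L) {
    warning("coverage too low: zero reads produced")
    return(new_read_set(genome$contig, L,
                        data.frame(name = character(), strand = character(),
                                   mapq = integer(), start = integer(),
                                   end = integer(), hap = integer(),
                                   truth_hap = integer()),
                        list(read = integer(), pos = integer(),
                             sym = integer(), qual = integer()),
                        data.frame(read = integer(), pos = integer(),
                                   len = integer(), seq = character(),
                                   qual = character())))
  }
  haps <- rep(c(1L, 2L), length.out = n)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  mapqs <- sample(c(60L, 55L, 50L, 40L, 30L), n, replace = TRUE,
                  prob = c(0.7, 0.1, 0.1, 0.06, 0.04))

  tv <- genome$truth_variants
  b_read <- b_pos <- b_sym <- b_qual <- vector("list", n)
  ins_list <- vector("list", n)
  reads_meta <- vector("list", n)

  for (i in seq_len(n)) {
    s <- starts[i]; e <- s + lens[i]
    pos <- s:(e - 1L)
    sym <- match(ref[pos + 1L], SYMBOLS)
    correct <- rep(TRUE, length(pos))
    ins_pos <- integer(0); ins_len <- integer(0); ins_seq <- character(0)
    ins_err <- logical(0)

    on_h <- tv$zyg == "hom_alt" | tv$hap == haps[i]
    vv <- tv[on_h & tv$pos0 >= s & tv$pos0 < e, , drop = FALSE]
    for (k in seq_len(nrow(vv))) {
      p <- vv$pos0[k] - s + 1L
      if (vv$class[k] == "SNP") {
        sym[p] <- sym_code(substr(vv$alt[k], 1L, 1L))
      } else if (vv$class[k] == "DEL") {
        dspan <- (p + 1L):(p + vv$len[k])
        dspan <- dspan[dspan <= length(pos)]
        sym[dspan] <- 5L
      } else if (vv$pos0[k] < e - 1L) {       # INS: anchor needs a following base
        ins_pos <- c(ins_pos, vv$pos0[k])
        ins_len <- c(ins_len, vv$len[k])
        ins_seq <- c(ins_seq, substr(vv$alt[k], 2L, nchar(vv$alt[k])))
        ins_err <- c(ins_err, FALSE)
      }
    }

    # sequencing errors: deletions first, then substitutions/insertions on
    # the surviving aligned bases
    alive <- sym != 5L
    derr <- alive & stats::runif(length(pos)) < em$del
    sym[derr] <- 5L
    alive <- sym != 5L
    serr <- alive & stats::runif(length(pos)) < em$sub
    if (any(serr)) {
      old <- sym[serr]
      shift <- sample(1:3, sum(serr), replace = TRUE)
      sym[serr] <- ((old - 1L + shift) %% 4L) + 1L
      correct[serr] <- FALSE
    }
    ierr <- alive & stats::runif(length(pos)) < em$ins
    ierr[length(pos)] <- FALSE
    ierr[pos %in% ins_pos] <- FALSE
    if (any(ierr)) {
      nl <- pmin(1L + stats::rgeom(sum(ierr), 0.7), 5L)
      ins_pos <- c(ins_pos, pos[ierr])
      ins_len <- c(ins_len, nl)
      ins_seq <- c(ins_seq, vapply(nl, function(l)
        paste0(sample(BASES, l, replace = TRUE), collapse = ""), ""))
      ins_err <- c(ins_err, rep(TRUE, sum(ierr)))
    }
    # insertions anchored on a base lost to a deletion error are dropped
    if (length(ins_pos)) {
      ok <- sym[ins_pos - s + 1L] != 5L
      ins_pos <- ins_pos[ok]; ins_len <- ins_len[ok]
      ins_seq <- ins_seq[ok]; ins_err <- ins_err[ok]
    }

    # trim leading/trailing deletions (a read cannot start or end with D)
    nz <- which(sym != 5L)
    if (length(nz) < 50L) next
    lo <- nz[1]; hi <- nz[length(nz)]
    pos <- pos[lo:hi]; sym <- sym[lo:hi]; correct <- correct[lo:hi]
    s2 <- pos[1]; e2 <- pos[length(pos)] + 1L

    qual <- integer(length(pos))
    alive <- sym != 5L
    qual[alive & correct] <- beta_phred(sum(alive & correct), 9, 3)
    qual[alive & !correct] <- beta_phred(sum(alive & !correct), 4, 8)

    iq <- vapply(seq_along(ins_pos), function(k) {
      band <- if (ins_err[k]) c(4, 8) else c(9, 3)
      paste0(intToUtf8(beta_phred(ins_len[k], band[1], band[2]) + 33L,
                       multiple = TRUE), collapse = "")
    }, "")

    reads_meta[[i]] <- data.frame(
      name = sprintf("read_%06d", i), strand = strands[i], mapq = mapqs[i],
      start = s2, end = e2, hap = 0L, truth_hap = haps[i])
    b_read[[i]] <- rep(i, length(pos)); b_pos[[i]] <- pos
    b_sym[[i]] <- sym; b_qual[[i]] <- qual
    ins_list[[i]] <- if (length(ins_pos))
      data.frame(read = i, pos = ins_pos, len = ins_len,
                 seq = ins_seq, qual = iq)
    else NULL
  }

  kept <- which(!vapply(reads_meta, is.null, TRUE))
  remap <- integer(n); remap[kept] <- seq_along(kept)
  reads <- do.call(rbind, reads_meta[kept])
  rownames(reads) <- NULL
  ins <- do.call(rbind, c(ins_list[kept],
                          list(data.frame(read = integer(), pos = integer(),
                                          len = integer(), seq = character(),
                                          qual = character()))))
  ins$read <- remap[ins$read]
  new_read_set(genome$contig, L, reads,
               list(read = remap[unlist(b_read[kept])],
                    pos = unlist(b_pos[kept]),
                    sym = unlist(b_sym[kept]),
                    qual = unlist(b_qual[kept])),
               ins)
}
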