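#' Merge the two rounds' call records under the quality threshold
#'
#' For each site: if the haplotype-model record's quality is strictly
#' greater than `delta` it is chosen; otherwise, if the pileup-model
#' record's quality is strictly greater than `delta` that one is chosen;
#' otherwise the site is discarded as a likely false positive. A missing
#' record is treated as quality 0. The chosen record yields a final call
#' only if it is a variant (not homozygous reference) with SNP
#' (single-base) alleles; pileup-model genotypes involving I/D are
#' suppressed — the final output is SNP-only.
#'
#' @param hap haplotype-model call records (data.frame or `NULL`).
#' @param pile pileup-model call records (data.frame or `NULL`).
#' @param delta quality threshold (default 14).
#' @return data.frame of final calls: `contig`, `pos0`, `ref`, `alt`
#'   (comma-joined for two non-reference alleles), `gt` (`0/1`, `1/1` or
#'   `1/2`), `qual`, `source`.
#' @export
merge_calls <- function(hap, pile, delta = 14) {
  key <- function(d) if (is.null(d) || !nrow(d)) character(0)
                     else paste(d$contig, d$pos0)
  hk <- key(hap); pk <- key(pile)
  all_keys <- union(hk, pk)
  out <- vector("list", length(all_keys))
  for (k in seq_along(all_keys)) {
    h <- if (all_keys[k] %in% hk) hap[match(all_keys[k], hk), ] else NULL
    p <- if (all_keys[k] %in% pk) pile[match(all_keys[k], pk), ] else NULL
    hq <- if (is.null(h)) 0 else h$qual
    pq <- if (is.null(p)) 0 else p$qual
    chosen <- if (hq > delta) cbind(h, source = "haplotype_model")
              else if (pq > delta) cbind(p, source = "pileup_model")
              else NULL
    if (is.null(chosen)) next
    if (chosen$zygosity == "hom_ref") next
    if (!(chosen$a1 %in% BASES && chosen$a2 %in% BASES)) next  # SNP-only
    out[[k]] <- finalize_call(chosen)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(contig = character(), pos0 = integer(),
                      ref = character(), alt = character(), gt = character(),
                      qual = numeric(), source = character())
  res <- res[order(res$contig, res$pos0), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Allele-pair -> VCF ALT/GT mapping. Het ref/alt -> 0/1; hom alt -> 1/1;
# het with two non-reference alleles -> two ALTs and 1/2.
finalize_call <- function(rec) {
  a <- c(rec$a1, rec$a2); r <- rec$ref
  if (rec$zygosity == "het") {
    if (r %in% a) {
      alt <- setdiff(a, r); gt <- "0/1"
    } else {
      alt <- sort(a); gt <- "1/2"
    }
  } else {
    alt <- a[1]; gt <- "1/1"
  }
  data.frame(contig = rec$contig, pos0 = rec$pos0, ref = r,
             alt = paste(alt, collapse = ","), gt = gt, qual = rec$qual,
             source = rec$source)
}

#' Write final SNP calls as a VCF v4.2 file
#'
#' Deterministic byte output: sorted records, GT and GQ fields, the
#' source model in the INFO `SRC` tag, no phase (`|`) separators (the
#' haplotype information used internally is not written to the output).
#'
#' @param calls data.frame from [merge_calls()] (must be sorted).
#' @param contig contig name.
#' @param contig_length contig length for the header.
#' @param path output path.
#' @param sample sample column name.
#' @return the path, invisibly.
#' @export
write_vcf <- function(calls, contig, contig_length, path, sample = "SAMPLE") {
  if (nrow(calls) && is.unsorted(calls$pos0[calls$contig == contig]))
    stop("calls must be sorted by position")
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=haplosnp",
               sprintf("##contig=<ID=%s,length=%d>", contig, contig_length),
               "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Calling model\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample)), con)
  if (nrow(calls))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\tSRC=%s\tGT:GQ\t%s:%d",
                       calls$contig, calls$pos0 + 1L, calls$ref, calls$alt,
                       calls$qual, calls$source, calls$gt,
                       as.integer(round(calls$qual))), con)
  close(con)
  invisible(path)
}

#' Evaluate SNP calls against a truth set
#'
#' Exact site + genotype matching restricted to BED regions: a call is a
#' true positive iff a truth SNP exists at its position and the unordered
#' allele pair matches ({ref, alt} for het, {alt, alt} for hom). Calls at
#' positions without a matching truth SNP are false positives; unmatched
#' truth SNPs are false negatives.
#'
#' @param calls data.frame from [merge_calls()] (or any frame with
#'   `pos0`, `ref`, `alt`, `gt`).
#' @param truth `truth_variants` data.frame ([generate_diploid()]), or a
#'   truth VCF path.
#' @param regions data.frame with `start`, `end` (0-based half-open), or
#'   a BED path; `NULL` for no restriction.
#' @return list: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, and
#'   `undefined_precision` flag (empty call set against nonempty truth).
#' @export
classify_against_truth <- function(calls, truth, regions = NULL) {
  if (is.character(truth)) {
    tv <- read_simple_vcf(truth)
    truth <- data.frame(pos0 = tv$pos0, ref = tv$ref, alt = tv$alt,
                        zyg = ifelse(tv$gt == "0/1", "het", "hom_alt"),
                        class = ifelse(nchar(tv$ref) == 1 & nchar(tv$alt) == 1,
                                       "SNP", "INDEL"))
  }
  if (is.character(regions)) {
    bed <- utils::read.table(regions, sep = "\t",
                             col.names = c("contig", "start", "end"))
    regions <- bed
  }
  in_regions <- function(p) {
    if (is.null(regions)) rep(TRUE, length(p))
    else Reduce(`|`, lapply(seq_len(nrow(regions)), function(i)
      p >= regions$start[i] & p < regions$end[i]), rep(FALSE, length(p)))
  }
  tsnp <- truth[truth$class == "SNP" & in_regions(truth$pos0), , drop = FALSE]
  calls <- calls[in_regions(calls$pos0), , drop = FALSE]
  truth_gt <- function(i) {
    if (tsnp$zyg[i] == "het") pair_to_class(tsnp$ref[i], tsnp$alt[i])
    else pair_to_class(tsnp$alt[i], tsnp$alt[i])
  }
  call_pair <- function(i) {
    alts <- strsplit(calls$alt[i], ",")[[1]]
    if (calls$gt[i] == "0/1") pair_to_class(calls$ref[i], alts[1])
    else if (calls$gt[i] == "1/2") pair_to_class(alts[1], alts[2])
    else pair_to_class(alts[1], alts[1])
  }
  tp <- 0L; fp <- 0L
  matched <- logical(nrow(tsnp))
  for (i in seq_len(nrow(calls))) {
    j <- match(calls$pos0[i], tsnp$pos0)
    if (!is.na(j) && call_pair(i) == truth_gt(j)) {
      tp <- tp + 1L; matched[j] <- TRUE
    } else fp <- fp + 1L
  }
  fn <- sum(!matched)
  undef <- (tp + fp) == 0L && nrow(tsnp) > 0L
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, undefined_precision = undef)
}
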