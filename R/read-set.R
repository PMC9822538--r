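#' Aligned read sets
#'
#' A `read_set` holds reads-to-reference alignments in a column-oriented
#' ("long") layout that the feature extractors consume directly:
#'
#' * `reads`: one row per read — `name`, `strand` (`"+"`/`"-"`), `mapq`,
#'   `start`/`end` (0-based half-open reference interval), `hap`
#'   (working haplotype tag: 0 = unphased, 1, 2) and `truth_hap`
#'   (simulator ground truth, 0 when unknown).
#' * `bases`: per aligned reference position — `read` (row index into
#'   `reads`), `pos` (0-based), `sym` (1..5 coding A, C, G, T, D) and
#'   `qual` (Phred base quality; 0 at deletions). A read covers exactly
#'   the positions `start:(end-1)`, one symbol each.
#' * `ins`: insertion events anchored at the aligned base immediately to
#'   their left — `read`, `pos` (anchor, 0-based), `len`, `seq`, `qual`
#'   (Phred+33 characters).
#'
#' @param contig contig name.
#' @param contig_length contig length in bases.
#' @param reads,bases,ins components as described above.
#' @return an object of class `read_set`.
#' @keywords internal
new_read_set <- function(contig, contig_length, reads, bases, ins) {
  structure(list(contig = contig, contig_length = contig_length,
                 reads = reads, bases = bases, ins = ins),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads on %s (%d bp), %d aligned bases, %d insertion events\n",
              nrow(x$reads), x$contig, x$contig_length,
              length(x$bases$pos), nrow(x$ins)))
  invisible(x)
}

#' Number of reads in a read set
#' @param rs a `read_set`.
#' @export
n_reads <- function(rs) nrow(rs$reads)

#' Extract a single read
#'
#' Returns one read in per-read form: aligned symbols `sym` over
#' `start:(end-1)`, base qualities `qual`, and its insertion events.
#'
#' @param rs a `read_set`.
#' @param i read index.
#' @return list with fields `name`, `strand`, `mapq`, `start`, `end`,
#'   `hap`, `truth_hap`, `sym`, `qual`, `ins`.
#' @export
get_read <- function(rs, i) {
  sel <- rs$bases$read == i
  o <- order(rs$bases$pos[sel])
  r <- rs$reads[i, ]
  list(name = r$name, strand = r$strand, mapq = r$mapq,
       start = r$start, end = r$end, hap = r$hap, truth_hap = r$truth_hap,
       sym = rs$bases$sym[sel][o], qual = rs$bases$qual[sel][o],
       ins = {ii <- rs$ins[rs$ins$read == i, , drop = FALSE]
              ii <- ii[order(ii$pos), , drop = FALSE]
              rownames(ii) <- NULL; ii})
}

#' Restrict a read set to a subset of reads
#'
#' Keeps the selected reads (indices refer to rows of `rs$reads`); read
#' indices in the result are renumbered.
#'
#' @param rs a `read_set`.
#' @param keep integer or logical index over reads.
#' @export
subset_reads <- function(rs, keep) {
  idx <- seq_len(n_reads(rs))[keep]
  map <- integer(n_reads(rs)); map[idx] <- seq_along(idx)
  bsel <- rs$bases$read %in% idx
  isel <- rs$ins$read %in% idx
  new_read_set(rs$contig, rs$contig_length,
               rs$reads[idx, , drop = FALSE],
               list(read = map[rs$bases$read[bsel]],
                    pos = rs$bases$pos[bsel],
                    sym = rs$bases$sym[bsel],
                    qual = rs$bases$qual[bsel]),
               {ii <- rs$ins[isel, , drop = FALSE]; ii$read <- map[ii$read]; ii})
}

#' Set working haplotype tags on a read set
#' @param rs a `read_set`.
#' @param hap integer vector (0 = unphased, 1, 2), one per read.
#' @export
set_haplotags <- function(rs, hap) {
  stopifnot(length(hap) == n_reads(rs), all(hap %in% 0:2))
  rs$reads$hap <- as.integer(hap)
  rs
}
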