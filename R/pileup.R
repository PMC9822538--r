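#' @importFrom Matrix sparseMatrix
NULL

# Weighted bincount over 0-based positions into a length-L vector.
wbincount <- function(pos, w, L) {
  if (!length(pos)) return(numeric(L))
  as.numeric(Matrix::sparseMatrix(i = pos + 1L, j = rep(1L, length(pos)),
                                  x = w, dims = c(L, 1L)))
}

# Deletion runs per read: data.frame(read, pos (each deleted position),
# len (total run length), strand index of the read).
deletion_events <- function(rs) {
  b <- rs$bases
  o <- order(b$read, b$pos)
  rd <- b$read[o]; pos <- b$pos[o]; isD <- b$sym[o] == 5L
  if (!any(isD)) return(data.frame(read = integer(), pos = integer(),
                                   len = integer()))
  # run starts: D preceded by non-D or read boundary
  newrun <- isD & (c(TRUE, !isD[-length(isD)]) | c(TRUE, rd[-length(rd)] != rd[-1]))
  runid <- cumsum(newrun)
  runid[!isD] <- NA
  len <- tabulate(runid[isD])
  data.frame(read = rd[isD], pos = pos[isD], len = len[runid[isD]])
}

#' Per-position strand-split pileup feature matrix
#'
#' Computes, for every reference position of the contig, the 16 pileup
#' features: 8 from forward-strand reads
#' (C\[A\], C\[C\], C\[G\], C\[T\], C\[I\], C\[D\], IMAX, DMAX) followed by
#' the same 8 from reverse-strand reads. C\[B\] counts reads whose aligned
#' symbol at the position is B; C\[I\] counts insertion events anchored at
#' the position (the aligned base immediately left of the insertion);
#' IMAX/DMAX are the maximum insertion/deletion lengths on that strand
#' (deletion lengths are attributed to every deleted position of the run).
#'
#' @param rs a `read_set`.
#' @return numeric matrix `contig_length x 16` with column names
#'   `fwd_A .. fwd_DMAX, rev_A .. rev_DMAX`.
#' @export
pileup_feature_matrix <- function(rs) {
  L <- rs$contig_length
  fwd <- rs$reads$strand == "+"
  mat <- matrix(0, L, 16)
  colnames(mat) <- paste0(rep(c("fwd_", "rev_"), each = 8),
                          c("A", "C", "G", "T", "I", "D", "IMAX", "DMAX"))
  b <- rs$bases
  read_fwd <- fwd[b$read]
  del <- deletion_events(rs)
  ins <- rs$ins
  for (sdx in 1:2) {
    m <- if (sdx == 1) read_fwd else !read_fwd
    off <- (sdx - 1L) * 8L
    for (s in 1:5) {
      sel <- m & (b$sym == s)
      col <- if (s == 5L) 6L else s        # D goes to column 6; I is column 5
      mat[, off + col] <- wbincount(b$pos[sel], rep(1, sum(sel)), L)
    }
    if (nrow(ins)) {
      im <- if (sdx == 1) fwd[ins$read] else !fwd[ins$read]
      mat[, off + 5L] <- wbincount(ins$pos[im], rep(1, sum(im)), L)
      if (any(im)) {
        mx <- tapply(ins$len[im], ins$pos[im], max)
        mat[as.integer(names(mx)) + 1L, off + 7L] <- as.numeric(mx)
      }
    }
    if (nrow(del)) {
      dm <- if (sdx == 1) fwd[del$read] else !fwd[del$read]
      if (any(dm)) {
        mx <- tapply(del$len[dm], del$pos[dm], max)
        mat[as.integer(names(mx)) + 1L, off + 8L] <- as.numeric(mx)
      }
    }
  }
  mat
}

#' Build per-position pileup columns over an interval
#'
#' One column per reference position in `[start, end)` (0-based
#' half-open): strand-split symbol counts, maximum indel lengths, and
#' depth (reads whose alignment spans the position, including reads with
#' a deletion there). Input may be a `read_set` or a BAM path.
#'
#' @param x a `read_set` or path to an indexed, coordinate-sorted BAM.
#' @param contig contig name (BAM input only).
#' @param start,end 0-based half-open interval; default whole contig.
#' @return object of class `pileup`: list with `contig`, `start`, `end`,
#'   `mat` (the `(end-start) x 16` feature matrix) and `depth`.
#' @export
build_pileup <- function(x, contig = NULL, start = 0L, end = NULL) {
  rs <- if (inherits(x, "read_set")) x else read_alignments(x, contig)
  if (is.null(end)) end <- rs$contig_length
  stopifnot(start >= 0L, end <= rs$contig_length, start < end)
  mat <- pileup_feature_matrix(rs)
  depth <- rowSums(mat[, c(1:4, 6, 9:12, 14), drop = FALSE])
  idx <- (start + 1L):end
  structure(list(contig = rs$contig, start = start, end = end,
                 mat = mat[idx, , drop = FALSE], depth = depth[idx]),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s:[%d,%d) mean depth %.2f\n", x$contig, x$start,
              x$end, mean(x$depth)))
  invisible(x)
}

#' Find candidate SNP sites by depth and alternative allele frequency
#'
#' A site is a candidate iff its depth is strictly greater than
#' `min_depth` and its alternative allele frequency is strictly greater
#' than `min_af`. The frequency is
#' `f_b = max(count of B at b, B != ref over {A,C,G,T,I,D}) / depth`,
#' with counts pooled over strands. Zero-depth columns are skipped.
#'
#' @param pile a [build_pileup()] result.
#' @param ref reference base vector (characters) covering the pileup
#'   interval, or the whole-contig vector of length `contig_length`.
#' @param min_depth depth threshold d (default 6).
#' @param min_af allele-frequency threshold e (default 0.12).
#' @return data.frame with `contig`, `pos0`, `ref`, `af`, `depth`.
#' @export
find_candidates <- function(pile, ref, min_depth = 6L, min_af = 0.12) {
  n <- pile$end - pile$start
  refv <- if (length(ref) == n) ref else ref[(pile$start + 1L):pile$end]
  m <- pile$mat
  pooled <- m[, 1:6, drop = FALSE] + m[, 9:14, drop = FALSE]  # A C G T I D
  colnames(pooled) <- c("A", "C", "G", "T", "I", "D")
  ref_col <- match(refv, colnames(pooled))
  masked <- pooled
  masked[cbind(seq_len(n), ref_col)] <- -Inf
  alt <- do.call(pmax, as.data.frame(masked))
  f <- ifelse(pile$depth > 0, alt / pile$depth, 0)
  keep <- which(pile$depth > min_depth & f > min_af)
  data.frame(contig = rep(pile$contig, length(keep)),
             pos0 = pile$start + keep - 1L,
             ref = refv[keep], af = f[keep], depth = pile$depth[keep])
}
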