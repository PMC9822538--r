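#' Combined per-position feature matrix (26 channels)
#'
#' For one alignment subset, computes at every reference position the
#' 26-element combined feature vector: symbol counts `C^B` over
#' B in \{A,C,G,T,D\} (5), symbol frequencies `F^B` (5, normalised by the
#' 5-symbol total; all zero at depth 0), base-quality sums `Q^B` over
#' B in \{A,C,G,T\} (4), base-quality means `U^B` (4), mapping-quality
#' sums `M^B` (4) and means `V^B` (4). Mean channels are 0 where the
#' corresponding count is 0. Insertions are invisible to this feature
#' (the symbol alphabet has no I).
#'
#' @param rs a `read_set` (possibly empty subset).
#' @return numeric matrix `contig_length x 26`, columns
#'   `C_A..C_D, F_A..F_D, Q_A..Q_T, U_A..U_T, M_A..M_T, V_A..V_T`.
#' @export
combined_feature_matrix <- function(rs) {
  L <- rs$contig_length
  mat <- matrix(0, L, 26)
  colnames(mat) <- c(paste0("C_", SYMBOLS), paste0("F_", SYMBOLS),
                     paste0("Q_", BASES), paste0("U_", BASES),
                     paste0("M_", BASES), paste0("V_", BASES))
  b <- rs$bases
  if (length(b$pos)) {
    mapq_of <- rs$reads$mapq[b$read]
    for (s in 1:5) {
      sel <- b$sym == s
      mat[, s] <- wbincount(b$pos[sel], rep(1, sum(sel)), L)
      if (s < 5L) {
        mat[, 10L + s] <- wbincount(b$pos[sel], b$qual[sel], L)        # Q
        mat[, 18L + s] <- wbincount(b$pos[sel], mapq_of[sel], L)       # M
      }
    }
    depth <- rowSums(mat[, 1:5, drop = FALSE])
    nz <- depth > 0
    mat[nz, 6:10] <- mat[nz, 1:5, drop = FALSE] / depth[nz]
    for (s in 1:4) {
      cnz <- mat[, s] > 0
      mat[cnz, 14L + s] <- mat[cnz, 10L + s] / mat[cnz, s]             # U
      mat[cnz, 22L + s] <- mat[cnz, 18L + s] / mat[cnz, s]             # V
    }
  }
  mat
}

#' Combined feature vector at a single position
#'
#' Convenience single-position form of [combined_feature_matrix()].
#'
#' @param rs a `read_set`.
#' @param j 0-based reference position.
#' @return named numeric vector of length 26.
#' @export
combined_feature <- function(rs, j) {
  m <- combined_feature_matrix(rs)
  stats::setNames(as.numeric(window_rows(m, j)), colnames(m))
}

# Stack the four alignment subsets' combined matrices into L x 104:
# channels 1-26 original, 27-52 haplotype 1, 53-78 haplotype 2,
# 79-104 unphased. Subsetting follows the working haplotags.
subset_feature_matrices <- function(rs) {
  hap <- rs$reads$hap
  cbind(combined_feature_matrix(rs),
        combined_feature_matrix(subset_reads(rs, hap == 1L)),
        combined_feature_matrix(subset_reads(rs, hap == 2L)),
        combined_feature_matrix(subset_reads(rs, hap == 0L)))
}

#' Short-range (pileup) image for the second-round model
#'
#' The combined features of the four alignment subsets (original,
#' haplotype 1, haplotype 2, unphased — fixed channel-block order) over
#' the window `[b-w, b+w]`: a `(2w+1) x 104` matrix with off-contig rows
#' zero.
#'
#' @param subsets `L x 104` matrix from an internal four-subset stack, or
#'   a `read_set` carrying haplotags (then the stack is computed).
#' @param b 0-based candidate position.
#' @param w flanking size (default 16).
#' @export
make_short_range_image <- function(subsets, b, w = 16L) {
  if (w < 1L) stop("w must be >= 1")
  if (inherits(subsets, "read_set")) subsets <- subset_feature_matrices(subsets)
  window_rows(subsets, (b - w):(b + w))
}

#' Long-range haplotype image for the second-round model
#'
#' Rows are the combined features (104 channels, same subset blocks as
#' [make_short_range_image()]) at the `t` nearest high-quality
#' heterozygous sites left of `b`, then `b` itself (middle row), then the
#' `t` nearest right of `b`, in genomic order. When fewer than `t`
#' qualifying sites exist on a side the missing rows are zero; the
#' logical attribute `"valid"` marks rows backed by a real site.
#'
#' @param subsets as in [make_short_range_image()].
#' @param b 0-based candidate position.
#' @param het_sites sorted integer vector of 0-based high-quality het
#'   positions (quality >= the het-site threshold).
#' @param t flanking het-site count per side (default 5).
#' @return `(2t+1) x 104` matrix with attribute `valid`.
#' @export
make_long_range_image <- function(subsets, b, het_sites, t = 5L) {
  if (inherits(subsets, "read_set")) subsets <- subset_feature_matrices(subsets)
  lft <- het_sites[het_sites < b]
  rgt <- het_sites[het_sites > b]
  lft <- if (length(lft)) lft[seq.int(max(1L, length(lft) - t + 1L), length(lft))] else integer(0)
  rgt <- rgt[seq_len(min(t, length(rgt)))]
  rows <- c(rep(NA_integer_, t - length(lft)), lft, b, rgt,
            rep(NA_integer_, t - length(rgt)))
  out <- matrix(0, 2L * t + 1L, ncol(subsets))
  ok <- !is.na(rows)
  out[ok, ] <- window_rows(subsets, rows[ok])
  attr(out, "valid") <- ok
  attr(out, "sites") <- rows               # audit: chosen l/r het positions
  out
}

#' Second-round model inputs for a set of candidate sites
#'
#' @param rs a haplotagged `read_set`.
#' @param sites 0-based candidate positions.
#' @param het_sites sorted 0-based high-quality het positions.
#' @param w,t flanking sizes.
#' @return list of arrays `short` (`n x (2w+1) x 104`) and `long`
#'   (`n x (2t+1) x 104`).
#' @export
haplotype_images <- function(rs, sites, het_sites, w = 16L, t = 5L) {
  sub <- subset_feature_matrices(rs)
  n <- length(sites)
  short <- array(0, c(n, 2L * w + 1L, 104L))
  long <- array(0, c(n, 2L * t + 1L, 104L))
  for (k in seq_len(n)) {
    short[k, , ] <- make_short_range_image(sub, sites[k], w)
    long[k, , ] <- make_long_range_image(sub, sites[k], het_sites, t)
  }
  list(short = short, long = long)
}
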