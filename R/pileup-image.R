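#' Strand-split pileup image of a candidate site
#'
#' Slices the window `[b-w, b+w]` out of a full-contig pileup feature
#' matrix into the first-round model input: a `(2w+1) x 16` matrix, rows
#' ordered left to right by reference position, columns 1-8 computed from
#' forward reads and 9-16 from reverse reads. Window rows falling outside
#' the contig are zero (fixed input shape for the recurrent model).
#'
#' @param mat full-contig `L x 16` matrix from [pileup_feature_matrix()],
#'   or a [build_pileup()] object covering the whole contig.
#' @param b 0-based candidate position.
#' @param w flanking size (default 16).
#' @return `(2w+1) x 16` numeric matrix.
#' @export
make_pileup_image <- function(mat, b, w = 16L) {
  if (inherits(mat, "pileup")) mat <- mat$mat
  if (w < 1L) stop("w must be >= 1")
  window_rows(mat, (b - w):(b + w))
}

# Rows of `mat` at the given 0-based positions; out-of-contig rows zero.
window_rows <- function(mat, pos0) {
  out <- matrix(0, length(pos0), ncol(mat))
  colnames(out) <- colnames(mat)
  ok <- pos0 >= 0L & pos0 < nrow(mat)
  out[ok, ] <- mat[pos0[ok] + 1L, , drop = FALSE]
  out
}

#' Pileup images for a set of candidate sites
#'
#' @param rs a `read_set`.
#' @param sites integer vector of 0-based candidate positions.
#' @param w flanking size.
#' @param mat optional precomputed [pileup_feature_matrix()] to avoid
#'   rebuilding it per call.
#' @return 3-d array `length(sites) x (2w+1) x 16`.
#' @export
pileup_images <- function(rs, sites, w = 16L, mat = NULL) {
  if (is.null(mat)) mat <- pileup_feature_matrix(rs)
  arr <- array(0, c(length(sites), 2L * w + 1L, 16L))
  for (k in seq_along(sites))
    arr[k, , ] <- window_rows(mat, (sites[k] - w):(sites[k] + w))
  arr
}
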