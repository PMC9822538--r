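#' Genotype and zygosity class tables
#'
#' The first-round (pileup) genotyper predicts one of 21 unordered allele
#' pairs over the symbol alphabet \{A, C, G, T, I, D\} (I = insertion,
#' D = deletion); the second-round (haplotype) genotyper predicts one of the
#' 10 base-only pairs. Zygosity is a 3-class state: homozygous reference
#' (0/0), homozygous variant (1/1), heterozygous (0/1).
#'
#' @return `genotype_classes()` returns the class labels in fixed head
#'   order; `zygosity_classes()` the 3 zygosity labels.
#' @param round1 logical; if `TRUE` (default) return all 21 round-one
#'   classes, otherwise the 10 base-only round-two classes.
#' @export
genotype_classes <- function(round1 = TRUE) {
  g <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT",
         "AI", "AD", "CI", "CD", "GI", "GD", "TI", "TD", "II", "DD", "ID")
  if (round1) g else g[1:10]
}

#' @rdname genotype_classes
#' @export
zygosity_classes <- function() c("hom_ref", "hom_alt", "het")

BASES <- c("A", "C", "G", "T")
SYMBOLS <- c("A", "C", "G", "T", "D")   # aligned-symbol alphabet (code 1..5)

#' Canonical genotype class for an unordered allele pair
#'
#' Alleles are single symbols from \{A, C, G, T, I, D\}. Base pairs are
#' ordered alphabetically; mixed base/indel pairs put the base first; the
#' indel-only pairs are II, DD and ID.
#'
#' @param a1,a2 character alleles.
#' @return class string, one of [genotype_classes()].
#' @export
pair_to_class <- function(a1, a2) {
  stopifnot(length(a1) == length(a2))
  out <- character(length(a1))
  for (k in seq_along(a1)) {
    p <- c(a1[k], a2[k])
    base <- p %in% BASES
    if (all(base)) {
      out[k] <- paste0(sort(p), collapse = "")
    } else if (any(base)) {
      out[k] <- paste0(p[base], p[!base])
    } else {
      q <- sort(p)                       # DD, DI, II -> canonical ID for DI
      out[k] <- if (identical(q, c("D", "I"))) "ID" else paste0(q, collapse = "")
    }
  }
  out
}

#' Allele pair of a genotype class
#'
#' Inverse of [pair_to_class()]: the unordered allele pair encoded by a
#' class label.
#'
#' @param class genotype class string(s).
#' @return character matrix with columns `a1`, `a2`.
#' @export
class_to_pair <- function(class) {
  m <- do.call(rbind, strsplit(class, ""))
  colnames(m) <- c("a1", "a2")
  m
}

#' Zygosity implied by a genotype class at a reference base
#'
#' @param class genotype class string(s).
#' @param ref reference base(s).
#' @return character vector over [zygosity_classes()].
#' @export
zygosity_of <- function(class, ref) {
  p <- class_to_pair(class)
  ifelse(p[, 1] != p[, 2], "het",
         ifelse(p[, 1] == ref, "hom_ref", "hom_alt"))
}

sym_code <- function(x) match(x, SYMBOLS)
code_sym <- function(i) SYMBOLS[i]
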