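#' Select high-quality heterozygous sites from first-round calls
#'
#' Retains calls that are heterozygous with quality at or above the
#' threshold and whose two alleles are distinct bases (indel alleles
#' cannot anchor read-backed phasing and are skipped).
#'
#' @param calls data.frame of call records ([call_pileup()]).
#' @param qual_threshold minimum quality (default 14).
#' @return data.frame `pos0`, `a1`, `a2`, sorted by position.
#' @export
select_het_sites <- function(calls, qual_threshold = 14) {
  sel <- calls$zygosity == "het" & calls$qual >= qual_threshold &
    calls$a1 %in% BASES & calls$a2 %in% BASES & calls$a1 != calls$a2
  out <- calls[sel, c("pos0", "a1", "a2")]
  out <- out[order(out$pos0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Observation matrix: per read, the 0/1 allele index observed at each
# overlapped het site (0 = a1, 1 = a2, NA = other base / deletion).
# Returned in sparse per-read form.
read_site_obs <- function(rs, sites) {
  m <- nrow(sites)
  hit <- match(rs$bases$pos, sites$pos0)
  sel <- which(!is.na(hit))
  if (!length(sel))
    return(list(read = integer(), site = integer(), obs = integer()))
  site <- hit[sel]
  base <- SYMBOLS[rs$bases$sym[sel]]
  obs <- ifelse(base == sites$a1[site], 0L,
                ifelse(base == sites$a2[site], 1L, NA_integer_))
  ok <- !is.na(obs)
  list(read = rs$bases$read[sel][ok], site = site[ok], obs = obs[ok])
}

# MEC cost of a phasing orientation `o` (0: a1 on haplotype 1) for reads
# given in per-read split form (list of data.frames site/obs).
mec_cost <- function(per_read, o) {
  cost <- 0L
  for (r in per_read) {
    h1 <- o[r$site]                       # haplotype-1 allele index per site
    d1 <- sum(r$obs != h1)
    cost <- cost + min(d1, length(r$obs) - d1)
  }
  cost
}

#' Phase heterozygous sites by minimum error correction
#'
#' Within each connected component of the site-read overlap graph
#' (a phase block), finds the orientation of each site's alleles across
#' the two haplotypes minimising the MEC cost (each read contributes the
#' smaller of its conflict counts against the two haplotypes). Blocks
#' with at most 2^12 enumerable phasings are solved exactly; larger
#' blocks use a position-ordered greedy pass followed by single-site flip
#' refinement. The first site of every block places its first allele on
#' haplotype 1 (fixed tie-break); blocks are never stitched across gaps
#' with no spanning read.
#'
#' @param rs a `read_set`.
#' @param sites het sites from [select_het_sites()].
#' @param exact_limit solve exactly when `2^(k-1) <= exact_limit`.
#' @return data.frame of class `phased_sites`: `pos0`, `hap1`, `hap2`
#'   (allele per haplotype), `block` id; attribute `mec` gives the total
#'   MEC cost. Zero het sites give an empty set.
#' @export
phase_sites <- function(rs, sites, exact_limit = 4096L) {
  m <- nrow(sites)
  empty <- structure(data.frame(pos0 = integer(), hap1 = character(),
                                hap2 = character(), block = integer()),
                     mec = 0L, class = c("phased_sites", "data.frame"))
  if (m == 0L) return(empty)
  obs <- read_site_obs(rs, sites)
  # connected components over sites via shared reads (union-find)
  parent <- seq_len(m)
  find <- function(a) { while (parent[a] != a) a <- parent[a] <- parent[parent[a]]; a }
  if (length(obs$read)) {
    for (sp in split(obs$site, obs$read)) {
      u <- unique(sp)
      if (length(u) > 1L)
        for (k in 2:length(u)) {
          ra <- find(u[1]); rb <- find(u[k])
          if (ra != rb) parent[rb] <- ra
        }
    }
  }
  comp <- vapply(seq_len(m), find, 1L)
  blocks <- match(comp, unique(comp[order(sites$pos0)]))

  o <- integer(m)                          # allele index on haplotype 1
  total_mec <- 0L
  per_read_all <- if (length(obs$read))
    split(data.frame(site = obs$site, obs = obs$obs), obs$read)
  else list()
  for (bid in unique(blocks)) {
    sidx <- which(blocks == bid)
    k <- length(sidx)
    reads_b <- Filter(function(r) any(r$site %in% sidx), per_read_all)
    reads_b <- lapply(reads_b, function(r) {
      r <- r[r$site %in% sidx, , drop = FALSE]
      r$site <- match(r$site, sidx)
      r
    })
    if (k == 1L) { o[sidx] <- 0L; next }
    if (2^(k - 1L) <= exact_limit) {
      best <- NULL; best_cost <- Inf
      for (code in 0:(2^(k - 1L) - 1L)) {
        oo <- c(0L, as.integer(intToBits(code))[seq_len(k - 1L)])
        cost <- mec_cost(reads_b, oo)
        if (cost < best_cost) { best_cost <- cost; best <- oo }
      }
      o[sidx] <- best
      total_mec <- total_mec + best_cost
    } else {
      flat <- do.call(rbind, lapply(seq_along(reads_b), function(ri)
        cbind(read = ri, site = reads_b[[ri]]$site, obs = reads_b[[ri]]$obs)))
      gp <- greedy_phase(flat[, "read"], flat[, "site"], flat[, "obs"],
                         k, length(reads_b), order(sites$pos0[sidx]))
      total_mec <- total_mec + gp$mec
      o[sidx] <- gp$o
    }
  }
  out <- data.frame(pos0 = sites$pos0,
                    hap1 = ifelse(o == 0L, sites$a1, sites$a2),
                    hap2 = ifelse(o == 0L, sites$a2, sites$a1),
                    block = blocks)
  out <- out[order(out$pos0), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, mec = total_mec, class = c("phased_sites", "data.frame"))
}

# Greedy orientation in genomic order with single-site flip refinement.
# Incremental: per read, d1 = mismatches against haplotype 1 over the
# sites oriented so far, cnt = overlapped oriented sites; a read's MEC
# contribution is min(d1, cnt - d1). Flat inputs: parallel vectors
# read/site/obs.
greedy_phase <- function(read, site, obs, k, n_read, pos_order) {
  by_site <- split(seq_along(site), site)
  d1 <- numeric(n_read); cnt <- numeric(n_read)
  o <- rep(NA_integer_, k)
  first <- TRUE
  for (s in pos_order) {
    rows <- by_site[[as.character(s)]]
    v <- 0L
    if (!is.null(rows)) {
      r <- read[rows]; ob <- obs[rows]
      if (!first) {
        cn <- cnt[r] + 1
        c0 <- sum(pmin(d1[r] + (ob != 0L), cn - d1[r] - (ob != 0L)))
        c1 <- sum(pmin(d1[r] + (ob != 1L), cn - d1[r] - (ob != 1L)))
        v <- if (c1 < c0) 1L else 0L
      }
      d1[r] <- d1[r] + (ob != v)
      cnt[r] <- cnt[r] + 1
    }
    o[s] <- v
    first <- FALSE
  }
  for (pass in 1:10) {
    improved <- FALSE
    for (s in seq_len(k)) {
      if (s == pos_order[1]) next          # anchor fixes the block labelling
      rows <- by_site[[as.character(s)]]
      if (is.null(rows)) next
      r <- read[rows]
      mis <- obs[rows] != o[s]
      d1n <- d1[r] + 1 - 2 * mis
      delta <- sum(pmin(d1n, cnt[r] - d1n)) - sum(pmin(d1[r], cnt[r] - d1[r]))
      if (delta < 0) {
        o[s] <- 1L - o[s]
        d1[r] <- d1n
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(o = o, mec = sum(pmin(d1, cnt - d1)))
}

#' Assign reads to haplotypes from phased sites (haplotagging)
#'
#' Each read votes at every phased het site it overlaps; it is assigned
#' to the haplotype matching strictly more of its alleles. Ties and reads
#' overlapping no phased site are left unphased. The partition is total
#' and deterministic.
#'
#' @param rs a `read_set`.
#' @param phased a [phase_sites()] result.
#' @return integer vector (one per read): 1, 2 or 0 (unphased).
#' @export
haplotag_reads <- function(rs, phased) {
  n <- n_reads(rs)
  if (nrow(phased) == 0L) return(integer(n))
  hit <- match(rs$bases$pos, phased$pos0)
  sel <- which(!is.na(hit))
  base <- SYMBOLS[rs$bases$sym[sel]]
  site <- hit[sel]
  v1 <- as.integer(base == phased$hap1[site])
  v2 <- as.integer(base == phased$hap2[site])
  rd <- rs$bases$read[sel]
  s1 <- wbincount(rd - 1L, v1, n)
  s2 <- wbincount(rd - 1L, v2, n)
  ifelse(s1 > s2, 1L, ifelse(s2 > s1, 2L, 0L))
}
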