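# Independent brute-force oracles and small instance generators.
# These deliberately iterate read by read (naive recounts) so they share
# no code path with the package's vectorised feature extractors.

# Materialise all reads of a read_set once (the naive oracles are
# O(reads x positions); extracting reads up front keeps them usable over
# many windows).
all_reads <- function(rs) lapply(seq_len(n_reads(rs)), function(i) get_read(rs, i))

# Naive per-read recount of the 16 strand-split pileup features at one
# 0-based position.
naive_pileup_features <- function(rs, p, rl = all_reads(rs)) {
  out <- stats::setNames(numeric(16),
                         paste0(rep(c("fwd_", "rev_"), each = 8),
                                c("A", "C", "G", "T", "I", "D", "IMAX", "DMAX")))
  for (rd in rl) {
    off <- if (rd$strand == "+") 0L else 8L
    if (p >= rd$start && p < rd$end) {
      s <- rd$sym[p - rd$start + 1L]
      col <- if (s == 5L) 6L else s
      out[off + col] <- out[off + col] + 1
      if (s == 5L) {
        # walk the deletion run containing p
        lo <- p; hi <- p
        while (lo - 1L >= rd$start && rd$sym[lo - 1L - rd$start + 1L] == 5L) lo <- lo - 1L
        while (hi + 1L < rd$end && rd$sym[hi + 1L - rd$start + 1L] == 5L) hi <- hi + 1L
        out[off + 8L] <- max(out[off + 8L], hi - lo + 1L)
      }
    }
    for (k in seq_len(nrow(rd$ins))) {
      if (rd$ins$pos[k] == p) {
        out[off + 5L] <- out[off + 5L] + 1
        out[off + 7L] <- max(out[off + 7L], rd$ins$len[k])
      }
    }
  }
  out
}

# Naive recount of the 26-channel combined feature at one position.
naive_combined_feature <- function(rs, p, rl = all_reads(rs)) {
  cnt <- stats::setNames(numeric(5), c("A", "C", "G", "T", "D"))
  qs <- ms <- stats::setNames(numeric(4), c("A", "C", "G", "T"))
  for (rd in rl) {
    if (p < rd$start || p >= rd$end) next
    s <- rd$sym[p - rd$start + 1L]
    b <- c("A", "C", "G", "T", "D")[s]
    cnt[b] <- cnt[b] + 1
    if (s != 5L) {
      qs[b] <- qs[b] + rd$qual[p - rd$start + 1L]
      ms[b] <- ms[b] + rd$mapq
    }
  }
  fr <- if (sum(cnt) > 0) cnt / sum(cnt) else cnt
  um <- ifelse(cnt[1:4] > 0, qs / cnt[1:4], 0)
  vm <- ifelse(cnt[1:4] > 0, ms / cnt[1:4], 0)
  unname(c(cnt, fr, qs, um, ms, vm))
}

# Exhaustive minimum-error-correction cost over all 2^k phasings.
brute_force_mec <- function(obs_read, obs_site, obs_allele, k) {
  best <- Inf
  reads <- split(data.frame(site = obs_site, a = obs_allele), obs_read)
  for (code in 0:(2^k - 1L)) {
    o <- as.integer(intToBits(code))[seq_len(k)]
    cost <- 0L
    for (r in reads) {
      d1 <- sum(r$a != o[r$site])
      cost <- cost + min(d1, nrow(r) - d1)
    }
    best <- min(best, cost)
  }
  best
}

# Random phasing instance: k het sites, n reads, each read covering a
# random site interval with allele flips at rate `noise`.
random_phasing_instance <- function(k, n, noise = 0.15) {
  sites <- data.frame(pos0 = seq_len(k) * 10L, a1 = rep("A", k), a2 = rep("C", k))
  truth <- sample(0:1, k, replace = TRUE)
  obs_read <- integer(0); obs_site <- integer(0); obs_allele <- integer(0)
  reads <- vector("list", n)
  for (i in seq_len(n)) {
    lo <- sample.int(k, 1L); hi <- min(k, lo + sample(0:3, 1L))
    hap <- sample(1:2, 1L)
    a <- if (hap == 1L) truth[lo:hi] else 1L - truth[lo:hi]
    flip <- stats::runif(length(a)) < noise
    a[flip] <- 1L - a[flip]
    obs_read <- c(obs_read, rep(i, hi - lo + 1L))
    obs_site <- c(obs_site, lo:hi)
    obs_allele <- c(obs_allele, a)
    reads[[i]] <- list(lo = lo, hi = hi, a = a)
  }
  list(sites = sites, obs_read = obs_read, obs_site = obs_site,
       obs_allele = obs_allele, reads = reads, k = k, n = n)
}

# Convert a random phasing instance into a minimal read_set whose reads
# carry A/C alleles at the site positions (and A elsewhere).
phasing_instance_read_set <- function(inst, contig_len = (inst$k + 2L) * 10L) {
  nr <- inst$n
  reads <- data.frame(name = sprintf("r%03d", seq_len(nr)), strand = "+",
                      mapq = 60L,
                      start = vapply(inst$reads, function(r) as.integer(r$lo * 10L), integer(1)),
                      end = vapply(inst$reads, function(r) as.integer(r$hi * 10L + 1L), integer(1)),
                      hap = 0L, truth_hap = 0L)
  b_read <- b_pos <- b_sym <- b_qual <- list()
  for (i in seq_len(nr)) {
    r <- inst$reads[[i]]
    pos <- (r$lo * 10L):(r$hi * 10L)
    sym <- rep(1L, length(pos))                      # A background
    at <- match(inst$sites$pos0[r$lo:r$hi], pos)
    sym[at] <- ifelse(r$a == 0L, 1L, 2L)             # allele 0 -> A, 1 -> C
    b_read[[i]] <- rep(i, length(pos)); b_pos[[i]] <- pos
    b_sym[[i]] <- sym; b_qual[[i]] <- rep(30L, length(pos))
  }
  haplosnp:::new_read_set("chrT", contig_len, reads,
                          list(read = unlist(b_read), pos = unlist(b_pos),
                               sym = unlist(b_sym), qual = unlist(b_qual)),
                          data.frame(read = integer(), pos = integer(),
                                     len = integer(), seq = character(),
                                     qual = character()))
}

# Small simulated fixture shared by several test files.
small_sim <- function(len = 20000, coverage = 8, seed = 5,
                      error = list(sub = 0.04, ins = 0.01, del = 0.01)) {
  g <- generate_diploid(len, seed = seed)
  list(genome = g, reads = simulate_reads(g, coverage, error, seed = seed + 1L))
}
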