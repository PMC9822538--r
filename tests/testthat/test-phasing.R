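mk_calls <- function(zyg, qual, a1 = "A", a2 = "C") {
  n <- length(zyg)
  data.frame(contig = "chrT", pos0 = seq_len(n) * 100L, ref = "A",
             genotype = "AC", a1 = a1, a2 = a2, zygosity = zyg,
             zygosity_head = zyg, head_conflict = FALSE,
             pg = 0.99, pz = 0.99, qual = qual)
}

test_that("het-site selection applies the quality threshold inclusively", {
  calls <- mk_calls(c("het", "het", "het", "het", "hom_alt", "hom_ref"),
                    c(20, 14, 13.9, 30, 40, 40))
  sel <- select_het_sites(calls, 14)
  expect_equal(nrow(sel), 3L)                  # 20, 14 and 30; 13.9 dropped
  expect_setequal(sel$pos0, c(100L, 200L, 400L))
  # indel-allele het calls cannot anchor phasing
  ind <- mk_calls("het", 30, a1 = "A", a2 = "I")
  expect_equal(nrow(select_het_sites(ind, 14)), 0L)
})

test_that("consistent spanning reads phase into one zero-conflict block", {
  inst <- random_phasing_instance(2, 4, noise = 0)
  rs <- phasing_instance_read_set(inst)
  # force every read to span both sites
  ph <- phase_sites(rs, inst$sites)
  expect_equal(attr(ph, "mec"), 0L)
  expect_equal(length(unique(ph$block)), 1L)
  expect_equal(ph$hap1[1], "A")                # anchor tie-break
})

test_that("site clusters without a spanning read become separate blocks", {
  sites <- data.frame(pos0 = c(10L, 20L, 200L, 210L),
                      a1 = "A", a2 = "C")
  reads <- data.frame(name = c("r1", "r2"), strand = "+", mapq = 60L,
                      start = c(10L, 200L), end = c(21L, 211L),
                      hap = 0L, truth_hap = 0L)
  mkspan <- function(i, s, e) {
    pos <- s:e; sym <- rep(1L, length(pos))
    list(read = rep(i, length(pos)), pos = pos, sym = sym,
         qual = rep(30L, length(pos)))
  }
  b1 <- mkspan(1L, 10L, 20L); b2 <- mkspan(2L, 200L, 210L)
  rs <- haplosnp:::new_read_set("chrT", 300L, reads,
                                list(read = c(b1$read, b2$read),
                                     pos = c(b1$pos, b2$pos),
                                     sym = c(b1$sym, b2$sym),
                                     qual = c(b1$qual, b2$qual)),
                                data.frame(read = integer(), pos = integer(),
                                           len = integer(), seq = character(),
                                           qual = character()))
  ph <- phase_sites(rs, sites)
  expect_equal(length(unique(ph$block)), 2L)
  expect_equal(nrow(ph), 4L)
})

test_that("exact phasing attains the brute-force MEC optimum", {
  set.seed(201)
  for (rep in 1:25) {
    k <- sample(2:6, 1L); n <- sample(4:10, 1L)
    inst <- random_phasing_instance(k, n, noise = 0.15)
    rs <- phasing_instance_read_set(inst)
    ph <- phase_sites(rs, inst$sites)
    opt <- brute_force_mec(inst$obs_read, inst$obs_site, inst$obs_allele, k)
    expect_equal(attr(ph, "mec"), opt, info = paste("rep", rep))
    # never exceeds the everything-conflicts upper bound
    expect_lte(attr(ph, "mec"), length(inst$obs_allele))
  }
})

test_that("greedy phasing with flip refinement matches the optimum on small instances", {
  set.seed(202)
  for (rep in 1:25) {
    k <- sample(3:6, 1L); n <- sample(6:10, 1L)
    inst <- random_phasing_instance(k, n, noise = 0.1)
    rs <- phasing_instance_read_set(inst)
    ph_greedy <- phase_sites(rs, inst$sites, exact_limit = 1L)
    opt <- brute_force_mec(inst$obs_read, inst$obs_site, inst$obs_allele, k)
    expect_gte(attr(ph_greedy, "mec"), opt)
    expect_lte(attr(ph_greedy, "mec"), length(inst$obs_allele))
  }
})

test_that("zero het sites degrade to an empty phasing and unphased reads", {
  sim <- small_sim(len = 10000, coverage = 4, seed = 211)
  ph <- phase_sites(sim$reads, data.frame(pos0 = integer(),
                                          a1 = character(), a2 = character()))
  expect_equal(nrow(ph), 0L)
  tags <- haplotag_reads(sim$reads, ph)
  expect_true(all(tags == 0L))
})

test_that("haplotagging votes per overlapped site with ties unphased", {
  sites <- data.frame(pos0 = c(10L, 20L, 30L), hap1 = c("A", "A", "A"),
                      hap2 = c("C", "C", "C"), block = 1L)
  class(sites) <- c("phased_sites", "data.frame")
  mkread <- function(i, sym_at) {
    pos <- 5:35; sym <- rep(4L, length(pos))
    sym[match(c(10L, 20L, 30L), pos)] <- sym_at
    list(read = rep(i, length(pos)), pos = pos, sym = sym,
         qual = rep(30L, length(pos)))
  }
  r1 <- mkread(1L, c(1L, 1L, 1L))        # matches hap1 3/3
  r2 <- mkread(2L, c(2L, 2L, 1L))        # matches hap2 2/3
  r3 <- mkread(3L, c(1L, 2L, 4L))        # 1-1 tie
  reads <- data.frame(name = c("r1", "r2", "r3"), strand = "+", mapq = 60L,
                      start = 5L, end = 36L, hap = 0L, truth_hap = 0L)
  rs <- haplosnp:::new_read_set("chrT", 100L, reads,
                                list(read = c(r1$read, r2$read, r3$read),
                                     pos = c(r1$pos, r2$pos, r3$pos),
                                     sym = c(r1$sym, r2$sym, r3$sym),
                                     qual = c(r1$qual, r2$qual, r3$qual)),
                                data.frame(read = integer(), pos = integer(),
                                           len = integer(), seq = character(),
                                           qual = character()))
  tags <- haplotag_reads(rs, sites)
  expect_equal(tags, c(1L, 2L, 0L))
  # reads overlapping no phased site are unphased
  far <- sites; far$pos0 <- far$pos0 + 60L
  expect_equal(haplotag_reads(rs, far), c(0L, 0L, 0L))
  # swapping the haplotype labels swaps the partition symmetrically
  swapped <- sites
  swapped$hap1 <- sites$hap2; swapped$hap2 <- sites$hap1
  tags_sw <- haplotag_reads(rs, swapped)
  expect_equal(tags_sw, c(2L, 1L, 0L))
})

test_that("haplotag partition is total and disjoint on simulated data", {
  sim <- small_sim(len = 30000, coverage = 16, seed = 221)
  g <- sim$genome; rs <- sim$reads
  het <- g$truth_variants[g$truth_variants$zyg == "het" &
                            g$truth_variants$class == "SNP", ]
  sites <- data.frame(pos0 = het$pos0, a1 = het$ref, a2 = het$alt)
  ph <- phase_sites(rs, sites)
  tags <- haplotag_reads(rs, ph)
  expect_length(tags, n_reads(rs))
  expect_true(all(tags %in% 0:2))
  # with truth het sites, most assigned reads agree with the truth label
  ok <- tags > 0L
  agree <- max(mean((tags == rs$reads$truth_hap)[ok]),
               mean((tags == 3L - rs$reads$truth_hap)[ok]))
  expect_gte(agree, 0.95)
})

test_that("phased sites and haplotags export to standard formats", {
  sim <- small_sim(len = 20000, coverage = 12, seed = 231)
  g <- sim$genome; rs <- sim$reads
  het <- g$truth_variants[g$truth_variants$zyg == "het" &
                            g$truth_variants$class == "SNP", ]
  sites <- data.frame(pos0 = het$pos0, a1 = het$ref, a2 = het$alt)
  ph <- phase_sites(rs, sites)
  f <- tempfile(fileext = ".vcf")
  write_phased_vcf(ph, g$ref_vec, g$contig, nchar(g$reference), f)
  v <- read_simple_vcf(f)
  expect_equal(v$pos0, ph$pos0)
  expect_true(all(v$gt %in% c("0|1", "1|0")))
  expect_equal(length(VariantAnnotation::readVcf(f)), nrow(ph))

  rs <- set_haplotags(rs, haplotag_reads(rs, ph))
  bam <- tempfile(fileext = ".bam")
  write_haplotagged_bam(rs, bam)
  back <- read_alignments(bam)
  m <- match(rs$reads$name, back$reads$name)
  expect_equal(back$reads$hap[m], rs$reads$hap)
})
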