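test_that("pileup image has fixed shape with zero padding at contig edges", {
  sim <- small_sim(len = 15000, coverage = 6, seed = 81)
  mat <- pileup_feature_matrix(sim$reads)
  img <- make_pileup_image(mat, 5000L)
  expect_equal(dim(img), c(33L, 16L))
  edge <- make_pileup_image(mat, 3L, w = 16L)
  expect_true(all(edge[1:13, ] == 0))                # rows before position 0
  expect_error(make_pileup_image(mat, 100L, w = 0L), "w")
})

test_that("a single forward read yields a pure forward half-image", {
  reads <- data.frame(name = "a", strand = "+", mapq = 60L,
                      start = 0L, end = 100L, hap = 0L, truth_hap = 0L)
  bases <- list(read = rep(1L, 100), pos = 0:99, sym = rep(1L, 100),
                qual = rep(30L, 100))
  rs <- haplosnp:::new_read_set("chrT", 100L, reads, bases,
                                data.frame(read = integer(), pos = integer(),
                                           len = integer(), seq = character(),
                                           qual = character()))
  img <- make_pileup_image(pileup_feature_matrix(rs), 50L)
  expect_true(all(img[, 1] == 1))                    # fwd C[A] everywhere
  expect_true(all(img[, 2:8] == 0))
  expect_true(all(img[, 9:16] == 0))                 # reverse half empty
})

test_that("pileup images equal a brute-force recount on random windows", {
  sim <- small_sim(len = 10000, coverage = 5, seed = 91)
  rs <- sim$reads
  mat <- pileup_feature_matrix(rs)
  set.seed(3)
  for (b in sample(20:9980, 10L)) {
    img <- make_pileup_image(mat, b)
    oracle <- t(vapply((b - 16L):(b + 16L),
                       function(p) naive_pileup_features(rs, p), numeric(16)))
    expect_equal(unname(img), unname(oracle), info = paste("site", b))
  }
})

test_that("strand decomposition and read-permutation invariance hold", {
  sim <- small_sim(len = 10000, coverage = 6, seed = 101)
  rs <- sim$reads
  img_all <- make_pileup_image(pileup_feature_matrix(rs), 5000L)
  fwd <- subset_reads(rs, rs$reads$strand == "+")
  rev <- subset_reads(rs, rs$reads$strand == "-")
  img_f <- make_pileup_image(pileup_feature_matrix(fwd), 5000L)
  img_r <- make_pileup_image(pileup_feature_matrix(rev), 5000L)
  expect_equal(img_all[, 1:8], img_f[, 1:8])
  expect_equal(img_all[, 9:16], img_r[, 9:16])
  expect_true(all(img_f[, 9:16] == 0))
  expect_true(all(img_r[, 1:8] == 0))
  # shuffling read order leaves the image unchanged
  set.seed(4)
  shuf <- subset_reads(rs, sample(n_reads(rs)))
  expect_equal(make_pileup_image(pileup_feature_matrix(shuf), 5000L), img_all)
})

test_that("combined feature matches its defining formulas for a single read", {
  reads <- data.frame(name = "a", strand = "+", mapq = 60L,
                      start = 10L, end = 12L, hap = 0L, truth_hap = 0L)
  bases <- list(read = c(1L, 1L), pos = c(10L, 11L), sym = c(1L, 2L),
                qual = c(30L, 20L))
  rs <- haplosnp:::new_read_set("chrT", 50L, reads, bases,
                                data.frame(read = integer(), pos = integer(),
                                           len = integer(), seq = character(),
                                           qual = character()))
  v <- combined_feature(rs, 10L)
  expect_length(v, 26L)
  expect_equal(unname(v), c(1, 0, 0, 0, 0,   # C
                            1, 0, 0, 0, 0,   # F
                            30, 0, 0, 0,     # Q
                            30, 0, 0, 0,     # U
                            60, 0, 0, 0,     # M
                            60, 0, 0, 0))    # V
  # empty subset gives the zero vector
  none <- subset_reads(rs, integer(0))
  expect_equal(unname(combined_feature(none, 10L)), rep(0, 26))
})

test_that("combined features equal the naive recount and normalise", {
  sim <- small_sim(len = 10000, coverage = 8, seed = 111)
  rs <- sim$reads
  cm <- combined_feature_matrix(rs)
  set.seed(5)
  for (p in sample(0:9999, 25L)) {
    expect_equal(unname(cm[p + 1L, ]), naive_combined_feature(rs, p),
                 info = paste("position", p))
  }
  fsum <- rowSums(cm[, 6:10])
  expect_true(all(abs(fsum) < 1e-12 | abs(fsum - 1) < 1e-12))
  # exact mean identity U * C = Q
  expect_equal(cm[, 15:18] * cm[, 1:4], cm[, 11:14], ignore_attr = TRUE)
  expect_equal(cm[, 23:26] * cm[, 1:4], cm[, 19:22], ignore_attr = TRUE)
})

test_that("short-range image stacks the four subsets in fixed order", {
  sim <- small_sim(len = 10000, coverage = 10, seed = 121)
  rs <- sim$reads
  set.seed(6)
  rs <- set_haplotags(rs, sample(0:2, n_reads(rs), replace = TRUE))
  img <- make_short_range_image(rs, 5000L)
  expect_equal(dim(img), c(33L, 104L))
  ori <- combined_feature_matrix(rs)
  h1 <- combined_feature_matrix(subset_reads(rs, rs$reads$hap == 1L))
  expect_equal(img[, 1:26], haplosnp:::window_rows(ori, 4984:5016),
               ignore_attr = TRUE)
  expect_equal(img[, 27:52], haplosnp:::window_rows(h1, 4984:5016),
               ignore_attr = TRUE)
  # count-channel additivity over the haplotype partition
  expect_equal(img[, 1:5], img[, 27:31] + img[, 53:57] + img[, 79:83],
               ignore_attr = TRUE)
  # an empty unphased subset zeroes channels 79-104
  rs2 <- set_haplotags(rs, rep(c(1L, 2L), length.out = n_reads(rs)))
  img2 <- make_short_range_image(rs2, 5000L)
  expect_true(all(img2[, 79:104] == 0))
})

test_that("long-range image selects the t nearest flanking het sites", {
  sim <- small_sim(len = 10000, coverage = 8, seed = 131)
  rs <- set_haplotags(sim$reads, integer(n_reads(sim$reads)))
  het <- sort(sample(100:9900, 30L))
  b <- 5000L
  img <- make_long_range_image(rs, b, het, t = 5L)
  expect_equal(dim(img), c(11L, 104L))
  # independent sorted-scan oracle for the flanking sites
  lft <- rev(rev(het[het < b])[1:5])
  rgt <- het[het > b][1:5]
  sub <- haplosnp:::subset_feature_matrices(rs)
  expect_equal(unname(img), unname(haplosnp:::window_rows(sub, c(lft, b, rgt))),
               ignore_attr = TRUE)
  # middle row is the candidate itself
  expect_equal(img[6, ], haplosnp:::window_rows(sub, b)[1, ], ignore_attr = TRUE)
  # no flanking sites: all rows except the middle are zero, mask records it
  img0 <- make_long_range_image(rs, b, integer(0), t = 5L)
  expect_true(all(img0[-6, ] == 0))
  expect_equal(attr(img0, "valid"), c(rep(FALSE, 5), TRUE, rep(FALSE, 5)))
  # deficit on one side zero-pads the outer rows
  img1 <- make_long_range_image(rs, b, c(4000L, 4500L, 6000L), t = 5L)
  expect_true(all(img1[1:3, ] == 0))
  expect_equal(attr(img1, "valid"),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, FALSE, FALSE))
})

test_that("long-range image records the chosen flanking sites for audit", {
  sim <- small_sim(len = 8000, coverage = 6, seed = 141)
  rs <- set_haplotags(sim$reads, integer(n_reads(sim$reads)))
  het <- c(1000L, 2000L, 3500L, 6000L, 7000L)
  img <- make_long_range_image(rs, 4000L, het, t = 2L)
  expect_equal(attr(img, "sites"), c(2000L, 3500L, 4000L, 6000L, 7000L))
})
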