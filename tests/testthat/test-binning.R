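# bin grid, variant binning, BVF and track profiles

test_that("the grid has 200 bins of 50 bp covering 10 kb with no bin 0", {
  J <- bin_indices()
  expect_length(J, 200)
  expect_false(0 %in% J)
  expect_equal(range(J), c(-100, 100))
  expect_equal(sum(oracle_bin_table$hi - oracle_bin_table$lo), 10000)
})

test_that("bin_index agrees with the interval-table oracle over the whole span", {
  for (d in -5100:5100) {
    expect_identical(bin_index(1000000 + d, 1000000, "+"),
                     oracle_bin_index(d))
  }
})

test_that("bin_index handles the stated boundary conventions and strands", {
  t0 <- 50000L
  expect_equal(bin_index(t0, t0, "+"), 1L)        # d = 0 lands in bin +1
  expect_equal(bin_index(t0 - 1L, t0, "+"), -1L)
  expect_equal(bin_index(t0 + 250L, t0, "+"), 6L)
  # minus strand: one bp on the genomic left is downstream
  expect_equal(bin_index(t0 - 1L, t0, "-"), 1L)
  expect_equal(bin_index(t0 + 1L, t0, "-"), -1L)
  # window edges
  expect_equal(bin_index(t0 + 4999L, t0, "+"), 100L)
  expect_true(is.na(bin_index(t0 + 5000L, t0, "+")))
  expect_equal(bin_index(t0 - 5000L, t0, "+"), -100L)
  expect_true(is.na(bin_index(t0 - 5001L, t0, "+")))
})

test_that("assign_bins counts shared variants once per TSS and respects windows", {
  tss <- make_tss(c(50000, 56000))
  v <- make_variants(c(50010, 53000, 70000))
  asg <- assign_bins(tss, v)
  # 50010 only in window 1; 53000 in both; 70000 in neither
  expect_equal(sum(asg$variant_id == "v0001"), 1)
  expect_equal(sum(asg$variant_id == "v0002"), 2)
  expect_equal(sum(asg$variant_id == "v0003"), 0)
  m <- bin_count_matrix(asg, tss$id)
  expect_equal(sum(m), 3)
  expect_equal(m["t001", "1"], 1L)
  # no variants: zero matrix
  m0 <- bin_count_matrix(assign_bins(tss, v[0, ]), tss$id)
  expect_equal(sum(m0), 0)
})

test_that("TSSs with truncated windows are dropped with a warning", {
  sizes <- tibble::tibble(chrom = "chr1", size = 100000L)
  tss <- make_tss(c(3000, 50000, 97000))
  expect_warning(asg <- assign_bins(tss, make_variants(50010), sizes), "2 TSS")
  expect_equal(unique(asg$tss_id), "t002")
})

test_that("bvf_profile normalizes per TSS, sums to one, drops empty rows", {
  tss <- make_tss(c(50000, 60000, 70000))
  # TSS 1: all 5 variants in bin +1; TSS 2: one in -1; TSS 3: none
  v <- make_variants(c(rep(50010, 5), 59990))
  m <- bin_count_matrix(assign_bins(tss, v), tss$id)
  prof <- bvf_profile(m)
  expect_equal(sum(prof$mean), 1, tolerance = 1e-12)
  expect_equal(prof$mean[prof$bin == 1], 0.5)   # (1 + 0)/2 over two kept rows
  expect_equal(prof$mean[prof$bin == -1], 0.5)
  expect_equal(unique(prof$n), 2L)
  expect_error(bvf_profile(bin_count_matrix(assign_bins(tss, v[0, ]), tss$id)),
               "empty")
})

test_that("strand mirroring leaves every profile unchanged", {
  withr::local_seed(31)
  C <- 2000000L  # reflection point
  tss <- make_tss(sample(seq(60000, 900000, by = 11000), 40), strand = "+")
  v <- make_variants(unlist(lapply(tss$position, function(p)
    p + sample(-5000:4999, 30))))
  m1 <- bin_count_matrix(assign_bins(tss, v), tss$id)
  p1 <- bvf_profile(m1)
  mir_tss <- dplyr::mutate(tss, position = C - position, strand = "-")
  mir_v <- dplyr::mutate(v, position = C - position)
  m2 <- bin_count_matrix(assign_bins(mir_tss, mir_v), mir_tss$id)
  p2 <- bvf_profile(m2)
  expect_equal(max(abs(p1$mean - p2$mean)), 0)
  expect_identical(unclass(m1), unclass(m2))
  # same invariance for a track profile: mirror the intervals, keep the values
  vals <- round(runif(nrow(tss)), 3)
  s1 <- as.integer(tss$position - 3000)
  e1 <- as.integer(tss$position + 1000)
  trk <- new_track_for_test(tibble::tibble(chrom = "chr1", start = s1,
                                           end = e1, value = vals))
  mir_trk <- new_track_for_test(tibble::tibble(
    chrom = "chr1", start = as.integer(C - e1 + 1), end = as.integer(C - s1 + 1),
    value = vals
  ))
  t1 <- track_profile(tss, trk, "pooled_base_mean")
  t2 <- track_profile(mir_tss, mir_trk, "pooled_base_mean")
  expect_equal(t1$mean, t2$mean)
  expect_equal(t1$n, t2$n)
})

test_that("track profiles aggregate by the documented modes", {
  tss <- make_tss(50000)
  # constant track: every bin mean equals the constant
  const <- new_track_for_test(tibble::tibble(chrom = "chr1", start = 40000L,
                                             end = 60000L, value = 2.5))
  bnp <- track_profile(tss, const, "pooled_base_mean")
  expect_true(all(abs(bnp$mean - 2.5) < 1e-12))
  # two bases scored 1 and 3 inside one bin: pooled mean 2, other bins missing
  two <- new_track_for_test(tibble::tibble(
    chrom = "chr1", start = c(50010L, 50020L), end = c(50011L, 50021L),
    value = c(1, 3)
  ))
  p2 <- track_profile(tss, two, "pooled_base_mean")
  expect_equal(p2$mean[p2$bin == 1], 2)
  expect_true(all(is.na(p2$mean[p2$bin != 1])))
  # membership tract covering exactly bins +1..+2 of the single TSS
  tract <- as_membership_track(tibble::tibble(chrom = "chr1", start = 50000L,
                                              end = 50100L))
  bbs <- track_profile(tss, tract, "per_tss_base_fraction")
  expect_equal(bbs$mean[bbs$bin %in% c(1, 2)], c(1, 1))
  expect_equal(sum(bbs$mean), 2)
  # per-variant scores: pooled mean per bin over assigned variants
  asg <- assign_bins(tss, make_variants(c(50010, 50020, 50060)))
  asg$raw_score <- c(1, 2, 6)
  bcs <- track_profile(tss, NULL, "pooled_variant_mean", assignments = asg)
  expect_equal(bcs$mean[bcs$bin == 1], 1.5)
  expect_equal(bcs$mean[bcs$bin == 2], 6)
  expect_error(track_profile(tss, const, "nonsense"))
})

test_that("pooled means weight TSSs by scored bases", {
  tss <- make_tss(c(50000, 70000))
  # TSS 1 contributes 2 bases at 1.0, TSS 2 one base at 4.0, same bin +1
  trk <- new_track_for_test(tibble::tibble(
    chrom = "chr1", start = c(50010L, 70015L), end = c(50012L, 70016L),
    value = c(1, 4)
  ))
  p <- track_profile(tss, trk, "pooled_base_mean")
  expect_equal(p$mean[p$bin == 1], (2 * 1 + 1 * 4) / 3)
})
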