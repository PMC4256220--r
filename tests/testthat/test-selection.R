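# variant filters, MAF classes, CGI prediction/overlap, multi-TSS exclusion,
# density contrast

variant_row <- function(submitters = "1000GENOMES,BUSHMAN",
                        var_class = "single", afc = 2L,
                        n1 = 500, n2 = 600) {
  tibble::tibble(id = "rs1", chrom = "chr1", position = 1L,
                 var_class = var_class, submitters = submitters,
                 allele_freq_count = afc, allele_n1 = n1, allele_n2 = n2)
}

test_that("filter_variants enforces all five criteria with a rejection tally", {
  rows <- dplyr::bind_rows(
    variant_row(),                                   # kept
    variant_row(submitters = "BUSHMAN"),             # fails submitters
    variant_row(var_class = "deletion"),             # fails class
    variant_row(afc = 3L),                           # fails count
    variant_row(n1 = 0, n2 = 2000),                  # fails positivity
    variant_row(n1 = 400, n2 = 600)                  # sum exactly 1000: fails v
  )
  kept <- filter_variants(rows)
  expect_equal(kept$id, "rs1")
  tally <- filter_tally(kept)
  expect_equal(unname(tally[c("submitters_1000genomes", "class_single",
                              "allele_freq_count_2", "both_allele_ns_positive",
                              "allele_ns_sum_gt_1000")]),
               c(1, 1, 1, 1, 1))
  expect_equal(unname(tally["n_kept"]), 1)
})

test_that("compute_maf is the symmetric minimum frequency and rejects zeros", {
  expect_equal(compute_maf(1, 2183), 1 / 2184)
  expect_equal(compute_maf(500, 500), 0.5)
  expect_equal(compute_maf(300, 700), 0.3)
  expect_equal(compute_maf(700, 300), compute_maf(300, 700))
  expect_error(compute_maf(0, 1000), "> 0")
})

test_that("class boundaries split intermediates at the median into equal halves", {
  b <- derive_class_boundaries(c(0.001, 0.002, 0.003, 0.004),
                               rare_threshold = 4.59e-4)
  expect_equal(b$upper[b$class == "mid1"], 0.0025)
  cls <- assign_class(c(0.001, 0.002, 0.003, 0.004), b)
  expect_equal(as.character(cls), c("mid1", "mid1", "mid2", "mid2"))
  # odd count: sizes differ by one
  b3 <- derive_class_boundaries(c(0.001, 0.002, 0.003), rare_threshold = 4.59e-4)
  cls3 <- assign_class(c(0.001, 0.002, 0.003), b3)
  expect_equal(sum(cls3 == "mid1") - sum(cls3 == "mid2"), 1)
  # degenerate: a single intermediate variant leaves mid2 empty, with warning
  expect_warning(b1 <- derive_class_boundaries(c(0.005), rare_threshold = 4.59e-4),
                 "mid2")
  expect_equal(as.character(assign_class(0.005, b1)), "mid1")
  expect_error(derive_class_boundaries(c(1e-4, 0.2), rare_threshold = 4.59e-4),
               "intermediate")
})

test_that("assign_class respects the stated boundary inclusivities", {
  mafs <- c(1e-4, 4.59e-4, 1e-3, 0.0014, 0.005, 0.01, 0.02, 0.5)
  b <- derive_class_boundaries(mafs, rare_threshold = 4.59e-4)
  # median of intermediates {1e-3, 0.0014, 0.005, 0.01} is 0.0032
  got <- as.character(assign_class(mafs, b))
  expect_equal(got[mafs == 4.59e-4], "rare")     # rare includes its upper bound
  expect_equal(got[mafs == 0.01], "mid2")        # common is strict > 0.01
  expect_equal(got[mafs == 0.02], "common")
  expect_equal(got[mafs == 0.5], "common")
})

test_that("class assignment is a partition of every variant", {
  withr::local_seed(5)
  mafs <- pmin(0.5, stats::rbeta(500, 0.3, 5) + 1e-5)
  b <- derive_class_boundaries(mafs)
  cls <- assign_class(mafs, b)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), length(mafs))
})

test_that("predict_cgi matches the brute-force segment oracle", {
  seqs <- list(
    strrep("CG", 150),                              # pure island
    strrep("AT", 150),                              # nothing
    paste0(strrep("AT", 40), strrep("CG", 160), strrep("TA", 40)),
    paste0(strrep("CG", 120), strrep("TTTT", 30), strrep("GC", 110))
  )
  withr::local_seed(99)
  rand <- paste(sample(c("A", "C", "G", "T", "N"), 800,
                       replace = TRUE, prob = c(.2, .3, .3, .15, .05)),
                collapse = "")
  seqs <- c(seqs, rand)
  for (s in seqs) {
    got <- predict_cgi(s)
    exp <- oracle_cgi(s)
    expect_equal(nrow(got), nrow(exp))
    if (nrow(exp)) {
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
    }
  }
})

test_that("predict_cgi applies the length, GC and obs/exp filters", {
  # 300 bp of CG repeats: one island covering the repeat
  got <- predict_cgi(strrep("CG", 150))
  expect_equal(nrow(got), 1)
  expect_equal(got$end - got$start, 300L)
  expect_equal(nrow(predict_cgi(strrep("AT", 150))), 0)
  # a segment of exactly 200 bp fails the strict length filter, 202 passes
  expect_equal(nrow(predict_cgi(strrep("CG", 100))), 0)
  expect_equal(nrow(predict_cgi(strrep("CG", 101))), 1)
})

test_that("classify_tss uses half-open islands and strand-oriented distances", {
  cgi <- tibble::tibble(chrom = "chr1", start = 100L, end = 300L)
  got <- classify_tss(make_tss(150), cgi)
  expect_equal(got$cgi_status, "CGI")
  expect_equal(got$cgi_center_distance, -50)       # center at 200, + strand
  expect_equal(classify_tss(make_tss(150, "-"), cgi)$cgi_center_distance, 50)
  # end coordinate is exclusive
  expect_equal(classify_tss(make_tss(300), cgi)$cgi_status, "nCGI")
  expect_equal(classify_tss(make_tss(100), cgi)$cgi_status, "CGI")
  # no islands at all
  none <- classify_tss(make_tss(150), cgi[0, ])
  expect_equal(none$cgi_status, "nCGI")
  expect_true(is.na(none$cgi_center_distance))
  # overlapping islands: first by coordinate wins, with a warning
  two <- dplyr::bind_rows(cgi, tibble::tibble(chrom = "chr1", start = 120L, end = 400L))
  expect_warning(got2 <- classify_tss(make_tss(150), two), "overlapping")
  expect_equal(got2$cgi_center_distance, -50)
  # order of non-overlapping islands is irrelevant
  far <- dplyr::bind_rows(tibble::tibble(chrom = "chr1", start = 5000L, end = 6000L), cgi)
  expect_equal(classify_tss(make_tss(150), far)$cgi_center_distance, -50)
})

test_that("exclude_multi_tss drops crowded sites against the full input list", {
  # two TSSs 4,000 bp apart: both excluded
  expect_equal(nrow(exclude_multi_tss(make_tss(c(10000, 14000)))), 0)
  # 10,001 bp apart: both kept
  expect_equal(nrow(exclude_multi_tss(make_tss(c(10000, 20001)))), 2)
  # exactly half_window apart: still excluded (inclusive window)
  expect_equal(nrow(exclude_multi_tss(make_tss(c(10000, 15000)))), 0)
  # singleton chromosome is kept; a crowded pair elsewhere does not affect it
  mixed <- make_tss(c(10000, 14000, 9000), chrom = c("chr1", "chr1", "chr2"))
  expect_equal(exclude_multi_tss(mixed)$chrom, "chr2")
})

test_that("density contrast uses union semantics and balances under uniform placement", {
  sizes <- tibble::tibble(chrom = "chr1", size = 1e6)
  tss <- make_tss(c(100000, 105000))  # overlapping windows: union of 15 kb
  v_in <- make_variants(seq(96000, 109000, by = 100))
  d <- density_contrast(v_in, tss, sizes)
  expect_equal(d$bp_in, 15000)
  expect_equal(d$n_in, nrow(v_in))
  expect_equal(d$density_out, 0)
  # uniform scatter: densities agree within 3 binomial SEs
  withr::local_seed(21)
  v_u <- make_variants(sort(sample.int(1e6, 5000)))
  du <- density_contrast(v_u, make_tss(c(100000, 300000, 500000)), sizes)
  p_hat <- 5000 / 1e6
  se3 <- 3 * sqrt(p_hat * (1 - p_hat) / du$bp_in)
  expect_lt(abs(du$density_in - du$density_out), se3 + 3e-4)
})
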