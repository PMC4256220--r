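# statistical machinery against closed forms, frozen reference values and
# brute-force oracles

test_that("bonferroni caps at one and preserves order", {
  expect_equal(bonferroni(0.001, 200), 0.2)
  expect_equal(bonferroni(0.9, 200), 1)
  expect_equal(bonferroni(c(0.5, 0.01), 2), c(1, 0.02))
  expect_equal(bonferroni(0.04, 1), 0.04)
  expect_error(bonferroni(1.2, 10), "lie in")
  expect_error(bonferroni(c(0.1, 0.2), 1), ">=")
})

test_that("fisher_combine follows the chi-square closed form and is monotone", {
  one <- fisher_combine(0.3)
  expect_equal(one$statistic, -2 * log(0.3), tolerance = 1e-12)
  expect_equal(one$p_value, 0.3, tolerance = 1e-12)  # k = 1 is the identity
  all_one <- fisher_combine(rep(1, 7))
  expect_equal(all_one$statistic, 0)
  expect_equal(all_one$p_value, 1)
  many <- fisher_combine(rep(0.5, 200))
  expect_equal(many$statistic, 277.2588722239781, tolerance = 1e-9)
  expect_equal(many$df, 400)
  expect_equal(many$p_value, 0.999999415559474, tolerance = 1e-9)
  expect_gt(many$p_value, 0.99)
  # monotonicity: lowering any p raises X
  withr::local_seed(8)
  p <- runif(20, 0.01, 1)
  for (i in c(1, 10, 20)) {
    q <- p
    q[i] <- q[i] / 2
    expect_gt(fisher_combine(q)$statistic, fisher_combine(p)$statistic)
  }
  expect_error(fisher_combine(c(0.5, 0)), "lie in")
})

test_that("pearson_test matches the hand-computed example and the sum-loop oracle", {
  got <- pearson_test(c(1, 2, 3, 4), c(1, 2, 4, 3))
  expect_equal(got$r, 0.8, tolerance = 1e-12)
  expect_equal(got$t, 0.8 * sqrt(2) / sqrt(1 - 0.64), tolerance = 1e-12)
  expect_equal(got$df, 2)
  # perfect linear relations
  expect_equal(pearson_test(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_test(1:5, 2 * (1:5) + 1)$p, 0)
  expect_equal(pearson_test(1:5, -(1:5))$r, -1)
  expect_error(pearson_test(1:5, rep(2, 5)), "undefined correlation")
  expect_error(pearson_test(c(1, 2), c(3, 4)), "at least 3")
  # random vectors against the explicit covariance loops
  withr::local_seed(13)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    got <- pearson_test(x, y)
    exp <- oracle_pearson(x, y)
    expect_equal(got$r, exp$r, tolerance = 1e-12)
    expect_equal(got$t, exp$t, tolerance = 1e-12)
    expect_equal(got$p, exp$p, tolerance = 1e-12)
  }
  # missing pairs are dropped
  expect_equal(pearson_test(c(1, 2, 3, 4, NA), c(1, 2, 4, 3, 10))$n, 4)
})

test_that("neutral_bin_test is quiet on uniform data and flags degenerate bins", {
  withr::local_seed(4)
  m <- simulate_null_counts(2000, 10)
  nt <- neutral_bin_test(m)
  expect_s3_class(nt, "bin_test")
  expect_equal(sum(nt$significant), 0)
  expect_equal(unique(nt$null_mean), 1 / 200)
  # identical uniform rows: t = 0 everywhere, no significance, flagged
  flat <- tssvar:::new_bin_matrix(
    matrix(1L, nrow = 5, ncol = 200,
           dimnames = list(paste0("t", 1:5), as.character(bin_indices()))),
    "BVF"
  )
  ft <- neutral_bin_test(flat)
  expect_true(all(ft$zero_variance))
  expect_true(all(is.na(ft$p)))
  expect_equal(sum(ft$significant), 0)
})

test_that("family-wise error of the uniform-null bin test stays below 5%", {
  withr::local_seed(190)
  rejections <- 0L
  for (r in 1:50) {
    nt <- neutral_bin_test(simulate_null_counts(2000, 10), alpha = 0.001)
    if (any(nt$significant)) rejections <- rejections + 1L
  }
  expect_lte(rejections / 50, 0.05)
})

test_that("neutral_bin_test detects a strong planted enrichment", {
  withr::local_seed(6)
  m <- unclass(simulate_null_counts(2000, 10))
  planted <- match(1:4, bin_indices())
  m[, planted] <- m[, planted] + rpois(2000 * 4, 0.05 * 0.7)  # 1.7-fold
  nt <- neutral_bin_test(tssvar:::new_bin_matrix(m, "BVF"))
  expect_true(all(nt$significant[planted]))
})

test_that("bvf_delta_test is antisymmetric and null on identical placements", {
  withr::local_seed(9)
  mr <- simulate_null_counts(300, 8)
  mc <- tssvar:::new_bin_matrix(unclass(mr) + 0L, "BVF")
  same <- bvf_delta_test(mr, mc)
  expect_true(all(same$test$observed_mean == 0))
  expect_equal(sum(same$test$significant), 0)
  mc2 <- simulate_null_counts(300, 12)
  ab <- bvf_delta_test(mr, mc2)
  ba <- bvf_delta_test(mc2, mr)
  expect_equal(ab$test$observed_mean, -ba$test$observed_mean)
  expect_equal(ab$test$p, ba$test$p)
  expect_error(bvf_delta_test(simulate_null_counts(1, 5),
                              simulate_null_counts(1, 5)),
               "Fewer than 2")
})

test_that("window_split recovers structure and fails cleanly on constants", {
  J <- bin_indices()
  inner <- abs(J) <= 20
  shape_in <- -cos(pi * J / 20) * inner
  shape_out <- sin(J / 15) * !inner
  delta <- tibble::tibble(bin = J, mean = shape_in * 0.01 + shape_out * 0.005)
  bbs <- tibble::tibble(bin = J, mean = 0.1 - 0.3 * shape_in)
  bgs <- tibble::tibble(bin = J, mean = 0.2 + shape_out)
  ws <- window_split(bbs, bgs, delta)
  expect_equal(ws$boundary, 20)
  expect_equal(ws$boundary_bp, 1000)
  expect_lt(ws$r_inner$r, -0.9)
  expect_gt(ws$r_outer$r, 0.9)
  expect_length(ws$flags, 0)
  expect_equal(nrow(ws$trace), 97)
  # constant delta: no correlation anywhere
  expect_error(window_split(bbs, bgs, tibble::tibble(bin = J, mean = rep(1, 200))),
               "undefined")
  # no inner coupling at all: weak-inner flag
  withr::local_seed(17)
  flat_bbs <- tibble::tibble(bin = J, mean = 0.1 + rnorm(200, sd = 1e-3))
  ws2 <- window_split(flat_bbs, bgs, delta)
  if (abs(ws2$r_inner$r) < 0.2) expect_true("weak_inner_signal" %in% ws2$flags)
})

test_that("bcs_class_anova matches the sum-of-squares oracle and handles edge cases", {
  withr::local_seed(23)
  # small groups, exact agreement with the direct formula
  sc <- tibble::tibble(
    bin = 1L,
    class = rep(c("rare", "mid1", "mid2", "common"), each = 6),
    raw_score = rnorm(24, mean = rep(c(2, 1.5, 1, 0.5), each = 6))
  )
  got <- bcs_class_anova(sc)
  row <- got[got$bin == 1, ]
  exp <- oracle_anova(sc$raw_score, sc$class)
  expect_equal(row$F, exp$F, tolerance = 1e-10)
  expect_equal(row$p, exp$p, tolerance = 1e-10)
  expect_true(all(is.na(got$p[got$bin != 1])))
  # identical constant scores in all classes: F = 0 by convention
  const <- dplyr::mutate(sc, raw_score = 3)
  con <- bcs_class_anova(const)
  expect_equal(con$F[con$bin == 1], 0)
  expect_equal(con$p[con$bin == 1], 1)
  # one strongly shifted class at n = 50/class: overwhelming significance
  big <- tibble::tibble(
    bin = 1L,
    class = rep(c("rare", "mid1", "mid2", "common"), each = 50),
    raw_score = rnorm(200) + rep(c(2, 0, 0, 0), each = 50)
  )
  bg <- bcs_class_anova(big)
  expect_lt(bg$p_adj[bg$bin == 1], 0.001)
  # a bin with a single populated class is missing
  one_cls <- tibble::tibble(bin = 1L, class = "rare", raw_score = rnorm(5))
  oc <- bcs_class_anova(one_cls)
  expect_true(is.na(oc$p[oc$bin == 1]))
})

test_that("null bcs_class_anova keeps roughly alpha * 200 raw rejections", {
  withr::local_seed(29)
  sc <- tibble::tibble(
    bin = rep(bin_indices(), each = 40),
    class = rep(rep(c("rare", "mid1", "mid2", "common"), each = 10), 200),
    raw_score = rnorm(200 * 40)
  )
  got <- bcs_class_anova(sc, alpha = 0.05)
  expect_lt(sum(got$p < 0.05, na.rm = TRUE), 30)  # ~10 expected
  expect_equal(sum(got$significant, na.rm = TRUE), 0)
})

test_that("profile_ttest_pair flags shifted signals and propagates missingness", {
  withr::local_seed(37)
  a <- matrix(rnorm(100 * 200), 100, 200)
  same <- profile_ttest_pair(a, a)
  expect_equal(sum(same$significant, na.rm = TRUE), 0)
  b <- a + 1
  shift <- profile_ttest_pair(a, b)
  expect_true(all(shift$significant))
  a_na <- a
  a_na[, 3] <- NA
  miss <- profile_ttest_pair(a_na, b)
  expect_true(is.na(miss$p[3]))
  expect_true(is.na(miss$p_adj[3]))
})

test_that("wilcoxon_updown matches exact references and the enumeration oracle", {
  # disjoint samples of 10 vs 10: the exact two-sided minimum
  p_min <- wilcoxon_updown(1:10, 101:110)$p
  expect_equal(p_min, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(p_min, 1.082508822446903e-05, tolerance = 1e-9)
  # identical samples: p = 1
  expect_equal(wilcoxon_updown(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # tie-free small samples agree with the enumeration oracle
  withr::local_seed(41)
  for (rep in 1:5) {
    up <- round(rnorm(sample(4:8, 1)), 6)
    dn <- round(rnorm(sample(4:8, 1)), 6)
    expect_equal(wilcoxon_updown(up, dn)$p, oracle_wilcoxon(up, dn),
                 tolerance = 1e-10)
  }
  # tie-heavy small samples agree with the enumeration oracle too
  up <- c(1, 1, 2, 2, 3)
  dn <- c(2, 2, 3, 3, 3, 4)
  expect_equal(wilcoxon_updown(up, dn)$p, oracle_wilcoxon(up, dn),
               tolerance = 1e-10)
})

test_that("dagostino_skewness reproduces reference values and detects skew", {
  x1 <- c(1.2, 3.4, 0.5, 2.2, 5.1, 0.3, 4.4, 2.8, 1.9, 3.3)
  got <- dagostino_skewness(x1)
  # frozen reference values for this fixture
  expect_equal(got$skewness, 0.11344010748997586, tolerance = 1e-9)
  expect_equal(got$z, 0.20293782058300452, tolerance = 1e-7)
  expect_equal(got$p, 0.839183632744274, tolerance = 1e-7)
  got2 <- dagostino_skewness((1:20)^3)
  expect_equal(got2$z, 2.0979016502033105, tolerance = 1e-7)
  expect_equal(got2$p, 0.035913834219281716, tolerance = 1e-6)
  # exactly symmetric sample: zero skewness, p = 1
  sym <- dagostino_skewness(c(-4:-1, 1:4))
  expect_equal(sym$skewness, 0)
  expect_equal(sym$p, 1)
  # heavy right skew at large n is overwhelmingly significant
  withr::local_seed(43)
  expect_lt(dagostino_skewness(rexp(5000))$p, 0.001)
  expect_error(dagostino_skewness(1:7), "n >= 8")
})
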