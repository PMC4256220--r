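# Statistical machinery: uniform-null bin tests, the rare-minus-common
# BVF-delta contrast, Fisher p-value combination, correlation tests, the
# inner/outer window-split search, per-bin ANOVA / two-sample tests,
# Wilcoxon, the D'Agostino skewness test, and Bonferroni correction.

#' Bonferroni adjustment
#'
#' `adjusted = min(1, p * m)`, order preserved; NA propagates.
#'
#' @param pvals Raw p-values in \[0, 1\].
#' @param m Number of tests; must be at least the number of non-missing
#'   p-values.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  check_prob(pvals, "pvals", allow_zero = TRUE)
  if (m < sum(!is.na(pvals))) abort("`m` must be >= the number of tests.")
  pmin(1, pvals * m)
}

# vectorized one-sample t-test per column against mu; returns a tibble
col_t_test <- function(mat, mu) {
  n <- colSums(!is.na(mat))
  mean <- colMeans(mat, na.rm = TRUE)
  s <- matrixStats_col_sd(mat)
  se <- s / sqrt(n)
  t <- (mean - mu) / se
  p <- 2 * pt(-abs(t), df = n - 1)
  zero_var <- !is.na(s) & s == 0
  p[zero_var & mean == mu] <- NA_real_  # 0/0: no information against the null
  tibble(n = as.integer(n), observed_mean = mean, se = se, t = t, p = p,
         zero_variance = zero_var)
}

new_bin_test <- function(df, alpha, m, null_mean, signal) {
  structure(df, class = c("bin_test", class(tibble())),
            alpha = alpha, m = m, null_mean = null_mean, signal = signal)
}

#' Per-bin test against the uniform-placement null
#'
#' Under uniform placement of a TSS's variants over its 200 bins the expected
#' normalized frequency is exactly 1/200 in every bin. Each bin's per-TSS
#' fractions `f(i, j)` are tested against that value with a two-sided
#' one-sample t-test; the 200 p-values are Bonferroni-corrected.
#'
#' @param matrix A `bin_matrix` of variant counts (see [bin_count_matrix()]).
#' @param alpha Family-wise significance level (default 0.001).
#' @return A `bin_test` tibble: `bin`, `offset_bp`, `n`, `observed_mean`,
#'   `null_mean`, `se`, `t`, `p`, `p_adj`, `significant`, `zero_variance`.
#'   Bins with zero variance across TSSs get a missing p and are flagged.
#' @export
neutral_bin_test <- function(matrix, alpha = 0.001) {
  f <- bvf_fractions(matrix)
  if (nrow(f) < 2) abort("Need at least 2 TSSs with variants for the bin test.")
  null_mean <- 1 / N_BINS
  res <- col_t_test(f, null_mean)
  J <- bin_indices()
  out <- dplyr::bind_cols(tibble(bin = J, offset_bp = bin_offset(J)), res)
  out$null_mean <- null_mean
  out$p_adj <- bonferroni(out$p, N_BINS)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  cols <- c("bin", "offset_bp", "n", "observed_mean", "null_mean", "se", "t",
            "p", "p_adj", "significant", "zero_variance")
  new_bin_test(out[cols], alpha, N_BINS, null_mean,
               attr(matrix, "signal") %||% "BVF")
}

#' Rare-minus-common BVF contrast (BVF-delta)
#'
#' For every TSS carrying variants of both classes, the paired per-bin
#' difference `delta(i, j) = f_rare(i, j) - f_common(i, j)` is formed; its
#' across-TSS mean is the BVF-delta profile, tested bin-wise against 0
#' (two-sided t, Bonferroni over 200). Positive values mark bins where rare
#' (young) variants are relatively more frequent than common (old) ones.
#'
#' @param matrix_rare,matrix_common `bin_matrix` objects over the same TSS
#'   universe (identical row names).
#' @param alpha Family-wise significance level.
#' @return A list with components `profile` (a `bin_profile` of delta means)
#'   and `test` (a `bin_test`); class `bvf_delta`.
#' @export
bvf_delta_test <- function(matrix_rare, matrix_common, alpha = 0.001) {
  if (!identical(rownames(matrix_rare), rownames(matrix_common))) {
    abort("The two matrices must be over the same TSS list.")
  }
  both <- rowSums(matrix_rare) > 0 & rowSums(matrix_common) > 0
  if (sum(both) < 2) {
    abort("Fewer than 2 TSSs carry both variant classes; delta is undefined.")
  }
  fr <- unclass(matrix_rare)[both, , drop = FALSE]
  fc <- unclass(matrix_common)[both, , drop = FALSE]
  delta <- fr / rowSums(fr) - fc / rowSums(fc)
  res <- col_t_test(delta, 0)
  J <- bin_indices()
  out <- dplyr::bind_cols(tibble(bin = J, offset_bp = bin_offset(J)), res)
  out$null_mean <- 0
  out$p_adj <- bonferroni(out$p, N_BINS)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  cols <- c("bin", "offset_bp", "n", "observed_mean", "null_mean", "se", "t",
            "p", "p_adj", "significant", "zero_variance")
  test <- new_bin_test(out[cols], alpha, N_BINS, 0, "BVF_delta")
  profile <- new_bin_profile(res$observed_mean, res$se, res$n, "BVF_delta")
  structure(list(profile = profile, test = test), class = "bvf_delta")
}

#' Combine p-values with Fisher's method
#'
#' `X = -2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom. Decreasing any input p strictly increases X.
#'
#' @param pvals p-values in (0, 1].
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `k`.
#' @export
fisher_combine <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) abort("No p-values to combine.")
  check_prob(pvals, "pvals")
  X <- -2 * sum(log(pvals))
  k <- length(pvals)
  tibble(statistic = X, df = 2 * k,
         p_value = pchisq(X, df = 2 * k, lower.tail = FALSE), k = k)
}

#' Pearson correlation with its t-test
#'
#' `r` is the product-moment correlation of the pairwise-complete
#' observations; `t = r * sqrt(n - 2) / sqrt(1 - r^2)` follows a Student t
#' with `n - 2` degrees of freedom under no correlation.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value are
#'   dropped.
#' @return A `pearson_test` one-row tibble: `r`, `t`, `df`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs for a correlation test.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined correlation: at least one input is constant")
  }
  r <- stats::cor(x, y)
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(t), df = n - 2)
  structure(tibble(r = r, t = t, df = n - 2, p = p, n = n),
            class = c("pearson_test", class(tibble())))
}

#' Split the window into gBGC-dominated and selection-dominated regions
#'
#' For each candidate half-width `i` in 2..98 the inner region is the bins
#' with `|j| <= i` and the outer region its complement. `r_in(i)` correlates
#' the gBGC coverage profile (BBS) with BVF-delta on the inner bins;
#' `r_out(i)` correlates the conservation profile (BGS) with BVF-delta on the
#' outer bins. The boundary `j*` maximizes `|r_in * r_out|` (smallest `i` on
#' ties). When `|r_in(j*)| < 0.2` the result is flagged `weak_inner_signal`.
#'
#' @param bbs_profile,bgs_profile,delta_profile `bin_profile` tibbles (or any
#'   tibble with `bin` and `mean` columns) on the same 200-bin grid.
#' @return A `region_split` list: `boundary` (j*), `boundary_bp`, `r_inner`,
#'   `r_outer` (each a `pearson_test` row), `trace` (tibble `i`, `r_in`,
#'   `r_out`, `abs_product`), and `flags`.
#' @export
window_split <- function(bbs_profile, bgs_profile, delta_profile) {
  J <- bin_indices()
  get <- function(p) {
    stopifnot(all(c("bin", "mean") %in% names(p)))
    p$mean[match(J, p$bin)]
  }
  bbs <- get(bbs_profile); bgs <- get(bgs_profile); delta <- get(delta_profile)
  safe_cor <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    stats::cor(a[ok], b[ok])
  }
  trace <- purrr::map_dfr(2:98, function(i) {
    inner <- abs(J) <= i
    tibble(i = i,
           r_in = safe_cor(bbs[inner], delta[inner]),
           r_out = safe_cor(bgs[!inner], delta[!inner]))
  })
  trace$abs_product <- abs(trace$r_in * trace$r_out)
  if (all(is.na(trace$abs_product))) {
    abort("Correlation undefined at every candidate split.")
  }
  jstar <- trace$i[which.max(trace$abs_product)]  # which.max: smallest on ties
  inner <- abs(J) <= jstar
  r_inner <- pearson_test(bbs[inner], delta[inner])
  r_outer <- pearson_test(bgs[!inner], delta[!inner])
  flags <- character(0)
  if (abs(r_inner$r) < 0.2) flags <- c(flags, "weak_inner_signal")
  structure(
    list(boundary = jstar, boundary_bp = jstar * BIN_WIDTH,
         r_inner = r_inner, r_outer = r_outer, trace = trace, flags = flags),
    class = "region_split"
  )
}

#' @export
print.region_split <- function(x, ...) {
  cat(sprintf("<region_split> boundary j* = %d (%d bp)\n", x$boundary, x$boundary_bp))
  cat(sprintf("  inner  BBS~delta: r = %+.3f (p = %.3g, n = %d)\n",
              x$r_inner$r, x$r_inner$p, x$r_inner$n))
  cat(sprintf("  outer  BGS~delta: r = %+.3f (p = %.3g, n = %d)\n",
              x$r_outer$r, x$r_outer$p, x$r_outer$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Per-bin one-way ANOVA of deleteriousness scores across frequency classes
#'
#' For each bin, the per-variant CADD scores of the four frequency classes
#' are compared with a classic (equal-variance) one-way ANOVA; the 200
#' p-values are Bonferroni-corrected. A bin needs at least two classes with
#' at least two scored variants each, otherwise it is missing. Degenerate
#' bins where every score is identical give F = 0, p = 1.
#'
#' @param scores A long tibble with columns `bin`, `class` and `raw_score`
#'   (e.g. [assign_bins()] output joined with CADD scores).
#' @param alpha Family-wise significance level.
#' @return A tibble: `bin`, `F`, `df1`, `df2`, `p`, `p_adj`, `significant`,
#'   `n`.
#' @export
bcs_class_anova <- function(scores, alpha = 0.001) {
  J <- bin_indices()
  res <- purrr::map_dfr(J, function(j) {
    d <- scores[scores$bin == j & !is.na(scores$raw_score), ]
    sizes <- table(as.character(d$class))
    sizes <- sizes[sizes >= 2]
    if (length(sizes) < 2) {
      return(tibble(bin = j, F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                    p = NA_real_, n = nrow(d)))
    }
    d <- d[as.character(d$class) %in% names(sizes), ]
    g <- factor(as.character(d$class))
    gm <- tapply(d$raw_score, g, mean)
    ss_between <- sum(tabulate(g) * (gm[levels(g)] - mean(d$raw_score))^2)
    if (ss_between == 0) {
      return(tibble(bin = j, F = 0, df1 = length(levels(g)) - 1,
                    df2 = nrow(d) - length(levels(g)), p = 1, n = nrow(d)))
    }
    ft <- stats::oneway.test(raw_score ~ g, data = d, var.equal = TRUE)
    p <- ft$p.value
    if (is.nan(p)) p <- 0  # zero within-group variance, non-zero between
    tibble(bin = j, F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
           df2 = unname(ft$parameter[2]), p = p, n = nrow(d))
  })
  res$p_adj <- bonferroni(res$p, N_BINS)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}

#' Per-bin two-sample t-tests between two TSS groups
#'
#' Compares per-TSS bin values (e.g. BNP means or BBS fractions, or per-TSS
#' BVF fractions) between two groups bin by bin with a two-sided t-test, and
#' Bonferroni-corrects over the 200 bins. The raw p-values also feed
#' [fisher_combine()] for whole-signal contrasts.
#'
#' @param matrix_a,matrix_b Numeric matrices (rows = TSSs, 200 aligned bin
#'   columns); see [bin_value_matrix()].
#' @param alpha Family-wise significance level.
#' @param var_equal Pass `TRUE` for the classic equal-variance t-test;
#'   default is Welch.
#' @return A tibble: `bin`, `mean_a`, `mean_b`, `t`, `df`, `p`, `p_adj`,
#'   `significant`, `n_a`, `n_b`. Bins with fewer than 2 values on either
#'   side are missing.
#' @export
profile_ttest_pair <- function(matrix_a, matrix_b, alpha = 0.001,
                               var_equal = FALSE) {
  stopifnot(ncol(matrix_a) == N_BINS, ncol(matrix_b) == N_BINS)
  J <- bin_indices()
  res <- purrr::map_dfr(seq_len(N_BINS), function(k) {
    a <- matrix_a[, k]; a <- a[!is.na(a)]
    b <- matrix_b[, k]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2 ||
        (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b))) {
      return(tibble(bin = J[k], mean_a = mean(a), mean_b = mean(b),
                    t = NA_real_, df = NA_real_, p = NA_real_,
                    n_a = length(a), n_b = length(b)))
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    tibble(bin = J[k], mean_a = mean(a), mean_b = mean(b),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, n_a = length(a), n_b = length(b))
  })
  res$p_adj <- bonferroni(res$p, N_BINS)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}

#' Wilcoxon rank-sum comparison of upstream vs downstream values
#'
#' Two-sided rank-sum test. Tie-free samples of at most 20 per side use the
#' exact rank-sum distribution; tied samples with a combined size of at most
#' 16 use an exact permutation enumeration of the rank sum (two-sided p =
#' probability of a rank-sum deviation from its exchangeability mean at
#' least as large as observed); everything else uses the normal
#' approximation with continuity and tie correction.
#'
#' @param values_up,values_down Non-empty numeric samples.
#' @return A one-row tibble: `statistic` (the Mann-Whitney W as in
#'   [stats::wilcox.test()]), `p`, `n_up`, `n_down`, `exact`.
#' @export
wilcoxon_updown <- function(values_up, values_down) {
  values_up <- values_up[!is.na(values_up)]
  values_down <- values_down[!is.na(values_down)]
  stopifnot(length(values_up) > 0, length(values_down) > 0)
  nu <- length(values_up); nd <- length(values_down)
  ties <- anyDuplicated(c(values_up, values_down)) > 0
  if (ties && nu + nd <= 16) {
    r <- rank(c(values_up, values_down))
    w_obs <- sum(r[seq_len(nu)])
    mu <- nu * (nu + nd + 1) / 2
    sets <- utils::combn(nu + nd, nu)
    w_all <- colSums(matrix(r[sets], nrow = nu))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    return(tibble(statistic = w_obs - nu * (nu + 1) / 2, p = p,
                  n_up = nu, n_down = nd, exact = TRUE))
  }
  exact <- !ties && nu <= 20 && nd <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(values_up, values_down, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  tibble(statistic = unname(wt$statistic), p = wt$p.value,
         n_up = nu, n_down = nd, exact = exact)
}

#' D'Agostino test of skewness
#'
#' Transforms the sample skewness `g1 = m3 / m2^(3/2)` to an approximately
#' standard normal `z` (D'Agostino 1970) and reports the two-sided p-value.
#' Requires at least 8 observations for the transformation to be valid.
#'
#' @param values Numeric sample, `n >= 8`.
#' @return A one-row tibble: `skewness`, `z`, `p`, `n`.
#' @export
dagostino_skewness <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8) abort("D'Agostino skewness transformation requires n >= 8.")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  tibble(skewness = g1, z = z, p = 2 * pnorm(-abs(z)), n = n)
}
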