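# broom-style tidy()/glance() methods for the package's result objects

#' Tidy a per-bin test table
#'
#' @param x A `bin_test` (from [neutral_bin_test()] or the `test` component
#'   of [bvf_delta_test()]).
#' @param ... Unused.
#' @return A plain tibble, one row per bin.
#' @method tidy bin_test
#' @export
tidy.bin_test <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.bin_test
#' @method glance bin_test
#' @export
glance.bin_test <- function(x, ...) {
  tibble(
    signal = attr(x, "signal"),
    alpha = attr(x, "alpha"),
    m = attr(x, "m"),
    null_mean = attr(x, "null_mean"),
    n_significant = sum(x$significant, na.rm = TRUE),
    significant_bins = bin_runs(x$bin[x$significant]),
    n_zero_variance = sum(x$zero_variance, na.rm = TRUE),
    min_p_adj = suppressWarnings(min(x$p_adj, na.rm = TRUE))
  )
}

#' Tidy the window-split search trace
#'
#' @param x A `region_split` from [window_split()].
#' @param ... Unused.
#' @return The candidate-boundary trace: `i`, `r_in`, `r_out`, `abs_product`.
#' @method tidy region_split
#' @export
tidy.region_split <- function(x, ...) x$trace

#' @rdname tidy.region_split
#' @method glance region_split
#' @export
glance.region_split <- function(x, ...) {
  tibble(
    boundary = x$boundary, boundary_bp = x$boundary_bp,
    r_inner = x$r_inner$r, p_inner = x$r_inner$p, n_inner = x$r_inner$n,
    r_outer = x$r_outer$r, p_outer = x$r_outer$p, n_outer = x$r_outer$n,
    flags = if (length(x$flags)) paste(x$flags, collapse = ",") else NA_character_
  )
}

#' Tidy a correlation test
#'
#' @param x A `pearson_test` row.
#' @param ... Unused.
#' @return A plain one-row tibble: `r`, `t`, `df`, `p`, `n`.
#' @method tidy pearson_test
#' @export
tidy.pearson_test <- function(x, ...) as_tibble(unclass(x)[names(x)])

#' One-line summary of a pipeline run
#'
#' @param x A `tss_pipeline_result`.
#' @param ... Unused.
#' @return A one-row tibble of headline counts and results.
#' @method glance tss_pipeline_result
#' @export
glance.tss_pipeline_result <- function(x, ...) {
  tibble(
    n_tss = x$counts$n_tss,
    n_tss_cgi = x$counts$n_tss_cgi,
    n_variants = unname(x$counts$n_variants_kept),
    density_in = x$density$density_in,
    density_out = x$density$density_out,
    split_boundary = if (!is.null(x$split)) x$split$boundary else NA_integer_,
    split_boundary_bp = if (!is.null(x$split)) x$split$boundary_bp else NA_integer_
  )
}
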