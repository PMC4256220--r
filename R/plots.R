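# ggplot2 methods for the result objects. All plots put the bin offset from
# the TSS (bp, transcription direction) on the x-axis.

#' Plot a bin profile
#'
#' Mean with the 2-SE confidence ribbon against the offset from the TSS.
#'
#' @param object A `bin_profile` (e.g. from [bvf_profile()] or
#'   [track_profile()]).
#' @param null_line Optional horizontal reference (e.g. 1/200 for BVF).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bin_profile
#' @export
autoplot.bin_profile <- function(object, null_line = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$offset_bp, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Position relative to TSS (bp)",
                  y = attr(object, "signal") %||% "mean",
                  title = attr(object, "signal"))
  if (!is.null(null_line)) {
    p <- p + ggplot2::geom_hline(yintercept = null_line, colour = "steelblue",
                                 linetype = "dashed")
  }
  p
}

#' Plot a per-bin test result
#'
#' Observed means with the 2-SE band, the null expectation, and a dot over
#' each Bonferroni-significant bin.
#'
#' @param object A `bin_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bin_test
#' @export
autoplot.bin_test <- function(object, ...) {
  df <- tidy(object)
  df$ci_lo <- df$observed_mean - 2 * df$se
  df$ci_hi <- df$observed_mean + 2 * df$se
  sig <- df[df$significant, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset_bp, y = .data$observed_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_hline(yintercept = attr(object, "null_mean"),
                        colour = "steelblue", linetype = "dashed") +
    ggplot2::geom_point(data = sig,
                        ggplot2::aes(y = .data$ci_hi + 0.02 * abs(.data$ci_hi)),
                        shape = 20) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Position relative to TSS (bp)",
                  y = sprintf("%s (mean, 2-SE band)", attr(object, "signal")),
                  title = sprintf("%s vs null (alpha = %g, Bonferroni over %d)",
                                  attr(object, "signal"), attr(object, "alpha"),
                                  attr(object, "m")))
}

#' Plot the window-split search trace
#'
#' `|r_in|`, `|r_out|` and their product for every candidate half-width,
#' with the chosen boundary marked.
#'
#' @param object A `region_split`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot region_split
#' @export
autoplot.region_split <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("r_in", "r_out", "abs_product"),
                            names_to = "series", values_to = "value")
  tr$value <- abs(tr$value)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$i, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$boundary, linetype = "dashed") +
    ggplot2::labs(x = "Candidate inner half-width (bins)",
                  y = "|correlation|",
                  title = sprintf("Inner/outer split: boundary %d bins (%d bp)",
                                  object$boundary, object$boundary_bp))
}

#' Overlay several bin profiles
#'
#' @param profiles Named list of `bin_profile` tibbles (e.g. the four
#'   frequency classes).
#' @param null_line Optional horizontal reference.
#' @return A ggplot with one line per profile.
#' @export
plot_profiles <- function(profiles, null_line = NULL) {
  df <- purrr::imap_dfr(profiles, function(p, nm) {
    dplyr::mutate(as_tibble(p), series = nm)
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$offset_bp, y = .data$mean,
                                        colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Position relative to TSS (bp)", y = "mean")
  if (!is.null(null_line)) {
    p <- p + ggplot2::geom_hline(yintercept = null_line, colour = "grey40",
                                 linetype = "dashed")
  }
  p
}
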