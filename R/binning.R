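# The 200 x 50 bp strand-aware bin grid around each TSS, and aggregation of
# variants and score tracks into it.
#
# Bin indices j run -100..-1, +1..+100 (no bin 0). Offsets d are measured in
# the direction of transcription: d = position - tss for "+" strand TSSs and
# d = tss - position for "-" strand. Bin j covers d in [(j-1)*50, j*50) for
# j > 0 and d in [j*50, (j+1)*50) for j < 0, so d = 0 (a variant exactly at
# the TSS) falls in bin +1 and the grid spans d in [-5000, 5000).

BIN_WIDTH <- 50L
N_BINS <- 200L
HALF_WINDOW <- 5000L

#' The bin index set
#'
#' @return The 200 bin indices, `-100..-1, +1..+100`, in grid order.
#' @export
bin_indices <- function() c(-100:-1, 1:100)

#' Transcription-direction offset of each bin center
#'
#' @param j Bin indices.
#' @return Offset in bp of the bin midpoint from the TSS (positive =
#'   downstream).
#' @export
bin_offset <- function(j) {
  ifelse(j > 0, (j - 0.5) * BIN_WIDTH, (j + 0.5) * BIN_WIDTH)
}

#' Map genomic positions to bin indices
#'
#' @param position Genomic positions (0-based bp).
#' @param tss_position TSS positions (recycled).
#' @param strand `"+"` or `"-"` per TSS.
#' @return Integer bin index in `-100..-1, +1..+100`, or `NA` when the
#'   position lies outside the 10 kb window.
#' @examples
#' bin_index(1000, 1000, "+")   # at the TSS: bin +1
#' bin_index(999, 1000, "+")    # one bp upstream: bin -1
#' @export
bin_index <- function(position, tss_position, strand) {
  d <- ifelse(strand == "-", tss_position - position, position - tss_position)
  j <- ifelse(d >= 0, d %/% BIN_WIDTH + 1L, d %/% BIN_WIDTH)
  j[d < -HALF_WINDOW | d >= HALF_WINDOW] <- NA_integer_
  as.integer(j)
}

# genomic [start, end) of bin j for a TSS; half-open in d-space, which makes
# minus-strand bins half-open on the opposite genomic side
bin_genomic_bounds <- function(tss_position, strand, j) {
  lo_d <- ifelse(j > 0, (j - 1) * BIN_WIDTH, j * BIN_WIDTH)
  hi_d <- lo_d + BIN_WIDTH
  start <- ifelse(strand == "-", tss_position - hi_d + 1L, tss_position + lo_d)
  tibble(start = as.integer(start), end = as.integer(start + BIN_WIDTH))
}

# drop TSSs whose 10 kb window would be truncated by a chromosome end
drop_edge_tss <- function(tss, genome_sizes) {
  if (is.null(genome_sizes)) return(tss)
  tss2 <- dplyr::left_join(tss, genome_sizes, by = "chrom")
  bad <- tss2$position - HALF_WINDOW < 0 |
    tss2$position + HALF_WINDOW + 1L > tss2$size
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    warn(sprintf("Dropped %d TSS(s) within %d bp of a chromosome end.",
                 sum(bad), HALF_WINDOW))
    tss <- tss[!bad, , drop = FALSE]
  }
  tss
}

#' Assign variants to TSS bins
#'
#' Every (TSS, variant) pair with the variant inside the TSS's 10 kb window
#' yields one row; a variant inside the windows of two TSSs is counted once
#' per TSS. Variant columns other than the coordinates are carried along.
#'
#' @param tss TSS tibble (`id`, `chrom`, `position`, `strand`).
#' @param variants Variant tibble (`id`, `chrom`, `position`, plus e.g.
#'   `class`, `maf`).
#' @param genome_sizes Optional `chrom`/`size` tibble; TSSs with truncated
#'   windows are dropped with a warning.
#' @return A long tibble: `tss_id`, `strand`, `bin`, `d` (transcription-
#'   direction offset) and the variant columns (variant `id` as
#'   `variant_id`).
#' @export
assign_bins <- function(tss, variants, genome_sizes = NULL) {
  tss <- drop_edge_tss(tss, genome_sizes)
  win <- tibble(tss_id = tss$id, chrom = tss$chrom,
                tss_position = tss$position, strand = tss$strand,
                lo = tss$position - HALF_WINDOW, hi = tss$position + HALF_WINDOW)
  vr <- dplyr::rename(variants, variant_id = "id")
  hit <- dplyr::inner_join(
    win, vr,
    by = dplyr::join_by(chrom, lo <= position, hi >= position)
  )
  hit$d <- ifelse(hit$strand == "-",
                  hit$tss_position - hit$position,
                  hit$position - hit$tss_position)
  hit$bin <- bin_index(hit$position, hit$tss_position, hit$strand)
  hit <- hit[!is.na(hit$bin), , drop = FALSE]
  dplyr::select(hit, -"lo", -"hi")
}

# -- count matrices -----------------------------------------------------------

#' Per-TSS x per-bin count matrix
#'
#' @param assignments Output of [assign_bins()], already restricted to the
#'   variant subset of interest (e.g. one frequency class).
#' @param tss_ids Row universe; TSSs without any assigned variant appear as
#'   zero rows.
#' @param signal Label stamped on the result (`"BVF"` by default).
#' @return A `bin_matrix`: an integer matrix with one row per TSS id and 200
#'   columns named by bin index.
#' @export
bin_count_matrix <- function(assignments, tss_ids, signal = "BVF") {
  J <- bin_indices()
  mat <- matrix(0L, nrow = length(tss_ids), ncol = N_BINS,
                dimnames = list(tss_ids, as.character(J)))
  if (nrow(assignments) > 0) {
    counts <- dplyr::count(assignments, .data$tss_id, .data$bin)
    ri <- match(counts$tss_id, tss_ids)
    ci <- match(counts$bin, J)
    ok <- !is.na(ri) & !is.na(ci)
    mat[cbind(ri[ok], ci[ok])] <- counts$n[ok]
  }
  new_bin_matrix(mat, signal)
}

new_bin_matrix <- function(mat, signal) {
  structure(mat, class = c("bin_matrix", "matrix", "array"), signal = signal)
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("<bin_matrix> %s: %d TSS x %d bins, %d non-zero cells\n",
              attr(x, "signal") %||% "?", nrow(x), ncol(x), sum(x != 0)))
  invisible(x)
}

# per-TSS normalized frequencies f(i, j) = vars(i, j) / V(i); rows with no
# variants carry no frequency information and are dropped
bvf_fractions <- function(matrix) {
  v <- rowSums(matrix)
  keep <- v > 0
  if (!any(keep)) abort("All TSS rows are empty; BVF is undefined.")
  unclass(matrix)[keep, , drop = FALSE] / v[keep]
}

#' Normalized bin variant frequency profile (BVF)
#'
#' Each retained TSS contributes its normalized per-bin variant fractions
#' `f(i, j) = vars(i, j) / V(i)`; the profile is the across-TSS mean with its
#' standard error and the 2-SE confidence band. The profile sums to 1 over
#' bins, so the uniform-placement expectation is exactly 1/200 per bin.
#'
#' @param matrix A `bin_matrix` of variant counts.
#' @return A `bin_profile` tibble: `bin`, `offset_bp`, `mean`, `se`, `ci_lo`,
#'   `ci_hi`, `n`.
#' @export
bvf_profile <- function(matrix) {
  f <- bvf_fractions(matrix)
  new_bin_profile(
    mean = colMeans(f),
    se = matrixStats_col_sd(f) / sqrt(nrow(f)),
    n = rep(nrow(f), ncol(f)),
    signal = attr(matrix, "signal") %||% "BVF"
  )
}

# column standard deviations without an extra dependency
matrixStats_col_sd <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(NA_real_, ncol(m)))
  mu <- colMeans(m)
  sqrt((colSums(m^2) - n * mu^2) / (n - 1))
}

new_bin_profile <- function(mean, se, n, signal, extra = NULL) {
  J <- bin_indices()
  out <- tibble(bin = J, offset_bp = bin_offset(J), mean = unname(mean),
                se = unname(se),
                ci_lo = unname(mean - 2 * se), ci_hi = unname(mean + 2 * se),
                n = unname(as.integer(n)))
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  structure(out, class = c("bin_profile", class(tibble())), signal = signal)
}

# -- track binning ------------------------------------------------------------

#' Overlap a score track with the bin grid
#'
#' Intersects track intervals with every (TSS, bin) cell and accumulates the
#' per-cell score sum (`value x` overlapped bases) and the number of scored
#' bases.
#'
#' @param tss TSS tibble.
#' @param track A `tssvar_track` (from [read_bedgraph()] or
#'   [as_membership_track()]).
#' @param genome_sizes Optional; see [assign_bins()].
#' @return A long tibble `tss_id`, `bin`, `score_sum`, `n_bases` containing
#'   only cells with at least one scored base.
#' @export
bin_track <- function(tss, track, genome_sizes = NULL) {
  tss <- drop_edge_tss(tss, genome_sizes)
  J <- bin_indices()
  cells <- tidyr::expand_grid(
    tibble(tss_id = tss$id, chrom = tss$chrom,
           tss_position = tss$position, strand = tss$strand),
    bin = J
  )
  b <- bin_genomic_bounds(cells$tss_position, cells$strand, cells$bin)
  cells$start <- b$start
  cells$end <- b$end
  hit <- dplyr::inner_join(
    cells, as_tibble(track),
    by = dplyr::join_by(chrom, x$start < y$end, x$end > y$start),
    suffix = c("", ".trk")
  )
  ov <- pmin(hit$end, hit$end.trk) - pmax(hit$start, hit$start.trk)
  hit$score_sum <- hit$value * ov
  hit$n_bases <- ov
  hit %>%
    dplyr::group_by(.data$tss_id, .data$bin) %>%
    dplyr::summarise(score_sum = sum(.data$score_sum),
                     n_bases = sum(.data$n_bases), .groups = "drop")
}

#' Bin-average track profiles (BNP, BGS, BBS, BCS)
#'
#' Three aggregation modes cover the pooled bin-average statistics:
#' \describe{
#'   \item{`pooled_base_mean`}{(nucleosome BNP, GERP BGS) per bin j:
#'     `sum_i score(i, j) / sum_i n_bases(i, j)` over scored bases, pooled
#'     across TSSs; bins with no scored base are missing. The reported SE is
#'     the across-TSS SE of the per-TSS bin means.}
#'   \item{`per_tss_base_fraction`}{(gBGC BBS) per-TSS fraction of the 50 bin
#'     bases covered by a tract, averaged over *all* TSSs (absent cells count
#'     as 0).}
#'   \item{`pooled_variant_mean`}{(CADD BCS) mean per-variant score over all
#'     variants assigned to bin j across TSSs; requires `assignments` with a
#'     `raw_score` column.}
#' }
#'
#' @param tss TSS tibble.
#' @param track A `tssvar_track`, or `NULL` for `pooled_variant_mean`.
#' @param mode One of the three modes above.
#' @param assignments For `pooled_variant_mean`: [assign_bins()] output joined
#'   with per-variant scores (column `raw_score`), restricted to the class of
#'   interest.
#' @param genome_sizes Optional; see [assign_bins()].
#' @return A `bin_profile` tibble.
#' @export
track_profile <- function(tss, track,
                          mode = c("pooled_base_mean", "per_tss_base_fraction",
                                   "pooled_variant_mean"),
                          assignments = NULL, genome_sizes = NULL) {
  mode <- rlang::arg_match(mode)
  J <- bin_indices()
  if (mode == "pooled_variant_mean") {
    if (is.null(assignments) || is.null(assignments$raw_score)) {
      abort("mode 'pooled_variant_mean' needs `assignments` with a raw_score column.")
    }
    agg <- assignments %>%
      dplyr::group_by(.data$bin) %>%
      dplyr::summarise(mean = mean(.data$raw_score),
                       se = sd(.data$raw_score) / sqrt(dplyr::n()),
                       n = dplyr::n(), .groups = "drop")
    idx <- match(J, agg$bin)
    return(new_bin_profile(agg$mean[idx], agg$se[idx],
                           ifelse(is.na(idx), 0L, agg$n[idx]), "BCS"))
  }
  binned <- bin_track(tss, track, genome_sizes)
  n_tss <- length(unique(drop_edge_tss(tss, genome_sizes)$id))
  semantics <- attr(track, "semantics")
  profile_from_binned(binned, mode, n_tss, semantics)
}

# shared back-end for track_profile(); also called by the pipeline, which
# reuses one bin_track() result for both the profile and the per-TSS matrix
profile_from_binned <- function(binned, mode, n_tss, semantics = "per_base_signal") {
  J <- bin_indices()
  if (mode == "pooled_base_mean") {
    agg <- binned %>%
      dplyr::group_by(.data$bin) %>%
      dplyr::summarise(mean = sum(.data$score_sum) / sum(.data$n_bases),
                       se = sd(.data$score_sum / .data$n_bases) /
                         sqrt(dplyr::n()),
                       n = sum(.data$n_bases), .groups = "drop")
    idx <- match(J, agg$bin)
    sig <- if (identical(semantics, "base_membership")) "BBS" else "BNP"
    new_bin_profile(agg$mean[idx], agg$se[idx],
                    ifelse(is.na(idx), 0L, agg$n[idx]), sig)
  } else {
    frac <- binned$score_sum / BIN_WIDTH
    sums <- as.numeric(tapply(frac, factor(binned$bin, levels = J), sum, default = 0))
    sq <- as.numeric(tapply(frac^2, factor(binned$bin, levels = J), sum, default = 0))
    mean <- sums / n_tss
    var <- (sq - n_tss * mean^2) / (n_tss - 1)   # absent cells are exact zeros
    new_bin_profile(mean, sqrt(pmax(var, 0) / n_tss), rep(n_tss, N_BINS), "BBS")
  }
}

#' Per-TSS x per-bin track value matrix
#'
#' Spreads [bin_track()] output into a matrix of per-TSS bin values for the
#' two-sample per-bin tests: `statistic = "mean"` gives score_sum / n_bases
#' (NA where no base is scored), `"fraction"` gives score_sum / 50 with
#' absent cells as 0.
#'
#' @param binned Output of [bin_track()].
#' @param tss_ids Row universe.
#' @param statistic `"mean"` or `"fraction"`.
#' @return A numeric matrix, rows `tss_ids`, columns the 200 bins.
#' @export
bin_value_matrix <- function(binned, tss_ids, statistic = c("mean", "fraction")) {
  statistic <- rlang::arg_match(statistic)
  J <- bin_indices()
  fill <- if (statistic == "mean") NA_real_ else 0
  mat <- matrix(fill, nrow = length(tss_ids), ncol = N_BINS,
                dimnames = list(tss_ids, as.character(J)))
  ri <- match(binned$tss_id, tss_ids)
  ci <- match(binned$bin, J)
  ok <- !is.na(ri) & !is.na(ci)
  val <- if (statistic == "mean") {
    binned$score_sum / binned$n_bases
  } else {
    binned$score_sum / BIN_WIDTH
  }
  mat[cbind(ri[ok], ci[ok])] <- val[ok]
  mat
}

`%||%` <- rlang::`%||%`
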