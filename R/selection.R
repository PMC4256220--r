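# Inclusion filters and classifications: variant filtering, MAF and frequency
# classes, CpG-island prediction and overlap, multi-TSS exclusion, and the
# in-window vs genome-wide density contrast.

#' Filter variants to robust bi-allelic 1000 Genomes SNPs
#'
#' Keeps records satisfying all of: the `submitters` field contains
#' `"1000GENOMES"`; the dbSNP `class` is `"single"`; `alleleFreqCount` is 2;
#' both allele counts are greater than 0; and their sum exceeds 1000 (strict).
#' The per-criterion rejection tally (number of records failing each
#' criterion, not mutually exclusive) is attached as attribute `"rejections"`
#' and is also available through [filter_tally()].
#'
#' @param variants A tibble as returned by [read_variant_table()].
#' @return The kept subset, with a `"rejections"` attribute.
#' @export
filter_variants <- function(variants) {
  n1 <- variants$allele_n1
  n2 <- variants$allele_n2
  crit <- cbind(
    submitters_1000genomes = grepl("1000GENOMES", variants$submitters, fixed = TRUE),
    class_single           = variants$var_class == "single",
    allele_freq_count_2    = variants$allele_freq_count == 2L,
    both_allele_ns_positive = !is.na(n1) & !is.na(n2) & n1 > 0 & n2 > 0,
    allele_ns_sum_gt_1000  = !is.na(n1) & !is.na(n2) & (n1 + n2) > 1000
  )
  crit[is.na(crit)] <- FALSE
  keep <- rowSums(crit) == ncol(crit)
  tally <- colSums(!crit)
  out <- variants[keep, , drop = FALSE]
  attr(out, "rejections") <- c(tally, n_input = nrow(variants), n_kept = sum(keep))
  out
}

#' @rdname filter_variants
#' @param filtered The tibble returned by [filter_variants()].
#' @export
filter_tally <- function(filtered) attr(filtered, "rejections")

#' Minor allele frequency from a pair of allele counts
#'
#' MAF = min(a, b) / (a + b). Vectorized; both counts must be positive.
#'
#' @param allele_n1,allele_n2 Positive allele counts.
#' @return MAF values in (0, 0.5].
#' @examples
#' compute_maf(1, 2183)   # one carrier chromosome among 2184
#' @export
compute_maf <- function(allele_n1, allele_n2) {
  if (any(allele_n1 <= 0 | allele_n2 <= 0, na.rm = TRUE)) {
    abort("Allele counts must both be > 0 to define a MAF.")
  }
  pmin(allele_n1, allele_n2) / (allele_n1 + allele_n2)
}

#' Default rare-MAF threshold
#'
#' The lowest MAF attainable in a phased panel of `n_individuals` diploid
#' samples: a single heterozygous carrier, `1 / (2 * n_individuals)`.
#'
#' @param n_individuals Panel size (default 1092, the 1000 Genomes Phase 1
#'   release).
#' @return A single MAF value.
#' @export
rare_maf_threshold <- function(n_individuals = 1092) {
  1 / (2 * n_individuals)
}

#' Derive the four frequency-class boundaries
#'
#' Classes partition (0, 0.5]: `rare` = (0, rare_threshold],
#' `common` = (common_threshold, 0.5], and the intermediate variants split at
#' their median MAF into `mid1` = (rare_threshold, median] and
#' `mid2` = (median, common_threshold], giving two groups of equal size
#' (within 1 for odd counts; ties at the median all fall in `mid1`).
#'
#' @param mafs MAF values of all selected variants.
#' @param rare_threshold Upper bound (inclusive) of the rare class; defaults
#'   to [rare_maf_threshold()].
#' @param common_threshold Lower bound (exclusive) of the common class.
#' @return A tibble with columns `class`, `lower` (exclusive), `upper`
#'   (inclusive).
#' @export
derive_class_boundaries <- function(mafs,
                                    rare_threshold = rare_maf_threshold(),
                                    common_threshold = 0.01) {
  stopifnot(length(mafs) > 0, rare_threshold < common_threshold)
  mid <- mafs[mafs > rare_threshold & mafs <= common_threshold]
  if (length(mid) == 0) {
    abort("No variants with intermediate MAF; cannot place the mid1/mid2 boundary.")
  }
  m <- stats::median(mid)
  if (sum(mid > m) == 0 && length(mid) > 1) {
    warn("mid2 class is empty: all intermediate MAFs are at or below the median.")
  }
  if (length(mid) == 1) {
    warn("Single intermediate variant: mid2 class is empty.")
  }
  tibble(
    class = c("rare", "mid1", "mid2", "common"),
    lower = c(0, rare_threshold, m, common_threshold),
    upper = c(rare_threshold, m, common_threshold, 0.5)
  )
}

#' Assign frequency-class labels
#'
#' Each MAF gets the unique class whose interval (lower, upper] contains it.
#'
#' @param maf MAF values in (0, 0.5].
#' @param boundaries A boundary table from [derive_class_boundaries()].
#' @return A factor with levels `rare`, `mid1`, `mid2`, `common`.
#' @export
assign_class <- function(maf, boundaries) {
  stopifnot(all(maf > 0 & maf <= 0.5, na.rm = TRUE))
  idx <- findInterval(maf, boundaries$upper, left.open = TRUE) + 1L
  idx[idx > nrow(boundaries)] <- NA_integer_
  factor(boundaries$class[idx], levels = boundaries$class)
}

# -- CpG island prediction ----------------------------------------------------

# maximum-scoring contiguous run of s[lo..hi]; ties resolved smallest start,
# then smallest end. Linear scan over prefix sums; the O(L^2) enumeration in
# the test suite uses the same tie rules.
max_segment <- function(cum, lo, hi) {
  # segment [a, b] has score cum[b + 1] - cum[a]; a,b are 1-based in s
  best_score <- -Inf
  best_a <- best_b <- NA_integer_
  min_pref <- Inf
  min_at <- NA_integer_
  for (b in lo:hi) {
    pref <- cum[b]          # cum index b == sum of s[1..b-1]
    if (pref < min_pref) {  # strict: keeps the earliest minimal prefix
      min_pref <- pref
      min_at <- b
    }
    sc <- cum[b + 1] - min_pref
    if (sc > best_score) {
      best_score <- sc
      best_a <- min_at
      best_b <- b
    }
  }
  list(a = best_a, b = best_b, score = best_score)
}

segment_candidates <- function(cum, lo, hi) {
  if (lo > hi) return(NULL)
  seg <- max_segment(cum, lo, hi)
  if (seg$score <= 0) return(NULL)
  c(list(seg),
    segment_candidates(cum, lo, seg$a - 1L),
    segment_candidates(cum, seg$b + 1L, hi))
}

#' Predict CpG islands from sequence
#'
#' Scores each dinucleotide (+17 for CG, -1 for anything else, including
#' dinucleotides containing N), extracts maximally scoring segments
#' (recursively: best segment, then left and right remainders), and keeps
#' segments with GC fraction >= 0.5, length > 200 bp, and observed/expected
#' CpG ratio > 0.6, where expected = (#C x #G) / length.
#'
#' @param sequence A DNA string over `A`, `C`, `G`, `T`, `N`.
#' @param chrom Chromosome name to stamp on the result.
#' @return A tibble of 0-based half-open intervals (`chrom`, `start`, `end`),
#'   ordered by start; zero rows when nothing qualifies.
#' @export
predict_cgi <- function(sequence, chrom = "seq") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 2) return(tibble(chrom = character(), start = integer(), end = integer()))
  base <- strsplit(sequence, "", fixed = TRUE)[[1]]
  is_cg <- base[-L] == "C" & base[-1] == "G"
  s <- ifelse(is_cg, 17, -1)
  cum <- c(0, cumsum(s))
  segs <- segment_candidates(cum, 1L, L - 1L)
  if (is.null(segs)) return(tibble(chrom = character(), start = integer(), end = integer()))
  keep <- purrr::keep(segs, function(seg) {
    bases <- base[seg$a:(seg$b + 1L)]
    len <- length(bases)
    n_c <- sum(bases == "C")
    n_g <- sum(bases == "G")
    obs <- sum(bases[-len] == "C" & bases[-1] == "G")
    expd <- n_c * n_g / len
    gc_ok <- (n_c + n_g) / len >= 0.5
    ratio_ok <- is.finite(obs / expd) && obs / expd > 0.6
    gc_ok && len > 200 && ratio_ok
  })
  if (length(keep) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  out <- tibble(
    chrom = chrom,
    start = vapply(keep, function(s) s$a - 1L, integer(1)),
    end = vapply(keep, function(s) s$b + 1L, integer(1))
  )
  dplyr::arrange(out, .data$start)
}

# -- TSS classification -------------------------------------------------------

#' Classify TSSs by CpG-island context
#'
#' A TSS is a CGI-TSS iff its position lies in `[start, end)` of some island.
#' For CGI-TSSs the signed distance from the island center
#' (`position - floor((start + end) / 2)`, sign flipped on the minus strand so
#' positive means downstream of the center) is reported. When a TSS falls in
#' several overlapping islands the first by coordinate is used, with a warning.
#'
#' @param tss TSS tibble (`id`, `chrom`, `position`, `strand`, ...).
#' @param cgi Island intervals (`chrom`, `start`, `end`).
#' @return `tss` with added columns `cgi_status` (`"CGI"`/`"nCGI"`) and
#'   `cgi_center_distance` (NA for nCGI).
#' @export
classify_tss <- function(tss, cgi) {
  if (nrow(cgi) == 0) {
    return(dplyr::mutate(tss, cgi_status = "nCGI", cgi_center_distance = NA_real_))
  }
  cgi <- dplyr::arrange(cgi, .data$chrom, .data$start, .data$end)
  hits <- dplyr::inner_join(
    dplyr::mutate(tss, .row = dplyr::row_number()),
    cgi,
    by = dplyr::join_by(chrom, x$position >= y$start, x$position < y$end)
  )
  if (anyDuplicated(hits$.row)) {
    warn("TSS inside multiple overlapping CpG islands; using the first by coordinate.")
    # the join preserves the coordinate-sorted island order within each TSS
    hits <- hits[!duplicated(hits$.row), ]
  }
  center <- floor((hits$start + hits$end) / 2)
  dist <- (hits$position - center) * ifelse(hits$strand == "-", -1, 1)
  out <- dplyr::mutate(tss, cgi_status = "nCGI", cgi_center_distance = NA_real_)
  out$cgi_status[hits$.row] <- "CGI"
  out$cgi_center_distance[hits$.row] <- dist
  out
}

#' Drop TSSs whose region hosts two or more TSSs
#'
#' A TSS is retained iff no other input TSS (retained or not) lies within
#' `[position - half_window, position + half_window]` on the same chromosome.
#' Proximity is judged against the full pre-exclusion list.
#'
#' @param tss TSS tibble.
#' @param half_window Half-window in bp (default 5000, the profile half-span).
#' @return The retained subset, original order preserved.
#' @export
exclude_multi_tss <- function(tss, half_window = 5000) {
  keep <- rep(TRUE, nrow(tss))
  for (chrom in unique(tss$chrom)) {
    idx <- which(tss$chrom == chrom)
    if (length(idx) < 2) next
    p <- tss$position[idx]
    ord <- order(p)
    ps <- p[ord]
    gap_prev <- c(Inf, diff(ps))
    gap_next <- c(diff(ps), Inf)
    crowded <- pmin(gap_prev, gap_next) <= half_window
    keep[idx[ord]] <- !crowded
  }
  tss[keep, , drop = FALSE]
}

#' Variant density inside vs outside the TSS windows
#'
#' Windows of `2 * half_window` bp centered on each TSS are merged into a
#' per-chromosome union; variants falling in the union define `density_in`
#' (variants per bp), the remainder of the genome defines `density_out`.
#'
#' @param variants Variant tibble (`chrom`, `position`).
#' @param tss TSS tibble.
#' @param genome_sizes Tibble with columns `chrom`, `size` (total bp).
#' @param half_window Half-window in bp.
#' @return A tibble with one row: `density_in`, `density_out`, `n_in`,
#'   `n_out`, `bp_in`, `bp_out`.
#' @export
density_contrast <- function(variants, tss, genome_sizes, half_window = 5000) {
  win <- tibble(chrom = tss$chrom,
                start = pmax(0L, tss$position - as.integer(half_window)),
                end = tss$position + as.integer(half_window))
  union <- merge_intervals(win)
  union <- dplyr::left_join(union, genome_sizes, by = "chrom")
  union$end <- pmin(union$end, union$size)
  bp_in <- sum(as.numeric(union$end - union$start))
  bp_total <- sum(as.numeric(genome_sizes$size))
  bp_out <- bp_total - bp_in
  if (bp_out <= 0) abort("TSS windows cover the whole genome; no complement left.")
  inside <- dplyr::semi_join(
    dplyr::mutate(variants, .row = dplyr::row_number()), union,
    by = dplyr::join_by(chrom, x$position >= y$start, x$position < y$end)
  )
  n_in <- nrow(inside)
  n_out <- nrow(variants) - n_in
  tibble(density_in = n_in / bp_in, density_out = n_out / bp_out,
         n_in = n_in, n_out = n_out, bp_in = bp_in, bp_out = bp_out)
}

# union of possibly-overlapping intervals, per chromosome
merge_intervals <- function(iv) {
  iv <- dplyr::arrange(iv, .data$chrom, .data$start, .data$end)
  iv %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(.grp = cumsum(.data$start > dplyr::lag(cummax(as.numeric(.data$end)),
                                                         default = -Inf))) %>%
    dplyr::group_by(.data$chrom, .data$.grp) %>%
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") %>%
    dplyr::select("chrom", "start", "end")
}
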