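# Readers and writers for the external file dialects the pipeline touches.
#
# Coordinate conventions, used everywhere in the package:
#   * all coordinates are 0-based; intervals are half-open [start, end)
#   * UCSC-style table "start" fields are already 0-based and adopted as-is
#   * TSS point = the "start" coordinate of the record regardless of strand
#     (the source track stores point features)

# -- generic line-oriented TSV reader ----------------------------------------
# Returns a list of character column vectors plus original line numbers, so
# parse errors can name the offending physical line. Lines starting with "#"
# and blank lines are skipped.
read_delim_lines <- function(path, n_min_fields, what) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  if (length(line_no) == 0) {
    return(list(fields = vector("list", 0), line_no = integer(0), n = 0L))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < n_min_fields)) {
    bad <- which(nf < n_min_fields)[1]
    abort_parse(path, line_no[bad], sprintf(
      "%s row has %d field(s), expected at least %d", what, nf[bad], n_min_fields
    ))
  }
  # fast column extraction when the table is rectangular
  cols <- if (length(unique(nf)) == 1L) {
    flat <- unlist(parts, use.names = FALSE)
    lapply(seq_len(nf[1]), function(i) flat[seq(i, by = nf[1], length.out = length(parts))])
  } else {
    lapply(seq_len(n_min_fields), function(i) vapply(parts, `[[`, character(1), i))
  }
  list(fields = cols, line_no = line_no, n = length(parts))
}

parse_numeric_col <- function(x, path, line_no, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(x %in% c("NA", ""))
  if (any(bad)) {
    i <- which(bad)[1]
    abort_parse(path, line_no[i], sprintf("non-numeric value '%s' in column '%s'", x[i], col))
  }
  out
}

# -- TSS table ----------------------------------------------------------------

#' Read a UCSC-style TSS table
#'
#' Reads a tab-separated table of transcription start sites with columns
#' `chrom, start, end, name, score, strand` (no header, or a header line
#' starting with `#`). The TSS point is the 0-based `start` coordinate.
#' Records on alternative-haplotype chromosomes (`*_hap*`, `*_alt*`) are
#' dropped with a message.
#'
#' @param path Path to the tab-separated file.
#' @param min_score Minimum confidence score; records with `score < min_score`
#'   are dropped. The conservative default of 20 keeps only well-supported
#'   sites.
#' @return A tibble with columns `id`, `chrom`, `position` (0-based bp),
#'   `strand` (`"+"` or `"-"`) and `score`, in file order.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t1000\t1001\ttss1\t35\t+", f)
#' read_tss_table(f)
#' @export
read_tss_table <- function(path, min_score = 20) {
  stopifnot(min_score >= 0)
  tab <- read_delim_lines(path, 6L, "TSS")
  if (tab$n == 0L) {
    return(tibble(id = character(), chrom = character(), position = integer(),
                  strand = character(), score = double()))
  }
  start <- parse_numeric_col(tab$fields[[2]], path, tab$line_no, "start")
  score <- parse_numeric_col(tab$fields[[5]], path, tab$line_no, "score")
  strand <- tab$fields[[6]]
  bad_strand <- !(strand %in% c("+", "-"))
  if (any(bad_strand)) {
    i <- which(bad_strand)[1]
    abort_parse(path, tab$line_no[i], sprintf("unknown strand symbol '%s'", strand[i]))
  }
  out <- tibble(
    id = tab$fields[[4]], chrom = tab$fields[[1]],
    position = as.integer(start), strand = strand, score = score
  )
  out <- drop_alt_chroms(out, "TSS")
  out[out$score >= min_score, ]
}

# -- variant table ------------------------------------------------------------

#' Read a dbSNP-style variant table
#'
#' Reads a tab-separated variant table with columns `chrom, position, name,
#' class, submitters, alleleFreqCount, alleleNs`. `alleleNs` holds
#' comma-separated allele counts; when exactly two are present they are parsed
#' into `allele_n1`/`allele_n2`. No filtering is applied here (see
#' [filter_variants()]); alternative-haplotype chromosomes are dropped.
#'
#' @param path Path to the tab-separated file.
#' @return A tibble with columns `id`, `chrom`, `position`, `var_class`,
#'   `submitters`, `allele_freq_count`, `allele_n1`, `allele_n2` (NA unless
#'   `alleleNs` has exactly two entries).
#' @export
read_variant_table <- function(path) {
  tab <- read_delim_lines(path, 7L, "variant")
  if (tab$n == 0L) {
    return(tibble(id = character(), chrom = character(), position = integer(),
                  var_class = character(), submitters = character(),
                  allele_freq_count = integer(),
                  allele_n1 = double(), allele_n2 = double()))
  }
  position <- parse_numeric_col(tab$fields[[2]], path, tab$line_no, "position")
  afc <- parse_numeric_col(tab$fields[[6]], path, tab$line_no, "alleleFreqCount")
  ns <- strsplit(tab$fields[[7]], ",", fixed = TRUE)
  ns_num <- suppressWarnings(lapply(ns, as.numeric))
  bad <- vapply(ns_num, function(v) anyNA(v), logical(1))
  if (any(bad)) {
    i <- which(bad)[1]
    abort_parse(path, tab$line_no[i],
                sprintf("non-numeric alleleNs value '%s'", tab$fields[[7]][i]))
  }
  two <- lengths(ns_num) == 2L
  out <- tibble(
    id = tab$fields[[3]], chrom = tab$fields[[1]],
    position = as.integer(position), var_class = tab$fields[[4]],
    submitters = tab$fields[[5]], allele_freq_count = as.integer(afc),
    allele_n1 = ifelse(two, vapply(ns_num, `[`, numeric(1), 1), NA_real_),
    allele_n2 = ifelse(two, vapply(ns_num, function(v) if (length(v) >= 2) v[2] else NA_real_, numeric(1)), NA_real_)
  )
  drop_alt_chroms(out, "variant")
}

# -- BED ----------------------------------------------------------------------

#' Read a BED3+ interval file
#'
#' Intervals are 0-based half-open; columns beyond the third are ignored.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, in file order.
#' @export
read_bed <- function(path) {
  tab <- read_delim_lines(path, 3L, "BED")
  if (tab$n == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  start <- parse_numeric_col(tab$fields[[2]], path, tab$line_no, "start")
  end <- parse_numeric_col(tab$fields[[3]], path, tab$line_no, "end")
  bad <- end <= start
  if (any(bad)) {
    i <- which(bad)[1]
    abort_parse(path, tab$line_no[i],
                sprintf("interval end (%g) <= start (%g)", end[i], start[i]))
  }
  out <- tibble(chrom = tab$fields[[1]], start = as.integer(start), end = as.integer(end))
  drop_alt_chroms(out, "BED")
}

# -- bedGraph -----------------------------------------------------------------

#' Read a bedGraph score track
#'
#' Lines are `chrom start end value` with 0-based half-open intervals: every
#' base in `[start, end)` receives `value`. Overlapping records are resolved
#' last-one-wins (file order) with a warning.
#'
#' @param path Path to a bedGraph file.
#' @return A `tssvar_track` tibble with columns `chrom`, `start`, `end`,
#'   `value` and disjoint intervals per chromosome; attribute `semantics` is
#'   `"per_base_signal"`.
#' @export
read_bedgraph <- function(path) {
  tab <- read_delim_lines(path, 4L, "bedGraph")
  if (tab$n == 0L) {
    return(new_score_track(tibble(chrom = character(), start = integer(),
                                  end = integer(), value = double())))
  }
  start <- parse_numeric_col(tab$fields[[2]], path, tab$line_no, "start")
  end <- parse_numeric_col(tab$fields[[3]], path, tab$line_no, "end")
  value <- parse_numeric_col(tab$fields[[4]], path, tab$line_no, "value")
  bad <- end <= start
  if (any(bad)) {
    i <- which(bad)[1]
    abort_parse(path, tab$line_no[i],
                sprintf("interval end (%g) <= start (%g)", end[i], start[i]))
  }
  if (any(!is.finite(value))) {
    i <- which(!is.finite(value))[1]
    abort_parse(path, tab$line_no[i], "non-finite score value")
  }
  trk <- tibble(chrom = tab$fields[[1]], start = as.integer(start),
                end = as.integer(end), value = value)
  trk <- drop_alt_chroms(trk, "bedGraph")
  new_score_track(resolve_track_overlaps(trk))
}

new_score_track <- function(df, semantics = "per_base_signal") {
  structure(df, class = c("tssvar_track", class(tibble())), semantics = semantics)
}

#' Treat BED intervals as a base-membership track
#'
#' Every base inside an interval scores 1 (implicit membership score); bases
#' outside score 0. Used for gBGC tract coverage fractions.
#'
#' @param bed A tibble of intervals as returned by [read_bed()].
#' @return A `tssvar_track` with `value = 1` and `semantics = "base_membership"`.
#' @export
as_membership_track <- function(bed) {
  new_score_track(dplyr::mutate(bed, value = 1), semantics = "base_membership")
}

# split overlapping records into disjoint intervals, later records winning
resolve_track_overlaps <- function(trk) {
  if (nrow(trk) == 0) return(trk)
  trk$.ord <- seq_len(nrow(trk))
  has_overlap <- function(d) {
    d <- d[order(d$start, d$end), ]
    any(d$start[-1] < cummax(d$end)[-nrow(d)])
  }
  by_chrom <- split(trk, trk$chrom)
  bad <- vapply(by_chrom, has_overlap, logical(1))
  if (!any(bad)) {
    trk$.ord <- NULL
    return(trk)
  }
  warn("Overlapping bedGraph records: later records override earlier ones.")
  fixed <- lapply(by_chrom, function(d) {
    if (!has_overlap(d)) {
      return(d)
    }
    bounds <- sort(unique(c(d$start, d$end)))
    seg <- tibble(chrom = d$chrom[1],
                  start = bounds[-length(bounds)], end = bounds[-1])
    hit <- dplyr::inner_join(
      seg, d,
      by = dplyr::join_by(chrom, x$start < y$end, x$end > y$start),
      suffix = c("", ".rec")
    )
    hit <- dplyr::slice_max(dplyr::group_by(hit, .data$start), .data$.ord,
                            n = 1, with_ties = FALSE)
    dplyr::select(dplyr::ungroup(hit), "chrom", "start", "end", "value", ".ord")
  })
  out <- dplyr::arrange(dplyr::bind_rows(fixed), .data$.ord, .data$start)
  # merge adjacent equal-value segments back together
  out$.ord <- NULL
  out
}

# -- CADD per-variant scores --------------------------------------------------

#' Read a per-variant CADD score table
#'
#' Columns: `chrom, pos, ref, alt, raw, scaled` (tab-separated, 0-based
#' positions as used throughout the package).
#'
#' @param path Path to the score file.
#' @return A tibble with columns `chrom`, `position`, `ref`, `alt`,
#'   `raw_score`, `scaled_score`.
#' @export
read_cadd_table <- function(path) {
  tab <- read_delim_lines(path, 6L, "CADD")
  if (tab$n == 0L) {
    return(tibble(chrom = character(), position = integer(), ref = character(),
                  alt = character(), raw_score = double(), scaled_score = double()))
  }
  pos <- parse_numeric_col(tab$fields[[2]], path, tab$line_no, "pos")
  raw <- parse_numeric_col(tab$fields[[5]], path, tab$line_no, "raw")
  scaled <- parse_numeric_col(tab$fields[[6]], path, tab$line_no, "scaled")
  out <- tibble(chrom = tab$fields[[1]], position = as.integer(pos),
                ref = tab$fields[[3]], alt = tab$fields[[4]],
                raw_score = raw, scaled_score = scaled)
  drop_alt_chroms(out, "CADD")
}

# -- profile TSV round-trip ---------------------------------------------------

profile_columns <- c("bin", "offset_bp", "mean", "se", "ci_lo", "ci_hi",
                     "p", "p_adj", "significant", "n")

#' Write a 200-bin profile to TSV
#'
#' One row per bin with bin index, genomic offset, mean, SE, the 2-SE
#' confidence bounds, raw and adjusted p-values and the significance flag.
#' Values are written with 15 significant digits so a round-trip read
#' reproduces them; missing cells are written as `NA`.
#'
#' @param profile A profile tibble (see [bvf_profile()] or [neutral_bin_test()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(nrow(profile) == 200)
  df <- as_tibble(profile)
  for (col in profile_columns) if (is.null(df[[col]])) df[[col]] <- NA
  df <- df[profile_columns]
  fmt <- vapply(df, function(x) {
    if (is.numeric(x)) sprintf("%.15g", x) else as.character(x)
  }, FUN.VALUE = character(nrow(df)))
  fmt[is.na(df)] <- "NA"
  lines <- c(paste0("#", paste(profile_columns, collapse = "\t")),
             apply(fmt, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a profile TSV written by [write_profile_tsv()]
#'
#' @param path Path to the TSV.
#' @return A profile tibble with the standard columns.
#' @export
read_profile_tsv <- function(path) {
  tab <- read_delim_lines(path, length(profile_columns), "profile")
  vals <- lapply(seq_along(profile_columns), function(i) {
    x <- tab$fields[[i]]
    if (profile_columns[i] == "significant") {
      out <- rep(NA, length(x))
      out[x %in% c("TRUE", "FALSE")] <- as.logical(x[x %in% c("TRUE", "FALSE")])
      out
    } else {
      parse_numeric_col(x, path, tab$line_no, profile_columns[i])
    }
  })
  names(vals) <- profile_columns
  out <- as_tibble(vals)
  out$bin <- as.integer(out$bin)
  out$n <- as.integer(out$n)
  out
}

# -- writers for the synthetic bundle ----------------------------------------

#' Write tables in the dialects the readers consume
#'
#' `write_tss_table()`, `write_variant_table()`, `write_bed()`,
#' `write_bedgraph()` and `write_cadd_table()` emit exactly the formats
#' [read_tss_table()] and friends read, each with a `#`-prefixed header line.
#'
#' @param tss,variants,bed,track,cadd Tibbles in the package's internal
#'   column layout (see the corresponding reader).
#' @param path Output path.
#' @return `path`, invisibly.
#' @name bundle_writers
NULL

#' @rdname bundle_writers
#' @export
write_tss_table <- function(tss, path) {
  lines <- c("#chrom\tstart\tend\tname\tscore\tstrand",
             sprintf("%s\t%d\t%d\t%s\t%.15g\t%s", tss$chrom, tss$position,
                     tss$position + 1L, tss$id, tss$score, tss$strand))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname bundle_writers
#' @export
write_variant_table <- function(variants, path) {
  lines <- c("#chrom\tposition\tname\tclass\tsubmitters\talleleFreqCount\talleleNs",
             sprintf("%s\t%d\t%s\t%s\t%s\t%d\t%.15g,%.15g",
                     variants$chrom, variants$position, variants$id,
                     variants$var_class, variants$submitters,
                     variants$allele_freq_count,
                     variants$allele_n1, variants$allele_n2))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname bundle_writers
#' @export
write_bed <- function(bed, path) {
  lines <- c("#chrom\tstart\tend",
             sprintf("%s\t%d\t%d", bed$chrom, bed$start, bed$end))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname bundle_writers
#' @export
write_bedgraph <- function(track, path) {
  lines <- c("#chrom\tstart\tend\tvalue",
             sprintf("%s\t%d\t%d\t%.15g", track$chrom, track$start,
                     track$end, track$value))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname bundle_writers
#' @export
write_cadd_table <- function(cadd, path) {
  lines <- c("#chrom\tpos\tref\talt\traw\tscaled",
             sprintf("%s\t%d\t%s\t%s\t%.15g\t%.15g", cadd$chrom, cadd$position,
                     cadd$ref, cadd$alt, cadd$raw_score, cadd$scaled_score))
  writeLines(lines, path)
  invisible(path)
}
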