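# Synthetic input generator. Produces every dialect the readers consume,
# with configurable positional structure: per-class enrichment peaks, a
# rare-vs-common asymmetry (the BVF-delta signal) coupled to gBGC tracts
# inside a configurable half-width and to the conservation track outside it,
# a nucleosome track coupled to the rare-class intensity, and per-variant
# deleteriousness scores with class means and a distance decay.

#' Configuration for the synthetic dataset
#'
#' Defaults emulate the scale and effect structure seen in real TSS-flanking
#' variant data: ~95 variants per 10 kb window split across the four
#' frequency classes roughly 21/23/23/33%, a 1.7-fold rare-class enrichment
#' over the first four downstream bins (the first ~200 transcribed bp), an
#' inner region of 14 bins (~700 bp) where the rare-minus-common contrast is
#' negatively coupled to gBGC tract coverage, an outer region where it is
#' positively coupled to conservation, and a nucleosome track positively
#' coupled to the rare-class intensity.
#'
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the config.
#' @param n_tss Number of TSSs.
#' @param n_chromosomes Chromosomes to spread the TSSs over.
#' @param frac_cgi Fraction of TSSs placed inside a generated CpG island.
#' @param prob_plus Probability of the + strand.
#' @param tss_spacing,tss_jitter,margin TSS placement: sites sit
#'   `tss_spacing` bp apart (>= 10 kb keeps windows disjoint and every region
#'   single-TSS) with uniform jitter of `+/- tss_jitter`, starting `margin`
#'   bp from the chromosome start.
#' @param class_intensity Named vector: expected variants per TSS window for
#'   each class.
#' @param modifiers List of `list(bins=, classes=, fold=)` positional
#'   intensity modifiers (fold > 0).
#' @param delta_amplitude Amplitude `a` of the rare/common asymmetry:
#'   per-bin rare intensity is multiplied by `1 + a * z(j)` and common by
#'   `1 - a * z(j)`, where `z` is a smooth unit-amplitude shape.
#' @param inner_half_width Bins `|j| <=` this form the inner (gBGC-coupled)
#'   region; the outer shape drives the conservation coupling.
#' @param bbs_coupling,bgs_coupling,nuc_coupling Coupling strengths linking
#'   the gBGC coverage (negatively, inner), the conservation track
#'   (positively, outer) and the nucleosome track (positively, rare class) to
#'   the planted intensity structure. Set to 0 to decouple.
#' @param nuc_noise,gerp_noise,bbs_noise,cadd_noise Gaussian noise SDs for
#'   the tracks and scores.
#' @param cadd_class_mean Named vector of raw-score class means.
#' @param cadd_slope Per-bp decay of the raw score with distance from the
#'   TSS.
#' @param n_individuals Diploid panel size used to build allele counts
#'   (default 1092).
#' @param null_model If `TRUE`, zero out all modifiers, the delta amplitude
#'   and every coupling: variants are placed uniformly, tracks carry only
#'   their base profiles.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_tss = 2000L,
                             n_chromosomes = 2L,
                             frac_cgi = 0.5,
                             prob_plus = 0.5,
                             tss_spacing = 12000L,
                             tss_jitter = 400L,
                             margin = 6000L,
                             class_intensity = c(rare = 20, mid1 = 22,
                                                 mid2 = 22, common = 31),
                             modifiers = list(list(bins = 1:4,
                                                   classes = "rare",
                                                   fold = 1.7)),
                             delta_amplitude = 0.35,
                             inner_half_width = 14L,
                             bbs_coupling = 0.1,
                             bgs_coupling = 0.3,
                             nuc_coupling = 0.4,
                             nuc_noise = 0.1,
                             gerp_noise = 0.1,
                             bbs_noise = 0.03,
                             cadd_noise = 0.25,
                             cadd_class_mean = c(rare = 0.9, mid1 = 0.7,
                                                 mid2 = 0.5, common = 0.3),
                             cadd_slope = 8e-5,
                             n_individuals = 1092L,
                             null_model = FALSE) {
  if (null_model) {
    modifiers <- list()
    delta_amplitude <- 0
    bbs_coupling <- bgs_coupling <- nuc_coupling <- 0
    # fully neutral scores too: no class effect, no distance decay
    cadd_class_mean[] <- mean(cadd_class_mean)
    cadd_slope <- 0
  }
  cfg <- list(
    seed = as.integer(seed), n_tss = as.integer(n_tss),
    n_chromosomes = as.integer(n_chromosomes), frac_cgi = frac_cgi,
    prob_plus = prob_plus, tss_spacing = as.integer(tss_spacing),
    tss_jitter = as.integer(tss_jitter), margin = as.integer(margin),
    class_intensity = class_intensity, modifiers = modifiers,
    delta_amplitude = delta_amplitude,
    inner_half_width = as.integer(inner_half_width),
    bbs_coupling = bbs_coupling, bgs_coupling = bgs_coupling,
    nuc_coupling = nuc_coupling, nuc_noise = nuc_noise,
    gerp_noise = gerp_noise, bbs_noise = bbs_noise, cadd_noise = cadd_noise,
    cadd_class_mean = cadd_class_mean, cadd_slope = cadd_slope,
    n_individuals = as.integer(n_individuals), null_model = null_model
  )
  stopifnot(all(class_intensity >= 0),
            all(vapply(modifiers, function(m) m$fold > 0, logical(1))),
            cfg$inner_half_width >= 2, cfg$inner_half_width <= 98,
            delta_amplitude >= 0, delta_amplitude < 1)
  structure(cfg, class = "synthetic_config")
}

# unit-amplitude delta shape. Inner piece: -cos(pi j / h), a common-variant
# excess peaking at the TSS that flips to a rare excess at the inner edges,
# so the planted coupling does not vanish at the boundary and the split is
# identifiable. Outer piece: a slow wave.
delta_shape <- function(cfg) {
  J <- bin_indices()
  h <- cfg$inner_half_width
  ifelse(abs(J) <= h, -cos(pi * J / h), sin(2 * pi * J / 120))
}

# per-class expected variants per bin for one TSS window (length-200 vectors)
class_lambda <- function(cfg) {
  J <- bin_indices()
  z <- delta_shape(cfg)
  lam <- lapply(names(cfg$class_intensity), function(cl) {
    base <- rep(cfg$class_intensity[[cl]] / N_BINS, N_BINS)
    for (m in cfg$modifiers) {
      if (cl %in% m$classes) base[match(m$bins, J)] <- base[match(m$bins, J)] * m$fold
    }
    if (cl == "rare") base <- base * (1 + cfg$delta_amplitude * z)
    if (cl == "common") base <- base * (1 - cfg$delta_amplitude * z)
    base
  })
  names(lam) <- names(cfg$class_intensity)
  lam
}

# expected BVF-delta profile implied by the intensity parameters
expected_delta <- function(cfg) {
  lam <- class_lambda(cfg)
  norm <- function(x) if (is.null(x) || sum(x) == 0) rep(1 / N_BINS, N_BINS) else x / sum(x)
  norm(lam$rare) - norm(lam$common)
}

standardize <- function(x) {
  if (sd(x) == 0) return(rep(0, length(x)))
  (x - mean(x)) / sd(x)
}

# minor-allele count ranges per class given 2N chromosomes and the 0.0014 /
# 0.01 style boundaries implied by count arithmetic
class_count_range <- function(cfg) {
  two_n <- 2L * cfg$n_individuals
  common_lo <- floor(0.01 * two_n) + 1L  # smallest count with MAF > 0.01
  mid_hi <- common_lo - 1L
  mid_break <- max(3L, floor(0.0014 * two_n))
  list(rare = c(1L, 1L),
       mid1 = c(2L, mid_break),
       mid2 = c(mid_break + 1L, mid_hi),
       common = c(common_lo, as.integer(two_n / 2)))
}

#' Generate a synthetic input bundle
#'
#' Deterministic in `config$seed`. TSSs are placed far enough apart that
#' every window is complete and single-TSS; per-class variant counts per bin
#' are Poisson with the configured intensities and planted modifiers; minor
#' allele counts are drawn within each class's range so MAF recomputation and
#' the variant filters round-trip; tracks realize the configured couplings.
#'
#' @param config A [synthetic_config()].
#' @param dir If non-NULL, the bundle is also written to files in `dir`
#'   (`tss.tsv`, `variants.tsv`, `cgi.bed`, `gbgc.bed`,
#'   `nucleosome.bedGraph`, `gerp.bedGraph`, `cadd.tsv`, `genome.tsv`,
#'   `truth.tsv`).
#' @return A list of tibbles: `tss`, `variants`, `cgi`, `gbgc`, `nucleosome`,
#'   `gerp`, `cadd`, `genome_sizes`, `truth`, plus `paths` when `dir` is
#'   given.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::local_seed(config$seed)
  cfg <- config
  J <- bin_indices()

  per_chrom <- ceiling(cfg$n_tss / cfg$n_chromosomes)
  chrom_len <- cfg$margin * 2L + per_chrom * cfg$tss_spacing
  if (2L * HALF_WINDOW > cfg$tss_spacing - 2L * cfg$tss_jitter) {
    abort("Infeasible config: TSS spacing too small for disjoint 10 kb windows.")
  }
  genome_sizes <- tibble(chrom = paste0("chr", seq_len(cfg$n_chromosomes)),
                         size = chrom_len)

  k <- seq_len(cfg$n_tss)
  chrom <- genome_sizes$chrom[(k - 1L) %/% per_chrom + 1L]
  slot <- (k - 1L) %% per_chrom
  position <- cfg$margin + slot * cfg$tss_spacing +
    as.integer(round(runif(cfg$n_tss, -cfg$tss_jitter, cfg$tss_jitter)))
  tss <- tibble(
    id = sprintf("tss_%05d", k), chrom = chrom, position = position,
    strand = ifelse(runif(cfg$n_tss) < cfg$prob_plus, "+", "-"),
    score = round(runif(cfg$n_tss, 20, 100), 1),
    is_cgi = runif(cfg$n_tss) < cfg$frac_cgi
  )

  # CpG islands containing their TSS, center jitter symmetric around the site
  cgi_tss <- tss[tss$is_cgi, ]
  half1 <- as.integer(round(runif(nrow(cgi_tss), 250, 750)))
  half2 <- as.integer(round(runif(nrow(cgi_tss), 250, 750)))
  cgi <- tibble(chrom = cgi_tss$chrom,
                start = cgi_tss$position - ifelse(cgi_tss$strand == "-", half2, half1),
                end = cgi_tss$position + ifelse(cgi_tss$strand == "-", half1, half2) + 1L)

  # variants: per TSS x class x bin Poisson counts
  lam <- class_lambda(cfg)
  ranges <- class_count_range(cfg)
  two_n <- 2L * cfg$n_individuals
  var_parts <- lapply(names(lam), function(cl) {
    counts <- matrix(rpois(cfg$n_tss * N_BINS, rep(lam[[cl]], each = cfg$n_tss)),
                     nrow = cfg$n_tss)
    total <- sum(counts)
    if (total == 0) return(NULL)
    idx <- which(counts > 0, arr.ind = TRUE)
    n_rep <- counts[idx]
    ti <- rep(idx[, 1], n_rep)
    j <- rep(J[idx[, 2]], n_rep)
    lo_d <- ifelse(j > 0, (j - 1L) * BIN_WIDTH, j * BIN_WIDTH)
    d <- lo_d + as.integer(floor(runif(total) * BIN_WIDTH))
    pos <- ifelse(tss$strand[ti] == "-", tss$position[ti] - d, tss$position[ti] + d)
    minor <- if (ranges[[cl]][1] == ranges[[cl]][2]) {
      rep(ranges[[cl]][1], total)
    } else {
      as.integer(ranges[[cl]][1] +
                   floor(runif(total) * (ranges[[cl]][2] - ranges[[cl]][1] + 1L)))
    }
    tibble(chrom = tss$chrom[ti], position = as.integer(pos),
           var_class = "single", submitters = "1000GENOMES,OTHER",
           allele_freq_count = 2L,
           allele_n1 = as.numeric(minor), allele_n2 = as.numeric(two_n - minor),
           true_class = cl, d_true = d)
  })
  variants <- dplyr::bind_rows(var_parts)
  if (nrow(variants) > 0) {
    variants <- dplyr::arrange(variants, .data$chrom, .data$position)
    variants$id <- sprintf("rs%07d", seq_len(nrow(variants)))
    variants <- dplyr::select(variants, "id", dplyr::everything())
  }

  # per-bin track values; couplings are driven by the expected delta profile
  # (inner/outer pieces standardized separately) and the rare intensity shape
  ed <- expected_delta(cfg)
  inner <- abs(J) <= cfg$inner_half_width
  s_in <- s_out <- rep(0, N_BINS)
  s_in[inner] <- standardize(ed[inner])
  s_out[!inner] <- standardize(ed[!inner])
  s_rare <- standardize(lam$rare %||% rep(0, N_BINS))

  # base profiles differ by CpG context, as in real chromatin architecture:
  # CGI promoters carry a nucleosome-depleted region and an upstream
  # conservation dip; nCGI promoters a downstream occupancy peak
  nuc_base_cgi <- 1 - 0.6 * exp(-(J / 12)^2)
  nuc_base_ncgi <- 1 + 0.3 * exp(-((J - 4) / 8)^2)
  gerp_base_cgi <- 0.1 + 0.5 * exp(-(J / 6)^2) - 0.3 * exp(-((J + 9) / 5)^2)
  gerp_base_ncgi <- 0.1 + 0.5 * exp(-(J / 6)^2)
  bbs_base_cgi <- ifelse(inner, 0.15, 0.02)
  bbs_base_ncgi <- ifelse(inner, 0.06, 0.02)

  bin_rows <- tidyr::expand_grid(
    tibble(tss_id = tss$id, chrom = tss$chrom, tss_position = tss$position,
           strand = tss$strand, is_cgi = tss$is_cgi),
    tibble(bin = J)
  )
  bb <- bin_genomic_bounds(bin_rows$tss_position, bin_rows$strand, bin_rows$bin)
  bin_rows$start <- bb$start
  bin_rows$end <- bb$end
  jj <- match(bin_rows$bin, J)
  n_cells <- nrow(bin_rows)
  cg <- bin_rows$is_cgi

  nuc_val <- pmax(0, ifelse(cg, nuc_base_cgi[jj], nuc_base_ncgi[jj]) +
                    cfg$nuc_coupling * s_rare[jj] +
                    rnorm(n_cells, sd = cfg$nuc_noise))
  gerp_val <- ifelse(cg, gerp_base_cgi[jj], gerp_base_ncgi[jj]) +
    cfg$bgs_coupling * s_out[jj] + rnorm(n_cells, sd = cfg$gerp_noise)
  bbs_frac <- clamp(ifelse(cg, bbs_base_cgi[jj], bbs_base_ncgi[jj]) -
                      cfg$bbs_coupling * s_in[jj] +
                      rnorm(n_cells, sd = cfg$bbs_noise), 0, 1)

  ord <- order(bin_rows$chrom, bin_rows$start)
  nucleosome <- new_score_track(tibble(
    chrom = bin_rows$chrom, start = bin_rows$start, end = bin_rows$end,
    value = round(nuc_val, 6)
  )[ord, ])
  gerp <- new_score_track(tibble(
    chrom = bin_rows$chrom, start = bin_rows$start, end = bin_rows$end,
    value = round(gerp_val, 6)
  )[ord, ])

  tract_len <- as.integer(round(bbs_frac * BIN_WIDTH))
  has_tract <- tract_len > 0
  gbgc <- tibble(chrom = bin_rows$chrom[has_tract],
                 start = bin_rows$start[has_tract],
                 end = bin_rows$start[has_tract] + tract_len[has_tract])
  gbgc <- dplyr::arrange(gbgc, .data$chrom, .data$start)

  # per-variant deleteriousness scores
  cadd <- NULL
  if (nrow(variants) > 0) {
    mu <- cfg$cadd_class_mean[variants$true_class]
    raw <- mu - cfg$cadd_slope * abs(variants$d_true) +
      rnorm(nrow(variants), sd = cfg$cadd_noise)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nrow(variants), replace = TRUE)
    alt_shift <- 1L + as.integer(floor(runif(nrow(variants)) * 3))
    alt <- bases[(match(ref, bases) - 1L + alt_shift) %% 4L + 1L]
    cadd <- tibble(chrom = variants$chrom, position = variants$position,
                   ref = ref, alt = alt, raw_score = round(raw, 6),
                   scaled_score = round(10 * stats::plogis(raw), 4))
  } else {
    cadd <- tibble(chrom = character(), position = integer(), ref = character(),
                   alt = character(), raw_score = double(), scaled_score = double())
  }

  truth <- truth_report(cfg)
  # achieved couplings: correlations of the planted per-bin track expectations
  # with the expected delta profile, on the inner / outer bins
  achieved <- tibble(
    parameter = c("achieved_bbs_delta_cor", "achieved_bgs_delta_cor",
                  "achieved_nuc_rare_cor"),
    value = c(
      if (sd(ed[inner]) > 0 && cfg$bbs_coupling != 0)
        stats::cor(bbs_base_cgi[inner] - cfg$bbs_coupling * s_in[inner], ed[inner])
      else NA_real_,
      if (sd(ed[!inner]) > 0 && cfg$bgs_coupling != 0)
        stats::cor(gerp_base_cgi[!inner] + cfg$bgs_coupling * s_out[!inner], ed[!inner])
      else NA_real_,
      if (sd(s_rare) > 0 && cfg$nuc_coupling != 0)
        stats::cor(nuc_base_cgi + cfg$nuc_coupling * s_rare, lam$rare)
      else NA_real_
    )
  )
  truth <- dplyr::bind_rows(truth, achieved)

  out <- list(tss = dplyr::select(tss, -"is_cgi"), variants = variants,
              cgi = cgi, gbgc = gbgc, nucleosome = nucleosome, gerp = gerp,
              cadd = cadd, genome_sizes = genome_sizes, truth = truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      tss = file.path(dir, "tss.tsv"), variants = file.path(dir, "variants.tsv"),
      cgi = file.path(dir, "cgi.bed"), gbgc = file.path(dir, "gbgc.bed"),
      nucleosome = file.path(dir, "nucleosome.bedGraph"),
      gerp = file.path(dir, "gerp.bedGraph"), cadd = file.path(dir, "cadd.tsv"),
      genome = file.path(dir, "genome.tsv"), truth = file.path(dir, "truth.tsv")
    )
    write_tss_table(out$tss, paths$tss)
    write_variant_table(out$variants, paths$variants)
    write_bed(out$cgi, paths$cgi)
    write_bed(out$gbgc, paths$gbgc)
    write_bedgraph(out$nucleosome, paths$nucleosome)
    write_bedgraph(out$gerp, paths$gerp)
    write_cadd_table(out$cadd, paths$cadd)
    writeLines(c("#chrom\tsize",
                 sprintf("%s\t%d", genome_sizes$chrom, genome_sizes$size)),
               paths$genome)
    readr::write_tsv(out$truth, paths$truth)
    out$paths <- paths
  }
  out
}

#' Machine-readable ground truth for a configuration
#'
#' Echoes the planted parameters (modified bins and folds, inner half-width,
#' couplings, delta amplitude) so recovery tests can compare estimates to
#' truth.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `parameter`, `value`, and for modifiers
#'   `detail` (bins and classes).
#' @export
truth_report <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rows <- tibble(
    parameter = c("inner_half_width", "delta_amplitude", "bbs_coupling",
                  "bgs_coupling", "nuc_coupling", "n_tss"),
    value = c(config$inner_half_width, config$delta_amplitude,
              config$bbs_coupling, config$bgs_coupling, config$nuc_coupling,
              config$n_tss),
    detail = NA_character_
  )
  mods <- purrr::imap_dfr(config$modifiers, function(m, i) {
    tibble(parameter = sprintf("modifier_%d_fold", i), value = m$fold,
           detail = sprintf("bins %s; classes %s", bin_runs(m$bins),
                            paste(m$classes, collapse = ",")))
  })
  dplyr::bind_rows(rows, mods)
}

#' Simulate a uniform-null bin count matrix directly
#'
#' Uniform placement of a Poisson(`lambda`) number of variants per TSS over
#' the 200 bins is, by Poisson thinning, the same as independent
#' Poisson(`lambda / 200`) counts per bin; this generates such a matrix
#' without materializing coordinates, for null-calibration studies.
#'
#' @param n_tss Number of TSS rows.
#' @param lambda Expected variants per TSS window.
#' @return A `bin_matrix` of counts.
#' @export
simulate_null_counts <- function(n_tss, lambda = 10) {
  mat <- matrix(rpois(n_tss * N_BINS, lambda / N_BINS), nrow = n_tss,
                dimnames = list(sprintf("tss_%05d", seq_len(n_tss)),
                                as.character(bin_indices())))
  new_bin_matrix(mat, "BVF")
}
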