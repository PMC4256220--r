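# End-to-end orchestration: selection -> class boundaries -> CGI split ->
# binning -> uniform-null tests -> BVF-delta -> track profiles and
# CGI-vs-nCGI Fisher contrasts -> nucleosome/BVF correlations ->
# window split -> deleteriousness analyses -> TSV bundle.

#' Pipeline configuration
#'
#' Collects input locations (file paths, or an in-memory bundle from
#' [generate_dataset()]) and run-level constants.
#'
#' @param paths Named list of file paths (`tss`, `variants`, `cgi`, `gbgc`,
#'   `nucleosome`, `gerp`, `cadd`, `genome`), e.g. `generate_dataset(...,
#'   dir=)$paths`. Ignored when `bundle` is given.
#' @param bundle An in-memory bundle (list of tibbles) from
#'   [generate_dataset()].
#' @param min_tss_score Confidence-score cutoff for TSS selection.
#' @param rare_threshold,common_threshold Frequency-class thresholds.
#' @param alpha Family-wise significance level for every test family.
#' @param exclude_multi Drop TSSs whose 10 kb region hosts another TSS.
#' @param out_dir If non-NULL, result TSVs are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(paths = NULL, bundle = NULL,
                            min_tss_score = 20,
                            rare_threshold = rare_maf_threshold(),
                            common_threshold = 0.01,
                            alpha = 0.001,
                            exclude_multi = FALSE,
                            out_dir = NULL) {
  stopifnot(!is.null(paths) || !is.null(bundle), alpha > 0, alpha < 1)
  structure(list(paths = paths, bundle = bundle,
                 min_tss_score = min_tss_score,
                 rare_threshold = rare_threshold,
                 common_threshold = common_threshold, alpha = alpha,
                 exclude_multi = exclude_multi, out_dir = out_dir),
            class = "pipeline_config")
}

read_pipeline_inputs <- function(config) {
  if (!is.null(config$bundle)) {
    b <- config$bundle
    b$tss <- b$tss[b$tss$score >= config$min_tss_score, ]
    return(b)
  }
  p <- config$paths
  genome <- read_delim_lines(p$genome, 2L, "genome")
  list(
    tss = read_tss_table(p$tss, min_score = config$min_tss_score),
    variants = read_variant_table(p$variants),
    cgi = read_bed(p$cgi),
    gbgc = read_bed(p$gbgc),
    nucleosome = read_bedgraph(p$nucleosome),
    gerp = read_bedgraph(p$gerp),
    cadd = read_cadd_table(p$cadd),
    genome_sizes = tibble(chrom = genome$fields[[1]],
                          size = as.numeric(genome$fields[[2]]))
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          parent = e)
  })
}

#' Run the full TSS variant-distribution analysis
#'
#' Executes every analysis stage on the configured inputs and returns a
#' structured result bundle. See the package vignette for the scientific
#' walk-through of each stage.
#'
#' @param config A [pipeline_config()].
#' @return A `tss_pipeline_result` list: `counts`, `boundaries`,
#'   `density`, `tss` (classified), `cgi_symmetry`, per-status BVF profiles
#'   and uniform-null tests (`bvf`), `delta`, track profiles (`tracks`),
#'   Fisher contrasts (`contrasts`), nucleosome/BVF correlations
#'   (`nuc_cor`), `split`, deleteriousness results (`deleteriousness`), and
#'   `log` (run decisions).
#' @export
run_tss_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- stage("read", read_pipeline_inputs(config))
  alpha <- config$alpha
  log <- c(sprintf("min_tss_score=%g", config$min_tss_score),
           sprintf("alpha=%g", alpha),
           sprintf("rare_threshold=%.8g", config$rare_threshold),
           sprintf("common_threshold=%g", config$common_threshold),
           sprintf("exclude_multi=%s", config$exclude_multi),
           "track_mean_mode=pooled", "bvf_zero_rows=dropped")

  sel <- stage("selection", {
    v <- filter_variants(inp$variants)
    v$maf <- compute_maf(v$allele_n1, v$allele_n2)
    bnd <- derive_class_boundaries(v$maf, config$rare_threshold,
                                   config$common_threshold)
    v$class <- assign_class(v$maf, bnd)
    list(variants = v, boundaries = bnd, tally = filter_tally(v))
  })

  tss <- stage("classify_tss", classify_tss(inp$tss, inp$cgi))
  if (config$exclude_multi) tss <- exclude_multi_tss(tss)
  tss <- drop_edge_tss(tss, inp$genome_sizes)

  cgi_symmetry <- NULL
  cgi_dist <- tss$cgi_center_distance[tss$cgi_status == "CGI"]
  if (sum(!is.na(cgi_dist)) >= 8) {
    cgi_symmetry <- stage("cgi_symmetry", dagostino_skewness(cgi_dist))
  }

  density <- stage("density", density_contrast(sel$variants, tss,
                                               inp$genome_sizes))

  asg <- stage("binning", assign_bins(tss, sel$variants))
  statuses <- unique(tss$cgi_status)
  classes <- levels(sel$variants$class)

  split_by_status <- function(status) tss$id[tss$cgi_status == status]

  bvf <- list()
  delta <- list()
  for (st in statuses) {
    ids <- split_by_status(st)
    mats <- lapply(classes, function(cl) {
      bin_count_matrix(asg[asg$class == cl & asg$tss_id %in% ids, ], ids,
                       signal = paste0("BVF_", cl))
    })
    names(mats) <- classes
    bvf[[st]] <- list(
      matrices = mats,
      profiles = lapply(mats, function(m) tryCatch(bvf_profile(m),
                                                   error = function(e) NULL)),
      tests = lapply(mats, function(m) tryCatch(neutral_bin_test(m, alpha),
                                                error = function(e) NULL))
    )
    delta[[st]] <- tryCatch(
      bvf_delta_test(mats$rare, mats$common, alpha),
      error = function(e) NULL
    )
  }

  tracks <- stage("tracks", {
    gbgc_trk <- as_membership_track(inp$gbgc)
    out <- list()
    for (st in statuses) {
      sub <- tss[tss$cgi_status == st, ]
      bnp_binned <- bin_track(sub, inp$nucleosome)
      bgs_binned <- bin_track(sub, inp$gerp)
      bbs_binned <- bin_track(sub, gbgc_trk)
      out[[st]] <- list(
        bnp = profile_from_binned(bnp_binned, "pooled_base_mean", nrow(sub)),
        bgs = profile_from_binned(bgs_binned, "pooled_base_mean", nrow(sub)),
        bbs = profile_from_binned(bbs_binned, "per_tss_base_fraction", nrow(sub),
                                  "base_membership"),
        bnp_binned = bnp_binned, bgs_binned = bgs_binned,
        bbs_binned = bbs_binned
      )
    }
    out
  })

  contrasts <- NULL
  if (all(c("CGI", "nCGI") %in% statuses)) {
    contrasts <- stage("contrasts", {
      ids_a <- split_by_status("CGI"); ids_b <- split_by_status("nCGI")
      per_signal <- function(slot, statistic) {
        ma <- bin_value_matrix(tracks$CGI[[slot]], ids_a, statistic)
        mb <- bin_value_matrix(tracks$nCGI[[slot]], ids_b, statistic)
        tt <- profile_ttest_pair(ma, mb, alpha)
        # underflowed p-values are floored at 1e-300 before combination
        list(per_bin = tt, fisher = fisher_combine(pmax(tt$p, 1e-300)))
      }
      list(bnp = per_signal("bnp_binned", "mean"),
           bgs = per_signal("bgs_binned", "mean"),
           bbs = per_signal("bbs_binned", "fraction"))
    })
    log <- c(log, paste("fisher_combination: per-bin t-tests treated as",
                        "independent; interpret combined p accordingly"))
  }

  nuc_cor <- stage("nuc_cor", {
    out <- list()
    for (st in statuses) {
      out[[st]] <- lapply(classes, function(cl) {
        prof <- bvf[[st]]$profiles[[cl]]
        if (is.null(prof)) return(NULL)
        pearson_test(tracks[[st]]$bnp$mean, prof$mean)
      })
      names(out[[st]]) <- classes
    }
    out
  })

  split <- NULL
  if (!is.null(delta$CGI)) {
    split <- stage("window_split", window_split(
      tracks$CGI$bbs, tracks$CGI$bgs, delta$CGI$profile
    ))
  }

  deleteriousness <- stage("deleteriousness", {
    scored <- dplyr::inner_join(asg, inp$cadd[c("chrom", "position", "raw_score")],
                                by = c("chrom", "position"),
                                relationship = "many-to-many")
    out <- list()
    for (st in statuses) {
      ids <- split_by_status(st)
      sub <- scored[scored$tss_id %in% ids, ]
      out[[st]] <- list(
        profiles = lapply(classes, function(cl) {
          track_profile(tss[tss$cgi_status == st, ], NULL,
                        "pooled_variant_mean",
                        assignments = sub[sub$class == cl, ])
        }),
        anova = bcs_class_anova(sub, alpha),
        wilcoxon = lapply(classes, function(cl) {
          d <- sub[sub$class == cl, ]
          if (sum(d$bin < 0) == 0 || sum(d$bin > 0) == 0) return(NULL)
          wilcoxon_updown(d$raw_score[d$bin < 0], d$raw_score[d$bin > 0])
        })
      )
      names(out[[st]]$profiles) <- classes
      names(out[[st]]$wilcoxon) <- classes
    }
    out
  })

  counts <- list(
    n_tss = nrow(tss),
    n_tss_cgi = sum(tss$cgi_status == "CGI"),
    n_tss_ncgi = sum(tss$cgi_status == "nCGI"),
    n_variants_input = unname(sel$tally["n_input"]),
    n_variants_kept = unname(sel$tally["n_kept"]),
    class_counts = table(sel$variants$class)
  )

  res <- structure(
    list(counts = counts, boundaries = sel$boundaries, density = density,
         tss = tss, cgi_symmetry = cgi_symmetry, bvf = bvf, delta = delta,
         tracks = tracks, contrasts = contrasts, nuc_cor = nuc_cor,
         split = split, deleteriousness = deleteriousness, log = log,
         alpha = alpha),
    class = "tss_pipeline_result"
  )
  if (!is.null(config$out_dir)) write_result_tsvs(res, config$out_dir)
  res
}

write_result_tsvs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (st in names(res$bvf)) {
    for (cl in names(res$bvf[[st]]$tests)) {
      t <- res$bvf[[st]]$tests[[cl]]
      if (is.null(t)) next
      prof <- tibble(bin = t$bin, offset_bp = t$offset_bp, mean = t$observed_mean,
                     se = t$se, ci_lo = t$observed_mean - 2 * t$se,
                     ci_hi = t$observed_mean + 2 * t$se, p = t$p,
                     p_adj = t$p_adj, significant = t$significant, n = t$n)
      write_profile_tsv(prof, file.path(dir, sprintf("bvf_%s_%s.tsv", st, cl)))
    }
    if (!is.null(res$delta[[st]])) {
      t <- res$delta[[st]]$test
      prof <- tibble(bin = t$bin, offset_bp = t$offset_bp, mean = t$observed_mean,
                     se = t$se, ci_lo = t$observed_mean - 2 * t$se,
                     ci_hi = t$observed_mean + 2 * t$se, p = t$p,
                     p_adj = t$p_adj, significant = t$significant, n = t$n)
      write_profile_tsv(prof, file.path(dir, sprintf("delta_%s.tsv", st)))
    }
  }
  if (!is.null(res$split)) {
    readr::write_tsv(res$split$trace, file.path(dir, "split_trace.tsv"))
  }
  writeLines(res$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Human-readable summary of a pipeline run
#'
#' A pure formatter over the result bundle: selection counts, significant bin
#' ranges per family, the downstream/upstream fold change of the rare class,
#' correlations, and the split boundary in bins and bp.
#'
#' @param result A `tss_pipeline_result`.
#' @return The report lines, invisibly; they are also printed.
#' @export
pipeline_report <- function(result) {
  stopifnot(inherits(result, "tss_pipeline_result"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  cc <- result$counts
  add("TSSs analysed: %d (CGI %d / nCGI %d)", cc$n_tss, cc$n_tss_cgi, cc$n_tss_ncgi)
  add("Variants kept: %s of %s", format(cc$n_variants_kept, big.mark = ","),
      format(cc$n_variants_input, big.mark = ","))
  add("Class counts: %s",
      paste(sprintf("%s=%d", names(cc$class_counts), cc$class_counts), collapse = ", "))
  add("Variant density in windows vs rest: %.4g vs %.4g",
      result$density$density_in, result$density$density_out)
  for (st in names(result$bvf)) {
    for (cl in names(result$bvf[[st]]$tests)) {
      t <- result$bvf[[st]]$tests[[cl]]
      if (is.null(t)) next
      add("BVF %s/%s significant bins: %s", st, cl, bin_runs(t$bin[t$significant]))
    }
    if (!is.null(result$delta[[st]])) {
      t <- result$delta[[st]]$test
      add("BVF-delta %s significant bins: %s", st, bin_runs(t$bin[t$significant]))
    }
    prof <- result$bvf[[st]]$profiles$rare
    if (!is.null(prof)) {
      fold <- mean(prof$mean[prof$bin %in% 1:4]) /
        mean(prof$mean[prof$bin %in% -4:-1])
      add("Rare-class downstream(+1..+4)/upstream(-4..-1) fold, %s: %.2f", st, fold)
    }
  }
  for (st in names(result$nuc_cor)) {
    for (cl in names(result$nuc_cor[[st]])) {
      pc <- result$nuc_cor[[st]][[cl]]
      if (is.null(pc)) next
      add("BNP~BVF correlation %s/%s: r=%.3f t=%.2f p=%.3g n=%d",
          st, cl, pc$r, pc$t, pc$p, pc$n)
    }
  }
  if (!is.null(result$contrasts)) {
    for (sig in names(result$contrasts)) {
      f <- result$contrasts[[sig]]$fisher
      add("CGI vs nCGI %s (Fisher over 200 bins): X2=%.1f df=%d p=%.3g",
          toupper(sig), f$statistic, f$df, f$p_value)
    }
  }
  if (!is.null(result$split)) {
    s <- result$split
    add("Window split boundary: %d bins (%d bp); inner BBS~delta r=%.3f, outer BGS~delta r=%.3f%s",
        s$boundary, s$boundary_bp, s$r_inner$r, s$r_outer$r,
        if (length(s$flags)) paste0(" [", paste(s$flags, collapse = ","), "]") else "")
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}

#' @export
print.tss_pipeline_result <- function(x, ...) {
  cat("<tss_pipeline_result>\n")
  pipeline_report(x)
  invisible(x)
}
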