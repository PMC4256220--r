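# shared internal helpers

# chromosome names carrying alternative-haplotype assemblies duplicate primary
# sequence; they are dropped at read time everywhere
is_alt_chrom <- function(chrom) {
  grepl("_hap|_alt", chrom)
}

drop_alt_chroms <- function(df, what) {
  alt <- is_alt_chrom(df$chrom)
  if (any(alt)) {
    inform(sprintf(
      "Dropped %d %s record(s) on alternative-haplotype chromosomes.",
      sum(alt), what
    ))
    df <- df[!alt, , drop = FALSE]
  }
  df
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stop with a parse error naming the offending (1-based, post-comment) line
abort_parse <- function(path, line, msg) {
  abort(sprintf("Parse error in '%s', line %d: %s", path, line, msg),
        class = "tssvar_parse_error")
}

check_prob <- function(p, arg = "p", allow_zero = FALSE) {
  bad <- if (allow_zero) p < 0 | p > 1 else p <= 0 | p > 1
  bad <- bad & !is.na(p)
  if (any(bad)) {
    abort(sprintf(
      "`%s` must lie in %s; offending value: %g",
      arg, if (allow_zero) "[0, 1]" else "(0, 1]", p[which(bad)[1]]
    ))
  }
  invisible(p)
}

# collapse a sorted integer vector into human-readable runs, e.g. "+1..+4, +9"
bin_runs <- function(j) {
  if (length(j) == 0) return("none")
  j <- sort(unique(j))
  brk <- c(0L, which(diff(j) != 1L), length(j))
  fmt <- function(x) ifelse(x > 0, paste0("+", x), as.character(x))
  runs <- vapply(seq_len(length(brk) - 1L), function(k) {
    seg <- j[(brk[k] + 1L):brk[k + 1L]]
    if (length(seg) == 1L) fmt(seg) else paste0(fmt(seg[1]), "..", fmt(seg[length(seg)]))
  }, character(1))
  paste(runs, collapse = ", ")
}
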