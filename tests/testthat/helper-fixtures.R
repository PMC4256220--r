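# small in-code fixtures shared across test files

make_tss <- function(position, strand = "+", chrom = "chr1",
                     score = 50, id = NULL) {
  n <- max(length(position), length(strand), length(chrom))
  tibble::tibble(
    id = id %||% sprintf("t%03d", seq_len(n)),
    chrom = rep_len(chrom, n),
    position = as.integer(rep_len(position, n)),
    strand = rep_len(strand, n),
    score = rep_len(score, n)
  )
}

make_variants <- function(position, chrom = "chr1", class = "rare",
                          maf = 0.0004, id = NULL) {
  n <- length(position)
  tibble::tibble(
    id = id %||% sprintf("v%04d", seq_len(n)),
    chrom = rep_len(chrom, n),
    position = as.integer(position),
    class = rep_len(class, n),
    maf = rep_len(maf, n)
  )
}

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, f)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a per-base-signal track from a plain interval tibble
new_track_for_test <- function(df) {
  structure(df, class = c("tssvar_track", class(tibble::tibble())),
            semantics = "per_base_signal")
}
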