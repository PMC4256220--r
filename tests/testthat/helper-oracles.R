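# Independent brute-force oracles. These deliberately use the slowest,
# most literal formulation of each quantity, and never call the package
# functions they are used to check.

# Pearson r, t and p from explicit sum loops
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, t = t, p = 2 * stats::pt(-abs(t), n - 2))
}

# all-segments O(L^2) maximal-scoring-segment extraction with the same tie
# rules (max score; smallest start; then smallest end), recursing on the
# flanks of each accepted segment
oracle_segments <- function(s, lo = 1L, hi = length(s)) {
  if (lo > hi) return(NULL)
  best <- list(score = -Inf, a = NA, b = NA)
  for (a in lo:hi) {
    acc <- 0
    for (b in a:hi) {
      acc <- acc + s[b]
      if (acc > best$score) best <- list(score = acc, a = a, b = b)
    }
  }
  if (best$score <= 0) return(NULL)
  c(list(best),
    oracle_segments(s, lo, best$a - 1L),
    oracle_segments(s, best$b + 1L, hi))
}

# CpG-island calls from the enumeration oracle plus a literal filter pass
oracle_cgi <- function(sequence) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  base <- strsplit(sequence, "")[[1]]
  s <- numeric(L - 1)
  for (t in seq_len(L - 1)) {
    s[t] <- if (base[t] == "C" && base[t + 1] == "G") 17 else -1
  }
  segs <- oracle_segments(s)
  out <- NULL
  for (seg in segs) {
    bb <- base[seg$a:(seg$b + 1)]
    len <- length(bb)
    nc <- sum(bb == "C"); ng <- sum(bb == "G")
    obs <- 0
    for (t in seq_len(len - 1)) if (bb[t] == "C" && bb[t + 1] == "G") obs <- obs + 1
    expd <- nc * ng / len
    if ((nc + ng) / len >= 0.5 && len > 200 && expd > 0 && obs / expd > 0.6) {
      out <- rbind(out, c(start = seg$a - 1L, end = seg$b + 1L))
    }
  }
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  out <- as.data.frame(out)
  out[order(out$start), ]
}

# bin lookup through an explicit 200-row interval table in offset space
oracle_bin_table <- local({
  j <- c(-100:-1, 1:100)
  lo <- ifelse(j > 0, (j - 1) * 50, j * 50)
  data.frame(j = j, lo = lo, hi = lo + 50)
})

oracle_bin_index <- function(d) {
  hit <- oracle_bin_table$j[d >= oracle_bin_table$lo & d < oracle_bin_table$hi]
  if (length(hit) == 0) NA_integer_ else hit
}

# exact two-sided rank-sum p by enumerating the Mann-Whitney pairwise-count
# statistic U = #(up > down) + 0.5 #(up == down) over all group assignments
oracle_wilcoxon <- function(up, down) {
  vals <- c(up, down)
  nu <- length(up)
  N <- length(vals)
  u_stat <- function(idx) {
    a <- vals[idx]; b <- vals[-idx]
    u <- 0
    for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
    u
  }
  u_obs <- u_stat(seq_len(nu))
  mu <- nu * (N - nu) / 2
  us <- apply(utils::combn(N, nu), 2, u_stat)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# classic one-way ANOVA from the literal sum-of-squares formulas
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  gl <- unique(groups)
  N <- length(values)
  k <- length(gl)
  grand <- mean(values)
  ssb <- ssw <- 0
  for (g in gl) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}
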