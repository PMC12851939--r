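# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

# printed/fold depletion scores from raw per-position counts and totals
bf_depletion <- function(c_t, c_nt, S_t, S_nt, alpha = 1) {
  n <- length(c_t)
  printed <- numeric(n)
  masked <- logical(n)
  for (p in seq_len(n)) {
    masked[p] <- c_t[p] == 0 && c_nt[p] == 0
    printed[p] <- (S_nt / S_t) * (c_t[p] + alpha) / (c_nt[p] + alpha)
  }
  printed[masked] <- NA_real_
  list(printed = printed, fold = 1 / printed, masked = masked)
}

# reference-wise z over unmasked fold scores, population sd
bf_z <- function(fold, masked) {
  v <- fold[!masked]
  m <- length(v)
  mu <- sum(v) / m
  ss <- 0
  for (x in v) ss <- ss + (x - mu)^2
  sd_pop <- sqrt(ss / m)
  z <- rep(NA_real_, length(fold))
  for (p in seq_along(fold)) {
    if (!masked[p]) z[p] <- if (sd_pop == 0) 0 else (fold[p] - mu) / sd_pop
  }
  z
}

# 5x4 position-by-base log2 fold change from named 5-mer count vectors
bf_lfc <- function(counts_t, counts_nt, alpha = 1) {
  bases <- c("A", "C", "G", "T")
  T_t <- sum(counts_t)
  T_nt <- sum(counts_nt)
  out <- matrix(NA_real_, 5, 4, dimnames = list(paste0("+", 1:5), bases))
  for (i in 1:5) {
    for (b in bases) {
      ct <- 0
      for (k in names(counts_t)) {
        if (substr(k, i, i) == b) ct <- ct + counts_t[[k]]
      }
      cnt <- 0
      for (k in names(counts_nt)) {
        if (substr(k, i, i) == b) cnt <- cnt + counts_nt[[k]]
      }
      out[i, b] <- log2((T_nt / T_t) * (ct + alpha) / (cnt + alpha))
    }
  }
  out
}

# interval-stabbing coverage: count alignments with ref_start < p <= ref_end
bf_coverage <- function(ref_start, ref_end, L) {
  counts <- integer(L)
  for (p in seq_len(L)) {
    for (j in seq_along(ref_start)) {
      if (ref_start[j] < p && p <= ref_end[j]) counts[p] <- counts[p] + 1L
    }
  }
  counts
}

# longest qualifying poly(A) suffix, re-derived by scanning every suffix
bf_tail_len <- function(seq, min_len = 5, min_frac = 0.9) {
  L <- nchar(seq)
  best <- 0L
  for (j in seq_len(L)) {
    suffix <- substr(seq, L - j + 1L, L)
    n_a <- sum(strsplit(suffix, "")[[1]] == "A")
    if (substr(suffix, 1, 1) == "A" && j >= min_len && n_a / j >= min_frac) {
      best <- j
    }
  }
  best
}

# a pfs_counts-shaped object from a named count vector (for direct scoring
# tests that bypass read extraction)
make_counts <- function(counts, condition = "target") {
  structure(list(condition = condition,
                 counts = counts[counts > 0],
                 total = sum(counts),
                 excluded = c(no_anchor = 0L, ambiguous_N = 0L,
                              low_phred = 0L)),
            class = "pfs_counts")
}
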