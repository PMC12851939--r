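# Scoring of the randomized-PFS depletion screen: anchored 5-mer extraction
# with exclusion accounting, per-5-mer depletion scores and the 5x4
# position-by-nucleotide log2 fold-change matrix.

#' Extract anchored PFS 5-mers from amplicon reads
#'
#' Each read is scanned for the first occurrence of the upstream anchor
#' immediately followed by five bases and the downstream anchor. The 5-mer is
#' counted unless the read fails one of the exclusion rules, which are
#' tallied: `no_anchor` (no such motif), `ambiguous_N` (an N inside the
#' 5-mer), `low_phred` (any of the five Phred scores below `phred_min`;
#' skipped for reads without quality strings). Counted reads plus the three
#' exclusion tallies always sum to the number of input reads.
#'
#' @param reads read tibble (single condition).
#' @param upstream_anchor,downstream_anchor the fixed flanks of the
#'   randomized cassette; defaults are the 20-nt target-encoding sequence and
#'   the 10-nt downstream sequence of the screen.
#' @param phred_min minimum per-base Phred score inside the 5-mer
#'   (default 20, i.e. a score of 19 excludes the read).
#' @param max_anchor_mismatch substitutions tolerated in each anchor
#'   (default 0, exact matching).
#' @return an object of class `pfs_counts`: list with `condition`, `counts`
#'   (named integer vector over observed 5-mers), `total` and `excluded`
#'   (named integer vector `no_anchor`, `ambiguous_N`, `low_phred`).
#' @export
extract_pfs <- function(reads,
                        upstream_anchor = PFS_UPSTREAM_ANCHOR,
                        downstream_anchor = PFS_DOWNSTREAM_ANCHOR,
                        phred_min = 20L,
                        max_anchor_mismatch = 0L) {
  condition <- unique(reads$condition)
  if (length(condition) > 1L) {
    stop("extract_pfs() expects reads from a single condition")
  }
  n_up <- nchar(upstream_anchor)
  if (max_anchor_mismatch == 0L) {
    pat <- paste0(upstream_anchor, "(.{5})", downstream_anchor)
    m <- regexpr(pat, reads$seq)
    start5 <- ifelse(m > 0L, m + n_up, NA_integer_)
  } else {
    start5 <- fuzzy_anchor_positions(reads$seq, upstream_anchor,
                                     downstream_anchor, max_anchor_mismatch)
  }
  has_anchor <- !is.na(start5)
  kmer <- rep(NA_character_, nrow(reads))
  kmer[has_anchor] <- substr(reads$seq[has_anchor], start5[has_anchor],
                             start5[has_anchor] + 4L)
  has_n <- has_anchor & grepl("N", kmer, fixed = TRUE)
  quals <- if ("qual" %in% names(reads)) reads$qual else
    rep(NA_character_, nrow(reads))
  low_q <- rep(FALSE, nrow(reads))
  check_q <- which(has_anchor & !has_n & !is.na(quals))
  if (length(check_q) > 0L) {
    q5 <- substr(quals[check_q], start5[check_q], start5[check_q] + 4L)
    # min Phred+33 code over the five bases
    min_code <- vapply(q5, function(q) min(as.integer(charToRaw(q))),
                       integer(1), USE.NAMES = FALSE)
    low_q[check_q] <- (min_code - 33L) < phred_min
  }
  counted <- has_anchor & !has_n & !low_q
  counts <- table(kmer[counted])
  counts <- setNames(as.integer(counts), names(counts))
  structure(
    list(condition = condition %||% NA_character_,
         counts = counts,
         total = sum(counts),
         excluded = c(no_anchor = sum(!has_anchor),
                      ambiguous_N = sum(has_n),
                      low_phred = sum(low_q))),
    class = "pfs_counts"
  )
}

# mismatch-tolerant anchor location; returns the 1-based start of the 5-mer
# for the first upstream-anchor hit with a compatible downstream anchor
fuzzy_anchor_positions <- function(seqs, up, down, max_mm) {
  n_up <- nchar(up)
  n_down <- nchar(down)
  vapply(seqs, function(s) {
    subject <- Biostrings::DNAString(s)
    hits <- Biostrings::matchPattern(up, subject, max.mismatch = max_mm,
                                     with.indels = FALSE)
    for (st in Biostrings::start(hits)) {
      dstart <- st + n_up + 5L
      if (dstart + n_down - 1L > nchar(s)) next
      mm <- sum(utf8ToInt(substr(s, dstart, dstart + n_down - 1L)) !=
                  utf8ToInt(down))
      if (mm <= max_mm) return(st + n_up)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' @export
print.pfs_counts <- function(x, ...) {
  cat("<pfs_counts>", x$condition, "\n")
  cat("  counted:", x$total, "5-mer observations over",
      length(x$counts), "distinct 5-mers\n")
  cat("  excluded:", paste(names(x$excluded), x$excluded, collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-5-mer depletion scores between conditions
#'
#' For 5-mer `k` with counts `c_t` / `c_nt` and counted totals `T_t` /
#' `T_nt`, the printed score is
#' `(T_nt/T_t) * (c_t + alpha) / (c_nt + alpha)`, its reciprocal the fold
#' score (high = depleted under target), and `log2_printed = log2(printed)`.
#' 5-mers absent from both conditions are omitted.
#'
#' @param counts_t,counts_nt `pfs_counts` for the target and non-target
#'   condition.
#' @param pseudocount alpha added to each 5-mer count (default 1).
#' @return tibble `pfs, count_t, count_nt, score_printed, score_fold,
#'   log2_printed`.
#' @export
pfs_depletion <- function(counts_t, counts_nt, pseudocount = 1) {
  a <- pseudocount
  if (counts_t$total == 0L || counts_nt$total == 0L) {
    stop("zero counted reads in one condition")
  }
  kmers <- sort(union(names(counts_t$counts), names(counts_nt$counts)))
  c_t <- unname(ifelse(kmers %in% names(counts_t$counts),
                       counts_t$counts[kmers], 0L))
  c_nt <- unname(ifelse(kmers %in% names(counts_nt$counts),
                        counts_nt$counts[kmers], 0L))
  printed <- (counts_nt$total / counts_t$total) * (c_t + a) / (c_nt + a)
  tibble(
    pfs = kmers, count_t = as.integer(c_t), count_nt = as.integer(c_nt),
    score_printed = printed, score_fold = 1 / printed,
    log2_printed = log2(printed)
  )
}

#' Position-by-nucleotide log2 fold-change matrix
#'
#' Marginal counts `C(i, b)` sum the 5-mer counts of all 5-mers carrying base
#' `b` at PFS position `i` (+1..+5); each cell is
#' `log2((T_nt/T_t) * (C_t(i,b) + alpha) / (C_nt(i,b) + alpha))` in the
#' printed orientation (negative = depleted under target). Marginals are
#' count-weighted (sum then score), so each position's marginals sum to the
#' counted total.
#'
#' @inheritParams pfs_depletion
#' @return 5 x 4 numeric matrix, rows `+1`..`+5`, columns A, C, G, T.
#' @export
position_nucleotide_lfc <- function(counts_t, counts_nt, pseudocount = 1) {
  a <- pseudocount
  if (counts_t$total == 0L || counts_nt$total == 0L) {
    stop("zero counted reads in one condition")
  }
  marg <- function(pc) {
    m <- matrix(0L, nrow = 5L, ncol = 4L,
                dimnames = list(paste0("+", 1:5), DNA_BASES))
    kmers <- names(pc$counts)
    for (i in 1:5) {
      base_i <- substr(kmers, i, i)
      agg <- tapply(pc$counts, base_i, sum)
      m[i, names(agg)] <- as.integer(agg)
    }
    m
  }
  m_t <- marg(counts_t)
  m_nt <- marg(counts_nt)
  log2((counts_nt$total / counts_t$total) * (m_t + a) / (m_nt + a))
}

#' Rank 5-mers by fold-depletion
#'
#' Most-depleted first (fold score descending), with a stable lexicographic
#' tie-break on the 5-mer.
#'
#' @param table per-5-mer tibble from [pfs_depletion()].
#' @param top_n number of rows to return (full table if larger).
#' @return the reordered (and truncated) tibble.
#' @export
rank_pfs <- function(table, top_n = Inf) {
  if (nrow(table) == 0L) stop("empty PFS table")
  out <- table[order(-table$score_fold, table$pfs), , drop = FALSE]
  head(out, n = min(top_n, nrow(out)))
}
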