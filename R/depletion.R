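# The core two-condition statistic: per-nucleotide depletion scores,
# per-reference z-scores, visualization clamping and cleavage-site calls.

#' Per-nucleotide depletion scores for one target/non-target pair
#'
#' At position `p` with per-position coverage `c_t(p)` / `c_nt(p)` and
#' per-reference mapped totals `S_t` / `S_nt`, the printed-orientation score
#' is
#' \deqn{(S_{nt}/S_t) \times (c_t(p)+\alpha)/(c_nt(p)+\alpha)}
#' (below 1 where target coverage is depleted). The working `score` column is
#' its reciprocal ("fold-depletion": high = depleted), which is the
#' orientation that a positive z-score threshold and a 0-2 colour clamp act
#' on; both orientations are always emitted. The pseudocount applies to
#' per-position counts only, never to totals, and positions with zero raw
#' coverage in both conditions are masked (`NA` scores).
#'
#' @param cov_t,cov_nt coverage tibbles from [coverage_profile()] for the
#'   target and non-target condition (may span several references; they are
#'   matched by `ref_id` and must agree on reference lengths).
#' @param pseudocount alpha added to each per-position count (default 1).
#' @param pair_id label for this replicate pair.
#' @return a depletion tibble: `ref_id`, `pair_id`, `position`, `score`
#'   (fold-depletion), `score_printed`, `z`, `z_vis` (filled by
#'   [zscores()]), `masked`, `total_t`, `total_nt`, `length`.
#' @export
depletion_profile <- function(cov_t, cov_nt, pseudocount = 1,
                              pair_id = NA_character_) {
  a <- pseudocount
  merged <- inner_join(
    cov_t[, c("ref_id", "position", "count", "total_mapped", "length")],
    cov_nt[, c("ref_id", "position", "count", "total_mapped", "length")],
    by = c("ref_id", "position"), suffix = c("_t", "_nt")
  )
  per_ref_t <- tapply(cov_t$position, cov_t$ref_id, length)
  per_ref_m <- tapply(merged$position, merged$ref_id, length)
  common <- intersect(names(per_ref_t), names(per_ref_m))
  if (any(per_ref_t[common] != per_ref_m[common]) ||
      any(merged$length_t != merged$length_nt)) {
    stop("target/non-target coverage length mismatch")
  }
  if (any(merged$total_mapped_t == 0L) || any(merged$total_mapped_nt == 0L)) {
    bad <- unique(merged$ref_id[merged$total_mapped_t == 0L |
                                  merged$total_mapped_nt == 0L])
    stop("reference(s) with zero mapped reads in one condition: ",
         paste(bad, collapse = ", "))
  }
  masked <- merged$count_t == 0L & merged$count_nt == 0L
  printed <- (merged$total_mapped_nt / merged$total_mapped_t) *
    (merged$count_t + a) / (merged$count_nt + a)
  printed[masked] <- NA_real_
  tibble(
    ref_id = merged$ref_id,
    pair_id = pair_id,
    position = merged$position,
    score = 1 / printed,
    score_printed = printed,
    z = NA_real_,
    z_vis = NA_real_,
    masked = masked,
    count_t = merged$count_t,
    count_nt = merged$count_nt,
    total_t = merged$total_mapped_t,
    total_nt = merged$total_mapped_nt,
    length = merged$length_t
  )
}

#' Reference-wise z-scores of depletion, with the 0-2 visualization clamp
#'
#' For each reference, `z = (score - reference mean) / reference standard
#' deviation`, with mean and population standard deviation (ddof 0) taken
#' over the unmasked fold-depletion scores. A zero-variance reference gets
#' `z = 0` everywhere. `z_vis = min(2, max(0, z))` is for colour maps only;
#' significance always uses the raw `z`. With m unmasked positions the
#' population z is bounded by `sqrt(m - 1)`, so references with fewer than 5
#' unmasked positions can never reach `z >= 2`.
#'
#' @param profile depletion tibble from [depletion_profile()].
#' @return the tibble with `z` and `z_vis` filled.
#' @export
zscores <- function(profile) {
  out <- profile
  for (rid in unique(profile$ref_id)) {
    rows <- which(profile$ref_id == rid)
    s <- profile$score[rows]
    ok <- !profile$masked[rows]
    m <- sum(ok)
    if (m < 2L) {
      stop("fewer than 2 unmasked positions for reference ", rid)
    }
    mu <- mean(s[ok])
    sd_pop <- sqrt(sum((s[ok] - mu)^2) / m)
    z <- rep(NA_real_, length(rows))
    z[ok] <- if (sd_pop == 0) 0 else (s[ok] - mu) / sd_pop
    out$z[rows] <- z
    out$z_vis[rows] <- pmin(2, pmax(0, z))
  }
  out
}

#' Call 3'-truncation cleavage sites across replicate pairs
#'
#' A reference is *detected* when every replicate pair has at least
#' `min_reads` mapped reads in both conditions. Among detected references, a
#' position is consensus-significant when its raw z-score reaches
#' `z_threshold` in the number of replicate pairs that `replicate_rule`
#' requires (`"all"`, `"majority"`, or `"any"`). A reference is *significant*
#' (class `3prime_truncation`) when a consensus-significant position lies
#' within the 3'-terminal `window_3p` positions; if significant positions
#' exist only outside the window the class is `internal`.
#'
#' The apparent product end `e` is the position just 5' of the 3'-terminal
#' contiguous run of consensus-significant positions, and the apparent offset
#' is `length - e`. Because every 3' end was poly(A)-extended before
#' sequencing, a product genuinely ending in adenosines is indistinguishable
#' from a shorter product: with `a` the length of the reference A-run
#' starting at `e + 1`, the reported `offset_range` is
#' `[offset - a, offset]`.
#'
#' @param profiles z-scored depletion tibble spanning one or more replicate
#'   pairs (distinct `pair_id`s) from [zscores()].
#' @param refs reference tibble (sequences are needed for the A-run).
#' @param annotations tRNA end annotations from [annotate_trna_end()].
#' @param z_threshold raw z significance threshold (default 2).
#' @param window_3p width of the 3'-terminal window in nt (default 10).
#' @param min_reads detection threshold per reference per condition per pair
#'   (default 10).
#' @param min_pos_coverage per-position support: a position can only count as
#'   significant in a replicate pair when the non-target condition covers it
#'   at least this many times there (default: `min_reads`). Depletion is
#'   unmeasurable where the control itself has no coverage; without this
#'   floor, the chronically uncovered terminal position (its genuine A is
#'   absorbed into every read's poly(A) tail) produces spurious
#'   single-outlier z-scores from stray error-carrying reads.
#' @param replicate_rule how many replicate pairs must agree (default all).
#' @return a tibble with one row per reference: `ref_id`, `detected`,
#'   `significant`, `offset`, `offset_lo`, `offset_hi`, `max_z`,
#'   `replicates_supporting`, `class`.
#' @export
call_cleavage <- function(profiles, refs, annotations = NULL,
                          z_threshold = 2, window_3p = 10L, min_reads = 10L,
                          min_pos_coverage = min_reads,
                          replicate_rule = c("all", "majority", "any")) {
  replicate_rule <- match.arg(replicate_rule)
  if (!"count_nt" %in% names(profiles)) {
    stop("profiles must carry per-position counts (count_nt); ",
         "build them with depletion_profile()")
  }
  if (is.null(annotations)) {
    if (all(refs$kind == "tRNA")) {
      annotations <- annotate_trna_end(refs)
    } else {
      stop("annotations are required for non-tRNA references")
    }
  }
  pairs <- unique(profiles$pair_id)
  n_pairs <- length(pairs)
  required <- switch(replicate_rule,
                     all = n_pairs,
                     majority = floor(n_pairs / 2) + 1L,
                     any = 1L)
  out <- vector("list", nrow(refs))
  for (i in seq_len(nrow(refs))) {
    rid <- refs$id[i]
    if (!rid %in% annotations$ref_id) {
      stop("missing 3'-end annotation for reference ", rid)
    }
    p <- profiles[profiles$ref_id == rid, , drop = FALSE]
    L <- refs$length[i]
    call <- tibble(ref_id = rid, detected = FALSE, significant = FALSE,
                   offset = NA_integer_, offset_lo = NA_integer_,
                   offset_hi = NA_integer_, max_z = NA_real_,
                   replicates_supporting = 0L, class = "none")
    pair_tot <- unique(p[, c("pair_id", "total_t", "total_nt")])
    detected <- nrow(p) > 0L &&
      all(pairs %in% p$pair_id) &&
      all(pair_tot$total_t >= min_reads & pair_tot$total_nt >= min_reads)
    if (!detected) {
      out[[i]] <- call
      next
    }
    call$detected <- TRUE
    # consensus: positions whose raw z reaches the threshold, with control
    # coverage behind it, in enough pairs
    sig <- !is.na(p$z) & p$z >= z_threshold &
      p$count_nt >= min_pos_coverage
    n_sig <- tapply(sig, p$position, sum)
    positions <- as.integer(names(n_sig))
    consensus <- positions[n_sig >= required]
    window_lo <- L - window_3p + 1L
    in_window <- !is.na(p$z) & p$position >= window_lo
    call$max_z <- if (any(in_window)) max(p$z[in_window]) else NA_real_
    call$replicates_supporting <- length(unique(
      p$pair_id[sig & p$position >= window_lo]))
    if (length(consensus) == 0L) {
      out[[i]] <- call
      next
    }
    if (!any(consensus >= window_lo)) {
      call$class <- "internal"
      out[[i]] <- call
      next
    }
    call$significant <- TRUE
    call$class <- "3prime_truncation"
    # 3'-terminal contiguous run of consensus positions
    run_start <- max(consensus)
    while ((run_start - 1L) %in% consensus) run_start <- run_start - 1L
    e <- run_start - 1L
    offset <- L - e
    a <- a_run_length(refs$seq[i], e + 1L)
    call$offset <- offset
    call$offset_lo <- max(0L, offset - a)
    call$offset_hi <- offset
    out[[i]] <- call
  }
  bind_rows(out)
}

# length of the contiguous A-run starting at 1-based position `from`
a_run_length <- function(seq, from) {
  L <- nchar(seq)
  a <- 0L
  while (from + a <= L && substr(seq, from + a, from + a) == "A") {
    a <- a + 1L
  }
  a
}

#' Wide z_vis matrix for heatmap-style output
#'
#' Rows are references, columns 1-based positions, values the clamped
#' visualization z (0-2 colour-map convention); positions beyond a
#' reference's length, and masked positions, are `NA`.
#'
#' @param profiles z-scored depletion tibble (a single replicate pair, or
#'   pre-averaged scores).
#' @return numeric matrix with reference ids as row names.
#' @export
zvis_matrix <- function(profiles) {
  refs <- unique(profiles$ref_id)
  maxL <- max(profiles$length)
  mat <- matrix(NA_real_, nrow = length(refs), ncol = maxL,
                dimnames = list(refs, seq_len(maxL)))
  for (rid in refs) {
    p <- profiles[profiles$ref_id == rid, , drop = FALSE]
    mat[rid, p$position] <- p$z_vis
  }
  mat
}
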