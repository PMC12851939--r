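# Poly(A) trimming, read-to-reference alignment (built-in k-mer mapper or
# SAM import) and per-position coverage.

#' Trim enzymatic poly(A) tails from read 3' ends
#'
#' Removes the longest 3'-terminal suffix whose A-fraction is at least
#' `min_frac`, whose length is at least `min_len`, and whose first (5'-most)
#' base is an A. The leading-A requirement keeps the removed segment anchored
#' to the A-run itself while still letting the tail absorb isolated non-A
#' bases (sequencing errors inside the tail). Because poly(A) extension is
#' applied to every 3' end, genuine terminal adenosines of the molecule are
#' absorbed into the removed run: this is the ambiguity that the cleavage
#' caller's `offset_range` later accounts for.
#'
#' A read that would be emptied by trimming is flagged `tail_only` (and its
#' trimmed sequence left empty); such reads are dropped before mapping.
#'
#' @param reads read tibble (columns `id`, `seq`, optionally `qual`).
#' @param min_len minimum qualifying suffix length (default 5).
#' @param min_frac minimum A-fraction of the suffix (default 0.9).
#' @return the input tibble with `seq`/`qual` trimmed and new columns
#'   `tail_len` and `tail_only`.
#' @export
trim_polya <- function(reads, min_len = 5L, min_frac = 0.9) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  tail_len <- vapply(reads$seq, polya_tail_len, integer(1),
                     min_len = min_len, min_frac = min_frac,
                     USE.NAMES = FALSE)
  len <- nchar(reads$seq)
  keep <- len - tail_len
  out <- reads
  out$seq <- substr(reads$seq, 1L, keep)
  if ("qual" %in% names(reads)) {
    out$qual <- ifelse(is.na(reads$qual), NA_character_,
                       substr(reads$qual, 1L, keep))
  }
  out$tail_len <- tail_len
  out$tail_only <- keep == 0L
  out
}

# length of the removed tail for one sequence (0 if no suffix qualifies)
polya_tail_len <- function(seq, min_len, min_frac) {
  L <- nchar(seq)
  if (L == 0L) return(0L)
  is_a_rev <- rev(utf8ToInt(seq) == 65L) # 'A', scanning 3' -> 5'
  j <- seq_len(L)
  valid <- is_a_rev & (cumsum(is_a_rev) / j >= min_frac) & (j >= min_len)
  if (!any(valid)) 0L else max(which(valid))
}

#' Assign reads to references with a minimal k-mer seed-and-extend mapper
#'
#' Exact k-mer seeds vote for (reference, diagonal) pairs; the best diagonal
#' per candidate reference is scored by ungapped extension (number of
#' matching bases over the read/reference overlap). The pseudo-MAPQ is
#' `min(60, 6 * (best - second best score))`, so a read matching two
#' references equally gets MAPQ 0 and is removed by the downstream MAPQ
#' filter. Reads shorter than `seed_k`, or with no seed hit, are unmapped.
#'
#' This is a deliberately small stand-in for an external long-read mapper,
#' calibrated only to separate unique from ambiguous assignments on
#' poly(A)-trimmed reads against mutually distinct references; import real
#' alignments with [import_sam()] instead when available.
#'
#' @param reads poly(A)-trimmed read tibble.
#' @param refs reference tibble.
#' @param seed_k seed k-mer length (default 13).
#' @param mapq_min alignments below this MAPQ are dropped (default 20).
#' @return alignment tibble (`read_id`, `ref_id`, `ref_start` 0-based,
#'   `ref_end` exclusive, `mapq`, `primary`, plus the read's `condition` /
#'   `replicate` when present), with an `unmapped` attribute counting reads
#'   without a retained alignment.
#' @export
map_reads <- function(reads, refs, seed_k = 13L, mapq_min = 20L) {
  stopifnot(nrow(refs) > 0L)
  drop <- reads$seq == ""
  if ("tail_only" %in% names(reads)) drop <- drop | reads$tail_only
  reads <- reads[!drop, , drop = FALSE]
  n_reads <- nrow(reads)
  if (n_reads == 0L) {
    return(empty_alignments(reads, unmapped = 0L))
  }
  idx <- kmer_table(refs$seq, seed_k, id = seq_len(nrow(refs)))
  data.table::setkey(idx, kmer)
  qlen <- nchar(reads$seq)
  mappable <- which(qlen >= seed_k)
  rt <- kmer_table(reads$seq[mappable], seed_k, id = mappable)
  data.table::setnames(rt, c("id", "pos"), c("read", "qpos"))
  hits <- idx[rt, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hits) == 0L) {
    return(empty_alignments(reads, unmapped = n_reads))
  }
  hits[, diag := pos - qpos]
  votes <- hits[, .N, by = .(read, id, diag)]
  # best diagonal per (read, ref); deterministic tie-break on smallest diag
  data.table::setorder(votes, read, id, -N, diag)
  best_diag <- votes[, .SD[1L], by = .(read, id)]

  ref_ints <- lapply(refs$seq, utf8ToInt)
  ref_len <- refs$length
  cand_by_read <- split(best_diag, by = "read")
  aln <- vector("list", length(cand_by_read))
  for (ci in seq_along(cand_by_read)) {
    cand <- cand_by_read[[ci]]
    r <- cand$read[1L]
    q_int <- utf8ToInt(reads$seq[r])
    ql <- length(q_int)
    scores <- numeric(nrow(cand))
    starts <- integer(nrow(cand))
    ends <- integer(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      d <- cand$diag[j]
      ref_i <- cand$id[j]
      qs <- max(0L, -d)
      qe <- min(ql, ref_len[ref_i] - d)
      if (qe <= qs) next
      scores[j] <- sum(q_int[(qs + 1L):qe] ==
                         ref_ints[[ref_i]][(qs + d + 1L):(qe + d)])
      starts[j] <- qs + d
      ends[j] <- qe + d
    }
    o <- order(-scores, cand$id)
    s1 <- scores[o[1L]]
    s2 <- if (length(o) > 1L) scores[o[2L]] else 0
    mapq <- as.integer(min(60, 6 * (s1 - s2)))
    aln[[ci]] <- list(read = r, ref = cand$id[o[1L]],
                      ref_start = starts[o[1L]], ref_end = ends[o[1L]],
                      mapq = mapq)
  }
  aln <- data.table::rbindlist(aln)
  aln <- aln[mapq >= mapq_min]
  out <- tibble(
    read_id = reads$id[aln$read],
    ref_id = refs$id[aln$ref],
    ref_start = aln$ref_start,
    ref_end = aln$ref_end,
    mapq = aln$mapq,
    primary = TRUE
  )
  for (extra in intersect(c("condition", "replicate"), names(reads))) {
    out[[extra]] <- reads[[extra]][aln$read]
  }
  attr(out, "unmapped") <- n_reads - nrow(out)
  out
}

kmer_table <- function(seqs, k, id) {
  lens <- nchar(seqs)
  keep <- lens >= k
  pieces <- lapply(which(keep), function(i) {
    n <- lens[i] - k + 1L
    data.table::data.table(id = id[i], pos = 0:(n - 1L),
                           kmer = substring(seqs[i], 1:n, k:lens[i]))
  })
  if (length(pieces) == 0L) {
    return(data.table::data.table(id = integer(), pos = integer(),
                                  kmer = character()))
  }
  data.table::rbindlist(pieces)
}

empty_alignments <- function(reads, unmapped) {
  out <- tibble(read_id = character(), ref_id = character(),
                ref_start = integer(), ref_end = integer(),
                mapq = integer(), primary = logical())
  for (extra in intersect(c("condition", "replicate"), names(reads))) {
    out[[extra]] <- reads[[extra]][0]
  }
  attr(out, "unmapped") <- unmapped
  out
}

#' Import alignments from a SAM file
#'
#' Retains only mapped, primary (neither secondary nor supplementary) records
#' with MAPQ at or above `mapq_min`; `ref_start`/`ref_end` come from POS plus
#' the reference-consuming CIGAR operations.
#'
#' @param path path to a SAM file with a header.
#' @param refs reference tibble; every RNAME must resolve against it.
#' @param mapq_min MAPQ filter threshold, inclusive (default 20: a MAPQ 19
#'   record is excluded, a MAPQ 20 record retained).
#' @return alignment tibble as from [map_reads()].
#' @export
import_sam <- function(path, refs, mapq_min = 20L) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, use.names = TRUE,
    param = Rsamtools::ScanBamParam(flag = flags, what = "mapq"))
  rname <- as.character(GenomicAlignments::seqnames(ga))
  unknown <- setdiff(unique(rname), refs$id)
  if (length(unknown) > 0L) {
    stop("SAM references not in the loaded reference set: ",
         paste(unknown, collapse = ", "))
  }
  mapq <- S4Vectors::mcols(ga)$mapq
  keep <- !is.na(mapq) & mapq >= mapq_min
  ga <- ga[keep]
  tibble(
    read_id = names(ga),
    ref_id = as.character(GenomicAlignments::seqnames(ga)),
    ref_start = GenomicAlignments::start(ga) - 1L,
    ref_end = GenomicAlignments::end(ga),
    mapq = as.integer(S4Vectors::mcols(ga)$mapq),
    primary = TRUE
  )
}

#' Per-position read coverage for each reference
#'
#' `count[p]` is the number of retained alignments overlapping 1-based
#' position `p` (i.e. with `ref_start < p <= ref_end`); `total_mapped` is the
#' number of retained primary alignments to the reference in this
#' condition/replicate. Mismatches inside an alignment still cover: coverage
#' counts read overlap, not base-level identity.
#'
#' @param alignments filtered alignment tibble.
#' @param refs reference tibble (references without alignments get all-zero
#'   counts).
#' @param condition,replicate labels recorded in the output (taken from the
#'   alignment tibble when present there).
#' @return tibble with columns `ref_id`, `condition`, `replicate`,
#'   `position`, `count`, `total_mapped`, `length`.
#' @export
coverage_profile <- function(alignments, refs, condition = NA_character_,
                             replicate = NA_integer_) {
  if (nrow(alignments) > 0L) {
    if (is.na(condition) && "condition" %in% names(alignments)) {
      condition <- unique(alignments$condition)
      stopifnot(length(condition) == 1L)
    }
    if (is.na(replicate) && "replicate" %in% names(alignments)) {
      replicate <- unique(alignments$replicate)
      stopifnot(length(replicate) == 1L)
    }
  }
  out <- vector("list", nrow(refs))
  for (i in seq_len(nrow(refs))) {
    L <- refs$length[i]
    a <- alignments[alignments$ref_id == refs$id[i], , drop = FALSE]
    if (nrow(a) > 0L && (any(a$ref_start < 0L) || any(a$ref_end > L) ||
                         any(a$ref_start >= a$ref_end))) {
      stop("alignment outside reference bounds for ", refs$id[i])
    }
    inc <- tabulate(a$ref_start + 1L, nbins = L)
    dec <- tabulate(a$ref_end + 1L, nbins = L + 1L)[seq_len(L)]
    counts <- cumsum(inc - dec)
    out[[i]] <- tibble(
      ref_id = refs$id[i], condition = condition,
      replicate = as.integer(replicate),
      position = seq_len(L), count = as.integer(counts),
      total_mapped = nrow(a), length = L
    )
  }
  bind_rows(out)
}
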