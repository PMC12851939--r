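# Synthetic-data generators with known ground truth: tRNA-like references,
# direct-RNA-style reads (3'-truncation + poly(A) extension + substitution
# noise) and randomized PFS amplicon libraries.
#
# Determinism contract: every generator takes an explicit seed and derives
# per-(reference, condition, replicate) RNG substreams from it, so identical
# configurations give byte-identical output regardless of the caller's RNG
# state or of which subsets are generated.

#' Generate tRNA-like reference sequences
#'
#' Random references of tRNA-typical length, each ending in a discriminator
#' base followed by the conserved `CCA` tail. References are regenerated until
#' every pair differs by a Hamming distance of at least 10 over their first
#' 40 nt, so that short reads can be assigned uniquely by the built-in mapper.
#'
#' @param n_refs number of references (>= 1).
#' @param length_range integer length range (min >= 60), sampled uniformly.
#' @param seed integer seed; the same call is byte-identical.
#' @param min_hamming,hamming_span distinctness requirement over the leading
#'   `hamming_span` nt.
#' @return list with `references` (tibble as from [read_fasta()]) and
#'   `annotations` (tibble as from [annotate_trna_end()]).
#' @export
make_trna_references <- function(n_refs, length_range = c(70L, 90L), seed,
                                 min_hamming = 10L, hamming_span = 40L) {
  if (missing(seed)) stop("an explicit seed is required")
  if (n_refs < 1L) stop("n_refs must be >= 1")
  if (min(length_range) < 60L) stop("reference lengths must be >= 60 nt")
  refs <- with_substream(seed, "make_trna_references", code = {
    lens <- sample(seq(length_range[1], length_range[2]), n_refs,
                   replace = TRUE)
    seqs <- character(n_refs)
    for (i in seq_len(n_refs)) {
      ok <- FALSE
      for (try in seq_len(100L)) {
        body <- random_dna(lens[i] - 4L)
        cand <- paste0(body, sample(DNA_BASES, 1L), "CCA")
        ok <- all(vapply(seqs[seq_len(i - 1L)], function(prev) {
          hamming_prefix(cand, prev, hamming_span) >= min_hamming
        }, logical(1)))
        if (ok) {
          seqs[i] <- cand
          break
        }
      }
      if (!ok) stop("could not generate ", n_refs,
                    " mutually distinct references after 100 retries")
    }
    tibble(id = sprintf("tRNA_%02d", seq_len(n_refs)), seq = seqs,
           kind = "tRNA", length = nchar(seqs))
  })
  list(references = refs, annotations = annotate_trna_end(refs))
}

hamming_prefix <- function(a, b, span) {
  n <- min(nchar(a), nchar(b), span)
  sum(utf8ToInt(substr(a, 1, n)) != utf8ToInt(substr(b, 1, n)))
}

#' Specify a tRNA cleavage / sequencing model
#'
#' Describes how target-condition reads are generated: each read of a
#' reference with cleavage efficiency `phi` is truncated (Bernoulli(`phi`))
#' by an offset drawn from `offset_weights` (nucleotides removed from the 3'
#' end); every read, cleaved or not and in either condition, then receives a
#' poly(A) tail of uniform length `polya_len[1]..polya_len[2]` and per-base
#' substitution noise at `error_rate` (tails are error-free). Under the
#' non-target condition `phi` is forced to 0.
#'
#' @param efficiency_by_ref named numeric vector, `ref_id -> phi` in `[0,1]`.
#' @param offset_weights named numeric vector, offset (nt) -> probability;
#'   normalized to sum to 1. Defaults to equal weight on 3, 4 and 5 nt
#'   (in vitro pattern); the TXTL pattern uses `offset_preset("txtl")`
#'   (2-4 nt).
#' @param polya_len integer `c(min, max)` of the appended tail length.
#' @param error_rate per-base substitution probability in `[0,1]`.
#' @param seed integer seed.
#' @param offset_mode `"per_read"` draws an offset independently for every
#'   cleaved read; `"per_ref"` draws one characteristic offset per reference
#'   (each tRNA has a single dominant cleavage site).
#' @return an object of class `cleavage_model`.
#' @export
cleavage_model <- function(efficiency_by_ref,
                           offset_weights = offset_preset("invitro"),
                           polya_len = c(10L, 30L),
                           error_rate = 0.005,
                           seed,
                           offset_mode = c("per_read", "per_ref")) {
  if (missing(seed)) stop("an explicit seed is required")
  offset_mode <- match.arg(offset_mode)
  if (is.null(names(efficiency_by_ref))) {
    stop("efficiency_by_ref must be a named vector (ref_id -> phi)")
  }
  if (any(efficiency_by_ref < 0 | efficiency_by_ref > 1)) {
    stop("cleavage efficiency phi must lie in [0, 1]")
  }
  offs <- as.integer(names(offset_weights))
  if (any(is.na(offs)) || any(offs < 1L)) {
    stop("offset_weights must be named by positive integer offsets")
  }
  if (any(offset_weights < 0) || sum(offset_weights) <= 0) {
    stop("offset_weights must be non-negative and sum to a positive value")
  }
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (length(polya_len) != 2L || polya_len[1] > polya_len[2] ||
      polya_len[1] < 0L) {
    stop("polya_len must be c(min, max) with 0 <= min <= max")
  }
  structure(
    list(efficiency_by_ref = efficiency_by_ref,
         offset_weights = offset_weights / sum(offset_weights),
         polya_len = as.integer(polya_len),
         error_rate = error_rate,
         seed = as.integer(seed),
         offset_mode = offset_mode),
    class = "cleavage_model"
  )
}

#' Cleavage offset presets
#'
#' `"invitro"` puts equal weight on offsets 3-5 nt (cleavage three to five
#' nucleotides upstream of the tRNA 3' end); `"txtl"` on 2-4 nt.
#'
#' @param preset `"invitro"` or `"txtl"`.
#' @return named numeric vector of offset weights.
#' @export
offset_preset <- function(preset = c("invitro", "txtl")) {
  preset <- match.arg(preset)
  offs <- if (preset == "invitro") 3:5 else 2:4
  setNames(rep(1 / 3, 3), offs)
}

#' @export
print.cleavage_model <- function(x, ...) {
  cat("<cleavage_model>\n")
  cat("  refs:", length(x$efficiency_by_ref),
      " phi range:", paste(range(x$efficiency_by_ref), collapse = "-"), "\n")
  cat("  offsets:", paste(sprintf("%s(%.2f)", names(x$offset_weights),
                                  x$offset_weights), collapse = " "), "\n")
  cat("  poly(A):", paste(x$polya_len, collapse = "-"),
      "nt  error:", x$error_rate, " seed:", x$seed,
      " offset_mode:", x$offset_mode, "\n")
  invisible(x)
}

#' Simulate direct-RNA-style reads with known cleavage truth
#'
#' Under the target condition each read is truncated with probability `phi`
#' by an offset drawn from the model's offset distribution; under the
#' non-target condition no read is truncated. Every 3' end (cleaved or not)
#' then receives an error-free poly(A) tail, and the pre-tail sequence gets
#' per-base substitution noise. Read counts are exact: `n_reads_per_ref`
#' reads per reference per condition per replicate.
#'
#' @param refs reference tibble.
#' @param model a [cleavage_model()].
#' @param n_reads_per_ref reads per reference per condition per replicate.
#' @param conditions character subset of `c("target", "non_target")`.
#' @param replicates integer vector of replicate indices.
#' @return list with `reads` (tibble `id, seq, qual, condition, replicate`)
#'   and `truth` (tibble `read_id, ref_id, condition, replicate, truncated,
#'   offset, polya_len`).
#' @export
simulate_direct_rna_reads <- function(refs, model, n_reads_per_ref,
                                      conditions = c("target", "non_target"),
                                      replicates = 1:3) {
  stopifnot(inherits(model, "cleavage_model"))
  if (nrow(refs) == 0L) stop("refs must be non-empty")
  conditions <- match.arg(conditions, several.ok = TRUE)
  offs <- as.integer(names(model$offset_weights))
  if (max(offs) >= min(refs$length)) {
    stop("cleavage offset (", max(offs),
         ") must be smaller than the shortest reference (",
         min(refs$length), " nt)")
  }
  phi_all <- model$efficiency_by_ref
  missing_phi <- setdiff(refs$id, names(phi_all))
  if (length(missing_phi) > 0L) {
    stop("efficiency_by_ref lacks entries for: ",
         paste(missing_phi, collapse = ", "))
  }
  # per-reference characteristic offset (used when offset_mode == "per_ref");
  # drawn from a stream keyed only by (seed, ref) so it is identical across
  # conditions and replicates
  ref_offset <- setNames(vapply(refs$id, function(rid) {
    with_substream(model$seed, "ref_offset", rid, code = {
      offs[sample.int(length(offs), 1L, prob = model$offset_weights)]
    })
  }, integer(1)), refs$id)

  out <- vector("list", nrow(refs) * length(conditions) * length(replicates))
  k <- 0L
  for (i in seq_len(nrow(refs))) {
    rid <- refs$id[i]
    rseq <- refs$seq[i]
    L <- refs$length[i]
    for (cond in conditions) {
      phi <- if (cond == "target") unname(phi_all[rid]) else 0
      for (rep_i in replicates) {
        k <- k + 1L
        out[[k]] <- with_substream(
          model$seed, "reads", rid, cond, rep_i, code = {
            n <- n_reads_per_ref
            truncated <- stats::runif(n) < phi
            offset <- rep(NA_integer_, n)
            n_trunc <- sum(truncated)
            if (n_trunc > 0L) {
              offset[truncated] <- if (model$offset_mode == "per_ref") {
                rep(ref_offset[[rid]], n_trunc)
              } else {
                offs[sample.int(length(offs), n_trunc, replace = TRUE,
                                prob = model$offset_weights)]
              }
            }
            keep_len <- ifelse(truncated, L - offset, L)
            polya <- sample(seq(model$polya_len[1], model$polya_len[2]),
                            n, replace = TRUE)
            body <- substr(rep(rseq, n), 1L, keep_len)
            if (model$error_rate > 0) {
              body <- mutate_bases(body, model$error_rate)
            }
            seqs <- paste0(body, strrep("A", polya))
            ids <- sprintf("%s|%s|r%d|%05d", rid, cond, rep_i, seq_len(n))
            list(
              reads = tibble(id = ids, seq = seqs,
                             qual = strrep("I", nchar(seqs)),
                             condition = cond,
                             replicate = as.integer(rep_i)),
              truth = tibble(read_id = ids, ref_id = rid, condition = cond,
                             replicate = as.integer(rep_i),
                             truncated = truncated, offset = offset,
                             polya_len = as.integer(polya))
            )
          })
      }
    }
  }
  list(reads = bind_rows(lapply(out, `[[`, "reads")),
       truth = bind_rows(lapply(out, `[[`, "truth")))
}

# substitution-only noise: each base flips to one of the three others with
# probability `rate`
mutate_bases <- function(seqs, rate) {
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}
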