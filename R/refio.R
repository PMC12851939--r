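# Reference and read I/O: FASTA references, FASTQ reads, tRNA 3'-end
# annotation. Sequences are stored uppercase over {A,C,G,T} (U -> T on input).

#' Read a FASTA file of reference sequences
#'
#' Parses a FASTA file into a reference table. Sequences are case-folded to
#' upper case and U is normalized to T; any other character outside
#' `{A,C,G,T}` is a parse error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @param kind reference kind for all records (`"tRNA"`, `"rRNA"` or
#'   `"other"`), or a two-column data frame / TSV path with columns
#'   `id`, `kind` assigning kinds per record.
#' @return a tibble with columns `id`, `seq`, `kind`, `length`.
#' @export
read_fasta <- function(path, kind = "other") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty FASTA input: ", path)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA input (no records): ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(normalize_seq(as.character(set)))
  bad <- vapply(seqs, function(s) !is.null(bad_alphabet_pos(s)), logical(1))
  if (any(bad)) {
    stop("non-ACGTU characters in FASTA record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  kinds <- resolve_kinds(ids, kind)
  tibble(id = ids, seq = seqs, kind = kinds, length = nchar(seqs))
}

resolve_kinds <- function(ids, kind) {
  valid <- c("tRNA", "rRNA", "other")
  if (is.character(kind) && length(kind) == 1L && file.exists(kind) &&
      !kind %in% valid) {
    kind <- read.table(kind, header = FALSE, sep = "\t",
                       col.names = c("id", "kind"),
                       stringsAsFactors = FALSE)
  }
  if (is.data.frame(kind)) {
    k <- kind$kind[match(ids, kind$id)]
    k[is.na(k)] <- "other"
    kind <- k
  } else {
    kind <- rep(match.arg(kind, valid), length(ids))
  }
  if (!all(kind %in% valid)) stop("reference kind must be one of ",
                                  paste(valid, collapse = "/"))
  kind
}

#' Write references to FASTA
#' @param refs reference tibble as from [read_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refs, path) {
  set <- Biostrings::DNAStringSet(setNames(refs$seq, refs$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Annotate the 3' end of tRNA references
#'
#' Locates the CCA tail and the discriminator base (the unpaired nucleotide
#' immediately 5' of the CCA). Positions are 1-based; `has_cca` is true iff
#' the final three bases are exactly `CCA`, in which case `cca_start` is
#' `length - 2` and `discriminator_pos` is `length - 3` (the discriminator of
#' a minimal 4-nt `ACCA` sequence is position 1).
#'
#' @param refs reference tibble; every row must have `kind == "tRNA"`.
#' @return tibble with columns `ref_id`, `has_cca`, `cca_start`,
#'   `discriminator_pos` (the last two `NA` when there is no CCA tail).
#' @export
annotate_trna_end <- function(refs) {
  stopifnot(is.data.frame(refs), all(c("id", "seq") %in% names(refs)))
  if (!all(refs$kind == "tRNA")) {
    stop("annotate_trna_end() expects tRNA references only")
  }
  len <- nchar(refs$seq)
  if (any(len < 4L)) {
    stop("tRNA reference(s) shorter than 4 nt: ",
         paste(refs$id[len < 4L], collapse = ", "))
  }
  has_cca <- substr(refs$seq, len - 2L, len) == "CCA"
  tibble(
    ref_id = refs$id,
    has_cca = has_cca,
    cca_start = ifelse(has_cca, len - 2L, NA_integer_),
    discriminator_pos = ifelse(has_cca, len - 3L, NA_integer_)
  )
}

#' Read a FASTQ file into a read table
#'
#' Phred+33 encoding is assumed. Sequences are normalized to the canonical
#' `{A,C,G,T}` alphabet (plus `N`, which downstream extraction rules handle
#' explicitly); a record whose quality string length differs from its
#' sequence length is a parse error reporting the record index.
#'
#' @param path path to a FASTQ file.
#' @param condition condition label, `"target"` or `"non_target"`.
#' @param replicate small integer replicate index.
#' @return tibble with columns `id`, `seq`, `qual`, `condition`, `replicate`.
#' @export
read_fastq <- function(path, condition = c("target", "non_target"),
                       replicate = 1L) {
  condition <- match.arg(condition)
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  validate_fastq_structure(path)
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) stop("malformed FASTQ in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    ),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(normalize_seq(as.character(set)))
  quals <- unname(as.character(Biostrings::quality(set)))
  tibble(id = ids, seq = seqs, qual = quals,
         condition = condition, replicate = as.integer(replicate))
}

# Structural pre-check of a 4-line-per-record FASTQ so that malformed input
# fails with the record index rather than an opaque decoder error. Biostrings
# remains the actual parser.
validate_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ in ", path, ": truncated record ",
         length(lines) %/% 4L + 1L)
  }
  rec <- seq_len(length(lines) / 4L)
  l1 <- lines[(rec - 1L) * 4L + 1L]
  l2 <- lines[(rec - 1L) * 4L + 2L]
  l3 <- lines[(rec - 1L) * 4L + 3L]
  l4 <- lines[(rec - 1L) * 4L + 4L]
  bad_marker <- which(!startsWith(l1, "@") | !startsWith(l3, "+"))
  if (length(bad_marker) > 0L) {
    stop("malformed FASTQ in ", path, ": bad record marker at record(s) ",
         paste(head(bad_marker, 5), collapse = ", "))
  }
  mism <- which(nchar(l2) != nchar(l4))
  if (length(mism) > 0L) {
    stop("malformed FASTQ in ", path,
         ": seq/qual length mismatch at record(s) ",
         paste(head(mism, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a read table to FASTQ (Phred+33)
#'
#' Round-trips with [read_fastq()]: write-then-read is the identity on
#' `(id, seq, qual)`. Reads lacking a quality string are written with a
#' constant Phred 40.
#'
#' @param reads tibble with columns `id`, `seq` and optionally `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else NA_character_
  qual <- ifelse(is.na(qual), strrep("I", nchar(reads$seq)), qual)
  if (any(nchar(qual) != nchar(reads$seq))) {
    stop("seq/qual length mismatch in reads to write")
  }
  # Biostrings warns that (empty) metadata columns are dropped on write
  withCallingHandlers({
    set <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
      Biostrings::PhredQuality(qual)
    )
    Biostrings::writeQualityScaledXStringSet(set, path)
  }, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  invisible(path)
}
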