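# Shared internal helpers: alphabet normalization, Phred codecs, seeded
# substreams. Coordinates are 0-based half-open internally and 1-based
# inclusive in every user-facing table.

DNA_BASES <- c("A", "C", "G", "T")

.datatable.aware <- TRUE

utils::globalVariables(c("diag", "pos", "qpos", "read", "id", "N", "mapq",
                         ".SD"))

#' Normalize a nucleotide string to the canonical DNA alphabet
#'
#' Uppercases and maps U to T. Used on every sequence read from disk so the
#' whole package works over a single `{A,C,G,T}` alphabet (basecalled FASTQ
#' and SAM use T).
#'
#' @param x character vector of sequences.
#' @return character vector over the canonical alphabet.
#' @keywords internal
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# positions (1-based) of characters outside {A,C,G,T}; NULL if clean
bad_alphabet_pos <- function(seq) {
  hits <- gregexpr("[^ACGT]", seq)[[1]]
  if (hits[1] == -1L) NULL else as.integer(hits)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual character vector of Phred+33-encoded quality strings.
#' @return list of integer vectors (one per input string).
#' @export
#' @examples
#' phred_scores("IIII")[[1]] # 40 40 40 40
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(NA_integer_)
    as.integer(charToRaw(q)) - 33L
  })
}

#' Encode integer Phred scores as a Phred+33 string
#' @param scores integer vector of Phred scores.
#' @return length-1 character string.
#' @export
phred_string <- function(scores) {
  rawToChar(as.raw(as.integer(scores) + 33L))
}

# Deterministic 31-bit substream seed from a base seed plus arbitrary keys
# (ref id, condition, replicate, ...). Plain polynomial string hash; all
# arithmetic stays < 2^53 so doubles are exact.
substream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "\r")
  h <- 5381
  for (v in utf8ToInt(key)) h <- (h * 33 + v) %% 2147483629
  as.integer(h)
}

# run code under a derived seed without touching the caller's RNG state
with_substream <- function(seed, ..., code) {
  withr::with_seed(substream_seed(seed, ...), code)
}

# random DNA string(s): n strings of the given lengths
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
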