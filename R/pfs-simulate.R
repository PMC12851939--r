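# Randomized-PFS amplicon simulator: a 1,024-member NNNNN cassette between
# fixed anchors, with condition-dependent depletion of a "functional" subset.

PFS_UPSTREAM_ANCHOR <- "TTCCTTCAGGTGTTGCTCCA"
PFS_DOWNSTREAM_ANCHOR <- "GGTGAGTTCT"

#' Enumerate the randomized PFS cassette
#'
#' @return character vector of all `4^5 = 1024` 5-mers over `{A,C,G,T}`,
#'   lexicographically sorted.
#' @export
pfs_library <- function() {
  g <- expand.grid(p5 = DNA_BASES, p4 = DNA_BASES, p3 = DNA_BASES,
                   p2 = DNA_BASES, p1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3, g$p4, g$p5))
}

#' Default functional-PFS predicate: purine at positions +1 and +2
#'
#' @param kmers character vector of 5-mers.
#' @return logical vector, `TRUE` where positions +1 and +2 are both A or G.
#' @export
pfs_purine_predicate <- function(kmers) {
  substr(kmers, 1, 1) %in% c("A", "G") & substr(kmers, 2, 2) %in% c("A", "G")
}

#' Specify a PFS depletion-screen model
#'
#' Per-5-mer abundances are drawn once from a symmetric Dirichlet (shared by
#' both conditions, mimicking a common plasmid library); under the target
#' condition the functional subset is down-weighted by `depletion_factor`
#' before renormalization, and per-condition counts are multinomial.
#'
#' @param depletion_factor d > 1; expected fold-depletion of functional
#'   5-mers under the target condition. `d = 1` gives the null screen.
#' @param reads_per_condition reads emitted per condition.
#' @param base_abundance symmetric-Dirichlet concentration per 5-mer;
#'   larger values give a more even library.
#' @param functional_predicate function mapping 5-mers to a logical vector;
#'   defaults to [pfs_purine_predicate()].
#' @param corrupt_frac fraction of reads corrupted to exercise the exclusion
#'   rules (half get an N inside the 5-mer, half a Phred score below 20).
#' @param flank_len length of the uniform-random flanks around the anchored
#'   motif.
#' @param seed integer seed.
#' @return an object of class `pfs_model`.
#' @export
pfs_model <- function(depletion_factor = 10,
                      reads_per_condition = 200000L,
                      base_abundance = 50,
                      functional_predicate = pfs_purine_predicate,
                      corrupt_frac = 0.02,
                      flank_len = 15L,
                      seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (depletion_factor < 1) stop("depletion_factor must be >= 1")
  if (base_abundance <= 0) stop("base_abundance must be positive")
  if (corrupt_frac < 0 || corrupt_frac >= 1) {
    stop("corrupt_frac must be in [0, 1)")
  }
  lib <- pfs_library()
  functional <- functional_predicate(lib)
  stopifnot(is.logical(functional), length(functional) == length(lib))
  structure(
    list(library = lib, functional = functional,
         depletion_factor = depletion_factor,
         reads_per_condition = as.integer(reads_per_condition),
         base_abundance = base_abundance,
         corrupt_frac = corrupt_frac,
         flank_len = as.integer(flank_len),
         seed = as.integer(seed)),
    class = "pfs_model"
  )
}

#' @export
print.pfs_model <- function(x, ...) {
  cat("<pfs_model>\n")
  cat("  library:", length(x$library), "5-mers;",
      sum(x$functional), "functional\n")
  cat("  d:", x$depletion_factor,
      " reads/condition:", x$reads_per_condition,
      " Dirichlet conc:", x$base_abundance, "\n")
  cat("  corrupt_frac:", x$corrupt_frac, " flank:", x$flank_len,
      "nt  seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate PFS amplicon reads with known depletion truth
#'
#' Each read is `flank + upstream anchor + 5-mer + downstream anchor + flank`
#' with uniform-random flanks. A `corrupt_frac` fraction of reads per
#' condition is corrupted: an `N` substituted inside the 5-mer, or one of the
#' five 5-mer quality scores dropped below Phred 20.
#'
#' @param model a [pfs_model()].
#' @param conditions character subset of `c("target", "non_target")`.
#' @return list with `reads` (tibble `id, seq, qual, condition, replicate`),
#'   `truth` (tibble `pfs, functional, expected_factor`) and `true_counts`
#'   (tibble `pfs, condition, count` of emitted, pre-corruption counts).
#' @export
simulate_pfs_reads <- function(model,
                               conditions = c("target", "non_target")) {
  stopifnot(inherits(model, "pfs_model"))
  conditions <- match.arg(conditions, several.ok = TRUE)
  lib <- model$library
  n_lib <- length(lib)
  if (model$reads_per_condition < n_lib) {
    warning("reads_per_condition (", model$reads_per_condition,
            ") is below the library size (", n_lib, "): sparse library")
  }
  abund <- with_substream(model$seed, "pfs_abundance", code = {
    a <- stats::rgamma(n_lib, shape = model$base_abundance, rate = 1)
    a / sum(a)
  })
  reads <- list()
  counts <- list()
  for (cond in conditions) {
    w <- abund
    if (cond == "target") {
      w[model$functional] <- w[model$functional] / model$depletion_factor
    }
    w <- w / sum(w)
    res <- with_substream(model$seed, "pfs_reads", cond, code = {
      cnt <- as.integer(stats::rmultinom(1L, model$reads_per_condition, w))
      kmers <- rep(lib, cnt)
      n <- length(kmers)
      kmers <- sample(kmers) # shuffle emission order
      seqs <- paste0(random_flanks(n, model$flank_len),
                     PFS_UPSTREAM_ANCHOR, kmers, PFS_DOWNSTREAM_ANCHOR,
                     random_flanks(n, model$flank_len))
      qual <- strrep("I", nchar(seqs))
      n_corrupt <- round(model$corrupt_frac * n)
      if (n_corrupt > 0L) {
        pick <- sample.int(n, n_corrupt)
        half <- pick[seq_len(floor(n_corrupt / 2))]
        other <- setdiff(pick, half)
        kpos <- model$flank_len + nchar(PFS_UPSTREAM_ANCHOR) +
          sample.int(5L, n_corrupt, replace = TRUE)
        # N inside the 5-mer
        for (j in seq_along(half)) {
          substr(seqs[half[j]], kpos[j], kpos[j]) <- "N"
        }
        # low Phred inside the 5-mer ('+' encodes Phred 10)
        for (j in seq_along(other)) {
          jj <- length(half) + j
          substr(qual[other[j]], kpos[jj], kpos[jj]) <- "+"
        }
      }
      list(reads = tibble(
             id = sprintf("pfs|%s|%06d", cond, seq_len(n)),
             seq = seqs, qual = qual, condition = cond, replicate = 1L),
           counts = tibble(pfs = lib, condition = cond, count = cnt))
    })
    reads[[cond]] <- res$reads
    counts[[cond]] <- res$counts
  }
  list(
    reads = bind_rows(reads),
    truth = tibble(
      pfs = lib, functional = model$functional,
      expected_factor = ifelse(model$functional, model$depletion_factor, 1)),
    true_counts = bind_rows(counts)
  )
}

random_flanks <- function(n, len) {
  if (len == 0L) return(rep("", n))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
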