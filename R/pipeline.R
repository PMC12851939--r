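# Pipeline orchestration: file-in/file-out wrappers chaining the simulator,
# mapper and scoring stages, with config snapshots and stage-boundary
# logging. These functions back the thin command-line script shipped at
# inst/cli/trnatail.

#' Run the simulator and write its outputs
#'
#' Writes the reference FASTA, one FASTQ per condition/replicate, the truth
#' tables (TSV) and a JSON config snapshot. Output is deterministic: the
#' same config and seed give byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed (required; there is no default).
#' @param n_refs,length_range passed to [make_trna_references()].
#' @param phi cleavage efficiency, either a single value applied to
#'   `n_cleaved` references (the rest get 0) or a named per-reference vector.
#' @param n_cleaved number of references with nonzero phi when `phi` is a
#'   scalar.
#' @param preset offset preset, `"invitro"` (3-5 nt) or `"txtl"` (2-4 nt).
#' @param n_reads_per_ref,replicates,polya_len,error_rate,offset_mode see
#'   [cleavage_model()] / [simulate_direct_rna_reads()].
#' @param quiet suppress stage logging.
#' @return (invisibly) list with the written paths.
#' @export
run_simulate <- function(out_dir, seed, n_refs = 20L,
                         length_range = c(70L, 90L), phi = 0.9,
                         n_cleaved = ceiling(0.75 * n_refs),
                         preset = c("invitro", "txtl"),
                         n_reads_per_ref = 300L, replicates = 1:3,
                         polya_len = c(10L, 30L), error_rate = 0.005,
                         offset_mode = "per_read", quiet = FALSE) {
  if (missing(seed)) stop("an explicit seed is required")
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- make_trna_references(n_refs, length_range, seed = seed)
  refs <- gen$references
  if (is.null(names(phi))) {
    stopifnot(length(phi) == 1L, n_cleaved <= n_refs)
    phi <- setNames(c(rep(phi, n_cleaved), rep(0, n_refs - n_cleaved)),
                    refs$id)
  }
  model <- cleavage_model(phi, offset_weights = offset_preset(preset),
                          polya_len = polya_len, error_rate = error_rate,
                          seed = seed, offset_mode = offset_mode)
  sim <- simulate_direct_rna_reads(refs, model, n_reads_per_ref,
                                   replicates = replicates)
  paths <- list(refs = file.path(out_dir, "references.fasta"))
  write_fasta(refs, paths$refs)
  sheet <- list()
  for (cond in unique(sim$reads$condition)) {
    for (rep_i in sort(unique(sim$reads$replicate))) {
      sel <- sim$reads$condition == cond & sim$reads$replicate == rep_i
      fq <- file.path(out_dir, sprintf("reads_%s_rep%d.fastq", cond, rep_i))
      write_fastq(sim$reads[sel, ], fq)
      sheet[[length(sheet) + 1L]] <- tibble(path = fq, condition = cond,
                                            replicate = rep_i)
      log_stage(quiet, "simulate: wrote ", sum(sel), " reads to ", fq)
    }
  }
  sheet <- bind_rows(sheet)
  paths$sample_sheet <- file.path(out_dir, "sample_sheet.tsv")
  write_tsv(sheet, paths$sample_sheet)
  paths$truth <- file.path(out_dir, "truth_reads.tsv")
  write_tsv(sim$truth, paths$truth)
  paths$config <- file.path(out_dir, "config_simulate.json")
  write_config(paths$config, list(
    subcommand = "simulate", seed = seed, n_refs = n_refs,
    length_range = length_range, phi = as.list(phi),
    n_reads_per_ref = n_reads_per_ref, preset = preset,
    offset_weights = as.list(offset_preset(preset)),
    replicates = replicates, polya_len = polya_len,
    error_rate = error_rate, offset_mode = offset_mode))
  invisible(paths)
}

#' Run the cleavage-mapping pipeline
#'
#' Chains poly(A) trimming, mapping (built-in mapper, or SAM import when the
#' sample sheet's `path` column points at `.sam` files), coverage, depletion
#' and z-scoring per replicate pair, and consensus cleavage calls. Each
#' target replicate is paired with the non-target replicate of the same
#' index; an unpaired replicate is an error.
#'
#' @param sample_sheet tibble (or TSV path) with columns `path`,
#'   `condition`, `replicate`.
#' @param refs_fasta reference FASTA path, or a reference tibble.
#' @param out_dir output directory.
#' @param z_threshold,window_3p,min_reads,replicate_rule see
#'   [call_cleavage()].
#' @param pseudocount see [depletion_profile()].
#' @param mapq_min,seed_k see [map_reads()] / [import_sam()].
#' @param polya_min_len,polya_min_frac see [trim_polya()].
#' @param quiet suppress stage logging.
#' @return (invisibly) list with `calls`, `profiles`, `summary` and the
#'   written paths.
#' @export
run_cleavage <- function(sample_sheet, refs_fasta, out_dir,
                         z_threshold = 2, window_3p = 10L, min_reads = 10L,
                         replicate_rule = "all", pseudocount = 1,
                         mapq_min = 20L, seed_k = 13L,
                         polya_min_len = 5L, polya_min_frac = 0.9,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(sample_sheet)) {
    sample_sheet <- tibble::as_tibble(
      read.table(sample_sheet, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE))
  }
  stopifnot(all(c("path", "condition", "replicate") %in%
                  names(sample_sheet)))
  refs <- if (is.character(refs_fasta)) {
    read_fasta(refs_fasta, kind = "tRNA")
  } else refs_fasta
  t_reps <- sort(sample_sheet$replicate[sample_sheet$condition == "target"])
  nt_reps <- sort(
    sample_sheet$replicate[sample_sheet$condition == "non_target"])
  if (!identical(t_reps, nt_reps)) {
    stop("unpaired replicates: target ", paste(t_reps, collapse = ","),
         " vs non-target ", paste(nt_reps, collapse = ","))
  }
  cov <- list()
  for (i in seq_len(nrow(sample_sheet))) {
    row <- sample_sheet[i, ]
    if (grepl("\\.sam$", row$path, ignore.case = TRUE)) {
      aln <- import_sam(row$path, refs, mapq_min = mapq_min)
      aln$condition <- row$condition
      aln$replicate <- row$replicate
    } else {
      reads <- read_fastq(row$path, condition = row$condition,
                          replicate = row$replicate)
      trimmed <- trim_polya(reads, min_len = polya_min_len,
                            min_frac = polya_min_frac)
      n_tail_only <- sum(trimmed$tail_only)
      aln <- map_reads(trimmed[!trimmed$tail_only, ], refs,
                       seed_k = seed_k, mapq_min = mapq_min)
      log_stage(quiet, "cleavage: ", row$path, ": ", nrow(reads),
                " reads, ", n_tail_only, " tail-only, ",
                attr(aln, "unmapped"), " unmapped/filtered, ",
                nrow(aln), " alignments retained")
    }
    cov[[i]] <- coverage_profile(aln, refs, condition = row$condition,
                                 replicate = row$replicate)
  }
  cov <- bind_rows(cov)
  profiles <- bind_rows(lapply(t_reps, function(rep_i) {
    zscores(depletion_profile(
      cov[cov$condition == "target" & cov$replicate == rep_i, ],
      cov[cov$condition == "non_target" & cov$replicate == rep_i, ],
      pseudocount = pseudocount,
      pair_id = sprintf("pair%d", rep_i)))
  }))
  calls <- call_cleavage(profiles, refs, z_threshold = z_threshold,
                         window_3p = window_3p, min_reads = min_reads,
                         replicate_rule = replicate_rule)
  summary <- list(n_refs = nrow(refs),
                  n_detected = sum(calls$detected),
                  n_significant = sum(calls$significant))
  log_stage(quiet, "cleavage: ", summary$n_detected, "/", summary$n_refs,
            " detected, ", summary$n_significant, " significant")
  header <- "# orientation: fold-depletion (score >= 1 means depleted under target); score_printed is its reciprocal"
  paths <- list(
    profiles = file.path(out_dir, "depletion_profiles.tsv"),
    calls = file.path(out_dir, "cleavage_calls.tsv"),
    heatmap = file.path(out_dir, "zvis_matrix.tsv"),
    summary = file.path(out_dir, "summary.json"),
    config = file.path(out_dir, "config_cleavage.json"))
  write_tsv(profiles[, c("ref_id", "pair_id", "position", "score",
                         "score_printed", "z", "z_vis", "masked")],
            paths$profiles, header = header)
  write_tsv(calls, paths$calls, header = header)
  mat <- zvis_matrix(profiles[profiles$pair_id == profiles$pair_id[1], ])
  write_matrix_tsv(mat, paths$heatmap, header = header)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE)
  write_config(paths$config, list(
    subcommand = "cleavage", z_threshold = z_threshold,
    window_3p = window_3p, min_reads = min_reads,
    replicate_rule = replicate_rule, pseudocount = pseudocount,
    mapq_min = mapq_min, seed_k = seed_k,
    polya_min_len = polya_min_len, polya_min_frac = polya_min_frac,
    orientation = "fold"))
  invisible(list(files = paths, calls = calls, profiles = profiles,
                 summary = summary))
}

#' Run the PFS screen scoring pipeline
#'
#' @param fastq_target,fastq_non_target one FASTQ per condition (paths or
#'   read tibbles).
#' @param out_dir output directory.
#' @param pseudocount,phred_min,max_anchor_mismatch see [extract_pfs()] /
#'   [pfs_depletion()].
#' @param quiet suppress stage logging.
#' @return (invisibly) list with `table` (per-5-mer scores), `lfc` (5x4
#'   matrix), `exclusions` and the written paths.
#' @export
run_pfs <- function(fastq_target, fastq_non_target, out_dir,
                    pseudocount = 1, phred_min = 20L,
                    max_anchor_mismatch = 0L, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  load_reads <- function(x, condition) {
    if (is.character(x)) read_fastq(x, condition = condition) else x
  }
  reads_t <- load_reads(fastq_target, "target")
  reads_nt <- load_reads(fastq_non_target, "non_target")
  if (nrow(reads_t) == 0L || nrow(reads_nt) == 0L) {
    stop("empty FASTQ input for one condition")
  }
  counts_t <- extract_pfs(reads_t, phred_min = phred_min,
                          max_anchor_mismatch = max_anchor_mismatch)
  counts_nt <- extract_pfs(reads_nt, phred_min = phred_min,
                           max_anchor_mismatch = max_anchor_mismatch)
  for (pc in list(counts_t, counts_nt)) {
    log_stage(quiet, "pfs: ", pc$condition, ": ", pc$total, " counted, ",
              paste(names(pc$excluded), pc$excluded, collapse = ", "))
  }
  table <- pfs_depletion(counts_t, counts_nt, pseudocount = pseudocount)
  lfc <- position_nucleotide_lfc(counts_t, counts_nt,
                                 pseudocount = pseudocount)
  header <- "# orientation: score_fold >= 1 means depleted under target; score_printed/log2_printed use the printed formula orientation"
  paths <- list(table = file.path(out_dir, "pfs_depletion.tsv"),
                lfc = file.path(out_dir, "pfs_position_lfc.tsv"),
                exclusions = file.path(out_dir, "pfs_exclusions.json"),
                config = file.path(out_dir, "config_pfs.json"))
  write_tsv(rank_pfs(table), paths$table, header = header)
  write_matrix_tsv(lfc, paths$lfc, header = header, rowname_col = "position")
  jsonlite::write_json(
    list(target = as.list(c(counted = counts_t$total, counts_t$excluded)),
         non_target = as.list(c(counted = counts_nt$total,
                                counts_nt$excluded))),
    paths$exclusions, auto_unbox = TRUE)
  write_config(paths$config, list(
    subcommand = "pfs", pseudocount = pseudocount, phred_min = phred_min,
    max_anchor_mismatch = max_anchor_mismatch, orientation = "fold"))
  invisible(list(files = paths, table = table, lfc = lfc,
                 exclusions = list(target = counts_t$excluded,
                                   non_target = counts_nt$excluded)))
}

log_stage <- function(quiet, ...) {
  if (!quiet) message(...)
}

write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(mat, path, header = NULL,
                             rowname_col = "ref_id") {
  df <- data.frame(rn = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- rowname_col
  write_tsv(df, path, header = header)
}

write_config <- function(path, config) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
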