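# Depletion scores, z-scores, clamping and cleavage calls.

mk_cov <- function(counts, total, ref_id = "t1", condition = "target",
                   replicate = 1L) {
  tibble::tibble(ref_id = ref_id, condition = condition,
                 replicate = replicate, position = seq_along(counts),
                 count = as.integer(counts), total_mapped = total,
                 length = length(counts))
}

# a z-scored profile built directly from raw counts
mk_profile <- function(c_t, S_t, c_nt, S_nt, pseudocount = 1,
                       pair_id = "pair1", ref_id = "t1") {
  zscores(depletion_profile(mk_cov(c_t, S_t, ref_id = ref_id),
                            mk_cov(c_nt, S_nt, ref_id = ref_id,
                                   condition = "non_target"),
                            pseudocount = pseudocount, pair_id = pair_id))
}

test_that("depletion scores match the direct substitution example", {
  prof <- depletion_profile(mk_cov(c(5, 5), 1000),
                            mk_cov(c(50, 50), 1000,
                                   condition = "non_target"),
                            pseudocount = 0)
  expect_equal(prof$score_printed, c(0.1, 0.1))
  expect_equal(prof$score, c(10, 10))
})

test_that("identical coverage gives scores of 1; condition swap inverts", {
  counts <- c(10, 25, 3, 40, 0, 7)
  prof <- depletion_profile(mk_cov(counts, 100),
                            mk_cov(counts, 100, condition = "non_target"),
                            pseudocount = 0)
  expect_equal(prof$score[!prof$masked], rep(1, sum(!prof$masked)))
  c_t <- c(4, 9, 30, 2)
  c_nt <- c(8, 3, 30, 11)
  fwd <- depletion_profile(mk_cov(c_t, 50),
                           mk_cov(c_nt, 70, condition = "non_target"))
  rev <- depletion_profile(mk_cov(c_nt, 70),
                           mk_cov(c_t, 50, condition = "non_target"))
  expect_equal(rev$score, 1 / fwd$score)
  expect_equal(rev$score_printed, fwd$score)
})

test_that("masking, pseudocount scope and degenerate inputs behave", {
  prof <- depletion_profile(mk_cov(c(0, 5), 100),
                            mk_cov(c(0, 5), 100,
                                   condition = "non_target"))
  expect_equal(prof$masked, c(TRUE, FALSE))
  expect_true(is.na(prof$score[1]))
  expect_equal(prof$score[2] * prof$score_printed[2], 1)
  expect_error(
    depletion_profile(mk_cov(c(1, 2), 10), mk_cov(c(1, 2, 3), 10,
                                                  condition = "non_target")),
    "length mismatch")
  expect_error(
    depletion_profile(mk_cov(c(1, 2), 0), mk_cov(c(1, 2), 10,
                                                 condition = "non_target")),
    "zero mapped")
})

test_that("z-scores use the population standard deviation and clamp to 0-2", {
  # fold scores [1, 1, 5]: mean 7/3, population sd 1.8856
  prof <- mk_profile(c(4, 4, 0), 10, c(4, 4, 4), 10, pseudocount = 1)
  expect_equal(prof$score, c(1, 1, 5))
  expect_equal(prof$z, c(-1 / sqrt(2), -1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # the single outlier attains the population-z upper bound sqrt(m - 1)
  expect_equal(max(prof$z), sqrt(3 - 1), tolerance = 1e-12)
  expect_equal(prof$z_vis, pmin(2, pmax(0, prof$z)))
  # zero variance -> all z zero
  flat <- mk_profile(c(5, 5, 5), 10, c(5, 5, 5), 10)
  expect_true(all(flat$z == 0))
  expect_true(all(flat$z_vis == 0))
  # clamping: a strong outlier z > 2 maps to exactly 2, negatives to 0
  out <- mk_profile(c(rep(10, 16), 0), 100, c(rep(10, 16), 50), 100)
  expect_gt(max(out$z), 2)
  expect_equal(max(out$z_vis), 2)
  expect_lt(min(out$z), 0)
  expect_equal(min(out$z_vis), 0)
  expect_error(zscores(depletion_profile(mk_cov(0, 10),
                                         mk_cov(0, 10,
                                                condition = "non_target"))),
               "fewer than 2")
})

test_that("single-outlier profiles attain max z = sqrt(m - 1) exactly, so
           references with < 5 unmasked positions never reach z >= 2", {
  for (m in c(3, 4, 5, 8, 20)) {
    prof <- mk_profile(c(rep(5, m - 1), 0), 50, rep(5, m), 50)
    expect_equal(max(prof$z), sqrt(m - 1), tolerance = 1e-12)
  }
  # m = 4: the bound sqrt(3) < 2 makes significance unreachable
  prof <- mk_profile(c(5, 5, 5, 0), 50, c(5, 5, 5, 5), 50)
  expect_lt(max(prof$z), 2)
})

test_that("cleavage calls follow the run / A-run rules", {
  ref <- tibble::tibble(
    id = "t1", seq = paste0(strrep("G", 68), "GCGT", "ACCA"),
    kind = "tRNA", length = 76L)
  # z >= 2 at positions 73..76 in all three replicate pairs
  mk_z <- function(pair) {
    tibble::tibble(ref_id = "t1", pair_id = pair, position = 1:76,
                   score = 1, score_printed = 1,
                   z = c(rep(0, 72), rep(3, 4)),
                   z_vis = c(rep(0, 72), rep(2, 4)), masked = FALSE,
                   count_t = 10L, count_nt = 100L,
                   total_t = 100L, total_nt = 100L, length = 76L)
  }
  profiles <- dplyr::bind_rows(lapply(paste0("pair", 1:3), mk_z))
  call <- call_cleavage(profiles, ref)
  expect_true(call$detected)
  expect_true(call$significant)
  expect_equal(call$class, "3prime_truncation")
  expect_equal(call$offset, 4L)          # e = 72
  expect_equal(call$offset_lo, 3L)       # ref[73] = 'A', ref[74] = 'C'
  expect_equal(call$offset_hi, 4L)
  expect_equal(call$replicates_supporting, 3L)

  # z everywhere below threshold: no call
  flat <- profiles
  flat$z <- 0
  call <- call_cleavage(flat, ref)
  expect_false(call$significant)
  expect_equal(call$class, "none")
  expect_true(is.na(call$offset))

  # significance only at positions 30-34: internal, not a 3' truncation
  internal <- profiles
  internal$z <- ifelse(internal$position %in% 30:34, 3, 0)
  call <- call_cleavage(internal, ref)
  expect_false(call$significant)
  expect_equal(call$class, "internal")

  # replicate rules: threshold reached in 2 of 3 pairs
  two <- dplyr::bind_rows(mk_z("pair1"), mk_z("pair2"), {
    p <- mk_z("pair3")
    p$z <- 0
    p
  })
  expect_false(call_cleavage(two, ref, replicate_rule = "all")$significant)
  expect_true(
    call_cleavage(two, ref, replicate_rule = "majority")$significant)
  expect_true(call_cleavage(two, ref, replicate_rule = "any")$significant)

  # low totals in one pair: not detected
  low <- profiles
  low$total_t[low$pair_id == "pair2"] <- 5L
  call <- call_cleavage(low, ref)
  expect_false(call$detected)
  expect_false(call$significant)
})

test_that("a near-uncovered terminal position cannot drive a call", {
  # both conditions essentially lack coverage at the last position (its
  # genuine terminal A is absorbed into every read's poly(A) tail); a stray
  # error-carrying read there makes a huge single-outlier z that must not
  # count as support
  ref <- tibble::tibble(id = "t1",
                        seq = paste0(strrep("G", 56), "ACCA"),
                        kind = "tRNA", length = 60L)
  mk_pair <- function(pair, c_t_last, c_nt_last) {
    zscores(depletion_profile(
      mk_cov(c(rep(200, 59), c_t_last), 200),
      mk_cov(c(rep(200, 59), c_nt_last), 200,
             condition = "non_target"),
      pair_id = pair))
  }
  profiles <- dplyr::bind_rows(mk_pair("pair1", 0, 2),
                               mk_pair("pair2", 0, 3),
                               mk_pair("pair3", 1, 4))
  expect_gt(max(profiles$z, na.rm = TRUE), 2) # the outlier is there...
  call <- call_cleavage(profiles, ref)
  expect_false(call$significant)             # ...but cannot support a call
  # with real control coverage behind it, the same z pattern does call
  deep <- dplyr::bind_rows(lapply(paste0("pair", 1:3), function(p) {
    mk_pair(p, 20, 200)
  }))
  expect_true(call_cleavage(deep, ref)$significant)
})

test_that("significance uses raw z, never the clamped z_vis", {
  ref <- tibble::tibble(id = "t1",
                        seq = paste0(strrep("G", 72), "ACCA"),
                        kind = "tRNA", length = 76L)
  prof <- tibble::tibble(ref_id = "t1", pair_id = "pair1", position = 1:76,
                         score = 1, score_printed = 1,
                         z = c(rep(0, 72), rep(1.9, 4)),
                         z_vis = c(rep(0, 72), rep(1.9, 4)), masked = FALSE,
                         count_t = 10L, count_nt = 100L,
                         total_t = 100L, total_nt = 100L, length = 76L)
  expect_false(call_cleavage(prof, ref)$significant)
  prof$z[73:76] <- 2
  expect_true(call_cleavage(prof, ref)$significant)
})

test_that("pipeline calls on error-free reads match a from-truth
           reconstruction", {
  gen <- make_trna_references(6, seed = 41)
  refs <- gen$references
  phi <- setNames(c(0.9, 0.9, 0.9, 0.9, 0, 0), refs$id)
  model <- cleavage_model(phi, error_rate = 0, seed = 41)
  sim <- simulate_direct_rna_reads(refs, model, 120, replicates = 1:2)
  trimmed <- trim_polya(sim$reads)
  profiles <- dplyr::bind_rows(lapply(1:2, function(r) {
    at <- map_reads(trimmed[trimmed$condition == "target" &
                              trimmed$replicate == r, ], refs)
    ant <- map_reads(trimmed[trimmed$condition == "non_target" &
                               trimmed$replicate == r, ], refs)
    zscores(depletion_profile(
      coverage_profile(at, refs, "target", r),
      coverage_profile(ant, refs, "non_target", r),
      pair_id = paste0("pair", r)))
  }))
  calls <- call_cleavage(profiles, refs)

  # reconstruct coverage from the truth table alone: each read's apparent
  # end is its true product end minus the brute-force poly(A) tail scan
  truth <- merge(sim$truth, refs[, c("id", "seq", "length")],
                 by.x = "ref_id", by.y = "id")
  bf_profiles <- dplyr::bind_rows(lapply(1:2, function(r) {
    dplyr::bind_rows(lapply(seq_len(nrow(refs)), function(i) {
      rid <- refs$id[i]
      L <- refs$length[i]
      rows <- truth[truth$ref_id == rid & truth$replicate == r, ]
      ends <- vapply(seq_len(nrow(rows)), function(j) {
        keep <- if (isTRUE(rows$truncated[j])) L - rows$offset[j] else L
        read_seq <- paste0(substr(rows$seq[j], 1, keep),
                           strrep("A", rows$polya_len[j]))
        nchar(read_seq) - bf_tail_len(read_seq)
      }, numeric(1))
      cond <- rows$condition
      mk <- function(which_cond) {
        e <- ends[cond == which_cond]
        tibble::tibble(ref_id = rid, condition = which_cond,
                       replicate = r, position = seq_len(L),
                       count = bf_coverage(rep(0, length(e)), e, L),
                       total_mapped = length(e), length = L)
      }
      dep <- bf_depletion(mk("target")$count, mk("non_target")$count,
                          length(ends[cond == "target"]),
                          length(ends[cond == "non_target"]))
      tibble::tibble(ref_id = rid, pair_id = paste0("pair", r),
                     position = seq_len(L), score = dep$fold,
                     score_printed = dep$printed,
                     z = bf_z(dep$fold, dep$masked),
                     z_vis = pmin(2, pmax(0, bf_z(dep$fold, dep$masked))),
                     masked = dep$masked,
                     count_t = mk("target")$count,
                     count_nt = mk("non_target")$count,
                     total_t = sum(cond == "target"),
                     total_nt = sum(cond == "non_target"), length = L)
    }))
  }))
  bf_calls <- call_cleavage(bf_profiles, refs)
  expect_equal(calls, bf_calls, tolerance = 1e-12)
  expect_true(all(calls$significant[phi[calls$ref_id] > 0]))
  expect_false(any(calls$significant[phi[calls$ref_id] == 0]))
})
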