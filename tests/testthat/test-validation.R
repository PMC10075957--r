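# FIC filtration, target-decoy FDR, ROC sweeps, confidence classes,
# cross-dataset loss rates.

fake_psms <- function(score, decoy = rep(FALSE, length(score)),
                      fic = rep(1, length(score))) {
  data.frame(scan_id = paste0("s", seq_along(score)), rank_score = score,
             is_decoy = decoy, fic = fic, stringsAsFactors = FALSE)
}

test_that("the coverage filter keeps the boundary and respects extremes", {
  psms <- fake_psms(1:5, fic = c(0.5, 0.49, 1, 0, 0.75))
  kept <- filter_fic(psms, 0.5)
  expect_identical(kept$scan_id, c("s1", "s3", "s5"))
  expect_identical(nrow(filter_fic(psms, 0)), nrow(psms))
  expect_identical(filter_fic(psms, 1)$scan_id, "s3")
  expect_error(filter_fic(psms, 1.2), "\\[0, 1\\]")
})

test_that("FDR thresholds reproduce the hand-computed small cases", {
  # three strong targets, one weak decoy: everything passes at 1%
  r1 <- target_decoy_fdr(fake_psms(c(10, 9, 8, 1),
                                   decoy = c(FALSE, FALSE, FALSE, TRUE)))
  expect_identical(r1$threshold, 8)
  # ten targets, decoy at 9.5: only the single best target survives
  r2 <- target_decoy_fdr(fake_psms(c(10:1, 9.5),
                                   decoy = c(rep(FALSE, 10), TRUE)))
  expect_identical(r2$threshold, 10)
  expect_identical(nrow(filter_fdr(fake_psms(c(10:1, 9.5),
                                             decoy = c(rep(FALSE, 10), TRUE)),
                                   r2)), 1L)
  # fully overlapping score multisets: nothing passes at 1%
  r3 <- target_decoy_fdr(fake_psms(c(5, 4, 3, 5, 4, 3),
                                   decoy = rep(c(FALSE, TRUE), each = 3)))
  expect_true(is.na(r3$threshold) || r3$threshold > 5)
  expect_identical(nrow(filter_fdr(fake_psms(c(5, 4, 3, 5, 4, 3),
                                             decoy = rep(c(FALSE, TRUE),
                                                         each = 3)), r3)), 0L)
  # no decoys at all: flagged
  expect_true(target_decoy_fdr(fake_psms(1:3))$no_decoys)
})

test_that("FDR agrees with the exhaustive sweep oracle on random instances", {
  set.seed(707)
  for (rep in 1:100) {
    n <- sample(5:200, 1)
    scores <- round(stats::rnorm(n, 10, 3), 2)
    decoy <- stats::runif(n) < 0.4
    if (!any(decoy) || all(decoy)) next
    level <- sample(c(0.01, 0.05, 0.2), 1)
    got <- target_decoy_fdr(fake_psms(scores, decoy), level)$threshold
    want <- oracle_fdr_threshold(scores, decoy, level)
    expect_identical(is.na(got), is.na(want))
    if (!is.na(got)) expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("q-values never increase with score", {
  set.seed(708)
  for (rep in 1:20) {
    scores <- stats::rnorm(50)
    decoy <- stats::runif(50) < 0.5
    r <- target_decoy_fdr(fake_psms(scores, decoy))
    o <- order(scores)
    expect_true(all(diff(r$qvalues[o]) <= 1e-12))
  }
})

test_that("ROC curves hit both endpoints and stay monotone", {
  set.seed(709)
  psms <- fake_psms(stats::rnorm(80, 10, 2), decoy = rep(c(FALSE, TRUE), 40),
                    fic = stats::runif(80))
  truth <- !psms$is_decoy
  roc <- roc_compare(psms, truth)
  for (s in c("fdr", "fic")) {
    cur <- roc[roc$strategy == s, ]
    expect_true(any(cur$fpr == 0 & cur$tpr == 0))
    expect_true(any(cur$fpr == 1 & cur$tpr == 1))
    expect_true(all(diff(cur$fpr) >= -1e-12))
    expect_true(all(diff(cur$tpr) >= -1e-12))
  }
})

test_that("a planted 2%-FPR coverage cutoff shows up in the FIC sweep", {
  # all 50 true PSMs at fic >= 0.5; exactly 2 of 100 false ones reach it
  fic <- c(stats::runif(50, 0.5, 1), stats::runif(98, 0, 0.49),
           c(0.6, 0.55))
  truth <- c(rep(TRUE, 50), rep(FALSE, 100))
  psms <- fake_psms(seq_along(fic), decoy = !truth, fic = fic)
  roc <- roc_compare(psms, truth)
  pt <- roc[roc$strategy == "fic" & !is.na(roc$cutoff) &
              abs(roc$cutoff - 0.5) < 1e-9, ]
  expect_equal(pt$fpr, 0.02, tolerance = 1e-12)
  expect_equal(pt$tpr, 1.0, tolerance = 1e-12)
})

test_that("confidence classification flags the planted violations", {
  f <- peptide_form("GSKKAVTKAQKK", c("8" = "la", "4" = "ac"))
  clean <- simulate_spectrum(f, p = 1, isotopes = TRUE, seed = 31L)
  expect_identical(classify_confidence(f, clean)$class, "high")
  # (i) a 20%-intensity peak above the precursor m/z
  noisy <- ms2_spectrum("n", clean$precursor_mz, clean$precursor_charge,
                        peaks = rbind(clean$peaks,
                                      c(clean$precursor_mz * 1.2,
                                        0.2 * max(clean$peaks[, 2]))))
  cl1 <- classify_confidence(f, noisy)
  expect_identical(cl1$class, "moderate")
  expect_false(cl1$checks[["no_high_unmatched"]])
  # (ii) ladder without isotope companions
  bare <- simulate_spectrum(f, p = 1, isotopes = FALSE, seed = 32L)
  cl2 <- classify_confidence(f, bare)
  expect_identical(cl2$class, "moderate")
  expect_false(cl2$checks[["isotopes"]])
})

test_that("cross-referencing computes loss rates from planted omissions", {
  set.seed(808)
  keys <- c("KSTGGKAPR/1:la", "KSTGGKAPR/6:ac", "GSKKAVTK/4:la",
            "KQLATKAAR/1:la", "KSAPATGGVKKPHR/1:la", "KVLR/1:la",
            "DNIQGITKPAIR/8:la", "KTESHHKAK/1:ac", "AQKKDGKK/3:la",
            "KAVTKYTSSK/1:la", "AKAKTR/2:la", "AGLQFPVGR")
  mk_run <- function(subset_keys, seed0) {
    forms <- lapply(subset_keys, parse_form)
    ds <- simulate_dataset(list(seed = seed0, forms = forms, p = 1))
    psms <- data.frame(
      scan_id = ds$truth$scan_id, sequence = NA, mods = NA,
      rt = vapply(ds$spectra, `[[`, numeric(1), "rt")[ds$truth$scan_id],
      stringsAsFactors = FALSE)
    parts <- strsplit(ds$truth$form_key, "/", fixed = TRUE)
    psms$sequence <- vapply(parts, `[`, character(1), 1)
    psms$mods <- vapply(parts, function(x) {
      if (length(x) > 1) x[2] else ""
    }, character(1))
    list(psms = psms, spectra = ds$spectra)
  }
  run_a <- mk_run(keys, 1)
  # run B: same spectra, but 3 of the 12 keys dropped from the PSM list
  run_b <- mk_run(keys, 1)
  drop <- run_b$psms$sequence %in% c("GSKKAVTK", "KVLR", "AGLQFPVGR")
  run_b$psms <- run_b$psms[!drop, ]
  res <- cross_reference(list(A = run_a, B = run_b))
  expect_equal(res$loss$loss_rate[res$loss$dataset == "A"], 0)
  expect_equal(res$loss$loss_rate[res$loss$dataset == "B"], 0.25)
  # identical datasets: loss 0 everywhere
  res2 <- cross_reference(list(A = run_a, B = mk_run(keys, 1)))
  expect_true(all(res2$loss$loss_rate == 0))
  # a key with no supporting precursor in B is absent, not missed
  run_c <- mk_run(keys[1:9], 3)
  res3 <- cross_reference(list(A = run_a, C = run_c))
  stat_c <- res3$keys[["C"]]
  absent_keys <- setdiff(rownames(res3$keys),
                         c(keys[1:9]))
  expect_true(all(stat_c[rownames(res3$keys) %in% absent_keys] == "absent"))
  expect_equal(res3$loss$loss_rate[res3$loss$dataset == "C"], 0)
})

test_that("equivalent-mass background placements count as the same hit", {
  expect_true(same_identification("AQKKDGKKR/4:la,8:me1,9:rme1",
                                  "AQKKDGKKR/4:la,7:me1,8:me1"))
  expect_false(same_identification("AQKKDGKKR/4:la,8:me1,9:rme1",
                                   "AQKKDGKKR/3:la,8:me1,9:rme1"))
  expect_false(same_identification("AQKKDGKKR/4:la", "AQKKDGKKR/4:la,8:me1"))
})
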