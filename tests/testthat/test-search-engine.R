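# Theoretical fragments, peak matching, FIC, candidate selection, ranking.

test_that("fragment ladders have 2(n-1) positions and known small values", {
  f9 <- peptide_form("KSTGGKAPR")
  fr <- fragment_ions(f9, 1L)
  expect_identical(nrow(fr), 16L)  # b1-b8, y1-y8
  gk <- fragment_ions(peptide_form("GK"), 1L)
  expect_equal(gk$mz[gk$series == "b"], 58.02874, tolerance = 1e-5)
  expect_equal(gk$mz[gk$series == "y"], 147.11280, tolerance = 1e-5)
  expect_identical(nrow(fragment_ions(peptide_form("K"))), 0L)
  # modification deltas land on the right side of the split
  fmod <- peptide_form("KSTGGKAPR", c("1" = "la"))
  frm <- fragment_ions(fmod, 1L)
  expect_equal(frm$mz[frm$series == "b"] - fr$mz[fr$series == "b"],
               rep(mod_delta("la")[[1]], 8), tolerance = 1e-9)
  expect_equal(frm$mz[frm$series == "y"], fr$mz[fr$series == "y"],
               tolerance = 1e-9)
})

test_that("b_i and y_(n-i) are complementary for every split of every form", {
  set.seed(404)
  for (rep in 1:20) {
    s <- random_peptide(sample(6:15, 1))
    ks <- which(strsplit(s, "")[[1]] == "K")
    mods <- stats::setNames("la", as.character(ks[1]))
    f <- peptide_form(s, mods)
    fr <- fragment_ions(f, 1L)
    n <- nchar(s)
    b <- fr$mz[fr$series == "b"][order(fr$index[fr$series == "b"])]
    y <- fr$mz[fr$series == "y"][order(fr$index[fr$series == "y"])]
    for (i in seq_len(n - 1L)) {
      expect_equal(b[i] + y[n - i],
                   neutral_mass(f) + 2 * ficms:::PROTON_MASS,
                   tolerance = 1e-9)
    }
  }
})

test_that("peak matching counts positions once and is not peak-exclusive", {
  f <- peptide_form("KSTGGKAPR")
  fr <- fragment_ions(f, 1L)
  sp_full <- ms2_spectrum("full", 500, 2, peaks = cbind(fr$mz, 100))
  m <- match_peaks(sp_full, fr)
  expect_identical(nrow(m$positions), 16L)
  sp_empty <- ms2_spectrum("empty", 500, 2)
  expect_identical(nrow(match_peaks(sp_empty, fr)$positions), 0L)
  # one peak inside the tolerance of two different fragments matches both
  fr2 <- fragment_ions(f, 2L)
  b3 <- fr2$mz[fr2$series == "b" & fr2$index == 3 & fr2$charge == 1]
  collide <- data.frame(series = c("b", "y"), index = c(3L, 5L),
                        charge = c(1L, 2L), mz = c(b3, b3 * (1 + 5e-6)))
  spc <- ms2_spectrum("collide", 500, 2, peaks = cbind(b3 * (1 + 2e-6), 50))
  mc <- match_peaks(spc, collide, frag_tol_ppm = 40)
  expect_identical(nrow(mc$positions), 2L)
  expect_identical(unique(mc$positions$peak), 1L)
})

test_that("low-intensity peaks can be excluded from matching", {
  f <- peptide_form("KSTGGKAPR")
  fr <- fragment_ions(f, 1L)
  peaks <- cbind(fr$mz, c(1000, rep(1, 15)))
  sp <- ms2_spectrum("int", 500, 2, peaks = peaks)
  expect_identical(nrow(match_peaks(sp, fr)$positions), 16L)
  m <- match_peaks(sp, fr, min_rel_intensity = 0.05)
  expect_identical(nrow(m$positions), 1L)
})

test_that("FIC is the matched fraction of 2(n-1) positions", {
  f <- peptide_form("KSTGGKAPR")
  fr <- fragment_ions(f, 1L)
  full <- ms2_spectrum("a", 500, 2, peaks = cbind(fr$mz, 10))
  expect_identical(compute_fic(f, full), 1)
  half <- ms2_spectrum("b", 500, 2, peaks = cbind(fr$mz[1:8], 10))
  expect_identical(compute_fic(f, half), 0.5)
  seven <- ms2_spectrum("c", 500, 2, peaks = cbind(fr$mz[1:7], 10))
  expect_identical(compute_fic(f, seven), 0.4375)
})

test_that("FIC ignores intensity scaling and never drops as peaks accrue", {
  f <- peptide_form("GSKKAVTKAQKK", c("8" = "la"))
  sp <- simulate_spectrum(f, p = 0.6, n_noise = 10L, seed = 42L)
  scaled <- ms2_spectrum("s", sp$precursor_mz, sp$precursor_charge,
                         peaks = cbind(sp$peaks[, 1], sp$peaks[, 2] * 1e3))
  expect_identical(compute_fic(f, sp), compute_fic(f, scaled))
  fr <- fragment_ions(f, 1L)
  fics <- vapply(seq_len(nrow(fr)), function(k) {
    aug <- ms2_spectrum("m", sp$precursor_mz, sp$precursor_charge,
                        peaks = rbind(sp$peaks, cbind(fr$mz[seq_len(k)], 5)))
    compute_fic(f, aug)
  }, numeric(1))
  expect_true(all(diff(fics) >= 0))
})

test_that("engine FIC equals the brute-force all-pairs oracle", {
  set.seed(505)
  for (rep in 1:100) {
    s <- random_peptide(sample(6:15, 1))
    f <- peptide_form(s)
    sp <- simulate_spectrum(f, p = stats::runif(1, 0.2, 1),
                            n_noise = sample(0:20, 1),
                            seed = sample.int(1e6, 1))
    expect_equal(compute_fic(f, sp), oracle_fic(f, sp), tolerance = 1e-12)
  }
})

test_that("candidate selection applies the ppm window and finds isomers", {
  db <- decoy_database(tiny_proteins())
  idx <- build_form_index(db, max_missed = 2L, min_length = 5L,
                          max_length = 20L)
  # a spectrum at exactly one form's mass selects that form
  row <- which(idx$forms$sequence == "KSTGGKAPR" &
                 idx$forms$mods == "1:la,6:ac")
  mass <- idx$forms$mass[row]
  sp <- ms2_spectrum("x", (mass + 2 * ficms:::PROTON_MASS) / 2, 2L,
                     peaks = cbind(200, 1))
  cand <- select_candidates(sp, idx, 10)
  expect_true(row %in% cand$row)
  picked <- idx$forms[cand$row, ]
  # isomeric forms (same mass, different sites) are all selected
  expect_true(all(abs(picked$mass - mass) / mass * 1e6 <= 10))
  expect_gt(sum(picked$sequence == "KSTGGKAPR"), 1L)
  # 10 ppm boundary arithmetic
  off <- ms2_spectrum("y", (mass * (1 + 2e-5) + 2 * ficms:::PROTON_MASS) / 2,
                      2L, peaks = cbind(200, 1))
  expect_false(row %in% select_candidates(off, idx, 10)$row)
})

test_that("unknown precursor charge unions candidates over charges 2-4", {
  db <- decoy_database(tiny_proteins())
  idx <- build_form_index(db, max_missed = 2L, min_length = 5L,
                          max_length = 20L)
  mass <- idx$forms$mass[100]
  sp2 <- ms2_spectrum("z2", (mass + 2 * ficms:::PROTON_MASS) / 2, 0L,
                      peaks = cbind(200, 1))
  sp3 <- ms2_spectrum("z3", (mass + 3 * ficms:::PROTON_MASS) / 3, 0L,
                      peaks = cbind(200, 1))
  expect_true(100 %in% select_candidates(sp2, idx, 10)$row)
  expect_true(100 %in% select_candidates(sp3, idx, 10)$row)
})

test_that("ranking is deterministic with the documented delta-score rule", {
  fa <- peptide_form("KSTGGKAPR", c("1" = "la", "6" = "ac"))
  fb <- peptide_form("KSTGGKAPR", c("1" = "ac", "6" = "la"))
  other <- peptide_form("KSTGGKAPR", c("1" = "me1"))
  sp <- simulate_spectrum(fa, p = 1, seed = 9L)
  single <- score_and_rank(sp, list(fa))
  expect_identical(single$delta_score, single$rank_score)
  ranked <- score_and_rank(sp, list(other, fb, fa))
  expect_identical(ranked$form_key[1], form_key(fa))
  # isomer pair: delta computed against the best non-isomer
  expect_equal(ranked$delta_score[1],
               ranked$rank_score[1] -
                 ranked$rank_score[ranked$form_key == form_key(other)],
               tolerance = 1e-12)
  # zero-match candidates sort last with score 0
  blank <- ms2_spectrum("blank", sp$precursor_mz, 2L,
                        peaks = cbind(1500.0, 1))
  r0 <- score_and_rank(blank, list(fa, fb))
  expect_identical(r0$rank_score, c(0, 0))
})

test_that("forms ending in a modified lysine are excluded off the C terminus", {
  db <- decoy_database(tiny_proteins())
  idx <- build_form_index(db, max_missed = 2L, min_length = 5L,
                          max_length = 20L)
  pep <- "GSKKAVTK" # internal tryptic peptide ending in K
  expect_true(pep %in% idx$forms$sequence)
  expect_false(any(grepl("(^|,)8:", idx$forms$mods[idx$forms$sequence == pep])))
  idx_off <- build_form_index(db, max_missed = 2L, min_length = 5L,
                              max_length = 20L, cterm_mod_k_filter = FALSE)
  expect_true(any(grepl("(^|,)8:",
                        idx_off$forms$mods[idx_off$forms$sequence == pep])))
})
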