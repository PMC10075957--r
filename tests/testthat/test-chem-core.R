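# Mass bookkeeping, modification table, combinatorial form enumeration.

test_that("neutral mass matches elemental-composition oracle on examples", {
  expect_equal(neutral_mass(peptide_form("G")), 75.03203, tolerance = 1e-7)
  f <- peptide_form("KSTGGKAPR", c("1" = "ac", "6" = "la"))
  expect_equal(neutral_mass(f), 1014.5458, tolerance = 1e-6)
  # additivity: adding an acetyl changes the mass by exactly its delta
  base <- peptide_form("KSTGGKAPR", c("6" = "la"))
  expect_equal(neutral_mass(f) - neutral_mass(base),
               mod_delta("ac")[["ac"]], tolerance = 1e-12)
})

test_that("masses agree with the elemental oracle for random peptides", {
  set.seed(101)
  for (i in 1:100) {
    s <- random_peptide(sample(5:20, 1))
    expect_equal(neutral_mass(peptide_form(s)), oracle_peptide_mass(s),
                 tolerance = 1e-5)
  }
})

test_that("modification table validates deltas against compositions", {
  mods <- default_mods()
  has_comp <- !is.na(mods$composition) & nzchar(mods$composition)
  expect_true(all(abs(mods$delta_mass[has_comp] -
                        formula_mass(mods$composition[has_comp])) < 1e-5))
  # duplicate names rejected
  bad <- rbind(as.data.frame(mods), as.data.frame(mods)[1, ])
  expect_error(ficms:::as_mod_table(bad), "unique")
  # delta/composition disagreement rejected
  wrong <- as.data.frame(mods)
  wrong$delta_mass[1] <- wrong$delta_mass[1] + 0.001
  expect_error(ficms:::as_mod_table(wrong), "disagrees")
})

test_that("invalid sequences and misplaced modifications are rejected", {
  expect_error(peptide_form("KXZ"), "invalid residue")
  expect_error(peptide_form("GAV", c("1" = "ac")), "not allowed")
  expect_error(peptide_form("KK", c("1" = "ac", "1" = "la")), "one modification")
  expect_error(neutral_mass(peptide_form("KK", c("1" = "ac")),
                            mod_table = default_mods())
               , NA)
  expect_error(peptide_form("KK", c("5" = "ac")), "indices")
})

test_that("the annotated two-site lysine peptide yields four target forms", {
  # target mark fixed on K8, acetylation variable on the two annotated sites
  forms <- enumerate_forms("GSKKAVTKAQKK", background_mods = "ac",
                           max_background = 3L, fixed_mods = c("8" = "la"),
                           site_restrict = list(ac = c(4L, 11L)))
  expect_length(forms, 4L)
  expect_true(all(vapply(forms, function(f) "la" %in% f$mods, logical(1))))
  expect_identical(sum(vapply(forms, function(f) "ac" %in% f$mods,
                              logical(1))), 3L)
})

test_that("enumeration handles no-site and subset cases", {
  expect_length(enumerate_forms("GAVG", background_mods = c("ac", "me1")), 1L)
  forms <- enumerate_forms("KK", background_mods = "ac", max_background = 2L)
  expect_length(forms, 4L)
  keys <- vapply(forms, form_key, character(1))
  expect_identical(keys, c("KK", "KK/1:ac", "KK/2:ac", "KK/1:ac,2:ac"))
})

test_that("enumeration count equals 2^s for s background sites", {
  set.seed(202)
  for (s in 1:6) {
    seq <- paste(c(rep("K", s), "GAV"), collapse = "")
    forms <- enumerate_forms(seq, background_mods = "ac", max_background = s)
    # brute force: all subsets of the s lysines
    expect_length(forms, 2^s)
    expect_false(anyDuplicated(vapply(forms, form_key, character(1))) > 0)
  }
})

test_that("max_background caps the number of background marks", {
  forms <- enumerate_forms("KKKKK", background_mods = "ac",
                           max_background = 2L)
  n_bg <- vapply(forms, function(f) length(f$mods), integer(1))
  expect_true(all(n_bg <= 2L))
  expect_length(forms, 1 + 5 + choose(5, 2))
})

test_that("combinatorial ceiling raises a capacity error naming the peptide", {
  expect_error(
    enumerate_forms("KKKKKKKKKK", target_mods = "la",
                    background_mods = c("ac", "me1"), max_background = 3L,
                    max_forms = 100L),
    "KKKKKKKKKK")
})

test_that("enumeration is deterministic and canonically ordered", {
  run <- function() {
    vapply(enumerate_forms("KAKRK", target_mods = "la",
                           background_mods = c("ac", "rme1")),
           form_key, character(1))
  }
  keys <- run()
  expect_identical(keys, run())
  n_mods <- lengths(regmatches(keys, gregexpr(":", keys)))
  expect_true(all(diff(n_mods) >= 0))
})

test_that("trimethyl and acetyl stay distinguishable at 40 ppm below m/z 900", {
  # near-isobaric pair: delta(me3) - delta(ac) = 0.03638 Da
  d <- mod_delta(c("me3", "ac"))
  expect_equal(abs(d[["me3"]] - d[["ac"]]), 0.03638, tolerance = 1e-4)
  f_ac <- peptide_form("GGKGGR", c("3" = "ac"))
  f_me3 <- peptide_form("GGKGGR", c("3" = "me3"))
  # spectrum holding only the acetyl form's b3..b5 (all below m/z 900)
  fr_ac <- fragment_ions(f_ac)
  b_ac <- fr_ac[fr_ac$series == "b" & fr_ac$index >= 3, ]
  expect_true(all(b_ac$mz < 900))
  sp <- ms2_spectrum("iso", 400, 2, peaks = cbind(b_ac$mz, 1000))
  hit_ac <- match_peaks(sp, fr_ac)$positions
  hit_me3 <- match_peaks(sp, fragment_ions(f_me3))$positions
  expect_identical(nrow(hit_ac), 3L)
  expect_identical(nrow(hit_me3[hit_me3$series == "b", ]), 0L)
})
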