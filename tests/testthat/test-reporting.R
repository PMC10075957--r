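# Site mapping in mature histone numbering and coexistence summaries.

mk_psm <- function(sequence, mods, protein, start, fic = 1,
                   conf = "high", scan = "s1") {
  data.frame(scan_id = scan, sequence = sequence, mods = mods,
             protein = protein, start = start,
             end = start + nchar(sequence) - 1L, fic = fic,
             confidence_class = conf, stringsAsFactors = FALSE)
}

test_that("the H3 tail peptide maps to K9la and K14ac in mature numbering", {
  proteins <- load_fasta(example_fasta())
  psm <- mk_psm("KSTGGKAPR", "1:la,6:ac", "H3_1", 10L)
  sites <- map_sites(psm, proteins)
  expect_identical(nrow(sites), 2L)
  expect_identical(sites$mature_position, c(9L, 14L))
  expect_identical(sites$full_position, c(10L, 15L))
  expect_identical(sites$residue, c("K", "K"))
  expect_identical(sites$mod, c("la", "ac"))
  expect_identical(sites$site, c("H3_1 K9la", "H3_1 K14ac"))
})

test_that("unmodified peptides yield no site records", {
  proteins <- load_fasta(example_fasta())
  expect_identical(nrow(map_sites(mk_psm("KSTGGKAPR", "", "H3_1", 10L),
                                  proteins)), 0L)
})

test_that("PSMs for one site aggregate and keep the best evidence", {
  proteins <- load_fasta(example_fasta())
  psms <- rbind(
    mk_psm("KSTGGKAPR", "6:la", "H3_1", 10L, fic = 0.6, conf = "moderate",
           scan = "s1"),
    mk_psm("KSTGGKAPR", "6:la", "H3_1", 10L, fic = 0.9, conf = "high",
           scan = "s2"),
    mk_psm("KSTGGKAPR", "6:la", "H3_1", 10L, fic = 0.7, conf = "moderate",
           scan = "s3"))
  sites <- map_sites(psms, proteins)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$n_psm, 3L)
  expect_equal(sites$best_fic, 0.9)
  expect_identical(sites$confidence_class, "high")
  # order invariance
  sites_rev <- map_sites(psms[3:1, ], proteins)
  expect_equal(sites, sites_rev)
})

test_that("coordinate mismatches raise an integrity error", {
  proteins <- load_fasta(example_fasta())
  expect_error(map_sites(mk_psm("KSTGGKAPR", "1:la", "H3_1", 11L), proteins),
               "coordinate mismatch")
})

test_that("site records regenerate their residue letters from the FASTA", {
  proteins <- load_fasta(example_fasta())
  db <- decoy_database(proteins)
  idx <- build_form_index(db, max_missed = 2L)
  pool <- which(!idx$forms$is_decoy & idx$forms$n_mods >= 1L &
                  nchar(idx$forms$sequence) >= 8L)
  set.seed(99)
  forms <- lapply(sample(pool, 8), ficms:::index_form, index = idx)
  ds <- simulate_dataset(list(seed = 5, forms = forms, p = 1))
  res <- search_spectra(ds$spectra, idx)
  acc <- filter_fic(res$psms)
  acc$confidence_class <- "high"
  sites <- map_sites(acc, proteins, idx$locations)
  expect_gt(nrow(sites), 0L)
  got <- substring(proteins$sequence[match(sites$protein, proteins$id)],
                   sites$full_position, sites$full_position)
  expect_identical(got, sites$residue)
})

test_that("multi-protein peptides carry a shared-evidence flag", {
  proteins <- data.frame(
    id = c("pA", "pB"), description = "",
    sequence = c("MAAKSTGGKAPRGG", "GGKSTGGKAPRFF"),
    is_decoy = FALSE, stringsAsFactors = FALSE)
  locations <- data.frame(
    sequence = "KSTGGKAPR", protein = c("pA", "pB"),
    start = c(4L, 3L), end = c(12L, 11L))
  psm <- mk_psm("KSTGGKAPR", "1:la", "pA", 4L)
  sites <- map_sites(psm, proteins, locations)
  expect_identical(nrow(sites), 2L)
  expect_true(all(sites$shared_evidence))
  # Met-initiated pA shifts numbering, pB does not
  expect_identical(sites$mature_position[sites$protein == "pA"], 3L)
  expect_identical(sites$mature_position[sites$protein == "pB"], 3L)
})

test_that("coexistence records and the background histogram count per type", {
  psms <- rbind(
    mk_psm("KSTGGKAPR", "1:la,6:ac", "H3_1", 10L, scan = "s1"),
    mk_psm("KSTGGKAPR", "1:la,6:ac", "H3_1", 10L, scan = "s2"),
    mk_psm("GSKKAVTKAQKK", "8:la,4:ac,11:me1", "H2B1C", 14L, scan = "s3"),
    mk_psm("KQLATKAAR", "6:la", "H3_1", 19L, scan = "s4"))
  cx <- summarize_coexistence(psms, "la")
  expect_identical(nrow(cx$records), 2L)
  expect_identical(cx$records$n_psm[cx$records$form_key ==
                                      "KSTGGKAPR/1:la,6:ac"], 2L)
  h <- stats::setNames(cx$histogram$n_peptides, cx$histogram$mod)
  expect_identical(h[["ac"]], 2L)   # both multi-mod peptides carry ac
  expect_identical(h[["me1"]], 1L)  # one carries me1 as well
  expect_identical(h[["rme1"]], 0L)
  # single-mod-only input: empty records, zero histogram
  cx0 <- summarize_coexistence(psms[4, ], "la")
  expect_identical(nrow(cx0$records), 0L)
  expect_true(all(cx0$histogram$n_peptides == 0L))
})
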