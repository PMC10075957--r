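# End-to-end pipeline: configuration, orchestration, run manifest.

#' Build a run configuration
#'
#' Defaults follow standard high-resolution histone-PTM practice: 10 ppm
#' precursor and 40 ppm fragment tolerances, a 50% fragment-ion-coverage
#' acceptance threshold, lactylation as the target PTM with acetylation and
#' K/R monomethylation as background variable modifications, and a 1% level
#' for the comparison target-decoy FDR.
#'
#' @param fasta Path to the target protein FASTA.
#' @param spectra Character vector of spectrum files (MGF/mzML).
#' @param target_mod,background_mods Modification names.
#' @param max_background Maximum background mods per peptide.
#' @param enzyme,max_missed,min_length,max_length Digestion settings.
#' @param precursor_tol_ppm,frag_tol_ppm Mass tolerances.
#' @param fic_cutoff Coverage acceptance threshold.
#' @param fdr_level Level for the comparison FDR filter.
#' @param decoy_prefix Decoy accession prefix.
#' @param mod_table_path Optional custom modification TSV.
#' @param out_dir Optional output directory for result tables.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fasta, spectra, target_mod = "la",
                       background_mods = c("ac", "me1", "rme1"),
                       max_background = 3L, enzyme = "trypsin",
                       max_missed = 4L, min_length = 5L, max_length = 35L,
                       precursor_tol_ppm = 10, frag_tol_ppm = 40,
                       fic_cutoff = 0.5, fdr_level = 0.01,
                       decoy_prefix = "rev_", mod_table_path = NULL,
                       out_dir = NULL, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of [run_config()]; unknown keys
#' raise a configuration error.
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- utils::modifyList(vals, list(...))
  do.call(run_config, vals)
}

#' Run the full identification pipeline
#'
#' Load FASTA, append reversed decoys, build the modified-form index, read
#' spectra, search, apply the coverage filter, classify confidence, map
#' sites (mature numbering) and summarize coexisting marks. Deterministic
#' given the configuration. When `config$out_dir` is set, PSM/site/
#' coexistence/chimera tables are written as TSV together with a JSON run
#' manifest (package version, parameters, input checksums).
#'
#' @param config A `run_config`.
#' @return An object of class `ptm_run`: list with `psms` (all search
#'   PSMs), `accepted` (coverage-filtered, confidence-classified),
#'   `fdr` (comparison target-decoy result), `sites`, `coexistence`,
#'   `chimera` (accepted chimera-member PSMs), `proteins`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  mod_table <- if (is.null(config$mod_table_path)) default_mods() else
    read_mod_table(config$mod_table_path)
  proteins <- stage("load_fasta", load_fasta(config$fasta,
                                             config$decoy_prefix))
  if (!any(proteins$is_decoy)) {
    proteins <- decoy_database(proteins, config$decoy_prefix)
  }
  index <- stage("build_form_index", build_form_index(
    proteins, target_mod = config$target_mod,
    background_mods = config$background_mods, enzyme = config$enzyme,
    max_missed = config$max_missed, min_length = config$min_length,
    max_length = config$max_length, max_background = config$max_background,
    mod_table = mod_table))
  spectra <- stage("read_spectra", {
    sp <- unlist(lapply(config$spectra, read_spectra), recursive = FALSE)
    if (!length(sp)) stop("no MS2 spectra found")
    sp
  })
  result <- stage("search", search_spectra(
    spectra, index, precursor_tol_ppm = config$precursor_tol_ppm,
    frag_tol_ppm = config$frag_tol_ppm, fic_cutoff = config$fic_cutoff))
  accepted <- stage("filter_fic", filter_fic(result$psms, config$fic_cutoff))
  accepted <- stage("classify", classify_psms(accepted, spectra,
                                              mod_table = mod_table))
  fdr <- target_decoy_fdr(result$psms, config$fdr_level)
  sites <- stage("map_sites", map_sites(accepted, proteins,
                                        index$locations))
  coex <- stage("coexistence", summarize_coexistence(
    accepted, config$target_mod, mod_table))
  run <- structure(
    list(psms = result$psms, accepted = accepted, fdr = fdr, sites = sites,
         coexistence = coex,
         chimera = accepted[accepted$chimera_member, , drop = FALSE],
         spectra = spectra, proteins = proteins, index = index,
         config = config),
    class = "ptm_run")
  if (!is.null(config$out_dir)) {
    write_run(run, config$out_dir)
  }
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_psm_table(run$psms, file.path(out_dir, "psms_all.tsv"))
  write_psm_table(run$accepted, file.path(out_dir, "psms_accepted.tsv"))
  write_psm_table(run$sites, file.path(out_dir, "sites.tsv"))
  write_psm_table(run$coexistence$records,
                  file.path(out_dir, "coexistence.tsv"))
  write_psm_table(run$coexistence$histogram,
                  file.path(out_dir, "coexistence_histogram.tsv"))
  write_psm_table(run$chimera, file.path(out_dir, "chimera.tsv"))
  cfg <- run$config
  manifest <- list(
    package = "ficms",
    version = as.character(utils::packageVersion("ficms")),
    parameters = cfg[setdiff(names(cfg), c("fasta", "spectra"))],
    inputs = list(
      fasta = list(path = cfg$fasta,
                   md5 = unname(tools::md5sum(cfg$fasta))),
      spectra = lapply(cfg$spectra, function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      })
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.ptm_run <- function(x, ...) {
  cat("<ptm_run>\n")
  cat("  spectra searched : ", length(x$spectra), "\n", sep = "")
  cat("  PSMs (all)       : ", nrow(x$psms), "\n", sep = "")
  cat("  accepted (FIC >= ", x$config$fic_cutoff, "): ", nrow(x$accepted),
      "\n", sep = "")
  if (nrow(x$accepted)) {
    cat("  confidence       : ",
        sum(x$accepted$confidence_class == "high"), " high / ",
        sum(x$accepted$confidence_class == "moderate"), " moderate\n",
        sep = "")
  }
  cat("  chimera members  : ", nrow(x$chimera), "\n", sep = "")
  cat("  modified sites   : ", nrow(x$sites), "\n", sep = "")
  invisible(x)
}

#' Path to the bundled example histone FASTA
#'
#' Human core histones (H3.1, H4, H2A type 1, H2B type 1-C) bundled for
#' worked examples and benchmarks.
#'
#' @return A file path.
#' @export
example_fasta <- function() {
  system.file("extdata", "histones.fasta", package = "ficms", mustWork = TRUE)
}

#' Build the standard small-dataset benchmark
#'
#' The package's evaluation scenario for the small-dataset failure mode of
#' target-decoy FDR: a 30-scan dataset holding 26 planted modified peptides
#' (fragment retention `p`), one engineered high-scoring decoy spectrum (a
#' decoy peptide's complete ladder) and three decoy-confusable random-peak
#' spectra at decoy precursor masses. Planted forms are drawn from the
#' supplied index: target forms carrying at least one modification, 7-20
#' residues long (typical tryptic histone peptides). The engineered decoy is
#' an unmodified decoy peptide of at least `decoy_min_length` residues, so
#' its complete ladder outranks every planted PSM — the score-overlap
#' failure mode that makes a small-dataset 1% FDR threshold unattainable.
#'
#' @param index A `form_index` built over a target+decoy database.
#' @param seed Integer seed.
#' @param n_true Number of planted true spectra (default 26).
#' @param n_decoy_ladder Engineered full-ladder decoy spectra (default 1).
#' @param n_decoy_noise Random-peak decoy-precursor spectra (default 3).
#' @param p Fragment retention probability (default 0.85).
#' @param n_noise Noise peaks per true spectrum (default 6).
#' @param decoy_min_length Minimum length of the engineered decoy peptide
#'   (default 25).
#' @return As [simulate_dataset()].
#' @export
benchmark_dataset <- function(index, seed, n_true = 26L, n_decoy_ladder = 1L,
                              n_decoy_noise = 3L, p = 0.85, n_noise = 6L,
                              decoy_min_length = 25L) {
  forms <- index$forms
  len <- nchar(forms$sequence)
  pool <- which(!forms$is_decoy & forms$n_mods >= 1L & len >= 7L & len <= 20L)
  ladder_pool <- which(forms$is_decoy & forms$n_mods == 0L &
                         len >= decoy_min_length)
  noise_pool <- which(forms$is_decoy & len >= 7L)
  if (length(pool) < n_true || length(ladder_pool) < n_decoy_ladder ||
      length(noise_pool) < n_decoy_noise) {
    stop("index too small for the requested benchmark", call. = FALSE)
  }
  set.seed(substream_seed(seed, 0L))
  pick <- sample(pool, n_true)
  dpick <- sample(ladder_pool, n_decoy_ladder)
  npick <- sample(noise_pool, n_decoy_noise)
  true_forms <- lapply(pick, index_form, index = index)
  decoy_forms <- lapply(dpick, index_form, index = index)
  noise_masses <- forms$mass[npick]
  simulate_dataset(list(
    seed = seed, forms = true_forms, p = p, n_noise = n_noise,
    decoy_forms = decoy_forms, noise_precursor_masses = noise_masses))
}
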