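# Deterministic, seeded generation of synthetic MS/MS spectra and small
# benchmark datasets. Every module of the package is testable on this
# simulator without any external data.

# Derive a per-spectrum RNG substream seed from a dataset seed; kept below
# 2^31 so it is always a valid R integer.
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + i * 7919) %% 2147483629)
}

#' Simulate one MS/MS spectrum of a peptide form
#'
#' Emits the charge-1 b/y ladder of the form, keeping each ladder peak
#' independently with probability `p` (fragment dropout), optionally adds a
#' +1 isotope companion to every retained peak, and sprinkles uniform noise
#' peaks over `noise_mz_range`. The precursor m/z is computed from the
#' form's neutral mass at the requested charge, with optional ppm jitter.
#' Intensities are uniform draws scaled to `base_intensity`; coverage-based
#' identification is deliberately intensity-agnostic, so no attempt is made
#' to model real fragmentation propensities.
#'
#' @param form A `peptide_form`.
#' @param charge Precursor charge (default 2).
#' @param p Per-ladder-peak retention probability in \[0, 1\].
#' @param n_noise Number of noise peaks (default 0).
#' @param noise_mz_range Noise m/z range; default `c(100, 1.05 * precursor)`,
#'   which deliberately allows noise beyond the precursor so the confidence
#'   classifier's planted-violation checks can be exercised.
#' @param noise_rel_max Noise intensity ceiling relative to base peak.
#' @param isotopes Add +1 isotope companions (default FALSE).
#' @param isotope_rel Companion intensity relative to its parent peak.
#' @param base_intensity Base peak intensity scale.
#' @param ppm_jitter Uniform precursor m/z jitter amplitude in ppm.
#' @param rt Retention time in minutes.
#' @param scan_id Scan identifier.
#' @param seed Optional integer; when given, the spectrum is reproducible.
#' @param mod_table Modification definitions.
#' @return An `ms2_spectrum` with attribute `truth`: a list with `form_key`,
#'   `n_retained` (ladder positions actually emitted), `n_positions`,
#'   `charge`.
#' @export
simulate_spectrum <- function(form, charge = 2L, p = 1, n_noise = 0L,
                              noise_mz_range = NULL, noise_rel_max = 0.3,
                              isotopes = FALSE, isotope_rel = 0.35,
                              base_intensity = 1e5, ppm_jitter = 0,
                              rt = NA_real_, scan_id = "sim_1", seed = NULL,
                              mod_table = default_mods()) {
  stopifnot(p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  mass <- neutral_mass(form, mod_table)
  pre_mz <- (mass + charge * PROTON_MASS) / charge
  if (ppm_jitter > 0) {
    pre_mz <- pre_mz * (1 + stats::runif(1, -ppm_jitter, ppm_jitter) * 1e-6)
  }
  frags <- fragment_ions(form, 1L, mod_table)
  keep <- stats::runif(nrow(frags)) < p
  mz <- frags$mz[keep]
  intensity <- stats::runif(sum(keep), 0.2, 1) * base_intensity
  if (isotopes && length(mz)) {
    mz <- c(mz, mz + ISOTOPE_SPACING)
    intensity <- c(intensity, intensity * isotope_rel)
  }
  if (n_noise > 0L) {
    if (is.null(noise_mz_range)) noise_mz_range <- c(100, 1.05 * pre_mz)
    mz <- c(mz, stats::runif(n_noise, noise_mz_range[1], noise_mz_range[2]))
    intensity <- c(intensity,
                   stats::runif(n_noise, 0, noise_rel_max) * base_intensity)
  }
  sp <- ms2_spectrum(scan_id, pre_mz, charge, rt,
                     cbind(mz, intensity), source = "simulated")
  attr(sp, "truth") <- list(form_key = form_key(form),
                            n_retained = sum(keep),
                            n_positions = nrow(frags), charge = charge)
  sp
}

#' Simulate a random-peak spectrum at a given precursor
#'
#' A decoy-confusable spectrum: a precursor consistent with some (decoy)
#' peptide mass but a peak list of pure uniform noise.
#'
#' @param precursor_mass Neutral mass the precursor should imply.
#' @param charge Precursor charge.
#' @param n_peaks Number of random peaks.
#' @param mz_range Peak m/z range; default `c(100, 1.05 * precursor mz)`.
#' @param base_intensity Intensity scale.
#' @param rt,scan_id,seed As in [simulate_spectrum()].
#' @return An `ms2_spectrum` with a `truth` attribute marking it as noise.
#' @export
simulate_noise_spectrum <- function(precursor_mass, charge = 2L,
                                    n_peaks = 40L, mz_range = NULL,
                                    base_intensity = 1e5, rt = NA_real_,
                                    scan_id = "noise_1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pre_mz <- (precursor_mass + charge * PROTON_MASS) / charge
  if (is.null(mz_range)) mz_range <- c(100, 1.05 * pre_mz)
  mz <- stats::runif(n_peaks, mz_range[1], mz_range[2])
  intensity <- stats::runif(n_peaks, 0.05, 1) * base_intensity
  sp <- ms2_spectrum(scan_id, pre_mz, charge, rt, cbind(mz, intensity),
                     source = "simulated")
  attr(sp, "truth") <- list(form_key = NA_character_, n_retained = 0L,
                            n_positions = 0L, charge = charge)
  sp
}

#' Simulate a chimeric spectrum of co-fragmented isomers
#'
#' The union of both members' ladders, with member intensities mixed at
#' `ratio` : (1 - `ratio`).
#'
#' @param form_a,form_b Isomeric `peptide_form`s.
#' @param ratio Intensity share of `form_a` in (0, 1).
#' @param charge,p,base_intensity,rt,scan_id,seed As in
#'   [simulate_spectrum()].
#' @param mod_table Modification definitions.
#' @return An `ms2_spectrum`; its `truth` attribute lists both form keys.
#' @export
simulate_chimera_spectrum <- function(form_a, form_b, ratio = 0.5,
                                      charge = 2L, p = 1,
                                      base_intensity = 1e5, rt = NA_real_,
                                      scan_id = "chim_1", seed = NULL,
                                      mod_table = default_mods()) {
  if (!is_isomeric(form_a, form_b)) {
    stop("chimera members must be isomeric", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mass <- neutral_mass(form_a, mod_table)
  pre_mz <- (mass + charge * PROTON_MASS) / charge
  build <- function(form, scale) {
    frags <- fragment_ions(form, 1L, mod_table)
    keep <- stats::runif(nrow(frags)) < p
    list(mz = frags$mz[keep],
         intensity = stats::runif(sum(keep), 0.2, 1) * base_intensity * scale,
         n_retained = sum(keep), n_positions = nrow(frags))
  }
  a <- build(form_a, ratio)
  b <- build(form_b, 1 - ratio)
  sp <- ms2_spectrum(scan_id, pre_mz, charge, rt,
                     cbind(c(a$mz, b$mz), c(a$intensity, b$intensity)),
                     source = "simulated")
  attr(sp, "truth") <- list(
    form_key = c(form_key(form_a), form_key(form_b)),
    n_retained = c(a$n_retained, b$n_retained),
    n_positions = c(a$n_positions, b$n_positions), charge = charge)
  sp
}

#' Simulate a benchmark dataset
#'
#' Generates a small labeled dataset the way the package's evaluation
#' machinery expects real data to look: planted true peptide forms with
#' fragment dropout, optional chimera pairs, optional engineered
#' high-scoring decoy spectra (a decoy peptide's full ladder) and
#' decoy-confusable random-peak spectra. Each spectrum is produced on its
#' own deterministic RNG substream, so identical `config` (including
#' `seed`) gives byte-identical output.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{seed}{integer; the only source of randomness.}
#'     \item{forms}{list of `peptide_form`s to plant (one spectrum each).}
#'     \item{charge}{precursor charge (default 2).}
#'     \item{p}{ladder retention probability (default 1).}
#'     \item{n_noise}{noise peaks per spectrum (default 0).}
#'     \item{isotopes}{add isotope companions (default FALSE).}
#'     \item{chimera_pairs}{list of `list(form_a, form_b, ratio)` (optional).}
#'     \item{decoy_forms}{list of decoy-derived `peptide_form`s emitted as
#'       full-ladder (high-scoring) decoy spectra (optional).}
#'     \item{noise_precursor_masses}{numeric vector; one random-peak
#'       spectrum is emitted per mass (optional).}
#'     \item{rt_start, rt_step}{retention-time ladder in minutes (defaults
#'       10 and 0.5).}
#'   }
#' @param out_mgf,out_truth Optional output paths (MGF and truth TSV).
#' @return A list with `spectra` (named list), `truth` (data frame:
#'   `scan_id`, `form_key`, `kind`, `n_retained`, `n_positions`, `charge`),
#'   and `config`.
#' @export
simulate_dataset <- function(config, out_mgf = NULL, out_truth = NULL) {
  stopifnot(is.list(config), !is.null(config$seed))
  cfg <- list(charge = 2L, p = 1, n_noise = 0L, isotopes = FALSE,
              forms = list(), chimera_pairs = list(), decoy_forms = list(),
              noise_precursor_masses = numeric(0), rt_start = 10,
              rt_step = 0.5)
  cfg[names(config)] <- config
  spectra <- list()
  truth <- list()
  i <- 0L
  add <- function(sp, kind) {
    tr <- attr(sp, "truth")
    spectra[[sp$scan_id]] <<- sp
    truth[[length(truth) + 1L]] <<- data.frame(
      scan_id = sp$scan_id, form_key = tr$form_key, kind = kind,
      n_retained = tr$n_retained, n_positions = tr$n_positions,
      charge = tr$charge, stringsAsFactors = FALSE)
  }
  for (f in cfg$forms) {
    i <- i + 1L
    add(simulate_spectrum(
      f, charge = cfg$charge, p = cfg$p, n_noise = cfg$n_noise,
      isotopes = cfg$isotopes, rt = cfg$rt_start + i * cfg$rt_step,
      scan_id = sprintf("sim_%03d", i),
      seed = substream_seed(cfg$seed, i)), "true")
  }
  for (pair in cfg$chimera_pairs) {
    i <- i + 1L
    add(simulate_chimera_spectrum(
      pair$form_a, pair$form_b,
      ratio = if (is.null(pair$ratio)) 0.5 else pair$ratio,
      charge = cfg$charge, p = cfg$p,
      rt = cfg$rt_start + i * cfg$rt_step,
      scan_id = sprintf("sim_%03d", i),
      seed = substream_seed(cfg$seed, i)), "chimera")
  }
  for (f in cfg$decoy_forms) {
    i <- i + 1L
    add(simulate_spectrum(
      f, charge = cfg$charge, p = 1, n_noise = 0L,
      rt = cfg$rt_start + i * cfg$rt_step,
      scan_id = sprintf("sim_%03d", i),
      seed = substream_seed(cfg$seed, i)), "decoy_ladder")
  }
  for (m in cfg$noise_precursor_masses) {
    i <- i + 1L
    add(simulate_noise_spectrum(
      m, charge = cfg$charge, rt = cfg$rt_start + i * cfg$rt_step,
      scan_id = sprintf("sim_%03d", i),
      seed = substream_seed(cfg$seed, i)), "decoy_noise")
  }
  truth <- do.call(rbind, truth)
  if (!is.null(out_mgf)) write_mgf(spectra, out_mgf)
  if (!is.null(out_truth)) {
    utils::write.table(truth, out_truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(spectra = spectra, truth = truth, config = cfg)
}
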