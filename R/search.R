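# Candidate selection, theoretical b/y fragments, peak matching, fragment
# ion coverage (FIC), and PSM ranking.

#' Theoretical b/y fragment ions of a peptide form
#'
#' For a length-n peptide there are exactly n-1 fragment positions per
#' series: b_i is the N-terminal piece of the first i residues (plus one
#' proton per charge), y_i the C-terminal piece of the last i residues (plus
#' water and protons). Modification deltas are included at their sites.
#' Only b and y ions are modeled; neutral losses and other series are
#' deliberately outside the coverage bookkeeping.
#'
#' @param form A `peptide_form` of length >= 2 (a length-1 peptide has no
#'   backbone fragments and yields an empty table).
#' @param max_frag_charge Fragment charge states 1..`max_frag_charge`.
#' @param mod_table Modification definitions.
#' @return A `data.frame` with columns `series` ("b"/"y"), `index`
#'   (1..n-1), `charge`, `mz` (ascending within each series and charge).
#' @export
fragment_ions <- function(form, max_frag_charge = 1L,
                          mod_table = default_mods()) {
  m <- site_masses(form, mod_table)
  n <- length(m)
  if (n < 2L) {
    return(data.frame(series = character(0), index = integer(0),
                      charge = integer(0), mz = numeric(0)))
  }
  b_neut <- cumsum(m)[seq_len(n - 1L)]
  y_neut <- cumsum(rev(m))[seq_len(n - 1L)] + WATER_MASS
  idx <- seq_len(n - 1L)
  out <- lapply(seq_len(max_frag_charge), function(z) {
    data.frame(
      series = rep(c("b", "y"), each = n - 1L),
      index = c(idx, idx),
      charge = z,
      mz = c((b_neut + z * PROTON_MASS) / z, (y_neut + z * PROTON_MASS) / z),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$series, out$charge, out$index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match theoretical fragments against a peak list
#'
#' A fragment matches a peak when the m/z error is within `frag_tol_ppm` and
#' the peak's intensity relative to the base peak is at least
#' `min_rel_intensity`. The nearest-in-ppm peak is recorded as the
#' assignment. A fragment *position* (series, index) counts as matched when
#' any of its charge states matches; peaks are not consumed, so one peak may
#' match several fragments.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param fragments Fragment table from [fragment_ions()].
#' @param frag_tol_ppm Fragment tolerance in ppm (default 40).
#' @param min_rel_intensity Minimum relative intensity for a peak to count
#'   (default 0: any centroid counts).
#' @return A list with `assignments` (the fragment table plus `peak`,
#'   `mz_obs`, `intensity`, `ppm`, `matched`) and `positions` (one row per
#'   matched position with its best assignment).
#' @export
match_peaks <- function(spectrum, fragments, frag_tol_ppm = 40,
                        min_rel_intensity = 0) {
  stopifnot(frag_tol_ppm > 0)
  peaks <- spectrum$peaks
  if (min_rel_intensity > 0 && nrow(peaks)) {
    peaks <- peaks[peaks[, 2] >= min_rel_intensity * max(peaks[, 2]), ,
                   drop = FALSE]
  }
  nf <- nrow(fragments)
  asg <- fragments
  asg$peak <- NA_integer_
  asg$mz_obs <- NA_real_
  asg$intensity <- NA_real_
  asg$ppm <- NA_real_
  asg$matched <- FALSE
  if (nf && nrow(peaks)) {
    pmz <- peaks[, 1]
    lo <- findInterval(asg$mz, pmz)
    hi <- pmin(lo + 1L, length(pmz))
    lo <- pmax(lo, 1L)
    ppm_lo <- abs(pmz[lo] - asg$mz) / asg$mz * 1e6
    ppm_hi <- abs(pmz[hi] - asg$mz) / asg$mz * 1e6
    use_hi <- ppm_hi < ppm_lo
    best <- ifelse(use_hi, hi, lo)
    best_ppm <- pmin(ppm_lo, ppm_hi)
    ok <- best_ppm <= frag_tol_ppm
    asg$peak[ok] <- best[ok]
    asg$mz_obs[ok] <- pmz[best[ok]]
    asg$intensity[ok] <- peaks[best[ok], 2]
    asg$ppm[ok] <- best_ppm[ok]
    asg$matched <- ok
  }
  hits <- asg[asg$matched, , drop = FALSE]
  if (nrow(hits)) {
    key <- paste(hits$series, hits$index)
    best_per_pos <- tapply(seq_len(nrow(hits)), key, function(i) {
      i[which.min(hits$ppm[i])]
    })
    positions <- hits[sort(as.integer(best_per_pos)), , drop = FALSE]
  } else {
    positions <- hits
  }
  rownames(positions) <- NULL
  list(assignments = asg, positions = positions)
}

#' Fragment ion coverage of a form against a spectrum
#'
#' The number of observed b/y fragment positions divided by the number of
#' theoretical positions, 2(n-1) for a length-n peptide. The denominator
#' counts ions, not charge states: a position observed at any charge counts
#' once.
#'
#' @param form A `peptide_form`.
#' @param spectrum An `ms2_spectrum`.
#' @param frag_tol_ppm Fragment tolerance in ppm.
#' @param max_frag_charge Highest fragment charge considered.
#' @param min_rel_intensity Passed to [match_peaks()].
#' @param mod_table Modification definitions.
#' @return A fraction in \[0, 1\].
#' @export
compute_fic <- function(form, spectrum, frag_tol_ppm = 40,
                        max_frag_charge = 1L, min_rel_intensity = 0,
                        mod_table = default_mods()) {
  frags <- fragment_ions(form, max_frag_charge, mod_table)
  n <- nchar(form$sequence)
  if (n < 2L) return(0)
  matched <- match_peaks(spectrum, frags, frag_tol_ppm, min_rel_intensity)
  nrow(matched$positions) / (2 * (n - 1L))
}

# Default fragment charge range given a precursor charge: 1..min(z-1, 2),
# at least 1.
default_frag_charge <- function(precursor_charge) {
  max(1L, min(precursor_charge - 1L, 2L))
}

# Score one candidate against a spectrum. Returns fic, matched-count,
# explained intensity and the matched-position table.
score_candidate <- function(form, spectrum, frag_tol_ppm = 40,
                            max_frag_charge = 1L, min_rel_intensity = 0,
                            mod_table = default_mods()) {
  frags <- fragment_ions(form, max_frag_charge, mod_table)
  matched <- match_peaks(spectrum, frags, frag_tol_ppm, min_rel_intensity)
  n <- nchar(form$sequence)
  total_int <- sum(spectrum$peaks[, 2])
  expl <- if (total_int > 0 && nrow(matched$assignments)) {
    pk <- unique(matched$assignments$peak[matched$assignments$matched])
    sum(spectrum$peaks[pk, 2]) / total_int
  } else {
    0
  }
  n_matched <- nrow(matched$positions)
  list(
    fic = n_matched / (2 * (n - 1L)),
    n_matched = n_matched,
    n_positions = 2L * (n - 1L),
    explained_intensity = expl,
    rank_score = n_matched + expl,
    positions = matched$positions,
    assignments = matched$assignments
  )
}

#' Score and rank candidate forms against one spectrum
#'
#' The rank score is the number of matched fragment positions plus the
#' explained-intensity fraction; ties break by higher explained intensity,
#' then lexicographic form key, making the ordering fully deterministic.
#' Each PSM's delta score is its rank score minus the best score among
#' candidates that are not positional isomers of it (its own score when no
#' non-isomer exists), so co-eluting isomers do not erode each other's delta.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param candidates A list of `peptide_form` objects (length >= 1).
#' @param frag_tol_ppm,max_frag_charge,min_rel_intensity Matching settings.
#' @param mod_table Modification definitions.
#' @return A `data.frame`, one row per candidate, ordered best-first, with
#'   columns `form_key`, `sequence`, `mods`, `fic`, `n_matched`,
#'   `n_positions`, `explained_intensity`, `rank_score`, `delta_score`.
#' @export
score_and_rank <- function(spectrum, candidates, frag_tol_ppm = 40,
                           max_frag_charge = 1L, min_rel_intensity = 0,
                           mod_table = default_mods()) {
  stopifnot(length(candidates) >= 1L)
  scored <- lapply(candidates, score_candidate, spectrum = spectrum,
                   frag_tol_ppm = frag_tol_ppm,
                   max_frag_charge = max_frag_charge,
                   min_rel_intensity = min_rel_intensity,
                   mod_table = mod_table)
  keys <- vapply(candidates, form_key, character(1))
  df <- data.frame(
    form_key = keys,
    sequence = vapply(candidates, `[[`, character(1), "sequence"),
    mods = vapply(candidates, function(f) {
      if (length(f$mods)) sub("^[^/]*/", "", form_key(f)) else ""
    }, character(1)),
    fic = vapply(scored, `[[`, numeric(1), "fic"),
    n_matched = vapply(scored, `[[`, numeric(1), "n_matched"),
    n_positions = vapply(scored, `[[`, numeric(1), "n_positions"),
    explained_intensity = vapply(scored, `[[`, numeric(1),
                                 "explained_intensity"),
    rank_score = vapply(scored, `[[`, numeric(1), "rank_score"),
    stringsAsFactors = FALSE
  )
  multisets <- vapply(candidates, mod_multiset, character(1))
  iso_key <- paste(df$sequence, multisets)
  df$delta_score <- vapply(seq_len(nrow(df)), function(i) {
    other <- df$rank_score[iso_key != iso_key[i]]
    df$rank_score[i] - if (length(other)) max(other) else 0
  }, numeric(1))
  o <- order(-df$rank_score, -df$explained_intensity, df$form_key)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "scored") <- scored[o]
  attr(df, "forms") <- candidates[o]
  df
}

#' Build a searchable index of modified peptide forms
#'
#' Digests a (target + decoy) protein database, enumerates modified forms of
#' each distinct peptide sequence under the configured target and background
#' modifications, and indexes them by neutral mass for precursor lookup.
#' Peptides whose enumeration would exceed `max_forms_per_peptide` are
#' skipped with a warning (`on_overflow = "skip"`, the default) or raise an
#' error. Because acylated lysine blocks tryptic cleavage in vitro, forms
#' whose C-terminal residue is a modified lysine are discarded unless the
#' peptide ends at a protein C terminus (`cterm_mod_k_filter`).
#'
#' @param proteins Protein `data.frame` (typically [decoy_database()] output).
#' @param target_mod Name(s) of the PTM(s) of interest (default `"la"`).
#' @param background_mods Background variable modifications (default
#'   `c("ac", "me1", "rme1")`).
#' @param enzyme,max_missed,min_length,max_length,met_clip Digestion
#'   settings, see [digest_protein()].
#' @param max_background Maximum background mods per peptide.
#' @param max_forms_per_peptide Combinatorial ceiling per peptide.
#' @param on_overflow `"skip"` or `"error"`.
#' @param cterm_mod_k_filter Drop forms ending in a modified lysine that is
#'   not a protein C terminus.
#' @param mod_table Modification definitions.
#' @return An object of class `form_index`: a mass-sorted form table plus a
#'   per-sequence location table.
#' @export
build_form_index <- function(proteins, target_mod = "la",
                             background_mods = c("ac", "me1", "rme1"),
                             enzyme = "trypsin", max_missed = 4L,
                             min_length = 5L, max_length = 35L,
                             met_clip = TRUE, max_background = 3L,
                             max_forms_per_peptide = 10000L,
                             on_overflow = c("skip", "error"),
                             cterm_mod_k_filter = TRUE,
                             mod_table = default_mods()) {
  on_overflow <- match.arg(on_overflow)
  peptides <- digest_proteins(proteins, enzyme, max_missed,
                              min_length, max_length, met_clip)
  if (!nrow(peptides)) stop("digestion produced no peptides", call. = FALSE)
  prot_len <- stats::setNames(nchar(proteins$sequence), proteins$id)
  peptides$cterm <- peptides$end == prot_len[peptides$protein]
  # location table: all (protein, start, end) per distinct sequence
  locations <- peptides[!duplicated(peptides[c("protein", "start", "end")]), ,
                        drop = FALSE]
  seqs <- unique(peptides$sequence)
  seq_is_decoy <- tapply(peptides$is_decoy, peptides$sequence, all)[seqs]
  seq_cterm <- tapply(peptides$cterm, peptides$sequence, any)[seqs]

  skipped <- character(0)
  rows <- vector("list", length(seqs))
  for (si in seq_along(seqs)) {
    sq <- seqs[si]
    forms <- tryCatch(
      enumerate_forms(sq, target_mods = target_mod,
                      background_mods = background_mods,
                      max_background = max_background,
                      max_forms = max_forms_per_peptide,
                      mod_table = mod_table),
      error = function(e) e
    )
    if (inherits(forms, "error")) {
      if (on_overflow == "error") stop(forms)
      skipped <- c(skipped, sq)
      next
    }
    if (cterm_mod_k_filter && !seq_cterm[[si]] &&
        substring(sq, nchar(sq)) == "K") {
      last <- as.character(nchar(sq))
      forms <- Filter(function(f) !last %in% names(f$mods), forms)
    }
    if (!length(forms)) next
    rows[[si]] <- data.frame(
      sequence = sq,
      mods = vapply(forms, function(f) {
        if (length(f$mods)) sub("^[^/]*/", "", form_key(f)) else ""
      }, character(1)),
      mass = vapply(forms, neutral_mass, numeric(1), mod_table = mod_table),
      n_mods = vapply(forms, function(f) length(f$mods), integer(1)),
      is_decoy = seq_is_decoy[[si]],
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped)) {
    warning(length(skipped), " peptide(s) exceeded the form ceiling and were",
            " skipped, e.g. ", skipped[1], call. = FALSE)
  }
  forms_df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  forms_df <- forms_df[order(forms_df$mass), , drop = FALSE]
  rownames(forms_df) <- NULL
  structure(
    list(forms = forms_df, locations = locations, mod_table = mod_table,
         params = list(target_mod = target_mod,
                       background_mods = background_mods,
                       max_background = max_background,
                       enzyme = enzyme, max_missed = max_missed,
                       min_length = min_length, max_length = max_length),
         skipped = skipped),
    class = "form_index"
  )
}

#' @export
print.form_index <- function(x, ...) {
  cat("<form_index> ", nrow(x$forms), " forms from ",
      length(unique(x$forms$sequence)), " peptides\n", sep = "")
  cat("  target mod(s): ", paste(x$params$target_mod, collapse = ", "),
      "; background: ", paste(x$params$background_mods, collapse = ", "),
      " (max ", x$params$max_background, ")\n", sep = "")
  if (length(x$skipped)) {
    cat("  ", length(x$skipped), " peptide(s) skipped at the form ceiling\n",
        sep = "")
  }
  invisible(x)
}

# Rebuild a peptide_form from an index row (primary location attached).
index_form <- function(index, row) {
  rec <- index$forms[row, ]
  loc <- index$locations[index$locations$sequence == rec$sequence, ,
                         drop = FALSE]
  key <- if (nzchar(rec$mods)) paste0(rec$sequence, "/", rec$mods) else
    rec$sequence
  f <- parse_form(key, mod_table = index$mod_table)
  if (nrow(loc)) {
    f$protein <- loc$protein[1]
    f$start <- loc$start[1]
    f$end <- loc$end[1]
  }
  f
}

#' Select candidate forms for a spectrum by precursor mass
#'
#' Accepts every indexed form whose neutral mass is within
#' `precursor_tol_ppm` of the observed precursor neutral mass. An unknown
#' precursor charge (0) is handled by taking the union over assumed charges
#' 2-4. Optionally a +1 isotope error window (observed mass one neutron too
#' high) is searched as well.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param index A `form_index`.
#' @param precursor_tol_ppm Precursor tolerance in ppm (default 10).
#' @param isotope_error Also allow a -1-neutron corrected mass.
#' @return A `data.frame` of index rows with columns `row` (index row
#'   number) and `charge` (the assumed precursor charge).
#' @export
select_candidates <- function(spectrum, index, precursor_tol_ppm = 10,
                              isotope_error = FALSE) {
  charges <- if (spectrum$precursor_charge >= 1L) {
    spectrum$precursor_charge
  } else {
    2:4
  }
  masses <- index$forms$mass
  out <- list()
  for (z in charges) {
    obs <- precursor_neutral(spectrum, z)
    targets <- obs
    if (isotope_error) targets <- c(obs, obs - ISOTOPE_SPACING)
    for (tm in targets) {
      # |obs - mass| / mass <= tol  <=>  mass in [tm/(1+tol), tm/(1-tol)]
      tol <- precursor_tol_ppm * 1e-6
      lo <- findInterval(tm / (1 + tol), masses) + 1L
      hi <- findInterval(tm / (1 - tol), masses)
      if (hi >= lo) {
        out[[length(out) + 1L]] <- data.frame(row = lo:hi, charge = z)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(row = integer(0), charge = integer(0)))
  }
  res <- do.call(rbind, out)
  res[!duplicated(res$row), , drop = FALSE]
}

#' Search spectra against a form index
#'
#' For each spectrum: select candidates by precursor mass, score and rank
#' them, keep the best PSM, and (optionally) dissect positional-isomer
#' chimeras so that co-fragmented isomers supported by their own
#' site-determining ions are co-reported. No FIC or FDR filtering happens
#' here; see [filter_fic()] and [target_decoy_fdr()].
#'
#' @param spectra List of `ms2_spectrum` objects.
#' @param index A `form_index`.
#' @param precursor_tol_ppm,frag_tol_ppm Mass tolerances in ppm (defaults 10
#'   and 40).
#' @param min_rel_intensity Passed to [match_peaks()].
#' @param chimera Dissect isomeric chimeras (default TRUE).
#' @param fic_cutoff FIC threshold used only for chimera member acceptance.
#' @param isotope_error Passed to [select_candidates()].
#' @param progress Print a dot every 50 spectra.
#' @return An object of class `search_result`: list with `psms` (data frame,
#'   one row per reported PSM), `spectra`, `index`.
#' @export
search_spectra <- function(spectra, index, precursor_tol_ppm = 10,
                           frag_tol_ppm = 40, min_rel_intensity = 0,
                           chimera = TRUE, fic_cutoff = 0.5,
                           isotope_error = FALSE, progress = FALSE) {
  mod_table <- index$mod_table
  loc <- index$locations
  psm_rows <- list()
  for (si in seq_along(spectra)) {
    if (progress && si %% 50L == 0L) cat(".")
    sp <- spectra[[si]]
    cand <- select_candidates(sp, index, precursor_tol_ppm, isotope_error)
    if (!nrow(cand)) next
    forms <- lapply(cand$row, index_form, index = index)
    charge <- cand$charge[1]
    zmax <- default_frag_charge(charge)
    ranked <- score_and_rank(sp, forms, frag_tol_ppm, zmax,
                             min_rel_intensity, mod_table)
    ranked$row <- cand$row[match(ranked$form_key, vapply(forms, form_key,
                                                         character(1)))]
    top <- ranked[1, ]
    top_form <- attr(ranked, "forms")[[1]]
    accepted <- list(list(rec = top, form = top_form,
                          chimera_member = FALSE, ambiguous = FALSE))
    if (chimera && nrow(ranked) > 1L) {
      iso <- which(vapply(attr(ranked, "forms"), is_isomeric,
                          logical(1), b = top_form))
      iso <- setdiff(iso, 1L)
      iso <- iso[vapply(iso, function(i) {
        ranked$form_key[i] != top$form_key
      }, logical(1))]
      if (length(iso)) {
        members <- c(list(top_form), attr(ranked, "forms")[iso])
        dis <- dissect_chimera(sp, members, fic_cutoff, frag_tol_ppm,
                               max_frag_charge = zmax,
                               min_rel_intensity = min_rel_intensity,
                               mod_table = mod_table)
        extra_keys <- setdiff(dis$table$form_key[dis$table$accepted],
                              top$form_key)
        if (length(extra_keys)) {
          accepted[[1]]$chimera_member <- TRUE
          for (k in extra_keys) {
            i <- which(ranked$form_key == k)
            accepted[[length(accepted) + 1L]] <- list(
              rec = ranked[i, ], form = attr(ranked, "forms")[[i]],
              chimera_member = TRUE, ambiguous = FALSE)
          }
        }
        accepted[[1]]$ambiguous <- dis$ambiguous
      }
    }
    for (a in accepted) {
      rec <- a$rec
      f <- a$form
      n_loc <- sum(loc$sequence == f$sequence)
      obs <- precursor_neutral(sp, charge)
      mass <- index$forms$mass[rec$row]
      psm_rows[[length(psm_rows) + 1L]] <- data.frame(
        scan_id = sp$scan_id, sequence = rec$sequence, mods = rec$mods,
        charge = charge, precursor_mz = sp$precursor_mz, rt = sp$rt,
        precursor_error_ppm = (obs - mass) / mass * 1e6,
        fic = rec$fic, n_matched = rec$n_matched,
        n_positions = rec$n_positions,
        explained_intensity = rec$explained_intensity,
        rank_score = rec$rank_score, delta_score = rec$delta_score,
        is_decoy = index$forms$is_decoy[rec$row],
        protein = f$protein, start = f$start, end = f$end,
        n_locations = n_loc, chimera_member = a$chimera_member,
        site_ambiguous = a$ambiguous,
        stringsAsFactors = FALSE
      )
    }
  }
  if (progress) cat("\n")
  psms <- if (length(psm_rows)) do.call(rbind, psm_rows) else NULL
  if (is.null(psms)) {
    stop("no spectrum yielded any candidate PSM", call. = FALSE)
  }
  rownames(psms) <- NULL
  structure(list(psms = psms, spectra = spectra, index = index,
                 params = list(precursor_tol_ppm = precursor_tol_ppm,
                               frag_tol_ppm = frag_tol_ppm,
                               fic_cutoff = fic_cutoff)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> ", nrow(x$psms), " PSMs over ",
      length(unique(x$psms$scan_id)), " of ", length(x$spectra),
      " spectra\n", sep = "")
  cat("  decoy top hits: ", sum(x$psms$is_decoy), "; chimera members: ",
      sum(x$psms$chimera_member), "\n", sep = "")
  invisible(x)
}

# Rebuild the peptide_form of a PSM table row.
psm_form <- function(psm_row, mod_table = default_mods()) {
  key <- if (nzchar(psm_row$mods)) {
    paste0(psm_row$sequence, "/", psm_row$mods)
  } else {
    psm_row$sequence
  }
  parse_form(key, protein = psm_row$protein, start = psm_row$start,
             end = psm_row$end, mod_table = mod_table)
}
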