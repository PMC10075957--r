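# PSM filtration and evaluation: FIC cutoff, target-decoy FDR, ROC sweeps,
# automated confidence classification, cross-dataset loss rates.

#' Filter PSMs by fragment ion coverage
#'
#' The package's primary acceptance criterion: keep PSMs whose fragment ion
#' coverage reaches the cutoff (inclusive, "at least 50%" by default). Row
#' order is preserved.
#'
#' @param psms PSM `data.frame` with an `fic` column (or a `search_result`).
#' @param cutoff Coverage threshold in \[0, 1\] (default 0.5).
#' @param drop_decoys Also remove decoy PSMs (default TRUE).
#' @return The accepted subset of `psms`.
#' @export
filter_fic <- function(psms, cutoff = 0.5, drop_decoys = TRUE) {
  if (inherits(psms, "search_result")) psms <- psms$psms
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 1) {
    stop("fic cutoff must be a single value in [0, 1]", call. = FALSE)
  }
  keep <- psms$fic >= cutoff
  if (drop_decoys) keep <- keep & !psms$is_decoy
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-decoy false discovery rate
#'
#' For a score cutoff s, FDR(s) = (decoy PSMs with score >= s) / (target
#' PSMs with score >= s), taken as 0 when no decoy scores that high (and
#' infinite when decoys but no targets do). Reported q-values are the
#' monotonized minimum FDR over all cutoffs at or below a PSM's score. The
#' threshold is the smallest score whose FDR is at or below `level`. No +1
#' pseudocount is added, matching a manually computed decoy/target ratio;
#' set `pseudocount = 1` for the conservative variant.
#'
#' @param psms PSM `data.frame` with `rank_score` and `is_decoy` columns (or
#'   a `search_result`).
#' @param level FDR level (default 0.01).
#' @param pseudocount Added to the decoy count (default 0).
#' @return An object of class `fdr_result`: `threshold` (NA when no cutoff
#'   achieves the level), `level`, `table` (per distinct score: counts, fdr,
#'   q), `qvalues` (per input PSM), `no_decoys` flag.
#' @export
target_decoy_fdr <- function(psms, level = 0.01, pseudocount = 0) {
  if (inherits(psms, "search_result")) psms <- psms$psms
  scores <- psms$rank_score
  is_decoy <- psms$is_decoy
  no_decoys <- !any(is_decoy)
  cuts <- sort(unique(scores))
  n_t <- vapply(cuts, function(s) sum(scores >= s & !is_decoy), numeric(1))
  n_d <- vapply(cuts, function(s) sum(scores >= s & is_decoy), numeric(1))
  fdr <- ifelse(n_d + pseudocount == 0, 0,
                ifelse(n_t == 0, Inf, (n_d + pseudocount) / n_t))
  q <- cummin(fdr) # cutoffs ascend, so q(s) = min FDR over t <= s
  tab <- data.frame(score = cuts, n_target = n_t, n_decoy = n_d,
                    fdr = fdr, q = q)
  ok <- which(fdr <= level)
  threshold <- if (length(ok)) cuts[min(ok)] else NA_real_
  structure(
    list(threshold = threshold, level = level, table = tab,
         qvalues = q[match(scores, cuts)],
         achieved_fdr = if (length(ok)) fdr[min(ok)] else NA_real_,
         no_decoys = no_decoys),
    class = "fdr_result"
  )
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("<fdr_result> level ", x$level, "\n", sep = "")
  if (x$no_decoys) cat("  WARNING: no decoy PSMs; threshold undefined\n")
  if (is.na(x$threshold)) {
    cat("  no score cutoff achieves the level; nothing passes\n")
  } else {
    cat(sprintf("  threshold %.4f (achieved FDR %.4f)\n",
                x$threshold, x$achieved_fdr))
  }
  invisible(x)
}

#' Apply an FDR threshold
#'
#' @param psms PSM `data.frame` (or `search_result`).
#' @param fdr An `fdr_result` from [target_decoy_fdr()].
#' @param drop_decoys Remove decoy PSMs from the accepted set (default TRUE).
#' @return Accepted PSMs (empty when no threshold exists).
#' @export
filter_fdr <- function(psms, fdr, drop_decoys = TRUE) {
  if (inherits(psms, "search_result")) psms <- psms$psms
  keep <- if (is.na(fdr$threshold)) rep(FALSE, nrow(psms)) else
    psms$rank_score >= fdr$threshold
  if (drop_decoys) keep <- keep & !psms$is_decoy
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ROC comparison of FDR-based and FIC-based filtration
#'
#' Sweeps both strategies from strictest to loosest over labeled PSMs: the
#' FDR sweep accepts PSMs whose q-value is at or below each level of
#' `fdr_grid`; the FIC sweep accepts PSMs whose coverage reaches each cutoff
#' of `fic_grid`. True/false-positive rates are computed against the
#' supplied truth labels (in benchmark use, decoy-derived PSMs are the false
#' class). Explicit strict (0,0) and loose (1,1) endpoints are added.
#'
#' @param psms PSM `data.frame` (or `search_result`).
#' @param truth Logical vector, one per PSM: is the identification correct?
#' @param fdr_grid FDR levels, strict to loose (default 1%..100%).
#' @param fic_grid Coverage cutoffs, strict to loose (default 100%..0%).
#' @return An object of class `roc_curves`: data frame with `strategy`
#'   ("fdr"/"fic"), `cutoff`, `fpr`, `tpr`.
#' @export
roc_compare <- function(psms, truth, fdr_grid = seq(0.01, 1, by = 0.01),
                        fic_grid = seq(1, 0, by = -0.01)) {
  if (inherits(psms, "search_result")) psms <- psms$psms
  stopifnot(length(truth) == nrow(psms))
  n_true <- sum(truth)
  n_false <- sum(!truth)
  if (n_true == 0L) {
    warning("no true PSMs; TPR undefined", call. = FALSE)
  }
  rate <- function(acc) {
    c(fpr = if (n_false) sum(acc & !truth) / n_false else 0,
      tpr = if (n_true) sum(acc & truth) / n_true else NA_real_)
  }
  fdr <- target_decoy_fdr(psms)
  q <- fdr$qvalues
  fdr_pts <- t(vapply(fdr_grid, function(lv) rate(q <= lv), numeric(2)))
  fic_pts <- t(vapply(fic_grid, function(ct) rate(psms$fic >= ct), numeric(2)))
  out <- rbind(
    data.frame(strategy = "fdr", cutoff = c(NA, fdr_grid, NA),
               fpr = c(0, fdr_pts[, 1], 1), tpr = c(0, fdr_pts[, 2], 1)),
    data.frame(strategy = "fic", cutoff = c(NA, fic_grid, NA),
               fpr = c(0, fic_pts[, 1], 1), tpr = c(0, fic_pts[, 2], 1))
  )
  structure(out, class = c("roc_curves", "data.frame"))
}

#' Does one ROC curve weakly dominate another?
#'
#' Curve `a` weakly dominates curve `b` when, at every false-positive rate
#' reached by `b`, `a` attains at least the same true-positive rate.
#'
#' @param roc A `roc_curves` object.
#' @param a,b Strategy names (default `"fic"` vs `"fdr"`).
#' @param tol Numerical slack.
#' @return TRUE/FALSE.
#' @export
roc_dominates <- function(roc, a = "fic", b = "fdr", tol = 1e-9) {
  ca <- roc[roc$strategy == a, ]
  cb <- roc[roc$strategy == b, ]
  best_tpr_at <- function(curve, fpr) {
    ok <- curve$fpr <= fpr + tol
    if (!any(ok)) 0 else max(curve$tpr[ok])
  }
  all(vapply(seq_len(nrow(cb)), function(i) {
    best_tpr_at(ca, cb$fpr[i]) + tol >= cb$tpr[i]
  }, logical(1)))
}

#' @method plot roc_curves
#' @export
plot.roc_curves <- function(x, ...) {
  cols <- c(fdr = "brown", fic = "steelblue")
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false positive rate", ylab = "true positive rate",
                 ...)
  graphics::abline(0, 1, col = "grey", lty = 2)
  for (s in unique(x$strategy)) {
    cur <- x[x$strategy == s, ]
    o <- order(cur$fpr, cur$tpr)
    graphics::lines(cur$fpr[o], cur$tpr[o], type = "s", col = cols[[s]],
                    lwd = 2)
  }
  graphics::legend("bottomright", legend = unique(x$strategy),
                   col = cols[unique(x$strategy)], lwd = 2, bty = "n")
  invisible(x)
}

#' Automated confidence classification of an accepted PSM
#'
#' Approximates the manual-scrutiny criteria used to grade identifications:
#' (i) no prominent unmatched peak with m/z above the precursor ion, (ii)
#' most intense matched fragments show a +1 isotope companion (spacing
#' 1.00335/z at the fragment's assigned charge), and (iii) no prominent peak
#' beyond the largest matched fragment m/z. A PSM passing all three is
#' `"high"`, otherwise `"moderate"`. These are flags for prioritizing
#' review, not verdicts: genuinely chimeric or noisy spectra can fail (i) or
#' (iii) while being correct.
#'
#' @param form A `peptide_form` (the accepted identification).
#' @param spectrum The matched `ms2_spectrum`.
#' @param frag_tol_ppm Fragment tolerance in ppm.
#' @param max_frag_charge Fragment charge states.
#' @param noise_rel Relative-intensity floor above which an unexplained peak
#'   counts as prominent (default 0.05 of the base peak).
#' @param isotope_frac Minimum fraction of the top-10 matched peaks that
#'   must show an isotope companion (default 0.5).
#' @param mod_table Modification definitions.
#' @return A list with `class` ("high"/"moderate") and logical `checks`.
#' @export
classify_confidence <- function(form, spectrum, frag_tol_ppm = 40,
                                max_frag_charge = 1L, noise_rel = 0.05,
                                isotope_frac = 0.5,
                                mod_table = default_mods()) {
  frags <- fragment_ions(form, max_frag_charge, mod_table)
  matched <- match_peaks(spectrum, frags, frag_tol_ppm)
  peaks <- spectrum$peaks
  if (!nrow(peaks)) {
    return(list(class = "moderate",
                checks = c(no_high_unmatched = FALSE, isotopes = FALSE,
                           no_trailing_noise = FALSE)))
  }
  base <- max(peaks[, 2])
  matched_idx <- unique(matched$assignments$peak[matched$assignments$matched])
  # peaks explained as +1 isotope companions of assigned peaks (z = 1..2)
  iso_idx <- integer(0)
  if (length(matched_idx)) {
    for (z in 1:2) {
      comp <- peaks[matched_idx, 1] + ISOTOPE_SPACING / z
      for (cm in comp) {
        near <- which(abs(peaks[, 1] - cm) / cm * 1e6 <= frag_tol_ppm)
        iso_idx <- c(iso_idx, near)
      }
    }
  }
  explained <- union(matched_idx, iso_idx)
  unexplained <- setdiff(seq_len(nrow(peaks)), explained)
  prominent <- unexplained[peaks[unexplained, 2] > noise_rel * base]

  check_i <- !any(peaks[prominent, 1] > spectrum$precursor_mz)

  pos <- matched$positions
  check_ii <- if (nrow(pos) == 0L) {
    FALSE
  } else {
    top <- pos[order(-pos$intensity), , drop = FALSE]
    top <- top[seq_len(min(10L, nrow(top))), , drop = FALSE]
    has_iso <- vapply(seq_len(nrow(top)), function(i) {
      cm <- top$mz_obs[i] + ISOTOPE_SPACING / top$charge[i]
      any(abs(peaks[, 1] - cm) / cm * 1e6 <= frag_tol_ppm)
    }, logical(1))
    mean(has_iso) >= isotope_frac
  }

  max_frag_mz <- if (length(matched_idx)) max(peaks[matched_idx, 1]) else 0
  check_iii <- !any(peaks[prominent, 1] > max_frag_mz)

  checks <- c(no_high_unmatched = check_i, isotopes = check_ii,
              no_trailing_noise = check_iii)
  list(class = if (all(checks)) "high" else "moderate", checks = checks)
}

#' Add a confidence class column to accepted PSMs
#'
#' @param psms Accepted PSM `data.frame`.
#' @param spectra Named list of `ms2_spectrum` (names = scan ids).
#' @param ... Passed to [classify_confidence()].
#' @param mod_table Modification definitions.
#' @return `psms` with a `confidence_class` column.
#' @export
classify_psms <- function(psms, spectra, ..., mod_table = default_mods()) {
  if (!nrow(psms)) {
    psms$confidence_class <- character(0)
    return(psms)
  }
  psms$confidence_class <- vapply(seq_len(nrow(psms)), function(i) {
    sp <- spectra[[psms$scan_id[i]]]
    zmax <- default_frag_charge(psms$charge[i])
    classify_confidence(psm_form(psms[i, ], mod_table), sp,
                        max_frag_charge = zmax, ...,
                        mod_table = mod_table)$class
  }, character(1))
  psms
}

#' Does a PSM report the same identification as a planted truth form?
#'
#' Benchmark truth predicate at the level the loss-rate bookkeeping counts:
#' the same peptide sequence, the same target-PTM site assignment, and the
#' same neutral mass. Placement of *background* marks among equal-delta
#' alternatives (e.g. monomethyl on a neighbouring K versus R) is not
#' resolvable from a spectrum that lost the relevant site-determining ions
#' and does not change the reported target site, so it is not scored as a
#' miss.
#'
#' @param psm_key,truth_key Form keys ([form_key()] strings).
#' @param target_mod Target PTM name(s) whose site assignment must agree.
#' @param mod_table Modification definitions.
#' @return TRUE/FALSE.
#' @export
same_identification <- function(psm_key, truth_key, target_mod = "la",
                                mod_table = default_mods()) {
  if (is.na(psm_key) || is.na(truth_key)) return(FALSE)
  a <- parse_form(psm_key, mod_table = mod_table)
  b <- parse_form(truth_key, mod_table = mod_table)
  if (!identical(a$sequence, b$sequence)) return(FALSE)
  tgt_sites <- function(f) names(f$mods)[unname(f$mods) %in% target_mod]
  if (!identical(tgt_sites(a), tgt_sites(b))) return(FALSE)
  abs(neutral_mass(a, mod_table) - neutral_mass(b, mod_table)) < 1e-6
}

#' Cross-reference accepted identifications across datasets
#'
#' Builds the union of accepted peptide forms over several datasets and, for
#' each dataset, flags every union key as detected, missed, or absent. A key
#' counts as *missed* in a dataset only when that dataset, while not
#' identifying the peptide, still contains a precursor consistent with it:
#' some spectrum within `mz_tol_ppm` of the form's mass and (when retention
#' times are available) within `rt_tol_min` of the median retention time of
#' the identifications elsewhere. The loss rate is missed / (detected +
#' missed).
#'
#' @param runs Named list; each element a list with `psms` (accepted PSM
#'   data frame) and `spectra` (that dataset's spectra).
#' @param mz_tol_ppm Precursor tolerance for evidence-of-presence (default
#'   10).
#' @param rt_tol_min Retention-time tolerance in minutes (default 2).
#' @param mod_table Modification definitions.
#' @return An object of class `crossref_result`: `keys` (per union key and
#'   dataset: status), `loss` (per dataset: counts and `loss_rate`).
#' @export
cross_reference <- function(runs, mz_tol_ppm = 10, rt_tol_min = 2,
                            mod_table = default_mods()) {
  if (length(runs) < 2L) stop("cross_reference needs >= 2 datasets",
                              call. = FALSE)
  if (is.null(names(runs))) names(runs) <- paste0("dataset_", seq_along(runs))
  key_of <- function(psms) {
    ifelse(nzchar(psms$mods), paste0(psms$sequence, "/", psms$mods),
           psms$sequence)
  }
  all_keys <- sort(unique(unlist(lapply(runs, function(r) key_of(r$psms)))))
  key_mass <- vapply(all_keys, function(k) {
    neutral_mass(parse_form(k, mod_table = mod_table), mod_table)
  }, numeric(1))
  # reference RT per key: median over all datasets' detections
  key_rts <- lapply(all_keys, function(k) {
    unlist(lapply(runs, function(r) {
      r$psms$rt[key_of(r$psms) == k]
    }))
  })

  status <- matrix("absent", nrow = length(all_keys), ncol = length(runs),
                   dimnames = list(all_keys, names(runs)))
  for (d in seq_along(runs)) {
    run <- runs[[d]]
    detected <- unique(key_of(run$psms))
    spec_mass <- lapply(run$spectra, function(sp) {
      z <- if (sp$precursor_charge >= 1) sp$precursor_charge else 2:4
      precursor_neutral(sp, z)
    })
    spec_rt <- vapply(run$spectra, `[[`, numeric(1), "rt")
    have_rt <- !all(is.na(spec_rt))
    if (!have_rt) {
      warning("dataset '", names(runs)[d],
              "' lacks retention times; RT criterion skipped", call. = FALSE)
    }
    for (ki in seq_along(all_keys)) {
      k <- all_keys[ki]
      if (k %in% detected) {
        status[ki, d] <- "detected"
        next
      }
      ref_rt <- stats::median(key_rts[[ki]], na.rm = TRUE)
      evidence <- vapply(seq_along(run$spectra), function(si) {
        dm <- abs(spec_mass[[si]] - key_mass[ki]) / key_mass[ki] * 1e6
        if (!any(dm <= mz_tol_ppm)) return(FALSE)
        if (have_rt && !is.na(ref_rt) && !is.na(spec_rt[si])) {
          abs(spec_rt[si] - ref_rt) <= rt_tol_min
        } else {
          TRUE
        }
      }, logical(1))
      if (any(evidence)) status[ki, d] <- "missed"
    }
  }
  loss <- data.frame(
    dataset = names(runs),
    n_detected = colSums(status == "detected"),
    n_missed = colSums(status == "missed"),
    row.names = NULL
  )
  loss$loss_rate <- ifelse(loss$n_detected + loss$n_missed == 0, NA_real_,
                           loss$n_missed / (loss$n_detected + loss$n_missed))
  structure(list(keys = as.data.frame(status), loss = loss),
            class = "crossref_result")
}

#' @export
print.crossref_result <- function(x, ...) {
  cat("<crossref_result> ", nrow(x$keys), " union peptide forms across ",
      nrow(x$loss), " datasets\n", sep = "")
  print(x$loss, row.names = FALSE)
  invisible(x)
}
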