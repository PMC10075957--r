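# Dissection of chimeric spectra produced by co-eluting positional isomers.

#' Site-determining ions of two positional isomers
#'
#' Two isomers (same sequence, same modification multiset, different sites)
#' share most of their b/y ladder; the positions whose theoretical m/z
#' differ between the two forms are site-determining. A position of form A is
#' unique when its m/z is not within the fragment tolerance of *any* ion in
#' form B's theoretical set, and vice versa; the remainder is shared.
#'
#' @param form_a,form_b Isomeric `peptide_form`s.
#' @param frag_tol_ppm Fragment tolerance in ppm.
#' @param max_frag_charge Fragment charge states compared.
#' @param mod_table Modification definitions.
#' @return A list with fragment tables `unique_a`, `unique_b`, `shared`
#'   (shared positions as seen from form A; the partition is symmetric).
#' @export
site_determining_ions <- function(form_a, form_b, frag_tol_ppm = 40,
                                  max_frag_charge = 1L,
                                  mod_table = default_mods()) {
  if (!is_isomeric(form_a, form_b)) {
    stop("site_determining_ions requires isomeric forms ",
         "(same sequence and modification multiset)", call. = FALSE)
  }
  fa <- fragment_ions(form_a, max_frag_charge, mod_table)
  fb <- fragment_ions(form_b, max_frag_charge, mod_table)
  uniq_against <- function(x, other_mz) {
    near <- vapply(x$mz, function(mz) {
      any(abs(other_mz - mz) / mz * 1e6 <= frag_tol_ppm)
    }, logical(1))
    # a position is unique if none of its charge states is near the other set
    pos_near <- tapply(near, paste(x$series, x$index), any)
    key <- paste(x$series, x$index)
    x$shared_pos <- as.logical(pos_near[key])
    x
  }
  fa <- uniq_against(fa, fb$mz)
  fb <- uniq_against(fb, fa$mz)
  list(
    unique_a = fa[!fa$shared_pos, c("series", "index", "charge", "mz")],
    unique_b = fb[!fb$shared_pos, c("series", "index", "charge", "mz")],
    shared = fa[fa$shared_pos, c("series", "index", "charge", "mz")]
  )
}

#' Dissect a chimeric spectrum of isomeric candidates
#'
#' A member of an isomeric candidate group is accepted as a
#' co-identification when (a) its own fragment ion coverage against the full
#' spectrum reaches `fic_cutoff` and (b) at least one of its site-determining
#' ions — theoretical ions matching no other member's ladder — is observed.
#' When no member has a matched unique ion but members pass the coverage
#' criterion, the group is reported as site-ambiguous: there is peptide-level
#' evidence but the modification sites cannot be localized.
#'
#' @param spectrum An `ms2_spectrum`.
#' @param members List of >= 2 mutually isomeric `peptide_form`s.
#' @param fic_cutoff Coverage threshold (default 0.5).
#' @param frag_tol_ppm Fragment tolerance in ppm.
#' @param max_frag_charge Fragment charge states.
#' @param min_rel_intensity Passed to [match_peaks()].
#' @param mod_table Modification definitions.
#' @return An object of class `chimera_group`: list with `table` (per-member
#'   data frame: `form_key`, `fic`, `n_unique`, `n_unique_matched`,
#'   `n_shared`, `accepted`), `accepted` (list of accepted forms),
#'   `ambiguous` flag.
#' @export
dissect_chimera <- function(spectrum, members, fic_cutoff = 0.5,
                            frag_tol_ppm = 40, max_frag_charge = 1L,
                            min_rel_intensity = 0,
                            mod_table = default_mods()) {
  if (length(members) < 2L) {
    stop("chimera dissection needs at least two members", call. = FALSE)
  }
  for (i in 2:length(members)) {
    if (!is_isomeric(members[[1]], members[[i]])) {
      stop("all chimera members must be mutually isomeric", call. = FALSE)
    }
  }
  frag_sets <- lapply(members, fragment_ions, max_frag_charge = max_frag_charge,
                      mod_table = mod_table)
  rows <- vector("list", length(members))
  accepted <- list()
  for (i in seq_along(members)) {
    fi <- frag_sets[[i]]
    other_mz <- unlist(lapply(frag_sets[-i], `[[`, "mz"))
    near <- vapply(fi$mz, function(mz) {
      any(abs(other_mz - mz) / mz * 1e6 <= frag_tol_ppm)
    }, logical(1))
    pos_key <- paste(fi$series, fi$index)
    pos_shared <- tapply(near, pos_key, any)
    unique_pos <- names(pos_shared)[!pos_shared]

    matched <- match_peaks(spectrum, fi, frag_tol_ppm, min_rel_intensity)
    mk <- paste(matched$positions$series, matched$positions$index)
    n <- nchar(members[[i]]$sequence)
    fic <- nrow(matched$positions) / (2 * (n - 1L))
    n_unique_matched <- sum(mk %in% unique_pos)
    ok <- fic >= fic_cutoff && n_unique_matched >= 1L
    rows[[i]] <- data.frame(
      form_key = form_key(members[[i]]), fic = fic,
      n_unique = length(unique_pos), n_unique_matched = n_unique_matched,
      n_shared = sum(pos_shared), n_matched = nrow(matched$positions),
      accepted = ok, stringsAsFactors = FALSE
    )
    if (ok) accepted[[length(accepted) + 1L]] <- members[[i]]
  }
  tab <- do.call(rbind, rows)
  ambiguous <- all(tab$n_unique_matched == 0L) && any(tab$fic >= fic_cutoff)
  structure(list(table = tab, accepted = accepted, ambiguous = ambiguous,
                 scan_id = spectrum$scan_id),
            class = "chimera_group")
}

#' @export
print.chimera_group <- function(x, ...) {
  cat("<chimera_group> scan ", x$scan_id, ": ", sum(x$table$accepted), " of ",
      nrow(x$table), " member(s) accepted",
      if (x$ambiguous) " (site-ambiguous)", "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
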