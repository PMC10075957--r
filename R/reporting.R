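# Site-level reporting in mature histone numbering and coexistence summary.

#' Map accepted PSMs to protein modification sites
#'
#' Aggregates accepted PSMs into one record per (protein, site,
#' modification). Positions are reported in mature numbering — when the
#' protein sequence starts with the initiator methionine, the mature
#' position is the full-sequence position minus one, matching the community
#' convention behind names like H3K9 or H2AK9la — with the full-sequence
#' coordinate retained for traceability. Peptides mapping to several
#' proteins yield a record per protein with a shared-evidence flag.
#'
#' @param psms Accepted PSM `data.frame` (with `confidence_class` if
#'   [classify_psms()] has been run).
#' @param proteins Protein `data.frame`.
#' @param locations Optional peptide-location table (from a `form_index`) so
#'   multi-mapping peptides produce a record per protein; defaults to each
#'   PSM's primary location only.
#' @return A `data.frame` with columns `protein`, `residue`,
#'   `mature_position`, `full_position`, `mod`, `site` (e.g. `"H3_1 K9la"`),
#'   `n_psm`, `best_fic`, `confidence_class`, `shared_evidence`.
#' @export
map_sites <- function(psms, proteins, locations = NULL) {
  empty <- data.frame(
    protein = character(0), residue = character(0),
    mature_position = integer(0), full_position = integer(0),
    mod = character(0), site = character(0), n_psm = integer(0),
    best_fic = numeric(0), confidence_class = character(0),
    shared_evidence = logical(0)
  )
  if (!nrow(psms)) return(empty)
  prot_seq <- stats::setNames(proteins$sequence, proteins$id)
  has_met <- stats::setNames(startsWith(proteins$sequence, "M"), proteins$id)
  conf_rank <- c(high = 2, moderate = 1)

  rows <- list()
  for (i in seq_len(nrow(psms))) {
    p <- psms[i, ]
    if (!nzchar(p$mods)) next
    locs <- if (!is.null(locations)) {
      locations[locations$sequence == p$sequence, , drop = FALSE]
    } else {
      data.frame(protein = p$protein, start = p$start, end = p$end)
    }
    shared <- nrow(locs) > 1L
    pairs <- strsplit(strsplit(p$mods, ",", fixed = TRUE)[[1]], ":",
                      fixed = TRUE)
    for (l in seq_len(nrow(locs))) {
      prot <- locs$protein[l]
      for (pr in pairs) {
        pep_idx <- as.integer(pr[1])
        full_pos <- locs$start[l] + pep_idx - 1L
        res <- substring(prot_seq[[prot]], full_pos, full_pos)
        pep_res <- substring(p$sequence, pep_idx, pep_idx)
        if (!identical(res, pep_res)) {
          stop("coordinate mismatch: PSM '", p$sequence, "' position ",
               pep_idx, " maps to '", res, "' at ", prot, ":", full_pos,
               call. = FALSE)
        }
        mature <- full_pos - if (has_met[[prot]]) 1L else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          protein = prot, residue = res, mature_position = mature,
          full_position = full_pos, mod = pr[2],
          fic = p$fic,
          confidence_class = if ("confidence_class" %in% names(p))
            p$confidence_class else NA_character_,
          shared_evidence = shared, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) return(empty)
  df <- do.call(rbind, rows)
  key <- paste(df$protein, df$full_position, df$mod)
  agg <- lapply(split(df, key), function(g) {
    best_conf <- if (all(is.na(g$confidence_class))) NA_character_ else
      names(which.max(conf_rank[g$confidence_class]))
    data.frame(
      protein = g$protein[1], residue = g$residue[1],
      mature_position = g$mature_position[1],
      full_position = g$full_position[1], mod = g$mod[1],
      site = paste0(g$protein[1], " ", g$residue[1], g$mature_position[1],
                    g$mod[1]),
      n_psm = nrow(g), best_fic = max(g$fic),
      confidence_class = best_conf,
      shared_evidence = any(g$shared_evidence),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$protein, out$full_position, out$mod), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize coexisting modifications on accepted peptides
#'
#' Lists every accepted peptide form carrying two or more modifications, and
#' tallies how often each background modification co-occurs with the target
#' PTM on the same peptide (the histogram behind "which marks travel
#' together").
#'
#' @param psms Accepted PSM `data.frame`.
#' @param target_mod Name of the PTM of interest (default `"la"`).
#' @param mod_table Modification definitions (used to list background mods).
#' @return A list with `records` (per multi-modified form: `form_key`,
#'   `mods`, `n_mods`, `n_psm`) and `histogram` (per background mod:
#'   `n_peptides` co-occurring with the target).
#' @export
summarize_coexistence <- function(psms, target_mod = "la",
                                  mod_table = default_mods()) {
  bg_mods <- mod_table$name[mod_table$role == "background"]
  histogram <- data.frame(mod = bg_mods, n_peptides = 0L)
  empty <- list(records = data.frame(form_key = character(0),
                                     mods = character(0), n_mods = integer(0),
                                     n_psm = integer(0)),
                histogram = histogram)
  if (!nrow(psms)) return(empty)
  key <- ifelse(nzchar(psms$mods), paste0(psms$sequence, "/", psms$mods),
                psms$sequence)
  per_form <- split(psms, key)
  recs <- list()
  for (k in sort(names(per_form))) {
    g <- per_form[[k]]
    mods <- if (nzchar(g$mods[1])) {
      vapply(strsplit(strsplit(g$mods[1], ",", fixed = TRUE)[[1]], ":",
                      fixed = TRUE), `[`, character(1), 2L)
    } else {
      character(0)
    }
    if (length(mods) >= 2L) {
      recs[[length(recs) + 1L]] <- data.frame(
        form_key = k, mods = paste(sort(mods), collapse = "+"),
        n_mods = length(mods), n_psm = nrow(g), stringsAsFactors = FALSE)
    }
    if (any(mods %in% target_mod)) {
      co <- unique(intersect(mods, bg_mods))
      histogram$n_peptides[histogram$mod %in% co] <-
        histogram$n_peptides[histogram$mod %in% co] + 1L
    }
  }
  list(
    records = if (length(recs)) do.call(rbind, recs) else empty$records,
    histogram = histogram
  )
}

#' Write a PSM table to TSV
#'
#' @param psms PSM `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
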