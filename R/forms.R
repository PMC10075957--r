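# Modified peptide forms: construction, mass arithmetic, combinatorial
# enumeration of variable-modification assignments.

#' Construct a modified peptide form
#'
#' A peptide form is a base sequence plus an assignment of at most one
#' modification per residue. It is the unit of identification: two forms with
#' the same sequence but different modification positions are distinct
#' (positional isomers).
#'
#' @param sequence Uppercase one-letter residue string.
#' @param mods Named character vector mapping 1-based residue index (as the
#'   name) to a modification name, e.g. `c("1" = "la", "6" = "ac")`. `NULL`
#'   for the unmodified peptide.
#' @param protein,start,end Optional provenance: protein id and 1-based
#'   inclusive coordinates of the peptide within it.
#' @param mod_table Modification definitions ([default_mods()] by default).
#' @return An object of class `peptide_form`.
#' @examples
#' peptide_form("KSTGGKAPR", c("1" = "la", "6" = "ac"))
#' @export
peptide_form <- function(sequence, mods = NULL, protein = NA_character_,
                         start = NA_integer_, end = NA_integer_,
                         mod_table = default_mods()) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  residue_masses(sequence) # validates the alphabet
  n <- nchar(sequence)
  if (is.null(mods) || length(mods) == 0L) {
    mods <- stats::setNames(character(0), character(0))
  }
  idx <- suppressWarnings(as.integer(names(mods)))
  if (anyNA(idx) || any(idx < 1L | idx > n)) {
    stop("modification indices must be integers in [1, ", n, "]", call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop("at most one modification per residue index", call. = FALSE)
  }
  mod_delta(unname(mods), mod_table) # validates names
  if (length(mods)) {
    residues <- substring(sequence, idx, idx)
    targets <- mod_table[unname(mods), "targets"]
    ok <- mapply(function(res, tgt) grepl(res, tgt, fixed = TRUE),
                 residues, targets)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop("modification '", mods[[bad]], "' not allowed on residue '",
           residues[[bad]], "' at index ", idx[[bad]], call. = FALSE)
    }
  }
  o <- order(idx)
  mods <- stats::setNames(unname(mods)[o], as.character(idx[o]))
  structure(
    list(sequence = sequence, mods = mods,
         protein = protein, start = start, end = end),
    class = "peptide_form"
  )
}

#' Monoisotopic neutral mass of a peptide form
#'
#' Sum of residue masses, one water, and all modification deltas.
#'
#' @param form A `peptide_form`.
#' @param mod_table Modification definitions.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass <- function(form, mod_table = default_mods()) {
  stopifnot(inherits(form, "peptide_form"))
  sum(residue_masses(form$sequence)) + WATER_MASS +
    sum(mod_delta(unname(form$mods), mod_table))
}

# Per-position residue + modification masses (used by the fragment ladder).
site_masses <- function(form, mod_table = default_mods()) {
  m <- residue_masses(form$sequence)
  if (length(form$mods)) {
    idx <- as.integer(names(form$mods))
    m[idx] <- m[idx] + mod_delta(unname(form$mods), mod_table)
  }
  m
}

#' Canonical string key of a peptide form
#'
#' `"KSTGGKAPR/1:la,6:ac"`; the bare sequence when unmodified. Stable across
#' sessions and used for grouping and deterministic tie-breaking.
#'
#' @param form A `peptide_form`.
#' @return A single string.
#' @export
form_key <- function(form) {
  mods_key(form$sequence, names(form$mods), unname(form$mods))
}

mods_key <- function(sequence, idx, mods) {
  if (!length(idx)) {
    return(sequence)
  }
  o <- order(as.integer(idx))
  paste0(sequence, "/", paste0(idx[o], ":", mods[o], collapse = ","))
}

#' Parse a form key back into a peptide form
#'
#' @param key A key as produced by [form_key()].
#' @param ... Passed to [peptide_form()].
#' @return A `peptide_form`.
#' @export
parse_form <- function(key, ...) {
  parts <- strsplit(key, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    return(peptide_form(parts, NULL, ...))
  }
  pairs <- strsplit(strsplit(parts[2], ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  idx <- vapply(pairs, `[`, character(1), 1L)
  mods <- vapply(pairs, `[`, character(1), 2L)
  peptide_form(parts[1], stats::setNames(mods, idx), ...)
}

# Sorted modification multiset, ignoring positions ("ac+la").
mod_multiset <- function(form) {
  paste(sort(unname(form$mods)), collapse = "+")
}

# Two forms are positional isomers: same sequence, same mod multiset
# (possibly identical site assignment).
is_isomeric <- function(a, b) {
  identical(a$sequence, b$sequence) && identical(mod_multiset(a), mod_multiset(b))
}

#' @method format peptide_form
#' @export
format.peptide_form <- function(x, ...) {
  chars <- strsplit(x$sequence, "", fixed = TRUE)[[1]]
  if (length(x$mods)) {
    idx <- as.integer(names(x$mods))
    chars[idx] <- paste0(chars[idx], "(", unname(x$mods), ")")
  }
  paste(chars, collapse = "")
}

#' @export
print.peptide_form <- function(x, ...) {
  cat("<peptide_form> ", format(x), "\n", sep = "")
  if (!is.na(x$protein)) {
    cat("  protein ", x$protein, " [", x$start, "-", x$end, "]\n", sep = "")
  }
  cat(sprintf("  neutral mass %.5f Da\n", neutral_mass(x)))
  invisible(x)
}

#' Enumerate variable-modification assignments of a peptide
#'
#' Generates every distinct assignment of at most one modification per
#' eligible residue: target modifications (the PTMs of interest) may occupy
#' any number of their target residues, while at most `max_background`
#' background modifications are placed. The unmodified form is included.
#' Output order is canonical: by total modification count, then by modified
#' positions, then by modification names.
#'
#' @param sequence Residue string.
#' @param target_mods,background_mods Character vectors of modification names
#'   from `mod_table` (either may be empty).
#' @param max_background Maximum number of background modifications per
#'   peptide (default 3, balancing multi-mark peptides against search-space
#'   growth).
#' @param fixed_mods Named character vector (index -> mod name) of
#'   modifications always present; fixed sites take no variable modification
#'   and fixed background marks do not count against `max_background`.
#' @param site_restrict Optional named list (mod name -> integer indices)
#'   restricting a modification to a subset of its target residues.
#' @param max_forms Capacity ceiling; exceeding it raises an error naming the
#'   peptide (default 10000).
#' @param mod_table Modification definitions.
#' @param protein,start,end Provenance carried onto each generated form.
#' @return A list of `peptide_form` objects.
#' @examples
#' # the two-lysine peptide under one background mod: 4 forms (2^2 subsets)
#' length(enumerate_forms("KK", background_mods = "ac", max_background = 2))
#' @export
enumerate_forms <- function(sequence, target_mods = character(),
                            background_mods = character(),
                            max_background = 3L, fixed_mods = NULL,
                            site_restrict = NULL, max_forms = 10000L,
                            mod_table = default_mods(),
                            protein = NA_character_, start = NA_integer_,
                            end = NA_integer_) {
  if (max_background < 0L) stop("max_background must be >= 0", call. = FALSE)
  residue_masses(sequence)
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  all_mods <- c(target_mods, background_mods)
  mod_delta(all_mods, mod_table) # validate names early

  fixed_idx <- integer(0)
  if (!is.null(fixed_mods) && length(fixed_mods)) {
    fixed_idx <- as.integer(names(fixed_mods))
  }

  eligible <- function(mod, i) {
    tgt <- mod_table[mod, "targets"]
    if (!grepl(chars[i], tgt, fixed = TRUE)) return(FALSE)
    restr <- site_restrict[[mod]]
    is.null(restr) || i %in% restr
  }

  # Per-site variable options (excluding "none"), split by role.
  site_opts <- lapply(seq_len(n), function(i) {
    if (i %in% fixed_idx) {
      return(list(target = character(0), background = character(0)))
    }
    list(
      target = Filter(function(m) eligible(m, i), target_mods),
      background = Filter(function(m) eligible(m, i), background_mods)
    )
  })

  # Capacity check by DP over sites: poly[b+1] = number of assignments with
  # exactly b background mods placed so far.
  poly <- c(1, rep(0, max_background))
  for (opt in site_opts) {
    c0 <- 1 + length(opt$target)
    c1 <- length(opt$background)
    new <- poly * c0
    if (c1 > 0 && max_background > 0) {
      new[-1] <- new[-1] + poly[-length(poly)] * c1
    }
    poly <- new
  }
  total <- sum(poly)
  if (total > max_forms) {
    stop("enumeration of '", sequence, "' would generate ", total,
         " forms (ceiling ", max_forms, ")", call. = FALSE)
  }

  # Enumerate: partial assignments as (index vector, mod vector, n_background).
  partials <- list(list(idx = integer(0), mods = character(0), nbg = 0L))
  for (i in seq_len(n)) {
    opt <- site_opts[[i]]
    if (!length(opt$target) && !length(opt$background)) next
    expanded <- vector("list", length(partials) * (1L + length(opt$target) +
                                                     length(opt$background)))
    k <- 0L
    for (p in partials) {
      k <- k + 1L
      expanded[[k]] <- p
      for (m in opt$target) {
        k <- k + 1L
        expanded[[k]] <- list(idx = c(p$idx, i), mods = c(p$mods, m), nbg = p$nbg)
      }
      if (p$nbg < max_background) {
        for (m in opt$background) {
          k <- k + 1L
          expanded[[k]] <- list(idx = c(p$idx, i), mods = c(p$mods, m),
                                nbg = p$nbg + 1L)
        }
      }
    }
    partials <- expanded[seq_len(k)]
  }

  forms <- lapply(partials, function(p) {
    idx <- c(fixed_idx, p$idx)
    mods <- c(unname(fixed_mods), p$mods)
    peptide_form(sequence, stats::setNames(mods, as.character(idx)),
                 protein = protein, start = start, end = end,
                 mod_table = mod_table)
  })

  # Canonical order: mod count, then positions, then mod names.
  ord_key <- vapply(forms, function(f) {
    sprintf("%03d|%s|%s", length(f$mods),
            paste(sprintf("%04d", as.integer(names(f$mods))), collapse = ","),
            paste(unname(f$mods), collapse = ","))
  }, character(1))
  forms[order(ord_key)]
}
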