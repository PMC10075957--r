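# Monoisotopic mass bookkeeping and modification definitions.

#' Physical constants (monoisotopic, Da)
#'
#' `PROTON_MASS` is the mass of a proton (charge carrier), `WATER_MASS` the
#' monoisotopic mass of H2O added to a residue chain to form a peptide, and
#' `ISOTOPE_SPACING` the mass difference between successive isotopologue
#' peaks (C13 - C12).
#'
#' @keywords internal
#' @name constants
NULL

PROTON_MASS <- 1.00727646688
WATER_MASS <- 18.0105646863
ISOTOPE_SPACING <- 1.00335483

# Monoisotopic element masses used to resolve elemental formulas.
ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.007825032,
  N = 14.003074005,
  O = 15.994914620,
  S = 31.972071174,
  P = 30.973761998
)

# Monoisotopic residue masses for the 20 standard amino acids.
AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style elemental formula such as `"C2H2O"` or `"C4H6O2"` and
#' returns its monoisotopic mass. Supported elements: C, H, N, O, S, P.
#'
#' @param formula Character vector of elemental formulas.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' formula_mass("C2H2O")   # acetyl delta
#' formula_mass("C3H4O2")  # lactyl delta
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) {
      return(NA_real_)
    }
    tokens <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (!identical(paste(tokens, collapse = ""), f)) {
      stop("cannot parse elemental formula: '", f, "'", call. = FALSE)
    }
    total <- 0
    for (tok in tokens) {
      el <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(ELEMENT_MASS)) {
        stop("unknown element '", el, "' in formula '", f, "'", call. = FALSE)
      }
      total <- total + ELEMENT_MASS[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a modification definition table
#'
#' Loads a TSV with columns `name`, `targets`, `composition`, `delta_mass`
#' and `role`. `targets` is a string of residue letters the modification may
#' occupy (e.g. `"K"`). `delta_mass` may be left `NA` when `composition` is
#' given, in which case it is computed from the formula. When both are given
#' they must agree to within 1e-5 Da. `role` is either `"target"` (the PTM of
#' interest, e.g. lactylation) or `"background"` (common co-occurring marks
#' carried along as variable modifications).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with class `mod_table`.
#' @seealso [default_mods()]
#' @export
read_mod_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "targets", "composition", "delta_mass", "role")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("modification table lacks column(s): ", paste(missing, collapse = ", "))
  }
  as_mod_table(tab)
}

as_mod_table <- function(tab) {
  if (anyDuplicated(tab$name)) {
    stop("modification names must be unique; duplicated: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  }
  has_comp <- !is.na(tab$composition) & nzchar(tab$composition)
  comp_mass <- rep(NA_real_, nrow(tab))
  comp_mass[has_comp] <- formula_mass(tab$composition[has_comp])
  no_delta <- is.na(tab$delta_mass)
  tab$delta_mass[no_delta] <- comp_mass[no_delta]
  if (anyNA(tab$delta_mass)) {
    stop("modification(s) without delta_mass or composition: ",
         paste(tab$name[is.na(tab$delta_mass)], collapse = ", "))
  }
  both <- has_comp & !no_delta
  off <- abs(tab$delta_mass[both] - comp_mass[both]) >= 1e-5
  if (any(off)) {
    stop("delta_mass disagrees with composition for: ",
         paste(tab$name[both][off], collapse = ", "))
  }
  if (!all(tab$role %in% c("target", "background"))) {
    stop("mod role must be 'target' or 'background'")
  }
  rownames(tab) <- tab$name
  class(tab) <- c("mod_table", "data.frame")
  tab
}

.mod_cache <- new.env(parent = emptyenv())

#' Default histone modification table
#'
#' The modifications shipped with the package: lysine acetylation (ac),
#' mono/di/tri-methylation on lysine (me1/me2/me3), mono/di-methylation on
#' arginine (rme1/rme2), and the four acylations lactylation (la),
#' crotonylation (cr), 2-hydroxyisobutyrylation (hib) and benzoylation (bz).
#' Deltas derive from the elemental composition of each adduct; they are
#' user-overridable by supplying a custom table to the search functions.
#'
#' @return A `mod_table` data.frame.
#' @export
default_mods <- function() {
  if (is.null(.mod_cache$default)) {
    path <- system.file("extdata", "modifications.tsv", package = "ficms",
                        mustWork = TRUE)
    .mod_cache$default <- read_mod_table(path)
  }
  .mod_cache$default
}

#' Look up modification mass deltas
#'
#' @param names Character vector of modification names.
#' @param mod_table A `mod_table`; defaults to [default_mods()].
#' @return Numeric vector of monoisotopic mass deltas (Da).
#' @export
mod_delta <- function(names, mod_table = default_mods()) {
  unknown <- setdiff(names, mod_table$name)
  if (length(unknown)) {
    stop("unknown modification(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(mod_table[names, "delta_mass"], names)
}

# Residue masses for a sequence string; errors on non-standard letters.
residue_masses <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- AA_MONO[chars]
  if (anyNA(m)) {
    bad <- unique(chars[is.na(m)])
    stop("invalid residue letter(s) in sequence '", sequence, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(m)
}
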