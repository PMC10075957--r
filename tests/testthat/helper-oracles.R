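# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Elemental compositions of the 20 residues; the mass oracle sums element
# masses rather than using the package's compiled residue table.
RESIDUE_FORMULA <- c(
  G = "C2H3NO", A = "C3H5NO", S = "C3H5NO2", P = "C5H7NO", V = "C5H9NO",
  T = "C4H7NO2", C = "C3H5NOS", L = "C6H11NO", I = "C6H11NO",
  N = "C4H6N2O2", D = "C4H5NO3", Q = "C5H8N2O2", K = "C6H12N2O",
  E = "C5H7NO3", M = "C5H9NOS", H = "C6H7N3O", F = "C9H9NO",
  R = "C6H12N4O", Y = "C9H9NO2", W = "C11H10N2O"
)

ORACLE_ELEMENT <- c(C = 12.0, H = 1.007825032, N = 14.003074005,
                    O = 15.994914620, S = 31.972071174)

oracle_formula_mass <- function(formula) {
  tokens <- regmatches(formula, gregexpr("[A-Z][0-9]*", formula))[[1]]
  sum(vapply(tokens, function(tok) {
    el <- substr(tok, 1, 1)
    n <- sub("^[A-Z]", "", tok)
    ORACLE_ELEMENT[[el]] * if (nzchar(n)) as.integer(n) else 1L
  }, numeric(1)))
}

# Neutral peptide mass from elemental compositions + water.
oracle_peptide_mass <- function(sequence, mod_deltas = numeric(0)) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(vapply(RESIDUE_FORMULA[chars], oracle_formula_mass, numeric(1))) +
    oracle_formula_mass("H2O") + sum(mod_deltas)
}

# FIC by an all-pairs tolerance scan over every fragment and every peak.
oracle_fic <- function(form, spectrum, frag_tol_ppm = 40,
                       max_frag_charge = 1L) {
  frags <- fragment_ions(form, max_frag_charge)
  n <- nchar(form$sequence)
  if (n < 2L) return(0)
  pmz <- spectrum$peaks[, 1]
  matched_pos <- character(0)
  for (i in seq_len(nrow(frags))) {
    for (p in pmz) {
      if (abs(p - frags$mz[i]) / frags$mz[i] * 1e6 <= frag_tol_ppm) {
        matched_pos <- c(matched_pos, paste(frags$series[i], frags$index[i]))
        break
      }
    }
  }
  length(unique(matched_pos)) / (2 * (n - 1L))
}

# Target-decoy FDR threshold by exhaustive sweep over all distinct scores.
oracle_fdr_threshold <- function(scores, is_decoy, level) {
  cuts <- sort(unique(scores))
  best <- NA_real_
  for (s in cuts) {
    nt <- sum(scores >= s & !is_decoy)
    nd <- sum(scores >= s & is_decoy)
    fdr <- if (nd == 0) 0 else if (nt == 0) Inf else nd / nt
    if (fdr <= level) {
      best <- s
      break
    }
  }
  best
}

# Site-determining partition by a double loop over both theoretical ladders.
oracle_site_partition <- function(form_a, form_b, frag_tol_ppm = 40) {
  fa <- fragment_ions(form_a, 1L)
  fb <- fragment_ions(form_b, 1L)
  near <- function(mz, others) {
    any(abs(others - mz) / mz * 1e6 <= frag_tol_ppm)
  }
  a_shared <- vapply(fa$mz, near, logical(1), others = fb$mz)
  list(unique_a = paste(fa$series, fa$index)[!a_shared],
       shared = paste(fa$series, fa$index)[a_shared])
}

# Brute-force tryptic digest: every substring whose boundaries are valid
# cleavage points, annotated with internal missed cleavages.
oracle_digest <- function(sequence, max_missed, min_length, max_length) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cleaves_after <- function(i) {
    i < n && chars[i] %in% c("K", "R") && chars[i + 1L] != "P"
  }
  out <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!(i == 1L || cleaves_after(i - 1L))) next
      if (!(j == n || cleaves_after(j))) next
      internal <- sum(vapply(i:(j - 1L), cleaves_after, logical(1)))
      if (j == i) internal <- 0L
      len <- j - i + 1L
      if (internal <= max_missed && len >= min_length && len <= max_length) {
        out <- c(out, substring(sequence, i, j))
      }
    }
  }
  sort(unique(out))
}

# Random test peptide with at least one K.
random_peptide <- function(len, residues = names(ficms:::AA_MONO)) {
  repeat {
    s <- paste(sample(residues, len, replace = TRUE), collapse = "")
    if (grepl("K", s, fixed = TRUE)) return(s)
  }
}

# A small in-memory protein db for tests that do not need the histone FASTA.
tiny_proteins <- function() {
  data.frame(
    id = c("protA", "protB"),
    description = c("test protein A", "test protein B"),
    sequence = c("MARTKQTARKSTGGKAPRKQLATKAARKSAP", "GSKKAVTKAQKKDGKKRKR"),
    is_decoy = FALSE, stringsAsFactors = FALSE
  )
}

# Shared fixtures for the acceptance-level scenarios; built once per session.
histone_index <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      db <- decoy_database(load_fasta(example_fasta()))
      cache <<- build_form_index(db)
    }
    cache
  }
})

# Peptide-level truth labels for a benchmark search result.
benchmark_truth_labels <- function(psms, truth) {
  planted <- stats::setNames(as.list(truth$form_key), truth$scan_id)
  kind <- stats::setNames(truth$kind, truth$scan_id)
  keys <- ifelse(nzchar(psms$mods), paste0(psms$sequence, "/", psms$mods),
                 psms$sequence)
  vapply(seq_len(nrow(psms)), function(i) {
    sc <- psms$scan_id[i]
    identical(unname(kind[sc]), "true") &&
      same_identification(keys[i], planted[[sc]])
  }, logical(1))
}
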