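# FASTA reading, decoy construction, in-silico enzymatic digestion.

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file.
#' @param decoy_prefix Accessions starting with this prefix are flagged as
#'   decoys (default `"rev_"`), so a previously written concatenated
#'   target-decoy database round-trips.
#' @return A `data.frame` with columns `id` (first whitespace-delimited
#'   header token), `description`, `sequence` (uppercased, `*` stripped) and
#'   `is_decoy`.
#' @export
load_fasta <- function(path, decoy_prefix = "rev_") {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records",
                              call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("*", "", as.character(set), fixed = TRUE))
  if (any(!nzchar(seqs))) {
    stop("FASTA record(s) with empty sequence: ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             is_decoy = startsWith(ids, decoy_prefix),
             stringsAsFactors = FALSE)
}

#' Write proteins to FASTA
#'
#' @param proteins A protein `data.frame` as returned by [load_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- ifelse(nzchar(proteins$description),
                       paste(proteins$id, proteins$description),
                       proteins$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Build reversed-sequence decoys
#'
#' One decoy per target protein, with the residue order fully reversed and
#' the id prefixed. Concatenating `rbind(targets, make_decoys(targets))`
#' yields the reverse-concatenated database used for target-decoy FDR
#' estimation.
#'
#' @param proteins Target protein `data.frame`.
#' @param decoy_prefix Prefix for decoy ids (default `"rev_"`).
#' @return A `data.frame` of decoy records (`is_decoy = TRUE`).
#' @export
make_decoys <- function(proteins, decoy_prefix = "rev_") {
  if (any(proteins$is_decoy)) {
    stop("input to make_decoys must contain only target proteins", call. = FALSE)
  }
  rev_seq <- vapply(strsplit(proteins$sequence, "", fixed = TRUE),
                    function(ch) paste(rev(ch), collapse = ""), character(1))
  data.frame(id = paste0(decoy_prefix, proteins$id),
             description = proteins$description,
             sequence = rev_seq, is_decoy = TRUE, stringsAsFactors = FALSE)
}

#' Concatenated target-decoy database
#'
#' @param proteins Target protein `data.frame`.
#' @param decoy_prefix Prefix for decoy ids.
#' @return Targets followed by their reversed decoys.
#' @export
decoy_database <- function(proteins, decoy_prefix = "rev_") {
  rbind(proteins, make_decoys(proteins, decoy_prefix))
}

# Resolve an enzyme specification to cleave/block residue sets.
enzyme_rule <- function(enzyme) {
  if (is.character(enzyme) && length(enzyme) == 1L) {
    return(switch(enzyme,
      trypsin = list(cleave = c("K", "R"), block = "P"),
      stop("unknown enzyme '", enzyme, "'; supply list(cleave=, block=)",
           call. = FALSE)
    ))
  }
  stopifnot(is.list(enzyme), !is.null(enzyme$cleave))
  if (is.null(enzyme$block)) enzyme$block <- character(0)
  enzyme
}

#' In-silico enzymatic digestion
#'
#' Cleaves after the enzyme's cleavage residues (trypsin: K/R) unless the
#' following residue is blocked (trypsin: P), and emits every peptide with at
#' most `max_missed` internal uncleaved sites and length within range.
#' Digestion is modification-agnostic; acyl-blocked cleavage is handled as a
#' post-filter during form indexing (see [build_form_index()]). When a
#' protein starts with methionine, the initiator-Met-clipped variant of each
#' N-terminal peptide is also emitted (`met_clip = TRUE`), since mature
#' histones lack the initiator Met.
#'
#' @param protein One row of a protein `data.frame` (or a list with `id`,
#'   `sequence`).
#' @param enzyme `"trypsin"` or `list(cleave = <residues>, block = <residues>)`.
#' @param max_missed Maximum internal missed cleavages (default 4; histone
#'   tails are K/R-rich and heavily modified, so generous values are needed).
#' @param min_length,max_length Peptide length range (defaults 5 and 35).
#' @param met_clip Also digest the initiator-Met-clipped variant.
#' @return A `data.frame` with columns `protein`, `sequence`, `start`, `end`
#'   (1-based inclusive, full-sequence coordinates), `missed_cleavages`,
#'   ordered by `start` then length.
#' @export
digest_protein <- function(protein, enzyme = "trypsin", max_missed = 4L,
                           min_length = 5L, max_length = 35L,
                           met_clip = TRUE) {
  if (min_length > max_length) {
    stop("min_length must not exceed max_length", call. = FALSE)
  }
  rule <- enzyme_rule(enzyme)
  seqstr <- protein$sequence
  n <- nchar(seqstr)
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  # cleavage after position i
  sites <- which(chars %in% rule$cleave)
  sites <- sites[sites < n]
  if (length(rule$block)) {
    sites <- sites[!chars[sites + 1L] %in% rule$block]
  }
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  k <- length(starts)
  out <- vector("list", k)
  for (j in seq_len(k)) {
    last <- min(k, j + max_missed)
    l <- j:last
    out[[j]] <- data.frame(start = starts[j], end = ends[l],
                           missed_cleavages = l - j)
  }
  df <- do.call(rbind, out)
  if (met_clip && n > 1L && chars[1] == "M") {
    nterm <- df[df$start == 1L & df$end > 1L, , drop = FALSE]
    if (nrow(nterm)) {
      df <- rbind(df, data.frame(start = 2L, end = nterm$end,
                                 missed_cleavages = nterm$missed_cleavages))
    }
  }
  len <- df$end - df$start + 1L
  df <- df[len >= min_length & len <= max_length, , drop = FALSE]
  df <- df[order(df$start, df$end - df$start), , drop = FALSE]
  data.frame(protein = rep(protein$id, nrow(df)),
             sequence = substring(seqstr, df$start, df$end),
             start = df$start, end = df$end,
             missed_cleavages = df$missed_cleavages,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Digest every protein in a database
#'
#' @param proteins Protein `data.frame` (targets and/or decoys).
#' @inheritParams digest_protein
#' @return Row-bound [digest_protein()] results with an `is_decoy` column.
#' @export
digest_proteins <- function(proteins, enzyme = "trypsin", max_missed = 4L,
                            min_length = 5L, max_length = 35L,
                            met_clip = TRUE) {
  pieces <- lapply(seq_len(nrow(proteins)), function(i) {
    d <- digest_protein(proteins[i, ], enzyme, max_missed,
                        min_length, max_length, met_clip)
    if (nrow(d)) d$is_decoy <- proteins$is_decoy[i]
    d
  })
  out <- do.call(rbind, pieces[vapply(pieces, nrow, integer(1)) > 0])
  if (is.null(out)) {
    out <- data.frame(protein = character(0), sequence = character(0),
                      start = integer(0), end = integer(0),
                      missed_cleavages = integer(0), is_decoy = logical(0))
  }
  rownames(out) <- NULL
  out
}
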