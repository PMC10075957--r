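# MS/MS spectrum container and MGF / mzML input-output.

#' Construct an MS/MS spectrum
#'
#' The internal representation of one centroided MS2 scan. Peaks are sorted
#' by m/z, zero-intensity centroids are dropped, and exact duplicate m/z
#' values are merged by summing intensity so the peak list is strictly
#' ascending.
#'
#' @param scan_id Scan identifier (string).
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Integer charge; 0 when unknown (downstream code
#'   then tries charges 2-4).
#' @param rt Retention time in minutes (`NA` if unknown).
#' @param peaks Two-column numeric matrix (m/z, intensity) or data.frame.
#' @param source Origin tag, e.g. `"file.mgf#3"`.
#' @return An object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(scan_id, precursor_mz, precursor_charge = 0L,
                         rt = NA_real_, peaks = matrix(numeric(0), 0, 2),
                         source = NA_character_) {
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L) stop("peaks must have two columns (mz, intensity)",
                              call. = FALSE)
  storage.mode(peaks) <- "double"
  peaks <- peaks[peaks[, 2] > 0, , drop = FALSE]
  if (nrow(peaks)) {
    peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
    if (anyDuplicated(peaks[, 1])) {
      inten <- tapply(peaks[, 2], peaks[, 1], sum)
      peaks <- cbind(as.numeric(names(inten)), as.numeric(inten))
    }
  }
  colnames(peaks) <- c("mz", "intensity")
  if (!is.na(precursor_mz) && precursor_charge > 0 &&
      precursor_mz * precursor_charge - precursor_charge * PROTON_MASS <= 0) {
    stop("precursor neutral mass must be positive", call. = FALSE)
  }
  structure(
    list(scan_id = as.character(scan_id), precursor_mz = precursor_mz,
         precursor_charge = as.integer(precursor_charge), rt = rt,
         peaks = peaks, source = source),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("<ms2_spectrum> ", x$scan_id, "\n", sep = "")
  cat(sprintf("  precursor m/z %.5f, charge %d%s\n", x$precursor_mz,
              x$precursor_charge,
              if (is.na(x$rt)) "" else sprintf(", RT %.2f min", x$rt)))
  cat("  ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

# Observed neutral mass of the precursor for an assumed charge.
precursor_neutral <- function(spectrum, charge = spectrum$precursor_charge) {
  spectrum$precursor_mz * charge - charge * PROTON_MASS
}

#' Read MS/MS spectra
#'
#' Reads centroided MS2 scans from MGF or mzML into a list of
#' [ms2_spectrum()] objects. MS1 scans in mzML are skipped; retention times
#' are normalized to minutes; scans without a charge annotation get charge 0.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"mgf"` or `"mzml"`.
#' @return A list of `ms2_spectrum` objects, named by scan id.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", mzml = "mzml",
                     stop("cannot infer spectrum format from extension '",
                          ext, "'", call. = FALSE))
  }
  spectra <- switch(format, mgf = read_mgf(path), mzml = read_mzml(path))
  names(spectra) <- vapply(spectra, `[[`, character(1), "scan_id")
  spectra
}

read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  begin <- which(lines == "BEGIN IONS")
  finish <- which(lines == "END IONS")
  if (length(begin) != length(finish) || any(finish < begin)) {
    stop("malformed MGF '", path, "': unbalanced BEGIN/END IONS", call. = FALSE)
  }
  lapply(seq_along(begin), function(i) {
    block <- lines[(begin[i] + 1L):(finish[i] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1), 1L))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
    getval <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    pep <- getval("PEPMASS")
    pmz <- if (is.na(pep)) {
      stop("MGF scan ", i, " lacks PEPMASS", call. = FALSE)
    } else {
      as.numeric(strsplit(trimws(pep), "\\s+")[[1]][1])
    }
    ch <- getval("CHARGE")
    charge <- if (is.na(ch)) 0L else {
      v <- suppressWarnings(as.integer(sub("\\+$", "", trimws(ch))))
      if (is.na(v)) 0L else abs(v)
    }
    rts <- getval("RTINSECONDS")
    rt <- if (is.na(rts)) NA_real_ else as.numeric(rts) / 60
    title <- getval("TITLE")
    scan_id <- if (is.na(title)) paste0("scan_", i) else trimws(title)
    peak_lines <- trimws(block[!is_kv])
    peak_lines <- peak_lines[nzchar(peak_lines)]
    peaks <- if (length(peak_lines)) {
      fields <- strsplit(peak_lines, "[ \t]+")
      bad <- vapply(fields, length, integer(1)) < 2L
      if (any(bad)) stop("malformed MGF peak line in scan '", scan_id, "'",
                         call. = FALSE)
      suppressWarnings(
        cbind(as.numeric(vapply(fields, `[`, character(1), 1L)),
              as.numeric(vapply(fields, `[`, character(1), 2L))))
    } else {
      matrix(numeric(0), 0, 2)
    }
    if (anyNA(peaks)) stop("non-numeric MGF peak in scan '", scan_id, "'",
                           call. = FALSE)
    ms2_spectrum(scan_id, pmz, charge, rt, peaks,
                 source = paste0(basename(path), "#", i))
  })
}

read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  if (!file.exists(path)) stop("mzML file not found: ", path, call. = FALSE)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  ms2 <- which(hdr$msLevel == 2L)
  lapply(ms2, function(i) {
    pk <- mzR::peaks(handle, i)
    charge <- hdr$precursorCharge[i]
    if (is.na(charge) || charge < 0) charge <- 0L
    scan_id <- if (!is.null(hdr$spectrumId) && nzchar(hdr$spectrumId[i])) {
      hdr$spectrumId[i]
    } else {
      paste0("scan_", hdr$acquisitionNum[i])
    }
    ms2_spectrum(scan_id, hdr$precursorMZ[i], charge,
                 rt = hdr$retentionTime[i] / 60, peaks = pk,
                 source = paste0(basename(path), "#", i))
  })
}

#' Write spectra to MGF
#'
#' Emits `BEGIN IONS` blocks with TITLE, PEPMASS, CHARGE (when known) and
#' RTINSECONDS (when known), at full double precision so a write/read
#' round trip preserves the peak list.
#'
#' @param spectra A list of `ms2_spectrum` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (sp in spectra) {
    lines <- c("BEGIN IONS",
               paste0("TITLE=", sp$scan_id),
               sprintf("PEPMASS=%.10f", sp$precursor_mz))
    if (sp$precursor_charge > 0) {
      lines <- c(lines, sprintf("CHARGE=%d+", sp$precursor_charge))
    }
    if (!is.na(sp$rt)) {
      lines <- c(lines, sprintf("RTINSECONDS=%.6f", sp$rt * 60))
    }
    if (nrow(sp$peaks)) {
      lines <- c(lines, sprintf("%.10f %.6f", sp$peaks[, 1], sp$peaks[, 2]))
    }
    lines <- c(lines, "END IONS", "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write spectra to mzML
#'
#' Thin wrapper over `mzR::writeMSData()`.
#'
#' @param spectra A list of `ms2_spectrum` objects.
#' @param path Output path (`.mzML`).
#' @return Invisibly, `path`.
#' @export
write_mzml <- function(spectra, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("writing mzML requires the mzR package", call. = FALSE)
  }
  n <- length(spectra)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = rep(2L, n), polarity = rep(1L, n),
    peaksCount = vapply(spectra, function(s) nrow(s$peaks), integer(1)),
    totIonCurrent = vapply(spectra, function(s) sum(s$peaks[, 2]), numeric(1)),
    retentionTime = vapply(spectra, function(s) {
      if (is.na(s$rt)) 0 else s$rt * 60
    }, numeric(1)),
    basePeakMZ = vapply(spectra, function(s) {
      if (nrow(s$peaks)) s$peaks[which.max(s$peaks[, 2]), 1] else 0
    }, numeric(1)),
    basePeakIntensity = vapply(spectra, function(s) {
      if (nrow(s$peaks)) max(s$peaks[, 2]) else 0
    }, numeric(1)),
    collisionEnergy = rep(0, n), ionisationEnergy = rep(0, n),
    lowMZ = vapply(spectra, function(s) {
      if (nrow(s$peaks)) min(s$peaks[, 1]) else 0
    }, numeric(1)),
    highMZ = vapply(spectra, function(s) {
      if (nrow(s$peaks)) max(s$peaks[, 1]) else 0
    }, numeric(1)),
    precursorScanNum = rep(0L, n),
    precursorMZ = vapply(spectra, `[[`, numeric(1), "precursor_mz"),
    precursorCharge = vapply(spectra, `[[`, integer(1), "precursor_charge"),
    precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = vapply(spectra, `[[`, character(1), "scan_id"),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = vapply(spectra, `[[`, numeric(1), "precursor_mz"),
    isolationWindowLowerOffset = rep(1, n),
    isolationWindowUpperOffset = rep(1, n),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  pks <- lapply(spectra, function(s) unname(s$peaks))
  mzR::writeMSData(object = pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}
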