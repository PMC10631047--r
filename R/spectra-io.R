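# Readers and writers for the standard interchange formats: MGF and mzML
# spectra in, delimited PSM tables in, CSV result tables out.

.read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) {
    stop("malformed MGF file (unbalanced BEGIN/END IONS): ", path, call. = FALSE)
  }
  recs <- vector("list", length(begins))
  kept <- 0L
  for (r in seq_along(begins)) {
    block <- lines[(begins[r] + 1L):(ends[r] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[[`, "", 1L))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      as.character(r - 1L)  # 0-based index fallback
    pepmass <- if ("PEPMASS" %in% keys) {
      as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "\\s+")[[1]][1])
    } else NA_real_
    charge <- if ("CHARGE" %in% keys) {
      cv <- vals[match("CHARGE", keys)]
      sgn <- if (grepl("-", cv, fixed = TRUE)) -1 else 1
      sgn * as.integer(gsub("[^0-9]", "", cv))
    } else NA_integer_
    if (is.na(pepmass) || is.na(charge) || charge < 1) {
      warning("skipping MGF record ", r, " (missing precursor information)")
      next
    }
    pk <- block[!hdr]
    pk <- pk[nzchar(trimws(pk))]
    m <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"), function(x) {
      as.numeric(x[1:2])
    }))
    if (is.null(m) || anyNA(m)) {
      warning("skipping MGF record ", r, " (malformed peak lines)")
      next
    }
    kept <- kept + 1L
    recs[[kept]] <- tibble::tibble(
      id = title, precursor_mz = pepmass, precursor_charge = as.integer(charge),
      peaks = list(.normalize_peaks(
        tibble::tibble(mz = m[, 1], intensity = m[, 2])))
    )
  }
  dplyr::bind_rows(recs[seq_len(kept)])
}

.read_mzml <- function(path) {
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  ms2 <- which(hdr$msLevel == 2L)
  recs <- vector("list", length(ms2))
  kept <- 0L
  for (i in ms2) {
    mz0 <- hdr$precursorMZ[i]
    z <- hdr$precursorCharge[i]
    if (is.na(mz0) || mz0 <= 0 || is.na(z) || z < 1) {
      warning("skipping mzML spectrum ", i, " (missing precursor information)")
      next
    }
    pk <- mzR::peaks(ms, i)
    id <- hdr$spectrumId[i]
    if (is.na(id) || !nzchar(id)) id <- as.character(hdr$seqNum[i] - 1L)
    kept <- kept + 1L
    recs[[kept]] <- tibble::tibble(
      id = id, precursor_mz = mz0, precursor_charge = as.integer(z),
      peaks = list(.normalize_peaks(
        tibble::tibble(mz = pk[, 1], intensity = pk[, 2])))
    )
  }
  dplyr::bind_rows(recs[seq_len(kept)])
}

#' Read fragmentation spectra from MGF or mzML
#'
#' Every MS2 spectrum with precursor m/z and charge is returned; records
#' lacking precursor information are skipped with a warning. Peak lists are
#' sorted ascending by m/z, with exact duplicate m/z values collapsed to the
#' most intense peak.
#'
#' @param path Path to the spectra file.
#' @param format `"auto"` (by file extension), `"mgf"` or `"mzml"`.
#' @return A tibble with one row per spectrum: `id` (MGF TITLE / mzML
#'   spectrum id, falling back to the 0-based scan index), `precursor_mz`,
#'   `precursor_charge`, `peaks` (list column of `mz`/`intensity` tibbles).
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("spectra file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "mgf"
  }
  out <- switch(format, mgf = .read_mgf(path), mzml = .read_mzml(path))
  if (!nrow(out)) {
    return(tibble::tibble(id = character(), precursor_mz = numeric(),
                          precursor_charge = integer(), peaks = list()))
  }
  out
}

#' Read a delimited PSM table
#'
#' Reads a delimited-text table pairing spectrum identifiers with candidate
#' peptides. The delimiter defaults to `";"`. Column names are
#' configurable; rows whose peptide contains a residue outside the 20
#' standard amino acids are rejected with a warning.
#'
#' @param path Path to the table.
#' @param delim Field delimiter (default `";"`).
#' @param spectrum_col,peptide_col,delta_col Column names (defaults
#'   `"spectrum"`, `"peptide"`, `"deltaM"`; `delta_col` is optional in the
#'   file and recomputed during alignment when absent).
#' @return A tibble with columns `spectrum_id`, `peptide`, `delta_m` (NA
#'   when not provided), in file order.
#' @export
read_psms <- function(path, delim = ";", spectrum_col = "spectrum",
                      peptide_col = "peptide", delta_col = "deltaM") {
  if (!file.exists(path)) stop("PSM table not found: ", path, call. = FALSE)
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  for (col in c(spectrum_col, peptide_col)) {
    if (!col %in% names(tab)) {
      stop("PSM table is missing mandatory column '", col, "'", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    spectrum_id = as.character(tab[[spectrum_col]]),
    peptide = toupper(as.character(tab[[peptide_col]])),
    delta_m = if (delta_col %in% names(tab)) as.numeric(tab[[delta_col]])
              else NA_real_
  )
  ok <- grepl(sprintf("^[%s]+$", paste(names(.residue_masses), collapse = "")),
              out$peptide)
  if (any(!ok)) {
    warning(sum(!ok), " PSM row(s) rejected (peptide outside the standard ",
            "amino-acid alphabet)")
    out <- out[ok, ]
  }
  out
}

#' Write the alignment result table
#'
#' Comma-delimited CSV with one line per input PSM, in input order. Columns
#' follow the result-table conventions: `preAlignedPeptide` is the alignment
#' straight after traceback, `alignedPeptide` the post-processed one,
#' `sharedPeaksBefore`/`sharedPeaksAfter` the native peaks shared with the
#' model before/after applying the final shifts, and `intensityExplained`
#' the fraction of total signal intensity carried by matched peaks.
#'
#' @param results Tibble from [align_psms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- tibble::tibble(
    spectrum = results$spectrum_id,
    peptide = results$peptide,
    deltaM = results$delta_m,
    preAlignedPeptide = results$pre_aligned,
    alignedPeptide = results$aligned,
    sharedPeaksBefore = results$shared_before,
    sharedPeaksAfter = results$shared_after,
    intensityExplained = results$intensity_explained,
    score = results$score,
    nonAlignedMass = results$non_aligned_mass,
    shifts = results$shifts,
    error = results$error
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to the CSV.
#' @return A tibble in [align_psms()] column layout.
#' @export
read_results <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    spectrum_id = as.character(tab$spectrum),
    peptide = tab$peptide,
    delta_m = tab$deltaM,
    pre_aligned = tab$preAlignedPeptide,
    aligned = tab$alignedPeptide,
    shared_before = tab$sharedPeaksBefore,
    shared_after = tab$sharedPeaksAfter,
    intensity_explained = tab$intensityExplained,
    score = tab$score,
    non_aligned_mass = tab$nonAlignedMass,
    shifts = as.character(tab$shifts),
    error = as.character(tab$error)
  )
}

#' Write spectra to MGF
#'
#' @param spectra Spectra tibble ([read_spectra()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    pk <- spectra$peaks[[i]]
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", spectra$id[i]),
      sprintf("PEPMASS=%.6f", spectra$precursor_mz[i]),
      sprintf("CHARGE=%d+", spectra$precursor_charge[i]),
      sprintf("%.6f %.6f", pk$mz, pk$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}
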