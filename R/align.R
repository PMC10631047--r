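#' Align one candidate peptide against one spectrum
#'
#' Runs the full pipeline for a single PSM: spectrum completion, dynamic
#' programming over (residues x completed peaks), traceback, and
#' post-processing of the suggested mass shifts. The precursor mass
#' difference between spectrum and peptide is split into localized shifts
#' plus a residual non-aligned mass.
#'
#' @param peptide Candidate peptide string.
#' @param peaks Native peak data frame (`mz`, `intensity`).
#' @param precursor_mz Precursor m/z (Da).
#' @param charge Precursor charge state.
#' @param frag_tol Fragment tolerance in Da (default 0.02).
#' @param merge_tol Completion merge tolerance in Da (default 0.01).
#' @param scores A [score_scheme()].
#' @return An object of class `specshift_alignment`: a list with the final
#'   alignment (`final`), the raw traceback (`raw`), the DP matrices
#'   (`matrix`), the completed spectrum (`completed`) and the model
#'   (`model`). Use [tidy()]/[glance()]/[autoplot()] on it.
#' @export
#' @examples
#' sp <- simulate_spectrum("HINATESVR",
#'   sim_params(frac_peaks_removed = 0, max_noise_peaks = 0, seed = 1))
#' align_pair("HINATESVR", sp$spectrum$peaks[[1]],
#'   sp$spectrum$precursor_mz, sp$spectrum$precursor_charge)
align_pair <- function(peptide, peaks, precursor_mz, charge,
                       frag_tol = 0.02, merge_tol = 0.01,
                       scores = score_scheme()) {
  model <- b_ion_series(peptide)
  peaks <- .normalize_peaks(peaks)
  completed <- complete_spectrum(peaks, precursor_mz, charge, merge_tol)
  mat <- fill_matrix(model, completed, scores, frag_tol)
  raw <- traceback_alignment(mat)
  final <- refine_alignment(raw, model, peaks, frag_tol)
  structure(list(
    final = final, raw = raw, matrix = mat,
    completed = completed, model = model,
    peptide = peptide, precursor_mz = precursor_mz, charge = charge
  ), class = "specshift_alignment")
}

.normalize_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks), "mz" %in% names(peaks))
  if (!"intensity" %in% names(peaks)) peaks$intensity <- 1
  peaks <- peaks[order(peaks$mz), c("mz", "intensity")]
  # duplicate m/z: keep the most intense peak
  if (anyDuplicated(peaks$mz)) {
    peaks <- peaks |>
      dplyr::group_by(.data$mz) |>
      dplyr::summarise(intensity = max(.data$intensity), .groups = "drop")
  }
  tibble::as_tibble(peaks)
}

.pack_shifts <- function(shifts) {
  if (!nrow(shifts)) return("")
  paste(sprintf("%d:%d:%.6f", shifts$span_start, shifts$position, shifts$value),
        collapse = ";")
}

#' Parse a packed shift string
#'
#' Inverse of the `shifts` column written by [align_psms()]/[write_results()]:
#' `"span_start:position:value"` triples separated by `;`. `span_start` is
#' the first residue of the bracketed group the shift localizes to and
#' `position` the realigned residue carrying it.
#'
#' @param x Character vector of packed shift strings.
#' @return List of tibbles with columns `span_start`, `position`, `value`.
#' @export
unpack_shifts <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble::tibble(span_start = integer(), position = integer(),
                            value = numeric()))
    }
    parts <- strsplit(strsplit(s, ";")[[1]], ":")
    tibble::tibble(
      span_start = as.integer(vapply(parts, `[[`, "", 1L)),
      position = as.integer(vapply(parts, `[[`, "", 2L)),
      value = as.numeric(vapply(parts, `[[`, "", 3L))
    )
  })
}

.align_one_row <- function(psm, spectra_by_id, frag_tol, merge_tol, scores) {
  sp <- spectra_by_id[[psm$spectrum_id]]
  base <- tibble::tibble(
    spectrum_id = psm$spectrum_id,
    peptide = psm$peptide,
    delta_m = NA_real_,
    pre_aligned = NA_character_,
    aligned = NA_character_,
    shared_before = NA_integer_,
    shared_after = NA_integer_,
    intensity_explained = NA_real_,
    score = NA_real_,
    non_aligned_mass = NA_real_,
    shifts = NA_character_,
    error = NA_character_
  )
  if (is.null(sp)) {
    base$error <- "spectrum_not_found"
    return(base)
  }
  al <- align_pair(psm$peptide, sp$peaks[[1]], sp$precursor_mz,
                   sp$precursor_charge, frag_tol, merge_tol, scores)
  f <- al$final
  base$delta_m <- f$delta_m
  base$pre_aligned <- f$pre_aligned
  base$aligned <- f$aligned
  base$shared_before <- f$shared_before
  base$shared_after <- f$shared_after
  base$intensity_explained <- f$intensity_explained
  base$score <- f$score
  base$non_aligned_mass <- f$non_aligned_mass
  base$shifts <- .pack_shifts(f$shifts)
  base
}

#' Align a table of PSMs against a spectra collection
#'
#' The batch entry point: one result row per PSM, in input order. Rows whose
#' spectrum identifier is absent from `spectra` are marked in the `error`
#' column and processing continues. Work is partitioned across `threads`
#' processes with order-preserving assembly; the alignment itself is
#' deterministic, so results do not depend on the thread count.
#'
#' @param psms Tibble from [read_psms()] (columns `spectrum_id`, `peptide`).
#' @param spectra Tibble from [read_spectra()].
#' @param frag_tol,merge_tol Tolerances in Da.
#' @param scores A [score_scheme()].
#' @param threads Number of worker processes (default 1).
#' @return A tibble with columns `spectrum_id`, `peptide`, `delta_m`,
#'   `pre_aligned`, `aligned`, `shared_before`, `shared_after`,
#'   `intensity_explained`, `score`, `non_aligned_mass`, `shifts` (packed
#'   `position:value` pairs) and `error`.
#' @export
align_psms <- function(psms, spectra, frag_tol = 0.02, merge_tol = 0.01,
                       scores = score_scheme(), threads = 1L) {
  stopifnot(all(c("spectrum_id", "peptide") %in% names(psms)))
  by_id <- split(spectra, seq_len(nrow(spectra)))
  names(by_id) <- spectra$id
  rows <- split(psms, seq_len(nrow(psms)))
  worker <- function(p) .align_one_row(p, by_id, frag_tol, merge_tol, scores)
  out <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(rows, worker, mc.cores = threads, mc.preschedule = TRUE)
  } else {
    lapply(rows, worker)
  }
  dplyr::bind_rows(out)
}
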