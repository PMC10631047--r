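#' @export
print.specshift_alignment <- function(x, ...) {
  f <- x$final
  cat("Spectral alignment of", x$peptide, "\n")
  cat("  pre-aligned: ", f$pre_aligned, "\n")
  cat("  aligned:     ", f$aligned, "\n")
  cat(sprintf("  score %d | deltaM %.4f | non-aligned mass %.4f\n",
              as.integer(f$score), f$delta_m, f$non_aligned_mass))
  cat(sprintf("  shared peaks %d -> %d | intensity explained %.1f%%\n",
              f$shared_before, f$shared_after, 100 * f$intensity_explained))
  invisible(x)
}

#' Tidy a spectral alignment into per-residue rows
#'
#' @param x A `specshift_alignment` from [align_pair()].
#' @param ... Unused.
#' @return A tibble with one row per residue: `position`, `residue`, `move`
#'   (align / realign / nonalign / removed), `peak_mz`, `shift`.
#' @exportS3Method generics::tidy
tidy.specshift_alignment <- function(x, ...) {
  tibble::as_tibble(x$final$steps)
}

#' One-row summary of a spectral alignment
#'
#' @param x A `specshift_alignment` from [align_pair()].
#' @param ... Unused.
#' @return A one-row tibble: `peptide`, `aligned`, `pre_aligned`, `score`,
#'   `delta_m`, `n_shifts`, `non_aligned_mass`, `shared_before`,
#'   `shared_after`, `intensity_explained`.
#' @exportS3Method generics::glance
glance.specshift_alignment <- function(x, ...) {
  f <- x$final
  tibble::tibble(
    peptide = x$peptide,
    aligned = f$aligned,
    pre_aligned = f$pre_aligned,
    score = f$score,
    delta_m = f$delta_m,
    n_shifts = nrow(f$shifts),
    non_aligned_mass = f$non_aligned_mass,
    shared_before = f$shared_before,
    shared_after = f$shared_after,
    intensity_explained = f$intensity_explained
  )
}

#' Mirror plot of a completed spectrum
#'
#' Native peaks point up; inferred complementary peaks point down, the way
#' completed spectra are usually drawn. Peaks merging native and
#' complementary evidence are highlighted.
#'
#' @param object A `specshift_completed` from [complete_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.specshift_completed <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!.data$virtual) |>
    dplyr::mutate(
      y = ifelse(.data$evidence == "complementary_only", -1, 1),
      evidence = factor(.data$evidence,
                        c("native_only", "both", "complementary_only"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                   y = 0, yend = .data$y,
                                   colour = .data$evidence)) +
    ggplot2::geom_segment() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "m/z (Da)", y = NULL,
                  title = "Completed spectrum",
                  colour = "ion evidence") +
    ggplot2::theme_minimal()
}

#' Plot an alignment path over the spectrum
#'
#' Native peaks are drawn as grey sticks; the b-ion boundaries of the
#' aligned residues are marked, coloured by move type, so realignments
#' (mass shifts) stand out.
#'
#' @param object A `specshift_alignment` from [align_pair()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.specshift_alignment <- function(object, ...) {
  peaks <- object$completed |>
    tibble::as_tibble() |>
    dplyr::filter(!.data$virtual, .data$evidence != "complementary_only")
  steps <- object$final$steps |>
    dplyr::filter(.data$move %in% c("align", "realign"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = peaks,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0,
                   yend = .data$intensity / max(c(peaks$intensity, 1))),
      colour = "grey60") +
    ggplot2::geom_point(
      data = steps,
      ggplot2::aes(x = .data$peak_mz, y = 1.05, colour = .data$move)) +
    ggplot2::geom_text(
      data = steps,
      ggplot2::aes(x = .data$peak_mz, y = 1.12, label = .data$residue),
      size = 3) +
    ggplot2::labs(x = "m/z (Da)", y = "relative intensity",
                  title = paste("Alignment of", object$peptide),
                  subtitle = object$final$aligned, colour = "move") +
    ggplot2::theme_minimal()
}
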