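#' Complementary peak position
#'
#' The b/y fragment pair of one backbone cleavage sums to `MH+ + proton`,
#' where `MH+` is the singly protonated precursor mass. Hypothesizing an
#' observed peak as a y-ion therefore places a b-frame "complementary peak"
#' at `MH+ + proton - mz`.
#'
#' @param mz Observed peak m/z (Da).
#' @param mh Singly protonated precursor mass MH+ (Da).
#' @return Complementary m/z in Da. The transformation is an involution:
#'   `complementary_mass(complementary_mass(x, mh), mh) == x`.
#' @export
#' @examples
#' complementary_mass(690.34, 1357.50)
complementary_mass <- function(mz, mh) {
  mh + .proton - mz
}

#' Complete a spectrum with complementary peaks
#'
#' Transforms an experimental peak list into its completed form: every
#' observed peak is kept (hypothesis: it is a b-ion) and its complementary
#' peak is added (hypothesis: it is a y-ion). A native peak and a
#' complementary image closer than `merge_tol` merge into a single peak at
#' the native m/z carrying "both" evidence — for a perfect fragmentation
#' producing both ions of a cleavage, completion adds no peak. Two virtual
#' anchor peaks are added: one at m/z = proton (the b0 position, so the first
#' residue has a left anchor) and its complementary image at MH+ (so the last
#' residue has a landing position); both carry "both" evidence.
#'
#' @param peaks Data frame of native peaks with columns `mz` and `intensity`.
#' @param precursor_mz Precursor m/z (Da).
#' @param charge Precursor charge state.
#' @param merge_tol Da; native/complementary pairs closer than this merge
#'   (default 0.01).
#' @return A tibble sorted by `mz` with columns `mz`, `intensity` (native
#'   intensity, 0 for purely inferred peaks), `evidence` (one of
#'   `"native_only"`, `"complementary_only"`, `"both"`), `source_index`
#'   (index into the native peak list, NA for the anchors) and `virtual`
#'   (TRUE for the two anchors). Attribute `mh` stores MH+.
#' @export
complete_spectrum <- function(peaks, precursor_mz, charge, merge_tol = 0.01) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  mh <- precursor_neutral_mass(precursor_mz, charge) + .proton

  native <- tibble::tibble(mz = as.numeric(peaks$mz),
                           intensity = as.numeric(peaks$intensity)) |>
    dplyr::mutate(source_index = dplyr::row_number()) |>
    dplyr::arrange(.data$mz)

  comp <- complementary_mass(native$mz, mh)
  keep <- comp > 0
  if (any(!keep) && isTRUE(getOption("specshift.verbose", FALSE))) {
    # peaks above MH+ have no complementary image; they stay as native-only
    message(sprintf("dropping %d complementary peaks at non-positive m/z", sum(!keep)))
  }

  # match each complementary image to the closest native peak
  idx <- findInterval(comp, native$mz)
  merged_with <- integer(length(comp))
  for (p in seq_along(comp)) {
    if (!keep[p]) { merged_with[p] <- -1L; next }
    cand <- c(idx[p], idx[p] + 1L)
    cand <- cand[cand >= 1L & cand <= nrow(native)]
    hit <- cand[abs(native$mz[cand] - comp[p]) <= merge_tol]
    merged_with[p] <- if (length(hit)) hit[which.min(abs(native$mz[hit] - comp[p]))] else 0L
  }

  evidence <- rep("native_only", nrow(native))
  evidence[merged_with[merged_with > 0L]] <- "both"

  extra <- tibble::tibble(
    mz = comp[keep & merged_with == 0L],
    intensity = 0,
    source_index = native$source_index[keep & merged_with == 0L],
    evidence = "complementary_only",
    virtual = FALSE
  )
  nat <- native |>
    dplyr::mutate(evidence = evidence, virtual = FALSE)
  body <- dplyr::bind_rows(nat, extra)
  # the two anchors merge into an existing peak if one already sits there;
  # unmerged they carry single-ion (inferred) evidence
  anchors <- tibble::tibble(
    mz = c(.proton, mh),
    intensity = 0,
    source_index = NA_integer_,
    evidence = "complementary_only",
    virtual = TRUE
  )
  for (a in seq_len(nrow(anchors))) {
    hit <- abs(body$mz - anchors$mz[a]) <= merge_tol
    if (any(hit)) body$evidence[hit] <- "both"
  }
  anchors <- anchors[vapply(
    anchors$mz, function(m) !any(abs(body$mz - m) <= merge_tol), logical(1)
  ), ]

  out <- dplyr::bind_rows(body, anchors) |>
    dplyr::arrange(.data$mz) |>
    dplyr::select("mz", "intensity", "evidence", "source_index", "virtual")
  attr(out, "mh") <- mh
  attr(out, "precursor_mz") <- precursor_mz
  attr(out, "charge") <- charge
  class(out) <- c("specshift_completed", class(out))
  out
}
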