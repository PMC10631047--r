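#' Scoring scheme for the spectral alignment
#'
#' Elementary scores for the dynamic program. Aligning an amino acid without
#' a mass shift scores `align_both` when the landing peak carries both b- and
#' y-ion evidence and `align_single` otherwise. Introducing a mass shift (a
#' realignment) scores the landing alignment decreased by the realignment
#' penalty (`align_both + realign_both`, e.g. 10 - 8 = +2, or
#' `align_single + realign_single` = +1); a non-aligned amino acid scores
#' `non_align`. A realignment is thus more heavily penalized (by 8 or 6)
#' than the non-alignment of one amino acid (by 4), so a spurious shift
#' only pays off when at least two subsequent residues align on the new
#' frame.
#'
#' @param align_both,align_single Positive alignment scores (default 10, 7).
#' @param realign_both,realign_single Negative realignment penalties,
#'   applied on top of the landing alignment score (default -8, -6).
#' @param non_align Negative non-alignment score (default -4).
#' @return A named list of class `specshift_scores`.
#' @export
score_scheme <- function(align_both = 10, align_single = 7,
                         realign_both = -8, realign_single = -6,
                         non_align = -4) {
  sc <- list(align_both = align_both, align_single = align_single,
             realign_both = realign_both, realign_single = realign_single,
             non_align = non_align)
  if (align_both <= 0 || align_single <= 0) {
    stop("alignment scores must be positive", call. = FALSE)
  }
  if (realign_both >= 0 || realign_single >= 0 || non_align >= 0) {
    stop("realignment and non-alignment scores must be negative", call. = FALSE)
  }
  if (abs(realign_both) <= abs(non_align) || abs(realign_single) <= abs(non_align)) {
    stop("a realignment must be more penalized than one non-aligned residue",
         call. = FALSE)
  }
  structure(sc, class = "specshift_scores")
}

#' Read a scoring/tolerance configuration file
#'
#' Flat `key = value` text file; recognised keys are the five score names of
#' [score_scheme()] plus `fragment_tol` and `merge_tol`. Unknown keys are an
#' error.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `scores` (a `specshift_scores`) and any
#'   tolerances present.
#' @export
read_score_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  vals <- stats::setNames(as.numeric(vapply(kv, `[[`, "", 2L)),
                          vapply(kv, `[[`, "", 1L))
  score_keys <- c("align_both", "align_single", "realign_both",
                  "realign_single", "non_align")
  extra <- setdiff(names(vals), c(score_keys, "fragment_tol", "merge_tol"))
  if (length(extra)) stop("unknown config key: ", extra[1], call. = FALSE)
  sc <- do.call(score_scheme, as.list(vals[intersect(names(vals), score_keys)]))
  out <- list(scores = sc)
  if ("fragment_tol" %in% names(vals)) out$fragment_tol <- unname(vals[["fragment_tol"]])
  if ("merge_tol" %in% names(vals)) out$merge_tol <- unname(vals[["merge_tol"]])
  out
}

#' Is an amino-acid mass found between two peaks?
#'
#' @param peak_j,peak_k Peak m/z values with `peak_k < peak_j` (Da).
#' @param residue Single amino-acid letter.
#' @param tol Absolute tolerance in Da.
#' @return TRUE iff `|(peak_j - peak_k) - mass(residue)| <= tol`.
#' @export
#' @examples
#' aa_found(138.066, 1.007, "H", 0.02)
aa_found <- function(peak_j, peak_k, residue, tol = 0.02) {
  if (!residue %in% names(.residue_masses)) {
    stop("unknown residue '", residue, "'", call. = FALSE)
  }
  abs((peak_j - peak_k) - .residue_masses[[residue]]) <= tol
}

# boundary targets and effective residue masses for the DP: boundaries are
# b_1 .. b_{n-1}; the n-th boundary is the precursor MH+ (b_n is not an
# observable fragment), so the last effective residue mass is r_n + water.
.dp_targets <- function(model, mh) {
  n <- nrow(model)
  bt <- model$b_mz
  rm <- model$residue_mass
  bt[n] <- attr(model, "neutral_mass") + .proton
  rm[n] <- rm[n] + .water
  list(bt = bt, rm = rm)
}

#' Fill the alignment score matrix
#'
#' Computes the dynamic-programming matrix over (residues x completed peaks).
#' Each cell holds the best score of an alignment of the first i residues
#' whose boundary sits at peak j; moves are alignment (residue mass found
#' between peaks, no shift), realignment (a recorded mass shift) and
#' non-alignment. A realignment whose implied shift is within `tol` of zero
#' (the signature of merely-missing peaks) is scored as an alignment.
#'
#' @param model A [b_ion_series()] tibble.
#' @param completed A [complete_spectrum()] tibble.
#' @param scores A [score_scheme()].
#' @param tol Fragment tolerance in Da (default 0.02).
#' @return A list of matrices (`score`, `move`, `pred`, `shift`, `cum`) with
#'   rows = residues, columns = completed peaks, plus the inputs as
#'   attributes. Move codes: 0 unreachable, 1 align, 2 realign, 3 non-align.
#' @export
fill_matrix <- function(model, completed, scores = score_scheme(), tol = 0.02) {
  stopifnot(inherits(model, "specshift_model"))
  mh <- attr(completed, "mh")
  tg <- .dp_targets(model, mh)
  evid <- as.integer(completed$evidence == "both")
  rank <- c(complementary_only = 0L, native_only = 1L, both = 2L)[completed$evidence]
  sc <- c(scores$align_both, scores$align_single, scores$realign_both,
          scores$realign_single, scores$non_align)
  out <- .dp_fill_cpp(tg$bt, tg$rm, completed$mz, evid, unname(rank), sc, tol)
  attr(out, "model") <- model
  attr(out, "completed") <- completed
  attr(out, "tol") <- tol
  out
}

#' Trace back the best alignment path
#'
#' Starts from the maximum-score cell of the last row (ties resolved toward
#' experimentally observed peaks before the virtual precursor column, then
#' toward the rightmost peak) and follows backpointers to the first residue,
#' producing one step per residue in N-to-C order.
#'
#' @param matrix A matrix set from [fill_matrix()].
#' @return A list of class `specshift_raw` with elements `steps` (tibble:
#'   `position`, `residue`, `move`, `peak_mz`, `shift`), `score`, `shifts`
#'   (tibble `position`/`value`), `delta_m` and `residual` (the part of the
#'   precursor mass difference not captured by shifts).
#' @export
traceback_alignment <- function(matrix) {
  model <- attr(matrix, "model")
  completed <- attr(matrix, "completed")
  n <- nrow(matrix$score)
  last <- matrix$score[n, ]
  best <- max(last)
  cand <- which(last >= best - 1e-9)
  # on ties, a path ending on an observed peak outranks one ending on the
  # inferred precursor column
  real <- cand[!completed$virtual[cand]]
  j <- if (length(real)) max(real) else max(cand)
  moves <- integer(n); cols <- integer(n); shifts <- numeric(n)
  for (i in n:1) {
    moves[i] <- matrix$move[i, j]
    cols[i] <- j
    shifts[i] <- matrix$shift[i, j]
    j <- matrix$pred[i, j] + 1L  # to 1-based; row 0 predecessor is the anchor
  }
  move_lab <- c("align", "realign", "nonalign")[moves]
  steps <- tibble::tibble(
    position = model$position,
    residue = model$residue,
    move = move_lab,
    peak_mz = ifelse(moves == 3L, NA_real_, completed$mz[cols]),
    shift = ifelse(moves == 2L, shifts, NA_real_)
  )
  mh <- attr(completed, "mh")
  dm <- (mh - .proton) - attr(model, "neutral_mass")
  sh <- steps[steps$move == "realign", c("position", "shift")]
  names(sh) <- c("position", "value")
  structure(list(
    steps = steps,
    score = best,
    shifts = tibble::as_tibble(sh),
    delta_m = dm,
    residual = dm - sum(sh$value)
  ), class = "specshift_raw")
}

#' Render an alignment as a string
#'
#' Amino acids without corroborating peaks and mass shifts are bracketed:
#' a non-aligned residue prints as `[X]`, a realigned residue prints its
#' shift (two decimals) in brackets before the residue, and a residual
#' non-aligned mass is appended after `_`. Residues removed by
#' post-processing (semi-tryptic trimming) are omitted.
#'
#' @param steps Step tibble with columns `residue`, `move`, `shift`.
#' @param residual Non-aligned mass in Da; values within `tol` of zero are
#'   not printed.
#' @param tol Da threshold below which the residual is dropped.
#' @return The alignment string.
#' @export
format_alignment <- function(steps, residual = 0, tol = 0.02) {
  piece <- function(res, move, shift) {
    switch(move,
      align = res,
      realign = sprintf("[%.2f]%s", shift, res),
      nonalign = sprintf("[%s]", res),
      removed = ""
    )
  }
  out <- paste0(mapply(piece, steps$residue, steps$move,
                       ifelse(is.na(steps$shift), 0, steps$shift)),
                collapse = "")
  if (!is.na(residual) && abs(residual) > tol) {
    out <- sprintf("%s_%.2f", out, residual)
  }
  out
}
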