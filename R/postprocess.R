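# Post-processing of raw alignments: relocate or discard shifts so that the
# number of native peaks shared between the (shifted) peptide model and the
# experimental spectrum is maximized; unsupported shift mass accumulates into
# the non-aligned mass printed after "_".

# b- and y-ion m/z of a peptide model carrying localized shifts (full series
# b1..bn / y1..yn; y_n is the intact-peptide position). Ions are generated
# from the aligned peptide's own mass (model + localized shifts); the
# non-aligned mass is by definition not on the peptide, so a genuine neutral
# loss leaves the predicted series at the unmodified positions.
.fragment_ions <- function(model, shifts) {
  n <- nrow(model)
  s <- numeric(n)
  if (!is.null(shifts) && nrow(shifts)) {
    agg <- tapply(shifts$value, shifts$position, sum)
    s[as.integer(names(agg))] <- agg
  }
  cum <- cumsum(s)
  b <- model$b_mz + cum
  mh <- attr(model, "neutral_mass") + sum(s) + .proton
  y <- mh + .proton - c(.proton, b[seq_len(n - 1)])
  list(b = b, y = rev(y))  # y[j] corresponds to the last j residues
}

.match_mask <- function(peak_mz, ions, tol) {
  if (!length(peak_mz)) return(logical(0))
  all_ions <- sort(c(ions$b, ions$y))
  idx <- findInterval(peak_mz, all_ions)
  near <- function(i, m) {
    lo <- if (i >= 1) all_ions[i] else -Inf
    hi <- if (i < length(all_ions)) all_ions[i + 1] else Inf
    min(abs(m - lo), abs(hi - m))
  }
  vapply(seq_along(peak_mz),
         function(p) near(idx[p], peak_mz[p]) <= tol, logical(1))
}

#' Count native peaks shared with a shifted peptide model
#'
#' Counts the experimental peaks matched (within `tol`) by any b- or y-ion of
#' the candidate peptide with the given localized shifts applied cumulatively
#' (a shift at position p displaces b_p..b_n and the corresponding y-ions).
#' Each native peak is counted at most once. The full series b1..bn and
#' y1..yn are predicted; y_n is the intact-peptide (precursor-minus-loss)
#' position.
#'
#' @param model A [b_ion_series()] tibble.
#' @param shifts Data frame with columns `position` and `value` (Da); may be
#'   empty or NULL.
#' @param peaks Native peak data frame with column `mz`.
#' @param tol Fragment tolerance in Da.
#' @return Integer count of matched native peaks.
#' @export
shared_peaks <- function(model, shifts, peaks, tol = 0.02) {
  if (!nrow(peaks)) return(0L)
  ions <- .fragment_ions(model, shifts)
  sum(.match_mask(peaks$mz, ions, tol))
}

#' Fraction of total signal intensity explained by an alignment
#'
#' @param model A [b_ion_series()] tibble (of the final, possibly trimmed,
#'   peptide).
#' @param shifts Data frame of localized shifts (`position`, `value`).
#' @param peaks Native peak data frame with columns `mz` and `intensity`.
#' @param tol Fragment tolerance in Da.
#' @return Fraction in \[0, 1\]; 0 with a warning when the spectrum carries
#'   no intensity.
#' @export
intensity_explained <- function(model, shifts, peaks, tol = 0.02) {
  tot <- sum(peaks$intensity)
  if (!nrow(peaks) || tot <= 0) {
    warning("spectrum has zero total intensity")
    return(0)
  }
  ions <- .fragment_ions(model, shifts)
  sum(peaks$intensity[.match_mask(peaks$mz, ions, tol)]) / tot
}

# span start of each shift: a realignment localizes its shift anywhere in the
# run of non-aligned residues immediately before the realigned residue; the
# reported position is the start of that bracketed group (the way the
# alignment string reads).
.shift_spans <- function(steps, shifts) {
  if (!nrow(shifts)) {
    return(tibble::tibble(position = integer(), value = numeric(),
                          span_start = integer()))
  }
  span <- integer(nrow(shifts))
  for (r in seq_len(nrow(shifts))) {
    p <- shifts$position[r]
    i <- match(p, steps$position)
    start <- p
    while (i > 1 && steps$move[i - 1] == "nonalign") {
      i <- i - 1
      start <- steps$position[i]
    }
    span[r] <- start
  }
  tibble::tibble(position = shifts$position, value = shifts$value,
                 span_start = span)
}

.trimmed_model <- function(steps) {
  kept <- steps$residue[steps$move != "removed"]
  b_ion_series(paste(kept, collapse = ""))
}

# re-index shift positions onto the trimmed peptide
.reindex_shifts <- function(shifts, steps) {
  if (!nrow(shifts)) return(shifts)
  keep <- steps$move != "removed"
  newpos <- cumsum(keep)
  shifts$position <- newpos[match(shifts$position, steps$position)]
  shifts
}

#' Refine a raw alignment
#'
#' Applies the three post-processing rules in order:
#' \enumerate{
#'   \item every shift must strictly increase the number of native peaks
#'     shared between spectrum and shifted model; otherwise it is removed and
#'     its mass accumulates into the non-aligned mass;
#'   \item a non-aligned mass is relocated as a modification on one of the
#'     two C-terminal residues when that strictly increases the shared-peak
#'     count (ties keep the non-aligned form);
#'   \item non-aligned terminal residues paired with a matching negative
#'     mass are trimmed from the alignment when this does not decrease the
#'     shared-peak count (the semi-tryptic case).
#' }
#'
#' Rules 1 and 1b (a consolidation pass that jointly removes or merges
#' shift pairs produced by hops between displaced peak ladders) iterate to a
#' fixed point, which makes the function idempotent.
#'
#' @param raw A `specshift_raw` from [traceback_alignment()] (or a previous
#'   [refine_alignment()] result, on which the function is idempotent).
#' @param model The [b_ion_series()] of the candidate peptide.
#' @param peaks Native peak data frame (`mz`, `intensity`).
#' @param tol Fragment tolerance in Da.
#' @param keep_ties Rule 1 alternative reading: keep a shift whose removal
#'   leaves the shared-peak count unchanged (default FALSE, the strict
#'   reading: a shift must strictly increase the count to survive).
#' @return A list of class `specshift_final`: `steps`, `shifts` (with
#'   `span_start`), `non_aligned_mass` (0 when below `tol`), `aligned`
#'   and `pre_aligned` strings, `shared_before`, `shared_after`,
#'   `intensity_explained`, `score`, `delta_m`.
#' @export
refine_alignment <- function(raw, model, peaks, tol = 0.02,
                             keep_ties = FALSE) {
  steps <- raw$steps
  shifts <- raw$shifts[, c("position", "value")]
  residual <- raw$residual
  pre_aligned <- if (!is.null(raw$pre_aligned)) raw$pre_aligned else
    format_alignment(steps, residual, tol)

  cur_model <- .trimmed_model(steps)
  cur_shifts <- .reindex_shifts(shifts, steps)
  n_shared <- function(sh) shared_peaks(cur_model, sh, peaks, tol)

  # rules 1 and 1b run to a fixed point, so shifts created by consolidation
  # are themselves re-examined (this also makes refinement idempotent)
  repeat {
  stable <- TRUE

  # rule 1: drop shifts that do not strictly increase the shared-peak count
  for (p in shifts$position) {
    r <- which(cur_shifts$position == .reindex_shifts(
      tibble::tibble(position = p, value = 0), steps)$position)[1]
    with_c <- n_shared(cur_shifts)
    without_c <- n_shared(cur_shifts[-r, ])
    if (without_c >= with_c && !(without_c == with_c && keep_ties)) {
      residual <- residual + cur_shifts$value[r]
      cur_shifts <- cur_shifts[-r, ]
      shifts <- shifts[shifts$position != p, ]
      steps$move[steps$position == p & steps$move == "realign"] <- "align"
      steps$shift[steps$position == p] <- NA_real_
      stable <- FALSE
    }
  }

  # rule 1b: frame-hop consolidation. A traceback that hops onto a displaced
  # peak ladder and back produces shift pairs whose members individually
  # survive rule 1 but jointly explain nothing (+x ... -x) or correspond to
  # one modification split across two hops (+x ... +y where x+y is the
  # modification mass). For every shift pair, try (i) removing both into the
  # non-aligned mass and (ii) merging both into their sum at the earlier
  # position; adopt the better option when it strictly increases the
  # shared-peak count (a pure cancellation is also adopted on ties).
  if (nrow(shifts) >= 2L) {
    repeat {
      changed <- FALSE
      ps <- shifts$position
      for (a in seq_along(ps)) {
        for (b in seq_along(ps)) {
          if (a >= b) next
          pa <- ps[a]; pb <- ps[b]
          vsum <- shifts$value[a] + shifts$value[b]
          base_c <- n_shared(cur_shifts)

          keep <- !(shifts$position %in% c(pa, pb))
          rm_shifts <- shifts[keep, ]
          rm_c <- n_shared(.reindex_shifts(rm_shifts, steps))

          mg_shifts <- shifts[shifts$position != pb, ]
          mg_shifts$value[mg_shifts$position == pa] <- vsum
          mg_c <- n_shared(.reindex_shifts(mg_shifts, steps))

          take_rm <- rm_c > base_c || (rm_c >= base_c && abs(vsum) <= tol)
          take_mg <- mg_c > base_c && mg_c >= rm_c && abs(vsum) > tol
          if (take_mg) {
            shifts <- mg_shifts
            steps$move[steps$position == pb & steps$move == "realign"] <- "align"
            steps$shift[steps$position == pb] <- NA_real_
            steps$shift[steps$position == pa] <- vsum
            cur_shifts <- .reindex_shifts(shifts, steps)
            changed <- TRUE
            break
          } else if (take_rm) {
            residual <- residual + vsum
            shifts <- rm_shifts
            for (p in c(pa, pb)) {
              steps$move[steps$position == p & steps$move == "realign"] <- "align"
              steps$shift[steps$position == p] <- NA_real_
            }
            cur_shifts <- .reindex_shifts(shifts, steps)
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
      if (changed) stable <- FALSE
      if (!changed || nrow(shifts) < 2L) break
    }
  }

  if (stable) break
  }

  # rule 2: prefer a C-terminal modification over a non-aligned mass when it
  # strictly increases the shared-peak count
  if (abs(residual) > tol) {
    kept_pos <- steps$position[steps$move != "removed"]
    n_kept <- length(kept_pos)
    cand_pos <- kept_pos[unique(pmax(n_kept - 1L, 1L):n_kept)]
    base_c <- n_shared(cur_shifts)
    best <- NULL; best_c <- base_c
    for (p in cand_pos) {
      pr <- .reindex_shifts(tibble::tibble(position = p, value = 0), steps)$position
      cand <- cur_shifts
      if (pr %in% cand$position) {
        cand$value[cand$position == pr] <- cand$value[cand$position == pr] + residual
      } else {
        cand <- rbind(cand, tibble::tibble(position = pr, value = residual))
        cand <- cand[order(cand$position), ]
      }
      cc <- n_shared(cand)
      if (cc > best_c || (cc == best_c && !is.null(best) && p > best$p)) {
        best <- list(p = p, cand = cand); best_c <- cc
      }
    }
    if (!is.null(best)) {
      p <- best$p
      if (p %in% shifts$position) {
        shifts$value[shifts$position == p] <- shifts$value[shifts$position == p] + residual
      } else {
        shifts <- rbind(shifts, tibble::tibble(position = p, value = residual))
        shifts <- shifts[order(shifts$position), ]
      }
      i <- match(p, steps$position)
      steps$move[i] <- "realign"
      steps$shift[i] <- shifts$value[shifts$position == p]
      cur_shifts <- best$cand
      residual <- 0
    }
  }

  # rule 3: trim terminal non-aligned residues explained by a negative mass
  if (residual < -tol) {
    kept <- which(steps$move != "removed")
    run <- integer(0)
    for (i in rev(kept)) {
      if (steps$move[i] == "nonalign") run <- c(i, run) else break
    }
    if (length(run)) {
      masses <- .residue_masses[steps$residue[run]]
      for (l in length(run):1) {
        drop_idx <- run[(length(run) - l + 1L):length(run)]
        m_sum <- sum(masses[(length(run) - l + 1L):length(run)])
        if (abs(residual + m_sum) <= (l + 1) * tol) {
          cand_steps <- steps
          cand_steps$move[drop_idx] <- "removed"
          cand_model <- .trimmed_model(cand_steps)
          cand_shifts <- .reindex_shifts(shifts, cand_steps)
          if (shared_peaks(cand_model, cand_shifts, peaks, tol) >=
              n_shared(cur_shifts)) {
            steps <- cand_steps
            residual <- residual + m_sum
            cur_model <- cand_model
            cur_shifts <- cand_shifts
          }
          break
        }
      }
    }
  }
  # C-terminal variant with the negative mass carried as a shift on the last
  # kept residue (the form rule 2 produces): trim the realigned residue
  # together with the non-aligned run before it when their masses absorb the
  # shift
  kept <- which(steps$move != "removed")
  lastk <- kept[length(kept)]
  if (length(kept) > 1L && steps$move[lastk] == "realign" &&
      !is.na(steps$shift[lastk]) && steps$shift[lastk] < -tol) {
    run <- integer(0)
    for (i in rev(kept[-length(kept)])) {
      if (steps$move[i] == "nonalign") run <- c(i, run) else break
    }
    if (length(run)) {
      s_val <- steps$shift[lastk]
      for (l in length(run):1) {
        drop_idx <- c(run[(length(run) - l + 1L):length(run)], lastk)
        m_sum <- sum(.residue_masses[steps$residue[drop_idx]])
        if (abs(s_val + m_sum) <= (l + 2) * tol) {
          cand_steps <- steps
          cand_steps$move[drop_idx] <- "removed"
          cand_model <- .trimmed_model(cand_steps)
          cand_sh <- shifts[shifts$position != steps$position[lastk], ]
          cand_shifts <- .reindex_shifts(cand_sh, cand_steps)
          if (shared_peaks(cand_model, cand_shifts, peaks, tol) >=
              n_shared(cur_shifts)) {
            steps <- cand_steps
            shifts <- cand_sh
            residual <- residual + (s_val + m_sum)  # drift only
            cur_model <- cand_model
            cur_shifts <- cand_shifts
          }
          break
        }
      }
    }
  }

  # same on the N-terminal side: a leading non-aligned run followed by a
  # realignment with a matching negative shift
  lead <- which(steps$move != "removed")
  run <- integer(0)
  for (i in lead) {
    if (steps$move[i] == "nonalign") run <- c(run, i) else break
  }
  if (length(run)) {
    nxt <- lead[lead > max(run)][1]
    if (!is.na(nxt) && steps$move[nxt] == "realign") {
      s_val <- steps$shift[nxt]
      masses <- .residue_masses[steps$residue[run]]
      for (l in length(run):1) {
        drop_idx <- run[1:l]
        m_sum <- sum(masses[1:l])
        if (!is.na(s_val) && s_val < -tol && abs(s_val + m_sum) <= (l + 1) * tol) {
          cand_steps <- steps
          cand_steps$move[drop_idx] <- "removed"
          cand_steps$move[nxt] <- "align"
          cand_steps$shift[nxt] <- NA_real_
          cand_model <- .trimmed_model(cand_steps)
          cand_sh <- shifts[steps$position[nxt] != shifts$position, ]
          cand_shifts <- .reindex_shifts(cand_sh, cand_steps)
          if (shared_peaks(cand_model, cand_shifts, peaks, tol) >=
              n_shared(cur_shifts)) {
            steps <- cand_steps
            shifts <- cand_sh
            residual <- residual + (s_val + m_sum)  # drift only
            cur_model <- cand_model
            cur_shifts <- cand_shifts
          }
          break
        }
      }
    }
  }

  if (abs(residual) <= tol) residual <- 0
  final_model <- .trimmed_model(steps)
  final_shifts <- .reindex_shifts(shifts, steps)
  shared_b <- shared_peaks(model, NULL, peaks, tol)
  shared_a <- shared_peaks(final_model, final_shifts, peaks, tol)
  inten <- if (nrow(peaks) && sum(peaks$intensity) > 0) {
    intensity_explained(final_model, final_shifts, peaks, tol)
  } else 0

  structure(list(
    steps = steps,
    shifts = .shift_spans(steps, shifts),
    non_aligned_mass = residual,
    residual = residual,
    aligned = format_alignment(steps, residual, tol),
    pre_aligned = pre_aligned,
    shared_before = shared_b,
    shared_after = shared_a,
    intensity_explained = inten,
    score = raw$score,
    delta_m = raw$delta_m,
    peptide = attr(model, "peptide")
  ), class = "specshift_final")
}
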