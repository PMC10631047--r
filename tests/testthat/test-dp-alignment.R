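test_that("aa_found detects residue masses between peak pairs", {
  expect_true(aa_found(138.066, 1.007, "H", 0.02))
  # a deamidated asparagine gap is aspartate's mass, not asparagine's
  expect_false(aa_found(366.177, 251.150, "N", 0.02))
  expect_true(aa_found(366.177, 251.150, "D", 0.02))
  expect_error(aa_found(100, 50, "B"), "unknown residue")
})

test_that("score scheme validates the realignment/non-alignment penalty ordering", {
  expect_s3_class(score_scheme(), "specshift_scores")
  expect_error(score_scheme(align_both = -1), "positive")
  expect_error(score_scheme(non_align = 1), "negative")
  expect_error(score_scheme(realign_single = -3, non_align = -4),
               "more penalized")
})

test_that("a two-residue perfect instance scores two both-evidence alignments", {
  sp <- perfect_spectrum("AG", full_series = TRUE)
  cc <- complete_spectrum(sp$peaks, sp$precursor_mz, sp$charge)
  m <- b_ion_series("AG")
  mat <- fill_matrix(m, cc)
  best <- max(mat$score[2, ])
  expect_equal(best, 20)
  expect_equal(best, oracle_best_score("AG", cc))
})

test_that("the worked two-modification example aligns exactly as published", {
  f <- fig_fixture()
  al <- align_pair(f$peptide, f$peaks, f$precursor_mz, f$charge)
  expect_equal(al$raw$steps$move,
               c("align", "align", "nonalign", "realign", "align", "align",
                 "nonalign", "realign", "align"))
  expect_equal(al$final$pre_aligned, "HI[N][0.98]ATE[S][27.99]VR")
  expect_equal(al$raw$shifts$value, c(0.984016, 27.994915), tolerance = 1e-4)
  # mass closure of the raw alignment
  expect_equal(sum(al$raw$shifts$value) + al$raw$residual, al$raw$delta_m,
               tolerance = 9 * 0.02)
})

test_that("a precursor inflated by a neutral loss yields a leading shift", {
  f <- fig_fixture(inflate = 301.99)
  al <- align_pair(f$peptide, f$peaks, f$precursor_mz, f$charge)
  expect_equal(al$final$pre_aligned, "[301.99]HI[N][0.98]ATE[S][27.99]VR")
  expect_equal(al$raw$shifts$value[1], 301.99, tolerance = 0.02)
})

test_that("an unalignable spectrum leaves residues non-aligned", {
  # only the two virtual anchors remain: one leading realignment onto the
  # precursor column at most, everything else non-aligned
  pep <- "LAVNTESK"
  pk <- tibble::tibble(mz = numeric(), intensity = numeric())
  cc <- complete_spectrum(pk, 600, 2)
  m <- b_ion_series(pep)
  mat <- fill_matrix(m, cc)
  raw <- traceback_alignment(mat)
  expect_true(all(raw$steps$move[-1] == "nonalign"))
  sc <- score_scheme()
  expect_equal(raw$score,
               (sc$align_single + sc$realign_single) + 7 * sc$non_align)
})

test_that("alignment strings follow the bracket grammar", {
  steps <- tibble::tibble(
    residue = strsplit("HINATESVR", "")[[1]],
    move = c("align", "align", "nonalign", "realign", "align", "align",
             "nonalign", "realign", "align"),
    shift = c(NA, NA, NA, 0.984016, NA, NA, NA, 27.994915, NA)
  )
  expect_equal(format_alignment(steps), "HI[N][0.98]ATE[S][27.99]VR")
  expect_equal(format_alignment(steps, residual = 301.99),
               "HI[N][0.98]ATE[S][27.99]VR_301.99")
  expect_equal(format_alignment(steps, residual = 0.005),
               "HI[N][0.98]ATE[S][27.99]VR")
  plain <- tibble::tibble(residue = strsplit("HINATESVR", "")[[1]],
                          move = "align", shift = NA_real_)
  expect_equal(format_alignment(plain), "HINATESVR")
  removed <- steps
  removed$move[9] <- "removed"
  expect_match(format_alignment(removed), "V$")
})

test_that("traceback score is reproduced move-by-move from the matrices", {
  set.seed(21)
  sc <- score_scheme()
  for (r in 1:25) {
    inst <- random_instance()
    cc <- complete_spectrum(inst$peaks, inst$precursor_mz, inst$charge)
    m <- b_ion_series(inst$peptide)
    mat <- fill_matrix(m, cc)
    raw <- traceback_alignment(mat)
    ev <- cc$evidence == "both"
    rescore <- 0
    for (i in seq_len(nrow(raw$steps))) {
      mv <- raw$steps$move[i]
      if (mv == "nonalign") {
        rescore <- rescore + sc$non_align
      } else {
        j <- which(abs(cc$mz - raw$steps$peak_mz[i]) < 1e-9)[1]
        a <- if (ev[j]) sc$align_both else sc$align_single
        p <- if (ev[j]) sc$realign_both else sc$realign_single
        rescore <- rescore + if (mv == "align") a else a + p
      }
    }
    expect_equal(rescore, raw$score)
  }
})

test_that("appending peaks to a spectrum never decreases the best score", {
  set.seed(31)
  for (r in 1:25) {
    inst <- random_instance()
    m <- b_ion_series(inst$peptide)
    n <- nrow(m)
    cc1 <- complete_spectrum(inst$peaks, inst$precursor_mz, inst$charge)
    s1 <- max(fill_matrix(m, cc1)$score[n, ])
    extra <- rbind(inst$peaks,
                   tibble::tibble(mz = runif(2, 60, max(inst$peaks$mz) + 50),
                                  intensity = 1))
    cc2 <- complete_spectrum(extra[order(extra$mz), ],
                             inst$precursor_mz, inst$charge)
    s2 <- max(fill_matrix(m, cc2)$score[n, ])
    expect_gte(s2, s1 - 1e-9)
  }
})

test_that("score and tolerance configuration files round-trip", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("align_both = 12", "align_single = 8", "realign_both = -9",
               "realign_single = -7", "non_align = -5",
               "fragment_tol = 0.03", "# comment", ""), path)
  cfg <- read_score_config(path)
  expect_equal(cfg$scores$align_both, 12)
  expect_equal(cfg$fragment_tol, 0.03)
  writeLines("nonsense = 1", path)
  expect_error(read_score_config(path), "unknown config key")
})
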