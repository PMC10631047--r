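test_that("tryptic digestion cleaves after K/R except before P", {
  params <- sim_params(min_len = 1L, max_len = 50L, seed = 1)
  prot <- tibble::tibble(name = "p1", sequence = "MAAAKRHINATESVRKPQK")
  expect_warning(peps <- tryptic_peptides(prot, 100, params), "eligible")
  expect_true("HINATESVR" %in% peps)
  expect_true("MAAAK" %in% peps)
  # K before P does not cleave
  expect_true("KPQK" %in% peps)
  expect_false("K" %in% setdiff(peps, "KPQK") && "PQK" %in% peps)
})

test_that("peptide sampling is deterministic under the seed", {
  prot <- synthetic_proteome(n_proteins = 30, seed = 5)
  params <- sim_params(seed = 9)
  expect_identical(tryptic_peptides(prot, 25, params),
                   tryptic_peptides(prot, 25, params))
  expect_true(all(nchar(tryptic_peptides(prot, 25, params)) >= 12))
  expect_true(all(nchar(tryptic_peptides(prot, 25, params)) <= 25))
})

test_that("FASTA written proteomes feed the digestion", {
  prot <- synthetic_proteome(n_proteins = 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(prot, path)
  params <- sim_params(seed = 2)
  expect_identical(tryptic_peptides(path, 10, params),
                   tryptic_peptides(prot, 10, params))
})

test_that("simulated spectra carry the deterministic N/D modifications and the loss", {
  pep <- "LNAVTNESDHLK"  # two N, one D
  params <- sim_params(seed = 4, frac_peaks_removed = 0, max_noise_peaks = 0)
  sim <- simulate_spectrum(pep, params)
  expect_equal(sim$truth$n_mods, 4L)  # 2 deamidations + 1 adduct + loss
  expect_equal(sim$truth$mod_positions, "2;6;9")
  expect_equal(as.numeric(strsplit(sim$truth$mod_masses, ";")[[1]]),
               c(0.984016, 0.984016, 21.981943))
  # complete ladder: 2n fragment peaks
  expect_equal(nrow(sim$spectrum$peaks[[1]]), 2 * nchar(pep))
  # precursor encodes residues + modifications + neutral loss
  expect_equal(
    precursor_neutral_mass(sim$spectrum$precursor_mz, 2),
    peptide_neutral_mass(pep) + 2 * 0.984016 + 21.981943 + 17.03,
    tolerance = 1e-4)

  plain <- simulate_spectrum("LAVTESHLK", params)
  expect_equal(plain$truth$n_mods, 1L)  # only the neutral loss
  expect_equal(
    precursor_neutral_mass(plain$spectrum$precursor_mz, 2) -
      peptide_neutral_mass("LAVTESHLK"), 17.03, tolerance = 1e-4)
})

test_that("peak removal honours the 2:1 b:y ratio and the removal fraction", {
  params <- sim_params(seed = 8)
  sim <- simulate_spectrum("HINATESVRKLAVK", params)
  n <- nchar("HINATESVRKLAVK")
  n_remove <- round(0.2 * 2 * n)
  expect_equal(sim$truth$n_removed_b + sim$truth$n_removed_y, n_remove)
  expect_equal(sim$truth$n_removed_b, round(2 / 3 * n_remove))
  expect_equal(nrow(sim$spectrum$peaks[[1]]),
               2 * n - n_remove + sim$truth$n_noise)
})

test_that("dataset simulation is reproducible and id-aligned", {
  prot <- synthetic_proteome(n_proteins = 30, seed = 5)
  params <- sim_params(seed = 11)
  peps <- tryptic_peptides(prot, 15, params)
  a <- simulate_dataset(peps, params)
  b <- simulate_dataset(peps, params)
  expect_identical(a$spectra$precursor_mz, b$spectra$precursor_mz)
  expect_identical(a$spectra$peaks, b$spectra$peaks)
  expect_identical(a$spectra$id, a$truth$spectrum_id)
  expect_true(all(a$truth$n_mods >= 1))
})

test_that("evaluation scores perfect, empty and mismatched inputs correctly", {
  prot <- synthetic_proteome(n_proteins = 30, seed = 6)
  params <- sim_params(seed = 12)
  peps <- tryptic_peptides(prot, 10, params)
  sim <- simulate_dataset(peps, params)
  # construct the ideal result rows straight from the truth
  ideal <- tibble::tibble(
    spectrum_id = sim$truth$spectrum_id,
    peptide = sim$truth$peptide,
    non_aligned_mass = sim$truth$neutral_loss,
    shifts = vapply(seq_along(peps), function(i) {
      tr <- sim$truth[i, ]
      if (!nzchar(tr$mod_positions)) return("")
      pos <- strsplit(tr$mod_positions, ";")[[1]]
      val <- strsplit(tr$mod_masses, ";")[[1]]
      paste(sprintf("%s:%s:%s", pos, pos, val), collapse = ";")
    }, "")
  )
  rep <- evaluate_alignments(ideal, sim$truth)
  expect_equal(rep$pct_neutral_loss_detected, 100)
  expect_equal(rep$pct_all_mods_correct, 100)
  expect_equal(rep$pct_mods_correct_of_expected, 100)

  # alignments carrying no shifts and no matching residual: nothing recovered
  empty <- ideal
  empty$shifts <- ""
  empty$non_aligned_mass <- 0
  rep0 <- evaluate_alignments(empty, sim$truth)
  expect_equal(rep0$pct_neutral_loss_detected, 0)
  expect_lte(rep0$pct_mods_correct_of_expected,
             100 * (1 - nrow(sim$truth) / sum(sim$truth$n_mods)))

  expect_error(evaluate_alignments(ideal[-1, ], sim$truth), "row counts")
})
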