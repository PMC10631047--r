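test_that("MGF records parse with sorted, deduplicated peaks", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS",
    "TITLE=scan_1",
    "PEPMASS=528.26 12345.0",
    "CHARGE=2+",
    sprintf("%.3f %.1f", seq(900, 100, length.out = 10), 1:10),
    "END IONS",
    "BEGIN IONS",
    "TITLE=dup",
    "PEPMASS=400.2",
    "CHARGE=3+",
    "200.5 1.0",
    "200.5 9.0",
    "300.1 2.0",
    "END IONS"
  ), path)
  sp <- read_spectra(path)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$id, c("scan_1", "dup"))
  expect_equal(sp$precursor_mz[1], 528.26)
  expect_equal(sp$precursor_charge[1], 2L)
  expect_equal(nrow(sp$peaks[[1]]), 10)
  expect_true(all(diff(sp$peaks[[1]]$mz) > 0))
  # duplicate m/z keeps the most intense peak
  expect_equal(nrow(sp$peaks[[2]]), 2)
  expect_equal(sp$peaks[[2]]$intensity[sp$peaks[[2]]$mz == 200.5], 9.0)
})

test_that("records without precursor information are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS", "TITLE=nocharge", "PEPMASS=500.1", "100.0 1", "END IONS",
    "BEGIN IONS", "TITLE=ok", "PEPMASS=500.1", "CHARGE=2+", "100.0 1",
    "END IONS"
  ), path)
  expect_warning(sp <- read_spectra(path), "missing precursor")
  expect_equal(sp$id, "ok")
  expect_error(read_spectra("/nonexistent/file.mgf"), "not found")
})

test_that("MGF writing and re-reading is a fixed point", {
  sim <- simulate_dataset(c("HINATESVRK", "LAVNTESHLVGEK"),
                          sim_params(seed = 3))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sim$spectra, path)
  back <- read_spectra(path)
  expect_equal(back$id, sim$spectra$id)
  expect_equal(back$precursor_mz, sim$spectra$precursor_mz, tolerance = 1e-6)
  for (i in 1:2) {
    expect_equal(back$peaks[[i]]$mz, sim$spectra$peaks[[i]]$mz,
                 tolerance = 1e-6)
  }
  # re-reading the same file twice is identical
  expect_identical(read_spectra(path), back)
})

test_that("mzML MS2 spectra are read with precursor and peaks", {
  path <- withr::local_tempfile(fileext = ".mzML")
  write_test_mzml(path, c(
    mzml_spectrum_xml(0, "scan=1", 1, c(400.1, 500.2), c(10, 20)),
    mzml_spectrum_xml(1, "scan=2", 2, c(100.1, 200.2, 300.3), 1:3, 528.26, 2),
    mzml_spectrum_xml(2, "scan=3", 2, c(150.5, 250.5), c(5, 6), 600.5, 3),
    mzml_spectrum_xml(3, "scan=4", 2, c(111.1, 222.2), c(7, 8), 450.1, 2)
  ))
  sp <- read_spectra(path, format = "mzml")
  expect_equal(nrow(sp), 3)  # the MS1 scan is not a fragmentation spectrum
  expect_equal(sp$precursor_mz[1], 528.26, tolerance = 1e-4)
  expect_equal(sp$precursor_charge, c(2L, 3L, 2L))
  expect_equal(sp$peaks[[1]]$mz, c(100.1, 200.2, 300.3), tolerance = 1e-6)
})

test_that("PSM tables parse with configurable delimiters and alphabet checks", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("spectrum;peptide;deltaM",
               "s1;HINATESVR;28.98",
               "s2;lavk;",
               "s3;PEPTIBE;1.0"), path)
  expect_warning(psms <- read_psms(path), "rejected")
  expect_equal(nrow(psms), 2)
  expect_equal(psms$peptide, c("HINATESVR", "LAVK"))
  expect_equal(psms$delta_m[1], 28.98)

  writeLines(c("scan,sequence", "s1,HINATESVR"), path)
  expect_error(read_psms(path, delim = ","), "mandatory column 'spectrum'")
  got <- read_psms(path, delim = ",", spectrum_col = "scan",
                   peptide_col = "sequence")
  expect_equal(got$spectrum_id, "s1")
})

test_that("result tables round-trip through CSV with exact alignment strings", {
  f <- fig_fixture(inflate = 301.99)
  sp <- tibble::tibble(id = "fig", precursor_mz = f$precursor_mz,
                       precursor_charge = 2L, peaks = list(f$peaks))
  res <- align_psms(tibble::tibble(spectrum_id = "fig", peptide = f$peptide), sp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path)
  lines <- readLines(path)
  expect_true(any(grepl("HI[N][0.98]ATE[S][27.99]VR_301.99", lines,
                        fixed = TRUE)))
  back <- read_results(path)
  expect_equal(back$aligned, res$aligned)
  expect_equal(back$pre_aligned, res$pre_aligned)
  expect_equal(back$shared_after, res$shared_after)
  expect_equal(back$score, res$score)
  expect_equal(back$non_aligned_mass, res$non_aligned_mass, tolerance = 1e-9)
  expect_equal(unpack_shifts(back$shifts), unpack_shifts(res$shifts))

  # empty result set: header-only file
  write_results(res[0, ], path)
  expect_equal(length(readLines(path)), 1L)
})
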