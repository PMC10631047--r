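# Shared fixtures and independent oracles, built in code at test time.

PROTON <- 1.007276
WATER <- 18.010565

# The worked two-modification example: peptide HINATESVR carrying a
# deamidation (+0.984016) on N3 and a formylation (+27.994915) on S7,
# observed with its full y-ion series plus b2 and b8. `inflate` adds a
# neutral loss to the precursor mass only.
fig_fixture <- function(inflate = 0) {
  pep <- "HINATESVR"
  aa <- strsplit(pep, "")[[1]]
  mod <- numeric(9)
  mod[3] <- 0.984016
  mod[7] <- 27.994915
  r <- unname(residue_masses()[aa]) + mod
  b <- PROTON + cumsum(r)[1:8]
  y <- PROTON + WATER + rev(cumsum(rev(r)))[-1]
  neutral <- sum(r) + WATER
  list(
    peptide = pep,
    peaks = tibble::tibble(mz = c(y, b[c(2, 8)]), intensity = 1),
    precursor_mz = (neutral + inflate + 2 * PROTON) / 2,
    charge = 2L,
    neutral = neutral,
    b_frame = b
  )
}

# perfect fragment spectrum of an unmodified peptide; full_series adds the
# terminal b_n/y_n ions
perfect_spectrum <- function(pep, full_series = FALSE) {
  r <- unname(residue_masses()[strsplit(pep, "")[[1]]])
  n <- length(r)
  idx <- if (full_series) seq_len(n) else seq_len(n - 1)
  b <- (PROTON + cumsum(r))[idx]
  y <- (PROTON + WATER + cumsum(rev(r)))[idx]  # y_j = proton + water + last j residues
  neutral <- sum(r) + WATER
  list(
    peaks = tibble::tibble(mz = c(b, y), intensity = 1),
    precursor_mz = (neutral + 2 * PROTON) / 2,
    charge = 2L,
    neutral = neutral
  )
}

# Exhaustive enumeration over all monotone step assignments under the
# scoring rules; independent of the dynamic-programming implementation.
oracle_best_score <- function(peptide, completed, scores = score_scheme(),
                              tol = 0.02) {
  rmv <- residue_masses()
  aa <- strsplit(peptide, "")[[1]]
  n <- length(aa)
  rm <- unname(rmv[aa])
  bt <- PROTON + cumsum(rm)
  bt[n] <- sum(rm) + WATER + PROTON
  rm[n] <- rm[n] + WATER
  pk <- completed$mz
  ev <- completed$evidence == "both"
  M <- length(pk)
  SA <- ifelse(ev, scores$align_both, scores$align_single)
  SR <- SA + ifelse(ev, scores$realign_both, scores$realign_single)
  kmax <- function(i, j) {
    w <- which(seq_len(M) < j & abs((pk[j] - pk) - rm[i]) <= tol)
    if (length(w)) max(w) else 0L
  }
  best <- -Inf
  rec <- function(i, col, cum, sc) {
    if (i > n) {
      best <<- max(best, sc)
      return(invisible(NULL))
    }
    for (j in seq_len(M)) {
      km <- kmax(i, j)
      bound <- if (km >= 1L) km else if (i == 1L && j > 1L) 1L else 0L
      if (bound >= 1L && col <= bound) {
        sh <- (pk[j] - bt[i]) - cum
        step <- if (abs(sh) <= tol) SA[j] else SR[j]
        rec(i + 1L, j, pk[j] - bt[i], sc + step)
      }
    }
    if (kmax(i, col) < 1L) rec(i + 1L, col, cum, sc + scores$non_align)
  }
  rec(1L, 1L, 0, 0)
  best
}

# random small alignment instance: a short peptide observed with a partial,
# possibly modified fragment ladder plus noise
random_instance <- function() {
  pep <- paste(sample(names(residue_masses()), sample(3:6, 1), replace = TRUE),
               collapse = "")
  r <- unname(residue_masses()[strsplit(pep, "")[[1]]])
  n <- length(r)
  mod <- numeric(n)
  if (runif(1) < 0.5) mod[sample(n, 1)] <- runif(1, 1, 80)
  rr <- r + mod
  b <- PROTON + cumsum(rr)
  y <- PROTON + WATER + rev(cumsum(rev(rr)))
  ions <- c(b[seq_len(n - 1)], y[seq_len(n - 1)])
  keep <- runif(length(ions)) < 0.6
  mz <- ions[keep]
  n_noise <- sample(0:2, 1)
  if (n_noise) mz <- c(mz, runif(n_noise, 60, sum(rr) + WATER))
  if (length(mz) < 1) mz <- ions[1]
  loss <- if (runif(1) < 0.3) 17.03 else 0
  list(
    peptide = pep,
    peaks = tibble::tibble(mz = sort(mz), intensity = 1),
    precursor_mz = (sum(rr) + WATER + loss + 2 * PROTON) / 2,
    charge = 2L
  )
}

# minimal uncompressed mzML writer for reader fixtures
mzml_b64 <- function(x) {
  jsonlite::base64_enc(writeBin(x, raw(), size = 8, endian = "little"))
}

mzml_spectrum_xml <- function(index, id, mslevel, mz, inten,
                              pre_mz = NA, pre_z = NA) {
  prec <- if (!is.na(pre_mz)) sprintf(paste0(
    '<precursorList count="1"><precursor><selectedIonList count="1">',
    '<selectedIon><cvParam cvRef="MS" accession="MS:1000744" ',
    'name="selected ion m/z" value="%.6f" unitCvRef="MS" ',
    'unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" ',
    'value="%d"/></selectedIon></selectedIonList><activation>',
    '<cvParam cvRef="MS" accession="MS:1000133" ',
    'name="collision-induced dissociation" value=""/></activation>',
    '</precursor></precursorList>'), pre_mz, pre_z) else ""
  arr <- function(acc, name, unit, x) sprintf(paste0(
    '<binaryDataArray encodedLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="%s" name="%s" value=""%s/>',
    '<binary>%s</binary></binaryDataArray>'),
    nchar(mzml_b64(x)), acc, name, unit, mzml_b64(x))
  sprintf(paste0(
    '<spectrum index="%d" id="%s" defaultArrayLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
    '<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>',
    '%s<binaryDataArrayList count="2">%s%s</binaryDataArrayList></spectrum>'),
    index, id, length(mz), mslevel, prec,
    arr("MS:1000514", "m/z array",
        ' unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"', mz),
    arr("MS:1000515", "intensity array",
        paste0(' unitCvRef="MS" unitAccession="MS:1000131"',
               ' unitName="number of detector counts"'), inten))
}

write_test_mzml <- function(path, specs) {
  xml <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.',
    'githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000294" ',
    'name="mass spectrum" value=""/></fileContent></fileDescription>',
    '<softwareList count="1"><software id="sw" version="1">',
    '<cvParam cvRef="MS" accession="MS:1000799" ',
    'name="custom unreleased software tool" value="sim"/></software>',
    '</softwareList><instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="ic"><cvParam cvRef="MS" ',
    'accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" ',
    'accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run" defaultInstrumentConfigurationRef="ic" ',
    'defaultDataProcessingRef="dp">',
    '<spectrumList count="%d" defaultDataProcessingRef="dp">%s</spectrumList>',
    '</run></mzML>'), length(specs), paste(specs, collapse = ""))
  writeLines(xml, path)
  path
}
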