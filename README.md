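# specshift

Spectral alignment of peptide-spectrum matches (PSMs) with localized mass
shifts and a residual non-aligned mass — open-modification interpretation of
tandem mass spectra without any a-priori modification list.

## The problem

Open modification search engines pair an experimental fragmentation spectrum
*Se* with a candidate peptide whose theoretical spectrum is *St*, leaving a
precursor mass difference ΔM. When the peptide carries one or several
unanticipated modifications — or the precursor lost a labile neutral group
before fragmentation — ΔM must be split into localized mass shifts plus a
residual that sits on no residue at all. `specshift` does this split by
dynamic programming:

1. **Completion.** The peptide is modeled by its b-ion prefix series alone
   (b<sub>i</sub> = proton + Σ residues 1..i). To use y-ion evidence in the
   same coordinate frame, every observed peak is also hypothesized as a
   y-ion and its *complementary peak* at MH⁺ + proton − m/z is added;
   native/complementary pairs closer than 0.01 Da merge into one peak with
   "both-ion" evidence.
2. **Alignment.** A score matrix D over (residues × completed peaks) is
   filled: aligning an amino acid whose mass is found between two peaks
   scores +10 (both-ion evidence) or +7; introducing a mass shift (a
   *realignment*) scores the landing alignment decreased by 8 or 6; a
   non-aligned amino acid scores −4. A realignment whose implied shift is
   null (the signature of merely-missing peaks) is scored as a plain
   alignment. Traceback from the best last-row cell yields the alignment
   string.
3. **Post-processing.** Each suggested shift must strictly increase the
   number of native peaks shared between spectrum and shifted model,
   otherwise its mass is moved into the non-aligned mass (printed after
   `_`); shift pairs that only hop between displaced peak ladders are
   consolidated; a non-aligned mass is relocated onto the C-terminal
   residues when that explains more peaks; terminal residues paired with a
   matching negative mass are trimmed (semi-tryptic case).

The package also ships a simulator producing modified tryptic-peptide
spectra with ground truth (deterministic deamidation on N, sodium adduct on
D, controlled peak removal, random noise, and a neutral loss on the
precursor mass) and an evaluation harness for modification-recovery
statistics.

## Worked example

The shipped example spectrum is the peptide `HINATESVR` carrying a
deamidation (+0.98 Da) on N3 and a formylation (+27.99 Da) on S7, observed
with its full y-ion series but only two b-ions; a second copy has the
precursor mass additionally inflated by a 301.99 Da neutral loss.

```r
library(specshift)
spectra <- read_spectra(system.file("extdata", "two_mod_example.mgf",
                                    package = "specshift"))
psms <- read_psms(system.file("extdata", "two_mod_example_psms.csv",
                              package = "specshift"))
results <- align_psms(psms, spectra)
results[, c("spectrum_id", "delta_m", "aligned", "shared_after", "score")]
#>          spectrum_id delta_m                           aligned shared_after score
#> 1           two_mods   28.98        HI[N][0.98]ATE[S][27.99]VR            8    33
#> 2 two_mods_plus_loss  330.97 HI[N][0.98]ATE[S][27.99]VR_301.99            8    23
```

Reading the first string: `H`, `I` align directly; `[N]` has no
corroborating peaks and the `[0.98]` shift localizes a deamidation to that
bracketed group; `ATE` align on the shifted frame; `[S][27.99]` localizes
the formylation; `VR` close the alignment. In the second spectrum ΔM
(330.97) additionally contains 301.99 Da that displaces no fragment — the
post-processing step recognizes that this shift explains no native peaks and
reports it as the trailing non-aligned mass `_301.99`.

Single-pair alignments expose the full machinery with broom-style
accessors and plots:

```r
al <- align_pair("HINATESVR", spectra$peaks[[1]], spectra$precursor_mz[1], 2)
al
#> Spectral alignment of HINATESVR
#>   pre-aligned:  HI[N][0.98]ATE[S][27.99]VR
#>   aligned:      HI[N][0.98]ATE[S][27.99]VR
#>   score 33 | deltaM 28.9789 | non-aligned mass 0.0000
#>   shared peaks 3 -> 8 | intensity explained 80.0%
tidy(al)      # one row per residue: move, landing peak, shift
glance(al)    # one-row summary
autoplot(al)  # spectrum with the alignment path
```

A command-line interface wraps the same functions
(`inst/cli/specshift.R align|simulate|evaluate`), and
`run_simulate()` / `run_align()` / `run_evaluate()` drive whole simulated
datasets; see `vignette("spectral-alignment")` for the model, the
simulation design, and the package's numerical choices.

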