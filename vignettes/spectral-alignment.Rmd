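---
title: "Aligning spectra with localized mass shifts: model, scoring and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning spectra with localized mass shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specshift)
```

## The model

A peptide of residues $a_1 a_2 \dots a_n$ fragments into N-terminal b-ions
and C-terminal y-ions. A modification of mass $s$ on residue $a_i$ displaces
$b_i \dots b_n$ and $y_1 \dots y_{n-i+1}$ by $s$, which makes a direct
peak-to-peak alignment awkward: only part of the spectrum moves. `specshift`
therefore represents the candidate peptide by its b-ion prefix series alone,
$b_i = m_p + \sum_{k \le i} m(a_k)$ with $m_p$ the proton mass, and
transfers y-ion evidence into the same coordinate frame by *completion*:
every observed peak is also hypothesized as a y-ion, adding its
complementary peak at $\mathrm{MH}^+ + m_p - \text{m/z}$, where
$\mathrm{MH}^+$ is the singly protonated precursor mass. Because the b/y
pair of one backbone cleavage sums to $\mathrm{MH}^+ + m_p$, a surviving
y-ion exactly replaces its missing b-partner. When both ions of a cleavage
are present the native peak and the complementary image merge (within
`merge_tol`, default 0.01 Da) into a single peak carrying *both-ion*
evidence — for perfect fragmentation, completion adds nothing.

Two virtual anchor peaks frame the alignment: one at m/z $= m_p$ (the $b_0$
position, giving the first residue a left anchor) and its complementary
image at $\mathrm{MH}^+$ (giving the last residue a landing position). They
carry single-ion evidence unless a real peak merges with them; in
particular, a precursor-derived peak observed at $\mathrm{MH}^+$ upgrades
that column to both-ion evidence. Because $b_n$ is not an observable
fragment, the final boundary targets $\mathrm{MH}^+$ and the last residue's
effective mass is $m(a_n) + m(\mathrm{H_2O})$.

## Alignment by dynamic programming

A matrix $D$ of size $N \times M$ (residues × completed peaks, sorted
ascending with the anchor first) is filled row by row. A boolean *aafound*
holds at cell $(i, j)$ when the mass of residue $i$ is found, within the
fragment tolerance, between peak $j$ and some earlier peak; the largest such
witness $k$ bounds the admissible predecessors $m \le k$. Each predecessor
contributes a candidate shift

$$ s = (\text{peak}_j - b_i) - \mathrm{cum}(i-1, m), $$

where $\mathrm{cum}$ tracks the cumulative displacement of the path
($\text{peak} - b$ at the last mapped cell, inherited unchanged across
non-aligned residues). Three outcomes are scored:

* **alignment** ($|s| \le$ `tol`): `align_both` = +10 when the landing peak
  carries both-ion evidence, `align_single` = +7 otherwise. This includes
  the *null-shift* case — a realignment across merely-missing peaks whose
  implied shift vanishes because the skipped residues' masses are accounted
  for in $b_i$;
* **realignment** ($|s| >$ `tol`): the landing alignment score decreased by
  the realignment penalty (8 with both-ion evidence, 6 otherwise), i.e. a
  net +2 or +1, with $s$ recorded as a localized shift. A realignment is
  thus penalized more heavily (8/6) than the non-alignment of one amino
  acid (4), so a spurious shift pays off only when at least two subsequent
  residues align on the displaced frame: one compensating alignment gives
  $+1+7+1 = 9$, less than the non-aligned detour $-4+7+7 = 10$, while two
  give $15 > 10$;
* **non-alignment** (no witness): stay in the column at `non_align` = −4.

The first row may additionally realign from the anchor without a witness —
this is what turns a constant displacement of all complementary peaks (a
neutral loss) into a leading shift. Score ties between predecessors break
toward alignment over realignment, then toward the peak with stronger ion
evidence (both > native > inferred), then toward the nearer predecessor;
without the evidence rule, score-tied paths hop between the native and
complementary peak ladders and corrupt the recovered shift values.
Traceback starts at the maximum of the last row; ties prefer cells on
observed peaks over the inferred precursor column, then the rightmost peak.
Scores are integers and are not length-normalized.

## Post-processing

The traceback maximizes a fragment-evidence score over the *completed*
spectrum; a shift can therefore be supported only by complementary peaks
that exist in no experimental spectrum (the leading shift induced by a
neutral loss is the canonical case). The refinement step re-examines every
shift against the *native* spectrum: predicted b- and y-series are generated
from the aligned peptide's own mass — peptide plus localized shifts; the
non-aligned mass is by definition not on the peptide — and native peaks
within tolerance are counted, each at most once.

1. **Shift support (rule 1).** A shift survives only if it strictly
   increases the native shared-peak count; otherwise its mass joins the
   non-aligned mass printed after `_`. The strict reading of "increases" is
   used (`keep_ties = FALSE` keeps the alternative testable).
2. **Frame-hop consolidation (rule 1b).** Pairs of shifts that individually
   survive but jointly explain nothing (+x … −x, the entry and exit of a
   displaced ladder) are moved together into the non-aligned mass; pairs
   that represent one modification split across two hops (+x … +y with
   x + y the modification mass) are merged into their sum at the earlier
   position when that strictly improves the count. Rules 1 and 1b iterate
   to a fixed point, which makes refinement idempotent: a shift kept only
   because of junk later removed is itself re-examined. This is more
   thorough than a single pass and measurably raises the neutral-loss
   detection rate of the simulation study by about two points.
3. **C-terminal arbitration (rule 2).** A modification on the last residues
   cannot win the alignment score (nothing remains to compensate the
   penalty), so it surfaces as a non-aligned mass. The residual is tested
   as a shift on each of the two C-terminal positions and relocated when
   that strictly increases the shared-peak count; ties conservatively keep
   the non-aligned form.
4. **Semi-tryptic trimming (rule 3).** Terminal non-aligned residues paired
   with a matching negative mass — whether carried as the residual or as a
   negative shift on the last kept residue — are removed when this does not
   decrease the shared-peak count.

Mass closure holds throughout: localized shifts plus the non-aligned mass
equal ΔM (computed against the possibly trimmed peptide) within
$n \times$ `tol`. A residual below `tol` in absolute value is dropped.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `frag_tol` | 0.02 Da | absolute tolerance for residue-mass gaps, shift nullity, and peak matching |
| `merge_tol` | 0.01 Da | native/complementary merge distance during completion |
| `score_scheme()` | 10/7, −8/−6, −4 | alignment scores, realignment penalties, non-alignment score |
| `keep_ties` | `FALSE` | rule 1 keeps shifts whose removal neither gains nor loses peaks |

All comparisons are absolute (no ppm mode); the scoring is loadable from a
flat `key = value` file so alternatives — e.g. swapping the −8/−6 evidence
ordering, whose literal direction is counter-intuitive but kept — can be
tested without code changes.

## The simulator and what it does (not) emulate

`simulate_spectrum()` reproduces the reference simulation design: doubly
charged spectra of fully tryptic peptides (cleavage after K/R except before
P, lengths 12–25), a deamidation (+0.984016 Da) on every N and a sodium
adduct (+21.981943 Da) on every D, removal of 20% of the fragment peaks
(two-thirds of them b-ions, the ratio observed in beam-type CID spectra),
up to 60 noise peaks (count uniform in [0, 60], m/z uniform between 50 Da
and MH⁺ — the design leaves the noise law open and uniform is the least
informative choice), and a 17.03 Da neutral loss added to every precursor
mass. Fragment series run $b_1 \dots b_n$ and $y_1 \dots y_n$; $y_n$ is the
intact peptide after shedding the labile group — the familiar
precursor-minus-loss peak — and its presence is what lets a clean alignment
end on an observed peak instead of the inferred precursor column.
Intensities are uniform (1.0): the alignment ignores intensity by design,
so only the explained-intensity report would be affected by a realistic
intensity model.

Without the real human proteome at hand, `synthetic_proteome()` draws
random protein sequences with human-like amino-acid frequencies, with N and
D set so that eligible tryptic peptides carry on average ~1.06 N+D residues
— matching the reference dataset's reported load of about 2.06
modifications per spectrum once the obligatory neutral loss is counted.
Real proteomes additionally contain sequence redundancy, low-complexity
regions and repeats that create ambiguous alignment witnesses; passing
tests on the synthetic proteome therefore bounds, but does not guarantee,
behaviour on real search results.

The evaluation harness scores three statistics per dataset: the fraction of
PSMs whose non-aligned mass matches the neutral loss (±0.02 Da); the
fraction whose detected modifications are *all* correct — the loss
recovered and every reported shift matching a true modification at the
first residue of its bracketed group (strict placement; span-placement
variants, crediting the whole bracketed group the string actually claims,
are reported alongside); and the number of correctly identified
modifications over all incorporated ones (residue modifications plus one
loss per spectrum).

## Problem sizes and numerical choices

The test suite runs the full protocol on 2,000 simulated PSMs (about 80 s),
verifies the dynamic program against exhaustive path enumeration on 200
random instances of at most 6 residues × 14 completed peaks, checks mass
closure and refinement guarantees on 1,000 simulated PSMs, and sweeps the
peak-removal fraction over {0, 0.2, 0.5} × 150 PSMs for monotone
degradation. Duplicate m/z values keep the most intense peak; peaks above
MH⁺ have no complementary image and stay native-only; an empty or
precursor-free record is skipped with a warning rather than failing the
batch. The alignment itself contains no randomness, so batch results are
byte-identical across repeated runs and thread counts.

## Known limitations

* A modification and a neutral loss merging into one composite shift cannot
  always be separated: when the fragment evidence around the modified
  residue is entirely complementary-derived, the composite interpretation
  is genuinely score-optimal, and post-processing can only discard (not
  decompose) it unless a hop-back pair exists.
* Adjacent modified residues are indistinguishable; the bracketed group is
  the honest localization granularity.
* Candidate peptides are plain sequences; fixed modifications on the input
  peptide string and ppm tolerances are out of scope, as are a-, c-, x-,
  z-ion series, isotope envelopes and fragment charge states above 1.
* The score is global: candidate ranking across peptides per spectrum is
  not attempted.

```{r example}
spectra <- read_spectra(system.file("extdata", "two_mod_example.mgf",
                                    package = "specshift"))
psms <- read_psms(system.file("extdata", "two_mod_example_psms.csv",
                              package = "specshift"))
align_psms(psms, spectra)[, c("spectrum_id", "aligned", "non_aligned_mass")]
```
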