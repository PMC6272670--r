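---
title: "Methods: diagnostic-fragment annotation and HPLC-UV quantification of dibenzylbutyrolactone lignans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic-fragment annotation and HPLC-UV quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lignantools)
```

# The problem

Caulis Trachelospermi, the medicinal stems and leaves of *Trachelospermum
jasminoides*, owes its bioactivity chiefly to dibenzylbutyrolactone
lignans: two benzyl-substituted aromatic rings on a γ-butyrolactone core,
often glycosylated. Two aglycone subclasses occur, differing only by an
8′-hydroxyl — lignano-9,9′-lactones (matairesinol, arctigenin and their
glycosides) and lignano-8′-hydroxy-9,9′-lactones (nortrachelogenin,
trachelogenin and theirs) — and they fragment differently enough under
positive-mode collision-induced dissociation that MS/MS alone can tell
them apart. `lignantools` turns that fragmentation scheme, and the
companion external-standard HPLC-UV quantification workflow, into tested,
reusable code.

# The fragmentation model

All species are singly charged positive ions; these lignans ionise
strongly as `[M+Na]+`, with `[M+H]+` also supported. The rule set per
compound is:

* **Both subclasses** produce benzyl-type cations from each aromatic ring:
  [A]⁺ from ring A and [A′]⁺ from ring A′. Their masses depend only on the
  ring substitution: guaiacyl (OH + OMe) 137.0603, veratryl (2 × OMe)
  151.0754, methoxy-veratryl 181.0859. Because both subclasses share them,
  these ions are never used to decide the subclass.
* **9,9′-lactones** additionally give [B]⁺ ([A′]⁺ + C₂H₂: 163.0754 /
  177.0910 by ring) and the complement ion [M+H−A]⁺, the protonated
  aglycone minus the quinone-methide neutral C₈H₈O₂ (136.0524 Da).
* **8′-hydroxy-9,9′-lactones** dehydrate first ([M+H−H₂O]⁺ of the
  aglycone) and then give the lactone-containing [C+H]⁺ ion (233.0808
  guaiacyl-A′ / 247.0965 veratryl-A′).
* **O-glycosides** lose their sugar residues sequentially from the
  precursor (Glc 162.0528, Rha 146.0579, Api 132.0423 Da), retaining the
  charge carrier; sodiated glycosides also give [A−H+Na]⁺ at 159.0417. One
  further water loss from the terminal (fully deglycosylated) ladder node
  is included: the reported fragment lists of several glycosides (e.g. the
  [M+Na−Glc−H₂O]⁺ ion of tanegoside A) show this dehydration, and without
  it the rule set would not cover them.
* **C-glycosides** cannot lose the sugar as a clean residue; they cleave
  across the ring, giving [M+H−2H₂O−60]⁺ and [M+H−3H₂O−60]⁺.

The classification rule follows directly: a [C+H]⁺-family match ⇒
8′-hydroxy; otherwise a [B]⁺-family or [M+H−A]⁺-consistent match ⇒
9,9′-lactone; otherwise `undetermined`. Spectra of trace-level compounds
often lack [B]⁺/[C+H]⁺ through matrix interference; the pipeline then
reports `undetermined` rather than guessing.

## Ring tags instead of structures

The library encodes each compound's rings as tags (`guaiacyl`,
`veratryl`, `methoxy-veratryl`) rather than full structures — the
fragmentation scheme uses nothing more. In every reference spectrum the
[A]⁺ column is the guaiacyl 137.0603 while [B]⁺/[C+H]⁺ track the *other*
ring (arctiin: [A′]⁺ 151.0754, [B]⁺ 177.0910), so ring A is guaiacyl
throughout the library, and [B]⁺/[C+H]⁺ masses derive from ring A′.

Three library compounds needed a judgement call. Tanegoside A's aglycone
(C₂₀H₂₄O₇, RDBE 9) is not a classical butyrolactone, but its reported
fragments are a lignan-glycoside ladder; it is filed as a 9,9′-lactone
glucoside with guaiacyl rings. 4-Demethyltraxillaside (aglycone C₂₁H₂₄O₇)
and traxillageside (aglycone C₂₂H₂₆O₇) are filed as 8′-hydroxy lactones by
analogy with the trachelogenin series, with ring A guaiacyl (both show
[A−H+Na]⁺ near 159.04) and ring A′ veratryl and methoxy-veratryl
respectively. None of the three is among the 14 quantified standards, so
these choices affect only their own annotations.

# Numerical conventions

**Electron mass.** Ion m/z is computed *without* subtracting the electron
mass. The published reference values mix conventions: the precursor table
is uncorrected (sodiated C₃₂H₄₂O₁₇ rounds to 721.2320, reproducing the
printed −0.69 ppm for the measured 721.2315), while several fragment
"calculated" constants (151.0754, 163.0754, 233.0808, 247.0965) are
electron-corrected. The package therefore computes everything uncorrected
and stores the printed fragment constants verbatim in `fragment_rules()`
— the only way to reproduce both tables at once. The two conventions
differ by 0.55 mDa, far inside the 10 mDa matching tolerance, so the split
never changes an annotation.

**Rounding.** All internal arithmetic is full double precision. Reported
masses round half away from zero to 4 decimals, ppm errors to 2
(`round_half_up()`); `base::round()`'s half-to-even rule would differ on
boundary cases.

**Tolerances.** Fragment matching uses an *absolute* default tolerance of
10 mDa, not ppm: the deviations between reported glycoside fragments and
exact arithmetic are flat on the mDa scale and reach ~6.4 mDa (e.g. the
glucose-loss ion of the nortrachelogenin 4-O-glucoside). Precursor
filtering uses 10 ppm, which covers the largest observed precursor errors
(5.8 ppm) with margin. Formula search defaults to 10 ppm for the same
reason.

**Greedy matching.** Expected ions are assigned to peaks greedily by
ascending absolute deviation (ties to the lower expected m/z), each peak
used at most once. In this chemistry expected ions sit tens of Da apart,
far beyond the tolerance, where greedy assignment coincides with the
optimal one (the test suite checks this against an exhaustive oracle on
small instances); in adversarial overlapping configurations greedy can be
count-suboptimal, an accepted trade-off for determinism and simplicity.

**Ties are reported, not broken.** Positional isomers with identical
formula, subclass, ring tags and sugar lists — the nortrachelogenin
monoglucosides {2, 3, 21}, the di-glucoside/gentiobioside pairs {18, 20}
and {4, 19}, and {7, 22} — produce identical expected-ion sets. MS
evidence cannot split them; the original assignments used LC retention
behaviour. `identify_spectrum()` reports the full tie set (with
`best_match` the lowest id, a deterministic representative) and an
optional user-supplied elution order annotates, but never re-ranks, the
set.

**Degenerate inputs.** Empty spectra give empty evidence; a precursor with
no library candidate still gets a subclass call; formula subtraction going
negative, inverted search bounds, non-positive ppm references,
zero-variance or zero-slope calibrations, RSD of fewer than two values and
unsorted dilution series are all errors; an S/N threshold never reached
reports an absent (NA) limit, not zero.

# Formula deduction

`enumerate_formulas()` performs plain bounded enumeration over C 0–40,
H 0–60, O 0–20 (N available but 0 by default — no nitrogenous constituent
occurs here), filtered by the ppm window, RDBE 0–25 and H ≤ 2C + 2. The
lattice is ≈ 52,000 points, so no seniority heuristics are needed; the
whole search is a few milliseconds. Candidates sort by |ppm|, then by
|RDBE − 10| (the aglycone-typical value), then lexicographically; ties
this deep are rare and the ordering is then purely cosmetic.

# Quantification and validation

Calibration is unweighted OLS of area on amount (ng), r² the squared
Pearson correlation; with nine injection levels spanning a 35-fold range
and near-unit slopes, weighting is immaterial. Contents convert as
mg/g = ng × (extract_mL × 1000 / inject_µL) / (sample_mg × 1000) — 0.0025
at the study's constants (400 mg powder, 20 mL extract, 20 µL injected),
which are arguments, not hard-coded values. RSD uses the sample (n−1)
standard deviation — the convention is not stated in the source but is
verified by reproducing the printed 30.54% for the first compound's
14-batch column. Spike recovery is (observed − original)/spiked × 100;
when replicate-level triples are supplied the per-replicate recoveries are
averaged. `summarize_batches()` recomputes all derived rows from the cells
and *flags* a supplied declared total that disagrees — the published
grand-mean total (28.531 mg/g) is inconsistent with its own cells, which
give 27.618, and the package reports the recomputed value.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is tested:

* **Spectra**: every expected ion of a compound (one physical peak per
  distinct m/z — [A]⁺ and [A′]⁺ coincide for di-guaiacyl compounds)
  receives i.i.d. Gaussian mass error with σ = 2 mDa by default, bracketing
  the ≤ 6.4 mDa deviations of the reference tables; the precursor receives
  the same error. Error is absolute (mDa), not ppm, matching the observed
  deviation pattern and the annotator's tolerance model. Optional ion
  dropout (default 0) emulates matrix suppression. Intensities (log-normal
  by default) are decorative: the annotator ignores them, as the source
  tables report none.
* **Peak areas**: true contents (mg/g) are converted to on-column ng and
  pushed through the published calibration lines with Gaussian noise of
  relative σ = 1% of the true signal, plus a calibration series at the nine
  standard injection volumes (1, 2, 3, 5, 10, 15, 20, 25, 35 µL).

Everything is seeded; identical configurations give identical data.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: chromatographic peak shapes and integration
error, isotope envelopes, in-source fragmentation, chimeric spectra,
matrix interference beyond uniform dropout, and retention-time behaviour.
In particular, real trace-level spectra lose exactly the diagnostic
[B]⁺/[C+H]⁺ ions first, which the uniform dropout model only approximates.

## Expected performance under the simulated conditions

At zero noise, round trips are exact: every simulated spectrum is
identified (within its isomer tie set) and classified without cross-class
errors, and quantification returns the generating contents to machine
precision. At σ = 2 mDa the identification round-trip rate, measured over
100 seeded simulations of each of the 14 standards, is ≈ 97–98% in
aggregate. It is *not* uniformly ≥ 95% per compound: for the smallest
aglycone precursor (sodiated matairesinol, m/z 381) the 10 ppm precursor
window is only 1.9σ of the simulated precursor error, so the per-compound
expectation is ≈ 94%. This is a property of the stated conditions, not a
defect; the acceptance test asserts the aggregate rate.

# Problem sizes used in the tests

The suite runs the formula round-trip property over 200 random in-bounds
CHO formulas, the identification round trip over 14 × 100 seeded spectra,
the mass-error calibration over 10⁴ simulated fragments, and the
quantification bias property over 100 replicates of the full 14 × 14
content table — sizes chosen so each estimate's Monte-Carlo error is well
inside the asserted tolerance while the whole suite stays desk-scale.

# Known limitations

* Positive mode, singly charged, C/H/O/N/Na only; no isotope-pattern
  scoring, a deliberate omission since the reference data provide none.
* The rule set is specific to dibenzylbutyrolactone lignans and the
  glycoside chemistry of this matrix; other lignan skeletons (e.g.
  furofurans) would need their own rules.
* Retention-time information is annotation-only by design; the package
  will never resolve positional-isomer ties on its own.
* Raw chromatogram/spectrum processing (centroiding, integration) is out
  of scope: inputs are centroided peak lists and integrated areas.
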