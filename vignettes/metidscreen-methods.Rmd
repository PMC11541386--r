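---
title: "Methods: suspect screening of pharmaceutical metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: suspect screening of pharmaceutical metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metidscreen)
```

## The screening model

`metidscreen` treats metabolite identification as a three-stage
inference: *candidate generation* (what could the metabolites be),
*spectral prediction* (what would they look like in MS²), and
*statistical screening* (which observed features are both
treatment-related and spectrally consistent with a candidate). The
package assumes its input is an aligned feature table — peak picking,
deconvolution and alignment are upstream responsibilities — and that
parent-compound MS² spectra are available, either predicted by an
external fragmenter or taken from measured reference spectra.

### Candidate generation

A reaction pathway is a signed elemental-formula delta: glucose
conjugation is `+C6H10O5` (+162.05282 Da), dehydration `-H2O`, malonyl
conjugation after hydroxylation `+C3H2O3 +O`. Applying a reaction to a
parent is pure formula arithmetic; no attempt is made to locate the
site of metabolism, so the resulting candidates are *tentative*: known
formula and mass, unknown structure. The elementwise sum must remain
non-negative — a loss reaction cannot remove atoms the parent lacks —
and violating pairs are rejected and logged rather than clamped,
because a clamped formula would silently misstate the mass.

The packaged library holds exactly 144 pathways in three blocks: 22
phase I transformations, 42 phase II conjugations, and 80 pairwise
combinations (ten frequent conjugations crossed with eight secondary
modifications). Entry order is fixed and entry 63 is glucose
conjugation, so candidate identifiers such as `Sulfamethoxazole-R63`
are stable across runs. The membership of the library is a curated
reconstruction of the phase I/II reaction classes reported for plant
and soil-organism xenobiotic metabolism; it is deliberately restricted
to deltas applicable to all six packaged parents, so the full
enumeration (6 × 144 = 864 candidates) completes without rejections.
Users can substitute any reaction table; the cardinality is not
special-cased anywhere.

Exact-structure candidates from external predictors or literature are
ingested as-is; when a row carries only a SMILES, the formula is
derived through OpenBabel (ChemmineR/ChemmineOB) with implicit
hydrogens added. Cross-source totals are straight sums — deduplication
happens only in the isomer-group Venn view, where every candidate
collapses to its (parent, formula) key, because tentative candidates
cannot distinguish structural isomers and a like-for-like comparison
must not count them separately.

### Mass conventions

Monoisotopic masses come from a fixed table frozen into the package
(`atomic_masses`; C 12.000000, H 1.0078250, O 15.9949146, ...).
Adducts use the hydrogen-atom convention: [M+H]⁺ = M + 1.00783 and
[M−H]⁻ = M − 1.00783, with no electron-mass correction. The choice is
deliberate — it reproduces published worked-example precursors exactly
(SMX 254.05994, its glucoside 416.11276) — and the ~0.5 mDa electron
mass is far inside the 1 mDa matching tolerance in any case.

### Spectral synthesis

In silico fragmenters emit one spectrum per collision energy. Library
records merge CE 10 and 20 eV by default, emulating the
collision-energy spread of DDA/DIA acquisition; the 40 eV level is
excluded because near-terminal fragments are shared by many small
molecules and inflate false positives. Merging is a union with a 5 mDa
collapse rule (the MS² match tolerance reused as the merge tolerance),
keeping the most intense member of each collapsed cluster — the
arithmetic of the merge is a design choice of this package, stated here
because upstream tools do not document one.

Tentative candidates get a *transplanted* spectrum: the parent's
merged fragments, plus the parent's own precursor ion appended as one
extra fragment, under a precursor shifted to the candidate's adduct
m/z. The rationale is empirical: conjugates tend to cleave the
conjugated moiety even at low collision energy, so the metabolite's MS²
typically contains the parent's fragments and often the intact parent
ion. Two details are deliberate:

* The appended fragment receives the *computed* parent precursor
  ([M+H]⁺/[M−H]⁻ of the parent), and its intensity is set to the
  maximum parent-fragment intensity so dot-product scoring cannot
  ignore it.
* The peak-count invariant (tentative record = parent fragments + 1)
  is kept for *all* reactions, including mass losses, where the
  transplanted parent precursor lies above the shifted record
  precursor. A measured spectrum could not contain such a peak, but a
  synthetic library record is a matching template, not a measurement;
  dropping the peak would make loss-reaction records strictly less
  informative. The fragments-below-precursor validity check therefore
  applies only to non-tentative records.

Negative-mode synthesis mirrors positive mode symmetrically with
[M−H]⁻; no polarity-specific fragmentation rules are attempted.

Libraries serialize to MSP (`NAME`, `PRECURSORMZ`, `PRECURSORTYPE`,
`IONMODE`, `FORMULA`, `COMMENT`, `Num Peaks`, tab-separated peak
lines). Intensities are normalized to max = 100 on write; m/z values
are written at five decimals, so a round-trip is lossless to 10 µDa.

### Matching and confidence

A feature matches a record when the precursor agrees within the MS1
tolerance (default 1 mDa) and the MS² similarity clears the acceptance
threshold with at least `min_matched_fragments` paired peaks.
Similarity is the cosine of square-root-intensity vectors over the
union of paired and unpaired peaks; pairing is greedy closest-first
within 5 mDa, each peak used once, ties broken toward the lower
library m/z. The default acceptance threshold of 0.80 mirrors the
identification cutoff customary in alignment software; both the
threshold and the tolerances are configurable, and every reported match
re-satisfies its bounds by construction. Features without MS² are never
reported: a precursor-only hit is below the reporting floor
(confidence levels 4–5 are excluded). Accepted matches carry level 2
(exact-structure record) or level 3 (tentative record); level 1 is
reserved for reference-standard confirmation supplied by the user.

The retention-time difference to the parent feature (ΔRt) is reported
but not gated: hydrophilic conjugations (sugars) should elute earlier
and acyl/alkyl modifications later on reversed phase, and the sign is
a manual plausibility check rather than a quantitative rule.

### Statistical triage

The pooled-QC prefilter keeps a feature only if its QC %RSD is below
30 (sample standard deviation over mean, times 100 — an undefined RSD
from a zero QC mean fails), its QC presence exceeds 0.5, and its
presence in at least one biological group exceeds 0.7. All three
comparisons are strict, exactly as thresholds of this form are
conventionally printed; "present" means area above a configurable
floor, zero by default.

Volcano selection computes the fold change on raw group means after
replacing zeros by half of the smallest positive area in the table
(the conventional half-minimum imputation), and the p-value from a
Welch two-sample t-test on log₁₀(area + half-minimum). A feature is
significant when *p* < 0.05 and FC > 3.0 — strictly, and in the
treated direction only, because drug metabolites should be absent from
control samples; a feature elevated in controls is excluded no matter
how small its p-value. No multiple-testing correction is applied by
default, matching the raw-p criterion the workflow is built around; a
Benjamini–Hochberg flag exists for users who want it. The PCA overview
log-transforms, autoscales, and fixes each component's sign by forcing
its largest-magnitude loading positive, making scores deterministic.

The final report is the inner join of the significant set with the
match report: significant-but-unmatched features are metabolome
changes outside the screening scope, matched-but-non-significant
features lack statistical support. Report rows are emitted per
(candidate, matrix, environment, timepoint) group where the compound
is present in more than half of the treated samples of that group.

## The synthetic-data generator

The simulator emulates the *table-level* structure of an exposure
study: small treated/control groups (default 3 + 3), eight pooled-QC
injections, a lognormal background metabolome with no group effect,
and spiked metabolite features generated from library records. Spiked
features receive the library precursor plus Gaussian m/z error
(default SD 0.3 mDa, comfortably inside the 1 mDa tolerance), MS²
peaks copied with 0.5 mDa jitter and 10 % intensity noise, and
retention times at the parent's RT shifted by a conjugation-dependent
sign (sugars −0.7 min, acetyl/methyl +0.8 min). Pooled-QC areas are
drawn around the pooled mean with a 15 % CV — pooling guarantees every
compound is present in QCs, which is why missingness (default 10 %)
applies to background features only. Decoy features sit at library
precursors plus a fixed offset that must exceed twice the MS1
tolerance, with shuffled fragment intensities, and probe the
false-match rate. The control-group areas of spiked features equal the
base area (trace-level carryover), so the true fold change is exactly
the configured multiplier.

What the simulator does **not** emulate — and what passing tests on it
therefore cannot show — includes chromatographic peak-shape artifacts,
isotopologue patterns, in-source fragmentation, DIA co-isolation,
matrix-dependent ionization suppression, and correlated missingness.
Spike-in recovery on simulated tables validates the *pipeline logic*
(tolerances, scoring, triage, joins), not instrument-level
performance on real extracts.

Default problem sizes were chosen to make the full validation suite
run comfortably on a laptop: 150–200 background features, tens of
spikes and decoys, and a 766-record positive-mode library after the
m/z 800 cutoff. All draws derive from a single mandatory seed;
identical configurations reproduce byte-identical tables.

## Numerical choices and degenerate inputs

* Formula parsing accepts Hill strings and signed multi-term delta
  expressions; Unicode minus is normalized to ASCII. Unknown element
  symbols are rejected by name.
* Peak-merge and fragment-pairing tie-breaks are deterministic (most
  intense member; lower library m/z), so libraries and match reports
  are reproducible byte-for-byte.
* A volcano test on two exactly constant, equal groups returns p = 1
  rather than NaN; constant features are dropped from PCA with a
  warning.
* Empty candidate tables, empty libraries and empty reports flow
  through every stage without special-casing by the caller.
* `mz_cutoff_filter` with cutoff 0 returns an empty set rather than
  erroring; the cutoff is a scan-range decision, not a validation.

## Known limitations

* Tentative spectra inherit the parent's fragments verbatim; a
  metabolite whose fragmentation is dominated by the modified moiety
  (common for phase I oxidations) will score poorly against its
  transplanted record. This is intrinsic to structure-free prediction.
* The similarity function and its 0.80 default stand in for whatever
  scoring an upstream alignment tool applies; users reproducing a
  specific tool's behaviour should calibrate `min_similarity` against
  it.
* Only singly charged [M+H]⁺/[M−H]⁻ precursors are modelled — no
  multi-charge adducts, sodium adducts, or in-source fragments.
* The packaged reaction library preserves the documented cardinality
  and the printed conjugation deltas, but its exact membership is a
  reconstruction; screening results for pathways outside the printed
  examples depend on that curation.
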