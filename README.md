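# metidscreen

Suspect screening of pharmaceutical metabolites in untargeted LC-HRMS
feature tables.

Plants and soil organisms transform pharmaceutical residues through
phase I reactions (hydroxylation, dealkylation, hydrolysis, ...) and
phase II conjugations (glucose, glucuronic acid, malonic acid, acetyl,
amino acids, ...). Most of these metabolites have no reference
standards and no deposited spectra, so they cannot be identified by
conventional library search. `metidscreen` implements the
suspect-screening alternative for analytical chemists working on
environmental exposure studies: it *predicts* what the metabolites of a
set of parent drugs could be, *synthesizes* an in silico MS² library
for them, and *screens* an aligned feature table against that library
with a statistical triage that separates treatment-related features
from the background metabolome.

## The method

Candidate metabolites come from three sources:

* **CMP** (common metabolic pathways): every reaction in a library of
  signed elemental-formula deltas is applied to every parent. A
  reaction with delta Δ applied to a parent with formula F yields a
  *tentative* candidate with formula F + Δ and monoisotopic mass
  m(F) + m(Δ); the site of metabolism — and hence the structure — stays
  unknown. The packaged library holds 144 pathways (phase I, phase II,
  and pairwise combinations). Reactions that would remove atoms a
  parent does not carry are rejected, not clamped.
* **SP / LS** (software prediction, literature search): externally
  predicted candidates with exact structures, ingested from tables
  (formulas derived from SMILES when absent).

Library spectra for exact structures are collision-energy merged
(10 + 20 eV by default; the 40 eV level is left out because its
unspecific low-mass fragments inflate false matches). For tentative
candidates the spectrum is synthesized by *fragment transplantation
with precursor shift*: the parent's fragments are kept, the parent's
own precursor ion is appended as one extra fragment (conjugates
commonly cleave the conjugated moiety and regenerate the parent ion),
and the record precursor becomes m/z = M + δ ± 1.00783 for the
candidate's neutral mass M.

Screening matches each feature against the library within ±1 mDa on
the precursor, scores MS² similarity as the cosine of
square-root-intensity vectors over greedily paired fragments (±5 mDa),
and assigns identification confidence levels: 1 (reference standard),
2 (exact-structure library match), 3 (tentative-structure match).
Matches without MS² support are never reported.

The statistical triage applies the classic pooled-QC prefilter
(QC %RSD < 30, QC presence > 0.5, group presence > 0.7, all strict)
followed by volcano selection: Welch's t-test on log₁₀ areas and a
raw fold-change threshold, keeping features with *p* < 0.05 **and**
FC > 3.0 in the treated direction only. The identification report is
the inner join of the significant set with the match report.

## Worked example

The glucose conjugate of sulfamethoxazole (SMX), end to end:

```r
library(metidscreen)

monoisotopic_mass("C6H10O5")      # glucose conjugation shift
#> [1] 162.0528

parents   <- read_parent_table()  # the six packaged parents
reactions <- cmp_reactions()      # the packaged 144-pathway library
smx <- parents[parents$id == "sulfamethoxazole", ]
glc <- reactions[reactions$label == "glucose conjugation", ][1, ]

cand <- apply_reaction(smx, glc)
cand[, c("id", "formula", "neutral_mass", "mz_pos", "mz_neg")]
#>                     id     formula neutral_mass   mz_pos   mz_neg
#> 1 Sulfamethoxazole-R63 C16H21N3O8S     415.1049 416.1128 414.0971

spec <- packaged_parent_spectra("positive")[["sulfamethoxazole"]]
syn  <- synthesize_tentative_spectrum(spec, cand)
syn
#> <ms2_spectrum> Sulfamethoxazole-R63 [M+H]+ precursor 416.11276, 4 peaks (tentative)
syn$peaks
#>         mz intensity
#> 1  92.0495        30
#> 2 108.0444        60
#> 3 156.0114       100
#> 4 254.0599       100
```

Reading the numbers: SMX ([M+H]⁺ 254.05994) plus the glucose delta
gives the conjugate precursor 416.11276; the synthesized spectrum
carries the three SMX fragment ions plus the SMX precursor itself as a
fourth fragment — the signature by which a glucoside reveals its parent.

Enumerating all sources and screening a table:

```r
cand <- enumerate_cmp(parents, reactions)       # 864 candidates, 6 x 144
lib  <- build_library(mz_cutoff_filter(cand, 800),
                      packaged_parent_spectra("positive"),
                      polarity = "positive")
cfg  <- pipeline_config(feature_table = "features.tsv",
                        sample_metadata = "metadata.tsv",
                        out_dir = "out")
res  <- run_pipeline(cfg)   # candidates, MSP library, matches, stats, report
```

A command-line wrapper with the same stages is installed at
`exec/metidscreen` (`predict`, `buildlib`, `run`, `simulate`, plus
`--config config.yaml` for structured configuration).

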