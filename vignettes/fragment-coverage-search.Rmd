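---
title: "Identifying histone marks from small MS/MS datasets by fragment ion coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying histone marks from small MS/MS datasets by fragment ion coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ficms)
```

## The problem

Histone post-translational modifications (PTMs) — lysine acetylation,
methylation, and the newer acyl marks such as lactylation (Kla),
crotonylation (Kcr), 2-hydroxyisobutyrylation (Khib) and benzoylation (Kbz)
— are identified by database searching of LC-MS/MS data. The standard
quality control for such searches is the target-decoy strategy: spectra are
searched against real protein sequences concatenated with their reversals,
and a score threshold is chosen so that the estimated false discovery rate
(FDR), the ratio of decoy to target matches above the threshold, stays
below a level such as 1%.

That estimate is a ratio of counts. After antibody enrichment, a histone-PTM
dataset often holds only dozens to a few hundred modified-peptide spectra,
and with so few observations the decoy and target score distributions
overlap heavily: a single well-scoring decoy forces the 1% threshold above
many genuine identifications, and which peptides survive becomes
essentially stochastic. `ficms` implements a search strategy tailored to
this regime, built around three ideas:

1. **Fragment ion coverage (FIC) replaces FDR as the acceptance
   criterion.** A peptide-spectrum match (PSM) is accepted when at least
   half of its theoretical b/y fragment ions are observed. For a peptide of
   length $n$ there are exactly $n-1$ b positions and $n-1$ y positions, so

   $$\mathrm{FIC} = \frac{\#\{\text{matched b/y positions}\}}{2(n-1)},$$

   and the default acceptance rule is $\mathrm{FIC} \ge 0.5$ (inclusive).
   A position counts once no matter how many charge states match, and only
   b/y ions enter either side of the fraction.

2. **Background variable modifications.** Histone peptides frequently carry
   several marks at once. Searching for a target PTM with lysine
   acetylation (ac) and lysine/arginine monomethylation (me1/rme1) as
   *background* variable modifications lets multiply modified peptides be
   identified at all; without them, a peptide bearing the target mark plus
   an acetyl is invisible because no candidate matches its precursor mass.

3. **Chimera dissection.** Positional isomers — identical sequence and
   modification multiset, different sites — co-elute and are co-isolated,
   producing chimeric spectra. Instead of rejecting these (their
   runner-up score gap collapses), the package tests each isomer
   independently: a member is co-reported when its own FIC clears the
   cutoff *and* at least one of its site-determining ions (theoretical ions
   matching no other member's ladder within tolerance) is observed.

## What the package computes

The pipeline is the classical one: FASTA → reversed decoys → in-silico
tryptic digestion → combinatorial enumeration of modified forms →
precursor-mass candidate lookup → b/y peak matching → ranking → FIC
filtration → confidence classification → site-level report. All stages are
exported individually; `run_pipeline()` ties them together.

```{r pipeline-sketch, eval = FALSE}
cfg <- run_config(fasta = example_fasta(), spectra = "spectra.mgf",
                  target_mod = "la", background_mods = c("ac", "me1", "rme1"))
run <- run_pipeline(cfg)
run$accepted   # coverage-filtered PSMs with confidence classes
run$sites      # one row per (protein, site, mark), mature numbering
```

### Ranking score

Candidate ranking is deliberately simple and fully deterministic: the rank
score is the number of matched fragment positions plus the explained
intensity fraction, with ties broken by explained intensity and then by the
lexicographic form key. The score exists to order candidates for one
spectrum, not to be comparable across spectra; acceptance is always the
coverage criterion. The delta score reported per PSM is the gap to the best
candidate that is *not* a positional isomer of it, so co-eluting isomers do
not erode each other's evidence.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `precursor_tol_ppm` | 10 | precursor mass window (ppm) |
| `frag_tol_ppm` | 40 | fragment matching window (ppm) |
| `fic_cutoff` | 0.5 | inclusive coverage acceptance threshold |
| `background_mods` | ac, me1, rme1 | background variable marks |
| `max_background` | 3 | background marks per peptide |
| `max_missed` | 4 | missed tryptic cleavages |
| peptide length | 5–35 | digestion length range |
| `fdr_level` | 0.01 | level for the *comparison* target-decoy filter |

The 10/40 ppm tolerances are standard for high-resolution instruments. The
generous missed-cleavage allowance reflects histone chemistry: tails are
K/R-rich and acylation blocks tryptic cleavage, so observable histone
peptides routinely span several nominal cleavage sites. For the same reason
the form indexer discards peptide forms whose C-terminal residue is a
modified lysine (trypsin could not have cut there), unless the peptide ends
at a protein C terminus; the filter is configurable off.

Modification deltas ship in `inst/extdata/modifications.tsv` (ac 42.01057,
me1 14.01565, me2 28.03130, me3 42.04695, la 72.02113, cr 68.02621, hib
86.03678, bz 104.02621 Da, each backed by an elemental composition and
validated against it at load time). Users may supply their own table, e.g.
to add N-terminal derivatization chemistry as an ordinary modification.

Two numerical points deserve mention. First, trimethylation and acetylation
differ by only 0.03638 Da; at 40 ppm they remain distinguishable for
fragments below roughly 900 m/z, and the matcher keeps them apart there (an
invariant covered by the test suite). Second, fragment charge states 1 to
min(precursor charge − 1, 2) are searched, but the FIC denominator is
always $2(n-1)$: the coverage fraction counts ions, not charge states.

## Enumeration of modified forms

`enumerate_forms()` generates every assignment of at most one modification
per eligible residue, with target marks unrestricted and at most
`max_background` background marks. The count is computed first by dynamic
programming; peptides whose form count would exceed a ceiling (default
10,000) raise a capacity error, which the indexer converts into a skip-with-
warning so one pathological K-rich peptide cannot stall a search. The
textbook example — a twelve-residue, two-acetylatable-site peptide with the
target mark fixed — enumerates to four forms, three of which carry an
acetyl:

```{r enumeration}
forms <- enumerate_forms("GSKKAVTKAQKK", background_mods = "ac",
                         fixed_mods = c("8" = "la"),
                         site_restrict = list(ac = c(4, 11)))
vapply(forms, format, character(1))
```

## The synthetic-data generator

No public raw files are required anywhere: `simulate_spectrum()` and
`simulate_dataset()` generate labeled test data. The generator emulates the
features the method actually depends on — b/y ladder peaks with
per-position Bernoulli dropout (retention probability `p`), optional +1
isotope companions, uniform noise peaks (deliberately allowed above the
precursor m/z so the confidence classifier's violation checks can be
exercised), precursor m/z derived from the form's neutral mass with
optional ppm jitter, and chimeric spectra as intensity-weighted unions of
two isomer ladders. It does *not* model real fragmentation propensities,
isotope envelopes beyond the first companion, co-isolation of
different-mass peptides, or retention-time structure beyond a simple
ladder. Passing tests therefore demonstrate the correctness of the
machinery and the claimed small-dataset properties, not instrument-level
performance on real chromatography.

Determinism is strict: each dataset draws every spectrum on its own RNG
substream derived from the dataset seed, so identical configurations give
byte-identical MGF output.

### The small-dataset benchmark

`benchmark_dataset()` builds the package's standard evaluation scenario: 30
scans per dataset, comprising 26 planted true modified peptides (7–20
residues, fragment retention p = 0.85, mild noise), one engineered
high-scoring decoy spectrum, and three decoy-confusable random-peak spectra
at decoy precursor masses. The engineered decoy is the complete ladder of
an unmodified decoy peptide of at least 25 residues; because rank scores
count matched positions, its 48+ matched ions necessarily outrank every
planted PSM, reproducing the score-overlap regime in which the decoy sits
at the top of the score list. With 26 targets, no cutoff can achieve a
decoy/target ratio of 1%, the threshold becomes unattainable, and FDR
filtration loses planted identifications — while every planted spectrum
that retained at least half of its ladder still clears the 50% coverage
criterion by construction. The dataset sizes (30 scans, 100 seeds in the
acceptance checks) were chosen to mirror the dozens-of-spectra regime the
method targets while keeping the whole evaluation desk-scale.

Truth accounting uses `same_identification()`: a reported PSM counts as the
planted one when sequence, target-PTM site assignment and neutral mass
agree. Monomethyl on a neighbouring lysine versus arginine is massless to
distinguish once the relevant site-determining ions have dropped out, and
the target site claim is unchanged, so such background-placement swaps are
not scored as losses.

## Validation machinery

`target_decoy_fdr()` implements the plain decoy/target ratio without a +1
pseudocount (set `pseudocount = 1` for the conservative variant), defining
FDR(s) as 0 when no decoy reaches s; q-values are the running minimum over
cutoffs. `roc_compare()` sweeps both strategies strictest-to-loosest (FDR
levels 1–100%, coverage cutoffs 100–0%) against truth labels and
`roc_dominates()` checks weak dominance. `cross_reference()` computes
cross-dataset loss rates: a union peptide form is *missed* in a dataset
only when that dataset shows a consistent precursor (10 ppm, and retention
time within 2 minutes of the other datasets' median when available) yet the
peptide was not identified; the loss rate is missed / (detected + missed).

`classify_confidence()` automates three screening checks on accepted PSMs:
(i) no prominent unmatched peak above the precursor m/z, (ii) at least half
of the ten most intense matched fragments show a +1 isotope companion at
1.00335/z spacing, (iii) no prominent peak beyond the largest matched
fragment. Peaks explainable as isotope companions of assigned fragments are
not held against the PSM. A PSM passing all three is flagged *high*,
otherwise *moderate*. These are prioritization flags, not verdicts — the
manual-scrutiny practice they approximate includes judgment the checks
cannot encode, and a correct identification over a genuinely chimeric or
noisy spectrum can legitimately land in the moderate class.

## Design choices made where the design was open

* **Inclusive 50% boundary** — a PSM with exactly half its ladder observed
  is accepted.
* **Any-charge-state matching** — a fragment position observed only at 2+
  counts as observed.
* **`min_rel_intensity = 0`** — any centroid can match; raise it for noisy
  data.
* **One modification per residue** — marks never stack on a single site.
* **Chimera membership needs one site-determining ion** — no minimum count
  beyond ≥ 1; groups where no member has a unique matched ion are reported
  with a site-ambiguity flag rather than dropped, preserving peptide-level
  evidence while withholding the site claim.
* **Chimera scope is exact isomers** — co-eluting different-mass peptides
  inside the isolation window are out of scope.
* **Initiator methionine** — Met-initiated proteins are digested both whole
  and Met-clipped, and all reported site positions use mature numbering
  (full-sequence position − 1 on Met-initiated proteins), the convention
  behind names like H3K9la; full-sequence coordinates are retained in the
  output.
* **Homologous-site merging across histone subtypes is not automated** —
  that is curation, not computation; subtypes are reported separately.

## Limitations

Scoring is coverage-based and intensity-light by design; it is not a
replacement for probabilistic scores on large datasets, where target-decoy
FDR remains the right tool. Neutral losses, a/c/z ions and immonium ions are
ignored throughout. Open (mass-offset) searching, semi-enzymatic digestion
and quantification are out of scope. The bundled FASTA contains four human
core histones for examples and benchmarks — real analyses should supply
their own database.
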