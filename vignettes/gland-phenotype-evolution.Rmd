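---
title: "Methods: gland phenotype diversity and clonal ancestry in Barrett's esophagus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gland phenotype diversity and clonal ancestry in Barrett's esophagus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(begland)
```

This vignette is the package's account of its methods: the models and
rules it implements, the parameters that matter and their defaults, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations.

## Phenotype classification

Barrett's glands are assigned to five phenotypes from the expression
states of six lineage markers. Each marker is scored `pos`, `low`, `neg`
or `na` (not assayed); `low` — weak but detectable staining — is treated
as expressed throughout, which is what makes a MUC5AC^low^/MUC2^+^ gland
specialized rather than mature intestinal. The rules, in order of
precedence:

| phenotype | rule |
|---|---|
| `ATROPHIC_CORPUS` | H+/K+-ATPase+ and pepsinogen+ |
| `OXYNTOCARDIAC` | H+/K+-ATPase+ and pepsinogen− |
| `CARDIAC` | MUC5AC+ and MUC2− |
| `SPECIALIZED` | MUC5AC+ and MUC2+ |
| `MATURE_INTESTINAL` | MUC5AC−, MUC2+, defensin positive or unassayed |

Parietal-marker rules come first: a H+/K+-ATPase-positive gland is gastric
by lineage and never receives a mucin label, whatever its mucin staining.
Design choices where the marker panel is genuinely ambiguous:

* **Defensins are one logical channel.** HD5 is only assayable on frozen
  tissue and HD6 only on FFPE, so they are alternatives, never both
  informative; either one positive makes the channel positive.
* **Mucins alone can call mature intestinal.** A MUC2+/MUC5AC− gland with
  both defensins unassayed is called `MATURE_INTESTINAL`; defensin
  positivity confirms the call rather than enabling it. An explicitly
  defensin-negative MUC2+/MUC5AC− gland matches no rule and is
  `UNCLASSIFIED`.
* **Contradictory profiles are flagged, not forced.** H+/K+-ATPase+
  together with MUC2+ describes no known gland; it returns `UNCLASSIFIED`
  with a warning.
* **Pepsinogen-unassayed parietal glands** default to `UNCLASSIFIED`
  (the panel cannot separate atrophic corpus from oxyntocardiac); setting
  `pepsinogen_na = "OXYNTOCARDIAC"` defaults the other way for panels
  where chief cells are excluded on morphology.
* **A mucin-positive gland whose partner mucin is unassayed** is
  `UNCLASSIFIED`: cardiac vs specialized (or specialized vs mature
  intestinal) cannot be separated.
* MUC6 is not part of the rule set; in practice it highlights gland bases
  rather than discriminating phenotypes.

The classifier is total and deterministic over the full 4^6 profile space
(property-tested), and `UNCLASSIFIED` is never counted as a phenotype.

## Diversity

For one specimen with phenotype counts `n_i` over the classified glands,
`p_i = n_i / Σ n_i`, richness is the number of phenotypes present, and the
Shannon index is `H = -Σ p_i ln(p_i)` in nats, with `0·ln 0 = 0`.
`UNCLASSIFIED` glands are excluded from the denominators: the five
phenotypes define the species set. `H` is `0` for a monophenotypic
specimen and at most `ln(richness)`; both bounds are tested to 1e-12.
Natural logarithms only; there is no base-2 option.

Group comparisons use the two-sided Mann-Whitney U test (exact null for
small samples without ties, normal approximation with tie correction
otherwise) and the tie-corrected Kruskal-Wallis test, via the standard
`stats` implementations behind a thin interface that also fixes the
degenerate all-tied case to `p = 1` (the underlying routines return `NaN`
there). P-values are reported raw, without multiplicity adjustment. The
primary comparison unit is the per-patient mean of per-specimen Shannon
values (patients are the independent units); `per_patient = FALSE`
switches to pooled per-specimen values, since either aggregation is
defensible when specimen counts per patient are unbalanced.

The bootstrap sampling-sufficiency analysis resamples glands with
replacement at a ladder of sample sizes (`n_reps = 1000` by default,
percentile 95% intervals) and reports the mean Shannon curve. Its purpose
is diagnostic: if the curve has plateaued by the number of glands actually
sampled, sampling more glands would not have changed the diversity
estimate. Two properties are worth knowing: the curve is nondecreasing in
sample size, and the plug-in Shannon estimator is biased downward, so at
the population size the bootstrap mean sits slightly below the population
`H`. All resampling flows from one user-supplied seed; there is no hidden
default seed, and stochastic operations refuse to run without one.

## Clonal inference from mtDNA variants

Somatic mitochondrial DNA mutations are used as neutral clonal marks: a
mutation observed at homoplasmy in two glands is far more plausibly
inherited from a common ancestral gland (fixed by niche succession and
spread by gland fission) than acquired twice independently.

Filtering, applied per case: (a) any variant also called in a stroma
sample of the same case is removed — stroma shares the germline, so this
subtracts polymorphisms and non-epithelial mutations; (b) variants on a
user-supplied known-polymorphism key list are removed (the list stands in
for a polymorphism-database comparison and may be empty); (c) in strict
mode (default), calls not confirmed by repeat PCR from the original DNA
are removed. Strict subtraction requires at least one stroma sample per
case; wild-type samples are represented by explicit placeholder rows so
that a sequenced-but-mutation-free sample is distinguishable from an
unsequenced one. Filtering is idempotent.

Variant identity for matching is `(position, alt)` for SNVs and deletions,
rendered `m.<pos><ref>><alt>`. Insertions in homopolymer tracts are keyed
at the region level (e.g. `MT-OHR:Cins` for a C-tract insertion in the
H-strand replication origin), because alignment cannot place an insertion
within a mononucleotide run.

Two samples are joined when they share at least one retained variant key
with each call homoplasmic or heteroplasmic at ≥ `het_threshold` (default
0.8). The threshold encodes "homoplasmic or highly heteroplasmic"; no
measured value constrains it, so it is a documented convention, exposed as
a parameter. Clones are connected components of this sharing graph within
a case (components via igraph; tests cross-check against a brute-force
transitive closure). A clone spanning ≥ 2 phenotypes yields an ancestry
statement listing the phenotype set and supporting variants. No direction
or ordering of phenotype transitions is inferred — shared variants
establish common ancestry, not which phenotype came first.

## The gland-fission simulator

`simulate_cohort()` is a forward model of one patient group generating the
exact table dialects the analysis consumes, plus ground truth (genealogy,
per-gland mutation events, true co-clonality). Per patient:

* A constant population of `glands_per_patient` glands (default 50) starts
  from founders; by default all founders are cardiac, the fulcrum
  phenotype from which the other types evolve.
* Each generation, each gland fissions with probability `fission_rate`
  (default 0.05). The daughter inherits the parent's mutations and
  phenotype and acquires `Poisson(mutation_rate)` new mutations (default
  2) at uniform positions on the 16,569-bp mitochondrial genome, each
  homoplasmic at birth (instant fixation; a heteroplasmic fraction is
  exposed but off by default). Each fission is balanced by the death of a
  random other gland — a Moran-style constant population, reflecting that
  the segment hardly changes size over time. The default fission rate is
  deliberately low: gland fission in adult gut epithelium is a rare event,
  and a low per-generation rate is also what keeps independent recurrence
  of the same variant negligible, which is the premise of the mtDNA
  clonal-mark method itself. Mutation positions are drawn with
  replacement — no infinite-sites assumption — so key collisions are
  possible in principle; with the default rates they are not observed
  (0 false merges in 200 replicate populations during development).
* Each generation, each gland switches phenotype with probability
  `transition_prob`, drawing the destination from a 5×5 row-stochastic
  transition matrix. The default matrix encodes the transitions for which
  clonal evidence exists (cardiac ⇄ specialized, cardiac ⇄ oxyntocardiac,
  oxyntocardiac ⇄ atrophic corpus, specialized ⇄ mature intestinal), with
  no numeric rates available to calibrate against. Mutations never
  influence transitions, fission or death (strict neutrality; tested).
* Biopsies sample disjoint sets of `biopsy_size` glands (default 8)
  uniformly from the final population. Marker profiles are the canonical
  profile of each gland's phenotype, so the classifier recovers the truth
  exactly. One stroma sample per patient carries only the patient's
  designated germline polymorphisms, which also appear in every gland —
  exercising both the stroma-subtraction and polymorphism-list filters.

`scenario_presets()` provides the four study groups. Cohort sizes follow
the study design (19/12/18/19 patients with 5/4/2/2 specimens each).
Transition probabilities are calibrated only to reproduce qualitative
behaviour, as no rates are measurable from the data: `nondysplastic` uses
0.005/generation, which yields roughly 70% single-phenotype, 30%
two-phenotype and rare three-phenotype biopsies; `predysplasia` and
`adjacent_dysplasia` use 0.08, giving markedly higher per-patient mean
diversity; `neo_be` uses 0 with a per-patient founder phenotype
(cardiac-dominant, occasionally specialized or atrophic corpus), so every
biopsy is monophenotypic — diversity in recently formed BE is absent and
must be acquired over time.

What the simulator does **not** emulate: spatial structure (biopsies
sample the population uniformly, not a contiguous neighbourhood, which if
anything overstates within-biopsy diversity), selection or driver
mutations, dysplasia onset, within-gland heteroplasmy drift, sequencing
error, and gland-level dropout. Passing tests on simulated cohorts
therefore validate the statistical machinery — classification, diversity,
filtering, clone recovery against known genealogy — not the biological
fidelity of any particular rate.

## Problem sizes and numerical choices

The test suite and analysis scripts run at desk scale, chosen as the
smallest sizes at which each property is meaningfully exercised: truth
recovery uses 20 replicate populations of 50 glands over 10 generations;
the type-I-error check uses 10,000 null replicates of two 15-sample
groups; scenario comparisons use 10 replicate cohort pairs at the preset
cohort sizes; bootstrap checks use 2,000–4,000 replicates. Monte Carlo
assertions use three-standard-error bands (or the stated acceptance band
for the type-I error rate). Exact identities (Shannon `ln k`, frequency
sums) are asserted to 1e-12. Ties in clone ids are broken automatically by
sorted sample id, so clone labels are order-invariant.

## Limitations

* The classifier is only as good as the marker calls; it deliberately
  refuses profiles the panel cannot separate rather than guessing.
* Shannon estimates from few glands are biased downward; the bootstrap
  curve diagnoses, but does not correct, under-sampling.
* Clone recovery is conservative: clone size is underestimated whenever a
  lineage carries no surviving mutation (recall is limited to pairs marked
  by at least one shared surviving variant), and the heteroplasmy
  threshold trades sensitivity against false sharing with no empirical
  calibration available.
* The simulator's rates are scenario conventions, not estimates; only the
  qualitative group ordering of diversity should be read off its output.
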