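---
title: "Trio variant triage and brain co-expression prioritization"
author: "trioTriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio variant triage and brain co-expression prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioTriage)
```

# Scope and model

`trioTriage` addresses candidate-gene discovery in small, phenotypically
ascertained trio-sequencing cohorts — the childhood apraxia of speech
setting is the motivating case — where cohort sizes preclude burden
statistics and discovery instead rests on (i) a strict deterministic
triage of each family's variants and (ii) orthogonal co-expression
evidence that surviving candidate genes act in the same developmental
brain programs as established disease genes.

The package deliberately separates three concerns:

1. **Deterministic triage** (`filterVariants`, `shortlistCandidates`):
   rule-based, exhaustively testable against brute-force re-evaluation.
2. **Stochastic evidence** (`monteCarloCoexpression`,
   `prioritizeGenes`): Monte-Carlo nulls whose calibration and power are
   themselves tested by simulation.
3. **Clinical judgement** (`applyReview`): ACMG classes and
   gene–phenotype consistency are *inputs* from expert review, never
   computed. The package only applies the tier rules to them.

# The triage cascade

Filters run in a fixed order and the attrition log names, per dropped
variant, the first rule violated; input count always equals kept plus the
per-reason drops.

| stage | rule (drop when) | default |
|---|---|---|
| site QC | non-PASS caller flag | — |
| | excess-heterozygosity Z | > 4.5 |
| | quality by depth QD | < 2 |
| | Fisher strand FS (SNV / indel) | > 60 / > 200 |
| | strand odds ratio SOR (SNV / indel) | > 3 / > 10 |
| | MQRankSum (SNV only) | < −12.6 |
| | ReadPosRankSum (SNV / indel) | < −8 / > −20 violated |
| genotype QC | read depth DP, any sequenced member | ≤ 10 (strict) |
| | genotype quality GQ | ≤ 20 (strict) |
| recurrence | identical allele in an unaffected member of another family | — |
| frequency | gnomAD allele count (dominant/de novo) | > 2 |
| | gnomAD allele frequency (compound het) | ≥ 0.05% |
| inheritance | inherited from an unaffected parent | — |

Three decisions here were genuinely open and are worth recording:

* **Missing QC metrics never drop a variant.** Only explicit flags and
  explicit threshold violations do; penalizing missingness would silently
  discard records from annotation sources that omit a metric.
* **Recurrence is cross-family only.** The "not carried by unaffected
  cohort members" rule is applied to *other* families; within the
  proband's own family, transmission from an unaffected parent is
  handled by the inheritance-consistency flag instead. Reading the rule
  family-internally would make every inherited candidate
  self-contradictory (clinically reported inherited variants from
  carrier parents do occur, e.g. on chromosome X).
* **X-linked relaxation.** Maternal transmission of a hemizygous allele
  to an affected male is treated as consistent even when the mother is
  unaffected: female carriers of X-linked alleles are frequently
  unaffected, so requiring an affected transmitting parent there would
  be wrong. Hemizygous de novo calls in males are reported as de novo +
  X-linked without parent-of-origin attribution.

Strictness is taken literally: DP > 10 means DP = 11 passes and DP = 10
fails. MQRankSum applies to SNVs only, matching the sentence structure of
GATK-style hard-filter recipes where the indel exceptions enumerate FS,
SOR and ReadPosRankSum.

# Deleteriousness rules

Predicted loss of function is the conjunction of a LoF consequence, a
LoF-intolerant gene (pLI ≥ 0.9 **or** LoFtool < 0.1), and damage evidence
(CADD Phred ≥ 20 **or** a splice-model score ≥ 0.6); frameshifts are
exempt from the third clause because CADD-style scores are poorly defined
for them. Predicted damaging missense counts four criteria — PolyPhen-2
probably/possibly damaging, SIFT deleterious (including low-confidence),
CADD ≥ 20, missense-tolerance-ratio FDR < 0.05 — and requires **at least
three**. The counting reading (rather than treating the list's final
"or" as a disjunction) is the only one under which "at least three" is
meaningful, and clinically reported damaging missense variants satisfy
exactly three. A missing annotation is a criterion *not met*, never a
free pass. Multi-transcript records collapse by the most-severe-transcript
rule: an allele qualifies if any overlapping transcript's consequence
qualifies, and the qualifying transcript is reported.

The two-stage shortlist searches the genes-of-interest union first and
falls back to a genome-wide, gene-agnostic search only in families where
the panels yield no reviewable candidate. Both stages use identical
classifier rules — relaxing gene-level intolerance genome-wide would
trade precision for recall in exactly the families with least
corroborating evidence.

# Co-expression statistics

All correlation is Spearman's ρ, computed as Pearson correlation of
average ranks; every downstream statistic is therefore invariant to
strictly monotone transforms of expression (tested bit-for-bit), which
makes the common log/RPKM-scale disputes irrelevant here.

* **Set statistic**: median |ρ| over the C(k, 2) unordered pairs of the
  gene set. Pairs with undefined ρ (constant expression) are excluded
  from medians and thresholds and counted.
* **Null**: `nIter` (default 5000) uniform same-size draws from the
  expression-eligible universe — genes detected in ≥ 50% of samples
  (floor configurable). Draws may overlap the observed set (excluding
  only its exact identity); excluding observed members would answer a
  subtly different question and the effect is negligible for small sets
  in genome-scale universes. The empirical p-value uses the add-one
  estimator (r + 1)/(n + 1), so p is never 0 and the resolution floor at
  4999 draws is 2 × 10⁻⁴.
* **Edge threshold**: the top-5% quantile (type-7) of |ρ| over gene
  pairs genome-wide, exact up to `maxPairs` pairs and estimated over a
  uniform without-replacement pair sample beyond that (method recorded).
  The threshold is always computed from the data at hand, never
  hard-coded.
* **Display order**: median-linkage (WPGMC) agglomeration on 1 − ρ, the
  conventional ordering for co-expression heatmaps; `stats::hclust` is
  the implementation and an independently coded Lance–Williams update
  serves as the test oracle.

# Connectivity prioritization

The connectivity of candidate gene *g* to seed set *S* is
Σ_{s∈S} |ρ(g, s)|, with self-pairs excluded — a deliberately simple,
monotone, decomposable score (it is exactly additive over disjoint seed
subsets). Where the historical analyses' exact score definition is not
public, this formula is a documented package choice, kept behind a single
function (`connectivityScore`) so an alternative can be swapped without
touching the testing or FDR machinery; the formula used is echoed in all
reports. Each candidate's score is compared against `nIter` uniformly
drawn eligible genes (one shared null per batch), and Benjamini–Hochberg
adjustment runs per batch — per region in CNV-region mode, over the
low-confidence list in variant mode — with prioritization at q < 0.1.
Null draws for regions come from the whole eligible universe; within-
region nulls would be degenerate for small regions.

# What the simulators emulate — and what they do not

`simulateCohort` plants causal variants that satisfy the full rule set
(clean QC, rarity, the requested inheritance pattern, classifier-passing
scores) and benign background variants each constructed to fail **exactly
one** named filter, with the failing filter recorded in the truth table —
uniform over failure modes, so every filter is exercised in every
sizeable cohort. `simulateExpression` draws log-scale multivariate
normals with equicorrelated blocks; the target within-block correlation
is interpreted on the Spearman scale and converted to the Gaussian scale
via r = 2 sin(πρ_s/6), then exponentiated to RPKM-like positive values
(a monotone transform, hence invisible to every statistic here).
`simulatePanels` builds panels whose cardinalities and redundant
membership count are hit exactly, e.g. sizes (81, 1399, 611, 131, 156)
with 233 overlaps giving a 2145-gene union.

These simulations validate the *machinery*, not biology: real cohorts
have linkage and recurrent artefacts rather than independent uniform
failure modes; real brain expression has donor structure, developmental
trajectories and heavy tails rather than exchangeable equicorrelated
samples (donor ids and stage labels are carried in metadata but samples
are generated independently). Passing tests therefore demonstrate
correctness and calibration of the methods under their stated
assumptions, not that any particular real gene set is co-expressed.

# Numerical and testing choices

Seeds fix every stochastic stage; identical configuration and seed give
byte-identical outputs, which the suite asserts at file level. Degenerate
inputs are defined rather than accidental: empty variant tables run to an
empty report; constant genes yield NA correlations that are excluded and
counted; singleton gene sets order trivially; a candidate identical to a
seed gene is an error, as is a compound-het plant in a non-trio family.
Tie-breaks in clustering follow `hclust`'s deterministic behaviour.

Test problem sizes were chosen as the smallest that make the statistical
assertions sharp: filter-oracle equivalence on 100 seeded 20-family
cohorts; classifier decisions on a 4000-point annotation grid against an
independent truth table; null calibration over 200 independent runs on
1000-gene × 100-sample matrices (type-I error in [0.02, 0.09] at
α = 0.05); power on 100 runs of an 18-gene block at Spearman 0.65 in a
5000-gene × 280-sample universe (p ≤ 0.01 in ≥ 95 runs); prioritization
sensitivity/false-positive rates over 50 seeded runs.

# Known limitations

* ACMG classification, annotation (VEP), alignment and calling are out
  of scope by design; the package consumes their outputs.
* The recurrence filter matches alleles exactly; equivalent indels with
  different normalizations are not unified.
* The eligible-universe rule for null draws is a configurable stand-in
  for dataset-specific preprocessing; its floor should be revisited for
  any real expression resource.
* Connectivity prioritization shares one null across a batch; candidates
  with wildly different missing-data patterns in ρ would deserve
  per-candidate nulls.
* Donor-level pseudoreplication in expression data is not modelled; with
  multiple samples per donor the Monte-Carlo null is anti-conservative
  to an extent the simulators cannot measure.
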