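# trioTriage

Candidate-gene discovery for trio genome sequencing studies of childhood
apraxia of speech (CAS) and related neurodevelopmental disorders.

Monogenic causes are found in roughly a quarter to a third of CAS
probands, but getting there requires a disciplined triage of millions of
variants per trio: hard quality filters, population-frequency filters,
inheritance-model reasoning, deleteriousness classification, and — because
single cohorts are too small for burden statistics — orthogonal evidence
that candidate genes behave like known disease genes, here their
co-expression in the developing human brain. `trioTriage` implements that
whole workflow as composable, tested R functions, together with seeded
simulators for every input it consumes, so the statistical behaviour of
each stage can be verified without access to private cohort data.

## What it computes

**Variant triage.** Site QC (drop when flagged by the caller's
recalibration, excess-heterozygosity Z > 4.5, QD < 2, and class-specific
strand/position biases: FS > 60, SOR > 3, MQRankSum < −12.6,
ReadPosRankSum < −8 for SNVs; FS > 200, SOR > 10, ReadPosRankSum < −20
for indels), genotype QC (DP > 10 and GQ > 20, strict, in the proband and
every sequenced relative), rarity (gnomAD allele count ≤ 2 for
dominant/de-novo models; allele frequency < 0.05% for compound
heterozygotes), cohort recurrence, and sex-aware inheritance inference
(de novo, inherited, homozygous recessive, X-linked, compound
heterozygous with phase from parental genotypes).

**Deleteriousness classification.** Predicted loss of function requires a
LoF consequence (frameshift, stop gained, start/stop lost, splice
acceptor/donor), a LoF-intolerant gene (pLI ≥ 0.9 or LoFtool < 0.1), and
damage evidence (CADD ≥ 20, or splice AdaBoost/random-forest ≥ 0.6);
frameshifts need only the intolerant gene. Predicted damaging missense
requires ≥ 3 of: PolyPhen-2 probably/possibly damaging, SIFT deleterious,
CADD ≥ 20, missense tolerance ratio deviating from 1 at FDR < 0.05.
Candidates are shortlisted in two stages — genes-of-interest panels
first, genome-wide only when the panels yield nothing — and tiered
(high/low confidence) from reviewer-supplied ACMG classes.

**Co-expression evidence.** For a gene set of size k, the statistic is
the median |ρ| over its C(k, 2) pairwise Spearman correlations across
developmental brain samples. Significance comes from a Monte-Carlo null of
uniform same-size gene draws with the add-one estimator
p = (r + 1)/(n + 1); edges above the genome-wide top-5% |ρ| quantile form
the co-expression network. Candidate genes (low-confidence variants,
genes inside CNV regions) are ranked by a connectivity score — the sum of
|ρ| to the implicated seed genes — against the same Monte-Carlo null,
with Benjamini–Hochberg control at FDR < 0.1.

## Worked example

```r
library(trioTriage)

planted <- list(
  list(family = 1, gene = "SETBP1", category = "lof", inheritance = "de_novo"),
  list(family = 2, gene = "DDX3X",  category = "lof", inheritance = "x_linked_de_novo"),
  list(family = 3, gene = "PURA",   category = "damaging_missense", inheritance = "maternal"))
sim <- simulateCohort(10, planted = planted, backgroundRate = 10, seed = 42)

res <- filterVariants(sim$variants, sim$pedigree)
table(ifelse(res$attrition$kept, "kept", res$attrition$reason))
#>        excess_het       filter_flag         frequency                fs
#>                 4                 1                20                 2
#>       genotype_qc       inheritance              kept       mq_rank_sum
#>                15                16                14                 1
#>                qd read_pos_rank_sum        recurrence               sor
#>                 1                 3                17                 4

panelSet <- GenePanelSet(list(speech = c("SETBP1", "DDX3X", "PURA", "FOXP2")))
shortlist <- applyReview(shortlistCandidates(res$pool, panelSet),
                         sim$review, res$pool)
shortlist[, c("family", "gene", "deleterious_class", "stage", "tier")]
#>   family   gene deleterious_class stage            tier
#> 1 FAM001 SETBP1               lof panel high_confidence
#> 2 FAM002  DDX3X               lof panel high_confidence
#> 3 FAM003   PURA damaging_missense panel high_confidence
```

The three planted causal variants — and nothing else — survive the
cascade at high confidence; every benign background variant is dropped at
the filter it was constructed to fail (attrition above), giving a 3/10
(30%) diagnostic yield for this toy cohort.

```r
blocks <- c(rep(1L, 18), rep(0L, 1982))
em <- simulateExpression(2000, 280, moduleAssignments = blocks,
                         withinBlockCorrelation = 0.65, seed = 7)
analyzeCoexpression(em, rownames(em)[1:18], nIter = 5000, seed = 7)
#> CoexpressionResult for 18 genes
#>   median |rho| = 0.6618 over 153 pairs
#>   Monte-Carlo p = 2e-04 ( 5000 draws, seed 7 )
#>   edge threshold |rho| >= 0.1174 : 153 edges
```

An 18-gene module planted at within-block Spearman 0.65 across 280
developmental samples is detected at the resolution floor of 5000 draws
(p = 2×10⁻⁴), with all 153 pairs above the genome-wide top-5% edge
threshold.

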