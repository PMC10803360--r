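---
title: "Individual identification and population genetics from SNP-genotyped scats"
author: "scatID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual identification and population genetics from SNP-genotyped scats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatID)
```

## The problem

Faecal DNA lets a monitoring program "capture" individuals of an elusive
species without ever handling them: each scat carries a multilocus
genotype that works as a permanent molecular tag. The catch is data
quality. Scat DNA is degraded and dilute, so calls go missing
(amplification failure) and heterozygotes are miscalled as homozygotes
(allelic dropout, ADO). A usable identification pipeline therefore needs
(i) a small panel of highly informative SNPs, (ii) a clustering rule that
tolerates a known error budget while still separating genuine
individuals, and (iii) diagnostics that justify where the line was drawn.
scatID implements that pipeline end to end, together with molecular
sexing from qPCR signals, consensus genotypes, population-genetic
summaries, and a truth-known simulator so every stage can be validated
offline.

## Panel design

`applyFilterCascade()` reduces a reduced-representation discovery set
(tens of thousands of candidate SNPs with DArT-style per-locus metadata)
to array-ready loci in thirteen fixed steps: single-SNP tags, tag length
(>= 50 bp), SNP position within the tag (25-45, leaving primer room),
mean read depth (5-200), locus and individual call rates (>= 0.8),
allele depth balance (alt fraction 0.2-0.8), reproducibility (> 0.95),
paralog removal by tag-sequence similarity, observed heterozygosity
(0.2-0.5), minor allele frequency (0.3-0.5), an exact Hardy-Weinberg
test, and LD pruning. Counts are order-dependent, so the `FilterReport`
records attrition per step in the order applied.

Numerical choices worth knowing:

* **Allele depth balance** is implemented as the alt/(ref+alt) mean-depth
  fraction — the only reading of "read depth difference ratio" that is
  bounded in [0, 1] and matches the printed 0.2-0.8 window.
* **Paralogs**: tags closer than 0.25 normalized Hamming distance (over
  the shared prefix for unequal lengths) are treated as one cluster and
  the later locus dropped.
* **HWE** uses the exact conditional (Levene) distribution of
  heterozygote counts given allele counts; the p-value sums all outcomes
  no more probable than the observed one. Multiple testing defaults to
  Bonferroni at alpha = 0.05 — deliberately conservative, matching a
  step that removes almost nothing from equilibrium data.
* **LD pruning** computes the squared genotypic correlation on
  pairwise-complete samples and greedily removes the later locus of any
  pair with r² > 0.2 (no threshold is standard; 0.2 is the conventional
  conservative choice and is configurable). Monomorphic loci have no
  defined correlation; they are flagged and left untouched.
* The cascade is idempotent on complete-call data. With missing calls an
  individual sitting exactly at the call-rate floor can flip when step 6
  re-runs on a shrunken locus set; this boundary effect is inherent to
  rate thresholds, not an implementation artefact.
* Two information filters sit mathematically *at* a boundary: a locus
  with MAF near 0.5 has expected heterozygosity at the 0.5 ceiling of
  the het window, so roughly half of such loci are trimmed by sampling
  noise alone. That is the filter working as printed, and it is why the
  heterozygosity step removes so many otherwise-informative loci.

`pidCurves()` sizes the panel: per locus, the probability two unrelated
individuals share a genotype is
$P_{ID} = \sum_i p_i^4 + \sum_{i<j}(2p_ip_j)^2$, and for full siblings
$P_{IDsib} = 0.25 + 0.5\sum p_i^2 + 0.5(\sum p_i^2)^2 - 0.25\sum p_i^4$.
Cumulative products over the panel identify the smallest prefix below
the 1e-4 threshold (exclusion probability 99.99%).

```{r pid}
set.seed(1)
pc <- pidCurves(runif(50, 0.3, 0.5))
pc
```

With panel-grade frequencies (MAF 0.3-0.5) about 10 loci separate
strangers and about 19-20 separate full siblings, which is why an
identification panel of ~47 SNPs leaves ample redundancy for missing
calls. `subsetDiversity()` addresses the complementary question — how
many loci stabilise diversity estimates — by re-estimating Ho/Hs/F~IS~
over random locus subsets (500 permutations by default) and reporting
the permutation spread.

## Identifying individuals from noisy scats

The identification chain is `cleanMatrix()` →
`pairwiseMismatches()` → `upgmaTree()` → `cutGroups()`, with
`elbowCurve()`, `heatmapOrder()` and `misassignmentModel()` as the
supporting diagnostics, and `runStepOne()` wrapping the lot.

**Cleaning.** Completely failed samples are set aside first; then locus
and sample filters alternate to a fixed point (loci < 0.8 amplification
on current samples, samples < 0.9 on current loci — both configurable;
the source texts disagree on which threshold belongs to which axis, so
the defaults follow the result actually used and both are parameters).
Cleaning matters twice over: poor scats carry more missing calls *and*
more dropout, so removing them concentrates the error budget.

**Dissimilarity.** For each sample pair, mismatches are counted on loci
called in both samples as the absolute difference of 0/1/2 codes —
allele-level counting, so het vs hom is 1 and opposite homozygotes are
2. Counts are deliberately not normalised by shared loci: the cut
height is then directly "number of allele mismatches". Pairs sharing no
locus are flagged and pushed to maximal dissimilarity.

**Clustering.** Average linkage (UPGMA) on raw mismatch counts, with a
deterministic lowest-leaf-index tie-break, returned as a standard
`hclust` object. Merge heights are non-decreasing for this
dissimilarity, so cutting at height h keeps exactly the merges at
mismatch <= h.

**Choosing h.** Three views on the same question — where does
genotyping error end and biological variation begin:

1. the elbow curve (groups vs h) should plateau at the true individual
   count;
2. the heat map in dendrogram order should show tight diagonal blocks;
3. `misassignmentModel()` fits binomials to within-group and
   between-group mismatch counts (n = 2 × median loci compared) and
   reports the overlap of the within 0.995 quantile with the between
   0.005 quantile — non-zero overlap means scats can plausibly be
   misassigned at this h.

```{r step1}
cfg <- simulationConfig(seed = 42, nIndividuals = 20)
sim <- simulateScats(simulateTruth(cfg), cfg)
s1 <- runStepOne(sim$genotypes, sampleMin = 0.9, locusMin = 0.8, h = 1)
s1$nIndividuals
s1$misassignment
```

**Error budget.** `adoRate()` estimates dropout from replicate pairs as
the fraction of heterozygous comparisons that disagree (het-vs-hom
discordant loci over co-called loci with at least one het call).
`errorBudget(ado, nLoci)` turns that into the expected within-individual
mismatch scale (0.025 × 47 ≈ 1.2), the arithmetic behind accepting h = 1.
Strictly, only heterozygous loci can drop out, so the realised
within-individual expectation is closer to ado × nLoci × Ho — the budget
is a deliberate upper bound.

A known limitation, visible in simulation: average linkage chains. If
one individual contributes two scats that each carry a dropout at a
*different* locus, those scats sit 2 mismatches apart; once the first
has joined the clean cluster, the second's average distance is
(g+2)/(g+1) > 1 and it splits off at h = 1. At a cleaned dropout rate of
0.003 over 47 loci this oversplits roughly one individual in every
ten simulated studies. The identical behaviour arises from
`stats::hclust` + `cutree`, so it is a property of the published method,
and it is the reason identification counts from scats are best read as
*minimum* counts.

## Molecular sexing

Endpoint qPCR signals for two Y-linked markers (DDX3Y, SRY; Zfy is
accepted but never required) and the X-linked control Zfx. A marker
amplifies successfully at RFU >= 50; a sample is male when the X control
works, at least one Y marker works, and max(Y)/Zfx > 0.1; female when
the X control works without such Y evidence; no call when the control
fails (a Y signal over a dead X control is flagged as possible
contamination). The max over Y markers is used because dropout censors
signals downwards. At the individual level, two or more agreeing
successful samples confirm a sex, a single success or a strict majority
gives a "likely" call, and ties or silence stay undetermined; up to
three samples per individual are consulted (the assay's budget).
`sexRatio()` reports males per female, excluding undetermined animals.

## Population genetics

On consensus genotypes (`consensusGenotypes()`: per-group majority call,
ties going missing), `diversityStats()` reports observed heterozygosity,
Nei's unbiased gene diversity $H_s = \frac{2n}{2n-1}\,2p(1-p)$, allelic
richness rarefied to the smallest per-locus sample of gene copies
(hypergeometric expectation), and $F_{IS} = 1 - H_o/H_s$, with means and
standard errors across loci. `ritlandRelatedness()` implements the
Ritland (1996) frequency-weighted moment estimator: per biallelic locus
$\hat r_\ell = 2\left(\sum_i \frac{x_i y_i}{p_i} - 1\right)$ with $x_i,
y_i$ allele dosages scaled to [0, 1], combined across loci with weights
(alleles − 1). Its expectation is 1 for clones, 0.5 for first-order kin,
0.25/0.125 for second/third order and 0 for strangers. Frequencies
default to being estimated from the supplied individuals (no external
reference panel existed); an external frequency vector is accepted, and
loci fixed in the reference are skipped with a warning.

```{r ritland}
cfgR <- simulationConfig(seed = 7, nLoci = 114, nIndividuals = 0,
                         dyads = c(clone = 200, parent_offspring = 200),
                         scatsPerIndividual = 1)
tr <- simulateTruth(cfgR)
r <- ritlandPairs(GenotypeMatrix(trueGenotypes(tr)),
                  truthDyads(tr)[, c("id1", "id2")],
                  freqs = trueAlleleFreqs(tr))
tapply(r, truthDyads(tr)$type, mean)
```

## The simulator and what passing tests mean

`simulateTruth()` / `simulateScats()` generate the study the other
modules expect: biallelic loci with alternative-allele frequency uniform
on the panel window [0.3, 0.5]; founders in Hardy-Weinberg proportions;
pedigreed dyads (unrelated, parent-offspring, full-sib, half-sib, clone)
by Mendelian transmission from hidden parents; per-scat amplification
quality Beta(2, 18) (mean 0.90 amplification with the long lower tail
seen in real collections, range stretching to ~0.5); allelic dropout at
a configured rate of 0.025 by default (the raw replicate-pair estimate
of a well-performing array); optional false alleles (default 0 — array
platforms essentially do not produce them); ~10% of scats re-genotyped
as replicate pairs sharing their original's DNA quality; sexes at a 1:1
ratio across seven roosts; and qPCR signals of N(300, 50) for a present
chromosome, N(5, 5) for an absent Y, with marker-level failure tied to
scat quality.

Two modelling decisions deserve emphasis:

* **Dropout scale.** The config's `adoRate` is defined on the
  *measurement* scale: it is what `adoRate()` recovers from replicate
  pairs. Internally each heterozygous call becomes a random homozygote
  with probability eps/(2−eps), which makes the two-sided discordance
  estimator unbiased for eps. Parameterising on the estimator's scale is
  what allows published rates (which are themselves replicate-pair
  estimates) to be plugged in directly.
* **Quality-linked dropout.** Unless a fixed `missingProb` is given,
  each scat's dropout rate scales with the cube of its realized missing
  fraction (normalized by the exact beta-binomial moment so the pooled
  estimate still recovers `adoRate`). This reproduces the empirical
  signature of degraded DNA: dropout negatively correlated with
  amplification, a raw pooled rate near 0.025, and a collapse to ~0.003
  once cleaning removes the low-amplification scats. With a fixed
  `missingProb` the link is off and every scat uses `adoRate` —
  the controlled mode used for calibration tests.

What the simulator does *not* emulate: genotyping chemistry (no
locus-specific failure profiles, no null alleles), cross-contamination
between scats, within-individual sampling correlation beyond shared
scat quality, and linkage between loci. Passing tests therefore show
the algorithms are correct under the stated error model, not that any
particular field dataset will be as well behaved.

Test problem sizes were chosen to keep the full suite within a few
minutes on one CPU while leaving Monte-Carlo error well inside the
asserted tolerances: clustering oracles run exhaustively to 7 leaves,
the exact-HWE oracle enumerates all tables to n = 6 plus larger spot
checks, dyad recovery uses 1,000 dyads at 114 loci, and the end-to-end
recovery experiment uses 100 seeded studies of 125 scats from 20
individuals.

## Known limitations

* Average-linkage chaining can oversplit error-bearing scats at h = 1
  (see above); counts are minimum counts.
* Cleaning thresholds interact badly with data whose mean amplification
  sits exactly at the sample threshold (half the scats are then removed
  by coin-flip); inspect the cleaning log rather than trusting defaults
  blindly.
* The misassignment model pools all pairs into a single binomial per
  side with n = 2 × median loci compared; heavy variation in shared-locus
  counts between pairs will blur its quantiles.
* Effective population size, capture-mark-recapture abundance and
  ordination are out of scope; export the consensus VCF and use the
  dedicated tools.
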