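# scatID

Individual identification and population genetics from SNP-genotyped
scats.

Non-invasive genetic monitoring "captures" animals through the DNA in
their droppings: each scat carries a multilocus genotype that acts as a
permanent molecular tag, so roost use, movements, sex ratios and
relatedness can be surveyed without ever handling a bat (or bear, or
otter). scatID is an R toolkit for the full workflow around targeted SNP
panels on degraded faecal DNA, written for wildlife geneticists running
such programs:

* **Panel design** — a thirteen-step filter cascade from
  reduced-representation (DArT-style) SNP metadata to array-ready loci
  (single-SNP tags, tag length, SNP position, read depth, call rates,
  allele-depth balance, reproducibility, paralog similarity,
  heterozygosity, MAF, an exact Hardy–Weinberg test, LD pruning), plus
  probability-of-identity panel sizing and subset-diversity evaluation.
* **Individual identification** — amplification-rate cleaning, pairwise
  allelic mismatch counts, average-linkage (UPGMA) clustering with a cut
  height *h* in mismatch units, and the diagnostics that justify *h*:
  elbow curve, ordered heat map, and a binomial misassignment model.
* **Error rates** — allelic dropout estimated from replicate pairs, and
  the mismatch error budget (ADO × loci) it implies.
* **Molecular sexing** — decision rules over qPCR RFU signals for
  Y-linked (DDX3Y, SRY) and X-linked (Zfx) markers.
* **Population genetics** — consensus genotypes with VCF 4.2 export,
  Ho / unbiased Hs / rarefied allelic richness / F_IS, and Ritland
  pairwise relatedness.
* **Simulation** — a truth-known generator of whole scat studies
  (pedigreed dyads, per-scat quality, quality-linked dropout, replicate
  pairs, sexing signals) so every stage is testable offline.

## The statistics at the core

For a biallelic locus with allele frequencies \(p_i\), the probability
that two random unrelated individuals — or two full siblings — share a
genotype is

> P_ID = Σ p_i⁴ + Σ_{i<j} (2 p_i p_j)²,
> P_IDsib = 0.25 + 0.5 Σ p_i² + 0.5 (Σ p_i²)² − 0.25 Σ p_i⁴,

and the cumulative product over loci sizes the panel (threshold 10⁻⁴).
Scats are grouped by the number of allelic mismatches over co-called
loci (|0/1/2 code difference|, so opposite homozygotes count 2) under
average linkage; within-group and between-group mismatch counts are
modelled as binomials with n = 2 × median loci compared, and the overlap
of the within 0.995 and between 0.005 quantiles measures misassignment
risk at the chosen cut. Allelic dropout is the fraction of heterozygous
replicate comparisons that disagree. Pairwise relatedness uses the
Ritland (1996) frequency-weighted moment estimator, r̂ = 2(Σ x_i y_i /
p_i − 1) per locus (expectation 1 for clones, 0.5 for parent–offspring
or full sibs, 0 for strangers).

## Worked example

Simulate a survey of 20 bats (about 195 scats incl. replicates on a
47-SNP identification panel), identify individuals, and summarise:

```r
library(scatID)

cfg <- simulationConfig(seed = 42, nIndividuals = 20)
sim <- simulateScats(simulateTruth(cfg), cfg)
sim$genotypes
#> GenotypeMatrix: 195 samples x 47 loci; 18 replicate links; 10.4% missing calls

s1 <- runStepOne(sim$genotypes, sampleMin = 0.9, locusMin = 0.8, h = 1)
s1$nIndividuals
#> [1] 20
s1$misassignment
#> MisassignmentModel: n = 86 allele trials
#>   p(within) = 0.000815  p(between) = 0.365
#>   0.995 within quantile = 1 ; 0.005 between quantile = 20
#>   overlap width = 0 ; misassignment mass = 0.00232

s2 <- runStepTwo(s1, rfu = sim$rfu)
s2$diversity$summary
#>   stat       mean          se
#> 1   Ho 0.46382979 0.018293408
#> 2   Hs 0.47272231 0.006133857
#> 3    A 2.00000000 0.000000000
#> 4  Fis 0.01708434 0.036915643
s2$sexRatios
#> confirmed       all
#>       0.8       0.8
```

Cleaning kept the high-quality scats, the 20 simulated bats were
recovered exactly, the within-group mismatch distribution is cleanly
separated from the between-group one (overlap width 0 at h = 1), and
diversity across the panel-design MAF window comes out near Ho ≈ 0.46
with no inbreeding signal, as drawn. `runProject()` drives the same
chain from a YAML file of CSV paths and writes the group table,
diagnostics, diversity/relatedness tables and a consensus VCF.

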