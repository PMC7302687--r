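---
title: "Designing and deploying a GT-seq SNP panel with gtpanel"
author: "gtpanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and deploying a GT-seq SNP panel with gtpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtpanel)
```

# The problem

Managing invasive rats on island archipelagos needs two questions
answered fast for every trapped animal: *which species is it* (brown rat,
*Rattus norvegicus*, or black rat, *R. rattus*) and *which island
population did it come from*. Reduced-representation sequencing (ddRAD)
answers both, but its cost and turnaround do not scale down to the one or
two animals a novel incursion typically yields. Genotyping-in-Thousands
by sequencing (GT-seq) — a multiplexed amplicon assay of a few hundred
SNPs — does, provided a well-designed panel exists.

`gtpanel` implements the full design-and-deployment cycle as a reusable
toolkit: starting from a population-scale ddRAD genotype matrix it
designs an optimized amplicon panel, QCs and genotypes the amplicon
sequencing output, and performs species identification and
source-population assignment of unknown individuals. A synthetic
archipelago simulator makes every stage testable without any external
data.

# Data model

The central container is `GenotypeExperiment`, a
`SummarizedExperiment` with loci as rows and individuals as columns.
Genotypes are biallelic-coded — 0 (hom-reference), 1 (het), 2
(hom-alternate), `NA` (missing) — because every downstream statistic
needs only allele counts; phase is discarded. An optional `depth` assay
carries per-cell read depth. Sample metadata (species, island
population, genotyping method, technical-replicate group) and locus
metadata (genomic position, RADtag id, 1-based SNP offset within the
RADtag, alleles) ride along as `colData`/`rowData`, and every output
references ids, never indices, so input order is free.

```{r quick-look}
cfg <- simConfig(seed = 42, n_loci = 300, n_per_pop = 10)
ge <- simulateGenotypes(cfg)
ge
```

# Candidate-locus filtering

`applyFilterCascade()` serializes the quality filters into one fixed,
fully logged order:

1. overall call rate **strictly above** 0.90;
2. overall minor-allele frequency **at least** 0.05;
3. overall observed heterozygosity **at most** 0.50;
4. one SNP per RADtag (to curb within-tag linkage);
5. variable (MAF > 0) in at least one species;
6. call rate strictly above 0.90 in *each species separately*;
7. mean depth of at least 6x in each species separately;
8. SNP offset within 40–60 bp of the RADtag start (so enough flank
   remains for primer design).

Comparison directions follow the stated rules literally: "more than
90%" is a strict inequality, the MAF, depth and heterozygosity bounds
are inclusive, and the 40–60 bp window is taken inclusive at both ends
(the boundary convention is not otherwise determined; inclusive was
chosen once and is configurable). When a RADtag carries several SNPs the
kept one is the highest-call-rate SNP, ties broken by higher MAF and
then smaller offset — any single choice is statistically equivalent
under within-tag linkage, so the rule is chosen purely for determinism.
Stage order affects only per-stage attribution, not the final set, for
the per-locus predicates; this is asserted by a test. If the object has
no depth assay, stage 7 is skipped with a warning rather than silently
passing loci. Every stage logs its removals, and the report satisfies
`|in| = |out| + removals` at each stage; the cascade is idempotent.

One subtlety: stage 5 deliberately removes loci that are *fixed between
the species* (monomorphic within each), because such loci carry no
within-species information. Those same loci are the best
species-diagnostic markers, so `designPanel()` builds the diagnostic
candidate pool with a second pass in which stage 5 is disabled (all
quality stages still apply). Species-informative and species-diagnostic
candidacy therefore use the same quality bar but different variability
requirements.

# Differentiation and ranking

Per-locus differentiation is measured with the Weir–Cockerham unbiased
estimator θ, computed from the among-population (a),
among-individual-within-population (b) and within-individual (c)
variance components for every unordered pair of island populations, plus
one species-vs-species contrast per locus that pools each species into a
single deme. θ = a/(a+b+c) is left as `NA` and flagged whenever the
denominator is zero (the locus is monomorphic across the pair) — never
silently zero — and negative estimates are retained unclamped, since
ranking needs only order. Fixed differences attain θ = 1 at any sample
size, and identical demes give θ ≤ 0; both are asserted by tests against
an independent transcription of the component formulas.

Each species' candidates get a single discriminatory-power score,
the **maximum** pairwise θ among that species' population pairs
(default; the mean is available via `score_method = "mean"`). The
maximum targets worst-case pair discrimination — a locus that separates
at least one pair of islands very well is more useful to an assignment
panel than one that is mediocre everywhere. Loci with no defined
pairwise θ in a species are excluded from that species' ranking, not
scored zero.

For summarizing differentiation across loci, `thetaMultilocus()`
combines loci the way the estimator's authors recommend — the ratio of
summed components Σa / Σ(a+b+c) — because the arithmetic mean of
per-locus ratios is biased downward at realistic sample sizes
(a Jensen effect of order 0.02 at 50 diploids per deme), whereas the
component-sum ratio is consistent; the simulator-recovery tests assert
the latter.

# Panel selection

`selectPanel()` assembles the putative panel from three ingredients:

* **Spacing pruning.** To keep panel loci in approximate linkage
  equilibrium, no two retained candidates on the same chromosome may be
  closer than 1 Mb. Candidates are visited in descending score order and
  a candidate is dropped when it falls within 1 Mb of an already-kept
  locus, recording the retained locus it conflicted with. This greedy
  rule guarantees two properties that an iterative closest-pair removal
  cannot: every removed locus has a *retained* conflicting neighbour
  whose score is at least its own, and the result is independent of
  input order. Score ties break lexicographically by locus id.
* **Top-K per species.** After pruning, the 350 highest-scoring loci per
  species are retained. Selection is sequential with exclusion (brown,
  then black from the remainder), so a locus that ranks for both species
  is used once and the panel reaches the full 2 × 350 whenever supply
  suffices; each panel entry carries exactly one role.
* **Species diagnostics.** Eight additional loci with the highest
  between-species θ, preferring θ = 1 fixed differences, drawn from the
  quality-filtered diagnostic pool and excluding anything already
  selected. Diagnostics need not be fixed differences — the criterion is
  the between-species θ ranking.

With default configuration and ample supply the panel is exactly
708 SNPs. The 1 Mb constraint is enforced within each species'
informative set (each species' loci are co-amplified and co-analysed as
one set); cross-role pairs are not constrained.

# Amplicon QC and genotype calling

Deployment starts from per-sample, per-locus allele read counts
(`AmpliconCounts`), plus library-wide per-locus diagnostics.
`cullLoci()` removes, in a fixed attribution order (each locus removed
once, first matching rule wins):

1. loci holding **more than 1%** of the library's total forward-primer
   reads (over-amplifiers that starve the rest of the multiplex);
2. loci whose PCR-artifact reads exceed **1%** of that locus's total
   reads (a library-wide denominator is available via
   `artifact_denominator = "library"`);
3. one locus per primer hetero-dimer pair — the member with the greater
   forward-primer share, the greedier primer being the likelier driver
   of the interaction (ties drop the lexicographically later id).

`callGenotypes()` is an allele-ratio caller: with on-target depth below
10 reads the cell is missing; otherwise the minor-allele read fraction
*m* calls a homozygote for the majority allele when *m* < 0.10, a
heterozygote when *m* ∈ [0.20, 0.80], and leaves the ambiguity gap
between the two as missing rather than forcing a call. These ratio
thresholds are pipeline-level defaults, all exposed in `qcConfig()`.
Calls are invariant to scaling both allele counts, and on counts
simulated at depth 100 with 0.5% allele error the caller recovers more
than 99% of true genotypes. Finally `dropFailedSamplesAndLoci()`
removes loci that never genotyped and *then* samples missing more than
50% of the remaining loci (strict; a sample at exactly 50% is kept) —
dead loci are dropped first because doing so can legitimately rescue a
borderline sample.

# Validation metrics

`crossMethodDiscordance()` aligns ddRAD and GT-seq calls of the same
individuals by sample and locus id and reports the fraction of
doubly-called cells that disagree; cells missing in either dataset are
excluded from numerator and denominator alike, and any mismatch counts
as one discordant cell (no het/hom weighting — a single percentage is
reported). `replicateError()` applies the same convention within
technical-replicate groups, using all pairs in groups larger than two,
and pools numerators and denominators for the overall rate (robust to
unequal per-pair denominators) while also reporting per-pair rates.

# Species identification and population assignment

**Bayesian assignment.** `assignPopulations()` implements the
Rannala–Mountain genotype likelihood: reference allele counts per
population define a posterior-predictive genotype probability under a
Dirichlet prior with 1/K per allele (K = 2 here), so for counts
*n* of allele *a* among *m* gene copies,
P(aa) = (n + ½)(n + 3∕2) / ((m + 1)(m + 2)) and
P(ab) = 2(n_a + ½)(n_b + ½) / ((m + 1)(m + 2)).
An individual's log-likelihood per population sums over its called loci
only (partially genotyped GT-seq individuals are handled naturally),
posteriors use a uniform prior over populations, and normalization
subtracts the maximum log-likelihood before exponentiating for numerical
safety. With leave-one-out (the default for individuals present in the
reference), the individual's own two gene copies are subtracted from its
population's counts before evaluation; the bookkeeping is asserted by a
counting test. Reference populations can be pooled (e.g. two islands
known to exchange migrants) with `buildReference(..., merges = )`.

**Projected PCA.** `fitReferencePCA()` standardizes reference genotypes
per locus by the mean genotype and √(p(1−p)) with *p* the reference
allele frequency, mean-imputes missing cells, drops
monomorphic-in-reference loci, and eigendecomposes by SVD.
`projectSamples()` maps new samples onto the *fixed* eigenvectors by
least squares over each sample's called loci: a complete sample projects
exactly to Vᵀz, and masking 30% of a sample's genotypes moves its score
only modestly (tested against a least-squares oracle). No shrinkage
correction is applied to projected samples; plain least-squares
projection is used, a difference immaterial for reading cluster
membership, which is the use here. The intended workflow for novel
invasions is two-step and user-driven: project against all references,
identify the regional cluster, then re-run restricted to that region.

**DAPC.** `dapcClassify()` reproduces the discriminant-analysis-of-
principal-components construction for species assignment: PCA on the
labelled reference, components retained to 90% cumulative variance
(capped at a third of the reference sample count — the standard guard
against overfitting the discriminant space), linear discriminant
analysis on the retained scores, and new samples projected and scored in
the same space. With a handful of fixed inter-species loci the class
posteriors are effectively 0/1.

# The simulator

`simulateGenotypes()` emulates the study system the panel targets: two
species, each structured into island populations, genotyped at
ddRAD-like biallelic SNPs. Per species, each locus draws an ancestral
allele frequency from Uniform(0.05, 0.95) and each island draws its
frequency from the Balding–Nichols Beta distribution at the target
F~ST~ — chosen over coalescent machinery because it gives direct,
per-species control of differentiation at desk scale with no external
simulator. Genotypes are Binomial(2, p) within islands
(Hardy–Weinberg), a configurable set of diagnostic loci is fixed
hom-ref/hom-alt between the species, positions are uniform over 20
chromosomes of 150 Mb (a rat-scale genome), each locus sits on its own
RADtag with an offset uniform on 1–90 bp (100 bp reads), missingness is
Bernoulli per cell, and technical replicates are exact pre-missingness
copies with independent missingness plus an optional per-genotype flip
rate for exercising nonzero replicate-error reporting. Defaults — three
islands per species, 20 diploids per island, 2000 loci, F~ST~ 0.1, 3%
missingness, depth 100, 0.5% allele error — are fixed study conditions,
not tuning knobs. `simulateAmpliconCounts()` layers the GT-seq failure
modes on top: Poisson depth, binomial allele sampling with error,
dropout at missing genotypes, and designated over-represented,
artifact-heavy and hetero-dimer loci for the QC stage to find.

What the simulator does *not* emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium between loci
(loci are independent, so the 1 Mb spacing rule is exercised only
geometrically), admixed or migrant individuals, batch and DNA-quality
effects on missingness (which is completely at random here), allele
dropout correlated with genotype, and ascertainment bias of the
candidate SNPs themselves.

# Problem sizes and numerical choices

The shipped tests run the estimator-recovery check at 500 loci and 50
diploids per island, the assignment checks at 300 loci and 25 per
island, the panel-size checks on a 6000-locus pool (124 individuals),
and the end-to-end round trip at the generator defaults with a 300-locus
panel; the whole suite completes in a few minutes on one CPU, and these
sizes are the package's chosen test conditions. Other conventions worth
knowing: undefined statistics are always `NA` with a reason, never 0;
all deterministic tie-breaks are lexicographic by id; every stochastic
path runs under a caller-supplied seed and reruns are byte-identical;
posterior normalization is max-subtracted; and VCF output is bgzipped
(vcfR's writer), which the reader round-trips losslessly.

# Limitations

The toolkit starts from called genotypes (a VCF); raw-read processing,
genotype calling from sequencer output and PCR primer design are out of
scope, as are multi-allelic sites, indels, polyploids, admixture
coefficient estimation and Monte-Carlo exclusion tests. Panel design
inherits the reference dataset's ascertainment: a panel optimized for
one archipelago's allele-frequency contrasts is not expected to be
informative elsewhere.
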