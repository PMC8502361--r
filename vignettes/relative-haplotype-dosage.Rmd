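---
title: "Proband-free NIPD by linked-read phasing and relative haplotype dosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proband-free NIPD by linked-read phasing and relative haplotype dosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplonipt)
```

## The problem

For a couple who both carry a pathogenic variant of an autosomal recessive
disease gene, the clinical question during pregnancy is which of each parent's
two haplotypes the fetus inherited. Maternal plasma contains a mixture of
maternal and fetal cell-free DNA; at a fetal fraction f the inherited
haplotypes perturb allele dosages by only f/2, so no single SNP is decisive —
but hundreds of phased SNPs around the gene, read jointly, are. This package
implements that inference end to end without requiring DNA from an affected
sibling (a proband): parental haplotypes are phased *directly* from barcoded
linked reads, and fetal inheritance is decoded from plasma allele counts by a
hidden Markov model.

## Direct haplotype phasing from barcodes

Linked-read libraries partition high-molecular-weight DNA molecules
(50 kb and longer) into barcoded droplets; short reads sharing a barcode
derive, with high probability, from the same long molecule and therefore the
same haplotype. `build_allele_barcode_graph()` reduces the observations to
pairwise evidence between heterozygous sites: a barcode whose majority alleles
at two sites have the same ref/alt polarity votes *cis*, otherwise *trans*.
`assemble_phase_blocks()` then 2-colors the sites greedily from left to right;
a site joins the current block only when its total evidence against the
already-phased members reaches `min_support` (default 2) and the orientation
margin reaches `min_margin` (default 2), so a single erroneous observation
cannot flip a site. Two caveats shaped the defaults:

* Because each droplet holds several molecules (about 10 by default), two
  *distant* sites can share a barcode through different molecules, which
  contributes symmetric cis/trans noise. Evidence from pairs farther apart
  than `max_pair_gap` (default 200 kb, the scale of the longest molecules) is
  therefore ignored during assembly; with enough members, accumulated noise
  from many weak distant pairs could otherwise out-vote the genuine local
  molecule signal.
* Orientation ties can only arise with `min_margin = 0`; they resolve toward
  the nearest upstream member, keeping assembly deterministic.

Blocks from complementary sources can be linked through overlapping sites
(`merge_blocks_by_overlap()`, at least 2 shared SNPs, majority orientation
vote; a 50:50 vote refuses the merge). `anchor_pathogenic_variant()` labels
the haplotype carrying the variant allele P (pathogenic-linked) and the other
N. If no block contains the variant site — or, at the pipeline level, only a
singleton block does — phasing has failed for that parent and its side of the
analysis is skipped, which surfaces in reports as a PARTIAL result.
`phase_block_stats()` summarizes contiguity as N50, longest block and the SNP
count of the gene-spanning block. Users with an already-phased VCF (pipe-
separated GT with PS tags) can bypass this stage entirely
(`read_phased_vcf()`, `hap_pair_from_diplotype()`).

## Informative SNPs and the dosage model

Only sites heterozygous in exactly one parent carry inheritance signal. With
the het parent's P/N labels fixed, the expected plasma fraction of the P
allele follows from the mixture — a fraction 1 − f of templates is maternal
(both maternal alleles equally likely), f is fetal (one maternal and one
paternal allele):

| category | homozygous parent matches | state P | state N |
|---|---|---|---|
| maternal-informative | P allele | (1+f)/2 | 1/2 |
| maternal-informative | N allele | 1/2 | (1−f)/2 |
| paternal-informative | N allele | f/2 | 0 |
| paternal-informative | P allele | 1 | 1 − f/2 |

Expected fractions are clamped into [ε, 1 − ε] (ε = 0.005 by default):
sequencing error makes an absent allele observable at roughly the error rate,
while interior fractions are left untouched (the O(ε) correction there is
negligible relative to binomial noise). Note the paternal-informative rows
need the same subtype distinction as the maternal ones — which haplotype the
homozygous mother matches — even though only the mother-lacks-P case is
usually quoted; both arise in practice and both are implemented.

## Fetal fraction

At paternal-informative sites any read carrying the allele the mother lacks
is fetal (error aside), with expected fraction f/2 — but only at the roughly
half of such sites where the fetus actually inherited the paternal-specific
allele; the rest sit at the error floor. `estimate_fetal_fraction()` therefore
splits the per-site specific-allele fractions q into signal and background
clusters with a deterministic 2-means (centers initialized at min(q) and
max(q)) and reports ff = 2 × median(q) over the signal cluster. The split is
honoured only when the cluster gap exceeds twice the summed within-cluster
spreads: splitting a unimodal cloud by 2-means produces a gap of about 1.6
standard deviations against summed spreads of about 2.4, so this criterion
accepts only genuine bimodality and leaves purely-signal site sets (e.g.
obligate-carrier sites where the father is homozygous for the allele the
mother lacks) undivided. Sites need `min_depth` 50; q above 0.4 is discarded
as a likely genotyping error; the median (rather than mean) resists
mis-genotyped sites, with `estimator = "mean"` available. An estimate below
0.01 aborts with instructions to supply f explicitly — at very low fetal
fraction the downstream inference is unreliable anyway and the confidence
score would flag it.

## HMM decoding and call rules

For each parent independently, the hidden state at each of its informative
SNPs is which parental haplotype the fetus inherited (P or N). Emissions are
binomial: the P-allele count at a site of depth d is Binomial(d, expected
fraction); a zero-depth site contributes log-probability 0. Transitions
between adjacent SNPs use the recombination fraction of their genetic-map
distance under the Haldane (no-interference) map function
r = (1 − e^(−2d/100))/2, floored at 10⁻⁸ so co-located SNPs never generate
−∞ log transitions; Kosambi is available via `map_function`. Genetic positions
come from piecewise-linear interpolation of a (bp, cM) anchor table, with
queries outside the anchors extrapolated at the terminal segment's local rate.
Initial state probabilities are uniform. `viterbi_decode()` runs the standard
log-space dynamic program; backtracking ties prefer the no-switch predecessor,
biasing against spurious recombination events, and a final-state tie resolves
to P — both choices make decoding deterministic.

The decoded path is collapsed into maximal constant-state segments and
`call_fetal_allele()` applies the call rules: the fetal allele is the state of
the *unique* segment whose bp interval contains the whole gene interval. This
subsumes the single-segment and two-segment cases; a segment boundary inside
the gene — possible fetal recombination at the critical locus — yields
NO_CALL, as does a gene interval outside the span of the informative SNPs.
Paths with more than two segments (not covered by the usual two-rule
statement) are handled conservatively by the same unique-spanning-segment
test.

## Confidence score and no-call criterion

`confidence_score()` quantifies how reliably this *design* — fetal fraction,
per-SNP depths, informative-SNP count and spacing — recovers the called
state: it simulates replicate datasets under the called state from the
emission model, re-runs decoding and calling, and reports the fraction of
replicates reproducing the call (default 1000 replicates; at least 100). A
score below 0.99 is a no-call; the boundary value itself remains callable.
Scoring conditions on the design rather than bootstrapping the observed
counts: the score is interpretable as pre-experiment power and is independent
of the particular noise realization that produced the call. Replicate depths
reuse the observed per-SNP depths (or resample a supplied depth profile with
replacement), preserving depth heterogeneity. Call rules run *before* the
confidence score: a boundary-inside-gene NO_CALL stands regardless of how
powerful the design is.

`classify_fetal_genotype()` combines the parental calls: P/P affected, one P
carrier, N/N normal; exactly one unavailable allele gives PARTIAL, both give
NO_CALL. `concordance_table()` tallies cohort counts against truth.

## The synthetic-data generator

`simulate_family()` emulates the study design the pipeline targets: a ~2 Mb
panel of biallelic SNPs centred on a 50 kb gene interval containing both
parental variant sites, phased carrier parents (het at their own variant,
with the pathogenic allele as ALT), a fetal genome transmitted with
genetic-map-driven crossovers, plasma counts, and optionally barcoded
linked-read observations. Defaults follow the cohort the package's fixtures
describe: fetal fraction 0.132 (the cohort mean; cohort range 5.9–27.7%),
per-SNP het rate 0.6 (capture panels target highly heterozygous SNPs), a
uniform 1 cM/Mb map (the genome-wide human average), and plasma depth 200 per
SNP — the source data report only the parental gDNA depth (about 400×), so
the plasma default is a deliberate, configurable choice of half that.
Molecule lengths are a truncated exponential — a 50 kb floor (the HMW size
requirement) plus an exponential of the configured mean, equivalent by
memorylessness to conditioning an exponential on exceeding the floor. Depths
are Poisson (no overdispersion); plasma allele counts are drawn from the
exact closed-form per-read mixture probability, so counts always sum to the
drawn depth. Each droplet holds 10 molecules by default and same-locus
collisions are permitted — downstream majority voting must (and does)
tolerate them. Deletions such as common alpha-thalassemia alleles are modeled
abstractly as a biallelic marker at one position, not as structural variants.

What the generator does *not* emulate: capture-efficiency and GC bias,
read-level errors correlated along fragments, index hopping, maternal or
placental mosaicism, and twin pregnancies. Passing tests on this generator
demonstrate the statistical machinery under the stated mixture model, not
robustness to every artifact of real sequencing.

## Numerical and testing choices

Problem sizes in the test suite are chosen to exercise each statistical claim
at meaningful power while keeping the default run fast: Viterbi is checked
against exhaustive path enumeration on 100 random instances of up to 12 SNPs
(2¹² paths each); end-to-end allele recovery uses 200 simulated pregnancies
at f = 0.10, depth 200 and 100 informative SNPs per parent; the fetal-fraction
estimator is audited over 50 simulations at depth 400 and 300 sites; and
confidence-score calibration draws 500 truth-known cases across mixed
regimes (f 0.04–0.2, depth 60–300, 20–120 SNPs) at 200 replicates each,
checking that calls accepted at CS ≥ 0.99 err at most 2% of the time.
`scripts/acceptance.R` re-derives the cohort summaries from the packaged
tables and re-runs these synthetic benchmarks from a single seed.

## Known limitations

* The phaser is a deliberately simple greedy 2-coloring; it has no switch-
  error model and no haplotype imputation, and its thresholds (support 2,
  margin 2, 200 kb pair window) are tuned for the simulated barcode model,
  not benchmarked against production phasing software.
* Fetal-fraction estimation needs tens of paternal-informative sites at
  adequate depth; below f ≈ 0.03 the signal/background clusters merge and the
  estimator refuses rather than guesses.
* The HMM assumes a single pregnancy, constant fetal fraction across the
  region, and independent binomial counts given the state; amplification
  overdispersion would require a beta-binomial emission, not provided.
* Viterbi reports the single best path without per-SNP posteriors; the
  confidence score, not a forward–backward pass, carries the uncertainty.
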