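---
title: "Discovering transcription-factor targets from promoter elements and co-expression"
author: "creNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering transcription-factor targets from promoter elements and co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creNet)
```

## The problem

Light-signalling bZIP transcription factors of the HY5/HYH family bind
short, degenerate ACGT-core elements in promoters. Candidate target
genes of such a factor can be nominated in silico by combining three
independent lines of evidence:

1. **Promoter motifs.** The promoter (here the 1 kb immediately upstream
   of the transcription start site, TSS) carries at least one of the
   factor's cis-regulatory elements (CREs).
2. **Co-expression.** The gene sits in the factor's co-expression
   neighborhood across one or more expression datasets, using the
   Pearson correlation coefficient (PCC) and the mutual rank (MR) as
   similarity indexes.
3. **Ortholog evidence.** The gene's ortholog in a reference species
   responds to loss of the factor, or is a direct ChIP-binding target of
   the orthologous factor.

creNet implements each step as a tested, reusable component, together
with a synthetic-data generator that plants known motifs and regulons so
the whole chain can be validated against ground truth.

## The motif catalog and promoter scanning

The built-in catalog holds five consensus elements: the C-box
(`HBACGTCD`), C/A-box (`HBACGTAD`), and C/G-box (`HBACGTGD`) — each a
degenerate octamer expanding to $3 \times 3 \times 3 = 27$ concrete
sequences over the IUPAC sets H = {A,C,T}, B = {C,G,T}, D = {A,G,T} —
plus the fixed UV-B-response T/G-box (`CCACGTTC`) and E-box (`CAATTGC`).
The three octamer boxes differ at their seventh base, so their
expansions are disjoint and the catalog comprises 83 distinct concrete
motifs:

```{r catalog}
catalog <- hy5MotifCatalog()
catalog
totalExpanded(catalog)
```

Scanning is exact string matching of the expanded sets against both
strands, reported in TSS-relative coordinates (offset $-1$ is the base
immediately upstream of the TSS). Design choices that matter downstream:

* Overlapping matches all count; no exclusion rule is applied.
* A palindromic motif matches both strands at the same position and
  contributes two occurrences; per-gene *presence* needs only one.
* `N` bases (assembly gaps, masked positions) never match.
* Matching is consensus membership, not position-weight-matrix scoring:
  the binding sites were defined as consensus sets, and expansion keeps
  the statistics exact and fast.
* Minus-strand promoters are stored reverse-complemented, so one
  scanning code path serves both gene orientations.

Promoters truncated at contig edges are kept (with their shorter
effective length) rather than dropped: excluding them would distort the
gene universe used by the enrichment tests.

## Positional bias

Real binding elements concentrate near the TSS. Occurrences are binned
in 50-bp windows anchored at the TSS (bin 1 = offsets $-50..-1$, ...,
bin 20 = $-1000..-951$), and each profile is baseline-adjusted by the
mean count over the distal half ($-501..-1000$). The bias statistic is a
Z-score for the most TSS-proximal bin; two models are provided because
the classical "uniform distribution model" is cited in the literature
without a reproducible formula:

* `empirical_baseline` (default):
  $Z = (c_1 - \bar{c}_{distal}) / s_{distal}$, with the sample standard
  deviation over the ten distal bins. This ties the statistic to the
  explicitly defined baseline region.
* `binomial_uniform`: with $N$ total occurrences in $k$ bins,
  $Z = (c_1 - N/k) / \sqrt{N \tfrac{1}{k}(1 - \tfrac{1}{k})}$.

$Z \ge 3$ is read as strong TSS-proximal bias. The single proximal bin
is the most conservative reading of "towards the TSS"; widening the
proximal window would only dilute a genuine spike.

One numerical subtlety: a motif of width $w$ cannot start within the
last $w - 1$ bases of the promoter, so bin 1 carries a small systematic
deficit ($(w-1)/50$ of a bin) even for a perfectly uniform motif. The
empirical-baseline model divides by the tight distal-bin standard
deviation and therefore amplifies this deficit into clearly negative Z
values for unbiased motifs; the binomial model's wider denominator
absorbs it. For claims of *absence* of bias (the uniform control in the
synthetic study) the binomial model is therefore the appropriate null,
and that is what the package's acceptance checks use; genuinely
TSS-biased motifs score far above 3 under both models.

## Enrichment in a gene set

Two complementary tests, both required for a call:

* **Hypergeometric presence test** (one-sided, upper tail): does a
  larger fraction of the set's promoters contain the motif than expected
  from the scanned universe?
* **Permutation occurrence test**: is the *total* occurrence count in
  the set's promoters higher than in random promoters? Each of the
  `nPerm = 1000` permutations generates fresh i.i.d. sequences matched
  to the set's promoter count and per-promoter lengths at the background
  base composition (default A:C:G:T = 0.33:0.16:0.16:0.34, the AT-rich
  ratio typical of plant promoters; supplied ratios are renormalized to
  proportions). The empirical P-value uses the add-one rule
  $(1 + \#\{null \ge obs\})/(n_{perm} + 1)$, so it is bounded below by
  $1/(n_{perm}+1)$ and never exactly zero. Fold enrichment is
  $obs / \overline{null}$.

A motif is `p<0.05` only if **both** tests fall below 0.05, and
`p<0.01 strict` if both fall below 0.01; no multiple-testing correction
is applied across motifs (per-motif thresholds are the method's
convention). Permutation RNG streams are derived from the run seed and a
permutation counter, so results do not depend on evaluation order.

Calibration: the package's acceptance suite draws 200 random gene sets
from an unplanted random-promoter universe (50 promoters of 500 bp per
set, 19 permutations per test — sizes chosen to make 200 repetitions
cheap) and checks that the mean fold enrichment lies in $[0.9, 1.1]$ and
that empirical P-values are approximately uniform. "Approximately" is
quantitative: with the add-one rule at $n_{perm} = 19$ the null
P-values live on the grid $\{1/20, \dots, 1\}$ with mean 0.525, and
integer-count ties push them slightly higher (conservative, never
anticonservative); the test bands reflect that discreteness.

## Co-expression neighborhoods

For a guide gene $g$ and gene $t$, the neighborhood records the PCC,
the descending-PCC rank of $t$ in $g$'s profile, the rank of $g$ in
$t$'s profile, and the mutual rank
$MR(g,t) = \sqrt{r_{g \to t}\, r_{t \to g}}$ — low MR means reciprocally
strong co-expression. Conventions (none of which are dictated by the
method's literature, so they are fixed here for determinism): ranks are
1-based with average ranks on PCC ties; zero-variance genes are excluded
(undefined PCC); the guide is excluded from its own list; top-$N$
selection orders by MR ascending, then PCC descending, then gene id.
Per-dataset top-$N$ lists (default $N = 300$) are merged into an
aggregate network whose edge support counts the number of (guide,
dataset) lists containing the target.

Variance-stabilizing transformations of raw counts are an external
preprocessing concern: the module accepts any pre-normalized matrix
(`passthrough`) and offers `log2(x+1)` for counts-like input.

## The community network

`integrateCommunity()` is a pure filter over the aggregate network's
targets: a gene is kept iff its total network support reaches
`minSupport` (default 1 — "network support" without a stated multiplicity
is read as at least one network), at least one catalog motif occurs in
its promoter, and at least one ortholog evidence flag is set. Ortholog
evidence is an *input* annotation (gene → flags), not something the
package computes: reproducing mutant microarrays or ChIP experiments in
another species is out of scope, and published evidence lists are the
natural input. Raising `minSupport` can only remove nodes, never add
them.

## The synthetic study

The generator emulates exactly the features the pipeline consumes, with
defaults that define the benchmark conditions:

* **Genome**: 2000 genes, 100 per contig, strands alternating (so both
  promoter-extraction paths are exercised), background drawn i.i.d. at
  A:C:G:T = 0.33:0.16:0.16:0.34; promoters are 1 kb.
* **Planted motif**: one T/G-box copy overwritten into each of 200
  target promoters at an offset whose magnitude is $1 + $ geometric with
  mean 80 bases (a single-parameter, heavy-near-TSS shape echoing
  observed CRE distribution profiles), truncated to the promoter.
* **Uniform control**: one E-box copy in 200 disjoint promoters at
  uniform offsets. The control exists so positional statistics can be
  contrasted against an unbiased motif within the same genome; chance
  background matches of all motifs are left in place, as in a real
  genome.
* **Expression**: a one-factor latent model over 30 samples. Each
  sample has activity $z \sim N(0,1)$; the 50 regulon members (drawn
  from the planted targets) follow $1 \cdot z + N(0, 0.5^2)$, the guide
  follows $z + N(0, 0.1^2)$, and background genes are independent unit
  noise. The guide's smaller noise reflects its role: it is the factor
  *driving* the regulon, so its expression is a near-faithful readout of
  the latent activity, while members respond through their own promoters
  and noise. Latent values become counts-like data via
  $\mathrm{round}(2^{x+8})$, so `log2(x+1)` normalization approximately
  recovers the latent scale. Correlation structure, not count
  dispersion, is what the downstream method consumes, hence a Gaussian
  latent-factor model rather than negative-binomial counts.
* **Evidence**: regulon members are flagged as mutant-DE with
  probability 0.9 and as ChIP targets with probability 0.5; background
  genes pick up 2% spurious DE flags — ortholog evidence in practice is
  incomplete and noisy.

What the synthetic data do **not** emulate: gene structure (introns,
UTRs), promoter overlap with neighboring genes, repeat content,
dinucleotide composition, batch effects, and count dispersion. Passing
tests therefore demonstrate the correctness and calibration of the
*computations*, not the biological error rates to expect on real
genomes, where background sequence is not i.i.d.

Under these defaults (fixed seed 42) the planted motif scores
positional Z far above 3 under both models with `p<0.01 strict`
enrichment in the regulon set, the uniform control stays below $|Z| = 2$
under the binomial model, and the guide's top-50 MR list recovers the
regulon completely. With the regulon effect set to 0 the recovery
collapses to chance, as it should.

## Determinism and degenerate inputs

* Every random component takes a seed; substreams are derived from
  (seed, counter) so stage order never changes results. Reruns of
  `runPipeline()` with one config are byte-identical on all statistic
  tables, and the manifest records input hashes.
* Zero-variance distal bins make the empirical Z undefined: reported as
  `NA` with a warning, never silently 0.
* A zero null mean makes fold enrichment undefined: `NA` with a warning.
* An empty prediction has undefined precision: `NA` with a warning,
  recall 0.
* Profiles with zero occurrences cannot be Z-tested (error), and
  occurrences outside the configured span indicate a promoter/span
  mismatch (error rather than silent clipping).

## Worked example

```{r example}
spec <- simulationSpec(nGenes = 300, nTargetGenes = 40, regulonSize = 20,
                       nControlGenes = 40, nSamples = 15, seed = 42)
sim <- simulateGenome(spec)
promoters <- extractPromoters(sim$genome, sim$genes)
occ <- scanPromoters(promoters, hy5MotifCatalog())

profile <- baselineAdjust(binOccurrences(occ, "T/G-box"))
positionalZscore(profile)

mat <- normalizeExpression(simulateExpression(spec, sim$truth), "log2p1")
nb <- mutualRankNeighborhood(mat, sim$truth$guide)
top <- topCoexpressed(nb, 20)
evaluateAgainstTruth(top, sim$truth, occurrences = occ)[c("precision", "recall")]
```

## Known limitations

* Exact consensus matching cannot rank partial or near-miss sites; a
  PWM extension would need a different null for the permutation test.
* The i.i.d. background null ignores local composition biases (CpG-like
  patches, TA-rich stretches); a Markov background would be a natural
  extension but changes the "composition-matched" contract.
* The TSS is the gene-feature boundary, not an isoform-aware 5′ end.
* MR neighborhoods are computed per guide over the full gene set;
  genome-scale all-pairs networks are out of scope.
* At very small permutation counts the empirical P-value grid is coarse;
  use `nPerm = 1000` (the default) for reportable P-values.
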