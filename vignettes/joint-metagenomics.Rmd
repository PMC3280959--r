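---
title: "Joint analysis of multiple metagenomic samples: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint analysis of multiple metagenomic samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(metajoint)
```

# The problem

Shotgun metagenomic studies increasingly sequence *sets* of related samples
— gut microbiomes of a patient cohort, ocean water along a transect — yet
each sample is usually analyzed on its own. `metajoint` implements three
connected tools built on the opposite premise: that the samples share
underlying structure (common taxa, common sequence components) which joint
modeling can exploit.

1. **Shared-component mixture model.** Per-sample counts of short canonical
   k-mers are modeled as a mixture of multinomials shared across samples
   (probabilistic latent semantic analysis, a row-stochastic non-negative
   matrix factorization), fitted by EM.
2. **Metagenome-wide association with stratification correction.** Every
   k-mer's relative abundance is regressed on a phenotype; the mixture
   model's estimated component proportions enter as covariates to absorb
   cohort-level compositional stratification, the metagenomic analogue of
   population-structure correction in GWAS.
3. **MultiBin.** A coverage-based read-binning algorithm that pools the
   reads of all samples, summarizes the read-overlap graph by *tag* reads
   with per-sample coverage vectors, and clusters those vectors by
   k-medoids — so that abundance differences in *any* sample help separate
   species in *all* samples.

# The mixture model

Let $R_{iw}$ count how many times canonical k-mer class $w$ was extracted
from sample $i$'s reads. The model posits $K$ latent components: a
row-stochastic $M \times K$ matrix $P$ of per-sample component proportions
and a row-stochastic $K \times W$ matrix $F$ of component-specific k-mer
distributions. A k-mer from sample $i$ is generated by drawing a component
$k \sim P_{i\cdot}$ and then the k-mer $w \sim F_{k\cdot}$, giving the
aggregate likelihood

$$\log L = \sum_{i}\sum_{w} R_{iw}\,\log\!\Big(\sum_{k} P_{ik}F_{kw}\Big).$$

`em_aggregate()` maximizes this with the standard PLSA EM — posterior
responsibilities $Q(k\,|\,i,w) \propto P_{ik}F_{kw}$, then
$P_{ik} \propto \sum_w R_{iw}Q$, $F_{kw} \propto \sum_i R_{iw}Q$ — from
several random row-stochastic starts, keeping the best run.

When several k-mers are extracted from the same read, they all came from one
component. The **refined model** (`em_refined()`) makes the component latent
*per read* $r$ with bag counts $c_{rw}$:

$$\log L = \sum_i \sum_{r \in i} \log\!\Big(\sum_k P_{i(r)k} \prod_w F_{kw}^{c_{rw}}\Big),$$

with E-step $Q(k\,|\,r) \propto P_{i(r)k}\prod_w F_{kw}^{c_{rw}}$ computed
in log space with max-subtraction (products of tens of probabilities
underflow otherwise), and M-step
$P_{ik} \propto \sum_{r\in i} Q(k|r)$, $F_{kw} \propto \sum_r Q(k|r)c_{rw}$.

**Canonical k-mers.** Strands are indistinguishable in shotgun data, so a
k-mer and its reverse complement are counted as one class, represented by
the lexicographic minimum of the pair. For $k=4$ this collapses the 256
words into 136 classes (120 complementary pairs + 16 reverse-complement
palindromes).

**Extraction strategies.** `count_matrix()`/`read_kmer_bags()` support
taking the first k-mer of each read, all overlapping k-mers, non-overlapping
k-mers at positions $0, k, 2k, \dots$, or `n` sparsely dispersed k-mers at
evenly spaced positions spanning the read (default $n = 9$ on 100 bp
reads). On an $L$-bp read with $k=4$ these give $1$, $L-k+1 = 97$,
$\lfloor L/k\rfloor = 25$ and $9$ k-mers respectively; we use the plain
arithmetic windowing convention throughout. k-mers containing non-ACGT
characters are skipped, never imputed. Mates of a pair are treated as
independent reads, and base qualities are ignored; the strategy is the
user's knob.

## Numerical choices

* Convergence: relative log-likelihood change below `tol` (default `1e-8`)
  or 500 iterations; 10 restarts by default; equal-likelihood restarts
  resolve to the lowest restart index. The EM trace is retained so
  monotonicity is checkable.
* Zero handling: no pseudocounts; $F$ entries may legitimately reach 0. An
  optional `floor` guards degenerate data in the refined E-step.
* Component matching for error metrics (`estimation_error()`): exhaustive
  permutation for $K \le 8$, greedy nearest-pair matching above.
* The refined EM holds the read bags in memory as one sparse matrix. At the
  scales this package targets (tens of thousands of reads per sample, 136
  classes) the bags are far below memory limits, so the added complexity of
  streaming them from disk per iteration is not warranted.

## Identifiability

The factorization $A = PF$ is generally not unique: any invertible $T$ with
$PT$ and $T^{-1}F$ still row-stochastic yields the same likelihood. With
many k-mer classes ($W = 136$) and few components the ambiguous wedge is
small, but it never vanishes: as counts grow, the permutation-matched error
of $P$ falls to a small floor (SSD around $10^{-1}$ and below in our
property tests) rather than to zero. Component estimates should be read as
a characterization of variation, not as uniquely determined quantities.

# Association testing

For phenotype $y$ and abundance vector $a_w$ (columns of
`relative_abundance()`, which sum to one per sample), `marginal_test()`
fits $y \sim a_w$ — simple linear regression for continuous phenotypes,
logistic for dichotomous ones — and reports the Wald test on the abundance
coefficient. `corrected_test()` adds the first $K-1$ columns of the fitted
$P$ as covariates; the $K$-th is dropped because proportions sum to one.
`component_phenotype_test()` regresses a phenotype directly on one
component's proportions, optionally adjusting for other phenotypes.

Design choices worth stating:

* The phenotype is always the response; this is forced by the dichotomous
  case (logistic regression) and kept for the continuous case for
  consistency.
* Degenerate fits are *flagged*, never dropped: constant abundance reports
  `degenerate` with $p = 1$; collinear covariates report `collinear`;
  logistic separation and non-convergence report `separation`.
* The two-group screening stage (`fraction_rejected()`) uses the Welch
  unequal-variance t-test per k-mer class and reports the fraction rejected
  at nominal $\alpha$ — the relevant quantity is the *excess* over
  $\alpha$, so no multiple-testing correction is applied by default.
* `permutation_test()` uses the $+1$-corrected estimator
  $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$, which cannot return 0.

The stratification phenomenon and its repair are exercised by
`experiment_stratified_qq()`: a cohort whose phenotype depends on the
samples' component proportions only makes most k-mers spuriously
significant marginally (the QQ curve leaves the identity), while the
corrected p-values pass a KS test for uniformity.

# MultiBin

Given per-sample read sets, `detect_overlaps_sequence()` joins two reads
when some suffix–prefix arrangement (either read first, either strand)
matches over at least `min_overlap` bases (default 50) with mismatch
fraction at most `max_mismatch_rate` (default 0, exact). Rather than
all-pairs alignment, reads are indexed by exact seed words from their
prefixes in both orientations and every seed hit is verified over the full
implied overlap — identical contract, near-linear behavior. In permissive
mode three shorter seeds are planted across the first `min_overlap` bases
so that scattered substitutions cannot hide every seed; a tolerance of
roughly twice the per-read substitution rate plus a small margin (we use
0.08 for rates up to 3%) keeps true overlaps detectable, since both reads
contribute errors to the shared region. `detect_overlaps_positional()` is
the design-phase shortcut: reads as (genome, start, length) layouts, an
edge when physical overlap exceeds `min_overlap` (computed by a sorted
per-genome sweep).

`greedy_mis()` scans reads in pool order and keeps each read whose
neighbours are all untagged — a deterministic greedy maximal independent
set. Every non-tag read is affiliated with its earliest-scanned tagged
neighbour. `coverage_vectors()` gives each tag its per-sample neighbour
counts, plus one for the tag itself in its own sample (so isolated tags
still carry their origin). Tags of one species share an expected coverage
vector proportional to the species' abundance profile across samples —
which is why nearly-balanced samples, hopeless one at a time, become
separable jointly.

`kmedoids()` clusters the tag vectors by local search: random initial
medoids, then repeatedly the best cost-improving swap of a medoid with a
non-medoid until none improves. Distance is L1 on the raw count vectors by
default (`l2` and `norml1` are available): tags of a species share an
expected vector, and L1 is robust to the Poisson spread around it.
Identical vectors are collapsed to weighted points first — a pure
implementation detail that leaves the optimum unchanged. The best of
`n_starts` starts is kept, and `assign_bins()` propagates each tag's
cluster to its affiliated reads.

**Precision.** `binning_precision()` scores a binning as the mean over
species of the fraction of the species' reads landing in its matched bin,
with the bin-to-species matching chosen by an optimal assignment (Hungarian
algorithm) on the recall matrix — deterministic, and invariant to bin
relabeling. Species left without a bin score 0.

**Choosing the number of bins.** `select_num_bins()` computes the Hartigan
index $H(S) = (W(S)/W(S+1) - 1)(n - S - 1)$ on the k-medoids cost curve.
The classical absolute rule (smallest $S$ with $H \le 10$) assumes k-means
variances and a particular scale of $n$; on a few thousand tag vectors $H$
at the true $S$ is typically 20–70, so the absolute rule overshoots. The
default rule therefore takes the *last sharp decrease before the plateau*:
the largest $S$ whose drop ratio $H(S-1)/H(S)$ exceeds 2 (falling back to
the single largest drop when none does). The rule is scale-free in $n$ and
recovers the species count whenever the binning itself is accurate
(precision $\ge 0.9$); the absolute rule remains available via
`rule = "threshold"`.

# The synthetic-data generators

`random_stochastic_matrix()`, `sample_counts()` and
`make_stratified_cohort()` generate the mixture-of-multinomials world the
model assumes, with uniform-drawn row-stochastic $P$ and $F$ —
deliberately matched to the model, since those experiments isolate the
estimation question.

`simulate_reads()` generates shotgun communities: per sample, each read
draws a species from the sample's proportions row, a uniform start
position, a uniform strand, and takes the (reverse-complemented) genome
substring; truth labels, starts and strands are retained.
`incremental_proportions()` builds nested proportion schemes — the
$S$-species vector extends the $(S-1)$-species vector by one uniform draw
and renormalizes, preserving pre-existing ratios — so datasets of
increasing complexity stay comparable. `add_substitutions()` flips each
base independently to one of the three other bases.

Generator defaults were fixed once, from the study designs the experiments
emulate: 4 genomes, 10 mixtures and 1,000 reads of 100 bp per sample for
the extraction-strategy comparison; 5 samples, 1 Mb genomes, 20,000 reads
of 400 bp per sample for the binning benchmarks (around 8x per-sample
genome coverage and at least 10x per-tag coverage); 20 experiments per
counts level for the PCA comparison; 10^6 total counts over up to 1,000
samples for the design-phase tradeoff.

**What the genomes do and do not emulate.** Genomes are linear i.i.d.-base
random sequences. Each species draws its own A/C/G/T composition from a
symmetric Dirichlet (`random_base_compositions()`, concentration 10, a
spread comparable to the 25–75% GC range of real bacteria): without this,
all species share one 4-mer profile and the component-estimation
experiments have no signal to find, whereas real taxa differ strongly in
k-mer composition. What i.i.d. genomes deliberately do *not* reproduce is
*within*-genome sequence dependence — regional composition, codon
structure, repeats. Two consequences, which say what passing tests do and
do not show about real data:

* Because non-overlapping k-mers from an i.i.d. genome are independent
  draws, using more of them is strictly more informative; the documented
  advantage of *few, sparsely dispersed* k-mers over all non-overlapping
  ones exists only when neighbouring k-mers are redundant, as on real
  genomes. Our experiments reproduce the model ordering (refined beats
  aggregate, multiple k-mers beat the first k-mer) but not the sparse-9
  advantage; block-composition genomes strong enough to flip it
  simultaneously erode the refined model's advantage, so we did not tune a
  dependence structure to force both.
* Repeat-free random genomes make sequence overlap detection essentially
  noiseless; real repeats would add spurious edges MultiBin would have to
  absorb.

Binning precision at the default depth is limited by per-tag per-sample
Poisson coverage (mean about $14 p$ overlapping reads for a species at
proportion $p$), so a few percent of tags fall on the wrong side of the
k-medoids boundary when samples are nearly balanced; deeper simulated
sequencing drives precision toward 1 but the defaults are kept at the
stated study design.

One design-phase caveat: when a fixed total of multinomial counts is split
among more and more samples, the finer split is a sufficiency refinement
of the merged data, so with adequate optimization the F-estimation error
in our experiments decreases monotonically with the number of samples
rather than peaking at an interior optimum; the binning tradeoff, by
contrast, does show an interior optimum (too few samples give
uninformative one-dimensional coverage vectors, too many give vectors too
noisy per dimension).

# Problem sizes in the test suite

The packaged end-to-end tests run the binning benchmarks at their stated
scale (1 Mb genomes, 20,000 reads of 400 bp per sample), the strategy
comparison at 20 replicates of 10 mixtures with 1,000 reads of 100 bp per
sample, and the design-phase experiments at 20 trials; unit tests use much
smaller fixtures (50 kb genomes, a few thousand reads) where only the
mechanics are at stake. EM correctness is checked against an independent
two-stage simplex grid search on 2x2 instances plus brute-force likelihood
evaluation, and the clustering and matching stages against exhaustive
oracles on small instances. All randomness flows from explicit seeds;
every generator is reproducible from (parameters, seed).

# Limitations

* k is a modeling choice: 4-mers capture composition signatures; the
  association layer is agnostic but counts become sparse for large k.
* $K$ is user-set; no automatic selection is attempted.
* No GC-bias normalization, quality handling, paired-end modeling, indel
  errors, or chimeric reads.
* Component estimates are identifiable only up to the factorization wedge
  discussed above.
* The k-medoids stage is a local search; with few starts on very flat cost
  surfaces the selected bin count can wobble before precision does.
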