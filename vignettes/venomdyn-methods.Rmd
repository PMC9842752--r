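---
title: "Models and methods in venomdyn"
author: "venomdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in venomdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomdyn)
```

# Scope

`venomdyn` studies how a venom expression phenotype — the vector of toxin-family
fractions of total toxin expression — evolves across a species phylogeny, and
how the gene family behind a dominant toxin varies within a species. The
macroevolution half fits continuous-trait models (Brownian motion, Ornstein-
Uhlenbeck, early burst, and a pulsed jump-normal Lévy process) with AIC-weight
model selection, reconstructs ancestral states, quantifies phylogenetic signal
(Pagel's λ), and estimates a multivariate evolutionary covariance with a
parametric bootstrap and a phylomorphospace ordination. The microevolution half
recovers sequence variants of a highly duplicated, near-identical toxin gene
from mapped read pairs, genotypes individuals from amplicon sequencing with
core-haplotype deduction, estimates diploid copy number from multiplex qPCR by
the ΔΔCt method, and analyses the architecture of assembled locus haplotypes.
A synthetic-data module generates every input the pipeline consumes, so all
analyses are testable end to end without external data.

# The venom phenotype

`aggregateFamilyExpression()` sums TPM over the transcripts annotated to each
toxin family and normalizes by the total annotated TPM, giving per-sample
family fractions $f_k$ with $\sum_k f_k = 1$. A family is *dominant* when its
fraction strictly exceeds the dominance threshold (default 0.5, i.e. ">50% of
total toxin expression"); strict inequality means at most one family can
qualify at the default, so no tie-break is needed. Samples with zero annotated
TPM are flagged undefined rather than silently dropped. Species-level
composition is the mean of the per-sample fraction vectors, renormalized —
per-sample composition is the general case and pooling is a caller decision.

Toxin discovery itself (ORF calling, homology search, signal-peptide
prediction) is upstream of this package; an annotation table maps transcripts
to families. Of that curation protocol only the cysteine-framework check is
implemented: `cysteineFramework()` encodes the count and spacing of cysteines
in a mature peptide as `"C<g1>C<g2>...C"`, and `frameworkMatch()` compares two
frameworks with a configurable per-gap tolerance.

# Continuous-trait models on the phylogeny

All comparative methods consume a rooted tree with branch lengths (an
`ape::phylo`). Trees are expected to be time-calibrated upstream; the
ultrametricity check uses a relative tolerance of 1e-6 of tree height. A
mean-path-length rescaling (`makeUltrametricMPL()`) is provided as a
convenience but is *not* equivalent to penalized-likelihood dating, and the
analyses here treat calibrated trees as given.

For a trait vector $x$ over tips, with $C$ the shared-path (BM) covariance
matrix of the tree:

* **BM** — $x \sim N(a\,\mathbf{1}, \sigma^2 C)$. The likelihood is evaluated
  by Felsenstein pruning; the ML solution is closed form
  ($\hat a$ by GLS, $\hat\sigma^2$ with divisor $n$), $k = 2$ parameters.
* **OU** (root at the optimum) —
  $V_{ij} = \frac{\sigma^2}{2\alpha} e^{-2\alpha(T - s_{ij})}
  (1 - e^{-2\alpha s_{ij}})$ on an ultrametric tree of height $T$ with
  shared paths $s_{ij}$. Fixing the root at the optimum $\theta$ keeps the
  model identifiable on ultrametric trees. Given $\alpha$, both $\theta$ and
  $\sigma^2$ are profiled in closed form, so the search is one-dimensional:
  a log-spaced multi-start grid spanning beyond $[10^{-3}/T,\,10/T]$ refined
  by Brent's method. $k = 3$.
* **EB** — $V_{ij} = \sigma^2 (e^{r s_{ij}} - 1)/r$ with $r \le 0$; the
  $r \to 0$ limit is BM and is handled analytically. Profiled the same way
  over a grid on $[-20/T, 0]$. $k = 3$.
* **JN (pulsed)** — displacement over a branch of length $t$ is
  $N(0, \sigma^2 t)$ convolved with a Poisson($\lambda_J t$) number of
  $N(0, \delta^2)$ jumps. The likelihood is computed by pruning with finite
  normal-mixture messages: the per-branch jump count is truncated at the
  smallest $K$ with Poisson tail mass $< 10^{-8}$; node products are taken
  component-wise; components with relative weight $< 10^{-10}$ are dropped
  and mixtures are merged down to a cap (default 256 components) by
  moment matching, merging the cheapest neighbours in (variance, mean)
  order under a Runnalls-style cost. For branches with very large jump
  intensity ($\lambda_J t > 15$) the compound distribution is collapsed to
  its moment-matched normal (central-limit regime), which bounds cost
  without affecting the regimes where pulses are detectable. $k = 4$.

The JN likelihood agrees with exact per-edge jump-count enumeration to
$\sim 10^{-6}$ on small trees, and equals the BM likelihood to $10^{-8}$ at
$\lambda_J = 0$. The mixture cap changes 64-tip log-likelihoods by only
$\sim 10^{-3}$ between 32 and 512 components.

## Numerical choices in the JN fit

`fitJN()` profiles the root state out of the optimization: the pruning pass
does not involve the root value, so one pass yields the root-message mixture
whose mode is the ML root. The remaining three parameters are searched by
Nelder-Mead over $(\log \sigma^2, \log v_J, \log \delta^2)$ where
$v_J = \lambda_J \delta^2$ is the jump contribution to variance per unit
time — this keeps the BM-like ridge ($\lambda_J$ large, $\delta^2$ small)
well conditioned. Two structured starts split the BM-fit variance between
drift and jumps in different proportions; the winner is polished at a tighter
tolerance. A box guard rejects jump rates above $60/T$, where the process is
empirically indistinguishable from BM (and the likelihood is already
represented by the $v_J$ ridge). During optimization the mixture cap defaults
to 32 components; as measured above this perturbs log-likelihoods far below
the AIC differences that drive model selection, while making ~100-replicate
recovery studies tractable on one CPU. The evaluation function `jnLogLik()`
keeps the full 256-component default.

Model comparison uses Akaike weights,
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$,
$\Delta_i = \mathrm{AIC}_i - \min_j \mathrm{AIC}_j$.

## Ancestral states, signal, covariance

`asrBM()` computes ML ancestral states by two-pass message passing (postorder
fold toward the root, preorder distribution of parent-side information);
each node estimate is the precision-weighted combination of its incident
messages, equal to the GLS prediction. Compositions are reconstructed per
family independently, clipped to $[0, 1]$, and renormalized per node; a node
clipped to all-zero falls back to the uniform composition with a warning.
Whether renormalization after per-family reconstruction matches the original
figures could not be determined from the source material; renormalization is
the package's choice because the phenotype is compositional by definition.

Pagel's λ scales the off-diagonal of $C$; the ML $\hat\lambda \in
[0, \lambda_{\max}]$ (with $\lambda_{\max}$ keeping $C_\lambda$ positive
definite) is found by the same profile-plus-Brent strategy. λ is reported
instead of an MCMC-based heritability: both live on a $[0,1]$-like scale but
are not numerically identical quantities.

`phyloCovariance()` fits a multivariate BM model by GLS
($\hat a$, then $\hat R$ with divisor $n - 1$) and attaches percentile 95%
intervals from a parametric bootstrap: $B$ datasets are simulated under the
fitted matrix-normal model (row covariance $C$, column covariance $\hat R$)
and refitted. An off-diagonal entry is significant when its interval excludes
zero. This replaces an MCMC mixed-model treatment deliberately: it estimates
the same evolutionary covariance with a fully specified, desk-scale
procedure; posterior summaries from the Bayesian machinery need not agree
numerically. Expression traits are analysed on the `log(TPM + 1)` scale
(`logTpm()`) because expression spans orders of magnitude; compositions are
reconstructed on raw fractions. `phylomorphospacePCA()` eigendecomposes
$\hat R$, projects root-centred tip traits on the eigenvectors, and projects
`asrBM()` node states into the same space; variance fractions are eigenvalues
over the trace.

# Transcriptomic variant recovery

Read pairs pre-extracted against a single collapsed gene model are re-placed
with a banded fitting aligner (global in the read, local in the model;
match +1, mismatch -1, gap open -2, gap extend -1, band half-width 16 around
the best ungapped diagonal) — a self-contained, testable stand-in for a
short-read mapper, with pairs rejected below 90% identity, approximating
default mapper behaviour. Each pair yields a consensus on model coordinates:
uncovered interior positions become `N`; where mates disagree, the
higher-quality base wins if qualities are present, otherwise the position
becomes `N` and a conflict is counted.

"Identical sequences" are only well defined on a shared interval, so
consensi are trimmed to a common region before exact clustering (consensi
with `N` in the region are discarded and counted). Retention applies the
union rule: the shortest count-sorted prefix reaching 70% of all sequences,
plus every cluster with at least 10 identical copies. The union reading of
the rule's "or" is a deliberate interpretation (the alternative — fallback —
is narrower); a dataset-specific single-sample exception from the original
curation is *not* special-cased. `detectNv3Signature()` classifies sequences
by the diagnostic 15-mers `AAACGCGGCATTCCT` (KRGIP) vs `AAACGCGGCTTTGCT`
(KRGFA).

# Amplicon haplotyping

QC keeps amplicons of 300-500 bp (inclusive) containing only A/C/G/T, with
rejection tallies partitioning the input (length checked before ambiguity).
Primer trimming requires the forward primer at the 5' end and the reverse
complement of the reverse primer at the 3' end, each within one substitution
by default. Samples are subsampled without replacement to exactly 14,800
reads; samples with fewer reads are excluded with an explicit record.

A sequence is called a variant when it reaches 100 reads in at least one
individual *and* occurs in more than one individual; the stricter reading
(100 reads in two or more individuals) is available via `strict = TRUE`.
Sample clustering uses $1 - \rho_s$ (Spearman) distances with complete
linkage — the linkage the original heatmap tooling defaults to; constant
abundance vectors have undefined correlation and get distance 1 with a
warning.

Core haplotypes are deduced from presence/absence (presence = count at or
above the calling threshold; heterozygote dosage is deliberately not used):
the candidate cores are the distinct observed presence sets, and an
iterative-deepening branch-and-bound finds the minimum number of candidates
such that every individual's presence set is the union of one or two
(possibly equal) cores. Ties prefer solutions that make more individuals
homozygous (their whole set is itself a core), then lexicographic order.
When no full cover of at most eight cores exists — as happens with noisy or
dropout-affected data — a greedy maximum-coverage fallback reports the best
partial cover and the unexplained individuals, rather than failing.

# Copy number by ΔΔCt

Reactions are multiplex, so triplicate QC is coupled across genes: within an
individual-by-plate triplicate and per gene, if the maximum pairwise Cq
difference exceeds 0.2 cycles, the single reaction whose removal restores the
tolerance (the most outlying relative to the remaining pair) is dropped — for
both genes; if no single removal suffices the whole triplicate goes, and
individuals with fewer than two surviving reactions are excluded. Per
reaction $\Delta Ct = Cq_{target} - Cq_{control}$; the individual's mean
ΔCt is taken over retained reactions, $\Delta\Delta Ct$ subtracts the
calibrator's mean ΔCt, and the diploid copy number is
$calibratorCopies \times 2^{-\Delta\Delta Ct}$ — exact doubling is assumed
once assay efficiencies from the dilution series
($E = 10^{-1/slope} - 1$) pass the 90-110% gate. Copy numbers are reported
as continuous values; rounding is presentation.

Population comparison fits `copyNumber ~ population * plate` with type II
sums of squares (robust to the unbalanced design) and runs Tukey-Kramer
pairwise comparisons at $\alpha = 0.05$ with a compact letter display
(insert-and-absorb).

# What the generators emulate — and what they do not

`simulateTree()` draws pure-birth trees by forward construction (exponential
waiting times at rate $k \times$ birth rate, uniform splitting lineage) and
rescales to height 1. `simulateTraits()` simulates recursively along
branches — BM increments, the exact OU transition, time-rescaled BM for EB,
and Poisson-timed jumps for JN — deliberately a different code path from the
pruning likelihoods, so parameter-recovery tests are not circular.

`simulateLocusPopulation()` draws Hardy-Weinberg genotype pairs, optionally
rejection-resampling until every haplotype has a homozygote.
`simulateAmpliconReads()` samples reads copy-proportionally from the union
of the two haplotypes' gene copies with iid per-base substitution errors.
`simulateQpcrPlate()` encodes copy number as
$-\log_2(copies/calibrator)$ cycles in the target Cq. Because the two genes
are multiplexed in one well, the reaction-level noise draw is shared between
them (it cancels in ΔCt); an independent per-gene noise component is
available via `geneNoiseSd` and defaults to 0. `simulateClusterReadPairs()`
draws uniformly placed inserts from variant sequences in proportion to
expression.

These generators reproduce the *statistical structure the analyses assume* —
not real data: no PCR chimeras, no instrument quality profiles, no
length-dependent amplification bias, no indel errors, no phylogenetic
non-ultrametricity. Passing recovery tests therefore demonstrates
correctness of the estimators under their own assumptions, not robustness to
every artifact of real sequencing.

# Problem sizes used in the test suite

The recovery studies run at the sizes the methods are designed for while
staying desk-scale: model-selection recovery uses 100 replicates of 64-tip
trees for the pulsed-vs-Brownian contrast and 20 replicates each for the
OU/EB sanity checks; BM rate recovery uses 200 replicates at 128 tips;
haplotype deduction uses 50 simulated populations; copy-number recovery uses
1000 individuals; rule-equivalence checks use 100-500 randomized instances
per rule. Likelihood oracles run on trees of 2-6 tips where exact
enumeration, quadrature, and dense linear algebra are feasible.

# Known limitations

* The OU fit uses the non-stationary, root-at-optimum parameterization;
  estimates are not comparable to stationary-OU software without
  transformation.
* The JN mixture pruning is an approximation with quantified error; at
  extreme parameter corners (very high jump rate with tiny jumps) it relies
  on the central-limit collapse.
* The exact-cover haplotype rule is one formalization of "deduced from
  homozygous individuals"; with heavy allelic dropout it degrades to a
  heuristic partial cover.
* The block-edit haplotype comparison counts tandem duplications and
  contiguous deletions only; inversions and translocations are out of scope,
  and the distance is inherently asymmetric because an arbitrary deletion
  has no duplication inverse.
* Efficiency correction beyond the 90-110% acceptance gate (e.g. Pfaffl-type
  per-assay correction) is not implemented.
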