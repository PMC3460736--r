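---
title: "Inferring pathway activity with sparse Bayesian matrix factorization"
author: "pathgaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring pathway activity with sparse Bayesian matrix factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathgaps)
```

## The model

`pathgaps` decomposes a non-negative gene expression matrix $D$
($N$ genes $\times$ $M$ samples) into non-negative amplitude and pattern
matrices under an element-wise Gaussian likelihood,

$$D \sim \mathcal{N}(AP, \Sigma),$$

where $A$ is $N \times p$, $P$ is $p \times M$, and $\Sigma_{ij}$ is the
standard deviation of the measurement for gene $i$ in sample $j$. For
microarray intensities the canonical error model sets
$\Sigma_{ij} = 0.1\,D_{ij}$ (10% multiplicative noise), with a positive
floor at $0.1 \times$ the first percentile of positive values so that the
$\chi^2$ statistic, which divides by $\Sigma$, is always defined
(`compute_uncertainty()`).

Each row of $P$ is a *pattern*: the relative strength of one latent
transcriptional programme across samples. The matching column of $A$ is the
pattern's *gene expression signature*. In a forced-expression cell-line
design the dominant patterns are a constitutive background programme, one
programme per engineered condition, and media/stimulation effects; because
patterns are inferred unsupervised, graded reuse across conditions (pathway
cross-talk) is captured rather than suppressed.

### The atomic prior

Sparsity and non-negativity come from an atomic prior on each factor
matrix. A factor is represented by a set of *atoms*; each atom occupies a
matrix cell and carries a positive mass, and a matrix entry is the summed
mass of its atoms. A priori the atom count is Poisson with intensity
$\alpha$ per matrix element (default $\alpha = 0.01$), locations are
uniform over cells, and masses are exponential with mean equal to the
typical entry magnitude $\sqrt{\overline{D}/p}$ (scaled by
`lambda_scale`). Mass conservation under this prior makes the two natural
moves — redistributing mass between two atoms, and small symmetric
transfers — accept on the likelihood alone.

### The Markov chain

`run_sampler()` runs a Metropolis–Hastings chain over both atomic domains.
One iteration is a sweep of single-atom steps (one per current atom, plus
two); each step picks a domain with probability 1/2 and then a birth/death
or a move/exchange proposal with probability 1/2:

* **birth** — a uniform cell receives a new atom. The mass is drawn from
  an equal mixture of the exponential prior (exploration) and the
  conditional likelihood-times-prior truncated normal for that cell
  (refinement); the Metropolis–Hastings ratio carries the mixture density,
  the Poisson count term $\Lambda/(k+1)$ and the mass prior.
* **death** — a uniformly chosen atom is removed, with the matching
  reverse-proposal density so the pair is in detailed balance.
* **move** — an atom is relocated to a uniform cell, accepted on the
  likelihood ratio.
* **exchange** — two atoms redistribute their summed mass, either by a
  uniform re-split (the conditional of two i.i.d. exponentials given
  their sum) or by a small Gaussian transfer ($\sigma = 0.05 \times$
  the pair's total); both are prior-invariant. The small transfer is what
  lets equilibrated masses fluctuate at the scale of their posterior
  spread, which the gene-set statistic's denominators depend on.

Likelihood changes are evaluated with incremental rank-one residual
updates ($O(M)$ per amplitude change, $O(N)$ per pattern change), and the
residual matrix is refreshed every 100 iterations to cancel float drift.
After `n_burn` burn-in sweeps, every `thin`-th of `n_sample` sweeps is
recorded; posterior means and standard deviations are element-wise moments
over the recorded states. Defaults: 2500 + 2500 sweeps, `thin = 5`,
3 chains (seeds `master + chain`), `max_atoms = 1e5`.

### Initialization and identifiability

Non-negative factorizations of block-design data are not unique: when the
elevated patterns' supports cover groups of samples, the background row
can be split across them (each block row absorbs the background over its
support, a complement row covers the rest) with no likelihood cost. The
atomic prior strongly prefers the consolidated representation — the split
one needs several amplitude atoms per background gene instead of one — but
a chain started in the wrong mode essentially never switches, because the
move set changes one atom at a time and any path between modes crosses a
deep likelihood valley.

The package therefore treats initialization as part of the numerical
design. Chains start from a deterministic rough fit: NNDSVD (non-negative
double SVD) refined by 500 Frobenius multiplicative updates, followed by a
*background consolidation* rotation — the non-negative combination of
pattern rows closest to a flat profile (found by non-negative least
squares) replaces the row it draws on most, with the inverse transform
applied to the amplitudes, whenever that combination is genuinely flat
(coefficient of variation below 0.2). If the rough fit already has a
dedicated background row, or the data have no flat direction, the rotation
is the identity. The start is a function of the data only, so chains with
different seeds sample around the same dominant mode, and cross-chain
agreement (`match_patterns()`) measures sampling stability.

The same degeneracy limits what is *learnable*: when the amplitude matrix
is dense (less than roughly half of its entries zero), background and
block representations come close to exchangeable and the background
pattern is recovered only weakly. The recovery and calibration studies in
the test suite therefore use amplitude sparsity 0.7; denser regimes are a
known limitation of block designs, not of the sampler.

## Choosing the number of patterns

`select_n_patterns()` scans candidate counts, running `n_chains`
independent chains per candidate, and returns the smallest $p$ for which
the relative $\chi^2$ improvement to $p+1$ falls below `rel_tol` while the
patterns reproduce across chains (minimum matched correlation $\ge 0.8$).
A subtlety: the posterior-mean $\chi^2$ keeps decreasing past the true
$p$, because each extra pattern adds roughly $N + M$ effective parameters
and absorbs about one $\chi^2$ unit apiece. The expected spurious relative
improvement is therefore $\approx (N+M)/(NM)$, which at desk scales
(hundreds of genes, tens of samples) exceeds the conservative 1% default.
The package's studies pass `rel_tol = (N+M)/(N*M)` — the
degrees-of-freedom overfitting allowance — which is the operational
reading of "the $\chi^2$ begins to plateau" that we recommend.

## The pattern-level gene-set statistic

Pathway activity is read from the amplitude posterior. For a gene set $G$
with $R$ members and pattern $q$,

$$Z_{G,q} = \frac{1}{R} \sum_{g \in G} \frac{\bar A_{gq}}{\sigma_{gq}},$$

the mean posterior signal-to-noise of the set's amplitudes
(`zscore()`; a $1/\sqrt{R}$ convention is available via
`normalization = "sqrt"` — the permutation null uses same-size sets, so
only the reported magnitude changes). $Z_{G,q}$ is compared with random
sets of the same size drawn from the analyzed gene universe
(`permutation_percentile()`, default 1000 draws), and the percentile $\pi$
is mapped to $\tilde p = 2\pi - 1 \in [-1, 1]$: $+1$ means the set's
amplitudes are over-represented in the pattern (activation), $-1$
under-represented (repression). The percentile estimator is the mid-p
add-one form $(0.5 + \#\{Z^\ast < Z\} + 0.5\,\#\{Z^\ast = Z\})/(1+n)$: it
is strictly inside $(0,1)$, centres an exchangeable null at $1/2$, and
agrees with the usual estimator to $0.5/(1+n)$ when ties are absent.
`score_catalog()` applies the statistic to every TF target set and every
pathway-level union set in a two-level catalog, and `summarize_chains()`
reports mean/min/max of $\tilde p$ across aligned chains.

Worth knowing when interpreting $Z$: under multiplicative noise the
posterior ratio $\bar A/\sigma$ saturates in amplitude (both scale
together), so the statistic is driven by how many set members carry *any*
consistent amplitude in the pattern more than by how large the amplitudes
are. Active target sets stand out because their members are expressed in
the pattern, and the synthetic generator plants sets accordingly.

## Projection onto new cohorts

`project()` transfers signatures to new samples by fixing $A$ (typically
the average of matched chains) and solving the per-sample least-squares
problem $\min_x \lVert d - A x \rVert^2$ over the shared genes. The solve
is unconstrained — the lmFit-style linear projection can and does go
negative when a signature is absent — and negative weights are flagged
rather than clipped. Gene matching is by exact identifier; unmatched
signature genes are dropped with a count, and fewer than 5 shared genes
per signature is an error. Group differences in the projected weights are
tested with Welch's unequal-variance $t$-test (`compare_groups()`), with
sidedness a flag since both one- and two-sided questions arise.

## The linear-model comparison arm

`fit_linear_model()` fits per-gene ordinary least squares against a design
matrix (intercept, cell type, serum in the emulated design), applies an
optional contrast transform, and moderates the variances with the
empirical-Bayes shrinkage of limma (the same construction as published:
prior $d_0, s_0^2$ estimated from the distribution of residual variances,
posterior variance $(d_0 s_0^2 + d\,s_g^2)/(d_0 + d)$). Gene sets are then
tested two ways: the rank-sum gene-set test (midranks, tie-corrected
normal approximation) whose down/up p-value pair is collapsed to the
signed display scale

$$\tilde p_{lm} = \begin{cases}\log_{10} p_{down} & p_{down} < p_{up}\\
-\log_{10} p_{up} & \text{otherwise,}\end{cases}$$

optionally rescaled per signature column to $[-1,1]$
(`heatmap_rescale()`); and the same permutation statistic as the
factorization arm with moderated $t$ in place of the posterior ratio
(`cogaps_style_stat_lm()`). `compare_signatures()` clusters factorization
and linear-model signature columns by average linkage on
$1 - \text{Pearson}$ to show which programmes the two approaches agree
on.

## The synthetic-data generator

`generate_truth()` emulates a forced-expression keratinocyte experiment:

* Amplitudes: $\text{Exp}(1)$ entries zeroed with probability `sparsity`
  (default studies use 0.7), at least 3 non-zeros per column so no pattern
  is degenerate.
* Patterns: a background row at 1 across all samples; samples split into
  $p$ contiguous groups, the first an empty-vector control carried by the
  background alone, the rest elevated to 1 on their group with a 0.05
  floor elsewhere. Every entry carries multiplicative
  $\text{Uniform}(0.85, 1.15)$ jitter — within-condition biological
  replicate variability at the scale typical of cell-line expression
  replicates — so no row is exactly constant and Pearson correlations
  against recovered patterns are well defined.
* Expression: $D = A_{true}P_{true} + \varepsilon$,
  $\varepsilon_{ij} \sim \mathcal{N}(0, (0.1\,(A_{true}P_{true})_{ij})^2)$,
  clipped at zero (clipping is negligible at 10% noise: it needs a
  $-10\sigma$ draw).
* `plant_genesets()` endows chosen patterns with active TF target sets:
  members are drawn from genes with non-zero amplitude in the designated
  column (activating extras only if the column is too sparse) and scaled
  by $1 + \text{effect}$; sets are disjoint within and across patterns
  and recorded in a two-level pathway/TF catalog.
* `add_batch_and_probes()` adds a per-gene additive offset shared by all
  samples of each non-reference batch (a processing-date effect removable
  by the linear model in `correct_batch()`) and duplicates genes into
  probe rows, the non-primary probes degraded with extra noise so
  `collapse_probes()`'s moderated-F selection has a well-defined target.

What the generator does **not** emulate: probe-level (CEL) structure and
normalization artifacts, heavy-tailed or count noise, correlated gene
modules beyond the planted sets, overlapping target sets, and conditions
with unequal replicate numbers. Passing tests therefore demonstrate the
pipeline's internal correctness and calibration under its own error
model, not robustness to everything real microarray data can do.

## Numerical choices and degenerate inputs

* Probe selection uses the moderated $F$ over the whole condition factor
  (the symmetric choice when no contrast list is given); ties break to the
  lexicographically smaller probe id.
* Batch correction fits `~ condition + media + batch` without
  interactions (identifiable in blocked designs), subtracts the fitted
  batch coefficients, clips at zero, and refuses rank-deficient designs
  naming the confounded factors. Correction is idempotent away from the
  clipping boundary.
* Zero posterior standard deviations (a gene untouched by atoms in a
  pattern) are replaced by the smallest positive standard deviation in the
  column before ratios are formed.
* All-zero pattern rows are left unscaled and flagged by
  `normalize_for_report()`; an all-zero expression matrix is rejected when
  uncertainties are built (no positive floor exists).
* Pattern matching solves the assignment problem exactly by enumeration
  (pattern counts are small); constant rows get correlation 0 in the
  matching score rather than NA.
* Every stochastic step takes an explicit integer seed; multi-chain runs
  derive chain seeds as `master + chain`. Identical seeds give
  bit-identical results.

## Study sizes

The bundled studies (test suite and `scripts/acceptance.R`) use
$200 \times 30$ with $p = 4$ for recovery, $500 \times 20$ for error-model
calibration, ten replicates of $100 \times 24$ with a planted $p = 3$ for
pattern-number selection (1000 + 1000 sweeps, 2 chains per candidate), ten
replicates of $300 \times 24$ for planted-set detection, and 5000 genes
for moderated-$t$ prior recovery — sizes at which every quantity of
interest is stable across seeds while a full run stays in the minutes
range on a single CPU.

## Known limitations

* Background recovery degrades for dense amplitude matrices
  (sparsity $\lesssim 0.5$) — see the identifiability discussion above.
* The $\chi^2$ plateau rule needs the degrees-of-freedom-aware `rel_tol`
  at small sample sizes; with the conservative 1% default it selects the
  largest candidate and flags non-convergence.
* Posterior standard deviations come from a single chain's recorded
  states; `average_results()` combines chains' standard deviations as a
  root mean square and deliberately ignores between-chain variance (the
  convention is recorded in the result object).
* The projection arm assumes the new cohort shares gene identifiers and
  scale with the training data; no cross-platform mapping or batch
  harmonization is attempted.
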