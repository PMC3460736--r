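# pathgaps

Pathway activity inference from gene expression by sparse Bayesian matrix
factorization.

`pathgaps` is for analysts who want to read *pathway-level signaling
activity* out of a bulk expression matrix — the kind of question that
arises when engineered cell lines (receptor over-expression, constitutive
pathway mutants, ligand stimulation) are profiled to build signatures that
are later projected onto tumor or drug-response cohorts. Standard
class-comparison pipelines answer "which genes differ between groups";
this package instead infers latent transcriptional programmes shared and
reused across samples, scores curated transcription-factor target sets
against them, and transfers the learned signatures to new data.

## The model

The expression matrix $D$ ($N$ genes × $M$ samples) is factored as

$$D \sim \mathcal{N}(A P,\ \Sigma), \qquad A \ge 0,\ P \ge 0,$$

with $\Sigma_{ij} = 0.1\,D_{ij}$ (the 10% multiplicative microarray error
model). Posteriors for $A$ (gene signatures) and $P$ (pattern weights per
sample) come from a Markov chain Monte Carlo sampler with an **atomic
prior**: each factor is a point process of positive-mass atoms on matrix
cells, which yields sparsity and non-negativity and lets births, deaths,
moves and mass exchanges be evaluated with fast incremental
$\Delta\chi^2$ updates (C++ under the hood). Pattern-level activity of a
gene set $G$ ($R$ genes) in pattern $q$ is the mean posterior
signal-to-noise

$$Z_{G,q} = \frac{1}{R}\sum_{g\in G} \frac{\bar A_{gq}}{\sigma_{gq}},$$

calibrated against random same-size sets by permutation and mapped to
$\tilde p = 2\,\mathrm{percentile} - 1 \in [-1, 1]$ (+1 activation, −1
repression). Signatures are projected onto new cohorts by least squares
with $A$ fixed, and an empirical-Bayes moderated-$t$ linear model
(via limma) provides the comparison arm.

A synthetic-data module emulates the forced-expression experimental
design end to end — block-structured patterns with a vector-control group,
multiplicative noise, batch effects by processing date, multi-probe genes,
and planted active TF target sets — so the whole pipeline is testable
without any external download.

## Worked example

```r
library(pathgaps)

# simulate a 3-pattern forced-expression experiment with planted sets
truth   <- generate_truth(n_genes = 150, n_samples = 24, n_patterns = 3,
                          sparsity = 0.7, seed = 81)
planted <- plant_genesets(truth, sets_per_pattern = 2, set_size = 10,
                          effect = 5, seed = 82)
expr    <- simulate_expression(planted$truth, noise_frac = 0.1, seed = 83)

# three chains, matched and averaged
chains  <- lapply(1:3, function(cc)
  run_sampler(expr, sampler_config(n_patterns = 3, seed = 90 + cc)))
matched <- match_patterns(chains)
avg     <- average_results(matched, D = expr)
avg
#> gaps_fit: 150 genes x 3 patterns x 24 samples; chi2 = 2295

round(matched$correlations, 3)
#>       [,1] [,2] [,3]
#> [1,] 1.000    1    1
#> [2,] 0.997    1    1
#> [3,] 0.998    1    1

# pathway activity per pattern
stats <- score_catalog(avg, planted$catalog, n_perm = 1000, seed = 5)
subset(stats, level == "pathway" & p_tilde > 0.9)
#>      level set_name pattern  R     Z percentile p_tilde n_perm
#> 19 pathway      PW1       1 20 53.05     0.9995  0.9990   1000
#> 22 pathway      PW2       1 20 31.53     0.9705  0.9411   1000
#> 24 pathway      PW2       3 20 27.75     0.9995  0.9990   1000
#> 26 pathway      PW3       2 20 25.74     0.9995  0.9990   1000
```

The cross-chain correlation matrix says the three independent chains found
the same three patterns (row 1 is the reference chain). Each planted
pathway peaks in exactly one recovered pattern — `p_tilde` near +1 means
its targets' amplitudes sit above ~99.9% of random same-size gene sets —
with recovered pattern indices assigned by the sampler, not by the truth
(the background programme came out as pattern 1 here, and PW2/PW3 landed
in patterns 3 and 2). PW2's moderate secondary signal in the background
pattern is genuine gene reuse: its planted members also carry background
amplitude. (`chi2` is the Gaussian goodness-of-fit of the averaged
factors; with the 10% error model a value near $N \times M$, here 3600,
indicates a fit compatible with the noise.)

Projection onto held-out data and group comparison:

```r
proj <- project(expr, avg$A_mean)              # (here: training data)
compare_groups(proj, setNames(planted$truth$design$condition,
                              planted$truth$design$sample_id),
               pattern = 2, sided = "two", group_order = c("EGFR", "p65"))
#> $t        -23.97
#> $p_value  4.7e-08
```

(Recovered pattern 2 carries the p65 group's programme here, so the
EGFR-vs-p65 contrast on it comes out strongly negative.)

An end-to-end run on generated data (preprocessing → factorization →
gene-set scoring → projection → linear baseline, with a manifest of every
artifact) is one call:

```r
pipeline_demo("demo_out", seed = 7)
```

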