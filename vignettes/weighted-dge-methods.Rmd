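---
title: "Weighted differential expression without model assumptions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted differential expression without model assumptions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weightedDGE)
```

## The problem

A UMI count matrix records, for every gene $Z$ and cell $i$, the number of
unique transcripts $N_{Z,i}$ detected in that cell. Total counts per cell
$N_i = \sum_Z N_{Z,i}$ routinely span two orders of magnitude even within a
homogeneous population, because of differences in transcriptional activity,
capture efficiency and sequencing depth. Any statement about differential
expression is therefore a statement about the *relative* expression

$$n_{Z,i} = N_{Z,i} / N_i,$$

and a cell with $N_i = 50{,}000$ measures $n_{Z,i}$ far more precisely than
a cell with $N_i = 800$. Common tests ignore this: rank tests (Wilcoxon)
and unweighted t-tests treat every cell as equally informative, while
pseudo-bulk aggregation treats cells as exactly proportionally informative
to their depth. Both extremes are wrong for most genes, and both produce
false findings when depth distributions differ between the compared groups
— which they essentially always do.

## Cells as clusters: the weighting model

weightedDGE treats each cell as an independent experimental cluster of size
$N_i$, borrowing the machinery of cluster-randomized experiments. The mean
relative expression is a weighted average
$\bar n_Z = \sum_i w_{Z,i}\, n_{Z,i}$ with normalized weights

$$w_{Z,i} \propto \frac{N_i}{1 + \rho_Z\,(N_i - 1)},$$

where $\rho_Z \in [0, 1]$ is the intracluster correlation coefficient
(ICC) of gene $Z$: the fraction of the total variance of $n_{Z,i}$
attributable to genuine cell-to-cell differences rather than transcript
sampling. At $\rho_Z = 0$ the weights reduce to $N_i / \sum N_i$
(aggregate counts, the pseudo-bulk limit); at $\rho_Z = 1$ they reduce to
$1/N$ (unweighted averaging). Real genes sit in between, and the package
reports where, per gene, through the weight distribution coefficient
$\mathrm{WDC}_Z = \mathrm{Var}(w_{Z,i}) / \mathrm{Var}(w_{AC,i})$, which is
0 in the equal-weight regime and 1 in the aggregate-count regime (both
variances are population variances, so the ratio is convention-free; values
slightly above 1 are mathematically possible and are not clipped).

### ICC estimation

$\rho_Z$ is estimated by the one-way ANOVA moment estimator for clustered
binary outcomes (Fleiss–Donner), the standard estimator in
cluster-randomized trials: with $k$ cells, $M = \sum N_i$, per-cell
proportions $p_i$ and pooled proportion $\bar p$,

$$\hat\rho_Z = \frac{MSB - MSW}{MSB + (n_0 - 1)\,MSW}, \qquad
n_0 = \frac{M - \sum N_i^2 / M}{k - 1},$$

clamped to $[0, 1]$. The estimate is a single moment-based pass — no
iteration between weights and ICC, no distributional fit, no shrinkage
across genes. A zero or negative denominator (a constant gene) yields
$\hat\rho = 0$: no between-cell variance is detectable, so the weights fall
back to the aggregate-count limit, which is exact for pure sampling noise.
Cells with $N_i = 0$ carry no information about relative expression and
must be removed before estimation; the high-level drivers drop them with a
warning, the low-level functions treat them as errors.

### Variance of the weighted mean

Because the weights approximate inverse variances of the per-cell
measurements, the package uses the classical unbiased variance formula for
means of measurements with non-uniform accuracy,

$$\widehat{\mathrm{Var}}(\bar n_Z)
  = \frac{\sum_i w_{Z,i}\,(n_{Z,i} - \bar n_Z)^2}{k - 1},$$

which reduces to $s^2/n$ at equal weights. The frequently seen alternative
$\sum w (x - \bar x)^2 \cdot \sum w^2 / (1 - \sum w^2)$ is unbiased only
when all observations share one variance and the weights are arbitrary —
the opposite of the situation here. The distinction matters in practice: in
a direct simulation with inverse-variance weights the homoscedastic form
overestimates the variance of the mean about threefold, and in the
package's own null calibration it drives the weighted t-test's empirical
size at $p < 0.05$ down to $\approx 0.02$; the formula above restores
nominal size ($0.050$, Kolmogorov–Smirnov distance from uniform $< 0.05$
over thousands of null genes). The Kish effective sample size
$n_{\mathrm{eff}} = 1 / \sum_i w_{Z,i}^2$ is carried alongside for degrees
of freedom.

## Statistical testing

**Weighted t-test.** Two groups are compared by
$t = (\bar n_A - \bar n_B) / \sqrt{\hat V_A + \hat V_B}$, two-tailed, with
unequal variances and Welch–Satterthwaite degrees of freedom in which each
group contributes $n_{\mathrm{eff}} - 1$ denominator degrees of freedom.
With equal weights this is *exactly* Welch's t-test (the test suite holds
the two to $10^{-10}$ in p across 1,000 random fixtures). The ICC — and
hence the weights — is estimated separately within each group, because the
weights describe measurement precision inside the sample being averaged.

**Aggregate χ² test.** A Pearson chi-squared test (df = 1, no continuity
correction — aggregate totals are of order $10^5$–$10^7$, where the
correction is negligible) on the 2×2 table of gene vs non-gene aggregate
counts. This test sees only transcript-sampling variance, not cell-to-cell
variance, so it underestimates the total variance and must never be used
alone. Its role is the opposite: a weighted-t discovery that the χ² test
does *not* support is suspicious — significant redistribution of counts
across cells without any change in aggregate expression, which can be real
biology but can also be cell-sampling bias.

**Combination rules.** Two rules are provided. `proxy` (default for
single-cell data): report the χ² p-value instead of the weighted-t one
when the former, but not the latter, exceeds the significance floor
(default 0.05) — moderately conservative. `max`: report the larger of the
two p-values — maximally conservative, and the default in spatial mode.
The proxy rule is deliberately non-monotone in the weighted-t p-value at
the floor (that is its definition); the max rule is monotone and dominates
both inputs. No multiple-testing correction is applied anywhere; adjusted
p-values are a question-dependent afterthought best left to `p.adjust()`
on the reported column.

**Comparators.** For benchmarking, the package carries the standard tests
alongside: the two-sided Wilcoxon rank-sum test (tie-corrected normal
approximation with continuity correction, exact enumeration for small
tie-free groups), and unweighted Welch t-tests on relative counts and on
log-normalized counts $\log(1 + 10^4\, n_{Z,i})$ (the scale-factor-10,000
natural-log convention of the mainstream single-cell toolchains). These
are implemented as vectorised internals for throughput over $10^4$ genes
and are pinned to `wilcox.test`/`t.test`/`chisq.test` oracles in the test
suite.

## Multiple samples: weighted averaging instead of pseudo-bulk

With several biological replicates per condition, each sample $s$ yields a
per-gene weighted mean $\bar n_{Z,s}$ and its variance. Samples are then
combined with inverse-variance weights $W_s \propto 1/\widehat{\mathrm{Var}}(\bar n_{Z,s})$,
the between-sample variance of the condition mean is estimated with the
same non-uniform-accuracy formula applied at the sample level, and
conditions are compared by a Welch-type t-test whose per-condition degrees
of freedom are $n_{\mathrm{eff}}(\text{samples}) - 1$ — equal to $S - 1$
at equal weights and smaller when one sample dominates, which is the
conservative direction. A sample with zero estimated variance (e.g. a gene
absent from it) is floored at $10^{-3}$ times the smallest positive
variance among its condition's samples, keeping weights finite while
preserving their ordering; when no sample has positive variance the
weights fall back to equal. Aggregate-count comparators (unweighted and
inverse-binomial-variance-weighted t-tests on per-sample aggregate ratios)
are included for benchmarking against pseudo-bulk-style analysis.

## Spatial mode

Spatial bins carry far fewer counts than cells and may mix material from
several cells, so per-bin biological variance is largely unresolvable and
the aggregate-count limit is the defensible choice: spatial mode forces
$\rho_Z = 0$, applies a 10% detection filter, and combines the weighted-t
and χ² p-values with the conservative `max` rule. In the low-count regime
the two p-values track each other closely (rank correlation > 0.95 in the
test suite), which is the expected behaviour when transcript-sampling
variance dominates. Bin QC mirrors routine spatial practice: strictly more
than a minimum number of detected features per bin, strictly more than a
minimum count after excluding user-listed dominating genes, a mitochondrial
UMI fraction inside an inclusive band (mitochondrial genes recognized by a
case-insensitive id prefix, default `mt-`), and minimum UMI fractions for
required marker genes. Spatial coordinates are never needed: bin selections
arrive as barcode lists.

## The simulation machinery

**Thinning.** `subsample_umis()` has two modes. `binomial` replaces each
entry by an independent $\mathrm{Binomial}(N_{Z,i}, p)$ draw — per-UMI
Bernoulli retention, the canonical depth-reduction model, and the mode
used for the retention-fraction law. `per_gene` retains exactly
$\mathrm{round}(p \cdot \sum_i N_{Z,i})$ of each gene's UMIs, selected
uniformly across cells (multivariate hypergeometric). The benchmark driver
defaults to `per_gene`: it makes every per-gene aggregate deterministic, so
the original-vs-thinned comparison isolates exactly the count-dropout and
redistribution effects that break rank and log-normalized tests, with no
residual aggregate-level noise for the χ² test to pick up. Under binomial
thinning the χ² statistic retains a small genuine aggregate signal
(deflated roughly 1.5-fold against its null, leaving a ~0.3% tail at
$p < 0.05$), which is a property of that thinning model, not of the test.

**Noise.** `noise_fn(alpha, N)` returns
$\mathrm{round}(U \cdot sf(\alpha, N)\sqrt{N})$ with $U \sim
\mathrm{Uniform}(-1, 1)$ and $sf = \sqrt{3\alpha} - (\sqrt{3\alpha} - 1) /
(1 + 0.1 N)$. This amplitude is the simplest form satisfying the
calibration constraints the noise model is built around:
$\mathrm{Var} \to \alpha N$ as $N \to \infty$ (the $\sqrt{3\alpha}$
factor), $f_n(\alpha, 0) = 0$, maximum amplitude close to $N$ for small
counts, and $N + f_n \ge 0$ for $\alpha < 10$ (counts are clamped at zero
defensively and the event counted). The mid-range $\alpha = 5$ is the
default throughout. Rounding is round-half-even everywhere.

**Upregulation.** `apply_upregulation()` maps $N \mapsto N +
\mathrm{round}((\beta - 1) N)$: an expected multiplicative change of
$\beta$, exact wherever $(\beta - 1)N$ is integral — so $\beta = 1.5$ adds
exactly 50% on even counts, while $\beta = 1.3$ on moderate counts
realizes a 25–30% aggregate increase because of rounding loss on small
integers.

**Synthetic matrices.** `generate_synthetic()` emulates the structural
features of a deeply sequenced droplet dataset that the method's behaviour
depends on: log-normal per-cell depths (defaults: median $10^4$,
$\sigma_{\log} = 0.82$, i.e. a ~25-fold central and ~100-fold overall
spread with totals roughly 2,000–50,000), a heavy-tailed log-normal
abundance spectrum sized so that roughly 12,000 of 14,000 genes clear the
30-total-count filter at 1,000 cells, and per-gene biological dispersion:
each gene's expected proportion is multiplied per cell by a gamma variate
of mean 1 and gene-specific variance drawn log-normally across three
orders of magnitude (median 0.25), renormalized within the cell, and
counts drawn multinomially so column sums equal the drawn depths exactly.
The dispersion spread produces estimated ICC/WDC values covering the full
(0, 1] range, with highly expressed and highly dispersed genes at low WDC
— the qualitative pattern seen in real populations. What the generator
does *not* emulate: doublets, ambient RNA, batch structure, gene–gene
correlation beyond compositional closure, and cell-type mixtures; passing
benchmarks on it therefore demonstrate the statistical properties of the
tests under depth variation, dropout and overdispersion, not robustness to
every experimental artifact. Because counts are compositional, planting a
fold change $\beta$ on a gene set with total abundance share $a$ realizes
$\beta / (1 + (\beta - 1)a)$ in relative expression — the tests account
for this when checking recovery.

**Tallying.** `tally_benchmark()` scores results against the generator's
truth table in two modes: calls by p-value alone, and calls requiring
$|\log_2 FC| > 0.1$ as well (a planted gene is missed when $p \ge$
threshold and/or its fold change falls below 0.1). False-positive
fractions are computed over unmodified and noise-only genes,
false-negative fractions over upregulated ones, with medians and quartiles
across replicates.

## Numerical and design notes

- Deterministic RNG streams: every stochastic operation derives an
  independent sub-seed from (user seed, operation tag), so pipelines are
  reproducible stage-by-stage and rerunning one stage does not perturb the
  next.
- Filters: the gene-total filter is strictly `>` (a "more than 30 counts"
  convention); the detection filter applies per group rather than pooled —
  conservative and symmetric. Filters are idempotent and genes failing
  them are absent from output rather than carried as NA rows.
- Degenerate inputs: both group variances zero with equal means gives
  $p = 1$; with unequal means $p = 0$ and an infinite t (flagged by the
  sign); a gene absent from both groups has an undefined χ² p (`NA`),
  and the combination falls back to the weighted-t p. A fold change with
  exactly one zero mean is `Inf`/`-Inf`; with both zero it is `NA`.
- Duplicate feature ids on disk are disambiguated deterministically with
  `.1`, `.2`, … suffixes; matrices with `real` Matrix Market headers are
  accepted but non-integral values are rejected, since every statistic in
  the package is defined on raw UMI counts.
- Problem sizes used by the shipped benchmarks: the thinning and
  noise-plus-upregulation studies run on a 1,000-cell, 14,000-gene
  synthetic base (~12,800 genes above the count filter); the multi-sample
  design uses 5 samples per condition subsetting 20–100% of those cells;
  the calibration study uses two independent 500-cell groups with ~3,000
  genes. These sizes resolve the claimed effects comfortably (the
  catastrophic comparator failure rates have standard errors well below a
  percentage point) while keeping a full benchmark run in minutes on one
  core.

## Known limitations

- The weighted t-test treats cells as independent replicates. When cells
  within one library share systematic technical structure, single-library
  p-values are optimistic regardless of weighting; the multi-sample mode
  exists precisely for that case.
- The ICC moment estimator is noisy for genes observed in few cells; no
  shrinkage is applied by design (the method is deliberately moment-based
  and assumption-free), so very sparse genes inherit wide weight
  uncertainty. The count filter is the blunt but honest guard.
- Spatial mode interprets fold changes at the aggregate level; per-cell
  biological variability within bins is not recoverable from binned
  counts. Grouping bins into cluster-level samples is a possible future
  refinement.
- Imaging-based panels (non-sequencing spatial assays) violate the
  relative-count normalization this package is built on and are out of
  scope.
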