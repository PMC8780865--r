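---
title: "Methods: dose-response toxicogenomics with hlctox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response toxicogenomics with hlctox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlctox)
```

hlctox analyses concentration-response toxicogenomics screens on
hepatocyte-like cell (HLC) models: an LDH cytotoxicity screen, a targeted
RNA-seq counts matrix over a chemical x concentration design, and
fold-change tables from other hepatocyte systems to benchmark against.
This vignette documents the statistical model behind each stage, the
default parameters and why they were chosen, the numerical decisions that
matter for reproducibility, and the realism limits of the bundled
synthetic-data generator.

## 1. Cytotoxicity and dose-response

LDH release is converted to percent cytotoxicity against the plate's
negative (vehicle) and positive (full-lysis) controls:

$$\mathrm{cytotoxicity\ \%} = 100 \cdot
  \frac{A_\mathrm{sample} - A_\mathrm{NC}}{A_\mathrm{PC} - A_\mathrm{NC}}$$

The transform is affine in absorbance, exactly 0% at the NC and 100% at
the PC, and deliberately not clipped: values slightly outside [0, 100]
are informative noise, not errors.

Dose-response curves use the four-parameter logistic (4PL)

$$f(x) = c + \frac{d - c}{1 + (x/e)^{-b}}$$

with lower asymptote $c$, upper asymptote $d$, slope $b > 0$ and
inflection concentration $e > 0$. The curve is parameterised on the
natural concentration scale, so the vehicle ($x = 0$) evaluates to $c$
exactly and no log-dose placeholder is needed. ICx values invert the
fitted curve in closed form:

$$\mathrm{ICx} = e \left( \frac{d - c}{x - c} - 1 \right)^{-1/b},$$

which composes with $f$ to the identity within 1e-9 (verified in the
test suite). Fitting is bounded Levenberg-Marquardt
(`minpack.lm::nlsLM`) from four deterministic starting points (slope
1 and 2, inflection at the dose-range midpoint and at the dose closest
to half-maximal response), keeping the fit deterministic without a
random multi-start.

A chemical is classified as acutely cytotoxic when (i) the 4PL fits
significantly better than a flat line under the extra-sum-of-squares
F-test at p < 0.05 and (ii) the fitted response range reaches at least
10% — the second condition screens out statistically significant but
biologically negligible slopes.

## 2. Differential expression

Counts are normalised with median-of-ratios size factors computed over
zero-free genes and rescaled to geometric mean one; `log2cpm()`
(log2 of counts per million plus one) is the expression scale for
heatmaps and networks only, never for testing.

Each gene is modelled with a negative-binomial GLM with log link,
`log(size factor)` offset, and linear predictor
$\beta_0 + \beta \cdot \mathrm{concentration}$, so $\beta$ is the
fold change per micromolar (reported on the log2 scale). The dispersion
$\alpha$ (variance $= \mu + \alpha \mu^2$) is a pooled method-of-moments
estimate across concentration groups with no cross-gene shrinkage — at
desk scale the transparency of a closed-form estimator outweighs the
efficiency gain of shrinkage.

**Why a quasi-likelihood Wald test.** The textbook Wald test
($\hat\beta / \mathrm{SE}$ against a standard normal) is anticonservative
at screen-typical replication: on a pure-null simulation (2000 genes,
six samples, $\alpha = 0.1$) it rejected 15.3% of genes at p < 0.05,
because the plug-in method-of-moments dispersion is itself noisy at
$n = 6$. hlctox therefore scales the standard error by the square root
of the fit's residual Pearson dispersion and refers the statistic to a
t distribution on the residual degrees of freedom. On the same null this
rejects 5.0% at p < 0.05 with a Kolmogorov-Smirnov distance of 0.018
from uniformity. A per-gene maximum-likelihood dispersion
(`glm.nb`-style) was evaluated and rejected (18.4% null rejections).
P-values are BH-adjusted per chemical; the DE set is `p_adj < 0.05`.

## 3. Pathway enrichment

Overrepresentation of a pathway with $R$ of the $N$ universe genes DE
and $r$ of the pathway's $n$ members DE is scored as a z-statistic
against the hypergeometric null:

$$z = \frac{r - nR/N}
  {\sqrt{n \frac{R}{N}\left(1 - \frac{R}{N}\right)
   \left(1 - \frac{n - 1}{N - 1}\right)}}$$

The numerator and denominator are exactly the hypergeometric mean and
standard deviation (the last factor is the finite-population
correction), so the score is symmetric in $n$ and $R$, and
$|z| \ge 1.96$ is an asymptotic 5% two-sided test. Degenerate
configurations ($R = 0$, $R = N$, $n = 0$, $n = N$) have zero variance
and return `NA` rather than an arbitrary value. Concentration profiles
(`enrichment_profile()`) contrast each positive concentration against
vehicle with DE at raw p < 0.05 — raw rather than adjusted, because the
profile is a descriptive trajectory, not an inferential endpoint.

Discreteness matters at small $N$: for example, at $N = 200$, $R = 30$,
$n = 20$ the exact null probability of $|z| \ge 1.96$ is about 7%, not
5%. The test suite checks Monte-Carlo rates against the exact
hypergeometric tail, not the nominal level.

## 4. Co-expression modules

The network is signed WGCNA-style: adjacency
$a_{ij} = \left(\frac{1 + \mathrm{cor}(x_i, x_j)}{2}\right)^\beta$, so
anticorrelated genes get adjacency near 0 instead of being conflated
with correlated ones. Zero-variance genes have their correlations set
to 0 (adjacency $0.5^\beta$ to everything) and a warning is issued. The
soft threshold $\beta$ defaults to the smallest power in {1, ..., 20}
whose degree distribution reaches a scale-free fit $R^2 \ge 0.8$
(falling back to the best power found).

Topological overlap smooths the adjacency by shared neighbourhoods:

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}}$$

Modules are average-linkage clusters of `1 - TOM`, cut at a fixed
0.99 x (maximum merge height), with a minimum size of 20 genes;
smaller clusters are left `"unassigned"`. Modules whose eigengenes
correlate above 0.9 are merged. The eigengene is the first right
singular vector of the row-standardised module submatrix, sign-oriented
so that the average gene correlates positively with it; kME is each
gene's correlation with its module eigengene. A fixed-height cut was
chosen over adaptive (dynamic) tree cutting for determinism and
auditability; the cost is sensitivity to weak correlation structure —
with faint module signal the whole tree can merge below the cut and
recovery degrades before it fails loudly (see Section 7).

Module activity per sample is rank-based:
$(\bar{r}_\mathrm{module} - \bar{r}_\mathrm{rest}) / (G/2)$ over the
within-sample expression ranks of the $G$ genes — bounded in $[-1, 1]$,
zero-mean under exchangeability, and invariant to any monotone
transform of the expression scale.

## 5. Candidate-gene selection

A gene is a candidate when all three filters hold: kME above 0.65 in a
target module (cluster centrality), a positive concentration slope with
`p_adj` below 0.05 for at least one chemical (induction), and membership
in a curated evidence list (prior support). The intersection is strict
by design: each filter admits a distinct failure mode and the
pipeline's purpose is a short reviewable list, not a ranking of the
transcriptome. Candidates are ordered by kME, then adjusted p.

## 6. Cross-model benchmark

For each gene in the harmonised universe the similarity ratio is

$$S_i = \frac{\log_2 \mathrm{FC}_\mathrm{model}}
  {\log_2 \mathrm{FC}_\mathrm{gold}}$$

($S_i = 1$: perfect agreement; 0.5: half the gold response; negative:
discordant direction). The universe is the intersection of all tables
restricted to the gold-standard DE set; ortholog maps translate model
gene symbols to the gold namespace, and ambiguous (one-to-many) or
unmapped symbols are dropped with a warning rather than guessed. The
recovery curve counts genes with $S_i \ge t$ over a threshold grid
(default 0 to 2 in steps of 0.05) and `recovered_at_one()` is its value
at $t = 1$. Because $S_i$ concentrates at the planted scale, thresholds
lying exactly on that scale are a floating-point knife edge; comparisons
should bracket the value of interest.

## 7. The synthetic-data generator: realism and limits

All generators are seeded and reproducible (`with_rng()` restores the
caller's RNG state; derived child seeds stay below 2^31). Plates draw
absorbances around a true 4PL with Gaussian noise plus NC/PC control
wells. Counts are negative binomial with
mean $= sf \cdot \mathrm{baseline} \cdot 2^{\mathrm{effect} \cdot
\mathrm{conc}} \cdot L$, where $L$ is a log-normal latent factor shared
by each (module, sample) pair — this is what makes planted modules
co-express. Defaults (400 genes, 8 modules, 7 chemicals, concentrations
0-2 uM, 3 replicates, dispersion 0.01-0.2, baseline mean 50-500,
library-size CV 0.2, module sdlog 0.2) keep a full study under a minute
on one CPU while leaving every stage's signal detectable but not
trivial.

Known limits, deliberately not tuned away:

- **Composition bias.** Median-of-ratios normalisation assumes most
  genes unchanged. When a chemical up-regulates a large fraction of a
  small panel (e.g. three stress pathways of a 400-gene panel), size
  factors absorb part of the shift and unaffected genes acquire small
  negative slopes; with enough replication some become "DE". On the
  default study the strongest chemical produces a few dozen such false
  positives. This is a faithful reproduction of a real failure mode of
  global-scaling normalisation on targeted panels, so the generator
  keeps it.
- **Weak-signal module merging.** With module sdlog around 0.2 the
  within-module expression correlation is ~0.3, and the fixed-height
  cut recovers modules only at high soft-thresholding powers; the
  automatic power selection usually lands there, but partial recovery
  (adjusted Rand index ~0.5 on the default study) is expected, not a
  bug.
- **No batch structure, no probe-level artefacts.** Samples are
  exchangeable given the design; there are no plate, lane or probe GC
  effects. Library size is a single log-normal factor.
- **Linear log-scale dose effects.** Planted expression effects are
  linear in concentration on the log2 scale, matching the GLM's
  alternative exactly — generator and test share the model class, so DE
  sensitivity estimates are upper bounds.

## 8. Pipeline and reproducibility

`run_pipeline()` executes the configured stages from a flat YAML config
(CLI flags override config keys), writes plain TSV/JSON outputs, and
ends with a `manifest.json` recording the package version, seed,
parameters, and MD5 hashes of all inputs and outputs. Outputs contain
no timestamps, so identical config + seed gives byte-identical files;
the manifest hashes change iff an input or parameter changes. A thin
command-line wrapper ships at `system.file("cli", "hlctox.R",
package = "hlctox")` with subcommands `simulate`, `cytotox`, `de`,
`enrich`, `modules`, `select-genes`, `benchmark` and `run-all`.

```{r demo, eval = FALSE}
dir <- tempfile("hlctox_demo")
run_demo(dir, seed = 7)          # synthetic inputs + full analysis
list.files(file.path(dir, "results"))
```
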