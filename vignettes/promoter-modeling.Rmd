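---
title: "Modeling gene expression from promoter TFBS content"
author: "promod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gene expression from promoter TFBS content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promod)
```

# The problem

Two closely related cell populations — the motivating system is long-term
versus short-term hematopoietic stem cells, generically "condition 1" and
"condition 2" — differ in the expression of a few thousand genes. The
package asks which transcription-factor binding sites (TFBSs) in the
proximal promoters of those differentially expressed genes (DEGs) explain
their expression, whether TF–TF co-occurrence carries additional signal,
and how inferred TFBS activities change between the two conditions.

The modeling assumption is the classic linear one: the (transformed)
expression of gene $i$ is a weighted sum of the promoter's TFBS content,

$$ y_i = \beta_0 + \sum_j \beta_j\, x_{ij} + \varepsilon_i, $$

where $x_{ij}$ is a *TFBS–gene association score* (TGAS) summarizing all
hits of site $j$ in promoter $i$, and the fitted coefficient $\beta_j$ is
read as the regulatory activity of site $j$ in that gene class and
condition — positive for activation, negative for repression.

# Stage by stage

## Gene classes

Genes are split into four classes from their two-condition FPKMs: **A**
(up in condition 1 by at least the fold-change threshold), **B** (up in
condition 2), **C** (expressed, steady state), **D** (below the expression
threshold in both conditions). Defaults: fold-change threshold 2
(inclusive at the boundary), expression threshold 1 FPKM; both
configurable. The fold change is `max(r, 1/r)` of the pseudo-counted FPKM
ratio; classification uses pseudo-count 0 with a `1e-9` guard when exactly
one value is zero, so that a ratio like 6.4252/1.0 is reported exactly as
printed. Classes A and B are modeled separately, in each condition — four
models in all.

## TGAS schemes

Each hit of TFBS $j$ at position $k$ in promoter $i$ contributes a score
$g_{ijk}$, and $x_{ij} = \sum_k g_{ijk}$. Five compositions are available:

| scheme | per-hit score | adds |
|--------|--------------|------|
| I   | $s$ | motif match score alone, $s \in [0,1]$ |
| II  | $s\,L$ | positional bias weight $L$ |
| III | $s\,L\,F_j$ | TF expression fold-change weight |
| IV  | as III | columns whose every binding TF is unexpressed are deleted |
| V   | $s\,L\,F_j\,(1+I_j)$ | TF–TF interaction score |

$F_j$ aggregates the expression-change weights of the TFs binding site
$j$ by their maximum; a sum would conflate the number of binding TFs with
the size of their expression change, and TF-count effects enter separately
through $I_j$. $F = 1$ (neutral) for TFs below the expression threshold in
both conditions or absent from the expression table. The interaction
score $I_j = \sum_{t \in \mathrm{bind}(j)} \sum_{t'} \Pr(t,t')\,F(t')$
sums over interaction partners; scheme V multiplies III by $(1+I_j)$ so
that it reduces *exactly* to III when all interaction probabilities are
zero. Ablations V-1/V-2 set $F := 0$ for masked TF sets (undetected TFs,
Class-D TFs) before aggregation, which can only reduce scores; V-3
deletes a supplied TFBS exclusion list.

## Positional weight L

For each TFBS the TSS-relative hit positions are binned (500 bp default)
over the promoter window (±5,000 bp default; the window is configuration,
never hard-coded), giving $h_{obs}$. A reference histogram $h_{rand}$ is
the mean over 100 uniform re-placements of the same number of positions —
averaging many draws rather than taking one reduces Monte-Carlo noise in
the denominator. The weight of a hit in bin $m$ is

$$ L = \frac{h_{obs}(m)}{h_{obs}(m) + h_{rand}(m)} \in [0,1], $$

0.5 when a bin is empty in both histograms. This form is the package's
single most consequential modeling assumption: it has the required range,
equals 0.5 for positionally random sites, and increases monotonically
with observed concentration. Histograms are computed per gene-class
promoter set, matching the per-class models. Strand is recorded but does
not enter any score.

## TF–TF interactions: log-linear models under random sampling

Co-occurrence of TFs in promoters is summarized by a binary occupancy
matrix (TF occupies promoter = any hit of any site it binds). For a set
of $k$ TFs the $2^k$ contingency table is modeled with hierarchical
log-linear models indexed by an edge set over the TFs; retained edges are
the inferred pairwise interactions. Fitting is by iterative proportional
fitting (IPF) from an independence start.

Backward elimination starts from the full model FM containing every
two-factor interaction term and repeatedly tests each remaining edge:
`p_RM` from the 1-df deviance increase against the current model, `p_FM`
from the deviance difference between FM and the reduced model. The
removal with the largest `p_RM` among candidates with both p-values above
$\alpha$ (default 0.05) is accepted; elimination stops when none
qualifies. Two numerical choices matter here:

* **FM is the all-two-factor hierarchy, not the saturated model.** With
  $n \approx 2{,}000$ promoters spread over $2^{10}$ cells, the table is
  sparse; likelihood-ratio tests against near-saturated graphical models
  are severely anti-conservative (we measured median per-pair retention
  of ~0.45 for truly independent TFs under that variant). Between smooth
  pairwise models every removal test has 1 df and remains calibrated
  under sparseness. `ipf_fit()` still offers clique generators, under
  which the complete graph is the saturated model with deviance exactly 0.
* **IPF stops at a margin gap below `1e-3`** (sweep cap 1,000). Dense
  non-decomposable generators on sparse tables converge linearly and
  would not reach much tighter gaps within any reasonable cap; the
  deviance differences that drive the tests are insensitive at this
  level, and decomposable fits reach machine precision regardless.
  Candidate fits warm-start from the current fit with the removed edge's
  interaction term flattened out, which is exact (the adjusted table lies
  inside the candidate hierarchy) and cuts fitting to a few sweeps.

Because all TFs at once are intractable, `run_sampling()` draws random
size-$k$ subsets ($k = 10$ default), counts a trial $t$ for every pair in
the subset and an edge observation $f$ for every retained edge, and
reports $\Pr = f/t$ per pair. Sampling stops when the set
$\{\Pr \ge 0.5\}$ is unchanged for `stop_window` consecutive iterations
or at `max_iter`. Failed fits are rolled back so $\Pr$ stays a frequency
over completed fits; pairs co-sampled fewer than `min_trials = 30` times
are excluded from retrieval to avoid small-$t$ artifacts.

**What Pr is and is not.** Pr averages over sampled TF *contexts*, not
over datasets. A pair whose sample association happens to clear the test
level — expected for a fraction $\approx \alpha$ of the null pairs at any
sample size — is retained in most contexts and ends with high Pr. On
synthetic data with 20 TFs and five planted odds-ratio-3 pairs
($n = 2{,}000$), all five planted edges reach $\Pr = 1.0$ and rank first,
but ~9 of the 185 null pairs also pass $\Pr \ge 0.5$, capping precision
near 0.35. Treat the thresholded list as a ranking with an
$\alpha$-governed false-positive floor, not as a calibrated edge set.

## Regression, pairwise search, and RC ensembles

Per class and condition, predictors are the z-scored TGAS columns
(zero-variance columns become inert zeros) and the response is
`log2(FPKM + 1)` by default — raw-FPKM regression is dominated by
outliers; the identity transform is available and recorded in the run
manifest. An intercept is always included (harmless under
standardization).

1. **AIC backward elimination** of main effects (Gaussian AIC,
   `n log(RSS/n) + 2(p+1)`): drop the column whose removal most decreases
   AIC until none does. This is deterministic, so it runs once per model.
2. **Randomized pairwise search.** Candidates are elementwise products of
   all distinct pairs of *removed* columns (standardized after forming);
   pairwise terms never combine retained main effects. In a
   seed-determined random order, each candidate joins the model iff the
   mean test-fold Pearson r of a 5-fold cross-validation strictly
   improves (ties reject, for parsimony). Folds are a seed-determined
   near-equal partition drawn once per run. Degenerate folds
   (zero-variance predictions) contribute 0. Internally the CV uses
   exact incremental orthogonal updates, since accepted terms can grow
   the model past a hundred columns.
3. **The run ends with a refit on all genes**; the model quality $R$ is
   the Pearson correlation between observed and fitted response.
4. **100 seeded repetitions** (`base_seed + i`) give each TFBS an
   ensemble of regression coefficients (RCs): its main-effect coefficient
   where retained, else the sum of coefficients of accepted pairwise
   terms containing it. Runs are embarrassingly parallel and independent
   of the thread count because every run's seed is fixed.

TFBS activity is then tested per ensemble (one-sample t against 0),
compared between conditions (Welch two-sample t; classified gain / loss /
sign-flip / unchanged, with `strength_increased` flagging growth in
magnitude), and significant sites are expanded into TF–gene networks
through the binding map. Reporting uses uncorrected p-values at
$\alpha = 0.05$ with Bonferroni-adjusted columns alongside.

**Known limitation: the ensemble test is anti-conservative.** The 100
runs share one dataset; only folds and candidate order differ. Junk
pairwise terms accepted by the CV gate reflect genuine whole-sample
chance correlations, so even a null TFBS's attributed RCs concentrate on
a stable nonzero value, and the one-sample t-test (n = 100, tiny
across-run variance) rejects far more often than $\alpha$: with a pure
noise response at the default synthetic scale, roughly three quarters of TFBSs test
significant. Sensitivity for genuinely planted effects is excellent
(1.0 at noise = 0.2 signal sd, mean $R \approx 0.98$), but significance
calls should be read as a ranking of effect stability, not as calibrated
hypothesis tests; the between-condition two-sample test partially cancels
the shared-data bias and is the safer comparison.

# The synthetic-data generator

`simulate_dataset()` (and the smaller `gen_*` generators it composes)
emulates the study's inputs with known ground truth: log-normal/uniform
FPKM pairs planted so classification recovers the labels exactly (default
2,000 genes at fractions A/B/C/D = 0.2/0.2/0.35/0.25, i.e. 400 genes per
DEG class); Poisson motif-hit counts with Beta(5, 1.5) match scores,
uniform positions except planted biased TFBSs concentrated in one 500-bp
bin (fraction 0.85); a binding map of 1–8 TFs per site with ~10% of TFs
left out of the expression table (undetected); and a 2,000 × 40 occupancy
matrix with five planted within-stratum odds-ratio-3 dependencies via the
Plackett bivariate-Bernoulli construction at marginal 0.4. The regression
fixture plants 8 main effects (4 positive, 4 negative, |β| = 1) and 4
pairwise effects among main-effect-free columns, with Gaussian noise at
0.2 of the signal sd on the transform scale — the same scale the OLS
likelihood assumes.

What it does **not** emulate: real motif redundancy (TRANSFAC matrices
overlap heavily; synthetic columns are independent), promoter sequence
composition, correlated TF modules beyond pairwise odds ratios, and
heavy-tailed FPKM measurement error. Passing recovery tests therefore
demonstrates correctness of the machinery under the model's own
assumptions, not performance on real promoters.

Test and example problem sizes (hundreds of genes, tens of TFBSs,
$n = 2{,}000$ promoters, 10–100 regression runs) were chosen so every
stage runs in seconds to a few minutes on a laptop while staying in the
regime where the statistical phenomena above are visible.

# Conventions and edge cases

* TSS-relative positions are signed integers, 0 = TSS base; genomic
  input uses point coordinates with per-gene TSS and strand (minus-strand
  position = TSS − coordinate). Conversion happens once; re-conversion is
  refused.
* Out-of-window hits are dropped with a logged count; scores outside
  [0, 1], negative FPKMs and duplicate gene rows are errors naming the
  offender.
* Ensembles with fewer than 2 values or zero variance are flagged
  degenerate and never significant; pairs never co-sampled report
  $\Pr = 0$ with $t = 0$.
* Every pipeline run writes a JSON manifest of its resolved settings and
  seeds; reruns with the same inputs and seed are byte-identical at any
  thread count.

# A short example

```{r example, eval = FALSE}
d <- simulate_dataset(n_genes = 600, n_tfbs = 20, n_tfs = 15,
                      n_promoters = 300, seed = 1)
res <- run_pipeline(d$expr, d$hits, d$binding, scheme = "V",
                    n_runs = 20, k = 6, sampling_max_iter = 50,
                    seed = 1, out_dir = "promod_out")
res$models$A$summary
head(res$models$A$activity$LT)
```
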