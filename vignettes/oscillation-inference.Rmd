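---
title: "Inferring oscillatory gene expression from unsynchronized single cells"
author: "oscinfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring oscillatory gene expression from unsynchronized single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oscinfer)
```

## The problem

Single-cell RNA-seq destroys the cell: every cell contributes one snapshot,
and the cells of a sample are not synchronized with respect to any internal
oscillator such as the cell cycle or an ultradian transcriptional clock.
Periodicity in time therefore cannot be observed directly. What *can* be
observed is its static footprint: if a gene's expression oscillates with some
latent phase that differs from cell to cell, its measured level is variable
across cells and follows a sinusoidal process of that latent phase, and two
genes oscillating with the same frequency but different phase offsets trace
an ellipse on a scatter plot of their expression values — independently of
any ordering of the cells.

oscinfer implements this inference strategy end-to-end for expression
matrices with per-cell cluster labels, together with a complementary
live-imaging analysis (Lomb–Scargle periodograms of fluorescence reporter
traces) that *can* see time directly, and a synthetic-data generator that
plants known oscillator groups so every stage can be validated against
ground truth.

## The model

For one cell cluster, let $X_{gs} \ge 0$ be the expression of gene $g$ in
cell $s$ (TPM-like units). Each cell carries a latent circular phase
$\theta_s \in [0, 2\pi)$; no ordering of cells is ever estimated or used.
A co-oscillating gene pair satisfies, after each gene is linearly rescaled
to $[-1, 1]$,

$$x_s = \sin(\theta_s), \qquad y_s = \sin(\theta_s + \psi),$$

for some phase shift $\psi$. Eliminating $\theta_s$ gives the implicit
ellipse equation $x^2 + y^2 - 2xy\cos\psi - \sin^2\psi = 0$, so the
**paired-sine distance** of a gene pair is

$$\varepsilon(x, y) \;=\; \min_{\psi \in [0, \pi]} \frac{1}{S}\sum_{s=1}^S
\left(x_s^2 + y_s^2 - 2 x_s y_s \cos\psi - \sin^2\psi\right)^2 ,$$

reported per cell so values are comparable across cluster sizes. A perfectly
co-oscillating pair has $\varepsilon = 0$ at the true shift; minimizing over
half a period suffices because cosine is even (asserted by a grid comparison
in the test suite).

### Numerical treatment

Writing $c = \cos\psi$, $u_s = x_s^2 + y_s^2 - 1$ and $b_s = x_s y_s$, the
residual is $u_s + c^2 - 2 b_s c$ and the objective is an exact quartic
polynomial in $c$,

$$f(c) = c^4 - 4\,\overline{b}\,c^3 + (4\,\overline{b^2} +
2\,\overline{u})\,c^2 - 4\,\overline{ub}\,c + \overline{u^2},$$

determined by five data moments. The minimizer follows a documented
two-stage scheme — a 1000-point uniform grid on $[0, \pi]$ followed by
bounded ternary refinement of the bracketing interval to $10^{-8}$ radians —
but each evaluation costs $O(1)$ after the one-off $O(S)$ moment pass, and
for the all-pairs computation the moments of every pair come from a handful
of $G \times S$ matrix cross-products. The result is identical to brute
force: the test suite checks 100 random pairs against a $10^6$-point
dense-grid evaluation of the raw residual sum and requires agreement to
$10^{-6}$ relative. Tiny negative values that floating point can leave near
$\varepsilon = 0$ are clamped to zero (the objective is a mean of squares).

### Significance, network, communities

Pair significance is assessed against a **pooled permutation null**: for
each of $B$ draws (default 1000), two distinct genes are chosen at random
and each gene's values are independently permuted across cells, which
destroys any co-oscillation while preserving marginal distributions. The
left-tail p-value uses the add-one correction,
$p = (1 + \#\{\varepsilon_{\text{null}} \le \varepsilon_{\text{obs}}\}) /
(B + 1)$, and q-values are Benjamini–Hochberg (via `stats::p.adjust`).
Pooling the null across pairs keeps the cost at $O(B)$ rather than
$O(G^2 B)$ and is equivalent to per-pair nulls under exchangeability of
marginals; where marginals differ (planted-signal simulations), the pooled
null proves *conservative* for noise pairs, because permuted pairs with
concentrated marginals populate the null's lower tail.

Pairs with $q \le \alpha$ (default 0.05) become edges of the co-oscillation
network over all tested genes. Communities are extracted per connected
component by multilevel greedy modularity maximization
(`igraph::cluster_louvain`); the multilevel algorithm is deterministic here
and merges through modularity ties, so a fully connected clique is returned
whole (the classic agglomerative variant strands one clique member as a
singleton at a tie, which would wrongly discard a genuinely connected gene).
Communities of a single gene are dropped, and **all** genes of the remaining
communities are the cluster's inferred oscillators — no further
per-community score or linearity flag is applied.

A caveat worth stating: gene pairs whose frequencies are harmonically
related (e.g. $\sin 2\theta + \pi/2 = 1 - 2\sin^2\theta$) partially satisfy
the paired-sine model and can form sparse cross-frequency edges. Frequency
groups are still separated, but at the community level — within-group edge
density far exceeds cross-group density, and modularity splits them — not by
the absence of individual cross edges. The test suite asserts exactly this
density separation.

## Gene filters

Inference runs per cell cluster on genes that pass two filters:

* **Zero filter** — detected ($> 0$) in at least 80% of the cluster's
  cells, inclusive comparison. Zeros damage the paired-sine fit (below), so
  genes dominated by zeros are excluded up front.
* **Variance filter** — sample variance (denominator $n - 1$) across the
  cluster's cells strictly greater than the mean of the candidate genes'
  variances. The mean is taken over the zero-filter survivors, reading the
  two criteria as a sequential cascade; ties at exactly the mean are
  excluded.

Both filters are invariant to a global positive rescaling of the matrix. No
normalization, log transform (available behind `log_transform`, default
off), batch correction, or clustering is performed: cluster labels are
inputs.

## The synthetic-data generator

`generate_cosc_matrix()` emulates exactly what the inference core needs and
no more. Each cell draws $\theta_s \sim \mathrm{Uniform}[0, 2\pi)$
independently (unsynchronized population). An oscillator gene in group $k$
takes $\max(0,\; \mu + A_k \sin(\nu_k \theta_s + \varphi_g) + N(0,
\sigma))$; a noise gene takes $\max(0,\; \mu + N(0, \sigma))$; each entry is
then zeroed with probability equal to the dropout rate (entrywise Bernoulli,
independent of magnitude by default; a magnitude-dependent option exists).
Negative values are clipped at zero and the realized clip rate is reported
in the ground truth. All outputs are bit-for-bit reproducible given the
spec's seed, and generation restores the caller's RNG state.

Reference defaults: 300 cells, one 20-gene oscillator group among 180 noise
genes, amplitude $A = 2$, noise $\sigma = 0.5$ (signal-to-noise ratio 4),
dropout 0.1, baseline $\mu = 2.5$. The baseline deserves its own paragraph.

**Why baseline 2.5.** A planted oscillator must satisfy the zero-filter
precondition — it has to be detected in at least 80% of cells to enter
inference at all — so its trough ($\mu - A$) must stay above zero. At the
same time, strong ultradian oscillators of the kind this method targets
(HES-family-like dynamics) approach silence at their trough. $\mu = 2.5$
places the trough at $0.5$, one noise SD above zero: expressed essentially
everywhere, yet dynamically spanning its whole range. This choice also
exposes, rather than hides, the method's documented sensitivity to zeros:
the $[-1, 1]$ rescaling maps dropout zeros to $-1$, so when the baseline is
far above the amplitude the zeros detach from the sinusoid's range, compress
the signal into a sub-interval, and destroy the elliptic structure — dropout
degrades inference through exactly this mechanism. At dropout $\ge 0.2$ the
expected detected fraction falls below the 80% threshold and recovery
collapses to zero via the filter itself.

**What the generator does not emulate**: library-size variation,
negative-binomial/UMI overdispersion, gene–gene correlation outside the
planted groups, doublets, or batch structure. Passing tests therefore
demonstrate correctness of the inference machinery under the sinusoid +
noise + zeros model, not performance on arbitrary real scRNA-seq data.

`generate_trace()` emulates a live-imaging acquisition: sinusoid of known
period (default 17 h) sampled every 20 minutes for 70 h on a positive
offset, plus an optional slow trend (linear, or a slow sinusoid of period
$4 \times$ duration with the same total excursion as the linear ramp) and
Gaussian noise, with optional random thinning of timepoints to create the
uneven sampling the Lomb–Scargle method is designed for.

## Gene-list statistics

Downstream list algebra mirrors how multi-tumour results are combined:
per-tumour union of subcluster oscillator calls, intersection across tumours
("shared oscillators"), global union ("all oscillators"), and expressed
genes never called oscillatory ("non-oscillators"). Overlap significance is
the upper-tail hypergeometric probability ($P(\text{overlap} \ge k)$; the
standard enrichment reading) via `stats::phyper`, cross-checked in the tests
against exhaustive enumeration for small universes and a log-space
`lchoose` sum for $N = 10^4$. Fold enrichment is $(k/n)/(K/N)$. Symbols are
compared case-sensitively after whitespace trimming, with an optional
uppercase normalization for human HGNC-style lists.

A cell cluster is classified **low-cycling** when any of the cell-cycle
Hallmark sets (E2F Targets, G2M Checkpoint, Mitotic Spindle) appears among
the top 3 significantly enriched *downregulated* sets of its enrichment
table (adjusted $p < 0.1$ by default, matching the cutoff of the upstream
enrichment analysis; the enrichment computation itself is consumed as a
table, not performed).

## Periodicity analysis of reporter traces

Traces (time in hours, intensity in arbitrary units) pass three stages:

1. **QC** — exclude traces shorter than 25 h (strict; exactly 25 h is kept)
   and traces whose intensity variance exceeds the cohort mean by more than
   5 cohort SDs. The variance rule is read as a cohort-level outlier test
   because a single trace has no reference population; both thresholds are
   configurable. Note the rule only triggers in reasonably large cohorts —
   a lone outlier inflates the SD it is compared against.
2. **Detrend** — Gaussian-weighted moving average with a 24 h window:
   $\sigma = \text{window}/5$ (so the window spans $\pm 2.5\sigma$,
   the common Gaussian-window convention), weights truncated at
   $\pm\text{window}/2$. Trend plus detrended reconstructs the input
   exactly; fluctuations slower than the window are removed (for a 48 h
   sinusoid less than 10% of variance survives on interior points; for a
   12 h sinusoid more than 50% is retained).
3. **Lomb–Scargle PSD** — classical variance-normalized periodogram on a
   frequency grid spanning periods 2–24 h (ultradian focus; 2 h is six
   sampling intervals at 20-minute acquisition, below which sampling
   artifacts dominate) at resolution $1/(4 \times \text{duration})$
   (oversampling 4). The implementation is hand-written because no
   installed package provides it; the test suite verifies it exactly
   against an independent least-squares sinusoid fit per frequency, which
   spans the same two-dimensional subspace (the $\tau$ shift merely
   orthogonalizes the regressors). The dominant period is the reciprocal of
   the argmax frequency; with variance normalization, powers are invariant
   to intensity scaling and comparable across traces.

Condition summaries collect per-trace dominant powers, dominant periods and
mean raw intensities, and average the PSDs on the intersection frequency
band at the finest input resolution (linear interpolation). Comparisons
between conditions (rank tests, paired t-tests) are left to standard
`stats` routines on the per-trace columns.

## Validation strategy and problem sizes

The test suite builds every fixture in code and validates against
independent oracles: dense-grid evaluation of the raw paired-sine residual,
exhaustive enumeration of hypergeometric draws, least-squares periodogram
fits, and planted ground truth from the generator. The end-to-end checks
run at deliberately desk-scale sizes — 200 genes $\times$ 300 cells with 50
seeded replicates for false-positive control (no oscillator group planted;
calls stay at or below 5% of tested genes), three seeded replicates of the
reference recovery condition (20 planted oscillators recovered with
sensitivity and precision $\ge 0.9$ at dropout 0.1, collapsing by dropout
0.5), and 50 seeded 68–90 h traces for period recovery (17 h planted period
recovered within one frequency-grid bin). `scripts/acceptance.R` recomputes
all of these from scratch with a caller-supplied seed.

## Known limitations

* No reconstruction of per-cell phase or pseudotime, and no estimation of
  oscillation periods from scRNA-seq — without real time information the
  frequency scale of the latent phase is unidentifiable.
* The paired-sine statistic responds to any tight functional relation on
  the $[-1,1]$ square, including harmonics (the linearity caveat above) —
  community structure, not individual edges, carries the frequency-group
  interpretation.
* The pooled permutation null assumes the tested genes' marginals are
  roughly exchangeable; extremely heterogeneous marginal shapes shift
  p-values conservatively for concentrated genes.
* Zeros are genuinely destructive: genes with 10–20% zeros pass the filter
  but enter the fit with a distorted rescaling. Imputation is intentionally
  out of scope.
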