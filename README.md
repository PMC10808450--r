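# oscinfer

Inference of oscillatory gene expression from **unsynchronized** single-cell
RNA-seq, plus Lomb–Scargle periodicity analysis of live-imaging reporter
traces.

## The scientific problem

scRNA-seq gives one snapshot per cell, and cells are not synchronized with
respect to internal oscillators (the cell cycle, ultradian transcriptional
clocks such as HES-family dynamics). Periodicity in time is therefore
invisible — but it leaves a static footprint: a gene oscillating against a
latent per-cell phase θ<sub>s</sub> ~ Uniform[0, 2π) has variable expression
that follows a sinusoidal process, and two genes sharing a frequency trace an
**ellipse** on a scatter plot across cells, independent of cell order.

oscinfer scores every gene pair in a cell cluster with the paired-sine
distance

ε(x, y) = min<sub>ψ∈[0,π]</sub> (1/S) Σ<sub>s</sub> (x<sub>s</sub>² +
y<sub>s</sub>² − 2 x<sub>s</sub> y<sub>s</sub> cos ψ − sin²ψ)²

over the two genes' expression vectors rescaled to [−1, 1] (ε = 0 for a
perfect co-oscillating pair at its phase shift ψ). Significance comes from a
pooled permutation null with add-one p-values and Benjamini–Hochberg FDR
control; significant pairs form a co-oscillation network; modularity
communities of the network (singletons dropped) define the cluster's
inferred oscillators. Upstream, genes are filtered per cluster (detected in
≥ 80% of cells; variance strictly above the mean candidate variance).
Downstream, gene-list algebra (shared/all/non-oscillators), upper-tail
hypergeometric overlap statistics, dynamic-motif fractions, and a
low-cycling cluster classifier operate on the calls. An independent
periodicity module (QC → Gaussian-weighted 24 h detrending → Lomb–Scargle
PSD → dominant period/power → per-condition averaging) analyses fluorescence
reporter traces where time *is* observed. A seeded synthetic-data generator
plants oscillator groups with known ground truth so every stage is testable.

See `vignettes/oscillation-inference.Rmd` for the full model, parameter
rationale, and limitations.

## Worked example

Simulate the reference condition — 300 unsynchronized cells, 20 planted
oscillators (signal-to-noise 4) among 180 noise genes, 10% dropout — and run
the per-cluster inference:

```r
library(oscinfer)

sim  <- generate_cosc_matrix(matrix_spec(seed = 3))
call <- infer_oscillators(sim$matrix, "cluster1", pipeline_config(seed = 3))
call
#> oscillator_call for cluster 'cluster1': 200 expressed -> 24 variable
#>   -> 20 oscillators in 2 communities

head(subset(call$pair_table, q_value <= 0.05), 3)
#>      gene_i   gene_j   epsilon  psi_hat     p_value    q_value
#> 15 OSC1_001 OSC1_002 0.1921741 1.074270 0.000999001 0.00530239
#> 28 OSC1_003 OSC1_004 0.2003954 1.267745 0.000999001 0.00530239
#> 42 OSC1_002 OSC1_006 0.2060150 1.167730 0.000999001 0.00530239

planted <- subset(sim$truth$genes, label == "oscillator")$gene
mean(planted %in% call$oscillators)
#> [1] 1
```

All 200 genes pass the zero filter, the variance filter keeps 24 (the 20
planted oscillators plus 4 borderline noise genes), and the network/community
stage calls exactly the 20 planted genes: sensitivity 1 at full precision.
`psi_hat` is each pair's optimal phase shift in radians; the permutation
p-value floor is 1/(B+1) = 1/1001.

The periodicity module on a synthetic 80 h trace (17 h period, linear trend,
noise):

```r
tr  <- generate_trace(trace_spec(period_h = 17, duration_h = 80,
                                 noise_sd = 0.4, trend_type = "linear",
                                 trend_slope = 0.03, seed = 9))
det <- gaussian_detrend(tr$time_h, tr$intensity)
lomb_scargle_psd(det$detrended, tr$time_h)
#> periodogram: 147 frequencies in [0.0417, 0.4979] /h;
#>   dominant period 16.55 h (power 79.71)
```

The dominant period lands within one frequency-grid bin of the planted 17 h.
`run_pipeline()` chains simulate/load → filter → infer → intersect and writes
a run directory with TSV outputs and a JSON manifest keyed by config hash and
seed; two runs with the same config and seed are byte-identical.

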