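# rollkernel

Reverse-correlation analysis of spiking responses to m-sequence optic-flow
stimuli, for characterising roll-sensitive widefield neurons — the
descending neurons of hoverflies being the motivating system. The package
is aimed at sensory-systems electrophysiologists who want a tested,
reproducible implementation of the full analysis chain, and ships its own
ground-truth spiking-neuron simulator so every stage can be verified
without recorded data.

## What it computes

A maximal-length shift-register sequence (m-sequence) `x(t)` of ±1 values
sets the direction of a train of small roll impulses displayed at the
monitor frame rate. Assuming the response `y(t)` is related to the
stimulus by convolution with a linear kernel `h(t)`,

    y(t) = (x * h)(t),

the kernel is estimated by cross-correlation over the final full
m-sequence period (M = 255 impulses at order 8),

    h(τ) = (1/M) Σᵢ sᵢ · y(tᵢ + τ),

followed by Gaussian smoothing (SD 5 ms). The delta-like circular
autocorrelation of m-sequences makes this estimator exact on linear
responses up to the known `h(1 + 1/N) − Σh/N` finite-length identity.
From each kernel, six parameters are extracted: amplitude, time to peak
(TTP), half-width, 1/e decay, return to baseline (on a 25 ms-smoothed
version, ±2 SD baseline band) and spike rate. An LN (linear–nonlinear)
model — the kernel plus a binned static nonlinearity — is validated by
predicting a shared m-sequence trial held out from fitting and correlating
the prediction with the summed, 200 ms-smoothed response of all other
neurons, alongside a 20-fold spike-shuffling control. Group statistics are
nonparametric: omnibus Kruskal–Wallis, pairwise Mann–Whitney U with
Benjamini–Hochberg correction, and percent change of medians.

The package also models the stimulus itself: a 3-D starfield (4 m cube,
100 spheres/m³, 2 cm spheres) projected onto a 155°×138° screen at 165 Hz,
with roll/lift transforms and per-frame stimulus traces; and a synthetic
LN–Poisson experiment generator reproducing the recording protocol (nine
flow conditions, 8 trials each, one shared m-sequence trial, QC frame
logs, inclusion gates at 159 spikes/s and 5 spikes/s).

## Worked example

```r
library(rollkernel)

m <- generate_msequence(3, c(3, 2))
print(m)
#> m-sequence: order 3, period 7, taps {3,2}, phase 0
#>   +1: 4, -1: 3

cfg <- default_config(
  n_neurons = 4, n_trials = 4,
  conditions = list(flow_condition(0.18), flow_condition(0.33),
                    flow_condition(0.48)),
  seed = 5)
res <- run_pipeline(cfg, n_shuffles = 5)

head(res$param_table[, 1:6], 6)
#>   neuron_id condition amplitude ttp_ms half_width_ms decay_ms
#> 1       n01    roll18    0.0215     19          16.9     11.0
#> 2       n01    roll33    0.0385     18          17.6     12.0
#> 3       n01    roll48    0.0515     19          17.5     11.9
#> 4       n02    roll18    0.0238     18          17.3     11.2
#> 5       n02    roll33    0.0415     19          16.7     11.0
#> 6       n02    roll48    0.0541     19          16.9     11.0

aggregate(amplitude ~ condition, res$param_table, median)
#>   condition amplitude
#> 1    roll18    0.0231
#> 2    roll33    0.0391
#> 3    roll48    0.0543

res$stats$omnibus
#>               parameter    H df       p
#> 1             amplitude 9.85  2 0.00728
#> 2                ttp_ms 2.44  2 0.29457
#> ...

res$validation
#> LOO prediction: median r = 0.815 (range 0.712..0.850, N = 4)
```

Reading the output: the recovered TTP of 18–19 ms matches the simulated
neurons' 18 ms ground truth; kernel amplitude grows monotonically with
impulse size (0.18° → 0.33° → 0.48°), and the Kruskal–Wallis omnibus
flags amplitude and spike rate — but not the timing parameters — as
condition-dependent, as expected when only the stimulus gain changes. The
leave-one-out median correlation of ~0.8 says the fitted LN models predict
a neuron's response to an unseen stimulus about as well as the other
neurons' pooled response does.

A thin command-line wrapper over the same functions lives at
`inst/scripts/rollkernel-pipeline.R`
(`simulate | extract | validate | stats | all`).

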