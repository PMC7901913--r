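# memstdp

Memristive devices implement analog synapses whose conductance — the
synaptic weight — changes incrementally under voltage pulses. The *shape*
of that weight response is a device property: linear between hard bounds
(L-HB), non-linear with soft asymptotic bounds (NL-SB), or non-linear and
truncated at hard bounds (NL-HB). `memstdp` is a toolkit for studying how
this shape affects unsupervised on-line learning in a two-layer spiking
neural network trained with a simplified spike-timing-dependent plasticity
(STDP) rule. It is aimed at neuromorphic-hardware and computational-
neuroscience researchers who want to evaluate device dynamics *before*
fabricating them.

## The models

Weights live in [0, 1]; per pulse *n*, with potentiation (+) and
depression (−) branches:

* **L-HB** — dw±/dn = ±α±, truncated at the bounds.
* **NL-SB** — dw+/dn = α+(1−w)^γ+, dw−/dn = −α− w^γ−; the update vanishes
  asymptotically at the bounds.
* **NL-HB** — the soft-bound trajectory truncated after N_stop,± pulses and
  rescaled to span the full range:
  dw+/dn = (α+/w_stop,+)(1 − w·w_stop,+)^γ+, where w_stop is the soft-bound
  trajectory value after N_stop pulses.

Each dynamics is summarized by two figures of merit computed on the
continuous trajectory:

* resolution **η = {∫₀^∞ [w′(n)]² dn}⁻¹**, the effective number of weight
  levels (η = 1/α for L-HB, (γ+1)/α for NL-SB);
* non-linearity **λ = (4/π) ∫₀^∞ |w″(n)| / (1+[w′(n)]²)^{3/2} dn**, the
  average curvature of w(n) (λ = 0 for L-HB).

The SNN side: pixels are rate-coded (83 Hz – 22.2 kHz, 350 µs per image)
into spike trains driving leaky integrate-and-fire output neurons
(τ_leak = 120 µs) coupled by lateral inhibition (winner-take-all,
t_inhibit = 10 µs, t_refrac = 1 ns); each output spike potentiates the
synapses active within the 60 µs STDP window and depresses all others.
Training, neuron class assignment, classification accuracy (CA), weight
contrast (2-means center separation), training duration Δ_train and
efficiency ε = (CA + (1 − Δ_train))/2 are implemented in a tidy pipeline.
A synthetic generator of MNIST-like digit images (plus IDX read/write)
makes everything runnable without downloads.

## Worked example

Figures of merit for three dynamics sharing the step scale or resolution:

```r
library(memstdp)
device_metrics(dynamics_grid()[c(3, 8, 11), ], round = TRUE)
#> # A tibble: 3 × 6
#>   family alpha gamma n_stop   eta lambda
#>   <chr>  <dbl> <dbl>  <dbl> <dbl>  <dbl>
#> 1 L_HB   0.01     NA     NA   100  0
#> 2 NL_SB  0.008     3     NA   500  0.01
#> 3 NL_HB  0.008     3    500   225  0.015
```

The L-HB device offers 100 evenly spaced levels; the soft-bound device
stretches the same step scale into 500 effective levels at the cost of
curvature; truncating it (NL-HB) trades levels back for a finite write
time.

Train a 50-neuron network on synthetic 5-class digits and watch it learn:

```r
sp    <- synthetic_spec(n_classes = 5, n_train = 600, n_test = 100, seed = 42)
pr    <- make_prototypes(sp)
train <- sample_dataset(sp, 600, pr)
test  <- sample_dataset(sp, 100, pr, split_seed_offset = 1L)

cfg <- neuron_config(threshold = calibrate_threshold(train))
dyn <- dynamics_spec("NL_HB", alpha_plus = 0.008, gamma_plus = 3, n_stop_plus = 500)
net <- snn_network(784, 50, cfg, stdp_rule(dyn), seed = 1)

fit <- train_snn(net, train, eval_data = test, checkpoints = 4, seed = 7)
fit
#> <snn_fit> 600 training images, 4 checkpoints
#>   CA final 0.740 (max 0.780), delta_train 0.250, efficiency 0.765
tidy(fit)
#> # A tibble: 4 × 3
#>   images_seen    ca contrast
#>         <int> <dbl>    <dbl>
#> 1         150  0.78   0.0554
#> 2         300  0.78   0.0935
#> 3         450  0.71   0.121
#> 4         600  0.74   0.145
```

After one pass over 600 images the network classifies 74% of held-out
digits (chance is 20%); the weight contrast grows as neurons specialize.
`autoplot(fit)` draws the trace, `plot_weight_distribution(fit$network)`
shows whether the trained weights are bimodal (hard bounds) or
concentrated (soft bounds), and `sweep_dynamics()` runs the whole grid of
dynamics through metrics + training into one tidy table.

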