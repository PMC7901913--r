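---
title: "Memristive synaptic dynamics and unsupervised STDP learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memristive synaptic dynamics and unsupervised STDP learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memstdp)
```

## The problem

Memristive devices store an analog synaptic weight as a conductance that
changes incrementally under voltage pulses. When such devices implement the
synapses of a spiking neural network (SNN) trained on-line by
spike-timing-dependent plasticity (STDP), the *shape* of the
conductance-versus-pulse-number response — linear or saturating, truncated at
hard bounds or approaching them asymptotically — becomes a design parameter of
the learning system itself. `memstdp` provides the modelling toolkit to ask
how that shape affects learning: the weight-dynamics families, device figures
of merit, an event-driven two-layer SNN simulator, and a training/evaluation
pipeline, exercised on synthetic digit-like images.

## Weight-dynamics families

A synaptic weight $w \in [0,1]$ (the normalized conductance) evolves per
pulse $n$ according to one of three families, with potentiation ($+$) and
depression ($-$) branches:

* **L-HB** (linear hard-bound): $dw_\pm/dn = \pm\alpha_\pm$, truncated at the
  bounds. The weight travels between bounds in exactly $1/\alpha$ pulses.
* **NL-SB** (non-linear soft-bound):
  $dw_+/dn = \alpha_+(1-w)^{\gamma_+}$,
  $dw_-/dn = -\alpha_- w^{\gamma_-}$. The update vanishes at the bounds,
  which are only reached asymptotically. This is the family that best
  describes filamentary memristive devices.
* **NL-HB** (non-linear hard-bound): the soft-bound trajectory truncated
  after $N_{stop,\pm}$ pulses and rescaled to span $[0,1]$:
  $dw_+/dn = (\alpha_+/w_{stop,+})(1 - w\,w_{stop,+})^{\gamma_+}$ and the
  mirrored depression branch. The normalization $w_{stop}$ is the value the
  soft-bound trajectory from $w=0$ attains after $N_{stop}$ pulses,
  $w_{stop} = 1 - [1 + \alpha(\gamma-1)N_{stop}]^{-1/(\gamma-1)}$
  ($\gamma>1$; the $\gamma=1$ limit is $1-e^{-\alpha N_{stop}}$).

Parameter ranges: $\alpha_\pm \in (0,1]$, $\gamma_\pm \ge 1$,
$N_{stop,\pm}>0$. Asymmetric branch parameters are supported by the data
model, but every configuration shipped in `dynamics_grid()` is symmetric
($\alpha_+=\alpha_-$, etc.), so potentiation and depression metrics coincide.

Two formulations coexist and are linked deliberately: the **discrete**
per-event update used during learning is a forward-Euler step of the
continuous ODE with $dn = 1$ (clipped to $[0,1]$ after each step), while the
**continuous** closed-form trajectory is the reference for the figures of
merit. The Euler iterate tracks the continuous solution to within
$O(\alpha)$; tests bound the deviation by 0.02 over the shipped grid. The
$\gamma = 1$ case uses its exponential closed form separately because the
power-law solution is singular there.

## Figures of merit

* **Resolution** $\eta = \{\int_0^\infty [w'(n)]^2\,dn\}^{-1}$: the effective
  number of distinguishable weight levels. Substituting $dn = dw/w'$ turns
  the integral into $\int_0^1 w'\,dw$, giving the exact forms
  $\eta = 1/\alpha$ (L-HB), $(\gamma+1)/\alpha$ (NL-SB), and
  $\frac{\gamma+1}{\alpha}\frac{w_{stop}^2}{1-(1-w_{stop})^{\gamma+1}}$
  (NL-HB).
* **Non-linearity** $\lambda = \frac{4}{\pi}\int_0^\infty
  \frac{|w''(n)|}{(1+[w'(n)]^2)^{3/2}}\,dn$: the average curvature of
  $w(n)$. Because the slope $p = w'(n)$ decreases monotonically, the
  integrand is the exact differential of $p/\sqrt{1+p^2}$, so
  $\lambda = \frac{4}{\pi}\left[\frac{s_0}{\sqrt{1+s_0^2}} -
  \frac{s_N}{\sqrt{1+s_N^2}}\right]$ with initial slope $s_0$ and final
  slope $s_N$. For NL-SB this depends on $\alpha$ only, not $\gamma$; L-HB
  has $\lambda = 0$ exactly (the interior curvature vanishes; the bound
  kinks are not counted).

Both metrics are also computed by adaptive quadrature on the $n$-domain
trajectory (absolute tolerance $10^{-12}$, domain $[0,\infty)$ for soft
bounds, $[0,N_{stop}]$ for NL-HB, $[0,1/\alpha]$ for L-HB); the two routes
agree to machine precision and the tests require $10^{-6}$ relative
agreement. For a handful of grid rows the conventional reported
non-linearity differs from this curvature integral by one unit in the last
printed digit (computed values 0.025, 0.005, 0.046, 0.003, 0.008 where
0.02, 0.006, 0.047, 0.004, 0.009 are conventionally quoted); the numerical
procedure behind those quoted digits is not public, so this package
documents its computed values rather than forcing agreement.

```{r metrics}
device_metrics(dynamics_grid(), round = TRUE)
```

## Network model

The network is two fully connected layers: one input neuron per pixel and a
layer of leaky integrate-and-fire (LIF) output neurons coupled by lateral
inhibition (winner-take-all, WTA).

* **Input encoding.** Pixel gray level $g \in 0..255$ maps linearly to a
  firing rate from $f_{MIN} = 83$ Hz to $f_{MAX} = 22.2$ kHz; each image is
  presented for 350 µs. Trains are jittered-periodic: inter-spike intervals
  are Normal with mean $1/f$ and coefficient of variation 0.1 (configurable;
  Poisson trains available), accumulated from $t = 0$ and truncated at a
  small positive floor. Because the first spike sits a full interval from
  the window start, the mean count per window is $fT$ minus about half a
  spike — visible for the brightest pixels (≈7.3 rather than 7.8 spikes).
* **LIF dynamics.** Membrane decays with $\tau_{leak} = 120$ µs and
  accumulates the synaptic weight of each arriving spike; decay is applied
  lazily at integration time, which is exact for exponential leak. On
  crossing threshold a neuron fires after its per-neuron delay $t_{emit}$
  (drawn once at construction from Normal(0.1 ns, 1 ps) under a dedicated
  seed), resets its membrane to 0, becomes refractory for
  $t_{refrac} = 1$ ns, and inhibits all other neurons for
  $t_{inhibit} = 10$ µs. A neuron whose scheduled fire time falls inside an
  inhibition window set by an earlier winner does not fire — the $t_{emit}$
  jitter is what breaks otherwise simultaneous races, and remaining ties
  resolve by (scheduled time, neuron index). During refractory/inhibition
  windows integration is blocked but leak continues and pre-spike times are
  still recorded for STDP. All internal times are double-precision
  microseconds.
* **Simplified STDP.** When an output neuron fires at $t_{post}$, every
  input synapse whose latest pre-spike lies in
  $[t_{post}-t_{STDP},\,t_{post}]$ (window 60 µs, boundary inclusive) is
  potentiated one event; every other input synapse — including never-active
  ones — is depressed one event. Exactly one update per synapse per
  post-spike, based on the latest pre-spike only.
* **State scope.** Membranes, inhibition/refractory windows, and pre-spike
  histories are reset between presentations; only weights persist. Weights
  initialize to 0.8 (a uniform high conductance, as an electroforming step
  would leave them). Homeostasis is deliberately absent: the modelled
  hardware cannot afford per-neuron adaptive thresholds.

**Threshold calibration.** The firing threshold is not a published constant
and cannot be: it scales with the input drive. `calibrate_threshold()` sets
it to a fraction $c$ of the steady-state membrane level a mean-intensity
image would sustain through the initial weights,
$\theta = c \cdot w_{init} \cdot \overline{\sum_{pixels} f} \cdot
\tau_{leak}$, with $c = 0.5$ chosen a priori so an average image elicits a
few winner spikes per presentation (about 3 at the defaults). The value is
a required, logged configuration entry, not a hidden constant.

## Training and evaluation pipeline

`train_snn()` presents each training image once with plasticity on. At
evenly spaced checkpoints (default every 10% of the stream) plasticity is
frozen and three quantities are recorded:

* **Class assignment**: each output neuron takes the class it spikes most
  for on a dedicated labeled subset (default: a random 10% of the training
  stream, re-presented frozen); silent neurons stay unassigned; count ties
  go to the lowest class label.
* **Classification accuracy (CA)**: per test digit the most active neuron
  within the window answers (ties: earliest first spike, then lowest
  index; no spikes counts as a miss); CA is the fraction answered
  correctly. The trace is computed on a held-out set when supplied,
  otherwise on the assignment subset (both supported; the choice is
  logged by the arguments themselves).
* **Weight contrast**: the distance between the two centers of a 2-means
  clustering (Lloyd) of all pooled weights — initialization at the 10th and
  90th percentiles makes it deterministic; a random-restart mode exists for
  cross-checking. Linear dynamics drive contrast toward the full range
  (bimodal weights); soft-bound dynamics keep it small (unimodal).

From the trace: $CA_{max}$ is the maximum over checkpoints (the reported
"final" value is also kept; the maximum guards against non-monotone
traces), $\Delta_{train}$ is the fraction of the stream at the first
checkpoint reaching $0.99\,CA_{max}$ (no interpolation), and the efficiency
$\epsilon = (CA + (1-\Delta_{train}))/2$ summarizes the
accuracy/training-time trade-off. Evaluations run under fixed dedicated
seeds so the checkpoint cadence cannot perturb the training spike streams,
and they never mutate weights.

## Synthetic data

`synthetic_spec()`/`sample_dataset()` generate labeled 28×28 8-bit images
that emulate handwritten-digit data in *format and coarse statistics only*:
dark background (≥ 60% of pixels below gray level 16), a few bright
smoothed strokes per class prototype, 256 gray levels exercised end-to-end,
and intra-class variability from ±2 px translation, ±10° rotation and
σ = 12 gray-level noise. Prototypes are redrawn until all pairwise
correlations fall below 0.5, so classes are separable — a linear classifier
on raw pixels reaches ≥ 90% held-out accuracy, establishing that the SNN's
task is learnable. The generator does not emulate stroke topology,
pen-width variation or elastic deformation; conclusions from passing tests
are therefore comparative across dynamics families, not claims about real
MNIST performance. IDX readers/writers are provided so real data can be
substituted where available.

## Study scales

The package's test surface uses a desk-scale study chosen to keep a full
sweep within minutes while preserving the comparative structure: 5 classes,
50 output neurons, 3 000 training images presented once, 300-image
evaluation sets, three seeds, with the reference timing constants
(350 µs presentation, $\tau_{leak}$ 120 µs, $t_{STDP}$ 60 µs, $t_{inhibit}$
10 µs, $t_{refrac}$ 1 ns). At this scale the comparative findings
reproduce: accuracy decreases with $\alpha$ within L-HB; at matched
resolution $\eta = 500$ the linear family develops a far larger weight
contrast than the soft-bound family while the soft-bound weights stay
concentrated; and every family learns several times above chance. The
full-scale configuration (10 classes, 500 output neurons, 60 000 training
digits, where accuracy settles near 85% on real data) is supported as a
long-running preset via the same functions with larger arguments and real
IDX inputs; it is not part of the test surface because it requires
external data and hours of compute.

## Numerical choices and edge cases

* Quadrature: `stats::integrate` with `abs.tol = 1e-12`; closed forms used
  by default.
* Degenerate traces: an all-zero CA trace meets the $\Delta_{train}$
  criterion trivially at the first checkpoint; all-identical weights give
  contrast 0; duplicate percentile centers fall back to the weight range.
* Clipping to $[0,1]$ after every discrete step; the continuous NL-HB
  trajectory is defined on $[0,N_{stop}]$ and pinned to the bound beyond.
* Serialized dynamics re-derive $w_{stop}$ on load rather than trusting
  the file.
* Seeds: every stochastic element (prototypes, sampling, encodings,
  $t_{emit}$ draws) is governed by explicit integer seeds, and helpers
  restore the caller's RNG stream.

## Limitations

Device noise and variability are deliberately absent — the point is to
isolate the effect of the dynamics shape. The genetic-algorithm
hyper-parameter optimization used historically to tune network constants is
out of scope (constants are taken as given). Single two-layer topology
only; no homeostasis; no pool-voting readout.
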