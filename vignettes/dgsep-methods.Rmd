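---
title: "Models and methods behind dgsep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dgsep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dgsep simulates pattern separation in the dentate gyrus (DG): the
transformation by which similar entorhinal input patterns are mapped onto
more dissimilar granule-cell output patterns. This vignette documents the
models, the numerical choices, and the design decisions that were genuinely
open, in enough detail to judge what the package's tests do and do not show.

## Neuron model

Every cell — granule (GC), basket (BC), mossy (MC) and HIPP (HC) — is an
adaptive exponential integrate-and-fire (aEIF) neuron:

$$c_m \frac{dV_m}{dt} = g_l (E_l - V_m)
  + g_l \Delta_T \exp\!\left(\frac{V_m - V_{th}}{\Delta_T}\right)
  + \textstyle\sum I_{syn} - w, \qquad
  \tau_w \frac{dw}{dt} = \alpha (V_m - V_{th}) - w,$$

with reset $V \to V_{reset}$, $w \to w + b$ on threshold crossing and a
5 ms absolute refractory period. Structure enters through the surface area
$A$: $c_m = C_m A$ and $g_l = A / R_m$. Ten parameters define a cell; the
subtype determines their defaults and sampling ranges.

Numerics: explicit forward Euler at $\Delta t = 0.1$ ms (the scheme all
tests and protocols assume; halving $\Delta t$ changes subthreshold
trajectories consistently with first-order convergence). The exponential
argument is clamped at a configurable ceiling (default 10) so a spiking
step cannot overflow before the reset is applied. During the refractory
window the membrane is held at $V_{reset}$ while $w$ and all synaptic
states keep evolving; synaptic input does not move the membrane. Refractory
semantics are a genuinely open modeling choice; this is the conventional one
and it is configurable.

Internally the engine uses the coherent unit set (mV, ms, µF, mS, µA), so
the membrane equation needs no conversion constants. User-facing arguments
keep laboratory units: injected currents in pA, synaptic peak conductances
in nS, $\alpha$ in µS, $b$ in nA.

## Electrophysiological protocols and validation

Six measurements characterize each model, following standard protocols
(500 ms settling precedes every stimulus; baselines average the 100 ms
before pulse onset; steady states average the last 10% of the pulse):

* $\tau_m$ — single-exponential fit
  $V = V_\infty(1 - e^{-t/\tau_m}) + V_0$ to the response to a 20 pA,
  1500 ms pulse (nonlinear least squares seeded from a log-linear
  estimate);
* sag — steady-state over peak deflection at −50 pA, 1 s;
* $R_{in}$ — regression slope of steady-state deflection vs. current over
  −40..40 pA in 10 pA steps (−20..20 in 5 pA steps for HC, which fire
  above 20 pA); spiking amplitudes are excluded, at least 3 points
  required;
* $f_{50}$, $f_{150}$ — spike counts for 1 s pulses;
* SFA — first over last inter-spike interval at 150 pA, undefined below
  3 spikes.

A model is valid only if all six lie inside the subtype's bounds; an
undefined measurement fails validation rather than being imputed. In the
passive limit the protocols recover their closed forms ($R_{in} = R_m/A$,
$\tau_m = R_m C_m$, sag $= 1$) to within 1–2%.

## Stochastic population search

The cellular search samples nine parameters uniformly and independently
per subtype (specific capacitance stays at 1 µF/cm², its biologically
near-universal value) and keeps the models that validate. Each subtype runs
on an independent child seed of a master seed, so results are
order-independent and exactly reproducible.

The granule-cell validation bands deserve comment because they were a
genuinely open design choice. The bands ship deliberately tight
($R_{in}$ 170–260 MΩ, $f_{150}$ 12–20 Hz, SFA 0.2–0.8): validation is what
bounds the *functional* spread of the heterogeneous population, while the
underlying parameters remain free to compensate across dimensions — which
is precisely the degeneracy the population-of-models approach is meant to
expose. With loose bands the most excitable tail of the population fires in
every input pattern and masks pattern separation at desk scale.

## Input patterns and morphing

A pattern is a set of independent spike trains. Each train's rate is drawn
from a Poisson distribution with mean 8 Hz — the population rate map is
Poisson-distributed, not uniform — and the train itself is a homogeneous
Poisson process at that rate (exponential inter-spike intervals; mean
125 ms at 8 Hz). The alternative rate-map form used by the invariance study
draws per-train rates from an exponential distribution with the same mean.

One estimation caveat: the pooled mean inter-spike interval of a *finite*
pattern underestimates the generating mean, because intervals are censored
at the pattern end — most strongly for low-rate trains, whose intervals are
longest. The bias is $O(1/T)$; summary ISI statistics in this package are
therefore measured on long (16 s) patterns, where the estimate sits within
about 2% of the generating 125 ms mean.

Two independent base patterns $P_0, P_1$ are accepted only if the Pearson
correlation of their rate maps is below 0.1 (0.05 in the reduced profile,
where the sampling error of that correlation is about 0.06; a residual
base-pattern correlation propagates directly into the low-β tail of the
similarity curves). Morphing swaps a β fraction of trains:
$P_\beta$ takes `round(β·n)` trains from $P_1$ (rounding half away from
zero), default β = 0, 0.1, …, 1 giving 11 patterns. Selection is *nested*
across β (one random permutation; $P_\beta$ replaces its first
`round(β·n)` entries) so the replaced set grows monotonically and the
patterns morph progressively; independent per-β selection is available via
`nested = FALSE`. Whether the original procedure nested its selection is
not stated; nesting matches the smooth monotone curves it reports.

## Network model

The circuit follows the DG template: PP excites GC and HC; GC excites BC
and MC; MC excites GC and BC; BC and HC inhibit GC — eight projections in
all, and no others. Population sizes default to 3600/500/180/50 with 700
PP afferents.

Wiring is random per projection at a connection probability. Two schemes
are provided. The default draws a *fixed in-degree* (each target samples
exactly `round(p·n_pre)` distinct partners); independent Bernoulli edges
are available (`wiring = "bernoulli"`). The binomial in-degree spread of
Bernoulli wiring (~30% relative SD at in-degree 10) acts as a frozen,
pattern-unspecific gain profile across the population; at desk scale it
dominates the output correlation structure and masks separation, which is
why the fixed-in-degree scheme is the default for these studies.

Connection probabilities ship as config defaults chosen for sparse,
input-selective granule-cell afferents: about 10 PP inputs per GC, with
convergent interneuron wiring (about 108 GC inputs per BC/MC, 30 BC and 4
HC inputs per GC, 70 PP inputs per HC). The reduced desk-scale profile
(360/50/18/5 neurons, 280 PP trains) preserves these in-degrees.

Weights are per-projection scalars (the eight-dimensional search space),
hand-tuned defaults in nS: PP→GC 3, PP→HC 0.35, GC→BC 6, GC→MC 3, MC→GC
0.15, MC→BC 0.3, BC→GC 10, HC→GC 1.8. Two calibration observations shaped
them. First, granule cells must operate sparsely (sparsity ≈ 0.7–0.85) and
near threshold, so that *which* cells fire tracks the identity of each
cell's own small input subset; rate ceilings (strong adaptation) or relay
firing (oversized EPSPs) both re-introduce a cell-specific gain that
correlates outputs across unrelated patterns. Second, inhibition is
deliberately basket-dominated: deleting BCs collapses GC sparsity to
nearly zero, reproducing the qualitative hierarchy in which basket-cell
deletion has the most dramatic effect, while HC deletion weakens but does
not abolish sparse firing.

Synapses: excitatory projections carry colocalized AMPA and NMDA
receptors, inhibitory ones GABA-A ($E = -90$ mV). Conductances follow the
difference of exponentials
$u(t) = e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}}$, normalized by its
analytic maximum so the weight is the true peak conductance. NMDA adds the
magnesium block $s(V) = 1/(1 + \eta\,[\mathrm{Mg}]_o e^{-\gamma V})$ with
$\eta = 0.28$ /mM, $[\mathrm{Mg}]_o = 1$ mM, $\gamma = 0.04$ /mV, and its
peak conductance is a fixed ratio (default 0.3) of the AMPA peak. Kinetics
and delays (0.8–1.5 ms, rounded to integer steps) are config defaults in
the ranges standard for these receptor classes. Synaptic state advances by
exact exponential decay each step; spike arrivals increment both
exponentials after the projection's delay; responses superpose linearly by
construction.

Perturbations: subtype deletion zeroes all weights onto and from that
interneuron class; weight jitter adds a zero-mean Gaussian of SD
$\sigma \times 0.02 \times$ weight (σ = 1/3/5 for low/medium/high; jittered
weights are floored at 0 because a conductance cannot be negative);
current noise adds a per-neuron, per-step zero-mean Gaussian of SD
$\sigma \times 10$ pA to the summed synaptic current. The σ levels'
physical scale was an open question; both unit factors are config entries.
Homogenization replaces every neuron of a subtype by the subtype's base
model while conserving adjacency and weights.

## Similarity metrics

Six metrics compare two patterns through their per-neuron rates
$F_{\beta,i}$ (Hz over the analysis window): Hamming distance
$\sum_i |F_{0,i} - F_{\beta,i}|$ and normalized Euclidean distance
$\sqrt{\sum_i (F_{0,i} - F_{\beta,i})^2 / N}$ (both on rates normalized by
the shared maximum — the normalizer was unstated; the correlation-based
metrics are invariant to it), cosine similarity, mutual information
(plug-in estimate over 10 equal-width bins spanning the pooled range), the
Pearson correlation of average rates $r_\beta$, and the
instantaneous-rate correlation $R_\beta$: each train is convolved with a
Gaussian of SD $1/(10 f)$ seconds ($f$ = that train's rate; kernel
truncated at 4 SD, sampled on a 1 ms grid by default), the $N \times N$
pairwise Pearson matrices of the two patterns are formed, and $R_\beta$ is
the Pearson correlation of their upper triangles (the diagonal is
constant and carries no information). Zero-rate trains smooth to the zero
function and correlate 0 with everything by convention.

The invariance harness regenerates ten independent morphed families per
setting of one factor (population size 1000/2000/3000, mean rate 5/15/25
Hz, or Poisson vs. exponential rate maps) and averages the
metric-versus-β curves. The correlation metrics produce coinciding
curves; the distance metrics shift with population size and rate, which is
the argument for quantifying separation with $r_\beta$ and $R_\beta$.

## Quantifying pattern separation

For the 11 morph levels, $S_{in}$ is the similarity among inputs and
$S_{out}$ the same metric among the granule-cell outputs. The
$(S_{in}, S_{out})$ points are rotated clockwise by 45°,
$(x', y') = ((S_{in}+S_{out})/\sqrt2,\ (S_{out}-S_{in})/\sqrt2)$, so
separation is the region $y' < 0$. A cubic is least-squares fitted to the
rotated points (rank-deficient designs fall back to a lower degree,
flagged), and four measurements are taken over the observed $x'$ range —
extrapolating a cubic beyond data is meaningless, so the integration limits
are the data range:

* $A_{PS}$ — area of the negative-rectified cubic (exact integration
  between the real roots, not quadrature);
* $A_{PC}$ — area of the positive-rectified cubic;
* $T_{PCPS}$ — the smallest $x'$ where the fit crosses from non-negative
  to negative scanning upward; the range start if already negative there,
  the range end if never negative (the crossing-direction convention is
  the most ambiguous part of the original definition; it is configurable
  in the sense that the raw fit is returned alongside);
* $PS_{max}$ — the peak negative deflection, evaluated at the stationary
  points and range ends.

A network is a valid pattern separator only if all four measurements
satisfy $A_{PS} > 0.15$, $A_{PC} < 0.02$, $T_{PCPS} < 0.25$,
$PS_{max} > 0.2$ under **both** correlation metrics — eight checks in
strict conjunction. The β = 0 self-comparison point is included in the
fit (all 11 patterns enter).

## Experiments

`run_network_mpmoss` draws candidate weight vectors uniformly from
per-projection ranges ([0.5, 1.5]× the hand-tuned defaults — bounds set
around the default network, mirroring the cellular search; the original
network-level ranges are unpublished), presents the same 11-pattern set to
every candidate over one fixed heterogeneous neuron assignment and
adjacency, and validates each candidate. Candidates whose curves are
undefined (e.g. silent granule layers under weak drive) are recorded
invalid and the search continues. `deletion_study` produces the
3 × N_valid deletion conditions; `robustness_study` crosses jitter, noise
and both at the three σ levels over heterogeneous networks and their
homogeneous counterparts, reporting percent changes against each
network's own unperturbed measurements.

## Problem sizes used by the tests and the acceptance script

The packaged study profile (`dg_config("reduced")`) runs the whole
pipeline at 360/50/18/5 neurons with 280 PP trains; cellular searches of
1500/120/50/30 candidates validate enough models for non-repeating
assignment, and weight searches of 10–24 candidates accept networks at a
comfortable rate. These sizes exercise every code path while one
11-pattern presentation takes ~2.6 s. The invariance harness samples the
instantaneous-rate metric on a 5–10 ms grid (the smoothing SD at 8 Hz is
12.5 ms, so this is well resolved) to keep the 3000-train settings
tractable.

## What the synthetic conditions do and do not show

All inputs are stationary, rate-coded Poisson trains; there is no temporal
code, no topography, no short-term plasticity, no learning, and interneuron
subtypes are single-compartment caricatures. Passing tests therefore show
that the *framework* — heterogeneous validated populations, morphed-input
presentation, correlation-based quantification, perturbation bookkeeping —
behaves correctly and that the packaged default circuit separates patterns
under the stated conditions. They do not show that real dentate gyrus
separates patterns, nor do the desk-scale yields reproduce published
full-scale yields, which depend on unpublished parameter ranges.

## Known limitations

* The full-scale profile (3600 GC, 20 000 candidates) is provided but not
  routinely executed; its defaults inherit the reduced-profile calibration
  with in-degree-preserving probabilities.
* Mutual information uses the plug-in estimator; bias-corrected estimators
  are out of scope.
* Deleting mossy cells can slightly *increase* granule sparsity in this
  calibration (their net effect on GCs is excitatory here); the
  basket-cell dependence, which dominates empirically, is the property the
  acceptance suite asserts.
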