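---
title: "Virtual electrophysiology of hippocampal neuron phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual electrophysiology of hippocampal neuron phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vclamp)
```

## The question the package addresses

Intrinsic excitability of a neuron is conventionally measured with step
current injections: the input-output (I-O) curve of spike count versus
injected current, the rheobase, the cumulative spike count over the
protocol. Neurons in a network, however, are driven by fluctuating synaptic
conductances, not constant currents. `vclamp` implements a virtual
electrophysiology rig to ask how well the static measures predict firing
under simulated synaptic bombardment, and which voltage-gated potassium
currents make the two measures diverge. Three conductance-based model
phenotypes of cultured hippocampal neurons — regular firing, delayed firing
and stuttering — are simulated as populations with randomly varied
parameters, run through both stimulation protocols, and summarised by the
Spearman correlation between their static and dynamic cumulative spike
counts, by virtual pharmacology (complete removal of a current), and by
kinetic-parameter sweeps of the inward-rectifier K-current (Kir) and the
slowly inactivating D-type K-current (Kv1).

## Model

Each model neuron has three compartments (soma, axon, dendrite) with
individual capacitances and leak conductances, coupled by ohmic
conductances `g_sx` (soma-axon) and `g_sd` (soma-dendrite). Every ionic
current is a Hodgkin-Huxley type current

$$I_i = g_i\, m^{p}\, h\, (E_i - V),$$

with activation $m$ (exponent $p$) and optional inactivation $h$ relaxing
as $dx/dt = (x_\infty(V) - x)/\tau_x(V)$. Steady states are sigmoids,
$x_\infty = \tfrac12 + \tfrac12\tanh((V - V_{1/2})/V_{sl})$, and time
constants are bell-shaped,
$\tau_x = (\tau_{max}-\tau_{min})\,[1-\tanh^2((V-V_{\tau,1/2})/V_{\tau,sl})]
+ \tau_{min}$. A first-order intracellular calcium pool (influx
proportional to the depolarizing part of the high-threshold Ca-current,
exponential removal to a resting level) drives a calcium-activated
K-current through a saturating activation `Ca/(Ca + K_half)`; this minimal
formalism stands in for the more elaborate published treatments of
Ca-dependent conductances.

Synaptic input uses a first-order transmitter release rate law. The
activation $S$ of each connection relaxes toward
$S_\infty = \tanh((V_{pre}-V_{th})/V_{slope})$ (zero below threshold) with
effective time constant $\tau_{syn}(1 - S_\infty)$, and the postsynaptic
current is $g_{syn} S (E_{syn} - V)$. $S_\infty$ is clamped below 1 by
$10^{-6}$ so the effective time constant stays positive. The presynaptic
drive $V_{pre}(t)$ is a voltage waveform: a subthreshold baseline
(-65 mV) with 1 ms rectangular suprathreshold pulses (+20 mV) at
homogeneous-Poisson event times, one waveform for the excitatory and one
for the inhibitory connection, generated once per experiment and replayed
identically to every instance and sweep.

## Protocols

* **Static**: 400 ms current steps from -160 pA to +200 pA in 5 pA
  increments (73 sweeps), 1.25 s cycle, spikes counted in the step window.
* **Dynamic**: 51 sweeps of 2.5 s mixed bombardment followed by 2.5 s of
  rest; sweep *k* applies `g_AMPA = 0.5k` nS (0-25 nS) and `g_GABA = 1k`
  nS through the release rate law, with reversal potentials 0 / -72 mV and
  a 10 ms synaptic time constant for both receptor types.

State is carried over between sweeps within a protocol, as in continuously
cycling experiments; each protocol starts from a settled resting state.

## Numerical scheme

The production integrator uses exponential-Euler updates for gating and
synaptic states and forward-Euler voltage updates at a fixed step of
0.025 ms, with traces recorded at 0.05 ms (20 kHz). The step was chosen as
the largest that divides the 20 kHz sampling grid while keeping the
fastest (axonal sodium) kinetics stable; correctness is checked against a
classical fixed-step RK4 reference integrator at one quarter of the step
with direct evaluation of all rate functions: per-sweep spike counts of
all three canonical phenotypes must agree up to at most one window-edge
spike (cumulative counts within 1.5%), stimulus-locked first spikes to
within 1 ms, and the accumulated phase drift along long adapting trains
must stay under 2.5% of the step window.
Gating steady states and per-step decay factors are evaluated from
precomputed 0.02 mV lookup tables with linear interpolation; the RK4
reference does not share this code path. Simulations abort with a
diagnostic if any compartment leaves ±200 mV for more than 50 consecutive
steps; population runners catch the failure and flag the row rather than
aborting the population.

## The phenotype parameter tables are synthetic

The canonical parameter sets in `canonical_model()` and the Gaussian
variation table in `phenotype_distribution()` were designed and calibrated
within this package; they are not published measurements. The calibration
targets were the qualitative signatures of the three phenotypes and the
pinned kinetic anchors of the two K-currents:

* **regular**: continuous, monotone I-O curve, rheobase below +100 pA,
  voltage sag (I_h), moderate spike-frequency adaptation (CaT/KCa);
* **delayed**: hyperpolarized rest set by the inward rectifier, voltage
  ramp and long first-spike latency (fitted `Latency_1.3` around 100 ms),
  input resistance above the stuttering phenotype, Kir activation midpoint
  -91 mV and peak activation time constant 10 ms (the starting points of
  the kinetic sweeps);
* **stuttering**: low input resistance, short-latency single spikes near
  rheobase, a discontinuous I-O curve, and a sharp transition to
  repetitive firing at +195 pA under the default step protocol; D-current
  activation time constant 10 ms, within the 2-18 ms sweep range, with
  slow inactivation.

Design choices worth noting, all fixed before the validation runs were
frozen:

* The delayed model's Kir is predominantly dendritic (10% somatic) with a
  broad activation slope (-22 mV) and a voltage-independent 10 ms
  activation time constant. The broad slope lets the rectifier shape responses
  over the whole subthreshold range rather than acting as a switch near
  rest; dendritic placement keeps the somatically measured input
  resistance above the leaky stuttering phenotype while preserving the
  rectifier's hold on excitability; slow deactivation lets Kir track the
  brief depolarizations of synaptic bombardment, which is what makes its
  removal boost synaptic responses more than step responses.
* The stuttering model's D-current inactivates very slowly (600 ms
  maximum) relative to the 400 ms step window. Below the transition
  current the cell fires one short-latency spike before the D-current
  activates and then stays silent; at the transition the injected current
  overcomes the fully activated D-current and firing becomes tonic. This
  makes the repetitive-firing transition a crisp dynamical bifurcation —
  the mid-step silence disappears abruptly within one 5 pA increment —
  rather than a fragile counting artifact.
* Spike-frequency adaptation through a slow Ca pool (600 ms) and KCa is
  present in the regular model (fed by the low-threshold CaT current) and
  the delayed model (fed by a high-threshold, spike-coupled `CaH`). It
  suppresses sustained tonic firing much more than sparse event-driven
  firing, which is what pushes the three phenotype clouds off a single
  diagonal in the static-dynamic count plane.
* Dispersion: current conductances vary with 25% CV (except Kir at 10%,
  see below), one common capacitance scale factor with 10% CV, leak
  reversal with 2 mV SD, couplings with 15% CV. Negative draws for
  nonnegative parameters are resampled, not clipped. Kir is dispersed
  less because its strength sets the delayed-firing resting level;
  stronger dispersion produces a tail of profoundly rectified instances
  whose near-zero static baselines dominate percent-change statistics.

## Presynaptic rates

The Poisson rates of the two presynaptic waveforms are free parameters of
the rig. The defaults are 8 Hz excitatory / 50 Hz inhibitory. They were
calibrated so that (i) all three canonical phenotypes reach firing
threshold within the 0-25 nS AMPA schedule, and (ii) the bombardment
stays in the fluctuation-driven regime: with a much faster excitatory
rate, responses become mean-driven, every phenotype saturates, and the
differential sensitivity of the synaptic response to the inward rectifier
is washed out.

## The LIF control

The leaky integrate-and-fire control population answers whether random
variation of passive properties alone can decorrelate the two excitability
measures. Four parameters are varied: capacitance and leak conductance
(5% CV), leak reversal (1 mV SD) and spike threshold (4 mV SD). The
variation is deliberately threshold-dominated: a common threshold-distance
axis then orders both protocols' counts almost identically, reproducing a
near-ceiling Spearman correlation (~0.99) with a severalfold range of
cumulative counts. Larger coefficients of variation on capacitance and
conductance act on the two protocols through different combinations
(rheobase scales with `g_L`, synaptic integration with `C/g_L`) and pull
the control correlation visibly below the ceiling while spreading the
counts over an implausibly wide range.

## Feature extraction

Spikes are upward crossings of -10 mV at the soma with a 2 ms refractory
guard, counted only in the stimulation window (step or on-phase). From the
static protocol the package extracts rheobase, cumulative count, input
resistance (steady-state slope over the -20 to 0 pA steps, last 50 ms of
the step), sag ratio on the -160 pA sweep, and `Latency_1.3`: a
three-parameter Belehradek power law $L(I) = a (I - b)^c$ ($c<0$,
$b \le \min I - 1$ pA) is fitted to the first-spike latencies in log space
(profiled linear fit for $a, c$; one-dimensional minimisation over $b$)
and read out at 1.3 times the rheobase. From the dynamic protocol it
extracts the threshold AMPA conductance and the cumulative count. Missing
rheobase or threshold conductance is kept as `NA` with a zero count;
zero-baseline instances are excluded from percent-change averages but
retained in the tables. The Spearman coefficient is computed as the
Pearson correlation of average ranks.

## Problem sizes

Populations of 200 instances per phenotype reproduce the full study; the
package's own validation suite runs desk-scale versions (25 instances per
phenotype for the headline correlation; 6-12 instances and 3-point
subgrids, always containing the published grid endpoints, for the
manipulation experiments), and `scripts/acceptance.R` uses 50 instances
per phenotype. The kinetic-sweep subsets are drawn by seeded stratified
sampling on the baseline static count so they span the population's
excitability range. A single master seed deterministically derives all
population, waveform and subset seeds, so any experiment is reproducible
from its configuration and one integer.

## What passing tests do and do not show

The synthetic populations vary only maximal conductances, capacitance,
leak reversal and couplings around hand-designed canonical models. Real
cultured neurons additionally vary in morphology, channel kinetics,
temperature and synaptic context, and their phenotypes form a continuum
rather than three parametric families. Reproducing the study's qualitative
structure here — a weak static-dynamic correlation with a near-ceiling LIF
control, differential Kir/D blockade effects, and opposite-direction
D-kinetics effects — shows the mechanisms are sufficient in a
conductance-based setting, not that the synthetic parameter values match
any particular biological cell. Quantities tied to the recorded dataset
(biological correlations and percent changes) are out of reach by
construction. The Kir blockade differential in particular is a small-margin
effect at the population median in this implementation, much weaker than
the corresponding biological effect.

## A minimal session

```{r example, eval = FALSE}
library(vclamp)

waves <- experiment_waveforms(master_seed = 1)
m <- canonical_model("stuttering")
static <- run_static_protocol(m)
dynamic <- run_dynamic_protocol(m, waveforms = waves)

feature_record(static, dynamic)
transition_current(static)

# population-level headline statistic at desk scale
res <- experiment_population(n = 25, seed = 1)
res$summary$corr_counts
```
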