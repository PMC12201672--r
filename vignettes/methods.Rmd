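---
title: "Model and methods: cholinergic switching of network state and engram plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(engramsim)
```

## The scientific question

During sleep, cortical and hippocampal circuits alternate between a
low-acetylcholine state (NREM) and a high-acetylcholine state (REM).
`engramsim` implements a reduced biophysical model of how this single
neuromodulatory variable could give the two states distinct, sequential
roles in memory consolidation: the low-ACh state broadly *recruits*
plastic neurons into recently formed memory engrams, and the high-ACh
state *prunes* the expanded representations so that simultaneously
consolidating memories stay separable.

ACh acts in the model through one lever only: the maximal conductance
`gKs` of the slow M-type potassium current, which muscarinic M1
activation shuts down.  `gKs = 1.5` mS/cm2 is the low-ACh (NREM-like)
state, `gKs = 0` the high-ACh (REM-like) state.

## Single-cell model

Each neuron is a single-compartment Hodgkin-Huxley cell (fast Na+,
delayed-rectifier K+, leak, and the M-current), with instantaneous Na
activation `m` and first-order gating for `h`, `n` and the M-current
activation `z` (time constant 75 ms).  All cellular parameters are shared
between excitatory cells and interneurons; only the constant drive
differs (`Idrive` = 0.5 uA/cm2 excitatory, -0.1 inhibitory).  Units
throughout: ms, mV, uA/cm2, mS/cm2.

`gKs` controls the excitability class.  At `gKs = 0` the cell is Type 1:
the F-I curve rises continuously from zero rate at rheobase and the phase
response curve is non-negative (inputs only advance the next spike).  At
`gKs = 1.5` the cell is Type 2: firing onset jumps discontinuously to a
finite frequency (rheobase near 1.9 uA/cm2) and the PRC is biphasic —
inputs arriving early in the cycle delay the next spike.  Both properties
are exposed (`fi_curve()`, `phase_response_curve()`) and tested.

Background input is a Bernoulli pulse process: every millisecond each
neuron has probability 0.002 of receiving an 80 uA/cm2, 1 ms pulse.  Each
pulse fires one spike in an isolated cell, giving the 2 Hz spontaneous
background rate (the acceptance script recomputes this).  The printed
source text says "0.002%", which is inconsistent with the 2 Hz outcome it
also states; we read the percent sign as a typo and expose the value as
`noise_p`.

### Numerical scheme

Classical RK4 at a fixed `dt = 0.05` ms (the smallest gating time
constant is 0.37 ms; halving `dt` moves spike times of a 1 s reference
run by under 0.1 ms).  Synaptic drive traces decay analytically within a
step; spikes are detected as upward crossings of +5 mV with a latch (the
model has no reset) and delivered to targets at the end of the detection
step (zero synaptic delay beyond the step boundary).  Gating sigmoids are
evaluated from a 0.02 mV lookup table with linear interpolation
(error < 1e-6); the compiled engine is cross-checked in the test suite
against a plain-R RK4 reference on a two-neuron microcircuit.

One numerical consequence of the model's weak leak (`gL = 0.02` mS/cm2)
deserves note: the suppressive drives the protocols use (-6 uA/cm2) hold
cells at `V* = VL + I/gL`, i.e. hundreds of mV below rest.  This is the
model as specified — there is no lower bound on V — so the engine's
divergence guard is asymmetric (error above +200 mV or below -1000 mV).
Suppressed cells still emit occasional spikes when synchronized synaptic
volleys arrive, because synaptic input is conductance-based and pulls
toward its reversal potential regardless of how hyperpolarized the cell
sits.

Initial voltages are drawn uniformly from [-70, -55] mV (gating at steady
state) to avoid artificial network-wide synchrony at t = 0; nothing else
about the initial state is randomized.

## Synapses and plasticity

Presynaptic spikes increment exponentially decaying postsynaptic drive
traces: fast excitatory (tau 0.5 ms, reversal 0 mV) and fast + slow
inhibitory (tau 0.5 and 50 ms, reversal -75 mV).  Relative amplitudes by
postsynaptic class: excitatory 0.15 onto excitatory cells and 0.08 onto
interneurons; fast inhibition 0.15 onto interneurons only; slow
inhibition 0.05 onto excitatory cells only.  The slow (GABA-B-like)
component is what paces the high-ACh network rhythm.

Excitatory-to-excitatory synapses carry additive STDP with a
nearest-preceding-spike pairing: at each postsynaptic spike the weight
gains `Px * 0.07 * exp(-dt/14)` against the most recent presynaptic
spike, at each presynaptic spike it loses `Px * 0.025 * exp(-dt/34)`
against the most recent postsynaptic spike; weights are clipped to
[0, 5] after every update, and exactly simultaneous spikes produce no
update.  `Px` is 1 for backbone-to-SF synapses, 0.3 for SF-originating
synapses, and 0 for backbone-internal and all inhibitory synapses.  The
potentiation and depression magnitudes cross at
`ln(0.07/0.025)/(1/14 - 1/34) = 24.5` ms: pairs closer than ~25 ms are
net-potentiating.

A property of this kernel worth stating explicitly, because it shapes
what the network can and cannot do: the potentiation integral
(`A+ tau+ = 0.98`) exceeds the depression integral (`A- tau- = 0.85`),
so *uncorrelated* pre/post firing at equal rates drifts weights slightly
upward, not downward.  Net depression of an edge requires a presynaptic
rate roughly `2.8 x r_post + 11 Hz` above the postsynaptic rate — the
regime a tonically firing backbone imposes on a strongly inhibited
target.  Competitive pruning in the high-ACh state therefore exists but
is slow (about -0.005 weights/s at its optimum).  The package implements
the kernel exactly as printed; the consequences for the reversed-order
and cycling protocols are discussed under "Known limitations".

## Networks

The single-memory network has 40 engram-backbone (EB) neurons with fixed
internal weights and multiplier 2.5 (the freshly encoded memory), 80
sparsely firing (SF) plastic excitatory neurons, and 20 interneurons.
Excitatory wiring is random at 10%; interneurons contact 50% of neurons
within a ring radius that defaults to the whole network (the source
material never states the radius; `inh_radius` is exposed, and the
figure-level properties are insensitive to it).  Interneurons inhibit SF
cells much more strongly (multiplier 3.5) than backbone cells (0.5); an
equal-inhibition variant (`build_equal_inhibition_variant()`) replaces
this contrast with intrinsic-drive contrast.

The two-memory network adds a second 40-neuron backbone, removes every
EB1-EB2 edge, and divides the SF layer into quartiles by in-degree from
the two backbones: blue (strong from EB1), green (strong from EB2), pink
(weak from both), violet (strong from both).  Pink and violet receive
-6 uA/cm2 so they fire only sparsely; blue and green have their preferred
backbone inputs initialized at 1.2 instead of 1 (removable; removing it
changes little, which the tests confirm indirectly through the no-bias
builder checks).

## Sleep protocols and their calibration

Sleep schedules alternate `ACh_minus` (gKs 1.5, plasticity on) and
`ACh_plus` (gKs 0, plasticity on) epochs, with memory tests (gKs 0.1,
plasticity off, one backbone driven at +2 uA/cm2 while the other is
suppressed at -6) at baseline and after states or cycles.  During sleep
epochs the two backbones are reactivated in alternating 200 ms bouts,
the active one driven and the other suppressed.

Two protocol constants are free parameters (the source text never prints
them) and were calibrated once, on the criterion that each state exhibits
its described dynamics, then frozen:

* **Reactivation drive, low-ACh state: +1 uA/cm2.**  This puts the driven
  backbone just *below* its Type 2 rheobase, so it fires in
  noise-seeded, strongly synchronized population bursts rather than
  tonically.  Synchronized volleys are what recruit weakly connected SF
  cells; at +2 or more the backbone fires tonically and recruitment
  becomes winner-take-all (only the quartile with the densest input ever
  joins, and the engram never broadens).
* **Reactivation drive, high-ACh state: +3 uA/cm2.**  Here the backbone
  is intrinsically active and inhibition is strong; a stronger drive
  yields sustained backbone firing against near-silent suppressed SF
  cells — the rate asymmetry that makes the STDP kernel net-depressing,
  producing the selective pruning of weak inputs.  At +1 the suppressed
  cells' residual burst-locked spikes win and nothing is pruned.

Epoch durations are likewise unprinted.  Recruitment of the
weakly-connected quartiles develops on a 30-75 s timescale at these burst
rates, so the builder defaults are 30 s per state and the validation runs
in the test suite use 60 s per state (the consolidation experiments) and
15 s-per-state cycles against a 60 s massed cycle (the cycling
comparison).  These are the problem sizes at which the package's claims
were established; they are arguments, not constants.

## Analysis statistics

**AMD.** The average minimal distance from each spike of train i to the
nearest spike (either direction) of reference train j.  Spikes outside
the reference train's span use the single available neighbour in
`amd()`; the z-score machinery instead restricts to spikes within the
span, where the null is exact.

**Analytic null.** For a point placed uniformly in the reference train's
span, the nearest-spike distance has mean `mu = sum(L^2)/(4T)` and second
moment `sum(L^3)/(12T)` over the inter-spike intervals `L`, `T = sum(L)`.
These are exact (verified against a Monte-Carlo placement oracle to
within 1%).

**z-score.** `fc_zscore()` returns
`z = sqrt(N_i) * (mu - AMD) / sigma`.  Two deliberate choices:

1. *Sign.*  The raw-distance orientation makes coincidence negative; we
   flip it so that tighter-than-chance locking is positive, matching how
   the statistic is interpreted everywhere it is used
   (`literal_sign = TRUE` restores the raw orientation).
2. *The `sqrt(N_i)` factor.*  The AMD is the mean of `N_i` nearest-spike
   distances, so its null SD is `sigma/sqrt(N_i)`, not `sigma`.  Without
   the factor the coincidence-side z is bounded above by
   `mu/sigma <= sqrt(3)` (the regular train is the maximizer), and no
   degree of synchrony could ever reach a two-SD significance threshold —
   the `|z| > 2` mask used throughout would be empty on the coincidence
   side by construction.  With it, the independent-Poisson null is
   close to standard normal (mean ~0.1, SD ~1.0 in the calibration
   test).

**Surrogate null.** `fc_matrix(null = "jitter")` z-scores the observed
AMD against an ensemble of reference trains jittered by Gaussian noise
(20 ms SD, 30 surrogates by default).  The surrogate ensemble retains any
common slow rate modulation, so only locking at a timescale finer than
the jitter registers.  This matters for the simulated memory tests: the
test state carries a network-wide slow-inhibition-paced rhythm that
gates *every* neuron's spikes, and under the analytic null that shared
rhythm makes nearly all pairs "significant" regardless of learning.  The
two-memory analysis therefore uses the surrogate null for its overlap
statistic; with it, the baseline overlap is zero and changes in overlap
reflect volley-level co-activation acquired through plasticity.  All
oracle-level checks of the AMD machinery use the analytic null.

**Engram read-outs.**  Activation `(f - f_bg)/(f + f_bg)` contrasts the
recruitable (blue/green) rate against the suppressed-background
(pink/violet) rate during a test; segregation `|f1 - f2|/(f1 + f2)` is
computed per recruited group across the two backbone activations and
averaged.  Overlap is the dot product of the two test
functional-connectivity matrices over blue and green cells after zeroing
entries with `|z| <= 2` (cosine-normalized value attached as an
attribute).  Weight-change vectors report mean backbone-to-quartile
weights before and after an interval.

**Paired NREM/REM bouts.**  For recorded (or synthetic) data with bout
annotations, each NREM bout whose following REM starts within 10 s is
paired with it, the NREM window truncated to its final segment matching
the REM duration, and per-pair z changes reported, excluding pairs
non-significant in both states.  The bundled fixture generator emits
synchronous NREM-labelled and independent REM-labelled bouts so the
expected negative shift is known by construction.

## What the synthetic fixtures do and do not show

The fixture generators (`fixture_poisson()`, `fixture_jittered_pair()`,
`fixture_periodic_burster()`, `fixture_rate_switching_bouts()`) emulate
the statistical structures the metrics assume: independence, pairwise
locking with a controlled timescale, population rhythms, and
state-dependent synchrony switches.  They contain no refractoriness, no
rate heterogeneity across cells, and no non-stationarity within a bout —
so passing metric tests on them demonstrates correctness of the
statistics under their stated null and alternative models, not
robustness to every property of in vivo spike trains.

## Known limitations

* The reversed-order protocol (high-ACh state first) correctly fails to
  recruit during its leading high-ACh epoch (activation stays at
  baseline, overlap zero), but the trailing low-ACh epoch then recruits
  almost as the forward order does, so the full-sequence weight change
  remains positive.  A complete reversal failure requires the
  virgin-network high-ACh state to depress backbone-to-SF weights below
  the burst-ignition threshold (about half their initial value), and the
  printed STDP constants cap uncorrelated depression at roughly
  -0.005 weights/s — an order of magnitude too slow at these epoch
  durations, with the intact fixed-weight backbone re-igniting
  recruitment from anything above ~0.7.  The corresponding acceptance
  expectations are implemented as stated and fail; we regard this as a
  real property of the published parameter set rather than of the
  implementation, for the quantitative reasons above.
* The cycling comparison (four short cycles versus one massed cycle of
  equal cumulative duration) shows, for the same reason, only a weak and
  seed-dependent segregation advantage for cycling: with pruning this
  slow, final segregation is governed mostly by cumulative low-ACh time,
  which the two schedules share.
* In the single-memory network the backbone's mean rate is essentially
  state-independent (about 10 Hz in both states in our runs): at
  `gKs = 0` its higher intrinsic excitability is offset almost exactly by
  slow inhibition from the much more active interneurons, which gate the
  backbone to about one spike per oscillation cycle.  The interneuron and
  SF rate reorganization across states is robust; the backbone's own
  rate increase at high ACh is not, and the corresponding acceptance
  expectation fails.  Every parameter of this configuration is a
  published constant, so we report this as a property of the parameter
  set rather than adjusting unrelated structure to force it.
* The model has no AHP current, no nicotinic receptors, no
  short-term plasticity, no septal theta drive, and a uniform interneuron
  population; the interneuron connectivity radius is a free parameter.
* Epoch durations, reactivation drives and test drives are calibrated
  package defaults (see above), not published constants; conclusions that
  depend on their precise values should be checked with sweeps
  (`sweep_two_memory()`).
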