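---
title: "Modeling the fly olfactory circuit with piecewise quadratic neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the fly olfactory circuit with piecewise quadratic neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysnn)
```

## The model

`flysnn` simulates the *Drosophila* olfactory pathway — antenna, antennal
lobe, and mushroom body — as a spiking neuronal network small enough to run
on a laptop (or, in its fixed-point incarnation, on digital arithmetic
hardware). The circuit contains olfactory receptor neurons (ORNs),
projection neurons (PNs), four electrophysiological subclasses of inhibitory
local neurons (LNs), Kenyon cells (KCs), the APL feedback neuron, two
mushroom-body output neurons of opposite valence (MBON-α1, inhibitory;
MBON-α3, excitatory), and a downstream integrator (SMP354) whose spiking is
the behavioral read-out for odor approach.

### Neuron dynamics

Every modeled neuron follows the piecewise quadratic neuron (PQN) model: a
qualitative dynamical model in the FitzHugh–Nagumo tradition whose
nullclines are built from pairs of parabolic branches, so that one Euler
step needs only additions and multiplications. The single-compartment
variant (LNs, APL, SMP354) integrates a membrane potential $v$, a recovery
variable $n$, and a slow variable $q$:

$$
\frac{dv}{dt} = \frac{\phi}{\tau}\bigl(f(v) - n - q + I_{b0} + m(I)\bigr),\quad
\frac{dn}{dt} = \frac{1}{\tau}\bigl(g(v) - n\bigr),\quad
\frac{dq}{dt} = \frac{\epsilon}{\tau}\bigl(h(v) - q\bigr),
$$

where $f$, $g$, $h$ are piecewise parabolas whose right-branch offsets are
derived so each function is continuous with a continuous first derivative
(`derive_dependent_params()` recomputes them; a property test verifies C1
continuity for random coefficient draws). The input transform
$m(I) = k_I\,\mathrm{clamp}(I;\,m_0, m_1)$ scales and saturates the synaptic
drive; saturation doubles as protection against depolarization block, which
in this phase-plane geometry would otherwise set in at roughly twice the
rheobase. $k_I$ is applied exactly once, inside $m$ — model variants that
write the drive as a product with $m(I)$ multiply its result and never
re-apply $k_I$, since a double application would square the intended gain.

Unipolar fly neurons generate spikes in the axon and the somatic recording
shows only attenuated copies, so PNs, KCs and MBONs use a two-compartment
variant: the spiking pair $(v, n)$ plus a passive somatic potential $v_s$
coupled through $I_c = k_0 (v - v_s)$, with no slow variable. Spikes are
detected on the axonal $v$ as a crossing from negative to zero-or-greater.

PNs additionally scale their synaptic drive by a homeostatic gain
$u \in [0, 1]$ (drive $= u\, m(I)$) with
$du/dt = (\kappa/\tau)(F_t - F)$, updated once per simulated second from the
spike count of the completed one-second window (tumbling windows aligned to
$t = 0$). All state variables start at zero; every run therefore opens with
a 300 s "warm-up" during which the homeostat brings the initially silent
PNs into their operating regime.

### Synapses, input accumulation, plasticity

Each presynaptic neuron owns one kinetic activation $s \in [0, 1]$:
$ds/dt = \alpha(1 - s)$ while $v \ge 0$ and $-\beta s$ otherwise, with
$\alpha = 250$ and $\beta = 203.125$ for all synapses ($1/\beta \approx
5$ ms, the measured decay of both cholinergic and GABAergic synapses; a
single spike of the tuned LN set drives $s$ to ≈ 1). ORN terminals are
spike-driven: $s \leftarrow 1$ on a spike, exponential decay otherwise.
The input current of neuron $i$ is
$I_i = \sum_j w_{ji}\, s_j\, p_{x\_y}$, a sparse weighted sum with one
scaling constant per (presynaptic class, postsynaptic class) pair; the sign
of $p_{x\_y}$ encodes the transmitter polarity and the four LN subclasses
share one value per target class.

Reward-driven learning depresses KC→MBON-α1 weights: every KC that spiked
within the five seconds preceding a reward has its weight set from 1 to
0.25 — an absolute, idempotent assignment, as in a two-bit hardware weight
store. Before learning MBON-α1 (inhibitory) and MBON-α3 (excitatory)
respond to every odor and cancel at SMP354; depression selectively removes
MBON-α1's response to the learned odor, disinhibiting SMP354 for that odor
alone.

### Topology

Connectome-style neuron/edge tables can be imported
(`build_from_connectome()`): connections with **more than ten** synapses
get weight 1, all others 0, and LN edges are ignored because LN connectivity
is regenerated from per-(subclass, glomerulus) innervation probabilities —
each LN Bernoulli-samples the glomeruli it innervates, and every ORN/PN
sharing a glomerulus with an LN connects to it. The same shared-glomerulus
rule also creates the LN→PN and reciprocal LN→LN edges; this direction is
not stated explicitly by the connectivity procedure we follow, but it is
the construction that reproduces the reported statistic of each LN
inhibiting ~91 of 121 PNs. The 191 LNs split 48/48/48/47 over the four
subclasses (NP2426_class1 takes the shortfall).

`generate_synthetic_topology()` stands in for a connectome export. It is
calibrated so that the full-size default (1815 ORNs, 121 PNs, 191 LNs,
1884 KCs, 51 glomeruli) reproduces the connectome's printed averages: each
ORN drives all PNs of its glomerulus (1.6 on average), each PN pools
24.0 ORNs, each KC draws ~Binomial PN inputs with mean 4.2 (minimum 1,
no regularity), each LN pools ≈ 1337 ORNs and inhibits ≈ 91 PNs, APL is
wired to/from the whole mushroom body, and all KCs excite both MBONs. The
KC count (not printed anywhere) defaults to 1884 so the modeled total is
about 2,200 neurons. Glomerular sizes are solved so that the ORN→PN in- and
out-degree targets hold simultaneously (a tail group of glomeruli carries
the extra PNs; ORNs are allocated between single- and multi-PN glomeruli by
a closed-form split).

The shipped innervation-probability table is **synthetic**: the measured
table is summarized by one probability per subclass (0.80, 0.75, 0.45,
0.95), pinned to the one entry reported in the literature (NP1227_class1 × DA1 = 75%)
and chosen so the subclass-average (~0.74) reproduces the LN degree
statistics while NP2426_class1 innervates broadly and NP1227_class1
sparsely, consistent with their reported roles in antennal-lobe
oscillations. Supply a measured table via the `probs` argument to replace
it.

### Odor input

ORN firing follows $r = c\,k_j\,r_{ij} + r_{spo}$ with gain $c = 192$,
spontaneous rate $r_{spo} = 8$ Hz, response intensity $r_{ij} \in [0,1]$
and concentration $k_j \in [0,1]$ (so the maximal rate is 200 Hz). Spikes
are Bernoulli draws with probability $r\,dt$ per 1 ms step. Three protocols
are provided: (1) six odorants, 1 s on every 5 s, cycling; (2) one odorant,
10 s on every 20 s; (3) six odorants, 10 s on every 20 s — each preceded by
the kind-1 warm-up. Concentrations default to 1 and can be set per odorant.

`generate_synthetic_or_table()` replaces the odorant-response database:
each odorant strongly activates a distinct OR subset (drawn from a shuffled
pool without replacement, so tuning sets are disjoint while the repertoire
allows) plus a configurable fraction of weak responders (intensities up to
`weak_max`). The weak fringe matters: it recruits many ORNs whose PNs stay
subthreshold, which is the first stage of the sparsening cascade
ORN → PN → KC.

## Numerical scheme

Explicit Euler at $dt = 1$ ms, matching the 1 ms update of the hardware
implementation the model is designed for; $dt$ is configurable and a test
verifies first-order convergence to the closed form on the linear somatic
subsystem. All right-hand sides are evaluated at the pre-step state and
committed synchronously, so results are independent of neuron ordering.
Chemical synapses are updated after the neuron step from the freshly
committed potentials, mirroring the hardware pipeline stage order. Non-finite
states raise an error naming the neuron (no silent clamping, which would
diverge unpredictably from the fixed-point backend). The engine advances all
neurons through one fused vectorized update (single-compartment neurons take
$k_0 = \theta = 0$, two-compartment ones $\epsilon = 0$, making the somatic
and slow-variable terms vanish exactly); equality with the per-population
`step_*()` operations is part of the test suite.

The fixed-point backend (`fixed_point = TRUE`) holds every state variable,
coefficient, and arithmetic stage in a signed 18-bit format with 10
fractional bits (range $[-128, 128 - 2^{-10}]$), rounding half-to-even and
saturating at the limits. Constant multiplications can be expressed as
signed right-shift sums (`plan_shift_add()`); e.g.
$0.021484375 = 2^{-6} + 2^{-8} + 2^{-9}$. The exact rounding behavior of
any particular hardware is not publicly documented, so the backend documents its
choices (round-half-even per stage, saturation logged) rather than claiming
bit-identity with a specific chip; fixed-vs-float divergence is bounded
empirically in the tests (matching rates within 5% for a periodic neuron,
a quantization micro-limit-cycle of a few percent of spike amplitude at
rest).

## Parameter provenance and tuning

Measured per-class PQN coefficient fits are not available in a
machine-readable form, so the package ships its own hand-tuned sets (`default_neuron_params()`), constructed to the qualitative
specifications: repetitive spiking over a bounded drive window for LNs,
PNs, KCs, MBONs and SMP354 (a stable rest ≈ −2, spiking onset near drive 1,
saturation via $m_1$ before depolarization block); a slow
($\tau_v = 250$ ms), graded, monotone, non-spiking APL whose threshold
crossing lags odor onset — the delayed inhibition that shapes the MBON-α1
time course; and somatic low-pass filtering for the two-compartment
classes. LN subclasses share one phase-plane geometry with excitability
ordered NP2426_class1 > Krasavietz_class1 > Krasavietz_class2 >
NP1227_class1, which makes NP2426_class1 the dominant antennal-lobe
oscillator, the Krasavietz classes entrained followers, and NP1227_class1
nearly silent — the configuration that reproduces the reported subclass
inactivation asymmetry. The LN recovery constant ($\tau = 35$ ms) and PN
recovery constant (12 ms) set the PN–LN loop resonance near 24 Hz.

Class-pair scaling constants (`scaling_table()`) were tuned at the network
level in this order (mirroring how such constants must be fit when absolute
synaptic gains are unknown): first the antennal-lobe pairs to produce
odor-locked 20–30 Hz oscillations with the right subclass structure, then
the mushroom-body input pairs so that each odor recruits a small, distinct
KC population, then the KC→MBON gain so that one odor's drive sits 2–4×
above MBON threshold — the window in which 4× depression silences the
response — and finally the MBON→SMP354 pair so inhibition dominates at
baseline. The PN→KC value 1.03125 is the reference operating point and is
kept verbatim. Because the raw input sum of a postsynaptic neuron scales
with its in-degree, `rescale_scaling()` multiplies convergence-dependent
pairs by (reference in-degree)/(actual in-degree) when simulating
size-reduced networks; the PN→KC pair is exempt because the generator holds
that in-degree at 4.2 at every size.

The homeostatic target is $F_t = 4$ Hz with $\kappa/\tau = 2\times10^{-3}$
per second: low enough that PNs are nearly silent between odors (keeping
KC eligibility confined to genuinely odor-driven spikes), converging within
a few tens of seconds.

## Analyses

* **Virtual LFP** — the mean synaptic activation $s$ over a class (or LN
  subclass), recorded each step.
* **Spectra** — Welch estimate with 1 s Hann segments, 50% overlap, mean
  removal, peak taken over 5–100 Hz. The segment length resolves 1 Hz;
  no reference recipe for this analysis is available in machine-readable
  form, so these are the package's own choices. For the
  LN-subclass inactivation comparison the peak is taken over the 20–30 Hz
  band in which the odor-evoked rhythm lives, so that slow broadband
  fluctuations released by disinhibition are not mistaken for the
  oscillation.
* **Peak-power experiments** — repeated 10 s presentations in one
  continuous run; per-window peak power averaged in the linear domain
  (whether the original analysis averaged in log or linear domain is not
  verifiable; linear was chosen).
* **Learning** — one set = warm-up, one rewarded presentation, then trials
  in which the six odors appear in fresh random order; a trial succeeds if
  SMP354 spikes (≥ 1, the smallest unambiguous criterion for a neuron
  silent at baseline) only in the learned odor's window. The reward
  arrives 4 s after odor onset — the reference timing (odor at
  300–301 s, reward at 304 s); either reading of that timing lands
  inside the 5 s eligibility window.
* **Firing time courses** — 50 ms tumbling windows, trial-averaged.

## Problem sizes

The full-size network (≈ 2,200 modeled neurons plus 1815 ORN input
terminals, ≈ 340,000 edges) simulates at roughly half a simulated second
per wall-clock second in this R implementation. The test suite and the
worked examples therefore run a size-reduced network — 16 glomeruli,
384 ORNs, 16 PNs, 40 LNs, 250 KCs, warm-up 60 s, with `rescale_scaling()`
preserving per-neuron drive — which reproduces every qualitative property
at a few minutes of total runtime. The synthetic-topology calibration
tests do build the full-size network (construction is fast; only long
simulations are costly).

## What the synthetic data do and do not show

The synthetic generators emulate glomerular convergence, probabilistic LN
innervation, random PN→KC divergence, near-all-to-all APL wiring, and
sparse distinct odor tuning with the stated spontaneous/maximal rates.
They do not emulate: correlated ORN noise, glomerulus-specific PN counts
taken from a real connectome (sizes are solved, not measured), graded
DoOR response spectra (tuning is strong/weak/zero), odorant-specific
concentrations, or any spatial structure. Passing the qualitative suite on
synthetic data therefore demonstrates that the mechanisms — homeostatic
recruitment, inhibition-paced oscillation, sparse coincidence coding,
depression-based valence switching, delayed APL feedback — behave as
described, not that quantitative outputs (e.g. the 84% success rate
obtained with measured connectome and receptor data) are reproduced; those
require the original inputs.

## Known limitations

* Per-class point estimates: no within-class parameter heterogeneity
  (as in the source model, where one fit serves each class).
* The dopaminergic reward pathway is an external event, not a modeled
  circuit.
* The innervation-probability table and OR response tables shipped are
  synthetic stand-ins (see above) — import measured tables for data-driven
  work.
* The fixed-point backend emulates the arithmetic format, not any
  particular chip's rounding pipeline.
* Peak oscillation frequency sits near 24 Hz by construction of the tuned
  time constants; the biological antennal lobe oscillates slower
  (10–15 Hz), a known gap attributed to unmodeled glomerular dynamics.
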