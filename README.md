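# flysnn

A lightweight, data-driven spiking neuronal network model of the
*Drosophila* olfactory system, written in R.

## The scientific problem

The fly olfactory pathway — olfactory receptor neurons (ORNs) on the
antenna, projection neurons (PNs) and inhibitory local neurons (LNs) in the
antennal lobe, Kenyon cells (KCs), the APL feedback neuron and mushroom-body
output neurons (MBONs) downstream — is one of the few neural circuits whose
complete wiring diagram, cell-type electrophysiology, and behavioral
function (olfactory associative learning) are all known. That makes it the
ideal target for *analysis by construction*: build the circuit from data,
run it, and ask whether the characteristic activity patterns and the
learning behavior emerge. `flysnn` is for computational neuroscientists who
want such a model in a scriptable package: connectome-style topology import
or a calibrated synthetic generator, qualitative-dynamics neuron models fast
enough for real-time-scale simulation, and the circuit-level experiments
(learning success rates, oscillation spectra, cell-type inactivations)
as callable functions.

## The model

Every neuron follows the **piecewise quadratic neuron (PQN) model**, a
qualitative model whose nullclines are parabolic branch pairs so that an
explicit-Euler step needs only adds and multiplies:

$$\dot v = \tfrac{\phi}{\tau}\left(f(v) - n - q + I_{b0} + m(I)\right),\qquad
\dot n = \tfrac{1}{\tau}\left(g(v) - n\right),\qquad
\dot q = \tfrac{\epsilon}{\tau}\left(h(v) - q\right),$$

with piecewise-parabolic $f, g, h$ (offsets derived for C1 continuity) and
a saturating input transform $m(I) = k_I\,\mathrm{clamp}(I; m_0, m_1)$.
PNs, KCs and MBONs add a passive somatic compartment
($\dot v_s = \tfrac{\theta}{\tau}(-\alpha v_s + I_{b1} + I_c + k_r I_r)$,
$I_c = k_0(v - v_s)$); PNs gate their drive by a homeostatic gain
$u \in [0,1]$ driven toward a target rate, updated once per second.
Synapses are kinetic: $\dot s = \alpha(1-s)$ while the presynaptic $v \ge 0$,
$-\beta s$ otherwise ($\alpha = 250$, $\beta = 203.125$, i.e. ≈ 5 ms decay);
input currents are $I_i = \sum_j w_{ji} s_j p_{x\_y}$ with one scaling
constant per class pair. ORNs fire as Poisson processes at
$r = 192\,k_j\,r_{ij} + 8$ Hz from an OR-by-odorant response table.
A reward depresses the KC→MBON-α1 weights of every KC that spiked in the
preceding 5 s from 1 to 0.25; because MBON-α1 (inhibitory) and MBON-α3
(excitatory) converge on the SMP354 read-out neuron, depression makes
SMP354 fire selectively to the learned odor. An 18-bit fixed-point backend
(10 fractional bits, shift-add constant multiplication) mirrors digital
hardware arithmetic.

## Worked example

Build a size-reduced synthetic circuit, train it on one odorant, and test
recall over the six-odor panel:

```r
library(flysnn)
set.seed(101)
cfg <- synthetic_config(n_orn = 384, n_pn = 16, n_ln = 40, n_kc = 250,
                        n_glomeruli = 16)
net <- generate_synthetic_topology(cfg)
or_tbl <- generate_synthetic_or_table(
  unique(net$neurons$or_type[net$neurons$class == "ORN"]),
  sparsity = 0.125, background = 0.15, weak_max = 0.15)
sc <- rescale_scaling(scaling_table(), net)   # preserve per-neuron drive

out <- run_learning_experiment(net, or_tbl, learned = "3-octanol",
                               n_sets = 1, n_trials = 5, warmup = 60,
                               scaling = sc, seed = 7)
print(out)
#> <learning_outcome> learned odor: 3-octanol
#>   5 trials, success rate 60.0%
sum(out$W_final[, "MBON_a1"] == 0.25)
#> [1] 19
```

A trial succeeds when SMP354 — silent before learning because MBON-α1's
inhibition cancels MBON-α3's excitation — spikes *only* in the learned
odor's window. Here the single reward depressed the 19 KC→MBON-α1 synapses
belonging to the odor's KC population, and recall succeeded in 3 of 5
trials (the variability comes from the stochastic ORN spike streams; the
unrewarded control scores 0%).

Odor-evoked antennal-lobe oscillations, from the same network:

```r
pp <- peak_power_experiment(net, or_tbl, "3-octanol", n_repeats = 2,
                            warmup = 60, scaling = sc, seed = 7,
                            groups = c("PN", "LN", "KC"))
print(pp, digits = 3)
#>   group peak_power       sd peak_freq
#> 1    PN   2.60e-04 1.20e-04      24.5
#> 2    LN   2.26e-03 7.73e-04      24.5
#> 3    KC   6.16e-06 3.28e-06       6.5
```

PN and LN virtual LFPs (class-mean synaptic currents) oscillate together
near 24 Hz during the odor, LN power well above PN power, while KCs show no
oscillation — the reported structure of antennal-lobe dynamics.

A thin command-line front end with `build-net`, `simulate`, `learn`, `lfp`
and `sweep-ppnkc` subcommands is installed under `exec/flysnn` inside the
package library.

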