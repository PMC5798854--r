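---
title: "Modelling pathogenic protein spread on a cortical-column network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pathogenic protein spread on a cortical-column network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteospread)
```

# The model

proteospread simulates two protein species — a normally folded variant `Cn`
and a pathogenically misfolded variant `Cp` — as concentration fractions in
every cylindrical section (dendrite, soma, axon) of every neuron of a
multi-column spiking network. Concentrations are bounded by the saturating
concentration `C_max = 1`. Nine processes apply to all neurons at every
timestep, in a fixed order that is part of the model contract: production,
misfolding, clearance, passive diffusion, active transport, the spiking
substep with spike-triggered synaptic transfer, the toxic threshold effect,
the toxicity update and the death check. Except for misfolding, every
process treats the two species identically.

The central modelling assumptions:

* **Templated misfolding is a mass-action encounter process.** The
  conversion per section and timestep is `b = R_M * Cn * Cp`. The package
  carries its own ground-truth justification: `runBox()` simulates
  individual molecules performing Brownian motion in a cube, converting a
  normal molecule whenever it comes within a contact radius of a pathogenic
  one, and `fitProductModel()` fits the product surface to the converted
  fractions over a grid of initial concentrations. In the dilute regime the
  product law describes the particle simulation closely (the acceptance
  suite requires R-squared above 0.9 on an 8-by-8 grid averaged over 10
  seeds).

* **Clearance is adaptive.** Removals are drawn around
  `mu = R_C * log(1 + (e - 1) * C / C_level)`, which equals `R_C` exactly at
  the normal level and rises only logarithmically above it. This is the
  mechanism behind the equilibrium knife edge discussed below: linear
  misfolding growth eventually outruns logarithmic clearance.

* **Spread uses the same operators for both species.** Passive diffusion,
  active transport and synaptic transfer move normal and pathogenic protein
  with the same parameters.

* **Toxicity integrates total protein burden.** The per-step increment
  `0.001 * (exp(10 * mean_section(Cn + Cp)) - 1)` deliberately includes the
  normal species, because the stated increment formula sums both; a neuron
  dies when its toxicity reaches 1, and afterwards only misfolding and
  diffusion out of its sections continue.

# Stochastic draws and the no-truncation choice

Production and clearance magnitudes are sampled from normal distributions
whose standard deviation equals their mean (coefficient of variation 1).
A draw can therefore be negative. We use the draws as sampled and clamp only
the applied update so that `0 <= C` and `Cn + Cp <= C_max` per section.

We initially considered truncating negative draws at zero, which looks like
the safer reading. It is not: truncation inflates the effective mean of
every production and clearance term by the factor
`E[max(0, N(m, m^2))]/m ~ 1.083` while leaving misfolding untouched, which
shifts the deterministic saddle-node bifurcation of the single-compartment
model (initial `Cn = 0.05`, `Cp = 0.01`, levels `0.05/0.01`, rates
`4e-4/0.8e-4`) from a misfolding rate of about 0.0625 up to roughly 0.068.
With nominal means, the bifurcation sits between `R_M = 0.0624` and
`R_M = 0.0626` — exactly where the model's sensitivity is expected to be —
and just below it the equilibrium is metastable: loss occurs by noise-driven
escape on a 1e5–1e6-step timescale, earlier for larger `R_M`. The
single-compartment inner loop is compiled (Rcpp) so those horizons are
practical; it consumes exactly four normal draws per step regardless of
which rates are active, so runs differing only in `R_M` share their noise
under a common seed.

# The network generator

`buildNetwork()` emulates a three-column, four-layer cortical network with
excitatory regular-spiking (RS) and intrinsically bursting (IB) cells and
inhibitory fast-spiking (FS) and low-threshold-spiking (LTS) cells, 470
neurons per column in the full configuration. The published connectivity it
stands in for comes from an external reference table, so connectivity here
is config-driven: a 4-by-4 (pre-type, post-type) Bernoulli density matrix,
scaled by `interScale` for cross-column pairs, with uniform synapse
strengths on `[0.1, 1]`. Synapses originate at the presynaptic axon;
excitatory synapses land on the dendrite, inhibitory on the soma. IB cells
are restricted to layers 5 and 6 (bursting pyramidal cells are a deep-layer
type), which yields 14 layer-by-type populations and, with the three
global-seed variants, the 17-entry seed menu of the factorial design.

Two things the generator deliberately does *not* emulate: reconstructed
morphology (sections have uniform default geometry — dendrite L=150 D=2,
soma L=20 D=20, axon L=300 D=1 micrometres — configurable but not
type-specific) and the reference network's literal connection densities.
Passing tests therefore show that the *mechanisms* behave lawfully on a
network of this character, not that any particular biological connectome
would produce the same numbers.

The reduced configuration (`miniNetworkConfig()`, 3 columns of 10 neurons
with denser connectivity) is a first-class substrate: all conservation,
directional and determinism tests, and the desk-scale sweeps, run on it.

# Spread operators

* **Boundary fraction.** `y = pnorm(-L / (2 * sigma_z))`: the probability
  mass of a centred Gaussian displacement that lies beyond half the section
  length. It tends to 0.5 as `L -> 0` and grows with the diffusion speed
  `sigma_z` (per-timestep displacement sd, micrometres).
* **One-hop fractions.** `z = y * min(R_src, R_dst)/R_src * w * p`, with
  `w = 20` intracellularly and the synaptic strength `r` intercellularly,
  and `p` the intercolumnar spread selectivity. Rows whose total outflow
  exceeds 1 are rescaled to sum to 1 — without the cap the geodesic push
  below need not converge.
* **Geodesic coefficients.** Each source pushes a unit impulse through `z`;
  any section receiving more than `t_sig` (default `1e-6`) re-pushes the
  received mass through its own row, retaining `1 - sum(z)`, until all
  circulating mass falls below `t_sig` and settles. "Amount received" is
  the per-round aggregate at a section, not an individual parcel. Rows of
  the resulting `D` are distributions (they sum to 1 exactly).
* **Diffusion matrix.** `M = (1 - f_pd) I + f_pd D` is stored as a
  row-stochastic source-by-destination matrix and applied to section
  *amounts* (`x = C * V`) as `t(M) %*% x`; dividing by destination volumes
  recovers concentrations. This is the only dimensionally consistent
  reading and conserves total amount to machine precision.
* **Self-retention.** Active transport and synaptic transfer carry explicit
  self-retention terms (`1 -` moved fractions); without them all
  untransferred protein would vanish.
* **Saturation.** If an operator would push a destination section above
  `C_max`, the inflow is scaled back proportionally and the residue stays
  at its sources; events are counted on the run record. The scaling is
  iterated a bounded number of passes because returned residue can push a
  source above the cap in turn.
* **Death rules.** Dead neurons keep misfolding and diffusion *out* of
  their sections; diffusion *into* them is blocked (the blocked mass stays
  at the source, preserving conservation), and production, clearance,
  transport and transfer stop.

# The spiking engine

The electrophysiology is intentionally simple: a leaky integrate-and-fire
engine with four per-type parameter presets, Poisson background drive and
strength-scaled synaptic kicks (excitatory depolarising, inhibitory
hyperpolarising). What the protein machinery needs from it is spike events
to trigger synaptic transfer and a firing threshold the toxic effect can
shift: `Vth_adapt = +k * txc` (loss of function, rates fall) or `-k * txc`
(gain of function, rates rise), with `k = 10` mV at full toxicity by
default. IB cells reset near threshold with a short refractory period,
giving burst doublets under drive; FS cells are essentially network-driven
at the default background level. Baseline rates are on the order of tens of
hertz for excitatory cells; no published baseline exists for this model, so
only qualitative spike-dependent behaviour (e.g. threshold monotonicity
under common random numbers) is asserted, never rate magnitudes.

Both clocks run at `dt = 0.025` ms and advance together: one spiking
substep per protein timestep.

# Randomness, determinism and common random numbers

Every run draws from three independent, individually seeded substreams
(production, clearance, spiking) derived from the master seed. Toggling one
mechanism therefore does not perturb the draw sequences of the others,
which is what makes the common-random-number comparisons meaningful
(threshold monotonicity, the directional parameter effects). Identical
configuration and master seed replay byte-identical death orders, spike
logs and metrics. The three global-seed variants of the seed menu
(`all1`–`all3`) are master-seed offsets, mirroring seeds that differ only
in random-number generation.

# Metrics conventions

* **SSG sign.** The prose definition — incoming minus outgoing strength, so
  'bottleneck' neurons have high SSG — is the default; the printed ordering
  of the two sums is available via `convention = "printed"`.
* **GDS direction.** Hop distances follow synapse direction (anterograde),
  matching the modelled transport bias; an undirected option exists. The
  choice is ours; the source text does not specify one.
* **tc and CONV.** `tc` is the smallest death-count fraction after which
  the Dice similarity of the two death orders stays at or above
  `t_conv = 0.8`, normalised by N. CONV entries average tc over cross
  pairs; pairs of a run with itself are excluded (a self-pair contributes
  the floor `1/N` and would bias within-set means). Censored runs are
  excluded from tc/CONV and counted.
* **Survival regressions** use only neurons that died and have a finite
  predictor; constant predictors raise an error rather than returning a
  meaningless R-squared.
* **ASY** is computed on the stored toxicity trace (default stride: every
  10 steps). The maximum of a subsampled trace can only underestimate the
  full-resolution maximum; toxicity varies slowly on that scale.
* **Ties.** Simultaneous toxicity crossings are ordered by ascending neuron
  id so the death order is a total order, which the Dice machinery
  requires.

# The particle-box defaults

The cube simulation has no published parameters; only the functional form
it validates is the claim. Two a-priori requirements pick the defaults
(side 1, contact radius 0.02, per-axis step sd 0.02, 200 steps, counts
5–40 against capacity 500): the per-molecule conversion hazard
`n_pathogenic * p_contact * steps` (with `p_contact ~ (4/3) pi a^3 / V`)
must stay below about 0.25, because the product law is the dilute
mass-action limit and saturated boxes measure exhaustion rather than
encounter kinetics; and each grid cell must hold enough molecules that the
Poisson noise of the converted counts is small against the signal, because
a noise-dominated surface cannot discriminate functional forms. Conversions
resolve synchronously at the end of each step; newly converted molecules
template from the next step onward.

# Problem sizes

The default test and sweep substrate is the reduced 30-neuron network;
conservation runs 1e4 steps, directional comparisons use 5 master seeds
(TTNB, ASY) or 4 seed locations times 2 replicates (convergence), and the
equilibrium experiments use 11 seeds with horizons up to 2e6 steps on the
compiled kernel. The full 1410-neuron network and the complete 11016-run
factorial design are supported (`defaultNetworkConfig()`,
`sweepMenus()`) but are experiment-scale, not test-scale; the sweep
harness accepts any subset design and derives its parameter-value sets
(35 in the full design) automatically.

# Known limitations

No aggregate-size classes, oligomer intermediates or chaperones; no
extracellular or glial spread route; no synaptic plasticity or
channel-level dynamics; synapse-level degeneration is not modelled (death
is whole-neuron). Firing-rate magnitudes are not calibrated to data. These
match the simplifications of the modelling tradition this package works
in, and several are natural extension points.
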