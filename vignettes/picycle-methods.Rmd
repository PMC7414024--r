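---
title: "Modelling the platelet phosphoinositide cycle with picycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the platelet phosphoinositide cycle with picycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picycle)
```

## The model

`picycle` implements a deterministic mass-action model of the
phosphoinositide (PI) cycle downstream of Gq-coupled receptors, built for
the human platelet and rescalable to other cell types. All state is carried
in **molecule copies per cell**, distributed over three well-mixed reaction
compartments: the plasma membrane (≈1 fl in the human platelet, including
the open canalicular system), the reaction cytosol (≈1 fl) and the
organelles (≈0.5 fl). Bimolecular and higher-order rate constants are
stored already folded with their compartment volume, so a rate constant has
units of s⁻¹ per molecule of each additional reactant; explicit volumes
enter only when a model is rescaled to another cell geometry.

The reaction network couples four functional blocks:

* **The PI4P/PI45P2 axis.** PI4K phosphorylates membrane PI to PI4P
  (`k16`), PIP5K phosphorylates PI4P to PI(4,5)P2 (`k14`), OCRL1
  dephosphorylates PI45P2 back to PI4P (`k15`) and SAC1 returns PI4P to PI
  (`k17`). PI4K, PIP5K and OCRL1 carry distinct basal and activated
  (primed) constants and are switched in concert by the activation event;
  SAC1 carries a single constant that activation never touches. This
  differential regulation is what lets the model hold PI ≈ 6×10⁶ against
  PI4P ≈ PI45P2 ≈ 1.5×10⁶ copies before activation and still produce the
  observed post-activation dynamics.
* **PLC-beta signalling.** Active PLC-beta cleaves free PI45P2 into IP3 and
  DAG. IP3 is removed quickly by a lumped pool of IP3-modifying enzymes
  (IP3 3-kinase B plus INPP5, species `IP3ME`) into a lumped intermediate
  `IPx`, which decays slowly into free inositol. A single direct IP3 → Ins
  reaction cannot reproduce both the fast IP3 transient and the slow
  inositol accumulation — the package's staged-fit tests demonstrate this —
  which is why the intermediate step is part of the canonical network.
* **Lipid resynthesis.** DAG and PA interconvert through DGK and LPP; PA
  and inositol condense (lumped CDS/CDIPT step) into an organelle PI pool,
  which is transferred back to the plasma membrane by a first-order
  exchange whose rate activation does not modify. Because the transfer
  responds only to the slowly-growing organelle pool, membrane PI lost
  during signalling is not replaced for tens of minutes — the model's
  explanation for signal termination by substrate exhaustion.
* **Receptor cascade.** A time-triggered event converts the quiescent
  receptor pool (RGq copies) to an active form; active receptors activate
  Gq, and active Gq activates PLC-beta with the small-G-protein pool (smG)
  as catalytic cofactor. Receptors, Gq and PLC-beta all inactivate
  first-order, so the signal is a transient burst.

Four lipid-binding-protein pairs (for PI45P2, PI4P, PA and DAG) sequester
their lipid by reversible mass-action binding. They buffer the free pools
in homeostasis — limiting what PLC-beta can reach — and cap the
post-activation excursions. Lipid observables (`pi_observables`) are
reported as free + bound totals, which is what lipidomics measures. A slow
cPLA2-driven deacylation of membrane PI into lyso-PI, balanced by a slow
reacylation return, closes the remaining flux loop so the unactivated model
has a true steady state; both reactions are disabled in the "closed"
variant used by the conservation tests.

## Parameters and calibration

The shipped platelet parameterisation
(`inst/extdata/platelet_core_model.yaml`, loaded by `pi_platelet_model()`)
was calibrated with the package's own scan machinery against the target
behaviours the model is meant to reproduce:

* homeostatic pools: membrane PI ≈ 6×10⁶, total PI4P and PI45P2 each
  1.2–1.8×10⁶ copies, flat to <0.1% over 1000 s without activation;
* a short, synchronised PI4P/PI45P2 burst after activation followed by a
  return toward initial levels (the shipped constants put the burst peak
  ≈30–40 s after the activation event, just before the primed constants
  reset);
* membrane PI falling to ≈half its basal level and recovering by less than
  20% over the following 30 min;
* an IP3 peak a few tens of seconds after activation whose magnitude at
  RGq = 1650 is roughly half that at RGq = 5000, and far smaller at
  RGq = 150;
* a PI45P2 binding-protein pool of 1.3×10⁶ copies per cell.

Calibration follows a quantified acceptance rule: a parameter set is
accepted only if every observable's maximum relative deviation from the
target time course is ≤ 20% (`deviation()`), with a floor of 1% of each
observable's maximum mean so that near-zero baselines (pre-activation IP3)
do not blow up the ratio. Scans are logarithmic (`scan_spec()`), by default
±4 orders of magnitude at 5 points per decade, with symmetric grids so the
centre value is always a grid point, deterministic ordering and ties broken
toward the smaller value. `fit_iteration()` runs the staged workflow —
basal lipid constants, then activated constants, then binding-protein
numbers, then the PLC-product branch — as a staged partition of parameters
and observables over the full network, freezing earlier stages;
`run_staged_calibration()` adds narrow restart passes over all staged
parameters until the 20% rule is met. The staged scans identify each
constant given the others (single-displacement recovery to within one grid
step is part of the test suite); they are not, and do not pretend to be, a
global optimiser — a simultaneous displacement of all constants can settle
in a compensating valley, which is a property of scan-based workflows in
sloppy kinetic models generally.

## Activation and termination

`activation_scheme()` encodes the stimulation design: at `t_activation`
the receptor pool is switched to its active form and the `k14`/`k15`/`k16`
constants jump to their primed values (`k17` is refused). Termination has
two modes: under `"inactivation"` (default) active receptors decay
first-order at `1/termination_timescale` and the switched constants are
reset to basal at `t_activation + termination_timescale`; under `"reset"`
the receptors are returned to the quiescent pool at that time instead. The
default timescale is 45 s: the burst-and-return of PI4P/PI45P2 within tens
of seconds, with membrane PI staying depleted, requires the primed
constants to act only briefly — a termination measured in minutes would
keep the axis displaced long after the observed lipid bursts have ended.

The platelet design activates 5000 receptors at t = 100 s over a 0–2000 s
horizon (5000 receptors representing the full thrombin + secreted TxA2/ADP
Gq-receptor complement, 1650 the TxA2 + ADP pair, 150 ADP alone);
nucleated-cell designs activate 85 000 receptors — the same receptor
concentration at 17-fold reaction volume — at t = 1000 s over 0–5000 s.

## Numerics

The ODE system is integrated with LSODA (`deSolve::ode`), switching
automatically between stiff and non-stiff methods, at absolute tolerance
10⁻⁶ molecules and relative tolerance 10⁻⁸ by default. Events are handled
by stopping the integration at the event time, applying the discrete
changes and restarting, so untouched species are continuous across events;
values reported exactly at an event time are the pre-event state. Solver
noise producing negative amounts within 10⁻⁹ of the run's largest amount is
clipped to zero; anything more negative raises an error. Steady states are
found by relaxation (long-horizon integration in doubling rounds) and
reported with their residual max |dX/dt|; the shipped model file stores the
relaxed state, so simulations start at homeostasis. Buffered lipid pools
supplied as totals are partitioned between free lipid and complex at the
closed-form binding equilibrium (the stable root of the conservation
quadratic). Bulk scans (the 4096-combination mosaic, proteome-gap scans)
integrate at the looser tolerances atol = 10⁻² molecules, rtol = 10⁻⁶;
on nucleated-cell amounts of 10⁶–10⁸ molecules this changes observables by
less than 10⁻⁵ relative while making the scans several-fold faster.

## Rescaling to other cell types

`rescale_model()` freezes the reaction structure and per-concentration
kinetics while swapping what is cell-specific: compartment volumes, the 12
key protein copy numbers (`pi_key_proteins`), the receptor count, and
lipid/binding-protein pools scaled from the platelet reference in
proportion to the compartment volume ratio. Folded constants are divided by
`ratio^(order-1)` (order = reactant molecularity plus enzyme), which makes
concentration-space kinetics exactly invariant — the `pltx17` control (a
platelet scaled 17-fold onto nucleated volumes) reproduces the platelet
trajectories to solver tolerance, per-concentration. `celltype_model()`
additionally relaxes the lipid side to the new cell's own pre-activation
steady state: a cell with a different enzyme balance holds different
homeostatic pools, and simulations of that cell should start there.

Proteome tables carry per-entry provenance (`native`,
`borrowed:<donor>`, `scanned`). Gaps are filled either by borrowing donor
values (`complete_proteome()` — the mosaic completion) or by scanning each
missing copy number against a reference behaviour
(`scan_missing_proteins()`). The gap scan runs coordinate-wise with a
narrowing multi-pass grid in a fixed mechanistic order — PI4P/PI45P2-axis
enzymes first, because the pre-activation drift pins them nearly
independently, then the signalling chain — which avoids the compensating
local optima an unordered greedy scan falls into. A flat objective (the
monitored outputs do not depend on the protein) is detected and the tie
broken to the grid minimum, flagged in the result.

## The mosaic experiment and its classifier

`mix_and_match()` enumerates all 2¹² = 4096 assignments of the 12 key
proteins to one of two source proteomes (lexicographic bitmask over the
fixed order of `pi_key_proteins`), simulates each at nucleated geometry
(5000 s, activation at 1000 s) starting from the reference cell's
homeostatic pools, and classifies every monitored observable against the
reference behaviour. The classifier is rule-based and explicit, because a
judgement of "correct dynamic behaviour" is otherwise under-specified:

1. **pre-activation stability** — drift before activation below 10% of the
   observable's initial level (with a floor of 1% of the reference's
   maximum for near-zero baselines);
2. **response direction** — the post-activation response (rise, fall, or
   flat within 10%) matches the reference;
3. **response magnitude** — the peak (or trough) change from the
   pre-activation baseline is within a 5-fold band of the reference's.

An observable failing any rule is incorrect; a combination is incorrect if
any observable is. Because the 5-fold band is a judgement call, the summary
also reports the fraction at 3- and 10-fold bands; in the shipped
conditions the fraction is insensitive to the band, because failures are
dominated by pre-activation drift and direction flips rather than by
magnitude alone.

## The synthetic-data generator

No experimental tables ship with the package. `generate_timecourses()`
emulates collated stimulated-platelet datasets: it simulates a truth model
and draws n = 10 multiplicative log-normal replicates per observable and
time point (mean-corrected, `exp(σz − σ²/2)`, so replicate means are
unbiased), reporting mean and SEM; the default σ = 0.15 gives SEM bars of
a few percent, a visual stand-in, not an estimate of any real assay.
`generate_proteome()` perturbs a template's copy numbers by median-
preserving log-normal fold factors. The shipped cell-type tables
(`pi_proteomes()`, files labelled *synthetic*) are fixed draws from this
generator: a HeLa-like table from the concentration-matched enlarged
platelet at fold-σ 1.2 (cross-cell-type differences of up to an order of
magnitude), a U2OS-like table from the HeLa table at fold-σ 1.0 with the
five canonical gaps deleted (Gq, the IP3-modifying pool, OCRL1, PI4K,
cPLA2), and a mouse-platelet table from the quarter-volume platelet at
fold-σ 0.8. The between-line spread of 1.0 was chosen so that the
borrowed-completion ("mosaic") table visibly misbehaves for the
PI45P2/PI4P/DAG/PA outputs while the scanned completion still recovers the
reference-like behaviour — the qualitative situation the mosaic experiment
is about. What the generator does **not** emulate: correlated measurement
error across time points, systematic inter-laboratory offsets, biological
co-regulation of enzymes (each protein is perturbed independently), or any
guarantee that a random table is homeostatically balanced. Passing tests
therefore show that the pipeline reproduces its own study design, not that
the synthetic tables equal any published proteome.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the full 4096-combination
mosaic scan (~35-state ODE, 5000 s horizon each, a few minutes on one
core), a ~60-point binding-protein scan, 3-point receptor titrations, and
staged-calibration scans of a few hundred simulations; synthetic datasets
use the default n = 10 replicates on grids of 30–80 time points. These
sizes were chosen to exercise every workflow at full fidelity while keeping
a complete run in the minutes range.

## Known limitations

* The PI3K/PIP3 branch, the Gα13 branch and calcium dynamics are out of
  scope; IP3 is the terminal second messenger reported.
* Rate constants are calibrated to the documented platelet behaviours, not
  transcribed from published kinetic tables; absolute fluxes should be read
  as order-of-magnitude.
* The behaviour classifier is this package's operationalisation of
  "correct dynamics"; headline mosaic fractions are reproducible only
  relative to it (hence the band bracket).
* Scan-based calibration identifies parameters given the others; it is not
  a global optimiser and inherits the sloppiness of mass-action kinetics.
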