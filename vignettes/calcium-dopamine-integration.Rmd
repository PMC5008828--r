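---
title: "Modeling calcium-dopamine integration in striatal medium spiny neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling calcium-dopamine integration in striatal medium spiny neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msnsig)
```

## The biological question

Reward learning requires striatal medium spiny neurons (MSNs) to detect the
coincidence of two transient inputs: an NMDA-receptor calcium signal driven by
cortical glutamate, and a dopamine signal from midbrain neurons reporting
reward. Corticostriatal potentiation through CaMKII/PP1 signaling occurs only
when the two inputs arrive close in time (the *input-interval constraint*) and
in the right order, dopamine after calcium (the *input-order constraint*).
`msnsig` implements a mass-action kinetic model of the D1-receptor MSN
signaling network in which these constraints emerge from two striatally
enriched phosphoproteins:

* **DARPP-32** — phosphorylated at Thr-34 by dopamine/D1R/cAMP/PKA signaling
  it becomes a potent PP1 inhibitor. Basal PP1 activity is strong enough to
  erase the substrate phosphorylation produced by calcium-activated CaMKII
  alone; a transient, dopamine-timed window of PP1 inhibition gates the
  response. Because both the CaMKII activation (deactivation time constant
  about 6 s) and the PP1 inhibition are transient, gating requires temporal
  proximity — the interval constraint.
* **ARPP-21** — phosphorylated at Ser-55 by the same PKA signal, it becomes a
  high-affinity sink for Ca2+/calmodulin. If dopamine arrives *before*
  calcium, phospho-ARPP-21 is already present when the calcium transient
  loads calmodulin, sequesters Ca2+/calmodulin away from CaMKII, and thereby
  suppresses the response — the order constraint. The same mechanism causes
  an inter-trial refractory period whose duration follows the decay of
  phospho-ARPP-21 (tens of seconds).

## Model structure

Every process is an elementary mass-action reaction
(`flux = kf * prod(reactants) - kr * prod(products)`; irreversible means
`kr = 0`); enzymatic steps are explicit binding + catalysis pairs
(`E + S <-> ES -> E + P`). There are no Michaelis-Menten or Hill rate laws
inside the network. The model is a single well-mixed volume; `cytosol`,
`PSD` and `input` are bookkeeping tags. Concentrations are in uM, time in s;
nM values from the experimental literature are converted at the boundary.

The wild-type network (74 species, 84 reactions) comprises:

* **Calcium axis** — two-step calmodulin loading (`CaM -> CaMCa2 -> CaMCa4`),
  calmodulin-target cycles for CaMKII, PP2B (calcineurin) and phospho-ARPP-21,
  CaMKII activation with cooperative autophosphorylation, two-pool
  (F-actin-rich cytosol / PSD) translocation, and phosphorylation of a generic
  PSD-localized CaMKII/PP1 substrate.
* **Dopamine axis** — D1R binding, Golf activation, AC5 basal and
  Golf-stimulated cAMP synthesis, degradation by a PDE10 plus PDE4 pool, PKA
  holoenzyme activation by cAMP, DARPP-32 Thr-34 (PKA/PP2B) and Thr-75
  (CDK5/PP2A) cycles, Thr-75 inhibition of PKA, Thr-34 inhibition of PP1, and
  PKA- and calcium-regulated PP2A.
* **ARPP-21** (wild type only) — Ser-55 phosphorylation by PKA,
  dephosphorylation by PP2A, and reversible phospho-ARPP-21 binding of
  Ca2+/calmodulin (Kd 30 nM, versus a sub-nanomolar PP2B-calmodulin Kd, so
  PP2B activation is insensitive to sequestration).

Calcium and dopamine are *clamped inputs*: their concentrations are forcing
functions generated by the stimulus module, reactions may read them, and
their derivatives are zeroed. Mutant variants are built structurally:
`D32T34A` and `A21S55A` remove the respective phosphorylation reactions,
`NO_ARPP21` removes the protein, `CAM_OVEREXPRESS` triples total calmodulin.

```{r}
m <- build_model("WT")
b <- model_basal(m)                       # basal steady state (Ca 60 nM, DA 20 nM)
r <- simulate(m, standard_protocol(delta_t = 1), t_end = 120, init = b)
plot(r$time, observable(r, m, "pSubstrate"), type = "l",
     xlab = "time (s)", ylab = "pSubstrate (uM)")
```

## Inputs

The stimulus generator reproduces the study conditions with no external data:
10 calcium pulses at 10 Hz, each a difference of two exponentials
(rise 5 ms, decay 30 ms — fast NMDAR-like kinetics; the exact constants are
not printed in the source literature and are exposed as configuration), with
the per-pulse amplitude auto-scaled so the summed train peaks at 5 uM over a
60 nM basal; and a 1.5 uM, 1.0 s dopamine transient over a 20 nM basal,
realized as a plateau with 10 ms exponential edges to avoid integrator
discontinuities. The input interval is `delta_t = t_dopamine - t_calcium`
measured start-to-start; the inter-trial interval (ITI) is measured
calcium-onset to calcium-onset.

## Numerical choices

* Stiff integration uses `deSolve`'s lsodes (BDF with a sparse Jacobian) through a
  compiled mass-action right-hand side, with a 0.01 s cap on the internal
  step so the pulsed calcium input is never stepped over; relative tolerance
  1e-6, absolute 1e-9 uM. Halving the step cap changes trajectories by less
  than 1e-4 relative (tested). Smooth constant-clamp protocols (slice
  treatments, steady states) use a larger cap.
* Steady states are located by long integration with a residual criterion
  `max |dX/dt| / max(X, 1e-6) < 1e-8` rather than root-finding, which is
  robust for this conservation-constrained stiff system.
* Forcing traces are linearly interpolated from a dense sampling (1 ms
  within pulse structure); clamped species follow the analytic stimulus
  exactly on the output grid.
* Activation areas are trapezoidal integrals of the excursion above the
  pre-stimulus basal, floored at zero, over a 100 s window from the calcium
  onset (the substrate response has returned to baseline well before that in
  every scenario used). Refractoriness and multi-trial analyses compute each
  trial's activation counterfactually — the positive excess of the k-trial
  trace over the (k-1)-trial trace in trial k's window — since a plain window
  integral either counts the previous trial's decaying response as activation
  or masks the new response entirely. `REF(reference ITI) = 0` holds exactly
  by construction.
* The one-at-a-time sensitivity scan re-runs the interval sweep for every
  parameter x direction on a reduced grid (delta-t in -2..2, 70 s windows,
  0.1 s step cap); only area *ratios* between identically configured runs
  enter the fractional response changes. The full scan is about 1,200
  simulations and runs in a few minutes.

## Calibration and the parameter file

The packaged parameter file (`inst/extdata/striatal_parameters.tsv`; columns
`name`, `value`, `units`, `provenance`) is this package's own
parameterization of the network. Totals that the literature fixes are used
directly (DARPP-32 50 uM, ARPP-21 20 uM, basal calcium 60 nM, basal dopamine
20 nM); everything else was calibrated against the molecular-phenotype table
implemented in `phenotype_specs()`: basal levels (cAMP 30-90 nM, Thr-34
about 0.4 uM, Thr-75 about 12 uM, Ser-55 about 0.7 uM), slice fold-changes
(saturating dopamine: Thr-34 x11, Thr-75 x0.5, Ser-55 x7, cAMP about 10 uM;
sustained calcium: Thr-34 and Thr-75 x0.5; PDE10 inhibition: Thr-34 x2),
kinetic parameterizations (G-protein activation 10-100 1/s, cAMP decay
0.508 1/s, CaMKII deactivation 0.166 1/s, a PKA-reporter rise/decay pair
0.227/0.043 1/s) and two dose responses (PKA vs cAMP: Hill h 1.4,
K 527.8 nM; calmodulin loading vs calcium: h 1, K 6.29 uM).
`divergence_table()` scores every variable as `log2(simulated/target)` and
classifies it into +-30% / +-80% bands; the packaged model has every
variable inside +-80% and all but the two reporter rates inside +-30%.

Design decisions taken where the problem was genuinely open:

* *Calmodulin loading.* Each Adair-Klotz step binds one calcium with the
  first step tighter than the second; this is the only two-step mass-action
  scheme compatible with the measured near-hyperbolic loading curve (h about
  1, K 6.29 uM). The loaded species are still named `CaMCa2`/`CaMCa4`.
* *PKA holoenzyme.* Two cooperative 2-cAMP binding steps followed by two
  single-subunit release steps. The equilibrium constants were fitted to the
  activation-curve target; the lumped release rates are deliberately fast so
  the release channel never throttles equilibration. Total PKA (0.2 uM
  catalytically available holoenzyme) keeps the receptor-bound cAMP
  reservoir small, which sets how quickly the PP1-inhibition window closes
  after a dopamine transient.
* *PKA-activity reporter.* The imaging reporter used for the PKA-dynamics
  phenotype is a PKA substrate, not a CaMKII substrate, so the model carries
  a 0.05 uM tracer reporter (phosphorylated by free catalytic subunit,
  dephosphorylated by PP1) that does not load the network; the
  difference-of-exponentials fit is performed on it.
* *Slice-treatment surrogates.* Saturating dopamine = clamp dopamine at
  10 uM (sampled at 5 min); NMDA = clamp calcium at 1 uM (sampled at
  10 min); PDE10 inhibition = PDE10 catalytic rate set to zero with the
  other PDE pool intact.
* *PP2B activation.* PP2B binds calmodulin at both loading states (a
  detailed-balance-closed cycle) and requires one further calcium binding to
  become catalytically active, mimicking its regulatory-subunit calcium
  sites; without this the sub-nanomolar calmodulin affinity would make PP2B
  insensitive to calcium at basal occupancy.
* *CaMKII autophosphorylation.* A holoenzyme-free pairwise approximation:
  phosphorylation flux is second order in the active (calmodulin-bound)
  subunit concentration. This is the major structural approximation of the
  calcium axis.
* *Thermodynamics.* The three calmodulin-target cycles close exactly (the
  cycle-closing dissociation constants are recomputed from the others and
  recorded as such in the provenance column). The CaMKII translocation loop
  is deliberately held out of equilibrium — activity-dependent F-actin
  release is implicitly energy-consuming — so detailed balance is asserted
  only for the declared calmodulin cycles.

## What the tests do and do not show

The synthetic stimulus module emulates amplitudes and timing conventions of
the underlying slice and imaging experiments; it does not model glutamate
transduction, dopamine diffusion and reuptake, spatial gradients, or
stochastic single-synapse chemistry. Passing tests therefore demonstrate
that the *deterministic, well-mixed* network reproduces the calibrated
phenotypes and the emergent temporal constraints; they do not validate the
model against raw experimental recordings. Known limitations: the T34A
mutant shows a mild suppression below baseline at negative intervals (the
ARPP-21 arm still sequesters calmodulin even though gating is absent) and
active PP1 shows a transient rise of up to about 20% during a calcium train
(PP2B-mediated Thr-34 dephosphorylation) — both consistent in direction
with the mechanism but not separately constrained by data.

## Reproducing the in-silico experiments

```{r}
sw  <- dt_sweep("WT")                       # interval/order curve (Fig-2C-style)
ck  <- camkii_amplitude_curve()             # CaMKII threshold (Fig-3B-style)
rf  <- refractoriness("WT")                 # REF vs ITI (Fig-4D-style)
mt  <- multi_trial("WT", 10, iti = 10)      # massed trials (Fig-4E-style)
rb  <- robustness_grid("dopamine_amplitude")# input-strength grid (Fig-5-style)
sens <- sensitivity_scan(0.2)               # +-20% one-at-a-time (Fig-6-style)
```

Problem sizes used by the packaged analyses: single trials span 110-135
model-seconds of the 74-species system; the interval sweeps use a
-6..+8 s grid; the sensitivity scan covers all 119 parameters x 2
directions x 4 intervals. `scripts/acceptance.R` re-runs the full set and
writes every headline quantity as JSON.
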