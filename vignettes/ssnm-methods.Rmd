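---
title: "Methods: kinetic modeling of SM-SNARE network motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic modeling of SM-SNARE network motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssnm)
```

## The model

`ssnm` models exocytic membrane fusion as a closed mass-action reaction
network over the SNARE proteins and their SM-family regulator. Every
species carries an explicit *moiety composition* — how many copies of each
protein it contains — so protein conservation is a structural property:
`validate_model()` rejects any reaction that does not conserve every
moiety, `conservation_laws()` returns one conserved total per protein
(rows of the left null space of the stoichiometric matrix), and the tests
verify these totals along every simulated trajectory.

The assembly cascade shared by all catalog motifs is

* R1: Syx + S25 ⇌ T (t-SNARE complex),
* R2: T + Syb ⇌ Pin (SNAREpin),
* R3: Pin + SM ⇌ Pin·SM (pattern-2 binding),
* R4: Pin → Fused (basal fusion, rate `kf0`),
* R5: Pin·SM → Fused·SM (SM-stimulated fusion, rate `kf1` ≫ `kf0`).

The wildtype neuronal motif adds the neuron-specific pattern-1 reaction

* R6: Syx + SM ⇌ closed complex,

a dead end with respect to assembly: the closed complex participates in no
other reaction and releases its constituents only by dissociation. The
mutant motif (open-syntaxin mutant) is the wildtype without R6; the
extended motif adds an abstract displacement factor,

* R7: DF + closed ⇌ DF·SM + Syx,

modeled as a single reversible exchange because the displacement reaction
names both products (SM removed from syntaxin, syntaxin freed). Fusion is
an irreversible state change to a `fused` species carrying the same
moieties, so mass balance holds through fusion; both fused products
(with and without bound SM) are absorbing — we take no position on any
distinct downstream fate of the SM-bound fused complex, which is
irrelevant to the fusion readout.

Assumptions worth stating explicitly: dilute well-mixed kinetics (no
membrane geometry, no crowding), binding collapsed to the two SM patterns
(the N-peptide sub-binding-site controversy is deliberately abstracted
away), no calcium triggering or docking as a separate observable, and
stoichiometric coefficients of 1 in all shipped motifs (the types support
higher coefficients).

## Readout: plateau fusion, not true steady state

The fusion level at time *t* is the fraction of the readout moiety (the
v-SNARE) residing in fused species. Because all binding steps are
reversible and fusion is irreversible, the *true* t → ∞ state of every
motif is complete fusion at every SM dose — the interesting,
dose-dependent quantity is the fusion *plateau* on the experimental time
scale. `plateau_readout()` therefore integrates until the fusion slope
falls below `epsilon` (default 1e-6 s⁻¹) or `t_max` (default 5000 s,
roughly the duration of a lipid-mixing assay record) and reports the
fusion level there, flagging whether the slope criterion was met. All
dose-response results in the package are this plateau readout;
"steady-state fusion" in the documentation always means this.

## Default rate constants and their calibration

The package's default rate set (units μM⁻¹ s⁻¹ for associations, s⁻¹
otherwise) is:

| reaction | kf | kr | Kd |
|---|---|---|---|
| R1 (t-complex assembly) | 1 | 0.1 | 0.1 μM |
| R2 (SNAREpin zippering) | 1 | 0.01 | 0.01 μM |
| R3 (SM on SNAREpin) | 5 | 0.05 | 0.01 μM |
| R4 (basal fusion) | 2e-5 | 0 | — |
| R5 (stimulated fusion) | 1e-3 | 0 | — |
| R6 (closed binding) | 30 | 0.003 | 0.1 nM |
| R7 (displacement) | 1 | 0.1 | 0.1 μM |

These are package choices, not measurements: the motifs' source
supplementary rate table is unavailable, so we fixed physically reasonable
values (sub-diffusion-limited associations of 10⁶–3×10⁷ M⁻¹s⁻¹;
strong binding throughout; nanomolar affinity for the closed
Munc18-syntaxin complex, in line with published estimates of that
interaction; closed-complex dissociation slower than SNAREpin·SM
dissociation) and then verified that the catalog reproduces the motifs'
qualitative repertoire. Three timescale constraints shape the calibration,
and they are worth recording because they are forced by the plateau
readout rather than free:

1. **Basal fusion must be slow relative to the horizon** (1/kf0 = 5×10⁴ s
   ≫ t_max): otherwise every dose fuses to completion within `t_max` and
   the dose-response flattens. kf0 = 2e-5 gives a visible but small basal
   plateau (0.089 at zero SM).
2. **Stimulated fusion must be fast enough to separate from basal but
   slow enough that no dose meets the plateau-slope criterion before
   `t_max`** (1/kf1 = 1000 s): if the slope criterion triggers, the
   readout for all saturated doses collapses onto nearly identical values
   and the argmax over a fine dose grid becomes a numerical sawtooth. With
   kf1 = 1e-3 every scanned condition reads out at `t_max` and the yeast
   and mutant curves are strictly increasing across the full 0–6 μM scan.
3. **Closed binding must be strong** (Kd ≈ 0.1 nM, slow off-rate): the
   high-dose decline of the neuronal motif exists only if syntaxin locked
   by excess SM stays locked on the readout timescale. With the default
   set, neuronal plateau fusion falls from 0.64 at 3 μM SM to 0.52 at
   6 μM — deep enough that a 2-fold overexpression from 3 μM is
   unambiguously inhibitory.

Under these defaults the neuronal optimum on a 0.05 μM grid sits at
4.45 μM, one grid step below exact SM–syntaxin equality: the last SM
equivalents funnel through the closed-complex pool slowest, so the kinetic
plateau peaks marginally below stoichiometric equality. This offset is a
structural property of the plateau readout, not a calibration artifact.

"Bifurcation" in the motif literature for this system means the biphasic
dose-response with an interior optimum, not a dynamical-systems bifurcation
of attractors; the package names the quantity the *optimum SM dose*
(`find_optimum_sm()`) and keeps "bifurcation point" as a documented alias.

## Numerical choices

* **Integrator.** `deSolve::ode(method = "lsoda")` — a variable-step,
  stiff-capable solver (automatic Adams/BDF switching) with rtol = 1e-6,
  atol = 1e-9 μM, reporting on a 500-point grid. Any stiff-capable method
  meeting the tolerances would do; tests check that halving the tolerances
  moves plateau fusion by < 1e-4, and that moiety totals are conserved to
  relative 1e-6 with no concentration below −1e-9 μM.
* **Plateau detection** uses finite differences of the fusion level on the
  reporting grid; the first interval with slope < `epsilon` defines the
  plateau time. A model with both fusion channels disabled plateaus
  immediately at zero.
* **Optimum search.** Grid scan at the stated resolution, then
  golden-section refinement (`stats::optimize`) inside the two-cell
  bracket; ties at equal maxima resolve to the smallest dose.
* **Classification** (`classify_response()`) works on the scanned
  sequence with a fusion-unit tolerance (default 1e-3): monotone labels
  require every successive difference within tolerance of the trend and a
  total change above it; biphasic requires a rise and a fall both above
  tolerance around the maximum; everything else is flat. Halving the scan
  step does not change any catalog label under the defaults.
* **Gillespie oracle.** `simulate_stochastic()` implements the exact
  direct method in C++ with falling-factorial propensities and a volume
  scale Ω (molecules per μM); it exists to cross-check the deterministic
  route, and the acceptance tests require ensemble means (200 runs,
  Ω = 10⁴) to match ODE fusion levels within three standard errors at
  five checkpoints for every catalog motif.
* **Latin hypercube sampling** (`lhs_sample()`) treats every rate constant
  as an independent dimension, uniform on [(1−v)k, (1+v)k] with exactly
  one draw per equal-width stratum (via the `lhs` package), v = 0.30 by
  default, seeded. The uniform choice and the per-dimension independence
  are package decisions; zero rates (irreversible reactions) stay exactly
  zero. `robustness_analysis()` counts a sample as "preserved" when its
  dose-response shape label matches the nominal label — a package
  definition of robustness; under the defaults the neuronal biphasic label
  survives ±30% perturbation in the clear majority of samples (asserted at
  desk scale in the tests).

## The synthetic assay generator

`generate_assay_trace()` emulates the observable of a FRET lipid-mixing
assay: a normalized dequenching signal driven by the simulated fusion
level with additive Gaussian noise, clamped to [0, 1−1e-6] so that the
fusion-round transform −log(1−f) (`fluorescence_to_rounds()`, the standard
Poisson-rounds convention) stays defined. Traces are normalized to the
moiety-fraction fusion level (not to a detergent-lysis maximum, which the
generator does not model). What it deliberately does *not* emulate:
photobleaching, inner-filter effects, baseline drift, donor-quenching
calibration, or vesicle-size heterogeneity. Passing tests on synthetic
traces therefore show that the analysis pipeline is internally consistent
under well-behaved noise — not that it is robust to every artifact of real
fluorimeter data. Note the clamp biases the mean of noisy traces wherever
the clean signal is within ~3 noise SD of 0 or 1; tests of unbiasedness
exclude those points.

`make_recovery_fixture()` chains the pieces end to end: one LHS-perturbed
rate draw, a dose-response scan, noise, and the requirement that noisy and
clean tables classify identically (with the classifier tolerance raised to
3× the noise SD, since the default 1e-3 tolerance cannot absorb
successive-difference noise of sd ≈ 1.4×noise SD).

## Problem sizes used by the shipped tests

The test-suite defaults are desk-scale choices: robustness at n = 50
samples on a 13-point dose grid (the full published-scale n = 2000 runs in
tens of minutes with the same code path), stochastic ensembles of 200 runs
at Ω = 10⁴ over 150 s, conservation/monotonicity sweeps over 20 perturbed
rate sets per motif, and the acceptance scan at the full 121-point
0.05 μM grid.

## Known limitations

* The reaction sets are reconstructions from published network diagrams
  and prose; the original model's exact supplementary equation list was
  not available for comparison, and the default rates are calibrated
  package choices. Conclusions that depend on absolute rates (time to
  plateau, absolute fusion levels) should be treated as illustrative;
  the comparative, shape-level conclusions are the robust output.
* The displacement factor's concentration (1 μM default) and rates are
  package choices; its exchange stoichiometry is the simplest form
  consistent with the described displacement activity.
* No spatial, compartmental, delay or non-mass-action kinetics; no
  thermodynamic cycle-consistency enforcement (the shipped motifs contain
  no closed binding cycles where it would bind).
* SBML support targets the package's own export profile (L3V1, mass-action
  kinetic laws, moiety annotations); arbitrary third-party SBML models are
  not guaranteed to import.
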