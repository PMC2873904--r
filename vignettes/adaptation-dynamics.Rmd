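---
title: "Dynamic MWC modelling of chemotaxis signalling and adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic MWC modelling of chemotaxis signalling and adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chemodyn` models the signalling response of *Escherichia coli*
chemoreceptor complexes to attractant step stimuli, and the adaptation
dynamics that follow, at the level observed in in-vivo FRET experiments.
This vignette is the package's account of the science: the model, its
assumptions, the tunable parameters, the numerical conventions, and what the
synthetic-data checks do and do not establish.

## The two-state receptor-complex model

Tar and Tsr chemoreceptors cluster into strongly coupled signalling teams of
`N` receptor dimers that switch between an active (*on*) and inactive
(*off*) state as one allosteric unit. The probability of the on state — the
complex activity — is

$$A = \frac{1}{1 + e^{F}},$$

where `F` (in units of kT) is the free-energy difference between the on and
off states of the whole complex:

$$F = N\left[ f(m)
  + \nu_a \ln\frac{1 + L/K^{\mathrm{off}}_a}{1 + L/K^{\mathrm{on}}_a}
  + \nu_s \ln\frac{1 + L/K^{\mathrm{off}}_s}{1 + L/K^{\mathrm{on}}_s}
  \right].$$

The ligand term (MeAsp concentration `L`, mM) is non-negative for an
attractant because each off-state dissociation constant is smaller than its
on-state partner: attractant binding favours the inactive state. The
methylation term `f(m)` is linear in the average methylation level per dimer
and has negative slope: methyl groups stabilise the active state. Since both
receptor species bind MeAsp, a mixed complex integrates them with weights
`nu_a`, `nu_s` (Tar and Tsr dimer fractions).

The phosphorylation cascade downstream of the receptors (CheA, CheY/CheY-P,
CheZ) is taken to be in quasi-steady state, with active-protein
concentrations proportional to `A`. The complex activity therefore stands in
directly for the FRET readout; the package never models the cascade
explicitly.

### Default calibration

All numeric constants are configuration (`inst/extdata/chemodyn-params.yaml`),
not code. The defaults transcribe the constants established for MeAsp
sensing by mixed Tar/Tsr complexes in the quantitative-modelling literature:

| constant | default | units | meaning |
|---|---|---|---|
| `nu_a : nu_s` | 1 : 1.4 | – | wild-type Tar:Tsr dimer ratio |
| `K_off_a`, `K_on_a` | 0.02, 0.5 | mM | Tar MeAsp dissociation constants (off/on) |
| `K_off_s`, `K_on_s` | 100, 1e6 | mM | Tsr MeAsp dissociation constants (off/on) |
| `f(m)` | `1 - 0.5 m` | kT | per-dimer methylation free energy |
| `N(L0)` | `17.5 + 3.35 L0` | dimers | complex size vs ambient concentration |
| `g_R` | 0.0069 | methyl/s | methylation rate constant (data-collapse fit scale) |
| `a` | 1/3 (WT1), 1/2 (WT2, CheB mutant) | – | adapted activity |

The complex size grows roughly linearly with the ambient concentration the
cells are adapted to; `N` is used as a continuous positive real because it
enters the free energy only multiplicatively and is itself obtained by
least squares (`fit_complex_size()` reproduces that calibration from
addition dose–response data). During a simulated protocol `N` is frozen at
the value for the concentration the cells start adapted to; dose–response
removal points, whose pre-stimulus state is the stepped-up concentration,
use the size interpolated there. The residual dependence of the collapse
curve on `N` across the concentrations considered is minor.

## Ligand flow

In a flow chamber a "step" establishes over seconds. Protocols
(`step_protocol()`) therefore relax the concentration exponentially towards
the post-event target, with separate rate constants for addition (`k_rise`)
and removal (`k_fall`); `k = Inf` recovers a perfect step. The shipped
flow calibration (1.0/1.3 s⁻¹ for the fast WT1-style flow, 0.35/0.45 s⁻¹
for the slower WT2-style flow) encodes order-of-seconds equilibration with
removal slightly faster than addition; these are per-setup fit parameters
and should be refitted from a dye profile for any real chamber. Event
instants follow a right-continuous convention, which matches restarting the
integrator at each event.

## The adaptation-model family

Adaptation acts through the methylation level. All precise models share the
Barkai–Leibler structure — rates depend on the activity only — which makes
the return to the adapted activity `a` robust:

| registry name | dm/dt |
|---|---|
| `power-h3` | `g_R (1-A) - g_B A^3` |
| `power-h2` | `g_R (1-A) - g_B A^2` |
| `power-h1` | `g_R (1-A) - g_B A` |
| `mm-feedback` | `g_R (1-A)/(K_R + 1-A) - g_B A · A/(K_B + A)` |
| `mm-nofeedback` | `g_R (1-A)/(K_R + 1-A) - g_B A/(K_B + A)` |
| `cheb-mutant` | `g_R (1-A) - g_B A` |

The headline model is `power-h3`: receptors are methylated (CheR) while
inactive and demethylated (CheB-P) while active, with the demethylation rate
carrying two extra activity factors for the phosphorylation feedback on CheB
and cooperativity between two CheB-P molecules. `cheb-mutant` describes a
non-regulatable CheB: the only remaining activity dependence of
demethylation is CheB binding to active receptors. The Michaelis–Menten
pair, with the default saturated constants `K_R = K_B = 0.1` (activity
units), represents the ultrasensitive class of models; without feedback its
net rate is nearly flat around the steady state, which is what produces its
extremely long adaptation times and its poor ranking against collapse data.

`g_B` is never free: `solve_gB()` ties it to `g_R` by the steady-state
condition `dm/dt(a) = 0` (closed form for the power-law and mutant
families, a bracketed root solve for the Michaelis family). This constraint
is why the marked asymmetry between slow adaptation to addition and fast
adaptation to removal cannot be produced by tuning the two rate constants
independently — it requires the steep activity dependence of demethylation.

### Imprecise adaptation

Methylation sites are finite. With `imprecise = TRUE` the methylation term
is scaled by `min{1, (M_max - m)/m_c}` and the demethylation term by
`min{1, m/m_c}`: each process loses efficiency once fewer than `m_c`
sites are available (or occupied) and stops entirely at the hard bound.
Defaults: `M_max = 8 * nu_a` (eight sites per homodimer, with only Tar —
not Tsr — allowed to take methyl groups, averaged over the complex) and
`m_c = 0.5`. The linear saturation shape is the simplest form consistent
with site counting; it is a package choice, and both the shape's scale and
`M_max` are configuration. The rate constants are shared with the precise
model; the imprecise steady state is found self-consistently by the
simulator. Two qualitative signatures follow, and are what the checks
assert: after a large addition the activity settles below its pre-stimulus
value (sites exhaust), and after removal to buffer it settles above it.

## The data collapse

At constant ligand the chain rule gives

$$\frac{dA}{dt} = \frac{\partial A}{\partial m}\,\frac{dm}{dt}
  \equiv g(A),$$

with `∂A/∂m = -A(1-A) N f'(m)` depending on `A` (and `N`) only, and `dm/dt`
on `A` only for precise models. Every adaptation segment of every time
course — whatever the size, direction, duration or number of steps — must
therefore fall on the single curve `g(A)`, with fixed points at 0, `a` and
1. This collapse is the package's central analysis: it condenses time
courses for model comparison (`fit_gR()`, one free parameter), exposes the
methylation kinetics (`effective_dm_dt()` divides the rates by `∂A/∂m`),
and deviations from it diagnose ligand flow (demethylation side) and
imprecise adaptation (methylation side, depressed; buffer removal, raised).

### Extraction conventions

`extract_collapse()` follows the measurement pipeline: per post-event
segment, discard the first 10 s after step onset (flow transients), average
every 20 subsequent samples into non-overlapping blocks, and take forward
difference quotients between block means. Conventions worth stating:

* **Blocks, not a sliding window.** Non-overlapping block means keep the
  per-point variance uniform; trailing partial blocks are dropped for the
  same reason.
* **Midpoint pairing (default).** The difference quotient between blocks
  `i` and `i+1` estimates the derivative near the midpoint, so it is paired
  with the mean of the two block activities. Pairing it with the left block
  instead (`pairing = "left"`, provided for comparison) incurs an O(Δt)
  bias — with 0.2 s sampling and 20-point blocks the quotient spans 4 s,
  and on the methylation branch that bias is of order 10%, an artifact
  large enough to mask real model differences. Midpoint pairing is O(Δt²),
  about half a percent under the same conditions.
* **Fixed-point neighbourhood.** `g(a) = 0`, so *relative* deviations from
  the curve are degenerate near `A = a`; collapse-accuracy checks exclude
  points with `|A - a| < 0.01`.
* **Demethylation branch and sampling.** After a removal the activity
  relaxes on a ~10 s timescale, so a 4 s quotient is biased by a few
  percent there no matter how the pairing is chosen; the package's
  invariance checks hold the methylation branch to 2% and the
  demethylation branch to an explicit O(Δt) ceiling of 6%. This is a
  property of the difference quotient, not of the model.

`fit_gR()` exploits the steady-state tie: with `g_B = solve_gB(g_R, a)` the
model curve is exactly proportional to `g_R`, so the one-parameter least
squares has the closed form `ĝ_R = Σ b y / Σ b²` (`b` the unit-rate curve).

### Permutation significance test

To ask whether two collapse sets (say, two strains with different adapted
activities) genuinely follow their own model curves,
`permutation_test()` bins the shared activity range (default: four
equal-width bins, one swap pair per bin), swaps one randomly chosen point
per chosen bin between the sets, and recomputes the summed squared error of
each set against its own model, swapped points scored against the other
set's model. If the sets match their models, every swap can only hurt: the
unpermuted error sits below the permuted distribution. Swapping between
identical sets under identical models leaves the error exactly unchanged,
which pins the implementation down. The swap RNG takes a single integer
seed; permuted errors are computed exactly, by adding each swap's
own-vs-cross cost difference to the unpermuted error.

## Synthetic experiments

`generate_fret_experiment()` emulates a FRET recording: simulate the
configured model under a protocol, sample at the strain's resolution
(0.2 s for WT1-like, 1 s for WT2/CheB-mutant-like), add i.i.d. Gaussian
noise to the normalized activity (default sd 0.05, matching the visually
uniform trace noise of such recordings), clamp at zero (a photon-count
readout cannot cross its saturation floor), and emit an intensity-ratio
series through the inverse of the configured ratio transform. The ground
truth is always returned alongside, because parameter recovery is the
acceptance surface of the whole pipeline.

The ratio transform itself ships in two variants behind a switch
(`method = "linear"` is the default; `"ratiometric"` weights by the
fluorescence efficiency ratio `alpha`). Both map the pre-stimulus ratio to
1 and the saturating-attractant ratio to 0 and are strictly monotone
between; analyses that depend on the exact algebra use the generator's own
inverse, so every result in the package is transform-consistent. Only the
saturating end is clamped on reading: ratios beyond the pre-stimulus value
are legitimate (normalized activity exceeds 1 after removal) and pass
through.

What the generator does **not** emulate: photon shot noise and
photobleaching, cell-to-cell variability within the 300–500-cell population
average, baseline drift, and receptor-population heterogeneity in `m`
(only the complex-average level is modelled). Passing recovery tests on
synthetic data therefore establishes that the pipeline is consistent and
well-conditioned at realistic noise levels — not that real recordings meet
the generator's assumptions.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable, adaptive) with
  `rtol = 1e-8`, `atol = 1e-10`, restarted at protocol events; halving the
  tolerances moves reported amplitudes by less than 1e-6. Demethylation at
  high activity is fast relative to methylation, hence the stiff-capable
  default.
* Activity evaluation clamps `|F| > 700` to the exact 0/1 limits; this
  cannot affect results in the physical range (|F| there is below ~50).
* `fixed_points()` scans `[0, 1]` at spacing 1e-4 and polishes sign
  changes by bisection to 1e-10, merging roots within 1e-8; the collapse
  curve is smooth and low-degree in `A`, so the scan cannot skip roots.
* The adapted methylation level inverts the free energy in closed form;
  the imprecise steady state is a bracketed 1-d root solve in `m` on
  `[0, M_max]`.
* Problem sizes used by the shipped checks: five-step perfect-step
  campaigns (0.03–2 mM at 0.1 mM ambient, 800 s, 0.2 s sampling) for
  collapse and recovery analyses; 100 noise seeds for the recovery
  distribution; 1000 seeded runs × 200 permutations for the permutation
  study. These sizes give stable medians and fractions while keeping a
  full run in minutes on one core.

## Known limitations

* Adaptation rates that best describe dose–response amplitudes are larger
  than those fitted to the collapse; the package keeps one default and
  leaves joint refitting of rates and complex size to the user.
* Only the complex-average methylation level is tracked: no per-site
  bookkeeping, no assistance-neighbourhood structure, no stochastic
  (Langevin/Gillespie) kinetics.
* Tsr minor modification sites and serine responses are out of scope; the
  ligand is MeAsp throughout.
* The linear site-saturation shape of the imprecise model is deliberately
  minimal; data showing strong variability of imprecision between
  experiments would motivate a richer form.
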