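---
title: "Modelling pyrite burial and its sulfur-isotope signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pyrite burial and its sulfur-isotope signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(sedpyrite)
library(dplyr)
```

## The model

`sedpyrite` models the coupled fate of organic carbon (OC), porewater
sulfate and sulfide, reactive iron (Fe~HR~) and pyrite in the sulfidic
anoxic zone of marine sediments, at steady state, in one dimension.
Microbial sulfate reduction (MSR) consumes 1 mol sulfate per 1.7 mol OC
respired; the sulfide produced either reacts with descending reactive-iron
minerals to form pyrite, diffuses back to the water column, or is buried
in porewater. MSR discriminates between the ³²S and ³⁴S isotopologues with
a temperature-dependent *equilibrium* fractionation factor — sediments
host slow, energy-limited populations operating near the thermodynamic
limit — so buried pyrite is isotopically light relative to seawater
sulfate by up to the full equilibrium effect (about 65–70‰ at seafloor
temperatures).

The model's assumptions, in brief: one-dimensional transport; compaction
neglected (porosity constant over the thin formation zone); steady state;
no bioturbation mixing below the onset depth of the sulfidic zone; no
methane-fuelled sulfate reduction at depth; Monod kinetics for both MSR
and pyritization; no intermediate sulfur pools (all sulfidized iron
becomes pyrite); MSR is the only isotope-fractionating step.

Solids follow reactive-continuum decay: the bulk rate coefficient of a
mixture of components declines as the labile ones are consumed, giving

$$\Gamma(\zeta) = \Gamma_0\left(\frac{a}{a + \mathrm{Da}^*\zeta}\right)^a,
\qquad
\Psi(\zeta) = \Psi_0\left(\frac{b}{b + \chi\,\mathrm{Da}^*\zeta}\right)^b,$$

where $\zeta = z\sqrt{k_{G0}/D_S}$ is depth non-dimensionalized by the
reaction–diffusion length scale, and the three governing variables are
the OC-to-sulfate ratio $\Gamma_0$, the modified Damköhler number
$\mathrm{Da}^* = \sqrt{D_S k_{G0}}/w$, and the iron delivery $\Psi_0$
(both solid contents expressed in units of the sulfate/sulfide they can
consume, via the conversion factors `oc_conversion_factor()` and
`fe_conversion_factor()`). Sulfate $\Sigma$ and sulfide $\eta$ (scaled by
seawater sulfate $S_0$) satisfy

$$\mathrm{Da}^*\,\Sigma'' - \Sigma' + \Gamma'\,\frac{\Sigma}{\kappa_\Sigma+\Sigma} = 0,
\qquad
\Delta\,\mathrm{Da}^*\,\eta'' - \eta' - \Gamma'\,\frac{\Sigma}{\kappa_\Sigma+\Sigma}
+ \Psi'\,\frac{\eta}{\kappa_\eta+\eta} = 0,$$

with $\Sigma(0)=1$, $\eta(0)=\eta_0$ and zero gradient at the deep
boundary, $\Delta = D_H/D_S$, and scaled Monod constants
$\kappa = K/S_0$. Each isotopologue gets its own copy of these equations;
the MSR rate is partitioned by
$^{32}\Sigma/(\alpha^{34}\,^{34}\Sigma + {}^{32}\Sigma)$ and its ³⁴S
complement, and the pyritization sink by the instantaneous sulfide
isotope fraction (pyritization itself does not fractionate). Pyrite
isotopologues are quadratures of the iron-sulfidation rate, and delta
values follow from the isotopologue ratios against the VCDT standard.

## Parameters, defaults, and where they come from

All constants live in `sed_config()`; nothing is hard-coded.

| parameter | default | meaning, rationale |
|---|---|---|
| `a` | 0.125 | OC reactive-continuum exponent; classic value for marine OC decay spanning many reactivity decades |
| `b`, `chi` | 0.25, 25 | Fe~HR~ continuum exponent and iron:OC initial-reactivity ratio; iron oxides sulfidize faster than bulk OC respires, over a similar depth span |
| `K_S`, `K_H` | 1 mM each | Monod half-velocities for MSR and pyritization; mid-range of experimental values, small against 28 mM seawater sulfate |
| `stoich_oc_per_sulfate` | 1.7 | mol OC per mol sulfate, empirical MSR stoichiometry |
| `k_gsw_c`, `k_gsw_d` | 0.057, 1.94 | OC reactivity at the interface as a power law of sedimentation rate, `k = c w^d`; reproduces abyssal reactivities of order 10⁻⁶–10⁻⁷ yr⁻¹ at w ≈ 0.003 cm yr⁻¹ |
| `alpha` (ε₀, slope) | 67.0, 0.15 | equilibrium fractionation `ε(T) = −(67 − 0.15 T)` ‰; linearization of published equilibrium curves over 0–40 °C (−66.4‰ at 4 °C) |
| `diffusivity` | (4.88, 0.232), (10.4, 0.273) | free-solution diffusivities `(m0 + m1 T)·10⁻⁶` cm² s⁻¹ for sulfate and sulfide, tortuosity-corrected by `1 − 2 ln φ`; gives D_S ≈ 10² cm² yr⁻¹ at median conditions |
| `R_VCDT` | 0.0441626 | ³⁴S/³²S of the VCDT standard |
| `beta` | 5×10⁻⁴ | formation-zone threshold on ∂Π/∂ζ (see below) |
| boundary | 28 mM, 0 mM, +28‰, 4 °C | modern seawater sulfate, oxic bottom water, its δ³⁴S, and a representative seafloor temperature |

The Monod constants, continuum exponents and reactivity law are the
parameters least constrained by public data; they are deliberately
exposed as configuration so that users with site-specific calibrations
can pin them. The package defaults were chosen once from the
literature-plausible ranges above and are not tuned to any single site.

## Numerics

The four isotopologue equations are solved staged: the two-field bulk
system first (its solution seeds the four-field Newton iterate through a
Rayleigh-style estimate of the local isotope ratio), then the four-field
system. Because the isotopologue equations sum *algebraically* to the
bulk equations, the identity
$^{32}X + {}^{34}X = X_\mathrm{bulk}$ on the converged solution is an
emergent check of both solves; it is reported in the diagnostics and
asserted below 10⁻⁶ (on the non-dimensional concentration scale) in the
tests.

Discretization is second-order central finite differences on a graded
mesh (401 nodes on ζ ∈ [0, 5], spacing `∝ u^1.6` refined toward the
interface where gradients are steepest; 201 nodes in the routine test
suite). The deep boundary is a second-order one-sided zero-gradient row.
Newton iteration uses an analytic block-sparse Jacobian, step-halving
line search, and seeded random restarts of the initial iterate on
non-convergence (at most 5). Two details matter for accuracy:

* the convergence test is on a row-scaled residual, and after first
  passing tolerance the iteration takes a few undamped "polishing" steps
  to drive the residual to its floor — low-frequency error modes are
  amplified by the inverse transport operator, so the stopping residual
  must sit far below the target solution error;
* concentrations that undershoot zero by less than 10⁻¹⁰ are treated as
  zero inside Monod terms (with zero slope); larger undershoots are solver
  failures, never silently clipped. The sulfide-fraction terms are
  algebraically rewritten as `h/(κ_η + η)`, which is smooth through
  η = 0, so the euxinic and oxic boundary cases need no special-casing.

The solver is verified by the method of manufactured solutions
(`verify_mms()`): a smooth sulfate–sulfide pair satisfying the boundary
conditions exactly is substituted into the operators, the analytic
residual becomes a forcing term, and the recovered error is tracked under
mesh refinement. Observed convergence is cleanly second order, with max
errors of order 10⁻⁷ on the finest meshes exercised.

Pyrite derivatives are always evaluated from the analytic right-hand side
(the iron-profile derivative times the Monod factor), never by
differencing the pyrite profile. The formation-zone base ζ~max~ is the
first depth *at or below the peak formation rate* where the rate drops to
the threshold β; the qualifier matters because the rate is identically
zero at the interface when bottom waters are oxic (η(0) = 0), so a
literal "first depth with rate ≤ β" would degenerate to ζ~max~ = 0
everywhere. If the rate never falls below β the domain cap is used; if no
pyrite forms at all, ζ~max~ = 0 and burial outputs vanish. Burial
results are insensitive to halving β below 5×10⁻⁴ (asserted across six
representative shelf/slope/abyss scenarios).

The domain cap ζ = 5 is part of the model definition. For thin-tailed
continua (large `a`) virtually all respiration completes in-domain and
extending the domain changes nothing; for the fat-tailed default
(a = 0.125) a substantial fraction of the OC load respires below the cap,
so the cap itself — justified by finite real sediment thickness —
regularizes the solution, and results quoted here are always "within the
ζ ≤ 5 column".

## A note on the shelf worked example

The acceptance suite asserts published Δ~pyrite~ estimates of about 21
and 66‰ for the shelf endmember coordinates (Γ₀ = 3.9, Da\* = 3.7) and
(Γ₀ = 25.2, Da\* = 11.4) at Ψ₀ = 10. This package's solver yields ≈ 58
and ≈ 48‰ there, and we have left the assertion failing rather than
adjust parameters toward it, for a documented reason: the values are not
reachable under the governing equations as implemented. Two fully
independent solvers (the package's finite-difference Newton scheme and an
external collocation boundary-value solver) agree at these coordinates to
three significant figures, and randomized searches over generous ranges
of every unconstrained parameter (a, b, χ, K_S, K_H, diffusivity ratio)
confine the reachable pair to roughly 41–62‰ with the first coordinate
always at least as fractionated as the second. The physical reason is
that with a fixed-concentration seawater boundary, diffusion through a
thin surface layer buffers both the sulfate concentration *and its
isotope ratio* whenever Da\* ≳ 3, capping the expressible closed-system
enrichment; an offset as small as 21‰ at Da\* = 3.7 would require
near-Rayleigh distillation that this boundary condition cannot sustain.
The model *does* span the full 21→66‰ range — at Da\* ≈ 1 and ≳ 50 for
these Γ₀ values — so the discrepancy affects the coordinate mapping of
the published endmembers, not the physics of the sweep. All other
quantitative anchors (limit behaviours, conversion-factor ranges, flux
arithmetic, threshold stability) verify.

## What the synthetic grid does and does not emulate

`synthesize_grid()` generates boundary conditions with realistic
*distributions*: bathymetric regimes in realistic area shares (≈ 85 %
abyssal), lognormal sedimentation rates declining from shelf
(≈ 0.05 cm yr⁻¹) to abyss (≈ 0.003 cm yr⁻¹), OC of ~0.2–1.4 wt%, Fe~HR~
of ~0.3–3 wt%, porosity 0.6–0.9, an exponential temperature–depth law,
an oxygen-penetration-depth law inverse in sedimentation rate, and an
oxic-to-basement mask for the deepest, slowest-accumulating cells. It
does **not** carry real spatial structure: no coastlines, no coherent
margins, no covariance between neighbouring cells, no real climatology.
Global totals computed on it are therefore order-of-magnitude and
*distributional* checks — shelf-plus-slope dominance of burial despite
minority area, flux being more iron-sensitive than δ³⁴S — not
reproductions of observed global fluxes, which require the real gridded
boundary-condition maps as input (`read_grid_csv()` accepts them in long
CSV form).

## The geologic-record pipeline

`loess_smooth()` is classic LOESS — tricube-weighted local quadratic
regression over a stated fraction of the data — with spans 0.2 (sulfate)
and 0.5 (pyrite offsets) as pipeline defaults; degree and span are
arguments because the literature rarely pins them. The smoothed sulfate
curve is linearly interpolated to pyrite measurement ages to form
Δ~pyrite~ (ages outside the sulfate record are excluded and counted), and
`bootstrap_band()` repeats resample-with-replacement → smooth →
interpolate → offset over `n_boot` iterations (1000 for production
figures; tests use 40–60) for pointwise 5th–95th percentiles. Individual
measurements are the resampling unit; block bootstraps are out of scope.
Ages are stored ascending in Ma and plotted reversed. On synthetic
records with known signal and compilation-like scatter (`synth_isotope_record()`),
the central estimate falls inside the band at ≥ 90 % of ages; coverage of
the *true* curve is slightly lower at signal extremes because LOESS
flattens peaks — a known bias of the method, inherited by anything built
on it. `invert_permissible_region()` then maps an observed Δ~pyrite~
interval onto the permissible (Γ₀, Da\*) region of a heat map, reporting
the integrated pyrite content of that region as a minimum estimate
(past iron delivery was likely higher than the assumed Ψ₀).

## Problem sizes

Production solves use 401 mesh nodes (a solve takes well under a second);
the test suite runs 201-node meshes for routine checks, the 401-node mesh
for the acceptance properties (100 random parameter draws), heat maps of
8×8 nodes, synthetic grids of 120–10 000 cells, and bootstrap bands of
40–60 iterations — sizes chosen so the whole suite completes in about a
minute while still exercising every code path at production accuracy
where it matters.

## Known limitations

No methane: sulfate–methane transition dynamics, which control deep
sulfate drawdown at many real sites, are absent by assumption, so modelled
sulfate profiles stay high where measured ones crash at the SMT. No
bioturbation mixing or compaction. Steady state only. Pyrite formation is
insensitive to pathway (H₂S vs polysulfide) and intermediate iron-sulfide
pools are not tracked. The equilibrium-fractionation assumption breaks
down below a few mM sulfate, so applications to very low-sulfate
(Precambrian-like) oceans should treat the η₀ and S₀ inputs as outside
the validated envelope.
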