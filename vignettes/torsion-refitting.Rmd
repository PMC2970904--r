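---
title: "Refitting side-chain torsion potentials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refitting side-chain torsion potentials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsionfit)
```

## The model

A force-field torsion term is a truncated cosine series in the Amber
convention,

$$V(\theta) = \sum_{m=1}^{M} k_m\,[1 + \cos(m\theta - \theta_0)],$$

with multiplicities $m$, force constants $k_m$ in kcal mol⁻¹ and the
phase $\theta_0$ fixed at 0°.  The "+1" offsets shift only the zero of
energy (they are absorbed into the fitted constant $k_0$) but are kept
for Amber compatibility.  Negative force constants are legal and occur in
the packaged parameter set; on export to `frcmod` they become a positive
barrier with phase 180°, which changes the potential by another additive
constant and leaves forces untouched.

Fixing $\theta_0 = 0$ has one important consequence: the three (or more)
atom quadruples that define χ1 and would be equivalent under ideal
rotational symmetry become inequivalent.  The chosen quadruple is
therefore part of the parameter set, and `select_dihedral_definition()`
implements the selection rule: fit every candidate under the same
specification and keep the one with the smallest weighted residual, ties
going to the first-listed candidate (fit quality is the only criterion we
apply; nothing else distinguishes the candidates).

## The objective and its weighting

Given scan conformations with a QM reference energy $E^{QM}_i$ and a base
MM energy $E^{MM,base}_i$ (the full MM energy *minus* the torsion term
being replaced — `subtract_torsion()` converts full energies), the fit
minimizes

$$J = \sum_i w_i \bigl(E^{MM,base}_i + \textstyle\sum_{\rm angles}
V(\theta_i) + k_0 - E^{QM}_i\bigr)^2,
\qquad w_i = \frac{e^{-\beta (E^{QM}_i - \min E^{QM})}}
{\sum_j e^{-\beta (E^{QM}_j - \min E^{QM})}}.$$

* **β (mol kcal⁻¹), default 1.0.**  β = 0 weights all conformations
  equally and fits the whole energy profile, at the cost of errors in the
  low-energy wells that control rotamer populations; β ≈ 1.7 (room
  temperature, 298 K) all but ignores the barriers.  The default β = 1.0
  corresponds to roughly 500 K and is the compromise that keeps both the
  wells and the barriers in play.  `beta_to_temperature()` makes the
  units explicit.
* **Weight normalization.**  Normalizing the weights (and shifting
  energies to min 0 before exponentiation) changes neither the argmin nor
  the relative weighting — only conditioning and overflow behaviour.  We
  normalize; the reported `weighted_residual` is on this normalized
  scale.
* **k₀, fitted by default.**  The offset between the QM and MM energy
  zeros is arbitrary, so $k_0$ is a free parameter unless
  `fit_spec(fit_offset = FALSE)` pins it at 0 for callers who have
  already aligned the scales.

The model is linear in every parameter, so the solution is closed-form:
a weighted least-squares solve via QR with column pivoting.  No iterative
optimizer, no starting values, no convergence criteria.  Rank deficiency
is detected from the QR rank and reported with the names of the
degenerate design columns rather than silently regularized.

## Scan grids

`make_chi1_grid()` and `make_chi1_chi2_grid()` build the two standard
protocols:

* 1D: χ1 over the full circle (15° steps by default) crossed with a few
  fixed χ2 values ({−60°, 60°, 180°} by default), backbone held at the
  extended conformation φ = −135°, ψ = 135° — 24 × 3 = 72 points;
* 2D: χ1 × χ2 at 30° steps — 144 points — with optional two-fold χ2
  symmetry folding for carboxylate-like side chains, which halves the
  grid to 72.

"From −180° to 180°" is read as a full circle of *unique* angles: −180°
and +180° are the same conformation and are counted once (the only
reading consistent with the 72/144 point counts).  All angles are wrapped
to (−180°, 180°].  The symmetric fold maps χ2 into [0°, 180°) — an
arbitrary but fixed, invertible convention; every folded value has
exactly the pre-image pair {χ2, χ2 ± 180°} in the full grid.

**Degeneracy on folded grids.**  On a folded grid the χ2 values take only
$n/2$ distinct values, and the odd-multiplicity basis functions
$\cos(m\chi_2)$ together with the intercept exceed the dimension of the
function space on those points: fitting all six χ2 multiplicities plus
$k_0$ is singular.  This is physics, not an artifact — odd χ2 terms are
forbidden by the two-fold symmetry — so the recipe fits only even χ2
multiplicities on folded grids and reports the odd ones as the zeros they
must be.  On a *full* grid the same symmetry manifests differently: data
generated with a symmetric χ2 potential return odd fitted constants of
zero (to numerical precision), which the test suite asserts.

## Rotamer statistics

χ1 values are classified into the three canonical wells: plus
(p, centred +60°), minus (m, −60°) and trans (t, 180°), with 120°-wide
half-open bins — p = (0°, 120°], m = (−120°, 0°], t otherwise.  The cited
naming conventions do not fix behaviour exactly *at* the edges, so the
half-open choice is ours, made for determinism; a frame at exactly 0°
counts as m, at exactly 120° as p, at exactly −120° as t.  Distributions
are compared by the three-state RMSD
$\sqrt{\tfrac13\sum_s (a_s-b_s)^2}$.

Reference (e.g. helix survey) distributions are a user-supplied table;
the packaged `helix_rotamer_reference_synthetic.csv` is a synthetic
stand-in with realistic m-dominant helix populations, present so the
workflow is runnable and testable — it is not survey data.

Dihedrals from coordinates follow the IUPAC sign convention (cis = 0°,
checked against an independent geometric construction and against
`bio3d::torsion.xyz`).  PDB input uses the first model and prefers
altloc "A".  The helical-peptide backbone restraint is the single-minimum
form $k_\theta[1+\cos(\theta-\theta_{\rm ref})]$ with
$\theta_{\rm ref}$ = 122°/133° and $k_\theta$ = 1 kcal mol⁻¹: the minima
sit at $\theta_{\rm ref}-180°$ = −58°/−47°, i.e. in the α-helical region,
which is the unique single-term cosine form consistent with reference
values outside the helical region keeping the peptide helical.  The form
is exposed as a plain function and is trivially replaceable if a
different convention is needed.

## NMR back-calculation

³J couplings use the Karplus relation
$J(\theta) = A\cos^2(\theta+\delta) + B\cos(\theta+\delta) + C$.
Coefficients are *not* hard-wired science: they live in a registry
(`default_karplus_registry()`, `read_karplus_registry()`) of named
presets with a `source` tag that is carried into every report.  The
built-in defaults are representative literature-style values meant to be
replaced by the coefficient set appropriate to the user's experiments.
The δ offset handles couplings whose defining dihedral is the χ1 heavy
atom dihedral ±120° (e.g. proton positions when explicit hydrogens are
absent from the input series).

RDCs use the molecular alignment (Saupe) tensor: symmetric, traceless,
five independent components, fitted linearly from ≥5 measured couplings
($D_i = D_{max,i}\sum_{kl} S_{kl}u_{ik}u_{il}$) by QR, with rank checking
for degenerate bond geometries.  $D_{max}$ depends on gyromagnetic ratios
and bond length and is supplied per bond type; predictions are linear in
it.  Side-chain amide experiments often resolve only the *sum* of the two
N–H couplings, so `sum_amide_rdcs()` predicts the same sum.

Averaging order matters and is fixed throughout: observables are
evaluated per frame and then averaged (ensemble averages of J and of
$u^TSu$), never computed from an average angle.

## The synthetic generator

`synth_scan()` emulates a QM scan as *background + generating torsion +
noise*, with the background exposed to the fit only through
`E_mm_base`.  The background is deliberately a structured low-order
cosine surface with an optional $\cos(\chi_1-\chi_2)$ coupling ridge — a
constant background would make the separation of signal from background
trivially easy and leave that code path untested.  The noise is Gaussian
with σ defaulting to 0.2 kcal mol⁻¹, the scale of the sub-kcal mol⁻¹
residuals one expects between a QM profile and the best attainable
single-torsion fit.

`sample_dihedral_trajectory()` draws from a three-component von Mises
mixture at the canonical well centres (a hand-implemented Best–Fisher
rejection sampler; concentration κ = 20 by default, ≈13° circular spread,
comfortably inside the 120° bins).  `synth_rdc_dataset()` draws isotropic
bond vectors and computes couplings from a known tensor.

What the generator does **not** emulate: real QM scans have anharmonic
couplings between the scanned dihedral and relaxing internal coordinates,
correlated (not i.i.d. Gaussian) errors, and backbone-dependent
variation; real trajectories have autocorrelation, transition kinetics
and non-von-Mises well shapes; real RDC data have structural noise in the
bond vectors, not just additive coupling noise.  Passing recovery tests
therefore demonstrates correctness of the estimators and plumbing — that
the fit recovers what generated the data — not that the physical
approximations hold for real proteins.

All generators take an explicit seed, restore the caller's RNG state, and
are bit-reproducible; file outputs record the seed in their headers.

## Numerical choices

* Angles are degrees in every interface and are wrapped internally to
  (−180°, 180°]; the wrap guards against floating-point landing exactly
  on −180.
* Scan tables serialize angles at 4 decimals and energies at 6 —
  lossless at the precision any of the downstream numerics use.
* `torsion_amplitude()` uses a 0.1° grid; for a single term the result is
  exact ($2|k_m|$), and the test suite cross-checks packaged series
  against a finer grid.
* Degenerate dihedral geometry (coincident or collinear points) is an
  error, not an NaN.
* frcmod emission is fixed-width and canonical: re-emitting a parsed
  file is byte-identical, and parse(to_frcmod(s)) defines the same
  energy as s up to an additive constant (≤ 1e−9 over a dense grid).

## Problem sizes

The packaged workflows run at the scan sizes of the original protocol
(72/144-point grids), trajectories of a few hundred to 10⁵ frames, and
RDC sets of tens of bonds; the full test suite and the end-to-end recipe
complete in seconds on a single CPU.  These sizes are the package's
choice for its own fixtures: estimator correctness is scale-free here,
and anything that would genuinely need microsecond MD or real QM scans
(absolute NMR RMSD improvements of a specific force field on specific
proteins) is by construction outside what synthetic fixtures can show.

## Limitations

* Torsion refitting cannot compensate errors in nonbonded parameters;
  residual rotamer-population errors for carboxylate/amide side chains
  may persist no matter how good the fit.
* The toolkit consumes precomputed QM and base-MM energies; it neither
  runs QM nor evaluates a full force field.
* Stereospecific assignment ambiguities (e.g. Hβ1/Hβ2) must be resolved
  upstream; the observable tables simply carry whichever assignment the
  user provides.
* The packaged reference rotamer table is synthetic; quantitative
  comparisons against structural-survey statistics require the user's
  own reference table.
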