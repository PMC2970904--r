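# torsionfit

Side-chain torsion potential refitting and NMR validation for
Amber-convention force fields.

## The problem

Long molecular-dynamics simulations expose systematic errors in the
side-chain dihedral (χ1/χ2) potentials of protein force fields: some
residue types populate the wrong rotamer wells, which shows up directly in
NMR observables (³J scalar couplings, residual dipolar couplings) and in
comparisons against rotamer statistics from experimental structures.  The
established remedy is to refit the offending cosine-series torsion terms
against quantum-mechanical (QM) dihedral scans — the approach behind the
ff99SB-ILDN corrections for Ile, Leu, Asp and Asn, which this package
ships as a ready-made parameter set.

`torsionfit` is for force-field developers and simulators who want to

* build the standard χ1 and χ1/χ2 conformational scan grids (including
  two-fold χ2 symmetry halving for carboxylates),
* fit replacement torsion potentials to QM − MM energy gaps by
  Boltzmann-weighted linear least squares,
* export the result as Amber `frcmod` DIHE records,
* and validate conformational ensembles through three-state rotamer
  statistics, Karplus ³J couplings and alignment-tensor-based RDCs.

A synthetic-data module generates scans, rotamer trajectories and RDC
datasets with known ground truth, so the whole workflow is testable
without QM or MD software.

## The model

A torsion potential is a cosine series in the Amber convention

$$V(\theta) = \sum_{m=1}^{M} k_m\,[1 + \cos(m\theta - \theta_0)],
\qquad \theta_0 = 0,$$

and the force constants $k_m$ (plus an offset $k_0$ absorbing the
arbitrary QM/MM energy-scale difference) minimize the Boltzmann-weighted
residual over the scan conformations $i$:

$$J = \sum_i w_i\,\bigl(E^{\rm MM,base}_i + V(\theta_i) + k_0 -
E^{\rm QM}_i\bigr)^2,\qquad
w_i \propto e^{-\beta E^{\rm QM}_i},$$

with $\beta = 1.0$ mol kcal⁻¹ by default (≈500 K), intermediate between an
unweighted fit to the energy profile ($\beta=0$) and a fit to
room-temperature populations ($\beta\approx1.7$).  The model is linear in
all parameters, so the solution is closed-form (rank-revealing weighted
QR).  Because the phase is fixed at 0, the candidate atom quadruples
defining χ1 are inequivalent; `select_dihedral_definition()` fits each and
keeps the best.

## Worked example

Recover the packaged Ile χ1 correction from a synthetic noisy scan:

```r
library(torsionfit)

ile  <- ildn_parameters("ILE", "chi1")   # published parameters + quadruple
grid <- make_chi1_grid(15, c(-60, 60, 180), residue = "ILE")  # 72 points
scan <- synth_scan(grid, generators = list(chi1 = ile$series),
                   background = list(chi1 = cosine_series(1:2, c(0.8, -0.5))),
                   sigma = 0.2, seed = 7)
fit  <- fit_torsion(scan, fit_spec(m_chi1 = 1:2, beta = 1.0))
fit
#> Torsion fit (Boltzmann-weighted least squares)
#>   k0 = 0.021986 kcal/mol; weighted residual = 0.0413598
#>   chi1 force constants: k1=0.1980, k2=-0.8411
```

With 0.2 kcal/mol of synthetic noise on a 72-point scan, the fit returns
k₁ = 0.198 and k₂ = −0.841 kcal/mol against the generating values 0.195
and −0.846 — parameter errors far below the noise floor — and a k₀ near
zero, as the background was already in the base MM energy.  The
peak-to-peak amplitude of the fitted potential is 1.89 kcal/mol
(`torsion_amplitude(fit$chi1)`).  `to_frcmod()` + `write_frcmod()` turn
`fit$chi1` into Amber DIHE records.

The command-line wrapper `exec/torsiontool` exposes the same steps as
subcommands (`grid`, `fit`, `eval-torsion`, `frcmod`, `rotamers`,
`jcoupling`, `rdc`, `simulate`, `recipe`); `run_ildn_recipe()` chains the
full screen → refit → validate workflow on synthetic fixtures and writes a
machine-readable summary.

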