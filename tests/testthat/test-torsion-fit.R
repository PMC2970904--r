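test_that("Boltzmann weights match hand-evaluated cases", {
  expect_equal(boltzmann_weights(c(5, 2, 9), beta = 0), rep(1 / 3, 3))
  expect_equal(boltzmann_weights(c(0, log(2)), beta = 1), c(2 / 3, 1 / 3))
  expect_equal(boltzmann_weights(rep(7.3, 5), beta = 1.0), rep(0.2, 5))
  # shift invariance
  e <- c(0.3, 1.2, 4.5)
  expect_equal(boltzmann_weights(e + 100, 1.3), boltzmann_weights(e, 1.3))
  expect_error(boltzmann_weights(numeric(0)), "non-empty")
})

test_that("zero-noise fits recover the generating parameters exactly", {
  bg <- list(chi1 = cosine_series(1:3, c(0.9, -0.4, 0.25)))
  for (res in c("ILE", "LEU")) {
    gen <- ildn_parameters(res, "chi1")$series
    sc <- synth_scan(make_chi1_grid(15, c(-60, 60, 180), residue = res),
                     list(chi1 = gen), background = bg, sigma = 0, seed = 1)
    fit <- fit_torsion(sc, fit_spec(gen$m))
    expect_lt(max(abs(fit$chi1$k - gen$k)), 1e-10)
    expect_lt(abs(fit$k0), 1e-10)
    expect_lt(fit$weighted_residual, 1e-20)
  }
})

test_that("a null signal fits to all-zero parameters", {
  g <- make_chi1_grid(30, c(-60, 60, 180))
  g$E_mm_base <- 0
  g$E_qm <- 0
  sc <- scan_table(as.data.frame(g))
  fit <- fit_torsion(sc, fit_spec(1:3))
  expect_equal(unname(fit$chi1$k), rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$k0, 0, tolerance = 1e-12)
  expect_equal(fit$weighted_residual, 0, tolerance = 1e-20)
})

test_that("a uniform shift of E_qm is absorbed entirely by k0", {
  gen <- ildn_parameters("LEU", "chi1")$series
  sc <- synth_scan(make_chi1_grid(15, c(-60, 60, 180)),
                   list(chi1 = gen), sigma = 0, seed = 2)
  f1 <- fit_torsion(sc, fit_spec(1:3))
  sc2 <- sc
  sc2$E_qm <- sc2$E_qm + 10
  # Boltzmann weights are shift invariant, so only k0 can move
  f2 <- fit_torsion(scan_table(as.data.frame(sc2)), fit_spec(1:3))
  expect_equal(f2$chi1$k, f1$chi1$k, tolerance = 1e-10)
  expect_equal(f2$k0, f1$k0 + 10, tolerance = 1e-10)
})

test_that("beta = 0 fit agrees with an independent normal-equations oracle", {
  set.seed(7)
  for (rep in 1:5) {
    chi1 <- wrap_angle(runif(10, -180, 180))
    y <- rnorm(10, sd = 2)
    sc <- scan_table(data.frame(chi1 = chi1, chi2 = NA, phi = -135,
                                psi = 135, E_qm = y, E_mm_base = 0))
    fit <- fit_torsion(sc, fit_spec(1:2, beta = 0))
    # oracle: ordinary least squares on [1, cos(th), cos(2th)] by
    # explicit normal equations; k_m = b_m, k0 = b0 - sum(b_m)
    A <- cbind(1, cos(chi1 * pi / 180), cos(2 * chi1 * pi / 180))
    b <- solve(crossprod(A), crossprod(A, y))
    expect_equal(fit$chi1$k, as.numeric(b[2:3]), tolerance = 1e-8)
    expect_equal(fit$k0, b[1] - sum(b[2:3]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("the closed-form solution is locally optimal", {
  gen <- ildn_parameters("ILE", "chi1")$series
  sc <- synth_scan(make_chi1_grid(15, c(-60, 60, 180)), list(chi1 = gen),
                   sigma = 0.3, seed = 3)
  fit <- fit_torsion(sc, fit_spec(1:2))
  w <- fit$weights
  obj <- function(k, k0) {
    v <- evaluate_torsion(cosine_series(1:2, k), sc$chi1)
    sum(w * (sc$E_mm_base + v + k0 - sc$E_qm)^2)
  }
  expect_equal(obj(fit$chi1$k, fit$k0), fit$weighted_residual,
               tolerance = 1e-10)
  set.seed(4)
  for (i in 1:25) {
    dk <- rnorm(2, sd = 0.01)
    d0 <- rnorm(1, sd = 0.01)
    expect_gte(obj(fit$chi1$k + dk, fit$k0 + d0), fit$weighted_residual)
  }
})

test_that("two-fold symmetric chi2 data forces odd chi2 constants to zero", {
  gen1 <- ildn_parameters("ASP", "chi1")$series
  gen2 <- ildn_parameters("ASP", "chi2")$series  # odd terms are zero
  sc <- synth_scan(make_chi1_chi2_grid(30, chi2_symmetric = FALSE,
                                       residue = "ASP"),
                   list(chi1 = gen1, chi2 = gen2), sigma = 0, seed = 5)
  fit <- fit_torsion(sc, fit_spec(1:6, 1:6))
  odd <- fit$chi2$k[c(1, 3, 5)]
  expect_lt(max(abs(odd)), 1e-8)
  expect_lt(max(abs(fit$chi2$k - gen2$k)), 1e-8)
  expect_lt(max(abs(fit$chi1$k - gen1$k)), 1e-8)
})

test_that("recovered parameters converge to the generators as noise shrinks", {
  gen <- ildn_parameters("ASN", "chi1")$series
  grid <- make_chi1_grid(15, c(-60, 60, 180))
  err <- vapply(c(0.5, 0.05, 0.005), function(sig) {
    sc <- synth_scan(grid, list(chi1 = gen), sigma = sig, seed = 11)
    max(abs(fit_torsion(sc, fit_spec(1:6))$chi1$k - gen$k))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("fits are invariant to scan-table row order", {
  gen <- ildn_parameters("LEU", "chi1")$series
  sc <- synth_scan(make_chi1_grid(15, c(-60, 60, 180)), list(chi1 = gen),
                   sigma = 0.2, seed = 6)
  f1 <- fit_torsion(sc, fit_spec(1:3))
  set.seed(8)
  perm <- sample(nrow(sc))
  sc2 <- scan_table(as.data.frame(sc)[perm, ])
  f2 <- fit_torsion(sc2, fit_spec(1:3))
  expect_equal(f2$chi1$k, f1$chi1$k, tolerance = 1e-10)
  expect_equal(f2$weighted_residual, f1$weighted_residual,
               tolerance = 1e-10)
})

test_that("rank deficiency is reported with the degenerate columns named", {
  # folded Asp-like grid: odd chi2 multiplicities + offset are degenerate
  g <- make_chi1_chi2_grid(30, chi2_symmetric = TRUE)
  g$E_qm <- cos(g$chi1 * pi / 180)
  g$E_mm_base <- 0
  sc <- scan_table(as.data.frame(g))
  expect_error(fit_torsion(sc, fit_spec(1:2, 1:6)), "rank-deficient")
  # fewer points than parameters
  small <- scan_table(data.frame(chi1 = c(0, 120), chi2 = NA, phi = -135,
                                 psi = 135, E_qm = c(1, 2), E_mm_base = 0))
  expect_error(fit_torsion(small, fit_spec(1:3)), "under-determined")
})

test_that("dihedral-definition selection picks the generating relabeling", {
  gen <- ildn_parameters("LEU", "chi1")$series
  base <- synth_scan(make_chi1_grid(15, c(-60, 60, 180), residue = "LEU"),
                     list(chi1 = gen), sigma = 0, seed = 9)
  # candidate B sees the same conformations through a quadruple offset by
  # the local geometry (-120 deg); only candidate A matches theta0 = 0
  shifted <- as.data.frame(base)
  shifted$chi1 <- wrap_angle(shifted$chi1 - 120)
  cand <- list(A = base, B = scan_table(shifted, residue = "LEU"))
  defs <- list(torsion_definition("LEU", "chi1", c("C", "CA", "CB", "CG")),
               torsion_definition("LEU", "chi1", c("N", "CA", "CB", "CG")))
  pick <- select_dihedral_definition(cand, fit_spec(1:3), defs)
  expect_identical(pick$definition$atoms, c("C", "CA", "CB", "CG"))
  expect_lt(pick$candidate_residuals[["A"]],
            pick$candidate_residuals[["B"]])
  # identical candidates tie; the first is returned
  tie <- select_dihedral_definition(list(A = base, B = base),
                                    fit_spec(1:3), defs)
  expect_identical(tie$definition$atoms, defs[[1]]$atoms)
  expect_equal(unname(diff(tie$candidate_residuals)), 0, tolerance = 1e-15)
  # single candidate returned unconditionally
  single <- select_dihedral_definition(list(base), fit_spec(1:3))
  expect_equal(single$chi1$k, gen$k, tolerance = 1e-10)
})

test_that("subtract_torsion converts full MM energies to base energies", {
  gen <- ildn_parameters("ILE", "chi1")$series
  old <- cosine_series(3, 0.4)
  g <- make_chi1_grid(30, c(-60, 60, 180))
  sc <- synth_scan(g, list(chi1 = gen), sigma = 0, seed = 10)
  full <- as.data.frame(sc)
  full$E_mm_base <- full$E_mm_base + evaluate_torsion(old, full$chi1)
  recovered <- subtract_torsion(scan_table(full), old, "chi1")
  expect_equal(recovered$E_mm_base, sc$E_mm_base, tolerance = 1e-12)
})

test_that("beta converts to temperature per 1/kT", {
  expect_equal(beta_to_temperature(1.0), 503.2, tolerance = 1e-3)
  expect_equal(temperature_to_beta(beta_to_temperature(2.2)), 2.2)
})
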