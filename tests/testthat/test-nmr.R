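test_that("Karplus evaluation matches direct substitution", {
  expect_equal(karplus_j(37, karplus_params(0, 0, 1.5)), 1.5)
  expect_equal(karplus_j(90, karplus_params(1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(karplus_j(0, karplus_params(7, -1, 1)), 7)
  # delta shifts the argument
  expect_equal(karplus_j(60, karplus_params(7, -1, 1, delta = -60)),
               karplus_j(0, karplus_params(7, -1, 1)))
})

test_that("ensemble couplings average J over frames, not the angle", {
  kp <- karplus_params(0, 1, 0)
  expect_equal(ensemble_j(dihedral_series(42), kp), karplus_j(42, kp))
  expect_equal(ensemble_j(c(0, 180), kp), 0, tolerance = 1e-12)
  # angle-averaging first would give J(90) = 0 instead of +1 here
  kp2 <- karplus_params(1, 0, 0)
  expect_equal(ensemble_j(c(0, 180), kp2), 1)
})

test_that("ensemble couplings are linear in the Karplus coefficients", {
  set.seed(12)
  th <- runif(200, -180, 180)
  j_a <- ensemble_j(th, karplus_params(1, 0, 0))
  j_b <- ensemble_j(th, karplus_params(0, 1, 0))
  j_c <- ensemble_j(th, karplus_params(0, 0, 1))
  expect_equal(ensemble_j(th, karplus_params(3.2, -1.1, 0.7)),
               3.2 * j_a - 1.1 * j_b + 0.7 * j_c, tolerance = 1e-12)
})

test_that("a high-concentration ensemble approaches the stationary coupling", {
  kp <- karplus_params(9.5, -1.6, 1.8, delta = -120)
  traj <- sample_dihedral_trajectory(c(p = 1, m = 0, t = 0), n = 3000,
                                     kappa = 1e6, seed = 21)
  expect_equal(ensemble_j(traj, kp), karplus_j(60, kp), tolerance = 1e-3)
})

test_that("a three-state delta mixture gives the population-weighted coupling", {
  kp <- karplus_params(7.2, -1.3, 1.7)
  pops <- c(p = 0.6, m = 0.3, t = 0.1)
  frames <- rep(c(60, -60, 180), times = pops * 1000)
  expect_equal(ensemble_j(frames, kp),
               sum(pops * karplus_j(c(60, -60, 180), kp)),
               tolerance = 1e-12)
})

test_that("alignment tensors are recovered from noise-free synthetic RDCs", {
  S <- alignment_tensor(c(4e-4, -1.5e-4, 2e-4, -1e-4, 3e-4))
  ds <- synth_rdc_dataset(S, n = 25, noise = 0, dmax = 21700, seed = 13)
  fit <- fit_alignment_tensor(ds$vectors, ds$rdcs, ds$dmax)
  expect_lt(max(abs(unclass(fit) - unclass(S))), 1e-10)
  # round trip: predictions on the fitting bonds reproduce the inputs
  pred <- vapply(seq_len(nrow(ds$vectors)), function(i)
    predict_rdc(fit, ds$vectors[i, ], ds$dmax), numeric(1))
  expect_equal(pred, ds$rdcs, tolerance = 1e-10)
})

test_that("tensor output is symmetric traceless even for noisy input", {
  S <- alignment_tensor(c(4e-4, -1.5e-4, 2e-4, -1e-4, 3e-4))
  ds <- synth_rdc_dataset(S, n = 40, noise = 2.0, dmax = 21700, seed = 14)
  fit <- fit_alignment_tensor(ds$vectors, ds$rdcs, ds$dmax)
  M <- unclass(fit)
  expect_lt(max(abs(M - t(M))), 1e-12)
  expect_lt(abs(sum(diag(M))), 1e-12)
})

test_that("all-zero RDCs fit to the zero tensor", {
  set.seed(15)
  v <- matrix(rnorm(30), ncol = 3)
  fit <- fit_alignment_tensor(v, rep(0, 10), 100)
  expect_equal(max(abs(unclass(fit))), 0, tolerance = 1e-15)
  expect_equal(predict_rdc(fit, c(1, 0, 0), 100), 0)
})

test_that("degenerate tensor fits are refused", {
  expect_error(fit_alignment_tensor(matrix(rnorm(9), ncol = 3),
                                    rep(1, 3), 1),
               "at least 5")
  # six copies of the same bond direction: rank 1 geometry
  v <- matrix(rep(c(1, 0, 0), 6), ncol = 3, byrow = TRUE)
  expect_error(fit_alignment_tensor(v, rep(1, 6), 1), "degenerate")
})

test_that("a bond along a principal axis predicts Dmax times the eigenvalue", {
  S <- alignment_tensor(c(4e-4, -1.5e-4, 2e-4, -1e-4, 3e-4))
  eig <- eigen(unclass(S), symmetric = TRUE)
  for (j in 1:3)
    expect_equal(predict_rdc(S, eig$vectors[, j], 21700),
                 21700 * eig$values[j], tolerance = 1e-10)
  # frame-order invariance
  set.seed(16)
  u <- matrix(rnorm(60), ncol = 3)
  expect_equal(predict_rdc(S, u, 21700),
               predict_rdc(S, u[sample(20), ], 21700))
})

test_that("amide RDC sums add the two bond predictions", {
  S <- alignment_tensor(c(4e-4, -1.5e-4, 2e-4, -1e-4, 3e-4))
  u1 <- matrix(rnorm(30), ncol = 3)
  u2 <- matrix(rnorm(30), ncol = 3)
  expect_equal(sum_amide_rdcs(S, u1, u2, 21700),
               predict_rdc(S, u1, 21700) + predict_rdc(S, u2, 21700))
  expect_equal(sum_amide_rdcs(S, u1, u1, 21700),
               2 * predict_rdc(S, u1, 21700))
  zero <- alignment_tensor(matrix(0, 3, 3))
  expect_equal(sum_amide_rdcs(zero, u1, u2, 21700), 0)
  expect_error(sum_amide_rdcs(S, u1, u2[1:5, ], 21700), "mismatch")
})

test_that("observable RMSD groups and reduces correctly", {
  obs <- data.frame(residue_type = c("ILE", "ILE", "LEU"),
                    exp = c(5, 7, 3), calc = c(6, 6, 3))
  out <- observable_rmsd(obs, "residue_type")
  expect_equal(out$rmsd[out$group == "ILE"], 1)
  expect_equal(out$rmsd[out$group == "LEU"], 0)
  # grouping by a constant equals the global RMSD
  obs$const <- "x"
  expect_equal(observable_rmsd(obs, "const")$rmsd,
               observable_rmsd(obs)$rmsd)
  expect_equal(observable_rmsd(obs)$rmsd, sqrt(mean(c(1, 1, 0))))
  expect_error(observable_rmsd(obs[0, ]), "empty")
})

test_that("the Karplus registry round-trips through a file", {
  reg <- default_karplus_registry()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,A,B,C,delta,class,source",
               paste("HA-HB", reg[["HA-HB"]]$A, reg[["HA-HB"]]$B,
                     reg[["HA-HB"]]$C, reg[["HA-HB"]]$delta,
                     "HA-HB", "file-test", sep = ",")), path)
  back <- read_karplus_registry(path)
  expect_equal(back[["HA-HB"]]$A, reg[["HA-HB"]]$A)
  expect_identical(back[["HA-HB"]]$source, "file-test")
  expect_equal(karplus_j(77, back[["HA-HB"]]),
               karplus_j(77, reg[["HA-HB"]]))
})
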