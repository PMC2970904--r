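# run code under a locally-seeded RNG without disturbing the caller's state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  force(code)
}

#' Synthetic QM/MM torsion scan with known ground truth
#'
#' Populates a scan grid with a base MM energy given by a smooth
#' background (standing in for nonbonded and residual bonded terms) and a
#' QM energy equal to background + generating torsion potential(s) +
#' Gaussian noise.  The fitting target \code{E_qm - E_mm_base} therefore
#' equals the generating potential plus noise, so fits can be checked
#' against known parameters.  The background is itself a low-order cosine
#' surface with an optional chi1/chi2 coupling ridge, so the fit has to
#' separate signal from a structured background rather than a constant.
#'
#' @param grid a [scan_table()] (typically from [make_chi1_grid()] or
#'   [make_chi1_chi2_grid()]); energy columns are overwritten.
#' @param generators list with a [cosine_series()] under \code{chi1} and
#'   optionally one under \code{chi2}.
#' @param background list with optional [cosine_series()] entries
#'   \code{chi1} and \code{chi2} and an optional scalar
#'   \code{coupling} a, adding \eqn{a\,\cos(\chi_1 - \chi_2)}; or
#'   \code{NULL} for a flat zero background.
#' @param sigma Gaussian noise standard deviation on \code{E_qm},
#'   kcal/mol.  Default 0.2, mimicking sub-kcal/mol discrepancies between
#'   a QM reference and the best attainable torsion fit.
#' @param seed integer seed for reproducibility (local to this call).
#' @return the grid as a [scan_table()] with \code{E_qm} and
#'   \code{E_mm_base} filled in.
#' @export
synth_scan <- function(grid, generators, background = NULL, sigma = 0.2,
                       seed = NULL) {
  stopifnot(inherits(grid, "scan_table"))
  if (is.null(generators$chi1))
    stop("'generators' must contain a chi1 cosine series")
  if (!is.numeric(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  bg <- numeric(nrow(grid))
  if (!is.null(background$chi1))
    bg <- bg + evaluate_torsion(background$chi1, grid$chi1)
  if (!is.null(background$chi2)) {
    if (anyNA(grid$chi2)) stop("chi2 background on a grid without chi2")
    bg <- bg + evaluate_torsion(background$chi2, grid$chi2)
  }
  if (!is.null(background$coupling)) {
    if (anyNA(grid$chi2)) stop("chi1/chi2 coupling on a grid without chi2")
    bg <- bg + background$coupling * cos(.deg2rad(grid$chi1 - grid$chi2))
  }
  sig <- evaluate_torsion(generators$chi1, grid$chi1)
  if (!is.null(generators$chi2)) {
    if (anyNA(grid$chi2)) stop("chi2 generator on a grid without chi2")
    sig <- sig + evaluate_torsion(generators$chi2, grid$chi2)
  }
  noise <- .with_seed(seed, stats::rnorm(nrow(grid), 0, sigma))
  if (sigma == 0) noise <- numeric(nrow(grid))
  grid$E_mm_base <- bg
  grid$E_qm <- bg + sig + noise
  scan_table(as.data.frame(grid), residue = attr(grid, "residue"))
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution;
# no installed package provides one.
.rvonmises <- function(n, mu_deg, kappa) {
  if (kappa <= 0) stop("'kappa' must be positive")
  mu <- .deg2rad(mu_deg)
  out <- numeric(n)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      i <- i + 1L
      u3 <- stats::runif(1)
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
    }
  }
  wrap_angle(out * 180 / pi)
}

#' Sample a rotamer-structured chi1 trajectory
#'
#' Draws frames from a three-component von Mises mixture with components
#' centred on the canonical chi1 wells (+60, -60, 180 degrees for p, m,
#' t), standing in for the chi1 time series of a long helical-peptide
#' simulation.
#'
#' @param populations named vector of state weights \code{c(p=, m=, t=)},
#'   summing to 1.
#' @param n number of frames.
#' @param kappa von Mises concentration (per state; scalar or length 3).
#'   The default 20 gives roughly 13-degree circular spread, well inside
#'   the 120-degree-wide rotamer bins.
#' @param seed integer seed (local to this call).
#' @param residue residue label carried on the series.
#' @return a [dihedral_series()].
#' @export
sample_dihedral_trajectory <- function(populations, n, kappa = 20,
                                       seed = NULL, residue = "UNK") {
  pops <- rotamer_distribution_vec(populations)
  if (n < 1L) stop("'n' must be positive")
  kappa <- rep_len(kappa, 3L)
  if (any(kappa <= 0)) stop("'kappa' must be positive")
  centers <- c(p = 60, m = -60, t = 180)
  values <- .with_seed(seed, {
    states <- sample(names(centers), n, replace = TRUE, prob = pops)
    v <- numeric(n)
    for (s in names(centers)) {
      idx <- which(states == s)
      if (length(idx))
        v[idx] <- .rvonmises(length(idx), centers[[s]],
                             kappa[match(s, names(centers))])
    }
    v
  })
  dihedral_series(values, residue = residue)
}

#' Synthetic RDC dataset from a known alignment tensor
#'
#' Draws isotropically distributed unit bond vectors and computes their
#' couplings from the given tensor, plus optional Gaussian noise: the
#' standard recovery fixture for [fit_alignment_tensor()].
#'
#' @param tensor an [alignment_tensor()].
#' @param n number of bonds (>= 5).
#' @param noise Gaussian noise standard deviation on the couplings, Hz.
#' @param dmax maximal dipolar coupling, Hz.
#' @param seed integer seed (local to this call).
#' @return list with \code{vectors} (n x 3 unit rows), \code{rdcs} (Hz)
#'   and \code{dmax}.
#' @export
synth_rdc_dataset <- function(tensor, n, noise = 0, dmax = 1, seed = NULL) {
  stopifnot(inherits(tensor, "alignment_tensor"))
  if (n < 5L) stop("'n' must be at least 5")
  if (noise < 0) stop("'noise' must be >= 0")
  .with_seed(seed, {
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- v / sqrt(rowSums(v^2))
    d <- dmax * rowSums((u %*% unclass(tensor)) * u)
    if (noise > 0) d <- d + stats::rnorm(n, 0, noise)
    list(vectors = u, rdcs = d, dmax = dmax)
  })
}
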