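#' Boltzmann weights for scan conformations
#'
#' Each conformation is weighted by \eqn{\exp(-\beta E^{QM})}, normalized
#' to sum to one.  Energies are shifted to a minimum of zero before
#' exponentiation; the shift cancels in the normalization and avoids
#' overflow.  \code{beta = 0} gives uniform weights (an unweighted fit to
#' the energy profile); larger beta concentrates the fit on the low-energy
#' wells, i.e. on the equilibrium populations.
#'
#' @param E_qm numeric vector of QM energies, kcal/mol.
#' @param beta inverse temperature in mol/kcal; the default 1.0
#'   corresponds to roughly 500 K, intermediate between a uniform fit
#'   (beta = 0) and room-temperature populations (beta ~ 1.7).
#' @return normalized weights summing to 1.
#' @export
boltzmann_weights <- function(E_qm, beta = 1.0) {
  if (length(E_qm) == 0L) stop("'E_qm' must be non-empty")
  if (any(!is.finite(E_qm))) stop("'E_qm' must be finite")
  if (!is.finite(beta) || beta < 0) stop("'beta' must be >= 0")
  w <- exp(-beta * (E_qm - min(E_qm)))
  w / sum(w)
}

# Boltzmann constant in kcal/mol/K
.kB <- 1.987204259e-3

#' Convert between inverse temperature and temperature
#'
#' \code{beta = 1/(kB T)} with kB in kcal/mol/K, so beta is in mol/kcal.
#' beta = 1.0 mol/kcal corresponds to about 500 K and room temperature
#' (298 K) to beta of about 1.7 mol/kcal.
#'
#' @param beta inverse temperature, mol/kcal.
#' @param temperature temperature in kelvin.
#' @return temperature in kelvin, or beta in mol/kcal.
#' @export
beta_to_temperature <- function(beta) {
  stopifnot(is.finite(beta), beta > 0)
  1 / (.kB * beta)
}

#' @rdname beta_to_temperature
#' @export
temperature_to_beta <- function(temperature) {
  stopifnot(is.finite(temperature), temperature > 0)
  1 / (.kB * temperature)
}

#' Specification of a torsion fit
#'
#' @param m_chi1 integer vector of cosine multiplicities for the chi1 term
#'   (e.g. \code{1:2} for Ile, \code{1:3} for Leu, \code{1:6} for Asp/Asn).
#' @param m_chi2 multiplicities for a simultaneously fitted chi2 term, or
#'   \code{NULL} for a chi1-only fit.
#' @param beta Boltzmann inverse temperature for the weights, mol/kcal.
#' @param fit_offset fit the additive constant k0 that absorbs the
#'   arbitrary offset between the QM and MM energy scales?  If
#'   \code{FALSE}, k0 is fixed at 0.
#' @return an object of class \code{fit_spec}.
#' @export
fit_spec <- function(m_chi1, m_chi2 = NULL, beta = 1.0, fit_offset = TRUE) {
  m_chi1 <- as.integer(m_chi1)
  if (length(m_chi1) < 1L || any(m_chi1 < 1L) || anyDuplicated(m_chi1))
    stop("'m_chi1' must be distinct positive integers")
  if (!is.null(m_chi2)) {
    m_chi2 <- as.integer(m_chi2)
    if (length(m_chi2) < 1L || any(m_chi2 < 1L) || anyDuplicated(m_chi2))
      stop("'m_chi2' must be distinct positive integers")
  }
  if (!is.finite(beta) || beta < 0) stop("'beta' must be >= 0")
  structure(list(m_chi1 = m_chi1, m_chi2 = m_chi2, beta = beta,
                 fit_offset = isTRUE(fit_offset)),
            class = "fit_spec")
}

# design matrix: one column per cosine term (1 + cos(m theta)), plus an
# intercept column for k0 when fitted
.fit_design <- function(scan, spec) {
  cols <- list()
  nms <- character()
  if (spec$fit_offset) {
    cols <- c(cols, list(rep(1, nrow(scan))))
    nms <- "k0"
  }
  for (m in spec$m_chi1) {
    cols <- c(cols, list(1 + cos(m * .deg2rad(scan$chi1))))
    nms <- c(nms, sprintf("chi1.m%d", m))
  }
  if (!is.null(spec$m_chi2)) {
    if (anyNA(scan$chi2))
      stop("chi2 fit requested but the scan table has missing chi2 values")
    for (m in spec$m_chi2) {
      cols <- c(cols, list(1 + cos(m * .deg2rad(scan$chi2))))
      nms <- c(nms, sprintf("chi2.m%d", m))
    }
  }
  A <- do.call(cbind, cols)
  colnames(A) <- nms
  A
}

#' Fit a replacement torsion potential to a QM - MM energy gap
#'
#' Solves the Boltzmann-weighted linear least-squares problem
#' \deqn{\min \sum_i w_i \left(E^{MM,base}_i + \sum_{angles} V(\theta_i)
#'   + k_0 - E^{QM}_i\right)^2}
#' for the force constants of one (chi1) or two (chi1 and chi2, jointly)
#' cosine-series torsion terms with phase fixed at 0, plus the offset k0.
#' The model is linear in all parameters, so the solution is closed form
#' (weighted QR with column pivoting); rank deficiency — for instance a
#' chi2-symmetric scan fitted with odd chi2 multiplicities only — is
#' reported as an error naming the degenerate columns.
#'
#' \code{E_mm_base} must already exclude the torsion term being replaced;
#' use [subtract_torsion()] if you have full MM energies.
#'
#' @param scan a [scan_table()] with finite \code{E_qm} and
#'   \code{E_mm_base} on every row.
#' @param spec a [fit_spec()].
#' @return an object of class \code{torsion_fit}: a list with elements
#'   \code{chi1} (fitted [cosine_series()]), \code{chi2} (or NULL),
#'   \code{k0}, \code{weighted_residual} (kcal^2/mol^2),
#'   \code{residuals} (per-point, kcal/mol), \code{weights}, \code{spec},
#'   and \code{definition} (filled by [select_dihedral_definition()]).
#' @examples
#' gen <- ildn_parameters("ILE", "chi1")$series
#' grid <- make_chi1_grid(15, c(-60, 60, 180))
#' sc <- synth_scan(grid, generators = list(chi1 = gen), seed = 1)
#' fit <- fit_torsion(sc, fit_spec(m_chi1 = 1:2))
#' fit$chi1$k   # recovers 0.195, -0.846
#' @export
fit_torsion <- function(scan, spec) {
  stopifnot(inherits(scan, "scan_table"), inherits(spec, "fit_spec"))
  if (anyNA(scan$E_qm) || anyNA(scan$E_mm_base))
    stop("scan table must have E_qm and E_mm_base on every row to fit")
  y <- scan$E_qm - scan$E_mm_base
  A <- .fit_design(scan, spec)
  if (nrow(A) < ncol(A))
    stop(sprintf("under-determined fit: %d points for %d parameters",
                 nrow(A), ncol(A)))
  w <- boltzmann_weights(scan$E_qm, spec$beta)
  sw <- sqrt(w)
  qrA <- qr(A * sw)
  if (qrA$rank < ncol(A)) {
    degen <- colnames(A)[qrA$pivot[(qrA$rank + 1):ncol(A)]]
    stop("rank-deficient design matrix; degenerate column(s): ",
         paste(degen, collapse = ", "))
  }
  coef <- qr.coef(qrA, y * sw)
  fitted <- drop(A %*% coef)
  res <- fitted - y
  k0 <- if (spec$fit_offset) unname(coef["k0"]) else 0
  kc1 <- unname(coef[sprintf("chi1.m%d", spec$m_chi1)])
  out <- list(
    chi1 = cosine_series(spec$m_chi1, kc1, theta0 = 0),
    chi2 = NULL,
    k0 = k0,
    weighted_residual = sum(w * res^2),
    residuals = res,
    weights = w,
    spec = spec,
    definition = NULL)
  if (!is.null(spec$m_chi2)) {
    kc2 <- unname(coef[sprintf("chi2.m%d", spec$m_chi2)])
    out$chi2 <- cosine_series(spec$m_chi2, kc2, theta0 = 0)
  }
  structure(out, class = "torsion_fit")
}

#' @export
print.torsion_fit <- function(x, ...) {
  cat("Torsion fit (Boltzmann-weighted least squares)\n")
  if (!is.null(x$definition))
    cat("  dihedral: ", format(x$definition), "\n", sep = "")
  cat(sprintf("  k0 = %.6f kcal/mol; weighted residual = %.6g\n",
              x$k0, x$weighted_residual))
  cat("  chi1 force constants:",
      paste(sprintf("k%d=%.4f", x$chi1$m, x$chi1$k), collapse = ", "), "\n")
  if (!is.null(x$chi2))
    cat("  chi2 force constants:",
        paste(sprintf("k%d=%.4f", x$chi2$m, x$chi2$k), collapse = ", "), "\n")
  invisible(x)
}

#' Subtract an existing torsion term from the MM base energy
#'
#' Helper for callers whose \code{E_mm_base} still contains the torsion
#' term that the fit is meant to replace.
#'
#' @param scan a [scan_table()].
#' @param series the old torsion [cosine_series()] to remove.
#' @param angle which scan angle the term acts on, \code{"chi1"} or
#'   \code{"chi2"}.
#' @return the scan table with \code{E_mm_base} reduced by the term.
#' @export
subtract_torsion <- function(scan, series, angle = c("chi1", "chi2")) {
  stopifnot(inherits(scan, "scan_table"))
  angle <- match.arg(angle)
  th <- scan[[angle]]
  if (anyNA(th)) stop("scan table has missing ", angle, " values")
  scan$E_mm_base <- scan$E_mm_base - evaluate_torsion(series, th)
  scan
}

#' Choose among candidate dihedral definitions by fit quality
#'
#' With the phase fixed at 0, the atom quadruples that could carry a chi1
#' correction (e.g. N-CA-CB-CG vs C-CA-CB-CG) are no longer equivalent, so
#' the fit is run once per candidate and the definition giving the lowest
#' weighted residual wins; ties go to the first-listed candidate.
#'
#' @param scans a list of [scan_table()]s, one per candidate, each with
#'   the chi1 column expressed in that candidate's dihedral convention.
#' @param spec a [fit_spec()] applied to every candidate.
#' @param definitions optional list of [torsion_definition()]s parallel to
#'   \code{scans}; recorded on the results.
#' @return the winning \code{torsion_fit}, with
#'   \code{candidate_residuals} (named numeric vector) attached.
#' @export
select_dihedral_definition <- function(scans, spec, definitions = NULL) {
  if (!is.list(scans) || length(scans) < 1L)
    stop("'scans' must be a non-empty list of scan tables")
  if (!is.null(definitions) && length(definitions) != length(scans))
    stop("'definitions' must parallel 'scans'")
  fits <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    fits[[i]] <- fit_torsion(scans[[i]], spec)
    if (!is.null(definitions)) fits[[i]]$definition <- definitions[[i]]
  }
  resid <- vapply(fits, function(f) f$weighted_residual, numeric(1))
  names(resid) <- if (!is.null(names(scans))) names(scans)
                  else sprintf("candidate%d", seq_along(scans))
  best <- which.min(resid)  # which.min takes the first on ties
  out <- fits[[best]]
  out$candidate_residuals <- resid
  out
}
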