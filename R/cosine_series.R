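#' Cosine-series torsion potential in the Amber convention
#'
#' Represents a periodic torsion potential
#' \deqn{V(\theta) = \sum_m k_m \left[1 + \cos(m\theta - \theta_0)\right]}
#' with multiplicities \eqn{m}, force constants \eqn{k_m} (kcal/mol) and
#' phase \eqn{\theta_0} (degrees).  The Amber convention fixes the phase at
#' 0 (or 180, which is equivalent to negating \eqn{k_m}); the general form
#' with an arbitrary per-term phase is supported so that parameter files
#' using explicit phases re-import losslessly.
#'
#' @param m integer vector of multiplicities (distinct, positive).
#' @param k numeric vector of force constants in kcal/mol, one per
#'   multiplicity.  Negative values are permitted.
#' @param theta0 phase in degrees; a scalar (applied to every term) or a
#'   vector with one phase per term.  Default 0, the Amber convention.
#' @return an object of class \code{cosine_series}.
#' @examples
#' ile <- cosine_series(m = 1:2, k = c(0.195, -0.846))
#' evaluate_torsion(ile, 0)      # 2 * (0.195 - 0.846)
#' torsion_amplitude(ile)
#' @seealso [evaluate_torsion()], [torsion_amplitude()], [ildn_parameters()]
#' @export
cosine_series <- function(m, k, theta0 = 0) {
  m <- as.integer(m)
  if (length(m) == 0L) stop("a cosine series needs at least one term")
  if (anyNA(m) || any(m < 1L)) stop("multiplicities must be positive integers")
  if (anyDuplicated(m)) stop("multiplicities must be distinct")
  if (length(k) != length(m)) stop("'k' and 'm' must have the same length")
  if (!is.numeric(k) || any(!is.finite(k)))
    stop("force constants must be finite numerics")
  if (!(length(theta0) %in% c(1L, length(m))) || any(!is.finite(theta0)))
    stop("'theta0' must be a finite scalar or one value per term")
  theta0 <- rep_len(as.numeric(theta0), length(m))
  structure(list(m = m, k = as.numeric(k), theta0 = theta0),
            class = "cosine_series")
}

#' @export
print.cosine_series <- function(x, ...) {
  cat("Cosine-series torsion potential (kcal/mol):\n")
  df <- data.frame(m = x$m, k = x$k, theta0 = x$theta0)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Evaluate a cosine-series torsion potential
#'
#' @param series a [cosine_series()].
#' @param theta dihedral angle(s) in degrees; any finite value (evaluation
#'   is 360-degree periodic).
#' @return energy in kcal/mol, one value per element of \code{theta}.
#' @export
evaluate_torsion <- function(series, theta) {
  stopifnot(inherits(series, "cosine_series"))
  if (!is.numeric(theta) || length(theta) == 0L || any(!is.finite(theta)))
    stop("'theta' must be finite numeric degrees")
  th <- .deg2rad(theta)
  v <- numeric(length(theta))
  for (i in seq_along(series$m)) {
    v <- v + series$k[i] *
      (1 + cos(series$m[i] * th - .deg2rad(series$theta0[i])))
  }
  v
}

#' Peak-to-peak amplitude of a torsion potential
#'
#' Maximum minus minimum of \eqn{V(\theta)} over one period, evaluated on a
#' dense grid.
#'
#' @inheritParams evaluate_torsion
#' @param step grid step in degrees (must be <= 0.1 for the documented
#'   accuracy; default 0.1).
#' @return amplitude in kcal/mol.
#' @export
torsion_amplitude <- function(series, step = 0.1) {
  stopifnot(inherits(series, "cosine_series"), step > 0, step <= 0.1)
  grid <- seq(-180, 180, by = step)
  v <- evaluate_torsion(series, grid)
  max(v) - min(v)
}

#' Single-well periodic dihedral restraint
#'
#' A weak backbone restraint of the form
#' \eqn{k_\theta [1 + \cos(\theta - \theta_{ref})]}, used to keep model
#' peptides helical during rotamer sampling.  The minimum sits at
#' \eqn{\theta_{ref} - 180^\circ}: reference values of 122 and 133 degrees
#' for phi and psi place the minima at -58 and -47 degrees, i.e. in the
#' alpha-helical region of the Ramachandran map.
#'
#' @param theta_ref reference angle in degrees.
#' @param k_theta force constant in kcal/mol (>= 0).
#' @return an object of class \code{restraint_spec}.
#' @export
restraint_spec <- function(theta_ref, k_theta = 1) {
  if (!is.finite(theta_ref)) stop("'theta_ref' must be finite")
  if (!is.finite(k_theta) || k_theta < 0) stop("'k_theta' must be >= 0")
  structure(list(theta_ref = as.numeric(theta_ref),
                 k_theta = as.numeric(k_theta)),
            class = "restraint_spec")
}

#' Evaluate a dihedral restraint energy
#'
#' @param spec a [restraint_spec()].
#' @param theta angle(s) in degrees.
#' @return restraint energy in kcal/mol.
#' @export
evaluate_restraint <- function(spec, theta) {
  stopifnot(inherits(spec, "restraint_spec"))
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite numeric degrees")
  spec$k_theta * (1 + cos(.deg2rad(theta - spec$theta_ref)))
}

#' Torsion definition: residue, angle label and atom quadruple
#'
#' Identifies which four atoms define the dihedral a torsion potential is
#' applied to.  With the phase fixed at 0 the rotational symmetry between
#' the candidate quadruples (e.g. N-CA-CB-CG vs C-CA-CB-CG for chi1) is
#' broken, so the chosen quadruple is part of the parameter set.
#'
#' @param residue 3-letter residue code (upper-cased internally).
#' @param angle angle label, \code{"chi1"} or \code{"chi2"}.
#' @param atoms character vector of exactly four atom names, in order.
#' @return an object of class \code{torsion_definition}.
#' @export
torsion_definition <- function(residue, angle, atoms) {
  angle <- match.arg(angle, c("chi1", "chi2"))
  if (length(atoms) != 4L || !is.character(atoms))
    stop("'atoms' must be exactly four atom names")
  structure(list(residue = toupper(residue), angle = angle,
                 atoms = atoms),
            class = "torsion_definition")
}

#' @export
print.torsion_definition <- function(x, ...) {
  cat(sprintf("%s %s: %s\n", x$residue, x$angle,
              paste(x$atoms, collapse = "-")))
  invisible(x)
}

#' @export
format.torsion_definition <- function(x, ...) {
  paste(x$atoms, collapse = "-")
}
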