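#' Wrap angles into the canonical interval (-180, 180]
#'
#' All user-facing angles in this package are degrees; internally every
#' dihedral is reduced to the half-open interval (-180, 180] so that
#' -180 and +180 denote the same (trans) conformation exactly once.
#'
#' @param theta numeric vector of angles in degrees.
#' @return numeric vector of the same length, each element in (-180, 180].
#' @examples
#' wrap_angle(c(-180, 180, 270, -541))
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta)) stop("'theta' must be numeric")
  w <- theta - 360 * ceiling((theta - 180) / 360)
  # guard against floating-point landing exactly on -180
  w[w <= -180] <- w[w <= -180] + 360
  w
}

# degrees -> radians
.deg2rad <- function(x) x * pi / 180
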