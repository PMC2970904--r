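#' Karplus relation coefficients
#'
#' A three-bond scalar coupling is mapped to the intervening dihedral by
#' the Karplus relation \eqn{J(\theta) = A\cos^2(\theta+\delta) +
#' B\cos(\theta+\delta) + C}.  The phase offset delta accounts for the
#' geometric offset between the heavy-atom dihedral carried in a time
#' series (typically chi1) and the proton dihedral the coupling actually
#' reports on (0 or +/-120 degrees for tetrahedral centres).
#'
#' @param A,B,C coefficients in Hz.
#' @param delta phase offset in degrees, default 0.
#' @param class coupling class label, one of \code{"HA-HB"},
#'   \code{"N-CG"}, \code{"C-CG"}, \code{"C-HB"}.
#' @param source free-text tag recording where the coefficients came from.
#' @return object of class \code{karplus_params}.
#' @export
karplus_params <- function(A, B, C, delta = 0,
                           class = c("HA-HB", "N-CG", "C-CG", "C-HB"),
                           source = "user") {
  class <- match.arg(class)
  vals <- c(A, B, C, delta)
  if (any(!is.finite(vals))) stop("Karplus coefficients must be finite")
  structure(list(A = A, B = B, C = C, delta = delta, class = class,
                 source = source),
            class = "karplus_params")
}

#' Default Karplus registry
#'
#' Named presets for the four supported coupling classes, with
#' representative literature-style coefficients and the geometric offsets
#' from chi1 to the reported dihedral.  These defaults are placeholders a
#' study should replace with the coefficient set appropriate to its
#' experiments ([read_karplus_registry()] loads a user table); every
#' computation carries the \code{source} tag of the preset used.
#'
#' @return named list of [karplus_params()].
#' @export
default_karplus_registry <- function() {
  list(
    "HA-HB"  = karplus_params(9.5, -1.6, 1.8, delta = -120, class = "HA-HB",
                              source = "builtin-default"),
    "N-CG"   = karplus_params(2.2, -0.6, 0.5, delta = 0, class = "N-CG",
                              source = "builtin-default"),
    "C-CG"   = karplus_params(3.4, -0.9, 0.5, delta = 120, class = "C-CG",
                              source = "builtin-default"),
    "C-HB"   = karplus_params(7.2, -1.3, 1.7, delta = 0, class = "C-HB",
                              source = "builtin-default"))
}

#' Read a Karplus registry file
#'
#' Delimited text (comma or tab) with columns
#' \code{name, A, B, C, delta, class, source}.
#'
#' @param path file path.
#' @return named list of [karplus_params()].
#' @export
read_karplus_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  raw <- readLines(path)
  content <- raw[!grepl("^\\s*(#|$)", raw)]
  sep <- if (grepl("\t", content[1])) "\t" else ","
  df <- utils::read.table(text = content, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("name", "A", "B", "C", "delta", "class")
  if (!all(need %in% names(df)))
    stop("registry must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$source)) df$source <- path
  out <- lapply(seq_len(nrow(df)), function(i)
    karplus_params(df$A[i], df$B[i], df$C[i], df$delta[i],
                   class = df$class[i], source = df$source[i]))
  names(out) <- df$name
  out
}

#' Evaluate a Karplus relation
#'
#' @param theta dihedral angle(s) in degrees.
#' @param params a [karplus_params()].
#' @return coupling(s) in Hz.
#' @export
karplus_j <- function(theta, params) {
  stopifnot(inherits(params, "karplus_params"))
  if (any(!is.finite(theta))) stop("'theta' must be finite")
  ct <- cos(.deg2rad(theta + params$delta))
  params$A * ct^2 + params$B * ct + params$C
}

#' Ensemble-averaged scalar coupling
#'
#' The coupling is evaluated frame by frame and then averaged — the
#' ensemble average of J, never J of the average angle.
#'
#' @param series a [dihedral_series()] or numeric angle vector (degrees).
#' @param params a [karplus_params()].
#' @return mean coupling in Hz.
#' @export
ensemble_j <- function(series, params) {
  values <- if (inherits(series, "dihedral_series")) series$values
            else series
  if (length(values) == 0L) stop("empty dihedral series")
  mean(karplus_j(values, params))
}

#' Molecular alignment (Saupe) tensor
#'
#' @param S symmetric traceless 3x3 matrix, or a length-5 vector of the
#'   independent components (Sxx, Syy, Sxy, Sxz, Syz).
#' @return object of class \code{alignment_tensor} (the 3x3 matrix).
#' @export
alignment_tensor <- function(S) {
  if (is.numeric(S) && length(S) == 5L) {
    S <- matrix(c(S[1], S[3], S[4],
                  S[3], S[2], S[5],
                  S[4], S[5], -S[1] - S[2]), 3, 3)
  }
  if (!is.matrix(S) || !all(dim(S) == c(3, 3)))
    stop("'S' must be a 3x3 matrix or length-5 component vector")
  if (max(abs(S - t(S))) > 1e-12) stop("alignment tensor must be symmetric")
  if (abs(sum(diag(S))) > 1e-12) stop("alignment tensor must be traceless")
  structure(S, class = c("alignment_tensor", "matrix", "array"))
}

# design row for one unit vector: D/Dmax as linear function of
# (Sxx, Syy, Sxy, Sxz, Syz) with Szz = -Sxx - Syy
.rdc_design <- function(u) {
  cbind(u[, 1]^2 - u[, 3]^2,
        u[, 2]^2 - u[, 3]^2,
        2 * u[, 1] * u[, 2],
        2 * u[, 1] * u[, 3],
        2 * u[, 2] * u[, 3])
}

.as_unit_rows <- function(vectors) {
  if (is.numeric(vectors) && is.null(dim(vectors)) && length(vectors) == 3L)
    vectors <- matrix(vectors, nrow = 1)
  if (!is.matrix(vectors) || ncol(vectors) != 3L)
    stop("bond vectors must be an n x 3 matrix")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm < 1e-12)) stop("zero-length bond vector")
  vectors / nrm
}

#' Fit an alignment tensor to measured RDCs
#'
#' Least-squares solution of the linear system
#' \eqn{D_i = D_{max,i} \sum_{kl} S_{kl} u_{ik} u_{il}} for the five
#' independent components of the symmetric traceless alignment tensor,
#' via QR decomposition.  Typically the inputs are backbone N-H bond
#' vectors and their measured couplings; the fitted tensor is then used to
#' predict side-chain RDCs.
#'
#' @param vectors n x 3 matrix of bond vectors (normalized internally);
#'   n >= 5 and not rank-deficient.
#' @param rdcs measured couplings, Hz.
#' @param dmax maximal dipolar coupling(s), Hz: scalar or one per bond
#'   (depends on the gyromagnetic ratios and bond length of the bond
#'   type).
#' @return an [alignment_tensor()].
#' @export
fit_alignment_tensor <- function(vectors, rdcs, dmax = 1) {
  u <- .as_unit_rows(vectors)
  n <- nrow(u)
  if (n < 5L) stop("need at least 5 bond vectors to fit an alignment tensor")
  if (length(rdcs) != n) stop("'rdcs' must have one value per bond vector")
  if (any(!is.finite(rdcs))) stop("'rdcs' must be finite")
  dmax <- rep_len(dmax, n)
  A <- .rdc_design(u) * dmax
  qrA <- qr(A)
  if (qrA$rank < 5L)
    stop("degenerate bond-vector geometry: alignment tensor not identifiable")
  s <- qr.coef(qrA, rdcs)
  alignment_tensor(unname(s))
}

#' Predict an ensemble-averaged RDC
#'
#' \eqn{D = D_{max} \langle u^T S u \rangle_{frames}}: the quadratic form
#' is evaluated per frame and then averaged.
#'
#' @param tensor an [alignment_tensor()].
#' @param vectors per-frame bond vectors, n_frames x 3 (or length 3 for a
#'   single frame); normalized internally.
#' @param dmax maximal dipolar coupling, Hz.
#' @return predicted coupling, Hz.
#' @export
predict_rdc <- function(tensor, vectors, dmax = 1) {
  stopifnot(inherits(tensor, "alignment_tensor"))
  u <- .as_unit_rows(vectors)
  q <- rowSums((u %*% unclass(tensor)) * u)
  mean(dmax * q)
}

#' Sum of the two side-chain amide N-H RDCs
#'
#' For primary amides (e.g. the Asn side chain) experiments often resolve
#' only the sum of the two N-H couplings; this predicts the same sum.
#'
#' @param tensor an [alignment_tensor()].
#' @param h1_vectors,h2_vectors per-frame bond vectors for the two N-H
#'   bonds; equal frame counts required.
#' @param dmax maximal dipolar coupling, Hz.
#' @return predicted summed coupling, Hz.
#' @export
sum_amide_rdcs <- function(tensor, h1_vectors, h2_vectors, dmax = 1) {
  u1 <- .as_unit_rows(h1_vectors)
  u2 <- .as_unit_rows(h2_vectors)
  if (nrow(u1) != nrow(u2))
    stop("frame-count mismatch between the two N-H bond series")
  predict_rdc(tensor, u1, dmax) + predict_rdc(tensor, u2, dmax)
}

#' RMSD between calculated and experimental observables
#'
#' @param observables data frame with columns \code{exp} and \code{calc}
#'   (Hz) and any grouping columns (e.g. \code{residue_type},
#'   \code{class}).
#' @param group_by name of the column to group on, or \code{NULL} for a
#'   single global RMSD.
#' @return data frame with columns \code{group}, \code{n}, \code{rmsd}.
#' @export
observable_rmsd <- function(observables, group_by = NULL) {
  stopifnot(is.data.frame(observables))
  if (nrow(observables) == 0L) stop("empty observable set")
  if (!all(c("exp", "calc") %in% names(observables)))
    stop("observable set needs 'exp' and 'calc' columns")
  g <- if (is.null(group_by)) rep("all", nrow(observables))
       else observables[[group_by]]
  if (is.null(g)) stop("no such grouping column: ", group_by)
  err2 <- (observables$calc - observables$exp)^2
  out <- do.call(rbind, lapply(split(err2, g), function(e)
    data.frame(n = length(e), rmsd = sqrt(mean(e)))))
  out <- data.frame(group = rownames(out), out, row.names = NULL)
  out
}
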