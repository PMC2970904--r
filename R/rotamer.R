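#' Signed dihedral angle from four points
#'
#' Standard torsion geometry: the angle between the plane through
#' (p1, p2, p3) and the plane through (p2, p3, p4), signed by the IUPAC
#' convention (cis/syn = 0, clockwise positive looking from p2 to p3),
#' returned in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (angstrom).
#' @return dihedral angle in degrees.
#' @examples
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))  # 180
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  pts <- list(p1, p2, p3, p4)
  if (any(vapply(pts, function(p) length(p) != 3L || any(!is.finite(p)),
                 logical(1))))
    stop("each point must be a finite length-3 coordinate")
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12 || sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate geometry: coincident or collinear points")
  m1 <- cross(n1, b2 / nb2)
  # IUPAC sign: positive when the far bond is rotated clockwise viewed
  # from p2 towards p3 (cis = 0)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

# fourth chi1 atom by residue type (N-CA-CB-X); Ile uses CG2 by the
# convention adopted for its packaged parameters
.chi1_fourth_atom <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG2", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1")

#' Extract chi1 from a PDB structure
#'
#' Reads the N, CA, CB and residue-specific fourth atom (CG by default,
#' CG2 for Ile, CG1 for Val, OG for Ser, OG1 for Thr, SG for Cys) of one
#' residue and returns the chi1 dihedral.  Accepts a path to a PDB file, a
#' \code{bio3d} pdb object, or a data frame with columns
#' \code{elety, resno, x, y, z} (and optionally \code{resid}).  The first
#' model is used; where alternate locations are present, altloc "A" is
#' preferred.
#'
#' @param structure PDB path, \code{bio3d::read.pdb()} object, or atom
#'   data frame.
#' @param resno residue number to extract.
#' @param restype 3-letter residue type; taken from the coordinates when
#'   available.
#' @return chi1 in degrees.
#' @export
extract_chi1 <- function(structure, resno, restype = NULL) {
  atoms <- .as_atom_frame(structure)
  sel <- atoms[atoms$resno == resno, , drop = FALSE]
  if (nrow(sel) == 0L) stop("residue ", resno, " not found in structure")
  if (is.null(restype)) {
    restype <- if (!is.null(sel$resid)) toupper(sel$resid[1]) else "UNK"
  }
  restype <- toupper(restype)
  fourth <- .chi1_fourth_atom[restype]
  if (is.na(fourth))
    stop(sprintf("residue type %s has no chi1 (or is unsupported)", restype))
  quad <- c("N", "CA", "CB", unname(fourth))
  coords <- lapply(quad, function(a) {
    hit <- sel[sel$elety == a, , drop = FALSE]
    if (nrow(hit) == 0L)
      stop(sprintf("missing atom %s in residue %s %d", a, restype, resno))
    as.numeric(hit[1, c("x", "y", "z")])
  })
  dihedral_angle(coords[[1]], coords[[2]], coords[[3]], coords[[4]])
}

# normalize the accepted structure inputs to a plain atom data frame
.as_atom_frame <- function(structure) {
  if (is.character(structure) && length(structure) == 1L) {
    structure <- bio3d::read.pdb(structure, multi = FALSE, verbose = FALSE)
  }
  if (inherits(structure, "pdb")) {
    atoms <- structure$atom
  } else if (is.data.frame(structure)) {
    atoms <- structure
  } else {
    stop("'structure' must be a PDB path, a bio3d pdb object, or a data frame")
  }
  need <- c("elety", "resno", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table must have columns: ", paste(need, collapse = ", "))
  if (!is.null(atoms$alt)) {
    keep <- is.na(atoms$alt) | atoms$alt %in% c("", "A")
    atoms <- atoms[keep, , drop = FALSE]
  }
  atoms
}

#' A chi1 (or other dihedral) time series
#'
#' @param values angles in degrees, one per frame; wrapped to (-180, 180].
#' @param residue residue identifier/type label.
#' @param label angle label, default \code{"chi1"}.
#' @return object of class \code{dihedral_series}.
#' @export
dihedral_series <- function(values, residue = "UNK", label = "chi1") {
  if (length(values) == 0L || any(!is.finite(values)))
    stop("'values' must be non-empty finite angles")
  structure(list(residue = residue, label = label,
                 values = wrap_angle(values)),
            class = "dihedral_series")
}

#' Classify chi1 into the three canonical rotamer states
#'
#' Bins are 120 degrees wide, centred on the canonical wells:
#' plus (p) at +60, minus (m) at -60 and trans (t) at 180.  Edges are
#' half-open for determinism: p is (0, 120], m is (-120, 0], t covers the
#' rest.
#'
#' @param chi1 angle(s) in degrees.
#' @return factor with levels \code{p}, \code{m}, \code{t}.
#' @examples
#' classify_rotamer(c(60, -60, 180))
#' @export
classify_rotamer <- function(chi1) {
  if (any(!is.finite(chi1))) stop("'chi1' must be finite")
  x <- wrap_angle(chi1)
  state <- ifelse(x > 0 & x <= 120, "p",
           ifelse(x > -120 & x <= 0, "m", "t"))
  factor(state, levels = c("p", "m", "t"))
}

#' Three-state rotamer population vector
#'
#' @param populations named numeric vector or list with entries p, m, t;
#'   non-negative, summing to 1 (within 1e-9; renormalized exactly).
#' @return object of class \code{rotamer_distribution} (named numeric).
#' @export
rotamer_distribution_vec <- function(populations) {
  p <- unlist(populations)[c("p", "m", "t")]
  if (anyNA(p) || any(p < 0)) stop("populations must be non-negative p, m, t")
  if (abs(sum(p) - 1) > 1e-9) stop("populations must sum to 1")
  structure(p / sum(p), class = "rotamer_distribution")
}

#' Rotamer populations of a dihedral series
#'
#' @param series a [dihedral_series()] or numeric vector of chi1 angles.
#' @return a \code{rotamer_distribution}: fractions of frames in the p, m
#'   and t states.
#' @export
rotamer_distribution <- function(series) {
  values <- if (inherits(series, "dihedral_series")) series$values
            else series
  if (length(values) == 0L) stop("empty dihedral series")
  counts <- table(classify_rotamer(values))
  fr <- as.numeric(counts) / length(values)
  names(fr) <- names(counts)
  rotamer_distribution_vec(fr)
}

#' RMSD between two three-state rotamer distributions
#'
#' \deqn{\mathrm{RMSD} = \sqrt{\tfrac{1}{3}\sum_{s \in \{p,m,t\}}
#'   (a_s - b_s)^2}}
#'
#' @param a,b \code{rotamer_distribution} objects (or named p/m/t
#'   vectors).
#' @return dimensionless RMSD in [0, sqrt(2/3)].
#' @export
distribution_rmsd <- function(a, b) {
  av <- unlist(a)[c("p", "m", "t")]
  bv <- unlist(b)[c("p", "m", "t")]
  if (anyNA(av) || anyNA(bv)) stop("both arguments need p, m, t entries")
  sqrt(mean((av - bv)^2))
}

#' Read a reference rotamer-distribution table
#'
#' Delimited text with columns \code{residue_type, p, m, t} (comma or tab,
#' auto-detected; comment lines start with '#').  Typical use: observed
#' helix rotamer statistics to compare simulated distributions against.
#'
#' @param path file path.
#' @return data frame with one validated distribution per residue type.
#' @export
read_rotamer_reference <- function(path) {
  if (!file.exists(path)) stop("reference table not found: ", path)
  raw <- readLines(path)
  content <- raw[!grepl("^\\s*(#|$)", raw)]
  sep <- if (grepl("\t", content[1])) "\t" else ","
  df <- utils::read.table(text = content, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("residue_type", "p", "m", "t")
  if (!all(need %in% names(df)))
    stop("reference table must have columns: ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(df)))
    rotamer_distribution_vec(c(p = df$p[i], m = df$m[i], t = df$t[i]))
  df[, need]
}

#' Compare per-residue rotamer distributions to a reference table
#'
#' @param observed named list of \code{rotamer_distribution}s (names are
#'   residue types).
#' @param reference data frame from [read_rotamer_reference()].
#' @return data frame with columns \code{residue_type, rmsd}, sorted by
#'   decreasing RMSD (worst-described residues first).
#' @export
compare_to_reference <- function(observed, reference) {
  rows <- lapply(names(observed), function(res) {
    ref <- reference[reference$residue_type == res, , drop = FALSE]
    if (nrow(ref) == 0L)
      stop("no reference distribution for residue type ", res)
    data.frame(residue_type = res,
               rmsd = distribution_rmsd(
                 observed[[res]],
                 c(p = ref$p[1], m = ref$m[1], t = ref$t[1])))
  })
  out <- do.call(rbind, rows)
  out[order(-out$rmsd), , drop = FALSE]
}
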