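# Published ff99SB-ILDN side-chain torsion corrections.
# Force constants in kcal/mol, phase 0 throughout (Amber convention).
# The Asp chi2 correction is applied to both carboxylate oxygens; the
# canonical quadruple below names OD1.
.ildn_table <- list(
  ILE = list(
    chi1 = list(atoms = c("N", "CA", "CB", "CG2"),
                k = c(0.195, -0.846))
  ),
  LEU = list(
    chi1 = list(atoms = c("C", "CA", "CB", "CG"),
                k = c(0.571, -0.358, 0.135))
  ),
  ASP = list(
    chi1 = list(atoms = c("N", "CA", "CB", "CG"),
                k = c(-2.635, -1.190, -0.007, 0.423, 0.232, -0.213)),
    chi2 = list(atoms = c("CA", "CB", "CG", "OD1"),
                k = c(0.0, -0.443, 0.0, -0.138, 0.0, -0.013))
  ),
  ASN = list(
    chi1 = list(atoms = c("C", "CA", "CB", "CG"),
                k = c(0.571, -0.596, 0.118, -0.417, 0.104, -0.101)),
    chi2 = list(atoms = c("CA", "CB", "CG", "ND2"),
                k = c(-1.046, -0.181, -0.035, 0.100, 0.130, -0.106))
  )
)

#' Published ff99SB-ILDN torsion parameters
#'
#' Returns the published replacement chi1/chi2 torsion potential for one of
#' the four re-parameterized residues (Ile, Leu, Asp, Asn), together with
#' the dihedral definition (atom quadruple) it applies to.  Multiplicities
#' run 1..M with M = 2 for Ile chi1, 3 for Leu chi1 and 6 for the Asp and
#' Asn chi1 and chi2 terms; the phase is 0 throughout.
#'
#' @param residue one of \code{"ILE"}, \code{"LEU"}, \code{"ASP"},
#'   \code{"ASN"} (case-insensitive).
#' @param angle \code{"chi1"} or \code{"chi2"} (chi2 exists only for Asp
#'   and Asn).
#' @return a list with elements \code{series} (a [cosine_series()]) and
#'   \code{definition} (a [torsion_definition()]).
#' @examples
#' p <- ildn_parameters("ILE", "chi1")
#' p$series$k          # 0.195, -0.846
#' p$definition$atoms  # N CA CB CG2
#' @export
ildn_parameters <- function(residue, angle = "chi1") {
  residue <- toupper(residue)
  angle <- match.arg(angle, c("chi1", "chi2"))
  entry <- .ildn_table[[residue]]
  if (is.null(entry))
    stop(sprintf("no packaged parameters for residue '%s' (have: %s)",
                 residue, paste(names(.ildn_table), collapse = ", ")))
  row <- entry[[angle]]
  if (is.null(row))
    stop(sprintf("residue %s has no packaged %s correction", residue, angle))
  list(series = cosine_series(m = seq_along(row$k), k = row$k, theta0 = 0),
       definition = torsion_definition(residue, angle, row$atoms))
}

#' Residues with packaged torsion corrections
#'
#' @return data frame with one row per packaged (residue, angle) pair.
#' @export
ildn_residues <- function() {
  rows <- do.call(rbind, lapply(names(.ildn_table), function(res) {
    data.frame(residue = res, angle = names(.ildn_table[[res]]),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Write a plain-text torsion parameter table
#'
#' One line per cosine term: residue, angle, atom quadruple, multiplicity,
#' force constant (3 decimals, as published) and phase.  Zero force
#' constants are retained so the table round-trips exactly.
#'
#' @param params a list of entries as returned by [ildn_parameters()], or a
#'   single such entry.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_param_table <- function(params, path) {
  if (!is.null(params$series)) params <- list(params)
  lines <- c("# torsion parameter table",
             "# columns: residue angle atoms m k theta0")
  for (p in params) {
    s <- p$series
    d <- p$definition
    lines <- c(lines, sprintf("%-3s %-4s %-15s %d %8.3f %6.1f",
                              d$residue, d$angle,
                              paste(d$atoms, collapse = "-"),
                              s$m, s$k, s$theta0))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text torsion parameter table
#'
#' @param path file written by [write_param_table()].
#' @return list of entries, each with \code{series} and \code{definition},
#'   named \code{RES.angle}.
#' @export
read_param_table <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  if (!any(keep)) stop("no parameter rows in ", path)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(lengths(fields) != 6L)
  if (length(bad))
    stop(sprintf("malformed parameter row at line %d of %s",
                 which(keep)[bad[1]], path))
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- c("residue", "angle", "atoms", "m", "k", "theta0")
  df$m <- as.integer(df$m)
  df$k <- as.numeric(df$k)
  df$theta0 <- as.numeric(df$theta0)
  if (anyNA(df$m) || anyNA(df$k) || anyNA(df$theta0))
    stop("non-numeric m/k/theta0 field in ", path)
  out <- list()
  for (key in unique(paste(df$residue, df$angle, sep = "."))) {
    rows <- df[paste(df$residue, df$angle, sep = ".") == key, ]
    atoms <- strsplit(rows$atoms[1], "-")[[1]]
    out[[key]] <- list(
      series = cosine_series(rows$m, rows$k, rows$theta0),
      definition = torsion_definition(rows$residue[1], rows$angle[1], atoms))
  }
  out
}
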