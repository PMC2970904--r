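#' Conformational scan tables
#'
#' A scan table pairs grid conformations, identified by their constrained
#' dihedral angles (chi1, optionally chi2, plus fixed backbone phi/psi),
#' with a QM reference energy \code{E_qm} and the base molecular-mechanics
#' energy \code{E_mm_base}.  By convention \code{E_mm_base} is the full MM
#' energy with the torsion term under refit already removed, so that the
#' fitting target is \code{E_qm - E_mm_base}.
#'
#' @param points data frame with columns \code{chi1}, \code{chi2} (may be
#'   NA for pure chi1 scans), \code{phi}, \code{psi}, and optionally
#'   \code{E_qm}, \code{E_mm_base}.
#' @param residue residue label recorded in the metadata.
#' @return an object of class \code{scan_table} (a data frame with
#'   attributes \code{residue}, \code{phi}, \code{psi}).
#' @export
scan_table <- function(points, residue = "UNK") {
  stopifnot(is.data.frame(points))
  for (col in c("chi1", "phi", "psi"))
    if (is.null(points[[col]])) stop("scan table missing column '", col, "'")
  if (is.null(points$chi2)) points$chi2 <- NA_real_
  points$chi2 <- as.numeric(points$chi2)
  if (is.null(points$E_qm)) points$E_qm <- NA_real_
  if (is.null(points$E_mm_base)) points$E_mm_base <- NA_real_
  points$chi1 <- wrap_angle(points$chi1)
  has2 <- !is.na(points$chi2)
  points$chi2[has2] <- wrap_angle(points$chi2[has2])
  key <- paste(round(points$chi1, 6), round(points$chi2, 6))
  if (anyDuplicated(key))
    stop("duplicate (chi1, chi2) grid points after wrapping")
  if (length(unique(points$phi)) > 1L || length(unique(points$psi)) > 1L)
    stop("backbone phi/psi must be constant across a scan table")
  for (col in c("E_qm", "E_mm_base")) {
    v <- points[[col]]
    if (any(!is.na(v) & !is.finite(v)))
      stop("non-finite values in column '", col, "'")
  }
  points <- points[, c("chi1", "chi2", "phi", "psi", "E_qm", "E_mm_base")]
  structure(points, residue = residue,
            phi = points$phi[1], psi = points$psi[1],
            class = c("scan_table", "data.frame"))
}

# unique grid angles in (-180, 180] at the given step
.grid_angles <- function(step) {
  if (step <= 0 || abs(360 / step - round(360 / step)) > 1e-9)
    stop("'step' must be a positive divisor of 360 degrees")
  sort(wrap_angle(seq(-180, 180 - step, by = step)))
}

#' Build a 1D chi1 scan grid
#'
#' chi1 is varied over the full circle at the given step (the endpoints
#' -180 and +180 are the same conformation and counted once), crossed with
#' a small set of fixed chi2 values; the backbone is held at the extended
#' conformation phi = -135, psi = 135 by default.  The canonical protocol
#' (15-degree steps, chi2 in {-60, 60, 180}) yields 24 x 3 = 72 points.
#'
#' @param step chi1 increment in degrees; must divide 360.
#' @param chi2_values chi2 values (degrees) to cross with the chi1 scan.
#' @param phi,psi fixed backbone dihedrals in degrees.
#' @param residue residue label for the table metadata.
#' @return a [scan_table()] with empty energy columns.
#' @examples
#' nrow(make_chi1_grid(15, c(-60, 60, 180)))  # 72
#' @export
make_chi1_grid <- function(step = 15, chi2_values = c(-60, 60, 180),
                           phi = -135, psi = 135, residue = "UNK") {
  chi1 <- .grid_angles(step)
  pts <- expand.grid(chi1 = chi1, chi2 = wrap_angle(chi2_values),
                     KEEP.OUT.ATTRS = FALSE)
  pts$phi <- phi
  pts$psi <- psi
  scan_table(pts, residue = residue)
}

#' Build a 2D chi1/chi2 scan grid
#'
#' Both chi1 and chi2 are varied over the full circle.  For side chains
#' whose chi2 has an exact two-fold symmetry (e.g. the Asp carboxylate,
#' where chi2 and chi2 + 180 are equivalent), \code{chi2_symmetric = TRUE}
#' folds chi2 into [0, 180), halving the point count: at 30-degree steps
#' the full grid has 144 points and the folded grid 72.
#'
#' @param step grid increment in degrees for both angles; must divide 360.
#' @param chi2_symmetric fold chi2 under the two-fold symmetry?
#' @inheritParams make_chi1_grid
#' @return a [scan_table()] with empty energy columns.
#' @export
make_chi1_chi2_grid <- function(step = 30, chi2_symmetric = FALSE,
                                phi = -135, psi = 135, residue = "UNK") {
  chi1 <- .grid_angles(step)
  chi2 <- .grid_angles(step)
  if (chi2_symmetric) chi2 <- sort(unique(chi2 %% 180))
  pts <- expand.grid(chi1 = chi1, chi2 = chi2, KEEP.OUT.ATTRS = FALSE)
  pts$phi <- phi
  pts$psi <- psi
  scan_table(pts, residue = residue)
}

#' Write a scan table to delimited text
#'
#' Angles are written with 4 decimals and energies with 6, so a write/read
#' cycle is lossless at that precision.  The header comment records the
#' residue and the backbone constraint.
#'
#' @param table a [scan_table()].
#' @param path output path.
#' @param sep field separator, \code{","} or \code{"\t"}.
#' @return \code{path}, invisibly.
#' @export
write_scan_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "scan_table"))
  fmt <- function(x, d) ifelse(is.na(x), "NA", sprintf(paste0("%.", d, "f"), x))
  header <- c(sprintf("# residue: %s", attr(table, "residue")),
              sprintf("# phi: %.4f", attr(table, "phi")),
              sprintf("# psi: %.4f", attr(table, "psi")))
  cols <- c("chi1", "chi2", "phi", "psi", "E_qm", "E_mm_base")
  body <- apply(cbind(fmt(table$chi1, 4), fmt(table$chi2, 4),
                      fmt(table$phi, 4), fmt(table$psi, 4),
                      fmt(table$E_qm, 6), fmt(table$E_mm_base, 6)),
                1, paste, collapse = sep)
  writeLines(c(header, paste(cols, collapse = sep), body), path)
  invisible(path)
}

#' Read a scan table from delimited text
#'
#' The separator (comma or tab) is auto-detected from the header row.
#' Malformed rows or non-finite energies raise an error naming the line.
#'
#' @param path file written by [write_scan_table()] or any delimited file
#'   with columns \code{chi1, chi2, phi, psi, E_qm, E_mm_base}.
#' @return a [scan_table()].
#' @export
read_scan_table <- function(path) {
  if (!file.exists(path)) stop("scan table file not found: ", path)
  raw <- readLines(path)
  meta <- grep("^#", raw, value = TRUE)
  residue <- sub("^# residue:\\s*", "", grep("^# residue:", meta, value = TRUE))
  if (length(residue) == 0L) residue <- "UNK"
  content <- which(!grepl("^\\s*(#|$)", raw))
  if (length(content) < 2L) stop("no data rows in ", path)
  hdr_line <- raw[content[1]]
  sep <- if (grepl("\t", hdr_line)) "\t" else ","
  cols <- strsplit(hdr_line, sep, fixed = TRUE)[[1]]
  need <- c("chi1", "chi2", "phi", "psi")
  if (!all(need %in% cols))
    stop("scan table ", path, " missing column(s): ",
         paste(setdiff(need, cols), collapse = ", "))
  rows <- strsplit(raw[content[-1]], sep, fixed = TRUE)
  bad <- which(lengths(rows) != length(cols))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s (expected %d fields)",
                 content[-1][bad[1]], path, length(cols)))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- cols
  for (col in cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    txt <- df[[col]]
    broken <- which(is.na(v) & txt != "NA")
    if (length(broken))
      stop(sprintf("non-numeric value '%s' at line %d of %s (column %s)",
                   txt[broken[1]], content[-1][broken[1]], path, col))
    df[[col]] <- v
  }
  scan_table(df, residue = residue)
}
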