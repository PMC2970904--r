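#' Convert a cosine series to Amber DIHE records
#'
#' Amber DIHE records require a non-negative barrier PK, so a negative
#' force constant is emitted as PK = |k_m| with phase 180, using the
#' identity \eqn{k(1+\cos m\theta) = |k|(1+\cos(m\theta - 180^\circ)) +
#' const}; the additive constant does not affect forces.  Multi-term
#' torsions are encoded with negative periodicity PN on all records but
#' the last (the Amber continuation convention).  Zero-k terms are dropped
#' with a note.
#'
#' @param series a [cosine_series()] (phase 0 or 180 per term).
#' @param atom_types character vector of four Amber atom-type names.
#' @param idivf divider factor (number of paths the torsion is applied
#'   over), default 1.
#' @return data frame of records with columns \code{types, idivf, pk,
#'   phase, pn}.
#' @examples
#' to_frcmod(cosine_series(1:2, c(0.195, -0.846)), c("CX", "2C", "3C", "2C"))
#' @export
to_frcmod <- function(series, atom_types, idivf = 1L) {
  stopifnot(inherits(series, "cosine_series"))
  if (length(atom_types) != 4L || !is.character(atom_types))
    stop("'atom_types' must be four Amber atom-type names")
  if (!all(series$theta0 %in% c(0, 180)))
    stop("frcmod export supports phases of 0 or 180 degrees only")
  keep <- series$k != 0
  if (any(!keep))
    message(sprintf("dropping %d zero-force-constant term(s): m = %s",
                    sum(!keep), paste(series$m[!keep], collapse = ", ")))
  m <- series$m[keep]
  k <- series$k[keep]
  th0 <- series$theta0[keep]
  if (length(m) == 0L) stop("no nonzero terms to export")
  # fold an explicit 180 phase into the sign, then sign into the phase
  k <- ifelse(th0 == 180, -k, k)
  phase <- ifelse(k < 0, 180, 0)
  pk <- abs(k)
  pn <- m
  if (length(pn) > 1L) pn[-length(pn)] <- -pn[-length(pn)]
  types <- paste(sprintf("%-2s", atom_types), collapse = "-")
  data.frame(types = types, idivf = as.integer(idivf), pk = pk,
             phase = phase, pn = as.numeric(pn),
             stringsAsFactors = FALSE)
}

# canonical fixed-width DIHE line
.format_dihe <- function(rec) {
  sprintf("%s %4d %14.8f %14.3f %15.3f",
          rec$types, rec$idivf, rec$pk, rec$phase, rec$pn)
}

#' Write DIHE records as an frcmod file
#'
#' Emits the canonical fixed-width dialect: a title line, a DIHE section
#' and a terminating blank line.  Re-emitting a parsed file is
#' byte-identical.
#'
#' @param records data frame from [to_frcmod()] (several may be
#'   \code{rbind}-ed together).
#' @param path output path.
#' @param title free-text title line.
#' @return \code{path}, invisibly.
#' @export
write_frcmod <- function(records, path,
                         title = paste("torsion modification; negative k",
                                       "emitted as phase 180 (energies",
                                       "shift by an additive constant,",
                                       "forces unchanged)")) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  lines <- c(title, "", "DIHE",
             vapply(seq_len(nrow(records)),
                    function(i) .format_dihe(records[i, ]), character(1)),
             "")
  writeLines(lines, path)
  invisible(path)
}

#' Parse the DIHE section of an frcmod file
#'
#' Continuation records (negative PN) are grouped into multi-term
#' torsions.  Phase 180 records are folded back into negative force
#' constants; any other explicit phase is retained on the reconstructed
#' term (general input form).
#'
#' @param x path to an frcmod file, or its lines as a character vector.
#' @return list with \code{records} (data frame as written) and
#'   \code{torsions}: a list of \code{list(types, series)} entries, one
#'   per atom-type quadruple group.
#' @export
parse_frcmod <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  start <- which(trimws(lines) == "DIHE")
  if (length(start) == 0L) stop("no DIHE section found")
  body <- lines[-seq_len(start[1])]
  end <- which(trimws(body) == "")
  if (length(end)) body <- body[seq_len(end[1] - 1L)]
  if (length(body) == 0L)
    return(list(records = data.frame(), torsions = list()))
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    ln <- body[i]
    types <- substr(ln, 1, 11)
    rest <- strsplit(trimws(substr(ln, 12, nchar(ln))), "\\s+")[[1]]
    if (length(rest) != 4L)
      stop(sprintf("malformed DIHE record at line %d: '%s'",
                   start[1] + i, ln))
    num <- suppressWarnings(as.numeric(rest))
    if (anyNA(num))
      stop(sprintf("non-numeric field in DIHE record at line %d: '%s'",
                   start[1] + i, ln))
    recs[[i]] <- data.frame(types = types, idivf = as.integer(num[1]),
                            pk = num[2], phase = num[3], pn = num[4],
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  # group: a torsion runs until its first non-negative PN
  torsions <- list()
  i <- 1L
  while (i <= nrow(records)) {
    j <- i
    while (records$pn[j] < 0) {
      j <- j + 1L
      if (j > nrow(records) || records$types[j] != records$types[i])
        stop(sprintf("dangling continuation (negative PN) at record %d", i))
    }
    grp <- records[i:j, , drop = FALSE]
    m <- as.integer(abs(grp$pn))
    k <- ifelse(grp$phase == 180, -grp$pk, grp$pk)
    th0 <- ifelse(grp$phase %in% c(0, 180), 0, grp$phase)
    torsions[[length(torsions) + 1L]] <-
      list(types = trimws(strsplit(grp$types[1], "-")[[1]]),
           series = cosine_series(m, k, th0))
    i <- j + 1L
  }
  list(records = records, torsions = torsions)
}
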