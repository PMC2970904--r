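# independent brute-force dihedral: magnitude from the plane normals via
# acos, sign from the triple product of n1, n2 with the central bond
brute_dihedral <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosphi <- max(-1, min(1, cosphi))
  phi <- acos(cosphi) * 180 / pi
  s <- sum(cross(n1, n2) * b2)
  if (s < 0) phi <- -phi
  wrap_angle(phi)
}

# right-handed rotation of point p about the axis through origin along u
rotate_about_axis <- function(p, u, angle_deg) {
  u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  p * cos(th) + cross(u, p) * sin(th) + u * sum(u * p) * (1 - cos(th))
}

# random cosine series with nonzero force constants
random_series <- function(max_terms = 6) {
  m <- sort(sample(1:6, sample(1:max_terms, 1)))
  k <- round(stats::runif(length(m), -2, 2), 4)
  k[k == 0] <- 0.5
  cosine_series(m, k)
}

# minimal atom data frame for a residue with ideal-ish geometry placing
# chi1 (N-CA-CB-X) at exactly chi1_deg; CG2 sits 120 deg from CG1 around
# the CA-CB bond (tetrahedral branching)
make_residue_atoms <- function(chi1_deg, restype = "LEU", resno = 1L) {
  ca <- c(0, 0, 0)
  cb <- c(1.53, 0, 0)
  n <- c(-0.52, 1.36, 0)
  # start from the cis (0 deg) position: same side as N, then rotate
  g0 <- cb + c(0.51, 1.44, 0)
  axis <- cb - ca
  g <- cb + rotate_about_axis(g0 - cb, axis, chi1_deg)
  atoms <- data.frame(
    elety = c("N", "CA", "CB"),
    resno = resno, resid = restype,
    x = c(n[1], ca[1], cb[1]),
    y = c(n[2], ca[2], cb[2]),
    z = c(n[3], ca[3], cb[3]),
    stringsAsFactors = FALSE)
  fourth <- switch(restype, ILE = "CG2", VAL = "CG1", THR = "OG1",
                   SER = "OG", CYS = "SG", "CG")
  atoms <- rbind(atoms, data.frame(elety = fourth, resno = resno,
                                   resid = restype,
                                   x = g[1], y = g[2], z = g[3]))
  if (restype == "ILE") {
    g1 <- cb + rotate_about_axis(g0 - cb, axis, chi1_deg + 120)
    atoms <- rbind(atoms, data.frame(elety = "CG1", resno = resno,
                                     resid = restype,
                                     x = g1[1], y = g1[2], z = g1[3]))
  }
  atoms
}
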