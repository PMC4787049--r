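# Small 3D geometry kernel shared by the fixture builder, the side-chain
# grafting code and the structural-property calculations. All angles are in
# degrees, all lengths in Angstrom.

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  a / n
}

#' Bond angle a-b-c in degrees
#' @param a,b,c numeric xyz coordinates
#' @return angle in degrees
#' @keywords internal
angle3 <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Dihedral angle a-b-c-d in degrees, signed, in (-180, 180]
#' @param a,b,c,d numeric xyz coordinates
#' @return dihedral in degrees
#' @keywords internal
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three previously placed atoms a-b-c, returns the position d such that
#' |c-d| = bond, angle(b,c,d) = ang and dihedral(a,b,c,d) = dih.
#'
#' @param a,b,c reference coordinates (numeric length 3)
#' @param bond bond length c-d in Angstrom
#' @param ang bond angle b-c-d in degrees
#' @param dih dihedral a-b-c-d in degrees
#' @return numeric length-3 coordinates of d
#' @keywords internal
nerfPlace <- function(a, b, c, bond, ang, dih) {
  th <- ang * pi / 180
  ch <- -dih * pi / 180
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Van der Waals radii (Angstrom) used by SASA, contacts and the clash term.
.vdwRadii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
.vdwDefault <- 1.70

vdwRadius <- function(element) {
  r <- .vdwRadii[toupper(element)]
  r[is.na(r)] <- .vdwDefault
  unname(r)
}

# Deterministic golden-spiral point lattice on the unit sphere.
goldenSpiralPoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}

# Deterministic polynomial string hash (31-base, mod 2^31-1). Used for the
# ligand path fingerprint; stable across platforms and R sessions.
stableStringHash <- function(s) {
  vapply(s, function(one) {
    bytes <- utf8ToInt(one)
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Amino-acid code tables ------------------------------------------------------

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
             MSE = "M", UNK = "X")

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
             X = "UNK")

aa3to1 <- function(x) {
  out <- .aa3to1[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa1to3 <- function(x) {
  out <- .aa1to3[toupper(x)]
  if (anyNA(out)) stop("unknown one-letter amino acid code: ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}
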