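# Small internal geometry/bookkeeping helpers shared across modules.

# Euclidean norms of the rows of a 3-column matrix.
.row_norms <- function(m) sqrt(rowSums(m * m))

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# All pairwise distances between the rows of two 3-column matrices (a: n x 3,
# b: m x 3), returned as an n x m matrix.  Used by every detector.
.cross_dist <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Angle (degrees) at vertex `v` formed by points `p` and `q`, vectorised over
# rows of the three matrices.
.angle_at <- function(p, v, q) {
  u1 <- p - v
  u2 <- q - v
  cosang <- rowSums(u1 * u2) / (.row_norms(u1) * .row_norms(u2))
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Standard atomic masses (amu) used when a structure arrives without masses.
.ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, NA. = 22.99,
  CL = 35.45, MG = 24.305, K = 39.098, CA = 40.078
)

# Lennard-Jones well parameters (r_min/2 in Angstrom, epsilon in kcal/mol)
# and generalized-Born intrinsic radii (Angstrom) by element, in the style of
# all-atom force fields.  The synthetic topology is parametrised with these;
# they are deliberately a small uniform class set, not a full force field.
.ELEMENT_VDW <- list(
  H = c(0.6000, 0.0157),
  C = c(1.9080, 0.1094),
  N = c(1.8240, 0.1700),
  O = c(1.6612, 0.2100),
  S = c(2.0000, 0.2500)
)

.ELEMENT_GB_RADIUS <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.5, S = 1.8)

#' Look up the atomic mass of an element
#'
#' @param element Character vector of element symbols (e.g. \code{"C"}).
#' @return Numeric vector of masses in amu. Unknown elements get the carbon
#'   mass with a warning, so that downstream mass-weighted quantities remain
#'   defined.
#' @export
element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .ELEMENT_MASS[key]
  if (anyNA(m)) {
    .warnf("unknown element(s) %s assigned carbon mass",
           paste(unique(element[is.na(m)]), collapse = ", "))
    m[is.na(m)] <- .ELEMENT_MASS[["C"]]
  }
  unname(m)
}

# Derive the element symbol from a PDB atom name ("NZ" -> "N", "1HB" -> "H").
.element_from_name <- function(name) {
  stripped <- sub("^[0-9']+", "", name)
  one <- toupper(substr(stripped, 1, 1))
  one[one == ""] <- "C"
  one
}

.vdw_for_element <- function(element) {
  out <- t(vapply(element, function(e) {
    p <- .ELEMENT_VDW[[toupper(e)]]
    if (is.null(p)) p <- .ELEMENT_VDW[["C"]]
    p
  }, numeric(2)))
  colnames(out) <- c("rmin2", "eps")
  out
}

.gb_radius_for_element <- function(element) {
  r <- .ELEMENT_GB_RADIUS[toupper(element)]
  r[is.na(r)] <- 1.7
  unname(r)
}

.AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
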