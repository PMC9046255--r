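# Backbone geometry: dihedral angles, internal-coordinate atom placement
# (NeRF), and ideal C-beta reconstruction. All coordinates in Angstrom,
# all angles in radians unless a function says degrees.

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a^2))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

#' Signed dihedral angle of four points (IUPAC convention)
#'
#' Returns the torsion about the p2-p3 axis in radians in (-pi, pi]. Looking
#' along p2 -> p3, a clockwise rotation from the p1 side to the p4 side is
#' positive. Returns NA (with a warning) for degenerate (collinear) inputs.
#' @param p1,p2,p3,p4 numeric 3-vectors in Angstrom.
#' @return angle in radians, or NA if undefined.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9 || vnorm(b2) < 1e-12) {
    warning("degenerate atom quadruple; dihedral undefined")
    return(NA_real_)
  }
  m1 <- vcross(b2 / vnorm(b2), n1)
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three previously placed atoms a, b, c, returns the position d with
#' bond length |cd| = `length`, bond angle b-c-d = `angle` and dihedral
#' a-b-c-d = `torsion`.
#' @param a,b,c numeric 3-vectors.
#' @param length bond length in Angstrom.
#' @param angle bond angle in radians.
#' @param torsion dihedral in radians.
#' @return numeric 3-vector.
#' @export
place_atom <- function(a, b, c, length, angle, torsion) {
  bc <- vunit(c - b)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-9) stop("degenerate backbone geometry")
  n <- vunit(n)
  m <- vcross(n, bc)
  d2 <- c(-length * cos(angle),
          length * sin(angle) * cos(torsion),
          length * sin(angle) * sin(torsion))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Ideal backbone constants (Engh-Huber-style values); shared by the chain
# builder and C-beta imputation so round trips are self-consistent.
.ideal <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.522,
  a_n_ca_c = 111.2 * pi / 180, a_ca_c_n = 116.2 * pi / 180,
  a_c_n_ca = 121.7 * pi / 180, a_ca_c_o = 120.5 * pi / 180,
  a_n_ca_cb = 110.4 * pi / 180, t_c_n_ca_cb = -122.5 * pi / 180
)

#' Impute an idealized C-beta position from the backbone frame
#'
#' Constructs the tetrahedral C-beta from the local N-CA-C frame with bond
#' length 1.522 A, bond angle N-CA-CB = 110.4 degrees and dihedral
#' C-N-CA-CB = -122.5 degrees. The construction uses a cross product, so it
#' preserves chirality: mirroring the inputs does not mirror the output.
#' @param n,ca,c backbone atom coordinates (numeric 3-vectors, Angstrom).
#' @return numeric 3-vector: the C-beta position.
#' @export
impute_cbeta <- function(n, ca, c) {
  place_atom(c, n, ca,
             length = .ideal$b_ca_cb,
             angle = .ideal$a_n_ca_cb,
             torsion = .ideal$t_c_n_ca_cb)
}
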