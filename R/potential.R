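# analytic gradients of internal coordinates w.r.t. site positions ---------

# gradient of the angle at p2 over (p1,p2,p3); returns 3 x 3 matrix, one row
# per point.  Degenerate (collinear) triplets are regularized by clamping
# sin(theta).
angle_grad <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
  cth <- sum(u * v) / (lu * lv)
  cth <- pmin(1, pmax(-1, cth))
  sth <- max(sqrt(1 - cth^2), 1e-10)
  g1 <- -(v / lv - cth * u / lu) / (lu * sth)
  g3 <- -(u / lu - cth * v / lv) / (lv * sth)
  rbind(g1, -(g1 + g3), g3)
}

# gradient of the signed dihedral over (p1..p4); 4 x 3 matrix.
dihedral_grad <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  lb2 <- sqrt(sum(b2^2))
  n1sq <- sum(n1^2); n2sq <- sum(n2^2)
  g1 <- -lb2 / n1sq * n1
  g4 <- lb2 / n2sq * n2
  t1 <- -sum(b1 * b2) / sum(b2^2)
  t3 <- -sum(b3 * b2) / sum(b2^2)
  g2 <- (t1 - 1) * g1 - t3 * g4
  g3 <- (t3 - 1) * g4 - t1 * g1
  rbind(g1, g2, g3, g4)
}

#' Surrogate coarse-grained potential configuration
#'
#' Parameters of the pluggable bonded + excluded-volume potential used in
#' place of a full physics-based coarse-grained force field.  The functional
#' form covers the same term taxonomy (virtual-bond stretching, virtual-bond
#' angle bending, optional backbone torsion, pairwise repulsion) but its
#' parameters are generic, temperature-independent surrogates.  All
#' harmonic terms use the 1/2 k x^2 convention.
#'
#' @param k_bond bond stiffness, kcal/(mol Angstrom^2).
#' @param d0 equilibrium virtual-bond length, Angstrom.
#' @param k_theta virtual-bond-angle stiffness, kcal/(mol rad^2).
#' @param theta0 equilibrium virtual-bond angle, rad.
#' @param eps_rep excluded-volume strength, kcal/mol.
#' @param r_rep excluded-volume radius, Angstrom; the repulsion
#'   eps_rep (1 - (r/r_rep)^2)^2 vanishes with continuous derivative at
#'   r = r_rep.
#' @param tor_c1,tor_c2 optional torsional coefficients of
#'   c1 (1 - cos g) + c2 (1 - cos 2g); c2 > 0 creates a double well with
#'   minima at g = 0 and pi and barrier 2 c2.  Either a scalar (applied to
#'   every dihedral) or one value per dihedral (length n_res - 3), which
#'   allows heterogeneous backbone rigidity.
#' @return A `potential_config` list.
#' @export
potential_config <- function(k_bond = 50, d0 = 3.8, k_theta = 10,
                             theta0 = 110 * pi / 180, eps_rep = 2,
                             r_rep = 4.0, tor_c1 = 0, tor_c2 = 0) {
  stopifnot(k_bond >= 0, k_theta >= 0, eps_rep >= 0, r_rep > 0, d0 > 0)
  structure(list(k_bond = k_bond, d0 = d0, k_theta = k_theta,
                 theta0 = theta0, eps_rep = eps_rep, r_rep = r_rep,
                 tor_c1 = tor_c1, tor_c2 = tor_c2),
            class = "potential_config")
}

#' Surrogate potential energy and forces
#'
#' Evaluates the surrogate coarse-grained potential on the C-alpha trace
#' and returns the exact negative gradient.  The potential is invariant
#' under rigid-body motion, so the total force and the total torque about
#' the centroid vanish.
#'
#' @param chain a [cg_chain()].
#' @param cfg a [potential_config()].
#' @return A list with `energy` (kcal/mol) and `forces` (n x 3,
#'   kcal/(mol Angstrom)).
#' @export
energy_and_forces <- function(chain, cfg = potential_config()) {
  stopifnot(inherits(chain, "cg_chain"), inherits(cfg, "potential_config"))
  if (!all(is.finite(chain$ca))) stop("non-finite coordinates")
  res <- surrogate_ef_cpp(chain$ca, unclass(cfg))
  list(energy = res$energy, forces = res$forces)
}
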