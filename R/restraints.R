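# numerically safe log(cosh(x))
logcosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)

#' Flat-bottom distance restraint penalty
#'
#' Zero inside \[d_l, d_u\]; outside, a quartic wall
#' A x^4 / (sigma^4 + x^4) (1 + kappa log cosh x) with x the distance to
#' the nearer boundary.  The wall saturates at depth A and, through the
#' log-cosh factor, acquires an asymptotically linear tail of slope
#' A kappa, so that far-violated restraints pull with a constant, bounded
#' force.  The default parameters (A = 5 kcal/mol, sigma = 1 Angstrom,
#' kappa = 0.01) are the values used throughout the package.
#'
#' @param d distance(s), Angstrom.
#' @param lower,upper flat-bottom boundaries d_l <= d_u, Angstrom.
#' @param A well depth, kcal/mol.
#' @param sigma wall thickness, Angstrom.
#' @param kappa asymptotic slope factor (dimensionless).
#' @return Penalty energy (kcal/mol), vectorized over `d`.
#' @examples
#' v_dist(3.0, 2.5, 4.0)               # inside: 0
#' v_dist(5.0, 2.5, 4.0)               # one Angstrom past the upper bound
#' @export
v_dist <- function(d, lower, upper, A = 5, sigma = 1, kappa = 0.01) {
  x <- ifelse(d < lower, d - lower, ifelse(d > upper, d - upper, 0))
  x4 <- x^4
  ifelse(x == 0, 0, A * x4 / (sigma^4 + x4) * (1 + kappa * logcosh(x)))
}

#' Derivative of the flat-bottom distance penalty
#'
#' Exact d/dd of [v_dist()]: zero inside the flat bottom and at both
#' boundaries (the wall is quartically tangent), continuous everywhere.
#'
#' @inheritParams v_dist
#' @return dV/dd in kcal/(mol Angstrom), vectorized over `d`.
#' @export
v_dist_deriv <- function(d, lower, upper, A = 5, sigma = 1, kappa = 0.01) {
  x <- ifelse(d < lower, d - lower, ifelse(d > upper, d - upper, 0))
  x4 <- x^4
  den <- sigma^4 + x4
  u <- x4 / den
  up <- 4 * x^3 * sigma^4 / den^2
  w <- 1 + kappa * logcosh(x)
  wp <- kappa * tanh(x)
  ifelse(x == 0, 0, A * (up * w + u * wp))
}

#' Signed offset of an angle from a restraint-window midpoint
#'
#' Maps an angular observable x into the periodic frame of the window
#' \[x_l, x_u\]: delta = (x - (x_l + x_u)/2) wrapped to (-pi, pi].  The
#' restraint is satisfied when |delta| <= (x_u - x_l)/2.
#'
#' @param x angle(s), rad.
#' @param x_l,x_u window boundaries, rad, with width x_u - x_l in \[0, 2 pi).
#' @return delta in (-pi, pi], vectorized over `x`.
#' @export
wrap_delta <- function(x, x_l, x_u) {
  if (any(x_u - x_l < 0) || any(x_u - x_l >= 2 * pi))
    stop("angular window width must lie in [0, 2*pi)")
  wrap_angle(x - (x_l + x_u) / 2)
}

#' Flat-bottom angular restraint penalty
#'
#' Zero when the wrapped offset delta from the window midpoint satisfies
#' |delta| <= h with h = (x_u - x_l)/2; outside, a quartic wall.  The
#' default wall is the continuous excess form amplitude (|delta| - h)^4/4,
#' whose value and first derivative vanish at the boundary.  With
#' `compat = TRUE` the wall is amplitude delta^4/4 immediately outside the
#' window, which jumps by amplitude h^4/4 at the boundary; it is provided
#' for comparison only and is unsuitable for dynamics.
#'
#' @param x angle(s), rad.
#' @param x_l,x_u window boundaries, rad.
#' @param amplitude well amplitude, kcal/mol (1 for virtual-bond angles,
#'   5 for virtual-bond dihedrals by package default).
#' @param compat use the discontinuous delta^4/4 wall.
#' @return Penalty energy (kcal/mol), vectorized over `x`.
#' @export
v_ang <- function(x, x_l, x_u, amplitude = 1, compat = FALSE) {
  d <- wrap_delta(x, x_l, x_u)
  h <- (x_u - x_l) / 2
  if (compat) {
    ifelse(abs(d) <= h, 0, amplitude * d^4 / 4)
  } else {
    e <- pmax(abs(d) - h, 0)
    amplitude * e^4 / 4
  }
}

#' Derivative of the angular restraint penalty
#'
#' Exact d/dx of [v_ang()] (away from the wrap point of delta).
#'
#' @inheritParams v_ang
#' @return dV/dx in kcal/(mol rad), vectorized over `x`.
#' @export
v_ang_deriv <- function(x, x_l, x_u, amplitude = 1, compat = FALSE) {
  d <- wrap_delta(x, x_l, x_u)
  h <- (x_u - x_l) / 2
  if (compat) {
    ifelse(abs(d) <= h, 0, amplitude * d^3)
  } else {
    e <- pmax(abs(d) - h, 0)
    amplitude * e^3 * sign(d)
  }
}

# restraint records --------------------------------------------------------

#' Distance restraint record
#'
#' @param i_res,j_res 1-based residue indices of the restrained pair.
#' @param lower,upper distance boundaries, Angstrom, 0 <= lower <= upper.
#' @param i_site,j_site site kind per residue: "CA" or "SC".
#' @param A,sigma,kappa penalty parameters, see [v_dist()].
#' @param m replica-averaging exponent (3 for distances).
#' @return One-row `restraint_set` data frame.
#' @export
distance_restraint <- function(i_res, j_res, lower, upper,
                               i_site = "CA", j_site = "CA",
                               A = 5, sigma = 1, kappa = 0.01, m = 3) {
  stopifnot(lower >= 0, lower <= upper, A > 0, sigma > 0, kappa >= 0)
  restraint_set(data.frame(kind = "dist", i_res = as.integer(i_res),
                           i_site = i_site, j_res = as.integer(j_res),
                           j_site = j_site, lower = lower, upper = upper,
                           amplitude = A, sigma = sigma, kappa = kappa,
                           m = m, stringsAsFactors = FALSE))
}

#' Angular (theta or gamma) restraint record
#'
#' @param kind "theta" (virtual-bond angle i over residues i..i+2) or
#'   "gamma" (virtual-bond dihedral i over residues i..i+3).
#' @param index 1-based internal-coordinate index.
#' @param lower,upper window boundaries, rad, width in \[0, 2 pi).
#' @param amplitude penalty amplitude, kcal/mol; defaults to 1 for theta
#'   and 5 for gamma.
#' @param m replica-averaging exponent (-1, i.e. arithmetic averaging, for
#'   angle-dependent observables).
#' @return One-row `restraint_set` data frame.
#' @export
angle_restraint <- function(kind = c("theta", "gamma"), index, lower, upper,
                            amplitude = NULL, m = -1) {
  kind <- match.arg(kind)
  if (is.null(amplitude)) amplitude <- if (kind == "theta") 1 else 5
  stopifnot(amplitude > 0, upper - lower >= 0, upper - lower < 2 * pi)
  restraint_set(data.frame(kind = kind, i_res = as.integer(index),
                           i_site = NA_character_, j_res = NA_integer_,
                           j_site = NA_character_, lower = lower,
                           upper = upper, amplitude = amplitude,
                           sigma = NA_real_, kappa = NA_real_, m = m,
                           stringsAsFactors = FALSE))
}

#' Combine restraint records into a restraint set
#'
#' @param ... `restraint_set` objects or data frames with the restraint
#'   columns (kind, i_res, i_site, j_res, j_site, lower, upper, amplitude,
#'   sigma, kappa, m).
#' @return A `restraint_set` data frame.
#' @export
restraint_set <- function(...) {
  parts <- list(...)
  rs <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(rs) <- NULL
  bad <- which(rs$lower > rs$upper)
  if (length(bad)) stop("lower > upper in restraint row(s) ", paste(bad, collapse = ", "))
  if (!all(rs$kind %in% c("dist", "theta", "gamma")))
    stop("unknown restraint kind")
  class(rs) <- c("restraint_set", "data.frame")
  rs
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("restraint_set: %d restraints (%d dist, %d theta, %d gamma)\n",
              nrow(x), sum(x$kind == "dist"), sum(x$kind == "theta"),
              sum(x$kind == "gamma")))
  invisible(x)
}

# default site mapping: resolve (i_res, site kind) to a coordinate row
resolve_site <- function(chain, i_res, site) {
  if (is.na(i_res) || i_res < 1L || i_res > chain$n_res)
    stop("restraint references residue ", i_res, " outside the chain")
  if (identical(site, "SC")) {
    if (is.null(chain$sc))
      stop("restraint maps to an SC site but the chain has no side-chain centers")
    list(coord = chain$sc[i_res, ], kind = "sc", index = i_res)
  } else {
    list(coord = chain$ca[i_res, ], kind = "ca", index = i_res)
  }
}

#' Observable values of a restraint set on a chain
#'
#' Evaluates, for each restraint in order, the restrained observable on the
#' chain: the Euclidean distance between the mapped sites for distance
#' restraints, the virtual-bond angle or dihedral for angular restraints.
#'
#' @param chain a [cg_chain()].
#' @param restraints a [restraint_set()].
#' @param mapping site-resolution function with signature
#'   `(chain, i_res, site)`; the default maps "CA" to the C-alpha site and
#'   "SC" to the side-chain center.
#' @return Numeric vector (Angstrom for distances, rad for angles), one
#'   value per restraint.
#' @export
observe_restraints <- function(chain, restraints, mapping = resolve_site) {
  stopifnot(inherits(chain, "cg_chain"))
  ic <- NULL
  vapply(seq_len(nrow(restraints)), function(r) {
    row <- restraints[r, ]
    if (row$kind == "dist") {
      a <- mapping(chain, row$i_res, row$i_site)
      b <- mapping(chain, row$j_res, row$j_site)
      sqrt(sum((a$coord - b$coord)^2))
    } else {
      if (is.null(ic)) ic <<- internal_coords(chain)
      vals <- if (row$kind == "theta") ic$thetas else ic$gammas
      if (row$i_res < 1L || row$i_res > length(vals))
        stop("restraint ", r, ": ", row$kind, " index ", row$i_res,
             " outside the chain")
      vals[row$i_res]
    }
  }, numeric(1))
}

# per-restraint penalty and derivative at given observable values
penalty_value <- function(restraints, y, compat = FALSE) {
  vapply(seq_len(nrow(restraints)), function(r) {
    row <- restraints[r, ]
    if (row$kind == "dist")
      v_dist(y[r], row$lower, row$upper, row$amplitude, row$sigma, row$kappa)
    else v_ang(y[r], row$lower, row$upper, row$amplitude, compat)
  }, numeric(1))
}

penalty_deriv <- function(restraints, y, compat = FALSE) {
  vapply(seq_len(nrow(restraints)), function(r) {
    row <- restraints[r, ]
    if (row$kind == "dist")
      v_dist_deriv(y[r], row$lower, row$upper, row$amplitude, row$sigma, row$kappa)
    else v_ang_deriv(y[r], row$lower, row$upper, row$amplitude, compat)
  }, numeric(1))
}

# gradient of observable r w.r.t. the sites it touches; returns a list of
# (site kind, residue index, 3-vector) contributions
observable_grad <- function(chain, row, mapping = resolve_site) {
  if (row$kind == "dist") {
    a <- mapping(chain, row$i_res, row$i_site)
    b <- mapping(chain, row$j_res, row$j_site)
    dv <- a$coord - b$coord
    d <- sqrt(sum(dv^2))
    if (d == 0) stop("coincident restrained sites")
    u <- dv / d
    list(list(kind = a$kind, index = a$index, g = u),
         list(kind = b$kind, index = b$index, g = -u))
  } else if (row$kind == "theta") {
    i <- row$i_res
    G <- angle_grad(chain$ca[i, ], chain$ca[i + 1L, ], chain$ca[i + 2L, ])
    lapply(0:2, function(k) list(kind = "ca", index = i + k, g = G[k + 1L, ]))
  } else {
    i <- row$i_res
    G <- dihedral_grad(chain$ca[i, ], chain$ca[i + 1L, ],
                       chain$ca[i + 2L, ], chain$ca[i + 3L, ])
    lapply(0:3, function(k) list(kind = "ca", index = i + k, g = G[k + 1L, ]))
  }
}

#' Total restraint penalty and forces on a single chain
#'
#' Sums the distance and angular penalty terms over a restraint set and
#' returns the exact negative gradient with respect to the site positions
#' (chain rule through the mapped distances and the internal coordinates).
#'
#' @inheritParams observe_restraints
#' @param compat use the discontinuous angular wall (see [v_ang()]).
#' @return List with `energy` (kcal/mol), `forces` (n x 3 on C-alpha
#'   sites), and `forces_sc` (n x 3 on side-chain sites, NULL when the
#'   chain has none).
#' @export
restraint_energy_forces <- function(chain, restraints, mapping = resolve_site,
                                    compat = FALSE) {
  n <- chain$n_res
  fca <- matrix(0, n, 3L)
  fsc <- if (is.null(chain$sc)) NULL else matrix(0, n, 3L)
  y <- observe_restraints(chain, restraints, mapping)
  V <- penalty_value(restraints, y, compat)
  dV <- penalty_deriv(restraints, y, compat)
  for (r in seq_len(nrow(restraints))) {
    if (dV[r] == 0) next
    for (contrib in observable_grad(chain, restraints[r, ], mapping)) {
      f <- -dV[r] * contrib$g
      if (contrib$kind == "ca") fca[contrib$index, ] <- fca[contrib$index, ] + f
      else fsc[contrib$index, ] <- fsc[contrib$index, ] + f
    }
  }
  list(energy = sum(V), forces = fca, forces_sc = fsc)
}
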