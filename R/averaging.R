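#' Inverse-power replica average
#'
#' The replica-averaged observable over M simultaneously running copies is
#' the power mean ybar = \[ (1/M) sum_j y_j^(-m) \]^(-1/m).  For
#' interproton-style distances m = 3, so short distances dominate, as they
#' do in NOE intensities; for angle-dependent observables m = -1, reducing
#' the expression to the arithmetic mean.
#'
#' @param values numeric vector of per-replica observable values (Angstrom
#'   or rad); must be strictly positive when m > 0.
#' @param m averaging exponent (nonzero).
#' @return The replica average (same units as `values`).
#' @examples
#' full_average(c(2, 4), m = 3)    # 2.4217...: short distance dominates
#' full_average(c(2, 4), m = -1)   # 3: arithmetic mean
#' @export
full_average <- function(values, m = 3) {
  if (m == 0) stop("averaging exponent must be nonzero")
  if (m > 0 && any(values <= 0))
    stop("inverse-power averaging with m > 0 requires positive values")
  M <- length(values)
  if (M < 1L) stop("need at least one replica value")
  (mean(values^(-m)))^(-1 / m)
}

#' Circular replica average of a dihedral
#'
#' Dihedral angles are averaged through their sines and cosines: the
#' arithmetic means of sin(g) and cos(g) are combined with the
#' two-argument arctangent, giving a wrap-correct average in (-pi, pi].
#'
#' @param angles numeric vector of per-replica dihedrals, rad.
#' @return Average angle in (-pi, pi].
#' @export
dihedral_average <- function(angles) {
  if (length(angles) < 1L) stop("need at least one replica value")
  s <- mean(sin(angles)); c <- mean(cos(angles))
  if (abs(s) < 1e-12 && abs(c) < 1e-12)
    stop("degenerate dihedral average: sine and cosine means both vanish")
  g <- atan2(s, c)
  if (g == -pi) pi else g
}

#' Partial (per-replica) update of the replica average
#'
#' Between full synchronisation points the average at replica J is
#' refreshed with that replica's current observable only; the other
#' replicas' contributions stay frozen at their values from the last full
#' update, carried as the power sum S_foreign = sum_(j != J) y_j^(-m).
#'
#' @param S_foreign frozen foreign power sum (units of y^(-m)).
#' @param y_own current observable at replica J.
#' @param M number of replicas in the averaging group.
#' @param m averaging exponent.
#' @return The partially updated average ybar^(J).
#' @export
partial_average <- function(S_foreign, y_own, M, m = 3) {
  if (m == 0) stop("averaging exponent must be nonzero")
  if (m > 0 && any(y_own <= 0))
    stop("inverse-power averaging with m > 0 requires positive values")
  if (M == 1L) return(y_own)  # exact: a lone replica averages to itself
  ((S_foreign + y_own^(-m)) / M)^(-1 / m)
}

# scalar d(ybar^(J)) / d(y_own), the exact derivative of partial_average
# with the foreign sum frozen
averaged_gradient_factor <- function(y_own, y_bar, M, m = 3) {
  if (M == 1L) return(rep(1, length(y_own)))
  (1 / M) * (y_bar / y_own)^(m + 1)
}

#' Gradient of the partially updated replica average
#'
#' Differentiating the partial update with the foreign power sum frozen
#' gives grad ybar^(J) = (1/M) (ybar^(J) / y_J)^(m+1) grad y_J.  For M = 1
#' the factor is exactly 1.
#'
#' @param y_own current observable at replica J.
#' @param y_bar the partially updated average from [partial_average()].
#' @param grad_y_own gradient of y_own w.r.t. the replica's coordinates
#'   (any numeric array; multiplied by the scalar factor).
#' @param M replicas in the averaging group.
#' @param m averaging exponent.
#' @return grad ybar^(J), same shape as `grad_y_own`.
#' @export
averaged_gradient <- function(y_own, y_bar, grad_y_own, M, m = 3) {
  averaged_gradient_factor(y_own, y_bar, M, m) * grad_y_own
}

# frozen replica-averaging state ------------------------------------------

#' Full averaging update over a replica ensemble
#'
#' Captures, from the current coordinates of all M replicas, the
#' per-restraint observables and the frozen foreign sums each replica
#' carries until the next full update: power sums sum_(j != J) y_j^(-m)
#' for distance and theta observables, sine and cosine sums for dihedrals.
#'
#' @param chains list of M [cg_chain()]s (the replicas).
#' @param restraints a [restraint_set()].
#' @param mapping site-resolution function, see [observe_restraints()].
#' @param step step index at which the update takes place (bookkeeping).
#' @return A `replica_observables` object with fields `y` (M x n_restraints
#'   matrix), `S_foreign`, `sin_foreign`, `cos_foreign`, `M`, `t_K`.
#' @export
full_update <- function(chains, restraints, mapping = resolve_site, step = 0L) {
  M <- length(chains)
  y <- t(vapply(chains, observe_restraints, numeric(nrow(restraints)),
                restraints = restraints, mapping = mapping))
  if (M == 1L) y <- matrix(y, nrow = 1L)
  nr <- nrow(restraints)
  S <- matrix(NA_real_, M, nr)
  Ssin <- matrix(NA_real_, M, nr)
  Scos <- matrix(NA_real_, M, nr)
  for (i in seq_len(nr)) {
    if (restraints$kind[i] == "gamma") {
      s <- sin(y[, i]); c <- cos(y[, i])
      for (J in seq_len(M)) {
        Ssin[J, i] <- sum(s[-J]); Scos[J, i] <- sum(c[-J])
      }
    } else {
      m <- restraints$m[i]
      p <- y[, i]^(-m)
      for (J in seq_len(M)) S[J, i] <- sum(p[-J])
    }
  }
  structure(list(y = y, S_foreign = S, sin_foreign = Ssin,
                 cos_foreign = Scos, M = M, t_K = as.integer(step)),
            class = "replica_observables")
}

#' Replica-averaged restraint energies and forces
#'
#' For each replica J, evaluates every penalty at the partially updated
#' average ybar^(J) (frozen foreign sums from `frozen`, current own
#' observable) and returns the per-replica forces
#' -M V'(ybar^(J)) grad ybar^(J), i.e. with the gradient scaled up by the
#' number of replicas so restraint forces do not fade as M grows.  The
#' reported energy is the unscaled sum of penalties unless `scale_energy`
#' is set (then multiplied by M, the convention used for microcanonical
#' energy-conservation checks, where the scaled energy is the conserved
#' quantity).
#'
#' Because the foreign sums are frozen, ybar^(J) depends on replica J's
#' coordinates only, so between full updates each replica moves in a
#' well-defined potential; this is what makes replica-averaged NVE
#' dynamics segment-symplectic.
#'
#' @param chains list of M [cg_chain()]s.
#' @param restraints a [restraint_set()].
#' @param frozen a `replica_observables` from [full_update()]; defaults to
#'   a fresh full update at the current coordinates.
#' @param scale_energy also multiply the reported energies by M.
#' @param mapping site-resolution function.
#' @param compat discontinuous angular wall (see [v_ang()]).
#' @return List with `energy` (length-M vector) and `forces` (list of M
#'   n x 3 matrices on the C-alpha sites).
#' @export
scaled_restraint_forces <- function(chains, restraints,
                                    frozen = full_update(chains, restraints, mapping),
                                    scale_energy = FALSE,
                                    mapping = resolve_site, compat = FALSE) {
  M <- length(chains)
  stopifnot(frozen$M == M)
  energies <- numeric(M)
  forces <- vector("list", M)
  for (J in seq_len(M)) {
    chain <- chains[[J]]
    if (M == 1L) {
      ef <- restraint_energy_forces(chain, restraints, mapping, compat)
      energies[J] <- ef$energy
      forces[[J]] <- ef$forces
      next
    }
    y_own <- observe_restraints(chain, restraints, mapping)
    n <- chain$n_res
    f <- matrix(0, n, 3L)
    V <- 0
    for (i in seq_len(nrow(restraints))) {
      row <- restraints[i, ]
      if (row$kind == "gamma") {
        sbar <- (frozen$sin_foreign[J, i] + sin(y_own[i])) / M
        cbar <- (frozen$cos_foreign[J, i] + cos(y_own[i])) / M
        ybar <- atan2(sbar, cbar)
        fac <- (cbar * cos(y_own[i]) + sbar * sin(y_own[i])) /
          (M * (sbar^2 + cbar^2))
        Vi <- v_ang(ybar, row$lower, row$upper, row$amplitude, compat)
        dVi <- v_ang_deriv(ybar, row$lower, row$upper, row$amplitude, compat)
      } else {
        ybar <- partial_average(frozen$S_foreign[J, i], y_own[i], M, row$m)
        fac <- averaged_gradient_factor(y_own[i], ybar, M, row$m)
        if (row$kind == "dist") {
          Vi <- v_dist(ybar, row$lower, row$upper, row$amplitude, row$sigma, row$kappa)
          dVi <- v_dist_deriv(ybar, row$lower, row$upper, row$amplitude,
                              row$sigma, row$kappa)
        } else {
          Vi <- v_ang(ybar, row$lower, row$upper, row$amplitude, compat)
          dVi <- v_ang_deriv(ybar, row$lower, row$upper, row$amplitude, compat)
        }
      }
      V <- V + Vi
      if (dVi != 0) {
        for (contrib in observable_grad(chain, row, mapping)) {
          if (contrib$kind != "ca")
            stop("replica-averaged dynamics supports C-alpha-mapped restraints only")
          f[contrib$index, ] <- f[contrib$index, ] - M * dVi * fac * contrib$g
        }
      }
    }
    energies[J] <- if (scale_energy) M * V else V
    forces[[J]] <- f
  }
  list(energy = energies, forces = forces)
}

#' Indicator weights for temperature-resolved replica averaging
#'
#' Under multiplexed temperature replica exchange, only the replicas
#' currently running at a given ladder temperature contribute to the
#' average computed at that temperature: each of the M co-located replicas
#' carries weight 1/M and every other replica weight 0, so the weights at
#' every temperature sum to exactly 1.
#'
#' @param assignment integer/numeric vector mapping each replica to its
#'   current ladder temperature (K).
#' @param M multiplexing: replicas per temperature (identical at every
#'   temperature).
#' @return Matrix of weights, one row per replica, one column per distinct
#'   ladder temperature (columns named by temperature).
#' @export
temperature_weights <- function(assignment, M) {
  temps <- sort(unique(assignment))
  counts <- table(assignment)
  if (any(counts != M))
    stop("unequal multiplexing: every temperature must host exactly M replicas")
  w <- vapply(temps, function(T) ifelse(assignment == T, 1 / M, 0),
              numeric(length(assignment)))
  colnames(w) <- as.character(temps)
  w
}
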