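#' Molecular-dynamics state for the single-system integrators
#'
#' A lightweight container for the R-level one-step integrators
#' [nve_step()] and [langevin_step()], which accept an arbitrary force
#' closure.  Units follow the package convention: coordinates in Angstrom,
#' velocities in Angstrom/fs, masses in amu, energies in kcal/mol
#' (accelerations are converted internally with
#' 1 kcal/(mol Angstrom)/amu = 4.184e-4 Angstrom/fs^2).
#'
#' @param x coordinates (numeric vector or matrix).
#' @param v velocities, same shape as `x`.
#' @param mass particle mass(es) in amu: scalar or one per row of `x`.
#' @return An `md_state` list with fields `x`, `v`, `mass`, `step`,
#'   `forces` (lazily filled), `energy`.
#' @export
md_state <- function(x, v, mass = 110) {
  stopifnot(all(is.finite(x)), all(is.finite(v)))
  structure(list(x = x, v = v, mass = mass, step = 0L,
                 forces = NULL, energy = NA_real_),
            class = "md_state")
}

# broadcast per-particle mass over coordinate layout
mass_like <- function(x, mass) {
  if (is.matrix(x)) {
    if (length(mass) == 1L) matrix(mass, nrow(x), ncol(x))
    else matrix(mass, nrow(x), ncol(x))
  } else rep_len(mass, length(x))
}

eval_force_fn <- function(force_fn, x, step) {
  res <- force_fn(x)
  if (!is.list(res) || is.null(res$forces))
    stop("force_fn must return list(energy=, forces=)")
  if (!all(is.finite(res$forces)))
    stop("non-finite force at step ", step)
  res
}

#' One velocity-Verlet (NVE) step
#'
#' Symplectic, time-reversible velocity Verlet.  `force_fn(x)` must return
#' `list(energy=, forces=)` with forces in kcal/(mol Angstrom) and must
#' not depend on time between calls (between full-averaging points, for
#' replica-averaged force closures).
#'
#' @param state an [md_state()].
#' @param force_fn force closure.
#' @param dt time step, fs.
#' @return Updated `md_state` (with `forces` and `energy` caches).
#' @export
nve_step <- function(state, force_fn, dt) {
  m <- mass_like(state$x, state$mass)
  if (is.null(state$forces))
    state[c("energy", "forces")] <- eval_force_fn(force_fn, state$x, state$step)[c("energy", "forces")]
  v <- state$v + 0.5 * dt * state$forces * .accel_conv / m
  x <- state$x + dt * v
  ef <- eval_force_fn(force_fn, x, state$step + 1L)
  v <- v + 0.5 * dt * ef$forces * .accel_conv / m
  state$x <- x; state$v <- v
  state$forces <- ef$forces; state$energy <- ef$energy
  state$step <- state$step + 1L
  state
}

#' One BAOAB Langevin (NVT) step
#'
#' Splitting-scheme Langevin integrator with an exact Ornstein-Uhlenbeck
#' velocity update in the middle (B-A-O-A-B).  With `friction = 0` the
#' step reduces exactly to [nve_step()] and no random numbers are drawn.
#' Noise comes from R's RNG, so a fixed seed reproduces the trajectory.
#'
#' @inheritParams nve_step
#' @param friction friction coefficient, 1/fs (>= 0).
#' @param temperature thermostat target, K.
#' @return Updated `md_state`.
#' @export
langevin_step <- function(state, force_fn, dt, friction, temperature) {
  stopifnot(friction >= 0)
  if (friction == 0) return(nve_step(state, force_fn, dt))
  m <- mass_like(state$x, state$mass)
  if (is.null(state$forces))
    state[c("energy", "forces")] <- eval_force_fn(force_fn, state$x, state$step)[c("energy", "forces")]
  c1 <- exp(-friction * dt)
  sig <- sqrt((1 - c1^2) * .kB * temperature * .accel_conv / m)
  v <- state$v + 0.5 * dt * state$forces * .accel_conv / m
  x <- state$x + 0.5 * dt * v
  v <- c1 * v + sig * array(rnorm(length(v)), dim = dim(m) %||% length(v))
  x <- x + 0.5 * dt * v
  ef <- eval_force_fn(force_fn, x, state$step + 1L)
  v <- v + 0.5 * dt * ef$forces * .accel_conv / m
  state$x <- x; state$v <- v
  state$forces <- ef$forces; state$energy <- ef$energy
  state$step <- state$step + 1L
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maxwell-Boltzmann velocities
#'
#' @param n number of sites.
#' @param temperature K.
#' @param mass amu.
#' @return n x 3 matrix of velocities (Angstrom/fs) drawn from R's RNG.
#' @export
maxwell_velocities <- function(n, temperature, mass = 110) {
  sig <- sqrt(.kB * temperature * .accel_conv / mass)
  matrix(rnorm(3 * n, sd = sig), n, 3L)
}

#' Local energy minimization of a chain
#'
#' L-BFGS minimization of the surrogate potential plus (optionally) the
#' non-averaged restraint penalty, using the analytic gradient.
#'
#' @param chain a [cg_chain()].
#' @param potential a [potential_config()].
#' @param restraints optional [restraint_set()] added to the objective.
#' @param gtol target max-norm of the gradient, kcal/(mol Angstrom).
#' @param maxit iteration cap per L-BFGS call.
#' @param rounds number of restarted L-BFGS calls allowed to reach `gtol`.
#' @return List with `chain` (minimized), `energy`, `gmax` (final gradient
#'   max-norm) and `converged`.
#' @export
minimize_chain <- function(chain, potential = potential_config(),
                           restraints = NULL, gtol = 1e-4, maxit = 500L,
                           rounds = 10L) {
  n <- chain$n_res
  # fast path: CA-only restraints evaluate in compiled code
  ca_only <- is.null(restraints) || nrow(restraints) == 0L ||
    all(restraints$kind != "dist" |
          (restraints$i_site == "CA" & restraints$j_site == "CA"))
  rmat <- if (ca_only) restraints_to_matrix(restraints, n)
  obj <- function(par) {
    xm <- matrix(par, n, 3L)
    if (ca_only) {
      e <- surrogate_ef_cpp(xm, unclass(potential))
      if (nrow(rmat)) {
        r <- restraint_ef_cpp(xm, rmat, FALSE)
        list(energy = e$energy + r$energy, forces = e$forces + r$forces)
      } else e
    } else {
      ch <- cg_chain(xm, sequence = chain$sequence)
      e <- energy_and_forces(ch, potential)
      r <- restraint_energy_forces(ch, restraints)
      list(energy = e$energy + r$energy, forces = e$forces + r$forces)
    }
  }
  par <- as.vector(chain$ca)
  if (!is.finite(obj(par)$energy)) stop("non-finite starting energy")
  energy <- NA_real_; gmax <- Inf
  for (k in seq_len(rounds)) {
    fit <- stats::optim(par,
                        fn = function(p) obj(p)$energy,
                        gr = function(p) -as.vector(obj(p)$forces),
                        method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 10))
    par <- fit$par
    res <- obj(par)
    energy <- res$energy
    gmax <- max(abs(res$forces))
    if (gmax < gtol) break
  }
  list(chain = cg_chain(matrix(par, n, 3L), sequence = chain$sequence),
       energy = energy, gmax = gmax, converged = gmax < gtol)
}

#' Averaging/exchange/snapshot schedule
#'
#' @param n_ave steps between full replica-averaging updates (default 100).
#' @param n_exch steps between temperature-exchange attempts (default
#'   10000); must be a multiple of `n_ave`.
#' @param n_snap steps between stored snapshots.
#' @return An `averaging_schedule` list.
#' @export
averaging_schedule <- function(n_ave = 100L, n_exch = 10000L, n_snap = 10000L) {
  n_ave <- as.integer(n_ave); n_exch <- as.integer(n_exch)
  n_snap <- as.integer(n_snap)
  stopifnot(n_ave >= 1L, n_exch >= 1L, n_snap >= 1L)
  if (n_exch %% n_ave != 0L)
    stop("n_ave must divide n_exch (full averages must align with exchanges)")
  structure(list(n_ave = n_ave, n_exch = n_exch, n_snap = n_snap),
            class = "averaging_schedule")
}

# convert a restraint_set to the numeric matrix the compiled core consumes
restraints_to_matrix <- function(restraints, n_res) {
  if (is.null(restraints) || nrow(restraints) == 0L)
    return(matrix(0, 0L, 9L))
  if (any(restraints$kind == "dist" &
          (restraints$i_site != "CA" | restraints$j_site != "CA")))
    stop("the dynamics core propagates C-alpha sites only; SC-mapped restraints are not supported in MD")
  type <- match(restraints$kind, c("dist", "theta", "gamma")) - 1L
  a <- restraints$i_res - 1L
  b <- ifelse(is.na(restraints$j_res), 0L, restraints$j_res - 1L)
  last_atom <- a + c(0L, 2L, 3L)[type + 1L]  # distance pairs checked below
  if (any(a < 0L) || any(last_atom > n_res - 1L) ||
      any(type == 0L & (b < 0L | b > n_res - 1L)))
    stop("restraint site index outside the chain")
  m <- cbind(type, a, b,
             restraints$lower, restraints$upper, restraints$amplitude,
             ifelse(is.na(restraints$sigma), 1, restraints$sigma),
             ifelse(is.na(restraints$kappa), 0, restraints$kappa),
             restraints$m)
  storage.mode(m) <- "double"
  m
}

#' Run a (replica-averaged) restrained MD trajectory
#'
#' Integrates M replicas of the chain under the surrogate potential plus
#' the restraint penalties.  With `averaging = TRUE` and M > 1, the
#' penalties act on the inverse-power replica averages: full updates are
#' synchronised every `n_ave` steps (averaging activates at step `n_ave`;
#' before that each replica is restrained by its own observables) and the
#' per-replica forces carry the M-fold gradient scaling.  `mode = "nve"`
#' runs microcanonical velocity Verlet; `mode = "nvt"` runs BAOAB Langevin
#' dynamics.  All randomness (initial velocities, thermostat noise) comes
#' from R's RNG seeded with `seed`.
#'
#' @param chains list of M starting [cg_chain()]s (C-alpha traces).
#' @param restraints a [restraint_set()] (may be empty/NULL).
#' @param potential a [potential_config()].
#' @param steps number of MD steps.
#' @param dt time step, fs.
#' @param mode "nvt" (Langevin) or "nve".
#' @param temperature target (NVT) or initial-velocity (NVE) temperature, K.
#' @param friction Langevin friction, 1/fs.
#' @param mass per-site mass, amu.
#' @param schedule an [averaging_schedule()].
#' @param averaging restrain replica averages (TRUE) or each replica
#'   individually (FALSE).
#' @param scale_energy report restraint energies multiplied by M (the
#'   convention under which the NVE total energy is conserved segmentwise).
#' @param seed integer seed.
#' @param log_every energy-log interval in steps (0 disables).
#' @param velocities optional list of M n x 3 starting-velocity matrices;
#'   drawn from the Maxwell-Boltzmann distribution when NULL.
#' @param step_offset global step counter at entry (multiple of `n_ave`).
#' @return A `rarmd_traj` list: `snapshots` (array frames x M x n x 3),
#'   `snap_steps`, `energy_log` (data frame: step, replica, e_kin, e_pot,
#'   e_restraint, e_total, temperature), `final` (chains + velocities),
#'   `e_pot`, `e_restraint` (per replica, at the final step).
#' @export
run_trajectory <- function(chains, restraints = NULL,
                           potential = potential_config(),
                           steps = 10000L, dt = 4.89,
                           mode = c("nvt", "nve"), temperature = 300,
                           friction = 0.05, mass = 110,
                           schedule = averaging_schedule(n_snap = 1000L),
                           averaging = TRUE, scale_energy = FALSE,
                           seed = NULL, log_every = 0L, velocities = NULL,
                           step_offset = 0L) {
  mode <- match.arg(mode)
  if (inherits(chains, "cg_chain")) chains <- list(chains)
  M <- length(chains)
  n <- chains[[1L]]$n_res
  for (ch in chains) stopifnot(inherits(ch, "cg_chain"), ch$n_res == n)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(velocities))
    velocities <- replicate(M, maxwell_velocities(n, temperature, mass),
                            simplify = FALSE)
  coords <- unlist(lapply(chains, function(ch) as.vector(t(ch$ca))))
  vels <- unlist(lapply(velocities, function(v) as.vector(t(v))))
  rmat <- restraints_to_matrix(restraints, n)
  res <- md_run_core(coords, vels, M, n, unclass(potential), rmat,
                     dt, as.integer(steps), schedule$n_ave, schedule$n_snap,
                     if (mode == "nve") 0 else friction, temperature, mass,
                     averaging, scale_energy, FALSE,
                     as.integer(step_offset), as.integer(log_every))
  unpack_chain <- function(vec, J) {
    nc <- 3L * n
    m <- matrix(vec[((J - 1L) * nc + 1L):(J * nc)], n, 3L, byrow = TRUE)
    cg_chain(m, sequence = chains[[1L]]$sequence)
  }
  nfr <- length(res$snap_steps)
  snaps <- if (nfr > 0)
    aperm(array(res$snapshots, dim = c(3L, n, M, nfr)), c(4L, 3L, 2L, 1L))
  else array(0, dim = c(0L, M, n, 3L))
  elog <- as.data.frame(res$energy_log)
  names(elog) <- c("step", "replica", "e_kin", "e_pot", "e_restraint",
                   "e_total", "temperature")
  structure(list(
    snapshots = snaps, snap_steps = res$snap_steps, energy_log = elog,
    final = list(
      chains = lapply(seq_len(M), function(J) unpack_chain(res$coords, J)),
      velocities = lapply(seq_len(M), function(J) {
        nc <- 3L * n
        matrix(res$vels[((J - 1L) * nc + 1L):(J * nc)], n, 3L, byrow = TRUE)
      })),
    e_pot = res$e_pot, e_restraint = res$e_restraint,
    n_res = n, M = M, mode = mode, dt = dt, steps = steps,
    schedule = schedule), class = "rarmd_traj")
}

#' Extract one snapshot as a chain
#'
#' @param traj a `rarmd_traj` from [run_trajectory()].
#' @param frame snapshot index.
#' @param replica replica index.
#' @return A [cg_chain()].
#' @export
snapshot_chain <- function(traj, frame, replica = 1L) {
  cg_chain(matrix(traj$snapshots[frame, replica, , ], ncol = 3L))
}
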