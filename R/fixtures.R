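#' Generate two related two-state parent conformations
#'
#' Builds the synthetic analogue of a two-state system whose experimental
#' observables are ensemble averages: two energy-minimized conformations
#' of the same chain that share most of their structure but differ by a
#' backbone transition.  Parent 1 is a random self-avoiding trace relaxed
#' to a local minimum of the surrogate potential; parent 2 is obtained by
#' flipping a small set of central virtual-bond dihedrals into the other
#' torsional well (adding pi) and re-minimizing, so that the two states
#' are separated by genuine conformational barriers while most
#' inter-residue distances — and hence most averaged restraints — remain
#' common to both.  The pair is accepted when the mutual C-alpha RMSD
#' reaches `min_separation`, keeping the states unambiguously
#' distinguishable under the 3-Angstrom assignment cutoff; if one flip
#' does not separate them enough, more dihedrals are flipped.
#'
#' @param n_res residue count (>= 8; default 12).
#' @param seed integer seed; the fixture is deterministic per seed.
#' @param potential a [potential_config()]; for a two-state landscape it
#'   should include torsional barriers (see [benchmark_potential()]).
#' @param min_separation required parent1-parent2 RMSD, Angstrom.
#' @param max_tries attempts before giving up.
#' @param restraint_args arguments passed on to [synthesize_restraints()]
#'   when scoring the penalty balance of candidate pairs (use the same
#'   settings the final restraint set will be built with).
#' @return List with `parent1`, `parent2` ([cg_chain()]s), `rmsd`
#'   (their separation), `flipped` (dihedral indices) and `seed`.
#' @export
make_parents <- function(n_res = 12L, seed = 1L,
                         potential = benchmark_potential(),
                         min_separation = 4, max_tries = 50L,
                         restraint_args = list()) {
  stopifnot(n_res >= 8L)
  with_local_seed(seed, {
    best <- NULL
    best_imb <- Inf
    for (k in seq_len(max_tries)) {
      c1 <- random_well_chain(n_res, potential)
      if (is.null(c1)) next
      p1 <- minimize_chain(c1, potential)$chain
      if (min_nonbonded_dist(p1) < 3.0) next
      for (cd in flip_candidates(p1, potential, min_separation)) {
        # prefer the pair whose synthetic restraints penalize the two
        # parents most evenly: a lopsided set collapses the benchmark
        # onto the favored state
        rs <- do.call(synthesize_restraints,
                      c(list(p1, cd$chain), restraint_args))
        v1 <- sum(penalty_value(rs, observe_restraints(p1, rs)))
        v2 <- sum(penalty_value(rs, observe_restraints(cd$chain, rs)))
        imb <- abs(v1 - v2) / max(v1 + v2, 1e-9)
        if (imb < best_imb) {
          best_imb <- imb
          best <- list(parent1 = p1, parent2 = cd$chain, rmsd = cd$rmsd,
                       flipped = cd$flip, seed = seed)
        }
      }
      if (best_imb < 0.25) break
    }
    if (is.null(best))
      stop("could not generate parents separated by ", min_separation,
           " Angstrom in ", max_tries, " attempts")
    best
  })
}

# enumerate single and adjacent-pair dihedral flips of p1 that give a
# clash-free minimized conformer at least min_separation away
flip_candidates <- function(p1, potential, min_separation) {
  n <- p1$n_res
  ic <- internal_coords(p1)
  sets <- c(as.list(seq_len(n - 3L)),
            lapply(seq_len(n - 4L), function(i) c(i, i + 1L)))
  out <- list()
  for (flip in sets) {
    g2 <- ic$gammas
    g2[flip] <- wrap_angle(g2[flip] + pi)
    cand <- chain_from_internals(ic$bond_lengths, ic$thetas, g2,
                                 sequence = p1$sequence)
    if (min_nonbonded_dist(cand) < 2.5) next
    p2 <- minimize_chain(cand, potential)$chain
    r <- superpose_rmsd(p1, p2)
    if (r >= min_separation && min_nonbonded_dist(p2) >= 3.0)
      out[[length(out) + 1L]] <- list(chain = p2, rmsd = r, flip = flip)
  }
  out
}

# random torsional-well conformer: every dihedral drawn from {0, pi} (the
# wells of the benchmark torsional term), equilibrium bonds and angles;
# NULL when the conformer clashes.  Unlike self-avoiding growth, which is
# biased towards extended traces, this samples compact and extended
# conformers alike.
random_well_chain <- function(n_res, potential) {
  g <- sample(c(0, pi), n_res - 3L, replace = TRUE)
  ch <- chain_from_internals(rep(potential$d0, n_res - 1L),
                             rep(potential$theta0, n_res - 2L), g)
  if (min_nonbonded_dist(ch) < 2.0) NULL else ch
}

#' Starting conformation of the two-state fixture by trajectory index
#'
#' Returns the two basins of the dual-basin landscape alternately
#' (parent 1 for odd indices, parent 2 for even), so that any even number
#' of trajectories starts balanced across the two states — the standard
#' initialization of ensemble-restrained runs from conformations covering
#' the candidate states.
#'
#' @param fixture a [two_state_fixture()].
#' @param index 1-based trajectory index.
#' @return A [cg_chain()] (not minimized).
#' @export
fixture_start <- function(fixture, index) {
  if (index %% 2L == 1L) fixture$parent1 else fixture$parent2
}

# minimum distance over non-bonded CA pairs (|i - j| >= 2)
min_nonbonded_dist <- function(chain) {
  n <- chain$n_res
  dm <- as.matrix(dist(chain$ca))
  mask <- abs(row(dm) - col(dm)) >= 2L
  min(dm[mask])
}

#' Synthetic inverse-sixth-power averaged distance restraints
#'
#' Builds the synthetic restraint table of a two-state benchmark: for each
#' selected residue pair, the restrained distance is the inverse-
#' sixth-power average of the two parent distances,
#' d_avg = \[ w1 d1^(-6) + w2 d2^(-6) \]^(-1/6), and the flat bottom is
#' d_avg +/- `tol`.  With a small tolerance the set is deliberately
#' unsatisfiable by any single conformation whenever d_avg falls between
#' d1 and d2 — only an ensemble split across the two states can satisfy
#' it on average, which is what replica averaging is meant to recover.
#'
#' @param parent1,parent2 [cg_chain()]s of equal length.
#' @param weights two non-negative weights (normalized internally).
#' @param pairs 2-column matrix of residue index pairs; when NULL, all
#'   CA-CA pairs with sequence separation >= `min_seq_sep` whose distance
#'   is at most `max_dist` in at least one parent (an NOE-like short-range
#'   bias).
#' @param tol half-width of the flat bottom, Angstrom (> 0).
#' @param min_seq_sep minimal |i - j| for the default pair selection.
#' @param max_dist parent-distance ceiling for the default selection,
#'   Angstrom.
#' @return A [restraint_set()] of distance restraints (default penalty
#'   parameters), one row per pair.
#' @export
synthesize_restraints <- function(parent1, parent2, weights = c(0.5, 0.5),
                                  pairs = NULL, tol = 0.5,
                                  min_seq_sep = 2L, max_dist = 12) {
  stopifnot(parent1$n_res == parent2$n_res, tol > 0,
            length(weights) == 2L, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  n <- parent1$n_res
  pdist <- function(ch, i, j) sqrt(sum((ch$ca[i, ] - ch$ca[j, ])^2))
  if (is.null(pairs)) {
    pairs <- do.call(rbind, lapply(1:(n - 1L), function(i) {
      j <- (i + min_seq_sep):n
      j <- j[j <= n]
      if (!length(j)) return(NULL)
      cbind(i, j)
    }))
    keep <- apply(pairs, 1L, function(p) {
      min(pdist(parent1, p[1], p[2]), pdist(parent2, p[1], p[2])) <= max_dist
    })
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!nrow(pairs)) stop("no restraint pairs selected")
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    d1 <- pdist(parent1, i, j); d2 <- pdist(parent2, i, j)
    if (d1 <= 0 || d2 <= 0) stop("coincident sites in pair ", i, "-", j)
    d_avg <- (w[1] * d1^(-6) + w[2] * d2^(-6))^(-1 / 6)
    distance_restraint(i, j, max(0, d_avg - tol), d_avg + tol)
  })
  do.call(restraint_set, rows)
}

#' Run configurations for the population-vs-replica-count benchmark
#'
#' Emits the canonical-mode run plan used to study how the number of
#' averaging replicas affects the recovered state populations: every
#' batch comprises 8 trajectories in total, split into 8/n_replicas
#' independent runs of n_replicas replicas each (n_replicas = 1 means no
#' averaging).  All runs are canonical (Langevin) at 300 K with full
#' averaging every 100 steps.
#'
#' @param n_replicas 1, 2, 4 or 8 replicas per averaged run.
#' @param batches number of independent batches (default 3).
#' @param steps MD steps per trajectory.
#' @param seed base seed; each run gets a distinct derived seed.
#' @param dt time step, fs.
#' @param friction Langevin friction, 1/fs.
#' @param n_snap snapshot interval, steps.
#' @return List of run-configuration lists with elements `n_replicas`,
#'   `batch`, `run`, `steps`, `dt`, `temperature`, `friction`, `n_ave`,
#'   `n_snap`, `averaging`, `seed`.
#' @export
benchmark_config <- function(n_replicas, batches = 3L, steps = 200000L,
                             seed = 1L, dt = 4.89, friction = 0.005,
                             n_snap = 2000L) {
  if (!n_replicas %in% c(1L, 2L, 4L, 8L))
    stop("n_replicas must be 1, 2, 4 or 8")
  runs_per_batch <- 8L %/% n_replicas
  cfgs <- list()
  idx <- 0L
  for (b in seq_len(batches)) for (r in seq_len(runs_per_batch)) {
    idx <- idx + 1L
    cfgs[[idx]] <- list(
      n_replicas = as.integer(n_replicas), batch = b, run = r,
      steps = as.integer(steps), dt = dt, temperature = 300,
      friction = friction, n_ave = 100L, n_snap = as.integer(n_snap),
      averaging = n_replicas > 1L,
      seed = as.integer(seed + 1000L * n_replicas + 64L * b + r))
  }
  cfgs
}

#' Surrogate potential used by the two-state benchmark
#'
#' The benchmark requires the chain to possess discrete metastable
#' backbone conformers — without conformational barriers every restrained
#' trajectory relaxes to the single compromise structure and no two-state
#' behavior exists to recover.  The benchmark potential therefore switches
#' on the double-well torsional term (wells at gamma = 0 and pi, barrier
#' 2 c2 = 3 kcal/mol, about 5 k_B T at 300 K), so that individual
#' trajectories stay locked in the conformer basin they first reach while
#' restraint forces acting on the replica average can still drive
#' transitions.
#'
#' The bending stiffness is raised alongside (k_theta = 25
#' kcal/(mol rad^2)) so that the elastic yield under a handful of
#' violated restraint walls (a few kcal/mol each) stays well below the
#' parent separation — intra-state fluctuations around 1-1.5 Angstrom
#' against a >= 4 Angstrom state distance.
#'
#' @return A [potential_config()] with `k_theta = 25`, `tor_c2 = 3`.
#' @export
benchmark_potential <- function() potential_config(k_theta = 25, tor_c2 = 3)

#' Build the complete two-state fixture
#'
#' Convenience wrapper: parents, synthetic restraints and the benchmark
#' potential from a single seed.
#'
#' @inheritParams make_parents
#' @param tol restraint flat-bottom half-width, Angstrom.
#' @param potential surrogate potential defining the parents' energy
#'   landscape (default [benchmark_potential()]).
#' @param max_dist parent-distance ceiling for restraint pair selection
#'   (NOE-like short-range bias; see [synthesize_restraints()]).
#' @param c2_lock,c2_flip torsional double-well coefficients of the run
#'   potential: `c2_lock` (barrier 2 c2_lock) freezes the backbone
#'   dihedrals the parents share, `c2_flip` sets the barrier along the
#'   transition coordinate (the flipped dihedrals).
#' @return List with `parent1`, `parent2`, `restraints`, `potential`,
#'   `seed`, `tol`, `rmsd` (parent separation), `flipped` (transition
#'   dihedral indices).
#' @export
two_state_fixture <- function(n_res = 12L, seed = 1L, tol = 0.5,
                              potential = benchmark_potential(),
                              max_dist = 12, c2_lock = 12, c2_flip = 5) {
  ra <- list(tol = tol, max_dist = max_dist)
  par <- make_parents(n_res, seed, potential, restraint_args = ra)
  rs <- synthesize_restraints(par$parent1, par$parent2, tol = tol,
                              max_dist = max_dist)
  # dual-basin landscape: the shared backbone dihedrals are locked by a
  # high torsional barrier while the flipped (transition-coordinate)
  # dihedrals keep a moderate one, making the parents the only two
  # accessible conformers -- the classic double-well validation system
  c2 <- rep(c2_lock, n_res - 3L)
  c2[par$flipped] <- c2_flip
  run_pot <- potential
  run_pot$tor_c2 <- c2
  p1 <- minimize_chain(par$parent1, run_pot)$chain
  p2 <- minimize_chain(par$parent2, run_pot)$chain
  list(parent1 = p1, parent2 = p2, restraints = rs,
       potential = run_pot, seed = seed, tol = tol, rmsd = par$rmsd,
       flipped = par$flipped)
}

#' Run one benchmark batch and summarize populations
#'
#' Executes the runs of one batch of a [benchmark_config()] plan against a
#' two-state fixture: each run starts from freshly generated random
#' energy-minimized conformations, integrates in canonical mode, and the
#' second-half snapshots of all its replicas are pooled.  Returns the
#' pooled state populations of the batch relative to the two parents.
#'
#' @param fixture a [two_state_fixture()].
#' @param configs run configurations (all from the same batch).
#' @param potential a [potential_config()]; defaults to the fixture's own.
#' @param cutoff state-assignment RMSD cutoff, Angstrom.
#' @return A [population_summary()] over the pooled second-half snapshots.
#' @export
run_benchmark_batch <- function(fixture, configs,
                                potential = fixture$potential %||%
                                  benchmark_potential(), cutoff = 3) {
  pool <- list()
  for (cfg in configs) {
    set.seed(cfg$seed)
    starts <- lapply(seq_len(cfg$n_replicas), function(J) {
      idx <- (cfg$run - 1L) * cfg$n_replicas + J
      minimize_chain(fixture_start(fixture, idx), potential,
                     fixture$restraints)$chain
    })
    tr <- run_trajectory(starts, fixture$restraints, potential,
                         steps = cfg$steps, dt = cfg$dt, mode = "nvt",
                         temperature = cfg$temperature,
                         friction = cfg$friction,
                         schedule = averaging_schedule(
                           n_ave = cfg$n_ave, n_exch = cfg$steps,
                           n_snap = cfg$n_snap),
                         averaging = cfg$averaging, seed = NULL)
    nfr <- length(tr$snap_steps)
    second_half <- which(tr$snap_steps > cfg$steps / 2)
    for (fr in second_half) for (J in seq_len(cfg$n_replicas))
      pool[[length(pool) + 1L]] <- snapshot_chain(tr, fr, J)
  }
  population_summary(pool, fixture$parent1, fixture$parent2, cutoff)
}
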