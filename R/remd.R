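# temperature sets of the four standard NT x M ladders (48 replicas each)
.ladder_sets <- list(
  "24x2" = c(262, 264, 267, 270, 274, 277, 279, 282, 285, 288, 290, 292,
             295, 298, 301, 305, 308, 315, 327, 333, 340, 355, 362, 370),
  "12x4" = c(262, 267, 274, 279, 285, 290, 295, 301, 308, 333, 355, 370),
  "8x6"  = c(274, 279, 285, 290, 295, 301, 308, 333),
  "6x8"  = c(279, 285, 290, 295, 301, 308)
)

#' Temperature ladder for multiplexed replica exchange
#'
#' Builds a ladder of bath temperatures with M replicas ("multiplexings")
#' per temperature.  Named sets "24x2", "12x4", "8x6" and "6x8" give the
#' standard 48-replica ladders; alternatively pass an explicit temperature
#' vector and M.
#'
#' @param set a set name, or a numeric vector of temperatures (K).
#' @param M multiplexing; inferred from the set name when omitted.
#' @return A `ladder` list with `temperatures`, `M`, and the initial
#'   `assignment` (replica index -> temperature), replicas ordered
#'   temperature-major.
#' @examples
#' make_ladder("12x4")          # 12 temperatures, 4 replicas each
#' make_ladder(c(300), M = 4)   # single-temperature 4-replica ensemble
#' @export
make_ladder <- function(set, M = NULL) {
  if (is.character(set)) {
    if (!set %in% names(.ladder_sets))
      stop("unknown ladder set '", set, "'; use one of ",
           paste(names(.ladder_sets), collapse = ", "),
           " or pass explicit temperatures")
    temps <- .ladder_sets[[set]]
    if (is.null(M)) M <- as.integer(sub(".*x", "", set))
  } else {
    temps <- as.numeric(set)
    if (is.null(M)) stop("M (multiplexing) required for a custom ladder")
  }
  M <- as.integer(M)
  stopifnot(M >= 1L, length(temps) >= 1L, all(temps > 0))
  assignment <- rep(temps, each = M)
  structure(list(temperatures = temps, M = M, assignment = assignment),
            class = "ladder")
}

#' @export
print.ladder <- function(x, ...) {
  cat(sprintf("ladder: %d temperatures x %d replicas (%d total), %g-%g K\n",
              length(x$temperatures), x$M,
              length(x$assignment), min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' Metropolis acceptance probability for a temperature swap
#'
#' For a temperature-independent potential the standard criterion applies:
#' p = min(1, exp\[(beta_a - beta_b)(E_a - E_b)\]) with beta = 1/(k_B T)
#' and E the extended potential energy (surrogate plus restraint penalty)
#' of each replica.
#'
#' @param E_a,E_b extended potential energies, kcal/mol.
#' @param T_a,T_b bath temperatures, K.
#' @return Acceptance probability in \[0, 1\].
#' @export
exchange_probability <- function(E_a, E_b, T_a, T_b) {
  d <- (1 / (.kB * T_a) - 1 / (.kB * T_b)) * (E_a - E_b)
  pmin(1, exp(d))
}

#' Attempt a temperature exchange between two replicas
#'
#' Draws from R's RNG and accepts with [exchange_probability()].
#'
#' @inheritParams exchange_probability
#' @return TRUE if the swap is accepted.
#' @export
attempt_exchange <- function(E_a, E_b, T_a, T_b) {
  p <- exchange_probability(E_a, E_b, T_a, T_b)
  p >= 1 || runif(1) < p
}

#' Multiplexed temperature replica-exchange MD
#'
#' Runs N_T x M replicas: within each same-temperature group of M replicas
#' the restraints act on the replica average (full updates every `n_ave`
#' steps); every `n_exch` steps neighbouring-temperature swaps are
#' attempted, alternating even/odd temperature pairs, with a random
#' pairing between the M replicas at each of the two levels.  Accepted
#' swaps move the replica to the partner temperature (velocities rescaled
#' by sqrt(T_new/T_old)).  Because `n_ave` divides `n_exch`, every
#' exchange point is also a full-averaging point, so averaging groups can
#' be re-formed after swaps.
#'
#' @param chains list of starting [cg_chain()]s, one per replica
#'   (length(ladder$assignment)); a single chain is replicated.
#' @param restraints a [restraint_set()].
#' @param ladder a [make_ladder()].
#' @param schedule an [averaging_schedule()].
#' @param steps total MD steps per replica.
#' @param potential,dt,friction,mass,seed,averaging as in
#'   [run_trajectory()].
#' @return A `rarmd_mremd` list: `streams` — per ladder temperature, a
#'   list with `frames` (list of n x 3 coordinate matrices) and `steps`;
#'   `swap_record` — data frame of attempted swaps; `assignment` — final
#'   replica -> temperature map; `e_pot` — final extended energies.
#' @export
run_mremd <- function(chains, restraints, ladder,
                      schedule = averaging_schedule(),
                      steps = 20000L, potential = potential_config(),
                      dt = 4.89, friction = 0.05, mass = 110,
                      seed = 1L, averaging = TRUE) {
  nrep <- length(ladder$assignment)
  if (inherits(chains, "cg_chain"))
    chains <- replicate(nrep, chains, simplify = FALSE)
  stopifnot(length(chains) == nrep)
  if (steps %% schedule$n_exch != 0L)
    stop("steps must be a multiple of n_exch")
  n <- chains[[1L]]$n_res
  set.seed(seed)
  assignment <- ladder$assignment
  temps <- ladder$temperatures
  M <- ladder$M
  vels <- lapply(seq_len(nrep), function(J)
    maxwell_velocities(n, assignment[J], mass))
  streams <- setNames(
    lapply(temps, function(T) list(frames = list(), steps = integer(0))),
    as.character(temps))
  swaps <- list()
  epot <- rep(NA_real_, nrep)
  rounds <- steps %/% schedule$n_exch
  for (round in seq_len(rounds)) {
    offset <- (round - 1L) * schedule$n_exch
    for (t in seq_along(temps)) {
      grp <- which(assignment == temps[t])
      tr <- run_trajectory(chains[grp], restraints, potential,
                           steps = schedule$n_exch, dt = dt, mode = "nvt",
                           temperature = temps[t], friction = friction,
                           mass = mass, schedule = schedule,
                           averaging = averaging, seed = NULL,
                           velocities = vels[grp], step_offset = offset)
      chains[grp] <- tr$final$chains
      vels[grp] <- tr$final$velocities
      epot[grp] <- tr$e_pot + tr$e_restraint
      key <- as.character(temps[t])
      nfr <- length(tr$snap_steps)
      if (nfr > 0) {
        for (fr in seq_len(nfr)) for (j in seq_along(grp)) {
          streams[[key]]$frames <- c(streams[[key]]$frames,
                                     list(matrix(tr$snapshots[fr, j, , ], ncol = 3L)))
        }
        streams[[key]]$steps <- c(streams[[key]]$steps,
                                  rep(offset + tr$snap_steps, each = length(grp)))
      }
    }
    # alternating even/odd neighbour-pair exchanges
    if (length(temps) >= 2L) {
      start <- if (round %% 2L == 1L) 1L else 2L
      pairs_at <- if (start > length(temps) - 1L) integer(0)
                  else seq(start, length(temps) - 1L, by = 2L)
      for (t in pairs_at) {
        ga <- which(assignment == temps[t])
        gb <- which(assignment == temps[t + 1L])
        gb <- gb[sample.int(length(gb))]   # random partner pairing
        for (k in seq_along(ga)) {
          a <- ga[k]; b <- gb[k]
          acc <- attempt_exchange(epot[a], epot[b], temps[t], temps[t + 1L])
          swaps[[length(swaps) + 1L]] <-
            data.frame(round = round, T_low = temps[t], T_high = temps[t + 1L],
                       replica_low = a, replica_high = b, accepted = acc)
          if (acc) {
            assignment[c(a, b)] <- assignment[c(b, a)]
            vels[[a]] <- vels[[a]] * sqrt(temps[t + 1L] / temps[t])
            vels[[b]] <- vels[[b]] * sqrt(temps[t] / temps[t + 1L])
          }
        }
      }
    }
  }
  structure(list(streams = streams,
                 swap_record = if (length(swaps)) do.call(rbind, swaps)
                               else data.frame(),
                 assignment = assignment, e_pot = epot,
                 ladder = ladder, schedule = schedule),
            class = "rarmd_mremd")
}
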