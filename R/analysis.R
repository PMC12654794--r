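#' Inverse-sixth-power ensemble-averaged restraint distances
#'
#' For each distance restraint, computes the weighted inverse-power
#' ensemble average dbar = \[ sum_k w_k d_k^(-p) \]^(-1/p) over the
#' supplied conformations (weights normalized internally).  The default
#' exponent p = 6 reflects NOE intensity scaling.
#'
#' @param chains list of [cg_chain()] conformations.
#' @param restraints a [restraint_set()]; only "dist" rows are used.
#' @param weights per-conformation weights (>= 0, positive sum); uniform
#'   when NULL.
#' @param exponent averaging exponent p.
#' @return Named list: `d_bar` (one value per distance restraint), `d_l`,
#'   `d_u` (the corresponding boundaries).
#' @export
ensemble_average_distances <- function(chains, restraints, weights = NULL,
                                       exponent = 6) {
  dist_rows <- which(restraints$kind == "dist")
  if (!length(dist_rows)) stop("no distance restraints in the set")
  K <- length(chains)
  if (is.null(weights)) weights <- rep(1, K)
  stopifnot(length(weights) == K, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  rsub <- restraints[dist_rows, ]
  D <- vapply(chains, function(ch) {
    observe_restraints(ch, rsub)
  }, numeric(length(dist_rows)))
  D <- matrix(D, nrow = length(dist_rows))
  if (any(D <= 0)) stop("nonpositive distance in ensemble averaging")
  d_bar <- (as.vector(D^(-exponent) %*% w))^(-1 / exponent)
  list(d_bar = d_bar, d_l = rsub$lower, d_u = rsub$upper)
}

#' Restraint-compatibility metrics of an ensemble
#'
#' Given ensemble-averaged distances and their boundaries, computes
#' rho_u_plus — the root-mean-square positive excess over the upper
#' boundaries (excesses delta_i = dbar_i - d_u_i when violated, else 0) —
#' together with the percentage of distances within their boundaries, the
#' number of upper-boundary violations (nviol) and the number of gross
#' violations exceeding the upper boundary by 2 Angstrom or more (Nviol).
#' Lower-boundary violations do not enter nviol; they are reported
#' separately as `nviol_lower`.
#'
#' @param d_bar ensemble-averaged distances, Angstrom.
#' @param d_u,d_l upper and lower boundaries (same length).
#' @param gross_cutoff excess defining a gross violation (Angstrom).
#' @return An `ensemble_metrics` list: `rho_u_plus`, `pct_satisfied`,
#'   `nviol`, `Nviol_gross`, `nviol_lower`, `n_restraints`.
#' @export
compute_metrics <- function(d_bar, d_u, d_l = rep(0, length(d_u)),
                            gross_cutoff = 2) {
  if (length(d_bar) != length(d_u) || length(d_bar) != length(d_l))
    stop("d_bar, d_u, d_l must have equal lengths")
  delta <- pmax(d_bar - d_u, 0)
  structure(list(
    rho_u_plus = sqrt(mean(delta^2)),
    pct_satisfied = 100 * mean(d_bar >= d_l & d_bar <= d_u),
    nviol = sum(d_bar > d_u),
    Nviol_gross = sum(d_bar >= d_u + gross_cutoff),
    nviol_lower = sum(d_bar < d_l),
    n_restraints = length(d_bar)), class = "ensemble_metrics")
}

#' @export
print.ensemble_metrics <- function(x, ...) {
  cat(sprintf(paste0("ensemble_metrics over %d restraints:\n",
                     "  rho_u_plus    %.4f Angstrom\n",
                     "  satisfied     %.1f %%\n",
                     "  nviol         %d (upper), %d lower\n",
                     "  gross (>=2 A) %d\n"),
              x$n_restraints, x$rho_u_plus, x$pct_satisfied,
              x$nviol, x$nviol_lower, x$Nviol_gross))
  invisible(x)
}

#' Assign a conformation to one of two reference states
#'
#' A conformation belongs to state 1 when RMSD1 < RMSD6 and RMSD1 is below
#' the cutoff; to state 6 in the mirrored case; otherwise (including
#' ties) it is unassigned.
#'
#' @param rmsd1,rmsd6 RMSDs from the two references, Angstrom (vectorized).
#' @param cutoff assignment cutoff, Angstrom (default 3).
#' @return Character vector: "state1", "state6" or "unassigned".
#' @export
assign_state <- function(rmsd1, rmsd6, cutoff = 3) {
  stopifnot(all(rmsd1 >= 0), all(rmsd6 >= 0))
  ifelse(rmsd1 < rmsd6 & rmsd1 < cutoff, "state1",
         ifelse(rmsd6 < rmsd1 & rmsd6 < cutoff, "state6", "unassigned"))
}

#' State populations of an ensemble relative to two parents
#'
#' Superposes every ensemble member on both reference structures and
#' applies [assign_state()].
#'
#' @param chains list of [cg_chain()] conformations.
#' @param ref1,ref6 reference [cg_chain()]s.
#' @param cutoff assignment cutoff, Angstrom.
#' @return A `population_summary` list: `p1`, `p6`, `p_unassigned`
#'   (fractions summing to 1), `counts`, `n`.
#' @export
population_summary <- function(chains, ref1, ref6, cutoff = 3) {
  if (!length(chains)) stop("empty ensemble")
  r1 <- vapply(chains, superpose_rmsd, numeric(1), ref = ref1)
  r6 <- vapply(chains, superpose_rmsd, numeric(1), ref = ref6)
  st <- assign_state(r1, r6, cutoff)
  n <- length(st)
  counts <- c(state1 = sum(st == "state1"), state6 = sum(st == "state6"),
              unassigned = sum(st == "unassigned"))
  structure(list(p1 = counts[["state1"]] / n, p6 = counts[["state6"]] / n,
                 p_unassigned = counts[["unassigned"]] / n,
                 counts = counts, n = n, rmsd1 = r1, rmsd6 = r6),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("populations over %d conformations: p1 = %.3f, p6 = %.3f, unassigned = %.3f\n",
              x$n, x$p1, x$p6, x$p_unassigned))
  invisible(x)
}

#' Ward clustering of an ensemble into representative families
#'
#' Hierarchical Ward clustering (ward.D2 linkage) on the pairwise
#' C-alpha-RMSD dissimilarity matrix, cut into k families.  Each family is
#' represented by the member with the lowest total restraint penalty; the
#' representative carries the cumulative weight of its family.
#'
#' @param chains list of [cg_chain()] conformations (length >= k).
#' @param restraints a [restraint_set()] used to pick representatives.
#' @param k number of families (default 20).
#' @param weights per-conformation statistical weights (uniform when NULL).
#' @return List with `representatives` (k chains), `weights` (cumulative,
#'   normalized), `assignments` (family index per member), `penalties`
#'   (per representative).
#' @export
cluster_families <- function(chains, restraints, k = 20, weights = NULL) {
  N <- length(chains)
  if (N < k) stop("ensemble smaller than the requested number of families")
  if (is.null(weights)) weights <- rep(1, N)
  weights <- weights / sum(weights)
  dm <- matrix(0, N, N)
  if (N > 1L) for (i in 1:(N - 1L)) for (j in (i + 1L):N) {
    dm[i, j] <- dm[j, i] <- superpose_rmsd(chains[[i]], chains[[j]])
  }
  assignments <- if (k == N) seq_len(N)
  else cutree(hclust(as.dist(dm), method = "ward.D2"), k = k)
  pen <- vapply(chains, function(ch)
    sum(penalty_value(restraints, observe_restraints(ch, restraints))),
    numeric(1))
  reps <- integer(k); wsum <- numeric(k)
  for (f in seq_len(k)) {
    members <- which(assignments == f)
    reps[f] <- members[which.min(pen[members])]
    wsum[f] <- sum(weights[members])
  }
  list(representatives = chains[reps], weights = wsum,
       assignments = assignments, penalties = pen[reps],
       representative_index = reps)
}

#' Joint RMSD histogram relative to two references
#'
#' Bins every conformation by its (RMSD1, RMSD6) pair; the counts sum to
#' the ensemble size.  The matrix is the raw material of the two-state
#' heat maps.
#'
#' @param chains list of [cg_chain()]s.
#' @param ref1,ref6 reference chains.
#' @param breaks number of bins per axis, or an explicit break vector
#'   (shared by both axes).
#' @return List: `counts` (matrix bins1 x bins6), `breaks1`, `breaks6`,
#'   `rmsd1`, `rmsd6`.
#' @export
rmsd_map <- function(chains, ref1, ref6, breaks = 20) {
  r1 <- vapply(chains, superpose_rmsd, numeric(1), ref = ref1)
  r6 <- vapply(chains, superpose_rmsd, numeric(1), ref = ref6)
  if (length(breaks) == 1L) {
    hi <- max(r1, r6) * 1.0001 + 1e-9
    breaks <- seq(0, hi, length.out = breaks + 1L)
  }
  b1 <- cut(r1, breaks, include.lowest = TRUE)
  b6 <- cut(r6, breaks, include.lowest = TRUE)
  list(counts = table(b1, b6), breaks1 = breaks, breaks6 = breaks,
       rmsd1 = r1, rmsd6 = r6)
}
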