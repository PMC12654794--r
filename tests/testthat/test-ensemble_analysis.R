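test_that("inverse-sixth-power ensemble averages match direct arithmetic", {
  ch1 <- cg_chain(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(7.6, 4, 0)))
  rs <- distance_restraint(1, 4, 3, 9)
  one <- ensemble_average_distances(list(ch1), rs)
  expect_equal(one$d_bar, observe_restraints(ch1, rs))

  # two conformations with pair distances 4 and 6 at equal weight
  mk <- function(d) cg_chain(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0),
                                   c(7.6, 0, 0) + c(0, 0, 0) +
                                     c(-7.6, 0, 0) + c(d, 0, 0) * 0 +
                                     c(0, d, 0)))
  a <- mk(4); b <- mk(6)
  expect_equal(sqrt(sum((a$ca[1, ] - a$ca[4, ])^2)), 4)
  oracle <- ((4^-6 + 6^-6) / 2)^(-1 / 6)
  got <- ensemble_average_distances(list(a, b), rs)$d_bar
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(oracle, 4.4273, tolerance = 1e-4)

  # splitting a conformation's weight across duplicates changes nothing
  got2 <- ensemble_average_distances(list(a, b, b), rs,
                                     weights = c(0.5, 0.25, 0.25))$d_bar
  expect_equal(got2, oracle, tolerance = 1e-12)

  # power-mean bound: inverse-6 average below the arithmetic mean
  with_seed_restore(71, for (rep in 1:20) {
    d <- runif(5, 3, 10)
    chains <- lapply(d, mk)
    expect_lte(ensemble_average_distances(chains, rs)$d_bar, mean(d) + 1e-12)
  })
})

test_that("compatibility metrics count violations per the upper-boundary rules", {
  m0 <- compute_metrics(c(3, 4, 5), d_u = c(4, 5, 6), d_l = c(0, 0, 0))
  expect_equal(m0$rho_u_plus, 0)
  expect_equal(m0$pct_satisfied, 100)
  expect_equal(m0$nviol, 0L)

  m1 <- compute_metrics(c(5, 3), d_u = c(4, 4), d_l = c(0, 0))
  expect_equal(m1$rho_u_plus, sqrt(1 / 2), tolerance = 1e-12)
  expect_equal(m1$nviol, 1L)
  expect_equal(m1$Nviol_gross, 0L)
  expect_equal(m1$pct_satisfied, 50)

  # exactly +2 A counts as gross (>= convention)
  m2 <- compute_metrics(c(5, 3, 6), d_u = c(4, 4, 4), d_l = c(0, 0, 0))
  expect_equal(m2$Nviol_gross, 1L)
  expect_equal(m2$nviol, 2L)
  # lower-bound violations are reported separately, not in nviol
  m3 <- compute_metrics(c(1, 5), d_u = c(4, 4), d_l = c(2, 0))
  expect_equal(m3$nviol, 1L)
  expect_equal(m3$nviol_lower, 1L)
  expect_error(compute_metrics(1:3, 1:2, 1:3), "lengths")

  # monotonicity: raising any single averaged distance cannot lower rho
  with_seed_restore(72, for (rep in 1:20) {
    db <- runif(6, 2, 8); du <- runif(6, 3, 7)
    r0 <- compute_metrics(db, du, rep(0, 6))$rho_u_plus
    i <- sample(6, 1)
    db[i] <- db[i] + runif(1, 0, 2)
    expect_gte(compute_metrics(db, du, rep(0, 6))$rho_u_plus, r0 - 1e-12)
  })
})

test_that("state assignment follows the nearer-reference-below-cutoff rule", {
  expect_equal(assign_state(1.0, 5.0), "state1")
  expect_equal(assign_state(3.5, 3.5), "unassigned")
  expect_equal(assign_state(2.9, 2.8), "state6")
  expect_equal(assign_state(c(0.5, 4, 2), c(4, 0.5, 2)),
               c("state1", "state6", "unassigned"))
})

test_that("population summaries partition the ensemble exactly", {
  fix <- two_state_fixture(10, seed = 23)
  ens1 <- replicate(5, fix$parent1, simplify = FALSE)
  p <- population_summary(ens1, fix$parent1, fix$parent2)
  expect_equal(p$p1, 1)
  expect_equal(p$p6, 0)

  half <- c(replicate(4, fix$parent1, simplify = FALSE),
            replicate(4, fix$parent2, simplify = FALSE))
  p2 <- population_summary(half, fix$parent1, fix$parent2)
  expect_equal(p2$p1, 0.5)
  expect_equal(p2$p6, 0.5)
  expect_equal(p2$p1 + p2$p6 + p2$p_unassigned, 1)

  # conformations far from both references stay unassigned
  coils <- lapply(1:4, function(s) build_random_chain(10, seed = 100 + s,
                                                      min_sep = 4.5))
  r1 <- vapply(coils, superpose_rmsd, numeric(1), ref = fix$parent1)
  r6 <- vapply(coils, superpose_rmsd, numeric(1), ref = fix$parent2)
  far <- which(r1 > 3 & r6 > 3)
  if (length(far)) {
    p3 <- population_summary(coils[far], fix$parent1, fix$parent2)
    expect_equal(p3$p_unassigned, 1)
  }
  expect_error(population_summary(list(), fix$parent1, fix$parent2), "empty")
})

test_that("Ward families have penalty-minimal representatives and honest weights", {
  fix <- two_state_fixture(10, seed = 23)
  jig <- function(parent, s, sd) with_seed_restore(s,
    cg_chain(parent$ca + matrix(rnorm(30, sd = sd), 10, 3)))
  bundle1 <- lapply(1:5, function(s) jig(fix$parent1, s, 0.1))
  bundle2 <- lapply(1:5, function(s) jig(fix$parent2, 10 + s, 0.1))
  ens <- c(bundle1, bundle2)
  cf <- cluster_families(ens, fix$restraints, k = 2)
  # families coincide with the bundles: verify against the brute-force
  # 2-partition minimizing the Ward objective on the RMSD matrix
  dm <- matrix(0, 10, 10)
  for (i in 1:9) for (j in (i + 1):10)
    dm[i, j] <- dm[j, i] <- superpose_rmsd(ens[[i]], ens[[j]])
  ward_obj <- function(members) {
    if (length(members) < 2) return(0)
    sum(dm[members, members]^2) / (2 * length(members))
  }
  best <- NULL; best_val <- Inf
  for (mask in 1:(2^9 - 1)) {  # fix member 10 in group 2 to kill symmetry
    g1 <- which(bitwAnd(mask, 2^(0:8)) > 0)
    val <- ward_obj(g1) + ward_obj(setdiff(1:10, g1))
    if (val < best_val) { best_val <- val; best <- g1 }
  }
  expect_setequal(best, 1:5)
  expect_equal(length(unique(cf$assignments[1:5])), 1L)
  expect_equal(length(unique(cf$assignments[6:10])), 1L)
  expect_false(cf$assignments[1] == cf$assignments[6])
  # representative minimizes the restraint penalty within its family
  for (f in 1:2) {
    members <- which(cf$assignments == f)
    pens <- vapply(ens[members], function(ch)
      sum(rarmd:::penalty_value(fix$restraints,
                                observe_restraints(ch, fix$restraints))),
      numeric(1))
    expect_equal(cf$penalties[f], min(pens), tolerance = 1e-12)
  }
  expect_equal(sum(cf$weights), 1)

  # k equal to the ensemble size: every conformation its own family
  cfN <- cluster_families(ens, fix$restraints, k = 10)
  expect_equal(sort(cfN$assignments), 1:10)
  expect_error(cluster_families(ens, fix$restraints, k = 11), "smaller")

  # invariance to reordering of the ensemble (up to label permutation)
  perm <- c(6:10, 1:5)
  cfP <- cluster_families(ens[perm], fix$restraints, k = 2)
  expect_equal(length(unique(cfP$assignments[1:5])), 1L)
  expect_false(cfP$assignments[1] == cfP$assignments[6])
})

test_that("RMSD maps conserve counts", {
  fix <- two_state_fixture(10, seed = 23)
  one <- rmsd_map(list(fix$parent1), fix$parent1, fix$parent2, breaks = 5)
  expect_equal(sum(one$counts), 1)
  ens <- c(replicate(3, fix$parent1, simplify = FALSE),
           replicate(4, fix$parent2, simplify = FALSE))
  mp <- rmsd_map(ens, fix$parent1, fix$parent2, breaks = 8)
  expect_equal(sum(mp$counts), 7)
})
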