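test_that("full_average implements the inverse-power mean", {
  expect_equal(full_average(rep(3.3, 5), m = 3), 3.3)
  expect_equal(full_average(rep(-0.4, 4), m = -1), -0.4)
  # direct arithmetic oracle for (2, 4), m = 3
  oracle <- ((2^-3 + 4^-3) / 2)^(-1 / 3)
  expect_equal(full_average(c(2, 4), m = 3), oracle, tolerance = 1e-14)
  expect_equal(full_average(c(2, 4), m = -1), 3)
  expect_equal(full_average(7.7, m = 3), 7.7)
  expect_error(full_average(c(2, -1), m = 3), "positive")
  expect_error(full_average(c(1, 2), m = 0), "nonzero")
})

test_that("full_average is permutation-invariant and obeys power-mean bounds", {
  with_seed_restore(41, for (rep in 1:50) {
    v <- runif(sample(2:8, 1), 1, 10)
    m <- sample(c(3, 6, -1, 2), 1)
    a <- full_average(v, m)
    expect_equal(full_average(sample(v), m), a, tolerance = 1e-12)
    expect_gte(a, min(v) - 1e-12)
    expect_lte(a, max(v) + 1e-12)
    if (m == 3) expect_lte(a, mean(v) + 1e-12)  # short distances dominate
  })
})

test_that("dihedral averaging is wrap-correct via atan2", {
  expect_equal(dihedral_average(rep(0.8, 4)), 0.8)
  # +170 and -170 degrees average to 180, not 0
  expect_equal(dihedral_average(c(170, -170) * pi / 180), pi)
  expect_error(dihedral_average(c(0, pi)), "degenerate")
  # brute-force sine/cosine oracle
  with_seed_restore(42, for (rep in 1:30) {
    g <- runif(sample(2:6, 1), -pi, pi)
    expect_equal(dihedral_average(g), atan2(mean(sin(g)), mean(cos(g))),
                 tolerance = 1e-14)
  })
})

test_that("partial updates freeze foreign contributions and extend the full average", {
  # own value unchanged since the full update -> identical to full average
  v <- c(2.0, 4.0, 5.5)
  S <- sum(v[-2]^-3)
  expect_equal(partial_average(S, v[2], M = 3, m = 3), full_average(v, 3),
               tolerance = 1e-14)
  # arithmetic oracle, M = 2
  expect_equal(partial_average(4^-3, 2, M = 2, m = 3),
               ((2^-3 + 4^-3) / 2)^(-1 / 3), tolerance = 1e-14)
  # single replica: the average IS the observable, bitwise
  expect_identical(partial_average(0, 3.7, M = 1, m = 3), 3.7)
  # theta averaging (m = -1) reduces to the arithmetic update
  expect_equal(partial_average(1.2 + 1.4, 1.9, M = 3, m = -1),
               mean(c(1.2, 1.4, 1.9)), tolerance = 1e-14)
})

test_that("the averaged-gradient factor is the exact derivative of the partial update", {
  # M = 1: gradient passes through unchanged
  g <- matrix(1:6, 2, 3)
  expect_identical(averaged_gradient(2.5, 2.5, g, M = 1, m = 3), g * 1)
  # scalar factor oracle for M = 2, foreign 4, own 2: (1/2) (ybar/2)^4
  ybar <- partial_average(4^-3, 2, M = 2, m = 3)
  expect_equal(averaged_gradient(2, ybar, 1, M = 2, m = 3),
               0.5 * (ybar / 2)^4, tolerance = 1e-12)
  # finite-difference check against partial_average w.r.t. y_own
  with_seed_restore(43, for (rep in 1:30) {
    M <- sample(2:8, 1)
    m <- sample(c(3, -1), 1)
    v <- runif(M, 1.5, 9)
    S <- sum(v[-1]^(-m))
    y <- v[1]
    yb <- partial_average(S, y, M, m)
    h <- 1e-5 * y
    fd <- (partial_average(S, y + h, M, m) -
             partial_average(S, y - h, M, m)) / (2 * h)
    expect_equal(averaged_gradient(y, yb, 1, M, m), fd, tolerance = 1e-8)
  })
})

test_that("replica-averaged forces vanish when the average complies although members violate", {
  # two replicas whose individual distances lie outside [d_l, d_u] while
  # the m = 3 average lies inside: the averaged penalty must be exactly 0
  ch1 <- cg_chain(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(7.6, 3, 0),
                        c(7.6, 3, 3)))
  ch1$ca[5, ] <- ch1$ca[1, ] + c(0, 0, 3.0)   # pair (1,5) at 3.0 A
  ch2 <- ch1
  ch2$ca[5, ] <- ch2$ca[1, ] + c(0, 0, 4.5)   # pair (1,5) at 4.5 A
  avg <- full_average(c(3.0, 4.5), m = 3)
  rs <- distance_restraint(1, 5, 3.4, 4.0)
  expect_gt(3.4, 3.0); expect_lt(4.0, 4.5)    # both members violate
  expect_gt(avg, 3.4); expect_lt(avg, 4.0)    # the average complies
  sf <- scaled_restraint_forces(list(ch1, ch2), rs)
  expect_equal(sf$energy, c(0, 0))
  expect_equal(max(abs(sf$forces[[1]])), 0)
  expect_equal(max(abs(sf$forces[[2]])), 0)
  # whereas the non-averaged penalty is strictly positive on each replica
  expect_gt(restraint_energy_forces(ch1, rs)$energy, 0)
  expect_gt(restraint_energy_forces(ch2, rs)$energy, 0)
})

test_that("M = 1 replica-averaged forces reduce to the plain restrained forces", {
  ch <- zigzag_chain(10, jitter = 0.2, seed = 6)
  rs <- mixed_restraints()
  sf <- scaled_restraint_forces(list(ch), rs)
  re <- restraint_energy_forces(ch, rs)
  expect_identical(sf$energy[1], re$energy)
  expect_identical(sf$forces[[1]], re$forces)
})

test_that("scaled forces are exact gradients of the frozen-sum extended energy", {
  rs <- mixed_restraints()
  chains <- lapply(1:4, function(s) zigzag_chain(10, jitter = 0.25, seed = s))
  frozen <- full_update(chains, rs)
  sf <- scaled_restraint_forces(chains, rs, frozen, scale_energy = TRUE)
  h <- 1e-5
  for (J in c(1, 3)) {
    err <- 0
    for (i in seq(1, 10, by = 3)) for (k in 1:3) {
      cp <- chains; cp[[J]]$ca[i, k] <- cp[[J]]$ca[i, k] + h
      cm <- chains; cm[[J]]$ca[i, k] <- cm[[J]]$ca[i, k] - h
      Ep <- sum(scaled_restraint_forces(cp, rs, frozen, scale_energy = TRUE)$energy)
      Em <- sum(scaled_restraint_forces(cm, rs, frozen, scale_energy = TRUE)$energy)
      fd <- -(Ep - Em) / (2 * h)
      an <- sf$forces[[J]][i, k]
      err <- max(err, abs(fd - an) / max(1e-6, abs(fd), abs(an)))
    }
    expect_lt(err, 1e-6)
  }
  # identical conformations across M = 4 replicas: forces equal on all
  same <- replicate(4, chains[[1]], simplify = FALSE)
  sf2 <- scaled_restraint_forces(same, rs)
  for (J in 2:4) expect_equal(sf2$forces[[J]], sf2$forces[[1]], tolerance = 1e-12)
})

test_that("indicator temperature weights are normalized and follow swaps", {
  lad <- make_ladder("12x4")
  w <- temperature_weights(lad$assignment, lad$M)
  expect_equal(dim(w), c(48L, 12L))
  expect_true(all(colSums(w) == 1))
  expect_true(all(w %in% c(0, 0.25)))
  expect_equal(colSums(w > 0), setNames(rep(4L, 12), colnames(w)))
  # after a swap the support follows the replicas now at T
  a2 <- lad$assignment
  a2[c(1, 5)] <- a2[c(5, 1)]
  w2 <- temperature_weights(a2, lad$M)
  expect_equal(unname(w2[1, ]), unname(w[5, ]))
  expect_true(all(colSums(w2) == 1))
  expect_error(temperature_weights(c(300, 300, 310), 2), "multiplexing")
})
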