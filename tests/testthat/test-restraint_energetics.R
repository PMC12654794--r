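test_that("the flat-bottom distance penalty matches its closed form", {
  # flat bottom
  expect_equal(v_dist(3.0, 2.5, 4.0, A = 7, sigma = 2, kappa = 0.3), 0)
  # one Angstrom past the upper bound, default parameters: independent
  # evaluation A * x^4/(sigma^4+x^4) * (1 + kappa*log(cosh x)) at x = 1
  oracle <- 5 * (1 / (1 + 1)) * (1 + 0.01 * log(cosh(1)))
  expect_equal(v_dist(5.0, 2.5, 4.0), oracle, tolerance = 1e-12)
  expect_equal(oracle, 2.5108445, tolerance = 1e-6)
  # far tail: slope approaches A * kappa
  expect_equal(v_dist_deriv(4.0 + 50, 2.5, 4.0), 5 * 0.01, tolerance = 0.01 * 0.05)
  # mirror symmetry v(d_l - x) = v(d_u + x)
  x <- c(0.1, 0.7, 2, 9)
  expect_equal(v_dist(2.5 - x, 2.5, 4.0), v_dist(4.0 + x, 2.5, 4.0),
               tolerance = 1e-12)
})

test_that("the distance-penalty derivative is exact and vanishes at the boundaries", {
  expect_equal(v_dist_deriv(3.2, 2.5, 4.0), 0)
  expect_equal(v_dist_deriv(4.0, 2.5, 4.0), 0)   # quartic tangency
  expect_equal(v_dist_deriv(2.5, 2.5, 4.0), 0)
  with_seed_restore(31, for (rep in 1:50) {
    dl <- runif(1, 1, 5); du <- dl + runif(1, 0, 3)
    A <- runif(1, 1, 10); sg <- runif(1, 0.5, 2); kp <- runif(1, 0, 0.1)
    d <- runif(1, 0.2, 12)
    h <- 1e-6
    fd <- (v_dist(d + h, dl, du, A, sg, kp) - v_dist(d - h, dl, du, A, sg, kp)) / (2 * h)
    an <- v_dist_deriv(d, dl, du, A, sg, kp)
    if (abs(fd) > 1e-8)
      expect_equal(an, fd, tolerance = 1e-6)
  })
})

test_that("v_dist is nonnegative and strictly increasing beyond the upper bound", {
  d <- seq(4.001, 30, length.out = 400)
  v <- v_dist(d, 2.5, 4.0)
  expect_true(all(v >= 0))
  expect_true(all(diff(v) > 0))
  expect_true(all(v_dist(seq(0.01, 30, length.out = 500), 2.5, 4.0) >= 0))
})

test_that("wrap_delta measures the signed offset from the window midpoint", {
  expect_equal(wrap_delta(0.6, 0.2, 1.0), 0)
  # x = 350 deg against a [-10, 10] deg window wraps inside: delta = -10 deg
  expect_equal(wrap_delta(350 * pi / 180, -10 * pi / 180, 10 * pi / 180),
               -10 * pi / 180, tolerance = 1e-12)
  x <- c(-2, 0.3, 3)
  expect_equal(wrap_delta(x + 2 * pi, -1, 1), wrap_delta(x, -1, 1),
               tolerance = 1e-12)
  expect_error(wrap_delta(0, 0, 2 * pi), "width")
})

test_that("the angular penalty uses the continuous excess wall by default", {
  expect_equal(v_ang(1.6, 1.5, 1.7), 0)
  h <- (1.7 - 1.5) / 2
  expect_equal(v_ang(1.6 + h + 0.2, 1.5, 1.7, amplitude = 1),
               0.2^4 / 4, tolerance = 1e-12)
  # continuity at the boundary from both sides
  eps <- 1e-8
  expect_lt(v_ang(1.7 + eps, 1.5, 1.7), 1e-20)
  expect_equal(v_ang(1.7 - eps, 1.5, 1.7), 0)
  # the printed (compat) wall jumps by h^4/4 at the boundary
  expect_equal(v_ang(1.7 + 1e-9, 1.5, 1.7, compat = TRUE), h^4 / 4,
               tolerance = 1e-6)
  # joint 2*pi shift invariance
  expect_equal(v_ang(2.5 + 2 * pi, 1.5 + 2 * pi, 1.7 + 2 * pi),
               v_ang(2.5, 1.5, 1.7), tolerance = 1e-12)
  # derivative consistency
  with_seed_restore(8, for (rep in 1:30) {
    xl <- runif(1, -3, 2); xu <- xl + runif(1, 0.1, 2)
    x <- runif(1, -pi, pi); h2 <- 1e-6
    fd <- (v_ang(x + h2, xl, xu, 2) - v_ang(x - h2, xl, xu, 2)) / (2 * h2)
    expect_equal(v_ang_deriv(x, xl, xu, 2), fd, tolerance = 1e-5)
  })
})

test_that("observables evaluate distances and internal angles per restraint", {
  ch <- cg_chain(rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(7.6, 5, 0)))
  rs <- restraint_set(distance_restraint(1, 4, 2, 12),
                      angle_restraint("theta", 1, 2, 3))
  y <- observe_restraints(ch, rs)
  expect_equal(y[1], sqrt(7.6^2 + 25))
  expect_equal(y[2], pi)  # collinear triplet

  # random chain: independent recomputation from raw coordinates
  rc <- build_random_chain(10, seed = 1, min_sep = 3.6)
  rs2 <- mixed_restraints()
  y2 <- observe_restraints(rc, rs2)
  ic <- internal_coords(rc)
  expect_equal(y2[1], sqrt(sum((rc$ca[1, ] - rc$ca[5, ])^2)))
  expect_equal(y2[4], ic$thetas[2])
  expect_equal(y2[6], ic$gammas[3])

  expect_error(observe_restraints(rc, distance_restraint(1, 99, 1, 2)),
               "outside the chain")
})

test_that("restraint forces are exact gradients and obey Newton's third law", {
  ch <- zigzag_chain(10, jitter = 0.3, seed = 2)
  rs <- mixed_restraints()
  re <- restraint_energy_forces(ch, rs)
  err <- fd_force_err(ch, function(c) restraint_energy_forces(c, rs)$energy,
                      re$forces, h = 1e-5)
  expect_lt(err, 1e-6)

  # all observables inside their windows -> zero energy and forces
  y <- observe_restraints(ch, rs)
  wide <- rs; wide$lower <- y - 1; wide$upper <- y + 1
  wide$lower[wide$kind == "dist"] <- pmax(0, wide$lower[wide$kind == "dist"])
  re0 <- restraint_energy_forces(ch, restraint_set(wide))
  expect_equal(re0$energy, 0)
  expect_equal(max(abs(re0$forces)), 0)

  # violated two-body restraint: antiparallel forces of magnitude |dV/dd|
  pair <- cg_chain(rbind(c(0, 0, 0), c(6, 0, 0)))
  rs1 <- distance_restraint(1, 2, 2, 5)
  re1 <- restraint_energy_forces(pair, rs1)
  expect_equal(re1$forces[1, ], -re1$forces[2, ], tolerance = 1e-12)
  expect_equal(sqrt(sum(re1$forces[1, ]^2)), abs(v_dist_deriv(6, 2, 5)),
               tolerance = 1e-12)
  expect_equal(colSums(re$forces), c(0, 0, 0), tolerance = 1e-10)
})

test_that("the compiled restraint evaluator agrees with the R implementation", {
  ch <- zigzag_chain(10, jitter = 0.25, seed = 9)
  rs <- mixed_restraints()
  r_ref <- restraint_energy_forces(ch, rs)
  cpp <- rarmd:::restraint_ef_cpp(ch$ca, rarmd:::restraints_to_matrix(rs, 10), FALSE)
  expect_equal(cpp$energy, r_ref$energy, tolerance = 1e-12)
  expect_equal(cpp$forces, r_ref$forces, tolerance = 1e-12)
})

test_that("restraint records validate their boundaries and sites", {
  expect_error(distance_restraint(1, 2, 5, 4), "lower")
  expect_error(restraint_set(data.frame(kind = "foo", i_res = 1,
                                        i_site = NA, j_res = 2, j_site = NA,
                                        lower = 1, upper = 2, amplitude = 1,
                                        sigma = 1, kappa = 0, m = 3)),
               "kind")
  ch <- build_random_chain(6, seed = 1, min_sep = 3.6)
  sc_rs <- distance_restraint(1, 3, 2, 8, i_site = "SC")
  expect_error(observe_restraints(ch, sc_rs), "side-chain")
})
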