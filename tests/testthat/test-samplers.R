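test_that("velocity Verlet integrates free and harmonic motion correctly", {
  free_fn <- function(x) list(energy = 0, forces = x * 0)
  st <- md_state(x = c(0), v = c(0.02), mass = 110)
  for (i in 1:100) st <- nve_step(st, free_fn, dt = 1)
  expect_equal(st$x, 0.02 * 100, tolerance = 1e-12)
  expect_equal(st$v, 0.02, tolerance = 1e-15)

  # 1D harmonic oscillator: energy oscillation O(dt^2), no drift
  k <- 50; m <- 110
  ho_fn <- function(x) list(energy = 0.5 * k * x^2, forces = -k * x)
  conv <- 4.184e-4
  omega <- sqrt(k * conv / m)
  dt <- 0.02 * 2 * pi / omega / 100   # dt = period/5000
  st <- md_state(x = 1, v = 0, mass = m)
  e <- numeric(2000)
  for (i in 1:2000) {
    st <- nve_step(st, ho_fn, dt)
    e[i] <- st$energy + 0.5 * m * st$v^2 / conv
  }
  e0 <- 0.5 * k
  expect_lt(max(abs(e - e0)) / e0, (omega * dt)^2)      # bounded by O(dt^2)
  # no secular drift: window means differ at most by the oscillation scale
  drift <- abs(mean(e[1901:2000]) - mean(e[1:100])) / e0
  expect_lt(drift, (omega * dt)^2)
  # position matches the closed-form solution
  t_tot <- 2000 * dt
  expect_equal(st$x, cos(omega * t_tot), tolerance = 1e-3)
})

test_that("Langevin dynamics reduces to NVE at zero friction and equipartitions", {
  ho_fn <- function(x) list(energy = 0.5 * 50 * sum(x^2), forces = -50 * x)
  s1 <- md_state(x = c(1, 0.5), v = c(0, 0.01), mass = 110)
  s2 <- s1
  for (i in 1:50) {
    s1 <- nve_step(s1, ho_fn, 1)
    s2 <- langevin_step(s2, ho_fn, 1, friction = 0, temperature = 300)
  }
  expect_identical(s1$x, s2$x)
  expect_identical(s1$v, s2$v)

  # free particle: mean kinetic energy per dof -> kB T / 2 within 3 SE
  free_fn <- function(x) list(energy = 0, forces = x * 0)
  with_seed_restore(77, {
    st <- md_state(x = rep(0, 100), v = rep(0, 100), mass = 110)
    ke <- c()
    for (i in 1:600) {
      st <- langevin_step(st, free_fn, 2, friction = 0.05, temperature = 300)
      if (i > 100) ke <- c(ke, 0.5 * 110 * mean(st$v^2) / 4.184e-4)
    }
    target <- 0.5 * kB() * 300
    se <- sd(ke) / sqrt(length(ke) / 20)  # generous correlation allowance
    expect_lt(abs(mean(ke) - target), 3 * se + 0.02 * target)
  })

  # fixed seed -> identical trajectory
  run <- function() with_seed_restore(5, {
    st <- md_state(x = rep(0, 10), v = rep(0, 10), mass = 110)
    for (i in 1:20) st <- langevin_step(st, free_fn, 1, 0.1, 300)
    st$x
  })
  expect_identical(run(), run())

  # configurational Boltzmann sampling: 1D harmonic variance = kB T / k
  with_seed_restore(78, {
    k <- 10
    hf <- function(x) list(energy = 0.5 * k * sum(x^2), forces = -k * x)
    st <- md_state(x = rep(0, 50), v = rep(0, 50), mass = 110)
    xs <- c()
    for (i in 1:2000) {
      st <- langevin_step(st, hf, 4, friction = 0.02, temperature = 300)
      if (i > 200 && i %% 10 == 0) xs <- c(xs, st$x)
    }
    expect_equal(var(xs), kB() * 300 / k, tolerance = 0.1)
  })
})

test_that("minimization reaches analytic minima and never raises the energy", {
  cfg <- potential_config(eps_rep = 0)
  at_min <- chain_from_internals(rep(cfg$d0, 5), rep(cfg$theta0, 4), c(1, -1, 2))
  res <- minimize_chain(at_min, cfg)
  expect_equal(res$energy, 0, tolerance = 1e-10)
  expect_equal(res$chain$ca, at_min$ca, tolerance = 1e-4)

  # stretched dimer relaxes to the equilibrium bond length
  dimer <- cg_chain(rbind(c(0, 0, 0), c(5.5, 0, 0)))
  res2 <- minimize_chain(dimer, potential_config(k_bond = 100))
  expect_equal(internal_coords(res2$chain)$bond_lengths, 3.8, tolerance = 1e-6)
  expect_true(res2$converged)

  ch <- build_random_chain(20, seed = 9, min_sep = 3.6)
  e0 <- energy_and_forces(ch, potential_config())$energy
  res3 <- minimize_chain(ch, potential_config())
  expect_lte(res3$energy, e0)
  expect_lt(res3$gmax, 1e-4)
})

test_that("the schedule enforces that full averaging divides the exchange interval", {
  expect_error(averaging_schedule(n_ave = 100, n_exch = 250), "divide")
  s <- averaging_schedule(100, 10000, 500)
  expect_equal(s$n_ave, 100L)
})

test_that("trajectories emit the scheduled snapshots deterministically", {
  ch <- build_random_chain(8, seed = 2, min_sep = 3.6)
  rs <- distance_restraint(1, 8, 5, 15)
  run <- function() run_trajectory(list(ch, ch), rs, potential_config(),
                                   steps = 1000, dt = 2, mode = "nvt",
                                   temperature = 300, friction = 0.02,
                                   schedule = averaging_schedule(100, 1000, 100),
                                   averaging = TRUE, seed = 31, log_every = 100)
  tr <- run()
  expect_equal(length(tr$snap_steps), 10L)
  expect_equal(tr$snap_steps, seq(100L, 1000L, by = 100L))
  expect_equal(dim(tr$snapshots), c(10L, 2L, 8L, 3L))
  expect_equal(nrow(tr$energy_log), 10L * 2L)
  tr2 <- run()
  expect_identical(tr$snapshots, tr2$snapshots)
  expect_identical(tr$final$chains[[1]]$ca, tr2$final$chains[[1]]$ca)
})

test_that("M = 1 averaged dynamics is bitwise identical to non-averaged dynamics", {
  ch <- build_random_chain(10, seed = 4, min_sep = 3.6)
  rs <- mixed_restraints()
  run_mode <- function(avg) run_trajectory(list(ch), rs, potential_config(),
                                           steps = 500, dt = 2, mode = "nvt",
                                           temperature = 300, friction = 0.05,
                                           schedule = averaging_schedule(100, 500, 50),
                                           averaging = avg, seed = 99)
  a <- run_mode(TRUE); b <- run_mode(FALSE)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$final$velocities[[1]], b$final$velocities[[1]])
})

test_that("replica-averaged NVE dynamics is segment-symplectic", {
  with_seed_restore(55, {
    fix <- two_state_fixture(10, seed = 17)
    starts <- lapply(1:4, function(J)
      minimize_chain(fixture_start(fix, J), fix$potential, fix$restraints)$chain)
    tr <- run_trajectory(starts, fix$restraints, fix$potential,
                         steps = 1500, dt = 0.489, mode = "nve",
                         temperature = 300,
                         schedule = averaging_schedule(100, 1500, 500),
                         averaging = TRUE, scale_energy = TRUE,
                         seed = 3, log_every = 1)
    for (J in 1:4) {
      el <- tr$energy_log[tr$energy_log$replica == J, ]
      seg <- split(el$e_total, (el$step - 1) %/% 100)
      cv <- vapply(seg, function(x) sd(x) / abs(mean(x)), numeric(1))
      expect_lt(max(cv), 1e-5)
      # energy jumps occur only at multiples of n_ave
      within_jumps <- vapply(seg, function(x) max(abs(diff(x))) / abs(mean(x)),
                             numeric(1))
      expect_lt(max(within_jumps), 1e-5)
    }
  })
})
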