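# shared test helpers: small chains and restraint sets built in code

# deterministic mildly irregular test chain
zigzag_chain <- function(n, jitter = 0, seed = 1) {
  ch <- chain_from_internals(rep(3.8, n - 1),
                             rep(110 * pi / 180, n - 2),
                             rep(c(0.6, -2.8), length.out = n - 3))
  if (jitter > 0) {
    ch <- with_seed_restore(seed, cg_chain(ch$ca + matrix(rnorm(3 * n, sd = jitter), n, 3)))
  }
  ch
}

with_seed_restore <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# mixed restraint set exercising all three observable kinds
mixed_restraints <- function() {
  restraint_set(
    distance_restraint(1, 5, 4.0, 5.0),
    distance_restraint(2, 9, 10.0, 11.0),
    distance_restraint(3, 7, 0.0, 2.0),
    angle_restraint("theta", 2, 1.5, 1.7),
    angle_restraint("theta", 5, 0.3, 0.5),
    angle_restraint("gamma", 3, -0.5, 0.5),
    angle_restraint("gamma", 1, 2.8, 3.1))
}

# central finite-difference force check for a chain-energy closure.
# energy_fn(chain) -> scalar; forces analytic n x 3.  Returns the norm-wise
# relative error ||F_fd - F_an|| / ||F_an|| (the per-component quotient is
# dominated by FD roundoff wherever a single component is tiny).
fd_force_err <- function(chain, energy_fn, forces, h = 1e-5) {
  fd <- forces * 0
  for (i in seq_len(chain$n_res)) for (k in 1:3) {
    cp <- chain; cp$ca[i, k] <- cp$ca[i, k] + h
    cm <- chain; cm$ca[i, k] <- cm$ca[i, k] - h
    fd[i, k] <- -(energy_fn(cp) - energy_fn(cm)) / (2 * h)
  }
  sqrt(sum((fd - forces)^2)) / max(sqrt(sum(forces^2)), 1e-8)
}
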