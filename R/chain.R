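#' Coarse-grained polypeptide chain
#'
#' A `cg_chain` holds the C-alpha trace of a polypeptide (one site per
#' residue) and, optionally, one side-chain-center pseudo-site per residue.
#' Consecutive C-alpha sites are connected by virtual bonds; the internal
#' geometry of the trace is described by virtual-bond lengths d_i,
#' virtual-bond angles theta_i (over three consecutive C-alpha) and
#' virtual-bond dihedrals gamma_i (over four consecutive C-alpha).
#'
#' @param ca numeric n x 3 matrix of C-alpha coordinates (Angstrom).
#' @param sc optional n x 3 matrix of side-chain-center coordinates.
#' @param sequence optional character vector of one-letter residue codes
#'   (length n); defaults to "A" (alanine) for every residue.
#' @return An object of class `cg_chain` with fields `n_res`, `ca`, `sc`,
#'   `sequence`.
#' @examples
#' ch <- cg_chain(matrix(c(0,0,0, 3.8,0,0, 7.6,0,0), 3, 3, byrow = TRUE))
#' internal_coords(ch)$thetas  # pi: the trace is collinear
#' @export
cg_chain <- function(ca, sc = NULL, sequence = NULL) {
  ca <- as.matrix(ca)
  storage.mode(ca) <- "double"
  if (ncol(ca) != 3L) stop("`ca` must be an n x 3 coordinate matrix")
  n <- nrow(ca)
  if (n < 2L) stop("a chain needs at least 2 residues")
  if (!all(is.finite(ca))) stop("non-finite C-alpha coordinates")
  bl <- sqrt(rowSums((ca[-1L, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  if (any(bl <= 0)) stop("zero-length virtual bond between consecutive residues")
  if (!is.null(sc)) {
    sc <- as.matrix(sc)
    storage.mode(sc) <- "double"
    if (!all(dim(sc) == c(n, 3L)))
      stop("`sc` must have the same number of rows as `ca`")
    if (!all(is.finite(sc))) stop("non-finite side-chain coordinates")
  }
  if (is.null(sequence)) sequence <- rep("A", n)
  if (length(sequence) != n) stop("`sequence` length must equal the residue count")
  structure(list(n_res = n, ca = ca, sc = sc, sequence = sequence),
            class = "cg_chain")
}

#' @export
print.cg_chain <- function(x, ...) {
  cat(sprintf("cg_chain: %d residues%s\n", x$n_res,
              if (is.null(x$sc)) " (CA trace)" else " (CA + SC sites)"))
  invisible(x)
}

# wrap an angle (rad) to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

#' Internal coordinates of a C-alpha trace
#'
#' Computes the virtual-bond lengths, virtual-bond angles theta_i (angle at
#' residue i+1 over residues i, i+1, i+2) and virtual-bond dihedrals
#' gamma_i (torsion over residues i..i+3, IUPAC sign convention, wrapped to
#' (-pi, pi]).
#'
#' @param chain a [cg_chain()].
#' @return A list with `bond_lengths` (n-1, Angstrom), `thetas` (n-2, rad,
#'   in \[0, pi\]) and `gammas` (n-3, rad, in (-pi, pi\]).
#' @export
internal_coords <- function(chain) {
  stopifnot(inherits(chain, "cg_chain"))
  n <- chain$n_res
  ca <- chain$ca
  b <- ca[-1L, , drop = FALSE] - ca[-n, , drop = FALSE]   # bond vectors
  bl <- sqrt(rowSums(b^2))
  thetas <- numeric(0)
  gammas <- numeric(0)
  if (n >= 3L) {
    u <- -b[-(n - 1L), , drop = FALSE]  # from middle atom back to first
    v <- b[-1L, , drop = FALSE]         # from middle atom on to third
    cosang <- rowSums(u * v) / (bl[-(n - 1L)] * bl[-1L])
    thetas <- acos(pmin(1, pmax(-1, cosang)))
  }
  if (n >= 4L) {
    gammas <- vapply(seq_len(n - 3L), function(i) {
      dihedral_value(ca[i, ], ca[i + 1L, ], ca[i + 2L, ], ca[i + 3L, ])
    }, numeric(1))
  }
  list(bond_lengths = bl, thetas = thetas, gammas = gammas)
}

# signed dihedral over four points, IUPAC convention, in (-pi, pi]
dihedral_value <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * b2) / sqrt(sum(b2^2))
  g <- atan2(y, x)
  if (g == -pi) pi else g
}

#' Minimal least-squares RMSD after rigid superposition
#'
#' Kabsch least-squares superposition of `mob` onto `ref` followed by the
#' root-mean-square deviation over the paired points.  Side-chain sites are
#' not involved: callers pass the coordinate selections they want compared
#' (for chains, typically the C-alpha matrix).
#'
#' @param ref,mob n x 3 coordinate matrices (or `cg_chain`s, whose `ca`
#'   matrices are then used) with equal point counts n >= 3.
#' @return The minimal RMSD in Angstrom (non-negative, symmetric in its
#'   arguments).
#' @export
superpose_rmsd <- function(ref, mob) {
  if (inherits(ref, "cg_chain")) ref <- ref$ca
  if (inherits(mob, "cg_chain")) mob <- mob$ca
  ref <- as.matrix(ref); mob <- as.matrix(mob)
  if (!all(dim(ref) == dim(mob)))
    stop("`ref` and `mob` must contain the same number of points")
  if (nrow(ref) < 3L) stop("superposition needs at least 3 points")
  # Kabsch via bio3d's least-squares fit; its eigen step can emit sqrt
  # warnings for tiny negative eigenvalues on near-degenerate point sets
  suppressWarnings(bio3d::rmsd(as.vector(t(ref)), as.vector(t(mob)), fit = TRUE))
}

#' Rebuild a C-alpha trace from internal coordinates
#'
#' Inverse of [internal_coords()] up to rigid-body placement: the first
#' residue sits at the origin, the second along +x, the third in the
#' xy-plane.  Used to construct chains with prescribed virtual-bond
#' geometry.
#'
#' @param bond_lengths n-1 virtual-bond lengths (Angstrom).
#' @param thetas n-2 virtual-bond angles (rad).
#' @param gammas n-3 virtual-bond dihedrals (rad).
#' @param sequence optional one-letter codes.
#' @return A [cg_chain()].
#' @export
chain_from_internals <- function(bond_lengths, thetas, gammas, sequence = NULL) {
  n <- length(bond_lengths) + 1L
  if (n >= 3L && length(thetas) != n - 2L) stop("need n-2 virtual-bond angles")
  if (n >= 4L && length(gammas) != n - 3L) stop("need n-3 virtual-bond dihedrals")
  ca <- matrix(0, n, 3L)
  ca[2L, ] <- c(bond_lengths[1L], 0, 0)
  if (n >= 3L)
    ca[3L, ] <- ca[2L, ] + bond_lengths[2L] * c(-cos(thetas[1L]), sin(thetas[1L]), 0)
  if (n >= 4L) {
    for (i in 4:n) {
      ca[i, ] <- place_next(ca[i - 3L, ], ca[i - 2L, ], ca[i - 1L, ],
                            bond_lengths[i - 1L], thetas[i - 2L], gammas[i - 3L])
    }
  }
  cg_chain(ca, sequence = sequence)
}

# natural-extension placement of point D after A,B,C given (d, theta, gamma)
place_next <- function(a, b, c, d, theta, gamma) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
         nrm[3] * bc[1] - nrm[1] * bc[3],
         nrm[1] * bc[2] - nrm[2] * bc[1])
  # local direction: bond angle theta with -bc, dihedral gamma about bc
  d2 <- c(-cos(theta), sin(theta) * cos(gamma), sin(theta) * sin(gamma))
  c + d * (d2[1] * bc + d2[2] * m + d2[3] * nrm)
}

#' Random non-overlapping C-alpha chain
#'
#' Grows a self-avoiding C-alpha trace with fixed 3.8-Angstrom virtual
#' bonds, virtual-bond angles drawn uniformly in \[75, 160\] degrees and
#' dihedrals uniform in (-pi, pi].  A placement is rejected when any
#' non-bonded pair falls below `min_sep`; growth restarts (boundedly) when
#' a residue cannot be placed.
#'
#' @param n_res residue count (>= 2).
#' @param seed integer seed; the same seed reproduces the chain bitwise.
#' @param min_sep minimal allowed non-bonded CA-CA distance (Angstrom, > 0).
#' @param max_restarts number of full-chain restarts before giving up.
#' @return A [cg_chain()] with all virtual bonds 3.8 Angstrom.
#' @export
build_random_chain <- function(n_res, seed, min_sep = 4.0, max_restarts = 200L) {
  stopifnot(n_res >= 2L, min_sep > 0)
  with_local_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      ca <- try_grow_chain(n_res, min_sep)
      if (!is.null(ca)) return(cg_chain(ca))
    }
    stop("failed to place a self-avoiding chain; try a smaller `min_sep`")
  })
}

try_grow_chain <- function(n_res, min_sep, tries_per_res = 60L) {
  bond <- 3.8
  ca <- matrix(NA_real_, n_res, 3L)
  ca[1L, ] <- 0
  if (n_res >= 2L) ca[2L, ] <- c(bond, 0, 0)
  if (n_res >= 3L) {
    ok <- FALSE
    for (k in seq_len(tries_per_res)) {
      th <- runif(1, 75, 160) * pi / 180
      cand <- ca[2L, ] + bond * c(-cos(th), sin(th), 0)
      if (sqrt(sum((cand - ca[1L, ])^2)) >= min_sep) {
        ca[3L, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) return(NULL)
  }
  i <- 4L
  while (i <= n_res) {
    placed <- FALSE
    for (k in seq_len(tries_per_res)) {
      th <- runif(1, 75, 160) * pi / 180
      ga <- runif(1, -pi, pi)
      cand <- place_next(ca[i - 3L, ], ca[i - 2L, ], ca[i - 1L, ], bond, th, ga)
      prev <- ca[seq_len(i - 2L), , drop = FALSE]  # non-bonded predecessors
      if (all(sqrt(rowSums(sweep(prev, 2, cand)^2)) >= min_sep)) {
        ca[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
    i <- i + 1L
  }
  ca
}
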