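# Independent oracles used across the suite. Each computes its target
# quantity by a route disjoint from the package implementation
# (direct lattice sums, quadrature, closed forms).

# Madelung constant of the rock-salt lattice by Evjen's neutral-shell
# direct summation (weights 1/2 on the faces of the truncation cube).
evjen_madelung <- function(nmax = 8) {
  idx <- -nmax:nmax
  g <- expand.grid(i = idx, j = idx, k = idx)
  g <- g[!(g$i == 0 & g$j == 0 & g$k == 0), ]
  w <- function(v) ifelse(abs(v) == nmax, 0.5, 1)
  wt <- w(g$i) * w(g$j) * w(g$k)
  q <- (-1)^(g$i + g$j + g$k)
  r <- sqrt(g$i^2 + g$j^2 + g$k^2)
  -sum(q * wt / r)
}

# Brute-force periodic Coulomb energy: direct sum over image cells in
# spherical order. Absolutely convergent (and equal to the tinfoil
# Ewald value) when the configuration has zero net dipole moment.
direct_image_sum <- function(pos, val, L, lB, shells) {
  n <- nrow(pos)
  U <- 0
  for (sx in -shells:shells) for (sy in -shells:shells)
    for (sz in -shells:shells) {
      if (sx^2 + sy^2 + sz^2 > shells^2) next
      shift <- c(sx, sy, sz) * L
      home <- all(shift == 0)
      for (i in 1:n) for (j in 1:n) {
        if (home && i >= j) next
        d <- pos[j, ] + shift - pos[i, ]
        fac <- if (home) 1 else 0.5
        U <- U + fac * val[i] * val[j] * lB / sqrt(sum(d^2))
      }
    }
  U
}

# a small neutral, dipole-free random charge configuration: pairs of
# antiparallel +/- dipoles
dipole_free_config <- function(n_dipole_pairs = 3, L = 10, seed = 2) {
  set.seed(seed)
  pos <- NULL; val <- NULL
  for (i in seq_len(n_dipole_pairs)) {
    b <- runif(3, 0.25 * L, 0.75 * L)
    d <- runif(3, -1, 1)
    pos <- rbind(pos, b, b + d, b + c(0.3 * L, 0, 0),
                 b + c(0.3 * L, 0, 0) - d)
    val <- c(val, 1L, -1L, 1L, -1L)
  }
  list(pos = pos, val = val, L = L)
}

# Boltzmann statistics of the bonded monomer dimer by 1-D quadrature
# over the full pair potential (bond + WCA + hydrophobic)
dimer_quadrature <- function(T_K, params = ng_model_params()) {
  u <- function(r) {
    pair_bond(r, params, T_K) +
      pair_wca(r, params$d_monomer, params$d_monomer, params, T_K) +
      pair_hydrophobic(r, T_K, params = params)
  }
  Z <- stats::integrate(function(r) r^2 * exp(-vapply(r, u, 0)),
                        0.2, 1.6)$value
  mean_r <- stats::integrate(function(r) r^3 * exp(-vapply(r, u, 0)),
                             0.2, 1.6)$value / Z
  p_below_r0 <- stats::integrate(function(r) r^2 * exp(-vapply(r, u, 0)),
                                 0.2, params$r0)$value / Z
  list(mean_r = mean_r, p_below_r0 = p_below_r0)
}

# Closed-form solution of the linearized (Debye-Hueckel) cell problem:
# uniformly charged ball of radius R (total charge Z) in symmetric
# monovalent salt at boundary concentration n0, gauge psi(Rc) = 0.
dh_cell_closed_form <- function(r, R, Rc, Z, n0, lB) {
  k <- sqrt(4 * pi * lB * 2 * n0)
  C <- 4 * pi * lB * (3 * Z / (4 * pi * R^3)) / k^2
  M <- rbind(
    c(sinh(k * R) / R, -exp(-k * R) / R, -exp(k * R) / R),
    c(k * cosh(k * R) / R - sinh(k * R) / R^2,
      k * exp(-k * R) / R + exp(-k * R) / R^2,
      -(k * exp(k * R) / R - exp(k * R) / R^2)),
    c(0, exp(-k * Rc) / Rc, exp(k * Rc) / Rc))
  abd <- solve(M, c(-C, 0, 0))
  A <- abd[1]; B <- abd[2]; D <- abd[3]
  out <- ifelse(r < R,
                C + A * sinh(k * r) / pmax(r, .Machine$double.eps),
                (B * exp(-k * r) + D * exp(k * r)) /
                  pmax(r, .Machine$double.eps))
  out[r == 0] <- C + A * k
  out
}

# distance between the two beads of a dimer frame (minimum image)
dimer_r <- function(frame, L) {
  d <- frame[1, ] - frame[2, ]
  sqrt(sum((d - L * round(d / L))^2))
}
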