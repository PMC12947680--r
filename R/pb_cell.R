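# Poisson-Boltzmann cell model: one nanogel, represented as a
# uniformly charged permeable sphere of radius R_NG, at the centre of
# an electroneutral spherical cell whose volume matches the simulation
# box. The dimensionless mean-field potential solves
#   psi'' + (2/r) psi' = -4 pi l_B [ rho_Z(r) + sum_i z_i n_i(r; psi) ]
# with n_i either ideal Boltzmann profiles or, with excluded-volume
# saturation enabled, Boltzmann factors divided by the shared
# denominator 1 + sum_j n_j0 exp(-z_j psi) / n_j,max so that no local
# concentration exceeds its close-packing estimate.

#' Maximum local concentration of a finite-size species
#'
#' Close-packing estimate \eqn{n_{i,max} = (1 - \phi_{NG}) / d_i^3}:
#' the free volume left by the polymer (volume fraction
#' \eqn{\phi_{NG}} in the gel core) divided by the species' own cubic
#' volume.
#'
#' @param phi_ng polymer volume fraction, in `[0, 1)`.
#' @param d_i species diameter (nm).
#' @return Concentration cap (1/nm^3).
#' @export
n_i_max <- function(phi_ng, d_i) {
  if (any(phi_ng < 0 | phi_ng >= 1)) stop("phi_ng must be in [0, 1)")
  if (any(d_i <= 0)) stop("diameters must be positive")
  (1 - phi_ng) / d_i^3
}

#' Specify a Poisson-Boltzmann cell problem
#'
#' @param r_ng gel radius (nm): the bare charge `Z` is spread
#'   uniformly over this sphere.
#' @param Z bare network charge (e).
#' @param cell_radius cell radius (nm); the default converts a cubic
#'   box of side `box` to the sphere of equal volume.
#' @param box cubic box side (nm), used only for the default
#'   `cell_radius`.
#' @param species data.frame with columns `label`, `z` (valence),
#'   `d` (diameter, nm), `N` (total count per cell). The cell must be
#'   electroneutral: `Z + sum(z * N) = 0`.
#' @param phi_ng polymer volume fraction in the gel core, used by the
#'   saturation term inside `r < r_ng` (outside the gel only the
#'   species' own size limits packing, `phi = 0`).
#' @param saturation enable the excluded-volume cap on local
#'   concentrations.
#' @param T_K temperature (K), which sets the Bjerrum length.
#' @param l_B Bjerrum length override (nm).
#' @param n_nodes radial mesh nodes.
#' @return A list of class `pb_cell_spec`.
#' @export
pb_cell_spec <- function(r_ng, Z, cell_radius = NULL, box = NULL,
                         species = NULL, phi_ng = 0,
                         saturation = TRUE, T_K = 293.15, l_B = NULL,
                         n_nodes = 2000) {
  if (is.null(cell_radius)) {
    if (is.null(box)) stop("give cell_radius or box")
    cell_radius <- (3 * box^3 / (4 * pi))^(1 / 3)
  }
  stopifnot(cell_radius > r_ng, r_ng > 0, n_nodes >= 50)
  if (is.null(l_B)) l_B <- bjerrum_length(T_K)
  if (is.null(species)) {
    species <- data.frame(label = character(), z = numeric(),
                          d = numeric(), N = numeric())
  }
  stopifnot(all(c("label", "z", "d", "N") %in% names(species)))
  species <- species[species$N > 0, , drop = FALSE]
  qtot <- Z + sum(species$z * species$N)
  if (abs(qtot) > 1e-9 * max(1, abs(Z))) {
    stop(sprintf("cell is not electroneutral: Z + sum(z N) = %g", qtot))
  }
  structure(list(r_ng = r_ng, Z = Z, cell_radius = cell_radius,
                 species = species, phi_ng = phi_ng,
                 saturation = isTRUE(saturation), l_B = l_B,
                 T_K = T_K, n_nodes = as.integer(n_nodes)),
            class = "pb_cell_spec")
}

# Thomas algorithm for a tridiagonal system (a: sub, b: diag, c: super)
.tridiag_solve <- function(a, b, c, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- c[1] / b[1]; dp[1] <- d[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- c[i] / m
    dp[i] <- (d[i] - a[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# species concentrations n_i(psi) and their psi-derivatives on the
# grid; returns list(n = matrix, dn = matrix) [nodes x species]
.pb_conc <- function(psi, inside, spec, n0) {
  sp <- spec$species
  ns <- nrow(sp)
  n <- matrix(0, length(psi), ns)
  dn <- matrix(0, length(psi), ns)
  if (ns == 0) return(list(n = n, dn = dn))
  g <- matrix(0, length(psi), ns)
  for (i in seq_len(ns)) g[, i] <- n0[i] * exp(-sp$z[i] * psi)
  if (!spec$saturation) {
    for (i in seq_len(ns)) {
      n[, i] <- g[, i]
      dn[, i] <- -sp$z[i] * g[, i]
    }
  } else {
    # n_max depends on position: gel core uses phi_NG, exterior phi = 0
    nmax <- matrix(0, length(psi), ns)
    for (i in seq_len(ns)) {
      nmax[, i] <- ifelse(inside, n_i_max(spec$phi_ng, sp$d[i]),
                          n_i_max(0, sp$d[i]))
    }
    D <- rowSums(g / nmax)
    Dz <- rowSums(sweep(g / nmax, 2, sp$z, "*"))
    for (i in seq_len(ns)) {
      n[, i] <- g[, i] / (1 + D)
      dn[, i] <- (-sp$z[i] * g[, i] * (1 + D) + g[, i] * Dz) / (1 + D)^2
    }
  }
  list(n = n, dn = dn)
}

# inner Newton solve at fixed boundary concentrations n0
.pb_newton <- function(spec, n0, psi0 = NULL, tol = 1e-10,
                       max_iter = 100) {
  M <- spec$n_nodes
  h <- spec$cell_radius / M
  r <- seq(0, spec$cell_radius, length.out = M + 1)
  inside <- r < spec$r_ng
  # bare-charge ball source, volume-weighted at the cell straddling
  # r_ng (second-order accurate) and renormalized so the discrete
  # quadrature carries exactly Z
  lo <- pmax(r - h / 2, 0)
  hi <- pmin(r + h / 2, spec$cell_radius)
  vin <- pmax(pmin(hi, spec$r_ng)^3 - lo^3, 0)
  wfrac <- ifelse(hi > lo, vin / (hi^3 - lo^3), 0)
  rhoZ <- 3 * spec$Z / (4 * pi * spec$r_ng^3) * wfrac
  if (spec$Z != 0) {
    qd <- .trapz(r, 4 * pi * r^2 * rhoZ)
    rhoZ <- rhoZ * spec$Z / qd
  }
  fourPiLb <- 4 * pi * spec$l_B
  psi <- if (is.null(psi0)) numeric(M + 1) else psi0
  sp <- spec$species
  zs <- sp$z

  resid <- function(psi) {
    cc <- .pb_conc(psi, inside, spec, n0)
    rho <- rhoZ + if (ncol(cc$n)) as.numeric(cc$n %*% zs) else 0
    F <- numeric(M)            # unknowns psi[1..M] (psi[M+1] = 0)
    # node 0: regularity, Laplacian -> 3 psi''(0)
    F[1] <- 6 * (psi[2] - psi[1]) / h^2 + fourPiLb * rho[1]
    j <- 2:M
    F[j] <- (psi[j + 1] - 2 * psi[j] + psi[j - 1]) / h^2 +
      (psi[j + 1] - psi[j - 1]) / (h * r[j]) + fourPiLb * rho[j]
    list(F = F, cc = cc)
  }

  rs <- resid(psi)
  for (it in seq_len(max_iter)) {
    normF <- max(abs(rs$F))
    drho <- if (ncol(rs$cc$dn)) as.numeric(rs$cc$dn %*% zs) else
      numeric(M + 1)
    # tridiagonal Jacobian over unknowns psi[1..M] (1-based grid index)
    a <- numeric(M); b <- numeric(M); cs <- numeric(M)
    b[1] <- -6 / h^2 + fourPiLb * drho[1]
    cs[1] <- 6 / h^2
    j <- 2:M
    a[j] <- 1 / h^2 - 1 / (h * r[j])
    b[j] <- -2 / h^2 + fourPiLb * drho[j]
    cs[j] <- 1 / h^2 + 1 / (h * r[j])
    step <- .tridiag_solve(a, b, cs, -rs$F)
    # damped update
    lam <- 1
    repeat {
      trial <- psi
      trial[1:M] <- psi[1:M] + lam * step
      rs_trial <- resid(trial)
      if (max(abs(rs_trial$F)) < normF || lam < 1e-6) break
      lam <- lam / 2
    }
    psi <- trial
    rs <- rs_trial
    if (max(abs(lam * step)) < tol) break
  }
  cc <- .pb_conc(psi, inside, spec, n0)
  list(r = r, psi = psi, n = cc$n, residual = max(abs(rs$F)),
       h = h, inside = inside)
}

#' Solve the Poisson-Boltzmann cell model
#'
#' Finite differences on a uniform radial mesh with damped Newton
#' iteration for the nonlinear equation, plus an outer fixed-point
#' loop that adjusts each species' boundary concentration until its
#' profile integrates to the prescribed total count per cell. The
#' converged solution satisfies the cell-edge gauge `psi = 0` exactly
#' and `dpsi/dr = 0` through electroneutrality.
#'
#' @param spec a [pb_cell_spec()].
#' @param n0 boundary concentrations (1/nm^3, one per species). When
#'   supplied with `fix_boundary = TRUE` the outer loop is skipped and
#'   the species counts are whatever the profiles integrate to.
#' @param fix_boundary treat `n0` as prescribed instead of iterating
#'   on species counts.
#' @param count_tol relative tolerance on the per-species counts.
#' @param max_outer outer-loop iteration cap.
#' @return A list of class `pb_cell_solution`: `r`, `psi`, `n`
#'   (nodes x species matrix), `n0`, `converged`, `residual`, `spec`.
#' @export
pb_solve <- function(spec, n0 = NULL, fix_boundary = FALSE,
                     count_tol = 1e-6, max_outer = 300) {
  sp <- spec$species
  ns <- nrow(sp)
  V <- 4 / 3 * pi * spec$cell_radius^3
  if (is.null(n0)) n0 <- if (ns) sp$N / V else numeric(0)
  stopifnot(length(n0) == ns)
  sol <- .pb_newton(spec, n0)
  converged <- TRUE
  if (!fix_boundary && ns > 0) {
    converged <- FALSE
    for (out in seq_len(max_outer)) {
      counts <- vapply(seq_len(ns), function(i) {
        .trapz(sol$r, 4 * pi * sol$r^2 * sol$n[, i])
      }, numeric(1))
      rel <- abs(counts - sp$N) / sp$N
      if (max(rel) < count_tol) { converged <- TRUE; break }
      n0 <- n0 * sp$N / counts
      sol <- .pb_newton(spec, n0, psi0 = sol$psi)
    }
    if (!converged) {
      warning(sprintf(paste0("outer loop not converged: max relative ",
                             "count error %.3g"), max(rel)))
    }
  }
  structure(list(r = sol$r, psi = sol$psi, n = sol$n, n0 = n0,
                 converged = converged, residual = sol$residual,
                 spec = spec),
            class = "pb_cell_solution")
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Number of particles of a species absorbed in the gel
#'
#' \eqn{\int_0^{R_{NG}} n_i(r) 4 \pi r^2 dr}.
#'
#' @param sol a [pb_solve()] solution.
#' @param species species label or index.
#' @return Mean number inside the gel sphere (real-valued).
#' @export
absorbed_count <- function(sol, species) {
  i <- if (is.character(species)) {
    match(species, sol$spec$species$label)
  } else as.integer(species)
  if (is.na(i) || i < 1 || i > ncol(sol$n)) stop("unknown species")
  keep <- sol$r <= sol$spec$r_ng
  r <- sol$r[keep]; n <- sol$n[keep, i]
  # extend to exactly r_ng by interpolation of the last sub-interval
  if (max(r) < sol$spec$r_ng) {
    nr <- stats::approx(sol$r, sol$n[, i], xout = sol$spec$r_ng)$y
    r <- c(r, sol$spec$r_ng); n <- c(n, nr)
  }
  .trapz(r, 4 * pi * r^2 * n)
}

#' Net charge of the gel in the cell model
#'
#' Bare charge plus the charge of every absorbed species,
#' optionally minus the `external_bare_charge`: the (simulation-
#' derived) network charge that actually sits outside the sphere of
#' radius `r_ng`, which the cell model wrongly books as internal.
#'
#' @inheritParams absorbed_count
#' @param external_bare_charge correction (e), default 0.
#' @return Net charge (e).
#' @export
net_charge_pbc <- function(sol, external_bare_charge = 0) {
  sp <- sol$spec$species
  zabs <- if (nrow(sp)) {
    sum(vapply(seq_len(nrow(sp)), function(i) {
      sp$z[i] * absorbed_count(sol, i)
    }, numeric(1)))
  } else 0
  sol$spec$Z + zabs - external_bare_charge
}

#' Surface potential in the cell model
#'
#' @inheritParams absorbed_count
#' @return Dimensionless \eqn{e\psi(R_{NG})/k_BT}, interpolated on the
#'   mesh.
#' @export
surface_potential_pbc <- function(sol) {
  stats::approx(sol$r, sol$psi, xout = sol$spec$r_ng)$y
}

#' @export
print.pb_cell_solution <- function(x, ...) {
  cat(sprintf(paste0("PB cell solution: R_NG %.3g nm, Z %+g e, cell ",
                     "%.3g nm, %d species\n"),
              x$spec$r_ng, x$spec$Z, x$spec$cell_radius,
              nrow(x$spec$species)))
  cat(sprintf("  psi(0) = %.4g, psi(R_NG) = %.4g, converged: %s\n",
              x$psi[1], surface_potential_pbc(x), x$converged))
  invisible(x)
}
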