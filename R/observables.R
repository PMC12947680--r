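# Observables computed from trajectory frames: gel size, absorbed
# nanoparticle counts, radial charge/density/potential profiles and
# the nanoparticle pair correlation function. Every radial quantity is
# measured from the instantaneous centre of mass of the polymer
# network, computed on bond-unwrapped network coordinates (the network
# is never split across the periodic boundary by construction); mobile
# species use minimum-image distances to that centre.

# network CM of one frame, after bond unwrapping
.frame_cm <- function(pos, sys) {
  ids <- .network_ids(sys)
  up <- unwrap_network(pos, sys$bonds, ids, sys$box)
  colMeans(up[ids, , drop = FALSE])
}

#' Radius of gyration of the polymer network
#'
#' \eqn{R_{gyr}^2 = N^{-1} \sum_i |r_i - r_{CM}|^2} over the network
#' beads of one frame, with the network unwrapped across the periodic
#' boundary first. Ensemble averaging over frames is done by the
#' caller.
#'
#' @param pos N x 3 position matrix of one frame (all beads, nm).
#' @param sys the `ng_system` the frame belongs to (for topology).
#' @return Radius of gyration (nm).
#' @export
radius_of_gyration <- function(pos, sys) {
  ids <- .network_ids(sys)
  if (!length(ids)) stop("system has no network beads")
  up <- unwrap_network(pos, sys$bonds, ids, sys$box)[ids, , drop = FALSE]
  cm <- colMeans(up)
  sqrt(mean(rowSums(sweep(up, 2, cm)^2)))
}

#' Geometric radius of the nanogel
#'
#' The effective spherical radius, \eqn{R_{NG} = \sqrt{5/3}\, R_{gyr}}
#' (exact for a uniform solid sphere).
#'
#' @param r_gyr radius of gyration (nm).
#' @return Geometric radius (nm).
#' @export
geometric_radius <- function(r_gyr) {
  stopifnot(all(r_gyr >= 0))
  sqrt(5 / 3) * r_gyr
}

#' Count nanoparticles inside the nanogel
#'
#' A nanoparticle is inside when the distance between its centre and
#' the network centre of mass is less than the geometric radius
#' (minimum image).
#'
#' @inheritParams radius_of_gyration
#' @param r_ng geometric radius (nm).
#' @return Integer count.
#' @export
count_inside <- function(pos, sys, r_ng) {
  stopifnot(r_ng >= 0)
  nps <- which_species(sys, "nanoparticle")
  if (!length(nps)) return(0L)
  cm <- .frame_cm(pos, sys)
  sum(.mi_dist(cm, pos[nps, , drop = FALSE], sys$box) < r_ng)
}

#' Shrinkage and desorption ratios
#'
#' `shrinkage = 1 - R_NG(hot) / R_NG(cold)` and
#' `desorption = (N_in(cold) - N_in(hot)) / N_in(cold)`: the fraction
#' of the swollen-state size lost on heating, and the fraction of the
#' absorbed nanoparticles expelled.
#'
#' @param r_ng_cold,r_ng_hot geometric radii at the low and high
#'   temperature (nm).
#' @param n_in_cold,n_in_hot mean numbers of absorbed nanoparticles
#'   (optional; NULL skips the desorption ratio).
#' @return List with `shrinkage` and `desorption` (the latter NA when
#'   counts are not supplied).
#' @export
shrink_desorb_ratios <- function(r_ng_cold, r_ng_hot,
                                 n_in_cold = NULL, n_in_hot = NULL) {
  if (r_ng_cold <= 0) stop("reference radius must be positive")
  des <- NA_real_
  if (!is.null(n_in_cold) && !is.null(n_in_hot)) {
    if (n_in_cold <= 0) stop("reference absorbed count must be positive")
    des <- (n_in_cold - n_in_hot) / n_in_cold
  }
  list(shrinkage = 1 - r_ng_hot / r_ng_cold, desorption = des)
}

.bin_grid <- function(sys, bin_width, r_max = NULL) {
  if (is.null(r_max)) r_max <- sys$box / 2
  seq(0, r_max, by = bin_width)
}

#' Cumulative net charge profile
#'
#' Frame-averaged total charge (elementary units) enclosed by a sphere
#' of radius r around the network centre of mass; bead charges count by
#' centre position. The net charge of the gel, `Z_net`, is this
#' profile evaluated at the geometric radius.
#'
#' @param frames list of N x 3 position matrices.
#' @param sys the `ng_system`.
#' @param bin_width radial bin width (nm).
#' @param r_max outermost radius (nm); default `box/2`.
#' @return A data.frame with `r` (outer bin edges) and `q_enc` (e).
#' @export
net_charge_profile <- function(frames, sys, bin_width = 0.5,
                               r_max = NULL) {
  edges <- .bin_grid(sys, bin_width, r_max)
  r_out <- edges[-1]
  acc <- numeric(length(r_out))
  for (pos in frames) {
    cm <- .frame_cm(pos, sys)
    d <- .mi_dist(cm, pos, sys$box)
    idx <- findInterval(d, edges)   # bins [e_i, e_{i+1}), d = 0 counts
    keep <- idx >= 1 & idx <= length(r_out)
    perbin <- vapply(seq_along(r_out), function(b) {
      sum(sys$valence[keep & idx == b])
    }, numeric(1))
    acc <- acc + cumsum(perbin)
  }
  data.frame(r = r_out, q_enc = acc / length(frames))
}

#' Net charge at the gel surface
#'
#' @inheritParams net_charge_profile
#' @param r_ng geometric radius (nm).
#' @return Mean enclosed charge at `r_ng` (e), by linear interpolation
#'   of the cumulative profile.
#' @export
net_charge_at <- function(frames, sys, r_ng, bin_width = 0.5) {
  prof <- net_charge_profile(frames, sys, bin_width)
  stats::approx(c(0, prof$r), c(0, prof$q_enc), xout = r_ng,
                rule = 2)$y
}

#' Spherically averaged electrostatic potential profile
#'
#' Gauss' law gives the radial field from the enclosed charge,
#' \eqn{E(r) = Q_{enc}(r) e / (4\pi\epsilon_0\epsilon_r(T) r^2)}, and
#' the dimensionless potential follows by inward quadrature,
#' \eqn{\psi(r) = -\int_{L/2}^{r} E\, dr'} (trapezoidal rule on the bin
#' grid), so \eqn{\psi(L/2) = 0} by construction. In kT units
#' \eqn{E(r) = l_B Q_{enc}(r)/r^2}.
#'
#' @inheritParams net_charge_profile
#' @param T_K temperature (K).
#' @return A data.frame with `r`, `q_enc`, and dimensionless `psi`
#'   (\eqn{e\psi/k_BT}).
#' @export
potential_profile <- function(frames, sys, T_K, bin_width = 0.5) {
  prof <- net_charge_profile(frames, sys, bin_width,
                             r_max = sys$box / 2)
  lB <- bjerrum_length(T_K)
  E <- lB * prof$q_enc / prof$r^2
  n <- length(E)
  # psi(r_i) = sum of trapezoids from r_i to r_n (= L/2)
  dr <- diff(prof$r)
  seg <- (E[-n] + E[-1]) / 2 * dr
  psi <- rev(c(0, cumsum(rev(seg))))
  prof$psi <- psi
  prof
}

#' Surface electrostatic potential
#'
#' @inheritParams potential_profile
#' @param r_ng geometric radius (nm).
#' @return Dimensionless \eqn{e\psi(R_{NG})/k_BT}.
#' @export
surface_potential <- function(frames, sys, r_ng, T_K,
                              bin_width = 0.5) {
  prof <- potential_profile(frames, sys, T_K, bin_width)
  stats::approx(prof$r, prof$psi, xout = r_ng, rule = 2)$y
}

#' Nanoparticle-nanoparticle radial distribution function
#'
#' Standard pair-distance histogram (minimum image), normalized by the
#' ideal-gas expectation at the overall nanoparticle number density of
#' the box.
#'
#' @inheritParams net_charge_profile
#' @param bin_width histogram bin width (nm); the default resolves the
#'   contact peak of 5 nm particles.
#' @return A data.frame with bin centres `r` and `g`.
#' @export
rdf_np_np <- function(frames, sys, bin_width = 0.1, r_max = NULL) {
  nps <- which_species(sys, "nanoparticle")
  if (length(nps) < 2) stop("need at least two nanoparticles")
  if (is.null(r_max)) r_max <- sys$box / 2
  edges <- seq(0, r_max, by = bin_width)
  counts <- numeric(length(edges) - 1)
  for (pos in frames) {
    p <- pos[nps, , drop = FALSE]
    for (i in seq_len(nrow(p) - 1)) {
      d <- .mi_dist(p[i, ], p[-seq_len(i), , drop = FALSE], sys$box)
      h <- graphics::hist(d[d < r_max], breaks = edges, plot = FALSE)
      counts <- counts + h$counts
    }
  }
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  shell_v <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  npairs <- length(nps) * (length(nps) - 1) / 2
  # ideal-gas expectation: each unordered pair falls in the shell with
  # probability shell volume / box volume (minimum image, r < L/2)
  ideal <- length(frames) * npairs * shell_v / sys$box^3
  data.frame(r = centres, g = counts / ideal)
}

#' Radial number-density profile of one species
#'
#' Per-shell number density (count / shell volume) around the network
#' centre of mass, frame-averaged.
#'
#' @inheritParams net_charge_profile
#' @param species role name (`"nanoparticle"`, `"anion"`, ...).
#' @param normalize_r divide the abscissa by `r_ng`.
#' @param r_ng geometric radius (nm), required when `normalize_r`.
#' @return A data.frame with bin centres `r` (nm, or `r / r_ng`) and
#'   `density` (1/nm^3).
#' @export
density_profile <- function(frames, sys, species, bin_width = 0.5,
                            r_max = NULL, normalize_r = FALSE,
                            r_ng = NULL) {
  ids <- which_species(sys, species)
  if (is.null(r_max)) r_max <- sys$box / 2
  edges <- seq(0, r_max, by = bin_width)
  counts <- numeric(length(edges) - 1)
  for (pos in frames) {
    cm <- .frame_cm(pos, sys)
    d <- .mi_dist(cm, pos[ids, , drop = FALSE], sys$box)
    h <- graphics::hist(d[d < r_max], breaks = edges, plot = FALSE)
    counts <- counts + h$counts
  }
  shell_v <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  out <- data.frame(r = centres,
                    density = counts / (length(frames) * shell_v))
  if (normalize_r) {
    if (is.null(r_ng)) stop("normalize_r = TRUE requires r_ng")
    out$r <- out$r / r_ng
  }
  out
}

#' Summarise a set of production runs at one temperature
#'
#' Production-phase means of the gel observables, with the statistical
#' error estimated as the standard deviation across the independent
#' runs (at least three seeds recommended).
#'
#' @param runs list of `ng_run` objects (independent seeds, same
#'   system and temperature).
#' @return A one-row data.frame: `T_C`, `r_gyr`, `r_ng`, `n_inside`
#'   and their `*_sd` columns.
#' @export
summarize_runs <- function(runs) {
  one <- function(run) {
    prod <- run$samples[run$samples$phase == 1, ]
    c(r_gyr = mean(prod$r_gyr), n_inside = mean(prod$n_inside))
  }
  m <- t(vapply(runs, one, numeric(2)))
  data.frame(T_C = runs[[1]]$schedule$temperature_C,
             r_gyr = mean(m[, "r_gyr"]),
             r_gyr_sd = stats::sd(m[, "r_gyr"]),
             r_ng = geometric_radius(mean(m[, "r_gyr"])),
             r_ng_sd = geometric_radius(stats::sd(m[, "r_gyr"])),
             n_inside = mean(m[, "n_inside"]),
             n_inside_sd = stats::sd(m[, "n_inside"]))
}
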