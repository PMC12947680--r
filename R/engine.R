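# Metropolis Monte Carlo driver. The sampling loop itself is compiled
# (src/engine.cpp); this file holds the user-facing configuration
# objects, the pure-R reference implementations of the elementary move
# rules, and the run wrapper.

#' Metropolis acceptance rule
#'
#' Accept iff `rng_draw < min(1, exp(-delta_u))`, with `delta_u` in kT
#' units. Downhill and null moves are always accepted.
#'
#' @param delta_u energy change of the proposed move (kT).
#' @param rng_draw uniform draw on `[0, 1)`.
#' @return Logical.
#' @export
metropolis_accept <- function(delta_u, rng_draw) {
  rng_draw < pmin(1, exp(-delta_u))
}

#' Select a nanoparticle-counterion cluster
#'
#' A nanoparticle moves together with its nearest counterions: the
#' cations whose centres lie in a spherical layer outside the
#' NP-cation contact distance, of thickness twice the cation diameter
#' by default (centre distance in
#' `[(d_NP + d_cat)/2, (d_NP + d_cat)/2 + shell]`).
#'
#' @param sys an `ng_system`.
#' @param np_index bead index of a nanoparticle.
#' @param shell layer thickness (nm); default `2 *` cation diameter.
#' @return Integer vector: the nanoparticle plus member cations.
#' @export
select_cluster <- function(sys, np_index, shell = NULL) {
  if (sys$species[np_index] != "nanoparticle") {
    stop("np_index must refer to a nanoparticle")
  }
  cats <- which_species(sys, "cation")
  if (!length(cats)) return(np_index)
  d_cat <- sys$diameter[cats[1]]
  if (is.null(shell)) shell <- 2 * d_cat
  rin <- (sys$diameter[np_index] + d_cat) / 2
  d <- .mi_dist(sys$pos[np_index, ], sys$pos[cats, , drop = FALSE],
                sys$box)
  c(np_index, cats[d >= rin & d <= rin + shell])
}

#' Multiplicative step-size adaptation
#'
#' During equilibration the maximum displacement of every move class is
#' nudged towards the value giving ~50% acceptance: multiplied by
#' `up` when the windowed acceptance rate exceeds 1/2 and by `down`
#' otherwise, clamped to `[1e-3, box/4]` nm. Step sizes are frozen
#' during production.
#'
#' @param accepted,attempted accepted and attempted move counts over
#'   the last adaptation window (same length as `max_disp`).
#' @param max_disp current maximum displacements (nm).
#' @param box box side (nm), for the upper clamp.
#' @param up,down multiplicative factors.
#' @return Updated `max_disp`.
#' @export
adapt_step_sizes <- function(accepted, attempted, max_disp, box,
                             up = 1.05, down = 0.95) {
  rate <- ifelse(attempted > 0, accepted / attempted, 0.5)
  out <- max_disp * ifelse(rate > 0.5, up, down)
  pmin(box / 4, pmax(1e-3, out))
}

#' Move-mix and step-size settings
#'
#' @param max_disp named numeric: initial maximum displacements (nm)
#'   for `network`, `anion`, `cation`, `nanoparticle` single-bead moves
#'   and `cluster` translations, plus the half-width `scale` of the
#'   log-scaling move. All are adapted towards 50% acceptance during
#'   equilibration.
#' @param cluster_shell thickness of the counterion shell (nm);
#'   default twice the cation diameter (set at run time).
#' @param cluster_interval attempt one cluster move every this many
#'   movements (default: the number of beads, so each nanoparticle gets
#'   roughly one cluster attempt per sweep).
#' @param scale_interval attempt one whole-network scaling move every
#'   this many movements during equilibration (default `5 *` beads).
#' @param scale_moves enable network expansion/contraction moves during
#'   thermalization.
#' @param adapt_interval adaptation window, in attempts per move class.
#' @return A list of class `move_settings`.
#' @export
move_settings <- function(max_disp = c(network = 0.25, anion = 1.0,
                                       cation = 1.0,
                                       nanoparticle = 0.5,
                                       cluster = 0.5, scale = 0.05),
                          cluster_shell = NULL,
                          cluster_interval = NULL,
                          scale_interval = NULL,
                          scale_moves = TRUE,
                          adapt_interval = 2000) {
  stopifnot(all(max_disp > 0), adapt_interval >= 1)
  structure(list(max_disp = max_disp, cluster_shell = cluster_shell,
                 cluster_interval = cluster_interval,
                 scale_interval = scale_interval,
                 scale_moves = isTRUE(scale_moves),
                 adapt_interval = adapt_interval),
            class = "move_settings")
}

#' Run schedule
#'
#' @param temperature_C run temperature in degrees Celsius.
#' @param n_equil equilibration movements (attempts).
#' @param n_prod production movements.
#' @param sample_interval record observables (and frames) every this
#'   many movements.
#' @param seed integer RNG seed; identical seed and inputs give a
#'   bit-identical trajectory.
#' @return A list of class `run_schedule`.
#' @export
run_schedule <- function(temperature_C = 20, n_equil = 1e5,
                         n_prod = 1e5, sample_interval = 500,
                         seed = 1) {
  stopifnot(n_equil >= 0, n_prod >= 0, sample_interval >= 1)
  structure(list(temperature_C = temperature_C,
                 T_K = celsius_to_kelvin(temperature_C),
                 n_equil = as.double(n_equil),
                 n_prod = as.double(n_prod),
                 sample_interval = as.double(sample_interval),
                 seed = as.integer(seed)),
            class = "run_schedule")
}

.move_class <- function(species) {
  c(monomer = 0L, crosslinker = 0L, anion = 1L, cation = 2L,
    nanoparticle = 3L)[species]
}

#' Run a Monte Carlo simulation
#'
#' Samples the canonical ensemble of the given system at the scheduled
#' temperature: single-bead displacements for all species,
#' nanoparticle-counterion cluster translations, and (during
#' equilibration only) whole-network scaling moves, with step sizes
#' adapted towards 50% acceptance. A proposed cluster translation whose
#' membership would differ when recomputed at the destination is
#' rejected outright, which preserves detailed balance under the
#' symmetric proposal.
#'
#' @param sys an electroneutral `ng_system`.
#' @param schedule a [run_schedule()].
#' @param moves a [move_settings()].
#' @param ewald an [ewald_settings()] (default tuned for `sys$box`).
#' @param store_frames keep production-phase configuration snapshots
#'   (needed for profile observables).
#' @return An `ng_run` list: `samples` (data.frame with step, phase,
#'   r_gyr, n_inside, energy), `frames` (list of N x 3 matrices,
#'   production phase), `system` (final configuration, wrapped),
#'   `acceptance`, `step_sizes`, `energy_running`,
#'   `energy_recomputed`, `schedule`.
#' @export
run_mc <- function(sys, schedule, moves = move_settings(),
                   ewald = ewald_settings(sys$box),
                   store_frames = TRUE) {
  if (total_charge(sys) != 0L) {
    stop("run_mc requires an electroneutral system")
  }
  n <- nrow(sys$pos)
  a <- .sys_args(sys, schedule$T_K, ewald)
  cls <- .move_class(sys$species)
  cats <- which_species(sys, "cation")
  shell <- moves$cluster_shell
  if (is.null(shell)) {
    shell <- 2 * (if (length(cats)) sys$diameter[cats[1]] else
      sys$params$d_ion)
  }
  ci <- moves$cluster_interval
  if (is.null(ci)) ci <- n
  si <- moves$scale_interval
  if (is.null(si)) si <- 5 * n
  step0 <- moves$max_disp[c("network", "anion", "cation",
                            "nanoparticle", "cluster", "scale")]
  res <- cpp_run_mc(a$pos, a$val, a$diam, a$hyd, a$bonds,
                    .network_ids(sys) - 1L, cls, a$L, a$lB, a$alpha,
                    a$rcut, a$nmax, a$epsW, a$ke, a$r0, a$kh, a$rh,
                    a$epsh, schedule$n_equil, schedule$n_prod,
                    schedule$sample_interval, ci, si,
                    moves$scale_moves, moves$adapt_interval,
                    as.numeric(step0), shell, schedule$seed,
                    store_frames)
  out_sys <- sys
  out_sys$pos <- res$pos - sys$box * floor(res$pos / sys$box)
  cls_names <- c("network", "anion", "cation", "nanoparticle",
                 "cluster", "scale")
  acc <- data.frame(class = cls_names, attempts = res$attempts,
                    accepts = res$accepts,
                    rate = ifelse(res$attempts > 0,
                                  res$accepts / res$attempts, NA))
  samples <- res$samples
  samples$r_ng <- sqrt(5 / 3) * samples$r_gyr
  structure(list(samples = samples, frames = res$frames,
                 system = out_sys, acceptance = acc,
                 step_sizes = stats::setNames(res$step_sizes, cls_names),
                 energy_running = res$energy_running,
                 energy_recomputed = res$energy_recomputed,
                 schedule = schedule),
            class = "ng_run")
}

#' @export
print.ng_run <- function(x, ...) {
  sc <- x$schedule
  cat(sprintf("ng_run: %g equil + %g prod movements at %.4g degC (seed %d)\n",
              sc$n_equil, sc$n_prod, sc$temperature_C, sc$seed))
  prod <- x$samples[x$samples$phase == 1, ]
  if (nrow(prod)) {
    cat(sprintf("  production <R_gyr> = %.3f nm, <R_NG> = %.3f nm\n",
                mean(prod$r_gyr), mean(prod$r_ng)))
    if (any(prod$n_inside > 0)) {
      cat(sprintf("  production <N_inside> = %.2f nanoparticles\n",
                  mean(prod$n_inside)))
    }
  }
  cat(sprintf("  energy: running %.6g kT, recomputed %.6g kT\n",
              x$energy_running, x$energy_recomputed))
  invisible(x)
}
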