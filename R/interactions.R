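# Pair potentials and periodic electrostatics. Pairwise energies are
# returned in kT units at the given temperature by default; `unit = "J"`
# gives joules for direct comparison with the tabulated constants.

.to_unit <- function(e_kT, T_K, unit) {
  unit <- match.arg(unit, c("kT", "J"))
  if (unit == "kT") e_kT else e_kT * .const$kB * T_K
}

#' WCA excluded-volume pair energy
#'
#' Purely repulsive truncated-shifted Lennard-Jones form,
#' \eqn{\epsilon_{WCA}[(d/r)^{12} - (d/r)^6 + 1/4]} for
#' \eqn{r \le 2^{1/6} d} and zero beyond, with
#' \eqn{d = (d_i + d_j)/2}. The bracket vanishes continuously at the
#' cutoff. With `wca_four_epsilon` set in the model parameters the
#' conventional prefactor 4 is applied instead.
#'
#' @param r centre-to-centre distance (nm), > 0.
#' @param d_i,d_j bead diameters (nm).
#' @param params an [ng_model_params()].
#' @param T_K temperature (K), used only to express the result in kT.
#' @param unit `"kT"` (default) or `"J"`.
#' @return Pair energy.
#' @export
pair_wca <- function(r, d_i, d_j, params = ng_model_params(),
                     T_K = 298.15, unit = "kT") {
  if (any(r <= 0)) stop("bead overlap: r must be positive")
  d <- (d_i + d_j) / 2
  pref <- params$eps_wca * (if (params$wca_four_epsilon) 4 else 1)
  e_J <- ifelse(r <= 2^(1 / 6) * d,
                pref * ((d / r)^12 - (d / r)^6 + 0.25), 0)
  .to_unit(e_J / (.const$kB * T_K), T_K, unit)
}

#' Harmonic bond pair energy
#'
#' \eqn{u(r) = k_e (r - r_0)^2 / 2} between chain-adjacent beads and
#' chain ends and their cross-linkers.
#'
#' @inheritParams pair_wca
#' @export
pair_bond <- function(r, params = ng_model_params(), T_K = 298.15,
                      unit = "kT") {
  if (any(r < 0)) stop("r must be non-negative")
  # k_e in N/m, r in nm -> J
  e_J <- 0.5 * params$k_e * ((r - params$r0) * 1e-9)^2
  .to_unit(e_J / (.const$kB * T_K), T_K, unit)
}

#' Hydrophobic pair attraction
#'
#' Sigmoidal approximation to a square well,
#' \eqn{u_h(r) = -(\epsilon_h(T)/2)(1 - \tanh(k_h (r - r_h)))}, acting
#' only between uncharged, hydrophobic-eligible network beads. The well
#' depth \eqn{\epsilon_h(T)} switches on with temperature
#' ([hydrophobic_depth()]), which is what drives thermal collapse.
#'
#' @inheritParams pair_wca
#' @param z_i,z_j bead valences; any charged bead switches the
#'   interaction off.
#' @param eligible_i,eligible_j hydrophobic eligibility flags (network
#'   species only).
#' @export
pair_hydrophobic <- function(r, T_K, z_i = 0, z_j = 0,
                             eligible_i = TRUE, eligible_j = TRUE,
                             params = ng_model_params(), unit = "kT") {
  if (any(r < 0)) stop("r must be non-negative")
  on <- (z_i == 0) & (z_j == 0) & eligible_i & eligible_j
  eps_h <- hydrophobic_depth(T_K, params)
  e_J <- ifelse(on,
                -eps_h / 2 * (1 - tanh(params$k_h * (r - params$r_h))), 0)
  .to_unit(e_J / (.const$kB * T_K), T_K, unit)
}

#' Coulomb pair energy
#'
#' \eqn{u(r) = z_i z_j l_B(T) / r} in kT units (the non-periodic,
#' unscreened form; periodic systems use [ewald_total()]).
#'
#' @inheritParams pair_wca
#' @param z_i,z_j valences (elementary units).
#' @export
pair_coulomb <- function(r, z_i, z_j, T_K, unit = "kT") {
  if (any(r <= 0)) stop("charge overlap: r must be positive")
  .to_unit(z_i * z_j * bjerrum_length(T_K) / r, T_K, unit)
}

#' Ewald summation settings
#'
#' The splitting parameter, real-space cutoff and reciprocal-space
#' extent are tuned from the standard truncation-error estimates so
#' that both halves of the sum are converged to `target_rel_accuracy`:
#' with \eqn{s = \sqrt{-\ln \delta}}, \eqn{\alpha = s / r_{cut}} and
#' the integer cutoff \eqn{n_{max} = \lceil s \alpha L / \pi \rceil}.
#'
#' @param box cubic box side (nm).
#' @param target_rel_accuracy relative truncation error target.
#' @param r_cut real-space cutoff (nm); default `box / 2`.
#' @param alpha,k_max override the tuned splitting parameter (1/nm) and
#'   integer reciprocal cutoff.
#' @return A list of class `ewald_settings`.
#' @export
ewald_settings <- function(box, target_rel_accuracy = 1e-4,
                           r_cut = NULL, alpha = NULL, k_max = NULL) {
  stopifnot(box > 0, target_rel_accuracy > 0)
  if (is.null(r_cut)) r_cut <- box / 2
  if (r_cut > box / 2) stop("r_cut must not exceed box/2")
  s <- sqrt(-log(target_rel_accuracy))
  if (is.null(alpha)) alpha <- s / r_cut
  if (is.null(k_max)) k_max <- ceiling(s * alpha * box / pi)
  structure(list(box = box, alpha = alpha, r_cut = r_cut,
                 k_max = as.integer(k_max),
                 target_rel_accuracy = target_rel_accuracy),
            class = "ewald_settings")
}

# flatten an ng_system + thermo state + ewald settings into the
# argument list of the compiled routines (0-based bonds)
.sys_args <- function(sys, T_K, settings) {
  st <- thermo_state(T_K, sys$params)
  bonds <- if (is.null(sys$bonds) || nrow(sys$bonds) == 0) {
    matrix(integer(), 0, 2)
  } else sys$bonds - 1L
  list(pos = sys$pos, val = sys$valence, diam = sys$diameter,
       hyd = sys$hydrophobic, bonds = bonds,
       L = sys$box, lB = st$l_B, alpha = settings$alpha,
       rcut = settings$r_cut, nmax = settings$k_max,
       epsW = st$eps_wca_kT, ke = st$k_e_kT, r0 = sys$params$r0,
       kh = sys$params$k_h, rh = sys$params$r_h, epsh = st$eps_h_kT,
       st = st)
}

#' Total periodic electrostatic energy (Ewald summation)
#'
#' Real-space, reciprocal-space and self terms under conducting
#' (tinfoil) boundary conditions, in kT units. The configuration must
#' be electroneutral.
#'
#' @param sys an `ng_system`.
#' @param T_K temperature (K).
#' @param settings an [ewald_settings()]; default tuned for the
#'   system's box.
#' @return A list with `real`, `recip`, `self` and `total` (kT).
#' @export
ewald_total <- function(sys, T_K,
                        settings = ewald_settings(sys$box)) {
  if (total_charge(sys) != 0L) {
    stop("Ewald sum requires an electroneutral configuration")
  }
  st <- thermo_state(T_K, sys$params)
  cpp_ewald_energy(sys$pos, sys$valence, sys$box, st$l_B,
                   settings$alpha, settings$r_cut, settings$k_max)
}

#' Full energy breakdown of a configuration
#'
#' @inheritParams ewald_total
#' @return A list with `wca`, `bond`, `hydrophobic`, `electrostatic`
#'   and `total`, all in kT at `T_K`.
#' @export
energy_breakdown <- function(sys, T_K,
                             settings = ewald_settings(sys$box)) {
  a <- .sys_args(sys, T_K, settings)
  cpp_total_energy(a$pos, a$val, a$diam, a$hyd, a$bonds, a$L, a$lB,
                   a$alpha, a$rcut, a$nmax, a$epsW, a$ke, a$r0, a$kh,
                   a$rh, a$epsh)
}

#' Incremental energy change of a rigid translation
#'
#' Computes \eqn{\Delta U = U(\mathrm{after}) - U(\mathrm{before})} for
#' displacing one bead or one rigid cluster, recomputing only the
#' pair terms that involve moved beads and updating the Ewald
#' structure factors rather than rebuilding them. Used by the sampler;
#' exposed so the bookkeeping can be validated against a full
#' recomputation.
#'
#' @inheritParams ewald_total
#' @param moved integer vector of bead indices (1-based).
#' @param disp length-3 displacement vector (nm).
#' @return Energy difference in kT.
#' @export
delta_energy <- function(sys, moved, disp, T_K,
                         settings = ewald_settings(sys$box)) {
  stopifnot(all(moved >= 1), all(moved <= nrow(sys$pos)),
            length(disp) == 3)
  a <- .sys_args(sys, T_K, settings)
  cpp_delta_energy(a$pos, a$val, a$diam, a$hyd, a$bonds, a$L, a$lB,
                   a$alpha, a$rcut, a$nmax, a$epsW, a$ke, a$r0, a$kh,
                   a$rh, a$epsh, as.integer(moved) - 1L,
                   as.numeric(disp))
}
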