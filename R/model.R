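# Physical constants (CODATA, SI)
.const <- list(
  e    = 1.602176634e-19,  # C
  eps0 = 8.8541878128e-12, # F/m
  kB   = 1.380649e-23      # J/K
)

#' Default coarse-grained model parameters
#'
#' Returns the interaction constants of the bead-spring nanogel model:
#' the WCA excluded-volume strength, the harmonic bond constant and
#' equilibrium length, and the parameters of the temperature-switched
#' hydrophobic well. All energies are stored in joules and converted to
#' units of \eqn{k_B T} at the simulation temperature when a system is
#' assembled; lengths are in nm.
#'
#' @param eps_wca WCA energy scale (J).
#' @param k_e bond elastic constant (N/m).
#' @param r0 bond equilibrium length (nm).
#' @param k_h slope of the hydrophobic sigmoid (1/nm).
#' @param r_h range of the hydrophobic attraction (nm).
#' @param eps_max maximum depth of the hydrophobic well (J), reached at
#'   high temperature.
#' @param T_half temperature at which the well depth equals
#'   `eps_max / 2` (K).
#' @param k_half slope parameter of the depth-vs-temperature sigmoid
#'   (1/K).
#' @param d_monomer,d_ion,d_nanoparticle bead diameters (nm). Ion
#'   diameters include the hydration shell.
#' @param wca_four_epsilon if `TRUE`, multiply the WCA bracket by the
#'   conventional prefactor 4 (i.e. read `eps_wca` as the Lennard-Jones
#'   epsilon). The default applies `eps_wca` directly to the bracket.
#' @return An object of class `ng_model_params` (a named list).
#' @export
ng_model_params <- function(eps_wca = 4.11e-21,
                            k_e = 0.40,
                            r0 = 0.65,
                            k_h = 12.1,
                            r_h = 0.90,
                            eps_max = 5.5e-21,
                            T_half = 307.5,
                            k_half = 0.0667,
                            d_monomer = 0.65,
                            d_ion = 0.70,
                            d_nanoparticle = 5.00,
                            wca_four_epsilon = FALSE) {
  p <- list(eps_wca = eps_wca, k_e = k_e, r0 = r0, k_h = k_h, r_h = r_h,
            eps_max = eps_max, T_half = T_half, k_half = k_half,
            d_monomer = d_monomer, d_ion = d_ion,
            d_nanoparticle = d_nanoparticle,
            wca_four_epsilon = isTRUE(wca_four_epsilon))
  num <- setdiff(names(p), "wca_four_epsilon")
  if (any(!vapply(p[num], is.numeric, logical(1))) ||
      any(unlist(p[num]) <= 0)) {
    stop("all model parameters must be strictly positive numbers")
  }
  p[num] <- lapply(p[num], as.numeric)   # config round-trip stability
  class(p) <- "ng_model_params"
  p
}

#' @export
print.ng_model_params <- function(x, ...) {
  cat("Coarse-grained nanogel model parameters\n")
  cat(sprintf("  eps_WCA  %.3g J   (4-eps prefactor: %s)\n",
              x$eps_wca, x$wca_four_epsilon))
  cat(sprintf("  k_e      %.3g N/m, r_0 %.3g nm\n", x$k_e, x$r0))
  cat(sprintf("  hydrophobic: k_h %.3g 1/nm, r_h %.3g nm, eps_max %.3g J\n",
              x$k_h, x$r_h, x$eps_max))
  cat(sprintf("  depth switch: T_1/2 %.4g K, k_1/2 %.3g 1/K\n",
              x$T_half, x$k_half))
  cat(sprintf("  diameters (nm): monomer %.3g, ion %.3g, NP %.3g\n",
              x$d_monomer, x$d_ion, x$d_nanoparticle))
  invisible(x)
}

.check_temperature <- function(T_K) {
  if (!is.numeric(T_K) || any(!is.finite(T_K)) || any(T_K <= 0)) {
    stop("temperature must be a positive, finite number (K)")
  }
  if (any(T_K < 273) || any(T_K > 373)) {
    warning("temperature outside the 273-373 K range where the ",
            "solvent permittivity fit is reliable")
  }
  invisible(T_K)
}

#' Relative permittivity of water
#'
#' Empirical polynomial fit of the static relative permittivity of
#' liquid water as a function of absolute temperature.
#'
#' @param T_K absolute temperature (K).
#' @return Dimensionless relative permittivity.
#' @examples
#' relative_permittivity(298.15) # about 78.4
#' @export
relative_permittivity <- function(T_K) {
  .check_temperature(T_K)
  5321 / T_K + 233.76 - 0.9297 * T_K +
    0.1417e-2 * T_K^2 - 0.8292e-6 * T_K^3
}

#' Bjerrum length
#'
#' Distance at which two elementary charges in the solvent dielectric
#' interact with energy \eqn{k_B T}:
#' \eqn{l_B = e^2 / (4 \pi \epsilon_0 \epsilon_r(T) k_B T)}.
#'
#' @inheritParams relative_permittivity
#' @return Bjerrum length in nm.
#' @examples
#' bjerrum_length(298.15) # about 0.715 nm
#' @export
bjerrum_length <- function(T_K) {
  eps_r <- relative_permittivity(T_K)
  with(.const, e^2 / (4 * pi * eps0 * eps_r * kB * T_K)) * 1e9
}

#' Temperature-dependent hydrophobic well depth
#'
#' The depth of the short-ranged attraction between uncharged network
#' beads grows sigmoidally with temperature,
#' \eqn{\epsilon_h(T) = (\epsilon_{max}/2)(1 + \tanh(k_{1/2}(T - T_{1/2})))},
#' which drives the collapse of the network on heating.
#'
#' @inheritParams relative_permittivity
#' @param params an [ng_model_params()] object.
#' @return Well depth in joules.
#' @export
hydrophobic_depth <- function(T_K, params = ng_model_params()) {
  if (!is.numeric(T_K) || any(!is.finite(T_K)) || any(T_K <= 0)) {
    stop("temperature must be a positive, finite number (K)")
  }
  params$eps_max / 2 * (1 + tanh(params$k_half * (T_K - params$T_half)))
}

#' Temperature-derived model state
#'
#' Bundles the per-temperature scalar quantities the simulation needs:
#' solvent permittivity, Bjerrum length, hydrophobic well depth, and the
#' thermal energy used to express all interactions in \eqn{k_B T} units.
#'
#' @inheritParams hydrophobic_depth
#' @return A list of class `ng_thermo_state` with elements `T_K`,
#'   `eps_r`, `l_B` (nm), `eps_h` (J), `kT` (J), `eps_h_kT`,
#'   `eps_wca_kT`, `k_e_kT` (kT/nm^2).
#' @export
thermo_state <- function(T_K, params = ng_model_params()) {
  eps_r <- relative_permittivity(T_K)
  kT <- .const$kB * T_K
  eps_h <- hydrophobic_depth(T_K, params)
  st <- list(
    T_K = T_K,
    eps_r = eps_r,
    l_B = bjerrum_length(T_K),
    eps_h = eps_h,
    kT = kT,
    eps_h_kT = eps_h / kT,
    eps_wca_kT = params$eps_wca / kT * (if (params$wca_four_epsilon) 4 else 1),
    # k_e in N/m = J/m^2 -> J/nm^2 -> kT/nm^2
    k_e_kT = params$k_e * 1e-18 / kT
  )
  class(st) <- "ng_thermo_state"
  st
}

#' Convert Celsius to Kelvin
#'
#' Temperatures are presented in degrees Celsius throughout the
#' user-facing interface (the experimental convention for
#' thermoresponsive gels) and converted to Kelvin internally.
#'
#' @param T_C temperature in degrees Celsius.
#' @return Temperature in K.
#' @export
celsius_to_kelvin <- function(T_C) T_C + 273.15
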