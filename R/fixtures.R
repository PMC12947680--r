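# Deterministic generators of small reference systems, used by the
# test-suite oracles and available to users for quick experiments.
# Every fixture is reproduced bit-identically from its arguments and
# seed.

#' Miniature nanogel fixture
#'
#' A trimmed-diamond network with a handful of cross-linkers and short
#' chains: the same construction as [build_network()] at a size where
#' the bond list can be enumerated by hand, in a box scaled to four
#' times the network diameter. Optionally charged and populated with
#' counterions and (scaled-down) nanoparticles.
#'
#' @param n_crosslinkers small cross-linker count (<= 20).
#' @param monomers_per_chain chain length (e.g. 3 or 5).
#' @param charged_per_chain charged monomers per chain.
#' @param n_nanoparticles number of nanoparticles to add.
#' @param np_valence nanoparticle valence (default -5).
#' @param d_np nanoparticle diameter (nm). The default, 2 nm, scales
#'   the 5 nm particle down in proportion to the miniature gel.
#' @param seed RNG seed for the random insertion step.
#' @param params model parameters.
#' @return An electroneutral `ng_system`.
#' @export
make_tiny_network <- function(n_crosslinkers = 8, monomers_per_chain = 3,
                              charged_per_chain = 0,
                              n_nanoparticles = 0, np_valence = -5L,
                              d_np = 2.0, seed = 1,
                              params = ng_model_params()) {
  stopifnot(n_crosslinkers <= 20)
  sys <- build_network(n_chains = NULL,
                       monomers_per_chain = monomers_per_chain,
                       n_crosslinkers = n_crosslinkers,
                       bond_length = params$r0, params = params)
  sys <- assign_chain_charges(sys, charged_per_chain)
  populate_box(sys, n_nanoparticles = n_nanoparticles,
               np_valence = np_valence, d_np = d_np, seed = seed)
}

#' Rock-salt crystal fixture for Ewald validation
#'
#' Alternating +1/-1 charges on a cubic lattice filling the periodic
#' box: the Ewald energy per ion pair equals the Madelung constant in
#' lattice units, a stringent closed-form check of the summation.
#'
#' @param n_cells_per_side unit cells per box edge (the box holds
#'   `8 * n^3` charges).
#' @param spacing nearest-neighbour distance (nm).
#' @param params model parameters.
#' @return An `ng_system` of alternating anions and cations (bead
#'   diameters are set small so excluded volume plays no role).
#' @export
make_madelung_crystal <- function(n_cells_per_side = 2, spacing = 1,
                                  params = ng_model_params()) {
  m <- 2 * n_cells_per_side            # ions per edge
  g <- as.matrix(expand.grid(i = 0:(m - 1), j = 0:(m - 1),
                             k = 0:(m - 1)))
  pos <- g * spacing
  val <- as.integer(ifelse((rowSums(g)) %% 2 == 0, 1L, -1L))
  ng_system(box = m * spacing, pos = pos,
            species = ifelse(val > 0, "cation", "anion"),
            valence = val,
            diameter = rep(spacing / 100, nrow(pos)),
            params = params)
}

#' Analytic reference systems
#'
#' Named small systems with closed-form expectations:
#' `ideal_gas` (uncharged, point-like beads: every move accepted),
#' `two_charge_box` (one +1/-1 pair at a set separation),
#' `harmonic_dimer` (two bonded beads, for Boltzmann-sampling checks),
#' `uniform_sphere_cloud` (uncharged beads uniform in a solid sphere,
#' the \eqn{R_{gyr} = \sqrt{3/5} R} oracle).
#'
#' @param kind one of the names above.
#' @param n number of beads (where applicable).
#' @param box box side (nm).
#' @param separation pair separation (nm), for `two_charge_box`.
#' @param radius sphere radius (nm), for `uniform_sphere_cloud`.
#' @param seed RNG seed.
#' @param params model parameters.
#' @return An `ng_system`.
#' @export
make_reference_system <- function(kind, n = 100, box = 20,
                                  separation = 1, radius = 10,
                                  seed = 1,
                                  params = ng_model_params()) {
  kind <- match.arg(kind, c("ideal_gas", "two_charge_box",
                            "harmonic_dimer", "uniform_sphere_cloud"))
  if (kind == "ideal_gas") {
    pos <- with_seed(seed, matrix(stats::runif(3 * n, 0, box), n, 3))
    return(ng_system(box = box, pos = pos,
                     species = rep("anion", n),
                     valence = integer(n),
                     diameter = rep(1e-3, n), params = params))
  }
  if (kind == "two_charge_box") {
    pos <- rbind(c(box / 2, box / 2, box / 2),
                 c(box / 2 + separation, box / 2, box / 2))
    return(ng_system(box = box, pos = pos,
                     species = c("cation", "anion"),
                     valence = c(1L, -1L),
                     diameter = rep(1e-3, 2), params = params))
  }
  if (kind == "harmonic_dimer") {
    pos <- rbind(c(box / 2, box / 2, box / 2),
                 c(box / 2 + params$r0, box / 2, box / 2))
    bonds <- matrix(c(1L, 2L), 1, 2)
    return(ng_system(box = box, pos = pos,
                     species = rep("monomer", 2),
                     valence = integer(2),
                     diameter = rep(params$d_monomer, 2),
                     bonds = bonds, chains = list(1:2),
                     params = params))
  }
  # uniform_sphere_cloud: rejection sampling inside radius
  pos <- with_seed(seed, {
    out <- matrix(0, n, 3)
    k <- 0
    while (k < n) {
      p <- stats::runif(3, -radius, radius)
      if (sum(p^2) <= radius^2) {
        k <- k + 1
        out[k, ] <- p
      }
    }
    out
  })
  # a cloud counts as "network" so the R_gyr machinery applies, but
  # carries no bonds: unwrapping is a no-op in a big-enough box
  ng_system(box = max(box, 4 * radius), pos = pos + max(box, 4 * radius) / 2,
            species = rep("monomer", n), valence = integer(n),
            diameter = rep(1e-3, n), params = params)
}
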