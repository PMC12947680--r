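# Nanogel network construction: cross-linkers on a trimmed diamond
# lattice, joined by straight chains of monomeric units.

# Diamond lattice sites (units of the cubic lattice constant a):
# FCC translations + two-atom basis (0,0,0), (1/4,1/4,1/4).
.diamond_sites <- function(nmax) {
  g <- as.matrix(expand.grid(i = -nmax:nmax, j = -nmax:nmax,
                             k = -nmax:nmax))
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  out <- matrix(0, 0, 3)
  for (b in seq_len(4)) {
    s <- sweep(g, 2, fcc[b, ], "+")
    out <- rbind(out, s, sweep(s, 2, c(.25, .25, .25), "+"))
  }
  out
}

# Select exactly n sites of the diamond lattice inside a trimming
# sphere. The sphere is centred on the interstitial point
# (1/2, 1/2, 1/2)a: for the reference gel size (66 cross-linkers) this
# centre yields a connected cluster whose surface sites keep two or
# three neighbours (no dangling sites) and exactly 100 nearest-
# neighbour links. Ties at the trimming radius are broken by
# lexicographic site order, so any count is reproducible.
.trim_diamond <- function(n_crosslinkers) {
  nmax <- max(2L, ceiling((3 * n_crosslinkers / (4 * pi * 8))^(1 / 3)) + 2L)
  sites <- .diamond_sites(nmax)
  centre <- c(.5, .5, .5)
  d2 <- rowSums(sweep(sites, 2, centre)^2)
  ord <- order(d2, sites[, 1], sites[, 2], sites[, 3])
  if (n_crosslinkers > length(ord)) {
    stop("internal: diamond lattice extent too small")
  }
  sites[ord[seq_len(n_crosslinkers)], , drop = FALSE]
}

#' Build a nanogel polymer network
#'
#' Cross-linkers are placed on diamond-lattice sites; a trimming sphere
#' keeps exactly `n_crosslinkers` of them; every surviving
#' nearest-neighbour pair of sites is joined by a straight chain of
#' `monomers_per_chain` equally spaced monomeric units, so chains start
#' at their relaxed bond length when the lattice spacing is
#' `(monomers_per_chain + 1) * bond_length` (the default). Interior
#' cross-linkers are tetrafunctional; those at the surface of the
#' trimmed sphere join only two or three chains. With the reference
#' counts (66 cross-linkers, 30-mer chains) the builder produces
#' exactly 100 chains and 3066 network beads.
#'
#' @param n_chains expected number of chains, or NULL to accept
#'   whatever the trimmed lattice produces. If supplied and the built
#'   network differs, the builder fails with a diagnostic.
#' @param monomers_per_chain number of monomeric units per chain.
#' @param n_crosslinkers number of cross-linkers to keep.
#' @param bond_length relaxed bond length r0 (nm).
#' @param box cubic box side (nm); NULL picks 4x the network diameter.
#' @param params an [ng_model_params()] object.
#' @return An `ng_system` containing only the (uncharged) network,
#'   centred in the box.
#' @export
build_network <- function(n_chains = NULL, monomers_per_chain = 30,
                          n_crosslinkers = 66,
                          bond_length = ng_model_params()$r0,
                          box = NULL, params = ng_model_params()) {
  stopifnot(n_crosslinkers >= 1, monomers_per_chain >= 1,
            bond_length > 0)
  xl <- .trim_diamond(n_crosslinkers)
  a <- 4 * (monomers_per_chain + 1) * bond_length / sqrt(3)
  xl <- xl * a
  nn <- (monomers_per_chain + 1) * bond_length
  # nearest-neighbour pairs among surviving sites
  edges <- matrix(0L, 0, 2)
  if (n_crosslinkers > 1) {
    D <- as.matrix(stats::dist(xl))
    hit <- which(abs(D - nn) < 1e-6 * nn & upper.tri(D), arr.ind = TRUE)
    edges <- matrix(as.integer(hit), ncol = 2)
  }
  if (!is.null(n_chains) && nrow(edges) != n_chains) {
    stop(sprintf(paste0(
      "trimming %d cross-linkers yields %d connecting chains, not the ",
      "%d requested; pick a cross-linker count whose trimmed cluster ",
      "has the desired connectivity"),
      n_crosslinkers, nrow(edges), n_chains))
  }
  m <- monomers_per_chain
  n_mono <- nrow(edges) * m
  pos <- matrix(0, n_crosslinkers + n_mono, 3)
  pos[seq_len(n_crosslinkers), ] <- xl
  bonds <- matrix(0L, 0, 2)
  chains <- vector("list", nrow(edges))
  nxt <- n_crosslinkers + 1L
  if (nrow(edges)) {
    bonds <- matrix(0L, nrow(edges) * (m + 1), 2)
    bi <- 1L
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      ts <- seq_len(m) / (m + 1)
      seg <- outer(ts, xl[j, ] - xl[i, ]) + rep(xl[i, ], each = m)
      ids <- nxt:(nxt + m - 1L)
      pos[ids, ] <- seg
      chains[[e]] <- ids
      path <- c(i, ids, j)
      for (k in seq_len(m + 1)) {
        bonds[bi, ] <- c(path[k], path[k + 1]); bi <- bi + 1L
      }
      nxt <- nxt + m
    }
  }
  # centre the network in the box
  diam <- if (n_crosslinkers > 1) {
    2 * max(sqrt(rowSums(sweep(pos, 2, colMeans(pos))^2)))
  } else 2 * bond_length
  if (is.null(box)) box <- 4 * max(diam, bond_length)
  if (diam >= 0.95 * box) {
    warning("network nearly spans the box; periodic images of the ",
            "network may come into contact")
  }
  pos <- sweep(pos, 2, colMeans(pos[seq_len(n_crosslinkers), , drop = FALSE]))
  pos <- pos + box / 2
  n <- nrow(pos)
  species <- c(rep("crosslinker", n_crosslinkers), rep("monomer", n_mono))
  ng_system(box = box, pos = pos, species = species,
            valence = integer(n),
            diameter = rep(params$d_monomer, n),
            bonds = bonds, chains = chains,
            crosslinkers = seq_len(n_crosslinkers),
            charged = integer(), params = params)
}

#' Anchor charged monomers to the network chains
#'
#' Gives exactly `n_charged_per_chain` monomers of each chain a valence
#' of +1e, at evenly spaced positions along the chain (position
#' `floor((j - 1/2) m / n) + 1` for the j-th charge on an m-mer). The
#' bare charge of the network becomes
#' `n_chains * n_charged_per_chain`.
#'
#' @param sys an `ng_system` from [build_network()].
#' @param n_charged_per_chain charges per chain, between 0 and the
#'   chain length.
#' @return The system with updated valences, `charged` ids and
#'   hydrophobic eligibility (charged beads are excluded from the
#'   hydrophobic attraction).
#' @export
assign_chain_charges <- function(sys, n_charged_per_chain) {
  m <- if (length(sys$chains)) length(sys$chains[[1]]) else 0L
  if (n_charged_per_chain < 0 ||
      (length(sys$chains) && n_charged_per_chain > m)) {
    stop("n_charged_per_chain must be between 0 and the chain length")
  }
  # reset network charges
  net <- .network_ids(sys)
  sys$valence[net] <- 0L
  charged <- integer()
  if (n_charged_per_chain > 0) {
    slots <- floor((seq_len(n_charged_per_chain) - 0.5) *
                     m / n_charged_per_chain) + 1L
    charged <- unlist(lapply(sys$chains, function(ch) ch[slots]))
    sys$valence[charged] <- 1L
  }
  sys$charged <- as.integer(charged)
  sys$hydrophobic <- sys$species %in% c("monomer", "crosslinker") &
    sys$valence == 0L
  sys
}

# random non-overlapping insertion of n beads of diameter d and valence
# z; returns their positions
.insert_random <- function(sys, n, d, role, max_attempts = 10000L) {
  if (n == 0) return(matrix(0, 0, 3))
  out <- matrix(0, n, 3)
  L <- sys$box
  occ_pos <- sys$pos
  occ_d <- sys$diameter
  for (k in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- stats::runif(3, 0, L)
      contact <- (occ_d + d) / 2
      if (all(.mi_dist(p, occ_pos, L) >= contact)) {
        out[k, ] <- p
        occ_pos <- rbind(occ_pos, p)
        occ_d <- c(occ_d, d)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("could not insert %s bead %d of %d without overlap",
                   role, k, n))
    }
  }
  out
}

#' Populate the box with counterions and nanoparticles
#'
#' Adds (i) one monovalent anion per unit of network bare charge,
#' (ii) `n_nanoparticles` nanoparticles of valence `np_valence`, and
#' (iii) the monovalent cations that neutralise the nanoparticle
#' charge, all at random positions that overlap no existing bead
#' (centre distance at least the contact distance, minimum image).
#' The resulting box is exactly electroneutral.
#'
#' @param sys an `ng_system` with charges already assigned.
#' @param n_nanoparticles number of nanoparticles to add.
#' @param np_valence nanoparticle valence (default -5).
#' @param d_np nanoparticle diameter (nm); defaults to the model value.
#' @param seed RNG seed for reproducible insertion.
#' @return The populated, electroneutral `ng_system`.
#' @export
populate_box <- function(sys, n_nanoparticles = 0, np_valence = -5L,
                         d_np = NULL, seed = NULL) {
  if (n_nanoparticles > 0 && np_valence == 0) {
    stop("nanoparticles must carry charge (np_valence != 0)")
  }
  p <- sys$params
  if (is.null(d_np)) d_np <- p$d_nanoparticle
  Z <- bare_charge(sys)
  n_anion <- Z
  n_cation <- abs(np_valence) * n_nanoparticles
  with_seed(seed, {
    add <- function(n, d, role, z) {
      if (n == 0) return(invisible(NULL))
      newpos <- .insert_random(sys, n, d, role)
      nn <- nrow(sys$pos)
      sys$pos <<- rbind(sys$pos, newpos)
      sys$species <<- c(sys$species, rep(role, n))
      sys$valence <<- c(sys$valence, rep(as.integer(z), n))
      sys$diameter <<- c(sys$diameter, rep(d, n))
      invisible(NULL)
    }
    add(n_anion, p$d_ion, "anion", -1L)
    add(n_nanoparticles, d_np, "nanoparticle", np_valence)
    add(n_cation, p$d_ion, "cation", 1L)
  })
  sys$hydrophobic <- sys$species %in% c("monomer", "crosslinker") &
    sys$valence == 0L
  stopifnot(total_charge(sys) == 0L)
  sys
}
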