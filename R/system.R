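# The ng_system object is the package's central container: one periodic
# cubic box plus every bead in it (positions, species, valences,
# diameters, hydrophobic eligibility) and the bonded topology of the
# polymer network (bonds, chains, cross-linker ids, charged-monomer ids).

.species_roles <- c("monomer", "crosslinker", "anion", "cation",
                    "nanoparticle")

#' Assemble a simulation system
#'
#' Low-level constructor; most users will get systems from
#' [build_network()], [populate_box()], [ng_preset()] or the fixture
#' generators.
#'
#' @param box cubic box side (nm).
#' @param pos N x 3 matrix of bead positions (nm).
#' @param species character vector of roles, one of monomer,
#'   crosslinker, anion, cation, nanoparticle.
#' @param valence integer vector of bead charges (elementary units).
#' @param diameter numeric vector of bead diameters (nm).
#' @param bonds two-column integer matrix of bonded pairs (1-based),
#'   or NULL.
#' @param chains list of integer vectors (ordered interior beads of each
#'   chain), or NULL.
#' @param crosslinkers integer vector of cross-linker bead ids.
#' @param charged integer vector of charged network bead ids.
#' @param params an [ng_model_params()] object.
#' @param wrap wrap positions into `[0, box)` (default TRUE).
#' @return An object of class `ng_system`.
#' @export
ng_system <- function(box, pos, species, valence, diameter,
                      bonds = NULL, chains = NULL,
                      crosslinkers = integer(), charged = integer(),
                      params = ng_model_params(), wrap = TRUE) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 3) stop("pos must be an N x 3 matrix")
  n <- nrow(pos)
  stopifnot(length(species) == n, length(valence) == n,
            length(diameter) == n)
  bad <- setdiff(unique(species), .species_roles)
  if (length(bad)) stop("unknown species role(s): ",
                        paste(bad, collapse = ", "))
  if (any(diameter <= 0)) stop("bead diameters must be positive")
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(bonds) && (min(bonds) < 1 || max(bonds) > n)) {
      stop("bond indices out of range")
    }
  }
  if (wrap) pos <- pos - box * floor(pos / box)
  sys <- list(box = box, pos = pos, species = species,
              valence = as.integer(valence), diameter = diameter,
              # hydrophobic attraction acts only between uncharged
              # network beads
              hydrophobic = species %in% c("monomer", "crosslinker") &
                valence == 0L,
              bonds = bonds, chains = chains,
              crosslinkers = as.integer(crosslinkers),
              charged = as.integer(charged),
              params = params)
  class(sys) <- "ng_system"
  sys
}

#' @export
print.ng_system <- function(x, ...) {
  cat(sprintf("ng_system: %d beads in a %.6g nm periodic cubic box\n",
              nrow(x$pos), x$box))
  print(table(x$species))
  cat(sprintf("  bonds: %d, chains: %d, bare charge Z = %+d e, total charge %+d e\n",
              if (is.null(x$bonds)) 0L else nrow(x$bonds),
              length(x$chains),
              sum(x$valence[x$species %in% c("monomer", "crosslinker")]),
              total_charge(x)))
  invisible(x)
}

#' Total charge of a system
#'
#' @param sys an `ng_system`.
#' @return Integer total charge in elementary units (0 for any valid
#'   simulation box: the canonical ensemble is electroneutral).
#' @export
total_charge <- function(sys) sum(sys$valence)

#' Bare (network-anchored) charge of a system
#'
#' @param sys an `ng_system`.
#' @return Total charge covalently anchored to the polymer network, in
#'   elementary units.
#' @export
bare_charge <- function(sys) {
  sum(sys$valence[sys$species %in% c("monomer", "crosslinker")])
}

#' Indices of beads of a given role
#' @param sys an `ng_system`.
#' @param role species role name.
#' @return Integer vector of bead indices.
#' @export
which_species <- function(sys, role) which(sys$species == role)

# network = monomers + crosslinkers
.network_ids <- function(sys) {
  which(sys$species %in% c("monomer", "crosslinker"))
}

# minimum-image displacement(s) dx (vector or matrix) in box L
min_image <- function(dx, L) dx - L * round(dx / L)

# minimum-image distance between one point and a matrix of points
.mi_dist <- function(p, mat, L) {
  d <- min_image(sweep(mat, 2, p), L)
  sqrt(rowSums(d * d))
}

# Unwrap bonded network coordinates by breadth-first traversal of the
# bond graph so that every bond uses the minimum-image displacement.
# Returns the full position matrix with network rows replaced.
unwrap_network <- function(pos, bonds, ids, L) {
  if (length(ids) <= 1 || is.null(bonds) || nrow(bonds) == 0) return(pos)
  adj <- vector("list", nrow(pos))
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(nrow(pos))
  out <- pos
  for (root in ids) {
    if (seen[root]) next
    seen[root] <- TRUE
    queue <- root
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      for (j in adj[[i]]) {
        if (!seen[j]) {
          seen[j] <- TRUE
          out[j, ] <- out[i, ] + min_image(pos[j, ] - pos[i, ], L)
          # propagate from the unwrapped parent, keep relative offsets
          pos[j, ] <- out[j, ]
          queue <- c(queue, j)
        }
      }
    }
  }
  out
}

# evaluate with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
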