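# File formats and system presets. Configurations travel as extended
# XYZ (species, position, valence, diameter) plus a two-column bond
# sidecar; run configurations as JSON.

#' Reference system presets
#'
#' The four nanogels NG1-NG4 share one architecture -- 100
#' polyelectrolyte chains of 30 monomeric units joined by 66
#' tetrafunctional cross-linkers (3066 network beads) in a 150 nm
#' periodic box -- and differ only in the number of charged monomers
#' per chain (1-4, so bare charge Z = 100, 200, 300, 400). The
#' nanocomposite presets NP@NGn add 40 nanoparticles of charge -5e
#' (0.02 mM) plus 200 neutralising monovalent cations (0.10 mM).
#'
#' @param name one of `"NG1"`..`"NG4"`, `"NP@NG1"`..`"NP@NG4"`.
#' @param seed RNG seed for the random ion/nanoparticle insertion.
#' @param params model parameters.
#' @return An electroneutral `ng_system`.
#' @export
ng_preset <- function(name, seed = 1, params = ng_model_params()) {
  m <- regmatches(name, regexec("^(NP@)?NG([1-4])$", name))[[1]]
  if (!length(m)) stop("unknown preset: ", name,
                       " (use NG1-NG4 or NP@NG1-NP@NG4)")
  with_np <- m[2] == "NP@"
  ncharged <- as.integer(m[3])
  sys <- build_network(n_chains = 100, monomers_per_chain = 30,
                       n_crosslinkers = 66, bond_length = params$r0,
                       box = 150, params = params)
  sys <- assign_chain_charges(sys, ncharged)
  populate_box(sys, n_nanoparticles = if (with_np) 40L else 0L,
               np_valence = -5L, seed = seed)
}

#' Species concentration in the box
#'
#' @param sys an `ng_system`.
#' @param role species role name.
#' @return Concentration in mM (mol per cubic metre).
#' @export
species_concentration_mM <- function(sys, role) {
  n <- length(which_species(sys, role))
  # n / L^3 in nm^-3 -> mol/L: 1 nm^-3 = 1e24 L^-1
  n / sys$box^3 * 1e24 / 6.02214076e23 * 1e3
}

#' Write a configuration as extended XYZ (+ bond sidecar)
#'
#' Plain-text extended XYZ: the comment line carries the box length
#' and column schema; each row holds species label, position (nm),
#' valence and diameter. Bonds go to `<path>.bonds` as two columns of
#' 0-based bead indices.
#'
#' @param sys an `ng_system`.
#' @param path output file path.
#' @param comment extra metadata appended to the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(sys, path, comment = "") {
  n <- nrow(sys$pos)
  hdr <- sprintf(paste0('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" ',
                        "Properties=species:S:1:pos:R:3:valence:I:1:",
                        "diameter:R:1 %s"),
                 sys$box, sys$box, sys$box, comment)
  lines <- sprintf("%s %.10g %.10g %.10g %d %.10g",
                   sys$species, sys$pos[, 1], sys$pos[, 2],
                   sys$pos[, 3], sys$valence, sys$diameter)
  writeLines(c(as.character(n), trimws(hdr), lines), path)
  if (!is.null(sys$bonds) && nrow(sys$bonds)) {
    utils::write.table(sys$bonds - 1L, paste0(path, ".bonds"),
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a configuration written by [write_xyz()]
#'
#' @param path XYZ file path; `<path>.bonds` is read when present.
#' @param params model parameters to attach.
#' @return An `ng_system` (chains and cross-linker ids are not stored
#'   in the XYZ format and come back empty).
#' @export
read_xyz <- function(path, params = ng_model_params()) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("malformed XYZ: line 1 is not a bead count")
  box <- as.numeric(regmatches(
    lines[2], regexec('Lattice="([0-9.eE+-]+) ', lines[2]))[[1]][2])
  if (is.na(box)) stop("malformed XYZ: no Lattice entry on line 2")
  if (n == 0) {
    return(ng_system(box = box, pos = matrix(0, 0, 3),
                     species = character(), valence = integer(),
                     diameter = numeric(), params = params))
  }
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  bad <- which(lengths(parts) != 6)
  if (length(bad)) stop("malformed XYZ line ", bad[1] + 2)
  tab <- do.call(rbind, parts)
  sys <- ng_system(box = box,
                   pos = matrix(as.numeric(tab[, 2:4]), n, 3),
                   species = tab[, 1],
                   valence = as.integer(tab[, 5]),
                   diameter = as.numeric(tab[, 6]),
                   params = params, wrap = FALSE)
  bpath <- paste0(path, ".bonds")
  if (file.exists(bpath)) {
    b <- as.matrix(utils::read.table(bpath))
    sys$bonds <- matrix(as.integer(b), ncol = 2) + 1L
  }
  sys
}

# ---------------------------------------------------------- run config
.config_defaults <- function() {
  list(
    model = unclass(ng_model_params()),
    system = list(preset = "NG2", n_chains = 100,
                  monomers_per_chain = 30, n_crosslinkers = 66,
                  charged_per_chain = 2, n_nanoparticles = 0,
                  np_valence = -5, box = 150),
    schedule = list(temperature_C = 20, n_equil = 1e5, n_prod = 1e5,
                    sample_interval = 500, seed = 1),
    moves = list(max_disp = list(network = 0.25, anion = 1, cation = 1,
                                 nanoparticle = 0.5, cluster = 0.5,
                                 scale = 0.05),
                 # 0 = choose automatically from the bead count
                 cluster_interval = 0, scale_interval = 0,
                 scale_moves = TRUE, adapt_interval = 2000),
    ewald = list(target_rel_accuracy = 1e-4)
  )
}

#' Read a run configuration (JSON)
#'
#' Omitted fields take the model defaults; unknown keys are rejected
#' with their location so typos never pass silently.
#'
#' @param path JSON file.
#' @return A `run_config` list with sections `model`, `system`,
#'   `schedule`, `moves`, `ewald`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- .config_defaults()
  bad_top <- setdiff(names(raw), names(def))
  if (length(bad_top)) stop("unknown config section: ",
                            paste(bad_top, collapse = ", "))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(def[[sec]]))
    if (length(bad)) stop(sprintf("unknown key in [%s]: %s", sec,
                                  paste(bad, collapse = ", ")))
    for (k in names(raw[[sec]])) {
      def[[sec]][[k]] <- raw[[sec]][[k]]
    }
  }
  # JSON carries no integer/double distinction; normalise to double
  def <- rapply(def, function(x) {
    if (is.integer(x)) as.numeric(x) else x
  }, how = "replace")
  cnt <- def$system[c("n_chains", "monomers_per_chain",
                      "n_crosslinkers", "n_nanoparticles")]
  if (any(unlist(cnt) < 0)) stop("system counts must be non-negative")
  structure(def, class = "run_config")
}

#' Write a run configuration (JSON)
#'
#' `write_run_config()` then [read_run_config()] is the identity.
#'
#' @param config a `run_config` (or the default-filled list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Move settings described by a run configuration
#'
#' @param config a `run_config`.
#' @return A [move_settings()] object (interval values of 0 mean
#'   "choose automatically from the bead count").
#' @export
config_moves <- function(config) {
  m <- config$moves
  iv <- function(x) if (is.null(x) || x == 0) NULL else x
  move_settings(max_disp = unlist(m$max_disp),
                cluster_interval = iv(m$cluster_interval),
                scale_interval = iv(m$scale_interval),
                scale_moves = m$scale_moves,
                adapt_interval = m$adapt_interval)
}

#' Build the system a run configuration describes
#'
#' @param config a `run_config`.
#' @return An electroneutral `ng_system`.
#' @export
config_system <- function(config) {
  p <- do.call(ng_model_params, config$model)
  s <- config$system
  if (!is.null(s$preset) && !is.na(s$preset) && nzchar(s$preset)) {
    return(ng_preset(s$preset, seed = config$schedule$seed, params = p))
  }
  sys <- build_network(n_chains = s$n_chains,
                       monomers_per_chain = s$monomers_per_chain,
                       n_crosslinkers = s$n_crosslinkers,
                       bond_length = p$r0, box = s$box, params = p)
  sys <- assign_chain_charges(sys, s$charged_per_chain)
  populate_box(sys, n_nanoparticles = s$n_nanoparticles,
               np_valence = s$np_valence, seed = config$schedule$seed)
}

#' Remove nanoparticles outside the nanogel
#'
#' Post-processing hook for boundary-condition studies: deletes the
#' nanoparticles whose centres lie farther than the geometric radius
#' from the network centre of mass, together with an equal measure of
#' neutralising cations so the box stays electroneutral, and returns
#' the reduced system (from which a run can be continued).
#'
#' @param sys an `ng_system`.
#' @param r_ng geometric radius (nm); default recomputed from the
#'   current configuration.
#' @return The reduced `ng_system`.
#' @export
strip_external_nps <- function(sys, r_ng = NULL) {
  nps <- which_species(sys, "nanoparticle")
  if (!length(nps)) return(sys)
  if (is.null(r_ng)) {
    r_ng <- geometric_radius(radius_of_gyration(sys$pos, sys))
  }
  cm <- .frame_cm(sys$pos, sys)
  d <- .mi_dist(cm, sys$pos[nps, , drop = FALSE], sys$box)
  gone <- nps[d >= r_ng]
  if (!length(gone)) return(sys)
  # drop the cations farthest from the gel to rebalance the charge
  qremoved <- sum(sys$valence[gone])
  cats <- which_species(sys, "cation")
  dc <- .mi_dist(cm, sys$pos[cats, , drop = FALSE], sys$box)
  ncat_drop <- abs(qremoved)
  drop_cats <- cats[order(-dc)][seq_len(min(ncat_drop, length(cats)))]
  keep <- setdiff(seq_len(nrow(sys$pos)), c(gone, drop_cats))
  remap <- match(seq_len(nrow(sys$pos)), keep)
  out <- sys
  out$pos <- sys$pos[keep, , drop = FALSE]
  out$species <- sys$species[keep]
  out$valence <- sys$valence[keep]
  out$diameter <- sys$diameter[keep]
  out$hydrophobic <- sys$hydrophobic[keep]
  if (!is.null(sys$bonds)) {
    out$bonds <- matrix(remap[sys$bonds], ncol = 2)
  }
  out$chains <- lapply(sys$chains, function(ch) remap[ch])
  out$crosslinkers <- remap[sys$crosslinkers]
  out$charged <- remap[sys$charged]
  stopifnot(total_charge(out) == 0L)
  out
}
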