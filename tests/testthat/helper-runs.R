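# Shared scaled-down study systems: one miniature nanogel family at the
# two reference temperatures. Runs are expensive, so they are computed
# lazily once per session and cached for every test that needs them.
#
# Study conditions (fixed): 8 cross-linkers on the trimmed diamond
# lattice, 5-mer chains, box 4x the network diameter; the composite
# carries 2 charges per chain (bare charge 16) plus 4 nanoparticles of
# charge -5e and diameter 2 nm with their 20 neutralising cations.
# 1.5e5 equilibration + 1e5 production movements per run; composite
# observables are averaged over three independent seeds.

.mini_cache <- new.env(parent = emptyenv())

mini_gel_run <- function(temp_C, charged_per_chain, seed = 5) {
  key <- sprintf("gel_%g_%d_%d", temp_C, charged_per_chain, seed)
  if (is.null(.mini_cache[[key]])) {
    sys <- make_tiny_network(8, 5, charged_per_chain = charged_per_chain,
                             seed = seed)
    run <- run_mc(sys, run_schedule(temp_C, 1.5e5, 1e5, 1000,
                                    seed = seed),
                  store_frames = FALSE)
    .mini_cache[[key]] <- run
  }
  .mini_cache[[key]]
}

mini_composite_run <- function(temp_C, seed) {
  key <- sprintf("comp_%g_%d", temp_C, seed)
  if (is.null(.mini_cache[[key]])) {
    sys <- make_tiny_network(8, 5, charged_per_chain = 2,
                             n_nanoparticles = 4, np_valence = -5L,
                             d_np = 2.0, seed = seed)
    run <- run_mc(sys, run_schedule(temp_C, 1.5e5, 1e5, 1000,
                                    seed = seed),
                  store_frames = TRUE)
    .mini_cache[[key]] <- run
  }
  .mini_cache[[key]]
}

mini_composite_seeds <- c(11, 17, 23)

prod_samples <- function(run) run$samples[run$samples$phase == 1, ]

prod_mean <- function(run, col) mean(prod_samples(run)[[col]])

# composite observables averaged over the independent seeds
mini_composite_summary <- function(temp_C) {
  runs <- lapply(mini_composite_seeds,
                 function(s) mini_composite_run(temp_C, s))
  list(runs = runs,
       r_ng = mean(vapply(runs, prod_mean, 0, col = "r_ng")),
       n_inside = mean(vapply(runs, prod_mean, 0, col = "n_inside")))
}
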