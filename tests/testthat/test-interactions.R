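# Pair potentials and Ewald electrostatics.

p <- ng_model_params()

test_that("WCA potential is repulsive, continuous at its cutoff", {
  d <- p$d_monomer
  expect_equal(pair_wca(2^(1 / 6) * d, d, d, p, unit = "J"), 0)
  expect_equal(pair_wca(2^(1 / 6) * d + 1e-9, d, d, p, unit = "J"), 0)
  expect_equal(pair_wca(d, d, d, p, unit = "J"), p$eps_wca / 4)
  expect_equal(pair_wca(0.9 * d, d, d, p, unit = "J"),
               p$eps_wca * ((1 / 0.9)^12 - (1 / 0.9)^6 + 0.25))
  # mixed diameters use the arithmetic mean
  expect_equal(pair_wca(2^(1 / 6) * (0.65 + 5) / 2, 0.65, 5, p,
                        unit = "J"), 0)
  expect_error(pair_wca(0, d, d, p), "overlap")
  # optional conventional 4-epsilon prefactor
  p4 <- ng_model_params(wca_four_epsilon = TRUE)
  expect_equal(pair_wca(d, d, d, p4, unit = "J"), p$eps_wca)
})

test_that("bond potential is harmonic about r0", {
  expect_equal(pair_bond(p$r0, p, unit = "J"), 0)
  expect_equal(pair_bond(p$r0 + 0.1, p, unit = "J"), 2.0e-21)
  expect_equal(pair_bond(p$r0 + 0.07, p),
               pair_bond(p$r0 - 0.07, p))
})

test_that("hydrophobic well has the sigmoidal shape and charge gating", {
  TK <- 310
  eps_h <- hydrophobic_depth(TK, p)
  expect_equal(pair_hydrophobic(p$r_h, TK, params = p, unit = "J"),
               -eps_h / 2)
  expect_equal(pair_hydrophobic(1e-6, TK, params = p, unit = "J"),
               -eps_h, tolerance = 1e-8)
  # switched off for any charged or ineligible partner
  expect_equal(pair_hydrophobic(p$r_h, TK, z_i = 1, params = p), 0)
  expect_equal(pair_hydrophobic(p$r_h, TK, z_j = -5, params = p), 0)
  expect_equal(pair_hydrophobic(p$r_h, TK, eligible_i = FALSE,
                                params = p), 0)
  # numerically dead beyond the truncation distance used in the engine
  tail <- abs(pair_hydrophobic(p$r_h + 1.5, TK, params = p,
                               unit = "J"))
  expect_lt(tail, 1e-6 * eps_h)
})

test_that("Coulomb pair energy equals lB z_i z_j / r", {
  expect_equal(pair_coulomb(1, 1, 1, 298.15),
               bjerrum_length(298.15))
  expect_equal(pair_coulomb(1, 1, -1, 298.15),
               -pair_coulomb(1, 1, 1, 298.15))
  expect_equal(pair_coulomb(2, 1, 1, 300),
               pair_coulomb(1, 1, 1, 300) / 2)
  expect_error(pair_coulomb(0, 1, 1, 300), "overlap")
})

test_that("Ewald sum reproduces the Madelung constant", {
  cr <- make_madelung_crystal(2, spacing = 1)
  ew <- ewald_total(cr, 298.15, ewald_settings(cr$box, 1e-6))
  M_sim <- -ew$total / (nrow(cr$pos) / 2) / bjerrum_length(298.15)
  M_ref <- evjen_madelung(8)
  expect_equal(M_sim, M_ref, tolerance = 1e-3)
  # translating the whole crystal leaves the energy unchanged
  cr2 <- cr
  cr2$pos <- cr2$pos + 0.3173
  ew2 <- ewald_total(cr2, 298.15, ewald_settings(cr$box, 1e-6))
  expect_equal(ew2$total, ew$total, tolerance = 1e-9)
})

test_that("Ewald matches brute-force image sums on small systems", {
  TK <- 298.15
  lB <- bjerrum_length(TK)
  # opposite charges at small separation in a large box
  two <- make_reference_system("two_charge_box", box = 50,
                               separation = 1)
  ew <- ewald_total(two, TK, ewald_settings(50, 1e-6))
  direct_pair <- pair_coulomb(1, 1, -1, TK)
  expect_equal(ew$total, direct_pair, tolerance = 0.01)
  # and within 0.1% of the full image sum
  wrapped <- two$pos
  ds2 <- direct_image_sum(wrapped, two$valence, 50, lB, shells = 8)
  expect_equal(ew$total, ds2, tolerance = 1e-3)
  # neutral dipole-free random configuration, tighter check
  cfg <- dipole_free_config(3, L = 10, seed = 2)
  sys <- ng_system(box = cfg$L, pos = cfg$pos,
                   species = ifelse(cfg$val > 0, "cation", "anion"),
                   valence = cfg$val,
                   diameter = rep(1e-3, length(cfg$val)), wrap = FALSE)
  ewr <- ewald_total(sys, TK, ewald_settings(cfg$L, 1e-6))
  dsr <- direct_image_sum(cfg$pos, cfg$val, cfg$L, lB, shells = 8)
  expect_equal(ewr$total, dsr, tolerance = 1e-3)
  # convergence self-consistency: tighter settings move the energy by
  # less than the looser accuracy target
  loose <- ewald_total(sys, TK, ewald_settings(cfg$L, 1e-4))
  tight <- ewald_total(sys, TK, ewald_settings(cfg$L, 1e-8))
  expect_lt(abs(loose$total - tight$total) / abs(tight$total), 1e-4)
  # non-neutral input is rejected
  bad <- sys
  bad$valence[1] <- 2L
  expect_error(ewald_total(bad, TK), "electroneutral")
})

test_that("incremental delta energy equals full recomputation", {
  sys <- make_tiny_network(8, 3, charged_per_chain = 1,
                           n_nanoparticles = 2, d_np = 2, seed = 3)
  expect_lte(nrow(sys$pos), 60)
  TK <- 298.15
  ew <- ewald_settings(sys$box, 1e-5)
  e0 <- energy_breakdown(sys, TK, ew)
  expect_equal(e0$total,
               e0$wca + e0$bond + e0$hydrophobic + e0$electrostatic)
  # null move (floating accumulation only)
  expect_lt(abs(delta_energy(sys, 5L, c(0, 0, 0), TK, ew)), 1e-12)
  # single-bead moves across species
  set.seed(1)
  for (i in c(1L, 12L, 40L, nrow(sys$pos))) {
    disp <- runif(3, -0.8, 0.8)
    dU <- delta_energy(sys, i, disp, TK, ew)
    moved <- sys
    moved$pos[i, ] <- moved$pos[i, ] + disp
    full <- energy_breakdown(moved, TK, ew)$total - e0$total
    expect_equal(dU, full, tolerance = 1e-10)
  }
  # rigid cluster move (nanoparticle + its counterions)
  np <- which_species(sys, "nanoparticle")[1]
  cl <- select_cluster(sys, np)
  disp <- c(0.4, -0.3, 0.2)
  dU <- delta_energy(sys, cl, disp, TK, ew)
  moved <- sys
  moved$pos[cl, ] <- sweep(moved$pos[cl, , drop = FALSE], 2, -disp)
  full <- energy_breakdown(moved, TK, ew)$total - e0$total
  expect_equal(dU, full, tolerance = 1e-10)
})

test_that("total energy is invariant under global translation", {
  sys <- make_tiny_network(8, 3, charged_per_chain = 1,
                           n_nanoparticles = 1, d_np = 2, seed = 9)
  TK <- 300
  ew <- ewald_settings(sys$box, 1e-5)
  e0 <- energy_breakdown(sys, TK, ew)$total
  sh <- sys
  sh$pos <- sh$pos + c(1.7, -2.3, 0.9)[col(sh$pos)]
  e1 <- energy_breakdown(sh, TK, ew)$total
  expect_equal(e1, e0, tolerance = 1e-9)
})
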