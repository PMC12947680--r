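# Size, counting, profile and correlation observables.

# helper: a bare "network" of free beads at given positions
cloud_sys <- function(pos, box, valence = NULL) {
  n <- nrow(pos)
  if (is.null(valence)) valence <- integer(n)
  ng_system(box = box, pos = pos, species = rep("monomer", n),
            valence = valence, diameter = rep(1e-3, n), wrap = FALSE)
}

test_that("radius of gyration matches closed forms", {
  # single bead
  s1 <- cloud_sys(matrix(c(3, 3, 3), 1, 3), 20)
  expect_equal(radius_of_gyration(s1$pos, s1), 0)
  # symmetric dumbbell 2a apart -> a
  a <- 1.7
  s2 <- cloud_sys(rbind(c(5, 5, 5), c(5 + 2 * a, 5, 5)), 30)
  expect_equal(radius_of_gyration(s2$pos, s2), a)
  # uniform solid sphere: R_gyr = sqrt(3/5) R
  R <- 10
  cl <- make_reference_system("uniform_sphere_cloud", n = 1e5,
                              radius = R, seed = 6)
  expect_equal(radius_of_gyration(cl$pos, cl), sqrt(3 / 5) * R,
               tolerance = 5e-3)
  # geometric radius inverts the sphere relation
  expect_equal(geometric_radius(sqrt(3 / 5) * R), R)
  expect_equal(geometric_radius(0), 0)
  expect_equal(geometric_radius(10), 12.9099, tolerance = 1e-5)
})

test_that("unwrapping restores a network split by the boundary", {
  sys <- build_network(monomers_per_chain = 3, n_crosslinkers = 8)
  rg0 <- radius_of_gyration(sys$pos, sys)
  # shift so the network straddles a box corner, then wrap
  sh <- sys
  sh$pos <- sh$pos + sys$box / 2 + 0.37
  sh$pos <- sh$pos - sys$box * floor(sh$pos / sys$box)
  expect_equal(radius_of_gyration(sh$pos, sh), rg0, tolerance = 1e-9)
})

test_that("inside-count applies the geometric-radius criterion", {
  net <- matrix(10, 1, 3)
  mk <- function(dists, rng) {
    pos <- rbind(net, t(vapply(dists, function(d) c(10 + d, 10, 10),
                               numeric(3))))
    ng_system(box = 40, pos = pos,
              species = c("monomer", rep("nanoparticle", length(dists))),
              valence = c(0L, rep(-5L, length(dists))),
              diameter = c(1e-3, rep(2, length(dists))), wrap = FALSE)
  }
  rng <- 5
  sys <- mk(c(0.5, 0.9, 1.1) * rng, rng)
  expect_equal(count_inside(sys$pos, sys, rng), 2)
  all_in <- mk(rep(0, 7), rng)
  expect_equal(count_inside(all_in$pos, all_in, rng), 7)
  all_out <- mk(rep(3 * rng, 7), rng)
  expect_equal(count_inside(all_out$pos, all_out, rng), 0)
})

test_that("shrinkage and desorption ratios are the defined quotients", {
  expect_equal(shrink_desorb_ratios(30, 30)$shrinkage, 0)
  expect_equal(shrink_desorb_ratios(30, 9.9)$shrinkage, 0.67)
  expect_equal(shrink_desorb_ratios(30, 20, 20, 10)$desorption, 0.5)
  expect_error(shrink_desorb_ratios(0, 1), "positive")
  expect_error(shrink_desorb_ratios(1, 1, 0, 0), "positive")
})

test_that("net charge profile enumerates enclosed charge correctly", {
  # +5 bead at the network CM: profile is +5 at every radius
  pos <- rbind(c(10, 10, 10), c(10, 10, 10))
  sys <- ng_system(box = 40, pos = pos,
                   species = c("monomer", "nanoparticle"),
                   valence = c(0L, 5L), diameter = c(1e-3, 1),
                   wrap = FALSE)
  prof <- net_charge_profile(list(sys$pos), sys, bin_width = 1)
  expect_true(all(prof$q_enc == 5))
  # a sphere covering every bead encloses zero net charge
  mini <- make_tiny_network(8, 3, charged_per_chain = 2,
                            n_nanoparticles = 2, d_np = 2, seed = 8)
  prof2 <- net_charge_profile(list(mini$pos), mini, bin_width = 0.5,
                              r_max = 0.9 * mini$box)
  expect_equal(prof2$q_enc[length(prof2$q_enc)], 0)
  # network-only enclosure: with mobile ions far away, Z_net at R_NG
  # equals the network charge within R_NG (direct enumeration)
  rg <- radius_of_gyration(mini$pos, mini)
  rng <- geometric_radius(rg)
  cm <- colMeans(mini$pos[mini$crosslinkers, , drop = FALSE])
  far <- mini
  mob <- which(!far$species %in% c("monomer", "crosslinker"))
  # park mobile beads on a distant shell (outside r_max of the profile)
  far$pos[mob, ] <- matrix(rep(cm, each = length(mob)), ncol = 3) +
    0.45 * far$box
  d <- sqrt(rowSums(sweep(far$pos, 2, cm)^2))
  znet_ref <- sum(far$valence[d < rng])
  expect_lt(abs(net_charge_at(list(far$pos), far, rng,
                              bin_width = 0.1) - znet_ref), 1)
})

test_that("Gauss-law potential matches the point-charge closed form", {
  L <- 40
  pos <- rbind(c(L / 2, L / 2, L / 2), c(L / 2, L / 2, L / 2))
  sys <- ng_system(box = L, pos = pos,
                   species = c("monomer", "cation"),
                   valence = c(0L, 3L), diameter = c(1e-3, 0.7),
                   wrap = FALSE)
  TK <- 298.15
  prof <- potential_profile(list(sys$pos), sys, TK, bin_width = 0.1)
  lB <- bjerrum_length(TK)
  ref <- 3 * lB * (1 / prof$r - 2 / L)
  sel <- prof$r > 2 & prof$r < L / 2 - 1
  expect_equal(prof$psi[sel], ref[sel], tolerance = 2e-3)
  # gauge: psi(L/2) = 0 by construction
  expect_equal(prof$psi[length(prof$psi)], 0)
  # neutral configuration: psi identically zero
  sys0 <- sys
  sys0$valence <- c(0L, 0L)
  prof0 <- potential_profile(list(sys0$pos), sys0, TK)
  expect_true(all(prof0$psi == 0))
})

test_that("potential of a sampled uniform charged ball matches theory", {
  set.seed(12)
  L <- 60; a <- 4; n <- 4000
  pts <- matrix(0, n, 3); k <- 0
  while (k < n) {
    p <- runif(3, -a, a)
    if (sum(p^2) <= a^2) { k <- k + 1; pts[k, ] <- p }
  }
  pos <- rbind(c(L / 2, L / 2, L / 2), sweep(pts, 2, -rep(L / 2, 3)))
  sys <- ng_system(box = L, pos = pos,
                   species = c("monomer", rep("cation", n)),
                   valence = c(0L, rep(1L, n)),
                   diameter = rep(1e-3, n + 1), wrap = FALSE)
  TK <- 293.15
  lB <- bjerrum_length(TK)
  prof <- potential_profile(list(sys$pos), sys, TK, bin_width = 0.25)
  psi_ref <- function(r) {
    ifelse(r < a,
           n * lB * ((3 * a^2 - r^2) / (2 * a^3) - 2 / L),
           n * lB * (1 / r - 2 / L))
  }
  sel <- prof$r > 1
  expect_equal(prof$psi[sel], psi_ref(prof$r[sel]), tolerance = 0.02)
})

test_that("pair correlation is flat for an ideal gas, sharp for a pair", {
  set.seed(3)
  L <- 20; nnp <- 30
  sys <- ng_system(box = L, pos = matrix(runif(3 * nnp, 0, L), nnp, 3),
                   species = rep("nanoparticle", nnp),
                   valence = rep(0L, nnp), diameter = rep(1e-3, nnp))
  frames <- replicate(150, matrix(runif(3 * nnp, 0, L), nnp, 3),
                      simplify = FALSE)
  g <- rdf_np_np(frames, sys, bin_width = 0.5)
  sel <- g$r > 3 & g$r < L / 2 - 0.5
  expect_equal(mean(g$g[sel]), 1, tolerance = 0.015)
  expect_lt(max(abs(g$g[sel] - 1)), 0.15)
  # two frozen particles 5 nm apart: a single populated bin at 5 nm
  two <- ng_system(box = L,
                   pos = rbind(c(5, 5, 5), c(10, 5, 5)),
                   species = rep("nanoparticle", 2),
                   valence = rep(0L, 2), diameter = rep(2, 2))
  g2 <- rdf_np_np(list(two$pos), two, bin_width = 0.1)
  expect_equal(g2$r[which(g2$g > 0)], 5, tolerance = 0.05)
  expect_equal(sum(g2$g > 0), 1)
})

# count of anions within r of the single network bead (minimum image)
.mini_dist_count <- function(sys, r_max) {
  cm <- sys$pos[1, ]
  d <- sweep(sys$pos[-1, , drop = FALSE], 2, cm)
  d <- d - sys$box * round(d / sys$box)
  sqrt(rowSums(d^2)) < r_max
}

test_that("density profiles conserve particle number and shape", {
  set.seed(5)
  L <- 30
  # one central network bead + uniform mobile beads
  nn <- 2000
  pos <- rbind(c(L / 2, L / 2, L / 2), matrix(runif(3 * nn, 0, L), nn, 3))
  sys <- ng_system(box = L, pos = pos,
                   species = c("monomer", rep("anion", nn)),
                   valence = c(0L, rep(0L, nn)),
                   diameter = rep(1e-3, nn + 1), wrap = FALSE)
  prof <- density_profile(list(sys$pos), sys, "anion", bin_width = 1,
                          r_max = L / 2)
  # uniform density within counting noise
  rho <- nn / L^3
  sel <- prof$r > 3
  expect_equal(mean(prof$density[sel]) / rho, 1, tolerance = 0.05)
  # volume integral returns the mean count within range
  edges <- seq(0, L / 2, by = 1)
  shell_v <- 4 / 3 * pi * diff(edges^3)
  expect_equal(sum(prof$density * shell_v),
               sum(.mini_dist_count(sys, L / 2)), tolerance = 1e-9)
  # everything at the centre lands in the first bin
  allc <- sys
  allc$pos[-1, ] <- matrix(rep(c(L / 2, L / 2, L / 2), nn),
                           ncol = 3, byrow = TRUE)
  pc <- density_profile(list(allc$pos), allc, "anion", bin_width = 1)
  expect_true(all(pc$density[-1] == 0) && pc$density[1] > 0)
})

test_that("independent-run summaries expose mean and spread", {
  sys <- make_reference_system("harmonic_dimer")
  runs <- lapply(1:3, function(s) {
    run_mc(sys, run_schedule(25, 2000, 8000, 200, seed = s),
           store_frames = FALSE)
  })
  sm <- summarize_runs(runs)
  expect_equal(sm$r_ng, geometric_radius(sm$r_gyr))
  expect_gte(sm$r_gyr_sd, 0)
  expect_equal(nrow(sm), 1)
})
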