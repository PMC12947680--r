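# Poisson-Boltzmann cell model and its excluded-volume modification.

test_that("concentration caps follow the free-volume estimate", {
  expect_equal(n_i_max(0, 5), 0.008)
  expect_equal(n_i_max(0.5, 5), 0.004)
  expect_equal(n_i_max(1 - 1e-12, 5), 1e-12 / 125)
  expect_error(n_i_max(1, 5), "phi_ng")
  expect_error(n_i_max(0.2, -1), "positive")
})

test_that("source-free cell has identically zero potential", {
  spec <- pb_cell_spec(r_ng = 10, Z = 0, cell_radius = 50)
  sol <- pb_solve(spec)
  expect_true(all(sol$psi == 0))
  expect_true(sol$converged)
  expect_equal(surface_potential_pbc(sol), 0)
  expect_equal(net_charge_pbc(sol), 0)
})

test_that("solver matches the linearized closed form at weak charge", {
  lB <- bjerrum_length(293.15)
  R <- 10; Rc <- 50; Z <- 2; n0 <- 1e-4
  # Z lB / R = 0.14 << 1: linearization valid to ~1%
  spec <- pb_cell_spec(
    r_ng = R, Z = Z, cell_radius = Rc,
    species = data.frame(label = c("cat", "an"), z = c(1, -1),
                         d = c(0.7, 0.7), N = c(1, 3)),
    saturation = FALSE, T_K = 293.15, n_nodes = 4000)
  sol <- pb_solve(spec, n0 = c(n0, n0), fix_boundary = TRUE)
  ref <- dh_cell_closed_form(sol$r, R, Rc, Z, n0, lB)
  expect_equal(max(abs(sol$psi - ref)) / max(abs(ref)), 0,
               tolerance = 0.01)
  expect_equal(surface_potential_pbc(sol),
               dh_cell_closed_form(R, R, Rc, Z, n0, lB),
               tolerance = 0.01)
  # sign of the surface potential follows the bare charge
  expect_gt(surface_potential_pbc(sol), 0)
})

mk_cell <- function(saturation, d_np = 2, n_nodes = 2000,
                    phi = 0.05) {
  sp <- data.frame(label = c("anion", "np", "cation"),
                   z = c(-1, -5, 1), d = c(0.7, d_np, 0.7),
                   N = c(16, 4, 20))
  pb_cell_spec(r_ng = 4, Z = 16, box = 40, species = sp,
               phi_ng = phi, saturation = saturation,
               T_K = 293.15, n_nodes = n_nodes)
}

test_that("saturated equation reduces to the ideal one as caps diverge", {
  ideal <- pb_solve(mk_cell(FALSE))
  # shrink all diameters so n_max explodes: shared denominator -> 1
  spec <- mk_cell(TRUE)
  spec$species$d <- rep(1e-4, 3)
  spec$phi_ng <- 0
  capped <- pb_solve(spec)
  expect_equal(capped$psi, ideal$psi, tolerance = 1e-8)
})

test_that("boundary and regularity conditions hold on converged cells", {
  sol <- pb_solve(mk_cell(TRUE))
  expect_true(sol$converged)
  n <- length(sol$psi)
  h <- diff(sol$r[1:2])
  expect_equal(sol$psi[n], 0)
  # Neumann at the edge (electroneutral cell) and at the origin
  expect_lt(abs(sol$psi[n] - sol$psi[n - 1]) / h,
            1e-3 * max(abs(sol$psi)))
  expect_lt(abs(sol$psi[2] - sol$psi[1]) / h,
            2e-3 * max(abs(sol$psi)) / h)
  # species counts integrate back to their prescribed totals
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  for (i in 1:3) {
    got <- trapz(sol$r, 4 * pi * sol$r^2 * sol$n[, i])
    expect_equal(got, sol$spec$species$N[i], tolerance = 1e-5)
  }
  # cell electroneutrality: bare + integrated species charge vanishes
  rho <- as.numeric(sol$n %*% sol$spec$species$z)
  qmobile <- trapz(sol$r, 4 * pi * sol$r^2 * rho)
  expect_equal(sol$spec$Z + qmobile, 0, tolerance = 1e-5 * 16)
})

test_that("mesh refinement changes the surface potential negligibly", {
  coarse <- pb_solve(mk_cell(TRUE, n_nodes = 2000))
  fine <- pb_solve(mk_cell(TRUE, n_nodes = 4000))
  expect_lt(abs(surface_potential_pbc(coarse) -
                  surface_potential_pbc(fine)), 1e-4)
})

test_that("saturation caps interior concentrations at n_max", {
  sol <- pb_solve(mk_cell(TRUE, phi = 0.3))
  caps_in <- n_i_max(0.3, sol$spec$species$d)
  inside <- sol$r < sol$spec$r_ng
  for (i in 1:3) {
    expect_lte(max(sol$n[inside, i]), caps_in[i] * (1 + 1e-9))
  }
  # switching the cap on never raises a species' interior peak
  ideal <- pb_solve(mk_cell(FALSE, phi = 0.3))
  for (i in 1:3) {
    expect_lte(max(sol$n[inside, i]), max(ideal$n[inside, i]) + 1e-12)
  }
})

test_that("absorbed counts, conservation and flat-potential partition", {
  sol <- pb_solve(mk_cell(TRUE))
  for (i in 1:3) {
    inside <- absorbed_count(sol, i)
    expect_gte(inside, 0)
    expect_lte(inside, sol$spec$species$N[i] + 1e-9)
  }
  # oppositely charged species accumulate inside the positive gel
  expect_gt(absorbed_count(sol, "np") / sol$spec$species$N[2],
            (sol$spec$r_ng / sol$spec$cell_radius)^3)
  # uncharged species with no field partition by volume alone
  spec0 <- pb_cell_spec(
    r_ng = 4, Z = 0, box = 40,
    species = data.frame(label = "tracer", z = 0, d = 1, N = 10),
    saturation = FALSE, T_K = 293.15)
  sol0 <- pb_solve(spec0)
  expect_equal(absorbed_count(sol0, "tracer"),
               10 * (4 / sol0$spec$cell_radius)^3, tolerance = 1e-4)
})

test_that("net charge combines bare, absorbed and external corrections", {
  # no mobile species: Z_net is the bare charge
  spec <- pb_cell_spec(r_ng = 5, Z = 0, cell_radius = 40)
  expect_equal(net_charge_pbc(pb_solve(spec)), 0)
  sol <- pb_solve(mk_cell(TRUE))
  z0 <- net_charge_pbc(sol)
  expect_equal(net_charge_pbc(sol, external_bare_charge = 16),
               z0 - 16)
  # screening cannot flip a positive gel negative here (|z| NP = 5,
  # partial absorption): net charge stays within (0, Z]
  expect_gt(z0, 0)
  expect_lte(z0, sol$spec$Z)
})

test_that("electroneutrality of the specification is enforced", {
  expect_error(pb_cell_spec(
    r_ng = 4, Z = 10, box = 40,
    species = data.frame(label = "an", z = -1, d = 0.7, N = 5)),
    "electroneutral")
})
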