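test_that("linear power density converts to surface fluence rate", {
  expect_equal(linear_to_surface_fluence(200, 0.11), 200 / (pi * 0.11))
  expect_equal(linear_to_surface_fluence(200, 0.11), 580, tolerance = 0.005)
  expect_equal(linear_to_surface_fluence(800, 0.11), 2320, tolerance = 0.005)
  expect_equal(linear_to_surface_fluence(0, 0.11), 0)
  expect_error(linear_to_surface_fluence(200, 0), "diameter")
})

test_that("emission samples are uniform on the lateral surface, outward-going", {
  d <- diffuser_spec(c(1, 2, 3), axis = c(1, 1, 0) / sqrt(2),
                     radiation_length = 4, outer_diameter = 0.11)
  set.seed(101)
  s <- sample_emission(d, 1e5)
  # every direction leaves the surface
  expect_true(all(s$cos_normal >= 0))
  # all points on the cylinder surface at the right radius and axial range
  rel <- cbind(s$x - 1, s$y - 2, s$z - 3)
  ax <- drop(rel %*% d$axis)
  expect_true(all(ax >= 0 & ax <= 4))
  r <- sqrt(rowSums(rel^2) - ax^2)
  expect_equal(max(abs(r - 0.055)), 0, tolerance = 1e-10)
  # uniform along the length: mean at L/2 within 3 standard errors
  se <- 4 / sqrt(12) / sqrt(length(ax))
  expect_lt(abs(mean(ax) - 2), 3 * se)
  # azimuth uniform over 36 bins (chi-square GoF at alpha = 0.01)
  e1 <- c(0, 0, 1)
  e1 <- e1 - sum(e1 * d$axis) * d$axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d$axis[2] * e1[3] - d$axis[3] * e1[2],
          d$axis[3] * e1[1] - d$axis[1] * e1[3],
          d$axis[1] * e1[2] - d$axis[2] * e1[1])
  psi <- atan2(drop(rel %*% e2), drop(rel %*% e1))
  counts <- table(cut(psi, breaks = seq(-pi, pi, length.out = 37)))
  expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 0.01)
})

test_that("energy ledger balances exactly and runs are bit-reproducible", {
  m <- small_cube(n = 24, spacing = 0.05)
  d <- point_like_diffuser(n = 24, spacing = 0.05)
  fm <- simulate_fluence(m, d, n_photons = 2e4, seed = 11)
  expect_lt(ledger_residual(fm), 1e-6)
  expect_true(all(fm$phi >= 0))
  fm2 <- simulate_fluence(m, d, n_photons = 2e4, seed = 11)
  expect_identical(fm$phi, fm2$phi)
  expect_identical(fm$ledger, fm2$ledger)
  fm3 <- simulate_fluence(m, d, n_photons = 2e4, seed = 12)
  expect_false(identical(fm$phi, fm3$phi))
})

test_that("fluence is exactly linear in diffuser power at fixed seed", {
  m <- small_cube(n = 16, spacing = 0.05)
  d1 <- diffuser_spec(c(0.4, 0.4, 0.2), radiation_length = 0.4,
                      outer_diameter = 0.11, linear_power_density = 100)
  d2 <- d1
  d2$linear_power_density <- 200
  f1 <- simulate_fluence(m, d1, n_photons = 5e3, seed = 3)
  f2 <- simulate_fluence(m, d2, n_photons = 5e3, seed = 3)
  expect_identical(f2$phi, 2 * f1$phi)
})

test_that("void voxels terminate packets and carry zero fluence", {
  m <- small_cube(n = 16, spacing = 0.05)
  m$labels[, , 13:16] <- 0L # void slab
  m$c0_field[, , 13:16] <- 0
  d <- diffuser_spec(c(0.4, 0.4, 0.2), radiation_length = 0.3,
                     outer_diameter = 0.05, linear_power_density = 100)
  fm <- simulate_fluence(m, d, n_photons = 5e3, seed = 5)
  expect_true(all(fm$phi[, , 13:16] == 0))
  expect_gt(fm$ledger$escaped_weight, 0)
  expect_lt(ledger_residual(fm), 1e-6)
  # all-void model is rejected
  mv <- m
  mv$labels[] <- 0L
  expect_error(simulate_fluence(mv, d, n_photons = 10, seed = 1), "void")
})

test_that("non-absorbing voxels fall back to the track-length estimator", {
  m2 <- small_cube(n = 16, spacing = 0.05)
  m2$labels[, , 8] <- 3L # scattering-only tissue slab
  m2$properties[["3"]] <- optical_properties(0, 100, 0.9)
  d <- diffuser_spec(c(0.4, 0.4, 0.1), radiation_length = 0.3,
                     outer_diameter = 0.05, linear_power_density = 100)
  fm <- simulate_fluence(m2, d, n_photons = 1e4, seed = 9)
  mid <- fm$phi[8, 8, 7:9]
  # fluence in the mu_a = 0 slab is finite, positive and continuous with
  # its absorbing neighbours (same order of magnitude)
  expect_true(all(is.finite(fm$phi)))
  expect_gt(mid[2], 0)
  expect_gt(mid[2], 0.2 * max(mid[1], mid[3]))
  expect_lt(mid[2], 5 * max(mid[1], mid[3]))
})

test_that("combining fluence maps is additive", {
  m <- small_cube(n = 12, spacing = 0.06)
  d <- diffuser_spec(c(0.36, 0.36, 0.1), radiation_length = 0.5,
                     outer_diameter = 0.11, linear_power_density = 100)
  f1 <- simulate_fluence(m, d, n_photons = 3e3, seed = 2)
  zero <- f1
  zero$phi <- array(0, dim = f1$grid$dims)
  zero$ledger <- list(launched_weight = 0, deposited_weight = 0,
                      escaped_weight = 0, roulette_discarded_weight = 0)
  zero$n_photons <- 0
  expect_equal(combine_fluence(list(f1, zero))$phi, f1$phi)
  f3 <- combine_fluence(list(f1, f1, f1))
  expect_equal(f3$phi, 3 * f1$phi)
  expect_equal(f3$n_photons, 3 * f1$n_photons)
  g2 <- f1
  g2$grid <- voxel_grid(c(12, 12, 12), rep(0.05, 3))
  expect_error(combine_fluence(list(f1, g2)), "grids")
})

test_that("parallel diffuser lattices have the requested interfiber distance", {
  for (case in list(c(8, 0.9), c(4, 1.25), c(1, 0.9))) {
    n <- case[1]
    L <- case[2]
    plan <- place_parallel_diffusers(n, L, axis = c(0, 0, 1),
                                     anchor = c(0, 0, 0))
    tips <- t(vapply(plan, `[[`, numeric(3), "tip_position"))
    if (n == 1) {
      expect_equal(drop(tips), c(0, 0, 0))
    } else {
      dd <- as.matrix(stats::dist(tips))
      diag(dd) <- Inf
      expect_equal(unname(apply(dd, 1, min)), rep(L, n))
    }
  }
})

test_that("multiple diffusers raise the fluence between them", {
  sp <- 0.1
  m <- build_uniform_phantom(c(32, 32, 24), rep(sp, 3))
  plan8 <- place_parallel_diffusers(8, 0.9, axis = c(0, 0, 1),
                                    anchor = c(0.7, 0.7, 0),
                                    radiation_length = 2.4,
                                    outer_diameter = 0.11,
                                    linear_power_density = 200)
  single <- plan8[1]
  f8 <- simulate_fluence(m, plan8, n_photons = 3e3, seed = 21)
  f1 <- simulate_fluence(m, single, n_photons = 3e3, seed = 21)
  mid <- c(12, 12, 12) # voxel amid the lattice
  expect_gt(f8$phi[mid[1], mid[2], mid[3]], f1$phi[mid[1], mid[2], mid[3]])
  expect_lt(ledger_residual(f8), 1e-6)
})

test_that("diffusion closed form has the documented shape", {
  props <- tumor_props()
  # mu_eff = sqrt(3 * 1.7 * (1.7 + 36.5)) ~ 13.96 /cm
  musp <- 365 * (1 - 0.9)
  expect_equal(sqrt(3 * 1.7 * (1.7 + musp)), 13.96, tolerance = 1e-3)
  r <- seq(0.1, 1, by = 0.1)
  phi <- point_source_diffusion_fluence(r, props, power = 10)
  expect_true(all(diff(phi) < 0))
  expect_equal(point_source_diffusion_fluence(r, props, power = 0), rep(0, 10))
  expect_equal(phi, 10 * point_source_diffusion_fluence(r, props, power = 1))
  expect_error(point_source_diffusion_fluence(0, props), "r")
})

test_that("MC fluence matches the diffusion oracle in the diffusive regime", {
  # desk-scale version of the validation: 1.5e5 packets, r = 0.3-0.6 cm
  n <- 48
  sp <- 0.04
  m <- small_cube(n = n, spacing = sp)
  d <- point_like_diffuser(n = n, spacing = sp)
  fm <- simulate_fluence(m, d, n_photons = 1.5e5, seed = 33)
  ctr <- c(n, n, n) * sp / 2
  r <- center_radii(fm$grid, ctr)
  for (r0 in c(0.3, 0.45, 0.6)) {
    sel <- r >= r0 - 0.05 & r < r0 + 0.05
    mc <- mean(fm$phi[sel])
    ref <- mean(point_source_diffusion_fluence(r[sel], tumor_props(),
                                               diffuser_power(d)))
    expect_lt(abs(mc - ref) / ref, 0.15)
  }
})
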