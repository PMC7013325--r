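test_that("photon-absorption prefactor has the expected value and scalings", {
  p <- pp()
  A <- dose_prefactor(p)
  # hand arithmetic: 1000 * 5000 * ln(10) * 6.35e-5 / (6.626e-34 * 3e10 * 6e23)
  expect_equal(A, 61.3, tolerance = 1e-3)
  expect_equal(dose_prefactor(pp(epsilon = 10000)), 2 * A)
  expect_equal(dose_prefactor(pp(lambda = 635e-7 / 10)), A / 10)
})

test_that("closed-form dose behaves at the reference points", {
  p <- pp(beta = 13.5)
  # 2.3 J/cm^2 on 5.8 uM: about 0.56 mM (within 10%)
  d <- singlet_oxygen_dose(2.3, 1, 5.8e-6, p)
  expect_equal(1000 * d, 0.56, tolerance = 0.10)
  expect_equal(singlet_oxygen_dose(0, 100, 5.8e-6, p), 0)
  expect_equal(singlet_oxygen_dose(1, 100, 0, p), 0)
  # without bleaching, 150 J/cm^2 drives the dose far past 7.9 mM while the
  # bleached model saturates below it
  poff <- pp(bleaching_enabled = FALSE)
  expect_gt(1000 * singlet_oxygen_dose(150, 1, 5.8e-6, poff), 7.9)
  expect_equal(1000 * singlet_oxygen_dose(150, 1, 5.8e-6, poff), 41,
               tolerance = 0.01)
  expect_lt(1000 * saturation_dose(5.8e-6, p), 7.9)
})

test_that("closed form agrees with the time-stepped integral oracle", {
  set.seed(42)
  for (i in 1:12) {
    fl <- stats::runif(1, 0.05, 30)       # J/cm^2, clinically relevant range
    time <- stats::runif(1, 100, 7200)    # s
    c0 <- stats::runif(1, 1e-7, 2e-5)     # mol/L
    p <- pp(beta = stats::runif(1, 2, 40),
            bleaching_enabled = i %% 2 == 0)
    closed <- singlet_oxygen_dose(fl / time, time, c0, p)
    numeric <- numeric_dose_integral(fl / time, time, c0, p, dt = time / 1e4)
    expect_equal(numeric, closed, tolerance = 1e-4)
  }
  # single-step trapezoid overestimates (decreasing convex integrand)
  p <- pp()
  expect_gt(numeric_dose_integral(0.01, 3600, 5.8e-6, p, dt = 3600),
            singlet_oxygen_dose(0.01, 3600, 5.8e-6, p))
  # no bleaching: exact for any dt
  poff <- pp(bleaching_enabled = FALSE)
  expect_equal(numeric_dose_integral(0.01, 3600, 5.8e-6, poff, dt = 3600),
               singlet_oxygen_dose(0.01, 3600, 5.8e-6, poff))
})

test_that("bleached dose is bounded by the unbleached dose and by saturation", {
  p <- pp()
  poff <- pp(bleaching_enabled = FALSE)
  fl <- c(0.01, 0.1, 1, 5, 20, 100, 1000)
  on <- singlet_oxygen_dose(fl, 1, 5.8e-6, p)
  off <- singlet_oxygen_dose(fl, 1, 5.8e-6, poff)
  expect_true(all(on < off))
  expect_true(all(on <= saturation_dose(5.8e-6, p)))
  expect_equal(singlet_oxygen_dose(0, 1, 5.8e-6, p),
               singlet_oxygen_dose(0, 1, 5.8e-6, poff))
  # beta -> Inf recovers the unbleached dose
  pbig <- pp(beta = 1e6)
  expect_equal(singlet_oxygen_dose(fl, 1, 5.8e-6, pbig), off,
               tolerance = 1e-3)
})

test_that("dose is monotone in fluence, c0, quantum yield, epsilon and beta", {
  set.seed(7)
  base <- list(fl = 3, c0 = 5.8e-6, phi_q = 0.77, eps = 5000, beta = 13.5)
  dose_of <- function(b) {
    singlet_oxygen_dose(b$fl, 1, b$c0,
                        pp(epsilon = b$eps, phi_quantum = b$phi_q,
                           beta = b$beta))
  }
  for (nm in names(base)) {
    for (i in 1:5) {
      lo <- base
      hi <- base
      f <- stats::runif(1, 1.05, 3)
      hi[[nm]] <- if (nm == "phi_q") min(1, base[[nm]] * f) else base[[nm]] * f
      expect_gt(dose_of(hi), dose_of(lo))
    }
  }
})

test_that("dose depends on exposure only through fluence = rate x time", {
  p <- pp()
  combos <- list(c(0.001, 3600), c(0.01, 360), c(0.1, 36), c(3.6, 1))
  doses <- vapply(combos, function(x) {
    singlet_oxygen_dose(x[1], x[2], 5.8e-6, p)
  }, numeric(1))
  expect_equal(max(doses) - min(doses), 0, tolerance = 1e-15)
})

test_that("required fluence inverts the dose model", {
  p <- pp(beta = 13.5)
  for (thr in c(0.4e-3, 0.56e-3, 0.72e-3)) {
    fl <- required_fluence(thr, 5.8e-6, p)
    expect_equal(singlet_oxygen_dose(fl, 1, 5.8e-6, p), thr,
                 tolerance = 1e-10)
  }
  # threshold at saturation is unreachable
  sat <- saturation_dose(5.8e-6, p)
  expect_identical(required_fluence(sat, 5.8e-6, p), Inf)
  expect_identical(required_fluence(2 * sat, 5.8e-6, p), Inf)
  # no bleaching: linear inversion
  poff <- pp(bleaching_enabled = FALSE)
  fl <- required_fluence(0.56e-3, 5.8e-6, poff)
  expect_equal(singlet_oxygen_dose(fl, 1, 5.8e-6, poff), 0.56e-3)
})

test_that("minimum initial concentration matches its closed form", {
  p <- pp(beta = 13.5)
  # saturation limit ~0.9 uM for the 0.56 mM threshold
  c0_inf <- min_initial_concentration(0.56e-3, Inf, p)
  expect_equal(1e6 * c0_inf, 0.9, tolerance = 0.1)
  expect_equal(c0_inf, 0.56e-3 / (dose_prefactor(p) * 0.77 * 13.5))
  # finite fluence: 2 J/cm^2 needs ~6.3-6.4 uM
  c0_2 <- min_initial_concentration(0.56e-3, 2, p)
  expect_gt(1e6 * c0_2, 6.3)
  expect_lt(1e6 * c0_2, 6.4)
  expect_equal(min_initial_concentration(0, 2, p), 0)
  # forward consistency: dose at (c0_min, F) hits the threshold exactly
  expect_equal(singlet_oxygen_dose(2, 1, c0_2, p), 0.56e-3, tolerance = 1e-12)
})

test_that("minimum bleaching coefficient is the root of the dose equation", {
  p <- pp()
  b <- min_bleaching_coefficient(0.56e-3, 3, 5.8e-6, p)
  expect_equal(b, 3.52, tolerance = 0.05)
  # forward residual at the root
  pb <- pp(beta = b)
  expect_equal(singlet_oxygen_dose(3, 1, 5.8e-6, pb), 0.56e-3,
               tolerance = 1e-6)
  # beta * (1 - exp(-F/beta)) increases in beta -> root is unique
  f <- function(bb) bb * (1 - exp(-3 / bb))
  bs <- seq(0.5, 50, length.out = 40)
  expect_true(all(diff(f(bs)) > 0))
  # unreachable when even unbleached dose misses the threshold
  expect_identical(min_bleaching_coefficient(0.56e-3, 0.1, 5.8e-6, p), Inf)
})

test_that("dose maps apply the scalar model voxelwise", {
  m <- small_cube(n = 8, spacing = 0.1)
  g <- m$grid
  phi <- array(stats::runif(8^3, 0, 500), dim = g$dims) # mW/cm^2
  fm <- structure(list(grid = g, phi = phi, n_photons = 1, seed = 1,
                       ledger = list(launched_weight = 1, deposited_weight = 1,
                                     escaped_weight = 0,
                                     roulette_discarded_weight = 0)),
                  class = "fluence_map")
  dm <- dose_map(fm, 3600, m)
  # spot-check one voxel against the scalar operation
  expect_equal(dm$d_so[3, 5, 7],
               singlet_oxygen_dose(phi[3, 5, 7] / 1000, 3600, 5.8e-6, pp()))
  # uniform fluence -> uniform dose
  fm$phi[] <- 100
  dmu <- dose_map(fm, 3600, m)
  expect_equal(max(dmu$d_so), min(dmu$d_so))
  # linear in the concentration field
  m2 <- m
  m2$c0_field <- 3 * m$c0_field
  expect_equal(dose_map(fm, 3600, m2)$d_so, 3 * dmu$d_so)
  # grid mismatch is an error
  m3 <- small_cube(n = 9, spacing = 0.1)
  expect_error(dose_map(fm, 3600, m3), "grid")
})
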