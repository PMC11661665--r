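# Electrostatics: radial binning, Gauss-theorem potential, the analytic
# Debye-Hueckel shell, and the two fitted capsid forms.

lB <- bjerrum_length()

test_that("radial binning conserves charge exactly and localizes it", {
  pc <- charge_distribution(matrix(0, 1, 3), 1)
  p <- radial_charge_profile(pc, bin_width = 0.5, r_max = 5)
  expect_equal(p$shell_charge[1], 1)
  expect_equal(sum(p$shell_charge), 1)

  sh <- make_shell_charges(10, 60, 60, seed = 2)
  p2 <- radial_charge_profile(sh, bin_width = 0.5, r_max = 12)
  k <- findInterval(10, p2$bin_edges)
  expect_equal(p2$shell_charge[k], 60)
  expect_equal(sum(p2$shell_charge != 0), 1L)

  rnd <- capsidfield:::with_seed(3, charge_distribution(
    matrix(stats::runif(3e4, -8, 8), 1e4, 3),
    rep(c(1, -1), 5e3)))
  p3 <- radial_charge_profile(rnd, bin_width = 0.2)
  expect_identical(sum(p3$shell_charge), 0)
})

test_that("particles beyond r_max are reported by index", {
  sh <- make_shell_charges(10, 1, 5, seed = 1)
  expect_error(radial_charge_profile(sh, bin_width = 0.5, r_max = 8),
               "beyond r_max")
})

test_that("Gauss potential matches the Coulomb closed form for a point charge", {
  pc <- charge_distribution(matrix(0, 1, 3), 5)
  prof <- radial_charge_profile(pc, bin_width = 0.2, r_max = 10)
  U <- gauss_potential(prof, q_test = 1)
  sel <- U$r >= 3 * 0.2 & U$r < 10
  exact <- 5 * lB * (1 / U$r[sel] - 1 / 10)
  expect_lt(max(abs(U$U[sel] - exact) / abs(exact)), 0.01)
})

test_that("the interior of a uniform shell is flat and neutral systems screen", {
  sh <- make_shell_charges(5, 60, 2000, seed = 3)
  prof <- radial_charge_profile(sh, bin_width = 0.05, r_max = 10)
  U <- gauss_potential(prof, q_test = 1)
  inside <- U$r < 4.9
  expect_lt(diff(range(U$U[inside])), 1e-9)

  # +Q at R1, -Q at R2 > R1: identically zero outside R2
  two <- charge_distribution(
    rbind(make_shell_charges(3, 10, 500, seed = 5)$positions,
          make_shell_charges(6, -10, 500, seed = 6)$positions),
    c(rep(10 / 500, 500), rep(-10 / 500, 500)))
  p2 <- radial_charge_profile(two, bin_width = 0.1, r_max = 10)
  U2 <- gauss_potential(p2, q_test = 1)
  expect_lt(max(abs(U2$U[U2$r > 6.2])), 1e-12)
})

test_that("halving the bin width halves the discretization error", {
  sh <- make_shell_charges(5, 60, 2000, seed = 3)
  dh <- dh_shell_potential(dh_shell_params(5, 60, 0))
  err_at <- function(bw) {
    p <- radial_charge_profile(sh, bin_width = bw, r_max = 10)
    u <- gauss_potential(p, q_test = 1)
    max(abs(u$U - (dh(u$r) - dh(10))))
  }
  e1 <- err_at(0.2); e2 <- err_at(0.1)
  expect_lt(e2 / e1, 0.6)
  expect_gt(e2 / e1, 0.4)
})

test_that("the DH shell reduces to the bare Coulomb shell as kappa -> 0", {
  p <- dh_shell_params(10, 60, kappa = 1e-8)
  phi <- dh_shell_potential(p)
  r_in <- seq(0, 9.9, by = 0.3)
  expect_lt(max(abs(phi(r_in) - lB * 60 / 10) / (lB * 60 / 10)), 1e-3)
  r_out <- seq(10.1, 30, by = 0.5)
  expect_lt(max(abs(phi(r_out) - lB * 60 / r_out) / (lB * 60 / r_out)), 1e-3)
})

test_that("the DH shell is continuous with the prescribed derivative jump", {
  p <- dh_shell_params(12, -1800, kappa = debye_kappa(0.15))
  phi <- dh_shell_potential(p)
  expect_lt(abs(phi(12 - 1e-9) - phi(12 + 1e-9)), 1e-9 * abs(phi(12)))
  # second-order one-sided differences on each side of the shell
  h <- 1e-4
  slope_in <- (3 * phi(12) - 4 * phi(12 - h) + phi(12 - 2 * h)) / (2 * h)
  slope_out <- (-3 * phi(12) + 4 * phi(12 + h) - phi(12 + 2 * h)) / (2 * h)
  jump <- slope_in - slope_out
  expect_lt(abs(jump - lB * (-1800) / 12^2) / abs(jump), 1e-6)
})

test_that("Gauss and DH potentials agree on the same shell at kappa = 0", {
  sh <- make_shell_charges(5, 60, 2000, seed = 3)
  prof <- radial_charge_profile(sh, bin_width = 0.05, r_max = 10)
  U <- gauss_potential(prof, q_test = 1)
  phi <- dh_shell_potential(dh_shell_params(5, 60, 0))
  ref <- phi(U$r) - phi(10)
  expect_lt(max(abs(U$U - ref)) / max(abs(ref)), 0.01)
})

test_that("the Yukawa+WCA fitter recovers known parameters from noisy data", {
  true <- yukawa_wca_params(alpha = -5, lam = 1.0, eps = 1, sigma = 0.5,
                     R_delta = 12.5)
  grid <- seq(6, 12.3, by = 0.05)
  well <- max(abs(-5 * exp(-(12.5 - grid) / 1) / (12.5 - grid)))
  prof <- make_potential_curve(true, grid, noise_sd = 1e-3 * well, seed = 7)
  fit <- fit_yukawa_wca(prof, R_delta = 12.5)
  expect_lt(abs(fit$params$alpha + 5) / 5, 0.02)
  expect_lt(abs(fit$params$lam - 1), 0.02)
  expect_true(fit$converged)
})

test_that("the Yukawa+WCA fitter interpolates its own noise-free data", {
  true <- yukawa_wca_params(alpha = -5, lam = 1.0, eps = 1, sigma = 0.5,
                     R_delta = 12.5)
  grid <- seq(6, 12.05, by = 0.05)
  prof <- make_potential_curve(true, grid, noise_sd = 0)
  fit <- fit_yukawa_wca(prof, R_delta = 12.5)
  expect_lt(fit$rms, 1e-8)
})

test_that("a flat zero profile fits with a vanishing amplitude", {
  grid <- seq(6, 12, by = 0.1)
  prof <- radial_potential_profile(grid, rep(0, length(grid)),
                                   strict_zero = FALSE)
  fit <- fit_yukawa_wca(prof, R_delta = 12.5)
  expect_lt(abs(fit$params$alpha), 1e-6)
  expect_lt(fit$rms, 1e-6)
})

test_that("the Yukawa+WCA form captures the DH shell interior", {
  phi <- dh_shell_potential(dh_shell_params(12, -1800, debye_kappa(0.15)))
  r <- seq(6, 11.9, by = 0.05)
  U <- phi(r) - phi(0.01)   # profile decays to zero away from the wall
  prof <- radial_potential_profile(r, U, strict_zero = FALSE)
  # the wall radius sits above the cavity; pick it by a coarse quality scan
  fits <- lapply(c(12.5, 13, 14, 15, 16), function(Rd)
    fit_yukawa_wca(prof, R_delta = Rd, n_starts = 4))
  best <- fits[[which.min(vapply(fits, `[[`, 1, "rms"))]]
  expect_lt(best$rms / diff(range(U)), 0.02)
})

test_that("the exponential-polynomial fitter recovers known parameters", {
  cc <- capsidfield:::with_seed(5, stats::rnorm(10)) / (11.5 / 2)^(1:10)
  true <- polyexp_params(A = 0.4, c = cc, R0 = 12)
  grid <- seq(0.5, 12, by = 0.1)
  prof <- make_potential_curve(true, grid, noise_sd = 0)
  fit <- fit_polyexp(prof, R0 = 12, N = 10)
  expect_lt(max(abs((fit$params$c - cc) / cc)), 1e-4)
  expect_lt(abs(fit$params$A - 0.4), 1e-4)
  expect_lt(fit$rms, 1e-8)
})

test_that("any polyexp fit vanishes identically at the cavity radius", {
  cc <- capsidfield:::with_seed(8, stats::rnorm(6)) / 4^(1:6)
  prof <- make_potential_curve(polyexp_params(0.3, cc, 10), seq(0.5, 10, 0.1),
                               noise_sd = 0.01, seed = 2)
  fit <- fit_polyexp(prof, R0 = 10, N = 6)
  expect_identical(eval_capsid_potential(10, fit$params)$energy, 0)
})

test_that("the polyexp form fits the Gauss-derived capsid-like profile", {
  caps <- make_capsid_like_charges(R0 = 12, seed = 7)
  prof <- radial_charge_profile(caps, bin_width = 0.2)
  U <- gauss_potential(prof)          # q_test = -1: nucleotide charge
  fit <- fit_polyexp(U, R0 = 12, N = 10)
  well <- max(abs(U$U[U$r <= 12]))
  expect_lt(fit$rms, 0.02 * well)
})

test_that("capsid potential forces are the analytic derivatives", {
  e2 <- yukawa_wca_params(alpha = -5, lam = 1, eps = 1, sigma = 0.5, R_delta = 12.5)
  cc <- capsidfield:::with_seed(5, stats::rnorm(10)) / 6^(1:10)
  e3 <- polyexp_params(A = 0.4, c = cc, R0 = 12)
  h <- 1e-5
  rs <- capsidfield:::with_seed(13, stats::runif(20, 2, 12.2))
  for (params in list(e2, e3)) {
    r <- if (inherits(params, "yukawa_wca_params")) pmin(rs, 12.2) else rs
    fd <- -(eval_capsid_potential(r + h, params)$energy -
              eval_capsid_potential(r - h, params)$energy) / (2 * h)
    an <- eval_capsid_potential(r, params)$force
    expect_lt(max(abs(fd - an) / pmax(abs(an), 1e-8)), 1e-6)
  }
})

test_that("the WCA wall switches off exactly at its cutoff", {
  e2 <- yukawa_wca_params(alpha = 0, lam = 1, eps = 2, sigma = 0.5, R_delta = 12.5)
  r_cut <- 12.5 - 2^(1 / 6) * 0.5
  expect_equal(eval_capsid_potential(r_cut, e2)$energy, 0)
  # just inside the cutoff the shifted minimum makes the energy tiny but > 0
  expect_gt(eval_capsid_potential(r_cut + 1e-4, e2)$energy, 0)
  expect_identical(eval_capsid_potential(r_cut - 1e-4, e2)$energy, 0)
})

test_that("Yukawa+WCA evaluation refuses radii at or beyond the wall", {
  e2 <- yukawa_wca_params(alpha = -5, lam = 1, eps = 1, sigma = 0.5, R_delta = 12.5)
  expect_error(eval_capsid_potential(12.5, e2), "R_delta")
})
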