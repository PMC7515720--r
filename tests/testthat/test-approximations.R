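test_that("analytic densities vanish in the empty-lattice limit", {
  kp <- kappa_profile("g", rep(1e7, 19), ell = 3L)
  expect_true(all(ila_density(kp)$rho < 1e-6))
  expect_true(all(meanfield_density(kp)$rho < 1e-6))
})

test_that("initiation-limited expansion is correct to second order", {
  # uniform kappa, small lattice: compare against the exact solver and
  # check that the residual error decays with the cube of 1/kappa
  ks <- c(25, 50, 100, 200)
  errs <- vapply(ks, function(kv) {
    kp <- kappa_profile("g", rep(kv, 7), ell = 2L)
    max(abs(ila_density(kp)$rho - exact_stationary(kp)$rho))
  }, numeric(1))
  # doubling kappa shrinks the error by at least ~ the truncation factor 8
  expect_true(all(errs[-length(errs)] / errs[-1] > 6))
  slope <- unname(coef(lm(log(errs) ~ log(ks)))[2])
  expect_lt(abs(slope + 3) / 3, 0.2)
})

test_that("leading-order density dominates deep in the dilute regime", {
  kp <- kappa_profile("g", rep(2000, 49), ell = 10L)
  expect_true(all(abs(ila_density(kp)$rho * 2000 - 1) < 0.01))
  # at kappa = 200 the second-order interference correction ~ (ell-1)/kappa
  # is itself ~4%; the expansion must capture it
  il <- ila_density(kappa_profile("g", rep(200, 49), ell = 10L))
  expect_true(all(abs(il$rho * 200 - 1) < 0.06))
  # the deviation from 1/kappa is the initiation-suppression factor: the
  # density is the (reduced) current times the dwell time, rho*kappa ~ J/alpha
  expect_true(all(abs(il$rho * 200 - il$J_over_alpha) < 0.01))
})

test_that("a validity warning is raised when elongation is not limiting", {
  kp <- kappa_profile("g", c(0.5, rep(5, 18)), ell = 3L)
  expect_warning(ila_density(kp), "validity")
})

test_that("mean-field and expansion agree where both are valid", {
  kp <- kappa_profile("g", rep(100, 30), ell = 10L)
  mf <- meanfield_density(kp)
  il <- ila_density(kp)
  expect_true(all(abs(il$rho - mf$rho) / mf$rho < 0.02))
})

test_that("mean-field tracks the exact solution at moderate density", {
  kp <- kappa_profile("g", rep(25, 7), ell = 2L)
  mf <- meanfield_density(kp)
  ex <- exact_stationary(kp)
  expect_true(all(abs(mf$rho - ex$rho) / ex$rho < 0.15))
})

test_that("mean-field inversion round-trips and obeys the dilute limit", {
  set.seed(5)
  kap0 <- exp(runif(20, log(10), log(40)))
  kp0 <- kappa_profile("g", kap0, ell = 3L)
  r0 <- meanfield_density(kp0, ell = 3L)$rho
  ki <- meanfield_invert(r0, ell = 3L)
  expect_true(all(abs(ki$kappa - kap0) / kap0 < 1e-6))
  r2 <- meanfield_density(ki, ell = 3L)$rho
  expect_lt(max(abs(r2 - r0)), 1e-8)

  # MacDonald-Gibbs value at uniform r = 0.01, ell = 10:
  # kappa = (J/alpha)(1-(ell-1)r)/(r(1-ell r)) = 0.9*0.91/0.009 = 91
  ki <- meanfield_invert(rep(0.01, 30), ell = 10L)
  expect_equal(ki$kappa[15], 91, tolerance = 1e-10)
  # leading order 1/r is approached as the profile gets dilute
  ki <- meanfield_invert(rep(0.001, 30), ell = 10L)
  expect_lt(abs(ki$kappa[15] - 1000) / 1000, 0.05)
})

test_that("a locally dense codon maps to a locally slow rate", {
  r <- rep(0.01, 30)
  r[15] <- 0.3
  ki <- meanfield_invert(r, ell = 10L)
  expect_lt(ki$kappa[15], ki$kappa[14])
  expect_lt(ki$kappa[15], ki$kappa[16])
})

test_that("densities respond monotonically to a single slowed codon", {
  kp <- kappa_profile("g", rep(10, 7), ell = 2L)
  base <- exact_stationary(kp)$rho
  slow <- kp
  slow$kappa[4] <- 5
  pert <- exact_stationary(kappa_profile("g", slow$kappa, ell = 2L))$rho
  expect_gte(pert[4], base[4])
  # and the expansion agrees on the direction
  base_i <- ila_density(kp)$rho
  pert_i <- ila_density(kappa_profile("g", slow$kappa, ell = 2L))$rho
  expect_gte(pert_i[4], base_i[4])
})

test_that("degenerate inputs are refused", {
  expect_error(meanfield_invert(c(0.5, 1.2, 0.1), ell = 1L), "strictly")
  expect_error(meanfield_invert(c(0.5, 0, 0.1), ell = 1L), "strictly")
  kp <- kappa_profile("g", rep(10, 19), ell = 3L)
  expect_error(meanfield_density(kp, max_iter = 1), "converge")
})
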