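test_that("initiation efficiency is the unoccupied-region probability", {
  prof <- density_profile("g", c(0.05, 0.15, 0.02, 0.01), 0.8, "EXACT",
                          ell = 2L)
  expect_equal(compute_tie(prof), 1 - 0.2)
  # empty lattice
  prof <- density_profile("g", rep(0, 6), 1, "EXACT", ell = 3L)
  expect_equal(compute_tie(prof), 1)
  # inconsistent profile
  prof <- density_profile("g", c(0.8, 0.5, 0.1, 0.1), 0, "EXACT", ell = 2L)
  expect_error(compute_tie(prof), "inconsistent")
})

test_that("TIE from densities equals the termination current exactly", {
  for (seed in c(2, 12)) {
    kp <- random_small_instance(seed)
    ex <- exact_stationary(kp)
    expect_equal(compute_tie(ex), attr(ex, "J"), tolerance = 1e-12)
  }
})

test_that("TEE formula equals the conditional clearance probability", {
  # worked arithmetic: TIE 0.8, kappa 10, rho 0.1 -> TEE 0.8
  kp <- kappa_profile("g", rep(10, 4), ell = 2L)
  prof <- density_profile("g", rep(0.1, 4), 0.8, "EXACT", ell = 2L)
  expect_equal(as.numeric(compute_tee(kp, prof, 0.8)), rep(0.8, 4))

  # exact solver: TIE/(kappa_i rho_i) is the probability that codons
  # i+1..i+ell are clear given an A-site at i, to machine precision
  for (seed in c(3, 23)) {
    kp <- random_small_instance(seed)
    ex <- exact_stationary(kp)
    tee <- as.numeric(compute_tee(kp, ex, compute_tie(ex)))
    expect_equal(tee, attr(ex, "clearance"), tolerance = 1e-10)
  }
})

test_that("TEE approaches one as traffic vanishes", {
  kp <- kappa_profile("g", rep(300, 7), ell = 2L)
  ex <- exact_stationary(kp)
  tee <- as.numeric(compute_tee(kp, ex, compute_tie(ex)))
  expect_true(all(tee > 0.98))
})

test_that("measured and formula TEE agree in simulation", {
  kp <- random_small_instance(33)
  sim <- simulate_tasep(kp, simulation_config(seed = 33,
                                              transitions_per_codon = 3e4))
  tee_formula <- as.numeric(compute_tee(kp, sim$profile,
                                        measure_tie(sim)))
  keep <- !is.na(sim$tee_measured) & !is.na(tee_formula)
  z <- abs(tee_formula[keep] - sim$tee_measured[keep]) /
    pmax(3 * sim$tee_se[keep], 0.01)
  expect_true(all(z < 3))
})

test_that("collision time is zero exactly at the no-interference boundary", {
  kp <- kappa_profile("g", rep(10, 4), ell = 2L)
  # r_i/TIE = 1/kappa_i -> zero
  r <- rep(0.08, 4)
  expect_equal(collision_time(r, 0.8, kp), rep(0, 4))
  # worked example: TIE 0.8, r 0.1, kappa 10 -> 0.125 - 0.1 = 0.025
  expect_equal(collision_time(rep(0.1, 4), 0.8, kp)[1], 0.025)
  # inconsistent inputs warn
  expect_warning(collision_time(rep(0.01, 4), 0.8, kp, warn_tol = 1e-9),
                 "negative")
})

test_that("collision times from a clean simulation are non-negative", {
  kp <- random_small_instance(43)
  sim <- simulate_tasep(kp, simulation_config(seed = 43,
                                              transitions_per_codon = 3e4))
  ct <- suppressWarnings(
    collision_time(sim$profile$rho, measure_tie(sim), kp))
  expect_true(all(ct > -3 * sim$profile$se / measure_tie(sim) - 1e-6))
})

test_that("metagene summary aggregates aligned TEE profiles", {
  mk_report <- function(tee, status = NULL) {
    n <- length(tee)
    if (is.null(status)) status <- rep("ACCEPTED_ILA", n)
    structure(list(gene_id = "g", tie = 0.9, tee = tee,
                   mean_tee = mean(tee, na.rm = TRUE),
                   alpha_t_coll = rep(0, n), rho_over_rhomax = 0.1,
                   status = factor(status,
                     levels = c("ACCEPTED_ILA", "ACCEPTED_MEANFIELD",
                                "REJECTED_ILA_CHECK", "REJECTED_FIT_CHECK"))),
              class = "efficiency_report")
  }
  tee <- seq(0.5, 0.95, length.out = 10)
  reports <- replicate(10, mk_report(tee), simplify = FALSE)
  meta <- metagene_tee(reports, max_position = 11L)
  expect_equal(meta$median, tee)
  expect_equal(meta$q1, tee)
  expect_equal(meta$q3, tee)
  expect_equal(meta$n_genes, rep(10L, 10))

  # a shorter gene drops out of positions beyond its length
  reports2 <- c(reports, list(mk_report(tee[1:5])))
  meta2 <- metagene_tee(reports2, max_position = 11L)
  expect_equal(meta2$n_genes, c(rep(11L, 5), rep(10L, 5)))

  # planted signal: elevated TEE at codons 2..6 shows up in the median
  set.seed(44)
  planted <- replicate(20, {
    base <- runif(10, 0.7, 0.8)
    base[1:5] <- base[1:5] + 0.15
    mk_report(base)
  }, simplify = FALSE)
  meta3 <- metagene_tee(planted, max_position = 11L)
  expect_gt(min(meta3$median[1:5]), max(meta3$median[6:10]))

  # rejected codons never enter
  rep4 <- mk_report(c(NA, tee[-1]),
                    status = c("REJECTED_FIT_CHECK",
                               rep("ACCEPTED_ILA", 9)))
  meta4 <- metagene_tee(list(rep4), max_position = 11L)
  expect_identical(meta4$n_genes[1], 0L)
})

test_that("the neglected drop-off rate is three orders below elongation", {
  expect_equal(dropoff_rate(), 1e-3)
  expect_lt(dropoff_rate() / 10, 1e-3)   # vs elongation ~10 codons/s
})
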