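#' Configuration for a stochastic simulation run
#'
#' @param seed integer seed for the run's random-number generator.
#' @param burn_in burn-in specification: either a number of completed
#'   terminations before sampling starts (default `max(100, L)`, resolved at
#'   run time) or a list `list(time = <span>)` for a fixed time span.
#' @param sample_time total simulated time over which time averages are
#'   accumulated.  When `NULL`, it is chosen so that each codon accrues
#'   about `transitions_per_codon` expected occupancy transitions, using the
#'   analytic current as the a-priori estimate.
#' @param target_se optional per-codon standard-error goal; sampling is
#'   extended (up to `max_extensions` times) until the largest codon SE
#'   falls below it.
#' @param transitions_per_codon expected hops through each codon used to
#'   size the default sampling window (default `1e4`, giving ~1% relative
#'   SE on typical densities).
#' @param n_batches number of batches for batch-means standard errors
#'   (default 20).
#' @param max_extensions cap on `target_se`-driven reruns (default 3).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, burn_in = NULL, sample_time = NULL,
                              target_se = NULL, transitions_per_codon = 1e4,
                              n_batches = 20L, max_extensions = 3L) {
  stopifnot(is.null(sample_time) || sample_time > 0,
            n_batches >= 2, transitions_per_codon > 0)
  structure(list(seed = as.integer(seed), burn_in = burn_in,
                 sample_time = sample_time, target_se = target_se,
                 transitions_per_codon = transitions_per_codon,
                 n_batches = as.integer(n_batches),
                 max_extensions = as.integer(max_extensions)),
            class = "simulation_config")
}

#' Simulate the translation exclusion process
#'
#' Continuous-time Monte Carlo (Gillespie) simulation of the inhomogeneous
#' exclusion process with extended particles, returning time-averaged
#' stationary densities with batch-means standard errors, the protein
#' production current (overall and per transition), the measured initiation
#' efficiency (fraction of time the initiation region is clear) and the
#' measured per-codon conditional clearance (elongation efficiency).
#'
#' @param rates a [gene_rates()] with absolute rates, or a
#'   [kappa_profile()] (simulated with `alpha = 1`, `k = kappa`; densities
#'   depend only on the ratios so this is exact).
#' @param config a [simulation_config()].
#' @return An object of class `simulated_densities`: a list with elements
#'   `profile` (a [density_profile()], `source = "SIMULATION"`), `J`,
#'   `J_se`, `J_per_bond` (currents through codons `2..L`), `J_init`,
#'   `tie_measured`, `tie_se`, `tee_measured`, `tee_se`,
#'   `n_terminations`, and `zero_terminations` (warning flag).
#' @export
simulate_tasep <- function(rates, config = simulation_config()) {
  p <- .as_alpha_k(rates)
  L <- p$L; ell <- p$ell

  burn_terms <- max(100L, L)
  burn_max_time <- Inf
  if (!is.null(config$burn_in)) {
    if (is.list(config$burn_in) && !is.null(config$burn_in$time)) {
      burn_terms <- .Machine$integer.max
      burn_max_time <- config$burn_in$time
    } else {
      burn_terms <- as.integer(config$burn_in)
    }
  }
  stopifnot(burn_max_time >= 0)

  sample_time <- config$sample_time
  if (is.null(sample_time)) {
    kp <- kappa_profile(p$gene_id, p$k / p$alpha, ell)
    J_est <- suppressWarnings(ila_density(kp)$J_over_alpha) * p$alpha
    J_est <- min(max(J_est, 0.05 * p$alpha), p$alpha)
    sample_time <- config$transitions_per_codon / J_est
  }

  run <- function(seed, tspan) {
    gillespie_cpp(p$k, p$alpha, as.integer(ell),
                  burn_terms, burn_max_time, tspan,
                  config$n_batches, as.double(seed))
  }
  res <- run(config$seed, sample_time)
  ext <- 0L
  while (!is.null(config$target_se) && ext < config$max_extensions &&
         max(res$rho_se) > config$target_se) {
    scale <- min(16, (max(res$rho_se) / config$target_se)^2 * 1.2)
    sample_time <- sample_time * max(2, scale)
    ext <- ext + 1L
    res <- run(config$seed + ext, sample_time)
  }

  if (res$n_terminations == 0)
    warning("no terminations in the sampling window; current estimates ",
            "are unreliable", call. = FALSE)

  profile <- density_profile(p$gene_id, res$rho,
                             res$J / p$alpha, "SIMULATION", ell,
                             se = res$rho_se)
  structure(list(profile = profile,
                 J = res$J, J_se = res$J_se,
                 J_per_bond = res$J_bond, J_init = res$J_init,
                 tie_measured = res$tie, tie_se = res$tie_se,
                 tee_measured = res$tee, tee_se = res$tee_se,
                 n_terminations = res$n_terminations,
                 zero_terminations = res$n_terminations == 0,
                 sample_time = sample_time,
                 seed = config$seed),
            class = "simulated_densities")
}

#' @export
print.simulated_densities <- function(x, ...) {
  cat(sprintf("<simulated_densities> %s: %d terminations over t = %.4g\n",
              x$profile$gene_id, x$n_terminations, x$sample_time))
  cat(sprintf("  J = %.4g (se %.2g), TIE = %.4g, mean rho = %.4g\n",
              x$J, x$J_se, x$tie_measured, x$profile$rho_mean))
  invisible(x)
}

#' Measured translation initiation efficiency of a simulation run
#'
#' The time fraction during which codons `2..ell+1` held no A-site, i.e.
#' the probability that an initiation attempt is not blocked.  Equals
#' `J/alpha` in the stationary state.
#'
#' @param sim a `simulated_densities` object from [simulate_tasep()].
#' @return Probability in `[0, 1]`.
#' @export
measure_tie <- function(sim) {
  stopifnot(inherits(sim, "simulated_densities"))
  sim$tie_measured
}
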