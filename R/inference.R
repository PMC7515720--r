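#' Configuration of the rate-inference step
#'
#' @param ila_check_tol relative-error threshold for the model-consistency
#'   check (analytic vs simulated density), default 0.10.
#' @param fit_check_tol relative-error threshold for the data-consistency
#'   check (simulated vs experimental density), default 0.05.  Both checks
#'   use relative errors; the denominator is the simulated density for the
#'   first check and the experimental density for the second.
#' @param kappa_bounds positive bounds on each fitted `kappa` (default
#'   `c(1e-3, 1e6)`); optimization runs on `log(kappa)` so positivity holds
#'   by construction.
#' @param max_iter optimizer iteration cap.
#' @param ftol optimizer tolerance on the objective.
#' @param sim_config a [simulation_config()] used for the check-stage
#'   simulations (one run per stage, not per codon).
#' @param seed seed forwarded to the check simulations when `sim_config`
#'   does not set one explicitly.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(ila_check_tol = 0.10, fit_check_tol = 0.05,
                       kappa_bounds = c(1e-3, 1e6), max_iter = 300L,
                       ftol = 1e-15, sim_config = NULL, seed = 1L) {
  stopifnot(ila_check_tol > 0, ila_check_tol < 1,
            fit_check_tol > 0, fit_check_tol < 1,
            length(kappa_bounds) == 2L, kappa_bounds[1] > 0,
            kappa_bounds[2] > kappa_bounds[1], is.finite(kappa_bounds[2]))
  if (is.null(sim_config)) sim_config <- simulation_config(seed = seed)
  structure(list(ila_check_tol = ila_check_tol,
                 fit_check_tol = fit_check_tol,
                 kappa_bounds = kappa_bounds, max_iter = as.integer(max_iter),
                 ftol = ftol, sim_config = sim_config, seed = as.integer(seed)),
            class = "fit_config")
}

#' Fit relative elongation rates to a density profile
#'
#' Least-squares fit of the relative rate profile `kappa` to a normalized
#' experimental density profile `r`, minimizing
#' `S = sum_i (rho_ILA(kappa)[i] - r[i])^2` with the initiation-limited
#' analytic density as forward model.  The fit runs on `log(kappa)` with a
#' Levenberg--Marquardt least-squares solver, started from the mean-field
#' inversion of `r`.  Codons with `r = 0` carry no information about a
#' finite rate (they imply unphysically fast elongation); their `kappa` is
#' pinned at the upper bound, excluded from optimization, and flagged.
#'
#' @param r a [normalized_profile()] that passed the coverage filter.
#' @param ell ribosome footprint in codons.
#' @param config a [fit_config()].
#' @return A [kappa_profile()] with attributes `S` (final objective),
#'   `pinned` (logical per codon), `convergence` (solver message) and
#'   `niter`.
#' @export
fit_kappa <- function(r, ell = 10L, config = fit_config()) {
  stopifnot(inherits(r, "normalized_profile"))
  rv <- r$r
  if (any(rv >= 1)) .gene_rejected(r$gene_id, "density>1")
  n <- length(rv)
  pinned <- rv == 0
  lo <- config$kappa_bounds[1]; hi <- config$kappa_bounds[2]

  # starting point: mean-field inversion (zero-density codons get the cap)
  r_start <- rv
  r_start[pinned] <- min(1e-6, min(rv[!pinned]) / 10)
  k0 <- meanfield_invert(r_start, ell, gene_id = r$gene_id)$kappa
  k0 <- pmin(pmax(k0, lo * 1.0001), hi * 0.9999)
  k0[pinned] <- hi

  kap_full <- k0
  free <- which(!pinned)
  resid_fn <- function(logk_free) {
    kap_full[free] <- exp(logk_free)
    ila_rho_cpp(kap_full, as.integer(ell)) - rv
  }
  fit <- minpack.lm::nls.lm(
    par = log(k0[free]), fn = resid_fn,
    lower = rep(log(lo), length(free)), upper = rep(log(hi), length(free)),
    control = minpack.lm::nls.lm.control(
      maxiter = config$max_iter, ftol = config$ftol, ptol = 1e-14))
  if (fit$info == 0 || fit$info == 9)
    stop("optimizer failed to converge: ", fit$message,
         " (best S = ", format(fit$deviance), ")")
  kap_full[free] <- exp(fit$par)
  kp <- kappa_profile(r$gene_id, kap_full, ell)
  attr(kp, "S") <- fit$deviance
  attr(kp, "pinned") <- pinned
  attr(kp, "convergence") <- fit$message
  attr(kp, "niter") <- fit$niter
  kp
}

#' Per-codon quality check of fitted rates
#'
#' Two-stage consistency check mirroring the inference workflow: (a) one
#' stochastic simulation with the fitted rates validates the analytic
#' (initiation-limited) density per codon; codons whose relative error
#' exceeds `ila_check_tol` get their `kappa` replaced by the mean-field
#' estimate and are re-checked against a second simulation of the hybrid
#' profile (analytic side: mean-field density); codons failing both are
#' `REJECTED_ILA_CHECK`.  (b) Surviving codons must reproduce the
#' experimental density within `fit_check_tol`, else `REJECTED_FIT_CHECK`.
#' Codons pinned during fitting (zero reads) are rejected at stage (b).
#'
#' @param kappa a [kappa_profile()] from [fit_kappa()].
#' @param r the [normalized_profile()] that was fitted.
#' @param ell ribosome footprint in codons.
#' @param config a [fit_config()]; its `sim_config` sets the simulation
#'   budget (one run per stage).
#' @return An object of class `inference_result`: list with `kappa` (final
#'   hybrid profile), `status` (factor per codon with levels ACCEPTED_ILA,
#'   ACCEPTED_MEANFIELD, REJECTED_ILA_CHECK, REJECTED_FIT_CHECK), `S`,
#'   `diagnostics` (per-codon data.frame with both relative errors),
#'   `fraction_accepted`, and the stage simulations.
#' @export
quality_check <- function(kappa, r, ell = kappa$ell, config = fit_config()) {
  stopifnot(inherits(kappa, "kappa_profile"),
            inherits(r, "normalized_profile"))
  n <- length(kappa$kappa)
  stopifnot(length(r$r) == n)
  pinned <- attr(kappa, "pinned")
  if (is.null(pinned)) pinned <- rep(FALSE, n)
  rv <- r$r

  sim_cfg <- config$sim_config
  rho_ila <- suppressWarnings(ila_density(kappa, ell))$rho
  sim1 <- simulate_tasep(kappa, sim_cfg)
  rho_sim <- sim1$profile$rho
  err_a <- abs(rho_ila - rho_sim) / ifelse(rho_sim > 0, rho_sim, NA_real_)

  ila_ok <- !is.na(err_a) & err_a < config$ila_check_tol & !pinned
  fail_a <- which(!ila_ok & !pinned)

  status <- rep("REJECTED_ILA_CHECK", n)
  kap_final <- kappa$kappa
  sim2 <- NULL
  mf_ok <- logical(n)
  rho_for_b <- rho_sim                     # per-codon density used in (b)

  if (length(fail_a)) {
    # fall back to the mean-field estimate at the failing codons only
    r_mf <- rv
    r_mf[rv == 0] <- min(1e-6, min(rv[rv > 0]) / 10)
    kap_mf <- meanfield_invert(r_mf, ell, gene_id = r$gene_id)$kappa
    kap_hyb <- kap_final
    kap_hyb[fail_a] <- kap_mf[fail_a]
    kp_hyb <- kappa_profile(kappa$gene_id, kap_hyb, ell)
    sim_cfg2 <- sim_cfg
    sim_cfg2$seed <- sim_cfg$seed + 1L
    sim2 <- simulate_tasep(kp_hyb, sim_cfg2)
    # in strongly saturated regimes the mean-field fixed point may not
    # exist; the fallback check then fails and those codons stay rejected
    rho_mf <- tryCatch(meanfield_density(kp_hyb, ell)$rho,
                       error = function(e) NULL)
    rho_sim2 <- sim2$profile$rho
    err_a2 <- if (is.null(rho_mf)) rep(NA_real_, n) else
      abs(rho_mf - rho_sim2) / ifelse(rho_sim2 > 0, rho_sim2, NA_real_)
    mf_ok[fail_a] <- !is.na(err_a2[fail_a]) &
      err_a2[fail_a] < config$ila_check_tol
    kap_final[fail_a] <- kap_mf[fail_a]
    rho_for_b[fail_a] <- rho_sim2[fail_a]
    err_a[fail_a] <- err_a2[fail_a]
  }

  err_b <- abs(rho_for_b - rv) / ifelse(rv > 0, rv, NA_real_)
  surv <- ila_ok | mf_ok
  status[ila_ok] <- "ACCEPTED_ILA"
  status[mf_ok] <- "ACCEPTED_MEANFIELD"
  fail_b <- surv & (is.na(err_b) | err_b >= config$fit_check_tol)
  status[fail_b] <- "REJECTED_FIT_CHECK"
  status[pinned] <- "REJECTED_FIT_CHECK"
  status <- factor(status, levels = c("ACCEPTED_ILA", "ACCEPTED_MEANFIELD",
                                      "REJECTED_ILA_CHECK",
                                      "REJECTED_FIT_CHECK"))

  kp_final <- kappa_profile(kappa$gene_id, kap_final, ell)
  S <- attr(kappa, "S")
  if (is.null(S)) S <- sum((rho_ila - rv)^2)
  structure(list(kappa = kp_final, status = status, S = S,
                 diagnostics = data.frame(
                   codon = seq(2L, kappa$L),
                   r = rv, kappa = kap_final,
                   err_ila_sim = err_a, err_sim_exp = err_b,
                   status = as.character(status)),
                 fraction_accepted = mean(status %in%
                   c("ACCEPTED_ILA", "ACCEPTED_MEANFIELD")),
                 sim = sim1, sim_fallback = sim2),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("<inference_result> %s: S = %.4g, %.1f%% codons accepted\n",
              x$kappa$gene_id, x$S, 100 * x$fraction_accepted))
  print(table(x$status))
  invisible(x)
}
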