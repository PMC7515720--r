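#' Options for the initiation-limited approximation
#'
#' @param validity_threshold smallest relative rate `kappa` below which a
#'   validity warning is raised (default 1: an elongation step slower than
#'   initiation is outside the initiation-limited regime; downstream quality
#'   checks catch actual failures).
#' @return A list of class `ila_options`.
#' @export
ila_options <- function(validity_threshold = 1) {
  stopifnot(validity_threshold > 0)
  structure(list(validity_threshold = validity_threshold, order = 2L),
            class = "ila_options")
}

#' Initiation-limited density approximation (ILA)
#'
#' Analytic stationary densities of the translation exclusion process from a
#' power-series expansion of the master equation in the initiation rate,
#' truncated after two-ribosome configurations (second order).  The leading
#' behaviour is `rho[i] ~ 1/kappa[i]` with a non-linear correction from
#' ribosome interference; the truncation error is third order in
#' `1/kappa`.  This is the forward model of the least-squares fit: it is
#' deterministic, cheap (`O(L^2)`), and smooth in each `kappa[i]`.
#'
#' @param kappa a [kappa_profile()] (or [gene_rates()] with `alpha` set).
#' @param ell ribosome footprint in codons; defaults to the profile's.
#' @param options an [ila_options()] list.
#' @return A [density_profile()] with `source = "ILA"` and
#'   `J_over_alpha = 1 - sum(rho[first ell codons])`.
#' @export
ila_density <- function(kappa, ell = NULL, options = ila_options()) {
  if (inherits(kappa, "gene_rates")) kappa <- as_kappa(kappa)
  stopifnot(inherits(kappa, "kappa_profile"))
  if (is.null(ell)) ell <- kappa$ell
  if (min(kappa$kappa) < options$validity_threshold)
    warning("min kappa = ", format(min(kappa$kappa)),
            " below the initiation-limited validity threshold ",
            options$validity_threshold,
            "; densities may be unreliable", call. = FALSE)
  rho <- ila_rho_cpp(kappa$kappa, as.integer(ell))
  J_over_alpha <- 1 - sum(rho[seq_len(ell)])
  density_profile(kappa$gene_id, rho, J_over_alpha, "ILA", ell)
}

# mean-field conditional clearance factor: probability that the hop from
# codon i is not blocked, in the MacDonald-Gibbs closure for extended
# particles.  S = sum of rho over codons i+1..i+ell (the blocking A-sites),
# T = the same sum without codon i+ell.
.mf_q <- function(rho, ell) {
  L <- length(rho) + 1L
  q <- numeric(L - 1L)
  for (i in 2:L) {
    js <- seq.int(i + 1L, min(i + ell, L))
    js <- js[js <= L & js > i]
    S <- if (length(js)) sum(rho[js - 1L]) else 0
    jt <- js[js < i + ell]
    T_ <- if (length(jt)) sum(rho[jt - 1L]) else 0
    q[i - 1L] <- (1 - S) / (1 - T_)
  }
  q
}

#' Mean-field stationary densities (MacDonald--Gibbs closure)
#'
#' Self-consistent solution of the current--density relation for extended
#' particles: `J = kappa[i] * rho[i] * q[i](rho)` with the MacDonald--Gibbs
#' conditional clearance factor `q`, closed by the initiation identity
#' `J/alpha = 1 - sum(rho[first ell codons])`.  Solved by damped backward
#' fixed-point iteration.  Used to initialize the least-squares fit and as a
#' per-codon fallback when the initiation-limited approximation fails.
#'
#' @inheritParams ila_density
#' @param tol convergence threshold on successive iterates (default `1e-12`).
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   final residual.
#' @return A [density_profile()] with `source = "MEANFIELD"`.
#' @export
meanfield_density <- function(kappa, ell = NULL, tol = 1e-12,
                              max_iter = 1e5) {
  if (inherits(kappa, "gene_rates")) kappa <- as_kappa(kappa)
  stopifnot(inherits(kappa, "kappa_profile"))
  if (is.null(ell)) ell <- kappa$ell
  K <- kappa$kappa
  L <- kappa$L
  rho <- pmin(1 / K, 1 / (2 * ell))
  damp <- 0.5
  prev_res <- Inf
  res <- Inf
  for (it in seq_len(max_iter)) {
    J <- 1 - sum(rho[seq_len(ell)])
    if (J <= 0) J <- 1e-12
    new_rho <- rho
    for (i in L:2) {
      js <- seq.int(i + 1L, min(i + ell, L))
      js <- js[js > i & js <= L]
      S <- if (length(js)) sum(new_rho[js - 1L]) else 0
      jt <- js[js < i + ell]
      T_ <- if (length(jt)) sum(new_rho[jt - 1L]) else 0
      q <- (1 - S) / (1 - T_)
      val <- J / (K[i - 1L] * q)
      if (!is.finite(val) || val <= 0) val <- 1e-12
      if (val > 1 / ell - 1e-9) val <- 1 / ell - 1e-9
      new_rho[i - 1L] <- (1 - damp) * rho[i - 1L] + damp * val
    }
    res <- max(abs(new_rho - rho))
    rho <- new_rho
    if (res < tol) break
    # oscillating or stalled iterates: damp harder
    if (res > prev_res && damp > 0.02) damp <- damp / 2
    prev_res <- res
  }
  if (res >= tol)
    stop("mean-field iteration did not converge after ", max_iter,
         " iterations (residual ", format(res), ")")
  J_over_alpha <- 1 - sum(rho[seq_len(ell)])
  density_profile(kappa$gene_id, rho, J_over_alpha, "MEANFIELD", ell)
}

#' Invert the mean-field relation for an observed density profile
#'
#' Direct inversion of the MacDonald--Gibbs current--density relation: given
#' densities `r`, the scaled current is `J/alpha = 1 - sum(r[first ell
#' codons])` and `kappa[i] = (J/alpha) / (r[i] * q[i](r))`.  The result is
#' the fixed point of [meanfield_density()], so the round trip reproduces
#' `r` (used as the starting point of the least-squares fit).
#'
#' @param r a [normalized_profile()] or bare numeric density vector for
#'   codons `2..L`, all strictly inside `(0, 1)`.
#' @param ell ribosome footprint in codons.
#' @param gene_id identifier for the returned profile (taken from `r` when
#'   it is a [normalized_profile()]).
#' @return A [kappa_profile()].
#' @export
meanfield_invert <- function(r, ell = 10L, gene_id = "gene") {
  if (inherits(r, "normalized_profile")) {
    gene_id <- r$gene_id
    r <- r$r
  }
  r <- as.numeric(r)
  if (any(r <= 0) || any(r >= 1))
    stop("all densities must lie strictly in (0, 1); ",
         "filter or reject the gene first")
  J <- 1 - sum(r[seq_len(ell)])
  if (J <= 0)
    stop("initiation region densities sum to >= 1; profile inconsistent")
  q <- .mf_q(r, ell)
  kappa_profile(gene_id, J / (r * q), ell)
}
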