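#' Kinetic parameters of one transcript
#'
#' Bundles the absolute rates of the translation exclusion process for a
#' single mRNA: initiation rate `alpha` (1/s), elongation rates `k[i]` (1/s)
#' for codons `i = 2..L`, with `k[L] = beta` the termination rate, and the
#' ribosome footprint `ell` in codons.  Codons are 1-based and codon 1 is the
#' START codon, which carries no density; all per-codon vectors therefore
#' have length `L - 1` and refer to codons `2..L`.
#'
#' @param gene_id character scalar identifying the transcript.
#' @param k numeric vector of elongation rates for codons `2..L` (the last
#'   entry is the termination rate), all positive, length `L - 1`.
#' @param alpha initiation rate in 1/s, or `NULL` when only relative rates
#'   are known.
#' @param ell ribosome footprint in codons (default 10).
#' @return An object of class `gene_rates`.
#' @seealso [kappa_profile()], [as_kappa()]
#' @export
gene_rates <- function(gene_id, k, alpha = NULL, ell = 10L) {
  k <- as.numeric(k)
  L <- length(k) + 1L
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (L < ell + 1L)
    stop("L must be at least ell + 1 (got L = ", L, ", ell = ", ell, ")")
  if (any(!is.finite(k)) || any(k <= 0))
    stop("all elongation/termination rates must be positive and finite")
  if (!is.null(alpha)) {
    alpha <- as.numeric(alpha)
    stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0)
  }
  structure(list(gene_id = gene_id, L = L, ell = as.integer(ell),
                 alpha = alpha, k = k),
            class = "gene_rates")
}

#' Relative (elongation-to-initiation) rate profile
#'
#' The inference target of the package: `kappa[i] = k[i]/alpha` for codons
#' `2..L`.  Ribosome density profiles depend on the rates only through these
#' ratios, so they are the only kinetic information recoverable from
#' profiling data.  `kappa[L]` is the termination-to-initiation ratio.
#'
#' @param gene_id character scalar.
#' @param kappa positive numeric vector for codons `2..L`.
#' @param ell ribosome footprint in codons.
#' @return An object of class `kappa_profile`.
#' @export
kappa_profile <- function(gene_id, kappa, ell = 10L) {
  kappa <- as.numeric(kappa)
  L <- length(kappa) + 1L
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (L < ell + 1L)
    stop("L must be at least ell + 1")
  if (any(!is.finite(kappa)) || any(kappa <= 0))
    stop("all kappa must be positive and finite")
  structure(list(gene_id = gene_id, L = L, ell = as.integer(ell),
                 kappa = kappa, kappa_L = kappa[length(kappa)]),
            class = "kappa_profile")
}

#' Convert absolute rates to relative rates
#'
#' @param rates a [gene_rates()] object with `alpha` set.
#' @return A [kappa_profile()] with `kappa = k/alpha`.
#' @export
as_kappa <- function(rates) {
  stopifnot(inherits(rates, "gene_rates"))
  if (is.null(rates$alpha))
    stop("alpha is unset; only relative rates are available")
  kappa_profile(rates$gene_id, rates$k / rates$alpha, rates$ell)
}

#' Elongation-to-termination view of a relative rate profile
#'
#' `kappa[i]/kappa[L] = k[i]/k[L]` is invariant under any rescaling of the
#' initiation rate, so it can be compared across genes.
#'
#' @param kp a [kappa_profile()].
#' @return Numeric vector for codons `2..L` (last entry 1).
#' @export
kappa_over_kappaL <- function(kp) {
  stopifnot(inherits(kp, "kappa_profile"))
  kp$kappa / kp$kappa_L
}

# rates used by the solvers: alpha = 1 and k = kappa when only ratios are
# known (densities depend on the ratios only, so this is exact)
.as_alpha_k <- function(x) {
  if (inherits(x, "gene_rates")) {
    alpha <- if (is.null(x$alpha)) 1 else x$alpha
    list(gene_id = x$gene_id, L = x$L, ell = x$ell, alpha = alpha, k = x$k)
  } else if (inherits(x, "kappa_profile")) {
    list(gene_id = x$gene_id, L = x$L, ell = x$ell, alpha = 1, k = x$kappa)
  } else {
    stop("expected a gene_rates or kappa_profile object")
  }
}

#' Per-codon model density profile
#'
#' Holds stationary A-site densities `rho[i]` for codons `2..L` together
#' with the scaled current `J/alpha` and the provenance of the numbers
#' (exact solver, simulation, or one of the analytic approximations).
#'
#' @param gene_id character scalar.
#' @param rho numeric vector of densities for codons `2..L`, each in `[0,1]`.
#' @param J_over_alpha current divided by the initiation rate, in `[0,1]`.
#' @param source one of `"ILA"`, `"MEANFIELD"`, `"SIMULATION"`, `"EXACT"`.
#' @param ell ribosome footprint in codons.
#' @param se optional per-codon standard errors (simulation only).
#' @return An object of class `density_profile` with derived fields
#'   `rho_mean` and `rho_max = 1/ell`.
#' @export
density_profile <- function(gene_id, rho, J_over_alpha, source, ell,
                            se = NULL) {
  source <- match.arg(source, c("ILA", "MEANFIELD", "SIMULATION", "EXACT"))
  rho <- as.numeric(rho)
  structure(list(gene_id = gene_id, L = length(rho) + 1L,
                 ell = as.integer(ell), rho = rho,
                 rho_mean = mean(rho), rho_max = 1 / ell,
                 J_over_alpha = J_over_alpha, source = source, se = se),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %s: L = %d, ell = %d, source = %s\n",
              x$gene_id, x$L, x$ell, x$source))
  cat(sprintf("  mean density %.4g ribosomes/codon (rho_max = %.3g), J/alpha = %.4g\n",
              x$rho_mean, x$rho_max, x$J_over_alpha))
  invisible(x)
}

#' @export
print.gene_rates <- function(x, ...) {
  cat(sprintf("<gene_rates> %s: L = %d codons, ell = %d, alpha = %s\n",
              x$gene_id, x$L, x$ell,
              if (is.null(x$alpha)) "unset" else format(x$alpha)))
  invisible(x)
}

#' @export
print.kappa_profile <- function(x, ...) {
  cat(sprintf("<kappa_profile> %s: L = %d codons, ell = %d, kappa_L = %.4g\n",
              x$gene_id, x$L, x$ell, x$kappa_L))
  cat(sprintf("  kappa range [%.4g, %.4g]\n", min(x$kappa), max(x$kappa)))
  invisible(x)
}

#' Serialize a density profile to TSV
#'
#' Columns: gene_id, codon, rho, se, source.
#'
#' @param profile a [density_profile()].
#' @param path output file path.
#' @export
write_density_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "density_profile"))
  df <- data.frame(gene_id = profile$gene_id,
                   codon = seq(2L, profile$L),
                   rho = profile$rho,
                   se = if (is.null(profile$se)) NA_real_ else profile$se,
                   source = profile$source)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
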