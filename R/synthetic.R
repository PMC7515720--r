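#' Specification of a mock gene
#'
#' Defines the study conditions for synthetic data: lattice geometry,
#' initiation rate, the distribution the relative elongation rates are
#' drawn from, and the sequencing depth of the sampled read profile.  The
#' defaults mirror an initiation-limited regime typical of yeast
#' transcripts: `L = 150` codons, footprint `ell = 10`, relative rates
#' log-uniform in `[5, 50]`, initiation rate 0.1/s.
#'
#' @param L transcript length in codons.
#' @param ell ribosome footprint in codons.
#' @param alpha initiation rate (1/s).
#' @param kappa_range bounds of the log-uniform draw of `kappa = k/alpha`.
#' @param depth total read count of the sampled profile (may be `Inf` for
#'   the noiseless variant).
#' @param seed integer seed.
#' @param overdispersion optional positive dispersion parameter; when set,
#'   per-codon sampling probabilities are multiplied by Gamma(1/od, od)
#'   noise before the multinomial draw (robustness testing hook).
#' @return A list of class `mock_spec`.
#' @export
mock_spec <- function(L = 150L, ell = 10L, alpha = 0.1,
                      kappa_range = c(5, 50), depth = 1e5, seed = 1L,
                      overdispersion = NULL) {
  stopifnot(L >= ell + 2, alpha > 0, depth > 0,
            length(kappa_range) == 2L, all(kappa_range > 0),
            kappa_range[2] >= kappa_range[1])
  structure(list(L = as.integer(L), ell = as.integer(ell), alpha = alpha,
                 kappa_range = kappa_range, depth = depth,
                 seed = as.integer(seed), overdispersion = overdispersion),
            class = "mock_spec")
}

#' Draw a mock gene with known rates
#'
#' Relative rates `kappa[i]` (including the termination ratio `kappa[L]`)
#' are drawn log-uniformly from `spec$kappa_range`; absolute rates are
#' `k = alpha * kappa`.  Reproducible given the spec's seed.
#'
#' @param spec a [mock_spec()].
#' @param gene_id identifier for the generated gene.
#' @return A [gene_rates()] object with attribute `kappa_true` (the
#'   [kappa_profile()] actually drawn).
#' @export
generate_gene <- function(spec, gene_id = sprintf("mock_%d", spec$seed)) {
  stopifnot(inherits(spec, "mock_spec"))
  n <- spec$L - 1L
  kappa <- withr_seed(spec$seed, {
    exp(runif(n, log(spec$kappa_range[1]), log(spec$kappa_range[2])))
  })
  gr <- gene_rates(gene_id, k = spec$alpha * kappa, alpha = spec$alpha,
                   ell = spec$ell)
  attr(gr, "kappa_true") <- kappa_profile(gene_id, kappa, spec$ell)
  gr
}

# evaluate expr under a local RNG seed without disturbing the global state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a read-count profile from a density profile
#'
#' Reads are conditionally independent given occupancy: counts are drawn
#' multinomially with probabilities proportional to the densities and a
#' fixed total `depth`.
#'
#' @param densities a [density_profile()].
#' @param depth total read count.
#' @param seed integer seed.
#' @param overdispersion optional Gamma noise multiplier, see [mock_spec()].
#' @return A [raw_profile()].
#' @export
sample_reads <- function(densities, depth, seed = 1L,
                         overdispersion = NULL) {
  stopifnot(inherits(densities, "density_profile"), sum(densities$rho) > 0)
  p <- densities$rho / sum(densities$rho)
  counts <- withr_seed(seed, {
    if (!is.null(overdispersion)) {
      m <- stats::rgamma(length(p), shape = 1 / overdispersion,
                         scale = overdispersion)
      p <- p * m / sum(p * m)
    }
    if (depth == 0) numeric(length(p))
    else as.numeric(rmultinom(1, size = depth, prob = p))
  })
  raw_profile(densities$gene_id, counts)
}

#' Generate a full synthetic fixture: truth plus observable
#'
#' Chains [generate_gene()], [simulate_tasep()], [sample_reads()] and
#' [normalize_profile()] so that the known rates and the observable profile
#' come out together.  Normalization uses the simulation's own mean density
#' as the "polysome profiling" value, so the synthetic observable has mean
#' density equal to the simulated one by construction.  With
#' `depth = Inf` the simulated densities are used directly as the
#' observable (noiseless variant).
#'
#' @param spec a [mock_spec()].
#' @param sim_config optional [simulation_config()]; default uses the
#'   spec's seed.
#' @return A list with `rates` ([gene_rates()]), `kappa_true`
#'   ([kappa_profile()]), `sim` (the simulation), `raw` ([raw_profile()] or
#'   `NULL` when `depth = Inf`) and `norm` ([normalized_profile()]).
#' @export
end_to_end_fixture <- function(spec, sim_config = NULL) {
  stopifnot(inherits(spec, "mock_spec"))
  if (is.null(sim_config)) sim_config <- simulation_config(seed = spec$seed)
  gr <- generate_gene(spec)
  sim <- simulate_tasep(gr, sim_config)
  prof <- sim$profile
  if (is.infinite(spec$depth)) {
    norm <- normalized_profile(gr$gene_id, prof$rho)
    raw <- NULL
  } else {
    raw <- sample_reads(prof, spec$depth, seed = spec$seed + 1L,
                        overdispersion = spec$overdispersion)
    norm <- normalize_profile(raw, prof$rho_mean)
  }
  list(rates = gr, kappa_true = attr(gr, "kappa_true"), sim = sim,
       raw = raw, norm = norm)
}
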