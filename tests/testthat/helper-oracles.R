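# brute-force configuration oracle: all subsets of codons 2..L filtered by
# pairwise A-site spacing >= ell (independent of the package's enumerator)
brute_force_configs <- function(L, ell) {
  sites <- 2:L
  out <- list(integer(0))
  for (n_occ in seq_len(length(sites))) {
    cmb <- utils::combn(sites, n_occ, simplify = FALSE)
    keep <- Filter(function(s) all(diff(s) >= ell), cmb)
    out <- c(out, keep)
  }
  out
}

# seeded random small instance for exact-vs-simulation comparisons
random_small_instance <- function(seed, Lmin = 5, Lmax = 8) {
  set.seed(seed)
  L <- sample(Lmin:Lmax, 1)
  ell <- sample(1:3, 1)
  while (L < ell + 2) L <- L + 1
  k <- exp(runif(L - 1, log(0.5), log(8)))
  kappa_profile(sprintf("inst%d", seed), k, ell = ell)
}

# z-scores of simulated densities against a reference profile
density_z <- function(sim, ref_rho) {
  se <- pmax(sim$profile$se, 1e-12)
  abs(sim$profile$rho - ref_rho) / se
}
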