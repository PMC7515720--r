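---
title: "Inferring relative elongation rates and ribosome traffic from Ribo-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring relative elongation rates and ribosome traffic from Ribo-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotraffic)
```

## The model

Translation of one mRNA is modelled as a totally asymmetric simple
exclusion process with extended particles (the l-TASEP).  The coding
sequence is a 1-based lattice of `L` codons; codon 1 is the START codon and
carries no density, so all per-codon quantities refer to codons `2..L`.
Ribosomes are tracked by the position of their A-site and occupy `ell`
codons (default 10, the ~30 nt footprint), which means two A-sites are
never closer than `ell` codons.

* **Initiation** at rate `alpha` places an A-site on codon 2, provided
  codons `2..ell+1` hold no A-site.
* **Elongation** moves an A-site from codon `i` to `i+1` at rate `k[i]`,
  provided the next A-site downstream is at `i+ell+1` or beyond.
* **Termination** removes the ribosome from codon `L` at rate
  `k[L] = beta`, with no further clearance requirement (the ribosome
  simply detaches; the model sketch implies none and we assume none).

The stationary state of the master equation defines the local densities
`rho[i]` (probability of an A-site at codon `i`), and the protein current
`J = k[L] * rho[L]`.  Premature drop-off is neglected: the drop-off rate
is of order `dropoff_rate()` = 1e-3/s (a per-codon premature-termination
probability ~1e-4 times an elongation rate ~10 codons/s), three orders of
magnitude below elongation.  With conserved current, the exact initiation
identity `J/alpha = 1 - sum(rho[2..(ell+1)])` holds.

A central property is *scale invariance*: densities depend on the rates
only through the ratios `kappa[i] = k[i]/alpha`.  Absolute rates are
therefore not identifiable from density profiles; the package fits
`kappa`, and the termination-scaled view `kappa[i]/kappa[L] = k[i]/k[L]`
is provided for cross-gene comparison because it is independent of the
gene-specific initiation rate.

## Solvers and their roles

Three independent routes to the stationary state back each other up:

1. `exact_stationary()` enumerates every admissible A-site configuration
   (spacing >= `ell`), assembles the sparse generator and solves the
   stationary linear system.  It is combinatorially limited (state-space
   cap 2e5 by default; practical for `L <= ~18` at `ell = 1`, smaller at
   larger `ell`) and serves as the machine-precision oracle in the tests.
2. `simulate_tasep()` is a continuous-time Gillespie simulation over the
   enabled-move catalogue, giving exact stochastic sampling with no
   time-discretization bias.  Time averages come with batch-means
   standard errors (20 batches); the repo-wide statistical-agreement
   convention is "within 3 SE".  Default burn-in runs until
   `max(100, L)` terminations; the default sampling window is sized so
   each codon accrues ~1e4 expected transitions (~1% relative SE),
   using the analytic current as the a-priori estimate.  Both are
   configurable; reported seeds make every run reproducible.
3. Two analytic approximations, below, used as the fit's forward model
   and fallback.

## The initiation-limited expansion

The stationary distribution is expanded in powers of the initiation rate:
a configuration with `n` ribosomes carries weight of order `alpha^n`.
Truncating after two-ribosome configurations and solving the per-state
balance equations order by order gives, in units `alpha = 1`:
single-ribosome amplitudes `1/kappa[i]` plus a second-order correction,
and pair amplitudes from a forward recursion over `O(L^2)` pairs.

One numerical subtlety matters for long genes.  Writing
`rho[i] = Num[i]/Z` and truncating numerator and normalization separately
fails once `sum(1/kappa)` is of order one (many ribosomes on the lattice),
even though per-site occupancies are small.  The implementation therefore
uses the consistent truncation of the *ratio*: the extensive part of the
normalization cancels against the factorized tail of the pair sum
(`d[i,j] -> c[i]c[j]` for distant pairs), leaving a local, bounded
correction.  The residual error is third order in `1/kappa`, which the
tests verify as a log-log slope of ~3 against the exact solver.

The expansion assumes initiation is the limiting step.  `ila_density()`
warns when `min(kappa) < 1` (an elongation step slower than initiation);
the warning is deliberately not an error because the inference workflow
has an explicit downstream check that catches actual failures.

In the dilute regime the leading behaviour is `rho[i] ~ 1/kappa[i]`, but
the first correction is of order `ell/kappa`, not `1/kappa`: at uniform
`kappa = 200` with `ell = 10` the density is ~5% below `1/kappa`, almost
entirely the initiation-suppression factor `J/alpha` (density = current x
dwell time).  Checks of the dilute limit must therefore either use the
`rho*kappa ~ J/alpha` identity or go much deeper (`kappa ~ 2000`) before
`1/kappa` alone is accurate to 1%.

## The mean-field solution

`meanfield_density()` closes the current-density relation with the
MacDonald--Gibbs conditional clearance factor for extended particles,
`q[i] = (1 - S[i])/(1 - T[i])` with `S[i]` the density sum over codons
`i+1..i+ell` and `T[i]` the same sum without `i+ell`, coupled to the
initiation identity for `J`.  The fixed point is found by damped backward
iteration (adaptive damping halves on oscillation; convergence at 1e-12,
capped at 1e5 iterations; in strongly saturated regimes the fixed point
may not exist and the solver errors out carrying the residual).
`meanfield_invert()` is the closed-form inverse - given an observed
profile `r`, `J/alpha = 1 - sum(r[first ell])` and
`kappa[i] = (J/alpha)/(r[i] q[i](r))` - and is the fixed point of the
forward map, so the round trip reproduces `r`.

A consequence worth knowing: the mean-field inverse of a uniform profile
`r = 0.01` at `ell = 10` is `kappa = 91`, not `1/r = 100`; the
`O(ell*r)` correction is ~10%.  The leading order `1/r` is only
approached for much more dilute profiles (at `r = 0.001`,
`kappa = 991`).

## The inference workflow

For each gene:

1. **Normalize** (`normalize_profile()`): A-site counts are scaled so the
   profile's mean equals the gene's absolute ribosome density
   (ribosomes/codon, e.g. from polysome profiling):
   `r[i] = (c[i]/total) * N` with `N = density * (L-1)`.  This makes the
   *mean* of `r` equal the supplied density, consistent with the
   definition of the mean density as `sum(r)/(L-1)`; the alternative
   reading (multiplying the read fraction by the density itself) would
   put the mean at `density/(L-1)` and contradict that definition.  A
   gene is rejected if any `r[i] > 1` (more than one ribosome per codon)
   or if it has no reads; genes below 10 mean reads/codon are filtered
   (`filter_gene()`), since zero-count codons imply unphysically fast
   elongation.
2. **Fit** (`fit_kappa()`): minimize
   `S = sum((rho_ILA(kappa) - r)^2)` over `log(kappa)` with a
   Levenberg--Marquardt least-squares solver, started from
   `meanfield_invert(r)`.  Bounds default to `kappa` in `[1e-3, 1e6]`;
   optimizing the logarithm enforces positivity.  Zero-read codons are
   pinned at the upper bound and flagged.  The termination codon is
   fitted like any other.
3. **Check stage (a)** (`quality_check()`): one simulation with the
   fitted rates; a codon's analytic density must match the simulated one
   within 10% relative error (simulated density in the denominator).
   Failing codons get the mean-field estimate substituted and are
   re-checked once against a second simulation of the hybrid profile,
   with the mean-field density on the analytic side.  Codons failing
   both are `REJECTED_ILA_CHECK`.
4. **Check stage (b)**: surviving codons must reproduce the experimental
   density within 5% relative error (experimental density in the
   denominator) - `ACCEPTED_ILA` / `ACCEPTED_MEANFIELD` or
   `REJECTED_FIT_CHECK`.  Both tolerances are relative and configurable
   (`fit_config()`); neither the denominator convention nor the
   absolute-vs-relative reading is forced by the procedure itself, so
   both are explicit knobs.

One simulation per check stage is used (not per codon); per-codon errors
are read off the same run, which keeps the cost linear in `L`.

## Efficiency scores

* `compute_tie()`: TIE `= 1 - sum(rho[first ell]) = J/alpha`, the
  probability an initiation attempt is not blocked.
* `compute_tee()`: TEE`[i] = TIE/(kappa[i] rho[i])`, the ratio of
  intrinsic to total dwell time, equal (exactly, via current
  conservation) to the probability that codons `i+1..i+ell` are clear
  given an A-site at `i`.  Values are clipped to `[0, 1]` with clipping
  logged; codons with `rho = 0` are skipped.
* `collision_time()`: `alpha*t_coll[i] = r[i]/TIE - 1/kappa[i]`, the
  extra dwell time due to queuing; zero exactly when there is no
  interference.
* `metagene_tee()` aligns genes at the START codon and reports per-codon
  medians and quartiles over accepted codons; whether mean-field-accepted
  codons enter is a flag (`include_meanfield`, default TRUE).

TIE and TEE for a fitted gene are computed from the check-stage
simulation (they are occupancy probabilities, which the analytic forward
model only approximates), and `mean_tee` averages accepted codons only.

## Synthetic study conditions

`mock_spec()` defaults define the synthetic conditions used throughout
the tests: `L = 150` codons, `ell = 10`, `alpha = 0.1/s`, relative rates
log-uniform in `[5, 50]` (an initiation-limited but not dilute regime),
and multinomial read sampling at a chosen depth - reads conditionally
independent given occupancy, the simplest model consistent with
profile-proportional sampling; an optional Gamma overdispersion hook
exists for robustness checks.  `end_to_end_fixture()` chains rate
generation, simulation, read sampling and normalization, using the
simulation's own mean density as the "polysome" value so the observable
closes the normalization loop by construction.

What this emulates - and what it does not: the generator reproduces the
statistical structure the model assumes (stationary occupancy, shot
noise from finite depth).  It does not emulate ligation or nuclease
biases, cycloheximide artifacts, footprint-size distortions, or
queuing-induced disome footprints that real libraries discard.  Passing
tests therefore demonstrate correctness of the inference machinery under
the model's assumptions, not robustness to every experimental bias.

Problem sizes in the tests and the acceptance script (exact-solver
lattices `L <= 8` with `ell <= 3`; cohorts of ~8 mock genes at `L = 150`;
simulation budgets of 2e4-4e5 transitions per codon) were chosen so the
oracle comparisons are decisive at the 3-SE convention while the whole
suite runs in minutes on one CPU.

## Design decisions and limitations

* Coordinate convention: codon 1 is START with no density; profiles
  cover `2..L`.  The minimal length is `L >= ell + 1` (an `ell`-codon
  initiation region must fit).
* Geometry beyond A-site spacing is not modelled: the dynamics depend
  only on A-site distances, so footprint placement around the A-site is
  irrelevant to the stationary law.
* A-site assignment from raw footprints is a pure table lookup by
  (fragment length 27-33 nt, frame); ambiguous cells and unsupported
  lengths are discarded with counted reasons.  Frame is the 5'-end
  position modulo 3 in 0-based CDS coordinates, isolated in one function
  so the convention can be swapped.  Reads mapping to the START codon
  are discarded (and counted), not merged into codon 2.
* Input is plain TSV throughout (counts, densities, footprint records);
  TSV is diffable and sufficient for the data sizes involved.
* Absolute rates are out of reach by construction; so are pooled
  codon-type fits (each transcript is fitted separately), drop-off,
  re-initiation, and secondary-structure effects.
* In saturated regimes (`min(kappa) < 1`) the analytic forward model
  degrades and most codons are resolved by the mean-field fallback or
  rejected; the per-codon status makes this visible rather than silent.
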