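# ribotraffic

Model-based analysis of ribosome profiling (Ribo-seq) at codon
resolution.  Given a gene's per-codon A-site read counts and its absolute
ribosome density (ribosomes/codon, e.g. from polysome profiling),
`ribotraffic` infers the codon-specific elongation-to-initiation ratios
κ<sub>i</sub> = k<sub>i</sub>/α of a stochastic translation model, and
turns them into interpretable traffic scores.  It is written for
quantitative biologists who want to separate a codon's *intrinsic*
decoding speed from the slow-down caused by ribosome queuing — a
distinction a raw density profile cannot make.

## The model and method

Translation is the totally asymmetric simple exclusion process with
extended particles (ℓ-TASEP): ribosomes occupy ℓ = 10 codons, initiate at
rate α onto codon 2 when the first ℓ codons are clear, hop i → i+1 at
rate k<sub>i</sub> when the next A-site is ≥ ℓ+1 codons downstream, and
terminate from codon L at rate k<sub>L</sub> = β.  Stationary densities
ρ<sub>i</sub> depend on the rates only through κ<sub>i</sub> =
k<sub>i</sub>/α, so only those ratios are identifiable from profiles.

The inference minimizes

&nbsp;&nbsp;&nbsp;&nbsp;S = Σ<sub>i</sub> (ρ<sub>i</sub><sup>ILA</sup>({κ}) − r<sub>i</sub>)²

where r<sub>i</sub> is the normalized experimental density and
ρ<sup>ILA</sup> an analytic initiation-limited expansion of the model,
started from the mean-field inversion of r.  Each fitted κ<sub>i</sub>
then passes a two-stage per-codon check against a stochastic simulation
(analytic-vs-simulated within 10%, with a mean-field fallback; then
simulated-vs-experimental within 5%).  Accepted rates feed the traffic
scores

* **TIE** = J/α = 1 − Σ ρ over the first ℓ codons — probability that an
  initiation attempt is not blocked;
* **TEE<sub>i</sub>** = TIE/(κ<sub>i</sub> ρ<sub>i</sub>) — probability
  that a ribosome decoding codon i is not blocked downstream;
* **α·t<sub>coll,i</sub>** = r<sub>i</sub>/TIE − 1/κ<sub>i</sub> — extra
  dwell time per codon due to queuing.

All three are dimensionless, lie in [0, 1] (collision time ≥ 0), and can
be compared across genes.  See the vignette
(`vignettes/ribosome-traffic-inference.Rmd`) for the solver details,
assumptions, and design choices.

## Worked example

A mock gene with known rates, an observed profile sampled from a
simulation, and the full workflow back to the rates:

```r
library(ribotraffic)

spec <- mock_spec(L = 120, ell = 10, kappa_range = c(8, 40),
                  depth = 5e4, seed = 42)
fx  <- end_to_end_fixture(spec, simulation_config(seed = 42,
                                                  transitions_per_codon = 5e4))
cfg <- fit_config(seed = 43, sim_config = simulation_config(
  seed = 43, transitions_per_codon = 5e4))
fit <- fit_kappa(fx$norm, ell = 10, config = cfg)
qc  <- quality_check(fit, fx$norm, config = cfg)
print(qc)
#> <inference_result> mock_42: S = 0.0001943, 64.7% codons accepted
#>
#>       ACCEPTED_ILA ACCEPTED_MEANFIELD REJECTED_ILA_CHECK REJECTED_FIT_CHECK
#>                  8                 69                 12                 30

rp <- efficiency_report(qc, fx$norm)
sprintf("TIE = %.3f, mean TEE = %.3f, rho/rho_max = %.3f",
        rp$tie, rp$mean_tee, rp$rho_over_rhomax)
#> "TIE = 0.611, mean TEE = 0.710, rho/rho_max = 0.534"

median(abs(qc$kappa$kappa - fx$kappa_true$kappa)[qc$status %in%
  c("ACCEPTED_ILA", "ACCEPTED_MEANFIELD")] /
  fx$kappa_true$kappa[qc$status %in%
  c("ACCEPTED_ILA", "ACCEPTED_MEANFIELD")])
#> [1] 0.04802... # median relative error of accepted rates: ~5%
```

Reading the output: 77 of 119 codons pass both consistency checks (8 via
the analytic forward model, 69 via the mean-field fallback — this gene
sits at half the maximal ribosome density, so traffic is heavy); their
inferred rates land within ~5% of the known truth.  A TIE of 0.61 means
four in ten initiation attempts are blocked by a ribosome still inside
the first 10 codons, and the mean TEE of 0.71 quantifies how much
queuing inflates dwell times along this crowded transcript.

For a cohort, `run_pipeline()` chains filtering, normalization, fitting,
checking, efficiency scores and the cross-gene metagene profile from two
TSV inputs (counts and per-gene densities), writing TSV outputs and a
per-gene manifest.  `inst/cli/ribotraffic.R` exposes the same steps as
shell subcommands (`synth`, `simulate`, `asite`, `normalize`, `fit`,
`efficiency`, `metagene`, `run`).

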