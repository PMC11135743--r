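# slamkinetics

Two-compartment kinetics of mRNA metabolism from SLAM-seq nucleotide
conversion data.

## The problem

SLAM-seq marks newly synthesized RNA chemically: 4-thiouridine (4sU)
incorporated during a labeling pulse is alkylated so that reverse
transcription produces T>C transitions, letting a sequencing library
distinguish new from pre-existing transcripts without physical separation.
Combined with nuclear/cytosolic fractionation, a pulse time series measures
*where* an mRNA spends its life: how long it stays in the nucleus after
polyadenylation and how fast it is degraded in the cytosol.

`slamkinetics` implements the full inference chain for such experiments,
for computational biologists analyzing subcellular SLAM-seq (or similar
nucleotide-conversion) time series:

1. **New/total RNA ratios** from read-level conversion counts. Each read is
   summarized by its number of genomic T positions `T_j` and observed T>C
   conversions `o_j`. Reads follow a two-component binomial mixture: with
   probability ρ a read is *new* and converts each T with probability
   `p1 = ℓ(1−ε) + (1−ℓ)p0` (labeling efficiency ℓ, T>C sequencing error
   `p0`, C>non-C error ε); otherwise it converts with probability `p0`.
   ρ and ℓ are estimated per region by EM; regions with ℓ̂ < 1% are flagged
   as overfit, ℓ is fixed to the sample median of the remaining regions,
   and all ratios are re-estimated with ℓ fixed. Sites that look like SNPs
   or editing sites (control conversion rate above 5% in either fraction)
   are masked first.

2. **Kinetic rates** from the ratio time series. The two-compartment model

       dN/dt = μ − (ν+τ) N
       dC/dt = τ N − λ C

   (synthesis μ, nuclear degradation ν, export τ, cytosolic degradation λ)
   gives closed-form new/total curves that are independent of μ:

       n(t) = 1 − e^{−(ν+τ)t}
       c(t) = 1 − (λ e^{−(ν+τ)t} − (ν+τ) e^{−λt}) / (λ − (ν+τ))

   The *nuclear removal rate* ν+τ is fitted first from nuclear data alone,
   then plugged into the cytosolic curve to fit λ, by minimizing the
   variance-stabilized weighted objective

       ℓ(Θ) = Σ_i R_i^nuc (arcsin√ρ_i^nuc − arcsin√n_i)²
            + Σ_i R_i^cyt (arcsin√ρ_i^cyt − arcsin√c_i)²

   (for `N ~ Binomial(R, p)`, `√(4R)·arcsin√(N/R)` is approximately
   Gaussian with unit variance). Point estimates come from Nelder-Mead
   seeded on a coarse log-grid; credible intervals are central 95%
   intervals of a random-walk Metropolis chain; rates are reported as
   half-lives `ln2/rate` and averaged across replicate series.

3. **Reliability filtering** by five criteria (read depth ≥ 30, constant
   expression, replicate agreement ≤ 33%, credible-bound deviation ≤ 0.3,
   goodness of fit R ≥ 0.4), with cytosolic verdicts gated on nuclear ones.

4. **Abundance ratios and model extensions**: three estimators of the
   steady-state cytosolic/nuclear RNA amount ratio (triplet spherical
   median, positive-degradation-rate curve, spike-in normalization), a
   nuclear-retention model with a non-exporting subpopulation, and a
   one-compartment comparator showing what classical whole-cell half-life
   fits actually measure.

5. **A forward simulator** generating read-level datasets with known
   ground-truth rates, used throughout the test suite to validate recovery.

## Worked example

Simulate a small cohort with known rates and run the full pipeline:

```r
library(slamkinetics)

cfg   <- sim_config(n_regions = 20, reads_mean = 300, seed = 42)
truth <- draw_rates(cfg)
sim   <- simulate_reads(truth, cfg)
res   <- run_pipeline(sim$reads, pipeline_config(seed = 7, verbose = TRUE))
#> [slamkinetics] error rates: p0 = 0.001, epsilon = 0.01
#> [slamkinetics] ratios: 20 regions, 560 sample points
#> [slamkinetics] fits: 40 nuclear / 40 cytosolic of 40 region x replicate fits
#> [slamkinetics] reliability: 13 nuclear / 0 cytosolic reliable of 20 regions

head(res$combined[, c("region_id", "nuc_halflife_min", "cyt_halflife_min")], 4)
#>     region_id nuc_halflife_min cyt_halflife_min
#> 1 region_0001         777.1263         74.59590
#> 2 region_0002         205.5652         21.06826
#> 3 region_0003         375.5386         53.59359
#> 4 region_0004         557.5424        105.53675

truth$nuc_halflife_min[1:4]
#> [1] 840.6896 216.8624 415.1922 501.4758
```

The combined table holds replicate-averaged rates and half-lives per
region; `res$reliability` marks which estimates pass the five criteria
(nuclear estimates are recoverable for most regions at this depth, while
the stringent credible-interval criterion leaves few cytosolic estimates
reliable — the same asymmetry seen in real fractionation data). A single
series can also be fitted directly:

```r
obs <- data.frame(time_min = c(15, 30, 45, 60, 90, 120, 180),
                  rho   = c(0.031, 0.062, 0.087, 0.118, 0.179, 0.226, 0.321),
                  reads = 300)
fit_nuclear(obs, mcmc_config(seed = 1))
#> Kinetic fit (nuc_removal): rate 0.00213 /min [0.0018, 0.00249], half-life 325.0 min, R = 1.00
```

A thin command-line front end wraps the same functions
(`inst/scripts/slamkinetics.R` with subcommands `simulate`, `mask`,
`estimate-ratios`, `fit`, `assess`, `retention`, `ratio`, `all`).

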