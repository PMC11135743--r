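test_that("rate draws are seeded, centered and convertible", {
  cfg <- sim_config(n_regions = 50, seed = 7)
  expect_identical(draw_rates(cfg), draw_rates(cfg))
  cfg0 <- sim_config(n_regions = 5, nuc_hl_logsd = 0, cyt_hl_logsd = 0,
                     seed = 7)
  tr0 <- draw_rates(cfg0)
  expect_equal(tr0$nuc_halflife_min, rep(322, 5))
  expect_equal(tr0$cyt_halflife_min, rep(58, 5))
  expect_equal(tr0$nuc_removal, log(2) / tr0$nuc_halflife_min)
  # law of large numbers on the configured log-normal medians
  big <- draw_rates(sim_config(n_regions = 1e4, seed = 8))
  expect_lt(abs(median(big$nuc_halflife_min) - 322), 5)
  expect_lt(abs(median(big$cyt_halflife_min) - 58), 2)
})

test_that("simulated reads are reproducible and respect the control", {
  cfg <- sim_config(n_regions = 6, reads_mean = 150, seed = 9)
  truth <- draw_rates(cfg)
  sim1 <- simulate_reads(truth, cfg)
  sim2 <- simulate_reads(truth, cfg)
  expect_identical(sim1$reads, sim2$reads)
  expect_true(all(sim1$reads$conversions <= sim1$reads$t_count))
  # unlabeled control: pooled conversion rate is the sequencing error rate
  ctrl <- sim1$reads[sim1$reads$time_min == 0, ]
  rate <- sum(ctrl$conversions * ctrl$multiplicity) /
    sum(ctrl$t_count * ctrl$multiplicity)
  expect_lt(abs(rate - 0.001), 5e-4)
  # truth table of ratios matches the kinetics curves
  r1 <- sim1$ratios[sim1$ratios$region_id == truth$region_id[1] &
                      sim1$ratios$compartment == "nuc" &
                      sim1$ratios$replicate == 1, ]
  expect_equal(r1$rho_true,
               nuclear_new_total(truth$nuc_removal[1], r1$time_min))
})

test_that("the empirical new-read fraction concentrates on the model curve", {
  cfg <- sim_config(n_regions = 1, reads_mean = 1e5, replicates = 1,
                    timepoints = c(0, 60), nuc_hl_logsd = 0,
                    cyt_hl_logsd = 0, seed = 10)
  truth <- draw_rates(cfg)
  sim <- simulate_reads(truth, cfg)
  d <- sim$reads[sim$reads$time_min == 60 & sim$reads$compartment == "nuc", ]
  # infer the new fraction from the pooled conversion rate
  p1 <- conversion_prob_new(0.05, error_rates(0.001, 0.01))
  rate <- sum(d$conversions * d$multiplicity) /
    sum(d$t_count * d$multiplicity)
  rho_emp <- (rate - 0.001) / (p1 - 0.001)
  expect_lt(abs(rho_emp - nuclear_new_total(truth$nuc_removal, 60)), 0.01)
})

test_that("conversion counts follow the analytic binomial mixture", {
  cfg <- sim_config(n_regions = 1, reads_mean = 1e5, replicates = 1,
                    timepoints = c(0, 90), nuc_hl_logsd = 0,
                    cyt_hl_logsd = 0, seed = 12)
  truth <- draw_rates(cfg)
  sim <- simulate_reads(truth, cfg)
  d <- sim$reads[sim$reads$time_min == 90 & sim$reads$compartment == "nuc" &
                   sim$reads$t_count == 30, ]
  obs <- tapply(d$multiplicity, factor(pmin(d$conversions, 4), levels = 0:4),
                sum, default = 0)
  rho <- nuclear_new_total(truth$nuc_removal, 90)
  p1 <- conversion_prob_new(0.05, error_rates(0.001, 0.01))
  probs <- rho * dbinom(0:3, 30, p1) + (1 - rho) * dbinom(0:3, 30, 0.001)
  probs <- c(probs, 1 - sum(probs))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = probs))
  expect_gt(gof$p.value, 0.001)
})

test_that("control mismatch tables recover the configured error rates", {
  cfg <- sim_config(n_regions = 100, seed = 14)
  ctrl <- simulate_control_mismatches(draw_rates(cfg), cfg)
  er <- estimate_error_rates(ctrl)
  expect_lt(abs(er$p0 - 0.001), 2e-4)
  expect_lt(abs(er$epsilon - 0.01), 1e-3)
})

test_that("a constant schedule makes ramp and plain simulators agree", {
  cfg <- sim_config(n_regions = 3, reads_mean = 300, seed = 4)
  truth <- draw_rates(cfg)
  a <- simulate_reads(truth, cfg)
  b <- simulate_ramp_efficiency(truth, cfg)
  expand <- function(res, t) {
    d <- res$reads[res$reads$time_min == t, ]
    rep(d$conversions, d$multiplicity)
  }
  for (t in c(30, 90, 180)) {
    ta <- table(factor(pmin(expand(a, t), 4), levels = 0:4))
    tb <- table(factor(pmin(expand(b, t), 4), levels = 0:4))
    hom <- suppressWarnings(chisq.test(rbind(ta, tb)))
    expect_gt(hom$p.value, 0.01)
  }
})

test_that("a fast efficiency ramp biases short pulses most", {
  cfg <- sim_config(n_regions = 1, nuc_hl_median = 30, nuc_hl_logsd = 0,
                    cyt_hl_logsd = 0, timepoints = c(0, 5, 180),
                    reads_mean = 5000, replicates = 1,
                    ell = list(ell_max = 0.05, t_ramp = 2), seed = 3)
  truth <- draw_rates(cfg)
  sim <- simulate_ramp_efficiency(truth, cfg)
  err <- error_rates(0.001, 0.01)
  bias_at <- function(t) {
    d <- sim$reads[sim$reads$time_min == t & sim$reads$compartment == "nuc", ]
    fit <- em_fit(d, err)
    true <- nuclear_new_total(truth$nuc_removal, t)
    abs(fit$rho - true) / true
  }
  expect_gt(bias_at(5), bias_at(180))
  expect_lt(bias_at(180), 0.05)
})

test_that("a zero-efficiency ramp produces only sequencing errors", {
  cfg <- sim_config(n_regions = 2, reads_mean = 500,
                    ell = list(ell_max = 0, t_ramp = 10), seed = 5)
  sim <- simulate_ramp_efficiency(draw_rates(cfg), cfg)
  d <- sim$reads[sim$reads$time_min > 0, ]
  rate <- sum(d$conversions * d$multiplicity) /
    sum(d$t_count * d$multiplicity)
  expect_lt(abs(rate - 0.001), 5e-4)
  expect_error(sim_config(ell = list(ell_max = 0.05, t_ramp = 0)),
               "t_ramp")
})
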