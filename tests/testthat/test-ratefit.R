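test_that("the variance-stabilizing transform has the right values", {
  expect_equal(vst(100, 0), 0)
  expect_equal(vst(25, 1), 5 * pi)
  expect_error(vst(100, 1.5), "0, 1")
  expect_error(vst(0.5, 0.3), ">= 1")
})

test_that("the weighted objective matches hand-computed values", {
  obs <- make_obs(60, 0.5, 100)
  # on-curve parameters give zero
  expect_equal(neg_log_lik(log(2) / 60, nuc_obs = obs), 0, tolerance = 1e-12)
  # one half-life of mismatch
  expect_equal(neg_log_lik(log(2) / 30, nuc_obs = obs),
               100 * (asin(sqrt(0.5)) - asin(sqrt(0.75)))^2,
               tolerance = 1e-9)
  # linear in the weights
  obs7 <- make_obs(60, 0.5, 700)
  expect_equal(neg_log_lik(log(2) / 30, nuc_obs = obs7),
               7 * neg_log_lik(log(2) / 30, nuc_obs = obs),
               tolerance = 1e-9)
  # either compartment term computable alone
  k <- log(2) / 300
  cyt <- noiseless_cyt_obs(k, log(2) / 45)
  expect_equal(neg_log_lik(k, log(2) / 45, cyt_obs = cyt), 0,
               tolerance = 1e-12)
  expect_error(neg_log_lik(-1, nuc_obs = obs), "positive")
})

test_that("rescaling all read counts leaves the objective argmin unchanged", {
  set.seed(3)
  tp <- pulse_grid
  rho <- pmin(pmax(nuclear_new_total(0.004, tp) +
                     rnorm(length(tp), 0, 0.03), 0), 1)
  obs <- make_obs(tp, rho, 100)
  obs_scaled <- make_obs(tp, rho, 900)
  f <- function(o) optimize(function(k) neg_log_lik(k, nuc_obs = o),
                            c(1e-5, 1e-1), tol = 1e-12)$minimum
  expect_equal(f(obs), f(obs_scaled), tolerance = 1e-6)
})

test_that("noiseless series are recovered to optimizer precision", {
  f <- fit_nuclear(noiseless_nuc_obs(0.003), mcmc_config(seed = 1))
  expect_lt(abs(f$rate - 0.003) / 0.003, 1e-6)
  expect_gt(f$goodness_R, 0.999)
  # a single informative observation inverts the curve exactly
  f1 <- fit_nuclear(make_obs(60, 0.5, 100), mcmc_config(seed = 2))
  expect_lt(abs(f1$rate - log(2) / 60) / (log(2) / 60), 1e-6)
  # cytosolic fit with the nuclear rate plugged in
  k <- log(2) / 300
  lam <- log(2) / 45
  f2 <- fit_cytosolic(noiseless_cyt_obs(k, lam), k, mcmc_config(seed = 3))
  expect_lt(abs(f2$rate - lam) / lam, 1e-6)
  # degenerate lam = nu + tau survives via the limit branch
  f3 <- fit_cytosolic(noiseless_cyt_obs(k, k), k, mcmc_config(seed = 4))
  expect_lt(abs(f3$rate - k) / k, 1e-5)
})

test_that("non-identifiable series are rejected or flagged", {
  flat0 <- make_obs(pulse_grid, 0, 100)
  expect_error(fit_nuclear(flat0, mcmc_config(seed = 1)), "identifiable")
  expect_error(fit_cytosolic(flat0, 0.003, mcmc_config(seed = 1)),
               "identifiable")
  all1 <- make_obs(pulse_grid, 1, 100)
  f <- fit_nuclear(all1, mcmc_config(seed = 1))
  expect_true(f$at_bound)
})

test_that("the Metropolis sampler reproduces a conjugate interval and seeds", {
  cfg <- mcmc_config(n_steps = 50000, burn_in = 5000, proposal_sd = 1,
                     seed = 9, rate_bounds = c(0.01, 100))
  q <- mcmc_interval(function(x) (x - 5)^2 / 2, 5, cfg, log_scale = FALSE)
  expect_lt(abs(q$central_95[1] - (5 - 1.96)), 0.15)
  expect_lt(abs(q$central_95[2] - (5 + 1.96)), 0.15)
  q2 <- mcmc_interval(function(x) (x - 5)^2 / 2, 5, cfg, log_scale = FALSE)
  expect_identical(q$chain, q2$chain)
  # acceptance tuned into a workable band on a typical rate objective
  obs <- noiseless_nuc_obs(0.003)
  f <- fit_nuclear(obs, mcmc_config(seed = 5))
  expect_gt(f$acceptance, 0.1)
  expect_lt(f$acceptance, 0.6)
  # a proposal that can never be accepted raises a tuning error
  expect_error(
    mcmc_interval(function(x) if (abs(x - 0.01) < 1e-9) 0 else 1e8,
                  0.01, mcmc_config(seed = 1)),
    "burn-in")
})

test_that("replicate averaging acts on rates and keeps both values", {
  o1 <- make_obs(60, 0.5, 100) # rate ln2/60
  e1 <- fit_nuclear(o1, mcmc_config(seed = 1), region_id = "g1", replicate = 1)
  e2 <- e1
  e2$rate <- 2 * e1$rate
  e2$replicate <- 2
  avg <- average_replicates(e1, e2)
  expect_equal(avg$rate, 1.5 * e1$rate)
  expect_equal(avg$x1, e1$rate)
  expect_equal(avg$x2, e2$rate)
  expect_equal(average_replicates(e1, e1)$rate, e1$rate)
  e3 <- e1
  e3$region_id <- "g2"
  expect_error(average_replicates(e1, e3), "different regions")
  # documented asymmetry: the half-life of the mean rate is not the mean
  # of the half-lives
  ea <- e1; ea$rate <- log(2) / 100
  eb <- e1; eb$rate <- log(2) / 300
  avg2 <- average_replicates(ea, eb)
  expect_equal(avg2$halflife_min, 150)
  expect_false(isTRUE(all.equal(avg2$halflife_min, 200)))
})

test_that("goodness of fit behaves like a correlation on the arcsin scale", {
  k <- 0.003
  obs <- noiseless_nuc_obs(k)
  expect_equal(goodness_r(obs, nuclear_new_total(k, obs$time_min)), 1,
               tolerance = 1e-12)
  rev_obs <- make_obs(obs$time_min, rev(obs$rho), 100)
  expect_lt(goodness_r(rev_obs, nuclear_new_total(k, obs$time_min)), 0)
  expect_error(goodness_r(obs[1:2, ], c(0.1, 0.2)), ">= 3")
  flat <- make_obs(pulse_grid, 0.4, 100)
  expect_true(is.na(goodness_r(flat, rep(0.4, 7))))
  # mild binomial noise keeps the correlation high
  set.seed(7)
  noisy <- make_obs(obs$time_min, rbinom(7, 100, obs$rho) / 100, 100)
  expect_gt(goodness_r(noisy, nuclear_new_total(k, obs$time_min)), 0.9)
})

test_that("the one-compartment comparator recovers its own model", {
  k <- log(2) / 120
  obs <- noiseless_nuc_obs(k, reads = 500)
  f <- fit_one_compartment(obs, mcmc_config(seed = 6))
  expect_lt(abs(f$rate - k) / k, 1e-6)
  expect_error(fit_one_compartment(make_obs(pulse_grid, 0, 100),
                                   mcmc_config(seed = 1)), "identifiable")
  # applied to two-compartment cytosolic data it reports a half-life longer
  # than either true one (the nuclear lag slows the apparent rise)
  cyt <- noiseless_cyt_obs(log(2) / 300, log(2) / 45, reads = 500)
  f2 <- fit_one_compartment(cyt, mcmc_config(seed = 7))
  expect_gt(f2$halflife_min, 300)
})

test_that("fit_kinetics emits the full rates table deterministically", {
  cfg <- sim_config(n_regions = 4, reads_mean = 300,
                    timepoints = c(0, 30, 90, 180), seed = 17)
  sim <- simulate_reads(draw_rates(cfg), cfg)
  ratios <- estimate_ratios(sim$reads, error_rates(0.001, 0.01))
  rt <- fit_kinetics(ratios, mcmc_config(), seed = 5)
  expect_equal(nrow(rt), 8) # 4 regions x 2 replicates
  expect_true(all(c("nuc_rate", "nuc_ci_low", "nuc_ci_high", "nuc_R",
                    "cyt_rate", "cyt_ci_low", "cyt_ci_high", "cyt_R",
                    "nuc_halflife_min", "cyt_halflife_min") %in% names(rt)))
  rt2 <- fit_kinetics(ratios, mcmc_config(), seed = 5)
  expect_identical(rt, rt2)
  comb <- combine_replicates(rt)
  expect_equal(nrow(comb), 4)
  expect_equal(comb$nuc_rate, (comb$nuc_x1 + comb$nuc_x2) / 2)
})
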