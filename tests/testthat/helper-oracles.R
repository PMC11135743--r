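# shared helpers: observation builders and the memoized default cohort

make_obs <- function(time_min, rho, reads = 1000) {
  data.frame(time_min = time_min, rho = rho, reads = reads)
}

# noiseless nuclear/cytosolic observation series on the standard pulse grid
pulse_grid <- c(15, 30, 45, 60, 90, 120, 180)

noiseless_nuc_obs <- function(k, reads = 1000, tp = pulse_grid) {
  make_obs(tp, nuclear_new_total(k, tp), reads)
}

noiseless_cyt_obs <- function(k, lam, reads = 1000, tp = pulse_grid) {
  make_obs(tp, vapply(tp, function(t) cytosolic_new_total(k, lam, t),
                      numeric(1)), reads)
}

# relative deviation of the closed forms from Runge-Kutta integration for
# one rate pair, over a time grid
closed_form_vs_ode <- function(k, lam, times = c(10, 30, 60, 120, 240, 500)) {
  r <- two_comp_rates(mu = 3, nu = 0, tau = k, lam = lam)
  ode <- ode_abundances(r, times)
  ode <- ode[ode$time_min > 0, ]
  cf <- solve_abundances(r, ode$time_min)
  ss <- steady_state(r)
  max(
    abs(cf$N - ode$N) / ss[["N_inf"]],
    abs(cf$C - ode$C) / ss[["C_inf"]],
    abs(nuclear_new_total(k, ode$time_min) - ode$N / ss[["N_inf"]]),
    abs(vapply(ode$time_min, function(t) cytosolic_new_total(k, lam, t),
               numeric(1)) - ode$C / ss[["C_inf"]])
  )
}

# the default-condition cohort (300 regions, generator and pipeline defaults)
# is expensive; compute it once per session and share across tests
.cohort_env <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (!is.null(.cohort_env$cohort)) return(.cohort_env$cohort)
  cfg <- sim_config(n_regions = 300, seed = 1)
  truth <- draw_rates(cfg)
  sim <- simulate_reads(truth, cfg)
  res <- run_pipeline(sim$reads, pipeline_config(seed = 1))
  .cohort_env$cohort <- list(cfg = cfg, truth = truth, sim = sim, res = res)
  .cohort_env$cohort
}

# one-compartment fits of the cohort's cytosolic series (replicate 1)
cohort_one_comp <- function() {
  if (!is.null(.cohort_env$one_comp)) return(.cohort_env$one_comp)
  co <- default_cohort()
  ratios <- co$res$ratios
  hl <- vapply(co$truth$region_id, function(g) {
    d <- ratios[ratios$region_id == g & ratios$compartment == "cyt" &
                  ratios$replicate == 1, ]
    obs <- make_obs(d$time_min, d$rho, d$total_reads)
    tryCatch(
      fit_one_compartment(obs, mcmc_config(seed = match(g, co$truth$region_id)))$halflife_min,
      error = function(e) NA_real_)
  }, numeric(1))
  .cohort_env$one_comp <- hl
  hl
}

# retention cohorts for the false-positive control and the detection check
retention_cohort <- function(r, n_regions, seed) {
  k <- log(2) / 322
  nu <- k / 11 # nu = tau / 10
  cfg <- sim_config(n_regions = n_regions, nuc_hl_logsd = 0,
                    cyt_hl_logsd = 0, reads_mean = 500,
                    retention = list(r = r, nu = nu), seed = seed)
  truth <- draw_rates(cfg)
  sim <- simulate_reads(truth, cfg)
  ratios <- estimate_ratios(sim$reads, error_rates(0.001, 0.01))
  fits <- do.call(rbind, lapply(truth$region_id, function(g) {
    obs_of <- function(comp) {
      d <- ratios[ratios$region_id == g & ratios$compartment == comp &
                    ratios$replicate == 1, ]
      make_obs(d$time_min, d$rho, d$total_reads)
    }
    cbind(region_id = g,
          fit_retention(obs_of("nuc"), nu,
                        mcmc_config(seed = match(g, truth$region_id)),
                        cyt_obs = obs_of("cyt")))
  }))
  classify_retained(fits)
}

# abundance triples from known scaling factors with a configured cyt/nuc
# ratio and multiplicative noise
make_triples <- function(n, cyt_nuc = 0.66, noise_sd = 0, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    m_n <- rlnorm(n, 0, 1)
    m_c <- rlnorm(n, 0, 1)
    m_c <- m_c * cyt_nuc * sum(m_n) / sum(m_c)
    noisy <- function(x) x * exp(rnorm(n, 0, noise_sd))
    t_rel <- noisy(m_n + m_c)
    n_rel <- noisy(m_n)
    c_rel <- noisy(m_c)
    data.frame(t_rel = t_rel / sum(t_rel), n_rel = n_rel / sum(n_rel),
               c_rel = c_rel / sum(c_rel))
  })
}
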