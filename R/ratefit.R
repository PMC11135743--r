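#' Variance-stabilizing transform of a binomial proportion
#'
#' For `N ~ Binomial(R, p)`, `sqrt(4 R) * arcsin(sqrt(N / R))` is
#' approximately Gaussian with mean `sqrt(4 R) * arcsin(sqrt(p))` and unit
#' variance for large `R`, independent of `p`. This makes new/total ratios
#' at different depths and different times directly comparable in a single
#' weighted least-squares objective.
#'
#' @param R Read count (binomial size), `>= 1`.
#' @param x Observed proportion in `[0, 1]`.
#' @return Transformed value(s).
#' @export
vst <- function(R, x) {
  if (any(R < 1)) stop("'R' must be >= 1")
  if (any(x < 0) || any(x > 1)) stop("'x' must lie in [0, 1]")
  sqrt(4 * R) * asin(sqrt(x))
}

# observation tables: time_min, rho, reads (per region x compartment x rep)
.check_obs <- function(obs, what) {
  .check_columns(obs, c("time_min", "rho", "reads"), what)
  if (nrow(obs) == 0) stop("'", what, "' is empty")
  if (any(obs$reads < 1)) stop("'", what, "': read counts must be >= 1")
  if (any(obs$rho < 0) || any(obs$rho > 1))
    stop("'", what, "': ratios must lie in [0, 1]")
  obs[order(obs$time_min), , drop = FALSE]
}

# fast closures over one series; 'a' is arcsin(sqrt(rho)), 'w' the weights
.nuc_objective <- function(obs) {
  t <- obs$time_min
  a <- asin(sqrt(obs$rho))
  w <- obs$reads
  function(k) sum(w * (a - asin(sqrt(-expm1(-k * t))))^2)
}

.cyt_objective <- function(obs, nuc_removal) {
  t <- obs$time_min
  a <- asin(sqrt(obs$rho))
  w <- obs$reads
  k <- nuc_removal
  function(l) {
    if (abs(l - k) < .DEGENERATE_REL_TOL * max(l, k)) {
      ct <- 1 - (1 + k * t) * exp(-k * t)
    } else {
      ct <- 1 - (l * exp(-k * t) - k * exp(-l * t)) / (l - k)
    }
    ct <- pmin(pmax(ct, 0), 1)
    sum(w * (a - asin(sqrt(ct)))^2)
  }
}

#' Weighted variance-stabilized objective of the two-compartment fit
#'
#' The negative Gaussian log-likelihood of the arcsin-square-root
#' transformed new/total ratios, up to additive and multiplicative
#' constants:
#' `l(Theta) = sum_i R_i^nuc (arcsin sqrt(rho_i^nuc) - arcsin sqrt(n_i))^2
#'           + sum_i R_i^cyt (arcsin sqrt(rho_i^cyt) - arcsin sqrt(c_i))^2`.
#' Either compartment term can be computed alone by passing only that
#' observation table.
#'
#' @param nuc_removal Nuclear removal rate `nu + tau` (1/min).
#' @param cyt_deg Cytosolic degradation rate `lam` (1/min); required when
#'   `cyt_obs` is given.
#' @param nuc_obs,cyt_obs Observation tables with columns `time_min`,
#'   `rho`, `reads`.
#' @return The scalar objective value.
#' @export
neg_log_lik <- function(nuc_removal, cyt_deg = NULL, nuc_obs = NULL,
                        cyt_obs = NULL) {
  if (nuc_removal <= 0) stop("'nuc_removal' must be positive")
  if (is.null(nuc_obs) && is.null(cyt_obs)) stop("no observations supplied")
  val <- 0
  if (!is.null(nuc_obs)) {
    nuc_obs <- .check_obs(nuc_obs, "nuc_obs")
    val <- val + .nuc_objective(nuc_obs)(nuc_removal)
  }
  if (!is.null(cyt_obs)) {
    if (is.null(cyt_deg) || cyt_deg <= 0)
      stop("'cyt_deg' must be positive when 'cyt_obs' is given")
    cyt_obs <- .check_obs(cyt_obs, "cyt_obs")
    val <- val + .cyt_objective(cyt_obs, nuc_removal)(cyt_deg)
  }
  val
}

#' Configuration of the Metropolis sampler
#'
#' Defaults (20,000 steps, 5,000 burn-in, proposal sd 0.15 on the log-rate
#' scale, rates bounded to `[1e-6, 1]` per minute) mix well for the
#' one-dimensional targets arising from single-rate fits at the scales of
#' mRNA metabolism.
#'
#' @param n_steps Total chain length.
#' @param burn_in Steps discarded before computing the interval.
#' @param proposal_sd Gaussian proposal standard deviation (log-rate scale).
#' @param seed Optional integer seed; identical seeds give identical chains.
#' @param rate_bounds Lower/upper bounds of the rate (1/min).
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_steps = 20000, burn_in = 5000, proposal_sd = 0.15,
                        seed = NULL, rate_bounds = c(1e-6, 1)) {
  stopifnot(n_steps > burn_in, burn_in >= 0, proposal_sd > 0,
            length(rate_bounds) == 2, all(rate_bounds > 0),
            rate_bounds[1] < rate_bounds[2])
  structure(list(n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
                 proposal_sd = proposal_sd, seed = seed,
                 rate_bounds = rate_bounds), class = "mcmc_config")
}

#' Random-walk Metropolis sampling with a central 95% interval
#'
#' Samples from the density proportional to `exp(-objective(x))`, truncated
#' to the configured bounds, by Gaussian random-walk Metropolis. With
#' `log_scale = TRUE` (the default, used for rate parameters) the walk takes
#' place on `log(x)` with a flat prior on the log scale, and the chain is
#' returned on the original scale.
#'
#' @param objective Function returning the negative log target density (for
#'   rate fits: the weighted variance-stabilized objective [neg_log_lik()]).
#' @param init Starting value, typically a minimizer of `objective`.
#' @param config An [mcmc_config].
#' @param log_scale Whether to propose on the log scale.
#' @return List with `chain` (post burn-in, original scale), `central_95`
#'   (2.5% and 97.5% quantiles), `best` (lowest-objective sample),
#'   `acceptance` (overall acceptance fraction).
#' @export
mcmc_interval <- function(objective, init, config = mcmc_config(),
                          log_scale = TRUE) {
  stopifnot(inherits(config, "mcmc_config"))
  trans <- if (log_scale) log else identity
  inv <- if (log_scale) exp else identity
  lower <- trans(config$rate_bounds[1])
  upper <- trans(config$rate_bounds[2])
  cur <- trans(init)
  if (cur < lower || cur > upper) cur <- min(max(cur, lower), upper)
  f_cur <- objective(inv(cur))
  if (!is.finite(f_cur)) stop("objective not finite at 'init'")

  n <- config$n_steps
  .with_seed(config$seed, {
    steps <- stats::rnorm(n, 0, config$proposal_sd)
    lus <- log(stats::runif(n))
  })
  chain <- numeric(n)
  fs <- numeric(n)
  n_acc <- 0L
  acc_burn <- 0L
  for (i in seq_len(n)) {
    prop <- cur + steps[i]
    if (prop >= lower && prop <= upper) {
      f_prop <- objective(inv(prop))
      if (lus[i] < f_cur - f_prop) {
        cur <- prop
        f_cur <- f_prop
        n_acc <- n_acc + 1L
        if (i <= config$burn_in) acc_burn <- acc_burn + 1L
      }
    }
    chain[i] <- cur
    fs[i] <- f_cur
  }
  if (config$burn_in > 0 && acc_burn == 0L)
    stop("MCMC accepted no proposals during burn-in; ",
         "check the proposal sd (", config$proposal_sd, ") and bounds")
  keep <- seq.int(config$burn_in + 1L, n)
  post <- inv(chain[keep])
  best <- inv(chain[which.min(fs)])
  list(
    chain = post,
    central_95 = stats::quantile(post, c(0.025, 0.975), names = FALSE),
    best = best,
    acceptance = n_acc / n
  )
}

#' Goodness of fit on the variance-stabilized scale
#'
#' Pearson correlation between `arcsin(sqrt(rho_i))` and the
#' arcsin-transformed model curve across the time series; values `>= 0.4`
#' gate the reliability of a compartment's estimate. Undefined (zero
#' variance in either vector) correlations are returned as `NA`.
#'
#' @param obs Observation table (`time_min`, `rho`, `reads`).
#' @param model_vals Model new/total ratios at `obs$time_min`.
#' @return Correlation coefficient, or `NA` if undefined.
#' @export
goodness_r <- function(obs, model_vals) {
  obs <- .check_obs(obs, "obs")
  if (nrow(obs) < 3) stop("goodness of fit requires >= 3 observations")
  x <- asin(sqrt(obs$rho))
  y <- asin(sqrt(pmin(pmax(model_vals, 0), 1)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# shared single-rate fitting pipeline: coarse log-grid -> Nelder-Mead ->
# MCMC -> re-optimization from the best-scoring sample.
# The weighted objective itself is the negative log target; on the VST scale
# this assumes residual variance 2 rather than the binomial-limit 1, which
# absorbs the extra sampling noise of EM-estimated ratios (see vignette).
.fit_single_rate <- function(objective, config, grid = NULL) {
  if (is.null(grid))
    grid <- exp(seq(log(1e-5), log(1e-1), length.out = 13))
  grid <- grid[grid >= config$rate_bounds[1] & grid <= config$rate_bounds[2]]
  f_grid <- vapply(grid, objective, numeric(1))
  k0 <- grid[which.min(f_grid)]
  nm <- function(start) {
    opt <- suppressWarnings(stats::optim(
      log(start), function(th) objective(exp(th)), method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 500)
    ))
    exp(opt$par)
  }
  k_hat <- nm(k0)
  k_hat <- min(max(k_hat, config$rate_bounds[1]), config$rate_bounds[2])
  mc <- mcmc_interval(objective, k_hat, config)
  k_final <- nm(mc$best)
  k_final <- min(max(k_final, config$rate_bounds[1]), config$rate_bounds[2])
  list(
    rate = k_final,
    ci_low = mc$central_95[1],
    ci_high = mc$central_95[2],
    objective = objective(k_final),
    acceptance = mc$acceptance,
    at_bound = k_final >= config$rate_bounds[2] * (1 - 1e-6) ||
      k_final <= config$rate_bounds[1] * (1 + 1e-6)
  )
}

.kinetic_fit <- function(res, param, obs, model_vals, region_id, replicate) {
  structure(list(
    param = param,
    region_id = region_id,
    replicate = replicate,
    rate = res$rate,
    ci_low = res$ci_low,
    ci_high = res$ci_high,
    halflife_min = half_life(res$rate),
    objective = res$objective,
    goodness_R = if (nrow(obs) >= 3) goodness_r(obs, model_vals) else NA_real_,
    acceptance = res$acceptance,
    at_bound = res$at_bound,
    ci_consistent = res$ci_low <= res$rate && res$rate <= res$ci_high,
    n_obs = nrow(obs)
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit (%s): rate %.3g /min [%.3g, %.3g], half-life %.1f min, R = %.2f\n",
              x$param, x$rate, x$ci_low, x$ci_high, x$halflife_min,
              x$goodness_R))
  invisible(x)
}

#' Fit the nuclear removal rate to a nuclear new/total series
#'
#' Minimizes the nuclear term of the variance-stabilized objective over the
#' single rate `nu + tau`: a coarse log-spaced grid seeds Nelder-Mead, the
#' optimum initializes a Metropolis chain whose central 95% interval gives
#' the credible bounds, and a final optimization from the best-scoring
#' sample gives the point estimate.
#'
#' @param nuc_obs Observation table (`time_min`, `rho`, `reads`) for the
#'   nuclear compartment of one region and replicate.
#' @param config An [mcmc_config].
#' @param region_id,replicate Optional identifiers carried into the result.
#' @return A `kinetic_fit` object for the nuclear removal rate.
#' @export
fit_nuclear <- function(nuc_obs, config = mcmc_config(), region_id = NA,
                        replicate = NA) {
  obs <- .check_obs(nuc_obs, "nuc_obs")
  obs <- obs[obs$time_min > 0, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations at time > 0")
  if (all(obs$rho == 0))
    stop("all nuclear ratios are zero; rate not identifiable")
  res <- .fit_single_rate(.nuc_objective(obs), config)
  .kinetic_fit(res, "nuc_removal", obs,
               nuclear_new_total(res$rate, obs$time_min),
               region_id, replicate)
}

#' Fit the cytosolic degradation rate with the nuclear rate fixed
#'
#' The nuclear removal estimate is plugged into the cytosolic new/total
#' curve and the cytosolic degradation rate `lam` is fitted alone, by the
#' same grid / Nelder-Mead / MCMC / re-optimization pipeline. Fitting is
#' strictly sequential because variation in `lam` does not affect nuclear
#' metabolism.
#'
#' @param cyt_obs Observation table for the cytosolic compartment.
#' @param nuc_removal Fixed nuclear removal rate (1/min).
#' @param config An [mcmc_config].
#' @param region_id,replicate Optional identifiers carried into the result.
#' @return A `kinetic_fit` object for the cytosolic degradation rate.
#' @export
fit_cytosolic <- function(cyt_obs, nuc_removal, config = mcmc_config(),
                          region_id = NA, replicate = NA) {
  if (nuc_removal <= 0) stop("'nuc_removal' must be positive")
  obs <- .check_obs(cyt_obs, "cyt_obs")
  obs <- obs[obs$time_min > 0, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations at time > 0")
  if (all(obs$rho == 0))
    stop("all cytosolic ratios are zero; rate not identifiable")
  res <- .fit_single_rate(.cyt_objective(obs, nuc_removal), config)
  .kinetic_fit(res, "cyt_deg", obs,
               cytosolic_new_total(nuc_removal, res$rate, obs$time_min),
               region_id, replicate)
}

#' One-compartment exponential comparator fit
#'
#' Fits the single-rate saturation curve `1 - exp(-k t)` to a new/total
#' series by the same variance-stabilized pipeline. Applied to cytosolic or
#' pseudo-whole-cell series, this is the classical one-compartment half-life
#' estimator whose results mostly reflect nuclear residence when export is
#' slow.
#'
#' @param obs Observation table (`time_min`, `rho`, `reads`).
#' @param config An [mcmc_config].
#' @param region_id,replicate Optional identifiers carried into the result.
#' @return A `kinetic_fit` object (`param = "one_comp"`).
#' @export
fit_one_compartment <- function(obs, config = mcmc_config(), region_id = NA,
                                replicate = NA) {
  obs <- .check_obs(obs, "obs")
  obs <- obs[obs$time_min > 0, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations at time > 0")
  if (all(obs$rho == 0))
    stop("all ratios are zero; rate not identifiable")
  res <- .fit_single_rate(.nuc_objective(obs), config)
  fit <- .kinetic_fit(res, "one_comp", obs,
                      nuclear_new_total(res$rate, obs$time_min),
                      region_id, replicate)
  fit
}

#' Average the rate estimates of two replicate time series
#'
#' Rates (not half-lives) are averaged arithmetically; both replicate values
#' are retained because the reliability criteria compare them. Note that the
#' half-life of the mean rate is not the mean of the half-lives.
#'
#' @param est_rep1,est_rep2 `kinetic_fit` objects for the same region and
#'   parameter.
#' @return List with `rate` (the mean), `x1`, `x2` (the replicate rates),
#'   `halflife_min`, `param`, `region_id`.
#' @export
average_replicates <- function(est_rep1, est_rep2) {
  stopifnot(inherits(est_rep1, "kinetic_fit"), inherits(est_rep2, "kinetic_fit"))
  if (est_rep1$param != est_rep2$param)
    stop("cannot average estimates of different parameters")
  same_region <- identical(est_rep1$region_id, est_rep2$region_id) ||
    (is.na(est_rep1$region_id) && is.na(est_rep2$region_id))
  if (!same_region)
    stop("cannot average estimates of different regions ('",
         est_rep1$region_id, "' vs '", est_rep2$region_id, "')")
  rate <- (est_rep1$rate + est_rep2$rate) / 2
  list(rate = rate, x1 = est_rep1$rate, x2 = est_rep2$rate,
       halflife_min = half_life(rate), param = est_rep1$param,
       region_id = est_rep1$region_id)
}

#' Fit both compartments for every region and replicate of a ratio table
#'
#' Runs [fit_nuclear()] followed by [fit_cytosolic()] for each region and
#' replicate. Per-fit MCMC seeds are derived deterministically from `seed`.
#' Regions whose fit fails (e.g. all-zero ratios) get `NA` rows.
#'
#' @param ratios Ratio table from [estimate_ratios()].
#' @param config An [mcmc_config]; its seed field is overridden per fit.
#' @param seed Base seed for the per-fit MCMC chains.
#' @return Rates table with one row per region x replicate: `region_id`,
#'   `replicate`, `nuc_rate`, `nuc_ci_low`, `nuc_ci_high`, `nuc_R`,
#'   `cyt_rate`, `cyt_ci_low`, `cyt_ci_high`, `cyt_R`, `nuc_halflife_min`,
#'   `cyt_halflife_min`.
#' @export
fit_kinetics <- function(ratios, config = mcmc_config(), seed = 1) {
  .check_columns(ratios, c("region_id", "compartment", "time_min",
                           "replicate", "total_reads", "rho"), "ratios")
  regions <- unique(ratios$region_id)
  reps <- sort(unique(ratios$replicate))
  rows <- list()
  idx <- 0L
  for (g in regions) {
    for (r in reps) {
      idx <- idx + 1L
      sel <- ratios$region_id == g & ratios$replicate == r
      nuc <- ratios[sel & ratios$compartment == "nuc", , drop = FALSE]
      cyt <- ratios[sel & ratios$compartment == "cyt", , drop = FALSE]
      obs <- function(df) data.frame(time_min = df$time_min, rho = df$rho,
                                     reads = df$total_reads)
      cfg_n <- config
      cfg_n$seed <- (seed + 2L * idx) %% .Machine$integer.max
      cfg_c <- config
      cfg_c$seed <- (seed + 2L * idx + 1L) %% .Machine$integer.max
      nf <- tryCatch(fit_nuclear(obs(nuc), cfg_n, g, r), error = function(e) NULL)
      cf <- if (!is.null(nf) && nrow(cyt) > 0)
        tryCatch(fit_cytosolic(obs(cyt), nf$rate, cfg_c, g, r),
                 error = function(e) NULL) else NULL
      rows[[idx]] <- data.frame(
        region_id = g, replicate = r,
        nuc_rate = if (is.null(nf)) NA_real_ else nf$rate,
        nuc_ci_low = if (is.null(nf)) NA_real_ else nf$ci_low,
        nuc_ci_high = if (is.null(nf)) NA_real_ else nf$ci_high,
        nuc_R = if (is.null(nf)) NA_real_ else nf$goodness_R,
        cyt_rate = if (is.null(cf)) NA_real_ else cf$rate,
        cyt_ci_low = if (is.null(cf)) NA_real_ else cf$ci_low,
        cyt_ci_high = if (is.null(cf)) NA_real_ else cf$ci_high,
        cyt_R = if (is.null(cf)) NA_real_ else cf$goodness_R,
        nuc_halflife_min = if (is.null(nf)) NA_real_ else nf$halflife_min,
        cyt_halflife_min = if (is.null(cf)) NA_real_ else cf$halflife_min,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average the per-replicate rates table across replicates
#'
#' @param rates_table Output of [fit_kinetics()] with two replicates.
#' @return Combined table with one row per region: averaged rates and the
#'   corresponding half-lives, plus the per-replicate rates `nuc_x1`,
#'   `nuc_x2`, `cyt_x1`, `cyt_x2` used by the reliability criteria.
#' @export
combine_replicates <- function(rates_table) {
  .check_columns(rates_table, c("region_id", "replicate", "nuc_rate",
                                "cyt_rate"), "rates_table")
  out <- lapply(split(rates_table, rates_table$region_id), function(df) {
    df <- df[order(df$replicate), , drop = FALSE]
    nuc <- mean(df$nuc_rate)
    cyt <- mean(df$cyt_rate)
    data.frame(
      region_id = df$region_id[1],
      nuc_rate = nuc, cyt_rate = cyt,
      nuc_halflife_min = if (is.finite(nuc) && nuc > 0) half_life(nuc) else NA_real_,
      cyt_halflife_min = if (is.finite(cyt) && cyt > 0) half_life(cyt) else NA_real_,
      nuc_x1 = df$nuc_rate[1], nuc_x2 = df$nuc_rate[min(2, nrow(df))],
      cyt_x1 = df$cyt_rate[1], cyt_x2 = df$cyt_rate[min(2, nrow(df))],
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
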