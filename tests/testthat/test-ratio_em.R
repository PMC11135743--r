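err_default <- error_rates(0.001, 0.01)

test_that("conversion probability of new reads combines labeling and errors", {
  expect_equal(conversion_prob_new(0, err_default), 0.001)
  expect_equal(conversion_prob_new(1, err_default), 0.99)
  expect_equal(conversion_prob_new(0.02, err_default),
               0.02 * 0.99 + 0.98 * 0.001)
  expect_error(conversion_prob_new(1.2, err_default), "0, 1")
  expect_error(error_rates(1, 0), "0, 1")
})

test_that("error rates are pooled mismatch rates over unmasked control sites", {
  ctrl <- data.frame(t_cov = c(4000, 6000), tc_mismatch = c(4, 6),
                     c_cov = c(5000, 5000), c_nonc_mismatch = c(0, 0))
  er <- estimate_error_rates(ctrl)
  expect_equal(er$p0, 0.001)
  expect_equal(er$epsilon, 0)
  # masking drops rows by position
  ctrl$chrom <- "chr1"; ctrl$pos <- c(10, 20); ctrl$strand <- "+"
  mask <- data.frame(chrom = "chr1", pos = 20, strand = "+",
                     reason = "snp_list")
  er2 <- estimate_error_rates(ctrl, mask)
  expect_equal(er2$p0, 0.001)
  mask_all <- data.frame(chrom = "chr1", pos = c(10, 20), strand = "+",
                         reason = "snp_list")
  expect_error(estimate_error_rates(ctrl, mask_all), "no control sites")
  bad <- data.frame(t_cov = 10, tc_mismatch = 9, c_cov = 10,
                    c_nonc_mismatch = 0)
  expect_error(estimate_error_rates(bad), "mislabeled")
})

test_that("site masking applies the strict 5% rule and SNP list", {
  st <- data.frame(
    chrom = "chr1", pos = c(100, 200, 300, 400), strand = "+",
    compartment = rep("nuc", 4), coverage = rep(100, 4),
    conversions = c(6, 4, 5, 1)
  )
  snp <- data.frame(chrom = "chr1", pos = 400, strand = "+")
  m <- mask_sites(st, snp)
  expect_setequal(m$pos, c(100, 400))
  expect_equal(m$reason[m$pos == 100], "control_conversion")
  expect_equal(m$reason[m$pos == 400], "snp_list")
  # exactly 5% stays unmasked (strict inequality), 4% stays unmasked
  expect_false(any(m$pos %in% c(200, 300)))
  # exceeding the threshold in either compartment masks the site
  st2 <- rbind(st, data.frame(chrom = "chr1", pos = 200, strand = "+",
                              compartment = "cyt", coverage = 100,
                              conversions = 8))
  m2 <- mask_sites(st2, snp)
  expect_true(200 %in% m2$pos)
  expect_error(mask_sites(transform(st, pos = pos + 0.5), NULL),
               "integer")
})

test_that("EM recovers mixture parameters from simulated reads", {
  set.seed(11)
  J <- 5000
  Tj <- pmax(rpois(J, 30), 1)
  new <- runif(J) < 0.5
  p1 <- conversion_prob_new(0.05, err_default)
  oj <- ifelse(new, rbinom(J, Tj, p1), rbinom(J, Tj, 0.001))
  fit <- em_fit(data.frame(t_count = Tj, conversions = oj), err_default)
  expect_true(fit$converged)
  expect_lt(abs(fit$rho - 0.5), 0.03)
  expect_lt(abs(fit$ell - 0.05), 0.01)
  expect_false(fit$overfit_suspect)
  # observed-data log-likelihood never decreases
  expect_true(all(diff(fit$loglik_trace) > -1e-9))
})

test_that("EM is consistent for the ratio as reads accumulate", {
  set.seed(21)
  for (rho in c(0.1, 0.5, 0.9)) {
    J <- 1e5
    Tj <- pmax(rpois(J, 30), 1)
    new <- runif(J) < rho
    p1 <- conversion_prob_new(0.05, err_default)
    oj <- ifelse(new, rbinom(J, Tj, p1), rbinom(J, Tj, 0.001))
    fit <- em_fit(data.frame(t_count = Tj, conversions = oj), err_default)
    expect_lt(abs(fit$rho - rho), 0.01)
  }
})

test_that("EM handles degenerate inputs", {
  # all conversion-free reads: fitted model is equivalent to the all-old one
  reads0 <- data.frame(t_count = rep(40, 200), conversions = 0)
  fit0 <- em_fit(reads0, err_default)
  ll_all_old <- 200 * dbinom(0, 40, 0.001, log = TRUE)
  expect_lt(abs(fit0$loglik - ll_all_old), 1e-3)
  p1 <- conversion_prob_new(fit0$ell, err_default)
  expect_lt(fit0$rho * (1 - (1 - p1)^40), 1e-3)
  # single read smoke case
  fit1 <- em_fit(data.frame(t_count = 10, conversions = 0), err_default)
  expect_true(all(diff(fit1$loglik_trace) > -1e-9))
  expect_error(em_fit(data.frame(t_count = numeric(0),
                                 conversions = numeric(0)), err_default),
               "no reads")
  expect_error(em_fit(data.frame(t_count = 10, conversions = 0),
                      err_default, tol = 0), "tol")
  expect_error(em_fit(data.frame(t_count = 10, conversions = 12),
                      err_default), "conversions")
})

test_that("pooled refit fixes the efficiency to the non-suspect median", {
  set.seed(31)
  ells <- c(0.005, 0.04, 0.05, 0.06, 0.07)
  reads_by_region <- list()
  fits <- list()
  for (i in seq_along(ells)) {
    J <- 400
    Tj <- pmax(rpois(J, 30), 1)
    p1 <- conversion_prob_new(0.05, err_default)
    new <- runif(J) < 0.5
    oj <- ifelse(new, rbinom(J, Tj, p1), rbinom(J, Tj, 0.001))
    g <- paste0("g", i)
    reads_by_region[[g]] <- data.frame(t_count = Tj, conversions = oj)
    f <- em_fit(reads_by_region[[g]], err_default)
    f$ell <- ells[i] # imprint the efficiency pattern under test
    f$overfit_suspect <- ells[i] < 0.01
    fits[[g]] <- f
  }
  pooled <- pooled_refit(fits, reads_by_region, err_default)
  # the suspect region (0.005) is excluded; median of the rest is 0.055
  expect_equal(pooled$ell, 0.055)
  expect_named(pooled$rho, names(fits))
  # a lone suspect region makes the sample unusable
  expect_error(pooled_refit(fits["g1"], reads_by_region["g1"], err_default),
               "unusable")
})

test_that("pooling the efficiency improves low-depth ratio estimates", {
  set.seed(41)
  n_regions <- 30
  J <- 40
  rho_true <- runif(n_regions, 0.2, 0.8)
  p1 <- conversion_prob_new(0.05, err_default)
  reads_by_region <- lapply(seq_len(n_regions), function(i) {
    Tj <- pmax(rpois(J, 30), 1)
    new <- runif(J) < rho_true[i]
    data.frame(t_count = Tj,
               conversions = ifelse(new, rbinom(J, Tj, p1),
                                    rbinom(J, Tj, 0.001)))
  })
  names(reads_by_region) <- paste0("g", seq_len(n_regions))
  fits <- lapply(reads_by_region, em_fit, err = err_default)
  pooled <- pooled_refit(fits, reads_by_region, err_default)
  rmse_free <- sqrt(mean((vapply(fits, `[[`, numeric(1), "rho") - rho_true)^2))
  rmse_pooled <- sqrt(mean((pooled$rho - rho_true)^2))
  expect_lt(abs(pooled$ell - 0.05), 0.005)
  expect_lt(rmse_pooled, rmse_free)
})

test_that("estimate_ratios produces one row per region and sample", {
  cfg <- sim_config(n_regions = 8, reads_mean = 300,
                    timepoints = c(0, 30, 90, 180), seed = 13)
  sim <- simulate_reads(draw_rates(cfg), cfg)
  ratios <- estimate_ratios(sim$reads, err_default)
  expect_setequal(names(ratios),
                  c("region_id", "compartment", "time_min", "replicate",
                    "total_reads", "rho", "ell", "ell_free", "suspect"))
  # 8 regions x 2 compartments x 3 labeled timepoints x 2 replicates
  expect_equal(nrow(ratios), 8 * 2 * 3 * 2)
  expect_true(all(ratios$rho >= 0 & ratios$rho <= 1))
  # pooled efficiencies land in the few-percent range of the generator
  expect_true(all(ratios$ell > 0.02 & ratios$ell < 0.10))
})
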