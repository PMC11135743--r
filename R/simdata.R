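#' Configuration of the forward read-level simulator
#'
#' Defaults emulate a subcellular-fractionation SLAM-seq time series: two
#' replicate series over the pulse grid 0, 15, 30, 45, 60, 90, 120, 180
#' minutes, nuclear half-lives log-normal around a median of 322 min and
#' cytosolic half-lives around 58 min (log-sd 0.7, matching the right-skewed
#' genome-wide distributions), negative-binomial read depth with mean 100
#' per region/timepoint/compartment, about 30 genomic T positions per read,
#' labeling efficiency 5%, T>C error 0.001 and C>non-C error 0.01.
#'
#' @param n_regions Number of simulated regions (3'UTRs).
#' @param nuc_hl_median,nuc_hl_logsd Nuclear half-life distribution
#'   (log-normal; median in minutes, sd on the log scale).
#' @param cyt_hl_median,cyt_hl_logsd Cytosolic half-life distribution.
#' @param timepoints Pulse durations in minutes (0 is the unlabeled control).
#' @param replicates Number of replicate time series.
#' @param reads_mean,reads_size Negative-binomial read depth per
#'   region/timepoint/compartment (mean and dispersion size).
#' @param t_per_read_mean Poisson mean of genomic T positions per read
#'   (minimum 1).
#' @param p0,epsilon Sequencing error rates.
#' @param ell Labeling efficiency: a constant, a vector matched to the
#'   positive timepoints, or `list(ell_max =, t_ramp =)` for the saturating
#'   ramp `ell(s) = ell_max (1 - exp(-s / t_ramp))` used in the bias study.
#' @param retention Optional `list(r =, nu =)` to simulate the retention
#'   model (scalars or per-region vectors).
#' @param seed Seed controlling every draw.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_regions = 300, nuc_hl_median = 322,
                       nuc_hl_logsd = 0.7, cyt_hl_median = 58,
                       cyt_hl_logsd = 0.7,
                       timepoints = c(0, 15, 30, 45, 60, 90, 120, 180),
                       replicates = 2, reads_mean = 100, reads_size = 10,
                       t_per_read_mean = 30, p0 = 0.001, epsilon = 0.01,
                       ell = 0.05, retention = NULL, seed = 1) {
  stopifnot(n_regions >= 1, nuc_hl_median > 0, cyt_hl_median > 0,
            nuc_hl_logsd >= 0, cyt_hl_logsd >= 0,
            all(timepoints >= 0), replicates >= 1,
            reads_mean > 0, reads_size > 0, t_per_read_mean > 0,
            p0 >= 0, p0 < 1, epsilon >= 0, epsilon < 1)
  if (is.list(ell)) {
    if (is.null(ell$ell_max) || is.null(ell$t_ramp))
      stop("ramp schedule needs 'ell_max' and 't_ramp'")
    if (ell$t_ramp <= 0) stop("'t_ramp' must be positive")
    if (ell$ell_max < 0 || ell$ell_max > 1) stop("'ell_max' must lie in [0, 1]")
  } else {
    n_pos <- sum(timepoints > 0)
    if (!length(ell) %in% c(1L, n_pos))
      stop("'ell' must be a scalar or one value per positive timepoint")
    if (any(ell < 0) || any(ell > 1)) stop("'ell' must lie in [0, 1]")
  }
  if (!is.null(retention)) {
    if (is.null(retention$r) || is.null(retention$nu))
      stop("retention settings need 'r' and 'nu'")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Draw ground-truth kinetic rates for a simulated cohort
#'
#' Half-lives are drawn log-normally around the configured medians and
#' converted to rates (`rate = log(2) / half-life`). With retention enabled
#' the configured `r` and `nu` are attached per region.
#'
#' @param config A [sim_config].
#' @return Truth table of class `sim_truth`: `region_id`, `nuc_halflife_min`,
#'   `cyt_halflife_min`, `nuc_removal`, `cyt_deg` (plus `r`, `nu` under
#'   retention).
#' @export
draw_rates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_regions
  .with_seed(config$seed, {
    nuc_hl <- stats::rlnorm(n, log(config$nuc_hl_median), config$nuc_hl_logsd)
    cyt_hl <- stats::rlnorm(n, log(config$cyt_hl_median), config$cyt_hl_logsd)
  })
  truth <- data.frame(
    region_id = sprintf("region_%04d", seq_len(n)),
    nuc_halflife_min = nuc_hl,
    cyt_halflife_min = cyt_hl,
    nuc_removal = rate_from_half_life(nuc_hl),
    cyt_deg = rate_from_half_life(cyt_hl),
    stringsAsFactors = FALSE
  )
  if (!is.null(config$retention)) {
    truth$r <- rep(config$retention$r, length.out = n)
    truth$nu <- rep(config$retention$nu, length.out = n)
  }
  class(truth) <- c("sim_truth", "data.frame")
  truth
}

# true new/total ratio of one region at one timepoint in one compartment
.true_ratio <- function(truth_row, compartment, t) {
  if (t == 0) return(0)
  if ("r" %in% names(truth_row) && !is.na(truth_row[["r"]])) {
    pars <- retention_params(nu = truth_row[["nu"]],
                             tau = truth_row[["nuc_removal"]] - truth_row[["nu"]],
                             lam = truth_row[["cyt_deg"]], r = truth_row[["r"]])
    rc <- retention_new_total(pars, t)
    if (compartment == "nuc") rc$nuclear else rc$cytosolic
  } else if (compartment == "nuc") {
    nuclear_new_total(truth_row$nuc_removal, t)
  } else {
    cytosolic_new_total(truth_row$nuc_removal, truth_row$cyt_deg, t)
  }
}

# labeling efficiency at pulse time t under the configured schedule
.ell_at <- function(config, t) {
  if (is.list(config$ell)) {
    config$ell$ell_max * (1 - exp(-t / config$ell$t_ramp))
  } else if (length(config$ell) == 1L) {
    config$ell
  } else {
    pos <- sort(unique(config$timepoints[config$timepoints > 0]))
    config$ell[match(t, pos)]
  }
}

#' Simulate a read-level SLAM-seq conversion dataset
#'
#' For every region x compartment x timepoint x replicate, a
#' negative-binomial number of reads is drawn; each read is new with
#' probability `n(t)` (nucleus) or `c(t)` (cytosol), carries a Poisson
#' number of genomic T positions (minimum 1), and shows
#' `Binomial(t_count, p1)` conversions if new, `Binomial(t_count, p0)` if
#' old, with `p1 = ell (1 - epsilon) + (1 - ell) p0`. Identical reads are
#' run-length collapsed into a `multiplicity` column. The `time_min = 0`
#' sample is the unlabeled control (all reads old).
#'
#' @param truth A [draw_rates()] truth table.
#' @param config The matching [sim_config].
#' @return List with `reads` (standard reads table), `ratios` (true
#'   new/total per region/compartment/timepoint/replicate) and `config`.
#' @export
simulate_reads <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  err <- error_rates(config$p0, config$epsilon)
  combos <- expand.grid(
    region = seq_len(nrow(truth)),
    compartment = c("nuc", "cyt"),
    time_min = config$timepoints,
    replicate = seq_len(config$replicates),
    stringsAsFactors = FALSE
  )
  .with_seed(config$seed + 1L, {
    parts <- vector("list", nrow(combos))
    ratio_truth <- numeric(nrow(combos))
    for (i in seq_len(nrow(combos))) {
      cb <- combos[i, ]
      tr <- truth[cb$region, ]
      rho <- .true_ratio(tr, cb$compartment, cb$time_min)
      ratio_truth[i] <- rho
      n_reads <- stats::rnbinom(1, size = config$reads_size,
                                mu = config$reads_mean)
      if (n_reads == 0) next
      tj <- pmax(stats::rpois(n_reads, config$t_per_read_mean), 1L)
      new <- stats::runif(n_reads) < rho
      ell_t <- .ell_at(config, cb$time_min)
      p1 <- conversion_prob_new(ell_t, err)
      oj <- integer(n_reads)
      oj[new] <- stats::rbinom(sum(new), tj[new], p1)
      oj[!new] <- stats::rbinom(sum(!new), tj[!new], config$p0)
      parts[[i]] <- data.frame(
        region_id = tr$region_id, compartment = cb$compartment,
        time_min = cb$time_min, replicate = cb$replicate,
        t_count = tj, conversions = oj, stringsAsFactors = FALSE
      )
    }
  })
  reads <- data.table::rbindlist(parts)
  reads <- as.data.frame(reads[, list(multiplicity = .N),
                               by = list(region_id, compartment, time_min,
                                         replicate, t_count, conversions)])
  reads <- reads[order(reads$region_id, reads$compartment, reads$replicate,
                       reads$time_min, reads$t_count, reads$conversions), ]
  rownames(reads) <- NULL
  ratios <- cbind(
    data.frame(region_id = truth$region_id[combos$region]),
    combos[c("compartment", "time_min", "replicate")],
    data.frame(rho_true = ratio_truth)
  )
  list(reads = reads, ratios = ratios, config = config)
}

#' Simulate aggregate control-sample mismatch counts
#'
#' Emits the per-region T and C coverage and mismatch totals of an
#' unlabeled control, from which [estimate_error_rates()] recovers `p0`
#' and `epsilon`.
#'
#' @param truth A [draw_rates()] truth table.
#' @param config The matching [sim_config].
#' @return Data frame with `region_id`, `t_cov`, `tc_mismatch`, `c_cov`,
#'   `c_nonc_mismatch`.
#' @export
simulate_control_mismatches <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  n <- nrow(truth)
  .with_seed(config$seed + 2L, {
    t_cov <- stats::rnbinom(n, size = config$reads_size,
                            mu = config$reads_mean * config$t_per_read_mean)
    c_cov <- stats::rnbinom(n, size = config$reads_size,
                            mu = config$reads_mean * config$t_per_read_mean)
    data.frame(
      region_id = truth$region_id,
      t_cov = t_cov,
      tc_mismatch = stats::rbinom(n, t_cov, config$p0),
      c_cov = c_cov,
      c_nonc_mismatch = stats::rbinom(n, c_cov, config$epsilon),
      stringsAsFactors = FALSE
    )
  })
}

# sample synthesis times of new molecules present at pulse time t.
# nucleus: age t - s is a truncated Exp(nuc_removal) on [0, t] (inverse CDF).
# cytosol: rejection sampling of the compartment passage (synthesis uniform
# in [0, t], nuclear residence Exp(nuc_removal), cytosolic survival to t).
.sample_synthesis_times <- function(n, compartment, t, nuc_removal, cyt_deg) {
  if (n == 0) return(numeric(0))
  k <- nuc_removal
  if (compartment == "nuc") {
    u <- stats::runif(n)
    age <- -log1p(-u * (-expm1(-k * t))) / k
    return(t - age)
  }
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 64L)
    s <- stats::runif(m, 0, t)
    w <- stats::rexp(m, k)
    ok <- (s + w < t) &
      (stats::runif(m) < exp(-cyt_deg * (t - s - w)))
    out <- c(out, s[ok])
  }
  out[seq_len(n)]
}

#' Simulate reads under a time-varying labeling efficiency
#'
#' Models the rise of 4sU incorporation after pulse onset: each new
#' molecule's synthesis time `s` is drawn from the steady-state age
#' distribution of its compartment (truncated exponential in the nucleus;
#' nuclear-passage sampling in the cytosol) and its conversion probability
#' uses the ramp efficiency `ell(s) = ell_max (1 - exp(-s / t_ramp))`.
#' With a constant schedule the output is distributionally identical to
#' [simulate_reads()].
#'
#' @param truth A [draw_rates()] truth table.
#' @param config A [sim_config] whose `ell` is a ramp
#'   (`list(ell_max =, t_ramp =)`) or a constant.
#' @return Same structure as [simulate_reads()].
#' @export
simulate_ramp_efficiency <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  err <- error_rates(config$p0, config$epsilon)
  ell_of <- function(s) {
    if (is.list(config$ell)) {
      config$ell$ell_max * (1 - exp(-s / config$ell$t_ramp))
    } else {
      rep(config$ell[1], length(s))
    }
  }
  combos <- expand.grid(
    region = seq_len(nrow(truth)),
    compartment = c("nuc", "cyt"),
    time_min = config$timepoints,
    replicate = seq_len(config$replicates),
    stringsAsFactors = FALSE
  )
  .with_seed(config$seed + 1L, {
    parts <- vector("list", nrow(combos))
    ratio_truth <- numeric(nrow(combos))
    for (i in seq_len(nrow(combos))) {
      cb <- combos[i, ]
      tr <- truth[cb$region, ]
      rho <- .true_ratio(tr, cb$compartment, cb$time_min)
      ratio_truth[i] <- rho
      n_reads <- stats::rnbinom(1, size = config$reads_size,
                                mu = config$reads_mean)
      if (n_reads == 0) next
      tj <- pmax(stats::rpois(n_reads, config$t_per_read_mean), 1L)
      new <- stats::runif(n_reads) < rho
      oj <- integer(n_reads)
      if (any(new)) {
        s <- .sample_synthesis_times(sum(new), cb$compartment, cb$time_min,
                                     tr$nuc_removal, tr$cyt_deg)
        p1 <- conversion_prob_new(ell_of(s), err)
        oj[new] <- stats::rbinom(sum(new), tj[new], p1)
      }
      oj[!new] <- stats::rbinom(sum(!new), tj[!new], config$p0)
      parts[[i]] <- data.frame(
        region_id = tr$region_id, compartment = cb$compartment,
        time_min = cb$time_min, replicate = cb$replicate,
        t_count = tj, conversions = oj, stringsAsFactors = FALSE
      )
    }
  })
  reads <- data.table::rbindlist(parts)
  reads <- as.data.frame(reads[, list(multiplicity = .N),
                               by = list(region_id, compartment, time_min,
                                         replicate, t_count, conversions)])
  reads <- reads[order(reads$region_id, reads$compartment, reads$replicate,
                       reads$time_min, reads$t_count, reads$conversions), ]
  rownames(reads) <- NULL
  ratios <- cbind(
    data.frame(region_id = truth$region_id[combos$region]),
    combos[c("compartment", "time_min", "replicate")],
    data.frame(rho_true = ratio_truth)
  )
  list(reads = reads, ratios = ratios, config = config)
}
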