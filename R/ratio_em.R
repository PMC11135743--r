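#' Sequencing error rates of the conversion model
#'
#' `p0` is the probability of observing a T>C mismatch at a genomic T in a
#' read from a pre-existing (unlabeled) transcript; `epsilon` is the
#' probability that a genuinely converted position is destroyed by a C>non-C
#' error. Both are estimated from unlabeled control samples, see
#' [estimate_error_rates()].
#'
#' @param p0 T>C error probability, in `[0, 1)`.
#' @param epsilon C>non-C error probability, in `[0, 1)`.
#' @return An object of class `error_rates`.
#' @export
error_rates <- function(p0, epsilon) {
  stopifnot(is.numeric(p0), is.numeric(epsilon))
  if (p0 < 0 || p0 >= 1 || epsilon < 0 || epsilon >= 1)
    stop("'p0' and 'epsilon' must lie in [0, 1)")
  structure(list(p0 = p0, epsilon = epsilon), class = "error_rates")
}

#' Conversion probability of a position in a new read
#'
#' A T position in a read from a newly synthesized transcript shows a T>C
#' conversion either through 4sU incorporation that survives sequencing
#' (`ell * (1 - epsilon)`) or through a plain sequencing error at an
#' unlabeled position (`(1 - ell) * p0`):
#' `p1 = ell (1 - epsilon) + (1 - ell) p0`.
#'
#' @param ell Labeling efficiency in `[0, 1]`.
#' @param err An [error_rates] object.
#' @return Probability `p1` in `[0, 1]`.
#' @export
conversion_prob_new <- function(ell, err) {
  stopifnot(inherits(err, "error_rates"))
  if (any(ell < 0) || any(ell > 1)) stop("'ell' must lie in [0, 1]")
  ell * (1 - err$epsilon) + (1 - ell) * err$p0
}

#' Mask SNP-like and editing-like sites
#'
#' Positions listed as known SNPs, and T sites whose conversion rate in the
#' unlabeled control exceeds `threshold` in *either* compartment, are masked
#' before error-rate estimation (they carry systematic, not stochastic,
#' mismatches). The threshold is a strict inequality: a site at exactly
#' `threshold` is kept.
#'
#' @param control_site_table Data frame with columns `chrom`, `pos`
#'   (0-based), `strand`, `compartment`, `coverage`, `conversions`, giving
#'   per-site T>C counts in the unlabeled control.
#' @param snp_list Optional data frame of known SNP positions with columns
#'   `chrom`, `pos`, `strand`.
#' @param threshold Control conversion rate above which a site is masked.
#' @return Data frame of masked sites with columns `chrom`, `pos`, `strand`,
#'   `reason` (one of `"snp_list"`, `"control_conversion"`).
#' @export
mask_sites <- function(control_site_table, snp_list = NULL, threshold = 0.05) {
  st <- control_site_table
  .check_columns(st, c("chrom", "pos", "strand", "compartment",
                       "coverage", "conversions"), "control_site_table")
  if (any(st$pos < 0) || any(st$pos != floor(st$pos)))
    stop("site positions must be non-negative integers (0-based)")
  if (any(!st$strand %in% c("+", "-")))
    stop("site strand must be '+' or '-'")
  if (any(st$coverage < 1)) stop("all listed sites must have coverage >= 1")

  key <- paste(st$chrom, st$pos, st$strand)
  rate <- st$conversions / st$coverage
  # a site is masked if its rate exceeds the threshold in any compartment
  hot <- tapply(rate > threshold, key, any)
  hot_keys <- names(hot)[hot]

  snp_keys <- character(0)
  if (!is.null(snp_list) && nrow(snp_list) > 0) {
    .check_columns(snp_list, c("chrom", "pos", "strand"), "snp_list")
    snp_keys <- unique(paste(snp_list$chrom, snp_list$pos, snp_list$strand))
  }

  all_keys <- unique(c(snp_keys, setdiff(hot_keys, snp_keys)))
  if (length(all_keys) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), reason = character(0)))
  }
  parts <- do.call(rbind, strsplit(all_keys, " ", fixed = TRUE))
  data.frame(
    chrom = parts[, 1],
    pos = as.integer(parts[, 2]),
    strand = parts[, 3],
    reason = ifelse(all_keys %in% snp_keys, "snp_list", "control_conversion"),
    stringsAsFactors = FALSE
  )
}

#' Estimate sequencing error rates from an unlabeled control
#'
#' `p0` is the pooled T>C mismatch rate over all unmasked T positions of the
#' control sample; `epsilon` is the pooled C>non-C mismatch rate over all C
#' positions. Masked sites (SNPs, editing sites) are excluded first.
#'
#' @param control Data frame with columns `t_cov`, `tc_mismatch`, `c_cov`,
#'   `c_nonc_mismatch` (totals per region or per site). If it also carries
#'   `chrom`, `pos`, `strand` columns and `mask` is given, masked rows are
#'   dropped.
#' @param mask Optional site mask from [mask_sites()].
#' @return An [error_rates] object.
#' @export
estimate_error_rates <- function(control, mask = NULL) {
  .check_columns(control, c("t_cov", "tc_mismatch", "c_cov", "c_nonc_mismatch"),
                 "control")
  if (!is.null(mask) && nrow(mask) > 0 &&
      all(c("chrom", "pos", "strand") %in% names(control))) {
    masked <- paste(control$chrom, control$pos, control$strand) %in%
      paste(mask$chrom, mask$pos, mask$strand)
    control <- control[!masked, , drop = FALSE]
  }
  if (nrow(control) == 0) stop("no control sites left after masking")
  t_cov <- sum(control$t_cov)
  c_cov <- sum(control$c_cov)
  if (t_cov == 0 || c_cov == 0)
    stop("control sample has zero T or C coverage")
  p0 <- sum(control$tc_mismatch) / t_cov
  eps <- sum(control$c_nonc_mismatch) / c_cov
  if (p0 > 0.5 || eps > 0.5)
    stop("estimated error rate exceeds 0.5; input is likely mislabeled")
  error_rates(p0, eps)
}

# log(exp(x) + exp(y)) elementwise, safe for -Inf
.logsumexp2 <- function(x, y) {
  m <- pmax(x, y)
  out <- m + log(exp(x - m) + exp(y - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Fit the binomial mixture model of read conversions by EM
#'
#' Each read of a region is summarized by its number of genomic T positions
#' `t_count` and observed T>C conversions. Reads come from newly synthesized
#' transcripts with probability `rho` (conversions ~ Binomial(`t_count`,
#' `p1`)) or pre-existing ones (Binomial(`t_count`, `p0`)), with
#' `p1 = ell (1 - epsilon) + (1 - ell) p0`. The EM algorithm alternates
#' posterior read weights with closed-form updates of `rho` and `ell`
#' (the latter by inverting `p1` from the weighted conversion rate,
#' clipped to `[0, 1]`).
#'
#' Fits with `ell` below `suspect_ell` are flagged `overfit_suspect`: at low
#' true new/total ratios the two mixture components both chase the
#' pre-existing reads and the efficiency estimate collapses. Such regions are
#' excluded from the pooled efficiency median in [pooled_refit()].
#'
#' @param reads Data frame with columns `t_count`, `conversions` and
#'   optionally `multiplicity` (run-length collapsed identical reads).
#' @param err An [error_rates] object.
#' @param rho_init,ell_init Initial values of the new/total ratio and
#'   labeling efficiency.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param fixed_ell If non-`NULL`, the labeling efficiency is held at this
#'   value and only `rho` is updated.
#' @param suspect_ell Efficiency below which the fit is flagged suspect.
#' @return List of class `mixture_fit` with elements `rho`, `ell`, `loglik`,
#'   `n_iter`, `converged`, `overfit_suspect`, `loglik_trace`.
#' @export
em_fit <- function(reads, err, rho_init = 0.1, ell_init = 0.05,
                   max_iter = 500, tol = 1e-8, fixed_ell = NULL,
                   suspect_ell = 0.01) {
  stopifnot(inherits(err, "error_rates"))
  .check_columns(reads, c("t_count", "conversions"), "reads")
  if (nrow(reads) == 0) stop("no reads supplied")
  if (tol <= 0) stop("'tol' must be positive")
  Tj <- reads$t_count
  oj <- reads$conversions
  m <- if ("multiplicity" %in% names(reads)) reads$multiplicity else
    rep(1, length(Tj))
  if (any(oj > Tj) || any(oj < 0) || any(Tj < 0))
    stop("need 0 <= conversions <= t_count")
  if (all(Tj < 1)) stop("need at least one read with t_count >= 1")

  p0 <- err$p0
  denom <- 1 - err$epsilon - p0
  if (denom <= 0) stop("need 1 - epsilon > p0 for identifiability")
  lb0 <- stats::dbinom(oj, Tj, p0, log = TRUE)

  rho <- rho_init
  ell <- if (is.null(fixed_ell)) ell_init else fixed_ell
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    p1 <- ell * (1 - err$epsilon) + (1 - ell) * p0
    lb1 <- stats::dbinom(oj, Tj, p1, log = TRUE)
    la <- log(rho) + lb1
    lb <- log1p(-rho) + lb0
    llj <- .logsumexp2(la, lb)
    ll <- sum(m * llj)
    trace <- c(trace, ll)
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w <- exp(la - llj)
    w[is.nan(w)] <- 0
    rho <- sum(m * w) / sum(m)
    rho <- min(max(rho, 0), 1)
    if (is.null(fixed_ell)) {
      wt <- sum(m * w * Tj)
      if (wt > 0) {
        p1_hat <- sum(m * w * oj) / wt
        ell <- min(max((p1_hat - p0) / denom, 0), 1)
      }
    }
  }
  structure(list(
    rho = rho, ell = ell, loglik = trace[length(trace)], n_iter = n_iter,
    converged = converged, overfit_suspect = ell < suspect_ell,
    loglik_trace = trace
  ), class = "mixture_fit")
}

#' Re-estimate ratios with the labeling efficiency pooled across regions
#'
#' Per-region efficiency estimates are noisy and collapse for lowly labeled
#' regions. Following the two-round scheme, regions whose free fit gave
#' `ell` below the suspect cutoff are excluded, the efficiency is fixed to
#' the median over the remaining regions of the sample, and every region's
#' `rho` is re-estimated by maximum likelihood with `ell` held fixed.
#'
#' @param fits Named list of [em_fit()] results, one per region.
#' @param reads_by_region Named list of read data frames (same names).
#' @param err An [error_rates] object.
#' @param ... Passed on to the one-parameter [em_fit()] refits.
#' @return List with `ell` (the pooled median), `fits` (named list of
#'   refitted `mixture_fit`s) and `rho` (named numeric vector).
#' @export
pooled_refit <- function(fits, reads_by_region, err, ...) {
  stopifnot(length(fits) == length(reads_by_region),
            all(names(fits) == names(reads_by_region)))
  suspect <- vapply(fits, `[[`, logical(1), "overfit_suspect")
  if (all(suspect))
    stop("all regions have suspect labeling efficiency (< 1%); ",
         "sample unusable for ratio estimation")
  ells <- vapply(fits, `[[`, numeric(1), "ell")
  ell_star <- stats::median(ells[!suspect])
  refits <- lapply(names(fits), function(g) {
    # keep the start away from the absorbing EM boundaries at 0 and 1
    rho0 <- min(max(fits[[g]]$rho, 0.01), 0.99)
    em_fit(reads_by_region[[g]], err, rho_init = rho0,
           fixed_ell = ell_star, ...)
  })
  names(refits) <- names(fits)
  list(
    ell = ell_star,
    fits = refits,
    rho = vapply(refits, `[[`, numeric(1), "rho")
  )
}

#' Estimate new/total ratios for every sample of a reads table
#'
#' Runs the two-round mixture estimation sample by sample (one sample = one
#' compartment x timepoint x replicate): free EM fits per region, pooling of
#' the labeling efficiency to the sample median over non-suspect regions,
#' then fixed-efficiency refits of every region's ratio. The unlabeled
#' `time_min == 0` control carries no labeling signal and is skipped.
#'
#' @param reads Reads table (see [read_reads_table()] for the schema).
#' @param err An [error_rates] object.
#' @param ... Passed to [em_fit()].
#' @return Ratio table: `region_id`, `compartment`, `time_min`, `replicate`,
#'   `total_reads`, `rho`, `ell` (pooled), `ell_free`, `suspect`.
#' @export
estimate_ratios <- function(reads, err, ...) {
  .check_columns(reads, c("region_id", "compartment", "time_min", "replicate",
                          "t_count", "conversions"), "reads")
  reads <- reads[reads$time_min > 0, , drop = FALSE]
  if (nrow(reads) == 0) stop("no labeled (time_min > 0) reads supplied")
  sample_key <- interaction(reads$compartment, reads$time_min,
                            reads$replicate, drop = TRUE)
  out <- lapply(split(reads, sample_key), function(sm) {
    by_region <- split(sm, sm$region_id, drop = TRUE)
    fits <- lapply(by_region, em_fit, err = err, ...)
    pooled <- pooled_refit(fits, by_region, err, ...)
    data.frame(
      region_id = names(by_region),
      compartment = sm$compartment[1],
      time_min = sm$time_min[1],
      replicate = sm$replicate[1],
      total_reads = vapply(by_region, function(x) {
        if ("multiplicity" %in% names(x)) sum(x$multiplicity) else nrow(x)
      }, numeric(1)),
      rho = unname(pooled$rho),
      ell = pooled$ell,
      ell_free = vapply(fits, `[[`, numeric(1), "ell"),
      suspect = vapply(fits, `[[`, logical(1), "overfit_suspect"),
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$region_id, res$compartment, res$replicate, res$time_min), ,
      drop = FALSE]
}
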