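#' Thresholds of the reliability criteria
#'
#' Defaults are the published constants: minimum average read count 30,
#' maximum absolute expression slope 0.0025 (fraction of mean expression per
#' minute), maximum relative replicate deviation 0.33, maximum relative
#' credible-bound deviation 0.3, minimum goodness of fit 0.4.
#'
#' @param min_count Minimum average reads per timepoint.
#' @param max_slope Maximum absolute expression-vs-time slope.
#' @param max_rep_dev Maximum `2|x1 - x2| / (x1 + x2)`.
#' @param max_ci_dev Maximum `|2 c / (x1 + x2) - 1|` for both bounds.
#' @param min_R Minimum goodness-of-fit correlation.
#' @return List of class `reliability_thresholds`.
#' @export
reliability_thresholds <- function(min_count = 30, max_slope = 0.0025,
                                   max_rep_dev = 0.33, max_ci_dev = 0.3,
                                   min_R = 0.4) {
  structure(list(min_count = min_count, max_slope = max_slope,
                 max_rep_dev = max_rep_dev, max_ci_dev = max_ci_dev,
                 min_R = min_R), class = "reliability_thresholds")
}

# expression slope of one series: counts normalized to the series mean,
# regressed on time in minutes (dimensionless expression, mean 1)
.expression_slope <- function(time_min, rel_counts) {
  if (length(time_min) < 2) return(NA_real_)
  y <- rel_counts / mean(rel_counts)
  unname(stats::coef(stats::lm(y ~ time_min))[2])
}

#' Apply the five reliability criteria to fitted regions
#'
#' A region's estimate for a compartment is reliable if (1) the average read
#' count per timepoint is at least `min_count` in *both* compartments of
#' both replicate series; (2) expression is constant over the series: the
#' replicate-averaged slope of library-size-normalized, series-mean-scaled
#' counts against time stays within `max_slope` in absolute value; (3) the
#' two replicate rate estimates `x1`, `x2` agree,
#' `2 |x1 - x2| / (x1 + x2) <= max_rep_dev`; (4) each replicate's credible
#' bounds are close to the replicate mean,
#' `|2 c / (x1 + x2) - 1| <= max_ci_dev` for both bounds of both
#' replicates; and (5) both replicate fits reach goodness `R >= min_R`.
#' Cytosolic estimates are reliable only if the nuclear estimate is, since
#' the nuclear rate enters the cytosolic fit.
#'
#' @param counts Data frame with columns `region_id`, `compartment`,
#'   `replicate`, `time_min`, `reads` (the ratio table works after renaming
#'   `total_reads` to `reads`).
#' @param rates_table Per-replicate rates table from [fit_kinetics()].
#' @param thresholds A [reliability_thresholds] object.
#' @return One row per region with per-criterion logical columns (`nuc_*`,
#'   `cyt_*`), the shared `min_count`, and verdicts `reliable_nuclear`,
#'   `reliable_cytosolic`.
#' @export
assess_reliability <- function(counts, rates_table,
                               thresholds = reliability_thresholds()) {
  .check_columns(counts, c("region_id", "compartment", "replicate",
                           "time_min", "reads"), "counts")
  .check_columns(rates_table, c("region_id", "replicate", "nuc_rate",
                                "nuc_ci_low", "nuc_ci_high", "nuc_R",
                                "cyt_rate", "cyt_ci_low", "cyt_ci_high",
                                "cyt_R"), "rates_table")
  stopifnot(inherits(thresholds, "reliability_thresholds"))
  th <- thresholds

  # library-size normalization: counts relative to the sample total
  skey <- paste(counts$compartment, counts$replicate, counts$time_min)
  totals <- tapply(counts$reads, skey, sum)
  counts$rel <- counts$reads / as.numeric(totals[skey])

  reps <- sort(unique(rates_table$replicate))
  out <- lapply(split(counts, counts$region_id), function(cg) {
    g <- cg$region_id[1]
    rg <- rates_table[rates_table$region_id == g, , drop = FALSE]
    rg <- rg[order(rg$replicate), , drop = FALSE]
    both_reps <- nrow(rg) == 2

    # (1) depth, shared between verdicts: every compartment x replicate
    series <- split(cg, paste(cg$compartment, cg$replicate))
    have_all <- length(series) == 2 * length(reps)
    min_count_ok <- have_all &&
      all(vapply(series, function(s) mean(s$reads) >= th$min_count,
                 logical(1)))

    crit <- function(comp) {
      # (2) constant expression, replicate-averaged slope per compartment
      slopes <- vapply(reps, function(r) {
        s <- cg[cg$compartment == comp & cg$replicate == r, , drop = FALSE]
        if (nrow(s) < 2) return(NA_real_)
        .expression_slope(s$time_min, s$rel)
      }, numeric(1))
      const_ok <- !anyNA(slopes) && abs(mean(slopes)) <= th$max_slope

      pre <- paste0(comp, "_")
      x <- rg[[paste0(pre, "rate")]]
      cl <- rg[[paste0(pre, "ci_low")]]
      cu <- rg[[paste0(pre, "ci_high")]]
      R <- rg[[paste0(pre, "R")]]
      if (!both_reps || anyNA(x)) {
        agree_ok <- FALSE
        ci_ok <- FALSE
      } else {
        xs <- sum(x)
        agree_ok <- 2 * abs(x[1] - x[2]) / xs <= th$max_rep_dev
        ci_ok <- !anyNA(c(cl, cu)) &&
          all(abs(2 * cu / xs - 1) <= th$max_ci_dev) &&
          all(abs(2 * cl / xs - 1) <= th$max_ci_dev)
      }
      good_ok <- both_reps && !anyNA(R) && all(R >= th$min_R)
      c(constant_expression = const_ok, replicate_agreement = agree_ok,
        ci_width = ci_ok, goodness = good_ok)
    }
    nuc <- crit("nuc")
    cyt <- crit("cyt")
    reliable_nuc <- min_count_ok && all(nuc)
    reliable_cyt <- reliable_nuc && all(cyt)
    df <- data.frame(region_id = g, min_count = min_count_ok,
                     stringsAsFactors = FALSE)
    for (nm in names(nuc)) df[[paste0("nuc_", nm)]] <- unname(nuc[nm])
    for (nm in names(cyt)) df[[paste0("cyt_", nm)]] <- unname(cyt[nm])
    df$reliable_nuclear <- reliable_nuc
    df$reliable_cytosolic <- reliable_cyt
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
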