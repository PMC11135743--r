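# table schemas shared by readers and writers
.SCHEMAS <- list(
  reads = c("region_id", "compartment", "time_min", "replicate",
            "t_count", "conversions", "multiplicity"),
  ratios = c("region_id", "compartment", "time_min", "replicate",
             "total_reads", "rho"),
  rates = c("region_id", "replicate", "nuc_rate", "nuc_ci_low",
            "nuc_ci_high", "nuc_R", "cyt_rate", "cyt_ci_low", "cyt_ci_high",
            "cyt_R", "nuc_halflife_min", "cyt_halflife_min"),
  retention = c("region_id", "nu_postulated", "r_hat", "retained_fraction",
                "retained_flag")
)

.read_tsv_checked <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.SCHEMAS[[schema]], names(df))
  if (length(missing) > 0)
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the tab-separated pipeline tables
#'
#' All pipeline tables are tab-separated with a header line; unknown extra
#' columns are preserved. Readers validate the schema and basic row
#' invariants and report the offending file and line (1-based, counting the
#' header) on failure.
#'
#' @param path File path.
#' @return The validated data frame (readers) or `path` invisibly (writers).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_reads_table <- function(path) {
  df <- .read_tsv_checked(path, "reads")
  bad <- which(df$conversions > df$t_count | df$conversions < 0 |
                 df$t_count < 0 | df$multiplicity < 1)
  if (length(bad) > 0)
    stop(path, ", line ", bad[1] + 1L,
         ": need 0 <= conversions <= t_count and multiplicity >= 1")
  if (any(!df$compartment %in% c("nuc", "cyt", "wce")))
    stop(path, ": compartment must be one of 'nuc', 'cyt', 'wce'")
  df
}

#' @rdname pipeline_io
#' @param df Table to write.
#' @export
write_reads_table <- function(df, path) {
  .check_columns(df, .SCHEMAS$reads, "reads table")
  .write_tsv(df, path)
}

#' @rdname pipeline_io
#' @export
read_ratio_table <- function(path) {
  df <- .read_tsv_checked(path, "ratios")
  bad <- which(df$rho < 0 | df$rho > 1 | df$total_reads < 1)
  if (length(bad) > 0)
    stop(path, ", line ", bad[1] + 1L,
         ": need rho in [0, 1] and total_reads >= 1")
  df
}

#' @rdname pipeline_io
#' @export
write_ratio_table <- function(df, path) {
  .check_columns(df, .SCHEMAS$ratios, "ratio table")
  .write_tsv(df, path)
}

#' @rdname pipeline_io
#' @export
read_rates_table <- function(path) {
  .read_tsv_checked(path, "rates")
}

#' @rdname pipeline_io
#' @export
write_rates_table <- function(df, path) {
  .check_columns(df, .SCHEMAS$rates, "rates table")
  .write_tsv(df, path)
}

#' @rdname pipeline_io
#' @export
write_retention_table <- function(df, path) {
  .check_columns(df, .SCHEMAS$retention, "retention table")
  .write_tsv(df, path)
}

#' Read region definitions from a BED file
#'
#' BED intervals are 0-based half-open; a strand column is required and
#' every region must have positive width.
#'
#' @param path BED file path.
#' @return A `GRanges` with region names.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop(path, ": malformed BED (",
                                          conditionMessage(e), ")"))
  if (any(BiocGenerics::width(gr) < 1))
    stop(path, ": regions with end <= start are not allowed")
  if (any(as.character(BiocGenerics::strand(gr)) == "*"))
    stop(path, ": a strand ('+'/'-') is required for every region")
  gr
}

#' Pipeline configuration
#'
#' Collects every tunable of the full pipeline; defaults are the published
#' constants (reliability thresholds 30 / 0.0025 / 0.33 / 0.3 / 0.4, masking
#' threshold 5%, labeling-efficiency suspect cutoff 1%).
#'
#' @param p0,epsilon Fallback sequencing error rates, used when no control
#'   mismatch table is available (`p0` is then estimated from the
#'   `time_min = 0` reads; `epsilon` is taken as configured).
#' @param mask_threshold Control conversion rate above which sites are
#'   masked.
#' @param suspect_ell Labeling-efficiency cutoff flagging overfit regions.
#' @param thresholds A [reliability_thresholds] object.
#' @param mcmc An [mcmc_config] object.
#' @param seed Base seed of all stochastic stages.
#' @param verbose Emit per-stage progress messages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(p0 = 0.001, epsilon = 0.01,
                            mask_threshold = 0.05, suspect_ell = 0.01,
                            thresholds = reliability_thresholds(),
                            mcmc = mcmc_config(), seed = 1,
                            verbose = FALSE) {
  stopifnot(inherits(thresholds, "reliability_thresholds"),
            inherits(mcmc, "mcmc_config"))
  structure(list(p0 = p0, epsilon = epsilon,
                 mask_threshold = mask_threshold, suspect_ell = suspect_ell,
                 thresholds = thresholds, mcmc = mcmc, seed = seed,
                 verbose = verbose), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys (`p0`, `epsilon`, `mask_threshold`, `suspect_ell`, `seed`,
#' `verbose`) plus nested `thresholds:` and `mcmc:` blocks whose entries
#' override the respective defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config] object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  th <- do.call(reliability_thresholds, y$thresholds %||% list())
  mc <- do.call(mcmc_config, y$mcmc %||% list())
  args <- y[setdiff(names(y), c("thresholds", "mcmc"))]
  do.call(pipeline_config, c(args, list(thresholds = th, mcmc = mc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage_msg <- function(verbose, ...) {
  if (verbose) message("[slamkinetics] ", ...)
}

#' Run the full estimation pipeline on a reads table
#'
#' Chains the stages: site masking (if a control site table is given),
#' error-rate estimation, per-sample mixture EM with pooled-efficiency
#' refits, sequential nuclear and cytosolic rate fits with MCMC intervals,
#' replicate averaging and reliability assessment; optionally the
#' retention fit and the positive-rate abundance-ratio curve. Fully
#' deterministic given the config seed.
#'
#' @param reads Reads table (or path to one).
#' @param config A [pipeline_config].
#' @param control Optional control mismatch table for
#'   [estimate_error_rates()].
#' @param control_sites Optional per-site control conversion table for
#'   [mask_sites()].
#' @param snp_list Optional SNP position table for [mask_sites()].
#' @param retention_nu_grid Optional grid of postulated nuclear degradation
#'   rates; when given, the retention model is fitted per region.
#' @return List with `error_rates`, `mask`, `ratios`, `rates` (per
#'   replicate), `combined`, `reliability` and optionally `retention`,
#'   `ratio_curve`.
#' @export
run_pipeline <- function(reads, config = pipeline_config(), control = NULL,
                         control_sites = NULL, snp_list = NULL,
                         retention_nu_grid = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(reads)) reads <- read_reads_table(reads)
  .check_columns(reads, c("region_id", "compartment", "time_min",
                          "replicate", "t_count", "conversions"), "reads")

  mask <- NULL
  if (!is.null(control_sites)) {
    mask <- mask_sites(control_sites, snp_list, config$mask_threshold)
    .stage_msg(config$verbose, "mask: ", nrow(mask), " sites masked")
  }

  err <- if (!is.null(control)) {
    estimate_error_rates(control, mask)
  } else {
    ctrl <- reads[reads$time_min == 0, , drop = FALSE]
    if (nrow(ctrl) > 0) {
      m <- if ("multiplicity" %in% names(ctrl)) ctrl$multiplicity else 1
      error_rates(sum(ctrl$conversions * m) / sum(ctrl$t_count * m),
                  config$epsilon)
    } else {
      error_rates(config$p0, config$epsilon)
    }
  }
  .stage_msg(config$verbose, sprintf("error rates: p0 = %.2g, epsilon = %.2g",
                                     err$p0, err$epsilon))

  ratios <- estimate_ratios(reads, err, suspect_ell = config$suspect_ell)
  .stage_msg(config$verbose, "ratios: ", length(unique(ratios$region_id)),
             " regions, ", nrow(ratios), " sample points")

  rates <- fit_kinetics(ratios, config$mcmc, seed = config$seed)
  .stage_msg(config$verbose, "fits: ", sum(!is.na(rates$nuc_rate)),
             " nuclear / ", sum(!is.na(rates$cyt_rate)), " cytosolic of ",
             nrow(rates), " region x replicate fits")

  combined <- combine_replicates(rates)

  counts <- data.frame(region_id = ratios$region_id,
                       compartment = ratios$compartment,
                       replicate = ratios$replicate,
                       time_min = ratios$time_min,
                       reads = ratios$total_reads)
  reliability <- assess_reliability(counts, rates, config$thresholds)
  .stage_msg(config$verbose, "reliability: ",
             sum(reliability$reliable_nuclear), " nuclear / ",
             sum(reliability$reliable_cytosolic), " cytosolic reliable of ",
             nrow(reliability), " regions")

  out <- list(error_rates = err, mask = mask, ratios = ratios,
              rates = rates, combined = combined, reliability = reliability)

  if (!is.null(retention_nu_grid)) {
    ret <- lapply(unique(ratios$region_id), function(g) {
      rep1 <- sort(unique(ratios$replicate))[1]
      obs_of <- function(comp) {
        d <- ratios[ratios$region_id == g & ratios$compartment == comp &
                      ratios$replicate == rep1, ]
        if (nrow(d) == 0) return(NULL)
        data.frame(time_min = d$time_min, rho = d$rho, reads = d$total_reads)
      }
      cfg <- config$mcmc
      cfg$seed <- (config$seed + 31L * match(g, unique(ratios$region_id))) %%
        .Machine$integer.max
      cbind(region_id = g,
            fit_retention(obs_of("nuc"), retention_nu_grid, cfg,
                          cyt_obs = obs_of("cyt")))
    })
    out$retention <- classify_retained(do.call(rbind, ret))
    .stage_msg(config$verbose, "retention: ",
               sum(out$retention$retained_flag), " retained flags")
  }

  ok <- is.finite(combined$nuc_rate) & is.finite(combined$cyt_rate)
  if (sum(ok) > 0) {
    out$ratio_curve <- positive_nu_curve(combined[ok, , drop = FALSE])
  }
  out
}
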