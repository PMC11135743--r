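#' Plane normals of random abundance triplets
#'
#' If whole-cell, nuclear and cytosolic relative abundances `t_g`, `n_g`,
#' `c_g` are scaled to absolute molecule numbers by transcript-independent
#' factors `T`, `N`, `C`, then `T t_g = N n_g + C c_g` for every region, so
#' the direction `(T, N, C)` is orthogonal to every vector
#' `v_g = (t_g, -n_g, -c_g)`. For each draw, three distinct regions are
#' sampled and the unit normal of the plane spanned by their `v_g`
#' (smallest right singular vector of the 3x3 matrix) is recorded,
#' sign-oriented so its first component is positive. Draws whose normal has
#' any non-positive component are discarded; rank-deficient triplets are
#' redrawn and counted.
#'
#' @param triples Data frame with columns `t_rel`, `n_rel`, `c_rel`
#'   (relative abundances; each column a simplex over regions).
#' @param n_draws Number of triplet draws.
#' @param seed Optional seed for reproducible sampling.
#' @return Matrix of kept unit normals (rows), with attributes
#'   `n_degenerate` (redraw count) and `n_discarded` (sign-filtered).
#' @export
triplet_normals <- function(triples, n_draws = 1000, seed = NULL) {
  .check_columns(triples, c("t_rel", "n_rel", "c_rel"), "triples")
  n <- nrow(triples)
  if (n < 3) stop("need at least 3 regions")
  V <- cbind(triples$t_rel, -triples$n_rel, -triples$c_rel)
  .with_seed(seed, {
    kept <- vector("list", n_draws)
    n_deg <- 0L
    n_disc <- 0L
    for (i in seq_len(n_draws)) {
      repeat {
        idx <- sample.int(n, 3)
        s <- svd(V[idx, , drop = FALSE])
        if (s$d[2] > 1e-12 * s$d[1]) break
        n_deg <- n_deg + 1L
        if (n_deg > 100 * n_draws) stop("too many degenerate triplets")
      }
      v <- s$v[, 3]
      if (v[1] < 0) v <- -v
      if (all(v > 0)) kept[[i]] <- v else n_disc <- n_disc + 1L
    }
    out <- do.call(rbind, kept[!vapply(kept, is.null, logical(1))])
    if (is.null(out)) out <- matrix(numeric(0), ncol = 3)
    attr(out, "n_degenerate") <- n_deg
    attr(out, "n_discarded") <- n_disc
    out
  })
}

#' Spherical (geodesic) median of unit vectors
#'
#' Minimizer of the summed great-circle distances on the unit sphere, found
#' by Weiszfeld iteration in the tangent space, started from (and, in tied
#' configurations, resolved by) the normalized Euclidean mean.
#'
#' @param unit_vectors Matrix with one unit vector per row.
#' @param tol Convergence tolerance on the update step.
#' @param max_iter Iteration cap.
#' @return Unit vector (length-3 numeric for 3D input).
#' @export
spherical_median <- function(unit_vectors, tol = 1e-10, max_iter = 1000) {
  X <- as.matrix(unit_vectors)
  if (nrow(X) == 0) stop("no vectors supplied")
  nrm <- sqrt(rowSums(X^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("rows must be unit vectors")
  X <- X / nrm
  m <- colMeans(X)
  if (sqrt(sum(m^2)) < 1e-12)
    stop("degenerate (near-antipodal) configuration: no unique median")
  m <- m / sqrt(sum(m^2))
  for (it in seq_len(max_iter)) {
    cosd <- pmin(pmax(X %*% m, -1), 1)
    d <- acos(cosd)
    far <- d > 1e-12
    if (!any(far)) break
    # tangent-space log map: log_m(x) = d * (x - cos(d) m) / sin(d)
    U <- (X[far, , drop = FALSE] - cosd[far] %*% t(m)) / sin(d[far])
    v <- colSums(U) / sum(1 / d[far])
    step <- sqrt(sum(v^2))
    if (step < tol) break
    m <- cos(step) * m + sin(step) * v / step
    m <- m / sqrt(sum(m^2))
  }
  as.numeric(m)
}

#' Cytosolic/nuclear abundance ratio from a scaling direction
#'
#' The direction of `(T, N, C)` determines the steady-state cytosolic to
#' nuclear RNA amount ratio as `C_total / N_total = v3 / v2` when relative
#' abundances are simplex-normalized per fraction.
#'
#' @param v Unit 3-vector proportional to `(T, N, C)`.
#' @return The ratio `v[3] / v[2]`.
#' @export
cyt_nuc_ratio_from_vector <- function(v) {
  stopifnot(length(v) == 3)
  if (v[2] <= 0 || v[3] <= 0)
    stop("second and third components must be positive")
  v[3] / v[2]
}

#' Triplet spherical-median estimate of the cyt/nuc RNA ratio
#'
#' Convenience driver: [triplet_normals()] then [spherical_median()] then
#' [cyt_nuc_ratio_from_vector()].
#'
#' @inheritParams triplet_normals
#' @return List with `ratio`, `median_vector`, `normals`.
#' @export
estimate_cyt_nuc_ratio <- function(triples, n_draws = 1000, seed = NULL) {
  normals <- triplet_normals(triples, n_draws, seed)
  if (nrow(normals) == 0) stop("no admissible (all-positive) normals found")
  med <- spherical_median(normals)
  list(ratio = cyt_nuc_ratio_from_vector(med), median_vector = med,
       normals = normals)
}

#' Fraction of non-negative implied nuclear degradation rates
#'
#' At steady state the export rate satisfies `tau = q * lam` for an assumed
#' cyt/nuc abundance ratio `q`, so the implied nuclear degradation rate is
#' `nu(q) = (nu + tau) - q * lam`. Because true rates are non-negative, the
#' share of regions with `nu(q) >= 0` — equivalently with
#' `(nu + tau) / lam >= q` — bounds the admissible `q` from above.
#'
#' @param rates_table Data frame with columns `nuc_rate` (nuclear removal)
#'   and `cyt_rate` (cytosolic degradation), both positive.
#' @param q_grid Grid of assumed cyt/nuc ratios.
#' @return Data frame of class `ratio_curve` with columns `q`, `fraction`.
#' @export
positive_nu_curve <- function(rates_table, q_grid = seq(0, 2, by = 0.01)) {
  .check_columns(rates_table, c("nuc_rate", "cyt_rate"), "rates_table")
  ok <- is.finite(rates_table$nuc_rate) & is.finite(rates_table$cyt_rate)
  rt <- rates_table[ok, , drop = FALSE]
  if (nrow(rt) == 0) stop("no regions with finite rates")
  if (any(rt$nuc_rate <= 0) || any(rt$cyt_rate <= 0))
    stop("rates must be positive")
  ratio <- rt$nuc_rate / rt$cyt_rate
  frac <- vapply(q_grid, function(q) mean(ratio >= q), numeric(1))
  structure(data.frame(q = q_grid, fraction = frac),
            class = c("ratio_curve", "data.frame"))
}

#' Largest admissible cyt/nuc ratio on a positive-rate curve
#'
#' The largest grid ratio at which at least `min_fraction` of regions still
#' have a non-negative implied nuclear degradation rate.
#'
#' @param curve A [positive_nu_curve()] result.
#' @param min_fraction Required share of non-negative estimates.
#' @return The admissible ratio `q*`.
#' @export
admissible_q <- function(curve, min_fraction = 0.5) {
  stopifnot(inherits(curve, "ratio_curve"))
  ok <- curve$fraction >= min_fraction
  if (!any(ok)) stop("no grid point reaches the required fraction")
  max(curve$q[ok])
}

#' Spike-in-normalized cyt/nuc RNA ratio per sample pair
#'
#' Endogenous totals are scaled by the spike-in totals of the same library,
#' making the compartments comparable:
#' `ratio = (endogenous_cyt / spike_cyt) / (endogenous_nuc / spike_nuc)`
#' per timepoint- and replicate-matched pair of libraries.
#'
#' @param sample_counts Data frame with columns `compartment` (`nuc`/`cyt`),
#'   `time_min`, `replicate`, `kind` (`endogenous`/`spike`), `count`.
#' @return Data frame with `time_min`, `replicate`, `cyt_nuc_ratio`.
#' @export
spikein_ratio <- function(sample_counts) {
  .check_columns(sample_counts,
                 c("compartment", "time_min", "replicate", "kind", "count"),
                 "sample_counts")
  sc <- sample_counts
  out <- lapply(split(sc, paste(sc$time_min, sc$replicate)), function(s) {
    tot <- function(comp, kind)
      sum(s$count[s$compartment == comp & s$kind == kind])
    sp_c <- tot("cyt", "spike")
    sp_n <- tot("nuc", "spike")
    if (sp_c == 0 || sp_n == 0) stop("zero spike-in totals in a sample pair")
    data.frame(
      time_min = s$time_min[1], replicate = s$replicate[1],
      cyt_nuc_ratio = (tot("cyt", "endogenous") / sp_c) /
        (tot("nuc", "endogenous") / sp_n)
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$replicate, res$time_min), , drop = FALSE]
}
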