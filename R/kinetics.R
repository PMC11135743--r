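#' Metabolic rate set for the two-compartment model
#'
#' Bundles the four first-order rates of the two-compartment model of mRNA
#' metabolism: synthesis (`mu`), nuclear degradation (`nu`), nuclear export
#' (`tau`) and cytosolic degradation (`lam`). Nuclear transcripts are removed
#' at the combined *nuclear removal rate* `nu + tau`, which is the only
#' nuclear parameter identifiable from new/total ratios.
#'
#' All rates are per minute; `mu` is in arbitrary molecule units per minute
#' and defaults to 1 because the new/total ratio curves do not depend on it.
#'
#' @param mu Synthesis rate (molecules/min, arbitrary units).
#' @param nu Nuclear degradation rate (1/min), `>= 0`.
#' @param tau Nuclear export rate (1/min), `>= 0`.
#' @param lam Cytosolic degradation rate (1/min), `> 0`.
#' @return An object of class `two_comp_rates`.
#' @examples
#' r <- two_comp_rates(tau = ln2_over(300), lam = ln2_over(45))
#' steady_state(r)
#' @export
two_comp_rates <- function(mu = 1, nu = 0, tau, lam) {
  stopifnot(is.numeric(mu), is.numeric(nu), is.numeric(tau), is.numeric(lam))
  if (nu < 0 || tau < 0) stop("'nu' and 'tau' must be non-negative")
  if (lam <= 0) stop("'lam' must be positive")
  if (nu + tau <= 0) stop("nuclear removal rate 'nu + tau' must be positive")
  structure(list(mu = mu, nu = nu, tau = tau, lam = lam),
            class = "two_comp_rates")
}

#' @export
print.two_comp_rates <- function(x, ...) {
  cat("Two-compartment rates (1/min):\n")
  cat(sprintf("  mu = %g, nu = %g, tau = %g, lam = %g\n", x$mu, x$nu, x$tau, x$lam))
  cat(sprintf("  nuclear removal nu+tau = %g (half-life %.1f min)\n",
              x$nu + x$tau, half_life(x$nu + x$tau)))
  cat(sprintf("  cytosolic half-life %.1f min\n", half_life(x$lam)))
  invisible(x)
}

# relative threshold below which Eq. (4) switches to its equal-rates limit
.DEGENERATE_REL_TOL <- 1e-8

#' Nuclear new/total RNA ratio
#'
#' Fraction of nuclear transcripts synthesized since labeling onset,
#' `n(t) = 1 - exp(-(nu+tau) t)`. Depends on the nuclear removal rate only.
#'
#' @param rate_nuc_removal Nuclear removal rate `nu + tau` (1/min), `> 0`.
#' @param t Time since labeling onset (minutes), `>= 0`. Vectorized.
#' @return Fraction in `[0, 1]`.
#' @export
nuclear_new_total <- function(rate_nuc_removal, t) {
  if (any(rate_nuc_removal <= 0)) stop("nuclear removal rate must be positive")
  if (any(t < 0)) stop("'t' must be non-negative")
  -expm1(-rate_nuc_removal * t)
}

#' Cytosolic new/total RNA ratio
#'
#' Fraction of cytosolic transcripts synthesized since labeling onset,
#' `c(t) = 1 - (lam exp(-(nu+tau) t) - (nu+tau) exp(-lam t)) / (lam - (nu+tau))`.
#' The expression is symmetric in the two rates; when they are (numerically)
#' equal the limit form `1 - (1 + k t) exp(-k t)` is used, since the printed
#' quotient is unstable near the degeneracy.
#'
#' @param rate_nuc_removal Nuclear removal rate `nu + tau` (1/min), `> 0`.
#' @param rate_cyt_deg Cytosolic degradation rate `lam` (1/min), `> 0`.
#' @param t Time since labeling onset (minutes), `>= 0`. Vectorized.
#' @return Fraction in `[0, 1]`.
#' @export
cytosolic_new_total <- function(rate_nuc_removal, rate_cyt_deg, t) {
  a <- rate_nuc_removal
  l <- rate_cyt_deg
  stopifnot(length(a) == 1L, length(l) == 1L)
  if (a <= 0 || l <= 0) stop("rates must be positive")
  if (any(t < 0)) stop("'t' must be non-negative")
  if (abs(l - a) < .DEGENERATE_REL_TOL * max(l, a)) {
    k <- (a + l) / 2
    res <- 1 - (1 + k * t) * exp(-k * t)
  } else {
    res <- 1 - (l * exp(-a * t) - a * exp(-l * t)) / (l - a)
  }
  pmin(pmax(res, 0), 1)
}

#' Solve the two-compartment abundances of new RNA
#'
#' Closed-form solution of the labeled (new) RNA abundances with initial
#' conditions `N(0) = C(0) = 0`:
#' `N(t) = N_inf (1 - exp(-(nu+tau) t))` and `C(t) = C_inf c(t)`.
#'
#' @param rates A [two_comp_rates] object.
#' @param t Times (minutes). Vectorized.
#' @return A data frame with columns `time_min`, `N`, `C`.
#' @export
solve_abundances <- function(rates, t) {
  stopifnot(inherits(rates, "two_comp_rates"))
  ss <- steady_state(rates)
  k <- rates$nu + rates$tau
  data.frame(
    time_min = t,
    N = ss[["N_inf"]] * nuclear_new_total(k, t),
    C = ss[["C_inf"]] * cytosolic_new_total(k, rates$lam, t)
  )
}

#' Steady-state nuclear and cytosolic abundances
#'
#' `N_inf = mu / (nu + tau)` and `C_inf = (tau / lam) N_inf`, so the
#' steady-state cytosolic/nuclear abundance ratio is `tau / lam`.
#'
#' @param rates A [two_comp_rates] object.
#' @return Named numeric vector `c(N_inf, C_inf)`.
#' @export
steady_state <- function(rates) {
  stopifnot(inherits(rates, "two_comp_rates"))
  n_inf <- rates$mu / (rates$nu + rates$tau)
  c(N_inf = n_inf, C_inf = rates$tau / rates$lam * n_inf)
}

#' Convert between first-order rates and half-lives
#'
#' `half_life(rate) = log(2) / rate` (minutes); `rate_from_half_life` is its
#' inverse. The nuclear half-life is `log(2) / (nu + tau)`, the cytosolic
#' half-life `log(2) / lam`.
#'
#' @param rate First-order rate (1/min), `> 0`. Vectorized.
#' @return Half-life in minutes.
#' @export
half_life <- function(rate) {
  if (any(rate <= 0)) stop("'rate' must be positive")
  log(2) / rate
}

#' @rdname half_life
#' @param hl Half-life (minutes), `> 0`. Vectorized.
#' @export
rate_from_half_life <- function(hl) {
  if (any(hl <= 0)) stop("'hl' must be positive")
  log(2) / hl
}

#' @rdname half_life
#' @param x Half-life (minutes); convenience alias `ln2_over(x) == log(2)/x`.
#' @export
ln2_over <- function(x) log(2) / x

#' Numerically integrate the two-compartment ODE system
#'
#' Runge-Kutta integration of `dN/dt = mu - (nu+tau) N`,
#' `dC/dt = tau N - lam C` with `N(0) = C(0) = 0`, used as an independent
#' oracle for the closed forms. Optionally integrates the three-pool
#' retention model (mobile + retained nuclear pools).
#'
#' @param rates A [two_comp_rates] object, or a [retention_params] object.
#' @param times Output times (minutes); must include 0.
#' @return Data frame with `time_min`, `N`, `C` (retention model: also `M`,
#'   `Q` with `N = M + Q`).
#' @export
ode_abundances <- function(rates, times) {
  if (times[1] != 0) times <- c(0, times)
  if (inherits(rates, "retention_params")) {
    deriv <- function(t, y, p) {
      list(c(
        M = p$mu * (1 - p$r) - (p$nu + p$tau) * y[["M"]],
        Q = p$mu * p$r - p$nu * y[["Q"]],
        C = p$tau * y[["M"]] - p$lam * y[["C"]]
      ))
    }
    y0 <- c(M = 0, Q = 0, C = 0)
    out <- deSolve::ode(y0, times, deriv, rates, method = "ode45",
                        rtol = 1e-10, atol = 1e-12)
    out <- as.data.frame(out)
    data.frame(time_min = out$time, M = out$M, Q = out$Q,
               N = out$M + out$Q, C = out$C)
  } else {
    stopifnot(inherits(rates, "two_comp_rates"))
    deriv <- function(t, y, p) {
      list(c(
        N = p$mu - (p$nu + p$tau) * y[["N"]],
        C = p$tau * y[["N"]] - p$lam * y[["C"]]
      ))
    }
    y0 <- c(N = 0, C = 0)
    out <- deSolve::ode(y0, times, deriv, rates, method = "ode45",
                        rtol = 1e-10, atol = 1e-12)
    out <- as.data.frame(out)
    data.frame(time_min = out$time, N = out$N, C = out$C)
  }
}
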