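#' Twist-defect coordinate from phosphate-progress series
#'
#' The tracking-strand defect size at SHL2 is the difference between the
#' phosphate progress at SHL1.5 and SHL2.5 plus 1 nt (the reference
#' remodeler-bound conformation already carries a +1 nt defect there):
#' `d2 = s15 - s25 + 1`.
#'
#' @param s15,s25 equal-length numeric vectors of phosphate progress (nt) at
#'   SHL1.5 and SHL2.5, or a `defect_series` object in `s15` (then `s25` is
#'   taken from it).
#' @return numeric vector `d2` (nt).
#' @export
defect_coordinate <- function(s15, s25 = NULL) {
  if (inherits(s15, "defect_series")) {
    ser <- s15
    s15 <- ser$s15
    s25 <- ser$s25
  }
  if (length(s15) != length(s25))
    stop("s15 and s25 differ in length")
  s15 - s25 + 1
}

#' Free-energy cost of the +1 nt twist defect
#'
#' Estimates `dF = -log P(d2 > 0.5) + log P(d2 < 0.5)` (in kBT, natural log)
#' from a sample of defect coordinates: the log-odds of the defect-formed
#' state (d2 above the 0.5 nt threshold) versus the defect-free state.
#' Samples exactly at 0.5 are excluded from both events. The standard error
#' is the binomial (delta-method) value `sqrt(1/n_above + 1/n_below)`.
#'
#' @param d2 numeric vector of defect coordinates (nt).
#' @param threshold event threshold in nt (0.5).
#' @return list with `dF` (kBT; `Inf`/`-Inf` when one tail is empty), `se`,
#'   `n_above`, `n_below`, and `finite` (FALSE flags an empty tail).
#' @export
defect_cost_estimate <- function(d2, threshold = 0.5) {
  d2 <- d2[is.finite(d2)]
  n_above <- sum(d2 > threshold)
  n_below <- sum(d2 < threshold)
  if (n_above == 0L || n_below == 0L) {
    return(list(dF = if (n_above == 0L) Inf else -Inf, se = NA_real_,
                n_above = n_above, n_below = n_below, finite = FALSE))
  }
  list(dF = log(n_below / n_above),
       se = sqrt(1 / n_above + 1 / n_below),
       n_above = n_above, n_below = n_below, finite = TRUE)
}

#' Histogram free-energy profile along the defect coordinate
#'
#' `-log` of the binned density of `d2`, shifted so the minimum is 0; a
#' small utility for inspecting defect landscapes.
#'
#' @param d2 numeric vector of defect coordinates.
#' @param bin_width histogram bin width in nt (default 0.05).
#' @return data.frame with bin `mid` (nt) and `F` (kBT; `Inf` in empty bins).
#' @export
defect_free_energy_profile <- function(d2, bin_width = 0.05) {
  rng <- range(d2)
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                ceiling(rng[2] / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(d2, breaks = breaks, plot = FALSE)
  F <- -log(h$density)
  data.frame(mid = h$mids, F = F - min(F[is.finite(F)]))
}

#' Gaussian fit of defect-cost change versus tract location
#'
#' Fits `ddF(k) = A exp(-(k - mu)^2 / (2 sigma^2))` to samples of the change
#' in +1 nt defect free energy as a function of poly(dA:dT) tract location
#' `k` (bp relative to the dyad, tract centre convention) by seeded
#' multistart nonlinear least squares.
#'
#' @param k numeric vector of tract locations (bp).
#' @param ddF numeric vector of defect-cost changes (kBT).
#' @param n_starts number of jittered restarts around moment estimates.
#' @param seed integer seed for the restart jitter.
#' @return list with `A`, `mu`, `sigma`, `rms_residual`, `degenerate`
#'   (TRUE when the input carries no peak) and the `fit` object.
#' @export
fit_gaussian_cost <- function(k, ddF, n_starts = 5L, seed = 1L) {
  stopifnot(length(k) == length(ddF))
  if (length(k) < 4L) stop("need at least 4 points spanning the peak")
  if (max(ddF) - min(ddF) <= 1e-12 || max(abs(ddF)) <= 1e-12) {
    return(list(A = 0, mu = NA_real_, sigma = NA_real_,
                rms_residual = stats::sd(ddF), degenerate = TRUE, fit = NULL))
  }
  set.seed(seed)
  w <- pmax(ddF, 0)
  mu0 <- if (sum(w) > 0) sum(k * w) / sum(w) else mean(k)
  sd0 <- if (sum(w) > 0) sqrt(sum(w * (k - mu0)^2) / sum(w)) else stats::sd(k)
  sd0 <- max(sd0, diff(range(k)) / 20, 0.5)
  A0 <- max(ddF)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- list(A = A0 * stats::runif(1, 0.8, 1.2),
                  mu = mu0 + stats::rnorm(1, 0, if (s == 1L) 0 else sd0 / 2),
                  sigma = sd0 * stats::runif(1, if (s == 1L) 1 else 0.5,
                                             if (s == 1L) 1 else 2))
    fit <- tryCatch(
      minpack.lm::nlsLM(ddF ~ A * exp(-(k - mu)^2 / (2 * sigma^2)),
                        start = start,
                        lower = c(A = 0, mu = -Inf, sigma = 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Gaussian fit failed to converge from all starts")
  cf <- stats::coef(best$fit)
  list(A = unname(cf["A"]), mu = unname(cf["mu"]),
       sigma = abs(unname(cf["sigma"])),
       rms_residual = sqrt(best$rss / length(k)),
       degenerate = FALSE, fit = best$fit)
}

#' Linear fit of Gaussian width versus tract length
#'
#' Ordinary least squares of the fitted defect-cost width `sigma_L` on tract
#' length `L`; the kinetic model uses the resulting line (default
#' `sigma = 0.22 L + 1.1` bp) to set the width of the tract-induced cost.
#'
#' @param L integer vector of tract lengths (bp), at least 2 distinct.
#' @param sigma fitted Gaussian widths (bp), same length.
#' @return list with `slope`, `intercept` and the `lm` fit.
#' @export
fit_sigma_vs_length <- function(L, sigma) {
  stopifnot(length(L) == length(sigma))
  if (length(unique(L)) < 2L)
    stop("need at least two distinct tract lengths")
  fit <- stats::lm(sigma ~ L)
  cf <- stats::coef(fit)
  list(slope = unname(cf["L"]), intercept = unname(cf["(Intercept)"]),
       fit = fit)
}
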