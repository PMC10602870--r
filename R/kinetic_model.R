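#' Parameter containers for the sliding kinetic model
#'
#' The model describes remodeler-driven back-and-forth nucleosome sliding on
#' a 1-bp grid `i = -N/2 .. N/2` (N + 1 = 225 sites by default, the DNA
#' length; the precise length does not matter for central positions).
#' Three ingredient energies, all in kBT:
#'
#' * the sequence positioning landscape `F(i) = -(A/2) cos(2 pi (i - i0) /
#'   period)`, amplitude `A = 10` kBT and period `10.5` bp (= 147/14) for a
#'   601-like sequence;
#' * the cost of forming the +1 nt twist-defect intermediate at the engaged
#'   SHL2, raised by a poly(dA:dT) tract by a Gaussian of height 2 kBT
#'   centred at tract location `k = -21` bp with width `sigma = 0.22 L +
#'   1.1` bp (SHL+2 uses the mirrored Gaussian at +21 bp, by nucleosome
#'   symmetry);
#' * the ATP hydrolysis free energy `dF_ATP = 20` kBT driving sliding from
#'   the engaged SHL2 toward the dyad.
#'
#' @param amplitude peak-to-trough landscape range A in kBT.
#' @param period landscape periodicity in bp.
#' @param optimum optimal (minimum-energy) position i0 in bp.
#' @return `landscape_params()`, `defect_cost_model()` and
#'   `kinetic_params()` return plain parameter lists of matching class.
#' @export
landscape_params <- function(amplitude = 10, period = 10.5, optimum = 0) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (period <= 0) stop("period must be > 0")
  structure(list(amplitude = amplitude, period = period, optimum = optimum),
            class = "landscape_params")
}

#' @rdname landscape_params
#' @param height Gaussian height of the tract-induced defect cost (kBT).
#' @param center tract location of the SHL-2 cost peak (bp, default -21).
#' @param sigma_slope,sigma_intercept linear width law `sigma(L) =
#'   sigma_slope * L + sigma_intercept` (bp).
#' @param tract_length poly(dA:dT) tract length L in bp, or `NULL` for no
#'   tract (zero added cost).
#' @param tract_x initial tract location x in bp relative to the dyad
#'   (tract-centre convention).
#' @export
defect_cost_model <- function(height = 2, center = -21, sigma_slope = 0.22,
                              sigma_intercept = 1.1, tract_length = NULL,
                              tract_x = NULL) {
  if (height < 0) stop("height must be >= 0")
  if (!is.null(tract_length)) {
    if (is.null(tract_x)) stop("tract_x required when tract_length is given")
    if (sigma_slope * tract_length + sigma_intercept <= 0)
      stop("sigma(L) must be > 0")
  }
  structure(list(height = height, center = center, sigma_slope = sigma_slope,
                 sigma_intercept = sigma_intercept,
                 tract_length = tract_length, tract_x = tract_x),
            class = "defect_cost_model")
}

#' @rdname landscape_params
#' @param dF_atp ATP hydrolysis free energy in kBT.
#' @param D overall rate constant (inverse time).
#' @param N grid half-width parameter; positions are `-N/2 .. N/2`
#'   (`N` even, `N + 1` sites; default 224 for a 225-bp DNA).
#' @export
kinetic_params <- function(dF_atp = 20, D = 1, N = 224L) {
  if (N %% 2L != 0L) stop("N must be even")
  if (D <= 0) stop("D must be > 0")
  structure(list(dF_atp = dF_atp, D = D, N = as.integer(N)),
            class = "kinetic_params")
}

#' Sinusoidal positioning free energy
#'
#' `F(i) = -(A/2) cos(2 pi (i - i0) / period)` in kBT; `i` may be any real
#' value (the landscape is continuous, nucleosome positions sit on the
#' integer grid).
#'
#' @param i numeric vector of positions (bp).
#' @param land a [landscape_params()].
#' @return numeric vector of energies (kBT).
#' @export
positioning_free_energy <- function(i, land = landscape_params()) {
  -(land$amplitude / 2) * cos(2 * pi * (i - land$optimum) / land$period)
}

#' Gaussian width of the tract defect cost
#' @param model a [defect_cost_model()].
#' @return sigma(L) in bp.
#' @export
defect_sigma <- function(model) {
  model$sigma_slope * model$tract_length + model$sigma_intercept
}

#' Position-dependent twist-defect cost at SHL-2 or SHL+2
#'
#' With the nucleosome at position `i` and a tract initially at `x`, the
#' tract sits at `k = x - i` relative to the dyad. The added defect cost at
#' SHL-2 is `height * exp(-(k - center)^2 / (2 sigma(L)^2))` (peak at
#' `k = -21` bp); SHL+2 uses the mirror Gaussian centred at `-center`.
#' Without a tract the cost is 0 everywhere.
#'
#' @param i numeric vector of nucleosome positions (bp).
#' @param model a [defect_cost_model()].
#' @param side `-2` (SHL-2) or `+2` (SHL+2).
#' @return numeric vector of added defect costs (kBT).
#' @export
defect_cost <- function(i, model = defect_cost_model(), side = -2) {
  if (!side %in% c(-2, 2)) stop("side must be -2 or +2")
  if (is.null(model$tract_length)) return(rep(0, length(i)))
  k <- model$tract_x - i
  mu <- if (side == -2) model$center else -model$center
  model$height * exp(-(k - mu)^2 / (2 * defect_sigma(model)^2))
}

#' Sliding rate table over the position grid
#'
#' For each transition `i -> i + 1` the four elementary rates: ATP-driven
#' sliding toward the dyad from the engaged SHL2 (forward from SHL+2,
#' backward from SHL-2) and spontaneous back-sliding away from it. Each rate
#' carries the Arrhenius penalty of forming the +1 nt defect at the engaged
#' SHL2 and a symmetric square-root split of the landscape difference; the
#' ATP factor `exp(+dF_ATP/kBT)` multiplies the two driven rates so that
#' driven sliding dominates back-sliding (the factor cancels from the
#' steady-state ratio, so equilibrium positions do not depend on it).
#' Totals use the dominant-term form `k(i+1|i) = k(i+1|i, shl+2)`,
#' `k(i|i+1) = k(i|i+1, shl-2)` (exact two-term sums via
#' `exact_totals = TRUE` change nothing perceptible at `dF_ATP = 20`).
#'
#' @param params a [kinetic_params()].
#' @param land a [landscape_params()].
#' @param model a [defect_cost_model()].
#' @param exact_totals include the spontaneous back-sliding terms in the
#'   totals instead of the dominant-term approximation.
#' @return data.frame with one row per bond `i -> i+1`: `i`, the four
#'   elementary rates `k_fwd_shl2p`, `k_back_shl2m`, `k_back_shl2p`,
#'   `k_fwd_shl2m`, and totals `k_fwd`, `k_back`.
#' @export
sliding_rates <- function(params = kinetic_params(),
                          land = landscape_params(),
                          model = defect_cost_model(),
                          exact_totals = FALSE) {
  half <- params$N %/% 2L
  i <- seq(-half, half - 1L)            # bonds i -> i+1
  Fi <- positioning_free_energy(i, land)
  Fi1 <- positioning_free_energy(i + 1L, land)
  dp2_i <- defect_cost(i, model, side = +2)
  dm2_i1 <- defect_cost(i + 1L, model, side = -2)
  atp <- exp(params$dF_atp)
  k_fwd_shl2p <- params$D * exp(-dp2_i) * exp(-(Fi1 - Fi) / 2) * atp
  k_back_shl2m <- params$D * exp(-dm2_i1) * exp(-(Fi - Fi1) / 2) * atp
  k_back_shl2p <- params$D * exp(-dp2_i) * exp(-(Fi - Fi1) / 2)
  k_fwd_shl2m <- params$D * exp(-dm2_i1) * exp(-(Fi1 - Fi) / 2)
  if (exact_totals) {
    k_fwd <- k_fwd_shl2p + k_fwd_shl2m
    k_back <- k_back_shl2m + k_back_shl2p
  } else {
    k_fwd <- k_fwd_shl2p
    k_back <- k_back_shl2m
  }
  data.frame(i = i, k_fwd_shl2p = k_fwd_shl2p, k_back_shl2m = k_back_shl2m,
             k_back_shl2p = k_back_shl2p, k_fwd_shl2m = k_fwd_shl2m,
             k_fwd = k_fwd, k_back = k_back)
}

#' Closed-form steady state of the sliding master equation
#'
#' Builds `p_eq` from cumulative products of the detailed ratio
#' `p(i+1)/p(i) = exp(-(dFd+2(i) - dFd-2(i+1) + F(i+1) - F(i)))`,
#' accumulated in log space from the left grid edge and normalized
#' (reflecting boundaries). Independent of `D` and `dF_ATP` by construction.
#'
#' @inheritParams sliding_rates
#' @return data.frame with `i` and `p_eq` (sums to 1).
#' @export
steady_state_closed_form <- function(params = kinetic_params(),
                                     land = landscape_params(),
                                     model = defect_cost_model()) {
  half <- params$N %/% 2L
  i <- seq(-half, half - 1L)
  dlog <- -(defect_cost(i, model, +2) - defect_cost(i + 1L, model, -2) +
              positioning_free_energy(i + 1L, land) -
              positioning_free_energy(i, land))
  logp <- c(0, cumsum(dlog))
  logp <- logp - max(logp)
  p <- exp(logp)
  data.frame(i = seq(-half, half), p_eq = p / sum(p))
}

# Tridiagonal generator K of dP/dt = K P (columns sum to zero).
build_generator <- function(rates) {
  n <- nrow(rates) + 1L
  K <- matrix(0, n, n)
  for (b in seq_len(nrow(rates))) {
    K[b + 1L, b] <- K[b + 1L, b] + rates$k_fwd[b]
    K[b, b + 1L] <- K[b, b + 1L] + rates$k_back[b]
  }
  diag(K) <- -colSums(K)
  K
}

#' Evolve the sliding master equation in time
#'
#' Propagates `dP/dt = K P` by exact linear propagation (matrix exponential
#' of the tridiagonal generator), which conserves probability to machine
#' precision and is unconditionally stable at the enormous driven rates.
#'
#' @param p0 initial probability vector over the `N + 1` grid sites.
#' @param times increasing vector of output times (in units of `1/D`).
#' @inheritParams sliding_rates
#' @return list with `times`, `P` (matrix, one column per time point, sites
#'   in rows) and `i` (grid positions).
#' @export
evolve_master_equation <- function(p0, times, params = kinetic_params(),
                                   land = landscape_params(),
                                   model = defect_cost_model()) {
  rates <- sliding_rates(params, land, model)
  K <- build_generator(rates)
  n <- nrow(K)
  if (length(p0) != n) stop("p0 must have length ", n)
  if (abs(sum(p0) - 1) > 1e-9 || any(p0 < 0))
    stop("p0 must be a probability vector")
  times <- sort(times)
  P <- matrix(NA_real_, n, length(times))
  p <- p0
  tprev <- 0
  for (j in seq_along(times)) {
    dt <- times[j] - tprev
    if (dt > 0) {
      E <- as.matrix(Matrix::expm(Matrix::Matrix(K * dt)))
      p <- as.numeric(E %*% p)
    }
    if (any(p < -1e-9))
      stop("propagation produced negative probabilities (instability)")
    p <- pmax(p, 0)
    p <- p / sum(p)
    P[, j] <- p
    tprev <- times[j]
  }
  half <- params$N %/% 2L
  list(times = times, P = P, i = seq(-half, half))
}

#' Steady state by long-time evolution
#'
#' Time-evolution oracle for [steady_state_closed_form()]: squares the
#' one-step propagator (time doubling) until the distribution stops moving.
#'
#' @inheritParams sliding_rates
#' @param tol L1 convergence tolerance between successive doublings.
#' @param max_doublings cap on time doublings.
#' @return data.frame with `i` and `p_eq`.
#' @export
steady_state_evolved <- function(params = kinetic_params(),
                                 land = landscape_params(),
                                 model = defect_cost_model(),
                                 tol = 1e-12, max_doublings = 80L) {
  rates <- sliding_rates(params, land, model)
  K <- build_generator(rates)
  n <- nrow(K)
  t0 <- 1 / max(abs(diag(K)))
  E <- as.matrix(Matrix::expm(Matrix::Matrix(K * t0)))
  p <- rep(1 / n, n)
  for (d in seq_len(max_doublings)) {
    pn <- as.numeric(E %*% p)
    pn <- pmax(pn, 0)
    pn <- pn / sum(pn)
    moved <- sum(abs(pn - p))
    p <- pn
    E <- E %*% E
    E <- sweep(E, 2L, colSums(E), `/`)   # re-stochasticize roundoff
    if (moved < tol && d > 5L) break
  }
  half <- params$N %/% 2L
  data.frame(i = seq(-half, half), p_eq = p)
}

#' Effective free energy from steady-state occupancies
#'
#' `F_eff(i) = -kBT log p_eq(i)`, anchored so `F_eff(0) = F(0)` (additive
#' constants are unobservable). The returned landscape also carries the
#' ingredient terms so the defining recursion `F_eff(i+1) - F_eff(i) =
#' dFd+2(i) - dFd-2(i+1) + F(i+1) - F(i)` can be checked directly
#' ([feff_recursion_residual()]).
#'
#' @inheritParams sliding_rates
#' @param p_eq optional precomputed steady state data.frame (`i`, `p_eq`);
#'   computed by [steady_state_closed_form()] when omitted.
#' @return object of class `effective_landscape`: data.frame with `i`, `F`,
#'   `dFd_m2`, `dFd_p2`, `p_eq`, `F_eff`.
#' @export
effective_landscape <- function(params = kinetic_params(),
                                land = landscape_params(),
                                model = defect_cost_model(),
                                p_eq = NULL) {
  if (is.null(p_eq)) p_eq <- steady_state_closed_form(params, land, model)
  i <- p_eq$i
  if (any(p_eq$p_eq <= 0)) stop("steady state contains zero probabilities")
  F <- positioning_free_energy(i, land)
  F_eff <- -log(p_eq$p_eq)
  F_eff <- F_eff - F_eff[i == 0] + F[i == 0]
  out <- data.frame(i = i, F = F,
                    dFd_m2 = defect_cost(i, model, -2),
                    dFd_p2 = defect_cost(i, model, +2),
                    p_eq = p_eq$p_eq, F_eff = F_eff)
  structure(out, class = c("effective_landscape", "data.frame"),
            land = land, model = model, params = params)
}

#' @rdname effective_landscape
#' @param el an `effective_landscape`.
#' @return `feff_recursion_residual()`: maximum absolute deviation of
#'   `F_eff` increments from the defining recursion.
#' @export
feff_recursion_residual <- function(el) {
  n <- nrow(el)
  lhs <- el$F_eff[-1] - el$F_eff[-n]
  rhs <- el$dFd_p2[-n] - el$dFd_m2[-1] + el$F[-1] - el$F[-n]
  max(abs(lhs - rhs))
}

#' Remodeling barrier metrics
#'
#' `dF10 = F_eff(-10) - F_eff(0)`, the overall barrier for the favoured
#' 10-bp shift toward the TA-poor side, and `dF1 = F_eff(-1) - F_eff(0)`,
#' the initial barrier reflecting only the starting defect-cost asymmetry.
#'
#' @param el an [effective_landscape()].
#' @return named numeric vector `c(dF10, dF1)` in kBT.
#' @export
barrier_metrics <- function(el) {
  f <- function(pos) {
    j <- which(el$i == pos)
    if (length(j) != 1L) stop("grid does not cover position ", pos)
    el$F_eff[j]
  }
  c(dF10 = f(-10L) - f(0L), dF1 = f(-1L) - f(0L))
}

#' Barrier heatmaps over tract location and length
#'
#' Computes one effective landscape per (tract location `x`, tract length
#' `L`) pair and collects the two barrier metrics into matrices (rows = `L`,
#' columns = `x`), the machinery behind location-by-length barrier maps.
#'
#' @param x_grid numeric vector of initial tract locations (bp).
#' @param L_grid integer vector of tract lengths (bp).
#' @inheritParams sliding_rates
#' @param cost_template a [defect_cost_model()] whose height/centre/width
#'   law is reused for every tract.
#' @return list of matrices `dF10` and `dF1` with dimnames (L, x).
#' @export
barrier_heatmap <- function(x_grid, L_grid, params = kinetic_params(),
                            land = landscape_params(),
                            cost_template = defect_cost_model()) {
  M10 <- M1 <- matrix(NA_real_, length(L_grid), length(x_grid),
                      dimnames = list(L_grid, x_grid))
  for (a in seq_along(L_grid)) {
    for (b in seq_along(x_grid)) {
      model <- defect_cost_model(
        height = cost_template$height, center = cost_template$center,
        sigma_slope = cost_template$sigma_slope,
        sigma_intercept = cost_template$sigma_intercept,
        tract_length = L_grid[a], tract_x = x_grid[b])
      bm <- barrier_metrics(effective_landscape(params, land, model))
      M10[a, b] <- bm["dF10"]
      M1[a, b] <- bm["dF1"]
    }
  }
  list(dF10 = M10, dF1 = M1)
}
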