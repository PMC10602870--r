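test_that("sinusoidal landscape evaluates the defining formula", {
  land <- landscape_params()
  expect_equal(positioning_free_energy(0, land), -5)
  expect_equal(positioning_free_energy(10.5 / 2, land), 5)
  expect_equal(positioning_free_energy(10, land), -5 * cos(2 * pi * 10 / 10.5))
  expect_equal(positioning_free_energy(10, land), -4.778, tolerance = 1e-3)
  # shifted optimum moves the minimum
  land2 <- landscape_params(optimum = 3)
  expect_equal(positioning_free_energy(3, land2), -5)
})

test_that("tract defect cost is a Gaussian at k = -21 with sigma(L)", {
  m <- defect_cost_model(tract_length = 10L, tract_x = 0)
  # nucleosome position i puts the tract at k = x - i
  expect_equal(defect_cost(21, m, -2), 2)          # k = -21: full 2 kBT
  expect_equal(defect_cost(-21, m, +2), 2)         # mirrored peak at +21
  expect_equal(defect_sigma(m), 0.22 * 10 + 1.1)
  expect_equal(defect_cost(21 + defect_sigma(m), m, -2), 2 * exp(-0.5),
               tolerance = 1e-12)
  # no tract: zero cost everywhere
  m0 <- defect_cost_model()
  expect_equal(defect_cost(-50:50, m0, -2), rep(0, 101))
  expect_error(defect_cost(0, m, side = 3), "side")
})

test_that("rates are unbiased on a flat landscape and obey the ratio law", {
  flat <- landscape_params(amplitude = 0)
  r <- sliding_rates(land = flat, model = defect_cost_model())
  expect_equal(r$k_fwd, r$k_back)
  # ratio independent of D and dF_ATP, equal to the printed expression
  land <- landscape_params()
  m <- defect_cost_model(tract_length = 8L, tract_x = -25)
  r1 <- sliding_rates(kinetic_params(dF_atp = 20, D = 1), land, m)
  r2 <- sliding_rates(kinetic_params(dF_atp = 7, D = 13), land, m)
  expect_equal(r1$k_fwd / r1$k_back, r2$k_fwd / r2$k_back, tolerance = 1e-10)
  i <- r1$i
  expected <- exp(-(defect_cost(i, m, +2) - defect_cost(i + 1, m, -2))) *
    exp(-(positioning_free_energy(i + 1, land) -
            positioning_free_energy(i, land)))
  expect_equal(r1$k_fwd / r1$k_back, expected, tolerance = 1e-10)
  # a 2 kBT defect at the engaged SHL scales that rate by e^-2
  m2 <- defect_cost_model(tract_length = 10L, tract_x = -21)
  r3 <- sliding_rates(land = flat, model = m2)
  r0 <- sliding_rates(land = flat, model = defect_cost_model())
  j <- which(r3$i == 0L)   # tract at k = -21 when i = 0
  expect_equal(r3$k_back_shl2m[j - 1L] / r0$k_back_shl2m[j - 1L], exp(-2),
               tolerance = 1e-10)
})

test_that("closed-form steady state matches Boltzmann limits", {
  # flat landscape, no tract: uniform occupancy
  ss0 <- steady_state_closed_form(land = landscape_params(amplitude = 0))
  expect_equal(ss0$p_eq, rep(1 / 225, 225), tolerance = 1e-12)
  # default 601 landscape: occupancy ratio between optimum and half-period
  ss <- steady_state_closed_form()
  expect_equal(sum(ss$p_eq), 1)
  land <- landscape_params()
  expect_equal(ss$p_eq[ss$i == 0] / ss$p_eq[ss$i == 5],
               exp(positioning_free_energy(5, land) -
                     positioning_free_energy(0, land)),
               tolerance = 1e-10)
  # ATP-free limit with no defects: exact Boltzmann distribution
  ssb <- steady_state_closed_form(kinetic_params(dF_atp = 0))
  boltz <- exp(-positioning_free_energy(ssb$i, land))
  expect_equal(ssb$p_eq, boltz / sum(boltz), tolerance = 1e-10)
})

test_that("steady state is invariant to D and dF_ATP", {
  set.seed(17)
  m <- defect_cost_model(tract_length = 10L, tract_x = -30)
  base <- steady_state_evolved(kinetic_params(), model = m)
  for (rep in 1:5) {
    kp <- kinetic_params(dF_atp = stats::runif(1, 0, 25),
                         D = stats::runif(1, 0.1, 10))
    alt <- steady_state_evolved(kp, model = m)
    expect_lt(sum(abs(alt$p_eq - base$p_eq)), 1e-9)
  }
})

test_that("master-equation evolution conserves probability and diffuses", {
  # flat landscape without ATP: symmetric walk, Var = 2 D t
  flat <- landscape_params(amplitude = 0)
  kp <- kinetic_params(dF_atp = 0, D = 1)
  n <- 225L
  p0 <- numeric(n); p0[113L] <- 1          # point mass at i = 0
  ev <- evolve_master_equation(p0, times = c(1, 2, 4), params = kp,
                               land = flat)
  expect_equal(colSums(ev$P), rep(1, 3), tolerance = 1e-9)
  vars <- apply(ev$P, 2L, function(p) sum(p * ev$i^2) - sum(p * ev$i)^2)
  expect_equal(vars, 2 * c(1, 2, 4), tolerance = 0.01)
  expect_error(evolve_master_equation(p0 * 2, 1, kp, flat), "probability")
})

test_that("long-time evolution reproduces the closed-form steady state", {
  for (m in list(defect_cost_model(),
                 defect_cost_model(tract_length = 10L, tract_x = -30),
                 defect_cost_model(tract_length = 5L, tract_x = 15))) {
    ss <- steady_state_closed_form(model = m)
    ev <- steady_state_evolved(model = m)
    expect_lt(sum(abs(ev$p_eq - ss$p_eq)), 1e-8)
  }
})

test_that("effective free energy matches its defining recursion", {
  el <- effective_landscape()
  expect_lt(feff_recursion_residual(el), 1e-10)
  # without a tract F_eff - F is constant
  expect_lt(max(abs((el$F_eff - el$F) - (el$F_eff - el$F)[1])), 1e-10)
  # anchored at the optimum
  expect_equal(el$F_eff[el$i == 0], el$F[el$i == 0])
  m <- defect_cost_model(tract_length = 10L, tract_x = -21)
  el2 <- effective_landscape(model = m)
  expect_lt(feff_recursion_residual(el2), 1e-10)
  expect_error(effective_landscape(p_eq = data.frame(i = el$i,
                                                     p_eq = rep(0, 225))),
               "zero")
})

test_that("p_eq peaks sit within 1 bp of multiples of the 10.5-bp period", {
  ss <- steady_state_closed_form()
  p <- ss$p_eq; i <- ss$i
  peaks <- i[which(diff(sign(diff(p))) == -2) + 1L]
  expect_gt(length(peaks), 10L)
  nearest <- round(peaks / 10.5) * 10.5
  expect_true(all(abs(peaks - nearest) <= 1))
})

test_that("barrier metrics reproduce landscape differences and defect costs", {
  el <- effective_landscape()
  bm <- barrier_metrics(el)
  land <- landscape_params()
  expect_equal(unname(bm["dF10"]),
               positioning_free_energy(-10, land) -
                 positioning_free_energy(0, land), tolerance = 1e-10)
  expect_equal(unname(bm["dF10"]), 0.222, tolerance = 1e-3)
  expect_equal(unname(bm["dF1"]), 0.869, tolerance = 1e-3)
  # a tract at x = -21 raises the initial barrier by the defect asymmetry
  m <- defect_cost_model(tract_length = 10L, tract_x = -21)
  bm2 <- barrier_metrics(effective_landscape(model = m))
  expected_rise <- defect_cost(0, m, -2) - defect_cost(-1, m, +2)
  expect_equal(unname(bm2["dF1"] - bm["dF1"]), expected_rise,
               tolerance = 1e-10)
})

test_that("barrier heatmaps decay to no-tract values and mirror in x", {
  land <- landscape_params()
  # far-away tract: both metrics at their no-tract constants
  bm0 <- barrier_metrics(effective_landscape())
  far <- barrier_heatmap(x_grid = c(-90, 90), L_grid = c(4L, 10L))
  expect_true(all(abs(far$dF10 - bm0["dF10"]) < 1e-6))
  expect_true(all(abs(far$dF1 - bm0["dF1"]) < 1e-6))
  # mirror property: reflecting the tract mirrors the steady state
  m_neg <- defect_cost_model(tract_length = 10L, tract_x = -30)
  m_pos <- defect_cost_model(tract_length = 10L, tract_x = 30)
  p_neg <- steady_state_closed_form(model = m_neg)
  p_pos <- steady_state_closed_form(model = m_pos)
  expect_equal(p_neg$p_eq, rev(p_pos$p_eq), tolerance = 1e-10)
  # hence dF10 for x equals the +10 bp barrier for -x
  el_pos <- effective_landscape(model = m_pos)
  dF10_mirror <- el_pos$F_eff[el_pos$i == 10] - el_pos$F_eff[el_pos$i == 0]
  el_neg <- effective_landscape(model = m_neg)
  expect_equal(unname(barrier_metrics(el_neg)["dF10"]), dF10_mirror,
               tolerance = 1e-10)
  # wider tracts widen the affected band of the dF1 profile
  xg <- seq(-45, 5, by = 1)
  hm <- barrier_heatmap(xg, c(4L, 12L))
  affected <- function(row) sum(abs(row - bm0["dF1"]) > 0.1)
  expect_gt(affected(hm$dF1["12", ]), affected(hm$dF1["4", ]))
})
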