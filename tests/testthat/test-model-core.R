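test_that("diastolic pressure-volume relation evaluates and is monotone", {
  phys <- physiology_params(p_lv0 = 1, v_ed0 = 50, r_valve = 0.05,
                            p_cvp = 5)
  # exponent zero at the unstressed volume
  expect_equal(lv_diastolic_pressure(50, phys, beta = 0.04), 0)
  # direct evaluation: P_LV0 = 1, beta = 0.04, V_ED0 = 50, v = 100
  phys1 <- physiology_params(1, 50, 1, 1)
  expect_equal(lv_diastolic_pressure(100, phys1, 0.04), exp(2) - 1,
               tolerance = 1e-12)
  # strictly increasing in volume
  v <- seq(10, 200, by = 5)
  expect_true(all(diff(lv_diastolic_pressure(v, phys, 0.04)) > 0))
  # overflow guard
  expect_error(lv_diastolic_pressure(1e6, phys, 0.04), "overflow")
})

test_that("combined inflow parameters follow from physiology with forced signs", {
  p <- params_from_physiology(physiology_params(1, 1e-9, 1, 1e-9), 0.04)
  expect_equal(p$k1, -1, tolerance = 1e-6)
  expect_equal(p$k3, 1, tolerance = 1e-6)
  # direct evaluation: P_LV0 = 2, R_valve = 0.05, P_cvp = 5, beta = 0.04,
  # V_ED0 = 50 -> k3 = 140, k1 = -40 exp(-2)
  p2 <- params_from_physiology(physiology_params(2, 50, 0.05, 5), 0.04)
  expect_equal(p2$k3, 140)
  expect_equal(p2$k1, -40 * exp(-2), tolerance = 1e-12)
  # sign property over random physiology
  withr::with_seed(5, {
    for (i in 1:25) {
      ph <- physiology_params(runif(1, 0.5, 5), runif(1, 10, 100),
                              runif(1, 0.01, 1), runif(1, 1, 15))
      k <- params_from_physiology(ph, runif(1, 0.01, 0.2))
      expect_true(k$k1 < 0)
      expect_true(k$k3 > 0)
      expect_lt(abs(k$k1), ph[["p_lv0"]] / ph[["r_valve"]])
    }
  })
})

test_that("closed-form filling volume matches Runge-Kutta integration of the ODE", {
  skip_if_not_installed("deSolve")
  ts <- seq(0.2, 2, length.out = 20)
  ode_fn <- function(t, y, parms) {
    list(parms$k3 - parms$k1m * exp(parms$beta * y))
  }
  for (p in random_params(100, seed = 21)) {
    v_cf <- end_diastolic_volume(ts, p)
    v0 <- end_diastolic_volume(0, p)
    sol <- deSolve::ode(c(V = v0), c(0, ts), ode_fn,
                        list(k3 = p[["k3"]], k1m = p[["k1_mag"]],
                             beta = p[["beta"]]),
                        rtol = 1e-11, atol = 1e-11)
    expect_lt(max(abs(sol[-1, "V"] - v_cf)), 1e-6)
  }
})

test_that("physiology round trip: combined parameters reproduce direct simulation of the filling ODE", {
  skip_if_not_installed("deSolve")
  phys <- physiology_params(p_lv0 = 2, v_ed0 = 10, r_valve = 0.05,
                            p_cvp = 5)
  beta <- 0.04
  k <- params_from_physiology(phys, beta)
  p <- model_params(k1_mag = -k$k1, k3 = k$k3, beta = beta, C = 0.1,
                    alpha = 1, delta = 40)
  ode_fn <- function(t, y, parms) {
    list((parms$p_cvp - lv_diastolic_pressure(y, parms$phys, parms$beta)) /
           parms$r_valve)
  }
  ts <- seq(0.1, 1.5, length.out = 10)
  v0 <- end_diastolic_volume(0, p)
  sol <- deSolve::ode(c(V = v0), c(0, ts), ode_fn,
                      list(phys = phys, beta = beta,
                           p_cvp = phys[["p_cvp"]],
                           r_valve = phys[["r_valve"]]),
                      rtol = 1e-11, atol = 1e-11)
  expect_lt(max(abs(sol[-1, "V"] - end_diastolic_volume(ts, p))), 1e-6)
})

test_that("filling curve is increasing, concave and bounded by its asymptote", {
  ts <- seq(0, 3, by = 0.05)
  for (p in random_params(20, seed = 31)) {
    v <- end_diastolic_volume(ts, p)
    vmax <- filling_asymptote(p)
    # strictly increasing with decreasing increments, up to floating-point
    # jitter once the plateau saturates (increments underflow to ~0 there)
    tol <- 1e-9 * max(1, abs(vmax))
    expect_true(all(diff(v) >= -tol))
    expect_gt(v[10] - v[1], 0)
    expect_true(all(diff(diff(v)) < tol))
    expect_true(all(v <= vmax + 1e-9 * abs(vmax)))
    expect_lte(end_diastolic_volume(10 * 0.68, p),
               vmax + 1e-9 * abs(vmax))
  }
})

test_that("filling asymptote matches the stationary point of the ODE", {
  p <- model_params(1, 100, 0.04, 0.1, 1, 40)
  expect_equal(filling_asymptote(p), log(100) / 0.04, tolerance = 1e-12)
  p2 <- model_params(100, 100, 0.05, 0.1, 1, 40)
  expect_equal(filling_asymptote(p2), 0)
})

test_that("vanishing k1 magnitude reduces filling to the linear limit", {
  p <- model_params(1e-12, 100, 0.04, 1e-9, 1, 40)
  expect_equal(end_diastolic_volume(0.5, p), 100 * (0.5 + 1e-9),
               tolerance = 1e-9)
})

test_that("overflow-prone arguments are evaluated via the asymptotic branch", {
  # beta*k3*(t+C) far beyond double-exponential range must still be finite
  p <- model_params(1, 399, 399, 399, 1, 40)
  v <- end_diastolic_volume(2, p)
  expect_true(is.finite(v))
  expect_equal(v, filling_asymptote(p), tolerance = 1e-6)
})

test_that("simple observation model is an affine map of volume", {
  p <- fixture_params()
  pid <- model_params(1, 150, 0.04, 0.1, 1, 1e-9)
  expect_equal(predict_pp_simple(0.7, pid),
               end_diastolic_volume(0.7, pid) + 1e-9)
  # delta shift
  pa <- model_params(1, 150, 0.04, 0.1, 1.5, 40)
  pb <- model_params(1, 150, 0.04, 0.1, 1.5, 65)
  expect_equal(predict_pp_simple(0.7, pb), predict_pp_simple(0.7, pa) + 25)
  # composite check against independent high-precision evaluation
  v <- 150 * 0.8 - (1 / 0.04) * log1p((1 / 150) * exp(0.04 * 150 * 0.8))
  expect_equal(predict_pp_simple(0.7, p), v / 1.5 + 40, tolerance = 1e-10)
})

test_that("expanded model nests the simple model at the k4 boundary", {
  td <- c(0.5, 0.7, 0.9)
  tdp <- c(0.6, 0.8, 0.7)
  for (ps in random_params(10, seed = 41)) {
    pe <- as_lv_params(c(unclass(ps), k4 = 1e-300))
    expect_identical(predict_pp_expanded(td, tdp, pe),
                     predict_pp_simple(td, ps))
    # k4 = 1 shifts the filling clock by the prepreceding interval
    pe1 <- as_lv_params(c(unclass(ps), k4 = 1))
    expect_equal(predict_pp_expanded(td, tdp, pe1),
                 predict_pp_simple(td + tdp, ps), tolerance = 1e-12)
  }
  # monotone in the prepreceding interval
  pe <- fixture_params(k4 = 0.3)
  pp <- predict_pp_expanded(rep(0.6, 5), seq(0.3, 1.1, length.out = 5), pe)
  expect_true(all(diff(pp) > 0))
})

test_that("parameter constructors enforce the open box and field validity", {
  expect_error(model_params(0, 150, 0.04, 0.1, 1.5, 40), "0, 400")
  expect_error(model_params(1, 400, 0.04, 0.1, 1.5, 40), "0, 400")
  expect_error(physiology_params(1, -1, 1, 1), "positive")
  expect_identical(model_kind(fixture_params()), "simple")
  expect_identical(model_kind(fixture_params(k4 = 0.2)), "expanded")
})

test_that("data-frame prediction respects model kind and missing prepreceding intervals", {
  beats <- tibble::tibble(t_dia = c(0.6, 0.7), t_dia_prev = c(NA, 0.6),
                          pp = c(50, 55))
  out_s <- predict_pp(beats, fixture_params())
  expect_false(anyNA(out_s$.pred))
  out_e <- predict_pp(beats, fixture_params(k4 = 0.3))
  expect_true(is.na(out_e$.pred[1]))
  expect_false(is.na(out_e$.pred[2]))
})
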