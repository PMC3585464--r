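# numeric realization, perturbation simulation, thresholds, response times,
# sensitivities, steady-state scans

omm_solution <- function() {
  f <- fixture("omm1")
  solve_steady_state(f$model, f$phi)$branches[[1]]
}

test_that("realization evaluates dependents and the residual vanishes", {
  sol <- omm_solution()
  vals <- c(E = 1, S = 1, ES = 1, P = 1, k2 = 1, k5 = 1)
  real <- realize(sol, vals)
  expect_lt(real$residual, 1e-12)
  expect_true(real$feasible)
  # k4 = k5*P and k3 = k5*P/ES under the homogeneous map
  expect_equal(unname(real$values["k4"]), 1)
  expect_equal(unname(real$values["k3"]), 1)
  expect_error(realize(sol, vals[-1]), "missing values")
})

test_that("unperturbed trajectories stay at the fixed point", {
  for (nm in c("omm1", "toy_switch")) {
    f <- fixture(nm)
    sol <- solve_steady_state(f$model, f$phi)$branches[[1]]
    vals <- if (nm == "toy_switch") f$values else
      stats::setNames(rep(1, length(sol$independents)), sol$independents)
    real <- realize(sol, vals)
    expect_true(real$feasible)
    tr <- simulate_perturbation(f$model, real, NULL, horizon = 48)
    base <- real$values[f$model$species]
    drift <- max(abs(sweep(as.matrix(tr[, f$model$species]), 2, base) /
                       rep(base, each = nrow(tr))))
    expect_lt(drift, 1e-6)
  }
})

test_that("a perturbed OMM relaxes to the closed-form new steady state", {
  sol <- omm_solution()
  real <- realize(sol, c(E = 1, S = 1, ES = 1, P = 1, k2 = 1, k5 = 1))
  # raise the synthesis rate by 20% and integrate to re-equilibration
  tr <- simulate_perturbation(fixture("omm1")$model, real,
                              list(quantity = "k4", fold = 1.2),
                              horizon = 400, n_steps = 401)
  k <- real$values[c("k1", "k2", "k3", "k4", "k5")]
  k[["k4"]] <- 1.2 * k[["k4"]]
  want <- omm_closed_form(k, e_total = real$values[["E"]] + real$values[["ES"]])
  got <- unlist(tr[nrow(tr), c("E", "S", "ES", "P")])
  expect_equal(unname(got), unname(want[c("E", "S", "ES", "P")]),
               tolerance = 1e-4)
  # total enzyme is conserved along the trajectory
  expect_lt(max(abs(tr$E + tr$ES - 2)), 1e-6)
})

test_that("time of half-max interpolates crossings and reports absences", {
  step <- tibble::tibble(time = 0:20, X = as.numeric(0:20 >= 10))
  expect_equal(time_of_half_max(step, "X"), 9.5, tolerance = 0.51)
  # logistic curve: half-max at its midpoint t0
  t <- seq(0, 20, by = 0.05)
  lg <- tibble::tibble(time = t, X = 1 / (1 + exp(-(t - 7.3) * 2)))
  expect_equal(time_of_half_max(lg, "X"), 7.3, tolerance = 0.01)
  dec <- tibble::tibble(time = t, X = exp(-t))
  expect_true(is.na(time_of_half_max(dec, "X")))
})

test_that("binary-search threshold matches the grid-scan oracle within 1%", {
  tw <- fixture("toy_switch")
  sol <- solve_steady_state(tw$model, tw$phi)$branches[[1]]
  real <- realize(sol, tw$values)
  th <- response_threshold(tw$model, real, "S", toy_event, bracket = c(1, 100))
  grid <- toy_grid_threshold(tw$model, real, toy_event)
  expect_false(is.na(th$L_min))
  expect_lt(abs(th$L_min - grid) / grid, 0.01)
  # halving the tolerance moves the estimate by less than the tolerance
  th2 <- response_threshold(tw$model, real, "S", toy_event,
                            bracket = c(1, 100), tol = 0.005)
  expect_lt(abs(th$L_min - th2$L_min) / th2$L_min, 0.01)
})

test_that("systems without a switch report no threshold in bracket", {
  f <- fixture("omm1")
  sol <- solve_steady_state(f$model, f$phi)$branches[[1]]
  real <- realize(sol, c(E = 1, S = 1, ES = 1, P = 1, k2 = 1, k5 = 1))
  th <- response_threshold(f$model, real, "S",
                           function(tr) any(tr$P > 100), bracket = c(1, 10))
  expect_true(is.na(th$L_min))
  expect_match(th$note, "no threshold")
})

test_that("sensitivities recover analytic slopes and are max-normalized", {
  tw <- fixture("toy_switch")
  sol <- solve_steady_state(tw$model, tw$phi)$branches[[1]]
  # an exactly linear metric: its backward difference equals the slope
  lin_metric <- function(model, real) 3 * real$values[["kda"]] + 1
  sens <- sensitivity_coefficients(tw$model, sol, tw$values, lin_metric,
                                   c("kda",  "kf"))
  expect_equal(sens$raw[sens$quantity == "kda"], 3, tolerance = 1e-9)
  expect_equal(sens$raw[sens$quantity == "kf"], 0)
  expect_equal(max(abs(sens$coefficient), na.rm = TRUE), 1)
})

test_that("threshold and response-time sensitivities are independent metrics", {
  tw <- fixture("toy_switch")
  sol <- solve_steady_state(tw$model, tw$phi)$branches[[1]]
  lmin_metric <- function(model, real) {
    response_threshold(model, real, "S", toy_event, bracket = c(1, 100),
                       n_steps = 241)$L_min
  }
  td_metric <- function(model, real) {
    tr <- simulate_perturbation(model, real, list(quantity = "S", fold = 4),
                                n_steps = 241)
    time_of_half_max(tr, "A")
  }
  qs <- c("S", "A", "kds", "kf", "kda", "kc")
  s1 <- sensitivity_coefficients(tw$model, sol, tw$values, lmin_metric, qs)
  s2 <- sensitivity_coefficients(tw$model, sol, tw$values, td_metric, qs)
  expect_equal(max(abs(s1$coefficient), na.rm = TRUE), 1)
  expect_equal(max(abs(s2$coefficient), na.rm = TRUE), 1)
  # the two metrics are computed independently and need not rank alike
  expect_false(identical(order(s1$coefficient), order(s2$coefficient)))
})

test_that("steady-state scans compensate dependents and span a 100-fold range", {
  tw <- fixture("toy_switch")
  sol <- solve_steady_state(tw$model, tw$phi)$branches[[1]]
  resid_metric <- function(model, real) real$residual
  sc <- steady_state_scan(tw$model, sol, tw$values, "A", resid_metric,
                          n_points = 5)
  expect_equal(sc$fold[1], 0.1, tolerance = 1e-9)
  expect_equal(sc$fold[nrow(sc)], 10, tolerance = 1e-9)
  expect_equal(sc$abundance, tw$values[["A"]] * sc$fold, tolerance = 1e-12)
  # every feasible scan point is again a steady state (sigma compensation)
  expect_true(all(sc$value[sc$feasible] < 1e-8))
  # a metric that ignores the scanned quantity gives a flat curve
  flat <- steady_state_scan(tw$model, sol, tw$values, "A",
                            function(model, real) real$values[["kds"]],
                            n_points = 5)
  expect_true(all(abs(flat$value - tw$values[["kds"]]) < 1e-12))
  expect_error(steady_state_scan(tw$model, sol, tw$values, "ks",
                                 resid_metric), "not an independent")
})
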