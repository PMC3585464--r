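# Numeric layer: realize a symbolic steady state, integrate perturbations,
# and compute response thresholds and normalized sensitivity coefficients.

#' Numerically realize a steady-state solution
#'
#' Evaluates every dependent quantity from numeric values for the
#' independents, solving the branch's quadratic constraint root when present,
#' and computes the steady-state residual `max |N v|`.
#'
#' @param solution a `steady_state_solution`.
#' @param values named numeric vector/list covering all independent
#'   quantities.
#' @return a `numeric_realization`: `values` (all quantities), `residual`,
#'   `feasible` (strict positivity of every concentration and rate constant),
#'   `branch_id`.
#' @export
realize <- function(solution, values) {
  stopifnot(inherits(solution, "steady_state_solution"))
  values <- unlist(values)
  indep <- setdiff(solution$independents,
                   if (!is.null(solution$quad)) solution$quad$u)
  missing <- setdiff(indep, names(values))
  if (length(missing))
    stop("missing values for independent quantities: ",
         paste(missing, collapse = ", "))
  vals <- values[indep]
  if (!is.null(solution$quad)) {
    qd <- solution$quad
    a <- rf_eval(qd$a, vals); b <- rf_eval(qd$b, vals); c <- rf_eval(qd$c, vals)
    disc <- b^2 - 4 * a * c
    if (disc < 0)
      return(structure(list(values = vals, residual = NA_real_,
                            feasible = FALSE, branch_id = solution$branch_id,
                            note = "complex quadratic root"),
                       class = "numeric_realization"))
    root <- (-b + qd$sign * sqrt(disc)) / (2 * a)
    vals[qd$u] <- root
  }
  qs <- quantities(solution$model)
  out <- stats::setNames(numeric(length(qs)), qs)
  for (q_ in qs) {
    out[q_] <- rf_eval(solution$sigma[[q_]], vals)
  }
  state <- out[solution$model$species]
  rates <- out[solution$model$rates]
  deriv <- model_derivative(solution$model, state, rates)
  names(deriv) <- solution$model$species
  varying <- setdiff(solution$model$species,
                     solution$phi$frozen %||% character(0))
  resid <- max(abs(deriv[varying]))
  feasible <- all(is.finite(out)) && all(out > 0) && resid <= 1e-8 * max(1, max(abs(out)))
  structure(list(values = out, residual = resid, feasible = feasible,
                 branch_id = solution$branch_id),
            class = "numeric_realization")
}

#' @export
print.numeric_realization <- function(x, ...) {
  cat("numeric_realization (branch ", x$branch_id, "): residual ",
      format(x$residual), ", ", if (isTRUE(x$feasible)) "feasible" else "INFEASIBLE",
      "\n", sep = "")
  print(x$values)
  invisible(x)
}

# dx/dt = N v(x; k) for numeric state and rates
model_derivative <- function(model, state, rates) {
  v <- vapply(seq_along(model$reactions), function(j) {
    r <- model$reactions[[j]]
    val <- rates[[r$rate]]
    if (length(r$orders))
      val <- val * prod(state[names(r$orders)]^r$orders)
    val
  }, numeric(1))
  as.numeric(model$N %*% v)
}

#' Simulate a perturbation away from a realized steady state
#'
#' Integrates the mass balance equations `dx/dt = N v` with `deSolve::lsoda`
#' (stiff-capable, adaptive; absolute tolerance 1e-8, relative 1e-6) from the
#' realized steady state, after applying a fold-change or step to one
#' quantity. A species perturbation changes the initial state; a rate
#' constant perturbation changes the parameter. With no perturbation the
#' trajectory stays at the fixed point.
#'
#' @param model a `mass_action_model`.
#' @param realization a `numeric_realization`.
#' @param perturbation `NULL`, or list with `quantity` and either `fold`
#'   (multiplicative) or `step` (additive).
#' @param horizon integration horizon (hours by convention); default 48.
#' @param n_steps number of saved time points.
#' @return tibble of class `ma_trajectories`: `time` plus one column per
#'   species.
#' @export
simulate_perturbation <- function(model, realization, perturbation = NULL,
                                  horizon = 48, n_steps = 481) {
  stopifnot(inherits(model, "mass_action_model"),
            inherits(realization, "numeric_realization"))
  state <- realization$values[model$species]
  rates <- realization$values[model$rates]
  if (!is.null(perturbation)) {
    q_ <- perturbation$quantity
    apply_to <- function(x) {
      if (!is.null(perturbation$fold)) x * perturbation$fold
      else x + perturbation$step
    }
    if (q_ %in% model$species) state[q_] <- apply_to(state[q_])
    else if (q_ %in% model$rates) rates[q_] <- apply_to(rates[q_])
    else stop("unknown quantity in perturbation: ", q_)
  }
  deriv <- function(t, y, parms) {
    list(model_derivative(model, y, parms))
  }
  times <- seq(0, horizon, length.out = n_steps)
  sol <- deSolve::lsoda(y = state, times = times, func = deriv, parms = rates,
                        atol = 1e-8, rtol = 1e-6)
  if (attr(sol, "istate")[1] < 0)
    stop("integrator failure (istate ", attr(sol, "istate")[1], ") at t = ",
         max(sol[, "time"]))
  out <- tibble::as_tibble(as.data.frame(unclass(sol)))
  class(out) <- c("ma_trajectories", class(out))
  out
}

#' Time at which an output first crosses half its maximum
#'
#' The response time is the first time the designated output crosses 50% of
#' its maximum over the horizon, linearly interpolated between saved points;
#' absent (NA) if the trajectory never crosses from below.
#'
#' @param traj trajectory tibble from [simulate_perturbation()].
#' @param output species column name.
#' @return numeric time, or `NA` when no crossing occurs.
#' @export
time_of_half_max <- function(traj, output) {
  stopifnot(output %in% names(traj))
  y <- traj[[output]]
  t <- traj$time
  half <- 0.5 * max(y)
  below <- y < half
  idx <- which(below[-length(below)] & !below[-1])
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1]
  t[i] + (half - y[i]) * (t[i + 1] - t[i]) / (y[i + 1] - y[i])
}

#' Minimal input fold-change that triggers a switch event
#'
#' Performs a bisection on the log fold-change of the input quantity between
#' a non-switching and a switching dose, to 1% relative tolerance. The event
#' predicate is any function of the simulated trajectory (for apoptosis-style
#' models, "the designated output exceeds 50% conversion at some time in the
#' horizon").
#'
#' @param model a `mass_action_model`.
#' @param realization a feasible `numeric_realization`.
#' @param input_quantity quantity stepped (fold-change applied).
#' @param event_predicate function(trajectory) -> logical.
#' @param bracket numeric(2): fold-change bracket, default `c(1, 1e6)`.
#' @param horizon,n_steps passed to [simulate_perturbation()].
#' @param tol relative tolerance on the fold-change (default 0.01).
#' @return list with `L_min` (geometric midpoint of the final bracket),
#'   `bracket`, and the bracketing trajectories; or a no-threshold report if
#'   the predicate does not change over the bracket.
#' @export
response_threshold <- function(model, realization, input_quantity,
                               event_predicate, bracket = c(1, 1e6),
                               horizon = 48, n_steps = 481, tol = 0.01) {
  run <- function(fold) {
    simulate_perturbation(model, realization,
                          list(quantity = input_quantity, fold = fold),
                          horizon = horizon, n_steps = n_steps)
  }
  lo <- bracket[1]; hi <- bracket[2]
  tr_lo <- run(lo); tr_hi <- run(hi)
  if (event_predicate(tr_lo))
    return(list(L_min = lo, bracket = bracket,
                note = "event already fires at the lower bracket"))
  if (!event_predicate(tr_hi))
    return(list(L_min = NA_real_, bracket = bracket,
                note = "no threshold in bracket"))
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (event_predicate(run(mid))) hi <- mid else lo <- mid
  }
  list(L_min = sqrt(lo * hi), bracket = c(lo, hi),
       low_trajectory = tr_lo, high_trajectory = tr_hi)
}

#' Normalized sensitivity coefficients of a response metric
#'
#' For each listed independent quantity, the quantity's steady-state value is
#' decreased by `rel_step` (backward finite difference), the dependent
#' quantities are recomputed through the steady-state map (so the perturbed
#' system is again at steady state), and the metric is re-evaluated. Raw
#' slopes `d(metric)/d(quantity)` are normalized to the maximum absolute
#' sensitivity, so the largest coefficient is 1 in magnitude.
#'
#' @param model a `mass_action_model`.
#' @param solution a `steady_state_solution`.
#' @param base_values named numeric values for the independents.
#' @param metric function(model, realization) -> scalar (e.g. a threshold or
#'   a response time); may return `NA` when undefined.
#' @param quantities_ character vector of independent quantities to probe.
#' @param rel_step backward relative step (default 0.01).
#' @return tibble: `quantity`, `raw` slope, `coefficient` (normalized).
#' @export
sensitivity_coefficients <- function(model, solution, base_values, metric,
                                     quantities_, rel_step = 0.01) {
  base_real <- realize(solution, base_values)
  m0 <- metric(model, base_real)
  if (is.na(m0)) stop("metric undefined at the base point")
  rows <- lapply(quantities_, function(q_) {
    vals <- unlist(base_values)
    if (!(q_ %in% names(vals)))
      stop(q_, " is not an independent quantity of this solution")
    vals[q_] <- vals[q_] * (1 - rel_step)
    real <- realize(solution, vals)
    m1 <- if (isTRUE(real$feasible)) metric(model, real) else NA_real_
    raw <- unname((m0 - m1) / (rel_step * unlist(base_values)[[q_]]))
    tibble::tibble(quantity = q_, metric_base = m0, metric_perturbed = m1,
                   raw = raw)
  })
  out <- dplyr::bind_rows(rows)
  mx <- max(abs(out$raw), na.rm = TRUE)
  out$coefficient <- out$raw / mx
  class(out) <- c("ma_sensitivity", class(out))
  out
}

#' Scan a species' steady-state abundance and re-evaluate a metric
#'
#' Varies the steady-state abundance of one independent species over a
#' geometric `fold_range` centered on its base value (default 100-fold:
#' base/10 to base*10), recomputing the compensating dependent quantities
#' from the steady-state map at every point so the system starts at steady
#' state, then evaluates the metric.
#'
#' @param model a `mass_action_model`.
#' @param solution a `steady_state_solution`.
#' @param base_values named numeric values for the independents.
#' @param species_ independent species to scan.
#' @param metric function(model, realization) -> scalar.
#' @param fold_range total fold range (default 100).
#' @param n_points number of scan points (log-spaced).
#' @return tibble: `abundance`, `fold`, `feasible`, `value`.
#' @export
steady_state_scan <- function(model, solution, base_values, species_, metric,
                              fold_range = 100, n_points = 9) {
  vals0 <- unlist(base_values)
  if (!(species_ %in% names(vals0)))
    stop(species_, " is not an independent quantity; re-derive the solution ",
         "with it independent (see select_independent)")
  base <- vals0[[species_]]
  half <- sqrt(fold_range)
  folds <- exp(seq(log(1 / half), log(half), length.out = n_points))
  rows <- lapply(folds, function(f) {
    vals <- vals0
    vals[species_] <- base * f
    real <- realize(solution, vals)
    ok <- isTRUE(real$feasible)
    tibble::tibble(abundance = base * f, fold = f, feasible = ok,
                   value = if (ok) metric(model, real) else NA_real_)
  })
  dplyr::bind_rows(rows)
}
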