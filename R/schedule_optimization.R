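#' Radiation fractionation problem under a total-dose budget
#'
#' Defines the schedule-optimization setting: radiation fractions on given
#' days whose doses must sum to a fixed budget, a concurrent constant
#' Nilotinib concentration, and an end-of-horizon viability objective.
#'
#' @param params A [model_parameters()] object (its `nu_drug` should be the
#'   conversion rate fitted for the drug-plus-radiation context).
#' @param fraction_days Days of the allowed fractions (default days 0-4).
#' @param budget Total radiation dose to distribute (Gy, default 2).
#' @param drug_nM Constant Nilotinib concentration (default 18).
#' @param objective_day Day at which viability is minimized (default 10);
#'   must not precede the last fraction day.
#' @param observable Viability mode of the objective (default
#'   `"relative_to_control"`).
#' @return An object of class `fractionation_problem` (the untreated control
#'   trajectory is pre-computed and cached for the relative observable).
#' @export
fractionation_problem <- function(params, fraction_days = 0:4, budget = 2,
                                  drug_nM = 18, objective_day = 10,
                                  observable = "relative_to_control") {
  stopifnot(inherits(params, "model_parameters"))
  if (budget < 0) stop("dose budget must be >= 0")
  if (is.unsorted(fraction_days) || any(fraction_days < 0)) {
    stop("fraction days must be non-decreasing and >= 0")
  }
  if (objective_day < max(fraction_days)) {
    stop("objective day must not precede the last fraction day")
  }
  control <- if (observable == "relative_to_control") {
    .integrate_states(params, treatment_schedule(),
                      t_out = sort(unique(c(0, fraction_days, objective_day))))
  } else NULL
  structure(list(params = params, fraction_days = fraction_days,
                 budget = budget, drug_nM = drug_nM,
                 objective_day = objective_day, observable = observable,
                 control = control),
            class = "fractionation_problem")
}

.problem_schedule <- function(problem, doses) {
  treatment_schedule(
    radiation_fractions = data.frame(time = problem$fraction_days,
                                     dose = doses),
    drug_segments = if (problem$drug_nM > 0) {
      data.frame(start = 0, end = problem$objective_day,
                 conc = problem$drug_nM)
    } else NULL)
}

#' Objective-day viability of a fractionation scheme
#'
#' Simulates the problem's treatment with the given per-fraction doses
#' (cumulative-dose rate rule in force between fractions) and returns the
#' viability percentage at the objective day.
#'
#' @param problem A [fractionation_problem()].
#' @param doses Dose vector (Gy), one entry per fraction day, all >= 0.
#' @return Viability percentage at the objective day.
#' @export
schedule_objective <- function(problem, doses) {
  stopifnot(inherits(problem, "fractionation_problem"))
  if (length(doses) != length(problem$fraction_days)) {
    stop("dose vector length must match the number of fraction days")
  }
  if (any(doses < 0)) stop("doses must be >= 0")
  sched <- .problem_schedule(problem, doses)
  if (problem$observable == "relative_to_control") {
    st <- .integrate_states(problem$params, sched,
                            t_out = c(0, problem$objective_day))
    i <- which(st[, "day"] == problem$objective_day)
    ctrl <- problem$control
    j <- which(ctrl[, "day"] == problem$objective_day)
    min(100, 100 * (st[i, "S"] + st[i, "R"]) /
          (ctrl[j, "S"] + ctrl[j, "R"]))
  } else {
    tr <- simulate_population(problem$params, sched,
                              t_out = c(0, problem$objective_day),
                              observable = problem$observable)
    tr$viability_pct[tr$day == problem$objective_day]
  }
}

#' Optimize the dose split of a fractionated radiation schedule
#'
#' Minimizes the objective-day viability over non-negative per-fraction
#' doses summing to the budget. The equality constraint is eliminated by
#' optimizing the first n-1 doses (the last is the remainder) with a
#' quadratic penalty against negative remainders; multi-start Nelder-Mead
#' from the budget-simplex vertices and the uniform split, followed by
#' projection of round-off onto the simplex.
#'
#' @param problem A [fractionation_problem()].
#' @param extra_starts Additional start dose-vectors (rows of a matrix), if
#'   any, beyond the deterministic vertex + uniform lattice.
#' @param seed Recorded in the diagnostics (the default start lattice is
#'   deterministic, so the seed only matters for user-supplied random
#'   starts).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return An object of class `optimal_schedule`: `doses`, `objective`
#'   (achieved viability percentage), and solver `diagnostics`. A warning is
#'   issued when starts disagree by more than 1e-3 (local minima).
#' @export
optimize_fractionation <- function(problem, extra_starts = NULL, seed = 1,
                                   maxit = 500) {
  stopifnot(inherits(problem, "fractionation_problem"))
  n <- length(problem$fraction_days)
  B <- problem$budget
  if (B == 0 || n == 1) {
    doses <- if (n == 1) B else rep(0, n)
    return(structure(list(doses = doses,
                          objective = schedule_objective(problem, doses),
                          diagnostics = list(trivial = TRUE, seed = seed)),
                     class = "optimal_schedule"))
  }
  quiet_obj <- function(d) {
    withCallingHandlers(schedule_objective(problem, d),
                        nilrad_rate_floor = function(w) invokeRestart("muffleWarning"))
  }
  pen_obj <- function(x) {
    d <- c(x, B - sum(x))
    viol <- pmax(-d, 0)
    if (any(viol > 0)) {
      dpos <- pmax(d, 0)
      feas <- if (sum(dpos) > 0) dpos * B / sum(dpos) else rep(B / length(d), length(d))
      return(1e4 * sum(viol^2) + quiet_obj(feas))
    }
    quiet_obj(d)
  }
  starts <- rbind(diag(n) * B, rep(B / n, n))
  if (!is.null(extra_starts)) starts <- rbind(starts, extra_starts)
  runs <- if (n == 2) {
    # one free dose: exact 1-D line search
    list(stats::optim(B / 2, pen_obj, method = "Brent", lower = 0, upper = B,
                      control = list(reltol = 1e-12)))
  } else {
    lapply(seq_len(nrow(starts)), function(i) {
      x0 <- starts[i, seq_len(n - 1)]
      stats::optim(x0, pen_obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10))
    })
  }
  finish <- function(x) {
    d <- pmax(c(x, B - sum(x)), 0)
    d * B / sum(d)
  }
  doses_all <- lapply(runs, function(r) finish(r$par))
  vals <- vapply(doses_all, quiet_obj, numeric(1))
  best <- which.min(vals)
  if (max(vals) - min(vals) > 1e-3) {
    warning("optimizer starts disagree by more than 1e-3; local minima present (best kept)")
  }
  structure(list(doses = doses_all[[best]], objective = vals[best],
                 diagnostics = list(seed = seed,
                                    start_objectives = vals,
                                    convergence = vapply(runs, `[[`,
                                                         numeric(1),
                                                         "convergence"))),
            class = "optimal_schedule")
}

#' @export
print.optimal_schedule <- function(x, ...) {
  cat("Optimal fractionation: doses (Gy) =",
      paste(sprintf("%.4f", x$doses), collapse = ", "),
      sprintf("\nobjective-day viability = %.4f%%\n", x$objective))
  invisible(x)
}

#' Compare named fractionation protocols on a common grid
#'
#' @param problem A [fractionation_problem()].
#' @param schedules Named list of dose vectors (one per protocol), all of the
#'   same length as the problem's fraction days.
#' @param t_out Common output grid (default daily to the objective day).
#' @return A list with `trajectories` (long data frame: `protocol`, `day`,
#'   `viability_pct`) and `objective` (named vector of objective-day values,
#'   sorted best first).
#' @export
compare_protocols <- function(problem, schedules,
                              t_out = seq(0, problem$objective_day, 0.25)) {
  stopifnot(inherits(problem, "fractionation_problem"),
            is.list(schedules), length(names(schedules)) == length(schedules))
  trs <- lapply(schedules, function(d) {
    simulate_population(problem$params, .problem_schedule(problem, d),
                        t_out = sort(unique(c(t_out, problem$objective_day))),
                        observable = problem$observable)
  })
  long <- do.call(rbind, lapply(names(trs), function(nm) {
    data.frame(protocol = nm, day = trs[[nm]]$day,
               viability_pct = trs[[nm]]$viability_pct)
  }))
  obj <- vapply(trs, function(tr) {
    tr$viability_pct[tr$day == problem$objective_day]
  }, numeric(1))
  list(trajectories = long, objective = sort(obj))
}

#' Evaluate a Nilotinib titration strategy against the constant-dose
#' reference
#'
#' Simulates the problem's radiation schedule with a time-varying drug
#' concentration and reports the objective-day viability next to the
#' constant-concentration reference.
#'
#' @param problem A [fractionation_problem()].
#' @param drug_segments Data frame `start`, `end`, `conc` describing the
#'   piecewise-constant titration.
#' @param doses Radiation dose vector to use (default: the uniform split).
#' @param require_same_average If `TRUE`, error unless the titration's
#'   time-average concentration over the horizon equals the problem's
#'   constant dose (tolerance 1e-6) — the comparability condition.
#' @param t_out Output grid.
#' @return A list with `trajectory` (data frame), `objective` (titration
#'   objective-day viability) and `reference_objective` (constant-dose
#'   value).
#' @export
evaluate_titration <- function(problem, drug_segments, doses = NULL,
                               require_same_average = TRUE,
                               t_out = seq(0, problem$objective_day, 0.25)) {
  stopifnot(inherits(problem, "fractionation_problem"))
  n <- length(problem$fraction_days)
  if (is.null(doses)) doses <- rep(problem$budget / n, n)
  drug_segments <- as.data.frame(drug_segments)
  horizon <- problem$objective_day
  if (require_same_average) {
    covered <- pmin(drug_segments$end, horizon) - pmax(drug_segments$start, 0)
    avg <- sum(pmax(covered, 0) * drug_segments$conc) / horizon
    if (abs(avg - problem$drug_nM) > 1e-6) {
      stop(sprintf("titration average (%.4f nM) differs from the reference constant dose (%g nM)",
                   avg, problem$drug_nM))
    }
  }
  sched <- treatment_schedule(
    radiation_fractions = data.frame(time = problem$fraction_days,
                                     dose = doses),
    drug_segments = drug_segments)
  tr <- simulate_population(problem$params, sched,
                            t_out = sort(unique(c(t_out, horizon))),
                            observable = problem$observable)
  ref <- schedule_objective(problem, doses)
  list(trajectory = as.data.frame(tr),
       objective = tr$viability_pct[tr$day == horizon],
       reference_objective = ref)
}
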