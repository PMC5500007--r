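#' Root-sum-of-squares viability loss
#'
#' The calibration objective: the square root of the sum of squared
#' differences between model and observed viability, over all observation
#' rows (replicates enter individually, not averaged). Each unique
#' `(radiation_Gy, nilotinib_nM)` condition is simulated once as an acute
#' arm: the radiation dose at day 0 and a constant drug concentration over
#' the horizon.
#'
#' @param obs Observation data frame (see [read_observations()]).
#' @param coeffs,rs,K,f_R0,N0 Model constants, see [model_parameters()].
#' @param nu_drug Conversion rate used for drug-only conditions.
#' @param nu_combo Conversion rate used for drug-plus-radiation conditions
#'   (defaults to `nu_drug`).
#' @param observable Viability mode used to map model states to the
#'   measurements (default `"live_fraction"`, the Trypan-blue-style
#'   read-out).
#' @param media_change_days Days at which the dead pool is cleared from the
#'   live-fraction read-out.
#' @param rtol,atol Solver tolerances.
#' @return Non-negative scalar; 0 iff the model reproduces every observation.
#' @export
viability_loss <- function(obs, coeffs, rs, K, f_R0 = 0.001, N0 = 1,
                           nu_drug = 0, nu_combo = nu_drug,
                           observable = "live_fraction",
                           media_change_days = c(0, 3, 6, 8),
                           rtol = 1e-8, atol = 1e-10) {
  sqrt(sum(viability_residuals(obs, coeffs, rs, K, f_R0, N0, nu_drug,
                               nu_combo, observable, media_change_days,
                               rtol, atol)^2))
}

#' Per-observation viability residuals
#'
#' The vector of (model - observed) viability differences underlying
#' [viability_loss()], in observation-row order. Used directly by the
#' least-squares calibration stages.
#'
#' @inheritParams viability_loss
#' @return Numeric vector, one residual per observation row.
#' @export
viability_residuals <- function(obs, coeffs, rs, K, f_R0 = 0.001, N0 = 1,
                                nu_drug = 0, nu_combo = nu_drug,
                                observable = "live_fraction",
                                media_change_days = c(0, 3, 6, 8),
                                rtol = 1e-8, atol = 1e-10) {
  obs <- validate_observations(obs)
  if (!nrow(obs)) stop("no observations supplied")
  plan <- .arm_plan(obs, media_change_days)
  .plan_residuals(plan, obs$viability_pct, coeffs, rs, K, f_R0, N0,
                  nu_drug, nu_combo, observable, rtol, atol)
}

# Pre-resolved per-condition simulation plan: schedules and row indices are
# built once per fit, not once per candidate parameter vector.
.arm_plan <- function(obs, media_change_days = c(0, 3, 6, 8)) {
  conds <- unique(obs[, c("radiation_Gy", "nilotinib_nM")])
  horizon <- max(obs$day)
  lapply(seq_len(nrow(conds)), function(i) {
    D <- conds$radiation_Gy[i]; conc <- conds$nilotinib_nM[i]
    rows <- which(obs$radiation_Gy == D & obs$nilotinib_nM == conc)
    udays <- sort(unique(obs$day[rows]))
    list(rows = rows, idx = match(obs$day[rows], udays), udays = udays,
         combo = conc > 0 && D > 0,
         sched = acute_schedule(D, conc, horizon = max(horizon, 1),
                                media_change_days = media_change_days))
  })
}

.plan_residuals <- function(plan, obs_v, coeffs, rs, K, f_R0, N0,
                            nu_drug, nu_combo, observable,
                            rtol = 1e-8, atol = 1e-10) {
  res <- numeric(length(obs_v))
  for (a in plan) {
    nu <- if (a$combo) nu_combo else nu_drug
    params <- .mk_params(coeffs, rs, nu, K, f_R0, N0)
    v <- .sim_viability(params, a$sched, a$udays, observable, rtol, atol)
    res[a$rows] <- v[a$idx] - obs_v[a$rows]
  }
  res
}

# Evaluate `expr` with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Bounded multi-start least-squares minimization: a deterministic (seeded)
# latin-hypercube start lattice plus the box midpoint, each polished with
# bounded Levenberg-Marquardt on the residual vector. Floored-rate warnings
# raised while probing candidates are muffled; they are expected during the
# search.
.fit_bounded <- function(resid_fn, lower, upper, n_starts = 8, seed = 1,
                         maxit = 200) {
  npar <- length(lower)
  stopifnot(length(upper) == npar, all(upper > lower))
  lat <- .with_seed(seed, lhs::randomLHS(max(1, n_starts - 1), npar))
  starts <- rbind((lower + upper) / 2,
                  sweep(sweep(lat, 2, upper - lower, "*"), 2, lower, "+"))
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]
  quiet_resid <- function(p) {
    r <- withCallingHandlers(resid_fn(p),
                             nilrad_rate_floor = function(w) invokeRestart("muffleWarning"))
    r[!is.finite(r)] <- 1e4
    r
  }
  quiet_loss <- function(p) sqrt(sum(quiet_resid(p)^2))
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    runs[[i]] <- tryCatch({
      # short quasi-Newton descent to reach a basin, then a
      # Levenberg-Marquardt polish on the residual vector
      rough <- stats::optim(starts[i, ], quiet_loss, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 40, factr = 1e9,
                                           parscale = pmax(upper - lower,
                                                           1e-3) / 4))
      minpack.lm::nls.lm(rough$par, lower = lower, upper = upper,
                         fn = quiet_resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit, ftol = 1e-12, ptol = 1e-10))
    }, error = function(e) NULL)
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all optimizer starts failed")
  vals <- vapply(runs[ok], function(r) sqrt(r$deviance), numeric(1))
  best <- runs[ok][[which.min(vals)]]
  par <- stats::setNames(best$par, names(lower))
  # one-dimensional curvature probe to flag near-degenerate directions
  h <- pmax(upper - lower, 1e-3) * 1e-4
  f0 <- quiet_loss(par)
  curv <- vapply(seq_len(npar), function(j) {
    pp <- par; pm <- par
    pp[j] <- min(par[j] + h[j], upper[j]); pm[j] <- max(par[j] - h[j], lower[j])
    (quiet_loss(pp) - 2 * f0 + quiet_loss(pm)) / ((pp[j] - pm[j]) / 2)^2
  }, numeric(1))
  list(par = par, value = min(vals),
       converged = best$info %in% 1:4,
       trace = list(seed = seed, n_starts = nrow(starts),
                    start_values = vals, lower = lower, upper = upper,
                    info = best$info, niter = best$niter,
                    curvature = stats::setNames(curv, names(lower)),
                    near_degenerate = names(lower)[abs(curv) < 1e-4]))
}

.as_fit_result <- function(stage, fit) {
  structure(list(stage = stage, estimates = fit$par, loss = fit$value,
                 converged = fit$converged, trace = fit$trace),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result (%s): loss = %.6g, converged = %s\n",
              x$stage, x$loss, x$converged))
  print(round(x$estimates, 5))
  if (length(x$trace$near_degenerate)) {
    cat("near-degenerate directions:",
        paste(x$trace$near_degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

.estimates_of <- function(x) {
  if (inherits(x, "fit_result")) x$estimates else unlist(x)
}

.check_arm_days <- function(obs, what, min_days = 3) {
  n_days <- length(unique(obs$day))
  if (n_days < min_days) {
    stop(sprintf("%s: only %d distinct measurement day(s); the stage is unidentifiable (need >= %d)",
                 what, n_days, min_days))
  }
}



#' Stage 1: baseline growth and radiosensitivity from drug-free arms
#'
#' Fits the shared baseline proliferation rate `r0` (= rS0 = rR0), baseline
#' death rate `d0` (= dS0 = dR0), carrying capacity `K`, and the LQ
#' radiosensitivity `alpha`, `beta`, to the control and radiation-only
#' viability time series (all rows with `nilotinib_nM == 0`).
#'
#' @param obs Observation data frame; rows with `nilotinib_nM > 0` are
#'   ignored.
#' @param f_R0,N0 Fixed initial condition (not fitted).
#' @param observable Viability mode used in the loss.
#' @param n_starts Number of multi-start points (>= 1).
#' @param seed Seed of the deterministic start lattice.
#' @param lower,upper Named bounds on `(r0, d0, K, alpha, beta)`.
#' @return A `fit_result` with estimates `(r0, d0, K, alpha, beta)`.
#' @export
fit_stage1 <- function(obs, f_R0 = 0.001, N0 = 1,
                       observable = "live_fraction",
                       n_starts = 8, seed = 1,
                       lower = c(r0 = 0.05, d0 = 0, K = 0.5, alpha = 0,
                                 beta = 0),
                       upper = c(r0 = 8, d0 = 8, K = 20, alpha = 3,
                                 beta = 0.5)) {
  obs <- validate_observations(obs)
  obs <- obs[obs$nilotinib_nM == 0, , drop = FALSE]
  if (!nrow(obs)) stop("stage 1 needs drug-free arms")
  .check_arm_days(obs, "drug-free data")
  arms <- unique(obs$radiation_Gy)
  if (length(arms) < 2) stop("stage 1 needs at least two drug-free arms (control plus radiation)")
  plan <- .arm_plan(obs)
  obs_v <- obs$viability_pct
  resid_fn <- function(p) {
    coeffs <- dose_response_coefficients(p[1], p[1], 0, 0, 0, 0,
                                         p[2], p[2], 0, 0, 0, 0)
    .plan_residuals(plan, obs_v, coeffs, radiosensitivity(p[4], p[5]),
                    K = p[3], f_R0 = f_R0, N0 = N0, nu_drug = 0,
                    nu_combo = 0, observable = observable)
  }
  .as_fit_result("stage1 (baseline growth + radiosensitivity)",
                 .fit_bounded(resid_fn, lower, upper, n_starts, seed))
}

#' Stage 2: drug dose-response coefficients from the Nilotinib-only arm
#'
#' With the stage-1 constants fixed, fits the per-nM coefficients
#' `(rS1, rR1, dS1, dR1)` and the conversion rate `nu` to the drug-only
#' viability time series (rows with `nilotinib_nM > 0`, `radiation_Gy == 0`).
#'
#' @param obs Observation data frame.
#' @param stage1 A stage-1 `fit_result`, or a named vector/list with
#'   `r0, d0, K, alpha, beta`.
#' @inheritParams fit_stage1
#' @param lower,upper Named bounds on `(rS1, rR1, dS1, dR1, nu)`. The default
#'   upper bound on the rate coefficients (0.15 per nM per day) is the scale
#'   beyond which an 18 nM dose drives the baseline rates past zero.
#' @return A `fit_result` with estimates `(rS1, rR1, dS1, dR1, nu)`.
#' @export
fit_stage2 <- function(obs, stage1, f_R0 = 0.001, N0 = 1,
                       observable = "live_fraction",
                       n_starts = 8, seed = 2,
                       lower = c(rS1 = 0, rR1 = 0, dS1 = 0, dR1 = 0, nu = 0),
                       upper = c(rS1 = 0.15, rR1 = 0.15, dS1 = 0.15,
                                 dR1 = 0.15, nu = 1)) {
  obs <- validate_observations(obs)
  s1 <- .estimates_of(stage1)
  obs <- obs[obs$nilotinib_nM > 0 & obs$radiation_Gy == 0, , drop = FALSE]
  if (!nrow(obs)) stop("stage 2 needs a drug-only arm (nilotinib_nM > 0, radiation_Gy == 0)")
  .check_arm_days(obs, "drug-only data")
  rs <- radiosensitivity(s1[["alpha"]], s1[["beta"]])
  plan <- .arm_plan(obs)
  obs_v <- obs$viability_pct
  resid_fn <- function(p) {
    coeffs <- dose_response_coefficients(s1[["r0"]], s1[["r0"]],
                                         p[1], p[2], 0, 0,
                                         s1[["d0"]], s1[["d0"]],
                                         p[3], p[4], 0, 0)
    .plan_residuals(plan, obs_v, coeffs, rs, K = s1[["K"]], f_R0 = f_R0,
                    N0 = N0, nu_drug = p[5], nu_combo = p[5],
                    observable = observable)
  }
  .as_fit_result("stage2 (drug coefficients + nu)",
                 .fit_bounded(resid_fn, lower, upper, n_starts, seed))
}

#' Stage 3: drug-radiation interaction coefficients from combination arms
#'
#' With stages 1-2 fixed, fits the per-nM-per-Gy interaction coefficients
#' `(rS2, rR2, dS2, dR2)` and a single conversion rate `nu_combo` shared
#' across the combination arms (the conversion rate is taken to be
#' independent of the radiation dose).
#'
#' @param obs Observation data frame; uses rows with `nilotinib_nM > 0` and
#'   `radiation_Gy > 0`.
#' @param stage1,stage2 Results of the earlier stages (or named
#'   vectors/lists).
#' @inheritParams fit_stage2
#' @return A `fit_result` with estimates `(rS2, rR2, dS2, dR2, nu_combo)`.
#' @export
fit_stage3 <- function(obs, stage1, stage2, f_R0 = 0.001, N0 = 1,
                       observable = "live_fraction",
                       n_starts = 8, seed = 3,
                       lower = c(rS2 = 0, rR2 = 0, dS2 = 0, dR2 = 0,
                                 nu_combo = 0),
                       upper = c(rS2 = 0.04, rR2 = 0.04, dS2 = 0.04,
                                 dR2 = 0.04, nu_combo = 1)) {
  obs <- validate_observations(obs)
  s1 <- .estimates_of(stage1); s2 <- .estimates_of(stage2)
  obs <- obs[obs$nilotinib_nM > 0 & obs$radiation_Gy > 0, , drop = FALSE]
  if (!nrow(obs)) stop("stage 3 needs at least one combination arm")
  .check_arm_days(obs, "combination data")
  arms <- unique(obs$radiation_Gy)
  if (length(arms) < 2) {
    warning("only one combination radiation dose supplied; interaction coefficients are fitted with reduced identifiability")
  }
  rs <- radiosensitivity(s1[["alpha"]], s1[["beta"]])
  plan <- .arm_plan(obs)
  obs_v <- obs$viability_pct
  resid_fn <- function(p) {
    coeffs <- dose_response_coefficients(s1[["r0"]], s1[["r0"]],
                                         s2[["rS1"]], s2[["rR1"]],
                                         p[1], p[2],
                                         s1[["d0"]], s1[["d0"]],
                                         s2[["dS1"]], s2[["dR1"]],
                                         p[3], p[4])
    .plan_residuals(plan, obs_v, coeffs, rs, K = s1[["K"]], f_R0 = f_R0,
                    N0 = N0, nu_drug = s2[["nu"]], nu_combo = p[5],
                    observable = observable)
  }
  .as_fit_result("stage3 (interaction coefficients + nu_combo)",
                 .fit_bounded(resid_fn, lower, upper, n_starts, seed))
}

#' Full three-stage calibration pipeline
#'
#' Runs [fit_stage1()], [fit_stage2()] and [fit_stage3()] in sequence on one
#' observation table and assembles the fitted constants into model objects.
#' Per-stage multi-start seeds are derived deterministically from `seed`.
#'
#' @param obs Observation data frame covering drug-free, drug-only and
#'   combination arms.
#' @inheritParams fit_stage1
#' @return A list of class `nilrad_fit` with elements `stage1`, `stage2`,
#'   `stage3`, the assembled `coeffs` and `rs`, and scalars `K`, `nu_drug`,
#'   `nu_combo`.
#' @export
fit_pipeline <- function(obs, f_R0 = 0.001, N0 = 1,
                         observable = "live_fraction",
                         n_starts = 8, seed = 1) {
  s1 <- fit_stage1(obs, f_R0, N0, observable, n_starts, seed = seed)
  s2 <- fit_stage2(obs, s1, f_R0, N0, observable, n_starts, seed = seed + 1L)
  s3 <- fit_stage3(obs, s1, s2, f_R0, N0, observable, n_starts,
                   seed = seed + 2L)
  e1 <- s1$estimates; e2 <- s2$estimates; e3 <- s3$estimates
  coeffs <- dose_response_coefficients(
    e1[["r0"]], e1[["r0"]], e2[["rS1"]], e2[["rR1"]], e3[["rS2"]], e3[["rR2"]],
    e1[["d0"]], e1[["d0"]], e2[["dS1"]], e2[["dR1"]], e3[["dS2"]], e3[["dR2"]],
    control_constrained = TRUE)
  structure(list(stage1 = s1, stage2 = s2, stage3 = s3,
                 coeffs = coeffs,
                 rs = radiosensitivity(e1[["alpha"]], e1[["beta"]]),
                 K = e1[["K"]], f_R0 = f_R0, N0 = N0,
                 nu_drug = e2[["nu"]], nu_combo = e3[["nu_combo"]],
                 seed = seed, observable = observable),
            class = "nilrad_fit")
}

#' @export
print.nilrad_fit <- function(x, ...) {
  cat("Three-stage calibration result\n")
  for (s in list(x$stage1, x$stage2, x$stage3)) print(s)
  invisible(x)
}

#' Sensitivity of the calibration to a fixed pipeline setting
#'
#' Re-runs the three-stage pipeline on the same data for each value of a
#' fixed (non-fitted) setting — e.g. the assumed initial resistant fraction —
#' and tabulates the drift of every estimate.
#'
#' @param obs Observation data frame.
#' @param parameter Name of the setting to vary: `"f_R0"` or `"N0"`.
#' @param grid Numeric values to scan (empty grid gives an empty table).
#' @inheritParams fit_pipeline
#' @return A data frame with one row per grid value: the varied setting, all
#'   15 stage estimates, and per-stage losses.
#' @export
sensitivity_analysis <- function(obs, parameter = c("f_R0", "N0"), grid,
                                 observable = "live_fraction", n_starts = 8,
                                 seed = 1) {
  parameter <- match.arg(parameter)
  rows <- lapply(grid, function(v) {
    args <- list(obs = obs, observable = observable, n_starts = n_starts,
                 seed = seed)
    args[[parameter]] <- v
    fit <- do.call(fit_pipeline, args)
    ests <- c(fit$stage1$estimates, fit$stage2$estimates,
              fit$stage3$estimates)
    data.frame(parameter = parameter, value = v, t(ests),
               loss1 = fit$stage1$loss, loss2 = fit$stage2$loss,
               loss3 = fit$stage3$loss)
  })
  if (!length(rows)) {
    return(data.frame(parameter = character(0), value = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Trajectory envelope under perturbed radiosensitivity
#'
#' Simulates a treatment arm at the four corners of an `alpha +/- d_alpha`,
#' `beta +/- d_beta` box and returns the pointwise viability envelope around
#' the unperturbed trajectory (the uncertainty-band construction used for
#' radiation-only fits).
#'
#' @param params A [model_parameters()] object.
#' @param schedule A [treatment_schedule()].
#' @param d_alpha,d_beta Half-widths of the perturbation (defaults 0.10 /Gy
#'   and 0.012 /Gy^2, about 15 percent of the fitted values).
#' @param t_out Output days.
#' @param observable Viability mode.
#' @return Data frame with columns `day`, `viability_pct` (unperturbed),
#'   `lower`, `upper`.
#' @export
radiosensitivity_envelope <- function(params, schedule, d_alpha = 0.10,
                                      d_beta = 0.012,
                                      t_out = seq(0, 10, 0.25),
                                      observable = "relative_to_control") {
  base <- simulate_population(params, schedule, t_out, observable)
  corners <- expand.grid(a = c(-1, 1), b = c(-1, 1))
  vs <- sapply(seq_len(nrow(corners)), function(i) {
    rs2 <- radiosensitivity(max(0, params$rs$alpha + corners$a[i] * d_alpha),
                            max(0, params$rs$beta + corners$b[i] * d_beta))
    p2 <- model_parameters(params$coeffs, rs2, params$nu_drug, params$K,
                           params$f_R0, params$N0)
    simulate_population(p2, schedule, t_out, observable)$viability_pct
  })
  data.frame(day = base$day, viability_pct = base$viability_pct,
             lower = pmin(base$viability_pct, apply(vs, 1, min)),
             upper = pmax(base$viability_pct, apply(vs, 1, max)))
}
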