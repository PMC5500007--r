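#' Model parameters for the sensitive/resistant population model
#'
#' @param coeffs A [dose_response_coefficients()] object.
#' @param rs A [radiosensitivity()] object.
#' @param nu_drug Conversion rate (per day) at which sensitive cells
#'   transform into resistant cells while drug is present; active only when
#'   the Nilotinib concentration is positive, and independent of the
#'   concentration value.
#' @param K Carrying capacity, in arbitrary population units (the absolute
#'   scale is unidentifiable from viability percentages; default 4.2 with
#'   the initial population at 1 unit).
#' @param f_R0 Initial resistant fraction of the population (default 0.001,
#'   i.e. 0.1 percent).
#' @param N0 Initial total population, same units as `K` (default 1).
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(coeffs, rs, nu_drug, K = 4.2, f_R0 = 0.001,
                             N0 = 1) {
  stopifnot(inherits(coeffs, "dose_response_coefficients"),
            inherits(rs, "radiosensitivity"))
  if (!is.finite(K) || K <= 0) stop("carrying capacity K must be > 0")
  if (!is.finite(f_R0) || f_R0 < 0 || f_R0 > 1) stop("f_R0 must be in [0, 1]")
  if (!is.finite(nu_drug) || nu_drug < 0) stop("nu_drug must be >= 0")
  if (!is.finite(N0) || N0 <= 0) stop("N0 must be > 0")
  structure(list(coeffs = coeffs, rs = rs, nu_drug = nu_drug, K = K,
                 f_R0 = f_R0, N0 = N0),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("Model parameters: K = %g, f_R0 = %g, N0 = %g, nu_drug = %g /day\n",
              x$K, x$f_R0, x$N0, x$nu_drug))
  print(x$rs)
  print(x$coeffs)
  invisible(x)
}

#' Treatment schedule: radiation fractions and piecewise-constant drug
#'
#' @param radiation_fractions Data frame with columns `time` (day) and
#'   `dose` (Gy), one row per fraction, times non-decreasing. `NULL` means no
#'   radiation.
#' @param drug_segments Data frame with columns `start`, `end` (days) and
#'   `conc` (nM), non-overlapping; time not covered by any segment has
#'   concentration 0. `NULL` means no drug.
#' @param media_change_days Days at which the culture medium is changed,
#'   clearing the accumulated dead-cell pool from the (live-fraction)
#'   viability read-out. Affects only the observable, not the dynamics.
#' @return An object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(radiation_fractions = NULL,
                               drug_segments = NULL,
                               media_change_days = c(0, 3, 6, 8)) {
  if (is.null(radiation_fractions)) {
    radiation_fractions <- data.frame(time = numeric(0), dose = numeric(0))
  }
  radiation_fractions <- as.data.frame(radiation_fractions)
  stopifnot(all(c("time", "dose") %in% names(radiation_fractions)))
  if (nrow(radiation_fractions)) {
    if (is.unsorted(radiation_fractions$time)) {
      stop("radiation fraction times must be non-decreasing")
    }
    if (any(radiation_fractions$time < 0) || any(radiation_fractions$dose < 0)) {
      stop("radiation fraction times and doses must be >= 0")
    }
  }
  if (is.null(drug_segments)) {
    drug_segments <- data.frame(start = numeric(0), end = numeric(0),
                                conc = numeric(0))
  }
  drug_segments <- as.data.frame(drug_segments)
  stopifnot(all(c("start", "end", "conc") %in% names(drug_segments)))
  if (nrow(drug_segments)) {
    drug_segments <- drug_segments[order(drug_segments$start), , drop = FALSE]
    if (any(drug_segments$end <= drug_segments$start)) {
      stop("drug segments must have end > start")
    }
    if (any(drug_segments$conc < 0)) stop("drug concentrations must be >= 0")
    if (nrow(drug_segments) > 1 &&
        any(drug_segments$start[-1] < drug_segments$end[-nrow(drug_segments)] - 1e-12)) {
      stop("drug segments must not overlap")
    }
  }
  media_change_days <- sort(unique(media_change_days))
  if (any(media_change_days < 0)) stop("media change days must be >= 0")
  structure(list(radiation_fractions = radiation_fractions,
                 drug_segments = drug_segments,
                 media_change_days = media_change_days),
            class = "treatment_schedule")
}

#' Acute single-condition schedule (one radiation dose, constant drug)
#'
#' Convenience constructor for the in vitro arms: an acute radiation dose at
#' day 0 and a constant Nilotinib concentration over the whole horizon.
#'
#' @param radiation_Gy Acute dose at day 0 (Gy); 0 for no radiation.
#' @param nilotinib_nM Constant drug concentration (nM); 0 for no drug.
#' @param horizon End of the drug coverage (day).
#' @inheritParams treatment_schedule
#' @return A [treatment_schedule()].
#' @export
acute_schedule <- function(radiation_Gy = 0, nilotinib_nM = 0, horizon = 10,
                           media_change_days = c(0, 3, 6, 8)) {
  rf <- if (radiation_Gy > 0) data.frame(time = 0, dose = radiation_Gy) else NULL
  ds <- if (nilotinib_nM > 0) {
    data.frame(start = 0, end = horizon, conc = nilotinib_nM)
  } else NULL
  treatment_schedule(rf, ds, media_change_days)
}

# Drug concentration in force on the interval [a, b); segments are
# half-open [start, end), gaps mean 0.
.drug_conc_on <- function(schedule, a) {
  seg <- schedule$drug_segments
  if (!nrow(seg)) return(0)
  i <- which(seg$start <= a + 1e-12 & a < seg$end - 1e-12)
  if (length(i)) seg$conc[i[1]] else 0
}

#' Time derivatives of the compartment model
#'
#' The sensitive and resistant populations proliferate logistically against a
#' shared carrying capacity, die at linear rates, and (while drug is present)
#' sensitive cells convert to resistant at rate `nu`:
#' \deqn{dS/dt = r_S S (1 - (S+R)/K) - d_S S - \nu S}
#' \deqn{dR/dt = r_R R (1 - (S+R)/K) - d_R R + \nu S}
#' \deqn{dDead/dt = d_S S + d_R R}
#'
#' @param state Named numeric vector or list with `S`, `R`, `Dead`.
#' @param rates A `model_rates` record from [effective_rates()].
#' @param nu Active conversion rate (per day; 0 when no drug present).
#' @param K Carrying capacity.
#' @return Named numeric vector of derivatives `(S, R, Dead)` per day.
#' @export
compartment_derivatives <- function(state, rates, nu, K) {
  S <- state[["S"]]; R <- state[["R"]]
  crowd <- 1 - (S + R) / K
  c(S = rates$rS * S * crowd - rates$dS * S - nu * S,
    R = rates$rR * R * crowd - rates$dR * R + nu * S,
    Dead = rates$dS * S + rates$dR * R)
}

#' Instantaneous linear-quadratic kill at a radiation fraction
#'
#' Both phenotypes are scaled by the same surviving fraction; the killed
#' cells move to the dead pool, so live + dead is conserved across the event.
#'
#' @param state Named list/vector with `S`, `R`, `Dead`.
#' @param rs A [radiosensitivity()] object.
#' @param dose Per-fraction dose (Gy).
#' @return The post-fraction state (same shape as `state`).
#' @export
apply_radiation_fraction <- function(state, rs, dose) {
  sf <- survival_fraction(rs, dose)
  live <- state[["S"]] + state[["R"]]
  out <- state
  out[["S"]] <- state[["S"]] * sf
  out[["R"]] <- state[["R"]] * sf
  out[["Dead"]] <- state[["Dead"]] + live * (1 - sf)
  out
}

# Piecewise integration of the compartment states over [0, horizon].
# Returns a matrix with columns day, S, R, Dead, Dead_pre at the requested
# output times (values at a fraction time are the post-kill right limits;
# Dead_pre is the dead pool just before any kill at that time).
.integrate_states <- function(params, schedule, t_out, rtol = 1e-8,
                              atol = 1e-10) {
  t_out <- sort(unique(t_out))
  if (any(t_out < 0)) stop("output times must be >= 0")
  horizon <- max(t_out, 0)
  rf <- schedule$radiation_fractions
  rf <- rf[rf$time <= horizon + 1e-12, , drop = FALSE]
  seg <- schedule$drug_segments
  breaks <- sort(unique(c(0, horizon, rf$time,
                          seg$start[seg$start < horizon],
                          seg$end[seg$end < horizon])))
  breaks <- breaks[breaks >= 0 & breaks <= horizon]

  state <- c(S = params$N0 * (1 - params$f_R0),
             R = params$N0 * params$f_R0,
             Dead = 0)
  # Dead_pre holds the dead pool just before any radiation event at that
  # time: a media change coinciding with a fraction (day 0 in the assay
  # protocol) clears only the dead cells present before irradiation.
  res <- matrix(NA_real_, nrow = length(t_out), ncol = 4,
                dimnames = list(NULL, c("S", "R", "Dead", "Dead_pre")))
  cumD <- 0
  record <- function(t, st, dead_pre = st[["Dead"]]) {
    hit <- which(abs(t_out - t) < 1e-12)
    if (length(hit)) res[hit, ] <<- matrix(c(st, dead_pre), nrow = length(hit),
                                           ncol = 4, byrow = TRUE)
  }

  apply_fractions_at <- function(t, st) {
    here <- which(abs(rf$time - t) < 1e-12)
    for (i in here) {
      st <- unlist(apply_radiation_fraction(as.list(st), params$rs, rf$dose[i]))
      cumD <<- cumD + rf$dose[i]
    }
    st
  }

  dead_pre0 <- state[["Dead"]]
  state <- apply_fractions_at(0, state)
  record(0, state, dead_pre0)

  for (k in seq_len(length(breaks) - 1)) {
    a <- breaks[k]; b <- breaks[k + 1]
    if (b - a > 1e-12) {
      conc <- .drug_conc_on(schedule, a)
      rates <- effective_rates(params$coeffs, conc, cumD)
      nu <- if (conc > 0) params$nu_drug else 0
      times <- sort(unique(c(a, t_out[t_out > a + 1e-12 & t_out < b - 1e-12], b)))
      sol <- deSolve::ode(y = state, times = times, func = "nilrad_derivs",
                          parms = c(rates$rS, rates$rR, rates$dS, rates$dR,
                                    nu, params$K),
                          dllname = "nilrad", initfunc = "nilrad_initmod",
                          rtol = rtol, atol = atol)
      if (attr(sol, "istate")[1] < 0) {
        stop(sprintf("ODE solver failed on [%g, %g] (istate = %d)",
                     a, b, attr(sol, "istate")[1]))
      }
      for (j in seq_along(times)[-1]) {
        if (times[j] < b - 1e-12) record(times[j], sol[j, c("S", "R", "Dead")])
      }
      state <- sol[nrow(sol), c("S", "R", "Dead")]
      # clamp solver round-off; the dynamics cannot cross zero
      state[state < 0 & state > -atol * 100] <- 0
    }
    dead_pre <- state[["Dead"]]
    state <- apply_fractions_at(b, state)
    record(b, state, dead_pre)
  }
  # solver round-off near extinction can dip microscopically below zero
  if (any(res < -1e-6, na.rm = TRUE)) {
    stop("integration produced substantially negative populations; solver failure")
  }
  res[res < 0] <- 0
  cbind(day = t_out, res)
}

# Live-fraction (Trypan-blue style) viability: live / (live + dead
# accumulated since the last media change strictly before t), in percent.
.viability_live_fraction <- function(states, media_change_days) {
  # clearance baseline: dead pool at the last media change strictly before t,
  # measured before any radiation kill delivered at that same instant
  day <- states[, "day"]
  base_at <- stats::approxfun(day, states[, "Dead_pre"], rule = 2)
  vapply(seq_len(nrow(states)), function(i) {
    t <- day[i]
    prior <- media_change_days[media_change_days < t - 1e-12]
    base <- if (length(prior)) base_at(max(prior)) else 0
    live <- states[i, "S"] + states[i, "R"]
    if (live <= 0) return(0)                     # extinct culture reads 0%
    denom <- live + max(states[i, "Dead"] - base, 0)
    100 * live / denom
  }, numeric(1))
}

# Parameter record without validation, for hot paths where the components
# are already known to be valid.
.mk_params <- function(coeffs, rs, nu_drug, K, f_R0, N0) {
  structure(list(coeffs = coeffs, rs = rs, nu_drug = nu_drug, K = K,
                 f_R0 = f_R0, N0 = N0),
            class = "model_parameters")
}

# Viability values at `days` only, skipping trajectory assembly; the
# workhorse of the calibration loss.
.sim_viability <- function(params, schedule, days,
                           observable = "live_fraction",
                           rtol = 1e-8, atol = 1e-10) {
  mc <- schedule$media_change_days
  if (observable == "live_fraction") {
    internal <- sort(unique(c(days, mc[mc <= max(days)])))
    st <- .integrate_states(params, schedule, internal, rtol, atol)
    v <- .viability_live_fraction(st, mc)
    v[match(days, st[, "day"])]
  } else {
    st <- .integrate_states(params, schedule, days, rtol, atol)
    ctrl <- .integrate_states(params,
                              treatment_schedule(media_change_days = mc),
                              days, rtol, atol)
    ctrl_live <- ctrl[, "S"] + ctrl[, "R"]
    if (any(ctrl_live <= 0)) stop("control population is zero")
    pmin(100, 100 * (st[, "S"] + st[, "R"]) / ctrl_live)
  }
}

#' Simulate the population model under a treatment schedule
#'
#' Integrates the sensitive/resistant/dead compartments piecewise between
#' treatment events. At each radiation fraction an instantaneous
#' linear-quadratic kill is applied, and thereafter the dose-response rates
#' are evaluated at the cumulative radiation dose delivered so far. The drug
#' concentration is the active segment's value; the sensitive-to-resistant
#' conversion is active only while the concentration is positive.
#'
#' @param params A [model_parameters()] object.
#' @param schedule A [treatment_schedule()].
#' @param t_out Numeric vector of output days (>= 0). The state reported at a
#'   fraction time is the post-kill value.
#' @param observable Viability read-out: `"relative_to_control"` is
#'   100 x live(treated) / live(untreated control), capped at 100;
#'   `"live_fraction"` is 100 x live / (live + dead accumulated since the
#'   last media change), the Trypan-blue-style percentage.
#' @param control Optional pre-computed untreated control trajectory (as
#'   returned by this function) to avoid recomputation in
#'   `relative_to_control` mode.
#' @param rtol,atol Solver tolerances (lsoda).
#' @return A data frame of class `nilrad_trajectory` with columns `day`, `S`,
#'   `R`, `Dead`, `viability_pct`, `resistant_fraction`, carrying the
#'   parameters, schedule and solver settings as attributes.
#' @export
simulate_population <- function(params, schedule, t_out = seq(0, 10, 0.1),
                                observable = c("relative_to_control",
                                               "live_fraction"),
                                control = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(schedule, "treatment_schedule"))
  observable <- match.arg(observable)
  t_out <- sort(unique(t_out))
  if (!length(t_out)) stop("t_out must contain at least one time")

  mc <- schedule$media_change_days
  internal <- if (observable == "live_fraction") {
    sort(unique(c(t_out, mc[mc <= max(t_out)])))
  } else t_out
  states <- .integrate_states(params, schedule, internal, rtol, atol)

  if (observable == "live_fraction") {
    v_all <- .viability_live_fraction(states, mc)
    keep <- states[, "day"] %in% t_out
    states <- states[keep, , drop = FALSE]
    viability <- v_all[keep]
  } else {
    if (is.null(control)) {
      control_sched <- treatment_schedule(media_change_days = mc)
      control <- .integrate_states(params, control_sched, t_out, rtol, atol)
    }
    if (is.data.frame(control) || inherits(control, "nilrad_trajectory")) {
      ctrl_day <- control$day; ctrl_live <- control$S + control$R
    } else {
      ctrl_day <- control[, "day"]; ctrl_live <- control[, "S"] + control[, "R"]
    }
    m <- match(states[, "day"], ctrl_day)
    ctrl_live <- if (!anyNA(m)) {
      ctrl_live[m]
    } else {
      stats::approx(ctrl_day, ctrl_live, xout = states[, "day"], rule = 2)$y
    }
    if (any(ctrl_live <= 0)) {
      stop("control population is zero; relative viability undefined")
    }
    viability <- pmin(100, 100 * (states[, "S"] + states[, "R"]) / ctrl_live)
  }

  live <- states[, "S"] + states[, "R"]
  out <- data.frame(day = states[, "day"], S = states[, "S"],
                    R = states[, "R"], Dead = states[, "Dead"],
                    viability_pct = viability,
                    resistant_fraction = ifelse(live > 0,
                                                states[, "R"] / live,
                                                NA_real_))
  rownames(out) <- NULL
  structure(out,
            params = params, schedule = schedule, observable = observable,
            solver = list(method = "lsoda", rtol = rtol, atol = atol),
            class = c("nilrad_trajectory", "data.frame"))
}

#' Viability read-out of a simulated trajectory
#'
#' Recomputes the viability observable from the compartment states of a
#' trajectory, optionally against a different control or in a different mode
#' than the one used at simulation time.
#'
#' @param trajectory A trajectory from [simulate_population()].
#' @param mode `"relative_to_control"` or `"live_fraction"`.
#' @param control For `relative_to_control`: a control trajectory on a grid
#'   covering the trajectory's days; defaults to an untreated simulation with
#'   the trajectory's own parameters.
#' @return Numeric vector of viability percentages at the trajectory's days.
#' @export
viability <- function(trajectory,
                      mode = c("relative_to_control", "live_fraction"),
                      control = NULL) {
  stopifnot(inherits(trajectory, "nilrad_trajectory"))
  mode <- match.arg(mode)
  sched <- attr(trajectory, "schedule")
  params <- attr(trajectory, "params")
  if (mode == "live_fraction") {
    # re-integrate on a grid including media-change days for exact clearance
    tr <- simulate_population(params, sched, t_out = trajectory$day,
                              observable = "live_fraction")
    return(tr$viability_pct)
  }
  if (is.null(control)) {
    control <- simulate_population(params,
                                   treatment_schedule(media_change_days =
                                                        sched$media_change_days),
                                   t_out = trajectory$day,
                                   observable = "relative_to_control")
  }
  ctrl_live <- stats::approx(control$day, control$S + control$R,
                             xout = trajectory$day, rule = 2)$y
  if (any(ctrl_live <= 0)) stop("control population is zero")
  pmin(100, 100 * (trajectory$S + trajectory$R) / ctrl_live)
}

#' Simulated dose-response assay
#'
#' Emulates the 72-hour dose-response experiments: for each grid value, a
#' single acute treatment at day 0 and a viability read-out at `readout_day`.
#'
#' @param params A [model_parameters()] object.
#' @param doses Grid of doses: Gy when `agent = "radiation"`, nM when
#'   `agent = "nilotinib"`.
#' @param agent Which treatment the grid varies.
#' @param other_dose The fixed dose of the other agent (nM of Nilotinib for a
#'   radiation grid; Gy for a drug grid).
#' @param readout_day Day of the viability read-out (default 3, i.e. 72 h).
#' @param observable Viability mode, see [simulate_population()].
#' @return Data frame with columns `dose` and `viability_pct`.
#' @export
dose_response_assay <- function(params, doses,
                                agent = c("radiation", "nilotinib"),
                                other_dose = 0, readout_day = 3,
                                observable = "relative_to_control") {
  agent <- match.arg(agent)
  if (any(doses < 0) || other_dose < 0) stop("doses must be >= 0")
  v <- vapply(doses, function(x) {
    sched <- if (agent == "radiation") {
      acute_schedule(radiation_Gy = x, nilotinib_nM = other_dose,
                     horizon = readout_day)
    } else {
      acute_schedule(radiation_Gy = other_dose, nilotinib_nM = x,
                     horizon = readout_day)
    }
    tr <- simulate_population(params, sched, t_out = c(0, readout_day),
                              observable = observable)
    tr$viability_pct[tr$day == readout_day]
  }, numeric(1))
  data.frame(dose = doses, viability_pct = v)
}

#' Interpolated dose at 50 percent viability
#'
#' Linear interpolation between the two grid points bracketing the target
#' viability level on a (monotone) dose-response curve.
#'
#' @param curve Data frame with columns `dose` and `viability_pct`.
#' @param level Target viability percentage (default 50).
#' @return A list with `reached` (logical) and `dose` (the interpolated dose,
#'   or `NA` when the level is not bracketed by the curve).
#' @export
find_dose50 <- function(curve, level = 50) {
  stopifnot(all(c("dose", "viability_pct") %in% names(curve)))
  curve <- curve[order(curve$dose), , drop = FALSE]
  v <- curve$viability_pct - level
  hit <- which(v == 0)
  if (length(hit)) return(list(reached = TRUE, dose = curve$dose[hit[1]]))
  cross <- which(v[-length(v)] * v[-1] < 0)
  if (!length(cross)) return(list(reached = FALSE, dose = NA_real_))
  i <- cross[1]
  d <- curve$dose[i] + (curve$dose[i + 1] - curve$dose[i]) *
    (level - curve$viability_pct[i]) /
    (curve$viability_pct[i + 1] - curve$viability_pct[i])
  list(reached = TRUE, dose = d)
}
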