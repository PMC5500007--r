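#' Measurement-noise specification for synthetic viability data
#'
#' @param sd Standard deviation of the additive Gaussian measurement noise,
#'   in percentage points (default 3, emulating triplicate hemocytometer
#'   counts).
#' @param n_replicates Replicate draws per assay point (default 3).
#' @param bounds Truncation interval for the noisy viability (default
#'   `c(0, 100)`); draws outside are rejected and resampled.
#' @param seed Optional seed applied by the generators.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 3, n_replicates = 3, bounds = c(0, 100),
                       seed = NULL) {
  if (sd < 0) stop("noise sd must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  structure(list(sd = sd, n_replicates = n_replicates, bounds = bounds,
                 seed = seed),
            class = "noise_spec")
}

# Truncated-normal draws by rejection; cheap because sd is small relative
# to the [0, 100] range in every intended use.
.rtrunc_norm <- function(n, mean, sd, bounds) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= bounds[1] & draw <= bounds[2]
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a noisy viability time series for one treatment arm
#'
#' Simulates the model under the given schedule, reads the viability at the
#' requested days, and adds truncated Gaussian measurement noise with
#' `noise$n_replicates` independent draws per day.
#'
#' @param params A [model_parameters()] object.
#' @param schedule A [treatment_schedule()].
#' @param days Measurement days.
#' @param noise A [noise_spec()].
#' @param observable Viability mode (default `"live_fraction"`, the
#'   Trypan-blue-style read-out that the assay actually measures).
#' @param radiation_Gy,nilotinib_nM Condition labels recorded with each
#'   observation; default to the schedule's total dose and first
#'   segment concentration.
#' @return An observation data frame (`day`, `radiation_Gy`, `nilotinib_nM`,
#'   `replicate`, `viability_pct`).
#' @export
generate_viability_series <- function(params, schedule, days,
                                      noise = noise_spec(),
                                      observable = "live_fraction",
                                      radiation_Gy = NULL,
                                      nilotinib_nM = NULL) {
  stopifnot(inherits(noise, "noise_spec"))
  if (is.null(radiation_Gy)) {
    radiation_Gy <- sum(schedule$radiation_fractions$dose)
  }
  if (is.null(nilotinib_nM)) {
    nilotinib_nM <- if (nrow(schedule$drug_segments)) {
      schedule$drug_segments$conc[1]
    } else 0
  }
  run <- function() {
    tr <- simulate_population(params, schedule, t_out = sort(unique(days)),
                              observable = observable)
    do.call(rbind, lapply(days, function(d) {
      mv <- tr$viability_pct[tr$day == d]
      data.frame(day = d, radiation_Gy = radiation_Gy,
                 nilotinib_nM = nilotinib_nM,
                 replicate = seq_len(noise$n_replicates),
                 viability_pct = .rtrunc_norm(noise$n_replicates, mv,
                                              noise$sd, noise$bounds))
    }))
  }
  if (is.null(noise$seed)) run() else .with_seed(noise$seed, run())
}

#' Generate the full in vitro experiment suite
#'
#' Emulates the design of the parameterization and validation experiments:
#' viability time series at days 1, 3, 6, 8, 10 for the six arms
#' control, 2 Gy, 4 Gy, 18 nM, 18 nM + 2 Gy and 18 nM + 4 Gy (acute
#' radiation at day 0, drug maintained throughout, media changed on days 0,
#' 3, 6 and 8, triplicate measurements), plus 72-hour dose-response assays
#' over a radiation grid at 0 and 18 nM and a Nilotinib grid without
#' radiation.
#'
#' @param coeffs,rs,K,f_R0,N0 Generating model constants (defaults are the
#'   fitted values shipped with the package when `NULL`).
#' @param nu_drug Conversion rate for the drug-only arm (default 0.0409).
#' @param nu_combo Conversion rate for the combination arms (default
#'   0.1768).
#' @param noise A [noise_spec()]; its `seed` field is ignored here in favour
#'   of `seed`.
#' @param seed Single seed governing all noise draws.
#' @param observable Viability mode of the generated measurements.
#' @param days Time-series measurement days.
#' @return An observation data frame with an extra `series` column
#'   (`"timeseries"`, `"radiation_dr"`, `"drug_dr"`).
#' @export
generate_experiment_suite <- function(coeffs = NULL, rs = NULL, K = 4.2,
                                      f_R0 = 0.001, N0 = 1,
                                      nu_drug = 0.0409, nu_combo = 0.1768,
                                      noise = noise_spec(), seed = 1,
                                      observable = "live_fraction",
                                      days = c(1, 3, 6, 8, 10)) {
  if (is.null(coeffs) || is.null(rs)) {
    fp <- fitted_parameters()
    if (is.null(coeffs)) coeffs <- fp$coeffs
    if (is.null(rs)) rs <- fp$rs
  }
  arms <- data.frame(radiation_Gy = c(0, 2, 4, 0, 2, 4),
                     nilotinib_nM = c(0, 0, 0, 18, 18, 18))
  .with_seed(seed, {
    nspec <- noise_spec(noise$sd, noise$n_replicates, noise$bounds)
    ts <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
      D <- arms$radiation_Gy[i]; conc <- arms$nilotinib_nM[i]
      nu <- if (conc > 0 && D > 0) nu_combo else nu_drug
      params <- model_parameters(coeffs, rs, nu_drug = nu, K = K,
                                 f_R0 = f_R0, N0 = N0)
      cbind(generate_viability_series(params, acute_schedule(D, conc,
                                                             horizon = max(days)),
                                      days, nspec, observable),
            series = "timeseries")
    }))
    assay_noise <- function(mv) {
      .rtrunc_norm(nspec$n_replicates, mv, nspec$sd, nspec$bounds)
    }
    rad_grid <- c(0, 1, 2, 4, 6, 8, 10)
    rad <- do.call(rbind, lapply(c(0, 18), function(conc) {
      # conversion is context-dependent: drug-only at 0 Gy, combination
      # value once radiation is added
      curve <- do.call(rbind, lapply(rad_grid, function(D) {
        nu <- if (conc > 0 && D > 0) nu_combo else nu_drug
        params <- model_parameters(coeffs, rs, nu_drug = nu, K = K,
                                   f_R0 = f_R0, N0 = N0)
        dose_response_assay(params, D, "radiation", other_dose = conc,
                            observable = observable)
      }))
      do.call(rbind, lapply(seq_len(nrow(curve)), function(j) {
        data.frame(day = 3, radiation_Gy = curve$dose[j],
                   nilotinib_nM = conc,
                   replicate = seq_len(nspec$n_replicates),
                   viability_pct = assay_noise(curve$viability_pct[j]),
                   series = "radiation_dr")
      }))
    }))
    drug_grid <- c(0, 6, 12.5, 18)
    params_d <- model_parameters(coeffs, rs, nu_drug = nu_drug, K = K,
                                 f_R0 = f_R0, N0 = N0)
    curve <- dose_response_assay(params_d, drug_grid, "nilotinib",
                                 observable = observable)
    drug <- do.call(rbind, lapply(seq_len(nrow(curve)), function(j) {
      data.frame(day = 3, radiation_Gy = 0, nilotinib_nM = curve$dose[j],
                 replicate = seq_len(nspec$n_replicates),
                 viability_pct = assay_noise(curve$viability_pct[j]),
                 series = "drug_dr")
    }))
    out <- rbind(ts, rad, drug)
    rownames(out) <- NULL
    out
  })
}
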