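#' Read a flat parameter file (YAML or JSON)
#'
#' Parameter files are flat maps keyed `rS0` ... `dR2` for the dose-response
#' coefficients and `alpha`, `beta` for the radiosensitivity, optionally with
#' `K`, `f_R0`, `N0`, `nu_drug` and `nu_combo`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `coeffs` ([dose_response_coefficients()]),
#'   `rs` ([radiosensitivity()]), and any of `K`, `f_R0`, `N0`, `nu_drug`,
#'   `nu_combo` present in the file.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  coef_keys <- c("rS0", "rR0", "rS1", "rR1", "rS2", "rR2",
                 "dS0", "dR0", "dS1", "dR1", "dS2", "dR2")
  missing <- setdiff(c(coef_keys, "alpha", "beta"), names(raw))
  if (length(missing)) {
    stop("parameter file is missing keys: ", paste(missing, collapse = ", "))
  }
  out <- list(
    coeffs = do.call(dose_response_coefficients,
                     lapply(raw[coef_keys], as.numeric)),
    rs = radiosensitivity(as.numeric(raw$alpha), as.numeric(raw$beta))
  )
  for (k in c("K", "f_R0", "N0", "nu_drug", "nu_combo")) {
    if (!is.null(raw[[k]])) out[[k]] <- as.numeric(raw[[k]])
  }
  out
}

#' Write parameters to a flat YAML or JSON file
#'
#' @param coeffs A [dose_response_coefficients()] object.
#' @param rs A [radiosensitivity()] object.
#' @param path Output path; format chosen by extension (`.json` vs YAML).
#' @param ... Further scalar entries to store (e.g. `K`, `f_R0`, `nu_drug`,
#'   `nu_combo`, `N0`).
#' @return The path, invisibly.
#' @export
write_parameters <- function(coeffs, rs, path, ...) {
  stopifnot(inherits(coeffs, "dose_response_coefficients"),
            inherits(rs, "radiosensitivity"))
  flat <- c(lapply(unclass(coeffs), as.numeric),
            list(alpha = rs$alpha, beta = rs$beta), list(...))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(flat, path)
  }
  invisible(path)
}

#' Fitted model constants shipped with the package
#'
#' Loads the packaged parameter file holding the fitted linear dose-response
#' coefficients, LQ radiosensitivity (alpha = 0.6647 /Gy, beta = 0.079
#' /Gy^2), carrying capacity K = 4.2, initial resistant fraction 0.001, and
#' the conversion rates for the drug-only (0.0409 /day) and
#' drug-plus-radiation (0.1768 /day) contexts.
#'
#' @return See [read_parameters()].
#' @export
fitted_parameters <- function() {
  read_parameters(system.file("extdata", "fitted_parameters.yaml",
                              package = "nilrad", mustWork = TRUE))
}

#' Read viability observations from CSV
#'
#' Expects the columns `day`, `radiation_Gy`, `nilotinib_nM`, `replicate`,
#' `viability_pct`; extra columns are carried through. Each row is one
#' measured (or simulated) assay point.
#'
#' @param path CSV path.
#' @return A validated data frame of observations.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_observations(obs)
}

#' Validate a viability observation table
#'
#' @param obs Data frame with columns `day`, `radiation_Gy`, `nilotinib_nM`,
#'   `replicate`, `viability_pct`.
#' @return `obs`, invisibly validated (errors name the offending row).
#' @export
validate_observations <- function(obs) {
  required <- c("day", "radiation_Gy", "nilotinib_nM", "replicate",
                "viability_pct")
  missing <- setdiff(required, names(obs))
  if (length(missing)) {
    stop("observation table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  for (col in c("day", "radiation_Gy", "nilotinib_nM", "viability_pct")) {
    v <- suppressWarnings(as.numeric(obs[[col]]))
    bad <- which(is.na(v) & !is.na(obs[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at row %d", col, bad[1]))
    }
    if (anyNA(v)) stop(sprintf("missing value in column '%s' at row %d",
                               col, which(is.na(v))[1]))
    obs[[col]] <- v
  }
  if (any(obs$day < 0)) {
    stop("negative day at row ", which(obs$day < 0)[1])
  }
  bad <- which(obs$viability_pct < 0 | obs$viability_pct > 100)
  if (length(bad)) {
    stop(sprintf("viability_pct outside [0, 100] at row %d (value %g)",
                 bad[1], obs$viability_pct[bad[1]]))
  }
  if (any(obs$radiation_Gy < 0) || any(obs$nilotinib_nM < 0)) {
    stop("negative treatment dose at row ",
         which(obs$radiation_Gy < 0 | obs$nilotinib_nM < 0)[1])
  }
  obs
}

#' Write viability observations to CSV
#'
#' Viability is stored to 4 decimal places so that rate-table style
#' comparisons are exact across a write/read round trip.
#'
#' @param obs Observation data frame (see [read_observations()]).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_observations <- function(obs, path) {
  obs <- validate_observations(obs)
  obs$viability_pct <- round(obs$viability_pct, 4)
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' @param trajectory A trajectory from [simulate_population()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  df$viability_pct <- round(df$viability_pct, 4)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
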