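#' Dose-response coefficients for the linear rate model
#'
#' Bundles the twelve constants that map a Nilotinib concentration `c` (nM)
#' and a radiation dose `D` (Gy) to effective per-day proliferation and death
#' rates of the sensitive (S) and resistant (R) phenotypes:
#'
#' \deqn{r_\bullet = r_{\bullet,0} - (r_{\bullet,1} + r_{\bullet,2} D)\,c}
#' \deqn{d_\bullet = d_{\bullet,0} + (d_{\bullet,1} + d_{\bullet,2} D)\,c}
#'
#' The `*0` coefficients are baseline rates (per day), the `*1` coefficients
#' are per nM per day, and the `*2` interaction coefficients are per nM per
#' Gy per day. A non-zero interaction coefficient means radiation modulates
#' the strength of the drug response (radiosensitization / synergy).
#'
#' @param rS0,rR0 Baseline proliferation rates of sensitive and resistant
#'   cells (per day).
#' @param rS1,rR1 Drug sensitivity of proliferation (per nM per day).
#' @param rS2,rR2 Drug-radiation interaction on proliferation
#'   (per nM per Gy per day).
#' @param dS0,dR0 Baseline death rates (per day).
#' @param dS1,dR1 Drug sensitivity of death (per nM per day).
#' @param dS2,dR2 Drug-radiation interaction on death (per nM per Gy per day).
#' @param control_constrained If `TRUE`, enforce the untreated-control
#'   constraint `rS0 == rR0` and `dS0 == dR0` (the two phenotypes are
#'   indistinguishable in the absence of drug); construction fails if the
#'   supplied baselines differ.
#'
#' @return An immutable object of class `dose_response_coefficients`.
#' @seealso [effective_rates()], [proliferation_rate()], [death_rate()]
#' @export
dose_response_coefficients <- function(rS0, rR0, rS1, rR1, rS2, rR2,
                                       dS0, dR0, dS1, dR1, dS2, dR2,
                                       control_constrained = FALSE) {
  vals <- stats::setNames(
    as.numeric(c(rS0, rR0, rS1, rR1, rS2, rR2, dS0, dR0, dS1, dR1, dS2, dR2)),
    c("rS0", "rR0", "rS1", "rR1", "rS2", "rR2",
      "dS0", "dR0", "dS1", "dR1", "dS2", "dR2"))
  if (length(vals) != 12) stop("all twelve coefficients must be scalars")
  if (any(!is.finite(vals))) {
    stop("all dose-response coefficients must be finite numbers")
  }
  if (any(vals < 0)) {
    stop("dose-response coefficients must be non-negative; offending: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  }
  if (control_constrained) {
    if (!isTRUE(all.equal(rS0, rR0)) || !isTRUE(all.equal(dS0, dR0))) {
      stop("control-constrained coefficients require rS0 == rR0 and dS0 == dR0")
    }
  }
  structure(as.list(vals),
            control_constrained = control_constrained,
            class = "dose_response_coefficients")
}

#' @export
print.dose_response_coefficients <- function(x, ...) {
  cat("Linear dose-response coefficients (per day; drug in nM, radiation in Gy)\n")
  m <- matrix(unlist(x), nrow = 2, byrow = TRUE,
              dimnames = list(c("proliferation", "death"),
                              c("S0", "R0", "S1", "R1", "S2", "R2")))
  print(m, ...)
  invisible(x)
}

#' Radiosensitivity parameters of the linear-quadratic model
#'
#' @param alpha Cell kill per single radiation track (per Gy).
#' @param beta Cell kill per pair of independent tracks (per Gy squared).
#' @return An object of class `radiosensitivity`.
#' @seealso [survival_fraction()]
#' @export
radiosensitivity <- function(alpha, beta) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha < 0 || beta < 0) {
    stop("alpha and beta must be finite and non-negative")
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "radiosensitivity")
}

#' @export
print.radiosensitivity <- function(x, ...) {
  cat(sprintf("LQ radiosensitivity: alpha = %g /Gy, beta = %g /Gy^2\n",
              x$alpha, x$beta))
  invisible(x)
}

.check_doses <- function(c, D) {
  if (any(!is.finite(c)) || any(c < 0)) stop("Nilotinib concentration c must be >= 0")
  if (any(!is.finite(D)) || any(D < 0)) stop("radiation dose D must be >= 0")
}

#' Effective proliferation rate under treatment
#'
#' Evaluates the linear dose-response \eqn{r = r_0 - (r_1 + r_2 D)\,c} for
#' one phenotype. The linear form can become negative at high combined doses,
#' outside its intended regime near the IC50; a negative logistic birth rate
#' is unphysical, so the result is floored at zero with a warning (class
#' `nilrad_rate_floor`).
#'
#' @param coeffs A [dose_response_coefficients()] object.
#' @param phenotype `"sensitive"` or `"resistant"`.
#' @param c Nilotinib concentration (nM, scalar >= 0).
#' @param D Radiation dose entering the rate modification (Gy, scalar >= 0).
#'   For fractionated protocols this is the cumulative dose delivered so far.
#' @return Proliferation rate (per day), floored at 0.
#' @export
proliferation_rate <- function(coeffs, phenotype = c("sensitive", "resistant"),
                               c, D) {
  stopifnot(inherits(coeffs, "dose_response_coefficients"))
  phenotype <- match.arg(phenotype)
  .check_doses(c, D)
  r <- if (phenotype == "sensitive") {
    coeffs$rS0 - (coeffs$rS1 + coeffs$rS2 * D) * c
  } else {
    coeffs$rR0 - (coeffs$rR1 + coeffs$rR2 * D) * c
  }
  if (r < 0) {
    warning(warningCondition(
      sprintf("linear dose-response gives negative %s proliferation rate (%.4g) at c = %g nM, D = %g Gy; floored at 0",
              phenotype, r, c, D),
      class = "nilrad_rate_floor"))
    r <- 0
  }
  r
}

#' Effective death rate under treatment
#'
#' Evaluates `d = d0 + (d1 + d2 * D) * c` for one phenotype. With
#' non-negative coefficients the result is non-negative by construction.
#'
#' @inheritParams proliferation_rate
#' @return Death (apoptosis) rate (per day).
#' @export
death_rate <- function(coeffs, phenotype = c("sensitive", "resistant"), c, D) {
  stopifnot(inherits(coeffs, "dose_response_coefficients"))
  phenotype <- match.arg(phenotype)
  .check_doses(c, D)
  if (phenotype == "sensitive") {
    coeffs$dS0 + (coeffs$dS1 + coeffs$dS2 * D) * c
  } else {
    coeffs$dR0 + (coeffs$dR1 + coeffs$dR2 * D) * c
  }
}

#' All four effective rates for a treatment condition
#'
#' Bundles the four linear dose-response evaluations (rS, rR, dS, dR) at a
#' given Nilotinib concentration and radiation dose — one row of the
#' fitted-model rate table.
#'
#' @inheritParams proliferation_rate
#' @return A named list of class `model_rates` with elements
#'   `rS`, `rR`, `dS`, `dR` (per day).
#' @export
effective_rates <- function(coeffs, c, D) {
  structure(list(
    rS = proliferation_rate(coeffs, "sensitive", c, D),
    rR = proliferation_rate(coeffs, "resistant", c, D),
    dS = death_rate(coeffs, "sensitive", c, D),
    dR = death_rate(coeffs, "resistant", c, D)
  ), class = "model_rates")
}

#' @export
print.model_rates <- function(x, ...) {
  cat(sprintf("rS = %.4f, rR = %.4f, dS = %.4f, dR = %.4f (per day)\n",
              x$rS, x$rR, x$dS, x$dR))
  invisible(x)
}

#' Linear-quadratic radiation survival fraction
#'
#' Fraction of cells surviving an acute radiation exposure of `dose` Gy:
#' `exp(-alpha * dose - beta * dose^2)`. Applied as an instantaneous kill at
#' each radiation fraction; both phenotypes share the same radiosensitivity.
#'
#' @param rs A [radiosensitivity()] object.
#' @param dose Acute (per-fraction) radiation dose (Gy, >= 0).
#' @return Surviving fraction in (0, 1]; exactly 1 at dose 0.
#' @export
survival_fraction <- function(rs, dose) {
  stopifnot(inherits(rs, "radiosensitivity"))
  if (any(!is.finite(dose)) || any(dose < 0)) stop("radiation dose must be >= 0")
  exp(-rs$alpha * dose - rs$beta * dose^2)
}
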