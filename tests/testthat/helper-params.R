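# Fitted constants used throughout the tests, built in code.

fitted_coeffs <- function() {
  dose_response_coefficients(
    rS0 = 2.5369, rR0 = 2.5369, rS1 = 0.0155, rR1 = 0, rS2 = 0.0140, rR2 = 0,
    dS0 = 2.0550, dR0 = 2.0550, dS1 = 0, dR1 = 0, dS2 = 0.0025, dR2 = 0.0114,
    control_constrained = TRUE)
}

fitted_rs <- function() radiosensitivity(alpha = 0.6647, beta = 0.079)

generating_truth <- function() {
  c(r0 = 2.5369, d0 = 2.0550, K = 4.2, alpha = 0.6647, beta = 0.079,
    rS1 = 0.0155, rR1 = 0, dS1 = 0, dR1 = 0, nu = 0.0409,
    rS2 = 0.0140, rR2 = 0, dS2 = 0.0025, dR2 = 0.0114, nu_combo = 0.1768)
}

combo_params <- function(nu = 0.1768) {
  model_parameters(fitted_coeffs(), fitted_rs(), nu_drug = nu,
                   K = 4.2, f_R0 = 0.001, N0 = 1)
}

# Brute-force fixed-step Euler integration of the compartment ODEs under
# constant rates; independent of the deSolve path it cross-checks.
euler_states <- function(rates, nu, K, S0, R0, t_end, dt = 1e-4) {
  n <- round(t_end / dt)
  S <- S0; R <- R0; D <- 0
  for (i in seq_len(n)) {
    crowd <- 1 - (S + R) / K
    dS <- rates$rS * S * crowd - rates$dS * S - nu * S
    dR <- rates$rR * R * crowd - rates$dR * R + nu * S
    dD <- rates$dS * S + rates$dR * R
    S <- S + dt * dS; R <- R + dt * dR; D <- D + dt * dD
  }
  c(S = S, R = R, Dead = D)
}
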