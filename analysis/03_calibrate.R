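#!/usr/bin/env Rscript
# Round-trip calibration study: generate the synthetic experiment suite from
# the fitted constants, run the three-stage estimation, and tabulate how
# well each generating parameter is recovered, noiselessly and at the
# 3-point replicate noise level.

library(nilrad)
dir.create("results", showWarnings = FALSE)

truth <- c(r0 = 2.5369, d0 = 2.0550, K = 4.2, alpha = 0.6647, beta = 0.079,
           rS1 = 0.0155, rR1 = 0, dS1 = 0, dR1 = 0, nu = 0.0409,
           rS2 = 0.0140, rR2 = 0, dS2 = 0.0025, dR2 = 0.0114,
           nu_combo = 0.1768)

run_one <- function(sd, seed, n_starts) {
  suite <- generate_experiment_suite(seed = seed, noise = noise_spec(sd = sd))
  fit <- suppressWarnings(fit_pipeline(suite, n_starts = n_starts,
                                       seed = seed))
  c(fit$stage1$estimates, fit$stage2$estimates, fit$stage3$estimates)
}

message("Noiseless round trip (exact recovery expected) ...")
est0 <- run_one(sd = 0, seed = 1, n_starts = 8)
tab0 <- data.frame(parameter = names(truth), truth = truth,
                   estimate = est0[names(truth)],
                   rel_error_pct = 100 * abs(est0[names(truth)] - truth) /
                     pmax(abs(truth), 0.01))
write.csv(tab0, "results/calibration_noiseless.csv", row.names = FALSE)
print(tab0, row.names = FALSE, digits = 4)

message("\nNoisy round trips (sd = 3 points, triplicates, 8 seeds) ...")
seeds <- 1:8
ests <- sapply(seeds, function(s) run_one(sd = 3, seed = s, n_starts = 3))
rel_err <- abs(ests - truth) / pmax(abs(truth), 0.01)
tab <- data.frame(parameter = names(truth),
                  truth = truth,
                  median_estimate = apply(ests, 1, median),
                  median_rel_error_pct = 100 * apply(rel_err, 1, median))
write.csv(tab, "results/calibration_noisy.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 4)

message("\nThe baseline constants (r0, d0, K, alpha, beta) and the dominant ",
        "coefficients (rS1, dR2) are recovered stably; the small interaction ",
        "coefficient dS2 and the conversion rates sit below the noise floor ",
        "of the compressed live-fraction scale and drift widely - see the ",
        "methods vignette for the identifiability discussion.")
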