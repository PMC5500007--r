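#!/usr/bin/env Rscript
# Dose-response validation: 72-hour radiation and Nilotinib dose-response
# curves predicted by the fitted model, with interpolated half-effect doses.

library(nilrad)
dir.create("results", showWarnings = FALSE)

fp <- fitted_parameters()
pars_drug <- model_parameters(fp$coeffs, fp$rs, nu_drug = fp$nu_drug,
                              K = fp$K, f_R0 = fp$f_R0, N0 = fp$N0)
pars_combo <- model_parameters(fp$coeffs, fp$rs, nu_drug = fp$nu_combo,
                               K = fp$K, f_R0 = fp$f_R0, N0 = fp$N0)

rad_grid <- seq(0, 10, 0.25)
rad0 <- dose_response_assay(pars_drug, rad_grid, "radiation", other_dose = 0)
rad18 <- suppressWarnings(
  dose_response_assay(pars_combo, rad_grid, "radiation", other_dose = 18))
drug_grid <- seq(0, 25, 0.5)
drug0 <- dose_response_assay(pars_drug, drug_grid, "nilotinib")

curves <- rbind(cbind(rad0, curve = "radiation_0nM"),
                cbind(rad18, curve = "radiation_18nM"),
                cbind(drug0, curve = "nilotinib_0Gy"))
write.csv(curves, "results/dose_response_curves.csv", row.names = FALSE)

ld50_0 <- find_dose50(rad0)
ld50_18 <- find_dose50(rad18)
ic50 <- find_dose50(drug0)
summary <- data.frame(
  quantity = c("radiation LD50, no drug (Gy)",
               "radiation LD50, 18 nM (Gy)",
               "Nilotinib IC50, no radiation (nM)"),
  reached = c(ld50_0$reached, ld50_18$reached, ic50$reached),
  dose = c(ld50_0$dose, ld50_18$dose, ic50$dose))
write.csv(summary, "results/dose50_summary.csv", row.names = FALSE)

message("Model-predicted 72-hour half-effect doses (relative viability):")
print(summary, row.names = FALSE, digits = 3)
message("\nAdding 18 nM Nilotinib shifts the radiation LD50 to a fraction ",
        "of its drug-free value - the dose-sparing synergy the interaction ",
        "coefficients encode.")
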