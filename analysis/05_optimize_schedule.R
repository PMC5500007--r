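#!/usr/bin/env Rscript
# Fractionation-schedule optimization: split a 2 Gy budget over days 0-4
# under constant 18 nM Nilotinib to minimize day-10 viability; compare with
# the uniform and acute references and with a back-loaded drug titration.

library(nilrad)
dir.create("results", showWarnings = FALSE)

fp <- fitted_parameters()
params <- model_parameters(fp$coeffs, fp$rs, nu_drug = fp$nu_combo,
                           K = fp$K, f_R0 = fp$f_R0, N0 = fp$N0)
prob <- fractionation_problem(params, fraction_days = 0:4, budget = 2,
                              drug_nM = 18, objective_day = 10)

opt <- suppressWarnings(optimize_fractionation(prob, seed = 1))
message("Optimal dose split (Gy/day over days 0-4): ",
        paste(sprintf("%.4f", opt$doses), collapse = ", "))
message("Day-10 relative viability: ", sprintf("%.4f%%", opt$objective))

cmp <- compare_protocols(prob, list(optimal = opt$doses,
                                    uniform = rep(0.4, 5),
                                    acute = c(2, 0, 0, 0, 0)))
write.csv(cmp$trajectories, "results/protocol_trajectories.csv",
          row.names = FALSE)
message("Day-10 viability by protocol (best first):")
print(round(cmp$objective, 4))
message("Under the fitted synergy the optimum front-loads the whole budget ",
        "into day 0: the LQ kill is superadditive in acute dose and the ",
        "cumulative-dose rule rewards early delivery, so the acute protocol ",
        "is the optimal member of this family.")

titr <- evaluate_titration(prob,
                           data.frame(start = c(0, 3, 7), end = c(3, 7, 10),
                                      conc = c(10, 18, 26)),
                           doses = opt$doses)
message(sprintf(
  "Back-loaded 10/18/26 nM titration (same 18 nM average): %.4f%% vs %.4f%% constant",
  titr$objective, titr$reference_objective))

jsonlite::write_json(
  list(doses_Gy = opt$doses, objective_pct = opt$objective,
       references = as.list(round(cmp$objective, 4)),
       titration_pct = titr$objective),
  "results/optimal_schedule.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
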