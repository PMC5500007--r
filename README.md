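# nilrad

Population dynamics of tyrosine-kinase-inhibitor resistance in
Philadelphia-chromosome-positive acute lymphoblastic leukemia (Ph+ ALL)
under combined Nilotinib and low-dose radiation.

Ph+ ALL is driven by the BCR-ABL fusion kinase; TKI therapy (here
Nilotinib) suppresses the bulk population but selects and induces resistant
subclones that regrow. `nilrad` is for modellers and radiation biologists
who want to simulate, calibrate and optimize this system in vitro: it
implements the deterministic two-phenotype model, fits it to cell-viability
time series the way the underlying experiments were staged, generates
synthetic data with the experiments' structure, and optimizes fractionated
radiation schedules under a total-dose budget.

## The model

Sensitive ($S$) and resistant ($R$) cells share a logistic carrying
capacity $K$, die by apoptosis, and convert $S \to R$ at rate $\nu$ while
drug is present:

    dS/dt = rS·S·(1 − (S+R)/K) − dS·S − ν·S
    dR/dt = rR·R·(1 − (S+R)/K) − dR·R + ν·S
    dDead/dt = dS·S + dR·R

Treatment enters twice. The per-day rates respond linearly to the Nilotinib
concentration `c` (nM) and radiation dose `D` (Gy),

    r = r0 − (r1 + r2·D)·c ,   d = d0 + (d1 + d2·D)·c ,

with the `·2` coefficients encoding drug–radiation synergy; and each
radiation fraction additionally kills instantaneously with the
linear-quadratic surviving fraction `exp(−αD − βD²)`. For fractionated
protocols the rate-modifying `D` is the cumulative dose delivered so far.
Calibration is staged least squares on viability percentages: drug-free
arms first (baselines, $K$, $\alpha$, $\beta$), then the drug-only arm
(per-nM coefficients and $\nu$), then the combination arms (interaction
coefficients and $\nu_{combo}$).

## Worked example

```r
library(nilrad)

fp <- fitted_parameters()            # packaged fitted constants

# effective rates under 18 nM + 2 Gy
effective_rates(fp$coeffs, c = 18, D = 2)
#> rS = 1.7539, rR = 2.5369, dS = 2.1450, dR = 2.4654 (per day)

survival_fraction(fp$rs, 2)          # LQ kill of an acute 2 Gy fraction
#> [1] 0.1929354

# simulate the combination arm: acute 2 Gy at day 0 + constant 18 nM
params <- model_parameters(fp$coeffs, fp$rs, nu_drug = fp$nu_combo)
tr <- simulate_population(params, acute_schedule(2, 18), t_out = 0:10)
round(tr$viability_pct, 2)
#> [1] 19.29 13.98 10.90  9.24  8.41  8.07  8.00  8.08  8.25  8.46  8.69
```

The trajectory is the model's account of the combination arm: the acute
fraction removes ~81% of cells at once, the drugged survivors decline
further, and the resistant compartment grows back too slowly to escape —
relative viability stays below 10% from day 3 onward (8.69% at day 10).
Under 18 nM alone the same model declines to a ~67% nadir near day 5 and
then recovers as resistant cells take over.

Optimizing a 2 Gy budget over days 0–4 under 18 nM:

```r
prob <- fractionation_problem(params, fraction_days = 0:4, budget = 2)
optimize_fractionation(prob)
#> Optimal fractionation: doses (Gy) = 2.0000, 0.0000, 0.0000, 0.0000, 0.0000
#> objective-day viability = 8.6874%
```

Under the fitted synergy the optimum front-loads the entire budget into
day 0 (uniform 0.4 Gy × 5 reaches only 13.63%); the methods vignette
(`vignettes/nilrad-methods.Rmd`) discusses why both the LQ kill and the
cumulative-dose rule push this way.

The numbered scripts under `analysis/` run the full workflow — rate
tables, arm simulations, calibration round trips, dose-response validation
and schedule optimization — writing tables under `results/`.

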