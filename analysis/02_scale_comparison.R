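#!/usr/bin/env Rscript
## Scale-dependent process behavior at the design center point (34 degC, F2):
## compare the bolus-fed shake flask against the continuously fed 15 L
## bioreactor and estimate the specific rates by smoothing splines.
## Writes results/center_point_comparison.csv and results/center_point_rates.csv.

suppressMessages(library(hybridoe))

sh <- simulate_run(static_design(34, "F2", planned_duration = 336),
                   "shake_flask", noiseless = TRUE, run_id = "shaker_cp")
br <- simulate_run(static_design(34, "F2", planned_duration = 360),
                   "bioreactor", noiseless = TRUE, run_id = "bioreactor_cp")

comp <- rbind(
  cbind(scale = "shake_flask", sh$samples[c("time", "vcc", "titer", "viability")]),
  cbind(scale = "bioreactor", br$samples[c("time", "vcc", "titer", "viability")]))
dir.create("results", showWarnings = FALSE)
write.csv(comp, "results/center_point_comparison.csv", row.names = FALSE)

rates <- rbind(
  cbind(scale = "shake_flask",
        estimate_specific_rates(sh, times = seq(12, max(sh$samples$time) - 12, 12))),
  cbind(scale = "bioreactor",
        estimate_specific_rates(br, times = seq(12, max(br$samples$time) - 12, 12))))
rates$mu_per_day <- rates$mu * 24
write.csv(rates, "results/center_point_rates.csv", row.names = FALSE)

cat(sprintf("shaker:    peak VCC %.1f e6/mL on day %g, max titer %.2f g/L, harvest day %g\n",
            max(sh$samples$vcc), sh$samples$time[which.max(sh$samples$vcc)] / 24,
            max(sh$samples$titer), max(sh$samples$time) / 24))
cat(sprintf("bioreactor: VCC %.1f e6/mL and titer %.2f g/L at day %g, viability %.0f%%\n",
            tail(br$samples$vcc, 1), tail(br$samples$titer, 1),
            max(br$samples$time) / 24, tail(br$samples$viability, 1)))
cat(sprintf("spline-estimated growth rate, shaker: %.2f (early) to %.2f (late) 1/day\n",
            max(rates$mu_per_day[rates$scale == "shake_flask"]),
            min(rates$mu_per_day[rates$scale == "shake_flask"])))
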