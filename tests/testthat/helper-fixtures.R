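# Shared fixtures, built once per test run and memoized.  Everything is
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Noiseless center-point runs (the scale-comparison pair).
fix_shaker_cp <- function() memo("shaker_cp",
  simulate_run(static_design(34, "F2", planned_duration = 336),
               "shake_flask", ground_truth(), noiseless = TRUE,
               run_id = "shaker_cp"))

fix_biorx_cp <- function() memo("biorx_cp",
  simulate_run(static_design(34, "F2", planned_duration = 360),
               "bioreactor", ground_truth(), noiseless = TRUE,
               run_id = "biorx_cp"))

# Default-noise study datasets (master seed 1, fixed for the whole suite).
fix_transfer_training <- function() memo("transfer_training",
  make_dataset("transfer_training", ground_truth(), seed = 1))

fix_transfer_test <- function() memo("transfer_test",
  make_dataset("transfer_test", ground_truth(), seed = 1))

fix_idoe_training <- function() memo("idoe_training",
  make_dataset("idoe_training", ground_truth(), seed = 1))

fix_idoe_test <- function() memo("idoe_test",
  make_dataset("idoe_test", ground_truth(), seed = 1))

# The transfer ensemble is expensive; several acceptance checks share it.
fix_transfer_ensemble <- function() memo("transfer_ensemble",
  fit_hybrid(fix_transfer_training(),
             cv = cv_config(n_repeats = 10, seed = 7)))

# A tiny run with constant rates for integrator oracles: no feed, short.
fix_const_run <- function(duration = 48) {
  samples <- data.frame(time = seq(0, duration, by = 24),
                        vcc = 1, viability = 100, titer = 0)
  for (a in ANALYTE_NAMES) samples[[a]] <- 1
  cultivation_run("const", "shake_flask", 0.3,
                  static_design(34, "F2", planned_duration = duration),
                  feed_schedule("bolus", feed_composition = feed_composition()),
                  samples,
                  data.frame(time = samples$time, volume = 0.3))
}
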