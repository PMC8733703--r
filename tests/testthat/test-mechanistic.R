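test_that("dilution rate is feed flow over volume", {
  expect_identical(dilution_rate(0, 15), 0)
  expect_equal(dilution_rate(0.015, 15), 0.001)
  expect_equal(dilution_rate(0.5, 0.3), 1.6667, tolerance = 1e-4)
  expect_error(dilution_rate(0.1, 0), "volume")
})

test_that("bolus addition dilutes cells and mixes analytes conservatively", {
  res <- apply_bolus(10, 0, c(glucose = 0), 0.3, 0.01, c(glucose = 0))
  expect_equal(res$X, 10 * 0.3 / 0.31, tolerance = 1e-10)

  res <- apply_bolus(10, 1, c(glucose = 1), 0.3, 0, c(glucose = 41))
  expect_equal(res$X, 10)
  expect_equal(res$analytes[["glucose"]], 1)

  res <- apply_bolus(10, 1, c(glucose = 1), 0.3, 0.0099, c(glucose = 41))
  expect_equal(res$analytes[["glucose"]], (0.3 + 0.40590) / 0.3099,
               tolerance = 1e-6)
})

test_that("bolus conserves total cell count and product mass", {
  # property over random states
  states <- with_seed(11, data.frame(X = runif(20, 0.1, 25),
                                     P = runif(20, 0, 1),
                                     V = runif(20, 0.2, 16),
                                     vB = runif(20, 1e-4, 0.05)))
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    res <- apply_bolus(s$X, s$P, c(glucose = 5), s$V, s$vB, c(glucose = 50))
    expect_equal(res$X * res$V, s$X * s$V, tolerance = 1e-12)
    expect_equal(res$P * res$V, s$P * s$V, tolerance = 1e-12)
  }
})

test_that("integrate_states matches closed forms for constant rates", {
  run <- fix_const_run(48)
  # exponential growth, no dilution
  tr <- integrate_states(function(t) c(0.03, 0), run, X0 = 0.25, P0 = 0)
  expect_equal(tr$X[tr$time == 24], 0.25 * exp(0.72), tolerance = 1e-6)
  # product accumulation at constant X (mu = 0)
  tr <- integrate_states(function(t) c(0, 2e-4), run, X0 = 10, P0 = 0)
  expect_equal(tr$P[tr$time == 48], 10 * 2e-4 * 48, tolerance = 1e-6)
})

test_that("continuous feed at mu = D holds the cell concentration steady", {
  dur <- 96
  samples <- data.frame(time = seq(0, dur, 24), vcc = 1, viability = 100,
                        titer = 0)
  for (a in ANALYTE_NAMES) samples[[a]] <- 1
  run <- cultivation_run("steady", "bioreactor", 15,
                         design("static",
                                data.frame(start_time = 0.0001,
                                           temperature = 34,
                                           feed_level = "F2"),
                                batch_end = 0.0001, planned_duration = dur),
                         feed_schedule("continuous", flow = 0.15,
                                       feed_composition = feed_composition()),
                         samples,
                         data.frame(time = samples$time,
                                    volume = 15 + 0.15 * samples$time))
  Dfun <- function(t) 0.15 / (15 + 0.15 * t)
  tr <- integrate_states(function(t) c(Dfun(t), 0), run, X0 = 2, P0 = 0,
                         dense_by = 4)
  expect_equal(tr$X, rep(2, nrow(tr)), tolerance = 1e-6)
})

test_that("refining the integration grid leaves the solution unchanged", {
  run <- fix_shaker_cp()
  # smooth synthetic rate profile over the run's span
  rate_fn <- function(t) c(0.04 * exp(-t / 150), 4e-4 * (1 - exp(-t / 100)))
  tr1 <- integrate_states(rate_fn, run, dense_by = 2)
  tr2 <- integrate_states(rate_fn, run, dense_by = 0.25)
  at <- match(run$samples$time, tr2$time)
  at1 <- match(run$samples$time, tr1$time)
  expect_equal(tr1$X[at1], tr2$X[at], tolerance = 1e-6)
  expect_equal(tr1$P[at1], tr2$P[at], tolerance = 1e-6)
})

test_that("integrating the simulator's true rates reproduces its trajectory", {
  # continuous feeding: rates are smooth, agreement is solver-limited
  run <- fix_biorx_cp()
  truth <- attr(run, "truth")
  mu_fn <- stats::approxfun(truth$time, truth$mu, rule = 2)
  v_fn <- stats::approxfun(truth$time, truth$vpx, rule = 2)
  tr <- integrate_states(function(t) c(mu_fn(t), v_fn(t)), run,
                         dense_by = 0.25)
  at <- match(run$samples$time, tr$time)
  expect_equal(tr$X[at], run$samples$vcc, tolerance = 1e-3)
  expect_equal(tr$P[at], run$samples$titer, tolerance = 2e-3)

  # bolus feeding: the true rates jump at each addition, so interpolating
  # the recorded truth is the limiting error, not the integrator
  run_s <- fix_shaker_cp()
  truth <- attr(run_s, "truth")
  mu_fn <- stats::approxfun(truth$time, truth$mu, rule = 2)
  v_fn <- stats::approxfun(truth$time, truth$vpx, rule = 2)
  tr_s <- integrate_states(function(t) c(mu_fn(t), v_fn(t)), run_s,
                           dense_by = 0.25)
  at <- match(run_s$samples$time, tr_s$time)
  expect_equal(tr_s$X[at], run_s$samples$vcc, tolerance = 0.08)
})

test_that("rate functions returning non-finite values are reported with time", {
  run <- fix_const_run(48)
  expect_error(integrate_states(function(t) c(ifelse(t > 10, NaN, 0.01), 0),
                                run),
               "non-finite")
})

test_that("input interpolation is exact at nodes, linear between, right-continuous at shifts", {
  run <- fix_biorx_cp()
  s <- run$samples
  u <- interpolate_inputs(run, s$time)
  expect_equal(unname(u[, "glutamine"]), s$glutamine)
  expect_equal(unname(u[, "alanine"]), s$alanine)

  # midpoint linearity
  u_mid <- interpolate_inputs(run, (s$time[3] + s$time[4]) / 2)
  expect_equal(u_mid[, "glutamine"],
               (s$glutamine[3] + s$glutamine[4]) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)

  # step CPPs around a shift (intensified design)
  d <- make_bioreactor_designs()[["bioreactor_04"]]
  run4 <- simulate_run(d, "bioreactor", noiseless = TRUE, run_id = "b04")
  eps <- 1e-6
  before <- interpolate_inputs(run4, 120 - eps)
  after <- interpolate_inputs(run4, 120 + eps)
  at <- interpolate_inputs(run4, 120)
  expect_equal(before[, "temperature"], 34, ignore_attr = TRUE)
  expect_equal(after[, "temperature"], 37, ignore_attr = TRUE)
  expect_equal(at[, "temperature"], 37, ignore_attr = TRUE)  # right-continuous

  # batch phase: batch temperature, no feed glucose
  u0 <- interpolate_inputs(run4, 10)
  expect_equal(u0[, "temperature"], 37, ignore_attr = TRUE)
  expect_equal(u0[, "feed_glucose"], 0, ignore_attr = TRUE)

  expect_error(interpolate_inputs(run4, max(run4$samples$time) + 5), "span")
})

test_that("smoothing-spline rate estimation recovers constant rates", {
  # noiseless exponential growth, no feeding
  times <- seq(0, 96, by = 12)
  samples <- data.frame(time = times, vcc = 0.25 * exp(0.02 * times),
                        viability = 100, titer = 0.5)
  for (a in ANALYTE_NAMES) samples[[a]] <- 1
  run <- cultivation_run("exp", "shake_flask", 0.3,
                         static_design(34, "F2", planned_duration = 96),
                         feed_schedule("bolus",
                                       feed_composition = feed_composition()),
                         samples, data.frame(time = times, volume = 0.3))
  # no boluses before 96 h? fed-batch starts at 72: override batch_end
  run$design$batch_end <- 200
  run$design$segments$start_time <- 200
  rates <- estimate_specific_rates(run, times = seq(6, 90, by = 6))
  expect_lt(max(abs(rates$mu - 0.02)) / 0.02, 0.02)
  # constant titer -> zero production
  expect_lt(max(abs(rates$vpx)), 1e-5)
})

test_that("spline rates on the noiseless center point show the published shape", {
  run <- fix_shaker_cp()
  s <- run$samples
  rates <- estimate_specific_rates(run, times = seq(24, max(s$time) - 12, 12))
  # growth starts high and ends negative (the crash), like the reported
  # almost-linear decline of the flask's specific growth rate
  expect_gt(max(rates$mu) * 24, 0.3)          # early, in 1/day
  expect_lt(rates$mu[length(rates$mu)], 0)    # negative at the end
  # the spline growth rate crosses zero near the observed VCC peak
  cross <- rates$time[which(diff(sign(rates$mu)) < 0)[1]]
  peak <- s$time[which.max(s$vcc)]
  expect_lte(abs(cross - peak), 36)
  expect_error(estimate_specific_rates(
    cultivation_run("tiny", "shake_flask", 0.3, run$design, run$feed,
                    run$samples[1:3, ], run$volume_trace[1:3, ])),
    ">= 4")
})
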