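## Ground-truth fed-batch CHO simulator and design factories.  The study the
## package emulates deposited no raw data, so every pipeline stage is tested
## against this simulator's known truth: smooth rate surfaces driven by the
## (adaptation-lagged) critical process parameters and the analyte state,
## analyte balances with feeding, a depletion/overflow-driven stress model for
## viability, and a lognormal observation model.

#' Default ground-truth parameters of the simulator
#'
#' The rate laws are minimal smooth forms.  The specific growth rate is a
#' temperature bell (optimum 37 degC) times a convex (Hill-2) glutamine
#' response with a small glutamine-independent floor, an asparagine term
#' and an alanine inhibition term, minus a sharply alanine-driven death
#' term; the specific production rate has a growth-associated share and is
#' a temperature bell (optimum 35 degC) times saturating feed-glucose,
#' aspartate/glutamate-ratio and asparagine terms, minus an alanine-driven
#' degradation term.  Cells adapt to CPP shifts through a first-order lag
#' (time constant \code{tau}, default 48 h).  Scale-dependent behavior
#' emerges from the feeding mode alone: daily boluses create glutamine
#' sawtooths (pulsed supply is more growth-effective through the convex
#' response, and high-glutamine consumption overflows to alanine, whose
#' accumulation drives the late shaker crash and the viability decline),
#' while continuous feeding settles into a supply-limited quasi-steady
#' state with slow, monotone growth.  Aspartate and glutamate start from
#' lot-dependent media compositions (three lots cycled deterministically
#' over run numbers), so the aspartate/glutamate ratio carries run-specific
#' information.
#'
#' @param ... named overrides of the defaults.
#' @return list of class \code{hd_ground_truth}.
#' @export
ground_truth <- function(...) {
  p <- list(
    tau = 48,                      # CPP adaptation time constant (h)
    ## growth rate surface
    mu_max = 0.1,                  # 1/h
    T_opt_mu = 37, T_w_mu = 4,     # degC
    K_gln = 0.22, hill_gln = 2,    # g/L, convex low-glutamine response
    gln_floor = 0.02,              # glutamine-independent growth fraction
    asn_w = 0.45, K_asn = 0.40,    # asparagine modulation of growth
    K_ala_i = 2.2,                 # g/L, alanine growth inhibition
    k_death = 0.035, K_ala_d = 1.7, # alanine-driven death (1/h, g/L)
    ## production rate surface
    v_max = 5.2e-3,                # g/L/h per 1e6 cells/mL
    v_growth_w = 0.60,             # growth-associated share of production
    T_opt_v = 35, T_w_v = 5,
    K_vG = 25,                     # g/L added feed glucose, saturation
    r_w = 0.50, K_r = 0.5,         # aspartate/glutamate ratio modulation
    asnv_w = 0.70, K_asn_v = 0.40, # asparagine modulation of production
    k_vdeath = 1.2e-3, K_vd = 1.7, # alanine-driven product loss
    ## consumption / production coefficients (g/L/h per 1e6 cells/mL)
    m_glc = 2.0e-3, y_glc = 1.0,
    m_gln = 0.0094, K_gln_M = 0.072, # maintenance-dominated glutaminolysis
    m_asn = 1.5e-3,
    y_ala = 0.52, K_ov = 0.5,      # glutaminolysis overflow to alanine
    ala_T_w = 0.6,                 # overflow rises with effective temperature
    y_ala0 = 2.0e-5,               # baseline alanine secretion
    m_asp = 1.2e-3, m_glu_c = 1.0e-4, y_glu = 6.0e-5,
    m_ser = 3.0e-3, y_gly = 1.0e-5, m_tyr = 2.0e-5,
    m_hyp = 1.5e-4, pro_slope = 2.2,     # proline tracks hydroxyproline
    ## stress -> viability
    s_ala = 6.0e-2, K_s_ala = 2.0, s_gln = 4.0e-4,
    via_drop = 40,                 # viability = 100 - drop * S^2/(S^2+1)
    ## media; aspartate/glutamate vary by medium lot (three lots cycled
    ## deterministically over the run numbers), so the aspartate/glutamate
    ## ratio carries run-specific information
    lot_aspartate = c(1, 1, 1), lot_glutamate = c(2.2, 1, 0.45),
    medium = c(glucose = 6, glutamine = 0.35, asparagine = 0.30,
               alanine = 0.05, aspartate = 0.25, glutamate = 0.08,
               serine = 0.50, glycine = 0.20, tyrosine = 0.20,
               hydroxyproline = 0.10, proline = 0.30),
    feed_base = c(glucose = 30, glutamine = 27, asparagine = 4,
                  alanine = 0, aspartate = 0.5, glutamate = 0.3,
                  serine = 2, glycine = 3, tyrosine = 0.8,
                  hydroxyproline = 0.2, proline = 0.44),
    ## observation model (lognormal CVs)
    cv = c(vcc = 0.05, titer = 0.07, analyte = 0.05, viability = 0.02),
    harvest_viability = 70)
  dots <- list(...)
  p[names(dots)] <- dots
  structure(p, class = "hd_ground_truth")
}

#' Feed composition map implied by ground-truth parameters
#'
#' Base feed plus the level-specific added glucose (F1/F2/F3 = +10/20/30 g/L).
#' @param gt an \code{\link{ground_truth}} object.
#' @return named list F1/F2/F3 of analyte concentration vectors.
#' @export
feed_composition <- function(gt = ground_truth()) {
  lapply(FEED_GLUCOSE_LEVELS, function(add) {
    comp <- gt$feed_base
    comp["glucose"] <- comp["glucose"] + add
    comp
  })
}

#' Shake-flask full-factorial design set
#'
#' The 18 shake-flask designs: full factorial {31, 34, 37} degC x
#' {F1, F2, F3}, each in duplicate, 72 h batch at 37 degC with the
#' temperature shift at the fed-batch start.  Run numbering follows the
#' factorial table (runs 1-2 = 31 degC/F1, ..., runs 17-18 = 37 degC/F3).
#'
#' @return named list of 18 \code{hd_design} objects.
#' @export
make_shaker_doe <- function() {
  grid <- expand.grid(feed_level = names(FEED_GLUCOSE_LEVELS),
                      temperature = c(31, 34, 37),
                      stringsAsFactors = FALSE)
  ## Table order: temperature outer, feed level inner, duplicates adjacent
  grid <- grid[order(grid$temperature, grid$feed_level), ]
  designs <- list()
  for (i in seq_len(nrow(grid))) {
    for (dup in 1:2) {
      no <- (i - 1) * 2 + dup
      designs[[sprintf("shaker_%02d", no)]] <-
        static_design(grid$temperature[i], grid$feed_level[i],
                      planned_duration = 336)
    }
  }
  designs
}

#' 15 L bioreactor design set (static and intensified)
#'
#' The 11 bioreactor designs: five static runs (one at 36.3 degC/F3, one at
#' 34 degC/F1, and the center-point triplicate at 34 degC/F2) and six
#' intensified runs with CPP shifts at 120/192/240 h.
#'
#' @return named list of 11 \code{hd_design} objects.
#' @export
make_bioreactor_designs <- function() {
  seg <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(start_time = as.numeric(m[, 1]),
               temperature = as.numeric(m[, 2]),
               feed_level = paste0("F", m[, 3]), stringsAsFactors = FALSE)
  }
  d <- list(
    bioreactor_01 = static_design(36.3, "F3"),
    bioreactor_02 = static_design(34, "F1"),
    bioreactor_03 = design("intensified", seg(72, 37, 3, 192, 37, 1)),
    bioreactor_04 = design("intensified",
                           seg(72, 34, 2, 120, 37, 2, 192, 34, 1, 240, 31, 1)),
    bioreactor_05 = design("intensified",
                           seg(72, 31, 2, 120, 34, 2, 192, 37, 3, 240, 34, 3)),
    bioreactor_06 = design("intensified",
                           seg(72, 34, 1, 120, 31, 1, 192, 31, 2, 240, 34, 2)),
    bioreactor_07 = design("intensified",
                           seg(72, 37, 2, 120, 34, 3, 192, 31, 2, 240, 34, 1)),
    bioreactor_08 = design("intensified",
                           seg(72, 34, 3, 120, 37, 2, 192, 31, 2, 240, 37, 3)),
    bioreactor_09 = static_design(34, "F2"),
    bioreactor_10 = static_design(34, "F2"),
    bioreactor_11 = static_design(34, "F2"))
  d
}

#' Effective (adaptation-lagged) CPP profiles
#'
#' Cells do not adapt instantly to CPP shifts: the effective temperature and
#' effective added feed glucose follow the set-point step profile through a
#' first-order lag dC_eff/dt = (C_set - C_eff)/tau, continuous across
#' shifts, starting equilibrated at the batch set point (batch temperature;
#' zero feed glucose).
#'
#' @param design an \code{hd_design}.
#' @param tau adaptation time constant in hours.
#' @param t times (h).
#' @return matrix with columns \code{T_eff} and \code{feed_glucose_eff}.
#' @export
effective_cpp <- function(design, tau, t) {
  knots <- c(0, design$segments$start_time)
  T_set <- c(design$batch_temperature, design$segments$temperature)
  G_set <- c(0, unname(FEED_GLUCOSE_LEVELS[design$segments$feed_level]))
  lag_profile <- function(set_vals) {
    c_eff_knot <- numeric(length(knots))
    c_eff_knot[1] <- set_vals[1]               # equilibrated at start
    if (length(knots) > 1)
      for (k in 2:length(knots))
        c_eff_knot[k] <- set_vals[k - 1] +
          (c_eff_knot[k - 1] - set_vals[k - 1]) *
          exp(-(knots[k] - knots[k - 1]) / tau)
    idx <- findInterval(t, knots)
    idx[idx < 1] <- 1
    set_vals[idx] + (c_eff_knot[idx] - set_vals[idx]) *
      exp(-(t - knots[idx]) / tau)
  }
  if (tau <= 0) {                              # limit: no lag
    idx <- pmax(findInterval(t, knots), 1)
    return(cbind(T_eff = T_set[idx], feed_glucose_eff = G_set[idx]))
  }
  cbind(T_eff = lag_profile(T_set), feed_glucose_eff = lag_profile(G_set))
}

## True rate surfaces; exported for oracle tests and rate-recovery checks.

#' Ground-truth specific rates
#'
#' Evaluate the simulator's true specific growth and production rates at
#' given effective CPPs and analyte concentrations.
#'
#' @param gt ground-truth parameters.
#' @param T_eff effective temperature (degC).
#' @param G_eff effective added feed glucose (g/L).
#' @param gln,asn,ala,asp,glu analyte concentrations (g/L); vectors recycle.
#' @return list with vectors \code{mu} (1/h) and \code{vpx}.
#' @export
true_rates <- function(gt, T_eff, G_eff, gln, asn, ala, asp, glu) {
  bellT <- exp(-0.5 * ((T_eff - gt$T_opt_mu) / gt$T_w_mu)^2)
  hgln <- gln^gt$hill_gln / (gln^gt$hill_gln + gt$K_gln^gt$hill_gln)
  fgln <- gt$gln_floor + (1 - gt$gln_floor) * hgln
  fasn <- (1 - gt$asn_w) + gt$asn_w * asn / (asn + gt$K_asn)
  fala <- 1 / (1 + (ala / gt$K_ala_i)^2)
  mu_g <- gt$mu_max * bellT * fgln * fasn * fala
  death <- gt$k_death * ala^4 / (ala^4 + gt$K_ala_d^4)
  bellP <- exp(-0.5 * ((T_eff - gt$T_opt_v) / gt$T_w_v)^2)
  fG <- 0.4 + 0.6 * G_eff / (G_eff + gt$K_vG)
  r <- asp / pmax(glu, 1e-3)
  fr <- (1 - gt$r_w) + gt$r_w * r / (r + gt$K_r)
  fasn_v <- (1 - gt$asnv_w) + gt$asnv_w * asn / (asn + gt$K_asn_v)
  fgrow_v <- (1 - gt$v_growth_w) + gt$v_growth_w * fgln  # growth-associated part
  vdeath <- gt$k_vdeath * ala^4 / (ala^4 + gt$K_vd^4)
  list(mu = mu_g - death, mu_gross = mu_g,
       vpx = gt$v_max * bellP * fG * fr * fasn_v * fgrow_v - vdeath)
}

## Full state derivative of the simulator (feedback on analytes).
sim_rhs_factory <- function(gt, design, cppfun, Dfun) {
  M <- function(c, K) c / (c + K)
  function(t, y, parms) {
    y <- pmax(y, 0)
    cpp <- cppfun(t)
    rr <- true_rates(gt, cpp[1], cpp[2], y["glutamine"], y["asparagine"],
                     y["alanine"], y["aspartate"], y["glutamate"])
    mu_g <- rr$mu_gross
    D <- Dfun(t)
    fa <- if (D > 0) parms$feed_analytes else
      stats::setNames(numeric(length(ANALYTE_NAMES)), ANALYTE_NAMES)
    X <- y["X"]
    wX <- X / (X + 10)
    q_gln <- gt$m_gln * X * M(y["glutamine"], gt$K_gln_M)
    bellT_ala <- exp(-0.5 * ((cpp[1] - gt$T_opt_mu) / gt$T_w_mu)^2)
    f_ala_T <- (1 - gt$ala_T_w) + gt$ala_T_w * bellT_ala
    d <- c(
      X = (rr$mu - D) * X,
      P = rr$vpx * X - D * y["P"],
      glucose = -(gt$m_glc + gt$y_glc * mu_g) * X * M(y["glucose"], 0.5) +
        D * (fa["glucose"] - y["glucose"]),
      glutamine = -q_gln + D * (fa["glutamine"] - y["glutamine"]),
      asparagine = -gt$m_asn * X * M(y["asparagine"], 0.05) +
        D * (fa["asparagine"] - y["asparagine"]),
      alanine = gt$y_ala * f_ala_T * q_gln * M(y["glutamine"], gt$K_ov) +
        gt$y_ala0 * X + D * (fa["alanine"] - y["alanine"]),
      aspartate = -gt$m_asp * X * M(y["aspartate"], 0.05) +
        D * (fa["aspartate"] - y["aspartate"]),
      glutamate = gt$y_glu * X - gt$m_glu_c * X * M(y["glutamate"], 0.1) +
        D * (fa["glutamate"] - y["glutamate"]),
      serine = -gt$m_ser * X * M(y["serine"], 0.05) +
        D * (fa["serine"] - y["serine"]),
      glycine = gt$y_gly * X + D * (fa["glycine"] - y["glycine"]),
      tyrosine = -gt$m_tyr * X * M(y["tyrosine"], 0.05) +
        D * (fa["tyrosine"] - y["tyrosine"]),
      hydroxyproline = -gt$m_hyp * X * M(y["hydroxyproline"], 0.02) +
        D * (fa["hydroxyproline"] - y["hydroxyproline"]),
      proline = -gt$pro_slope * gt$m_hyp * X * M(y["hydroxyproline"], 0.02) +
        D * (fa["proline"] - y["proline"]),
      S = gt$s_ala * y["alanine"]^2 / (y["alanine"]^2 + gt$K_s_ala^2) +
        gt$s_gln * (1 - M(y["glutamine"], 0.02)) * wX
    )
    list(unname(d))
  }
}

sim_viability <- function(gt, S) 100 - gt$via_drop * S^2 / (S^2 + 1)

#' Simulate one cultivation run
#'
#' Integrates the ground-truth balances (cells, titer, eleven analytes,
#' stress) under the design's CPP schedule and the scale's feeding mode:
#' bolus feeding (shake flask, 3.3 percent v/v daily, samples taken before
#' the addition) or continuous feeding (bioreactor, constant flow of the
#' same cumulative v/v per day).  Viability declines with accumulated
#' depletion/overflow stress; shake-flask runs are truncated at the first
#' sample whose viability falls below the harvest threshold, bioreactor
#' runs end at their planned duration.  A multiplicative lognormal
#' observation model is applied unless \code{noiseless}.
#'
#' @param design an \code{hd_design}.
#' @param scale "shake_flask" or "bioreactor".
#' @param gt ground-truth parameters.
#' @param seed integer seed for the observation noise.
#' @param noiseless logical; if TRUE no noise is drawn (the result is then
#'   independent of the seed).
#' @param run_id identifier for the resulting run.
#' @return An \code{hd_run} with attribute \code{"truth"} holding the dense
#'   noiseless trajectories (times, states, true rates, viability).
#' @export
simulate_run <- function(design, scale, gt = ground_truth(), seed = 1,
                         noiseless = FALSE, run_id = "run") {
  if (!scale %in% c("shake_flask", "bioreactor"))
    stopf("simulate_run: unknown scale '%s'", scale)
  ## medium lot by run number (deterministic, so noiseless runs stay
  ## seed-independent); runs without a number get the middle lot
  num <- suppressWarnings(as.integer(sub(".*?(\\d+)$", "\\1", run_id)))
  lot <- if (is.na(num)) 2L else (num - 1L) %% 3L + 1L
  gt <- local({
    g <- gt
    g$medium["aspartate"] <- g$medium["aspartate"] * g$lot_aspartate[lot]
    g$medium["glutamate"] <- g$medium["glutamate"] * g$lot_glutamate[lot]
    g$feed_base["aspartate"] <- g$feed_base["aspartate"] * g$lot_aspartate[lot]
    g$feed_base["glutamate"] <- g$feed_base["glutamate"] * g$lot_glutamate[lot]
    g
  })
  bolus <- identical(scale, "shake_flask")
  if (!bolus && design$planned_duration < max(design$segments$start_time))
    stopf("simulate_run: design exceeds planned duration")
  V0 <- if (bolus) 0.3 else 15
  comp <- feed_composition(gt)
  feed <- if (bolus)
    feed_schedule("bolus", bolus_fraction = 0.033, feed_composition = comp)
  else
    feed_schedule("continuous", flow = 0.033 * V0 / 24,
                  feed_composition = comp)
  end <- design$planned_duration
  shifts <- design$segments$start_time[-1]
  sample_times <- sort(unique(c(seq(0, end, by = 24),
                                shifts[shifts + 6 <= end] + 6)))
  tb <- if (bolus) {
    tb0 <- seq(design$batch_end, end, by = 24)
    tb0[tb0 < end - 1e-9]
  } else numeric(0)
  cppfun <- function(t) effective_cpp(design, gt$tau, t)[1, ]
  seg <- design$segments
  level_at <- function(t) {
    i <- findInterval(t, seg$start_time)
    if (i < 1) NA_character_ else seg$feed_level[i]
  }
  flow <- feed$flow %||% 0
  Vfun <- function(t) {       # pre-bolus convention
    if (bolus) V0 * (1 + feed$bolus_fraction)^sum(tb < t - 1e-9)
    else V0 + flow * max(0, t - design$batch_end)
  }
  Dfun_piece <- function(t) if (!bolus && t >= design$batch_end)
    flow / Vfun(t) else 0

  y <- c(X = 0.25, P = 0, gt$medium[ANALYTE_NAMES], S = 0)
  names(y) <- c("X", "P", ANALYTE_NAMES, "S")
  brk <- sort(unique(c(0, tb, seg$start_time[seg$start_time < end], end)))
  ## quarter-hour output grid: bolus-driven nutrient transients are fast, and
  ## the recorded dense truth doubles as an interpolation oracle in tests
  grid <- sort(unique(c(seq(0, end, by = 0.25), sample_times, brk)))
  rows <- list()
  first <- TRUE
  for (k in seq_len(length(brk) - 1)) {
    a <- brk[k]; b <- brk[k + 1]
    lev <- level_at((a + b) / 2)
    parms <- list(feed_analytes = if (is.na(lev)) gt$feed_base else comp[[lev]])
    rhs <- sim_rhs_factory(gt, design, cppfun, Dfun_piece)
    tt <- c(a, grid[grid > a + 1e-12 & grid <= b + 1e-12])
    out <- deSolve::lsoda(y, tt, rhs, parms = parms,
                          rtol = 1e-8, atol = 1e-10)
    y <- pmax(out[nrow(out), -1], 0)
    if (b %in% tb) {   # bolus added before the day's sample: row at b is post
      lev_b <- level_at(b)
      Vpre <- Vfun(b) / (1 + feed$bolus_fraction)
      res <- apply_bolus(y[["X"]], y[["P"]], y[ANALYTE_NAMES], Vpre,
                         feed$bolus_fraction * Vpre, comp[[lev_b]])
      y[["X"]] <- res$X; y[["P"]] <- res$P
      y[ANALYTE_NAMES] <- res$analytes
      out[nrow(out), -1] <- y
    }
    keep <- if (first) seq_len(nrow(out)) else seq_len(nrow(out))[-1]
    rows[[length(rows) + 1]] <- out[keep, , drop = FALSE]
    first <- FALSE
  }
  dense <- as.data.frame(do.call(rbind, rows))
  names(dense)[1] <- "time"
  dense <- dense[!duplicated(dense$time, fromLast = TRUE), , drop = FALSE]
  cppm <- effective_cpp(design, gt$tau, dense$time)
  tr <- true_rates(gt, cppm[, 1], cppm[, 2], dense$glutamine,
                   dense$asparagine, dense$alanine, dense$aspartate,
                   dense$glutamate)
  dense$mu <- tr$mu
  dense$vpx <- tr$vpx
  dense$viability <- sim_viability(gt, dense$S)
  dense$T_eff <- cppm[, 1]
  dense$G_eff <- cppm[, 2]

  obs <- dense[match(sample_times, dense$time), ]
  samples <- data.frame(time = obs$time, vcc = pmax(obs$X, 0),
                        viability = obs$viability, titer = pmax(obs$P, 0))
  for (a in ANALYTE_NAMES) samples[[a]] <- pmax(obs[[a]], 0)
  if (!noiseless) {
    sdlog <- function(cv) sqrt(log(1 + cv^2))
    n <- nrow(samples)
    samples <- with_seed(seed, {
      samples$vcc <- samples$vcc * exp(rnorm(n, 0, sdlog(gt$cv["vcc"])))
      samples$titer <- samples$titer * exp(rnorm(n, 0, sdlog(gt$cv["titer"])))
      samples$viability <- pmin(
        samples$viability * exp(rnorm(n, 0, sdlog(gt$cv["viability"]))), 100)
      for (a in ANALYTE_NAMES)
        samples[[a]] <- samples[[a]] * exp(rnorm(n, 0, sdlog(gt$cv["analyte"])))
      samples
    })
  }
  if (bolus) {   # harvest rule: truncate at first sample below threshold
    low <- which(samples$viability < gt$harvest_viability)
    if (length(low)) samples <- samples[seq_len(low[1]), , drop = FALSE]
  }
  vt <- data.frame(time = samples$time,
                   volume = vapply(samples$time, Vfun, numeric(1)))
  run <- cultivation_run(run_id, scale, V0, design, feed, samples, vt)
  attr(run, "truth") <- dense
  run
}

#' Assemble a simulated dataset for one study scenario
#'
#' Scenarios mirror the study's training/test splits: \code{shaker_doe}
#' (18 shake-flask runs), \code{bioreactor_all} (11 bioreactor runs),
#' \code{transfer_training} (18 shaker + the 3 bioreactor center points),
#' \code{transfer_test} (the other 8 bioreactor runs),
#' \code{idoe_training} (the 6 intensified runs) and \code{idoe_test}
#' (the 5 static bioreactor runs).  Per-run seeds derive from the master
#' seed by run identity, so the same physical run is identical across
#' scenarios sharing a master seed.
#'
#' @param scenario scenario name (see above).
#' @param gt ground-truth parameters.
#' @param seed master seed.
#' @param noiseless logical, passed to \code{\link{simulate_run}}.
#' @return named list of \code{hd_run}.
#' @export
make_dataset <- function(scenario = c("shaker_doe", "bioreactor_all",
                                      "transfer_training", "transfer_test",
                                      "idoe_training", "idoe_test"),
                         gt = ground_truth(), seed = 1, noiseless = FALSE) {
  scenario <- match.arg(scenario)
  shaker <- make_shaker_doe()
  biorx <- make_bioreactor_designs()
  all_ids <- c(names(shaker), names(biorx))
  seeds <- stats::setNames(spawn_seeds(seed, length(all_ids)), all_ids)
  ids <- switch(scenario,
    shaker_doe = names(shaker),
    bioreactor_all = names(biorx),
    transfer_training = c(names(shaker), paste0("bioreactor_", c("09", "10", "11"))),
    transfer_test = paste0("bioreactor_0", 1:8),
    idoe_training = paste0("bioreactor_0", 3:8),
    idoe_test = paste0("bioreactor_", c("01", "02", "09", "10", "11")))
  runs <- lapply(ids, function(id) {
    d <- c(shaker, biorx)[[id]]
    scale <- if (startsWith(id, "shaker")) "shake_flask" else "bioreactor"
    simulate_run(d, scale, gt, seed = seeds[[id]], noiseless = noiseless,
                 run_id = id)
  })
  stats::setNames(runs, ids)
}
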