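## Mechanistic half of the hybrid model: feeding and dilution, the two
## fed-batch mass balances
##   dX/dt = (mu - D) X,   dP/dt = v_px X - D P,
## input interpolation for the rate network, and data-driven specific-rate
## estimation via cubic smoothing splines.

#' Dilution rate of a continuously fed reactor
#'
#' Ratio between the feed flow into the reactor (L/h) and the overall
#' reactor volume (L).
#'
#' @param feed_flow feed flow, L/h (>= 0).
#' @param volume working volume, L (> 0).
#' @return dilution rate in 1/h.
#' @export
dilution_rate <- function(feed_flow, volume) {
  if (any(volume <= 0)) stopf("dilution_rate: volume must be positive")
  if (any(feed_flow < 0)) stopf("dilution_rate: feed_flow must be >= 0")
  feed_flow / volume
}

#' Apply an instantaneous bolus feed addition
#'
#' Cells and product are only diluted (the feed contains neither); analytes
#' mix conservatively with the feed concentrations.
#'
#' @param X viable cell concentration before the bolus.
#' @param P product titer before the bolus.
#' @param analytes named numeric vector of analyte concentrations (g/L).
#' @param V working volume before the bolus (L).
#' @param bolus_volume added feed volume (L).
#' @param feed_analytes named vector of analyte concentrations in the feed.
#' @return list with diluted \code{X}, \code{P}, \code{analytes} and the new
#'   volume \code{V}.
#' @export
apply_bolus <- function(X, P, analytes, V, bolus_volume, feed_analytes) {
  if (V <= 0 || bolus_volume < 0)
    stopf("apply_bolus: volumes must be positive")
  Vn <- V + bolus_volume
  f <- V / Vn
  fa <- feed_analytes[names(analytes)]
  fa[is.na(fa)] <- 0
  list(X = X * f, P = P * f,
       analytes = (analytes * V + fa * bolus_volume) / Vn,
       V = Vn)
}

## Bolus addition times of a run: daily from fed-batch onset.  The bolus is
## added immediately before the day's sample is drawn, so sampled values on
## bolus days reflect the post-addition state.
bolus_times <- function(run, end = max(run$samples$time)) {
  if (!identical(run$feed$mode, "bolus") ||
      run$design$planned_duration < run$design$batch_end) return(numeric(0))
  tb <- seq(run$design$batch_end, run$design$planned_duration, by = 24)
  tb[tb <= end + 1e-9]
}

#' Working volume of a run at arbitrary times (post-bolus convention)
#'
#' Continuous feeding grows the volume linearly from the fed-batch start;
#' bolus feeding multiplies it by (1 + bolus_fraction) at each addition.  At
#' a bolus time the post-addition volume is reported, matching the sampling
#' convention (boluses are added just before the day's sample).
#'
#' @param run an \code{hd_run}.
#' @param t times (h).
#' @return volumes in L.
#' @export
volume_at <- function(run, t) {
  V0 <- run$working_volume
  if (identical(run$feed$mode, "continuous")) {
    flow <- run$feed$flow %||% 0
    V0 + flow * pmax(0, t - run$design$batch_end)
  } else {
    tb <- bolus_times(run, end = max(t))
    nb <- vapply(t, function(ti) sum(tb <= ti + 1e-9), numeric(1))
    V0 * (1 + run$feed$bolus_fraction)^nb
  }
}

## Dilution response Phi(t) = V(0)/V(t): the factor by which an inert,
## non-fed concentration has been diluted by time t (both X and P obey it).
dilution_response <- function(run, t) run$working_volume / volume_at(run, t)

#' Integrate the fed-batch mass balances for given rate functions
#'
#' Solves dX/dt = (mu - D) X and dP/dt = v_px X - D P with the run's feed
#' schedule: continuous feeding enters through the dilution rate D =
#' flow/V(t); bolus feeding enters as instantaneous dilution events at the
#' daily bolus times (D = 0 in between).  Rows at bolus times report the
#' post-bolus state, matching the sampling convention (bolus added just
#' before the sample).
#'
#' @param rate_fn function of time returning \code{c(mu, vpx)} (1/h and
#'   g/L/h per 1e6 cells/mL).
#' @param run an \code{hd_run} providing the feed schedule and time span.
#' @param X0,P0 initial conditions (default: seeding density and 0).
#' @param rtol,atol solver tolerances.
#' @param dense_by spacing of the dense output grid (h); sampling times,
#'   segment boundaries and bolus times are always included.
#' @return data.frame (class \code{hd_trajectory}) with columns time, X, P,
#'   V, D.
#' @export
integrate_states <- function(rate_fn, run, X0 = run$seeding_density, P0 = 0,
                             rtol = 1e-8, atol = 1e-10, dense_by = 1) {
  if (X0 < 0 || P0 < 0) stopf("integrate_states: X0 and P0 must be >= 0")
  end <- max(run$samples$time)
  tb <- bolus_times(run, end)
  seg <- run$design$segments$start_time
  grid <- sort(unique(c(seq(0, end, by = dense_by), end, run$samples$time,
                        seg[seg <= end], tb)))
  brk <- sort(unique(c(0, tb, seg[seg < end], end)))
  cont <- identical(run$feed$mode, "continuous")
  flow <- if (cont) run$feed$flow %||% 0 else 0
  Dfun <- function(t) if (cont && t >= run$design$batch_end)
    flow / volume_at(run, t) else 0
  rhs <- function(t, y, parms) {
    r <- rate_fn(t)
    if (any(!is.finite(r)))
      stopf("integrate_states: rate function returned non-finite values at t = %g h", t)
    D <- Dfun(t)
    list(c(r[1] * y[1] - D * y[1], r[2] * y[1] - D * y[2]))
  }
  y <- c(X = X0, P = P0)
  rows <- list(data.frame(time = 0, X = X0, P = P0))
  for (k in seq_len(length(brk) - 1)) {
    a <- brk[k]; b <- brk[k + 1]
    tt <- c(a, grid[grid > a + 1e-12 & grid <= b + 1e-12])
    out <- deSolve::lsoda(y, tt, rhs, parms = NULL, rtol = rtol, atol = atol)
    y <- c(X = out[nrow(out), 2], P = out[nrow(out), 3])
    if (any(y < 0)) {
      if (any(y < -1e-9))
        warnf("integrate_states: state undershoot %.3g clipped at t = %g h",
              min(y), b)
      y <- pmax(y, 0)
    }
    if (b %in% tb) {            # bolus dilutes before the row at b is kept
      f <- 1 / (1 + run$feed$bolus_fraction)
      y <- y * f
      out[nrow(out), 2:3] <- y
    }
    rows[[length(rows) + 1]] <-
      data.frame(time = out[-1, 1], X = out[-1, 2], P = out[-1, 3])
  }
  traj <- do.call(rbind, rows)
  traj <- traj[!duplicated(traj$time), , drop = FALSE]
  traj$V <- volume_at(run, traj$time)
  traj$D <- vapply(traj$time, Dfun, numeric(1))
  rownames(traj) <- NULL
  class(traj) <- c("hd_trajectory", "data.frame")
  traj
}

#' Interpolate model inputs of a run at arbitrary times
#'
#' Critical process parameters (temperature, added feed glucose) are step
#' functions of the design segments, right-continuous at shift times; the
#' batch phase has the batch temperature and zero feed glucose.  Analyte
#' inputs are linear interpolations between sampling times, and the
#' aspartate/glutamate ratio is formed after interpolation with a 1e-3 g/L
#' denominator floor.
#'
#' @param run an \code{hd_run}.
#' @param t times within the observed span (h).
#' @param input_names which inputs to return (any of the CPPs, analyte
#'   names, or \code{"asp_glu_ratio"}).
#' @return numeric matrix, length(t) rows, one column per input.
#' @export
interpolate_inputs <- function(run, t, input_names = MODEL_INPUTS) {
  s <- run$samples
  if (any(t < min(s$time) - 1e-9 | t > max(s$time) + 1e-9))
    stopf("interpolate_inputs: time outside the observed span [%g, %g] h",
          min(s$time), max(s$time))
  seg <- run$design$segments
  seg_idx <- findInterval(t, seg$start_time)   # 0 = batch phase
  out <- matrix(NA_real_, length(t), length(input_names),
                dimnames = list(NULL, input_names))
  an <- function(name) approx(s$time, s[[name]], xout = t, rule = 2)$y
  for (nm in input_names) {
    out[, nm] <- switch(nm,
      temperature = ifelse(seg_idx == 0, run$design$batch_temperature,
                           seg$temperature[pmax(seg_idx, 1)]),
      feed_glucose = ifelse(seg_idx == 0, 0,
                            FEED_GLUCOSE_LEVELS[seg$feed_level[pmax(seg_idx, 1)]]),
      asp_glu_ratio = an("aspartate") / pmax(an("glutamate"), 1e-3),
      {
        if (!nm %in% ANALYTE_NAMES)
          stopf("interpolate_inputs: unknown input '%s'", nm)
        an(nm)
      })
  }
  out
}

#' Estimate specific rates from measured time series
#'
#' Fits cubic smoothing splines to the log of the dilution-corrected VCC and
#' to the dilution-corrected titer, then reads the specific growth rate as
#' mu(t) = d ln X/dt + D(t) and the specific production rate as
#' v_px(t) = (dP/dt + D P)/X, both evaluated on the spline.  Dilution
#' correction uses the run's feed schedule (continuous dilution and bolus
#' jumps alike), so the spline sees the feeding-free dynamics.
#'
#' @param run an \code{hd_run} with at least 4 samples.
#' @param times evaluation times (default: the sampling times).
#' @param spar,df optional smoothing controls passed to
#'   \code{\link[stats]{smooth.spline}}; by default the smoothing is chosen
#'   by generalized cross-validation.
#' @return data.frame (class \code{hd_rates}) with columns time, mu (1/h)
#'   and vpx (g/L/h per 1e6 cells/mL).
#' @export
estimate_specific_rates <- function(run, times = run$samples$time,
                                    spar = NULL, df = NULL) {
  s <- run$samples
  if (nrow(s) < 4)
    stopf("estimate_specific_rates: need >= 4 sampling points, got %d", nrow(s))
  if (any(s$vcc <= 0))
    stopf("estimate_specific_rates: VCC must be positive (log transform)")
  phi_s <- dilution_response(run, s$time)
  fit_one <- function(y) {
    args <- list(x = s$time, y = y, all.knots = TRUE)
    if (!is.null(spar)) args$spar <- spar
    if (!is.null(df)) args$df <- df
    do.call(smooth.spline, args)
  }
  f_lnx <- fit_one(log(s$vcc / phi_s))
  f_p <- fit_one(s$titer / phi_s)
  phi_t <- dilution_response(run, times)
  mu <- predict(f_lnx, times, deriv = 1)$y
  X_fit <- phi_t * exp(predict(f_lnx, times)$y)
  vpx <- phi_t * predict(f_p, times, deriv = 1)$y / X_fit
  out <- data.frame(time = times, mu = mu, vpx = vpx)
  class(out) <- c("hd_rates", "data.frame")
  out
}
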