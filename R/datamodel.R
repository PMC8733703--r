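## Domain types for cultivation runs, designs and feed schedules, their
## validation, and the on-disk dataset dialect (long CSV + JSON + YAML).

#' Names of the offline analytes carried by every run
#' @export
ANALYTE_NAMES <- c("glucose", "glutamine", "asparagine", "alanine",
                   "aspartate", "glutamate", "serine", "glycine",
                   "tyrosine", "hydroxyproline", "proline")

#' Default model input names of the hybrid rate network
#'
#' The two critical process parameters (cultivation temperature and the
#' added-glucose level of the feed) plus glutamine, asparagine, alanine and
#' the aspartate-to-glutamate ratio.
#' @export
MODEL_INPUTS <- c("temperature", "feed_glucose", "glutamine", "asparagine",
                  "alanine", "asp_glu_ratio")

#' Added glucose (g/L) encoded by each feed level
#' @export
FEED_GLUCOSE_LEVELS <- c(F1 = 10, F2 = 20, F3 = 30)

TEMPERATURE_LEVELS <- c(31, 34, 36.3, 37)

#' Construct a cultivation design
#'
#' A design is the batch phase (37 degC, no feed, until \code{batch_end})
#' followed by one or more fed-batch segments, each a (start time,
#' temperature, feed level) triple.  Static designs have exactly one
#' fed-batch segment; intensified designs add intra-experimental CPP shifts.
#'
#' @param doe_mode "static" or "intensified".
#' @param segments data.frame with columns \code{start_time} (h),
#'   \code{temperature} (degC) and \code{feed_level} ("F1","F2","F3").
#' @param batch_end end of the batch phase in hours (72).
#' @param planned_duration planned process duration in hours.
#' @param batch_temperature batch-phase temperature in degC.
#' @return An object of class \code{hd_design}.
#' @export
design <- function(doe_mode, segments, batch_end = 72,
                   planned_duration = 360, batch_temperature = 37) {
  segments <- as.data.frame(segments)
  structure(list(doe_mode = doe_mode, segments = segments,
                 batch_end = batch_end, planned_duration = planned_duration,
                 batch_temperature = batch_temperature),
            class = "hd_design")
}

#' Construct a static (single fed-batch segment) design
#' @param temperature fed-batch temperature (degC).
#' @param feed_level "F1", "F2" or "F3".
#' @param planned_duration planned duration (h).
#' @return An \code{hd_design}.
#' @export
static_design <- function(temperature, feed_level, planned_duration = 360) {
  design("static",
         data.frame(start_time = 72, temperature = temperature,
                    feed_level = feed_level, stringsAsFactors = FALSE),
         planned_duration = planned_duration)
}

#' Construct a feed schedule
#'
#' @param mode "bolus" (shake flask, daily additions) or "continuous"
#'   (bioreactor, constant inflow).
#' @param bolus_fraction daily bolus volume as a fraction of current working
#'   volume (v/v per day); shaker default 0.033.
#' @param flow constant feed flow in L/h for continuous mode (active from the
#'   fed-batch start).
#' @param feed_composition named list mapping feed level to a named numeric
#'   vector of analyte concentrations in that feed (g/L).
#' @return An object of class \code{hd_feed}.
#' @export
feed_schedule <- function(mode, bolus_fraction = 0.033, flow = NULL,
                          feed_composition) {
  structure(list(mode = mode, bolus_fraction = bolus_fraction, flow = flow,
                 feed_composition = feed_composition),
            class = "hd_feed")
}

#' Construct a cultivation run
#'
#' @param run_id character identifier, e.g. \code{"shaker_09"}.
#' @param scale "shake_flask" or "bioreactor".
#' @param working_volume initial working volume in L (0.3 or 15).
#' @param design an \code{hd_design}.
#' @param feed an \code{hd_feed}.
#' @param samples data.frame with columns \code{time} (h), \code{vcc}
#'   (1e6 cells/mL), \code{viability} (percent), \code{titer} (g/L) and one
#'   column per analyte (g/L).  Samples at bolus days are taken before the
#'   bolus addition.
#' @param volume_trace data.frame with columns \code{time}, \code{volume}
#'   (pre-bolus working volume, L).
#' @param seeding_density seeding VCC, 1e6 cells/mL (0.25).
#' @return An object of class \code{hd_run}.
#' @export
cultivation_run <- function(run_id, scale, working_volume, design, feed,
                            samples, volume_trace, seeding_density = 0.25) {
  structure(list(run_id = run_id, scale = scale,
                 working_volume = working_volume, design = design,
                 feed = feed, seeding_density = seeding_density,
                 samples = as.data.frame(samples),
                 volume_trace = as.data.frame(volume_trace)),
            class = "hd_run")
}

#' @export
print.hd_run <- function(x, ...) {
  cat(sprintf("<cultivation run %s: %s, %.1f L, %s design, %d samples over %g h>\n",
              x$run_id, x$scale, x$working_volume, x$design$doe_mode,
              nrow(x$samples), max(x$samples$time)))
  invisible(x)
}

#' Validate a cultivation run against the domain invariants
#'
#' Total: always returns (never throws); an empty character vector means the
#' run satisfies every invariant, otherwise each element names the field and
#' the violated rule.
#'
#' @param run an \code{hd_run} (or anything; malformed objects yield
#'   violations rather than errors).
#' @return character vector of violation descriptions.
#' @export
validate_run <- function(run) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!inherits(run, "hd_run") || !is.list(run)) {
    return("run: not an hd_run object")
  }
  s <- run$samples
  d <- run$design
  ## design invariants
  if (!is.null(d)) {
    seg <- d$segments
    if (is.null(seg) || nrow(seg) == 0) {
      add("design.segments: at least one fed-batch segment required")
    } else {
      if (any(diff(seg$start_time) <= 0))
        add("design.segments: start times must be strictly increasing")
      if (seg$start_time[1] != d$batch_end)
        add("design.segments: first fed-batch segment must start at batch_end")
      bad_t <- setdiff(unique(seg$temperature), TEMPERATURE_LEVELS)
      if (length(bad_t))
        add(sprintf("design.segments: temperature(s) %s outside {31, 34, 36.3, 37}",
                    paste(bad_t, collapse = ", ")))
      if (!all(seg$feed_level %in% names(FEED_GLUCOSE_LEVELS)))
        add("design.segments: unknown feed level")
      if (identical(d$doe_mode, "static") && nrow(seg) != 1)
        add("design.doe_mode: static designs must have exactly one fed-batch segment")
    }
  } else add("design: missing")
  ## feed / scale coupling
  if (!is.null(run$feed)) {
    if (identical(run$scale, "shake_flask") && !identical(run$feed$mode, "bolus"))
      add("feed.mode: shake_flask runs require bolus feeding")
    if (identical(run$scale, "bioreactor") && !identical(run$feed$mode, "continuous"))
      add("feed.mode: bioreactor runs require continuous feeding")
    bf <- run$feed$bolus_fraction
    if (identical(run$feed$mode, "bolus") &&
        (!is.numeric(bf) || bf <= 0 || bf >= 0.1))
      add("feed.bolus_fraction: must lie in (0, 0.1)")
    if (!is.null(run$feed$flow) && any(run$feed$flow < 0))
      add("feed.flow: must be non-negative")
    if (!is.null(d) && !is.null(d$segments)) {
      lv <- unique(d$segments$feed_level)
      if (!all(lv %in% names(run$feed$feed_composition)))
        add("feed.feed_composition: composition missing for a used feed level")
    }
  } else add("feed: missing")
  if (!isTRUE(all.equal(run$seeding_density, 0.25)))
    add("seeding_density: must equal 0.25e6 cells/mL")
  ## samples
  if (is.null(s) || nrow(s) == 0) {
    add("samples: missing")
  } else {
    need <- c("time", "vcc", "viability", "titer", ANALYTE_NAMES)
    miss <- setdiff(need, names(s))
    if (length(miss)) {
      add(sprintf("samples: missing column(s) %s", paste(miss, collapse = ", ")))
    } else {
      if (s$time[1] != 0) add("samples.time: must start at 0")
      if (any(diff(s$time) <= 0))
        add("samples.time: must be strictly increasing")
      if (anyNA(s[need])) add("samples: missing values at sampled times")
      if (any(s$vcc < 0, na.rm = TRUE)) add("samples.vcc: must be >= 0")
      if (any(s$viability < 0 | s$viability > 100, na.rm = TRUE))
        add("samples.viability: must lie in [0, 100]")
      if (any(s$titer < 0, na.rm = TRUE)) add("samples.titer: must be >= 0")
      for (a in ANALYTE_NAMES)
        if (any(s[[a]] < 0, na.rm = TRUE))
          add(sprintf("samples.%s: must be >= 0", a))
    }
  }
  vt <- run$volume_trace
  if (is.null(vt) || nrow(vt) == 0) add("volume_trace: missing")
  else if (any(vt$volume <= 0, na.rm = TRUE))
    add("volume_trace.volume: must be positive")
  v
}

## ---------------------------------------------------------------------------
## Dataset I/O: directory with runs.csv (long format), designs.json,
## manifest.yaml.

design_to_list <- function(d) {
  list(doe_mode = d$doe_mode,
       batch_end = d$batch_end,
       planned_duration = d$planned_duration,
       batch_temperature = d$batch_temperature,
       segments = lapply(seq_len(nrow(d$segments)), function(i)
         list(start_time = d$segments$start_time[i],
              temperature = d$segments$temperature[i],
              feed_level = d$segments$feed_level[i])))
}

design_from_list <- function(l) {
  seg <- do.call(rbind, lapply(l$segments, function(s)
    data.frame(start_time = s$start_time, temperature = s$temperature,
               feed_level = s$feed_level, stringsAsFactors = FALSE)))
  if (any(diff(seg$start_time) <= 0))
    stopf("designs.json: segment start times not strictly increasing (Design invariant)")
  design(l$doe_mode, seg, batch_end = l$batch_end,
         planned_duration = l$planned_duration,
         batch_temperature = l$batch_temperature)
}

feed_to_list <- function(f) {
  list(mode = f$mode, bolus_fraction = f$bolus_fraction, flow = f$flow,
       feed_composition = lapply(f$feed_composition, as.list))
}

feed_from_list <- function(l) {
  comp <- lapply(l$feed_composition, function(x) unlist(x))
  bad <- setdiff(names(comp), names(FEED_GLUCOSE_LEVELS))
  if (length(bad)) stopf("designs.json: unknown feed level '%s'", bad[1])
  feed_schedule(l$mode, bolus_fraction = l$bolus_fraction,
                flow = l$flow, feed_composition = comp)
}

#' Save a dataset of cultivation runs
#'
#' Writes \code{runs.csv} (long format: run_id, time_h, variable, value; the
#' variables are vcc, viability, titer, the analytes and volume),
#' \code{designs.json} (per-run design, feed schedule and scalar metadata)
#' and \code{manifest.yaml} into a directory.
#'
#' @param runs list of \code{hd_run}.
#' @param path directory to create/fill.
#' @param meta optional named list recorded in the manifest (e.g. ground
#'   truth parameters and seeds).
#' @return \code{path}, invisibly.
#' @export
save_dataset <- function(runs, path, meta = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(runs, function(r) {
    s <- r$samples
    vars <- c("vcc", "viability", "titer", ANALYTE_NAMES)
    main <- do.call(rbind, lapply(vars, function(v)
      data.frame(run_id = r$run_id, time_h = s$time, variable = v,
                 value = s[[v]], stringsAsFactors = FALSE)))
    vol <- data.frame(run_id = r$run_id, time_h = r$volume_trace$time,
                      variable = "volume", value = r$volume_trace$volume,
                      stringsAsFactors = FALSE)
    rbind(main, vol)
  }))
  long$value <- sprintf("%.15g", long$value)
  write.csv(long, file.path(path, "runs.csv"), row.names = FALSE, quote = FALSE)
  designs <- lapply(runs, function(r)
    list(run_id = r$run_id, scale = r$scale,
         working_volume = r$working_volume,
         seeding_density = r$seeding_density,
         design = design_to_list(r$design), feed = feed_to_list(r$feed)))
  names(designs) <- vapply(runs, function(r) r$run_id, character(1))
  jsonlite::write_json(designs, file.path(path, "designs.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- c(list(n_runs = length(runs),
                     run_ids = unname(names(designs)),
                     format = "hybridoe-dataset-v1"),
                meta %||% list())
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))
  invisible(path)
}

#' Load a dataset of cultivation runs
#'
#' @param path dataset directory written by \code{\link{save_dataset}}.
#' @return list of \code{hd_run}, named by run id.
#' @export
load_dataset <- function(path) {
  csv <- file.path(path, "runs.csv")
  if (!file.exists(csv)) stopf("%s: no runs.csv found", path)
  long <- read.csv(csv, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("run_id", "time_h", "variable", "value")
  if (!all(need %in% names(long)))
    stopf("%s: missing column(s) %s", csv,
          paste(setdiff(need, names(long)), collapse = ", "))
  num <- suppressWarnings(as.numeric(long$value))
  if (anyNA(num)) {
    i <- which(is.na(num))[1]
    stopf("%s: non-numeric value '%s' in column 'value' at line %d",
          csv, long$value[i], i + 1L)  # +1 for header
  }
  long$value <- num
  tnum <- suppressWarnings(as.numeric(long$time_h))
  if (anyNA(tnum)) {
    i <- which(is.na(tnum))[1]
    stopf("%s: non-numeric value '%s' in column 'time_h' at line %d",
          csv, long$time_h[i], i + 1L)
  }
  long$time_h <- tnum
  designs <- jsonlite::read_json(file.path(path, "designs.json"))
  runs <- lapply(designs, function(dd) {
    rid <- dd$run_id
    sub <- long[long$run_id == rid, , drop = FALSE]
    if (nrow(sub) == 0) stopf("runs.csv: no rows for run '%s'", rid)
    vol <- sub[sub$variable == "volume", ]
    obs <- sub[sub$variable != "volume", ]
    wide <- stats::reshape(obs[, c("time_h", "variable", "value")],
                           idvar = "time_h", timevar = "variable",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    wide <- wide[order(wide$time_h), , drop = FALSE]
    samples <- data.frame(time = wide$time_h)
    for (v in c("vcc", "viability", "titer", ANALYTE_NAMES)) {
      if (is.null(wide[[v]]))
        stopf("runs.csv: run '%s' lacks variable '%s'", rid, v)
      samples[[v]] <- wide[[v]]
    }
    cultivation_run(rid, dd$scale, dd$working_volume,
                    design_from_list(dd$design), feed_from_list(dd$feed),
                    samples,
                    data.frame(time = vol$time_h, volume = vol$value),
                    seeding_density = dd$seeding_density)
  })
  names(runs) <- vapply(runs, function(r) r$run_id, character(1))
  runs
}
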