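# Validation procedures: device intercomparison correction, bladder-voiding
# categorization, series-vs-band comparison, morphology sensitivity
# statistics, and the seeded synthetic measurement generator.

#' Construct a measurement series
#'
#' @param patient_id Identifier.
#' @param pharmaceutical Radiopharmaceutical name.
#' @param activity_MBq Administered activity, residual-corrected (MBq).
#' @param time_min Measurement times, minutes post administration,
#'   increasing.
#' @param h10_uSv_h Measured ambient dose equivalent rates (uSv/h, >= 0).
#' @param device_id Measurement device identifier.
#' @param first_void_min Patient's first bladder voiding time (min).
#' @return An object of class `measurement_series`.
#' @export
measurement_series <- function(patient_id, pharmaceutical, activity_MBq,
                               time_min, h10_uSv_h, device_id = NA,
                               first_void_min = NA) {
  if (activity_MBq <= 0) stop("administered activity must be positive")
  if (any(h10_uSv_h < 0)) stop("dose rates must be non-negative")
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  structure(list(patient_id = patient_id, pharmaceutical = pharmaceutical,
                 activity_MBq = activity_MBq, time_min = as.numeric(time_min),
                 h10_uSv_h = as.numeric(h10_uSv_h), device_id = device_id,
                 first_void_min = first_void_min, corrections = character(0)),
            class = "measurement_series")
}

#' Read a measurement series from CSV
#'
#' Expected columns: patient_id, pharmaceutical, activity_MBq, time_min,
#' h10_uSv_per_h, device_id, first_void_min.
#' @param path CSV file.
#' @return A list of `measurement_series`, one per patient_id.
#' @export
read_measurements_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$patient_id), function(p) {
    p <- p[order(p$time_min), ]
    measurement_series(p$patient_id[1], p$pharmaceutical[1],
                       p$activity_MBq[1], p$time_min, p$h10_uSv_per_h,
                       p$device_id[1], p$first_void_min[1])
  })
}

#' Correct a series for the device intercomparison deviation
#'
#' Divides the measured rates by (1 + deviation), where deviation is the
#' device's relative deviation against the nominal reference value from
#' the equipment intercomparison exercise.
#'
#' @param series A `measurement_series`.
#' @param device_relative_deviation Relative deviation (> -1), e.g. -0.45
#'   for a device reading 45% low.
#' @return The corrected series; the correction is recorded in the
#'   series metadata.
#' @export
device_correction <- function(series, device_relative_deviation) {
  stopifnot(inherits(series, "measurement_series"))
  if (device_relative_deviation <= -1)
    stop("deviation must be > -1")
  series$h10_uSv_h <- series$h10_uSv_h / (1 + device_relative_deviation)
  series$corrections <- c(series$corrections,
                          sprintf("device_intercomparison:%+.3f",
                                  device_relative_deviation))
  series
}

#' Categorize a patient by first bladder voiding time
#'
#' Nearest-regime assignment to the four modelled voiding regimes with
#' first voids at 30, 45, 120 and 210 min (midpoint boundaries 37.5, 82.5
#' and 165 min; a time exactly on a boundary goes to the lower category).
#'
#' @param first_void_time First void time (min, > 0).
#' @return `"a"`, `"b"`, `"c"` or `"d"`.
#' @export
categorize_voiding <- function(first_void_time) {
  if (first_void_time <= 0) stop("voiding time must be positive")
  bounds <- c(37.5, 82.5, 165)
  c("a", "b", "c", "d")[findInterval(first_void_time, bounds,
                                     left.open = TRUE) + 1L]
}

#' The four modelled bladder-voiding regimes
#'
#' @param category `"a"` (first void 30 min, then hourly), `"b"` (45 min,
#'   then hourly), `"c"` (120-min interval) or `"d"` (210-min interval,
#'   the reference biokinetic assumption).
#' @return A [voiding_schedule].
#' @export
voiding_regime <- function(category = c("a", "b", "c", "d")) {
  category <- match.arg(category)
  switch(category,
         a = voiding_schedule(first_void = 30, interval = 60),
         b = voiding_schedule(first_void = 45, interval = 60),
         c = voiding_schedule(first_void = 120, interval = 120),
         d = voiding_schedule(first_void = 210, interval = 210))
}

#' Fraction of measured points inside the simulated confidence band
#'
#' Interpolates the simulated series and its 95% band linearly at the
#' measurement times and flags each normalized measured rate against
#' [ci95_low, ci95_high].
#'
#' @param measured A `measurement_series` (rates are normalized by the
#'   administered activity to uSv/h/MBq).
#' @param simulated A `dose_rate_series` with `ci95_low`/`ci95_high`
#'   columns (from [propagate]).
#' @return List: `fraction` inside, logical `inside` per point, and the
#'   normalized measured values.
#' @export
compare_within_ci <- function(measured, simulated) {
  stopifnot(inherits(measured, "measurement_series"))
  if (!all(c("ci95_low", "ci95_high") %in% names(simulated)))
    stop("simulated series lacks a confidence band; run propagate() first")
  t <- measured$time_min
  if (any(t < min(simulated$time_min)) || any(t > max(simulated$time_min)))
    stop("measurement time outside the simulated grid")
  lo <- stats::approx(simulated$time_min, simulated$ci95_low, t)$y
  hi <- stats::approx(simulated$time_min, simulated$ci95_high, t)$y
  norm <- measured$h10_uSv_h / measured$activity_MBq
  inside <- norm >= lo & norm <= hi
  list(fraction = mean(inside), inside = inside, normalized = norm)
}

#' Morphology sensitivity statistics
#'
#' Per-region max/min ratios of dose-rate factors across patient models,
#' and (optionally) the per-time-point relative standard deviation of the
#' cumulated series across models.
#'
#' @param factor_table Data frame or matrix: rows = source regions (row
#'   names or a `source_region` column), columns = phantoms; >= 2 phantom
#'   columns.
#' @param series Optional list of `dose_rate_series` (one per phantom, on
#'   a common grid) for the RSD-over-time analysis.
#' @return An object of class `morphology_report`: `ratios` data frame
#'   (region, max_min_ratio rounded to 1 decimal) and, when series are
#'   given, `rsd` data frame (time_min, rsd as a fraction).
#' @export
morphology_stats <- function(factor_table, series = NULL) {
  ft <- factor_table
  if (is.data.frame(ft) && "source_region" %in% names(ft)) {
    rn <- ft$source_region
    ft <- as.matrix(ft[, setdiff(names(ft), "source_region"), drop = FALSE])
    rownames(ft) <- rn
  } else ft <- as.matrix(ft)
  if (ncol(ft) < 2L) stop("need at least two phantoms")
  if (any(ft <= 0)) stop("factors must be positive")
  ratios <- data.frame(
    region = rownames(ft),
    max_min_ratio = round(apply(ft, 1, max) / apply(ft, 1, min), 1),
    row.names = NULL, stringsAsFactors = FALSE)
  rsd <- NULL
  if (!is.null(series)) {
    V <- vapply(series, function(s) s$value, numeric(nrow(series[[1]])))
    m <- rowMeans(V)
    if (any(m == 0)) stop("zero mean series value; RSD undefined")
    rsd <- data.frame(time_min = series[[1]]$time_min,
                      rsd = apply(V, 1, stats::sd) / m)
  }
  structure(list(ratios = ratios, rsd = rsd), class = "morphology_report")
}

#' @export
print.morphology_report <- function(x, ...) {
  cat("<morphology_report>\n")
  print(x$ratios, row.names = FALSE)
  if (!is.null(x$rsd))
    cat(sprintf("  RSD over %d time points: max %.1f%% at %g min\n",
                nrow(x$rsd), 100 * max(x$rsd$rsd),
                x$rsd$time_min[which.max(x$rsd$rsd)]))
  invisible(x)
}

#' Bundled benchmark factor table for the morphology study
#'
#' Published per-region H*(10) factors at 1 m across four male models of
#' increasing mass and a female reference phantom, for a Tc-99m bone-scan
#' patient; shipped as validation input.
#' @return Data frame with a `source_region` column and one column per
#'   model.
#' @export
benchmark_morphology_factors <- function() {
  path <- system.file("extdata", "reference", "morphology_h10_factors.csv",
                      package = "nmdoserate")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Bundled benchmark morphology (height/mass) set
#' @return Data frame: model, height_cm, mass_kg.
#' @export
benchmark_morphology_models <- function() {
  path <- system.file("extdata", "reference", "morphology_models.csv",
                      package = "nmdoserate")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Generate a synthetic measurement series
#'
#' Draws measurement times uniformly over the simulated grid, evaluates
#' the true curve there, and applies (i) a fixed multiplicative device
#' bias, (ii) inverse-square positioning jitter for a Gaussian positioning
#' error, and (iii) multiplicative Gaussian device noise. Seeded and
#' reproducible; a synthetic stand-in for hospital campaign data.
#'
#' @param true_series A `dose_rate_series` (uSv/h/MBq).
#' @param activity_MBq Administered activity used to de-normalize.
#' @param device_bias Relative device bias (e.g. -0.10 reads 10% low).
#' @param positioning_sd Positioning error SD as a fraction of the nominal
#'   distance (the rate scales with 1/(1+x)^2 for a relative offset x).
#' @param noise_sd Relative SD of the multiplicative device noise.
#' @param n_points Number of measurement points.
#' @param seed Integer seed.
#' @param patient_id,pharmaceutical,device_id Metadata.
#' @param first_void_min First void time recorded in the metadata.
#' @return A `measurement_series`.
#' @export
generate_measurements <- function(true_series, activity_MBq = 700,
                                  device_bias = 0, positioning_sd = 0,
                                  noise_sd = 0, n_points = 10, seed = 1L,
                                  patient_id = "SYN-1",
                                  pharmaceutical = "Tc99m-HDP/MDP",
                                  device_id = "SYN", first_void_min = NA) {
  stopifnot(n_points >= 1)
  .with_seed(seed, {
    t <- sort(stats::runif(n_points, min(true_series$time_min),
                           max(true_series$time_min)))
    v <- stats::approx(true_series$time_min, true_series$value, t)$y
    pos <- (1 + stats::rnorm(n_points, 0, positioning_sd))
    pos[pos < 0.2] <- 0.2                 # clamp pathological jitter
    v <- v * (1 + device_bias) / pos^2
    v <- v * (1 + stats::rnorm(n_points, 0, noise_sd))
    v[v < 0] <- 0
    measurement_series(patient_id, pharmaceutical, activity_MBq, t,
                       v * activity_MBq, device_id, first_void_min)
  })
}
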