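# Superposition of per-region dose-rate factors with fractional activities
# into cumulated time series, and GUM-style uncertainty propagation with a
# log-normal biokinetic variability transform.

#' Cumulated dose-rate series over time
#'
#' Pointwise weighted sum over source regions: the dose rate at time t is
#' sum_region a_region(t) x C_region, with C the per-region dose-rate
#' factor per unit administered activity. Every region present in the
#' activity set must have a factor; a missing factor is an error, never a
#' silent drop.
#'
#' @param factors A `dose_rate_factor` data frame (or any data frame with
#'   `source_region` and `value_uSv_h_MBq`).
#' @param tacs A `tac_set` from [solve_tacs].
#' @param regions Regions to include (default: all regions of `tacs`).
#' @return An object of class `dose_rate_series`: data frame `time_min`,
#'   `value` (uSv/h/MBq); uncertainty columns are added by [propagate].
#' @export
cumulate <- function(factors, tacs, regions = NULL) {
  stopifnot(inherits(tacs, "tac_set"))
  if (is.null(regions)) regions <- tacs$regions
  miss <- setdiff(regions, factors$source_region)
  if (length(miss))
    stop("no dose-rate factor for region(s): ", paste(miss, collapse = ", "))
  miss2 <- setdiff(regions, tacs$regions)
  if (length(miss2))
    stop("no activity curve for region(s): ", paste(miss2, collapse = ", "))
  C <- factors$value_uSv_h_MBq[match(regions, factors$source_region)]
  vals <- as.numeric(C %*% tacs$A[regions, , drop = FALSE])
  structure(data.frame(time_min = tacs$times, value = vals),
            class = c("dose_rate_series", "data.frame"),
            regions = regions, factors = factors)
}

#' Absolute uncertainty of a log-normally variable activity fraction
#'
#' Transforms a multiplicative variability factor (activities within
#' [a/f, f a] at roughly 95% confidence) into the standard-type absolute
#' uncertainty of a normal distribution:
#' u(a) = a [exp((ln f / k)^2) - 1]^(1/2).
#'
#' @param a Fractional activity (>= 0), vectorized.
#' @param factor Multiplicative variability factor (>= 1), default 2.
#' @param k Coverage factor (default 2, ~95% confidence).
#' @return Absolute uncertainty, same shape as `a`.
#' @export
lognormal_sd <- function(a, factor = 2, k = 2) {
  if (any(a < 0)) stop("fractions must be non-negative")
  if (factor < 1) stop("variability factor must be >= 1")
  stopifnot(k > 0)
  a * sqrt(exp((log(factor) / k)^2) - 1)
}

#' Propagate factor and activity uncertainties into a series band
#'
#' GUM quadrature over regions at each time:
#' U(t) = ( sum_i [a_i(t) u(C_i)]^2 + sum_i [C_i u(a_i(t))]^2 )^(1/2),
#' with u(a_i(t)) from [lognormal_sd] (the coverage factor is embedded
#' there), and the 95% band reported as value +/- U(t).
#'
#' @param factors `dose_rate_factor` data frame.
#' @param tacs A `tac_set`.
#' @param u_C Named numeric: absolute uncertainty of each region's factor
#'   (uSv/h/MBq). Unnamed scalar = common relative uncertainty applied to
#'   all factors.
#' @param lognormal_factor Biokinetic variability factor (default 2).
#' @param k Coverage factor (default 2).
#' @param regions Regions to include (default: all of `tacs`).
#' @return A `dose_rate_series` with columns `time_min`, `value`, `U`,
#'   `ci95_low`, `ci95_high`.
#' @export
propagate <- function(factors, tacs, u_C, lognormal_factor = 2, k = 2,
                      regions = NULL) {
  ser <- cumulate(factors, tacs, regions)
  regions <- attr(ser, "regions")
  C <- factors$value_uSv_h_MBq[match(regions, factors$source_region)]
  if (is.null(names(u_C)) && length(u_C) == 1L) {
    uC <- C * u_C
  } else {
    miss <- setdiff(regions, names(u_C))
    if (length(miss))
      stop("no factor uncertainty for region(s): ",
           paste(miss, collapse = ", "))
    uC <- as.numeric(u_C[regions])
  }
  A <- tacs$A[regions, , drop = FALSE]
  uA <- lognormal_sd(A, lognormal_factor, k)
  U <- sqrt(colSums((A * uC)^2) + colSums((C * uA)^2))
  ser$U <- U
  ser$ci95_low <- pmax(ser$value - U, 0)
  ser$ci95_high <- ser$value + U
  ser
}

#' Combined relative measurement uncertainty
#'
#' Quadrature combination of the relative uncertainty components of a
#' patient dose-rate measurement (device response, detector positioning,
#' administered-activity calibration), reported as an integer percentage.
#'
#' @param device,positioning,activity Relative uncertainties (fractions,
#'   >= 0).
#' @param ... Further named components, also fractions.
#' @return Combined relative uncertainty in percent, rounded to integer.
#' @export
measurement_budget <- function(device = 0, positioning = 0, activity = 0,
                               ...) {
  comps <- c(device, positioning, activity, ...)
  if (any(comps < 0)) stop("components must be non-negative")
  round(100 * sqrt(sum(comps^2)))
}

#' Positioning uncertainty from the inverse-square law
#'
#' A possible error of +/- delta along the patient-detector line at
#' distance r changes the dose rate by r^2/(r -/+ delta)^2; the relative
#' uncertainty is the symmetrized mean of the two deviations.
#'
#' @param delta Positioning error (m), 0 <= delta < r.
#' @param r Nominal distance (m).
#' @return Relative uncertainty (fraction).
#' @export
positioning_uncertainty <- function(delta, r) {
  if (delta < 0 || delta >= r) stop("need 0 <= delta < r")
  (abs(r^2 / (r - delta)^2 - 1) + abs(r^2 / (r + delta)^2 - 1)) / 2
}

#' Export a dose-rate series to CSV
#' @param series A `dose_rate_series`.
#' @param path Output file.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
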