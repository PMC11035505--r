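# Compartmental biokinetics: linear first-order transfer between named
# compartments, solved exactly by matrix exponentials (piecewise between
# bladder voids), with physical decay applied as a multiplicative factor.
# Time unit is minutes post administration throughout; t = 0 is injection.

#' Source-region labels recognized by the framework
#'
#' The fixed vocabulary of anatomical source regions that biokinetic models
#' may map their compartments to (plus the implicit urinary bladder target
#' of the excretion pathway).
#' @export
SOURCE_REGIONS <- c(
  "Urinary bladder content", "Kidneys", "Bone", "Remainder", "Liver",
  "Blood", "Brain", "Heart", "Lungs", "Pancreas", "Spleen",
  "Salivary glands", "Stomach wall", "Thyroid", "Small intestine content",
  "Right colon content", "Left colon content", "Recto-sigmoid colon content")

BLADDER_REGION <- "Urinary bladder content"
BLADDER_NAME <- "bladder"   # reserved transfer target feeding the bladder

#' Construct a compartmental biokinetic model
#'
#' @param compartments Named character vector: compartment name ->
#'   source-region label (one of [SOURCE_REGIONS]). The urinary bladder is
#'   not a compartment; it is fed by transfers whose `to` is `"bladder"`.
#' @param transfers Data frame with columns `from`, `to`, `rate_per_min`
#'   (first-order transfer coefficients, all >= 0).
#' @param injection_compartment Compartment receiving the administered
#'   activity at t = 0.
#' @param nuclide Name of the bundled radionuclide providing physical decay
#'   (or a [radionuclide] object).
#' @param name Optional model name.
#' @param excretion_sink Name of the compartment feeding the bladder
#'   (defaults to the unique `from` of the transfers into `"bladder"`).
#' @return An object of class `compartment_model`.
#' @export
compartment_model <- function(compartments, transfers, injection_compartment,
                              nuclide, name = "model", excretion_sink = NULL) {
  comp <- names(compartments)
  if (is.null(comp) || anyDuplicated(comp))
    stop("compartments must be uniquely named")
  if (BLADDER_NAME %in% comp)
    stop("'bladder' is the implicit excretion target, not a compartment")
  bad <- setdiff(unname(compartments), SOURCE_REGIONS)
  if (length(bad))
    stop("unknown source-region label(s): ", paste(bad, collapse = ", "))
  stopifnot(is.data.frame(transfers),
            all(c("from", "to", "rate_per_min") %in% names(transfers)))
  if (any(transfers$rate_per_min < 0))
    stop("negative transfer coefficient")
  if (!all(transfers$from %in% comp))
    stop("transfer from unknown compartment")
  if (!all(transfers$to %in% c(comp, BLADDER_NAME)))
    stop("transfer to unknown compartment")
  if (!injection_compartment %in% comp)
    stop("injection compartment not among compartments")
  if (is.character(nuclide)) nuclide <- load_nuclide(nuclide)
  to_bladder <- transfers$from[transfers$to == BLADDER_NAME]
  if (is.null(excretion_sink))
    excretion_sink <- if (length(to_bladder)) to_bladder[[1L]] else NA_character_

  n <- length(comp)
  M <- matrix(0, n, n, dimnames = list(comp, comp))
  binflow <- stats::setNames(numeric(n), comp)
  for (i in seq_len(nrow(transfers))) {
    fr <- transfers$from[i]; to <- transfers$to[i]; r <- transfers$rate_per_min[i]
    M[fr, fr] <- M[fr, fr] - r
    if (to == BLADDER_NAME) binflow[fr] <- binflow[fr] + r
    else M[to, fr] <- M[to, fr] + r
  }
  structure(
    list(name = name, compartments = comp,
         region_map = stats::setNames(unname(compartments), comp),
         transfers = transfers, M = M, bladder_inflow = binflow,
         injection_compartment = injection_compartment,
         excretion_sink = excretion_sink, nuclide = nuclide),
    class = "compartment_model")
}

#' Read a compartmental model from a structured text (JSON) file
#'
#' @param path Path to a model file: fields `compartments` (name -> region
#'   label), `transfers` (from/to/rate_per_min), `injection_compartment`,
#'   `nuclide`, optional `name` and `excretion_sink`.
#' @return A [compartment_model].
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- as.data.frame(j$transfers)
  compartment_model(unlist(j$compartments), tr, j$injection_compartment,
                    j$nuclide, name = if (is.null(j$name)) "model" else j$name,
                    excretion_sink = j$excretion_sink)
}

#' Load a bundled biokinetic model
#'
#' @param name `"Tc99m_HDP_MDP"`, `"F18_FDG"` or `"I131_NaI"`. The bundled
#'   transfer coefficients are illustrative, documented defaults and are
#'   intended to be replaced by compilation values via [read_model_json].
#' @return A [compartment_model].
#' @export
bundled_model <- function(name) {
  path <- system.file("extdata", "biokinetics", paste0(name, ".json"),
                      package = "nmdoserate")
  if (path == "") stop("no bundled biokinetic model '", name, "'")
  read_model_json(path)
}

#' Bladder voiding schedule
#'
#' Either an explicit strictly-increasing vector of void times, or a
#' (first void, interval) pair generating first, first + interval, ...
#'
#' @param void_times Explicit void times, minutes post administration.
#' @param first_void First void time (min).
#' @param interval Interval between subsequent voids (min); defaults to
#'   `first_void` when only an interval-type regime is given.
#' @return An object of class `voiding_schedule`.
#' @export
voiding_schedule <- function(void_times = NULL, first_void = NULL,
                             interval = NULL) {
  if (!is.null(void_times)) {
    if (any(void_times <= 0) || any(diff(void_times) <= 0))
      stop("void times must be positive and strictly increasing")
    structure(list(kind = "explicit", void_times = as.numeric(void_times)),
              class = "voiding_schedule")
  } else {
    if (is.null(first_void) && is.null(interval))
      stop("give void_times, or first_void and/or interval")
    if (is.null(first_void)) first_void <- interval
    if (is.null(interval)) interval <- first_void
    if (first_void <= 0 || interval <= 0)
      stop("first void and interval must be positive")
    structure(list(kind = "regular", first_void = first_void,
                   interval = interval), class = "voiding_schedule")
  }
}

#' Expand a voiding schedule up to a horizon
#'
#' @param schedule A [voiding_schedule] (or `NULL` for no voiding).
#' @param horizon Last time of interest (min).
#' @return Numeric vector of void times in (0, horizon].
#' @export
void_times <- function(schedule, horizon) {
  if (is.null(schedule)) return(numeric(0))
  stopifnot(inherits(schedule, "voiding_schedule"))
  if (schedule$kind == "explicit") {
    schedule$void_times[schedule$void_times <= horizon]
  } else {
    if (schedule$first_void > horizon) return(numeric(0))
    seq(schedule$first_void, horizon, by = schedule$interval)
  }
}

.expm <- function(A) {
  as.matrix(Matrix::expm(Matrix::Matrix(A, sparse = FALSE)))
}

# Augmented system: compartments plus a bladder row that only accumulates.
.aug_matrix <- function(model) {
  n <- length(model$compartments)
  A <- rbind(cbind(model$M, rep(0, n)),
             c(model$bladder_inflow, 0))
  dimnames(A) <- NULL
  A
}

# Exact propagation of the undecayed state (compartments + bladder) across
# a time grid with complete, instantaneous voids. Returns the state matrix
# (n+1 rows x length(t_grid) cols), right-continuous at void times, plus
# the cumulative voided (undecayed) fraction at each grid time.
.propagate <- function(model, schedule, t_grid) {
  n <- length(model$compartments)
  A <- .aug_matrix(model)
  s0 <- numeric(n + 1L)
  s0[match(model$injection_compartment, model$compartments)] <- 1
  vts <- void_times(schedule, max(t_grid))
  events <- sort(unique(c(t_grid, vts)))
  state <- s0
  t_cur <- 0
  voided <- 0
  out <- matrix(NA_real_, n + 1L, length(t_grid))
  voided_out <- numeric(length(t_grid))
  # value at t = 0 if requested
  hit <- which(t_grid == 0)
  if (length(hit)) { out[, hit] <- state; voided_out[hit] <- voided }
  step_cache <- new.env(parent = emptyenv())
  for (ev in events[events > 0]) {
    dt <- ev - t_cur
    key <- sprintf("%.12g", dt)
    P <- get0(key, envir = step_cache)
    if (is.null(P)) { P <- .expm(A * dt); assign(key, P, envir = step_cache) }
    state <- as.numeric(P %*% state)
    t_cur <- ev
    if (ev %in% vts) {              # complete instantaneous emptying
      voided <- voided + state[n + 1L]
      state[n + 1L] <- 0
    }
    hit <- which(t_grid == ev)
    if (length(hit)) { out[, hit] <- state; voided_out[hit] <- voided }
  }
  list(state = out, voided = voided_out, void_times = vts)
}

#' Solve a compartmental model to per-compartment time-activity curves
#'
#' Closed-form solution of dA/dt = M A - lambda_p A with the administered
#' activity in the injection compartment at t = 0, evaluated exactly on the
#' grid (matrix exponential per step; no truncation error). The urinary
#' bladder is excluded here; see [solve_tacs] for the full region-level set.
#'
#' @param model A [compartment_model].
#' @param t_grid Increasing time grid (min), starting at >= 0.
#' @return A list of `tac` objects (one per compartment), fractions of
#'   administered activity with physical decay included.
#' @export
solve_compartments <- function(model, t_grid) {
  .check_grid(t_grid)
  pr <- .propagate(model, NULL, t_grid)
  lam <- decay_constant(model$nuclide, "per_min")
  dec <- exp(-lam * t_grid)
  lapply(stats::setNames(seq_along(model$compartments), model$compartments),
         function(i) {
           .tac(region = model$region_map[[i]], times = t_grid,
                a = pr$state[i, ] * dec, label = model$compartments[i])
         })
}

.check_grid <- function(t_grid) {
  if (length(t_grid) < 1L || any(t_grid < 0) || any(diff(t_grid) <= 0))
    stop("time grid must be non-negative and strictly increasing")
}

.tac <- function(region, times, a, label = region, generator = NULL) {
  structure(list(region = region, times = as.numeric(times),
                 a = as.numeric(a), label = label, generator = generator),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s  %d points on [%g, %g] min, a in [%.3g, %.3g]\n",
              x$label, length(x$times), min(x$times), max(x$times),
              min(x$a), max(x$a)))
  invisible(x)
}

#' Bladder content curve from an arbitrary inflow function
#'
#' Integrates an externally supplied urine inflow rate (fraction of
#' administered activity per minute, not decay-corrected) into the bladder
#' with physical decay, emptying completely and instantaneously at each
#' void. Model-driven bladder curves use the exact matrix-exponential route
#' in [solve_tacs]; this operation supports measured or ad-hoc inflows via
#' adaptive quadrature between voids.
#'
#' @param inflow Function of time (min) returning inflow rate >= 0.
#' @param schedule A [voiding_schedule] or `NULL`.
#' @param lambda_p Physical decay constant (1/min).
#' @param t_grid Evaluation grid (min).
#' @return A `tac` for the urinary bladder content (right-continuous:
#'   at a void time the post-void value 0 is reported).
#' @export
bladder_tac <- function(inflow, schedule, lambda_p, t_grid) {
  .check_grid(t_grid)
  stopifnot(is.function(inflow), lambda_p >= 0)
  vts <- void_times(schedule, max(t_grid))
  a <- vapply(t_grid, function(t) {
    t0 <- c(0, vts)[findInterval(t, c(0, vts))]  # last void at or before t
    if (t == t0) return(0)
    val <- stats::integrate(function(s) {
      r <- inflow(s)
      if (any(r < -1e-12)) stop("negative inflow")
      r * exp(-lambda_p * (t - s))
    }, lower = t0, upper = t, rel.tol = 1e-10)$value
    val
  }, numeric(1))
  a[t_grid == 0] <- 0
  .tac(BLADDER_REGION, t_grid, a)
}

#' Region-level time-activity curves under a voiding schedule
#'
#' Solves the full model (compartments plus accumulating bladder) exactly,
#' applies physical decay, empties the bladder completely at each void time
#' and aggregates compartments into source regions via the model's region
#' map.
#'
#' @param model A [compartment_model].
#' @param schedule A [voiding_schedule] or `NULL` (no voiding).
#' @param t_grid Evaluation grid (min). Values at void times are
#'   right-continuous (post-void).
#' @return An object of class `tac_set`: regions x times matrix of
#'   fractional activities plus bookkeeping (cumulative voided fraction,
#'   decay factor) supporting conservation checks and exact integration.
#' @export
solve_tacs <- function(model, schedule, t_grid) {
  .check_grid(t_grid)
  pr <- .propagate(model, schedule, t_grid)
  lam <- decay_constant(model$nuclide, "per_min")
  dec <- exp(-lam * t_grid)
  regions <- unique(c(unname(model$region_map), BLADDER_REGION))
  A <- matrix(0, length(regions), length(t_grid),
              dimnames = list(regions, NULL))
  for (i in seq_along(model$compartments)) {
    rg <- model$region_map[[i]]
    A[rg, ] <- A[rg, ] + pr$state[i, ] * dec
  }
  A[BLADDER_REGION, ] <- A[BLADDER_REGION, ] +
    pr$state[length(model$compartments) + 1L, ] * dec
  structure(list(times = as.numeric(t_grid), regions = regions, A = A,
                 voided_undecayed = pr$voided, decay = dec,
                 model = model, schedule = schedule),
            class = "tac_set")
}

#' @export
print.tac_set <- function(x, ...) {
  cat(sprintf("<tac_set> %s: %d regions on [%g, %g] min (%d points)\n",
              x$model$name, length(x$regions), min(x$times), max(x$times),
              length(x$times)))
  invisible(x)
}

#' Extract one region's curve from a tac_set
#' @param tacs A `tac_set` from [solve_tacs].
#' @param region Source-region label.
#' @return A `tac` object carrying its generating model for exact
#'   integration.
#' @export
region_tac <- function(tacs, region) {
  if (!region %in% tacs$regions)
    stop("region '", region, "' not in this model's curves")
  .tac(region, tacs$times, tacs$A[region, ],
       generator = list(model = tacs$model, schedule = tacs$schedule))
}

#' Fractional activities per source region at one time
#'
#' @param model A [compartment_model].
#' @param schedule A [voiding_schedule] or `NULL`.
#' @param t Time post administration (min, >= 0).
#' @return Named vector: region -> fraction of administered activity
#'   (physical decay included). The sum never exceeds exp(-lambda_p t).
#' @export
fractional_activities <- function(model, schedule, t) {
  stopifnot(length(t) == 1L, t >= 0)
  ts <- solve_tacs(model, schedule, if (t == 0) 0 else c(0, t))
  ts$A[, length(ts$times)]
}

#' Time-integrated activity of a curve
#'
#' Integral of the fractional activity over time, in MBq h per MBq
#' administered. For model-generated curves (from [solve_tacs] /
#' [region_tac]) the integral is evaluated in closed form piecewise between
#' void times (matrix-exponential integral; no quadrature error); for bare
#' grid curves a trapezoidal integral over the stored grid is returned.
#'
#' @param curve A `tac` object.
#' @param horizon Upper limit (min), may be `Inf` for model-generated
#'   curves (analytic tail, voiding continued until activity is exhausted).
#' @return Time-integrated activity (h).
#' @export
time_integrated_activity <- function(curve, horizon = Inf) {
  stopifnot(inherits(curve, "tac"))
  if (!is.null(curve$generator)) {
    g <- curve$generator
    return(.tia_model(g$model, g$schedule, curve$region, horizon) / 60)
  }
  if (!is.finite(horizon))
    stop("infinite horizon requires a model-generated curve")
  t <- curve$times; a <- curve$a
  keep <- t <= horizon
  t <- t[keep]; a <- a[keep]
  if (length(t) < 2L) return(0)
  sum(diff(t) * (utils::head(a, -1) + utils::tail(a, -1)) / 2) / 60
}

# Exact integral (min units) of one region's decayed activity from 0 to
# horizon: piecewise over void intervals with the decayed augmented matrix.
.tia_model <- function(model, schedule, region, horizon) {
  lam <- decay_constant(model$nuclide, "per_min")
  n <- length(model$compartments)
  A <- .aug_matrix(model) - lam * diag(n + 1L)   # decayed dynamics
  w <- numeric(n + 1L)                           # weights selecting region
  w[which(model$region_map == region)] <- 1
  if (region == BLADDER_REGION) w[n + 1L] <- 1
  s <- numeric(n + 1L)
  s[match(model$injection_compartment, model$compartments)] <- 1
  vmax <- if (is.finite(horizon)) horizon else 1e7
  vts <- void_times(schedule, vmax)
  bounds <- c(0, vts[vts < horizon], if (is.finite(horizon)) horizon)
  total <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    dt <- bounds[i + 1L] - bounds[i]
    B <- rbind(cbind(A, s), rep(0, n + 2L))
    E <- .expm(B * dt)
    intg <- E[seq_len(n + 1L), n + 2L]           # int_0^dt expm(A u) s du
    total <- total + sum(w * intg)
    s <- as.numeric(E[seq_len(n + 1L), seq_len(n + 1L)] %*% s)
    if (bounds[i + 1L] %in% vts) s[n + 1L] <- 0
    if (sum(abs(s)) < 1e-14) break
  }
  if (!is.finite(horizon) && sum(abs(s)) >= 1e-14) {
    # analytic tail after the last relevant void: -A^{-1} s
    tail_int <- solve(A, -s)
    total <- total + sum(w * tail_int)
  }
  total
}
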