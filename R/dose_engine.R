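# Dose engine: fluence-to-H*(10) conversion, Monte Carlo and point-kernel
# backends on scenes, the vial reference simulation, effective dose.

#' Ambient dose equivalent per unit fluence
#'
#' Log-log interpolation of the bundled monoenergetic conversion table
#' (operational-quantity coefficients); exact at table nodes, no
#' extrapolation outside the tabulated range.
#'
#' @param energy_keV Photon energies (keV).
#' @return h*(10) in pSv cm2.
#' @export
h10_per_fluence <- function(energy_keV) {
  tab <- .h10_table()
  .interp_loglog(tab$energy_keV, tab$h10, energy_keV)
}

.h10_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "conversion", "h10_per_fluence.tsv",
                          package = "nmdoserate")
      cache <<- utils::read.table(path, header = FALSE, comment.char = "#",
                                  col.names = c("energy_keV", "h10"))
    }
    cache
  }
})

#' ICRP-103 tissue weighting factors
#' @return Data frame `tissue`, `w_T`; the weights sum to 1 exactly.
#' @export
tissue_weights <- function() {
  path <- system.file("extdata", "conversion", "tissue_weights.tsv",
                      package = "nmdoserate")
  utils::read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("tissue", "w_T"),
                    stringsAsFactors = FALSE)
}

#' Sex-averaged effective dose from organ dose maps
#'
#' E = sum_T w_T (D_T,male + D_T,female) / 2. A weighted tissue missing
#' from a map falls back to that map's remainder dose when present
#' (documented remainder rule); otherwise an error is raised. Units are
#' preserved.
#'
#' @param organ_doses_female,organ_doses_male Named numeric vectors,
#'   tissue -> dose; names match the `tissue` column of [tissue_weights]
#'   (a `"remainder"` entry backs unlisted tissues).
#' @param weights Tissue weight table, default [tissue_weights].
#' @return Effective dose (same units as the inputs).
#' @export
effective_dose <- function(organ_doses_female, organ_doses_male,
                           weights = tissue_weights()) {
  pick <- function(map, tissue) {
    if (tissue %in% names(map)) return(map[[tissue]])
    if ("remainder" %in% names(map)) return(map[["remainder"]])
    stop("tissue '", tissue, "' missing and no remainder dose given")
  }
  sum(vapply(seq_len(nrow(weights)), function(i) {
    tw <- weights$tissue[i]
    weights$w_T[i] * (pick(organ_doses_female, tw) + pick(organ_doses_male, tw)) / 2
  }, numeric(1)))
}

#' Convert Sv/s per Bq to uSv/h per MBq
#' @param x Dose rate(s) in Sv/s/Bq.
#' @return Same in uSv/h/MBq (factor 3.6e15).
#' @export
convert_units <- function(x) {
  stopifnot(all(x >= 0))
  x * 3.6e15
}

.buildup_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "buildup", "water_berger.tsv",
                          package = "nmdoserate")
      cache <<- utils::read.table(path, header = FALSE, comment.char = "#",
                                  col.names = c("energy_keV", "a", "b", "beta", "gamma"))
    }
    cache
  }
})

# Assemble the per-label material arrays a scene needs for transport:
# one coefficient row per label (label densities applied), air for label 0
# and outside the grid.
.scene_arrays <- function(scene) {
  lm <- scene$label_map
  mats <- vector("list", nrow(lm) + 1L)
  # scenes may override the ambient density (e.g. near-vacuum benchmarks)
  mats[[1L]] <- load_material("air", density = scene$ambient_density)
  for (i in seq_len(nrow(lm)))
    mats[[i + 1L]] <- load_material(lm$material[i], density = lm$density[i])
  mt <- .mu_tables(mats)
  maxlab <- max(lm$label)
  lab2mat <- integer(maxlab + 1L)            # index by label value + 1
  lab2mat[1L] <- 0L                          # label 0 -> air (row 0-based)
  for (i in seq_len(nrow(lm))) lab2mat[lm$label[i] + 1L] <- i
  list(lab = as.integer(scene$labels), dims = dim(scene$labels),
       vox = scene$voxel_mm / 10, origin = scene$origin_cm,
       lab2mat = lab2mat, air_mat = 0L,
       e_keV = exp(mt$log_e), mu_tot = exp(mt$log_mu_tot),
       mu_com = mt$mu_com)
}

# 0-based source voxel indices for a region of the scene's patient side
.scene_source_voxels <- function(scene, source_region) {
  lm <- scene$label_map
  pat <- lm[lm$who == "patient", ]
  lbls <- if (source_region == "Blood") pat$label
  else pat$label[pat$region == source_region]
  if (!length(lbls))
    stop("source region '", source_region, "' not present in the scene")
  idx <- which(array(scene$labels %in% lbls, dim(scene$labels))) - 1L
  if (!length(idx)) stop("source region '", source_region, "' is empty")
  idx
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed))
  on.exit(if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
          else assign(".Random.seed", old, .GlobalEnv))
  force(expr)
}

#' Monte Carlo photon transport on a scene
#'
#' Samples emission positions uniformly over the source-region voxels,
#' isotropic directions and line energies from the nuclide spectrum, and
#' transports with photoelectric absorption and Klein-Nishina Compton
#' scattering (Woodcock tracking; 15 keV cutoff, absorbed locally). Point
#' scenes score the tally with a next-event (forced-detection) estimator
#' at every vertex, converted with the chosen response; two-phantom scenes
#' additionally score analog energy deposition per counterpart organ.
#' Reproducible for a fixed seed.
#'
#' @param scene A `scene`.
#' @param nuclide A [radionuclide] or bundled nuclide name.
#' @param source_region Region of the patient carrying the activity.
#' @param n_histories Number of source particles (>= 1).
#' @param seed Integer seed.
#' @param response `"h10"` (pSv cm2 weighting, the default) or
#'   `"fluence"` (unit response; tally in 1/cm2 per particle).
#' @param e_cut_keV Energy cutoff (default 15).
#' @return An object of class `tally_result`: per-particle point tally and
#'   standard error, per-organ energy deposition (keV/particle), energy
#'   bookkeeping, histories and seed.
#' @export
mc_transport <- function(scene, nuclide, source_region, n_histories,
                         seed = 1L, response = c("h10", "fluence"),
                         e_cut_keV = 15) {
  response <- match.arg(response)
  if (is.character(nuclide)) nuclide <- load_nuclide(nuclide)
  stopifnot(n_histories >= 1)
  arr <- .scene_arrays(scene)
  src <- .scene_source_voxels(scene, source_region)
  det <- if (is.null(scene$detector_cm)) numeric(0) else scene$detector_cm
  rtab <- .h10_table()
  resp_v <- if (response == "h10") rtab$h10 else rep(1, nrow(rtab))
  organ <- integer(0); n_org <- 0L
  if (!is.null(scene$counterpart)) {
    off <- scene$counterpart_offset
    organ <- as.integer(ifelse(scene$labels > off, scene$labels - off, 0L))
    n_org <- max(organ)
  }
  res <- .with_seed(seed, cpp_mc_transport(
    arr$lab, arr$dims, arr$vox, arr$origin, arr$lab2mat, arr$air_mat,
    arr$e_keV, arr$mu_tot, arr$mu_com,
    rtab$energy_keV, resp_v,
    nuclide$energy_keV, nuclide$intensity,
    src, det, organ, n_org,
    as.integer(n_histories), e_cut_keV,
    FALSE, numeric(3), numeric(3)))
  organ_edep <- NULL
  if (n_org > 0L) {
    clm <- scene$counterpart$label_map
    ed <- res$organ_edep_keV[clm$label + 1L]
    organ_edep <- stats::setNames(ed, clm$region)
  }
  structure(list(quantity = response, source_region = source_region,
                 nuclide = nuclide$name,
                 tally_per_particle = res$tally_mean,
                 tally_se = res$tally_se,
                 organ_edep_keV = organ_edep,
                 e_emitted_keV = res$e_emitted_keV,
                 e_deposited_keV = res$e_deposited_keV,
                 e_escaped_keV = res$e_escaped_keV,
                 n_histories = n_histories, seed = as.integer(seed)),
            class = "tally_result")
}

#' @export
print.tally_result <- function(x, ...) {
  cat(sprintf("<tally_result> %s from '%s' (%s), %g histories, seed %d\n",
              x$quantity, x$source_region, x$nuclide, x$n_histories, x$seed))
  if (!is.na(x$tally_per_particle))
    cat(sprintf("  point tally %.4g +/- %.2g per particle\n",
                x$tally_per_particle, x$tally_se))
  invisible(x)
}

# tally (resp per emitted particle) -> uSv/h/MBq: x yield -> per decay
# (pSv, = 1e-12 Sv/s/Bq) -> x 3.6e15 x 1e-12
.tally_to_uSv_h_MBq <- function(tally_per_particle, nuclide) {
  convert_units(tally_per_particle * total_yield(nuclide) * 1e-12)
}

#' Per-region dose-rate factor via the Monte Carlo backend
#'
#' @inheritParams mc_transport
#' @return One-row data frame of class `dose_rate_factor`: source_region,
#'   quantity, geometry, value_uSv_h_MBq, rel_SE, n_histories, seed,
#'   backend.
#' @export
mc_dose_rate_factor <- function(scene, nuclide, source_region, n_histories,
                                seed = 1L) {
  if (is.character(nuclide)) nuclide <- load_nuclide(nuclide)
  tr <- mc_transport(scene, nuclide, source_region, n_histories, seed)
  val <- .tally_to_uSv_h_MBq(tr$tally_per_particle, nuclide)
  rel <- if (tr$tally_per_particle > 0) tr$tally_se / tr$tally_per_particle
  else NA_real_
  .factor_row(source_region, "H*(10)",
              sprintf("%s@%gcm", scene$configuration, scene$gap),
              val, rel, n_histories, seed, "mc")
}

.factor_row <- function(region, quantity, geometry, value, rel_se,
                        n_hist, seed, backend) {
  structure(data.frame(source_region = region, quantity = quantity,
                       geometry = geometry, value_uSv_h_MBq = value,
                       rel_SE = rel_se, n_histories = n_hist,
                       seed = as.integer(seed), backend = backend,
                       stringsAsFactors = FALSE),
            class = c("dose_rate_factor", "data.frame"))
}

#' Per-region dose-rate factor via the deterministic point kernel
#'
#' Sums, over the source-region voxels, the attenuated line-of-sight
#' primary fluence to the tally point (exact voxel-by-voxel optical depth)
#' times an energy- and depth-dependent Berger-form water buildup factor,
#' converted with the ambient-dose-equivalent response. Fast and
#' noise-free; the Monte Carlo backend is the reference.
#'
#' @inheritParams mc_transport
#' @param buildup Apply the bundled water buildup table (default TRUE);
#'   with `FALSE` only the uncollided component is scored.
#' @param stride Deterministic source-voxel subsampling (every
#'   `stride`-th voxel); 1 = all voxels.
#' @return A `dose_rate_factor` row.
#' @export
point_kernel <- function(scene, nuclide, source_region, buildup = TRUE,
                         stride = 1L) {
  if (is.character(nuclide)) nuclide <- load_nuclide(nuclide)
  if (is.null(scene$detector_cm))
    stop("point kernel needs a point-configuration scene")
  arr <- .scene_arrays(scene)
  src <- .scene_source_voxels(scene, source_region)
  rtab <- .h10_table()
  bu <- .buildup_table()
  res <- cpp_point_kernel(
    arr$lab, arr$dims, arr$vox, arr$origin, arr$lab2mat, arr$air_mat,
    arr$e_keV, arr$mu_tot, arr$mu_com,
    rtab$energy_keV, rtab$h10,
    nuclide$energy_keV, nuclide$intensity,
    src, scene$detector_cm,
    log(bu$energy_keV), bu$a, bu$b, bu$beta, bu$gamma, isTRUE(buildup),
    as.integer(stride))
  # the kernel includes line intensities, so the sum is already per decay
  val <- convert_units(res$value * 1e-12)
  .factor_row(source_region, "H*(10)",
              sprintf("%s@%gcm", scene$configuration, scene$gap),
              val, 0, NA_real_, NA_integer_, "point_kernel")
}

#' Dose-rate factors for a set of source regions
#'
#' @inheritParams mc_transport
#' @param regions Character vector of source regions.
#' @param backend `"mc"` or `"point_kernel"`.
#' @param ... Passed to the backend.
#' @return A `dose_rate_factor` data frame, one row per region.
#' @export
dose_rate_factors <- function(scene, nuclide, regions,
                              backend = c("mc", "point_kernel"), ...) {
  backend <- match.arg(backend)
  rows <- lapply(regions, function(rg) {
    if (backend == "mc") mc_dose_rate_factor(scene, nuclide, rg, ...)
    else point_kernel(scene, nuclide, rg, ...)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dose_rate_factor", "data.frame")
  out
}

#' Reference vial simulation
#'
#' Ambient dose equivalent rate per unit activity at a given distance from
#' the half-filled reference vial, computed by Monte Carlo fluence scoring
#' at the tally point with forced detection, converted with the
#' monoenergetic conversion coefficients.
#'
#' @param nuclide Bundled nuclide name or [radionuclide].
#' @param distance_cm Tally distance from the vial centre (default 100).
#' @param n_histories Source particles (default 2e5).
#' @param seed Integer seed.
#' @param backend `"mc"` (reference) or `"point_kernel"`.
#' @return A `dose_rate_factor` row in uSv/h/MBq.
#' @export
vial_reference <- function(nuclide, distance_cm = 100, n_histories = 2e5,
                           seed = 1L, backend = c("mc", "point_kernel")) {
  backend <- match.arg(backend)
  if (is.character(nuclide)) nuclide <- load_nuclide(nuclide)
  sc <- vial_scene(distance_cm = distance_cm)
  if (backend == "mc") {
    tr <- mc_transport(sc, nuclide, "solution", n_histories, seed)
    val <- .tally_to_uSv_h_MBq(tr$tally_per_particle, nuclide)
    rel <- tr$tally_se / tr$tally_per_particle
    .factor_row("solution", "H*(10)", sprintf("vial@%gcm", distance_cm),
                val, rel, n_histories, seed, "mc")
  } else {
    pk <- point_kernel(sc, nuclide, "solution")
    pk$geometry <- sprintf("vial@%gcm", distance_cm)
    pk
  }
}

#' Organ dose rates of the exposed individual in a two-phantom scene
#'
#' Analog Monte Carlo energy deposition per counterpart organ, divided by
#' the organ masses (collision kerma approximation, no electron transport)
#' and expressed per unit administered activity in the source region.
#'
#' @inheritParams mc_transport
#' @return Named vector of organ equivalent dose rates (uSv/h/MBq) by
#'   counterpart region label.
#' @export
organ_dose_rates <- function(scene, nuclide, source_region, n_histories,
                             seed = 1L) {
  if (is.character(nuclide)) nuclide <- load_nuclide(nuclide)
  if (is.null(scene$counterpart)) stop("scene has no exposed individual")
  tr <- mc_transport(scene, nuclide, source_region, n_histories, seed)
  m <- organ_masses(scene$counterpart)
  keV_to_J <- 1.602176634e-16
  # keV/particle -> Gy/particle -> Sv/s/Bq (x yield) -> uSv/h/MBq
  gy <- tr$organ_edep_keV * keV_to_J / m$mass_kg[match(names(tr$organ_edep_keV),
                                                       m$region)]
  convert_units(gy * total_yield(nuclide))
}
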