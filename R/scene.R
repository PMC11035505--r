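# Scenes: a patient phantom plus either a point tally (ambient dose
# equivalent) or a second phantom (effective dose of an exposed
# individual). Distances are skin-to-skin along the horizontal line through
# the tally/chest point; chest height is 75% of the phantom height. Both
# conventions are fixed, documented choices of this framework.

.CHEST_FRACTION <- 0.75

# world-coordinate centres of voxels along one axis
.axis_centres <- function(origin, n, vox) origin + (seq_len(n) - 0.5) * vox

# anterior skin y (outer voxel face) on the horizontal line x = x0, z = z0
.anterior_skin_y <- function(phantom, z0) {
  vox <- phantom$voxel_mm / 10
  iz <- max(1L, min(phantom$shape[3],
                    ceiling((z0 - phantom$origin_cm[3]) / vox)))
  ix <- as.integer(round(phantom$shape[1] / 2))
  col <- phantom$labels[ix, , iz]
  iy <- which(col > 0L)
  if (!length(iy)) stop("no body voxels on the chest line")
  phantom$origin_cm[2] + max(iy) * vox    # anterior face of last body voxel
}

#' Build an exposure scene
#'
#' @param patient A `voxel_phantom` (the nuclear-medicine patient).
#' @param configuration `"point"` (tally point at chest height),
#'   `"face_to_face"` or `"side_by_side"` (second phantom).
#' @param gap Skin-to-skin distance (cm), > 0. For `"point"`, the distance
#'   from the anterior skin surface to the tally point.
#' @param counterpart A second `voxel_phantom` for the two-phantom
#'   configurations (the exposed individual).
#' @param gap_from `"skin"` (default) or `"centre"`: for the `"point"`
#'   configuration only, measure the distance from the anterior skin or
#'   from the phantom centre axis.
#' @return An object of class `scene`: a combined labeled voxel grid in
#'   world coordinates, a combined label map with a `who` column, and for
#'   point scenes the tally position.
#' @export
build_scene <- function(patient, configuration = c("point", "face_to_face",
                                                   "side_by_side"),
                        gap, counterpart = NULL, gap_from = "skin") {
  configuration <- match.arg(configuration)
  stopifnot(inherits(patient, "voxel_phantom"))
  if (gap <= 0) stop("gap must be positive (phantoms/tally must not overlap)")
  vox <- patient$voxel_mm / 10
  z_chest <- .CHEST_FRACTION * patient$height_cm

  if (configuration == "point") {
    y_skin <- if (identical(gap_from, "centre")) 0 else
      .anterior_skin_y(patient, z_chest)
    det <- c(0, y_skin + gap, z_chest)
    lm <- cbind(patient$label_map, who = "patient",
                stringsAsFactors = FALSE)
    return(structure(list(configuration = "point", gap = gap,
                          labels = patient$labels, label_map = lm,
                          voxel_mm = patient$voxel_mm,
                          origin_cm = patient$origin_cm,
                          detector_cm = det, patient = patient,
                          counterpart = NULL),
                     class = "scene"))
  }

  stopifnot(inherits(counterpart, "voxel_phantom"))
  if (counterpart$voxel_mm != patient$voxel_mm)
    stop("patient and counterpart must share the voxel size")

  plab <- patient$labels
  clab <- counterpart$labels
  po <- patient$origin_cm
  if (configuration == "face_to_face") {
    # counterpart rotated 180 degrees about the vertical axis: anterior
    # surfaces face each other across the gap (offset along +y)
    clab <- clab[rev(seq_len(dim(clab)[1])), rev(seq_len(dim(clab)[2])), ,
                 drop = FALSE]
    y_skin_p <- .anterior_skin_y(patient, z_chest)
    zc_c <- .CHEST_FRACTION * counterpart$height_cm
    y_skin_c <- .anterior_skin_y(counterpart, zc_c)  # before rotation
    # counterpart anterior face sits at gap beyond the patient's skin
    c_extent_y <- counterpart$shape[2] * vox
    # after rotation the counterpart's anterior surface is at its local -y;
    # its world origin y: rotated anterior face offset from origin =
    # c_extent_y - y_skin_c (local). Place so that face at y_skin_p + gap.
    co_y <- y_skin_p + gap - (c_extent_y - (y_skin_c - counterpart$origin_cm[2]))
    co <- c(-counterpart$shape[1] * vox / 2, co_y, 0)
  } else {
    # side by side: same orientation, offset along +x, gap between the
    # lateral (arm-side) surfaces at chest height
    x_max_p <- .lateral_extent(patient, "max")
    x_min_c <- .lateral_extent(counterpart, "min")
    co_x <- x_max_p + gap - (x_min_c - counterpart$origin_cm[1])
    co <- c(co_x, -counterpart$shape[2] * vox / 2, 0)
  }

  # combined grid bounding both phantoms
  lo <- pmin(po, co)
  hi <- pmax(po + patient$shape * vox, co + dim(clab) * vox)
  nshape <- as.integer(round((hi - lo) / vox))
  lab <- array(0L, nshape)
  .paste_block <- function(lab, block, org) {
    i0 <- as.integer(round((org - lo) / vox))
    d <- dim(block)
    sl <- lab[i0[1] + seq_len(d[1]), i0[2] + seq_len(d[2]),
              i0[3] + seq_len(d[3]), drop = FALSE]
    if (any(sl != 0L & block != 0L)) stop("phantoms overlap")
    sl[block != 0L] <- block[block != 0L]
    lab[i0[1] + seq_len(d[1]), i0[2] + seq_len(d[2]),
        i0[3] + seq_len(d[3])] <- sl
    lab
  }
  COUNTER_OFFSET <- 100L
  lab <- .paste_block(lab, plab, po)
  lab <- .paste_block(lab, ifelse(clab > 0L, clab + COUNTER_OFFSET, 0L), co)

  lm <- rbind(cbind(patient$label_map, who = "patient"),
              cbind(transform(counterpart$label_map,
                              label = label + COUNTER_OFFSET),
                    who = "counterpart"))
  structure(list(configuration = configuration, gap = gap, labels = lab,
                 label_map = lm, voxel_mm = patient$voxel_mm,
                 origin_cm = lo, detector_cm = NULL,
                 patient = patient, counterpart = counterpart,
                 counterpart_offset = COUNTER_OFFSET,
                 patient_origin = po, counterpart_origin = co),
            class = "scene")
}

.lateral_extent <- function(phantom, side = c("max", "min")) {
  side <- match.arg(side)
  vox <- phantom$voxel_mm / 10
  z0 <- .CHEST_FRACTION * phantom$height_cm
  iz <- max(1L, min(phantom$shape[3],
                    ceiling((z0 - phantom$origin_cm[3]) / vox)))
  sl <- phantom$labels[, , iz]
  ix <- which(rowSums(sl > 0L) > 0)
  if (side == "max") phantom$origin_cm[1] + max(ix) * vox
  else phantom$origin_cm[1] + (min(ix) - 1L) * vox
}

#' Minimal skin-to-skin distance of a two-phantom scene
#'
#' Measured along the configuration's separation axis (y for face-to-face,
#' x for side-by-side) as the minimum over all transverse positions of the
#' distance between the facing body surfaces.
#' @param scene A two-phantom `scene`.
#' @return Distance in cm.
#' @export
min_surface_distance <- function(scene) {
  if (scene$configuration == "point")
    stop("surface distance applies to two-phantom scenes")
  vox <- scene$voxel_mm / 10
  off <- scene$counterpart_offset
  lab <- scene$labels
  pat <- lab > 0L & lab <= off
  cpt <- lab > off
  if (scene$configuration == "face_to_face") {
    # for each (x, z) column: anterior face of patient vs nearest face of
    # counterpart along y
    d_min <- Inf
    ny <- dim(lab)[2]
    ymax_p <- apply(pat, c(1, 3), function(v) if (any(v)) max(which(v)) else NA)
    ymin_c <- apply(cpt, c(1, 3), function(v) if (any(v)) min(which(v)) else NA)
    ok <- !is.na(ymax_p) & !is.na(ymin_c)
    if (!any(ok)) stop("phantoms do not face each other")
    d_min <- min((ymin_c - 1 - ymax_p)[ok]) * vox
  } else {
    xmax_p <- apply(pat, c(2, 3), function(v) if (any(v)) max(which(v)) else NA)
    xmin_c <- apply(cpt, c(2, 3), function(v) if (any(v)) min(which(v)) else NA)
    ok <- !is.na(xmax_p) & !is.na(xmin_c)
    if (!any(ok)) stop("phantoms are not side by side")
    d_min <- min((xmin_c - 1 - xmax_p)[ok]) * vox
  }
  d_min
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %s, gap %g cm, grid %s @ %g mm\n", x$configuration,
              x$gap, paste(dim(x$labels), collapse = " x "), x$voxel_mm))
  invisible(x)
}

#' Reference vial scene
#'
#' The activity-calibration reference geometry: a 50 mm high cylinder of
#' 20 mm outer diameter with a 1 mm borosilicate glass wall, half-filled
#' with a water solution carrying the source, tallied in air at a given
#' distance from the vial centre.
#'
#' @param distance_cm Distance from the vial centre to the tally point
#'   (default 100 cm).
#' @param voxel_mm Voxel edge for the vial grid (default 1 mm).
#' @return A point-configuration `scene` whose source region is
#'   `"solution"`.
#' @export
vial_scene <- function(distance_cm = 100, voxel_mm = 1) {
  vox <- voxel_mm / 10
  r_out <- 1.0; wall <- 0.1; h <- 5.0            # cm
  nx <- ny <- as.integer(ceiling(2 * r_out / vox)) + 2L
  nz <- as.integer(ceiling(h / vox)) + 2L
  origin <- c(-nx * vox / 2, -ny * vox / 2, -nz * vox / 2)
  cx <- .axis_centres(origin[1], nx, vox)
  cy <- .axis_centres(origin[2], ny, vox)
  cz <- .axis_centres(origin[3], nz, vox)
  X <- array(rep(cx, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(cy, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(cz, each = nx * ny), c(nx, ny, nz))
  R2 <- X^2 + Y^2
  inside_z <- abs(Z) <= h / 2
  lab <- array(0L, c(nx, ny, nz))
  glass <- inside_z & R2 <= r_out^2 &
    (R2 > (r_out - wall)^2 | abs(Z) > h / 2 - wall)
  inner <- inside_z & R2 <= (r_out - wall)^2 & abs(Z) <= h / 2 - wall
  fill_top <- 0                                   # half-filled: z < centre
  water <- inner & Z < fill_top
  lab[glass] <- 2L
  lab[water] <- 1L                                # solution
  lm <- data.frame(label = c(1L, 2L), region = c("solution", "wall"),
                   material = c("water", "glass"),
                   density = c(1.00, 2.23), who = "patient",
                   stringsAsFactors = FALSE)
  structure(list(configuration = "point", gap = distance_cm, labels = lab,
                 label_map = lm, voxel_mm = voxel_mm, origin_cm = origin,
                 detector_cm = c(0, distance_cm, 0), patient = NULL,
                 counterpart = NULL),
            class = "scene")
}
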