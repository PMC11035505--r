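# Stylized voxel phantoms. Coordinates: x lateral, y antero-posterior
# (+y = anterior), z vertical (0 = soles, height = vertex), cubic voxels.
# The generator builds a trunk + head + neck + legs body of the requested
# height and mass, carves the requested source-region organs as ellipsoids
# at fixed fractional positions, and labels a homogenized skeleton. It is a
# synthetic, fully documented stand-in for segmented reference anatomies:
# the framework's acceptance surface uses ratios and bounds across
# morphologies, not absolute organ-dose replication.

.LBL_SOFT <- 1L; .LBL_BONE <- 2L; .LBL_LUNG <- 3L; .ORGAN_BASE <- 10L

# organ placement table: centre in trunk-fractional coordinates
# (fx in [-1,1] of half-width, fy in [-1,1] of half-depth, fz in [0,1] of
# trunk height) and fixed adult semi-axes (cm). "frame" head/neck organs use
# their segment's frame instead.
.organ_table <- function() {
  o <- list(
    list(region = "Urinary bladder content", frame = "trunk",
         c = c(0, 0.45, 0.08), s = c(3.9, 3.9, 3.9),
         material = "water", density = 1.00),
    list(region = "Kidneys", frame = "trunk",
         c = c(-0.55, -0.50, 0.42), s = c(3.2, 2.2, 5.5), mirror = TRUE),
    list(region = "Liver", frame = "trunk",
         c = c(-0.38, 0.15, 0.62), s = c(9, 7, 6)),
    list(region = "Stomach wall", frame = "trunk",
         c = c(0.32, 0.25, 0.68), s = c(4, 3, 5)),
    list(region = "Spleen", frame = "trunk",
         c = c(0.60, -0.35, 0.62), s = c(3.5, 2.5, 5.5)),
    list(region = "Pancreas", frame = "trunk",
         c = c(0.05, -0.05, 0.58), s = c(7, 2, 2)),
    list(region = "Heart", frame = "trunk",
         c = c(0.12, 0.20, 0.80), s = c(5.5, 5, 5.5)),
    list(region = "Lungs", frame = "trunk",
         c = c(-0.52, -0.05, 0.80), s = c(5.5, 6.5, 10), mirror = TRUE,
         material = "lung", density = 0.26),
    list(region = "Small intestine content", frame = "trunk",
         c = c(0, 0.20, 0.28), s = c(6.5, 4, 4.3)),
    list(region = "Right colon content", frame = "trunk",
         c = c(-0.55, 0.20, 0.32), s = c(2.5, 2.5, 6)),
    list(region = "Left colon content", frame = "trunk",
         c = c(0.55, 0.20, 0.34), s = c(2.5, 2.5, 6)),
    list(region = "Recto-sigmoid colon content", frame = "trunk",
         c = c(0, -0.20, 0.06), s = c(3, 2.5, 3.5)),
    list(region = "Thyroid", frame = "neck",
         c = c(0, 0.55, 0.5), s = c(2.2, 1.2, 2.2)),
    list(region = "Brain", frame = "head",
         c = c(0, 0, 0.60), s = c(6.5, 8, 6)),
    list(region = "Salivary glands", frame = "head",
         c = c(-0.55, 0.15, 0.12), s = c(2, 1.8, 2.2), mirror = TRUE))
  o
}

#' Generate a stylized adult voxel phantom
#'
#' Deterministic for a fixed seed. The trunk is an elliptical cylinder
#' (half-width : half-depth = 1.8 : 1) whose cross-section is calibrated so
#' that the voxelized mass matches the requested body mass within 1%;
#' heavier bodies at fixed height therefore have thicker trunks and more
#' self-shielding over deep organs. Named organs are ellipsoids at fixed
#' fractional anatomical positions (bladder low in the pelvis, kidneys
#' posterior at mid-trunk, thyroid anterior in the neck, ...); a small
#' seeded jitter (up to 1.5% of the local frame) individualizes organ
#' positions. The homogenized skeleton (spine, pelvis, skull, leg bones) is
#' labeled as bone at 1.40 g/cm3.
#'
#' @param height_cm Body height, 140-200 cm.
#' @param mass_kg Body mass, 40-120 kg.
#' @param region_set Character vector of source regions to carve (subset of
#'   [SOURCE_REGIONS]); `"Remainder"`, `"Blood"` and `"Bone"` need no
#'   explicit organ. Organs not requested are not segmented and remain part
#'   of the remainder tissue.
#' @param seed Integer seed for the position jitter.
#' @param voxel_mm Cubic voxel edge (default 5 mm).
#' @return An object of class `voxel_phantom`.
#' @export
generate_phantom <- function(height_cm, mass_kg, region_set = "Remainder",
                             seed = 1L, voxel_mm = 5) {
  if (height_cm < 140 || height_cm > 200) stop("height outside 140-200 cm")
  if (mass_kg < 40 || mass_kg > 120) stop("mass outside 40-120 kg")
  bad <- setdiff(region_set, SOURCE_REGIONS)
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))

  H <- height_cm
  vox <- voxel_mm / 10                      # cm
  # segment extents (fractions of height)
  z_leg <- c(0, 0.51) * H
  z_trk <- c(0.51, 0.81) * H
  z_nck <- c(0.81, 0.85) * H
  z_hed <- c(0.85, 1.00) * H
  head_s <- c(8, 9.5, (z_hed[2] - z_hed[1]) / 2)   # semi-axes, cm
  r_neck <- 5.5

  # analytic first guess for the trunk half-width (a), with b = a / 1.8,
  # legs scaling with the trunk: leg radius = 0.55 b
  soft_rho <- 1.05
  vol_target <- mass_kg * 1000 / soft_rho   # cm3, as if all soft tissue
  vol_head <- 4 / 3 * pi * prod(head_s) + pi * r_neck^2 * diff(z_nck)
  len_trk <- diff(z_trk); len_leg <- diff(z_leg)
  # pi a b len_trk + 2 pi (0.55 b)^2 len_leg = vol_target - vol_head
  bb <- sqrt((vol_target - vol_head) /
               (pi * 1.8 * len_trk + 2 * pi * 0.55^2 * len_leg))
  a <- 1.8 * bb

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  jit <- stats::runif(3 * 20, -0.015, 0.015)   # per-organ jitter pool

  build <- function(a) {
    b <- a / 1.8
    r_leg <- 0.55 * b
    nx <- as.integer(ceiling((2 * a + 2) / vox))
    ny <- as.integer(ceiling((2 * max(b, head_s[2]) + 2) / vox))
    nz <- as.integer(ceiling(H / vox))
    cx <- (seq_len(nx) - 0.5) * vox - nx * vox / 2    # centred x
    cy <- (seq_len(ny) - 0.5) * vox - ny * vox / 2
    cz <- (seq_len(nz) - 0.5) * vox
    X <- array(rep(cx, times = ny * nz), c(nx, ny, nz))
    Y <- array(rep(rep(cy, each = nx), times = nz), c(nx, ny, nz))
    Z <- array(rep(cz, each = nx * ny), c(nx, ny, nz))

    lab <- array(0L, c(nx, ny, nz))
    trunk <- (X / a)^2 + (Y / b)^2 <= 1 & Z >= z_trk[1] & Z < z_trk[2]
    legs <- Z < z_leg[2] &
      (((X - 0.5 * a)^2 + Y^2 <= r_leg^2) | ((X + 0.5 * a)^2 + Y^2 <= r_leg^2))
    neck <- X^2 + Y^2 <= r_neck^2 & Z >= z_nck[1] & Z < z_nck[2]
    hz <- (z_hed[1] + z_hed[2]) / 2
    head <- (X / head_s[1])^2 + (Y / head_s[2])^2 +
      ((Z - hz) / head_s[3])^2 <= 1
    body <- trunk | legs | neck | head
    lab[body] <- .LBL_SOFT
    list(lab = lab, body = body, X = X, Y = Y, Z = Z, a = a, b = b,
         r_leg = r_leg, nx = nx, ny = ny, nz = nz, cx = cx, cy = cy, cz = cz,
         hz = hz)
  }

  organ_regions <- setdiff(region_set, c("Remainder", "Blood", "Bone"))
  otab <- .organ_table()

  assemble <- function(g) {
    lab <- g$lab
    label_map <- data.frame(label = .LBL_SOFT, region = "Remainder",
                            material = "soft_tissue", density = soft_rho,
                            stringsAsFactors = FALSE)
    next_lbl <- .ORGAN_BASE
    ji <- 0L
    for (o in otab) {
      if (!o$region %in% organ_regions) next
      ji <- ji + 1L
      frame <- o$frame
      if (frame == "trunk") {
        ctr0 <- c(o$c[1] * g$a, o$c[2] * g$b, z_trk[1] + o$c[3] * len_trk)
        scale_j <- c(g$a, g$b, len_trk)
      } else if (frame == "neck") {
        ctr0 <- c(o$c[1] * r_neck, o$c[2] * r_neck,
                  z_nck[1] + o$c[3] * diff(z_nck))
        scale_j <- c(r_neck, r_neck, diff(z_nck))
      } else {
        ctr0 <- c(o$c[1] * head_s[1], o$c[2] * head_s[2],
                  z_hed[1] + o$c[3] * diff(z_hed))
        scale_j <- head_s
      }
      ctr <- ctr0 + jit[(3 * ji - 2):(3 * ji)] * scale_j
      mirror <- isTRUE(o$mirror)
      inside <- ((g$X - ctr[1]) / o$s[1])^2 + ((g$Y - ctr[2]) / o$s[2])^2 +
        ((g$Z - ctr[3]) / o$s[3])^2 <= 1
      if (mirror)
        inside <- inside | (((g$X + ctr[1]) / o$s[1])^2 +
                              ((g$Y - ctr[2]) / o$s[2])^2 +
                              ((g$Z - ctr[3]) / o$s[3])^2 <= 1)
      place <- inside & lab == .LBL_SOFT
      target_vox <- (4 / 3 * pi * prod(o$s) * (1 + mirror)) / vox^3
      if (sum(place) < 0.6 * target_vox)
        stop("organ '", o$region, "' does not fit the body envelope (",
             sum(place), " of ~", round(target_vox), " voxels)")
      lab[place] <- next_lbl
      label_map <- rbind(label_map, data.frame(
        label = next_lbl, region = o$region,
        material = if (is.null(o$material)) "soft_tissue" else o$material,
        density = if (is.null(o$density)) soft_rho else o$density))
      next_lbl <- next_lbl + 1L
    }

    # homogenized skeleton: spine, pelvis, skull shell, leg bones
    spine <- (g$X^2 + (g$Y + 0.55 * g$b)^2 <= 2.2^2) &
      g$Z >= z_trk[1] & g$Z < z_trk[2] + 0.04 * H
    pelvis <- ((g$X / (0.75 * g$a))^2 + ((g$Y + 0.15 * g$b) / (0.75 * g$b))^2 <= 1) &
      !((g$X / (0.55 * g$a))^2 + ((g$Y + 0.15 * g$b) / (0.5 * g$b))^2 <= 1) &
      g$Z >= z_trk[1] & g$Z < z_trk[1] + 0.055 * H
    skull <- ((g$X / head_s[1])^2 + (g$Y / head_s[2])^2 +
                ((g$Z - g$hz) / head_s[3])^2 <= 1) &
      ((g$X / (0.85 * head_s[1]))^2 + (g$Y / (0.85 * head_s[2]))^2 +
         ((g$Z - g$hz) / (0.85 * head_s[3]))^2 > 1)
    legbone <- g$Z < z_leg[2] &
      (((g$X - 0.5 * g$a)^2 + g$Y^2 <= 1.6^2) |
         ((g$X + 0.5 * g$a)^2 + g$Y^2 <= 1.6^2))
    bone <- (spine | pelvis | skull | legbone) & lab == .LBL_SOFT
    lab[bone] <- .LBL_BONE
    label_map <- rbind(label_map, data.frame(
      label = .LBL_BONE,
      region = if ("Bone" %in% region_set) "Bone" else "Remainder",
      material = "bone", density = 1.40))
    label_map <- label_map[order(label_map$label), ]
    v3 <- vox^3
    counts <- tabulate(lab[lab > 0L], nbins = max(label_map$label))
    mass <- sum(counts[label_map$label] * label_map$density) * v3 / 1000
    list(lab = lab, label_map = label_map, mass = mass)
  }

  # calibrate the trunk half-width on the fully assembled voxel phantom
  # (skeleton and lung densities included); mass scales ~ a^2 through the
  # trunk and leg cross-sections, head and neck are fixed
  g <- build(a); asm <- assemble(g)
  for (it in 1:8) {
    if (abs(asm$mass - mass_kg) / mass_kg < 0.004) break
    m_fix <- (4 / 3 * pi * prod(head_s) + pi * r_neck^2 * diff(z_nck)) *
      soft_rho / 1000
    a <- a * sqrt(max(mass_kg - m_fix, 0.1) / max(asm$mass - m_fix, 0.1))
    g <- build(a); asm <- assemble(g)
  }
  lab <- asm$lab
  label_map <- asm$label_map

  ph <- structure(
    list(shape = c(g$nx, g$ny, g$nz), voxel_mm = voxel_mm, labels = lab,
         label_map = label_map,
         height_cm = height_cm, mass_kg = mass_kg, seed = as.integer(seed),
         region_set = region_set,
         origin_cm = c(-g$nx * vox / 2, -g$ny * vox / 2, 0)),
    class = "voxel_phantom")
  m <- phantom_mass(ph)
  if (abs(m - mass_kg) / mass_kg > 0.01)
    stop(sprintf("calibrated mass %.2f kg misses target %.2f kg by >1%%",
                 m, mass_kg))
  ph
}

#' Voxelized mass of a phantom (kg)
#' @param phantom A `voxel_phantom`.
#' @export
phantom_mass <- function(phantom) {
  v3 <- (phantom$voxel_mm / 10)^3
  lm <- phantom$label_map
  counts <- tabulate(phantom$labels[phantom$labels > 0L], nbins = max(lm$label))
  sum(counts[lm$label] * lm$density) * v3 / 1000
}

#' Organ mass report
#' @param phantom A `voxel_phantom`.
#' @return Data frame: region, voxels, mass_kg.
#' @export
organ_masses <- function(phantom) {
  lm <- phantom$label_map
  v3 <- (phantom$voxel_mm / 10)^3
  counts <- tabulate(phantom$labels[phantom$labels > 0L], nbins = max(lm$label))
  data.frame(region = lm$region, label = lm$label,
             voxels = counts[lm$label],
             mass_kg = counts[lm$label] * lm$density * v3 / 1000)
}

#' 0-based linear voxel indices of a source region
#'
#' `"Blood"` is a distributed source: it samples the whole body uniformly.
#' `"Remainder"` is every body voxel not carved as a named source organ
#' (including skeleton and lungs when those are not source regions).
#'
#' @param phantom A `voxel_phantom`.
#' @param region A source-region label present in the phantom.
#' @return Integer vector of 0-based linear indices into the label array.
#' @export
source_voxels <- function(phantom, region) {
  lm <- phantom$label_map
  if (region == "Blood") {
    idx <- which(phantom$labels > 0L)
  } else {
    lbls <- lm$label[lm$region == region]
    if (!length(lbls))
      stop("region '", region, "' not present in this phantom")
    idx <- which(array(phantom$labels %in% lbls, dim(phantom$labels)))
  }
  if (!length(idx)) stop("region '", region, "' has no voxels")
  idx - 1L
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf(
    "<voxel_phantom> %.1f cm, %.1f kg (voxelized %.2f kg), %d x %d x %d @ %g mm, seed %d\n",
    x$height_cm, x$mass_kg, phantom_mass(x), x$shape[1], x$shape[2],
    x$shape[3], x$voxel_mm, x$seed))
  cat("  regions:", paste(unique(x$label_map$region), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a phantom to a plain-text file
#'
#' JSON header (shape, voxel size, label map, height, mass, seed) plus a
#' run-length encoding of the label array; round-trips bit-exactly.
#' @param phantom A `voxel_phantom`.
#' @param path Output file.
#' @export
write_phantom <- function(phantom, path) {
  r <- rle(as.integer(phantom$labels))
  obj <- list(shape = phantom$shape, voxel_mm = phantom$voxel_mm,
              height_cm = phantom$height_cm, mass_kg = phantom$mass_kg,
              seed = phantom$seed, region_set = phantom$region_set,
              origin_cm = phantom$origin_cm,
              label_map = phantom$label_map,
              rle_lengths = r$lengths, rle_values = r$values)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom written by [write_phantom]
#' @param path File path.
#' @export
read_phantom <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lab <- array(inverse.rle(structure(list(
    lengths = as.integer(j$rle_lengths),
    values = as.integer(j$rle_values)), class = "rle")),
    dim = as.integer(j$shape))
  structure(
    list(shape = as.integer(j$shape), voxel_mm = j$voxel_mm, labels = lab,
         label_map = as.data.frame(j$label_map),
         height_cm = j$height_cm, mass_kg = j$mass_kg,
         seed = as.integer(j$seed), region_set = j$region_set,
         origin_cm = as.numeric(j$origin_cm)),
    class = "voxel_phantom")
}
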