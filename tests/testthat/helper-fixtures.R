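# Shared fixtures: tiny compartment models and hand-built scenes.

# single compartment draining to the bladder
one_comp_model <- function(rate_out = 0.02, nuclide = "Tc99m") {
  compartment_model(
    compartments = c(blood = "Remainder"),
    transfers = data.frame(from = "blood", to = "bladder",
                           rate_per_min = rate_out),
    injection_compartment = "blood", nuclide = nuclide)
}

# A -> B chain (Bateman), no excretion
chain_model <- function(l1 = 0.03, l2 = 0.01, nuclide = "Tc99m") {
  compartment_model(
    compartments = c(A = "Blood", B = "Liver"),
    transfers = data.frame(from = c("A", "B"), to = c("B", "bladder"),
                           rate_per_min = c(l1, l2)),
    injection_compartment = "A", nuclide = nuclide)
}

# random strongly-connected-ish model with 2-4 compartments
random_model <- function(n_comp, nuclide = "Tc99m") {
  regions <- c("Blood", "Liver", "Kidneys", "Spleen")[seq_len(n_comp)]
  comps <- stats::setNames(regions, paste0("c", seq_len(n_comp)))
  fr <- c(); to <- c(); rt <- c()
  for (i in seq_len(n_comp)) {
    for (j in seq_len(n_comp)) {
      if (i != j && stats::runif(1) < 0.6) {
        fr <- c(fr, paste0("c", i)); to <- c(to, paste0("c", j))
        rt <- c(rt, stats::runif(1, 0, 0.05))
      }
    }
    if (stats::runif(1) < 0.5) {
      fr <- c(fr, paste0("c", i)); to <- c(to, "bladder")
      rt <- c(rt, stats::runif(1, 0, 0.03))
    }
  }
  if (!length(fr)) { fr <- "c1"; to <- "bladder"; rt <- 0.01 }
  compartment_model(comps,
                    data.frame(from = fr, to = to, rate_per_min = rt),
                    injection_compartment = "c1", nuclide = nuclide)
}

# numerical ODE oracle for the undecayed + decayed compartment system
desolve_oracle <- function(model, t_grid) {
  lam <- decay_constant(model$nuclide, "per_min")
  M <- model$M - lam * diag(nrow(model$M))
  y0 <- stats::setNames(numeric(nrow(M)), model$compartments)
  y0[model$injection_compartment] <- 1
  out <- deSolve::lsoda(y0, t_grid, function(t, y, p) list(M %*% y),
                        parms = NULL, rtol = 1e-12, atol = 1e-14)
  out[, -1, drop = FALSE]
}

# hand-built point scene over a raw label array (world origin centred)
toy_scene <- function(labels, label_map, voxel_mm, detector_cm,
                      ambient_density = NULL) {
  d <- dim(labels)
  vox <- voxel_mm / 10
  structure(list(configuration = "point", gap = NA_real_, labels = labels,
                 label_map = cbind(label_map, who = "patient"),
                 voxel_mm = voxel_mm,
                 origin_cm = -d * vox / 2,
                 detector_cm = detector_cm, patient = NULL,
                 counterpart = NULL, ambient_density = ambient_density),
            class = "scene")
}

# single-line test nuclide
mono_nuclide <- function(energy_keV = 140.511, intensity = 1,
                         half_life_s = 21624.1) {
  radionuclide("mono", half_life_s, energy_keV, intensity)
}

# vacuum-like point-source scene: one source voxel in a near-massless box
vacuum_scene <- function(r_cm, voxel_mm = 10) {
  n <- 5L
  lab <- array(0L, c(n, n, n))
  lab[3, 3, 3] <- 1L
  lm <- data.frame(label = 1L, region = "src", material = "air",
                   density = 1e-9, stringsAsFactors = FALSE)
  toy_scene(lab, lm, voxel_mm, detector_cm = c(r_cm, 0, 0),
            ambient_density = 1e-9)
}
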