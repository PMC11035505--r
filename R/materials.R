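# Material handling: bundled mass attenuation / energy-absorption tables on
# a 15 keV - 1 MeV grid, log-log interpolated. Total linear attenuation for
# a voxel label is mu/rho (material) x density (label), so phantom labels
# can override the default density (e.g. homogenized skeleton).

.material_index <- function() {
  path <- system.file("extdata", "materials", "materials.tsv",
                      package = "nmdoserate")
  utils::read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("name", "density_g_cm3", "z_over_a"),
                    stringsAsFactors = FALSE)
}

#' Load a bundled material
#'
#' @param name One of `"water"`, `"soft_tissue"`, `"bone"`, `"lung"`,
#'   `"air"`, `"glass"`.
#' @param density Optional density override (g/cm3); defaults to the bundled
#'   reference density.
#' @return An object of class `material` with the photon mass attenuation
#'   (`mu_over_rho`) and mass energy-absorption (`mu_en_over_rho`) tables
#'   (cm2/g) on the bundled energy grid, the density and the mean Z/A.
#' @export
load_material <- function(name, density = NULL) {
  idx <- .material_index()
  row <- idx[idx$name == name, ]
  if (nrow(row) != 1L)
    stop("no bundled material '", name, "'")
  path <- system.file("extdata", "materials", paste0(name, ".tsv"),
                      package = "nmdoserate")
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("energy_keV", "mu_over_rho",
                                         "mu_en_over_rho"))
  structure(
    list(name = name,
         density = if (is.null(density)) row$density_g_cm3 else density,
         z_over_a = row$z_over_a,
         energy_keV = tab$energy_keV,
         mu_over_rho = tab$mu_over_rho,
         mu_en_over_rho = tab$mu_en_over_rho),
    class = "material")
}

# log-log interpolation, exact at nodes, no extrapolation
.interp_loglog <- function(x, y, xq) {
  if (any(xq < min(x) | xq > max(x)))
    stop("energy ", paste(xq[xq < min(x) | xq > max(x)], collapse = ", "),
         " keV outside table range [", min(x), ", ", max(x), "] keV")
  exp(stats::approx(log(x), log(y), xout = log(xq), ties = "ordered")$y)
}

#' Linear attenuation coefficient of a material
#'
#' @param material A [load_material] object.
#' @param energy_keV Photon energies (keV) within the table range.
#' @param quantity `"mu"` (total attenuation) or `"mu_en"`
#'   (energy absorption).
#' @return Coefficients in 1/cm at the material's density, log-log
#'   interpolated between table nodes.
#' @export
mu_linear <- function(material, energy_keV, quantity = c("mu", "mu_en")) {
  quantity <- match.arg(quantity)
  col <- if (quantity == "mu") material$mu_over_rho else material$mu_en_over_rho
  .interp_loglog(material$energy_keV, col, energy_keV) * material$density
}

# Klein-Nishina total cross section per electron (cm2), E in keV
.kn_sigma <- function(energy_keV) {
  re2 <- 7.940775e-26          # classical electron radius squared (cm2)
  k <- energy_keV / 510.99895
  t1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k)
  t2 <- log(1 + 2 * k) / (2 * k)
  t3 <- (1 + 3 * k) / (1 + 2 * k)^2
  2 * pi * re2 * (t1 + t2 - t3)
}

# Compton linear attenuation (1/cm): electron density x KN cross section
.mu_compton <- function(material, energy_keV) {
  n_avogadro <- 6.02214076e23
  e_density <- material$density * n_avogadro * material$z_over_a  # e-/cm3
  e_density * .kn_sigma(energy_keV)
}

# Build the per-material coefficient tables handed to the C++ transport
# kernels: log-energy grid, log(mu_total) and Compton fraction per material.
# `materials` is a list of material objects; densities already applied.
.mu_tables <- function(materials) {
  egrid <- materials[[1L]]$energy_keV
  mu_tot <- vapply(materials, function(m) mu_linear(m, egrid), numeric(length(egrid)))
  mu_com <- vapply(materials, function(m) pmin(.mu_compton(m, egrid),
                                               mu_linear(m, egrid)),
                   numeric(length(egrid)))
  list(log_e = log(egrid), log_mu_tot = log(mu_tot), mu_com = mu_com,
       names = vapply(materials, `[[`, "", "name"))
}
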