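# Flat key-value configuration files (YAML). Keys use dotted sections:
#
#   field.flux_density_mT: 3.4
#   field.frequency_Hz: 40
#   field.axis: [0.0, 0.8660254, -0.5]
#   bead.diameter_um: 4.5
#   bead.density_g_cm3: 1.5
#   bead.chi_imag: 0.1
#   fluid.viscosity_mPa_s: 1.0
#   model.coupling_length_um: 0.05
#   aerosol.mmd_um: 3.5
#   aerosol.gsd: 2.0
#   aerosol.concentration_per_ml: 4.0e6
#
# Nested YAML sections (field: {flux_density_mT: ...}) are accepted too.

flatten_config <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    v <- x[[nm]]
    if (is.list(v) && !is.null(names(v))) {
      out <- c(out, flatten_config(v, key))
    } else {
      out[[key]] <- unlist(v)
    }
  }
  out
}

cfg_get <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) return(default)
  v <- unlist(cfg[[key]])
  # tolerate YAML readers that leave exponent literals as strings
  if (is.character(v)) v <- as.numeric(v)
  v
}

#' Read an experiment configuration
#'
#' Reads a YAML configuration (flat dotted keys or nested sections; see
#' the package default in \code{system.file("extdata",
#' "default-config.yaml", package = "aerowheel")}) and builds the domain
#' specification objects, falling back to package defaults for missing
#' keys.
#'
#' @param path YAML file path, or \code{NULL} for the package defaults.
#' @return list with \code{field} ([field_spec()]), \code{bead}
#'   ([bead_spec()]), \code{fluid} ([fluid_spec()]), \code{population}
#'   ([droplet_population()]), \code{coupling_length_um} and
#'   \code{concentration_per_ml}.
#' @examples
#' cfg <- read_config()
#' cfg$field
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
         else flatten_config(yaml::read_yaml(path))
  list(
    field = field_spec(
      flux_density_mT = cfg_get(raw, "field.flux_density_mT", 3.4),
      frequency_Hz = cfg_get(raw, "field.frequency_Hz", 40),
      axis = cfg_get(raw, "field.axis", c(0, cos(pi / 6), -0.5))),
    bead = bead_spec(
      diameter_um = cfg_get(raw, "bead.diameter_um", 4.5),
      density_g_cm3 = cfg_get(raw, "bead.density_g_cm3", 1.5),
      chi_imag = cfg_get(raw, "bead.chi_imag", 0.1)),
    fluid = fluid_spec(
      viscosity_mPa_s = cfg_get(raw, "fluid.viscosity_mPa_s", 1)),
    population = droplet_population(
      mmd_um = cfg_get(raw, "aerosol.mmd_um", 3.5),
      gsd = cfg_get(raw, "aerosol.gsd", 2.0)),
    coupling_length_um = cfg_get(raw, "model.coupling_length_um", 0.05),
    concentration_per_ml = cfg_get(raw, "aerosol.concentration_per_ml",
                                   4e6))
}
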