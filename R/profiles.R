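#' Morphological profiles of the three innate immune cell types
#'
#' A profile records a cell type's mean projected area (um^2, as measured on
#' a micrograph), its shape class for the synthetic imaging arm, and the
#' coefficient of variation of per-cell area. The default set encodes the
#' size ordering MAC > DC > THP1: round THP-1 monocytes (~150 um^2),
#' branched dendritic cells (~450 um^2) and large spread macrophages
#' (~900 um^2).
#'
#' @param name Cell type label, one of `"THP1"`, `"DC"`, `"MAC"`.
#' @param mean_area Mean projected area (um^2), > 0.
#' @param shape_class `"round"` (disks), `"branched"` (star polygons with
#'   radial arms) or `"spread"` (large low-eccentricity blobs).
#' @param area_cv Coefficient of variation of per-cell area, >= 0.
#' @return A one-row tibble (`cell_type_profile()`); a three-row tibble
#'   (`default_cell_profiles()`).
#' @examples
#' default_cell_profiles()
#' @export
cell_type_profile <- function(name, mean_area, shape_class = c("round", "branched", "spread"),
                              area_cv = 0.2) {
  shape_class <- match.arg(shape_class)
  if (!name %in% c("THP1", "DC", "MAC")) {
    stop_voltphen("`name` must be one of THP1, DC, MAC.")
  }
  check_number(mean_area, "mean_area", min = 0, strict_min = TRUE)
  check_number(area_cv, "area_cv", min = 0)
  tibble(
    name = name, mean_area_um2 = mean_area,
    shape_class = shape_class, area_cv = area_cv
  )
}

#' @rdname cell_type_profile
#' @export
default_cell_profiles <- function() {
  bind_rows(
    cell_type_profile("THP1", 150, "round", area_cv = 0.15),
    cell_type_profile("DC", 450, "branched", area_cv = 0.25),
    cell_type_profile("MAC", 900, "spread", area_cv = 0.25)
  )
}

#' Build a suspension model for a cell type profile
#'
#' Links the imaging and electrical arms: the per-cell effective membrane
#' area is taken as `area_factor` times the projected area (default 4, the
#' surface/cross-section ratio of a sphere), and the electrical area CV is
#' the profile's area CV.
#'
#' @param profile One row of a profiles tibble (see [cell_type_profile()]).
#' @param n_cells Cells per 500 uL.
#' @param base A [suspension_model()] supplying all non-area parameters
#'   (media capacitance, noise, Faradaic peak, ...).
#' @param area_factor Membrane-to-projected area factor, > 0.
#' @param seed Seed for this model (defaults to the base model's).
#' @return A [suspension_model()].
#' @examples
#' prof <- default_cell_profiles()
#' suspension_model_for(prof[prof$name == "MAC", ], n_cells = 1000)
#' @export
suspension_model_for <- function(profile, n_cells, base = suspension_model(),
                                 area_factor = 4, seed = base$seed) {
  if (nrow(profile) != 1) stop_voltphen("`profile` must be a single profile row.")
  check_number(area_factor, "area_factor", min = 0, strict_min = TRUE)
  m <- base
  m$a_cell <- profile$mean_area_um2 * 1e-12 * area_factor
  m$area_cv <- profile$area_cv
  m$n_cells <- as.double(n_cells)
  m$seed <- as.integer(seed)
  validate <- suspension_model(
    c_media = m$c_media, c_spec = m$c_spec, a_cell = m$a_cell,
    area_cv = m$area_cv, n_cells = m$n_cells, r_series = m$r_series,
    faradaic_peak_v = m$faradaic_peak_v, faradaic_peak_i = m$faradaic_peak_i,
    faradaic_width = m$faradaic_width, noise_sd = m$noise_sd, seed = m$seed
  )
  validate
}
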