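#' Equivalent-circle diameter from pixel area
#'
#' The standard size proxy in islet counting: the diameter of a circle with
#' the same area as the islet's 2-D projection, `d = 2 * sqrt(A / pi)` with
#' `A = area_px * pixel_size^2` in um^2.
#'
#' @param area_px Pixel count (>= 0), vectorized.
#' @param pixel_size Pixel size in um/px (> 0).
#' @return Diameter(s) in um; 0 where `area_px` is 0.
#' @export
equivalent_diameter <- function(area_px, pixel_size) {
  if (any(area_px < 0)) stopf("area_px must be non-negative")
  if (any(pixel_size <= 0)) stopf("pixel_size must be positive")
  2 * sqrt(area_px * pixel_size^2 / pi)
}

#' 50 um size category of an islet diameter
#'
#' Islets are conventionally sorted into 50 um-wide diameter bins for
#' counting. Bins are half-open, closed at the lower edge: a 50.0 um islet
#' falls in category 50 (i.e. \[50, 100)), a 112.8 um islet in category 100.
#'
#' @param diameter_um Diameter(s) in um (>= 0).
#' @param bin_width_um Bin width, default 50.
#' @return Integer lower bound(s) of the containing bin, in um.
#' @export
size_category <- function(diameter_um, bin_width_um = 50) {
  if (any(diameter_um < 0)) stopf("diameter must be non-negative")
  as.integer(floor(diameter_um / bin_width_um) * bin_width_um)
}

# IE per islet by 50 um category under the classical stepwise conversion
# (manual-count emulation); lower bin edges 50..350+.
ricordi_factors <- c(`50` = 0.167, `100` = 0.648, `150` = 1.685, `200` = 3.5,
                     `250` = 6.315, `300` = 10.352, `350` = 15.833)

#' Islet-equivalent volume under the spherical model
#'
#' One islet equivalent (IE) is the volume of a sphere 150 um in diameter.
#' The continuous spherical model assigns `V = (d / 150)^3` IE to an islet
#' of equivalent diameter `d`: the sphere volume of diameter `d` divided by
#' that of the 150 um reference sphere. A stepwise per-category mode
#' (`method = "ricordi"`) is offered for emulating classical manual counts,
#' where every islet in a 50 um bin gets that bin's fixed IE factor; the
#' continuous model is the default because it makes volume comparisons
#' between contours well-defined.
#'
#' @param diameter_um Equivalent diameter(s) in um (>= 0).
#' @param method `"spherical"` (continuous, default) or `"ricordi"`.
#' @return Volume(s) in IE.
#' @export
islet_volume_ie <- function(diameter_um, method = c("spherical", "ricordi")) {
  method <- match.arg(method)
  if (any(diameter_um < 0)) stopf("diameter must be non-negative")
  if (method == "spherical") return((diameter_um / 150)^3)
  cat_lo <- pmin(size_category(diameter_um), 350L)
  v <- rep(0, length(diameter_um))
  in_range <- cat_lo >= 50L
  v[in_range] <- ricordi_factors[as.character(cat_lo[in_range])]
  v
}

#' Per-islet morphometry records for one image
#'
#' One record per labeled component: pixel and physical area, equivalent
#' diameter, 50 um size category, IE volume (continuous spherical model) and
#' centroid (arithmetic mean of the component's pixel coordinates).
#'
#' @param components A `labeled_components` from [label_islets()].
#' @param pixel_size Pixel size in um/px.
#' @return Data frame sorted by `islet_label` with columns `islet_label`,
#'   `area_px`, `area_um2`, `eq_diameter_um`, `size_category`, `volume_ie`,
#'   `centroid_row`, `centroid_col`.
#' @export
summarize_image <- function(components, pixel_size) {
  stopifnot(inherits(components, "labeled_components"))
  if (pixel_size <= 0) stopf("pixel_size must be positive")
  n <- components$n_components
  if (n == 0L)
    return(data.frame(islet_label = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), eq_diameter_um = numeric(0),
                      size_category = integer(0), volume_ie = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  idx <- which(components$labels > 0L, arr.ind = TRUE)
  labs <- components$labels[components$labels > 0L]
  area_px <- as.integer(tabulate(labs, nbins = n))
  centroid_row <- as.numeric(tapply(idx[, 1], labs, mean))
  centroid_col <- as.numeric(tapply(idx[, 2], labs, mean))
  d <- equivalent_diameter(area_px, pixel_size)
  data.frame(islet_label = seq_len(n),
             area_px = area_px,
             area_um2 = area_px * pixel_size^2,
             eq_diameter_um = d,
             size_category = size_category(d),
             volume_ie = islet_volume_ie(d),
             centroid_row = centroid_row,
             centroid_col = centroid_col)
}

#' Write a morphometry table to CSV
#'
#' @param records Data frame from [summarize_image()], optionally with an
#'   `image` column prepended for multi-image tables.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphometry <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
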