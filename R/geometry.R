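#' Screen and viewing geometry of the eye-tracking tablet
#'
#' Describes the acquisition setup assumed throughout the package: a
#' 14-inch 1920x1080 tablet viewed from 600 mm, sampling gaze at 120 Hz.
#' Pixels are assumed square, so one physical scale converts both axes.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param diagonal_in Physical screen diagonal in inches.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#' @param fs Sampling rate in Hz.
#' @return An object of class `screen_geometry`: a list with the supplied
#'   fields plus `mm_per_px`, the physical size of one pixel.
#' @examples
#' geom <- screen_geometry()
#' px_to_deg(100, geom)
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            diagonal_in = 14, viewing_distance_mm = 600,
                            fs = 120) {
  stopifnot(width_px > 0, height_px > 0, diagonal_in > 0,
            viewing_distance_mm > 0, fs > 0)
  diag_px <- sqrt(width_px^2 + height_px^2)
  structure(
    list(width_px = width_px, height_px = height_px,
         diagonal_in = diagonal_in,
         viewing_distance_mm = viewing_distance_mm, fs = fs,
         mm_per_px = diagonal_in * 25.4 / diag_px),
    class = "screen_geometry")
}

#' Convert on-screen distances between pixels, millimetres and degrees
#'
#' Visual angle uses the arctangent of physical extent over viewing
#' distance, which is consistent with the small-angle approximation for
#' foveal distances but stays exact for large excursions.
#'
#' @param d_px,d_mm,d_deg Distances to convert (vectorised).
#' @param geometry A [screen_geometry()].
#' @return Numeric vector of converted distances.
#' @export
px_to_mm <- function(d_px, geometry = screen_geometry()) {
  d_px * geometry$mm_per_px
}

#' @rdname px_to_mm
#' @export
mm_to_px <- function(d_mm, geometry = screen_geometry()) {
  d_mm / geometry$mm_per_px
}

#' @rdname px_to_mm
#' @export
px_to_deg <- function(d_px, geometry = screen_geometry()) {
  atan(px_to_mm(d_px, geometry) / geometry$viewing_distance_mm) * 180 / pi
}

#' @rdname px_to_mm
#' @export
deg_to_px <- function(d_deg, geometry = screen_geometry()) {
  mm_to_px(tan(d_deg * pi / 180) * geometry$viewing_distance_mm, geometry)
}
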