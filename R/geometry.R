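#' Half-ring transducer array geometry
#'
#' Builds the element layout of a half-ring ultrasound transducer array:
#' `n_elements` point elements placed on a circular arc of `arc_deg` degrees
#' with radius `radius_mm`, symmetric about the downward vertical axis, with
#' inward-pointing normals. Element angular position is measured from the
#' downward vertical (the arc "bowl" opens upward), so the first and last
#' elements sit at the top rim of the bowl. Default values describe a
#' 512-element, 176-degree, 130-mm-radius array with a 3-MHz center
#' frequency.
#'
#' @param n_elements number of elements (>= 3).
#' @param radius_mm arc radius in mm (> 0).
#' @param arc_deg angular extent of the arc in degrees, in (0, 360].
#' @param spacing `"uniform"` for uniform angular spacing, or a numeric
#'   vector of per-element angles (degrees from the downward vertical,
#'   increasing) for a custom table.
#' @param f_center_MHz transducer center frequency, MHz.
#' @param bandwidth_frac fractional bandwidth of the element response.
#' @param tx_half_angle_deg in-plane transmit diffraction half-angle
#'   interval, degrees; transmission gating uses its upper end.
#' @return An object of class `array_geometry`: list with `n_elements`,
#'   `radius_mm`, `arc_deg`, `angle_deg` (per-element angle), `element_xy`
#'   (n x 2, mm, array-centered Cartesian, +y up), `element_normal`
#'   (inward unit vectors), `f_center_MHz`, `bandwidth_frac`,
#'   `tx_half_angle_deg`, and role vectors `emitter_idx`, `reserved_idx`,
#'   `receiver_idx` (1-based; roles unset until [assign_element_roles()]).
#' @seealso [assign_element_roles()], [build_grid()]
#' @export
build_half_ring_geometry <- function(n_elements = 512L, radius_mm = 130,
                                     arc_deg = 176, spacing = "uniform",
                                     f_center_MHz = 3, bandwidth_frac = 0.7,
                                     tx_half_angle_deg = c(38, 48)) {
  n_elements <- as.integer(n_elements)
  if (n_elements < 3L) stop("invalid-geometry: n_elements must be >= 3")
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("invalid-geometry: radius_mm must be positive")
  if (arc_deg <= 0 || arc_deg > 360)
    stop("invalid-geometry: arc_deg must lie in (0, 360]")
  if (identical(spacing, "uniform")) {
    ang <- seq(-arc_deg / 2, arc_deg / 2, length.out = n_elements)
  } else {
    ang <- as.numeric(spacing)
    if (length(ang) != n_elements)
      stop("invalid-geometry: custom angle table must have n_elements entries")
    if (is.unsorted(ang)) stop("invalid-geometry: custom angles must increase")
  }
  phi <- ang * pi / 180
  xy <- cbind(x = radius_mm * sin(phi), y = -radius_mm * cos(phi))
  geom <- structure(list(
    n_elements = n_elements, radius_mm = radius_mm, arc_deg = arc_deg,
    angle_deg = ang, element_xy = xy, element_normal = -xy / radius_mm,
    f_center_MHz = f_center_MHz, bandwidth_frac = bandwidth_frac,
    tx_half_angle_deg = tx_half_angle_deg,
    emitter_idx = integer(0), reserved_idx = c(1L, n_elements),
    receiver_idx = setdiff(seq_len(n_elements), c(1L, n_elements))
  ), class = "array_geometry")
  geom
}

#' Assign emitter / receiver roles to array elements
#'
#' Reserves the first and last elements (the top rim, never pulsed), picks
#' `n_emitters` evenly spaced emitters among the remaining elements, and
#' makes all other elements receivers. Within one frame an element is
#' exclusively an emitter or a receiver.
#'
#' @param geom an `array_geometry`.
#' @param n_emitters number of emitters; must not exceed
#'   `n_elements - 2`.
#' @return The geometry with `emitter_idx`, `reserved_idx`,
#'   `receiver_idx` filled in (a partition of all element indices).
#' @export
assign_element_roles <- function(geom, n_emitters = 30L) {
  stopifnot(inherits(geom, "array_geometry"))
  n_emitters <- as.integer(n_emitters)
  n <- geom$n_elements
  if (n_emitters > n - 2L)
    stop("role-assignment: n_emitters exceeds n_elements - 2 reserved")
  geom$reserved_idx <- c(1L, n)
  if (n_emitters > 0L) {
    geom$emitter_idx <- as.integer(round(seq(2L, n - 1L,
                                             length.out = n_emitters)))
  } else {
    geom$emitter_idx <- integer(0)
  }
  geom$receiver_idx <- setdiff(seq_len(n), c(geom$reserved_idx,
                                             geom$emitter_idx))
  geom
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf(
    "Half-ring array: %d elements, %.0f-mm radius, %.0f deg arc, %.1f MHz\n",
    x$n_elements, x$radius_mm, x$arc_deg, x$f_center_MHz))
  cat(sprintf("  roles: %d emitters, %d reserved, %d receivers\n",
              length(x$emitter_idx), length(x$reserved_idx),
              length(x$receiver_idx)))
  invisible(x)
}

#' Cartesian imaging grid
#'
#' Regular pixel grid in array coordinates. Pixels are stored as an
#' `n_y x n_x` matrix, row 1 at the top (+y); pixel centers are sampled,
#' extents are half-open. The default matches a 120 mm x 50 mm cross
#' section centered 5 mm beneath the array center.
#'
#' @param width_mm lateral extent (x), mm.
#' @param depth_mm vertical extent (y), mm.
#' @param pitch_mm pixel pitch, mm; 0.25 for display-rate grids, 0.1 for
#'   refined offline grids.
#' @param center_xy grid midpoint `(x, y)` in array coordinates, mm.
#' @return An `imaging_grid`: list with the arguments plus `n_x`, `n_y`.
#' @export
build_grid <- function(width_mm = 120, depth_mm = 50, pitch_mm = 0.25,
                       center_xy = c(0, -5)) {
  if (!is.finite(pitch_mm) || pitch_mm <= 0)
    stop("invalid-grid: pitch_mm must be positive")
  n_x <- round(width_mm / pitch_mm)
  n_y <- round(depth_mm / pitch_mm)
  if (abs(n_x - width_mm / pitch_mm) > 0.5 ||
      abs(n_y - depth_mm / pitch_mm) > 0.5)
    stop("invalid-grid: pitch must divide extents to within half a pixel")
  if (n_x < 1 || n_y < 1) stop("invalid-grid: empty grid")
  structure(list(width_mm = width_mm, depth_mm = depth_mm,
                 pitch_mm = pitch_mm, center_xy = as.numeric(center_xy),
                 n_x = as.integer(n_x), n_y = as.integer(n_y)),
            class = "imaging_grid")
}

#' @export
print.imaging_grid <- function(x, ...) {
  cat(sprintf("Imaging grid: %d x %d px (%g x %g mm at %g mm), center (%g, %g)\n",
              x$n_x, x$n_y, x$width_mm, x$depth_mm, x$pitch_mm,
              x$center_xy[1], x$center_xy[2]))
  invisible(x)
}

#' Physical coordinates of grid pixel centers
#'
#' @param grid an `imaging_grid`.
#' @return `grid_coords()`: list with `x` (length `n_x`, left to right)
#'   and `y` (length `n_y`, top row first) pixel-center coordinates, mm.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "imaging_grid"))
  list(
    x = grid$center_xy[1] - grid$width_mm / 2 +
      (seq_len(grid$n_x) - 0.5) * grid$pitch_mm,
    y = grid$center_xy[2] + grid$depth_mm / 2 -
      (seq_len(grid$n_y) - 0.5) * grid$pitch_mm
  )
}

#' @rdname grid_coords
#' @param i,j row / column pixel indices (1-based).
#' @return `pixel_to_xy()`: n x 2 matrix of `(x, y)` mm coordinates.
#' @export
pixel_to_xy <- function(grid, i, j) {
  co <- grid_coords(grid)
  cbind(x = co$x[j], y = co$y[i])
}

#' @rdname grid_coords
#' @param x,y physical coordinates, mm.
#' @return `xy_to_pixel()`: n x 2 matrix of nearest `(i, j)` indices.
#' @export
xy_to_pixel <- function(grid, x, y) {
  j <- round((x - (grid$center_xy[1] - grid$width_mm / 2)) /
               grid$pitch_mm + 0.5)
  i <- round(((grid$center_xy[2] + grid$depth_mm / 2) - y) /
               grid$pitch_mm + 0.5)
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Serialize an array geometry to JSON
#'
#' Writes an element table (index, x_mm, y_mm, role) plus scalar metadata.
#'
#' @param geom an `array_geometry`.
#' @param path output file; if `NULL`, the JSON string is returned.
#' @export
geometry_to_json <- function(geom, path = NULL) {
  stopifnot(inherits(geom, "array_geometry"))
  role <- rep("receiver", geom$n_elements)
  role[geom$reserved_idx] <- "reserved"
  role[geom$emitter_idx] <- "emitter"
  obj <- list(
    n_elements = geom$n_elements, radius_mm = geom$radius_mm,
    arc_deg = geom$arc_deg, f_center_MHz = geom$f_center_MHz,
    bandwidth_frac = geom$bandwidth_frac,
    tx_half_angle_deg = geom$tx_half_angle_deg,
    elements = data.frame(index = seq_len(geom$n_elements),
                          x_mm = geom$element_xy[, 1],
                          y_mm = geom$element_xy[, 2], role = role)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
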