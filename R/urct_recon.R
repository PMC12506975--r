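#' Synthetic-aperture ultrasound reconstruction with incoherent compounding
#'
#' Per emitter frame: the analytic signal of every gated receiver channel
#' (Hilbert transform along time) is delayed by the two-leg time of
#' flight `(|e - x| + |x - d|) / c` and summed complexly per pixel; the
#' per-frame envelope is the magnitude of that sum. Frames are combined
#' by incoherent compounding (arithmetic mean of envelopes), which is
#' invariant to frame order. Receivers whose inward axis makes an angle
#' of 90 degrees or more with the emitter's axis are excluded from that
#' frame to avoid artifacts from the transmitted wave.
#'
#' @param frames list of `channel_data`, one per assigned emitter.
#' @param geom `array_geometry` with roles assigned.
#' @param grid output `imaging_grid`.
#' @param c_mm_per_us speed of sound for beamforming.
#' @param require_complete refuse to compound unless every assigned
#'   emitter has a frame (default); `FALSE` permits partial compounds,
#'   e.g. single-frame comparisons.
#' @return A `recon_image`, variant `"envelope"`.
#' @export
sa_compound_recon <- function(frames, geom, grid,
                              c_mm_per_us = frames[[1]]$c_mm_per_us,
                              require_complete = TRUE) {
  stopifnot(inherits(geom, "array_geometry"), inherits(grid, "imaging_grid"))
  emitters <- vapply(frames, function(f) as.integer(f$emitter_index), 1L)
  missing_em <- setdiff(geom$emitter_idx, emitters)
  if (require_complete && length(missing_em))
    stop(sprintf("incomplete-compound: missing frames for emitters %s",
                 paste(missing_em, collapse = ", ")))
  frames <- frames[order(emitters)]  # frame order never affects the sum
  co <- grid_coords(grid)
  px <- rep(co$x, each = grid$n_y)
  py <- rep(co$y, times = grid$n_x)
  acc <- matrix(0, grid$n_y, grid$n_x)
  for (f in frames) {
    if (f$modality != "US") stop("sa_compound_recon: frame is not ultrasound")
    e <- as.integer(f$emitter_index)
    en <- geom$element_normal[e, ]
    gate <- geom$receiver_idx[
      geom$element_normal[geom$receiver_idx, , drop = FALSE] %*% en > 0]
    if (length(gate) == 0) next
    an <- analytic_signal(f$samples[, gate, drop = FALSE])
    res <- cpp_sa_das(Re(an), Im(an),
                      geom$element_xy[e, 1], geom$element_xy[e, 2],
                      geom$element_xy[gate, , drop = FALSE],
                      px, py, f$fs_MHz, c_mm_per_us, f$t0_us)
    acc <- acc + matrix(sqrt(res$re^2 + res$im^2), grid$n_y, grid$n_x)
  }
  new_recon_image(acc / length(frames), "envelope", grid,
                  list(op = "sa_compound_recon", c = c_mm_per_us,
                       n_frames = length(frames)))
}

#' Display conditioning of an envelope ultrasound image
#'
#' Logarithmic compression of the envelope to decibels relative to the
#' image maximum, clipping to `[-dynamic_range_db, 0]`, rescaling to
#' `[0, 1]`, and contrast-limited adaptive histogram equalization.
#'
#' @param img a `recon_image` with variant `"envelope"`.
#' @param dynamic_range_db displayed dynamic range, dB.
#' @param clahe_params list with `nx`, `ny` (tile counts) and `limit`
#'   (CLAHE clip limit, `EBImage::clahe` parameterization). `NULL`
#'   disables equalization.
#' @return A `recon_image` in `[0, 1]`, variant `"conditioned"`.
#' @export
condition_us <- function(img, dynamic_range_db = 50,
                         clahe_params = list(nx = 8, ny = 8, limit = 2)) {
  stopifnot(inherits(img, "recon_image"))
  if (img$variant != "envelope")
    stop("condition_us: input must be an envelope image")
  env <- img$pixels
  mx <- max(env)
  if (mx <= 0) {
    out <- env * 0
  } else {
    db <- 20 * log10(pmax(env / mx, 10^(-dynamic_range_db / 20 - 1)))
    db <- pmin(pmax(db, -dynamic_range_db), 0)
    out <- (db + dynamic_range_db) / dynamic_range_db
    if (!is.null(clahe_params) && stats::sd(out) > 0) {
      nx <- clahe_params$nx %||% 8
      ny <- clahe_params$ny %||% 8
      # pad to a tile multiple by edge replication, equalize, crop back
      nr <- nrow(out); nc <- ncol(out)
      nr_p <- ceiling(nr / ny) * ny; nc_p <- ceiling(nc / nx) * nx
      pad <- out[c(seq_len(nr), rep(nr, nr_p - nr)),
                 c(seq_len(nc), rep(nc, nc_p - nc)), drop = FALSE]
      eq <- as.matrix(EBImage::clahe(EBImage::Image(pad), nx = nx, ny = ny,
                                     limit = clahe_params$limit %||% 2,
                                     keep.range = TRUE))
      out <- pmin(pmax(eq[seq_len(nr), seq_len(nc)], 0), 1)
    }
  }
  new_recon_image(out, "conditioned", img$grid,
                  c(img$provenance,
                    list(dynamic_range_db = dynamic_range_db,
                         clahe = clahe_params)))
}
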