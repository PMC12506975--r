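new_channel_data <- function(samples, fs_MHz, c_mm_per_us, t0_us, modality,
                             emitter_index = NA_integer_, geometry = NULL) {
  stopifnot(t0_us >= 0, all(is.finite(samples)))
  structure(list(samples = samples, fs_MHz = fs_MHz,
                 c_mm_per_us = c_mm_per_us, t0_us = t0_us,
                 modality = modality, emitter_index = emitter_index,
                 geometry = geometry),
            class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  cat(sprintf("ChannelData [%s]: %d samples x %d elements, fs %g MHz, c %g mm/us%s\n",
              x$modality, nrow(x$samples), ncol(x$samples), x$fs_MHz,
              x$c_mm_per_us,
              if (!is.na(x$emitter_index))
                sprintf(", emitter %d", x$emitter_index) else ""))
  invisible(x)
}

# time samples needed to cover the farthest grid corner (plus pulse tail)
required_window_us <- function(grid, geom, legs = 1) {
  co <- grid_coords(grid)
  corners <- cbind(x = co$x[c(1, 1, length(co$x), length(co$x))],
                   y = co$y[c(1, length(co$y), 1, length(co$y))])
  dmax <- max(sqrt(outer(corners[, 1], geom$element_xy[, 1], "-")^2 +
                     outer(corners[, 2], geom$element_xy[, 2], "-")^2))
  legs * dmax
}

#' Simulate photoacoustic channel data
#'
#' Linear superposition forward model: every absorbing pixel, weighted by
#' the depth-dependent optical fluence, emits a band-limited bipolar
#' pulse (derivative of Gaussian at the array center frequency) that
#' arrives at each element after the one-way time of flight, with 1/r
#' geometric decay (distances floored at one pixel pitch).
#'
#' @param phantom a `vessel_phantom`.
#' @param fluence a [make_fluence()] profile.
#' @param geom an `array_geometry` (all elements record; role subsetting
#'   happens at reconstruction).
#' @param fs_MHz sampling rate, MHz.
#' @param c_mm_per_us speed of sound, mm/us.
#' @param n_t number of time samples; default covers the farthest grid
#'   corner. A window shorter than the maximum time of flight is refused
#'   (truncation error) rather than silently clipping.
#' @return A `channel_data` with `modality = "PA"`, `t0_us = 0` at the
#'   laser pulse.
#' @export
forward_pa <- function(phantom, fluence, geom, fs_MHz = 40,
                       c_mm_per_us = 1.52, n_t = NULL) {
  stopifnot(inherits(phantom, "vessel_phantom"),
            inherits(geom, "array_geometry"))
  grid <- phantom$grid
  sig <- pulse_sigma_us(geom$f_center_MHz, geom$bandwidth_frac)
  need <- ceiling((required_window_us(grid, geom) / c_mm_per_us +
                     6 * sig) * fs_MHz)
  if (is.null(n_t)) n_t <- need
  else if (n_t < need)
    stop(sprintf("truncation: window %d samples shorter than max time-of-flight (%d needed)",
                 n_t, need))
  idx <- which(phantom$absorption_map > 0)
  if (length(idx) == 0) {
    return(new_channel_data(matrix(0, n_t, geom$n_elements), fs_MHz,
                            c_mm_per_us, 0, "PA", geometry = geom))
  }
  co <- grid_coords(grid)
  nr <- grid$n_y
  i <- (idx - 1) %% nr + 1
  j <- (idx - 1) %/% nr + 1
  depth <- i * grid$pitch_mm - phantom$skin_line[j]
  amp <- phantom$absorption_map[idx] * fluence_at(fluence, depth)
  samples <- cpp_forward_pa(co$x[j], co$y[i], amp, geom$element_xy,
                            fs_MHz, c_mm_per_us, as.integer(n_t), sig,
                            grid$pitch_mm)
  new_channel_data(samples, fs_MHz, c_mm_per_us, 0, "PA", geometry = geom)
}

#' Simulate one synthetic-aperture ultrasound frame
#'
#' Single-emitter pulse-echo forward model: scatterers inside the
#' emitter's in-plane diffraction cone (half-angle = upper end of
#' `geom$tx_half_angle_deg`) return a Gaussian-windowed tone burst at the
#' two-leg time of flight, with 1/(r_tx * r_rx) decay (distances floored
#' at one pixel pitch); scatterers outside the cone contribute nothing.
#' All elements record; reconstruction selects gated receivers.
#'
#' @inheritParams forward_pa
#' @param emitter_index element index; must be one of `geom$emitter_idx`.
#' @return A `channel_data` with `modality = "US"`, `t0_us = 0` at the
#'   transmit pulse.
#' @param max_scatterers cap on simulated scatterers; the strongest ones
#'   are kept (an i.i.d. thinning within homogeneous speckle regions).
#' @export
forward_urct_frame <- function(phantom, geom, emitter_index, fs_MHz = 40,
                               c_mm_per_us = 1.52, n_t = NULL,
                               max_scatterers = Inf) {
  stopifnot(inherits(phantom, "vessel_phantom"),
            inherits(geom, "array_geometry"))
  if (!emitter_index %in% geom$emitter_idx)
    stop("forward_urct_frame: emitter_index is not an assigned emitter")
  grid <- phantom$grid
  sig <- pulse_sigma_us(geom$f_center_MHz, geom$bandwidth_frac)
  need <- ceiling((required_window_us(grid, geom, legs = 2) / c_mm_per_us +
                     6 * sig) * fs_MHz)
  if (is.null(n_t)) n_t <- need
  else if (n_t < need)
    stop(sprintf("truncation: window %d samples shorter than max time-of-flight (%d needed)",
                 n_t, need))
  idx <- which(phantom$scatterer_map > 0)
  if (length(idx) > max_scatterers) {
    ord <- order(phantom$scatterer_map[idx], decreasing = TRUE)
    idx <- idx[ord[seq_len(max_scatterers)]]
  }
  if (length(idx) == 0) {
    return(new_channel_data(matrix(0, n_t, geom$n_elements), fs_MHz,
                            c_mm_per_us, 0, "US", emitter_index, geom))
  }
  co <- grid_coords(grid)
  nr <- grid$n_y
  i <- (idx - 1) %% nr + 1
  j <- (idx - 1) %/% nr + 1
  em <- geom$element_xy[emitter_index, ]
  en <- geom$element_normal[emitter_index, ]
  cos_half <- cos(max(geom$tx_half_angle_deg) * pi / 180)
  samples <- cpp_forward_us(co$x[j], co$y[i], phantom$scatterer_map[idx],
                            em[1], em[2], en[1], en[2], cos_half,
                            geom$element_xy, fs_MHz, c_mm_per_us,
                            as.integer(n_t), sig, geom$f_center_MHz,
                            grid$pitch_mm)
  new_channel_data(samples, fs_MHz, c_mm_per_us, 0, "US", emitter_index,
                   geom)
}

#' Add white Gaussian noise at a target channel SNR
#'
#' SNR is defined as peak absolute signal over noise RMS. An infinite
#' `snr_db` returns the input unchanged.
#'
#' @param cd a `channel_data`.
#' @param snr_db target SNR in dB; `Inf` for noise-free.
#' @param seed integer RNG seed (reproducible).
#' @export
add_noise <- function(cd, snr_db, seed = 1L) {
  stopifnot(inherits(cd, "channel_data"))
  if (is.infinite(snr_db)) return(cd)
  peak <- max(abs(cd$samples))
  if (peak == 0) return(cd)
  sigma <- peak / 10^(snr_db / 20)
  set.seed(seed)
  cd$samples <- cd$samples + matrix(stats::rnorm(length(cd$samples), 0, sigma),
                                    nrow(cd$samples), ncol(cd$samples))
  cd
}

#' Save / load channel data
#'
#' Serializes the sample matrix and acquisition attributes (sampling
#' rate, speed of sound, time origin, modality, emitter index) to an RDS
#' container.
#'
#' @param cd a `channel_data`.
#' @param path file path.
#' @export
write_channel_data <- function(cd, path) {
  stopifnot(inherits(cd, "channel_data"))
  saveRDS(unclass(cd), path)
  invisible(path)
}

#' @rdname write_channel_data
#' @export
read_channel_data <- function(path) {
  x <- readRDS(path)
  new_channel_data(x$samples, x$fs_MHz, x$c_mm_per_us, x$t0_us, x$modality,
                   x$emitter_index, x$geometry)
}
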