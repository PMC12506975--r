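`%||%` <- function(a, b) if (is.null(a)) b else a

# binary dilation/erosion with a disc kernel, radius in pixels
dilate_mask <- function(mask, radius_px) {
  if (radius_px < 1) return(mask)
  kern <- EBImage::makeBrush(2 * floor(radius_px) + 1, shape = "disc")
  as.matrix(EBImage::dilate(EBImage::Image(mask * 1), kern)) > 0.5
}

erode_mask <- function(mask, radius_px) {
  if (radius_px < 1) return(mask)
  kern <- EBImage::makeBrush(2 * floor(radius_px) + 1, shape = "disc")
  as.matrix(EBImage::erode(EBImage::Image(mask * 1), kern)) > 0.5
}

# connected-component labels (8-connectivity) of a logical matrix
label_components <- function(mask) {
  cpp_label8(mask)
}

# 4-connected labels; the right complement convention for holes of an
# 8-connected foreground
label_components4 <- function(mask) {
  round(as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1))))
}

# min-max normalization to [0, 1]; all-constant input maps to 0
normalize01 <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) < .Machine$double.eps) return(x * 0)
  (x - rng[1]) / diff(rng)
}

# analytic signal of each column via FFT (one-sided spectrum doubling)
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
}

#' Band-limited pulse width parameter
#'
#' Time-domain Gaussian width (microseconds) used by the simulated
#' transducer pulses: the derivative-of-Gaussian photoacoustic pulse peaks
#' spectrally at the center frequency when `sigma = 1/(2 pi f_c)`; the
#' fractional bandwidth scales the width inversely around the 0.7
#' reference.
#'
#' @param f_center_MHz center frequency, MHz.
#' @param bandwidth_frac fractional bandwidth.
#' @return width in microseconds.
#' @keywords internal
pulse_sigma_us <- function(f_center_MHz, bandwidth_frac = 0.7) {
  0.7 / (2 * pi * f_center_MHz * bandwidth_frac)
}
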