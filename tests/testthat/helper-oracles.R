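# Independent brute-force oracles and small fixture builders. The
# oracles deliberately re-state the beamforming definitions as plain
# triple loops so the optimized kernels are checked against an
# implementation that shares no code with them.

toy_geometry <- function(n = 16, radius = 40, arc = 176, emitters = 0) {
  assign_element_roles(build_half_ring_geometry(n, radius, arc), emitters)
}

toy_grid <- function(width = 32, depth = 32, pitch = 1, center = c(0, -10)) {
  build_grid(width, depth, pitch, center)
}

# minimal phantom container for forward-model tests
make_test_phantom <- function(grid, absorption = NULL, scatterer = NULL,
                              skin_mm = 0) {
  z <- matrix(0, grid$n_y, grid$n_x)
  structure(list(absorption_map = absorption %||% z,
                 scatterer_map = scatterer %||% z,
                 vessel_paths = list(),
                 tumor_mask = z > 1, breast_mask = z == 0,
                 skin_line = rep(skin_mm, grid$n_x),
                 label = "benign", archetype_params = list(), seed = 0L,
                 grid = grid),
            class = "vessel_phantom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain-loop weighted delay-and-sum (PA), mirroring the documented
# definition: linear delay interpolation, angle apodization, optional
# derivative term and per-contribution rectification
r_das_oracle <- function(cd, geom, grid, c_mm = cd$c_mm_per_us,
                         apod = "cosine", mode = 0, deriv_scale = 1) {
  recv <- geom$receiver_idx
  co <- grid_coords(grid)
  s <- cd$samples
  fs <- cd$fs_MHz
  n_t <- nrow(s)
  kappa <- deriv_scale / (2 * pi * geom$f_center_MHz)
  out <- matrix(0, grid$n_y, grid$n_x)
  for (e in recv) {
    ex <- geom$element_xy[e, 1]; ey <- geom$element_xy[e, 2]
    nx <- geom$element_normal[e, 1]; ny <- geom$element_normal[e, 2]
    ds <- numeric(n_t)
    ds[2:(n_t - 1)] <- (s[3:n_t, e] - s[1:(n_t - 2), e]) * fs / 2
    ds[1] <- (s[2, e] - s[1, e]) * fs
    ds[n_t] <- (s[n_t, e] - s[n_t - 1, e]) * fs
    for (i in seq_len(grid$n_y)) for (j in seq_len(grid$n_x)) {
      dx <- co$x[j] - ex; dy <- co$y[i] - ey
      d <- sqrt(dx^2 + dy^2)
      w <- 1
      if (apod != "none") {
        ca <- if (d > 0) (dx * nx + dy * ny) / d else 1
        w <- if (ca > 0) (if (apod == "hann") ca^2 else ca) else 0
        if (w == 0) next
      }
      tau <- (d / c_mm - cd$t0_us) * fs
      k <- floor(tau)
      if (k < 0 || k >= n_t - 1) next
      fr <- tau - k
      v <- s[k + 1, e] * (1 - fr) + s[k + 2, e] * fr
      if (mode != 0) v <- v - kappa * (ds[k + 1] * (1 - fr) + ds[k + 2] * fr)
      if (mode == 2 && v < 0) v <- 0
      out[i, j] <- out[i, j] + w * v
    }
  }
  out
}

# plain-loop complex synthetic-aperture DAS with receiver gating and
# envelope compounding over frames
r_sa_oracle <- function(frames, geom, grid, c_mm = frames[[1]]$c_mm_per_us) {
  co <- grid_coords(grid)
  acc <- matrix(0, grid$n_y, grid$n_x)
  for (f in frames) {
    e <- as.integer(f$emitter_index)
    en <- geom$element_normal[e, ]
    re_im <- apply(f$samples, 2, function(col) {
      n <- length(col)
      h <- numeric(n)
      if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
      else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
      stats::fft(stats::fft(col) * h, inverse = TRUE) / n
    })
    n_t <- nrow(f$samples)
    fs <- f$fs_MHz
    cplx <- matrix(0 + 0i, grid$n_y, grid$n_x)
    for (d in geom$receiver_idx) {
      if (sum(geom$element_normal[d, ] * en) <= 0) next
      for (i in seq_len(grid$n_y)) for (j in seq_len(grid$n_x)) {
        d1 <- sqrt(sum((c(co$x[j], co$y[i]) - geom$element_xy[e, ])^2))
        d2 <- sqrt(sum((c(co$x[j], co$y[i]) - geom$element_xy[d, ])^2))
        tau <- ((d1 + d2) / c_mm - f$t0_us) * fs
        k <- floor(tau)
        if (k < 0 || k >= n_t - 1) next
        fr <- tau - k
        cplx[i, j] <- cplx[i, j] + re_im[k + 1, d] * (1 - fr) +
          re_im[k + 2, d] * fr
      }
    }
    acc <- acc + Mod(cplx)
  }
  acc / length(frames)
}

# Clopper-Pearson bounds by direct bisection of the binomial tail
# equations (independent of the beta-quantile route): the lower bound
# solves P(X >= x | p) = alpha/2 (increasing in p), the upper bound
# solves P(X <= x | p) = alpha/2 (decreasing in p).
cp_bisect <- function(x, n, level = 0.99) {
  a <- (1 - level) / 2
  solve_root <- function(f) {  # f increasing with a sign change in (0,1)
    lo <- 0; hi <- 1
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    solve_root(function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) - a)
  upper <- if (x == n) 1 else
    solve_root(function(p) a - stats::pbinom(x, n, p))
  c(lower = lower, upper = upper)
}

# draw a disc in a matrix
stamp_disc <- function(m, ci, cj, r, value = 1) {
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if ((i - ci)^2 + (j - cj)^2 <= r^2) m[i, j] <- value
  m
}

disk_mask <- function(n, r, ci = n / 2, cj = n / 2) {
  stamp_disc(matrix(FALSE, n, n), ci, cj, r, TRUE)
}

# point-absorber photoacoustic acquisition on a toy ring
point_pa_setup <- function(n_elem = 16, fs = 20, xy = c(2, -12),
                           pitch = 1) {
  geom <- toy_geometry(n_elem, 40)
  gr <- toy_grid(pitch = pitch)
  ph <- make_test_phantom(gr)
  ij <- xy_to_pixel(gr, xy[1], xy[2])
  ph$absorption_map[ij[1], ij[2]] <- 1
  cd <- forward_pa(ph, make_fluence("dark_field"), geom, fs_MHz = fs)
  list(geom = geom, grid = gr, cd = cd, ij = ij)
}

# point-scatterer multi-emitter ultrasound acquisition on a toy ring
us_setup <- function(n_elem = 16, n_emit = 4, fs = 20, xy = c(0, -12)) {
  geom <- toy_geometry(n_elem, 40, emitters = n_emit)
  gr <- toy_grid()
  ph <- make_test_phantom(gr)
  ij <- xy_to_pixel(gr, xy[1], xy[2])
  ph$scatterer_map[ij[1], ij[2]] <- 1
  frames <- lapply(geom$emitter_idx, function(e)
    forward_urct_frame(ph, geom, e, fs_MHz = fs))
  list(geom = geom, grid = gr, frames = frames, ij = ij, ph = ph)
}
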