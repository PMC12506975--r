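img_on_grid <- function(m, pitch = 0.5) {
  gr <- build_grid(ncol(m) * pitch, nrow(m) * pitch, pitch, c(0, 0))
  duotomo:::new_recon_image(m, "unipolar", gr)
}

test_that("the skin line is recovered from flat, tilted and noisy surfaces", {
  m <- matrix(0, 60, 80)
  m[30, ] <- 1
  skin <- detect_skin_surface(img_on_grid(m, 0.5))
  expect_true(all(abs(skin / 0.5 + 0.5 - 30) <= 1))

  tilt <- matrix(0, 60, 80)
  rows <- round(seq(20, 40, length.out = 80))
  tilt[cbind(rows, 1:80)] <- 1
  skin_t <- detect_skin_surface(img_on_grid(tilt, 0.5))
  expect_lte(max(abs(skin_t / 0.5 + 0.5 - rows)), 2)

  expect_error(detect_skin_surface(img_on_grid(matrix(0, 20, 20))),
               "surface-not-found")
})

test_that("depth compensation is identity on uniform images and capped", {
  m <- matrix(1, 60, 80)
  img <- img_on_grid(m, 0.5)
  skin <- rep(0, 80)
  out <- depth_compensate(img, skin)
  expect_equal(out$pixels, m, tolerance = 1e-9)
  expect_true(all(depth_compensate(img, skin, gain_cap = 1)$pixels == m))

  # gains never reduce pixels and never exceed the cap
  set.seed(9)
  rnd <- img_on_grid(matrix(stats::runif(60 * 80), 60, 80), 0.5)
  comp <- depth_compensate(rnd, skin, gain_cap = 7)
  ratio <- comp$pixels / rnd$pixels
  expect_true(all(ratio >= 1 - 1e-9))
  expect_true(all(ratio <= 7 + 1e-9))
})

test_that("depth compensation equalizes fluence-attenuated twin targets", {
  # two identical absorbers at 10 and 40 mm depth under a 62-fold
  # dark-field fluence profile
  gr <- build_grid(40, 50, 0.5, c(0, -20))
  fl <- make_fluence("dark_field", 62, 50)
  m <- matrix(0, gr$n_y, gr$n_x)
  i10 <- round(10 / 0.5); i40 <- round(40 / 0.5)
  m <- stamp_disc(m, i10, 30, 3, fluence_at(fl, 10))
  m <- stamp_disc(m, i40, 50, 3, fluence_at(fl, 40))
  img <- duotomo:::new_recon_image(m, "unipolar", gr)
  out <- depth_compensate(img, rep(0, gr$n_x))
  ratio <- out$pixels[i40, 50] / out$pixels[i10, 30]
  expect_gte(ratio, 0.8)
  expect_lte(ratio, 1.25)
})

test_that("Frangi enhancement boosts tube contrast and respects defaults", {
  expect_equal(formals(frangi_enhance)$blend_weight, 0.1)
  # constant image: zero vesselness, output equals normalized input
  const <- img_on_grid(matrix(5, 40, 40))
  out_c <- frangi_enhance(const)
  expect_true(all(out_c$provenance$vesselness == 0))
  expect_true(all(out_c$pixels == 0))  # min-max of a constant is 0

  set.seed(2)
  m <- matrix(stats::rnorm(80 * 80, 0, 0.05), 80, 80)
  m[39:42, 10:70] <- m[39:42, 10:70] + 0.6  # 4-px tube
  img <- img_on_grid(m)
  out <- frangi_enhance(img)
  tube <- matrix(FALSE, 80, 80); tube[39:42, 15:65] <- TRUE
  bg <- matrix(FALSE, 80, 80); bg[5:25, 15:65] <- TRUE
  expect_gt(compute_cnr(out$pixels, tube, bg),
            compute_cnr(duotomo:::normalize01(m), tube, bg))
})

test_that("skeletonization yields clean unbranched centerline segments", {
  blank <- skeletonize_vessels(img_on_grid(matrix(0, 40, 40)))
  expect_length(blank$segments, 0)

  # straight tube: one segment with the right length
  m <- matrix(0, 60, 80)
  m[30:33, 11:70] <- 1
  sk <- skeletonize_vessels(img_on_grid(m))
  expect_length(sk$segments, 1)
  seg <- sk$segments[[1]]
  path_len <- sum(sqrt(rowSums(diff(seg$pixels)^2)))
  expect_lt(abs(path_len - 59) / 59, 0.05)

  # Y junction: branch point removed leaves three unbranched segments
  y <- matrix(0, 80, 80)
  y[40:42, 6:40] <- 1
  for (k in 0:30) {
    y[40 + k + (0:2), 40 + k] <- 1
    y[40 - k - (2:0), 40 + k] <- 1
  }
  sky <- skeletonize_vessels(img_on_grid(y))
  expect_equal(length(sky$segments), 3)
  # no branch points: every skeleton pixel has at most 2 neighbors
  expect_lte(max(duotomo:::neighbor_count(sky$skeleton_mask * 1L)[
    sky$skeleton_mask]), 2)
  # no component smaller than 5 px
  lab <- duotomo:::label_components(sky$skeleton_mask)
  expect_gte(min(tabulate(lab[lab > 0])), 5)
})

test_that("re-skeletonizing a rendered skeleton keeps the segment count", {
  m <- matrix(0, 60, 80)
  m[20:22, 11:70] <- 1
  m[40:42, 21:60] <- 1
  sk1 <- skeletonize_vessels(img_on_grid(m))
  rendered <- duotomo:::dilate_mask(sk1$skeleton_mask, 2) * 1
  sk2 <- skeletonize_vessels(img_on_grid(rendered))
  expect_equal(length(sk2$segments), length(sk1$segments))
})

test_that("volume assembly recovers injected shifts and resamples z", {
  set.seed(6)
  base <- matrix(stats::rnorm(50 * 50), 50, 50)
  base <- as.matrix(EBImage::gblur(EBImage::Image(base), 2))
  gr <- build_grid(25, 25, 0.5, c(0, 0))
  mk <- function(m) duotomo:::new_recon_image(m, "unipolar", gr)

  same <- assemble_volume(list(mk(base), mk(base), mk(base)), step_mm = 1)
  expect_equal(max(abs(same$shifts)), 0)

  shifts_true <- rbind(c(0, 0), c(2, -1), c(-1.5, 2.5))
  slices <- lapply(seq_len(3), function(k)
    mk(duotomo:::shift_image(base, shifts_true[k, 1], shifts_true[k, 2])))
  vol <- assemble_volume(slices, step_mm = 1)
  rel <- vol$shifts[2:3, ] - shifts_true[2:3, ]
  expect_lt(sqrt(mean(rel^2)), 0.25)

  # 86 slices at 1.0 mm with 0.1-mm in-plane pitch resample to 851 planes
  gr2 <- build_grid(2, 2, 0.1, c(0, 0))
  small <- lapply(1:86, function(k)
    duotomo:::new_recon_image(matrix(k, 20, 20), "unipolar", gr2))
  vol2 <- assemble_volume(small, step_mm = 1)
  expect_equal(dim(vol2$voxels)[3], 851)
  expect_equal(vol2$z_mm[2] - vol2$z_mm[1], 0.1)

  one <- assemble_volume(list(mk(base)), step_mm = 1)
  expect_equal(dim(one$voxels)[3], 1)
})

test_that("depth-encoded projections report distance to the skin surface", {
  gr <- build_grid(30, 30, 0.5, c(0, 0))
  n_z <- 10
  vox <- array(0, c(gr$n_y, gr$n_x, n_z))
  # flat skin at the grid top; one vessel plane at 10 mm depth
  i10 <- round(10 / 0.5)
  vox[i10, , ] <- 1
  vol <- structure(list(voxels = vox, grid = gr,
                        z_mm = (0:(n_z - 1)) * 0.5, shifts = NULL,
                        step_mm = 0.5), class = "recon_volume")
  skin <- matrix(0, gr$n_x, n_z)
  prj <- depth_encoded_projection(vol, skin, slab = c(2, 18))
  expect_true(all(abs(prj$depth_mm - 10) <= 0.5))
  expect_true(all(prj$intensity == 1))

  # two vessels at 5 and 25 mm: the projection takes the per-column max
  vox2 <- array(0, c(gr$n_y, gr$n_x, n_z))
  vox2[round(5 / 0.5), , ] <- 0.4
  vox2[round(25 / 0.5), , ] <- 0.9
  vol2 <- structure(list(voxels = vox2, grid = gr,
                         z_mm = (0:(n_z - 1)) * 0.5, shifts = NULL,
                         step_mm = 0.5), class = "recon_volume")
  prj2 <- depth_encoded_projection(vol2, skin, slab = c(0, 20))
  expect_true(all(prj2$intensity == 0.4))  # slab excludes the deep vessel
  prj3 <- depth_encoded_projection(vol2, skin, slab = c(0, 30))
  expect_true(all(prj3$intensity == 0.9))
  expect_error(depth_encoded_projection(vol2, skin, c(100, 120)),
               "empty slab")
})

test_that("encoded depth is 3D distance to a curved skin, not vertical depth", {
  # domed skin (curvature along x); a vessel offset 8 mm along the local
  # inward normal must encode as 8 mm everywhere, although its vertical
  # depth below the skin exceeds 8 mm on the flanks
  gr <- build_grid(40, 30, 0.5, c(0, 0))
  n_z <- 6
  co <- grid_coords(gr)
  s_of_x <- function(x) 2 + 14 * (x / 22)^2   # skin depth below grid top
  skin <- matrix(rep(s_of_x(co$x), n_z), gr$n_x, n_z)
  vox <- array(0, c(gr$n_y, gr$n_x, n_z))
  y_top <- co$y[1] + 0.25
  placed <- 0
  for (x0 in seq(-15, 15, by = 1)) {
    sp <- 28 * x0 / 22^2                       # s'(x): slope of the dome
    nrm <- c(-sp, -1) / sqrt(1 + sp^2)         # inward normal in (x, y)
    p <- c(x0, y_top - s_of_x(x0)) + 8 * nrm
    ij <- xy_to_pixel(gr, p[1], p[2])
    if (ij[1] >= 1 && ij[1] <= gr$n_y && ij[2] >= 1 && ij[2] <= gr$n_x) {
      vox[ij[1], ij[2], ] <- 1
      placed <- placed + 1
    }
  }
  expect_gt(placed, 20)
  vol <- structure(list(voxels = vox, grid = gr,
                        z_mm = (0:(n_z - 1)) * 0.5, shifts = NULL,
                        step_mm = 0.5), class = "recon_volume")
  prj <- depth_encoded_projection(vol, skin, slab = c(0, 30))
  d <- prj$depth_mm[prj$intensity > 0]
  expect_gt(length(d), 20)
  expect_true(all(abs(d - 8) <= 0.5))
  # a vertical-depth reading on the flank would be clearly larger
  vert <- (8 / abs(-1)) * sqrt(1 + (28 * 15 / 22^2)^2)
  expect_gt(vert, 8.5)
})

test_that("CNR follows its definition and guards degenerate input", {
  m <- matrix(0.2, 30, 30)
  set.seed(3)
  m <- m + matrix(stats::rnorm(900, 0, 0.1), 30, 30)
  vessel <- matrix(FALSE, 30, 30); vessel[15, 5:25] <- TRUE
  bg <- matrix(FALSE, 30, 30); bg[1:10, ] <- TRUE
  m[vessel] <- 1.0
  m[bg] <- 0.2 + stats::rnorm(sum(bg), 0, 0.1)
  cnr <- compute_cnr(m, vessel, bg)
  expect_equal(cnr, (mean(m[vessel]) - mean(m[bg])) / stats::sd(m[bg]))

  flat <- matrix(1, 10, 10)
  v <- matrix(FALSE, 10, 10); v[5, ] <- TRUE
  b <- matrix(FALSE, 10, 10); b[1:2, ] <- TRUE
  expect_error(compute_cnr(flat, v, b), "undefined-CNR")
  expect_error(compute_cnr(m, vessel, vessel), "overlap")
  # equal vessel and background statistics give zero
  m2 <- matrix(rep(c(0.1, 0.3), 450), 30, 30)
  v2 <- matrix(FALSE, 30, 30); v2[15:16, 5:24] <- TRUE
  expect_equal(compute_cnr(m2, v2, bg), 0, tolerance = 1e-9)
})

test_that("a simulated deep vessel remains detectable by CNR", {
  # 0.4-mm vessel at 40 mm depth under dark-field fluence with noise
  geom <- assign_element_roles(build_half_ring_geometry(128, 130, 176), 8)
  gr <- build_grid(40, 50, 0.5, c(0, -5))
  ph <- make_test_phantom(gr)
  fl <- make_fluence("dark_field", 62, 50)
  i40 <- round(40 / 0.5)
  ph$absorption_map[i40, 30:50] <- 1
  cd <- add_noise(forward_pa(ph, fl, geom, fs_MHz = 20), 40, seed = 2)
  img <- das_unipolar(cd, geom, gr)
  vessel <- matrix(FALSE, gr$n_y, gr$n_x); vessel[i40 + (-1:1), 32:48] <- TRUE
  bg <- matrix(FALSE, gr$n_y, gr$n_x); bg[i40 + (-10:10), 5:15] <- TRUE
  bg <- bg & !vessel
  expect_gt(compute_cnr(img, vessel, bg), 2)
})
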