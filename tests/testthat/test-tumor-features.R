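zones_setup <- function() {
  gr <- build_grid(60, 40, 0.5, c(0, -10))
  us <- duotomo:::new_recon_image(matrix(0.5, gr$n_y, gr$n_x),
                                  "conditioned", gr)
  tumor <- matrix(FALSE, gr$n_y, gr$n_x)
  tumor <- stamp_disc(tumor, 40, 60, 10, TRUE)
  skin <- rep(2, gr$n_x)
  breast <- matrix(TRUE, gr$n_y, gr$n_x)
  breast[seq_len(round(2 / 0.5) + 1), ] <- FALSE
  list(grid = gr, us = us, tumor = tumor, skin = skin, breast = breast)
}

test_that("zones form an annular boundary and a distant equal-depth reference", {
  s <- zones_setup()
  z <- define_zones(s$us, s$tumor, 3, s$skin, s$breast)
  expect_false(any(z$tumor & z$boundary))
  expect_false(any(z$reference & (z$tumor | z$boundary)))
  # boundary is an annulus of the configured width around the disk
  expect_true(all(duotomo:::dilate_mask(s$tumor, 6) & !s$tumor | !z$boundary))
  ring_px <- sum(z$boundary)
  expect_gt(ring_px, 0.7 * (pi * (16^2 - 10^2)))  # close to ideal annulus area
  # reference stays > 5 mm from the boundary's outer edge
  dist_b <- as.matrix(EBImage::distmap(EBImage::Image(1 - z$boundary * 1))) * 0.5
  expect_gt(min(dist_b[z$reference]), 5)
  # reference depth band overlaps the tumor depth band
  depth <- outer((seq_len(s$grid$n_y) - 0.5) * 0.5, s$skin, "-")
  expect_gte(min(depth[z$reference]), min(depth[z$tumor]))
  expect_lte(max(depth[z$reference]), max(depth[z$tumor]))

  expect_error(define_zones(s$us, s$tumor & FALSE, 3, s$skin, s$breast),
               "zone-construction")
})

test_that("a tumor at the breast edge still finds a one-sided reference", {
  s <- zones_setup()
  tumor <- matrix(FALSE, s$grid$n_y, s$grid$n_x)
  tumor <- stamp_disc(tumor, 40, 12, 8, TRUE)  # near the left edge
  z <- define_zones(s$us, tumor, 3, s$skin, s$breast)
  ref_cols <- which(colSums(z$reference) > 0)
  expect_true(all(ref_cols > 12 + 8))  # reference lies to the right
})

test_that("extracted features follow their constructed ground truth", {
  s <- zones_setup()
  z <- define_zones(s$us, s$tumor, 3, s$skin, s$breast)
  pa <- duotomo:::new_recon_image(matrix(1, s$grid$n_y, s$grid$n_x),
                                  "unipolar", s$grid)
  empty_sk <- structure(list(
    skeleton_mask = matrix(FALSE, s$grid$n_y, s$grid$n_x),
    segments = list(), source_grid = s$grid), class = "vessel_skeleton")
  f0 <- extract_features(pa, s$us, empty_sk, z)
  expect_equal(unname(f0[c("v_count_tumor", "v_density_tumor",
                           "v_count_boundary", "v_density_boundary")]),
               c(0, 0, 0, 0))
  # tumor amplitudes identical to reference: relative amplitudes are 1
  expect_equal(unname(f0["amp_mean_tumor_rel"]), 1)
  expect_equal(unname(f0["amp_p90_tumor_rel"]), 1)

  # three disjoint segments crossing the tumor
  sk <- empty_sk
  for (r in c(35, 40, 45)) sk$skeleton_mask[r, 50:70] <- TRUE
  sk$segments <- duotomo:::trace_segments(sk$skeleton_mask)
  f3 <- extract_features(pa, s$us, sk, z)
  expect_equal(unname(f3["v_count_tumor"]), 3)
  expect_equal(unname(f3["v_density_tumor"]),
               sum(sk$skeleton_mask & z$tumor) / sum(z$tumor))
})

test_that("reference-relative features are invariant to global PA rescaling", {
  s <- zones_setup()
  z <- define_zones(s$us, s$tumor, 3, s$skin, s$breast)
  set.seed(8)
  base <- matrix(stats::runif(s$grid$n_y * s$grid$n_x, 0.1, 1),
                 s$grid$n_y, s$grid$n_x)
  sk <- structure(list(skeleton_mask = base > 0.8,
                       segments = list(), source_grid = s$grid),
                  class = "vessel_skeleton")
  sk$segments <- duotomo:::trace_segments(sk$skeleton_mask)
  pa1 <- duotomo:::new_recon_image(base, "unipolar", s$grid)
  pa5 <- duotomo:::new_recon_image(5 * base, "unipolar", s$grid)
  f1 <- extract_features(pa1, s$us, sk, z)
  f5 <- extract_features(pa5, s$us, sk, z)
  rel <- c("amp_mean_tumor_rel", "amp_p90_tumor_rel")
  expect_equal(f1[rel], f5[rel], tolerance = 1e-12)
  # absolute amplitude features are covariant
  expect_equal(unname(f5["amp_hetero_sd_tumor"]),
               5 * unname(f1["amp_hetero_sd_tumor"]), tolerance = 1e-12)
})

test_that("form factor matches closed forms for disks and squares", {
  expect_lt(abs(form_factor(disk_mask(220, 100)) - 1), 0.02)
  sq <- matrix(FALSE, 140, 140); sq[21:120, 21:120] <- TRUE
  expect_lt(abs(form_factor(sq) - pi / 4), 0.02)
  # isoperimetric bound up to discretization
  set.seed(1)
  for (r in c(12, 30)) {
    blob <- disk_mask(90, r)
    expect_lte(form_factor(blob), 1.03)
  }
  expect_error(form_factor(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 20, 20); two[3, 3] <- TRUE; two[15, 15] <- TRUE
  expect_error(form_factor(two), "single connected")
})

test_that("axis ratio reflects the second-moment ellipse and is rotation invariant", {
  expect_equal(axis_ratio(disk_mask(120, 50)), 1, tolerance = 0.02)
  rect <- matrix(FALSE, 140, 60); rect[21:120, 18:42] <- TRUE
  expect_equal(axis_ratio(rect), 4, tolerance = 0.1)
  # same rectangle rotated by 37 degrees
  th <- 37 * pi / 180
  rot <- matrix(FALSE, 160, 160)
  for (i in 1:160) for (j in 1:160) {
    u <- (i - 80) * cos(th) + (j - 80) * sin(th)
    v <- -(i - 80) * sin(th) + (j - 80) * cos(th)
    if (abs(u) <= 50 && abs(v) <= 12.5) rot[i, j] <- TRUE
  }
  expect_equal(axis_ratio(rot), axis_ratio(rect), tolerance = 0.02 * 4)
  expect_error(axis_ratio(matrix(c(TRUE, rep(FALSE, 8)), 3, 3)),
               "degenerate")
})

test_that("angiogenesis occurrence counts hot tiles against the breast mean", {
  # uniform density: no tile exceeds 1.5x the mean
  sk <- matrix(FALSE, 80, 80)
  sk[seq(1, 80, by = 4), ] <- TRUE
  breast <- matrix(TRUE, 80, 80)
  res <- angiogenesis_occurrence(sk, breast, tile_mm = 4, pitch_mm = 1)
  expect_equal(res$count, 0)
  expect_equal(res$eligible_tiles, 400)

  # 100 tiles, 2 tiles at twice the density of the rest
  sk2 <- matrix(FALSE, 40, 40)
  sk2[seq(1, 40, by = 4), ] <- TRUE           # base density 1/4 per tile row
  sk2[3, 1:4] <- TRUE                          # tile (1,1) doubled
  sk2[23, 21:24] <- TRUE                       # tile (6,6) doubled
  res2 <- angiogenesis_occurrence(sk2, matrix(TRUE, 40, 40),
                                  tile_mm = 4, pitch_mm = 1)
  expect_equal(res2$eligible_tiles, 100)
  expect_equal(res2$count, 2)

  # defaults carry the 4-mm tile and 1.5x factor
  expect_equal(eval(formals(angiogenesis_occurrence)$tile_mm), 4)
  expect_equal(eval(formals(angiogenesis_occurrence)$factor), 1.5)
  expect_error(angiogenesis_occurrence(sk2, matrix(FALSE, 40, 40),
                                       pitch_mm = 1), "smaller than one tile")
})

test_that("the vascular distance metric measures straightness", {
  straight <- list(list(pixels = cbind(10, 1:40)))
  expect_equal(vascular_distance_metric(straight)$mean, 1)

  th <- seq(0, pi, length.out = 200)
  arc <- list(list(pixels = cbind(30 + 25 * sin(th), 40 + 25 * cos(th))))
  expect_equal(vascular_distance_metric(arc)$mean, 2 / pi, tolerance = 0.02)

  loop <- list(list(pixels = cbind(round(20 + 10 * sin(2 * pi * th / pi)),
                                   round(20 + 10 * cos(2 * pi * th / pi)))))
  res <- vascular_distance_metric(loop)
  expect_equal(res$per_segment, 0)
  expect_true(res$closed)
})

test_that("superficial exclusion removes only shallow vessels", {
  gr <- build_grid(40, 30, 0.5, c(0, 0))
  mask <- matrix(FALSE, gr$n_y, gr$n_x)
  mask[round(3 / 0.5), 11:40] <- TRUE   # 3 mm deep
  mask[round(20 / 0.5), 11:40] <- TRUE  # 20 mm deep
  sk <- structure(list(skeleton_mask = mask,
                       segments = duotomo:::trace_segments(mask),
                       source_grid = gr), class = "vessel_skeleton")
  skin <- rep(0, gr$n_x)
  out <- exclude_superficial(sk, skin, 6)
  expect_length(out$segments, 1)
  expect_length(sk$segments, 2)
  expect_identical(exclude_superficial(sk, skin, 0)$skeleton_mask, mask)
  deep_only <- exclude_superficial(out, skin, 6)
  expect_identical(deep_only$skeleton_mask, out$skeleton_mask)
})
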