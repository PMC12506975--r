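#' Tumor / boundary / reference zone masks
#'
#' The tumor zone is the (given) hypoechoic mass segmentation; the
#' boundary zone is a morphological dilation band of width
#' `halo_width_mm` around it (the echogenic halo); the reference zone
#' consists of breast pixels whose depth below the skin overlaps the
#' tumor's depth band and that lie more than `ref_margin_mm` beyond the
#' outer edge of the boundary zone.
#'
#' @param us_img conditioned ultrasound `recon_image` (defines the grid).
#' @param tumor_mask logical matrix, the hypoechoic mass region.
#' @param halo_width_mm boundary-band width, mm.
#' @param skin per-column skin depth below the grid top, mm.
#' @param breast_mask logical matrix; default: everything below the skin.
#' @param ref_margin_mm minimum distance from the reference zone to the
#'   boundary outer edge, mm.
#' @return A `zone_masks`: `tumor`, `boundary`, `reference`, `breast`
#'   logical matrices, `skin`, `grid_ref`.
#' @export
define_zones <- function(us_img, tumor_mask, halo_width_mm = 3, skin,
                         breast_mask = NULL, ref_margin_mm = 5) {
  grid <- us_img$grid
  pitch <- grid$pitch_mm
  if (!any(tumor_mask)) stop("zone-construction: empty tumor mask")
  nr <- grid$n_y; nc <- grid$n_x
  depth <- outer((seq_len(nr) - 0.5) * pitch, skin, "-")
  if (is.null(breast_mask)) breast_mask <- depth > 0
  if (any(tumor_mask & !breast_mask))
    stop("zone-construction: tumor extends outside the breast")
  boundary <- dilate_mask(tumor_mask, round(halo_width_mm / pitch)) &
    !tumor_mask & breast_mask
  zr <- range(depth[tumor_mask])
  # distance of every pixel to the boundary zone, mm
  dist_b <- as.matrix(EBImage::distmap(EBImage::Image(1 - boundary * 1))) * pitch
  reference <- breast_mask & !tumor_mask & !boundary &
    depth >= zr[1] & depth <= zr[2] & dist_b > ref_margin_mm
  if (!any(reference))
    stop("zone-construction: no eligible reference pixels")
  structure(list(tumor = tumor_mask, boundary = boundary,
                 reference = reference, breast = breast_mask,
                 skin = skin, grid_ref = grid),
            class = "zone_masks")
}

#' Isoperimetric form factor of a mask
#'
#' `4 pi A / P^2`: 1 for a circle, smaller for irregular shapes. The
#' perimeter is the subpixel marching-squares contour length of the
#' lightly smoothed mask (level 0.5), which removes the rasterization
#' staircase bias of pixel-count perimeters.
#'
#' @param mask logical matrix, one connected component.
#' @param pitch_mm pixel pitch (cancels in the ratio; kept for area/
#'   perimeter provenance).
#' @export
form_factor <- function(mask, pitch_mm = 1) {
  if (!any(mask)) stop("form_factor: empty mask")
  if (max(label_components(mask)) != 1)
    stop("form_factor: mask must be a single connected component")
  a_px <- sum(mask)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(mask * 1), sigma = 1))
  cl <- grDevices::contourLines(seq_len(nrow(sm)), seq_len(ncol(sm)), sm,
                                levels = 0.5)
  if (length(cl) == 0) stop("form_factor: no contour found")
  perim_px <- sum(vapply(cl, function(ct) {
    x <- c(ct$x, ct$x[1]); y <- c(ct$y, ct$y[1])
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, 1))
  4 * pi * (a_px * pitch_mm^2) / (perim_px * pitch_mm)^2
}

#' Major-to-minor axis ratio of a mask
#'
#' Ratio of the axis lengths of the best-fit second-moment ellipse
#' (square root of the ratio of the principal variances of the pixel
#' coordinates); always >= 1 and rotation invariant.
#'
#' @param mask logical matrix.
#' @export
axis_ratio <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) < 2) stop("axis_ratio: degenerate mask")
  ev <- eigen(stats::cov(pix), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= .Machine$double.eps) stop("axis_ratio: degenerate mask")
  sqrt(ev[1] / ev[2])
}

#' Diagnostic feature vector from coregistered dual-modal images
#'
#' Eleven features per mass. Photoacoustic (unipolar, depth-compensated
#' angiogram + skeleton): vessel counts (skeleton segments intersecting
#' the zone) and densities (skeleton pixels / zone pixels) in the tumor
#' and boundary zones; mean and 90th-percentile amplitude in the tumor
#' relative to the same statistic in the equal-depth reference zone (a
#' relative hemoglobin proxy); amplitude SD over vessel pixels in the
#' tumor and boundary zones (vascular distribution heterogeneity).
#' Ultrasound (conditioned): the mass form factor, its major/minor axis
#' ratio, and the SD of the conditioned echo amplitude inside the tumor.
#'
#' @param pa_img photoacoustic `recon_image`.
#' @param us_img conditioned ultrasound `recon_image`.
#' @param skeleton a `vessel_skeleton` on the same grid.
#' @param zones a `zone_masks`.
#' @return Named numeric vector of the 11 features.
#' @export
extract_features <- function(pa_img, us_img, skeleton, zones) {
  pa <- as_pixels(pa_img); us <- as_pixels(us_img)
  sk <- skeleton$skeleton_mask
  stopifnot(all(dim(pa) == dim(sk)), all(dim(us) == dim(sk)))
  seg_count <- function(zone) {
    if (length(skeleton$segments) == 0) return(0)
    sum(vapply(skeleton$segments, function(s)
      any(zone[s$pixels]), TRUE))
  }
  dens <- function(zone) sum(sk & zone) / sum(zone)
  ref <- pa[zones$reference]
  if (length(ref) == 0 || mean(ref) == 0 ||
      stats::quantile(ref, 0.9, names = FALSE) == 0)
    stop("undefined-feature: empty reference statistic")
  hetero <- function(zone) {
    v <- pa[sk & zone]
    if (length(v) < 2) 0 else stats::sd(v)
  }
  c(v_count_tumor = seg_count(zones$tumor),
    v_count_boundary = seg_count(zones$boundary),
    v_density_tumor = dens(zones$tumor),
    v_density_boundary = dens(zones$boundary),
    amp_mean_tumor_rel = mean(pa[zones$tumor]) / mean(ref),
    amp_p90_tumor_rel = stats::quantile(pa[zones$tumor], 0.9, names = FALSE) /
      stats::quantile(ref, 0.9, names = FALSE),
    amp_hetero_sd_tumor = hetero(zones$tumor),
    amp_hetero_sd_boundary = hetero(zones$boundary),
    form_factor = form_factor(zones$tumor, zones$grid_ref$pitch_mm),
    axis_ratio = axis_ratio(zones$tumor),
    echo_sd_tumor = stats::sd(us[zones$tumor]))
}

#' Angiogenesis occurrence over a breast cross section
#'
#' Tiles the breast mask with nonoverlapping square tiles of side
#' `tile_mm` and counts tiles whose vascular density (skeleton pixels /
#' breast pixels in the tile) exceeds `factor` times the whole-breast
#' mean density. Tiles with less than half their area inside the breast
#' are ineligible.
#'
#' @param skeleton a `vessel_skeleton` or logical skeleton mask.
#' @param breast_mask logical matrix.
#' @param tile_mm tile side, mm.
#' @param factor density threshold multiplier.
#' @param pitch_mm pixel pitch, mm (taken from the skeleton's grid when
#'   available).
#' @return List: `count`, `eligible_tiles`, `rate`.
#' @export
angiogenesis_occurrence <- function(skeleton, breast_mask, tile_mm = 4,
                                    factor = 1.5, pitch_mm = NULL) {
  sk <- if (inherits(skeleton, "vessel_skeleton")) skeleton$skeleton_mask
        else as.matrix(skeleton)
  pitch_mm <- pitch_mm %||%
    (if (inherits(skeleton, "vessel_skeleton") &&
         !is.null(skeleton$source_grid)) skeleton$source_grid$pitch_mm
     else stop("pitch_mm required"))
  t_px <- max(1L, round(tile_mm / pitch_mm))
  nr <- nrow(sk); nc <- ncol(sk)
  if (sum(breast_mask) * pitch_mm^2 < tile_mm^2)
    stop("angiogenesis_occurrence: breast smaller than one tile")
  mean_density <- sum(sk & breast_mask) / sum(breast_mask)
  count <- 0L; eligible <- 0L
  for (i0 in seq(1, nr, by = t_px)) for (j0 in seq(1, nc, by = t_px)) {
    ii <- i0:min(i0 + t_px - 1, nr); jj <- j0:min(j0 + t_px - 1, nc)
    if (length(ii) < t_px || length(jj) < t_px) next
    b <- breast_mask[ii, jj]
    if (sum(b) < t_px^2 / 2) next
    eligible <- eligible + 1L
    if (sum(sk[ii, jj] & b) / sum(b) > factor * mean_density)
      count <- count + 1L
  }
  if (eligible == 0L)
    stop("angiogenesis_occurrence: no eligible tiles inside the breast")
  list(count = count, eligible_tiles = eligible, rate = count / eligible)
}

#' Vascular distance metric (vessel straightness)
#'
#' Per skeleton segment: straight-line distance between the two
#' endpoints divided by the ordered path length along the segment. 1 for
#' a straight vessel, approaching 0 for tortuous ones; exactly 0 (and
#' flagged) for closed loops.
#'
#' @param segments list of segments (`$pixels` ordered chains), e.g.
#'   from a `vessel_skeleton`, or the skeleton itself.
#' @return List: `per_segment` ratios, `mean`, `closed` logical flags.
#' @export
vascular_distance_metric <- function(segments) {
  if (inherits(segments, "vessel_skeleton")) segments <- segments$segments
  if (length(segments) == 0)
    return(list(per_segment = numeric(0), mean = NA_real_,
                closed = logical(0)))
  rat <- vapply(segments, function(s) {
    p <- s$pixels
    if (nrow(p) < 2) stop("vascular_distance_metric: segment shorter than 2 px")
    path <- sum(sqrt(rowSums(diff(p)^2)))
    chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    if (chord == 0) 0 else chord / path
  }, 1)
  list(per_segment = rat, mean = mean(rat), closed = rat == 0)
}

#' Remove superficial skeleton features near the skin
#'
#' Deletes skeleton pixels whose depth below the skin line is smaller
#' than `margin_mm` (large superficial vessels would otherwise dominate
#' whole-breast vascular metrics), then re-traces segments and drops
#' fragments below 5 pixels.
#'
#' @param skeleton a `vessel_skeleton`.
#' @param skin per-column skin depth below the grid top, mm.
#' @param margin_mm exclusion margin, mm.
#' @export
exclude_superficial <- function(skeleton, skin, margin_mm = 6) {
  stopifnot(inherits(skeleton, "vessel_skeleton"))
  if (margin_mm <= 0) return(skeleton)
  grid <- skeleton$source_grid
  sk <- skeleton$skeleton_mask
  depth <- outer((seq_len(nrow(sk)) - 0.5) * grid$pitch_mm, skin, "-")
  sk[depth < margin_mm] <- FALSE
  lab <- label_components(sk)
  if (max(lab) > 0) {
    sz <- tabulate(lab[lab > 0])
    sk[lab > 0 & sz[pmax(lab, 1)] < 5] <- FALSE
  }
  structure(list(skeleton_mask = sk, segments = trace_segments(sk),
                 source_grid = grid),
            class = "vessel_skeleton")
}
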