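as_pixels <- function(img) {
  if (inherits(img, "recon_image")) img$pixels else as.matrix(img)
}

#' Detect the skin surface line
#'
#' Finds, per image column, the first depth at which the image crosses an
#' adaptive threshold (a fraction of the robust image maximum), then
#' median-filters the line; columns with no crossing are interpolated
#' from their neighbors. The phantom skin band (and the real skin signal)
#' is the brightest superficial structure, so the first crossing tracks
#' it.
#'
#' @param img a `recon_image` (or matrix; then `pitch_mm` is required).
#' @param frac threshold as a fraction of the 99.9th amplitude percentile.
#' @param median_k median filter window (columns, odd).
#' @param pitch_mm pixel pitch when `img` is a bare matrix.
#' @return Numeric vector (one per column) of skin depth below the grid
#'   top, mm.
#' @export
detect_skin_surface <- function(img, frac = 0.5, median_k = 9,
                                pitch_mm = NULL) {
  px <- as_pixels(img)
  pitch <- pitch_mm %||% (if (inherits(img, "recon_image"))
    img$grid$pitch_mm else stop("pitch_mm required for matrix input"))
  thr <- frac * stats::quantile(px, 0.999, names = FALSE)
  if (thr <= 0) stop("surface-not-found: image has no bright surface band")
  rows <- apply(px >= thr, 2, function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_integer_
  })
  if (all(is.na(rows))) stop("surface-not-found: no threshold crossing")
  idx <- seq_along(rows)
  if (anyNA(rows))
    rows <- stats::approx(idx[!is.na(rows)], rows[!is.na(rows)], idx,
                          rule = 2)$y
  k <- min(median_k, length(rows) - (1 - length(rows) %% 2))
  if (k >= 3) rows <- stats::runmed(rows, k)
  # enforce smoothness: clamp column-to-column jumps
  for (j in 2:length(rows))
    rows[j] <- rows[j - 1] + max(-5, min(5, rows[j] - rows[j - 1]))
  (rows - 0.5) * pitch
}

#' Adaptive depth compensation
#'
#' Estimates a per-depth gain from the image itself: in sliding depth
#' bands below the skin line, the bright-structure amplitude (mean of the
#' top 5% of band amplitudes) is compared to the first populated band;
#' the gain `reference / band` is clipped to `[1, gain_cap]`, made
#' nondecreasing in depth by isotonic regression, and applied per pixel
#' by linear interpolation over depth below skin. Pixels are never
#' reduced below their input value.
#'
#' @param img a `recon_image` (nonnegative amplitudes expected).
#' @param skin per-column skin depth, mm (from [detect_skin_surface()]).
#' @param gain_cap maximum gain.
#' @param band_mm band width, mm.
#' @param step_mm band spacing, mm.
#' @export
depth_compensate <- function(img, skin, gain_cap = 20, band_mm = 2,
                             step_mm = 1) {
  stopifnot(inherits(img, "recon_image"))
  px <- img$pixels
  grid <- img$grid
  nr <- grid$n_y
  depth <- outer(seq_len(nr) * grid$pitch_mm - 0.5 * grid$pitch_mm, skin, "-")
  zmax <- max(depth)
  centers <- seq(band_mm / 2, max(zmax, band_mm), by = step_mm)
  band_stat <- function(z) {
    sel <- depth >= z - band_mm / 2 & depth < z + band_mm / 2
    v <- abs(px[sel])
    v <- v[v > 0]
    if (length(v) < 5) return(NA_real_)
    mean(v[v >= stats::quantile(v, 0.95, names = FALSE)])
  }
  stats_z <- vapply(centers, band_stat, 1)
  if (all(is.na(stats_z))) return(img)
  ref <- stats_z[which(!is.na(stats_z))[1]]
  gains <- ref / stats_z
  # carry the previous gain through empty bands
  last <- 1
  for (k in seq_along(gains)) {
    if (is.na(gains[k])) gains[k] <- last else last <- gains[k]
  }
  gains <- pmin(pmax(gains, 1), gain_cap)
  if (length(gains) > 1) gains <- stats::isoreg(centers, gains)$yf
  gains <- pmin(pmax(gains, 1), gain_cap)
  gmap <- matrix(stats::approx(centers, gains, xout = pmax(depth, centers[1]),
                               rule = 2)$y, nr, grid$n_x)
  gmap[depth < 0] <- 1
  new_recon_image(px * gmap, img$variant, grid,
                  c(img$provenance, list(depth_gain_cap = gain_cap,
                                         depth_band_mm = band_mm)))
}

# multiscale Frangi vesselness for bright curvilinear structures.
# scales_px: Gaussian scales; beta: blob discrimination; gamma: structure
# threshold (NULL = half the maximum Frobenius norm per scale).
frangi_vesselness <- function(px, scales_px, beta = 0.5, gamma = NULL) {
  nr <- nrow(px); nc <- ncol(px)
  best <- matrix(0, nr, nc)
  for (s in scales_px) {
    sm <- as.matrix(EBImage::gblur(EBImage::Image(px), sigma = s))
    dxx <- matrix(0, nr, nc); dyy <- dxx; dxy <- dxx
    dyy[2:(nr - 1), ] <- sm[1:(nr - 2), ] - 2 * sm[2:(nr - 1), ] + sm[3:nr, ]
    dxx[, 2:(nc - 1)] <- sm[, 1:(nc - 2)] - 2 * sm[, 2:(nc - 1)] + sm[, 3:nc]
    dxy[2:(nr - 1), 2:(nc - 1)] <-
      (sm[3:nr, 3:nc] - sm[3:nr, 1:(nc - 2)] -
         sm[1:(nr - 2), 3:nc] + sm[1:(nr - 2), 1:(nc - 2)]) / 4
    # scale-normalized Hessian eigenvalues
    dxx <- dxx * s^2; dyy <- dyy * s^2; dxy <- dxy * s^2
    tmp <- sqrt(((dxx - dyy) / 2)^2 + dxy^2)
    mid <- (dxx + dyy) / 2
    l1 <- mid + tmp; l2 <- mid - tmp  # l2 <= l1
    # order by |lambda|: lam2 = larger magnitude
    swap <- abs(l1) > abs(l2)
    lam2 <- ifelse(swap, l1, l2)
    lam1 <- ifelse(swap, l2, l1)
    S2 <- lam1^2 + lam2^2
    g <- gamma %||% (0.5 * sqrt(max(S2)))
    if (g <= 0) next
    rb2 <- (lam1 / pmin(lam2, -.Machine$double.eps))^2
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * g^2)))
    v[lam2 >= 0] <- 0
    best <- pmax(best, v)
  }
  best
}

#' Frangi vessel enhancement
#'
#' Multiscale Hessian vesselness tuned to vessel diameters between
#' `diameter_px_range[1]` and `diameter_px_range[2]` pixels (Gaussian
#' scales from a quarter of the smallest to half of the largest
#' diameter), weighted by `blend_weight` and superimposed on the min-max
#' normalized input image.
#'
#' @param img a `recon_image`.
#' @param diameter_px_range vessel diameters to enhance, pixels.
#' @param blend_weight weight of the vesselness term.
#' @return A `recon_image`; also carries the raw vesselness in
#'   `provenance$vesselness`.
#' @export
frangi_enhance <- function(img, diameter_px_range = c(2, 7),
                           blend_weight = 0.1) {
  stopifnot(inherits(img, "recon_image"))
  scales <- seq(max(diameter_px_range[1] / 4, 0.5), diameter_px_range[2] / 2,
                by = 0.5)
  v <- frangi_vesselness(as_pixels(img), scales)
  out <- normalize01(img$pixels) + blend_weight * v
  res <- new_recon_image(out, img$variant, img$grid,
                         c(img$provenance,
                           list(frangi_diameters_px = diameter_px_range,
                                frangi_blend = blend_weight)))
  res$provenance$vesselness <- v
  res
}

# march skeleton endpoints outward along the chain direction while the
# segmentation mask continues (limited to max_step px per end)
extend_endpoints <- function(skel, mask, max_step = 12) {
  nr <- nrow(skel); nc <- ncol(skel)
  for (seg in trace_segments(skel)) {
    p <- seg$pixels
    n <- nrow(p)
    if (n < 4) next
    for (end in c(1, 2)) {
      tip <- if (end == 1) p[1, ] else p[n, ]
      back <- if (end == 1) p[min(4, n), ] else p[n - min(3, n - 1), ]
      d <- sign(tip - back)
      if (all(d == 0)) next
      cur <- tip
      for (s in seq_len(max_step)) {
        nxt <- cur + d
        if (nxt[1] < 1 || nxt[1] > nr || nxt[2] < 1 || nxt[2] > nc) break
        if (!mask[nxt[1], nxt[2]] || skel[nxt[1], nxt[2]]) break
        # stepping next to any other skeleton pixel would create a branch
        ngb <- skel[max(1, nxt[1] - 1):min(nr, nxt[1] + 1),
                    max(1, nxt[2] - 1):min(nc, nxt[2] + 1)]
        if (sum(ngb) > 1) break
        skel[nxt[1], nxt[2]] <- TRUE
        cur <- nxt
      }
    }
  }
  skel
}

# ordered pixel chains of a (branch-free) skeleton mask
trace_segments <- function(mask) {
  lab <- label_components(mask)
  segs <- list()
  for (id in seq_len(max(lab))) {
    pix <- which(lab == id, arr.ind = TRUE)
    n <- nrow(pix)
    if (n == 0) next
    if (n == 1) {
      segs[[length(segs) + 1]] <- list(pixels = pix,
                                       endpoints = pix[c(1, 1), , drop = FALSE])
      next
    }
    key <- paste(pix[, 1], pix[, 2])
    lookup <- stats::setNames(seq_len(n), key)
    nbrs <- function(k) {
      i <- pix[k, 1]; j <- pix[k, 2]
      cand <- expand.grid(i = i + (-1):1, j = j + (-1):1)
      cand <- cand[!(cand$i == i & cand$j == j), ]
      hits <- lookup[paste(cand$i, cand$j)]
      as.integer(hits[!is.na(hits)])
    }
    deg <- vapply(seq_len(n), function(k) length(nbrs(k)), 1L)
    start <- if (any(deg == 1)) which(deg == 1)[1] else 1L
    order_idx <- integer(n)
    seen <- logical(n)
    cur <- start; seen[cur] <- TRUE; order_idx[1] <- cur
    for (step in 2:n) {
      nx <- nbrs(cur)
      nx <- nx[!seen[nx]]
      if (length(nx) == 0) { order_idx <- order_idx[seq_len(step - 1)]; break }
      cur <- nx[1]; seen[cur] <- TRUE; order_idx[step] <- cur
    }
    chain <- pix[order_idx, , drop = FALSE]
    segs[[length(segs) + 1]] <-
      list(pixels = chain,
           endpoints = chain[c(1, nrow(chain)), , drop = FALSE])
  }
  segs
}

neighbor_count <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  cnt <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    cnt <- cnt + p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  cnt
}

#' Extract a vessel skeleton from an enhanced angiogram
#'
#' Pipeline: Gaussian smoothing, Frangi vesselness, hysteresis
#' thresholding, removal of small objects, filling of small holes,
#' thinning to a one-pixel skeleton, elimination of branch points,
#' clearing of small spurs, and removal of isolated components smaller
#' than 5 pixels. The result is a set of unbranched centerline segments.
#'
#' @param img a `recon_image` (values in `[0, 1]` expected) or matrix.
#' @param threshold_params list: `sigma_px` smoothing width; `high_q`
#'   vesselness quantile for the strong hysteresis threshold (computed
#'   over positive vesselness); `low_frac` low threshold as fraction of
#'   the high; `min_object_px` pre-thinning small-object size;
#'   `max_hole_px` largest hole filled; `spur_px` spur length;
#'   `diameter_px_range` Frangi diameters.
#' @param grid `imaging_grid` when `img` is a matrix.
#' @return A `vessel_skeleton`: `skeleton_mask`, `segments` (ordered
#'   pixel chains with endpoints), `source_grid`.
#' @export
skeletonize_vessels <- function(img, threshold_params = list(),
                                grid = NULL) {
  tp <- utils::modifyList(list(sigma_px = 1, high_q = 0.7, low_frac = 0.4,
                               intensity_frac = 0.5, min_object_px = 12,
                               max_hole_px = 20, spur_px = 5,
                               diameter_px_range = c(2, 7)),
                          threshold_params)
  px <- as_pixels(img)
  grid <- grid %||% (if (inherits(img, "recon_image")) img$grid else NULL)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(px), sigma = tp$sigma_px))
  scales <- seq(max(tp$diameter_px_range[1] / 4, 0.5),
                tp$diameter_px_range[2] / 2, by = 0.5)
  v <- frangi_vesselness(sm, scales)
  pos <- v[v > 0]
  empty <- structure(list(skeleton_mask = matrix(FALSE, nrow(px), ncol(px)),
                          segments = list(), source_grid = grid),
                     class = "vessel_skeleton")
  if (length(pos) < 5) return(empty)
  high <- stats::quantile(pos, tp$high_q, names = FALSE)
  low <- tp$low_frac * high
  strong <- v >= high
  weak <- v >= low
  lab <- label_components(weak)
  keep_ids <- unique(lab[strong & lab > 0])
  mask <- matrix(lab %in% keep_ids, nrow(px), ncol(px)) & weak
  # vesselness decays at vessel endpoints (a tube end looks blob-like);
  # morphological reconstruction by image intensity restores them: grow
  # the mask into connected bright pixels
  if (tp$intensity_frac > 0 && any(mask)) {
    ref <- stats::quantile(sm[mask], 0.9, names = FALSE)
    if (ref > 0) {
      cand <- mask | (sm >= tp$intensity_frac * ref)
      labc <- label_components(cand)
      keep <- unique(labc[mask & labc > 0])
      mask <- cand & matrix(labc %in% keep, nrow(px), ncol(px))
    }
  }
  # remove small objects
  lab <- label_components(mask)
  if (max(lab) > 0) {
    sz <- tabulate(lab[lab > 0])
    mask[lab > 0 & sz[pmax(lab, 1)] < tp$min_object_px] <- FALSE
  }
  # fill small holes
  holes <- label_components4(!mask)
  if (max(holes) > 0) {
    hsz <- tabulate(holes[holes > 0])
    border_ids <- unique(c(holes[1, ], holes[nrow(mask), ],
                           holes[, 1], holes[, ncol(mask)]))
    fill <- holes > 0 & hsz[pmax(holes, 1)] <= tp$max_hole_px &
      !(holes %in% border_ids)
    mask[fill] <- TRUE
  }
  if (!any(mask)) return(empty)
  # thin, remove branch points, clear spurs and tiny components
  skel <- cpp_thin(mask)
  skel[neighbor_count(skel * 1L) >= 3 & skel] <- FALSE
  lab <- label_components(skel)
  if (max(lab) > 0) {
    sz <- tabulate(lab[lab > 0])
    skel[lab > 0 & sz[pmax(lab, 1)] < max(tp$spur_px, 5)] <- FALSE
  }
  # thinning erodes free ends by about half the vessel width; march each
  # endpoint back out along its chain direction through the segmentation
  skel <- extend_endpoints(skel, mask)
  structure(list(skeleton_mask = skel, segments = trace_segments(skel),
                 source_grid = grid),
            class = "vessel_skeleton")
}

#' @export
print.vessel_skeleton <- function(x, ...) {
  cat(sprintf("Vessel skeleton: %d segments, %d skeleton px\n",
              length(x$segments), sum(x$skeleton_mask)))
  invisible(x)
}

#' Contrast-to-noise ratio
#'
#' `(mean(vessel) - mean(background)) / sd(background)` over the given
#' disjoint masks, computed on the unfiltered reconstruction.
#'
#' @param img a `recon_image` or matrix.
#' @param vessel_mask,background_mask disjoint logical masks.
#' @export
compute_cnr <- function(img, vessel_mask, background_mask) {
  px <- as_pixels(img)
  if (any(vessel_mask & background_mask))
    stop("compute_cnr: masks overlap")
  sb <- stats::sd(px[background_mask])
  if (!is.finite(sb) || sb == 0)
    stop("undefined-CNR: background variance is zero")
  (mean(px[vessel_mask]) - mean(px[background_mask])) / sb
}

# translation between two images by phase of the cross-correlation peak,
# with quadratic subpixel refinement (wraparound-aware)
estimate_shift <- function(ref, mov) {
  fa <- stats::fft(ref)
  fb <- stats::fft(mov)
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nr <- nrow(cc); nc <- ncol(cc)
  wrap <- function(k, n) ((k - 1) %% n) + 1
  subpix <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (cm1 - cp1) / den
  }
  di <- subpix(cc[wrap(pk[1] - 1, nr), pk[2]], cc[pk[1], pk[2]],
               cc[wrap(pk[1] + 1, nr), pk[2]])
  dj <- subpix(cc[pk[1], wrap(pk[2] - 1, nc)], cc[pk[1], pk[2]],
               cc[pk[1], wrap(pk[2] + 1, nc)])
  si <- pk[1] - 1 + di; sj <- pk[2] - 1 + dj
  if (si > nr / 2) si <- si - nr
  if (sj > nc / 2) sj <- sj - nc
  c(-si, -sj)  # mov is ref shifted by the returned (rows, cols)
}

shift_image <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  ii <- seq_len(nr) - di; jj <- seq_len(nc) - dj
  i0 <- floor(ii); j0 <- floor(jj)
  fi <- ii - i0; fj <- jj - j0
  g <- function(i, j) {
    i <- pmin(pmax(i, 1), nr); j <- pmin(pmax(j, 1), nc)
    m[cbind(rep(i, times = length(j)), rep(j, each = length(i)))]
  }
  a <- matrix(g(i0, j0), nr, nc); b <- matrix(g(i0 + 1, j0), nr, nc)
  cM <- matrix(g(i0, j0 + 1), nr, nc); d <- matrix(g(i0 + 1, j0 + 1), nr, nc)
  FI <- matrix(fi, nr, nc); FJ <- matrix(fj, nr, nc, byrow = TRUE)
  (a * (1 - FI) + b * FI) * (1 - FJ) + (cM * (1 - FI) + d * FI) * FJ
}

#' Assemble registered cross sections into a volume
#'
#' Each slice is rigidly registered (translation only, subpixel
#' cross-correlation peak) to its registered predecessor, then the stack
#' is linearly interpolated along the scan direction to voxels matching
#' the in-plane pitch.
#'
#' @param slices list of `recon_image` on a common grid.
#' @param step_mm scan step between slices, mm.
#' @return A `recon_volume`: `voxels` (`n_y x n_x x n_z`), `grid`,
#'   `z_mm`, `shifts` (per-slice recovered `(rows, cols)` translations).
#' @export
assemble_volume <- function(slices, step_mm = 1) {
  stopifnot(length(slices) >= 1)
  grid <- slices[[1]]$grid
  n <- length(slices)
  reg <- list(as_pixels(slices[[1]]))
  shifts <- matrix(0, n, 2)
  if (n > 1) for (k in 2:n) {
    sh <- estimate_shift(reg[[k - 1]], as_pixels(slices[[k]]))
    shifts[k, ] <- sh
    reg[[k]] <- shift_image(as_pixels(slices[[k]]), -sh[1], -sh[2])
  }
  if (n == 1) {
    vox <- array(reg[[1]], c(grid$n_y, grid$n_x, 1))
    z_mm <- 0
  } else {
    z_in <- (seq_len(n) - 1) * step_mm
    z_mm <- seq(0, z_in[n], by = grid$pitch_mm)
    vox <- array(0, c(grid$n_y, grid$n_x, length(z_mm)))
    for (t in seq_along(z_mm)) {
      k <- min(max(findInterval(z_mm[t], z_in), 1), n - 1)
      w <- (z_mm[t] - z_in[k]) / step_mm
      vox[, , t] <- (1 - w) * reg[[k]] + w * reg[[k + 1]]
    }
  }
  structure(list(voxels = vox, grid = grid, z_mm = z_mm, shifts = shifts,
                 step_mm = step_mm),
            class = "recon_volume")
}

#' Depth-encoded maximum-amplitude projection
#'
#' Projects the maximum amplitude through a depth slab and encodes, for
#' each projected voxel, its shortest 3D Euclidean distance to the skin
#' surface. The same fixed color map (`hcl.colors(..., "viridis")`)
#' applies to every output.
#'
#' @param volume a `recon_volume`.
#' @param skin_surface_3d matrix (`n_x x n_z`) of skin depth below the
#'   grid top, mm.
#' @param slab `(min, max)` depth below the grid top to project, mm.
#' @return List with `intensity` and `depth_mm` (`n_x x n_z` matrices)
#'   and the fixed `colormap` name.
#' @export
depth_encoded_projection <- function(volume, skin_surface_3d, slab) {
  stopifnot(inherits(volume, "recon_volume"))
  grid <- volume$grid
  row_depth <- (seq_len(grid$n_y) - 0.5) * grid$pitch_mm
  rows <- which(row_depth >= slab[1] & row_depth <= slab[2])
  if (length(rows) == 0) stop("depth_encoded_projection: empty slab")
  nx <- grid$n_x; nz <- dim(volume$voxels)[3]
  co <- grid_coords(grid)
  sx <- rep(co$x, times = nz)
  sz <- rep(volume$z_mm, each = nx)
  sy <- co$y[1] + 0.5 * grid$pitch_mm - as.numeric(skin_surface_3d)
  intensity <- matrix(0, nx, nz)
  depth_mm <- matrix(NA_real_, nx, nz)
  for (k in seq_len(nz)) {
    sl <- volume$voxels[rows, , k, drop = FALSE]
    mi <- apply(sl[, , 1, drop = FALSE], 2, which.max)
    intensity[, k] <- sl[cbind(mi, seq_len(nx), 1)]
    vy <- co$y[rows[mi]]
    # per projected voxel: min 3D distance to the skin point cloud
    for (j in seq_len(nx)) {
      dd <- (co$x[j] - sx)^2 + (vy[j] - sy)^2 + (volume$z_mm[k] - sz)^2
      depth_mm[j, k] <- sqrt(min(dd))
    }
  }
  list(intensity = intensity, depth_mm = depth_mm, colormap = "viridis")
}
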