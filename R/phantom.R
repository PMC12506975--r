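#' Archetype parameters for synthetic breast phantoms
#'
#' Default generation parameters for the benign and malignant phantom
#' archetypes. Malignant masses carry more intertwined vasculature inside
#' the tumor and boundary zones, more irregular shapes (lower form factor,
#' higher axis ratio) and more heterogeneous internal echoes than benign
#' ones; both share the same background breast vasculature model.
#'
#' @param label `"benign"` or `"malignant"`.
#' @return Named list of generation parameters: background vessel count
#'   and diameter range (mm), heading diffusion (`tortuosity`, rad per
#'   sqrt(mm) of path), tumor/boundary vessel rates (vessels per cm^2),
#'   tumor radius range (mm), axis-ratio distribution, boundary
#'   irregularity amplitude, echogenic-halo gain, and echo-texture SD
#'   (log-amplitude units) inside the tumor.
#' @export
default_archetype <- function(label = c("benign", "malignant")) {
  label <- match.arg(label)
  base <- list(
    n_vessels_bg = 14, vessel_diam_range = c(0.2, 3),
    vessel_len_range = c(12, 40), tumor_vessel_len_range = c(3, 9),
    tumor_diam_range = c(0.2, 0.8),
    tumor_radius_range = c(5, 10), tumor_depth_range = c(12, 26),
    halo_width_mm = 2, halo_gain = 1.6, hypo_level = 0.22,
    background_absorption = 0, skin_thickness_mm = 0.8,
    skin_absorption = 1.2, vessel_absorption = 1,
    vessel_reflectivity = 0.35, tissue_reflectivity = 0.5,
    skin_reflectivity = 1.4
  )
  arch <- if (label == "benign") list(
    tortuosity = 0.12, tumor_vessel_rate = 3, boundary_vessel_rate = 3,
    shape_irregularity = 0.06, axis_ratio_mean = 1.25, axis_ratio_sd = 0.15,
    echo_texture_sd = 0.25
  ) else list(
    tortuosity = 0.28, tumor_vessel_rate = 9, boundary_vessel_rate = 9,
    shape_irregularity = 0.22, axis_ratio_mean = 1.9, axis_ratio_sd = 0.3,
    echo_texture_sd = 0.65
  )
  c(base, arch)
}

#' Depth-dependent optical fluence profile
#'
#' Parametric exponential stand-in for light transport: relative fluence
#' `exp(-mu_eff * z)` versus depth below the skin, with `mu_eff` fixed by
#' the surface-to-maximum-depth fluence ratio. Dark-field illumination
#' corresponds to a 62-fold drop over 50 mm, bright-field to 220-fold.
#'
#' @param mode `"dark_field"` or `"bright_field"`; selects the default
#'   `depth_ratio` (62 and 220 respectively) when it is `NULL`.
#' @param depth_ratio fluence at depth 0 divided by fluence at
#'   `depth_mm`; must be >= 1.
#' @param depth_mm depth over which `depth_ratio` is realized, mm.
#' @return A `fluence_profile` with `mu_eff` (1/mm); evaluate with
#'   [fluence_at()].
#' @export
make_fluence <- function(mode = c("dark_field", "bright_field"),
                         depth_ratio = NULL, depth_mm = 50) {
  mode <- match.arg(mode)
  if (is.null(depth_ratio))
    depth_ratio <- if (mode == "dark_field") 62 else 220
  if (!is.finite(depth_ratio) || depth_ratio < 1)
    stop("invalid-profile: depth_ratio must be >= 1")
  structure(list(mode = mode, depth_ratio = depth_ratio,
                 depth_mm = depth_mm,
                 mu_eff = log(depth_ratio) / depth_mm),
            class = "fluence_profile")
}

#' @rdname make_fluence
#' @param fluence a `fluence_profile`.
#' @param z_mm depth below the skin surface, mm (values < 0 clamp to 0).
#' @export
fluence_at <- function(fluence, z_mm) {
  stopifnot(inherits(fluence, "fluence_profile"))
  exp(-fluence$mu_eff * pmax(z_mm, 0))
}

# smooth unit-SD Gaussian random field on an nr x nc grid
smooth_field <- function(nr, nc, sigma_px) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  f <- as.matrix(EBImage::gblur(EBImage::Image(f), sigma = sigma_px))
  s <- stats::sd(f)
  if (s < .Machine$double.eps) return(matrix(0, nr, nc)) else f / s
}

# random smooth polyline inside the breast; returns list(xy, diameter)
walk_vessel <- function(start_xy, len_mm, diam_mm, tortuosity, step_mm,
                        inside_fun) {
  n <- max(2L, ceiling(len_mm / step_mm))
  theta <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(NA_real_, n, 2)
  pts[1, ] <- start_xy
  for (k in 2:n) {
    theta <- theta + stats::rnorm(1, 0, tortuosity * sqrt(step_mm))
    cand <- pts[k - 1, ] + step_mm * c(cos(theta), sin(theta))
    if (!inside_fun(cand)) {
      theta <- theta + pi / 2  # deflect along the boundary
      cand <- pts[k - 1, ] + step_mm * c(cos(theta), sin(theta))
      if (!inside_fun(cand)) { pts <- pts[seq_len(k - 1), , drop = FALSE]; break }
    }
    pts[k, ] <- cand
  }
  list(xy = pts, diameter = diam_mm)
}

#' Generate a synthetic 2D breast phantom
#'
#' Builds a labeled breast cross section on an imaging grid: a curved skin
#' line with an absorbing/echogenic skin band, a half-elliptical breast
#' region filled with speckle-generating scatterers, a background vascular
#' tree (random smooth thick polylines, apparent diameters 0.2-3 mm), and
#' a tumor with an irregular boundary, a hypoechoic core with
#' label-dependent internal echo texture, an echogenic halo, and extra
#' tumor/boundary-zone vessels at label-dependent rates. Everything is
#' reproducible from the seed.
#'
#' @param grid an [build_grid()] `imaging_grid`.
#' @param label `"benign"` or `"malignant"`.
#' @param archetype_params parameter list, see [default_archetype()].
#' @param seed integer RNG seed.
#' @return A `vessel_phantom`: `absorption_map` and `scatterer_map`
#'   (`n_y x n_x`), `vessel_paths` (list of polylines with diameters, mm),
#'   `tumor_mask`, `breast_mask`, `skin_line` (per-column skin depth below
#'   the grid top, mm), `label`, `archetype_params`, `seed`, `grid`.
#' @export
generate_breast_phantom <- function(grid, label = c("benign", "malignant"),
                                    archetype_params = NULL, seed = 1L) {
  label <- match.arg(label)
  stopifnot(inherits(grid, "imaging_grid"))
  p <- archetype_params %||% default_archetype(label)
  bad <- vapply(p[c("tortuosity", "tumor_vessel_rate", "boundary_vessel_rate",
                    "shape_irregularity")], function(v) any(v < 0), TRUE)
  if (any(bad)) stop("generation: archetype parameter ranges must be nonnegative")
  set.seed(seed)
  nr <- grid$n_y; nc <- grid$n_x; pitch <- grid$pitch_mm
  co <- grid_coords(grid)

  # skin line: gentle parabola + low-frequency ripple, mm below grid top
  xn <- (co$x - grid$center_xy[1]) / (grid$width_mm / 2)
  skin_mm <- 3 + 2.5 * xn^2 +
    0.4 * sin(2 * pi * xn * stats::runif(1, 0.5, 1.5) + stats::runif(1, 0, 2 * pi))
  skin_row <- skin_mm / pitch

  # breast: half-ellipse below the skin line
  a_br <- 0.46 * grid$width_mm
  b_br <- grid$depth_mm - max(skin_mm) - 4
  depth_below_skin <- outer(seq_len(nr) * pitch, skin_mm, function(r, s) r - s)
  breast_depth <- b_br * sqrt(pmax(0, 1 - ((co$x - grid$center_xy[1]) / a_br)^2))
  breast_mask <- sweep(depth_below_skin, 2, breast_depth, "<") &
    depth_below_skin > 0
  inside_breast <- function(xy) {
    ij <- xy_to_pixel(grid, xy[1], xy[2])
    i <- ij[1]; j <- ij[2]
    i >= 1 && i <= nr && j >= 1 && j <= nc && breast_mask[i, j]
  }

  # tumor: irregular ellipse placed fully inside the breast
  r0 <- stats::runif(1, p$tumor_radius_range[1], p$tumor_radius_range[2])
  ar <- max(1, stats::rnorm(1, p$axis_ratio_mean, p$axis_ratio_sd))
  r_major <- r0 * sqrt(ar); r_minor <- r0 / sqrt(ar)
  orient <- stats::runif(1, 0, pi)
  n_harm <- 6
  amp_h <- p$shape_irregularity * stats::rnorm(n_harm) / sqrt(n_harm)
  pha_h <- stats::runif(n_harm, 0, 2 * pi)
  tumor_mask <- NULL
  for (try in 1:60) {
    cx <- grid$center_xy[1] + stats::runif(1, -0.25, 0.25) * grid$width_mm
    zc <- stats::runif(1, p$tumor_depth_range[1], p$tumor_depth_range[2])
    jc <- which.min(abs(co$x - cx))
    cy <- co$y[1] - (skin_mm[jc] + zc) + 0  # y at depth zc under skin col jc
    X <- matrix(rep(co$x, each = nr), nr, nc) - cx
    Y <- matrix(rep(co$y, nc), nr, nc) - cy
    U <- X * cos(orient) + Y * sin(orient)
    V <- -X * sin(orient) + Y * cos(orient)
    th <- atan2(V / r_minor, U / r_major)
    pert <- 1
    for (h in seq_len(n_harm)) pert <- pert + amp_h[h] * cos(h * th + pha_h[h])
    cand <- (U / r_major)^2 + (V / r_minor)^2 <= pert^2
    if (sum(cand) > 0 && all(breast_mask[cand])) { tumor_mask <- cand; break }
  }
  if (is.null(tumor_mask))
    stop("generation: tumor does not fit inside the breast region")

  halo_px <- max(1L, round(p$halo_width_mm / pitch))
  halo <- dilate_mask(tumor_mask, halo_px) & !tumor_mask & breast_mask

  # vasculature
  vessels <- list()
  add_vessel <- function(region_mask, len_range, diam_range) {
    idx <- which(region_mask)
    if (length(idx) == 0) return(NULL)
    k <- idx[sample.int(length(idx), 1)]
    i <- (k - 1) %% nr + 1; j <- (k - 1) %/% nr + 1
    walk_vessel(c(co$x[j], co$y[i]),
                stats::runif(1, len_range[1], len_range[2]),
                stats::runif(1, diam_range[1], diam_range[2]),
                p$tortuosity, step_mm = max(pitch / 2, 0.15), inside_breast)
  }
  for (v in seq_len(p$n_vessels_bg)) {
    vs <- add_vessel(breast_mask & depth_below_skin > 2,
                     p$vessel_len_range, p$vessel_diam_range)
    if (!is.null(vs)) vessels[[length(vessels) + 1]] <- vs
  }
  area_cm2 <- function(m) sum(m) * pitch^2 / 100
  n_tum <- stats::rpois(1, p$tumor_vessel_rate * area_cm2(tumor_mask))
  n_bnd <- stats::rpois(1, p$boundary_vessel_rate * area_cm2(halo))
  for (v in seq_len(n_tum)) {
    vs <- add_vessel(tumor_mask, p$tumor_vessel_len_range, p$tumor_diam_range)
    if (!is.null(vs)) vessels[[length(vessels) + 1]] <- vs
  }
  for (v in seq_len(n_bnd)) {
    vs <- add_vessel(halo, p$tumor_vessel_len_range, p$tumor_diam_range)
    if (!is.null(vs)) vessels[[length(vessels) + 1]] <- vs
  }

  # absorption map: skin band + vessels (background tissue configurable)
  absorption <- matrix(p$background_absorption, nr, nc) * breast_mask
  in_skin <- depth_below_skin > -p$skin_thickness_mm & depth_below_skin <= 0
  absorption[in_skin] <- p$skin_absorption
  if (length(vessels)) {
    rows <- cols <- rads <- vals <- numeric(0)
    for (vs in vessels) {
      ij <- xy_to_pixel(grid, vs$xy[, 1], vs$xy[, 2])
      rows <- c(rows, ij[, 1]); cols <- c(cols, ij[, 2])
      rads <- c(rads, rep(vs$diameter / 2 / pitch, nrow(ij)))
      vals <- c(vals, rep(p$vessel_absorption, nrow(ij)))
    }
    absorption <- cpp_stamp_discs(absorption, rows - 1, cols - 1, rads, vals)
  }
  absorption[!breast_mask & !in_skin] <- 0

  # scatterer map: speckle texture, hypoechoic tumor core with
  # label-dependent multiplicative echo texture, echogenic halo
  scat <- matrix(0, nr, nc)
  nbr <- sum(breast_mask)
  scat[breast_mask] <- p$tissue_reflectivity * abs(stats::rnorm(nbr))
  tex <- smooth_field(nr, nc, sigma_px = max(1, 2 / pitch))
  scat[tumor_mask] <- p$hypo_level * abs(stats::rnorm(sum(tumor_mask))) *
    exp(p$echo_texture_sd * tex[tumor_mask])
  scat[halo] <- scat[halo] * p$halo_gain
  if (length(vessels)) {
    rows2 <- cols2 <- rads2 <- vals2 <- numeric(0)
    for (vs in vessels) {
      ij <- xy_to_pixel(grid, vs$xy[, 1], vs$xy[, 2])
      rows2 <- c(rows2, ij[, 1]); cols2 <- c(cols2, ij[, 2])
      rads2 <- c(rads2, rep(vs$diameter / 2 / pitch, nrow(ij)))
      vals2 <- c(vals2, rep(p$vessel_reflectivity, nrow(ij)))
    }
    scat <- cpp_stamp_discs(scat, rows2 - 1, cols2 - 1, rads2, vals2)
  }
  scat[in_skin] <- p$skin_reflectivity

  structure(list(absorption_map = absorption, scatterer_map = scat,
                 vessel_paths = vessels, tumor_mask = tumor_mask,
                 breast_mask = breast_mask, skin_line = skin_mm,
                 label = label, archetype_params = p, seed = seed,
                 grid = grid),
            class = "vessel_phantom")
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf("Breast phantom (%s, seed %d): %d x %d px, %d vessels, tumor %d px\n",
              x$label, x$seed, x$grid$n_y, x$grid$n_x,
              length(x$vessel_paths), sum(x$tumor_mask)))
  invisible(x)
}
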