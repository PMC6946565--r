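#' Render a super-resolved intensity map from localizations
#'
#' Bins single-molecule localizations into a 2D intensity histogram at
#' super-resolution pixel size (25 nm by default, the typical reconstruction
#' zoom for sptPALM data). Every localization contributes exactly one count,
#' so the grid total equals the number of input points.
#'
#' @param localizations Data frame or matrix with columns `x`, `y` (um).
#' @param pixel_size Reconstruction pixel size (um).
#' @param extent Optional `list(xlim =, ylim =)` (um) fixing the map bounds;
#'   inferred from the data when missing. Points on the upper boundary fall
#'   in the last pixel.
#' @return A `superres_map`: list with `grid` (matrix indexed `[ix, iy]`,
#'   counts), `pixel_size` and `origin` (um coordinates of the lower-left
#'   corner of pixel (1, 1)).
#' @export
render_superres <- function(localizations, pixel_size = 0.025,
                            extent = NULL) {
  localizations <- as.data.frame(localizations)
  if (!nrow(localizations))
    stop("no localizations to render", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  x <- localizations$x; y <- localizations$y
  if (is.null(extent)) {
    xlim <- c(floor(min(x) / pixel_size), ceiling(max(x) / pixel_size) +
                1e-9) * pixel_size
    ylim <- c(floor(min(y) / pixel_size), ceiling(max(y) / pixel_size) +
                1e-9) * pixel_size
  } else {
    xlim <- extent$xlim; ylim <- extent$ylim
  }
  nx <- max(1L, as.integer(ceiling((xlim[2] - xlim[1]) / pixel_size - 1e-9)))
  ny <- max(1L, as.integer(ceiling((ylim[2] - ylim[1]) / pixel_size - 1e-9)))
  ix <- pmin(pmax(floor((x - xlim[1]) / pixel_size) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((y - ylim[1]) / pixel_size) + 1L, 1L), ny)
  grid <- matrix(0, nx, ny)
  counts <- table(factor(ix + (iy - 1L) * nx, levels = seq_len(nx * ny)))
  grid[] <- as.integer(counts)
  structure(list(grid = grid, pixel_size = pixel_size,
                 origin = c(xlim[1], ylim[1])),
            class = "superres_map")
}

#' @export
print.superres_map <- function(x, ...) {
  cat(sprintf("<superres_map: %d x %d px at %g um/px, %g counts>\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size, sum(x$grid)))
  invisible(x)
}

# um coordinates of pixel centers along each axis of a map
map_axes <- function(map) {
  list(x = map$origin[1] + (seq_len(nrow(map$grid)) - 0.5) * map$pixel_size,
       y = map$origin[2] + (seq_len(ncol(map$grid)) - 0.5) * map$pixel_size)
}

#' Segment confinement nanodomains from a super-resolved map
#'
#' Isolates nanodomains from the surrounding signal by intensity
#' thresholding (`mean + k_sd * SD` of the map, computed over `mask` when
#' given, or an absolute threshold), labels connected components, and sizes
#' each domain by fitting its x and y marginal intensity profiles with a
#' product of rising and falling logistic edges; the domain size along an
#' axis is the distance between the two half-maximum edge midpoints.
#' Components whose edge fit does not converge are reported with their
#' pixel-bounding-box size and flagged `degraded`.
#'
#' @param map A [render_superres()] map.
#' @param threshold `"relative"` (mean + k_sd * SD) or `"absolute"`.
#' @param k_sd Multiplier of the SD for the relative threshold.
#' @param absolute Absolute intensity threshold (counts) when
#'   `threshold = "absolute"`.
#' @param mask Optional logical matrix (same grid) over which the relative
#'   threshold statistics are computed.
#' @param min_pixels Minimum component size in pixels.
#' @return A `domain_table` data frame: `center_x`, `center_y` (um,
#'   intensity-weighted centroid), `size_x`, `size_y`, `mean_size` (um),
#'   `peak_intensity` (counts), `n_pixels`, `degraded`.
#' @export
detect_domains <- function(map, threshold = c("relative", "absolute"),
                           k_sd = 2, absolute = NULL, mask = NULL,
                           min_pixels = 4L) {
  threshold <- match.arg(threshold)
  g <- map$grid
  thr <- if (threshold == "absolute") {
    if (is.null(absolute)) stop("absolute threshold not given", call. = FALSE)
    absolute
  } else {
    v <- if (is.null(mask)) as.numeric(g) else g[mask]
    mean(v) + k_sd * stats::sd(v)
  }
  bin <- (g > thr) * 1
  lab <- EBImage::bwlabel(bin)
  nlab <- max(lab)
  ax <- map_axes(map)
  rows <- list()
  for (l in seq_len(nlab)) {
    sel <- lab == l
    if (sum(sel) < min_pixels) next
    comp <- g * sel
    idx <- which(sel, arr.ind = TRUE)
    w <- g[sel]
    cx <- sum(ax$x[idx[, 1]] * w) / sum(w)
    cy <- sum(ax$y[idx[, 2]] * w) / sum(w)
    fx <- fit_edge_profile(rowSums(comp), ax$x, map$pixel_size)
    fy <- fit_edge_profile(colSums(comp), ax$y, map$pixel_size)
    degraded <- fx$degraded || fy$degraded
    size_x <- if (fx$degraded)
      diff(range(ax$x[idx[, 1]])) + map$pixel_size else fx$size
    size_y <- if (fy$degraded)
      diff(range(ax$y[idx[, 2]])) + map$pixel_size else fy$size
    rows[[length(rows) + 1L]] <- data.frame(
      center_x = cx, center_y = cy, size_x = size_x, size_y = size_y,
      mean_size = (size_x + size_y) / 2, peak_intensity = max(w),
      n_pixels = sum(sel), degraded = degraded)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(center_x = numeric(0), center_y = numeric(0),
               size_x = numeric(0), size_y = numeric(0),
               mean_size = numeric(0), peak_intensity = numeric(0),
               n_pixels = integer(0), degraded = logical(0))
  structure(out, class = c("domain_table", "data.frame"),
            threshold = thr)
}

# fit a 1D marginal profile with A * logistic rise * logistic fall;
# size = distance between the half-maximum edge midpoints e2 - e1
fit_edge_profile <- function(profile, coord, pixel_size) {
  keep <- profile > 0
  if (sum(keep) < 3L) return(list(size = NA_real_, degraded = TRUE))
  i1 <- which(keep)[1]; i2 <- which(keep)[sum(keep)]
  lo <- max(1L, i1 - 3L); hi <- min(length(profile), i2 + 3L)
  p <- profile[lo:hi]; u <- coord[lo:hi]
  half <- max(p) / 2
  above <- which(p >= half)
  e1_0 <- u[above[1]]; e2_0 <- u[above[length(above)]]
  if (e2_0 - e1_0 < pixel_size / 2) { e1_0 <- e1_0 - pixel_size / 2
                                      e2_0 <- e2_0 + pixel_size / 2 }
  dat <- data.frame(u = u, p = p)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      p ~ A * stats::plogis((u - e1) / w) * stats::plogis(-(u - e2) / w),
      data = dat,
      start = list(A = max(p), e1 = e1_0, e2 = e2_0, w = pixel_size / 2),
      lower = c(A = 0, e1 = min(u) - pixel_size, e2 = min(u) - pixel_size,
                w = pixel_size / 20),
      upper = c(A = 10 * max(p), e1 = max(u) + pixel_size,
                e2 = max(u) + pixel_size, w = diff(range(u)) + pixel_size),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(size = NA_real_, degraded = TRUE))
  cf <- stats::coef(fit)
  size <- unname(cf["e2"] - cf["e1"])
  if (!is.finite(size) || size <= 0)
    return(list(size = NA_real_, degraded = TRUE))
  list(size = size, degraded = FALSE)
}

#' Cone-shaped mask on a map grid
#'
#' Logical mask of the pixels whose centers lie inside the conical growth
#' cone (apex at `apex`, radius, half angle), on the grid of `map`.
#'
#' @param map A [render_superres()] map.
#' @param radius Cone radius (um).
#' @param half_angle Half opening angle (degrees).
#' @param apex Apex coordinates (um).
#' @return Logical matrix with the dimensions of `map$grid`.
#' @export
cone_mask <- function(map, radius = 12, half_angle = 45, apex = c(0, 0)) {
  ax <- map_axes(map)
  X <- outer(ax$x - apex[1], rep(1, length(ax$y)))
  Y <- outer(rep(1, length(ax$x)), ax$y - apex[2])
  r <- sqrt(X^2 + Y^2)
  th <- atan2(Y, X)
  r <= radius & abs(th) <= half_angle * pi / 180
}

#' Peripheral band of a cone mask
#'
#' The sub-mask within `band_fraction` of the cone radius from the leading
#' edge (default: outer 20% of the radius), where the actin treadmill and
#' most adhesion activity take place.
#'
#' @inheritParams cone_mask
#' @param band_fraction Fraction of the radius forming the peripheral band.
#' @return Logical matrix with the dimensions of `map$grid`.
#' @export
periphery_mask <- function(map, radius = 12, half_angle = 45,
                           apex = c(0, 0), band_fraction = 0.2) {
  ax <- map_axes(map)
  X <- outer(ax$x - apex[1], rep(1, length(ax$y)))
  Y <- outer(rep(1, length(ax$x)), ax$y - apex[2])
  r <- sqrt(X^2 + Y^2)
  th <- atan2(Y, X)
  r <= radius & r >= (1 - band_fraction) * radius &
    abs(th) <= half_angle * pi / 180
}

#' Domain density and periphery enrichment
#'
#' Density is the number of detected domains per um^2 of the growth-cone
#' mask; the periphery ratio compares the domain density in the peripheral
#' band with the whole-cone density (1 = uniform placement, 2 = all domains
#' in a band covering half the area, etc.).
#'
#' @param domains A `domain_table` from [detect_domains()].
#' @param cone_mask Logical matrix of the growth-cone footprint (same grid
#'   as `map`).
#' @param map The [render_superres()] map supplying the grid geometry.
#' @param periphery Optional logical matrix of the peripheral band.
#' @return A list with `n_domains`, `density` (domains/um^2),
#'   `periphery_ratio` (NA when `periphery` is missing) and `area_um2`.
#' @export
domain_stats <- function(domains, cone_mask, map, periphery = NULL) {
  px2 <- map$pixel_size^2
  area <- sum(cone_mask) * px2
  if (area <= 0) stop("cone mask has zero area", call. = FALSE)
  density <- nrow(domains) / area
  ratio <- NA_real_
  if (!is.null(periphery)) {
    p_area <- sum(periphery) * px2
    if (p_area <= 0) stop("periphery mask has zero area", call. = FALSE)
    ix <- pmin(pmax(floor((domains$center_x - map$origin[1]) /
                            map$pixel_size) + 1L, 1L), nrow(map$grid))
    iy <- pmin(pmax(floor((domains$center_y - map$origin[2]) /
                            map$pixel_size) + 1L, 1L), ncol(map$grid))
    in_p <- periphery[cbind(ix, iy)]
    ratio <- (sum(in_p) / p_area) / density
  }
  list(n_domains = nrow(domains), density = density,
       periphery_ratio = ratio, area_um2 = area)
}

#' Shape Index of a growth-cone mask
#'
#' The Shape Index S.I. = 4 * pi * Area / Perimeter^2 equals 1 for a circle
#' and tends to 0 for elongated, filopodial shapes. Area comes from the
#' pixel count; the perimeter is the sub-pixel iso-contour length at level
#' 0.5 (marching-squares style), which avoids the systematic overestimate of
#' pixel-edge counting and makes a rasterized disk score close to 1.
#'
#' @param mask Logical (or 0/1) matrix with exactly one connected foreground
#'   component.
#' @param pixel_size Pixel size (um).
#' @return A `shape_metrics` list: `area` (um^2), `perimeter` (um),
#'   `shape_index`.
#' @export
shape_index <- function(mask, pixel_size = 1) {
  m <- (mask > 0) * 1
  if (!sum(m)) stop("mask is empty", call. = FALSE)
  ncomp <- max(EBImage::bwlabel(m))
  if (ncomp != 1L)
    stop("mask must have exactly one connected component (found ",
         ncomp, ")", call. = FALSE)
  pad <- matrix(0, nrow(m) + 6L, ncol(m) + 6L)
  pad[4:(nrow(m) + 3L), 4:(ncol(m) + 3L)] <- m
  # two passes of a 3x3 box blur turn the binary staircase into a smooth
  # field whose 0.5 iso-contour tracks the true boundary at sub-pixel
  # accuracy (raw marching squares on a binary disk overestimates the
  # perimeter by ~6%)
  sm <- box_blur3(box_blur3(pad))
  cl <- grDevices::contourLines(x = seq_len(nrow(pad)) * pixel_size,
                                y = seq_len(ncol(pad)) * pixel_size,
                                z = sm, levels = 0.5)
  per <- sum(vapply(cl, function(cc) {
    xs <- c(cc$x, cc$x[1]); ys <- c(cc$y, cc$y[1])
    sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }, numeric(1)))
  area <- sum(m) * pixel_size^2
  structure(list(area = area, perimeter = per,
                 shape_index = 4 * pi * area / per^2),
            class = "shape_metrics")
}

# 3x3 box blur with zero padding at the borders
box_blur3 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  z <- matrix(0, n + 2L, p + 2L)
  z[2:(n + 1L), 2:(p + 1L)] <- m
  out <- matrix(0, n, p)
  for (di in 0:2) for (dj in 0:2)
    out <- out + z[(1L + di):(n + di), (1L + dj):(p + dj)]
  out / 9
}

#' @export
print.shape_metrics <- function(x, ...) {
  cat(sprintf("<shape: area %.4g um^2, perimeter %.4g um, S.I. %.3f>\n",
              x$area, x$perimeter, x$shape_index))
  invisible(x)
}
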