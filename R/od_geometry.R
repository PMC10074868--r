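# Optic-disc geometry: Canny edges -> circular Hough transform -> ROI.
#
# Coordinate convention used throughout the package: 0-based, pixel-center.
# A matrix element [row, col] is the pixel with center (x, y) =
# (col - 1, row - 1); distances are Euclidean in pixel units.

#' Canny edge detection
#'
#' Compact Canny detector: Gaussian smoothing, central-difference gradients,
#' non-maximum suppression along the quantized gradient direction, and
#' hysteresis thresholding. Thresholds are automatic: the high threshold is
#' the Otsu split of the non-zero gradient magnitudes, the low threshold is
#' half of it.
#'
#' @param img numeric matrix or [binary_mask]; masks are converted to 0/1.
#' @param sigma Gaussian smoothing scale in pixels.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma = 1) {
  if (inherits(img, "binary_mask")) img <- img$pixels * 1
  g <- .gaussian_blur(img, sigma)
  H <- nrow(g); W <- ncol(g)
  xm <- g[, c(1L, seq_len(W - 1L))]; xp <- g[, c(seq_len(W - 1L) + 1L, W)]
  ym <- g[c(1L, seq_len(H - 1L)), ]; yp <- g[c(seq_len(H - 1L) + 1L, H), ]
  gx <- (xp - xm) / 2
  gy <- (yp - ym) / 2
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, H, W))

  # quantize direction into 4 bins: 0 = E-W, 1 = NE-SW, 2 = N-S, 3 = NW-SE
  ang <- atan2(gy, gx)
  bin <- as.integer(round(ang / (pi / 4))) %% 4L
  shift2 <- function(m, dr, dc) {
    out <- matrix(0, H, W)
    rs <- max(1L, 1L + dr):min(H, H + dr)
    cs <- max(1L, 1L + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  # neighbor offsets (dr, dc) along each direction bin
  off <- list(c(0L, 1L), c(-1L, 1L), c(1L, 0L), c(1L, 1L))
  nms <- matrix(FALSE, H, W)
  for (b in 0:3) {
    o <- off[[b + 1L]]
    n1 <- shift2(mag, o[1], o[2])
    n2 <- shift2(mag, -o[1], -o[2])
    nms <- nms | (bin == b & mag >= n1 & mag >= n2)
  }
  nzm <- mag[mag > 0]
  hi <- EBImage::otsu(EBImage::Image(matrix(nzm / max(nzm))),
                      range = c(0, 1)) * max(nzm)
  lo <- hi / 2
  strong <- nms & mag >= hi
  weak <- nms & mag >= lo
  # hysteresis: grow strong set through weak pixels (8-connectivity)
  repeat {
    grown <- .dilate8(strong) & weak & !strong
    if (!any(grown)) break
    strong <- strong | grown
  }
  strong
}

# 8-neighborhood dilation of a logical matrix (zero-padded borders).
.dilate8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1L, 1L + dr):min(H, H + dr)
    cs <- max(1L, 1L + dc):min(W, W + dc)
    out[rs, cs] <- out[rs, cs] | m[rs - dr, cs - dc]
  }
  out
}

# integer offsets (dx, dy) whose rounded Euclidean norm equals r
.circle_offsets <- function(r) {
  d <- -(r + 1L):(r + 1L)
  dx <- rep(d, each = length(d))
  dy <- rep(d, times = length(d))
  keep <- floor(sqrt(dx^2 + dy^2) + 0.5) == r
  cbind(dx = dx[keep], dy = dy[keep])
}

#' Detect the optic disc with a circular Hough transform
#'
#' Edges are extracted from the disc mask with [canny_edges]; every edge
#' pixel then votes for all integer circle centers at rounded distance `r`
#' for each radius in the search range. The returned circle maximizes the
#' vote count; ties are broken by smaller radius, then smaller (row, column)
#' of the center. The vote for center c and radius r equals the number of
#' edge pixels e with `floor(|e - c| + 0.5) == r`, so the accumulator is
#' identical to an exhaustive edge-overlap search over all centers and radii.
#'
#' @param od_mask optic-disc [binary_mask] (or logical matrix).
#' @param radius_range integer vector `c(r_min, r_max)` of radii to search,
#'   in pixels.
#' @param min_votes minimum accumulator votes to accept a circle; default is
#'   a quarter of the circumference of `r_min`.
#' @return An object of class `optic_disc` with fields `center_x`,
#'   `center_y` (0-based pixel-center coordinates), `radius_px` and `votes`.
#' @export
detect_disc <- function(od_mask, radius_range, min_votes = NULL) {
  m <- if (inherits(od_mask, "binary_mask")) od_mask$pixels else od_mask
  if (!any(m)) stop("no-disc: mask is empty")
  r_min <- as.integer(radius_range[1]); r_max <- as.integer(radius_range[2])
  if (!(r_min > 0 && r_min < r_max)) stop("invalid radius range")
  if (is.null(min_votes)) min_votes <- ceiling(0.25 * 2 * pi * r_min)

  edges <- canny_edges(m * 1)
  idx <- which(edges, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no-disc: no edge pixels found")
  ex <- idx[, 2] - 1L; ey <- idx[, 1] - 1L
  H <- nrow(m); W <- ncol(m)

  best <- list(votes = -1L, r = NA_integer_, cx = NA_integer_, cy = NA_integer_)
  for (r in r_min:r_max) {
    off <- .circle_offsets(r)
    cx <- rep(ex, times = nrow(off)) + rep(off[, 1], each = length(ex))
    cy <- rep(ey, times = nrow(off)) + rep(off[, 2], each = length(ex))
    ok <- cx >= 0L & cx < W & cy >= 0L & cy < H
    if (!any(ok)) next
    lin <- cy[ok] * W + cx[ok] + 1L    # row-major linear index, 1-based
    acc <- tabulate(lin, nbins = H * W)
    vmax <- max(acc)
    if (vmax > best$votes) {           # strict > keeps the smaller radius on ties
      cand <- which(acc == vmax)       # row-major: ordered by (y, x) already
      ccy <- (cand[1] - 1L) %/% W
      ccx <- (cand[1] - 1L) %% W
      best <- list(votes = vmax, r = r, cx = ccx, cy = ccy)
    }
  }
  if (best$votes < min_votes)
    stop(sprintf("no-disc: best accumulator votes %s below floor %s",
                 best$votes, ceiling(min_votes)))
  structure(list(center_x = best$cx, center_y = best$cy,
                 radius_px = best$r, votes = best$votes),
            class = "optic_disc")
}

#' @export
print.optic_disc <- function(x, ...) {
  cat(sprintf("<optic_disc center (%g, %g), radius %g px, %d votes>\n",
              x$center_x, x$center_y, x$radius_px, x$votes))
  invisible(x)
}

#' Build the peripapillary region of interest
#'
#' The ROI is the annulus between the disc radius and six disc radii: a
#' pixel with center at Euclidean distance d from the disc center belongs to
#' the ROI iff `ODr < d <= 6 * ODr`. The disc interior is excluded, so the
#' ROI area is directly the density denominator ("ROI area without the
#' disc").
#'
#' @param disc an [optic_disc][detect_disc].
#' @param image_shape integer `c(height, width)`.
#' @param outer_factor multiple of the disc radius for the outer boundary.
#' @return An object of class `roi_region` with the annulus membership mask
#'   and its in-bounds pixel count `area_px`.
#' @export
build_roi <- function(disc, image_shape, outer_factor = 6) {
  H <- as.integer(image_shape[1]); W <- as.integer(image_shape[2])
  if (H < 1L || W < 1L) stop("invalid image shape")
  inner <- disc$radius_px
  outer <- outer_factor * inner
  if (outer < 1) stop("outer ROI radius below one pixel")
  x <- matrix(rep(0:(W - 1L), each = H), H, W)
  y <- matrix(rep(0:(H - 1L), times = W), H, W)
  d2 <- (x - disc$center_x)^2 + (y - disc$center_y)^2
  annulus <- d2 > inner^2 & d2 <= outer^2
  structure(list(center_x = disc$center_x, center_y = disc$center_y,
                 inner_radius_px = inner, outer_radius_px = outer,
                 area_px = sum(annulus), mask = annulus),
            class = "roi_region")
}

#' @export
print.roi_region <- function(x, ...) {
  cat(sprintf("<roi_region %g..%g px around (%g, %g), area %d px>\n",
              x$inner_radius_px, x$outer_radius_px,
              x$center_x, x$center_y, x$area_px))
  invisible(x)
}

#' Resolve the physical pixel scale
#'
#' If a configured scale is available it wins; otherwise the scale is
#' calibrated from the detected disc, using the typical human optic-disc
#' diameter of 1.83 mm: microns per pixel = 1830 / (2 * ODr).
#'
#' @param disc an [optic_disc][detect_disc].
#' @param config_scale microns per pixel from configuration, or `NULL`.
#' @param assumed_od_diameter_mm assumed physical disc diameter.
#' @return An object of class `pixel_scale` with `microns_per_pixel` and
#'   `source` (`"config"` or `"od_calibration"`).
#' @export
resolve_pixel_scale <- function(disc, config_scale = NULL,
                                assumed_od_diameter_mm = 1.83) {
  if (!is.null(config_scale)) {
    if (config_scale <= 0) stop("configured scale must be positive")
    return(structure(list(microns_per_pixel = config_scale, source = "config"),
                     class = "pixel_scale"))
  }
  if (is.null(disc) || !is.finite(disc$radius_px) || disc$radius_px <= 0)
    stop("no configured scale and no valid disc radius to calibrate from")
  structure(list(
    microns_per_pixel = assumed_od_diameter_mm * 1000 / (2 * disc$radius_px),
    source = "od_calibration"), class = "pixel_scale")
}
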