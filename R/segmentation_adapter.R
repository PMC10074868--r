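#' @importFrom stats median mad sd quantile cor pt pchisq shapiro.test
#'   wilcox.test kruskal.test oneway.test chisq.test smooth.spline predict
#'   plogis dlogis rnorm runif rbinom qnorm setNames complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

# Standard analysis resolution: all images and masks are brought to this
# height x width before any geometry is computed.
STD_HEIGHT <- 480L
STD_WIDTH <- 640L

#' Construct a fundus image object
#'
#' Lightweight container for one eye's fundus image: a grayscale matrix (or
#' RGB array) of intensities with an identifier and free-form metadata
#' (group, stage, sex, age in days, gestational age, birth weight, ...).
#'
#' @param pixels numeric matrix (rows x cols, grayscale) or 3-d array
#'   (rows x cols x channels) of intensities.
#' @param eye_id character identifier.
#' @param meta named list of metadata.
#' @return An object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, eye_id = "eye", meta = list()) {
  if (is.null(dim(pixels)) || length(dim(pixels)) < 2L)
    stop("pixels must be a matrix or array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L) stop("invalid input: empty image")
  structure(list(pixels = pixels, height = d[1], width = d[2],
                 eye_id = eye_id, meta = meta),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("<fundus_image '%s' %d x %d>\n", x$eye_id, x$height, x$width))
  invisible(x)
}

#' Construct a binary mask object
#'
#' @param pixels logical matrix; `TRUE` is foreground.
#' @param kind `"vessel"` or `"optic_disc"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, kind = c("vessel", "optic_disc")) {
  kind <- match.arg(kind)
  if (is.numeric(pixels)) {
    if (!all(pixels %in% c(0, 1)))
      stop("mask values must be strictly binary")
    pixels <- pixels > 0
  }
  if (!is.logical(pixels) || is.null(dim(pixels)))
    stop("mask must be a logical matrix")
  structure(list(pixels = pixels, kind = kind,
                 height = nrow(pixels), width = ncol(pixels)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask (%s) %d x %d, %d foreground px>\n",
              x$kind, x$height, x$width, sum(x$pixels)))
  invisible(x)
}

# 1-d area-overlap resampling weights: W[i, j] is the fraction of output
# cell i covered by input cell j (both cells as half-open unit intervals).
.area_weights <- function(n_in, n_out) {
  s <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * s
    hi <- i * s
    j0 <- floor(lo) + 1L
    j1 <- min(ceiling(hi), n_in)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov / s
    }
  }
  W
}

.resample_area <- function(mat, out_h, out_w) {
  Wr <- .area_weights(nrow(mat), out_h)
  Wc <- .area_weights(ncol(mat), out_w)
  Wr %*% mat %*% t(Wc)
}

.nearest_idx <- function(n_in, n_out) {
  pmin(n_in, pmax(1L, floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1L))
}

.resample_nearest <- function(mat, out_h, out_w) {
  mat[.nearest_idx(nrow(mat), out_h), .nearest_idx(ncol(mat), out_w)]
}

#' Standardize a fundus image or mask to the analysis resolution
#'
#' Resamples to 480 rows x 640 columns. Images use area-weighted (box)
#' resampling so intensities stay within the input range; binary masks use
#' nearest-neighbor resampling so they stay strictly binary. Already-standard
#' inputs are returned unchanged.
#'
#' @param x a [fundus_image] or [binary_mask].
#' @return The standardized object of the same class.
#' @export
standardize_image <- function(x) {
  UseMethod("standardize_image")
}

#' @export
standardize_image.fundus_image <- function(x) {
  if (x$height < 2L || x$width < 2L)
    stop("invalid input: image smaller than 2 x 2")
  if (x$height == STD_HEIGHT && x$width == STD_WIDTH) return(x)
  px <- x$pixels
  if (length(dim(px)) == 3L) {
    out <- array(0, c(STD_HEIGHT, STD_WIDTH, dim(px)[3]))
    for (ch in seq_len(dim(px)[3]))
      out[, , ch] <- .resample_area(px[, , ch], STD_HEIGHT, STD_WIDTH)
  } else {
    out <- .resample_area(px, STD_HEIGHT, STD_WIDTH)
  }
  fundus_image(out, x$eye_id, x$meta)
}

#' @export
standardize_image.binary_mask <- function(x) {
  if (x$height < 2L || x$width < 2L)
    stop("invalid input: mask smaller than 2 x 2")
  if (x$height == STD_HEIGHT && x$width == STD_WIDTH) return(x)
  binary_mask(.resample_nearest(x$pixels, STD_HEIGHT, STD_WIDTH), x$kind)
}

#' Binarize a vesselness probability map
#'
#' A pixel is foreground iff its probability is greater than or equal to
#' `threshold`. The default 0.5 is a configurable choice, not a calibrated
#' value.
#'
#' @param probmap numeric matrix with values in \[0, 1\].
#' @param threshold scalar in (0, 1).
#' @param kind mask kind, see [binary_mask].
#' @return A [binary_mask].
#' @export
binarize_probability_map <- function(probmap, threshold = 0.5,
                                     kind = "vessel") {
  if (!is.numeric(probmap) || is.null(dim(probmap)))
    stop("probmap must be a numeric matrix")
  if (anyNA(probmap) || min(probmap) < 0 || max(probmap) > 1)
    stop("probability values must lie in [0, 1]")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly in (0, 1)")
  binary_mask(probmap >= threshold, kind)
}

# Separable Gaussian blur with replicated borders.
.gaussian_blur <- function(mat, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(m, n) {
    rbind(m[rep(1L, n), , drop = FALSE], m, m[rep(nrow(m), n), , drop = FALSE])
  }
  conv_rows <- function(m) {
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(mat))))
}

# Second partial derivatives by central differences (replicated borders).
.hessian_components <- function(g) {
  H <- nrow(g); W <- ncol(g)
  xm <- g[, c(1L, seq_len(W - 1L))]; xp <- g[, c(seq_len(W - 1L) + 1L, W)]
  ym <- g[c(1L, seq_len(H - 1L)), ]; yp <- g[c(seq_len(H - 1L) + 1L, H), ]
  gxx <- xp - 2 * g + xm
  gyy <- yp - 2 * g + ym
  gx <- (xp - xm) / 2
  gxy <- (gx[c(seq_len(H - 1L) + 1L, H), ] - gx[c(1L, seq_len(H - 1L)), ]) / 2
  list(xx = gxx, yy = gyy, xy = gxy)
}

#' Classical multi-scale ridge segmentation of vessels
#'
#' A deterministic fallback segmenter so the pipeline can run end-to-end
#' without an externally trained network: dark ridges on a bright background
#' are enhanced by the largest Hessian eigenvalue at several Gaussian scales
#' (scale-normalized), the per-pixel maximum response is taken across scales,
#' and the response is binarized with an Otsu threshold. The output is
#' invariant to positive affine rescaling of the input intensities.
#'
#' @param image a [fundus_image] (grayscale).
#' @param scales numeric vector of target ridge widths in pixels.
#' @return A vessel [binary_mask] of the same shape.
#' @export
classical_vessel_segment <- function(image, scales = c(2, 4, 8)) {
  px <- image$pixels
  if (length(dim(px)) == 3L) px <- px[, , 1]
  resp <- matrix(0, nrow(px), ncol(px))
  for (w in scales) {
    sigma <- w / 2
    h <- .hessian_components(.gaussian_blur(px, sigma))
    tr <- h$xx + h$yy
    dt <- sqrt(pmax((h$xx - h$yy)^2 + 4 * h$xy^2, 0))
    lam_max <- (tr + dt) / 2          # > 0 across a dark ridge
    resp <- pmax(resp, sigma^2 * pmax(lam_max, 0))
  }
  if (max(resp) <= 0)
    return(binary_mask(matrix(FALSE, nrow(px), ncol(px)), "vessel"))
  resp <- resp / max(resp)
  thr <- EBImage::otsu(EBImage::Image(resp))
  m <- resp > thr
  # the positive-curvature ridge response is narrower than the vessel
  # lumen near its boundary; one dilation restores the lost support
  binary_mask(.dilate8(m), "vessel")
}

#' Read an 8-bit mask image (PNG/TIFF) as a binary mask
#'
#' Foreground is any pixel above half intensity (the 0/255 convention).
#'
#' @param path file path; `.png`, `.tif` or `.tiff`.
#' @param kind mask kind, see [binary_mask].
#' @return A [binary_mask].
#' @export
read_mask <- function(path, kind = "vessel") {
  px <- .read_image_file(path)
  binary_mask(px > 0.5, kind)
}

#' Read a grayscale image (PNG/TIFF) as a fundus image
#'
#' @param path file path.
#' @param eye_id identifier for the image.
#' @return A [fundus_image].
#' @export
read_fundus <- function(path, eye_id = basename(path)) {
  fundus_image(.read_image_file(path), eye_id = eye_id)
}

.read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF files")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px
}

#' Write a binary mask as an 8-bit PNG (0 background, 255 foreground)
#'
#' @param mask a [binary_mask].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask$pixels * 1, path)
  invisible(path)
}

#' Adapt external segmentations into standardized masks
#'
#' Entry point mirroring the ingestion step of the analysis: takes a vessel
#' probability map (or ready mask) and an optic-disc mask, standardizes both
#' to 480 x 640 and binarizes the probability map.
#'
#' @param vessel numeric matrix: probability map in \[0,1\] or binary.
#' @param od_mask logical/0-1 matrix: optic disc mask.
#' @param threshold binarization threshold for the probability map.
#' @return list with elements `vessel` and `od`, both standardized
#'   [binary_mask] objects.
#' @export
adapt_segmentations <- function(vessel, od_mask, threshold = 0.5) {
  vm <- if (is.logical(vessel) || all(vessel %in% c(0, 1))) {
    binary_mask(vessel > 0, "vessel")
  } else {
    binarize_probability_map(vessel, threshold, "vessel")
  }
  dm <- binary_mask(od_mask > 0, "optic_disc")
  list(vessel = standardize_image(vm), od = standardize_image(dm))
}
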