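# Synthetic inputs for end-to-end testing:
#  (a) retina phantoms -- rasterized disc + vessel primitives (line / arc /
#      sine) with analytically known tortuosity, width and pixel counts;
#  (b) cohort feature tables with the published group structure (counts,
#      means, SDs) of a neonatal FEVR case-control study;
#  (c) proportional-odds cohorts with known coefficients, the oracle for
#      the ordinal regression fit.

#' Specify a retina phantom
#'
#' @param image_shape integer `c(height, width)`; default 480 x 640.
#' @param disc list with `cx`, `cy` (0-based center) and `r` (radius px).
#' @param vessels list of primitives. Each is a list with `kind` one of
#'   `"line"` (`x0,y0,x1,y1`), `"arc"` (`cx,cy,R,theta0,theta1` radians) or
#'   `"sine"` (`x0,y0,amp,period,length`: `y = y0 + amp*sin(2*pi*(x-x0)/period)`
#'   for `x` in `[x0, x0+length]`), plus `width_px`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(480L, 640L),
                         disc = list(cx = 320, cy = 240, r = 40),
                         vessels = list()) {
  for (v in vessels) {
    if (!v$kind %in% c("line", "arc", "sine")) stop("unknown vessel kind")
    if (v$width_px < 1) stop("vessel width must be >= 1 px")
  }
  structure(list(image_shape = as.integer(image_shape), disc = disc,
                 vessels = vessels), class = "phantom_spec")
}

# dense polyline sampling of a primitive (step in px along the curve) and
# its analytic tortuosity tau = (1/L) integral k^2 ds
.primitive_polyline <- function(v, step = 0.25) {
  if (v$kind == "line") {
    L <- sqrt((v$x1 - v$x0)^2 + (v$y1 - v$y0)^2)
    t <- seq(0, 1, length.out = max(2L, ceiling(L / step) + 1L))
    list(x = v$x0 + t * (v$x1 - v$x0), y = v$y0 + t * (v$y1 - v$y0),
         tau = 0, length = L)
  } else if (v$kind == "arc") {
    L <- abs(v$theta1 - v$theta0) * v$R
    th <- seq(v$theta0, v$theta1,
              length.out = max(2L, ceiling(L / step) + 1L))
    list(x = v$cx + v$R * cos(th), y = v$cy + v$R * sin(th),
         tau = 1 / v$R^2, length = L)
  } else {
    # y = y0 + A sin(2 pi (x - x0) / T); curvature k = y'' / (1+y'^2)^(3/2)
    xs <- seq(v$x0, v$x0 + v$length,
              length.out = max(2L, ceiling(4 * v$length / step) + 1L))
    om <- 2 * pi / v$period
    y1 <- v$amp * om * cos(om * (xs - v$x0))
    y2 <- -v$amp * om^2 * sin(om * (xs - v$x0))
    speed <- sqrt(1 + y1^2)
    k <- y2 / speed^3
    L <- .trapz(xs, speed)
    list(x = xs, y = v$y0 + v$amp * sin(om * (xs - v$x0)),
         tau = .trapz(xs, k^2 * speed) / L, length = L)
  }
}

# rasterize: pixel is foreground iff its center lies within width/2 of the
# curve (minimum distance to the dense polyline)
.rasterize_curve <- function(shape, poly, width_px) {
  H <- shape[1]; W <- shape[2]
  half <- width_px / 2
  x0 <- max(0L, floor(min(poly$x) - half - 1))
  x1 <- min(W - 1L, ceiling(max(poly$x) + half + 1))
  y0 <- max(0L, floor(min(poly$y) - half - 1))
  y1 <- min(H - 1L, ceiling(max(poly$y) + half + 1))
  if (x1 < x0 || y1 < y0) return(matrix(FALSE, H, W))
  xs <- x0:x1; ys <- y0:y1
  px <- matrix(rep(xs, each = length(ys)), length(ys))
  py <- matrix(rep(ys, times = length(xs)), length(ys))
  d2min <- matrix(Inf, length(ys), length(xs))
  for (i in seq_along(poly$x)) {
    d2 <- (px - poly$x[i])^2 + (py - poly$y[i])^2
    d2min <- pmin(d2min, d2)
  }
  m <- matrix(FALSE, H, W)
  m[ys + 1L, xs + 1L] <- d2min <= half^2
  m
}

.rasterize_disk <- function(shape, cx, cy, r) {
  H <- shape[1]; W <- shape[2]
  x <- matrix(rep(0:(W - 1L), each = H), H, W)
  y <- matrix(rep(0:(H - 1L), times = W), H, W)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

#' Rasterize a retina phantom with known ground truth
#'
#' Vessels are rasterized by exact sub-pixel distance to the parametric
#' curve (`distance <= width/2`); the truth manifest carries each vessel's
#' analytic tortuosity (line: 0; arc of radius R: 1/R^2; sine: quadrature of
#' the analytic curvature), its nominal width, and exact pixel counts of the
#' vessel area and annulus inside the 1..6 disc-radius ROI.
#'
#' @param spec a [phantom_spec].
#' @return List: `image` ([fundus_image], dark vessels on bright fundus),
#'   `vessel` and `od` ([binary_mask]s), `truth` (list with `disc`,
#'   per-vessel `tau` and `width_px`, `a_vessel_px`, `a_roi_px`, `vd_pct`).
#' @export
make_phantom <- function(spec) {
  shape <- spec$image_shape
  dsc <- spec$disc
  od <- .rasterize_disk(shape, dsc$cx, dsc$cy, dsc$r)
  x <- matrix(rep(0:(shape[2] - 1L), each = shape[1]), shape[1])
  y <- matrix(rep(0:(shape[1] - 1L), times = shape[2]), shape[1])
  d2 <- (x - dsc$cx)^2 + (y - dsc$cy)^2
  annulus <- d2 > dsc$r^2 & d2 <= (6 * dsc$r)^2
  if (!any(annulus)) stop("phantom annulus is empty (disc outside image?)")
  vm <- matrix(FALSE, shape[1], shape[2])
  taus <- numeric(0); widths <- numeric(0)
  for (v in spec$vessels) {
    poly <- .primitive_polyline(v)
    vm <- vm | .rasterize_curve(shape, poly, v$width_px)
    taus <- c(taus, poly$tau)
    widths <- c(widths, v$width_px)
  }
  a_vessel <- sum(vm & annulus)
  a_roi <- sum(annulus)
  img <- matrix(0.9, shape[1], shape[2])
  img[od] <- 0.95
  img[vm] <- 0.2
  list(image = fundus_image(img, eye_id = "phantom"),
       vessel = binary_mask(vm, "vessel"),
       od = binary_mask(od, "optic_disc"),
       truth = list(disc = dsc, tau = taus, width_px = widths,
                    a_vessel_px = a_vessel, a_roi_px = a_roi,
                    vd_pct = 100 * a_vessel / a_roi))
}

#' Default phantom: central disc with radiating spokes and arcs
#'
#' Disc of radius 40 px at (320, 240) with six straight spokes (width 6 px)
#' crossing the annulus, optionally replaced by arcs of known curvature.
#'
#' @param n_spokes number of straight spokes.
#' @param width_px vessel width.
#' @param arcs optional list of arc primitives to add.
#' @return A [phantom_spec].
#' @export
default_phantom_spec <- function(n_spokes = 6, width_px = 6, arcs = list()) {
  cx <- 320; cy <- 240; r <- 40
  vessels <- list()
  for (i in seq_len(n_spokes)) {
    th <- 2 * pi * (i - 1) / n_spokes + 0.1
    vessels[[i]] <- list(kind = "line", width_px = width_px,
                         x0 = cx + (r + 2) * cos(th), y0 = cy + (r + 2) * sin(th),
                         x1 = cx + (6 * r - 2) * cos(th),
                         y1 = cy + (6 * r - 2) * sin(th))
  }
  phantom_spec(vessels = c(vessels, arcs))
}

# Published group structure of the neonatal cohort: per-eye counts and
# mean +/- SD of each vascular metric per group, plus covariate summaries.
# VT in the study's display unit (1e4 cm^-3), VW in um, VD in %.
.cohort_defaults <- function() {
  list(
    groups = data.frame(
      group = c("control", "stage1", "stage2", "stage3"),
      stage = 0:3,
      n = c(53L, 18L, 28L, 12L),
      vt_mean = c(70.80, 71.09, 72.22, 74.91),
      vt_sd = c(4.05, 2.83, 3.65, 3.42),
      vw_mean = c(63.46, 63.68, 66.33, 70.76),
      vw_sd = c(3.30, 2.32, 2.34, 3.10),
      vd_mean = c(4.59, 4.61, 5.21, 6.50),
      vd_sd = c(0.69, 0.85, 1.00, 0.79),
      stringsAsFactors = FALSE),
    covariates = list(
      control = list(p_female = 11 / 30, age = c(2.67, 1.21),
                     ga = c(275.97, 5.70), bw = c(3385.83, 263.87)),
      fevr = list(p_female = 13 / 43, age = c(2.26, 1.29),
                  ga = c(275.00, 8.32), bw = c(3266.51, 420.46))))
}

#' Specify a synthetic cohort
#'
#' Defaults reproduce the published group sizes (53 control eyes, 18 / 28 /
#' 12 eyes at stages 1-3), per-group means and SDs of VT, VW and VD, and the
#' covariate summaries (sex ratio, age in days, gestational age, birth
#' weight) of the source cohort.
#'
#' @param groups data.frame with columns `group`, `stage`, `n`, `vt_mean`,
#'   `vt_sd`, `vw_mean`, `vw_sd`, `vd_mean`, `vd_sd`.
#' @param covariates list with entries `control` and `fevr`, each holding
#'   `p_female`, and `c(mean, sd)` for `age`, `ga`, `bw`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = NULL, covariates = NULL) {
  def <- .cohort_defaults()
  spec <- list(groups = groups %||% def$groups,
               covariates = covariates %||% def$covariates)
  stopifnot(all(spec$groups$n > 0), all(spec$groups$vt_sd >= 0),
            all(spec$groups$vw_sd >= 0), all(spec$groups$vd_sd >= 0))
  structure(spec, class = "cohort_spec")
}

#' Draw a synthetic cohort of per-eye records
#'
#' Metric values are independent Gaussian draws per group with the
#' specified means and SDs; covariates are drawn from the group-level
#' summaries (Bernoulli sex, Gaussian age/gestational age/birth weight,
#' ages rounded to whole days and floored at 1).
#'
#' @param spec a [cohort_spec]; default is the published group structure.
#' @param seed integer seed for reproducibility.
#' @return data.frame with one row per eye: `eye_id`, `patient_id`,
#'   `group`, `stage`, `vt`, `vw_um`, `vd_pct`, `sex`, `age_days`,
#'   `ga_days`, `bw_g`.
#' @export
make_cohort <- function(spec = cohort_spec(), seed = 0L) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(spec$groups))) {
    g <- spec$groups[i, ]
    cv <- if (g$stage == 0) spec$covariates$control else spec$covariates$fevr
    n <- g$n
    out[[i]] <- data.frame(
      eye_id = sprintf("%s_%02d", g$group, seq_len(n)),
      patient_id = sprintf("%s_p%02d", g$group, seq_len(n)),
      group = if (g$stage == 0) "control" else "fevr",
      stage = g$stage,
      vt = rnorm(n, g$vt_mean, g$vt_sd),
      vw_um = rnorm(n, g$vw_mean, g$vw_sd),
      vd_pct = rnorm(n, g$vd_mean, g$vd_sd),
      sex = ifelse(runif(n) < cv$p_female, "F", "M"),
      age_days = pmax(1, round(rnorm(n, cv$age[1], cv$age[2]))),
      ga_days = round(rnorm(n, cv$ga[1], cv$ga[2])),
      bw_g = round(rnorm(n, cv$bw[1], cv$bw[2])),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Draw records from a proportional-odds model
#'
#' Covariates are independent standard normal; the stage of each record is
#' sampled from the cumulative-logit probabilities
#' `P(Y <= k | x) = plogis(theta_k - x %*% beta)`. This is the parameter
#' oracle for [fit_ordinal_logistic].
#'
#' @param betas numeric vector of coefficients.
#' @param thresholds strictly increasing numeric vector (K-1 cutpoints for
#'   K ordered levels).
#' @param n number of records.
#' @param seed integer seed.
#' @return data.frame with covariate columns `x1..xd` and ordered integer
#'   `stage` in `1..K`.
#' @export
make_ordinal_cohort <- function(betas, thresholds, n, seed = 0L) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  set.seed(seed)
  d <- length(betas)
  X <- matrix(rnorm(n * d), n, d)
  colnames(X) <- paste0("x", seq_len(d))
  eta <- as.numeric(X %*% betas)
  K <- length(thresholds) + 1L
  cum <- vapply(thresholds, function(th) plogis(th - eta), numeric(n))
  cum <- cbind(cum, 1)
  u <- runif(n)
  stage <- apply(u <= cum, 1L, function(row) which(row)[1])
  data.frame(X, stage = as.integer(stage))
}
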