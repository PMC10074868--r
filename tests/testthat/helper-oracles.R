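# Shared fixtures and independent oracles, all built in code.

# an ROI covering the whole frame (for isolating metric operations from
# disc detection)
full_roi <- function(H = 480L, W = 640L) {
  structure(list(center_x = (W - 1) / 2, center_y = (H - 1) / 2,
                 inner_radius_px = 0, outer_radius_px = Inf,
                 area_px = H * W, mask = matrix(TRUE, H, W)),
            class = "roi_region")
}

# rasterized filled disk as a logical matrix
disk_mask <- function(H, W, cx, cy, r) {
  x <- matrix(rep(0:(W - 1L), each = H), H, W)
  y <- matrix(rep(0:(H - 1L), times = W), H, W)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# axis-aligned bar of odd width w centered on row `row`
bar_mask <- function(H, W, row, w, col0, col1) {
  m <- matrix(FALSE, H, W)
  half <- (w - 1L) %/% 2L
  m[(row - half):(row + half), col0:col1] <- TRUE
  m
}

# phantom with a single arc vessel (plus a far-away dummy disc)
arc_phantom <- function(R, width_px = 5, theta0 = 0.3, len = 100) {
  spec <- phantom_spec(disc = list(cx = 50, cy = 50, r = 10),
                       vessels = list(list(kind = "arc", width_px = width_px,
                                           cx = 320, cy = 240, R = R,
                                           theta0 = theta0,
                                           theta1 = theta0 + len / R)))
  make_phantom(spec)
}

# longest extracted segment of a mask (refined against its distance map)
main_segment <- function(mask) {
  d <- EBImage::distmap(mask * 1)
  segs <- extract_vessels(mask, full_roi(nrow(mask), ncol(mask)),
                          min_branch_px = 10, distance_map = d)
  lens <- vapply(segs, function(s) s$arc_length_px, numeric(1))
  list(seg = segs[[which.max(lens)]], dmap = d, n = length(segs))
}

# exhaustive circular-disc search: for every center and radius, count edge
# pixels whose rounded distance to the center equals the radius
brute_force_disc <- function(edges, r_range) {
  idx <- which(edges, arr.ind = TRUE)
  ex <- idx[, 2] - 1; ey <- idx[, 1] - 1
  H <- nrow(edges); W <- ncol(edges)
  best <- c(votes = -1, r = NA, cx = NA, cy = NA)
  # distance matrix centers x edges, then per-radius counts
  cx <- rep(0:(W - 1L), each = H)
  cy <- rep(0:(H - 1L), times = W)
  D <- sqrt(outer(cx, ex, function(a, b) (a - b)^2) +
              outer(cy, ey, function(a, b) (a - b)^2))
  Dr <- floor(D + 0.5)
  for (r in r_range[1]:r_range[2]) {
    votes <- rowSums(Dr == r)
    vmax <- max(votes)
    if (vmax > best["votes"]) {
      i <- which(votes == vmax)
      # ties: smallest (row, column); cy varies fastest in column-major,
      # so order explicitly by (cy, cx)
      i <- i[order(cy[i], cx[i])][1]
      best <- c(votes = vmax, r = r, cx = cx[i], cy = cy[i])
    }
  }
  best
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
mw_enumeration_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# closed-form Pearson chi-square statistic for a 2x2 table
chi2_closed_form <- function(tb) {
  a <- tb[1, 1]; b <- tb[1, 2]; c <- tb[2, 1]; d <- tb[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# silhouette score computed from its definition
silhouette_by_def <- function(coords, labels) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# quadrature tortuosity of an analytic sine vessel (independent of the
# generator's own quadrature: finer grid, different rule)
sine_tau_oracle <- function(amp, period, len, n = 20001L) {
  om <- 2 * pi / period
  xs <- seq(0, len, length.out = n)
  y1 <- amp * om * cos(om * xs)
  y2 <- -amp * om^2 * sin(om * xs)
  sp <- sqrt(1 + y1^2)
  k2 <- (y2 / sp^3)^2
  h <- xs[2] - xs[1]
  num <- sum((k2 * sp)[-1] + (k2 * sp)[-n]) * h / 2
  den <- sum(sp[-1] + sp[-n]) * h / 2
  num / den
}
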