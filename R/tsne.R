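# Exact (O(n^2)) t-SNE of the per-eye feature vectors, written for
# small cohorts (~10^2 points): Gaussian affinities calibrated per point by
# binary search on the conditional entropy, Student-t low-dimensional
# kernel, gradient descent on KL(P || Q) with early exaggeration and a
# momentum schedule.

#' Calibrate symmetric t-SNE affinities
#'
#' For every point a Gaussian bandwidth is found by binary search so that
#' the Shannon entropy of its conditional neighbor distribution equals
#' `log(perplexity)` within `tol`; the conditionals are then symmetrized
#' and normalized to sum to one.
#'
#' @param features numeric matrix, one row per observation.
#' @param perplexity effective neighbor count, in `(1, n - 1)`.
#' @param tol entropy tolerance (nats).
#' @return Symmetric n x n probability matrix with zero diagonal summing
#'   to 1; attribute `entropies` holds the per-point conditional entropies.
#' @export
calibrate_affinities <- function(features, perplexity, tol = 1e-5) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 points")
  if (perplexity <= 1 || perplexity >= n)
    stop("perplexity must lie in (1, n)")
  ss <- rowSums(X^2)
  D2 <- pmax(outer(ss, ss, "+") - 2 * tcrossprod(X), 0)
  diag(D2) <- Inf
  if (all(!is.finite(D2) | D2 < 1e-24))
    stop("degenerate affinities: all points coincide")
  target <- log(perplexity)
  P <- matrix(0, n, n)
  ent <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- D2[i, ]
    if (all(d2[is.finite(d2)] < 1e-24))
      stop("degenerate affinities: point has only duplicates")
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:200) {
      w <- exp(-d2 * beta)
      w[i] <- 0
      sw <- sum(w)
      p <- w / sw
      # H = log(sw) + beta * sum(p * d2)
      h <- log(sw) + beta * sum(p * d2, na.rm = TRUE)
      if (abs(h - target) < tol) break
      if (h > target) {                 # too flat -> larger beta
        lo <- beta
        beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (lo + hi) / 2
      }
    }
    P[i, ] <- p
    ent[i] <- h
  }
  P <- (P + t(P)) / (2 * n)
  structure(P, entropies = ent)
}

# Student-t kernel Q and the unnormalized weights W from coordinates
.tsne_q <- function(Y) {
  ss <- rowSums(Y^2)
  W <- 1 / (1 + pmax(outer(ss, ss, "+") - 2 * tcrossprod(Y), 0))
  diag(W) <- 0
  list(W = W, Q = W / sum(W))
}

.tsne_kl <- function(P, Y) {
  Q <- pmax(.tsne_q(Y)$Q, 1e-12)
  Pp <- pmax(P, 1e-12)
  sum(P * (log(Pp) - log(Q)))
}

# analytic KL gradient: 4 * sum_j (p_ij - q_ij) w_ij (y_i - y_j)
.tsne_grad <- function(P, Y) {
  qq <- .tsne_q(Y)
  M <- (P - qq$Q) * qq$W
  4 * (diag(rowSums(M)) - M) %*% Y
}

#' Exact t-SNE embedding
#'
#' @param features numeric matrix (n x d); columns are standardized to
#'   zero mean / unit variance first (constant columns dropped).
#' @param perplexity target perplexity; clipped to `(n - 1) / 3` for small
#'   n.
#' @param seed integer seed for the Gaussian initialization.
#' @param n_iter gradient-descent iterations.
#' @param eta learning rate.
#' @param exaggeration early-exaggeration factor (first 250 iterations).
#' @return An object of class `tsne_embedding`: `coords` (n x 2),
#'   `kl_initial`, `kl_final`, `perplexity`, `seed`, `n_iter`.
#' @export
tsne <- function(features, perplexity = 30, seed = 0L, n_iter = 1000L,
                 eta = 200, exaggeration = 12) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) stop("features must be finite")
  n <- nrow(X)
  if (n < 5) stop("need at least 5 points")
  keep <- apply(X, 2, function(v) sd(v) > 0)
  X <- scale(X[, keep, drop = FALSE])
  perplexity <- min(perplexity, (n - 1) / 3)
  P <- calibrate_affinities(X, perplexity)

  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  kl_initial <- .tsne_kl(P, Y)
  V <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  stop_exag <- min(250L, n_iter %/% 2L)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= stop_exag) P * exaggeration else P
    G <- .tsne_grad(Pe, Y)
    mom <- if (it <= stop_exag) 0.5 else 0.8
    # adaptive per-coordinate gains (Jacobs rule), as in the reference
    # implementations; stabilizes the fixed learning rate
    same_dir <- sign(G) == sign(V)
    gains <- ifelse(same_dir, gains * 0.8, gains + 0.2)
    gains[gains < 0.01] <- 0.01
    V <- mom * V - eta * gains * G
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  structure(list(coords = Y, kl_initial = kl_initial,
                 kl_final = .tsne_kl(P, Y), perplexity = perplexity,
                 seed = seed, n_iter = n_iter),
            class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("<tsne_embedding n = %d, perplexity %.3g, KL %.4g -> %.4g>\n",
              nrow(x$coords), x$perplexity, x$kl_initial, x$kl_final))
  invisible(x)
}

#' Severity ordering of an embedding
#'
#' Projects the 2-D coordinates onto the line through the centroid of the
#' least severe and the centroid of the most severe stage and reports the
#' Spearman correlation of the projection with the stage, plus a one-sided
#' permutation p-value (the statistic is recomputed, centroids included,
#' under each label shuffle).
#'
#' @param coords n x 2 matrix of embedding coordinates.
#' @param stages integer vector of stages (same length as rows of coords).
#' @param n_perm number of label permutations.
#' @param seed seed for the permutations.
#' @return List with `rho` and `p_perm`, or `NA`s (undefined marker) when
#'   fewer than 2 stages are present or all points coincide.
#' @export
severity_ordering_check <- function(coords, stages, n_perm = 1000L,
                                    seed = 0L) {
  coords <- as.matrix(coords)
  undefined <- list(rho = NA_real_, p_perm = NA_real_)
  if (length(unique(stages)) < 2) return(undefined)
  if (all(apply(coords, 2, sd) == 0)) return(undefined)
  stat <- function(st) {
    c0 <- colMeans(coords[st == min(st), , drop = FALSE])
    c1 <- colMeans(coords[st == max(st), , drop = FALSE])
    v <- c1 - c0
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(NA_real_)
    proj <- as.numeric(coords %*% (v / nv))
    suppressWarnings(stats::cor(proj, st, method = "spearman"))
  }
  rho <- stat(stages)
  if (!is.finite(rho)) return(undefined)
  set.seed(seed)
  perm <- replicate(n_perm, stat(sample(stages)))
  p <- (1 + sum(perm >= rho, na.rm = TRUE)) / (1 + n_perm)
  list(rho = rho, p_perm = p)
}
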