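# Morphological skeletonization and branch decomposition of vessel masks.

# shift a logical matrix by (dr, dc) with FALSE padding
.shift_l <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- max(1L, 1L + dr):min(H, H + dr)
  cs <- max(1L, 1L + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iterative two-subcycle thinning to a 1-pixel-wide, 8-connected skeleton.
#' Deterministic; preserves connectivity of the input regions.
#'
#' @param mask logical matrix or [binary_mask].
#' @return Logical matrix: the skeleton.
#' @export
skeletonize <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbors clockwise from north: P2..P9
      p2 <- .shift_l(m, 1L, 0L)   # value of pixel above: shift down
      p3 <- .shift_l(m, 1L, -1L)
      p4 <- .shift_l(m, 0L, -1L)
      p5 <- .shift_l(m, -1L, -1L)
      p6 <- .shift_l(m, -1L, 0L)
      p7 <- .shift_l(m, -1L, 1L)
      p8 <- .shift_l(m, 0L, 1L)
      p9 <- .shift_l(m, 1L, 1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1L) {
        cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        m <- m & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# number of 8-neighbors that are TRUE, per pixel
.neighbor_count <- function(m) {
  n <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + .shift_l(m, dr, dc)
  }
  n
}

# crossing number: 0->1 transitions in the circular neighbor sequence
# (N, NE, E, SE, S, SW, W, NW). 1 = endpoint, 2 = line interior,
# >= 3 = junction. Robust to diagonal staircasing, unlike a raw
# neighbor count.
.crossing_number <- function(m) {
  ns <- list(.shift_l(m, 1L, 0L), .shift_l(m, 1L, -1L), .shift_l(m, 0L, -1L),
             .shift_l(m, -1L, -1L), .shift_l(m, -1L, 0L), .shift_l(m, -1L, 1L),
             .shift_l(m, 0L, 1L), .shift_l(m, 1L, 1L))
  a <- matrix(0L, nrow(m), ncol(m))
  for (k in 1:8) {
    nxt <- ns[[if (k == 8L) 1L else k + 1L]]
    a <- a + (!ns[[k]] & nxt)
  }
  a
}

# label 8-connected components of a logical matrix by flood fill;
# returns integer matrix (0 = background)
.label8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  drs <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dcs <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  cur <- 0L
  for (s in which(m)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      r <- ((frontier - 1L) %% H) + 1L
      cc <- ((frontier - 1L) %/% H) + 1L
      cand <- integer(0)
      for (k in 1:8) {
        r2 <- r + drs[k]; c2 <- cc + dcs[k]
        ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
        cand <- c(cand, (c2[ok] - 1L) * H + r2[ok])
      }
      cand <- unique(cand[m[cand] & lab[cand] == 0L])
      if (length(cand)) lab[cand] <- cur
      frontier <- cand
    }
  }
  lab
}

# order the pixels of one 1-px-wide branch end-to-end.
# px: 2-col matrix of (row, col) 1-based indices belonging to the branch.
# Returns the ordered matrix. Start point: the endpoint (pixel with <= 1
# neighbor in the branch) with smallest x then smallest y; for cycles, the
# pixel with smallest x then y.
.order_branch <- function(px, H) {
  n <- nrow(px)
  if (n == 1L) return(px)
  key <- px[, 1] * 1e-6 + px[, 2]        # x (col) dominant, then y (row)
  lin <- (px[, 2] - 1L) * H + px[, 1]
  set <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(lin[i]), i, envir = set)
  nb_idx <- function(i) {
    r <- px[i, 1]; cc <- px[i, 2]
    out <- integer(0)
    for (dc in -1:1) for (dr in -1:1) {
      if (dr == 0 && dc == 0) next
      k <- as.character((cc + dc - 1L) * H + (r + dr))
      j <- get0(k, envir = set, ifnotfound = NULL)
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }
  deg <- vapply(seq_len(n), function(i) length(nb_idx(i)), integer(1))
  ends <- which(deg <= 1L)
  start <- if (length(ends)) ends[order(key[ends])][1] else order(key)[1]
  ord <- integer(n)
  visited <- logical(n)
  cur <- start; visited[cur] <- TRUE; ord[1] <- cur
  for (step in seq_len(n - 1L)) {
    nbs <- nb_idx(cur)
    nbs <- nbs[!visited[nbs]]
    if (!length(nbs)) break
    if (length(nbs) > 1L) {
      # prefer 4-connected continuation, then deterministic key order
      d4 <- abs(px[nbs, 1] - px[cur, 1]) + abs(px[nbs, 2] - px[cur, 2])
      nbs <- nbs[order(d4, key[nbs])]
    }
    cur <- nbs[1]
    visited[cur] <- TRUE
    ord[step + 1L] <- cur
  }
  px[ord[ord > 0L], , drop = FALSE]
}

#' Decompose a skeleton into branches
#'
#' Junction pixels (crossing number 3 or more) are removed; the remaining
#' 8-connected components are traced end-to-end into ordered point lists.
#'
#' @param skel logical matrix, a 1-px-wide skeleton.
#' @return List of ordered coordinate matrices, columns `x`, `y` (0-based).
#'   Branches are sorted by their leftmost-topmost starting point.
#' @keywords internal
.skeleton_branches <- function(skel) {
  H <- nrow(skel)
  junction <- skel & .crossing_number(skel) >= 3L
  # removing only the junction pixel leaves arms 8-connected through its
  # diagonals; clear its whole 3x3 neighborhood so branches separate
  body <- skel & !.dilate8(junction) & !junction
  lab <- .label8(body)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  branches <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    w <- which(lab == ids[i], arr.ind = TRUE)
    w <- .order_branch(w, H)
    branches[[i]] <- cbind(x = w[, 2] - 1L, y = w[, 1] - 1L)
  }
  if (!length(branches)) return(branches)
  keys <- vapply(branches, function(b) b[1, 1] * 1e6 + b[1, 2], numeric(1))
  branches[order(keys)]
}
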