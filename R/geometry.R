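#' Signed polygon area (shoelace formula)
#'
#' @param xy two-column matrix of vertices, open ring (first vertex not
#'   repeated). Positive for counter-clockwise orientation in a y-up frame.
#' @return signed area.
#' @export
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (absolute)
#' @inheritParams polygon_signed_area
#' @return nonnegative area.
#' @export
polygon_area <- function(xy) abs(polygon_signed_area(xy))

#' Polygon perimeter
#' @inheritParams polygon_signed_area
#' @return total boundary length.
#' @export
polygon_perimeter <- function(xy) {
  d <- xy[c(2:nrow(xy), 1), , drop = FALSE] - xy
  sum(sqrt(rowSums(d^2)))
}

# Orient an open vertex ring counter-clockwise (positive shoelace area).
ensure_ccw <- function(xy) {
  if (polygon_signed_area(xy) < 0) xy[nrow(xy):1, , drop = FALSE] else xy
}

# Drop consecutive duplicate vertices (and a repeated closing vertex).
dedup_ring <- function(xy, tol = 1e-12) {
  n <- nrow(xy)
  if (n > 1 && all(abs(xy[1, ] - xy[n, ]) < tol)) xy <- xy[-n, , drop = FALSE]
  n <- nrow(xy)
  if (n < 2) return(xy)
  d <- xy - xy[c(n, 1:(n - 1)), , drop = FALSE]
  keep <- rowSums(abs(d)) > tol
  keep[1] <- TRUE
  xy[keep, , drop = FALSE]
}

#' Convex hull of a polygon
#'
#' @inheritParams polygon_signed_area
#' @return open CCW vertex ring of the hull.
#' @export
convex_hull <- function(xy) {
  h <- grDevices::chull(xy[, 1], xy[, 2])  # returned clockwise
  ensure_ccw(xy[h, , drop = FALSE])
}

# Proper-intersection test between segment sets, used to reject
# self-intersecting input polygons. O(n * k) with bounding-interval
# prefilter on x.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  a <- xy
  b <- xy[c(2:n, 1), , drop = FALSE]
  xmin <- pmin(a[, 1], b[, 1]); xmax <- pmax(a[, 1], b[, 1])
  ymin <- pmin(a[, 2], b[, 2]); ymax <- pmax(a[, 2], b[, 2])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    j <- seq.int(i + 2, n)
    # adjacent segments share a vertex; segment n is adjacent to segment 1
    if (i == 1) j <- j[j != n]
    j <- j[xmin[j] <= xmax[i] & xmax[j] >= xmin[i] &
           ymin[j] <= ymax[i] & ymax[j] >= ymin[i]]
    if (!length(j)) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
    d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
    d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

# Ramer-Douglas-Peucker simplification of a closed ring (iterative stack).
# tol in coordinate units. The ring is anchored at its four axis-extreme
# vertices so that corners near the bounding box are never chamfered away,
# then each arc is simplified independently.
simplify_ring <- function(xy, tol, extra_anchors = integer()) {
  n <- nrow(xy)
  if (n <= 4 || tol <= 0) return(xy)
  anchors <- sort(unique(c(which.min(xy[, 1]), which.max(xy[, 1]),
                           which.min(xy[, 2]), which.max(xy[, 2]),
                           extra_anchors)))
  if (length(anchors) < 2) return(xy)
  idx <- c(seq.int(anchors[1], n), seq.int(1, anchors[1]))  # closed walk
  p <- xy[idx, , drop = FALSE]
  cuts <- c(vapply(anchors, function(a) which(idx == a)[1], 0L), length(idx))
  cuts <- sort(unique(cuts))
  keep <- logical(length(idx))
  keep[cuts] <- TRUE
  for (k in seq_len(length(cuts) - 1)) {
    span <- dp_polyline(p[cuts[k]:cuts[k + 1], , drop = FALSE], tol)
    keep[seq.int(cuts[k], cuts[k + 1])][span] <- TRUE
  }
  out <- p[keep & c(rep(TRUE, length(idx) - 1), FALSE), , drop = FALSE]
  if (nrow(out) < 3) xy else out
}

# Douglas-Peucker on an open polyline; returns a logical keep vector.
dp_polyline <- function(p, tol) {
  np <- nrow(p)
  keep <- logical(np)
  keep[c(1, np)] <- TRUE
  if (np <= 2) return(keep)
  stack <- list(c(1, np))
  while (length(stack)) {
    s <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    lo <- s[1]; hi <- s[2]
    if (hi - lo < 2) next
    a <- p[lo, ]; b <- p[hi, ]
    ab <- b - a; len <- sqrt(sum(ab^2))
    m <- seq.int(lo + 1, hi - 1)
    d <- if (len < 1e-12) {
      sqrt((p[m, 1] - a[1])^2 + (p[m, 2] - a[2])^2)
    } else {
      abs(ab[1] * (a[2] - p[m, 2]) - (a[1] - p[m, 1]) * ab[2]) / len
    }
    k <- which.max(d)
    if (d[k] > tol) {
      keep[m[k]] <- TRUE
      stack[[length(stack) + 1]] <- c(lo, m[k])
      stack[[length(stack) + 1]] <- c(m[k], hi)
    }
  }
  keep
}

# Circular Gaussian smoothing of a closed boundary. sigma in vertex steps
# (the marching-squares boundary is sampled at ~1 px spacing, so sigma is
# effectively in pixels).
smooth_ring <- function(xy, sigma) {
  n <- nrow(xy)
  if (sigma <= 0 || n < 8) return(xy)
  half <- max(1L, ceiling(3 * sigma))
  if (2 * half + 1 >= n) half <- max(1L, (n - 1) %/% 2)
  k <- stats::dnorm(seq.int(-half, half), sd = sigma)
  k <- k / sum(k)
  pad <- function(v) c(v[(n - half + 1):n], v, v[1:half])
  sm <- function(v) as.numeric(stats::filter(pad(v), k, sides = 2))[(half + 1):(half + n)]
  cbind(sm(xy[, 1]), sm(xy[, 2]))
}

# Turning angle (degrees, signed) at each vertex of a closed ring.
turning_angles <- function(xy) {
  n <- nrow(xy)
  prv <- xy[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- xy[c(2:n, 1), , drop = FALSE]
  v1 <- xy - prv
  v2 <- nxt - xy
  atan2(v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1],
        v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2]) * 180 / pi
}

# Local-maximum vertices of windowed absolute turning, used to anchor the
# simplifier at true shape corners (smoothing disperses each corner's turn
# over ~2 sigma vertices, so the turn is summed over a +/-window first).
corner_anchors <- function(xy, window = 4, min_turn = 45) {
  n <- nrow(xy)
  if (n < 2 * window + 3) return(integer())
  turn <- turning_angles(xy)
  idx <- function(k) ((seq_len(n) - 1 + k) %% n) + 1
  acc <- turn
  for (k in c(-seq_len(window), seq_len(window))) acc <- acc + turn[idx(k)]
  cand <- abs(acc) >= min_turn
  ismax <- abs(acc) >= pmax(abs(acc)[idx(-1)], abs(acc)[idx(1)])
  which(cand & ismax)
}

# Interior angles (degrees) of a CCW polygon at each vertex, in (0, 360).
interior_angles <- function(xy) {
  n <- nrow(xy)
  prv <- xy[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- xy[c(2:n, 1), , drop = FALSE]
  v1 <- xy - prv   # incoming direction
  v2 <- nxt - xy   # outgoing direction
  turn <- atan2(v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1],
                v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2]) * 180 / pi
  180 - turn  # CCW ring: left turn shrinks the interior angle below 180
}
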