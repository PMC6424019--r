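#' Detect boundary corners and classify vertices vs notches
#'
#' Corners are polygon vertices where the local boundary direction changes
#' by more than `angle_threshold` degrees. Each corner is classified from
#' its interior angle: convex vertices have interior angle below 180
#' degrees, notches (reflex corners) above 180. Detection operates on the
#' silhouette's polygon (turning-angle criterion); for mask-derived
#' silhouettes the polygon has already been boundary-smoothed and
#' simplified, which controls the sensitivity of the vertex count.
#'
#' @param s a [silhouette()] or bare polygon matrix (CCW ring).
#' @param angle_threshold direction-change threshold in degrees, in (0, 90)
#'   (default 30).
#' @return object of class `corner_set`: list with `corners` (data.frame:
#'   `x`, `y`, `interior_angle`, `class` in vertex_convex/notch),
#'   `n_vertices`, `n_notches`, and `degenerate` (TRUE when fewer than 4
#'   corners were found, leaving the frequency of vibration undefined).
#' @export
detect_corners <- function(s, angle_threshold = 30) {
  if (!is.numeric(angle_threshold) || angle_threshold <= 0 ||
      angle_threshold >= 90)
    stopf("'angle_threshold' must be in (0, 90) degrees")
  poly <- if (inherits(s, "silhouette")) s$polygon else ensure_ccw(as.matrix(s))
  ang <- interior_angles(poly)
  turn <- abs(180 - ang)
  sel <- turn > angle_threshold
  corners <- data.frame(x = poly[sel, 1], y = poly[sel, 2],
                        interior_angle = ang[sel],
                        class = ifelse(ang[sel] > 180, "notch", "vertex_convex"))
  out <- list(corners = corners,
              n_vertices = nrow(corners),
              n_notches = sum(corners$class == "notch"),
              degenerate = nrow(corners) < 4)
  if (out$degenerate)
    warnf("fewer than 4 corners detected; the frequency of vibration is undefined for this silhouette")
  class(out) <- "corner_set"
  out
}

#' @export
print.corner_set <- function(x, ...) {
  cat(sprintf("Corner set: %d vertices of which %d notches%s\n",
              x$n_vertices, x$n_notches,
              if (x$degenerate) " (degenerate: < 4 corners)" else ""))
  invisible(x)
}
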