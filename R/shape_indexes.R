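#' Frequency of vibration of a polygon boundary
#'
#' Quartic in the normalized notch count nu = n_notches / (n_vertices - 3):
#' F = 16 (nu - 0.5)^4 - 8 (nu - 0.5)^2 + 1. F ranges over [0, 1] for nu in
#' [0, 1], vanishing at nu = 0 and nu = 1 and peaking (F = 1) at nu = 0.5,
#' and is symmetric about nu = 0.5. Corner sets detected on free-form
#' boundaries can yield nu > 1 (more notches than n_vertices - 3); the
#' formula is evaluated anyway with a warning, since the polygonal model it
#' comes from excludes that case.
#'
#' @param n_vertices total corner count (>= 4).
#' @param n_notches reflex corner count (>= 0).
#' @return frequency of vibration (unitless).
#' @examples
#' frequency_of_vibration(5, 1)   # nu = 0.5 -> 1
#' frequency_of_vibration(12, 4)  # nu = 4/9 -> 0.9755
#' @export
frequency_of_vibration <- function(n_vertices, n_notches) {
  if (any(n_vertices < 4))
    stopf("frequency of vibration undefined: n_vertices must be >= 4")
  if (any(n_notches < 0)) stopf("n_notches must be nonnegative")
  nu <- n_notches / (n_vertices - 3)
  if (any(nu > 1))
    warnf("normalized notch count exceeds 1 (%s); outside the formula's intended range",
          paste(format(nu[nu > 1]), collapse = ", "))
  16 * (nu - 0.5)^4 - 8 * (nu - 0.5)^2 + 1
}

#' Amplitude of vibration
#'
#' Relative excess of the silhouette boundary over its convex-hull
#' boundary: A = (P_s - P_h) / P_s. Zero exactly for convex shapes and
#' strictly below 1 otherwise.
#'
#' @param h a `hull_summary` from [measure_hull()] (or a list with
#'   `boundary_silhouette` and `boundary_hull`).
#' @return amplitude of vibration (unitless).
#' @export
amplitude_of_vibration <- function(h) {
  ps <- h$boundary_silhouette; ph <- h$boundary_hull
  if (any(ps <= 0)) stopf("silhouette boundary length must be positive")
  if (any(ph > ps + 1e-9 * ps))
    stopf("inconsistent geometry: hull boundary exceeds silhouette boundary")
  pmax(0, (ps - ph) / ps)
}

#' Deviation from the convex hull
#'
#' Relative area deficit of the silhouette inside its convex hull:
#' D = (A_h - A_s) / A_h. Zero exactly for convex shapes and strictly
#' below 1 otherwise.
#'
#' @param h a `hull_summary` from [measure_hull()] (or a list with
#'   `area_silhouette` and `area_hull`).
#' @return deviation from the convex hull (unitless).
#' @export
deviation_from_convex_hull <- function(h) {
  as_ <- h$area_silhouette; ah <- h$area_hull
  if (any(ah <= 0)) stopf("hull area must be positive")
  if (any(as_ > ah + 1e-9 * ah))
    stopf("inconsistent geometry: silhouette area exceeds hull area")
  pmax(0, (ah - as_) / ah)
}

#' Brinkhoff composite complexity index
#'
#' B = 0.8 * amplitude * frequency + 0.2 * deviation. Zero for convex
#' shapes, bounded below 1, and monotone nondecreasing in each component.
#'
#' @param frequency frequency of vibration in [0, 1].
#' @param amplitude amplitude of vibration in [0, 1].
#' @param deviation deviation from the convex hull in [0, 1].
#' @return Brinkhoff index (unitless).
#' @examples
#' brinkhoff_index(0.98, 0.66, 0.45)  # 0.60744
#' @export
brinkhoff_index <- function(frequency, amplitude, deviation) {
  v <- c(frequency, amplitude, deviation)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stopf("frequency, amplitude and deviation must all lie in [0, 1]")
  0.8 * amplitude * frequency + 0.2 * deviation
}

#' Secondary-fold branching index
#'
#' Skeleton branch count normalized by the number of secondary folds:
#' I_br = n_branches / n_secondary_folds. Values cluster near 2 for
#' unbranched folds, 3-4 for folds with a few branches, and 7 for highly
#' branched folds.
#'
#' @param n_branches skeleton branch count (>= 1).
#' @param n_secondary_folds number of secondary folds (>= 1), from user
#'   annotation or the synthetic generator's ground truth.
#' @return branching index (unitless).
#' @export
branching_index <- function(n_branches, n_secondary_folds) {
  if (any(n_secondary_folds < 1))
    stopf("n_secondary_folds must be >= 1 (no folds to normalize by)")
  n_branches / n_secondary_folds
}

#' Classify a branching index into the three morphological groups
#'
#' Nearest-class assignment against the cluster centres 2 (unbranched),
#' 3.5 (a few branches) and 7 (highly branched), i.e. cut points at 2.75
#' and 5.5.
#'
#' @param I_br branching index (> 0).
#' @return factor with levels `unbranched`, `few_branches`,
#'   `highly_branched`.
#' @examples
#' classify_branching(c(1.96, 3.67, 7.9))
#' @export
classify_branching <- function(I_br) {
  if (any(I_br <= 0)) stopf("branching index must be positive")
  cut(I_br, breaks = c(0, 2.75, 5.5, Inf),
      labels = c("unbranched", "few_branches", "highly_branched"),
      right = TRUE)
}

#' Estimate the secondary-fold count from the skeleton (extension)
#'
#' Counts skeleton branches incident on exactly one junction and ending in
#' an endpoint, i.e. terminal branches leaving the central axis. This is an
#' optional automatic estimator of the fold count; the branching index is
#' canonically computed against an annotated or ground-truth fold count.
#'
#' @param g a `skeleton_graph` from [skeletonize()].
#' @return estimated number of secondary folds.
#' @export
estimate_fold_count <- function(g) {
  if (nrow(g$edges) == 0) return(0L)
  ft <- cbind(g$nodes$type[g$edges$from], g$nodes$type[g$edges$to])
  sum(rowSums(ft == "endpoint", na.rm = TRUE) == 1 &
      rowSums(ft == "junction", na.rm = TRUE) == 1)
}

#' All 2D shape indexes of a silhouette
#'
#' Convenience pipeline: hull summary, skeletonization, corner detection,
#' then the dimensionless indexes.
#'
#' @param s a [silhouette()].
#' @param n_secondary_folds annotated fold count; when `NULL` the skeleton
#'   estimator [estimate_fold_count()] is used (labelled estimate).
#' @param angle_threshold corner threshold in degrees, see
#'   [detect_corners()].
#' @param prune_px spur pruning length, see [skeletonize()].
#' @return object of class `shape_indexes`: list with counts (`n_vertices`,
#'   `n_notches`, `n_branches`, `n_secondary_folds`), the four indexes
#'   (`frequency`, `amplitude`, `deviation`, `brinkhoff`), the
#'   `branching_index`, its `branching_class`, and `fold_count_estimated`.
#'   When the detected corner set leaves the polygonal model's range
#'   (fewer than 4 corners, or more notches than `n_vertices - 3` driving
#'   the frequency above 1) the frequency is reported as computed but the
#'   Brinkhoff index is `NA`.
#' @export
shape_indexes <- function(s, n_secondary_folds = NULL, angle_threshold = 30,
                          prune_px = 3) {
  h <- measure_hull(s)
  g <- skeletonize(s, prune_px = prune_px)
  cs <- detect_corners(s, angle_threshold = angle_threshold)
  estimated <- is.null(n_secondary_folds)
  if (estimated) n_secondary_folds <- max(1L, estimate_fold_count(g))
  freq <- if (cs$degenerate) NA_real_
          else frequency_of_vibration(cs$n_vertices, cs$n_notches)
  amp <- amplitude_of_vibration(h)
  dev <- deviation_from_convex_hull(h)
  b <- if (is.na(freq) || freq < 0 || freq > 1) NA_real_ else
    brinkhoff_index(freq, amp, dev)
  out <- list(
    n_vertices = cs$n_vertices, n_notches = cs$n_notches,
    n_branches = g$n_branches, n_secondary_folds = n_secondary_folds,
    frequency = freq, amplitude = amp, deviation = dev,
    brinkhoff = b,
    branching_index = branching_index(g$n_branches, n_secondary_folds),
    fold_count_estimated = estimated)
  out$branching_class <- classify_branching(out$branching_index)
  class(out) <- "shape_indexes"
  out
}

#' @export
print.shape_indexes <- function(x, ...) {
  cat("2D shape indexes\n")
  cat(sprintf("  corners: %d vertices (%d notches); skeleton branches: %d; folds: %d%s\n",
              x$n_vertices, x$n_notches, x$n_branches, x$n_secondary_folds,
              if (x$fold_count_estimated) " (estimated)" else ""))
  cat(sprintf("  frequency %.2f, amplitude %.2f, deviation %.2f -> Brinkhoff %.2f\n",
              x$frequency, x$amplitude, x$deviation, x$brinkhoff))
  cat(sprintf("  branching index %.2f (%s)\n", x$branching_index,
              as.character(x$branching_class)))
  invisible(x)
}
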