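#' Silhouette of a primary olfactory lamella
#'
#' A `silhouette` bundles the two representations of one sectioned primary
#' lamella with its secondary folds: a binary raster mask (optional) and a
#' simple closed polygon in physical units (mm). The polygon is stored as an
#' open counter-clockwise vertex ring. All downstream shape statistics
#' (convex-hull summaries, skeleton branch counts, corner classification)
#' operate on this object.
#'
#' @param polygon two-column matrix or data.frame of vertices in mm; the
#'   closing vertex may be repeated or omitted.
#' @param mask logical or 0/1 matrix, `TRUE`/nonzero = lamella tissue;
#'   optional when a polygon is given.
#' @param scale physical pixel size in mm per pixel (must be > 0).
#' @param id specimen/lamella label.
#' @param holes_filled flag recording whether interior holes were filled
#'   during normalization.
#' @param check validate polygon simplicity (segment-intersection test);
#'   disable for large machine-generated boundaries that are simple by
#'   construction.
#' @return object of class `silhouette` with elements `polygon`, `mask`,
#'   `scale`, `id`, `holes_filled`.
#' @export
silhouette <- function(polygon, mask = NULL, scale = 1, id = NULL,
                       holes_filled = FALSE, check = TRUE) {
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) || scale <= 0)
    stopf("'scale' must be a single positive number (mm per pixel), got %s",
          format(scale))
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  dimnames(polygon) <- NULL
  if (ncol(polygon) != 2) stopf("polygon must have two columns (x, y)")
  polygon <- dedup_ring(polygon)
  if (nrow(polygon) < 3) stopf("polygon needs at least 3 distinct vertices")
  if (check && !polygon_is_simple(polygon))
    stopf("polygon is self-intersecting; silhouettes must be simple closed curves")
  polygon <- ensure_ccw(polygon)
  if (polygon_area(polygon) <= 0) stopf("degenerate silhouette: zero area")
  if (!is.null(mask)) {
    mask <- mask != 0
    if (!any(mask)) stopf("mask has no foreground pixels")
  }
  structure(list(polygon = polygon, mask = mask, scale = scale,
                 id = id, holes_filled = holes_filled),
            class = "silhouette")
}

#' @export
print.silhouette <- function(x, ...) {
  cat("Lamella silhouette", if (!is.null(x$id)) sprintf("'%s'", x$id), "\n")
  cat(sprintf("  polygon: %d vertices, area %.4g mm^2, perimeter %.4g mm\n",
              nrow(x$polygon), polygon_area(x$polygon),
              polygon_perimeter(x$polygon)))
  if (!is.null(x$mask))
    cat(sprintf("  mask: %d x %d px at %.4g mm/px%s\n", nrow(x$mask),
                ncol(x$mask), x$scale,
                if (x$holes_filled) " (holes filled)" else ""))
  invisible(x)
}

# ---- mask utilities ---------------------------------------------------------

# Label 8-connected foreground components by iterative frontier expansion.
count_components <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask)
  todo <- which(mask)
  comp <- 0L
  offs <- if (connectivity == 8) {
    c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  } else c(-1L, 1L, -nr, nr)
  npix <- length(mask)
  row_of <- function(i) ((i - 1L) %% nr) + 1L
  while (length(todo)) {
    seed <- todo[1]
    comp <- comp + 1L
    frontier <- seed
    lab[seed] <- comp
    while (length(frontier)) {
      # guard row wrap-around across matrix columns
      rs <- row_of(rep(frontier, times = length(offs)))
      cand_all <- as.vector(outer(frontier, offs, `+`))
      dr <- abs(row_of(pmin(pmax(cand_all, 1L), npix)) - rs)
      ok <- cand_all >= 1L & cand_all <= npix & dr <= 1L
      cand <- unique(cand_all[ok])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- comp
      frontier <- cand
    }
    todo <- todo[lab[todo] == 0L]
  }
  list(n = comp, labels = lab)
}

# Fill interior holes: background components not reachable from the border.
fill_holes <- function(mask) {
  bg <- !mask
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  border <- unique(c(which(bg[1, ]) * nr - nr + 1L,
                     which(bg[nr, ]) * nr,
                     which(bg[, 1]),
                     (nc - 1L) * nr + which(bg[, nc])))
  border <- border[bg[border]]
  frontier <- border
  reach[frontier] <- TRUE
  offs <- c(-1L, 1L, -nr, nr)  # 4-connectivity for background keeps duality
  npix <- nr * nc
  row_of <- function(i) ((i - 1L) %% nr) + 1L
  while (length(frontier)) {
    cand_all <- as.vector(outer(frontier, offs, `+`))
    rs <- row_of(rep(frontier, times = length(offs)))
    dr <- abs(row_of(pmin(pmax(cand_all, 1L), npix)) - rs)
    ok <- cand_all >= 1L & cand_all <= npix & dr <= 1L
    cand <- unique(cand_all[ok])
    cand <- cand[bg[cand] & !reach[cand]]
    reach[cand] <- TRUE
    frontier <- cand
  }
  holes <- bg & !reach
  list(mask = mask | holes, n_hole_px = sum(holes))
}

#' Trace the boundary polygon of a binary mask
#'
#' Marching-squares contour at the 0.5 level (pixel centres at integer
#' coordinates), followed by Gaussian boundary smoothing and
#' Ramer-Douglas-Peucker simplification. Smoothing and simplification
#' stabilize the perimeter against pixel staircase inflation, which would
#' otherwise bias the amplitude of vibration upward.
#'
#' @param mask binary matrix (rows = y, columns = x).
#' @param scale mm per pixel.
#' @param simplify_tol simplification tolerance in pixels (default 0.5).
#' @param smooth_sigma Gaussian sigma in pixels applied to the dense
#'   boundary before simplification (default 2); 0 disables.
#' @return open CCW polygon matrix in mm.
#' @export
mask_to_polygon <- function(mask, scale = 1, simplify_tol = 0.5, smooth_sigma = 2) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- mask * 1
  # contourLines treats z[i, j] with x along i: feed t(z) so x = column index
  cl <- grDevices::contourLines(x = 0:(nc + 1), y = 0:(nr + 1), z = t(z),
                                levels = 0.5)
  if (!length(cl)) stopf("empty mask: no boundary at the 0.5 level")
  areas <- vapply(cl, function(cc) polygon_area(cbind(cc$x, cc$y)), 0)
  ring <- cl[[which.max(areas)]]
  xy <- dedup_ring(cbind(ring$x, ring$y))
  xy <- smooth_ring(xy, smooth_sigma)
  xy <- simplify_ring(xy, simplify_tol, extra_anchors = corner_anchors(xy))
  ensure_ccw(dedup_ring(xy)) * scale
}

#' Rasterize a polygon to a binary mask
#'
#' Even-odd scanline fill; a pixel (row r, column c) is foreground when its
#' centre (x = c, y = r in pixel units) lies inside the polygon.
#'
#' @param polygon open vertex ring in mm.
#' @param scale mm per pixel.
#' @param pad background margin in pixels around the shape.
#' @return list with `mask` (logical matrix) and `origin` (mm offset of
#'   pixel (1,1) centre).
#' @export
polygon_to_mask <- function(polygon, scale, pad = 2) {
  p <- polygon / scale
  ox <- floor(min(p[, 1])) - pad
  oy <- floor(min(p[, 2])) - pad
  p[, 1] <- p[, 1] - ox
  p[, 2] <- p[, 2] - oy
  nc <- ceiling(max(p[, 1])) + pad
  nr <- ceiling(max(p[, 2])) + pad
  mask <- matrix(FALSE, nr, nc)
  n <- nrow(p)
  x1 <- p[, 1]; y1 <- p[, 2]
  x2 <- p[c(2:n, 1), 1]; y2 <- p[c(2:n, 1), 2]
  for (r in seq_len(nr)) {
    y <- r
    crosses <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(crosses)) next
    xs <- x1[crosses] + (y - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (x2[crosses] - x1[crosses])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      lo <- ceiling(xs[k]); hi <- floor(xs[k + 1])
      if (xs[k + 1] == floor(xs[k + 1])) hi <- hi - 1  # right-open spans
      if (hi >= lo && hi >= 1 && lo <= nc)
        mask[r, max(1, lo):min(nc, hi)] <- TRUE
    }
  }
  list(mask = mask, origin = c(ox, oy) * scale)
}

#' Load a silhouette from a raster image or polygon CSV
#'
#' PNG/TIFF rasters must be single-channel binary-interpretable images
#' (0 = background, nonzero = lamella). Polygon files are CSV with header
#' `x_mm,y_mm`, one vertex per row, implicit closure. Masks are normalized:
#' exactly one 8-connected foreground component is required, interior holes
#' are filled with a warning, and the boundary polygon is extracted by
#' marching squares.
#'
#' @param path file path ending in `.png`, `.tif(f)` or `.csv`.
#' @param scale mm per pixel (rasters only; default 1).
#' @param simplify_tol,smooth_sigma see [mask_to_polygon()].
#' @return a [silhouette()].
#' @export
load_silhouette <- function(path, scale = 1, simplify_tol = 0.5, smooth_sigma = 2) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    d <- utils::read.csv(path)
    if (!all(c("x_mm", "y_mm") %in% names(d)))
      stopf("polygon CSV must have columns 'x_mm' and 'y_mm'")
    if (nrow(d) < 3) stopf("polygon CSV needs at least 3 vertices")
    return(silhouette(cbind(d$x_mm, d$y_mm), scale = scale,
                      id = basename(path)))
  }
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported silhouette format '.%s' (png, tiff or csv)", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  vals <- sort(unique(as.vector(img)))
  if (length(vals) > 2)
    stopf("raster is not binary-interpretable: %d grey levels", length(vals))
  mask_from_raw(img > min(vals), scale, id = basename(path),
                simplify_tol = simplify_tol, smooth_sigma = smooth_sigma)
}

# Normalize a raw logical mask into a silhouette.
mask_from_raw <- function(mask, scale, id = NULL, simplify_tol = 0.5,
                          smooth_sigma = 2) {
  if (!any(mask)) stopf("mask has no foreground pixels")
  comps <- count_components(mask)
  if (comps$n != 1)
    stopf("mask must contain exactly one connected component, found %d",
          comps$n)
  filled <- fill_holes(mask)
  if (filled$n_hole_px > 0)
    warnf("filled %d interior hole pixel(s); the analysis concerns the outer epithelial boundary",
          filled$n_hole_px)
  poly <- mask_to_polygon(filled$mask, scale, simplify_tol, smooth_sigma)
  silhouette(poly, mask = filled$mask, scale = scale, id = id,
             holes_filled = filled$n_hole_px > 0, check = FALSE)
}

#' Coerce a binary matrix to a silhouette
#'
#' @inheritParams mask_to_polygon
#' @param id optional label.
#' @return a [silhouette()].
#' @export
as_silhouette <- function(mask, scale = 1, id = NULL, simplify_tol = 0.5,
                          smooth_sigma = 2) {
  mask_from_raw(mask != 0, scale, id, simplify_tol, smooth_sigma)
}

# ---- hull summary -----------------------------------------------------------

#' Convex-hull summary of a silhouette
#'
#' Measures the four quantities entering the vibration amplitude and the
#' hull deviation: silhouette perimeter and area, convex-hull perimeter and
#' area. For any simple polygon the hull perimeter is a lower bound on the
#' silhouette perimeter and the hull area an upper bound on the silhouette
#' area, with equality exactly for convex shapes.
#'
#' @param s a [silhouette()] (or a bare polygon matrix).
#' @return object of class `hull_summary`: list with `boundary_silhouette`,
#'   `boundary_hull` (mm), `area_silhouette`, `area_hull` (mm^2).
#' @export
measure_hull <- function(s) {
  poly <- if (inherits(s, "silhouette")) s$polygon else ensure_ccw(as.matrix(s))
  a_s <- polygon_area(poly)
  if (a_s <= 0) stopf("degenerate silhouette: zero area")
  hull <- convex_hull(poly)
  out <- list(boundary_silhouette = polygon_perimeter(poly),
              boundary_hull = polygon_perimeter(hull),
              area_silhouette = a_s,
              area_hull = polygon_area(hull))
  class(out) <- "hull_summary"
  out
}

#' @export
print.hull_summary <- function(x, ...) {
  cat(sprintf("Hull summary: P_s %.4g, P_h %.4g mm; A_s %.4g, A_h %.4g mm^2\n",
              x$boundary_silhouette, x$boundary_hull,
              x$area_silhouette, x$area_hull))
  invisible(x)
}
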