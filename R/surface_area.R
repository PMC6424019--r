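#' Gross olfactory surface area, round raphe
#'
#' For a round raphe all primary lamellae are of comparable size, so the
#' organ's gross (fold-ignoring) epithelial area is the one-face area of a
#' representative largest mid-organ lamella times two faces times the
#' lamellar number: S_gross = 2 * a_L * LN.
#'
#' @param a_L one-face surface area of a largest mid-organ lamella (mm^2).
#' @param LN lamellar number (count of primary lamellae, >= 1).
#' @param raphe raphe type of the specimen; calling this on an elongated
#'   raphe is an error (use [gross_area_elongated()]).
#' @return gross surface area (mm^2).
#' @examples
#' gross_area_round(12.5, 34)  # 850
#' gross_area_round(33.5, 34)  # 2278
#' @export
gross_area_round <- function(a_L, LN, raphe = "round") {
  if (!all(raphe == "round"))
    stopf("round-raphe formula called on an elongated-raphe specimen")
  if (any(a_L <= 0)) stopf("a_L must be positive")
  if (any(LN < 1)) stopf("lamellar number must be >= 1")
  2 * a_L * LN
}

#' Gross olfactory surface area, elongated raphe
#'
#' Elongated (linear or bent) raphes carry large central and small
#' peripheral lamellae, so the gross area weights the two measured
#' lamellae: S_gross = 2 a_L (w_max LN) + 2 a_S ((1 - w_max) LN). The
#' default weight w_max = 0.7 averages the two raphe-shape presets, 0.6
#' for a bent raphe (which under-weights the large lamellae) and 0.8 for a
#' linear raphe.
#'
#' @param a_L one-face area of a largest mid-organ lamella (mm^2).
#' @param a_S one-face area of a smallest peripheral lamella (mm^2,
#'   a_S <= a_L).
#' @param LN lamellar number.
#' @param w_max fraction of LN attributed to largest-lamella-sized
#'   lamellae, in (0, 1); default 0.7, presets 0.6 (bent) and 0.8 (linear).
#' @return gross surface area (mm^2).
#' @examples
#' gross_area_elongated(10, 2, 50)             # 760
#' gross_area_elongated(10, 2, 50, w_max = 0.8) # 860
#' @export
gross_area_elongated <- function(a_L, a_S, LN, w_max = 0.7) {
  if (anyNA(c(a_L, a_S, LN, w_max)))
    stopf("a_L, a_S and LN must all be given (a_S is required for an elongated raphe)")
  if (any(w_max <= 0) || any(w_max >= 1)) stopf("w_max must lie in (0, 1)")
  if (any(a_S > a_L)) stopf("a_S must not exceed a_L")
  if (any(a_L <= 0) || any(a_S <= 0)) stopf("lamella areas must be positive")
  if (any(LN < 1)) stopf("lamellar number must be >= 1")
  2 * a_L * (w_max * LN) + 2 * a_S * ((1 - w_max) * LN)
}

#' Percentage increase of epithelial length due to secondary folds
#'
#' Compares the straight-line (linear) length of a sectioned primary
#' lamella with its semi-boundary, the epithelial contour along one face
#' including the secondary folds: p = 100 (L_semi - L_lin) / L_lin. Both
#' faces carry the same factor, so the one-face percentage applies to the
#' two-faced gross area.
#'
#' @param L_lin linear length of the primary lamella in section (mm, > 0).
#' @param L_semi semi-boundary including secondary folds (mm,
#'   >= `L_lin`).
#' @return percentage increase.
#' @examples
#' pct_increase(10, 21.4)  # 114
#' @export
pct_increase <- function(L_lin, L_semi) {
  if (any(L_lin <= 0)) stopf("linear length must be positive")
  if (any(L_semi < L_lin))
    stopf("semi-boundary cannot be shorter than the linear length")
  100 * (L_semi - L_lin) / L_lin
}

#' Per-specimen percentage increase: mean and standard deviation
#'
#' The percentage increase is measured on several lamellae per specimen
#' (canonically four) and summarized by the arithmetic mean and the sample
#' standard deviation.
#'
#' @param L_lin,L_semi numeric vectors of per-lamella linear lengths and
#'   semi-boundaries (same length, >= 2 pairs).
#' @return list with `mean`, `sd`, `n`, and the per-lamella `percent`
#'   vector.
#' @examples
#' specimen_pct_increase(c(10, 10, 10, 10), c(16, 17, 18, 19))
#' @export
specimen_pct_increase <- function(L_lin, L_semi) {
  if (length(L_lin) != length(L_semi))
    stopf("L_lin and L_semi must have the same length")
  if (length(L_lin) < 2)
    stopf("at least 2 lamellae are required (sd undefined for fewer)")
  p <- pct_increase(L_lin, L_semi)
  list(mean = mean(p), sd = stats::sd(p), n = length(p), percent = p)
}

#' Fold-inclusive surface area
#'
#' Scales the gross surface area by the specimen's average percentage
#' increase: S_folds = S_gross * (1 + p / 100).
#'
#' @param S_gross gross surface area (mm^2).
#' @param p average percentage increase due to secondary folds (>= 0).
#' @return surface area including secondary folds (mm^2).
#' @examples
#' area_with_folds(850, 114)   # 1819
#' area_with_folds(2278, 464)  # 12847.92
#' @export
area_with_folds <- function(S_gross, p) {
  if (any(p < 0)) stopf("percentage increase must be nonnegative")
  S_gross * (1 + p / 100)
}

#' Size-normalized surface area
#'
#' Relative surface area for comparison across body sizes:
#' 100 * S / size^2 with S in mm^2 and size in cm (disk width for batoids,
#' total length otherwise). The mixed mm^2/cm^2 units are the convention of
#' the source measurement tables and are preserved as such.
#'
#' @param S surface area (mm^2).
#' @param size body size (cm, > 0).
#' @param size_kind optional size-kind labels (`"TL"`, `"SL"`, `"DW"`);
#'   supplying a mix triggers a warning since normalized areas are only
#'   comparable within one size kind.
#' @return normalized area (unitless, reported x100).
#' @examples
#' normalize_area(1819, 52)  # 67.27
#' @export
normalize_area <- function(S, size, size_kind = NULL) {
  if (any(size <= 0)) stopf("size must be positive")
  if (!is.null(size_kind) && length(unique(size_kind)) > 1)
    warnf("mixed size kinds (%s): normalized areas are not comparable across kinds",
          paste(unique(size_kind), collapse = ", "))
  100 * S / size^2
}

#' Recompute all derived surface-area columns of a measurement table
#'
#' Takes a per-specimen measurement table (one row per specimen) and
#' recomputes gross area, per-specimen percentage increase, fold-inclusive
#' area and both normalized areas at full precision.
#'
#' @param measurements data.frame with columns `id`, `size_cm`,
#'   `size_kind`, `raphe_type` (`"round"`/`"elongated"`),
#'   `lamellar_number`, `area_largest_mm2`, `area_smallest_mm2` (may be NA
#'   for round raphes), optional `w_max`, and four pairs
#'   `L_lin_1..4`/`L_semi_1..4` (mm).
#' @return data.frame with the input identification columns plus
#'   `S_gross`, `pct_mean`, `pct_sd`, `S_folds`, `norm_gross`,
#'   `norm_folds`, `norm_largest`.
#' @export
surface_area_table <- function(measurements) {
  m <- measurements
  need <- c("id", "size_cm", "size_kind", "raphe_type", "lamellar_number",
            "area_largest_mm2")
  miss <- setdiff(need, names(m))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  lin <- as.matrix(m[, grep("^L_lin_", names(m)), drop = FALSE])
  semi <- as.matrix(m[, grep("^L_semi_", names(m)), drop = FALSE])
  if (ncol(lin) < 2 || !all(dim(lin) == dim(semi)))
    stopf("need matching L_lin_i / L_semi_i columns (>= 2 pairs)")
  w <- if ("w_max" %in% names(m)) ifelse(is.na(m$w_max), 0.7, m$w_max) else
    rep(0.7, nrow(m))
  S_gross <- ifelse(
    m$raphe_type == "round",
    gross_area_round(m$area_largest_mm2, m$lamellar_number),
    gross_area_elongated(m$area_largest_mm2,
                         ifelse(is.na(m$area_smallest_mm2),
                                m$area_largest_mm2, m$area_smallest_mm2),
                         m$lamellar_number, w))
  pcts <- t(vapply(seq_len(nrow(m)), function(i) {
    r <- specimen_pct_increase(lin[i, ], semi[i, ])
    c(r$mean, r$sd)
  }, c(0, 0)))
  S_folds <- area_with_folds(S_gross, pcts[, 1])
  data.frame(
    id = m$id, size_cm = m$size_cm, size_kind = m$size_kind,
    raphe_type = m$raphe_type, lamellar_number = m$lamellar_number,
    S_gross = S_gross, pct_mean = pcts[, 1], pct_sd = pcts[, 2],
    S_folds = S_folds,
    norm_largest = normalize_area(m$area_largest_mm2, m$size_cm),
    norm_gross = normalize_area(S_gross, m$size_cm),
    norm_folds = normalize_area(S_folds, m$size_cm))
}

#' Grouped bar chart of normalized gross vs fold-inclusive areas
#'
#' Two bars per specimen (normalized gross area and normalized
#' fold-inclusive area); the fold-inclusive bar carries an error bar from
#' the standard deviation of the percentage increase.
#'
#' @param tab output of [surface_area_table()].
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot_normalized_areas <- function(tab, ...) {
  hts <- rbind(tab$norm_gross, tab$norm_folds)
  err <- normalize_area(tab$S_gross * tab$pct_sd / 100, tab$size_cm)
  mid <- graphics::barplot(hts, beside = TRUE, names.arg = tab$id,
                           col = c("grey85", "grey40"),
                           ylab = "100 * area / size^2",
                           ylim = c(0, max(hts[2, ] + err) * 1.05), ...)
  graphics::arrows(mid[2, ], tab$norm_folds - err, mid[2, ],
                   tab$norm_folds + err,
                   angle = 90, code = 3, length = 0.03)
  graphics::legend("topleft", fill = c("grey85", "grey40"),
                   legend = c("gross", "with secondary folds"), bty = "n")
  invisible(mid)
}
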