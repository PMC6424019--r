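#' Specification of a synthetic lamella silhouette
#'
#' Parameter record for the generator. A lamella is modelled as a stadium
#' body (rectangle with semicircular caps) with `n_folds` rounded
#' rectangular secondary folds protruding normally from one long side;
#' branches are child protrusions from the fold sides (depth 1: one branch
#' near the tip; depth 2: a second branch lower on the opposite side).
#' This reproduces the three morphologies seen in sectioned lamellae -
#' short unbranched, long dense unbranched, and branched folds - with
#' three knobs (fold count, fold length, branch depth).
#'
#' @param body_length_mm,body_width_mm stadium body dimensions (mm).
#' @param n_folds number of secondary folds along the dorsal side.
#' @param fold_length_mm,fold_width_mm nominal fold dimensions (mm).
#' @param branch_depth 0 (unbranched), 1 or 2 child protrusions per
#'   branching fold.
#' @param branch_prob probability that a given fold carries branches.
#' @param jitter_sd relative s.d. of multiplicative jitter on fold lengths
#'   and positions.
#' @param px_per_mm raster resolution.
#' @param cap_segments chords per semicircular cap.
#' @param seed integer seed; generation is fully deterministic per seed.
#' @return object of class `lamella_spec`.
#' @export
lamella_spec <- function(body_length_mm = 12, body_width_mm = 1.6,
                         n_folds = 8, fold_length_mm = 2,
                         fold_width_mm = 0.3, branch_depth = 0,
                         branch_prob = 1, jitter_sd = 0.05,
                         px_per_mm = 20, cap_segments = 10, seed = 1) {
  stopifnot(body_length_mm > 0, body_width_mm > 0, n_folds >= 0,
            fold_length_mm >= 0, fold_width_mm > 0,
            branch_depth %in% 0:2, branch_prob >= 0, branch_prob <= 1,
            jitter_sd >= 0, px_per_mm > 0, cap_segments >= 6)
  structure(as.list(environment()), class = "lamella_spec")
}

# Semicircular cap arc from angle a0 to a1 (radians) around centre (cx, cy),
# excluding the end points (the straight sides supply those).
cap_arc <- function(cx, cy, r, a0, a1, k) {
  th <- seq(a0, a1, length.out = k + 1)[2:k]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Rounded protrusion from (x - w/2) to (x + w/2) on baseline y0, pointing up
# (dir = +1) or down (dir = -1), of total length len, traversed so that the
# interior stays on the left. side_branches: list of (height_frac, len, w,
# side) stubs; side +1 = the side met first when ascending (right for an
# upward fold).
protrusion_path <- function(x, y0, len, w, dir, k, branches = list()) {
  r <- w / 2
  tipy <- y0 + dir * len
  up_side_x <- x + r    # ascended first for dir = +1 (walking right-to-left)
  dn_side_x <- x - r
  path <- list()
  yy <- y0
  asc <- Filter(function(b) b$side > 0, branches)
  dsc <- Filter(function(b) b$side < 0, branches)
  asc <- asc[order(vapply(asc, `[[`, 0, "h"))]
  dsc <- dsc[order(-vapply(dsc, `[[`, 0, "h"))]
  add <- function(p) path[[length(path) + 1L]] <<- p
  add(cbind(up_side_x, y0))
  for (b in asc) {
    by <- y0 + dir * b$h
    rb <- b$w / 2
    bx <- up_side_x
    tip <- bx + b$len
    add(cbind(bx, by - dir * rb))
    add(cbind(tip - rb, by - dir * rb))
    add(cap_arc(tip - rb, by, rb, -dir * pi / 2, dir * pi / 2, 8))
    add(cbind(tip - rb, by + dir * rb))
    add(cbind(bx, by + dir * rb))
  }
  add(cbind(up_side_x, tipy - dir * r))
  add(cap_arc(x, tipy - dir * r, r, if (dir > 0) 0 else pi,
              if (dir > 0) pi else 2 * pi, k))
  add(cbind(dn_side_x, tipy - dir * r))
  for (b in dsc) {
    by <- y0 + dir * b$h
    rb <- b$w / 2
    bx <- dn_side_x
    tip <- bx - b$len
    add(cbind(bx, by + dir * rb))
    add(cbind(tip + rb, by + dir * rb))
    add(cap_arc(tip + rb, by, rb, dir * pi / 2, 3 * dir * pi / 2 -
                  if (dir > 0) 0 else 2 * pi, 8))
    add(cbind(tip + rb, by - dir * rb))
    add(cbind(bx, by - dir * rb))
  }
  add(cbind(dn_side_x, y0))
  do.call(rbind, path)
}

#' Generate a synthetic lamella silhouette with ground truth
#'
#' Builds the polygon analytically, rasterizes it, and returns both with a
#' ground-truth record: exact polygon area and perimeter (shoelace), fold
#' count, per-fold branch counts, the expected skeleton branch count
#' (one axis segment per fold interval plus, per fold with b branches,
#' 2 b + 1 segments), and the expected notch count (two reflex corners per
#' fold base and per branch base). Geometry violating the fold-spacing
#' constraint is re-jittered; after 100 failed attempts an error names the
#' violated constraint.
#'
#' @param spec a [lamella_spec()].
#' @return list with `silhouette` (a [silhouette()] carrying polygon and
#'   mask) and `truth`.
#' @export
make_lamella <- function(spec) {
  stopifnot(inherits(spec, "lamella_spec"))
  set.seed(substream_seed(spec$seed, 1))
  L <- spec$body_length_mm; W <- spec$body_width_mm
  r <- W / 2
  k <- spec$cap_segments
  F_ <- spec$n_folds
  have_folds <- F_ > 0 && spec$fold_length_mm > 0
  for (attempt in seq_len(100)) {
    branches_per_fold <- integer(0)
    folds <- list()
    if (have_folds) {
      x0 <- r + 0.5; x1 <- L - r - 0.5
      if (x1 <= x0) stopf("body too short for the requested folds")
      spacing <- (x1 - x0) / F_
      gap <- spacing - spec$fold_width_mm
      if (gap <= 0)
        stopf("infeasible geometry: fold width %.3g exceeds fold spacing %.3g",
              spec$fold_width_mm, spacing)
      len_i <- spec$fold_length_mm *
        pmax(0.3, 1 + stats::rnorm(F_, 0, spec$jitter_sd))
      xc <- x0 + (seq_len(F_) - 0.5) * spacing +
        stats::rnorm(F_, 0, spec$jitter_sd * spacing / 2)
      branching <- spec$branch_depth > 0 &
        stats::runif(F_) < spec$branch_prob
      bl <- min(0.4 * spec$fold_length_mm, 0.45 * gap)
      bw <- 0.7 * spec$fold_width_mm
      for (i in seq_len(F_)) {
        bs <- list()
        if (branching[i] && bl > bw) {
          bs[[1]] <- list(h = 0.65 * len_i[i], len = bl, w = bw, side = 1)
          if (spec$branch_depth >= 2)
            bs[[2]] <- list(h = 0.4 * len_i[i], len = bl, w = bw, side = -1)
        }
        folds[[i]] <- list(x = xc[i], len = len_i[i], branches = bs)
        branches_per_fold[i] <- length(bs)
      }
    }
    # walk CCW (y up): bottom edge, right cap, top edge right-to-left with
    # folds, left cap
    pieces <- list(cbind(c(r, L - r), c(0, 0)))
    pieces[[2]] <- cap_arc(L - r, r, r, -pi / 2, pi / 2, k)
    pieces[[3]] <- cbind(L - r, W)
    if (have_folds) {
      for (i in rev(seq_along(folds))) {
        f <- folds[[i]]
        pieces[[length(pieces) + 1L]] <-
          protrusion_path(f$x, W, f$len, spec$fold_width_mm, +1, k,
                          f$branches)
      }
    }
    pieces[[length(pieces) + 1L]] <- cbind(r, W)
    pieces[[length(pieces) + 1L]] <- cap_arc(r, r, r, pi / 2, 3 * pi / 2, k)
    poly <- dedup_ring(do.call(rbind, pieces))
    if (polygon_is_simple(poly)) break
    if (attempt == 100)
      stopf("infeasible geometry after 100 retries: folds/branches self-intersect at spacing %.3g mm",
            if (have_folds) spacing else NA)
  }
  scale <- 1 / spec$px_per_mm
  ras <- polygon_to_mask(poly, scale)
  sil <- silhouette(poly, mask = ras$mask, scale = scale,
                    id = sprintf("synthetic_seed%d", spec$seed),
                    check = FALSE)
  nb <- branches_per_fold
  truth <- list(
    n_folds = if (have_folds) F_ else 0L,
    branches_per_fold = nb,
    expected_branches = if (have_folds) (F_ + 1L) + sum(2L * nb + 1L) else 1L,
    expected_notches = if (have_folds) 2L * F_ + 2L * sum(nb) else 0L,
    polygon_area = polygon_area(poly),
    polygon_perimeter = polygon_perimeter(poly),
    mask_origin = ras$origin,
    spec = spec)
  list(silhouette = sil, truth = truth)
}

#' Specification for a synthetic measurement table
#'
#' Per-specimen parameter table for [make_measurement_table()]. The default
#' regime mirrors the published study conditions: the 16 specimens'
#' printed sizes, raphe types, lamellar numbers, largest-lamella areas and
#' percentage-increase means/standard deviations are used as the
#' generating truth (recycled when more specimens are requested).
#'
#' @param params data.frame with columns `id`, `size_cm`, `size_kind`,
#'   `raphe_type`, `lamellar_number`, `area_largest_mm2`, `true_p`,
#'   `true_sd`; defaults to the published table.
#' @param a_S_ratio smallest/largest lamella area ratio for elongated
#'   raphes (default 0.2).
#' @param n_lamellae sectioned lamellae measured per specimen (default 4).
#' @param noise_scale multiplier on `true_sd` (0 gives exact recovery).
#' @param seed integer seed.
#' @return object of class `measurement_spec`.
#' @export
measurement_spec <- function(params = NULL, a_S_ratio = 0.2, n_lamellae = 4,
                             noise_scale = 1, seed = 1) {
  if (is.null(params)) {
    m <- study_measurements()
    params <- data.frame(id = m$id, size_cm = m$size_cm,
                         size_kind = m$size_kind, raphe_type = m$raphe_type,
                         lamellar_number = m$lamellar_number,
                         area_largest_mm2 = m$area_largest_mm2,
                         true_p = m$pct_mean_pub, true_sd = m$pct_sd_pub)
  }
  structure(list(params = params, a_S_ratio = a_S_ratio,
                 n_lamellae = n_lamellae, noise_scale = noise_scale,
                 seed = seed),
            class = "measurement_spec")
}

#' Generate a synthetic per-specimen measurement table
#'
#' Draws, for each specimen, `n_lamellae` sectioned lamellae with linear
#' lengths around 2 mm and semi-boundaries
#' `L_semi = L_lin (1 + p_i / 100)` where the per-lamella percentage
#' `p_i ~ N(true_p, noise_scale * true_sd)` (truncated at 0): the
#' multiplicative noise model of fold-driven epithelial lengthening. Each
#' specimen uses its own seed substream, so adding specimens never
#' perturbs earlier ones.
#'
#' @param spec a [measurement_spec()].
#' @param n_specimens number of rows to generate (default: all rows of the
#'   parameter table).
#' @return list with `measurements` (data.frame consumable by
#'   [surface_area_table()] and [tukey_matrix()]) and `truth` (per-specimen
#'   generating values including `true_S_gross`).
#' @export
make_measurement_table <- function(spec, n_specimens = nrow(spec$params)) {
  stopifnot(inherits(spec, "measurement_spec"))
  if (n_specimens < 2) stopf("need at least 2 specimens")
  idx <- rep_len(seq_len(nrow(spec$params)), n_specimens)
  pars <- spec$params[idx, , drop = FALSE]
  pars$id <- make.unique(as.character(pars$id), sep = "_r")
  nl <- spec$n_lamellae
  rows <- vector("list", n_specimens)
  for (i in seq_len(n_specimens)) {
    set.seed(substream_seed(spec$seed, i))
    L_lin <- exp(stats::rnorm(nl, log(2), 0.2))
    p_i <- pmax(0, stats::rnorm(nl, pars$true_p[i],
                                spec$noise_scale * pars$true_sd[i]))
    L_semi <- L_lin * (1 + p_i / 100)
    row <- data.frame(id = pars$id[i], size_cm = pars$size_cm[i],
                      size_kind = pars$size_kind[i],
                      raphe_type = pars$raphe_type[i],
                      lamellar_number = pars$lamellar_number[i],
                      area_largest_mm2 = pars$area_largest_mm2[i],
                      area_smallest_mm2 = if (pars$raphe_type[i] == "round")
                        NA_real_ else spec$a_S_ratio * pars$area_largest_mm2[i])
    for (j in seq_len(nl)) {
      row[[paste0("L_lin_", j)]] <- L_lin[j]
      row[[paste0("L_semi_", j)]] <- L_semi[j]
    }
    rows[[i]] <- row
  }
  meas <- do.call(rbind, rows)
  truth <- data.frame(
    id = pars$id, true_p = pars$true_p, true_sd = pars$true_sd,
    true_S_gross = ifelse(
      pars$raphe_type == "round",
      2 * pars$area_largest_mm2 * pars$lamellar_number,
      gross_area_elongated(pars$area_largest_mm2,
                           spec$a_S_ratio * pars$area_largest_mm2,
                           pars$lamellar_number, 0.7)))
  list(measurements = meas, truth = truth)
}

#' Simulate Brownian-motion traits on a tree
#'
#' Draws a specimens-by-traits matrix from the matrix-normal model with
#' row covariance C (the tree's Brownian covariance) and column covariance
#' `Sigma`: X = C^{1/2} Z Sigma^{1/2}.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param Sigma trait covariance matrix (PSD, m x m).
#' @param seed integer seed.
#' @return numeric matrix, tips x traits, rownames = tip labels.
#' @export
simulate_brownian_traits <- function(tree, Sigma, seed = 1) {
  Sigma <- as.matrix(Sigma)
  es <- eigen(Sigma, symmetric = TRUE)
  if (any(es$values < -1e-8 * max(abs(es$values))))
    stopf("Sigma is not positive semi-definite")
  sqS <- es$vectors %*% diag(sqrt(pmax(es$values, 0)),
                             ncol(Sigma)) %*% t(es$vectors)
  C <- phylo_covariance(tree)
  ec <- eigen(C, symmetric = TRUE)
  sqC <- ec$vectors %*% diag(sqrt(pmax(ec$values, 0)),
                             nrow(C)) %*% t(ec$vectors)
  set.seed(substream_seed(seed, 1))
  Z <- matrix(stats::rnorm(nrow(C) * ncol(Sigma)), nrow(C), ncol(Sigma))
  X <- sqC %*% Z %*% sqS
  rownames(X) <- rownames(C)
  colnames(X) <- colnames(Sigma) %||% paste0("trait", seq_len(ncol(Sigma)))
  X
}
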