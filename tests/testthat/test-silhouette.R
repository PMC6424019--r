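test_that("polygon silhouettes are normalized to simple CCW rings", {
  s <- silhouette(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))  # given CW
  expect_gt(polygon_signed_area(s$polygon), 0)
  expect_equal(polygon_area(s$polygon), 1)
  # repeated closing vertex is dropped
  s2 <- silhouette(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)))
  expect_equal(nrow(s2$polygon), 4)
  expect_error(silhouette(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               "self-intersecting")
  expect_error(silhouette(unit_square(), scale = 0), "positive")
  expect_error(silhouette(rbind(c(0, 0), c(1, 0))), "3 distinct")
})

test_that("CSV loading gives the unit square with correct metadata", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x_mm = c(0, 1, 1, 0), y_mm = c(0, 0, 1, 1)), f,
            row.names = FALSE)
  s <- load_silhouette(f)
  expect_s3_class(s, "silhouette")
  expect_equal(polygon_area(s$polygon), 1)
  expect_equal(nrow(s$polygon), 4)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1, b = 2), f2, row.names = FALSE)
  expect_error(load_silhouette(f2), "x_mm")
})

test_that("raster masks load as one component with hole filling and scale", {
  m <- matrix(FALSE, 100, 100)
  m[41:60, 31:70] <- TRUE
  s <- as_silhouette(m, scale = 0.01, smooth_sigma = 0)
  expect_equal(polygon_area(s$polygon), 0.4 * 0.2, tolerance = 0.01)
  # default smoothing shrinks small shapes by the corner rounding only
  sd_ <- as_silhouette(m, scale = 0.01)
  expect_equal(polygon_area(sd_$polygon), 0.08, tolerance = 0.08)
  # two components rejected with the count in the message
  m2 <- m; m2[10:15, 10:15] <- TRUE
  expect_error(as_silhouette(m2, scale = 0.01), "2")
  # interior hole filled with a warning and flagged
  m3 <- m; m3[48:52, 48:52] <- FALSE
  expect_warning(s3 <- as_silhouette(m3, scale = 0.01), "hole")
  expect_true(s3$holes_filled)
  expect_equal(sum(s3$mask), sum(m))
})

test_that("PNG and TIFF rasters round-trip through the loader", {
  m <- matrix(0, 60, 80)
  m[20:40, 15:65] <- 1
  fp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(m, fp)
  sp <- load_silhouette(fp, scale = 0.05, smooth_sigma = 0)
  expect_equal(polygon_area(sp$polygon), (21 * 51) * 0.05^2, tolerance = 0.05)
  ft <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(m, ft)
  st <- load_silhouette(ft, scale = 0.05, smooth_sigma = 0)
  expect_equal(polygon_area(st$polygon), polygon_area(sp$polygon))
  expect_error(load_silhouette("nope.png"), "not found")
})

test_that("hull summary matches hand-computed values and bounds", {
  h <- measure_hull(silhouette(unit_square()))
  expect_equal(h$boundary_silhouette, 4)
  expect_equal(h$boundary_hull, 4)
  expect_equal(h$area_silhouette, 1)
  expect_equal(h$area_hull, 1)
  hp <- measure_hull(silhouette(plus_polygon()))
  expect_equal(hp$area_silhouette, 5)
  expect_equal(hp$area_hull, 7)           # hull of the 12 listed vertices
  expect_equal(hp$boundary_silhouette, 12)
  expect_equal(hp$boundary_hull, 4 + 4 * sqrt(2))
  # against the naive oracles
  expect_equal(hp$area_silhouette, oracle_area(plus_polygon()))
  expect_equal(hp$boundary_silhouette, oracle_perimeter(plus_polygon()))
  expect_error(measure_hull(rbind(c(0, 0), c(1, 0), c(2, 0))), "degenerate")
})

test_that("hull bounds hold exactly on random star polygons", {
  set.seed(42)
  for (i in 1:250) {
    p <- random_star_polygon(sample(5:30, 1))
    h <- measure_hull(silhouette(p, check = FALSE))
    expect_lte(h$boundary_hull, h$boundary_silhouette + 1e-12)
    expect_lte(h$area_silhouette, h$area_hull + 1e-12)
  }
})

test_that("mask-polygon round trip preserves >= 99% of pixels", {
  gen <- make_lamella(lamella_spec(seed = 7))
  m0 <- gen$silhouette$mask
  s2 <- as_silhouette(m0, scale = gen$silhouette$scale)
  r2 <- polygon_to_mask(s2$polygon, s2$scale)
  o <- round(r2$origin / s2$scale)
  B <- matrix(FALSE, nrow(m0), ncol(m0))
  rr <- seq_len(nrow(r2$mask)) + o[2]
  cc <- seq_len(ncol(r2$mask)) + o[1]
  okr <- rr >= 1 & rr <= nrow(m0)
  okc <- cc >= 1 & cc <= ncol(m0)
  B[rr[okr], cc[okc]] <- r2$mask[okr, okc]
  expect_gte(mean(m0 == B), 0.99)
})

test_that("scaling a polygon scales perimeter by k and area by k^2", {
  p <- plus_polygon()
  for (k in c(0.1, 3, 42)) {
    h1 <- measure_hull(silhouette(p))
    h2 <- measure_hull(silhouette(p * k))
    expect_equal(h2$boundary_silhouette, k * h1$boundary_silhouette)
    expect_equal(h2$area_silhouette, k^2 * h1$area_silhouette)
    expect_equal(amplitude_of_vibration(h2), amplitude_of_vibration(h1))
    expect_equal(deviation_from_convex_hull(h2), deviation_from_convex_hull(h1))
  }
})
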