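test_that("round-raphe gross area reproduces the published rows", {
  expect_equal(gross_area_round(12.5, 34), 850)
  expect_equal(gross_area_round(33.5, 34), 2278)
  expect_equal(gross_area_round(1, 1), 2)
  expect_error(gross_area_round(12.5, 34, raphe = "elongated"), "elongated")
})

test_that("elongated-raphe gross area weights the two lamellae", {
  expect_equal(gross_area_elongated(10, 2, 50), 760)
  expect_equal(gross_area_elongated(10, 2, 50, w_max = 0.8), 840)
  expect_equal(gross_area_elongated(10, 2, 50, w_max = 0.6), 680)
  # equal lamellae: independent of the weight
  for (w in c(0.3, 0.5, 0.7)) {
    expect_equal(gross_area_elongated(5, 5, 40, w_max = w), 2 * 5 * 40)
  }
  expect_error(gross_area_elongated(10, 2, 50, w_max = 1), "0, 1")
  expect_error(gross_area_elongated(2, 10, 50), "exceed")
  # monotone in w_max when a_L > a_S; linear in each area
  expect_gt(gross_area_elongated(10, 2, 50, 0.8),
            gross_area_elongated(10, 2, 50, 0.6))
  expect_equal(gross_area_elongated(30, 2, 50) - gross_area_elongated(20, 2, 50),
               gross_area_elongated(20, 2, 50) - gross_area_elongated(10, 2, 50))
  expect_equal(gross_area_elongated(10, 6, 50) - gross_area_elongated(10, 4, 50),
               gross_area_elongated(10, 4, 50) - gross_area_elongated(10, 2, 50))
})

test_that("percentage increase inverts the published averages", {
  expect_equal(pct_increase(10, 10), 0)
  expect_equal(pct_increase(10, 21.4), 114)
  expect_equal(pct_increase(5, 29.75), 495)
  expect_error(pct_increase(10, 9), "shorter")
  expect_error(pct_increase(0, 1), "positive")
})

test_that("per-specimen percentage summary gives closed-form mean and sd", {
  r <- specimen_pct_increase(rep(10, 4), rep(20, 4))
  expect_equal(r$mean, 100)
  expect_equal(r$sd, 0)
  r2 <- specimen_pct_increase(rep(10, 4), c(16, 17, 18, 19))
  expect_equal(r2$mean, 75)
  expect_equal(r2$sd, sd(c(60, 70, 80, 90)))
  expect_equal(r2$sd, 12.9099, tolerance = 1e-4)
  expect_error(specimen_pct_increase(10, 20), "at least 2")
})

test_that("fold-inclusive area scales the gross area", {
  expect_equal(area_with_folds(850, 114), 1819)
  expect_equal(area_with_folds(2278, 464), 12847.92)
  expect_equal(round_half_up(area_with_folds(2278, 464)), 12848)
  expect_equal(area_with_folds(500, 0), 500)
  expect_error(area_with_folds(500, -1), "nonnegative")
})

test_that("size normalization follows the published mm^2 / cm^2 convention", {
  expect_equal(normalize_area(1819, 52), 67.27, tolerance = 1e-3)
  expect_equal(round_half_up(normalize_area(1819, 52)), 67)
  expect_equal(round_half_up(normalize_area(351, 14.5)), 167)
  expect_equal(normalize_area(0.01 * 7^2, 7), 1)
  expect_warning(normalize_area(c(100, 100), c(10, 10),
                                size_kind = c("TL", "DW")), "mixed")
})

test_that("fold-driven increase recomputed from published areas spans 70-495", {
  m <- study_measurements()
  p <- 100 * (m$S_folds_pub / m$S_gross_pub - 1)
  expect_equal(round_half_up(min(p)), 70)
  expect_equal(round_half_up(max(p)), 495)
  expect_equal(m$id[which.min(p)], "Pv")
  expect_equal(m$id[which.max(p)], "Sr")
})

test_that("fold-inclusive area always dominates and re-ranks the published table", {
  m <- study_measurements()
  expect_true(all(m$S_folds_pub >= m$S_gross_pub))
  nb <- m[m$size_kind == "TL", ]  # non-batoids
  expect_false(identical(order(nb$norm_gross_pub), order(nb$norm_folds_pub)))
})

test_that("surface_area_table recomputes every derived column coherently", {
  tab <- make_measurement_table(measurement_spec(noise_scale = 0))
  out <- surface_area_table(tab$measurements)
  m <- study_measurements()
  expect_equal(out$pct_mean, m$pct_mean_pub, tolerance = 1e-10)
  expect_equal(out$pct_sd, rep(0, 16), tolerance = 1e-8)
  expect_equal(out$S_folds, out$S_gross * (1 + out$pct_mean / 100))
  expect_equal(out$norm_folds, 100 * out$S_folds / out$size_cm^2)
  # round-raphe rows reproduce the published gross areas exactly
  expect_equal(out$S_gross[out$id == "Cm"], 850)
  expect_equal(out$S_gross[out$id == "Hp"], 2278)
  expect_error(surface_area_table(tab$measurements[, 1:4]), "missing columns")
})
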