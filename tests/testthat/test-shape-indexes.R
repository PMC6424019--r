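test_that("frequency of vibration matches the printed quartic", {
  expect_equal(frequency_of_vibration(4, 0), 0)       # nu = 0
  expect_equal(frequency_of_vibration(5, 1), 1)       # nu = 0.5
  expect_equal(frequency_of_vibration(7, 4), 0)       # nu = 1
  # nu = 4/9: 16/18^4 - 8/18^2 + 1
  expect_equal(frequency_of_vibration(12, 4),
               16 / 18^4 - 8 / 18^2 + 1)
  expect_equal(frequency_of_vibration(12, 4), 0.9754611, tolerance = 1e-6)
  expect_error(frequency_of_vibration(3, 0), ">= 4")
  expect_warning(frequency_of_vibration(5, 3), "exceeds 1")
})

test_that("frequency is symmetric about nu = 0.5 and peaks there", {
  for (nu in seq(0, 0.5, by = 0.05)) {
    f1 <- frequency_of_vibration(103, round(nu * 100))
    f2 <- frequency_of_vibration(103, round((1 - nu) * 100))
    expect_equal(f1, f2)
    expect_lte(f1, 1)
    expect_gte(f1, 0)
  }
})

test_that("amplitude and deviation match hand-derived plus-polygon values", {
  h <- measure_hull(silhouette(plus_polygon()))
  expect_equal(amplitude_of_vibration(h), (12 - (4 + 4 * sqrt(2))) / 12)
  expect_equal(deviation_from_convex_hull(h), 2 / 7)
  hc <- measure_hull(silhouette(unit_square()))
  expect_equal(amplitude_of_vibration(hc), 0)
  expect_equal(deviation_from_convex_hull(hc), 0)
  bad <- list(boundary_silhouette = 3, boundary_hull = 4,
              area_silhouette = 5, area_hull = 4)
  expect_error(amplitude_of_vibration(bad), "inconsistent")
  expect_error(deviation_from_convex_hull(bad), "inconsistent")
})

test_that("Brinkhoff index composes its three terms and is monotone", {
  expect_equal(brinkhoff_index(0, 0, 0), 0)
  expect_equal(brinkhoff_index(0.61, 0.42, 0.3), 0.26496)
  expect_equal(brinkhoff_index(0.98, 0.66, 0.45), 0.60744)
  expect_error(brinkhoff_index(1.2, 0.5, 0.5), "\\[0, 1\\]")
  set.seed(1)
  for (i in 1:50) {
    f <- runif(1); a <- runif(1); d <- runif(1)
    eps <- runif(1, 0, 1 - max(f, a, d))
    b0 <- brinkhoff_index(f, a, d)
    expect_gte(brinkhoff_index(f + eps, a, d), b0)
    expect_gte(brinkhoff_index(f, a + eps, d), b0)
    expect_gte(brinkhoff_index(f, a, d + eps), b0)
  }
})

test_that("branching index and its three-group classification", {
  expect_equal(branching_index(10, 5), 2)
  expect_error(branching_index(10, 0), ">= 1")
  expect_equal(as.character(classify_branching(c(1.96, 3.67, 7.9))),
               c("unbranched", "few_branches", "highly_branched"))
  # published column partitions into the three verbal groups
  m <- study_measurements()
  cls <- classify_branching(m$branching_index_pub)
  expect_setequal(m$id[cls == "unbranched"],
                  c("Cm", "Dl", "Es", "Gm1", "Gm3", "Pg", "Pv", "Sb",
                    "Sc7", "Sc8"))
  expect_setequal(m$id[cls == "few_branches"], c("Hp", "Rb", "Rm", "Rp"))
  expect_setequal(m$id[cls == "highly_branched"], c("Sm", "Sr"))
})

test_that("recomposing Brinkhoff from printed sub-indexes stays within the rounding budget", {
  m <- study_measurements()
  b <- brinkhoff_index(m$frequency_pub, m$amplitude_pub, m$deviation_pub)
  # half-unit rounding of the printed sub-indexes and of the printed index
  # itself propagates to 0.8*0.005*(A+F) + 0.2*0.005 + 0.005 per row
  budget <- 0.8 * 0.005 * (m$amplitude_pub + m$frequency_pub) +
    0.2 * 0.005 + 0.005
  expect_true(all(abs(b - m$brinkhoff_pub) <= budget))
  exact <- c("Es", "Rb", "Gm3", "Sc7")
  expect_equal(round_half_up(b[m$id %in% exact], 2),
               m$brinkhoff_pub[m$id %in% exact])
})

test_that("normalized area is uncorrelated with the complexity indexes", {
  m <- study_measurements()
  r2 <- cor.test(m$brinkhoff_pub, m$norm_folds_pub)
  r3 <- cor.test(m$norm_folds_pub, m$branching_index_pub)
  expect_gt(r2$p.value, 0.05)
  expect_gt(r3$p.value, 0.05)
  expect_lt(abs(r2$estimate), 0.497)  # 5% critical |r| at n = 16
  expect_lt(abs(r3$estimate), 0.497)
})

test_that("shape_indexes pipeline ties all pieces together", {
  # plus polygon: every quantity known in closed form
  si <- shape_indexes(silhouette(plus_polygon() * 2), n_secondary_folds = 4,
                      prune_px = 2)
  expect_equal(si$n_vertices, 12)
  expect_equal(si$n_notches, 4)
  expect_equal(si$frequency, 16 / 18^4 - 8 / 18^2 + 1)
  expect_equal(si$brinkhoff,
               0.8 * si$amplitude * si$frequency + 0.2 * si$deviation)
  expect_equal(si$branching_index, si$n_branches / 4)

  # generated lamella: branching/hull parts defined, Brinkhoff NA because
  # every detected corner is a notch (nu > 1, outside the polygonal model)
  gen <- make_lamella(lamella_spec(n_folds = 8, branch_depth = 0, seed = 5))
  si3 <- suppressWarnings(shape_indexes(gen$silhouette,
                                        n_secondary_folds = gen$truth$n_folds))
  expect_equal(si3$n_secondary_folds, 8)
  expect_false(si3$fold_count_estimated)
  expect_equal(si3$branching_index, si3$n_branches / 8)
  expect_gt(si3$amplitude, 0)
  expect_gt(si3$deviation, 0)
  expect_true(is.na(si3$brinkhoff) || si3$brinkhoff >= 0)
  # fold-count estimator: terminal branches off the axis ~ fold count
  si4 <- suppressWarnings(shape_indexes(gen$silhouette))
  expect_true(si4$fold_count_estimated)
  expect_lte(abs(si4$n_secondary_folds - 8), 2)
})

test_that("convex silhouettes score zero on all complexity indexes", {
  for (k in c(4, 8, 16)) {
    s <- silhouette(regular_polygon(k, r = 3))
    h <- measure_hull(s)
    a <- amplitude_of_vibration(h)
    d <- deviation_from_convex_hull(h)
    expect_equal(a, 0)
    expect_equal(d, 0)
    expect_equal(brinkhoff_index(1, a, d), 0)
  }
})
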