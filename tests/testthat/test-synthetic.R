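test_that("lamella generation is byte-deterministic per seed", {
  g1 <- make_lamella(lamella_spec(seed = 13))
  g2 <- make_lamella(lamella_spec(seed = 13))
  expect_identical(g1$silhouette$polygon, g2$silhouette$polygon)
  expect_identical(g1$silhouette$mask, g2$silhouette$mask)
  g3 <- make_lamella(lamella_spec(seed = 14))
  expect_false(identical(g1$silhouette$polygon, g3$silhouette$polygon))
})

test_that("ground truth equals the emitted polygon's shoelace geometry", {
  gen <- make_lamella(lamella_spec(seed = 4))
  expect_equal(gen$truth$polygon_area, oracle_area(gen$silhouette$polygon))
  expect_equal(gen$truth$polygon_perimeter,
               oracle_perimeter(gen$silhouette$polygon))
  # raster area within 2% at 20 px/mm
  px_area <- sum(gen$silhouette$mask) * gen$silhouette$scale^2
  expect_equal(px_area, gen$truth$polygon_area, tolerance = 0.02)
})

test_that("zero fold length gives a convex unbranched body", {
  gen <- make_lamella(lamella_spec(fold_length_mm = 0, seed = 3))
  expect_equal(gen$truth$n_folds, 0)
  expect_equal(gen$truth$expected_notches, 0)
  h <- measure_hull(gen$silhouette)
  expect_lt(amplitude_of_vibration(h), 0.02)
  expect_lt(deviation_from_convex_hull(h), 0.02)
  g <- skeletonize(gen$silhouette)
  expect_equal(g$n_branches, 1)
})

test_that("branch depth raises the branching index in paired seeds", {
  wins <- 0
  n <- 20
  for (seed in seq_len(n)) {
    b0 <- skeletonize(make_lamella(
      lamella_spec(branch_depth = 0, seed = seed))$silhouette)$n_branches
    b2 <- skeletonize(make_lamella(
      lamella_spec(branch_depth = 2, seed = seed))$silhouette)$n_branches
    wins <- wins + (branching_index(b2, 8) > branching_index(b0, 8))
  }
  expect_gte(wins, ceiling(0.95 * n))
})

test_that("measurement tables are deterministic and respect the noise model", {
  t1 <- make_measurement_table(measurement_spec(seed = 2))
  t2 <- make_measurement_table(measurement_spec(seed = 2))
  expect_identical(t1$measurements, t2$measurements)
  # zero noise: specimen_pct_increase recovers the truth exactly
  t0 <- make_measurement_table(measurement_spec(noise_scale = 0))
  for (i in seq_len(nrow(t0$measurements))) {
    r <- t0$measurements[i, ]
    est <- specimen_pct_increase(unlist(r[paste0("L_lin_", 1:4)]),
                                 unlist(r[paste0("L_semi_", 1:4)]))
    expect_equal(est$mean, t0$truth$true_p[i], tolerance = 1e-10)
  }
  # adding specimens never changes earlier rows
  t16 <- make_measurement_table(measurement_spec(seed = 2), 16)
  t20 <- make_measurement_table(measurement_spec(seed = 2), 20)
  expect_equal(t20$measurements[1:16, names(t16$measurements)],
               t16$measurements, ignore_attr = TRUE)
})

test_that("study-regime tables re-rank non-batoids between gross and fold-inclusive area", {
  tab <- make_measurement_table(measurement_spec(noise_scale = 0))
  out <- surface_area_table(tab$measurements)
  nb <- out[out$size_kind == "TL", ]
  expect_false(identical(order(nb$norm_gross), order(nb$norm_folds)))
})

test_that("Brownian traits on a star tree are i.i.d. standard normal", {
  tips <- paste0("t", 1:40)
  st <- parse_newick(paste0("(", paste(tips, collapse = ","), ");"))
  draws <- unlist(lapply(1:25, function(s)
    simulate_brownian_traits(st, diag(1), seed = s)))
  ks <- ks.test(draws, "pnorm")
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(draws), 0, tolerance = 0.1)
  expect_equal(sd(draws), 1, tolerance = 0.1)
})

test_that("rank-1 trait covariance loads everything on PC1", {
  tr <- study_tree()
  S <- outer(c(1, 2, 0.5, 1, 1.5), c(1, 2, 0.5, 1, 1.5))
  X <- simulate_brownian_traits(tr, S, seed = 9)
  fit <- ppca(X, tr, mode = "covariance")
  expect_gt(fit$percent_variance[1], 99.9)
  expect_error(simulate_brownian_traits(tr, -diag(3)), "positive semi-definite")
})

test_that("covariance-mode pPCA recovers a known eigenvalue spectrum", {
  tr <- study_tree()
  lambda <- c(3, 1, 0.5, 0.3, 0.2)
  S <- diag(lambda)
  V_acc <- 0
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    X <- simulate_brownian_traits(tr, S, seed = 1000 + s)
    V_acc <- V_acc + ppca(X, tr, mode = "covariance")$evolutionary_vcv
  }
  ev <- sort(eigen(V_acc / n_rep, symmetric = TRUE)$values, decreasing = TRUE)
  expect_lt(mean(abs(ev - lambda) / lambda), 0.15)
})
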