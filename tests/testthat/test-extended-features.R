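test_that("directional descriptors follow hand geometry", {
  diag <- make_traj(c(0, 1, 2), c(0, 1, 2))
  d <- directional_features(diff_series(diag))
  expect_equal(d[["MA"]], 45)
  expect_equal(d[["MS"]], 1)

  # purely pressure motion: elevation straight up
  press <- make_traj(c(0, 0), c(0, 0), pressure = c(0, 5))
  expect_equal(directional_features(diff_series(press))[["Altitude"]], 90)

  # dx = dy = dz: asin(1/sqrt(3))
  eq3 <- make_traj(c(0, 1, 2), c(0, 1, 2), pressure = c(0, 1, 2))
  expect_equal(directional_features(diff_series(eq3))[["Altitude"]],
               asin(1 / sqrt(3)) * 180 / pi, tolerance = 1e-9)

  # vertical steps contribute sign(dy) * 90; no valid slope
  vert <- make_traj(c(0, 0), c(0, 3))
  dv <- directional_features(diff_series(vert))
  expect_equal(dv[["MA"]], 90)
  expect_true(is.na(dv[["MS"]]))
})

test_that("displacements sum step lengths and respect the triangle bounds", {
  square <- make_traj(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(displacement_features(diff_series(square))[["TD"]], 4)
  path <- make_traj(c(0, 3, 1), c(0, 0, 0))
  expect_equal(displacement_features(diff_series(path))[["HD"]], 5)

  for (seed in 1:50) {
    tr <- random_traj(seed, n = 40L)
    d <- displacement_features(diff_series(tr))
    expect_gte(d[["TD"]] + 1e-12, max(d[["HD"]], d[["VD"]]))
    expect_lte(d[["TD"]], d[["HD"]] + d[["VD"]] + 1e-12)
  }
})

test_that("stroke geometry features follow endpoint definitions", {
  # one stroke whose pen-up point is 7 units above its start
  tr <- make_traj(c(0, 1, 1), c(0, 0, 7), pen = c(1, 1, 0))
  g <- stroke_geometry_features(segment_strokes(tr))
  expect_equal(g[["MSH"]], 7)
  expect_equal(g[["MSW"]], 1)
  expect_true(is.na(g[["MCD"]]))  # a single stroke has no pairs

  # two strokes: centroids (0.5,0) and (4.5,0); gap 3 between closest points
  tr2 <- make_traj(c(0, 1, 2, 4, 5), c(0, 0, 0, 0, 0),
                   pen = c(1, 1, 0, 1, 1))
  g2 <- stroke_geometry_features(segment_strokes(tr2))
  expect_equal(g2[["MCD"]], 4)
  expect_equal(g2[["MMDS"]], 3)
  expect_equal(g2[["MSED"]], 3)
  expect_equal(g2[["MVA"]], 0)
  expect_equal(g2[["MHA"]], 4)

  # a trailing stroke with no following air point is excluded from MSH/MSW
  only_trailing <- make_traj(c(0, 1), c(0, 0), pen = c(1, 1))
  g3 <- stroke_geometry_features(segment_strokes(only_trailing))
  expect_true(is.na(g3[["MSH"]]))
})

test_that("discrete entropies match closed forms and order by Renyi alpha", {
  expect_equal(discrete_shannon_entropy(c(5, 5, 5, 5)), 0)
  expect_equal(discrete_shannon_entropy(1:4), 2)
  expect_equal(discrete_shannon_entropy(c(1, 1, 2, 2)), 1)
  expect_equal(discrete_renyi_entropy(1:4, 2), 2)
  expect_equal(discrete_renyi_entropy(1:4, 3), 2)
  # (3/4, 1/4) hand values
  v <- c(1, 1, 1, 2)
  expect_equal(discrete_renyi_entropy(v, 2), -log2(10 / 16), tolerance = 1e-12)
  expect_equal(discrete_renyi_entropy(v, 3), -log2(28 / 64) / 2, tolerance = 1e-12)
  expect_true(is.na(discrete_shannon_entropy(numeric())))

  # monotone ordering in alpha over random empirical distributions
  for (seed in 1:100) {
    set.seed(seed)
    vals <- sample(1:8, 30, replace = TRUE, prob = runif(8))
    h1 <- discrete_shannon_entropy(vals)
    h2 <- discrete_renyi_entropy(vals, 2)
    h3 <- discrete_renyi_entropy(vals, 3)
    expect_gte(h1 + 1e-12, h2)
    expect_gte(h2 + 1e-12, h3)
  }
})

test_that("energies follow their closed forms and scaling laws", {
  expect_equal(conventional_energy(c(1, 2, 3))$total, 14)
  expect_equal(conventional_energy(rep(0, 5))$total, 0)
  s <- rnorm(20)
  expect_equal(conventional_energy(3 * s)$total, 9 * conventional_energy(s)$total)

  expect_equal(teager_kaiser_energy(rep(4, 10))$total, 0)
  ramp <- teager_kaiser_energy(c(0, 1, 2, 3))
  expect_equal(ramp$per_sample, c(1, 1))
  expect_equal(ramp$total, 2)
  # unit-step ramps give exactly n - 2
  expect_equal(teager_kaiser_energy(0:19)$total, 18)
  expect_true(is.na(teager_kaiser_energy(c(1, 2))$total))

  # classic operator identity: Psi of A sin(w i) is about A^2 sin^2(w)
  A <- 2.5; w <- 0.3
  sig <- A * sin(w * (1:200))
  psi <- teager_kaiser_energy(sig)$per_sample
  expect_equal(psi, rep(A^2 * sin(w)^2, length(psi)), tolerance = 1e-8)
})

test_that("signal-to-noise ratios use the sample sd and flag regular series", {
  x <- c(1, 1, 3)
  e <- x^2  # 1, 1, 9
  expect_equal(snr_ratio(e), mean(e) / sd(e), tolerance = 1e-12)
  expect_equal(round(snr_ratio(e), 3), 0.794)
  expect_true(is.na(snr_ratio(rep(4, 5))))
  expect_true(is.na(snr_ratio(7)))
  expect_equal(snr_ratio(3 * e), snr_ratio(e), tolerance = 1e-12)
})

test_that("variability features follow the sample-sd definitions", {
  const <- make_traj(c(0, 1, 2, 3), rep(0, 4))
  expect_equal(variability_features(diff_series(const), const)[["SSD"]], 0)
  tr <- make_traj(1:3, 1:3, pressure = c(2, 4, 6))
  expect_equal(variability_features(diff_series(tr), tr)[["PSD"]], 2)
  two <- make_traj(c(0, 1), c(0, 0))
  expect_true(is.na(variability_features(diff_series(two), two)[["SSD"]]))

  # PSD includes in-air samples; PV does not
  mix <- make_traj(1:4, 1:4, pressure = c(10, 20, 0, 0), pen = c(1, 1, 0, 0))
  expect_equal(variability_features(diff_series(mix), mix)[["PSD"]],
               sd(c(10, 20, 0, 0)))
  expect_equal(compute_pressure_summary(mix)[["PV"]], var(c(10, 20)))
})

test_that("the 48-slot vector is complete, deterministic and NA-propagating", {
  expect_length(feature_names(), 48L)
  empty <- extract_features(pen_trajectory())
  expect_true(all(is.na(empty[feature_names()])))

  tr <- random_traj(21)
  f1 <- extract_features(tr)
  f2 <- extract_features(tr)
  expect_identical(f1, f2)
  expect_named(f1, c("subject_id", "task_id", feature_names()))
})

test_that("every extended feature matches the naive oracle on random trajectories", {
  n_mismatch <- 0
  for (seed in 1:100) {
    tr <- random_traj(seed)
    df <- as.data.frame(tr)
    got <- extract_features(tr)
    want <- oracle_extended_features(df)
    for (name in setdiff(names(want), "H_IMF1")) {
      expect_equal(got[[name]], unname(want[[name]]), tolerance = 1e-9,
                   label = sprintf("%s (seed %d)", name, seed))
    }
    expect_equal(got[["H_IMF1"]], unname(want[["H_IMF1"]]), tolerance = 1e-6,
                 label = sprintf("H_IMF1 (seed %d)", seed))
  }
})
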