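test_that("durations partition total time by the forward-attribution rule", {
  tr <- make_traj(1:3, rep(0, 3), pen = c(1, 1, 0), t_ms = c(0, 100, 200))
  tt <- compute_time_features(tr)
  expect_equal(unname(tt), c(0.2, 0, 0.2))  # TT, AT, PT

  air <- make_traj(1:3, rep(0, 3), pen = c(0, 0, 0), t_ms = c(0, 500, 1000))
  expect_equal(unname(compute_time_features(air)), c(1, 1, 0))

  expect_true(all(is.na(compute_time_features(make_traj(1, 1)))))

  # AT + PT = TT exactly on random trajectories
  for (seed in 1:5) {
    v <- compute_time_features(random_traj(seed))
    expect_equal(v[["AT"]] + v[["PT"]], v[["TT"]])
  }
})

test_that("motion features match constant-speed geometry and flag absent phases", {
  tr <- make_traj(c(0, 1, 2), rep(0, 3), pen = rep(1L, 3), t_ms = c(0, 200, 400))
  m <- compute_motion_features(segment_strokes(tr))
  expect_equal(m[["MSP"]], 5)
  expect_equal(m[["MAP"]], 0)
  expect_true(is.na(m[["MSA"]]))
  expect_true(is.na(m[["MAA"]]))
  expect_true(is.na(m[["MJA"]]))
})

test_that("motion features match a brute-force finite-difference oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    tr <- make_traj(cumsum(rnorm(n)), cumsum(rnorm(n)), pen = rep(1L, n),
                    t_ms = seq(0, by = 20, length.out = n))
    m <- compute_motion_features(segment_strokes(tr))
    dt <- diff(tr$timestamp) / 1000
    sp <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / dt
    ac <- diff(sp) / dt[-1]
    jk <- diff(ac) / dt[-(1:2)]
    expect_equal(m[["MSP"]], mean(sp), tolerance = 1e-9)
    expect_equal(m[["MAP"]], mean(abs(ac)), tolerance = 1e-9)
    expect_equal(m[["MJP"]], mean(abs(jk)), tolerance = 1e-9)
  }
})

test_that("pressure summary uses on-paper samples only", {
  tr <- make_traj(1:3, rep(0, 3), pressure = c(10, 20, 999), pen = c(1, 1, 0))
  p <- compute_pressure_summary(tr)
  expect_equal(unname(p), c(15, 50))
  expect_equal(compute_pressure_summary(
    make_traj(1:3, 1:3, pressure = rep(7, 3)))[["PV"]], 0)
  expect_true(all(is.na(compute_pressure_summary(
    make_traj(1:2, 1:2, pen = c(0L, 0L))))))
})

test_that("tremor descriptors measure turning angles", {
  line <- make_traj(1:5, rep(0, 5))
  g <- compute_tremor_gmrt(segment_strokes(line))
  expect_equal(g[["GMRTP"]], 0)
  expect_true(is.na(g[["GMRTA"]]))
  expect_true(is.na(g[["GMRT"]]))

  # right-angle zigzag turns 90 degrees at every vertex
  zig <- make_traj(c(0, 1, 1, 2, 2), c(0, 0, 1, 1, 2))
  expect_equal(compute_tremor_gmrt(segment_strokes(zig))[["GMRTP"]], 90)

  # random walk vs direct angle accumulation
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    tr <- make_traj(cumsum(rnorm(n)), cumsum(rnorm(n)))
    got <- compute_tremor_gmrt(segment_strokes(tr))[["GMRTP"]]
    dx <- diff(tr$x); dy <- diff(tr$y)
    ang <- numeric(0)
    for (i in seq_len(length(dx) - 1)) {
      a <- atan2(dx[i] * dy[i + 1] - dy[i] * dx[i + 1],
                 dx[i] * dx[i + 1] + dy[i] * dy[i + 1])
      ang <- c(ang, abs(a) * 180 / pi)
    }
    expect_equal(got, mean(ang), tolerance = 1e-9)
  }

  # turning angles are invariant under a global rotation
  tr <- random_traj(8)
  th <- 0.73
  rot <- pen_trajectory(cos(th) * tr$x - sin(th) * tr$y,
                        sin(th) * tr$x + cos(th) * tr$y,
                        tr$pressure, tr$pen_status, tr$timestamp)
  expect_equal(compute_tremor_gmrt(segment_strokes(tr))[["GMRTP"]],
               compute_tremor_gmrt(segment_strokes(rot))[["GMRTP"]],
               tolerance = 1e-9)
})

test_that("layout features count pen-downs, extents and grid occupancy", {
  tr <- make_traj(1:5, rep(0, 5), pen = c(1, 0, 1, 0, 1))
  l <- compute_layout_features(tr, segment_strokes(tr))
  expect_equal(l[["PWN"]], 3)

  tr2 <- make_traj(c(0, 5, 2), c(0, 1, 2))
  expect_equal(compute_layout_features(tr2, segment_strokes(tr2))[["XE"]], 5)

  # points in all four cells of a 2x2 grid
  tr3 <- make_traj(c(0, 10, 0, 10), c(0, 0, 10, 10))
  expect_equal(compute_layout_features(tr3, segment_strokes(tr3),
                                       grid_g = 2L)[["DI"]], 1)

  # degenerate: a single repeated position
  tr4 <- make_traj(rep(1, 3), rep(1, 3))
  expect_true(is.na(compute_layout_features(tr4, segment_strokes(tr4))[["DI"]]))
})

test_that("extents and speeds transform correctly under translation and scaling", {
  tr <- random_traj(5)
  shift <- pen_trajectory(tr$x + 100, tr$y - 50, tr$pressure, tr$pen_status,
                          tr$timestamp)
  f <- extract_features(tr)
  g <- extract_features(shift)
  for (name in c("XE", "YE", "MSP", "TD", "HD", "VD", "MA", "MS", "SSD")) {
    expect_equal(f[[name]], g[[name]], tolerance = 1e-9, label = name)
  }
  # coordinate energies are deliberately not translation-invariant;
  # exact-value-count entropies are (the value multiset only shifts)
  expect_false(isTRUE(all.equal(f$CE_X, g$CE_X)))
  expect_equal(f$HSE, g$HSE)

  scaled <- pen_trajectory(2 * tr$x, 2 * tr$y, tr$pressure, tr$pen_status,
                           tr$timestamp)
  h <- extract_features(scaled)
  expect_equal(h$MSP, 2 * f$MSP, tolerance = 1e-9)
  slowed <- pen_trajectory(tr$x, tr$y, tr$pressure, tr$pen_status,
                           2 * tr$timestamp)
  expect_equal(extract_features(slowed)$MSP, f$MSP / 2, tolerance = 1e-9)
})
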