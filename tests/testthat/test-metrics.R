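test_that("a perfect triangular lattice is fully hexagonal and evenly spaced", {
  tri <- tri_lattice(10, 10)
  expect_equal(hexagonality(tri), 1.0)
  # interior nearest-neighbour distances are all equal
  j <- pavotrain:::tie_break_jitter(tri$x, tri$y)
  interior <- pavotrain:::interior_indices(j$x, j$y)
  expect_lt(nn_distance_cv(tri[interior, ]), 1e-9)
})

test_that("square-grid degeneracy handling matches the brute-force oracle", {
  grid <- expand.grid(x = 0:4, y = 0:4)
  expect_equal(hexagonality(grid), bf_hexagonality(grid))
  expect_equal(hexagonality(grid), 5 / 9) # frozen from the oracle
  j <- pavotrain:::tie_break_jitter(grid$x, grid$y)
  expect_identical(pavotrain:::delaunay_degrees(j$x, j$y),
                   as.integer(bf_delaunay_degrees(j$x, j$y)))
})

test_that("hexagonality and nn CV agree with brute force on random sets", {
  set.seed(101)
  for (i in 1:6) {
    n <- sample(12:40, 1)
    pts <- data.frame(x = runif(n), y = runif(n))
    expect_equal(hexagonality(pts), bf_hexagonality(pts), info = i)
    expect_equal(nn_distance_cv(pts), bf_nn_cv(pts), tolerance = 1e-12)
  }
})

test_that("symmetry error is zero for symmetric sets and tracks displacement", {
  expect_lt(symmetry_error(make_pattern()), 1e-9)
  # single point on the axis
  expect_equal(symmetry_error(data.frame(x = 0, y = 3), axis_angle = 90), 0)
  # symmetric set with one point nudged off-mirror: matches the literal
  # definition recomputed independently
  set.seed(5)
  half <- data.frame(x = runif(20, 0.5, 3), y = runif(20, -2, 2))
  pts <- rbind(half, data.frame(x = -half$x, y = half$y))
  expect_lt(symmetry_error(pts, axis_angle = 90), 1e-12)
  pts$x[3] <- pts$x[3] + 0.01
  expect_equal(symmetry_error(pts, axis_angle = 90),
               bf_symmetry_error(pts, 90), tolerance = 1e-12)
  expect_gt(symmetry_error(pts, axis_angle = 90), 0)
  expect_error(symmetry_error(data.frame(x = numeric(0), y = numeric(0))),
               class = "pavotrain_empty_input")
})

test_that("radial line counts separate zigzag from parallel arrangements", {
  # 21 interleaved lines: 11 grid angles + 10 stagger-midpoint angles
  expect_identical(radial_line_count(make_pattern()), 21L)
  # parallel constant rows collapse onto one radial line per position
  p10 <- make_pattern("parallel", "const_10")
  expect_identical(radial_line_count(p10), 10L)
  p11 <- make_pattern("parallel", "const_11")
  expect_identical(radial_line_count(p11), 11L)
  # a single row yields one cluster per point
  one <- expand_train(build_lattice(arrangement_scheme(), 1))
  expect_identical(radial_line_count(one), 10L)
  expect_error(radial_line_count(make_pattern(), angular_tolerance = -1),
               class = "pavotrain_invalid_parameter")
})

test_that("dimensionless metrics are invariant under rotation and scaling", {
  # generic (non-degenerate) point sets: the triangulation is stable, so all
  # three dimensionless metrics must be rigid-motion and scale invariant
  set.seed(31)
  pts <- data.frame(x = runif(40), y = runif(40))
  h0 <- hexagonality(pts); c0 <- nn_distance_cv(pts)
  pat <- make_pattern()
  ppts <- data.frame(x = pat$points$x, y = pat$points$y)
  cp0 <- nn_distance_cv(ppts); sp0 <- symmetry_error(ppts, axis_angle = 90)
  for (theta in c(17, 113)) {
    th <- theta * pi / 180; s <- 3.7
    rot <- function(d) data.frame(x = s * (cos(th) * d$x - sin(th) * d$y),
                                  y = s * (sin(th) * d$x + cos(th) * d$y))
    expect_equal(hexagonality(rot(pts)), h0, tolerance = 1e-9)
    expect_equal(nn_distance_cv(rot(pts)), c0, tolerance = 1e-9)
    expect_equal(nn_distance_cv(rot(ppts)), cp0, tolerance = 1e-9)
    expect_equal(symmetry_error(rot(ppts), axis_angle = 90 + theta), sp0,
                 tolerance = 1e-6)
  }
})

test_that("zigzag beats parallel across display-like geometries", {
  # display-like: span of at least ~a half disc, eyespots spaced wider along
  # arcs than between rows; the ordering can invert for narrow, radially
  # stretched fans, which no peafowl displays
  for (radial_pitch in c(0.5, 0.8, 1.2)) {
    for (span in c(150, 180, 240, 300)) {
      z <- pattern_metrics(make_pattern("zigzag", "alt_10_11",
                                        fan_span = span,
                                        radial_pitch = radial_pitch))
      p <- pattern_metrics(make_pattern("parallel", "alt_10_11",
                                        fan_span = span,
                                        radial_pitch = radial_pitch))
      info <- sprintf("pitch=%g span=%g", radial_pitch, span)
      expect_gt(z$hexagonality, p$hexagonality, label = info)
      expect_lt(z$nn_distance_cv, p$nn_distance_cv, label = info)
    }
  }
})

test_that("metric preconditions are enforced", {
  expect_error(hexagonality(data.frame(x = 1:3, y = 1:3)),
               class = "pavotrain_insufficient_points")
  expect_error(hexagonality(data.frame(x = 1:10, y = 1:10)),
               class = "pavotrain_insufficient_points")  # collinear
  expect_error(nn_distance_cv(data.frame(x = 1, y = 1)),
               class = "pavotrain_insufficient_points")
  expect_equal(nn_distance_cv(data.frame(x = c(0, 1), y = c(0, 0))), 0)
})
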