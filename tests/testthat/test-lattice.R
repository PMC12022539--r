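test_that("alternating and constant row-size sums match enumeration", {
  # enumerated by summing the explicit 10,11,10,... sequence
  expect_identical(total_follicles("alt_10_11", 16, 10), 168L)
  expect_identical(total_follicles("alt_10_11", 20, 10), 210L)
  expect_identical(total_follicles("alt_10_11", 18, 10), 189L)
  expect_identical(total_follicles("alt_10_11", 0, 10), 0L)
  expect_identical(total_follicles("const_10", 7), 70L)
  expect_identical(total_follicles("const_11", 7), 77L)
  # pairing identity: starting on 10 or on 11 must tile 21 per row pair
  for (n in 0:30) {
    expect_identical(total_follicles("alt_10_11", n, 10) +
                       total_follicles("alt_10_11", n, 11), 21L * n)
  }
  expect_error(total_follicles("alt_10_11", 5, 9),
               class = "pavotrain_invalid_parameter")
  expect_error(total_follicles("alt_10_11", -1),
               class = "pavotrain_invalid_parameter")
})

test_that("built lattices agree with the closed-form counts for every scheme", {
  for (alignment in c("zigzag", "parallel")) {
    for (rs in c("alt_10_11", "const_10", "const_11")) {
      for (first in if (rs == "alt_10_11") c(10, 11) else 10) {
        for (n_rows in c(1, 2, 5, 18)) {
          lat <- build_lattice(arrangement_scheme(alignment, rs, first), n_rows)
          expect_identical(nrow(lat$follicles),
                           as.integer(total_follicles(rs, n_rows, first)),
                           info = sprintf("%s %s n=%d", alignment, rs, n_rows))
          # anterior row at y = 0, rows at multiples of the row pitch
          expect_equal(sort(unique(lat$follicles$y)), (seq_len(n_rows) - 1))
          # lattice centred on the midline
          expect_lt(abs(mean(range(lat$follicles$x))), 1e-12)
        }
      }
    }
  }
})

test_that("zigzag staggers consecutive rows by half the within-row pitch", {
  p <- 1
  check_offsets <- function(lat, skip_midline = FALSE) {
    f <- lat$follicles
    for (r in seq_len(lat$n_rows - 1)) {
      x0 <- f$x[f$row_index == r - 1]
      x1 <- f$x[f$row_index == r]
      if (skip_midline) x1 <- x1[abs(x1) > 1e-12]
      for (v in x1) expect_equal(min(abs(v - x0)), p / 2, tolerance = 1e-12)
    }
  }
  check_offsets(build_lattice(arrangement_scheme("zigzag", "alt_10_11"), 18))
  check_offsets(build_lattice(arrangement_scheme("zigzag", "const_10"), 6))
  # odd constant sizes keep the mid-feather on the midline in every row and
  # stagger the flanks
  lat11 <- build_lattice(arrangement_scheme("zigzag", "const_11"), 6)
  for (r in 0:5)
    expect_true(any(abs(lat11$follicles$x[lat11$follicles$row_index == r]) < 1e-12))
  check_offsets(lat11, skip_midline = TRUE)
})

test_that("zigzag const_10 second row sits on the first row's gap midpoints", {
  lat <- build_lattice(arrangement_scheme("zigzag", "const_10"), 2)
  expect_identical(nrow(lat$follicles), 20L)
  x0 <- sort(lat$follicles$x[lat$follicles$row_index == 0])
  x1 <- sort(lat$follicles$x[lat$follicles$row_index == 1])
  for (v in x1) expect_equal(min(abs(v - x0)), 0.5, tolerance = 1e-12)
  # off-midline gap midpoints of row 0 all appear in row 1 (the midline
  # midpoint is traded for the two symmetric overhang positions)
  mid <- setdiff((x0[-1] + x0[-length(x0)]) / 2, 0)
  expect_true(all(mid %in% x1))
  expect_equal(sort(x1), -rev(sort(x1)))  # row 1 mirror-symmetric itself
})

test_that("single-row lattice shares one row coordinate and sizes are valid", {
  lat <- build_lattice(arrangement_scheme(), 1)
  expect_identical(nrow(lat$follicles), 10L)
  expect_identical(unique(lat$follicles$y), 0)
  expect_error(build_lattice(arrangement_scheme(), 0),
               class = "pavotrain_invalid_parameter")
  expect_error(build_lattice(arrangement_scheme(), 5, row_pitch = -1),
               class = "pavotrain_invalid_parameter")
  expect_error(build_lattice(arrangement_scheme(), 5, within_row_pitch = 0),
               class = "pavotrain_invalid_parameter")
  expect_error(arrangement_scheme("zigzag", "alt_10_11", first_row_size = 12),
               class = "pavotrain_invalid_parameter")
})

test_that("follicle diameters grow from anterior to posterior", {
  lat <- build_lattice(arrangement_scheme(), 18)
  d <- tapply(lat$follicles$diameter, lat$follicles$row_index, unique)
  expect_true(all(diff(unlist(d)) >= 0))
  expect_equal(unname(d[[1]]), 0.5)
  expect_equal(unname(d[[18]]), 1.0)
  expect_error(
    build_lattice(arrangement_scheme(), 5,
                  diameter_profile = function(r, n) 1 - 0.1 * r),
    class = "pavotrain_invalid_parameter")
})

test_that("anchor outline strictly contains every follicle centre", {
  inside_ellipse <- function(lat) {
    o <- anchor_outline(lat)
    cx <- mean(range(o$x)); cy <- mean(range(o$y))
    a <- diff(range(o$x)) / 2; b <- diff(range(o$y)) / 2
    f <- lat$follicles
    all(((f$x - cx) / a)^2 + ((f$y - cy) / b)^2 < 1)
  }
  expect_true(inside_ellipse(build_lattice(arrangement_scheme(), 18)))
  expect_true(inside_ellipse(build_lattice(arrangement_scheme(), 1)))
  expect_error(anchor_outline(list()), class = "pavotrain_empty_input")
})
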