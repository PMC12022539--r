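#' Define a feather arrangement scheme
#'
#' A scheme fixes how follicle rows on the uropygial anchor plate are sized
#' and aligned. Peafowl lay their train-feather follicles down in alternating
#' rows of 10 and 11 with consecutive rows staggered ("zigzag"); the
#' alternative arrangements (parallel alignment, constant row sizes of 10 or
#' 11) exist as contrasts for the simulation.
#'
#' @param alignment `"zigzag"` (consecutive rows staggered by half the
#'   within-row pitch) or `"parallel"` (no stagger).
#' @param row_sizes `"alt_10_11"` (alternating 10/11 feathers per row),
#'   `"const_10"`, or `"const_11"`.
#' @param first_row_size 10 or 11; the size of the anterior (newest) row.
#'   Only used for `"alt_10_11"`.
#' @return An object of class `arrangement_scheme`.
#' @examples
#' arrangement_scheme("zigzag", "alt_10_11")
#' @export
arrangement_scheme <- function(alignment = c("zigzag", "parallel"),
                               row_sizes = c("alt_10_11", "const_10", "const_11"),
                               first_row_size = 10) {
  alignment <- match.arg(alignment)
  row_sizes <- match.arg(row_sizes)
  check_number(first_row_size, "first_row_size", integer = TRUE)
  if (row_sizes == "alt_10_11" && !first_row_size %in% c(10, 11))
    stop_invalid("`first_row_size` must be 10 or 11 for the alt_10_11 scheme")
  structure(list(alignment = alignment, row_sizes = row_sizes,
                 first_row_size = as.integer(first_row_size)),
            class = "arrangement_scheme")
}

#' @export
print.arrangement_scheme <- function(x, ...) {
  lbl <- switch(x$row_sizes,
                alt_10_11 = sprintf("10/11 (first row %d)", x$first_row_size),
                const_10 = "10/10", const_11 = "11/11")
  cat(sprintf("<arrangement_scheme> %s %s\n", lbl, x$alignment))
  invisible(x)
}

# Row-size sequence for a scheme, anterior (row 0) first.
row_size_seq <- function(row_sizes, n_rows, first_row_size = 10) {
  check_number(n_rows, "n_rows", nonneg = TRUE, integer = TRUE)
  if (n_rows == 0) return(integer(0))
  switch(row_sizes,
    alt_10_11 = {
      if (!first_row_size %in% c(10, 11))
        stop_invalid("`first_row_size` must be 10 or 11 for the alt_10_11 scheme")
      as.integer(rep(c(first_row_size, 21L - first_row_size),
                     length.out = n_rows))
    },
    const_10 = rep(10L, n_rows),
    const_11 = rep(11L, n_rows),
    stop_invalid(sprintf("unknown row_sizes scheme '%s'", row_sizes))
  )
}

#' Total follicle count for a row-size scheme
#'
#' Closed-form count of follicles over `n_rows` rows: the alternating 10/11
#' sum for the natural scheme, or a constant multiple for the 10/10 and 11/11
#' contrasts. Sixteen alternating rows give 168 follicles, inside the
#' 165--170 eyespot band reported for mature males; twenty rows give 210.
#'
#' @param row_sizes One of `"alt_10_11"`, `"const_10"`, `"const_11"`.
#' @param n_rows Number of rows (>= 0).
#' @param first_row_size 10 or 11 (alt scheme only).
#' @return Integer follicle count.
#' @examples
#' total_follicles("alt_10_11", 16) # 168
#' total_follicles("alt_10_11", 20) # 210
#' @export
total_follicles <- function(row_sizes, n_rows, first_row_size = 10) {
  sum(row_size_seq(row_sizes, n_rows, first_row_size))
}

# x-positions of one row, centred on the midline (x = 0), in pitch units * p.
# Zigzag staggering preserves exact mirror symmetry of every row:
#  - alternating 10/11: centred grids are automatically offset by half a
#    pitch (integer vs half-integer grid);
#  - constant even size: rows alternate between the half-integer grid and the
#    integer grid without 0 (gap midpoints), every follicle half a pitch from
#    the nearest follicle of the neighbouring row;
#  - constant odd size: the mid-feather stays on the midline in every row and
#    the flanking feathers stagger onto gap midpoints.
row_x_positions <- function(scheme, sizes, r, p) {
  n <- sizes[r]
  centred <- (seq_len(n) - 1 - (n - 1) / 2) * p
  if (scheme$alignment == "parallel") {
    if (scheme$row_sizes == "alt_10_11") {
      W <- (max(sizes) - 1) * p
      if (n == 1L) return(0)
      return(seq(-W / 2, W / 2, length.out = n))
    }
    return(centred)
  }
  # zigzag
  if (scheme$row_sizes == "alt_10_11") return(centred)
  if (r %% 2 == 1L) return(centred)         # even row index (r is 1-based)
  if (n %% 2 == 0L) {
    k <- n / 2
    return(sort(c(-(1:k), 1:k)) * p)        # integer grid minus 0
  }
  k <- (n - 1) / 2
  sort(c(0, -(1:k) + 0.5, (1:k) - 0.5)) * p # mid-feather kept on midline
}

#' Build the follicle lattice on the anchor plate
#'
#' Constructs the condensed developmental layout: rows of follicle insertion
#' points on the oval anchor plate, anterior (newest, smallest) row at y = 0
#' and the midline at x = 0. Follicle diameters grow from anterior to
#' posterior, mirroring the observed size gradient.
#'
#' @param scheme An [arrangement_scheme()].
#' @param n_rows Number of rows (>= 1).
#' @param row_pitch Distance between consecutive rows (abstract units).
#' @param within_row_pitch Distance between neighbouring follicles in a row.
#' @param diameter_profile Optional function `f(row_index, n_rows)` returning
#'   a follicle diameter, non-decreasing in `row_index` (0-based, anterior
#'   first). Default: linear from 0.5 to 1.0 across the rows.
#' @return A `follicle_lattice`: list with `scheme`, `n_rows`, `row_pitch`,
#'   `within_row_pitch`, and `follicles` (data.frame with `row_index`,
#'   `position_index`, `x`, `y`, `diameter`).
#' @examples
#' lat <- build_lattice(arrangement_scheme(), n_rows = 18)
#' nrow(lat$follicles) # 189
#' @export
build_lattice <- function(scheme, n_rows, row_pitch = 1, within_row_pitch = 1,
                          diameter_profile = NULL) {
  if (!inherits(scheme, "arrangement_scheme"))
    stop_invalid("`scheme` must be an arrangement_scheme")
  check_number(n_rows, "n_rows", positive = TRUE, integer = TRUE)
  check_number(row_pitch, "row_pitch", positive = TRUE)
  check_number(within_row_pitch, "within_row_pitch", positive = TRUE)
  if (is.null(diameter_profile)) {
    diameter_profile <- function(row_index, n_rows) {
      if (n_rows == 1) return(rep(0.75, length(row_index)))
      0.5 + 0.5 * row_index / (n_rows - 1)
    }
  }
  sizes <- row_size_seq(scheme$row_sizes, n_rows, scheme$first_row_size)
  rows <- lapply(seq_len(n_rows), function(r) {
    x <- row_x_positions(scheme, sizes, r, within_row_pitch)
    d <- diameter_profile(r - 1L, n_rows)
    if (any(!is.finite(d)) || any(d <= 0))
      stop_invalid("`diameter_profile` must return positive finite diameters")
    data.frame(row_index = r - 1L, position_index = seq_along(x) - 1L,
               x = x, y = (r - 1L) * row_pitch,
               diameter = rep_len(d, length(x)))
  })
  fol <- do.call(rbind, rows)
  diam_by_row <- vapply(rows, function(df) df$diameter[1L], numeric(1))
  if (any(diff(diam_by_row) < 0))
    stop_invalid("`diameter_profile` must be non-decreasing in row_index")
  structure(list(scheme = scheme, n_rows = as.integer(n_rows),
                 row_pitch = row_pitch, within_row_pitch = within_row_pitch,
                 follicles = fol),
            class = "follicle_lattice")
}

#' @export
print.follicle_lattice <- function(x, ...) {
  cat(sprintf("<follicle_lattice> %d rows, %d follicles (%s %s)\n",
              x$n_rows, nrow(x$follicles), x$scheme$row_sizes,
              x$scheme$alignment))
  invisible(x)
}

#' @export
as.data.frame.follicle_lattice <- function(x, ...) x$follicles

#' Oval outline of the anchor plate
#'
#' Returns a closed elliptical polygon strictly enclosing all follicle
#' centres, for rendering the uropygial anchor plate.
#'
#' @param lattice A `follicle_lattice`.
#' @param margin Relative margin added beyond the follicle extent.
#' @param n_vertices Number of polygon vertices.
#' @return data.frame with `x`, `y`; first and last vertex coincide.
#' @export
anchor_outline <- function(lattice, margin = 0.2, n_vertices = 64) {
  if (!inherits(lattice, "follicle_lattice") || nrow(lattice$follicles) == 0)
    stop_empty("`lattice` must be a non-empty follicle_lattice")
  f <- lattice$follicles
  cx <- mean(range(f$x)); cy <- mean(range(f$y))
  a <- diff(range(f$x)) / 2; b <- diff(range(f$y)) / 2
  pad <- max(f$diameter, lattice$within_row_pitch)
  a <- (a + pad) * (1 + margin); b <- (b + pad) * (1 + margin)
  # inflate until every centre is strictly inside
  q <- sqrt(((f$x - cx) / a)^2 + ((f$y - cy) / b)^2)
  s <- max(q, 0)
  if (s >= 1) { a <- a * s * 1.05; b <- b * s * 1.05 }
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)
  data.frame(x = cx + a * cos(t), y = cy + b * sin(t))
}

#' Export a lattice to CSV (and optionally its parameters to JSON)
#'
#' @param lattice A `follicle_lattice`.
#' @param csv_path Path for the follicle table CSV.
#' @param json_path Optional path for a JSON description of the scheme and
#'   geometry parameters.
#' @return Invisibly, `csv_path`.
#' @export
export_lattice <- function(lattice, csv_path, json_path = NULL) {
  if (!inherits(lattice, "follicle_lattice"))
    stop_invalid("`lattice` must be a follicle_lattice")
  utils::write.csv(lattice$follicles, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    meta <- list(scheme = unclass(lattice$scheme), n_rows = lattice$n_rows,
                 row_pitch = lattice$row_pitch,
                 within_row_pitch = lattice$within_row_pitch)
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
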