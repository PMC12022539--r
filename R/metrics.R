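# Quantitative statistics for the expanded display pattern: they turn the
# visual zigzag-vs-parallel contrast into assertable numbers.

# Deterministic tie-break jitter for triangulation degeneracies (co-circular
# quadruples, e.g. square grids), with a fixed, documented seed so neighbour
# degrees are reproducible. Magnitude 1e-5 x the pattern extent: large enough
# that the in-circle decisions it induces are resolved identically by any
# double-precision triangulation (margins ~1e-4 relative), yet ~4 orders of
# magnitude below any inter-point spacing, so non-degenerate patterns are
# unaffected.
METRIC_JITTER_SEED <- 20250923L
METRIC_JITTER_REL <- 1e-5

tie_break_jitter <- function(x, y, seed = METRIC_JITTER_SEED) {
  ext <- max(diff(range(x)), diff(range(y)))
  if (ext == 0) ext <- 1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  list(x = x + stats::runif(length(x), -1, 1) * METRIC_JITTER_REL * ext,
       y = y + stats::runif(length(y), -1, 1) * METRIC_JITTER_REL * ext)
}

# Delaunay neighbour degrees via deldir; eps below the jitter magnitude so
# the tie-break is decided by the jitter, not deldir's collinearity guard.
delaunay_degrees <- function(x, y) {
  dd <- deldir::deldir(x, y, eps = 1e-13, suppressMsge = TRUE)
  tabulate(c(dd$delsgs$ind1, dd$delsgs$ind2), nbins = length(x))
}

#' Hexagonal packing fraction of a point set
#'
#' Fraction of interior points (points not on the convex hull) whose Delaunay
#' neighbour degree is exactly 6. A perfect triangular lattice scores 1 on
#' its interior; the zigzag train expansion scores markedly higher than the
#' parallel arrangement, which is the quantitative form of the hexagonal
#' cellular packing seen on the bird.
#'
#' @param points A two-column matrix/data.frame of coordinates, or a
#'   `train_pattern` (all points are used; subset upstream if needed).
#' @param jitter_seed Seed of the deterministic degeneracy-breaking jitter.
#' @return Fraction in \[0, 1\].
#' @export
hexagonality <- function(points, jitter_seed = METRIC_JITTER_SEED) {
  pts <- as_points(points)
  if (nrow(pts) < 7)
    stop_insufficient("hexagonality needs at least 7 points")
  j <- tie_break_jitter(pts$x, pts$y, jitter_seed)
  interior <- interior_indices(j$x, j$y)
  if (length(interior) == 0)
    stop_insufficient("hexagonality needs interior (non-hull) points; input may be collinear")
  deg <- delaunay_degrees(j$x, j$y)
  mean(deg[interior] == 6)
}

# Interior points: not on the convex-hull boundary. Hull VERTICES alone are
# not enough -- points lying on a straight hull edge (grid borders) are
# boundary too, so anything within 1e-4 x extent of a hull segment is
# excluded (tolerance safely above the tie-break jitter, safely below any
# inter-point spacing).
interior_indices <- function(x, y) {
  n <- length(x)
  h <- grDevices::chull(x, y)
  ext <- max(diff(range(x)), diff(range(y)))
  tol <- 1e-4 * if (ext > 0) ext else 1
  on_boundary <- rep(FALSE, n)
  on_boundary[h] <- TRUE
  hseq <- c(h, h[1])
  for (e in seq_len(length(h))) {
    ax <- x[hseq[e]]; ay <- y[hseq[e]]
    bx <- x[hseq[e + 1]]; by <- y[hseq[e + 1]]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    if (L2 == 0) next
    t <- pmin(pmax(((x - ax) * vx + (y - ay) * vy) / L2, 0), 1)
    d <- sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2)
    on_boundary <- on_boundary | d <= tol
  }
  which(!on_boundary)
}

#' Coefficient of variation of nearest-neighbour distances
#'
#' SD / mean of each point's distance to its nearest neighbour; 0 for
#' perfectly uniform spacing. Lower values mean a more even eyespot field.
#'
#' @inheritParams hexagonality
#' @return Non-negative real; 0 when only one distance exists.
#' @export
nn_distance_cv <- function(points) {
  pts <- as_points(points)
  n <- nrow(pts)
  if (n < 2) stop_insufficient("nn_distance_cv needs at least 2 points")
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  if (n == 2) return(0)
  stats::sd(nn) / mean(nn)
}

#' Bilateral symmetry error of a point set
#'
#' Reflects the set across the axis through `axis_point` at `axis_angle` and
#' scores the mean distance from each point to the nearest reflected point,
#' normalised by the mean nearest-neighbour distance. Exactly symmetric sets
#' score 0.
#'
#' @inheritParams hexagonality
#' @param axis_angle Mirror-axis direction in degrees (90 = vertical). For a
#'   `train_pattern` the default is its midline angle.
#' @param axis_point A point on the axis; the fan pole (origin) by default.
#' @return Non-negative real. With fewer than 2 points the raw (unnormalised)
#'   mirror distance is returned, so a single point on the axis scores 0.
#' @export
symmetry_error <- function(points, axis_angle = NULL, axis_point = c(0, 0)) {
  if (is.null(axis_angle))
    axis_angle <- if (inherits(points, "train_pattern"))
      points$geometry$midline_angle else 90
  pts <- as_points(points)
  n <- nrow(pts)
  if (n == 0) stop_empty("symmetry_error needs at least 1 point")
  th <- axis_angle * pi / 180
  dx <- pts$x - axis_point[1]; dy <- pts$y - axis_point[2]
  mx <- axis_point[1] + cos(2 * th) * dx + sin(2 * th) * dy
  my <- axis_point[2] + sin(2 * th) * dx - cos(2 * th) * dy
  # distance from each original point to nearest mirrored point
  d2 <- outer(pts$x, mx, "-")^2 + outer(pts$y, my, "-")^2
  mirror_nn <- sqrt(apply(d2, 1, min))
  if (n < 2) return(mean(mirror_nn))
  d <- as.matrix(stats::dist(pts)); diag(d) <- Inf
  mean_nn <- mean(apply(d, 1, min))
  if (mean_nn == 0) return(mean(mirror_nn))
  mean(mirror_nn) / mean_nn
}

#' Number of radial eyespot lines in a pattern
#'
#' Groups the points' angles into clusters separated by more than
#' `angular_tolerance`; parallel arrangements line their eyespots up on few
#' radial "palm-leaf" lines (10 for a 10/10 parallel fan), while the zigzag
#' 10/11 fan interleaves grid and midpoint angles into 21 lines.
#'
#' @param pattern A `train_pattern` (or bare angles via a data.frame with an
#'   `angle_deg` column).
#' @param angular_tolerance Cluster-splitting gap in degrees. Default: a
#'   quarter of the smallest within-row angular pitch, which cleanly
#'   separates grid angles from stagger-midpoint angles (their gap is half a
#'   pitch).
#' @return Integer cluster count.
#' @export
radial_line_count <- function(pattern, angular_tolerance = NULL) {
  if (inherits(pattern, "train_pattern")) {
    ang <- pattern$points$angle_deg
    rows <- pattern$points$source_row
    if (is.null(angular_tolerance)) {
      pitches <- vapply(split(ang, rows), function(a) {
        a <- sort(unique(a)); if (length(a) < 2) Inf else min(diff(a))
      }, numeric(1))
      angular_tolerance <- min(pitches) / 4
      if (!is.finite(angular_tolerance)) angular_tolerance <- 1e-6
    }
  } else {
    ang <- as_points_angles(pattern)
    if (is.null(angular_tolerance))
      stop_invalid("`angular_tolerance` is required for bare angle input")
  }
  if (length(ang) == 0) stop_empty("pattern has no points")
  check_number(angular_tolerance, "angular_tolerance", positive = TRUE)
  a <- sort(ang)
  n_clusters <- sum(diff(a) > angular_tolerance) + 1L
  # wrap-around merge for full-circle fans
  if ((a[length(a)] - a[1]) > 360 - angular_tolerance && n_clusters > 1L)
    n_clusters <- n_clusters - 1L
  as.integer(n_clusters)
}

as_points_angles <- function(x) {
  if (is.data.frame(x) && "angle_deg" %in% names(x)) return(x$angle_deg)
  if (is.numeric(x)) return(x)
  stop_invalid("cannot extract angles from `pattern`")
}

# Convex hull area (shoelace) for the density metric.
hull_area <- function(x, y) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Compute the full metric bundle for a train pattern
#'
#' @param pattern A `train_pattern`.
#' @param classes Feather classes included (default `"eyespot"` only, since
#'   the packing claims concern the eyespot field); use
#'   `c("eyespot", "fishtail", "minor")` for all points.
#' @param angular_tolerance Passed to [radial_line_count()].
#' @return A `pattern_metrics` list: `hexagonality`, `nn_distance_cv`,
#'   `symmetry_error`, `n_radial_lines`, `density`, `n_points`.
#' @export
pattern_metrics <- function(pattern, classes = "eyespot",
                            angular_tolerance = NULL) {
  if (!inherits(pattern, "train_pattern"))
    stop_invalid("`pattern` must be a train_pattern")
  keep <- pattern$points$feather_class %in% classes
  if (!any(keep))
    stop_empty(sprintf("pattern has no points in classes: %s",
                       paste(classes, collapse = ", ")))
  sub <- pattern
  sub$points <- pattern$points[keep, , drop = FALSE]
  pts <- data.frame(x = sub$points$x, y = sub$points$y)
  structure(list(
    hexagonality = hexagonality(pts),
    nn_distance_cv = nn_distance_cv(pts),
    symmetry_error = symmetry_error(sub),
    n_radial_lines = radial_line_count(sub, angular_tolerance),
    density = nrow(pts) / hull_area(pts$x, pts$y),
    n_points = nrow(pts)), class = "pattern_metrics")
}

#' @export
print.pattern_metrics <- function(x, ...) {
  cat(sprintf(paste0("<pattern_metrics> n=%d  hexagonality=%.3f  nn_cv=%.3f  ",
                     "symmetry_error=%.2e  radial_lines=%d  density=%.3f\n"),
              x$n_points, x$hexagonality, x$nn_distance_cv, x$symmetry_error,
              x$n_radial_lines, x$density))
  invisible(x)
}
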