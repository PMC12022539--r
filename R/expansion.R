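#' Fan-expansion geometry
#'
#' Parameters mapping the condensed anchor-plate lattice onto the erected
#' train: rows land on concentric arcs (oldest, posterior row outermost),
#' within-row positions map onto angles through one common linear scale, and
#' dot sizes grow outward like the eyespots they represent. All lengths are
#' abstract units; the display has no absolute scale.
#'
#' @param fan_span Angular width of the fan in degrees (0 < span <= 360).
#' @param base_radius Radius of the innermost (anterior, newest) row arc.
#' @param radial_pitch Radial distance between consecutive row arcs.
#' @param midline_angle Angle of the bilateral midline in degrees
#'   (90 = vertical).
#' @param dot_size_profile Optional function `f(row_index, n_rows)` giving the
#'   dot (eyespot) diameter per row, non-decreasing in `row_index`; default
#'   carries the lattice's follicle diameters.
#' @return An `expansion_geometry` object.
#' @export
expansion_geometry <- function(fan_span = 180, base_radius = 5,
                               radial_pitch = 1, midline_angle = 90,
                               dot_size_profile = NULL) {
  check_number(fan_span, "fan_span", positive = TRUE)
  if (fan_span > 360) stop_invalid("`fan_span` must be <= 360 degrees")
  check_number(base_radius, "base_radius", nonneg = TRUE)
  check_number(radial_pitch, "radial_pitch", positive = TRUE)
  check_number(midline_angle, "midline_angle")
  structure(list(fan_span = fan_span, base_radius = base_radius,
                 radial_pitch = radial_pitch, midline_angle = midline_angle,
                 dot_size_profile = dot_size_profile),
            class = "expansion_geometry")
}

#' Expand a follicle lattice into the train display pattern
#'
#' Bilaterally and symmetrically unfolds the anchor-plate lattice into the
#' fan: row r is placed on the arc of radius `base_radius + r * radial_pitch`
#' (row 0, the newest, innermost; the oldest row outermost), and each
#' follicle's lattice x-position is mapped to an angle by one common scale of
#' `fan_span / (lattice width + within-row pitch)` degrees per unit. The
#' common scale turns the half-pitch zigzag stagger into exactly half the
#' angular pitch, and a full-circle span places n equally spaced points
#' 360/n degrees apart with no overlap at the wrap.
#'
#' @param lattice A [build_lattice()] result.
#' @param geometry An [expansion_geometry()].
#' @return A `train_pattern`: list with `points` (data.frame: `angle_deg`,
#'   `radius`, `x`, `y`, `dot_diameter`, `feather_class`, `source_row`,
#'   `source_position`), `geometry`, `scheme`, and `n_rows`. All feathers
#'   start classified as `"eyespot"`; see [classify_feathers()].
#' @examples
#' pat <- expand_train(build_lattice(arrangement_scheme(), 18))
#' nrow(pat$points) # 189
#' @export
expand_train <- function(lattice, geometry = expansion_geometry()) {
  if (!inherits(lattice, "follicle_lattice"))
    stop_invalid("`lattice` must be a follicle_lattice")
  if (!inherits(geometry, "expansion_geometry"))
    stop_invalid("`geometry` must be an expansion_geometry")
  f <- lattice$follicles
  W <- diff(range(f$x))
  scale_deg <- geometry$fan_span / (W + lattice$within_row_pitch)
  angle <- geometry$midline_angle + f$x * scale_deg
  radius <- geometry$base_radius + f$row_index * geometry$radial_pitch
  prof <- geometry$dot_size_profile
  if (is.null(prof)) {
    dot <- f$diameter
  } else {
    dot <- prof(f$row_index, lattice$n_rows)
    if (any(!is.finite(dot)) || any(dot <= 0))
      stop_invalid("`dot_size_profile` must return positive finite diameters")
    dot <- rep_len(dot, nrow(f))
  }
  theta <- angle * pi / 180
  pts <- data.frame(angle_deg = angle, radius = radius,
                    x = radius * cos(theta), y = radius * sin(theta),
                    dot_diameter = dot,
                    feather_class = rep("eyespot", nrow(f)),
                    source_row = f$row_index,
                    source_position = f$position_index,
                    stringsAsFactors = FALSE)
  structure(list(points = pts, geometry = geometry, scheme = lattice$scheme,
                 n_rows = lattice$n_rows,
                 angular_pitch_deg = scale_deg * lattice$within_row_pitch),
            class = "train_pattern")
}

#' @export
print.train_pattern <- function(x, ...) {
  cls <- table(x$points$feather_class)
  cat(sprintf("<train_pattern> %d points, %d rows (%s %s); %s\n",
              nrow(x$points), x$n_rows, x$scheme$row_sizes,
              x$scheme$alignment,
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.train_pattern <- function(x, ...) x$points

#' Classify feathers as fishtail, eyespot, or minor
#'
#' The oldest (posterior, outermost) rows carry eyespot-less fishtail
#' feathers that fringe the display, and the newest (anterior, innermost)
#' rows carry small, developmentally immature minor eyespots; the remainder
#' are the full eyespot feathers.
#'
#' @param pattern A `train_pattern`.
#' @param n_fishtail_rows Number of outermost rows labelled `"fishtail"`
#'   (typically 3--5, increasing with age).
#' @param n_minor_rows Number of innermost rows labelled `"minor"`
#'   (typically 2--3).
#' @return The pattern with `feather_class` reassigned.
#' @examples
#' pat <- expand_train(build_lattice(arrangement_scheme(), 18))
#' pat <- classify_feathers(pat, 4, 2)
#' table(pat$points$feather_class) # eyespot 126, fishtail 42, minor 21
#' @export
classify_feathers <- function(pattern, n_fishtail_rows, n_minor_rows) {
  if (!inherits(pattern, "train_pattern"))
    stop_invalid("`pattern` must be a train_pattern")
  check_number(n_fishtail_rows, "n_fishtail_rows", nonneg = TRUE, integer = TRUE)
  check_number(n_minor_rows, "n_minor_rows", nonneg = TRUE, integer = TRUE)
  if (n_fishtail_rows + n_minor_rows > pattern$n_rows)
    stop_invalid("fishtail and minor rows together exceed the total row count")
  r <- pattern$points$source_row
  cls <- rep("eyespot", length(r))
  cls[r >= pattern$n_rows - n_fishtail_rows] <- "fishtail"
  cls[r < n_minor_rows] <- "minor"
  pattern$points$feather_class <- cls
  pattern$n_fishtail_rows <- n_fishtail_rows
  pattern$n_minor_rows <- n_minor_rows
  pattern
}

#' Export a train pattern to CSV
#'
#' @param pattern A `train_pattern`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_pattern <- function(pattern, path) {
  if (!inherits(pattern, "train_pattern"))
    stop_invalid("`pattern` must be a train_pattern")
  utils::write.csv(pattern$points, path, row.names = FALSE)
  invisible(path)
}

feather_class_colors <- c(eyespot = "#1f6f8b", fishtail = "#3a9b46",
                          minor = "#9fc6d4")

#' Render a train pattern to SVG
#'
#' Writes one filled circle per point at its planar position, sized by dot
#' diameter and coloured by feather class (fishtails in green at the fringe,
#' as on the bird). The writer composes the SVG text directly, so identical
#' input yields byte-identical output.
#'
#' @param pattern A non-empty `train_pattern`.
#' @param path Output `.svg` path.
#' @param width_px Image width in pixels (height follows the aspect ratio).
#' @param colors Named vector of fill colours per feather class.
#' @return Invisibly, `path`.
#' @export
render_svg <- function(pattern, path, width_px = 800,
                       colors = feather_class_colors) {
  if (!inherits(pattern, "train_pattern") || nrow(pattern$points) == 0)
    stop_empty("`pattern` must be a non-empty train_pattern")
  p <- pattern$points
  pad <- max(p$dot_diameter)
  xr <- range(p$x) + c(-pad, pad); yr <- range(p$y) + c(-pad, pad)
  s <- width_px / diff(xr)
  height_px <- diff(yr) * s
  px <- (p$x - xr[1]) * s
  py <- (yr[2] - p$y) * s   # SVG y grows downward
  rr <- p$dot_diameter / 2 * s
  fill <- unname(colors[p$feather_class])
  fill[is.na(fill)] <- "#888888"
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.1f" height="%.1f" viewBox="0 0 %.1f %.1f">',
            width_px, height_px, width_px, height_px),
    '<rect width="100%" height="100%" fill="white"/>',
    sprintf('<circle cx="%.4f" cy="%.4f" r="%.4f" fill="%s"/>', px, py, rr, fill),
    "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' @export
plot.train_pattern <- function(x, ..., colors = feather_class_colors) {
  p <- x$points
  graphics::plot(p$x, p$y, asp = 1, pch = 19,
                 cex = p$dot_diameter / max(p$dot_diameter) * 1.5,
                 col = unname(colors[p$feather_class]),
                 xlab = "x", ylab = "y",
                 main = sprintf("%s %s train pattern", x$scheme$row_sizes,
                                x$scheme$alignment), ...)
  invisible(x)
}
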