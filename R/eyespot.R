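#' Build the palindromic follicle-type row
#'
#' The eyespot-development model: an 11-feather row carries a central
#' follicle type flanked on each side by the same k structurally distinct
#' types in mirrored order (an inverted tandem duplication). With the
#' natural k = 5 the row has 11 positions, matching an 11-feather lattice
#' row, and the five flanking types correspond to the five structural
#' colours of the eyespot's rings.
#'
#' @param follicle_types Number of distinct flanking types k (>= 1).
#' @return A `follicle_palindrome`: list with `row` (character vector of
#'   length 2k + 1, e.g. `T5 ... T1 C T1 ... T5`) and `follicle_types`.
#' @examples
#' build_palindrome(5)$row
#' @export
build_palindrome <- function(follicle_types = 5) {
  check_number(follicle_types, "follicle_types", positive = TRUE, integer = TRUE)
  k <- as.integer(follicle_types)
  flank <- paste0("T", seq_len(k))
  structure(list(row = c(rev(flank), "C", flank), follicle_types = k),
            class = "follicle_palindrome")
}

#' @export
print.follicle_palindrome <- function(x, ...) {
  cat("<follicle_palindrome>", paste(x$row, collapse = " "), "\n")
  invisible(x)
}

#' Map a follicle palindrome to concentric eyespot rings
#'
#' Zone i (0 = centre) takes the follicle type at distance i from the
#' palindrome's centre, so k flanking types yield k + 1 concentric zones:
#' the central follicle becomes the eyespot's core and each flanking type
#' one surrounding colour ring.
#'
#' @param palindrome A [build_palindrome()] result.
#' @return A `ring_sequence`: list with `zones` (character vector, centre
#'   first) and `follicle_types`.
#' @examples
#' palindrome_to_rings(build_palindrome(5))$zones # "C" "T1" ... "T5"
#' @export
palindrome_to_rings <- function(palindrome) {
  if (!inherits(palindrome, "follicle_palindrome"))
    stop_invalid("`palindrome` must be a follicle_palindrome")
  k <- palindrome$follicle_types
  centre <- k + 1L
  structure(list(zones = palindrome$row[seq.int(centre, 2L * k + 1L)],
                 follicle_types = k),
            class = "ring_sequence")
}

#' @export
print.ring_sequence <- function(x, ...) {
  cat("<ring_sequence>", paste(x$zones, collapse = " -> "),
      "(centre outward)\n")
  invisible(x)
}

default_ring_palette <- c("#10304a", "#1c6e8c", "#3a9b8f", "#b08d2f",
                          "#7a4a21", "#4a2c17", "#8a8a8a", "#c0c0c0")

#' Render an eyespot as nested concentric ovals (SVG)
#'
#' Draws the ring sequence outermost-first as nested ellipses, so the centre
#' zone ends up on top. Deterministic text output: identical input gives
#' byte-identical SVG.
#'
#' @param rings A [palindrome_to_rings()] result.
#' @param path Output `.svg` path.
#' @param aspect Vertical/horizontal axis ratio of the ovals (1 = circles).
#' @param palette Fill colours, centre first; recycled if short.
#' @param size_px Image width in pixels.
#' @return Invisibly, `path`.
#' @export
render_eyespot_svg <- function(rings, path, aspect = 1.4,
                               palette = default_ring_palette,
                               size_px = 400) {
  if (!inherits(rings, "ring_sequence") || length(rings$zones) == 0)
    stop_empty("`rings` must be a non-empty ring_sequence")
  check_number(aspect, "aspect", positive = TRUE)
  nz <- length(rings$zones)
  cols <- rep_len(palette, nz)
  cx <- size_px / 2
  h <- size_px * max(aspect, 1)
  cy <- h / 2
  rmax <- size_px / 2 * 0.95 / max(aspect, 1) * min(aspect, 1)^0
  rx <- rmax * seq_len(nz) / nz
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.1f" height="%.1f" viewBox="0 0 %.1f %.1f">',
            size_px, h, size_px, h),
    '<rect width="100%" height="100%" fill="white"/>',
    sprintf('<ellipse cx="%.2f" cy="%.2f" rx="%.4f" ry="%.4f" fill="%s"/>',
            cx, cy, rev(rx), rev(rx) * aspect, rev(cols)),
    "</svg>")
  writeLines(lines, path)
  invisible(path)
}
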