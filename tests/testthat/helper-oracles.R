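# Independent brute-force oracles: naive O(n^4) Delaunay by the empty-
# circumcircle definition, naive nearest-neighbour scans, and a literal
# transcription of the symmetry-score definition. Used to cross-check the
# package's triangulation-library-based implementations on small instances.

bf_delaunay_degrees <- function(x, y) {
  n <- length(x)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 2)) {
    for (j in seq.int(i + 1, n - 1)) {
      for (k in seq.int(j + 1, n)) {
        ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
        d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
        if (abs(d) < 1e-300) next  # collinear triple
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
        r2 <- (ax - ux)^2 + (ay - uy)^2
        inside <- (x - ux)^2 + (y - uy)^2 < r2 * (1 - 1e-12)
        inside[c(i, j, k)] <- FALSE
        if (!any(inside)) {
          adj[i, j] <- adj[j, i] <- TRUE
          adj[j, k] <- adj[k, j] <- TRUE
          adj[i, k] <- adj[k, i] <- TRUE
        }
      }
    }
  }
  rowSums(adj)
}

# Interior test matching the metric's definition, written against the hull
# independently (point-in-segment scan on the jittered coordinates).
bf_interior <- function(x, y, tol_rel = 1e-4) {
  h <- grDevices::chull(x, y)
  ext <- max(diff(range(x)), diff(range(y)))
  tol <- tol_rel * ext
  hseq <- c(h, h[1])
  boundary <- rep(FALSE, length(x))
  boundary[h] <- TRUE
  for (e in seq_along(h)) {
    ax <- x[hseq[e]]; ay <- y[hseq[e]]
    bx <- x[hseq[e + 1]]; by <- y[hseq[e + 1]]
    L2 <- (bx - ax)^2 + (by - ay)^2
    if (L2 == 0) next
    for (p in seq_along(x)) {
      t <- min(max(((x[p] - ax) * (bx - ax) + (y[p] - ay) * (by - ay)) / L2, 0), 1)
      d <- sqrt((x[p] - (ax + t * (bx - ax)))^2 + (y[p] - (ay + t * (by - ay)))^2)
      if (d <= tol) boundary[p] <- TRUE
    }
  }
  which(!boundary)
}

bf_hexagonality <- function(pts) {
  j <- pavotrain:::tie_break_jitter(pts$x, pts$y)
  deg <- bf_delaunay_degrees(j$x, j$y)
  interior <- bf_interior(j$x, j$y)
  mean(deg[interior] == 6)
}

bf_nn_cv <- function(pts) {
  n <- nrow(pts)
  nn <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
      if (d < best) best <- d
    }
    nn[i] <- best
  }
  stats::sd(nn) / mean(nn)
}

bf_symmetry_error <- function(pts, axis_angle = 90) {
  th <- axis_angle * pi / 180
  n <- nrow(pts)
  mx <- cos(2 * th) * pts$x + sin(2 * th) * pts$y
  my <- sin(2 * th) * pts$x - cos(2 * th) * pts$y
  num <- numeric(n); nn <- numeric(n)
  for (i in seq_len(n)) {
    num[i] <- min(sqrt((pts$x[i] - mx)^2 + (pts$y[i] - my)^2))
    others <- setdiff(seq_len(n), i)
    nn[i] <- min(sqrt((pts$x[i] - pts$x[others])^2 +
                      (pts$y[i] - pts$y[others])^2))
  }
  mean(num) / mean(nn)
}

# Convenience: default classified pattern for a scheme.
make_pattern <- function(alignment = "zigzag", row_sizes = "alt_10_11",
                         n_rows = 18, first_row_size = 10,
                         fan_span = 180, base_radius = 5, radial_pitch = 1,
                         n_fishtail_rows = 4, n_minor_rows = 2) {
  lat <- build_lattice(arrangement_scheme(alignment, row_sizes, first_row_size),
                       n_rows)
  pat <- expand_train(lat, expansion_geometry(fan_span, base_radius,
                                              radial_pitch))
  if (n_fishtail_rows + n_minor_rows <= n_rows && n_rows > 1)
    pat <- classify_feathers(pat, n_fishtail_rows, n_minor_rows)
  pat
}

# Parallelogram-form triangular lattice (straight edges, truly 6-regular
# interior).
tri_lattice <- function(nx = 10, ny = 10, a = 1) {
  g <- expand.grid(i = seq_len(nx) - 1, j = seq_len(ny) - 1)
  data.frame(x = (g$i + g$j / 2) * a, y = g$j * a * sqrt(3) / 2)
}
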