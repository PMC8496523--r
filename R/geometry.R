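# Planar geometry primitives. All coordinates are meters in a projected
# system; no geographic (lon/lat) handling anywhere in the package.

#' Build a segment matrix
#'
#' Segments are stored as a numeric matrix with columns `ax, ay, bx, by`
#' (endpoint coordinates in meters). A point is represented as a
#' degenerate segment with `a == b`.
#'
#' @param ax,ay,bx,by Numeric vectors of endpoint coordinates.
#' @return A numeric matrix with one row per segment.
#' @export
seg_mat <- function(ax, ay, bx, by) {
  m <- cbind(ax = as.numeric(ax), ay = as.numeric(ay),
             bx = as.numeric(bx), by = as.numeric(by))
  if (any(!is.finite(m))) stop("segment coordinates must be finite")
  m
}

#' Nearest point on a set of segments
#'
#' For each query point, finds the closest point over all segments.
#'
#' @param px,py Numeric vectors of query point coordinates.
#' @param seg Segment matrix from [seg_mat()].
#' @return List with `dist` (meters), `index` (row of the nearest
#'   segment) and `offset_m` (distance from the segment's `a` endpoint
#'   to the foot point), each of length `length(px)`.
#' @export
nearest_on_segments <- function(px, py, seg) {
  np <- length(px)
  if (np != length(py)) stop("px and py must have equal length")
  best_d2 <- rep(Inf, np)
  best_i <- rep(NA_integer_, np)
  best_t <- rep(NA_real_, np)
  for (i in seq_len(nrow(seg))) {
    ax <- seg[i, 1L]; ay <- seg[i, 2L]
    dx <- seg[i, 3L] - ax; dy <- seg[i, 4L] - ay
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, np) else
      pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
    ex <- ax + t * dx - px
    ey <- ay + t * dy - py
    d2 <- ex * ex + ey * ey
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_i[upd] <- i
      best_t[upd] <- t[upd] * sqrt(L2)
    }
  }
  list(dist = sqrt(best_d2), index = best_i, offset_m = best_t)
}

ring_signed_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- nrow(ring)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Even-odd point-in-ring (strict, boundary not handled): crossing count
# of the upward ray. Vectorized over points, loops over ring edges.
ring_crossings <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  x1 <- ring[, 1L]; y1 <- ring[, 2L]
  j <- c(2:n, 1L)
  x2 <- ring[j, 1L]; y2 <- ring[j, 2L]
  for (k in seq_len(n)) {
    cross <- ((y1[k] > py) != (y2[k] > py))
    if (any(cross)) {
      xin <- x1[k] + (py - y1[k]) / (y2[k] - y1[k]) * (x2[k] - x1[k])
      flip <- cross & (px < xin)
      inside <- xor(inside, flip)
    }
  }
  inside
}

ring_edges_seg <- function(ring) {
  n <- nrow(ring)
  j <- c(2:n, 1L)
  seg_mat(ring[, 1L], ring[, 2L], ring[j, 1L], ring[j, 2L])
}

# ---- polygon classes -------------------------------------------------
# Three concrete polygon representations share one generic interface:
#   geo_disc      exact disc (straight-line catchment baseline)
#   geo_capsules  union of buffer_m-radius neighbourhoods of segments
#                 (network catchment); containment is exact via the
#                 distance predicate, the ring outline is a marching-
#                 squares level set used for export, area and clipping
#   geo_ringpoly  explicit rings with even-odd interior (arbitrary
#                 polygons, e.g. read from GeoJSON)
# Boundary convention: a point exactly on the boundary is inside.

#' Disc polygon
#' @param cx,cy Center (meters). @param r Radius (meters).
#' @param n_vertices Vertices of the ring discretization used for
#'   export, area and area-weighted clipping (containment is exact).
#' @return A `geo_disc` / `geo_polygon` object.
#' @export
geo_disc <- function(cx, cy, r, n_vertices = 128L) {
  if (!is.finite(r) || r <= 0) {
    stop(mc_condition("invalid_cutoff", "disc radius must be positive"))
  }
  structure(list(cx = cx, cy = cy, r = r, n_vertices = as.integer(n_vertices)),
            class = c("geo_disc", "geo_polygon"))
}

#' Buffered-segment polygon (dissolved union of segment buffers)
#'
#' The interior is the exact set of points within `buffer_m` of at
#' least one segment. `ring_step` controls the resolution of the
#' marching-squares outline extracted for export/area.
#'
#' @param segments Segment matrix from [seg_mat()]; degenerate rows
#'   (points) are allowed.
#' @param buffer_m Buffer radius in meters.
#' @param ring_step Grid step of the level-set outline (meters).
#' @return A `geo_capsules` / `geo_polygon` object.
#' @export
geo_capsules <- function(segments, buffer_m, ring_step = buffer_m / 4) {
  stopifnot(is.matrix(segments), ncol(segments) == 4, nrow(segments) >= 1,
            buffer_m > 0)
  structure(list(segments = segments, buffer_m = buffer_m,
                 ring_step = ring_step),
            class = c("geo_capsules", "geo_polygon"))
}

#' Explicit ring polygon (even-odd interior)
#' @param rings List of n-by-2 coordinate matrices (closed implicitly;
#'   a repeated last vertex is dropped).
#' @return A `geo_ringpoly` / `geo_polygon` object.
#' @export
geo_ringpoly <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)[, 1:2, drop = FALSE]
    n <- nrow(r)
    if (n >= 2 && all(r[1L, ] == r[n, ])) r <- r[-n, , drop = FALSE]
    if (nrow(r) < 3) stop(mc_condition("geometry_error",
                                       "a polygon ring needs >= 3 vertices"))
    r
  })
  structure(list(rings = rings), class = c("geo_ringpoly", "geo_polygon"))
}

#' Point-in-polygon test (boundary counts as inside)
#' @param poly A `geo_polygon`. @param px,py Point coordinates.
#' @return Logical vector.
#' @export
geo_contains <- function(poly, px, py) UseMethod("geo_contains")

#' @export
geo_contains.geo_disc <- function(poly, px, py) {
  (px - poly$cx)^2 + (py - poly$cy)^2 <= poly$r^2
}

#' @export
geo_contains.geo_capsules <- function(poly, px, py) {
  nearest_on_segments(px, py, poly$segments)$dist <= poly$buffer_m + 1e-9
}

#' @export
geo_contains.geo_ringpoly <- function(poly, px, py) {
  inside <- rep(FALSE, length(px))
  for (ring in poly$rings) {
    inside <- xor(inside, ring_crossings(px, py, ring))
  }
  # boundary points count as inside regardless of crossing parity
  on_edge <- rep(FALSE, length(px))
  for (ring in poly$rings) {
    d <- nearest_on_segments(px, py, ring_edges_seg(ring))$dist
    on_edge <- on_edge | d <= 1e-9
  }
  inside | on_edge
}

#' Bounding box of a polygon
#' @param poly A `geo_polygon`.
#' @return Numeric vector `c(xmin, ymin, xmax, ymax)`.
#' @export
geo_bbox <- function(poly) UseMethod("geo_bbox")

#' @export
geo_bbox.geo_disc <- function(poly) {
  c(poly$cx - poly$r, poly$cy - poly$r, poly$cx + poly$r, poly$cy + poly$r)
}

#' @export
geo_bbox.geo_capsules <- function(poly) {
  s <- poly$segments
  b <- poly$buffer_m
  c(min(s[, c(1, 3)]) - b, min(s[, c(2, 4)]) - b,
    max(s[, c(1, 3)]) + b, max(s[, c(2, 4)]) + b)
}

#' @export
geo_bbox.geo_ringpoly <- function(poly) {
  xs <- unlist(lapply(poly$rings, function(r) r[, 1L]))
  ys <- unlist(lapply(poly$rings, function(r) r[, 2L]))
  c(min(xs), min(ys), max(xs), max(ys))
}

#' Polygon outline rings, orientation-normalized
#'
#' Returns the rings describing the polygon boundary with outer rings
#' counter-clockwise and holes clockwise, so that signed shoelace areas
#' sum to the polygon area.
#'
#' @param poly A `geo_polygon`.
#' @return List of n-by-2 matrices.
#' @export
geo_rings <- function(poly) UseMethod("geo_rings")

#' @export
geo_rings.geo_disc <- function(poly) {
  th <- 2 * pi * (seq_len(poly$n_vertices) - 1) / poly$n_vertices
  list(cbind(poly$cx + poly$r * cos(th), poly$cy + poly$r * sin(th)))
}

#' @export
geo_rings.geo_ringpoly <- function(poly) orient_rings(poly$rings)

#' @export
geo_rings.geo_capsules <- function(poly) {
  seg <- poly$segments
  b <- poly$buffer_m
  step <- poly$ring_step
  pad <- b + 3 * step
  xmin <- min(seg[, c(1, 3)]) - pad; xmax <- max(seg[, c(1, 3)]) + pad
  ymin <- min(seg[, c(2, 4)]) - pad; ymax <- max(seg[, c(2, 4)]) + pad
  xs <- seq(xmin, xmax, by = step)
  ys <- seq(ymin, ymax, by = step)
  if (length(xs) < 4) xs <- seq(xmin, xmax, length.out = 4)
  if (length(ys) < 4) ys <- seq(ymin, ymax, length.out = 4)
  # only evaluate the distance field near some segment; elsewhere the
  # field is provably > b so a large constant is safe
  mask <- matrix(FALSE, length(xs), length(ys))
  for (i in seq_len(nrow(seg))) {
    ix <- which(xs >= min(seg[i, c(1, 3)]) - pad & xs <= max(seg[i, c(1, 3)]) + pad)
    iy <- which(ys >= min(seg[i, c(2, 4)]) - pad & ys <= max(seg[i, c(2, 4)]) + pad)
    mask[ix, iy] <- TRUE
  }
  z <- matrix(b + pad, length(xs), length(ys))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    d <- nearest_on_segments(xs[idx[, 1L]], ys[idx[, 2L]], seg)$dist
    z[idx] <- d
  }
  cl <- grDevices::contourLines(xs, ys, z, levels = b)
  if (length(cl) == 0) {
    # buffer thinner than the grid can resolve; fall back to a disc
    # around the segment midpoint so the outline is never empty
    ctr <- c(mean(seg[, c(1, 3)]), mean(seg[, c(2, 4)]))
    return(geo_rings(geo_disc(ctr[1L], ctr[2L], b)))
  }
  rings <- lapply(cl, function(cc) {
    r <- cbind(cc$x, cc$y)
    n <- nrow(r)
    if (n >= 2 && all(abs(r[1L, ] - r[n, ]) < 1e-12)) r <- r[-n, , drop = FALSE]
    r
  })
  rings <- rings[vapply(rings, nrow, 1L) >= 3]
  orient_rings(rings)
}

# Set outer rings CCW (+) and holes CW (-) using even-odd nesting depth.
orient_rings <- function(rings) {
  if (length(rings) <= 1) {
    return(lapply(rings, function(r) if (ring_signed_area(r) < 0) r[rev(seq_len(nrow(r))), , drop = FALSE] else r))
  }
  depth <- vapply(seq_along(rings), function(i) {
    p <- rings[[i]][1L, ]
    sum(vapply(seq_along(rings), function(j) {
      if (j == i) return(FALSE)
      ring_crossings(p[1L], p[2L], rings[[j]])
    }, logical(1)))
  }, integer(1))
  lapply(seq_along(rings), function(i) {
    r <- rings[[i]]
    want_ccw <- depth[i] %% 2L == 0L
    is_ccw <- ring_signed_area(r) > 0
    if (want_ccw != is_ccw) r[rev(seq_len(nrow(r))), , drop = FALSE] else r
  })
}

#' Polygon area from the (normalized) outline rings
#' @param poly A `geo_polygon`.
#' @return Area in square meters.
#' @export
geo_area <- function(poly) {
  sum(vapply(geo_rings(poly), ring_signed_area, numeric(1)))
}

# Sutherland-Hodgman clip of one ring against an axis-aligned
# rectangle. Preserves orientation; returns a matrix (possibly 0-row).
clip_ring_rect <- function(ring, xmin, ymin, xmax, ymax) {
  clip_halfplane <- function(pts, inside_fn, intersect_fn) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    prev <- pts[n, ]
    prev_in <- inside_fn(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside_fn(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect_fn(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect_fn(prev, cur))
      }
      prev <- cur
      prev_in <- cur_in
    }
    out
  }
  at_x <- function(p, q, x0) {
    t <- (x0 - p[1L]) / (q[1L] - p[1L])
    c(x0, p[2L] + t * (q[2L] - p[2L]))
  }
  at_y <- function(p, q, y0) {
    t <- (y0 - p[2L]) / (q[2L] - p[2L])
    c(p[1L] + t * (q[1L] - p[1L]), y0)
  }
  r <- ring
  r <- clip_halfplane(r, function(p) p[1L] >= xmin, function(p, q) at_x(p, q, xmin))
  r <- clip_halfplane(r, function(p) p[1L] <= xmax, function(p, q) at_x(p, q, xmax))
  r <- clip_halfplane(r, function(p) p[2L] >= ymin, function(p, q) at_y(p, q, ymin))
  r <- clip_halfplane(r, function(p) p[2L] <= ymax, function(p, q) at_y(p, q, ymax))
  r
}

# Area of polygon-rectangle intersection via orientation-preserving
# clipping of each normalized ring.
polygon_rect_area <- function(rings, xmin, ymin, xmax, ymax) {
  a <- 0
  for (ring in rings) {
    cl <- clip_ring_rect(ring, xmin, ymin, xmax, ymax)
    if (nrow(cl) >= 3) a <- a + ring_signed_area(cl)
  }
  max(a, 0)
}
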