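# Planar geometry primitives (used for tree-crown polygons).
# All operate in a local projected coordinate system in meters.

# Ray-casting point-in-polygon. `poly` is a matrix with columns x, y
# (open ring: last vertex != first). Points on an edge count as inside.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary check
    if (dist_point_segment(px, py, xi, yi, xj, yj) < 1e-9) return(TRUE)
    if ((yi > py) != (yj > py)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Euclidean distance from point (px, py) to segment (x1,y1)-(x2,y2)
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else ((px - x1) * dx + (py - y1) * dy) / len2
  t <- min(1, max(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Distance from a point to a polygon boundary (0 if inside)
dist_point_polygon <- function(px, py, poly) {
  if (point_in_polygon(px, py, poly)) return(0)
  n <- nrow(poly)
  j <- n
  d <- Inf
  for (i in seq_len(n)) {
    d <- min(d, dist_point_segment(px, py, poly[i, 1], poly[i, 2],
                                   poly[j, 1], poly[j, 2]))
    j <- i
  }
  d
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Convexity-preserving test of polygon overlap via separating axes
# (both polygons convex, as generated crowns are).
polygons_overlap <- function(a, b) {
  axes <- function(p) {
    n <- nrow(p)
    nx <- p[c(2:n, 1), 1] - p[, 1]
    ny <- p[c(2:n, 1), 2] - p[, 2]
    cbind(-ny, nx)
  }
  ax <- rbind(axes(a), axes(b))
  for (i in seq_len(nrow(ax))) {
    pa <- a %*% ax[i, ]
    pb <- b %*% ax[i, ]
    if (max(pa) < min(pb) || max(pb) < min(pa)) return(FALSE)
  }
  TRUE
}
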