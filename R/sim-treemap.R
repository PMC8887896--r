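#' Generate a map of sleep-tree crown polygons
#'
#' Lays out `n_trees` non-overlapping convex crown polygons (5-15 m
#' diameter) near a site centre, mimicking tree crowns traced from drone
#' imagery of a sleep site. Crowns are placed on jittered grid positions at
#' least 18 m apart, which guarantees pairwise disjointness given the
#' maximum 7.5 m crown radius.
#'
#' @param n_trees Number of trees (>= 1).
#' @param site_center Numeric `c(lon, lat)` of the site centre.
#' @param seed Integer seed; the map is deterministic given the seed.
#' @return A `tree_map`: list with `trees` (named list of polygon matrices,
#'   columns x/y in site-local meters), `centroids`, `site_lon`, `site_lat`.
#' @export
#' @examples
#' tm <- make_tree_map(3, site_center = c(36.87, 0.29), seed = 1)
#' names(tm$trees)
make_tree_map <- function(n_trees, site_center = c(36.87, 0.29), seed = 1L) {
  if (length(n_trees) != 1 || is.na(n_trees) || n_trees < 1) {
    stop("n_trees must be a positive count", call. = FALSE)
  }
  n_trees <- as.integer(n_trees)
  with_seed(seed, {
    # jittered grid of crown centres, >= 18 m apart
    ncol_grid <- ceiling(sqrt(n_trees))
    spacing <- 25
    idx <- seq_len(n_trees) - 1L
    gx <- (idx %% ncol_grid) * spacing
    gy <- (idx %/% ncol_grid) * spacing
    gx <- gx - mean(gx) + stats::runif(n_trees, -3, 3)
    gy <- gy - mean(gy) + stats::runif(n_trees, -3, 3)
    trees <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      nv <- sample(6:9, 1)
      ang <- sort(stats::runif(nv, 0, 2 * pi))
      rad <- stats::runif(nv, 2.5, 7.5)
      poly <- cbind(x = gx[i] + rad * cos(ang), y = gy[i] + rad * sin(ang))
      # convex hull of the sampled ring keeps crowns convex
      h <- grDevices::chull(poly)
      trees[[i]] <- poly[h[order(h)], , drop = FALSE]
    }
    names(trees) <- sprintf("tree_%02d", seq_len(n_trees))
    structure(
      list(
        trees = trees,
        centroids = t(vapply(trees, polygon_centroid, numeric(2))),
        site_lon = site_center[1],
        site_lat = site_center[2]
      ),
      class = "tree_map"
    )
  })
}

#' @export
print.tree_map <- function(x, ...) {
  cat("<tree_map>", length(x$trees), "crowns about",
      sprintf("(%.4f, %.4f)\n", x$site_lon, x$site_lat))
  invisible(x)
}

#' Write a tree map to GeoJSON
#'
#' Crown polygons are unprojected from site-local meters back to lon/lat.
#'
#' @param tree_map A `tree_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_geojson <- function(tree_map, path) {
  feats <- lapply(names(tree_map$trees), function(id) {
    poly <- tree_map$trees[[id]]
    ll <- local_unproject(poly[, 1], poly[, 2],
                          tree_map$site_lon, tree_map$site_lat)
    ring <- cbind(ll$lon, ll$lat)
    ring <- rbind(ring, ring[1, ])  # closed ring per GeoJSON spec
    list(
      type = "Feature",
      properties = list(tree_id = id),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(i) ring[i, ])))
    )
  })
  fc <- list(type = "FeatureCollection",
             properties = list(site_lon = tree_map$site_lon,
                               site_lat = tree_map$site_lat),
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Read a tree map from GeoJSON
#'
#' @param path GeoJSON file with Polygon features carrying a `tree_id`
#'   property.
#' @param site_center Optional `c(lon, lat)` projection origin; defaults to
#'   the `site_lon`/`site_lat` collection properties, else the mean vertex.
#' @return A `tree_map`.
#' @export
read_tree_geojson <- function(path, site_center = NULL) {
  gj <- jsonlite::read_json(path)
  rings <- lapply(gj$features, function(f) {
    coords <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), ]
    m
  })
  ids <- vapply(gj$features, function(f) f$properties$tree_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate tree_id in GeoJSON", call. = FALSE)
  if (is.null(site_center)) {
    if (!is.null(gj$properties$site_lon)) {
      site_center <- c(gj$properties$site_lon, gj$properties$site_lat)
    } else {
      all_v <- do.call(rbind, rings)
      site_center <- colMeans(all_v)
    }
  }
  trees <- lapply(rings, function(m) {
    xy <- local_project(m[, 1], m[, 2], site_center[1], site_center[2])
    cbind(x = xy$x, y = xy$y)
  })
  names(trees) <- ids
  structure(
    list(trees = trees,
         centroids = t(vapply(trees, polygon_centroid, numeric(2))),
         site_lon = site_center[1],
         site_lat = site_center[2]),
    class = "tree_map"
  )
}
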