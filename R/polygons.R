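#' Tile a study region into rectangular area polygons
#'
#' Builds a set of non-overlapping rectangles that exactly tile a planar
#' bounding box, standing in for the public-use microdata areas (PUMAs) the
#' method aggregates over. Coordinates are planar miles; the default box has
#' the area of Missouri (69,707 square miles). Rows of the tiling get
#' seeded-random heights and each row is split into seeded-random column
#' widths, so area sizes vary while conservation of total area is exact.
#'
#' @param area_count Number of polygons (>= 1).
#' @param seed Integer seed for the random breakpoints.
#' @param bbox Numeric \code{c(xmin, ymin, xmax, ymax)} in miles. The default
#'   is a 300-mile-wide box with total area 69,707 square miles.
#' @return An object of class \code{uisae_polygons}: a list with \code{ids}
#'   (character), \code{rings} (list of closed x/y matrices, one per area),
#'   \code{area_sqmi} (named numeric) and \code{bbox}.
#' @examples
#' polys <- generate_polygons(4, seed = 2)
#' sum(polys$area_sqmi)  # 69707
#' @export
generate_polygons <- function(area_count, seed = 1L,
                              bbox = c(0, 0, 300, 69707 / 300)) {
  if (length(area_count) != 1 || is.na(area_count) || area_count < 1)
    stop("`area_count` must be a single integer >= 1", call. = FALSE)
  area_count <- as.integer(area_count)
  stopifnot(length(bbox) == 4, bbox[3] > bbox[1], bbox[4] > bbox[2])

  with_seed(seed, {
    n_rows <- max(1L, as.integer(floor(sqrt(area_count))))
    per_row <- rep(area_count %/% n_rows, n_rows)
    extra <- area_count %% n_rows
    if (extra > 0) per_row[seq_len(extra)] <- per_row[seq_len(extra)] + 1L

    # random interior breakpoints, kept away from 0/1 so no cell degenerates
    rbreaks <- c(0, sort(stats::runif(n_rows - 1, 0.2, 0.8)), 1)
    ys <- bbox[2] + rbreaks * (bbox[4] - bbox[2])

    ids <- character(0); rings <- list(); areas <- numeric(0)
    k <- 0L
    for (r in seq_len(n_rows)) {
      nc <- per_row[r]
      cbreaks <- c(0, sort(stats::runif(nc - 1, 0.15, 0.85)), 1)
      xs <- bbox[1] + cbreaks * (bbox[3] - bbox[1])
      for (cc in seq_len(nc)) {
        k <- k + 1L
        id <- sprintf("A%02d", k)
        x0 <- xs[cc]; x1 <- xs[cc + 1]; y0 <- ys[r]; y1 <- ys[r + 1]
        ring <- cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
        ids <- c(ids, id)
        rings[[id]] <- ring
        areas[id] <- (x1 - x0) * (y1 - y0)
      }
    }
    structure(list(ids = ids, rings = rings, area_sqmi = areas, bbox = bbox),
              class = "uisae_polygons")
  })
}

#' @method print uisae_polygons
#' @export
print.uisae_polygons <- function(x, ...) {
  cat(sprintf("Area tiling: %d polygons, total %.1f sq mi (box %g x %g mi)\n",
              length(x$ids), sum(x$area_sqmi),
              x$bbox[3] - x$bbox[1], x$bbox[4] - x$bbox[2]))
  invisible(x)
}

#' Write area polygons as GeoJSON
#'
#' Serialises a polygon tiling to a GeoJSON FeatureCollection. Coordinates
#' are the generator's planar miles, recorded as such in a top-level
#' \code{crs_note} property rather than pretending to be geodetic.
#'
#' @param polygons A \code{uisae_polygons} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(polygons$ids, function(id) {
    ring <- polygons$rings[[id]]
    list(
      type = "Feature",
      properties = list(id = id,
                        area_sqmi = unname(polygons$area_sqmi[[id]])),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(i) c(ring[i, 1], ring[i, 2])))
      )
    )
  })
  fc <- list(type = "FeatureCollection",
             crs_note = "planar miles, not geodetic",
             bbox = polygons$bbox,
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read area polygons from GeoJSON
#'
#' Inverse of [write_polygons_geojson()]; also accepts FeatureCollections
#' with estimate fields attached to the properties (they are ignored).
#'
#' @param path GeoJSON file path.
#' @return A \code{uisae_polygons} object.
#' @export
read_polygons_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(fc$type, "FeatureCollection"))
  ids <- character(0); rings <- list(); areas <- numeric(0)
  for (ft in fc$features) {
    id <- ft$properties$id
    coords <- ft$geometry$coordinates[[1]]
    ring <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    colnames(ring) <- c("x", "y")
    ids <- c(ids, id)
    rings[[id]] <- ring
    a <- ft$properties$area_sqmi
    areas[id] <- if (is.null(a)) ring_area(ring) else a
  }
  bbox <- if (!is.null(fc$bbox)) unlist(fc$bbox) else {
    allxy <- do.call(rbind, rings)
    c(min(allxy[, 1]), min(allxy[, 2]), max(allxy[, 1]), max(allxy[, 2]))
  }
  structure(list(ids = ids, rings = rings, area_sqmi = areas, bbox = bbox),
            class = "uisae_polygons")
}

# Shoelace area of a closed ring.
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}
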