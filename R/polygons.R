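#' Reference degradation polygon
#'
#' A planar polygon in raster pixel coordinates (x = column, y = row from
#' the top, 0-based) with a degradation class and the calendar year of the
#' disturbance event.  The ring must be closed (first vertex repeated
#' last) and is used with the even-odd fill rule.
#'
#' @param geometry numeric matrix with columns x, y; a closed ring.
#' @param dclass `"logged"` or `"burned"`.
#' @param event_year calendar year of the disturbance.
#' @return an object of class `ref_polygon`.
#' @export
ref_polygon <- function(geometry, dclass, event_year) {
  geometry <- as.matrix(geometry)
  if (ncol(geometry) != 2L || nrow(geometry) < 4L)
    stop("`geometry` must be an n x 2 closed ring with >= 4 vertices")
  if (!isTRUE(all.equal(geometry[1L, ], geometry[nrow(geometry), ],
                        check.attributes = FALSE)))
    stop("polygon ring is not closed")
  if (!dclass %in% c("logged", "burned"))
    stop("`dclass` must be 'logged' or 'burned'")
  structure(list(geometry = unname(geometry), dclass = dclass,
                 event_year = as.integer(event_year)),
            class = "ref_polygon")
}

#' @export
print.ref_polygon <- function(x, ...) {
  cat(sprintf("<ref_polygon> %s (%d), %d vertices\n",
              x$dclass, x$event_year, nrow(x$geometry) - 1L))
  invisible(x)
}

## even-odd point-in-polygon for pixel centers; vectorized over px/py
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize reference polygons to class and year maps
#'
#' Pixels whose centers fall inside a polygon take its class code
#' (1 = logged, 2 = burned) and event year; later polygons in the list
#' overwrite earlier ones where they overlap.  Everything else is intact
#' (class 0, year `NA`).
#'
#' @param polygons list of [ref_polygon] objects.
#' @param template a `dgx_raster` defining the output grid.
#' @return list with `class_map` and `year_map` rasters.
#' @export
rasterize_polygons <- function(polygons, template) {
  stopifnot(is_raster(template))
  nr <- nrow(template$values); nc <- ncol(template$values)
  cls <- matrix(0, nr, nc)
  yr <- matrix(NA_real_, nr, nc)
  px <- rep(seq_len(nc) - 0.5, each = nr)   # pixel-center coords
  py <- rep(seq_len(nr) - 0.5, times = nc)
  code <- c(logged = 1, burned = 2)
  for (p in polygons) {
    stopifnot(inherits(p, "ref_polygon"))
    inside <- point_in_ring(px, py, p$geometry)
    cls[inside] <- code[[p$dclass]]
    yr[inside] <- p$event_year
  }
  list(class_map = dgx_raster(cls, template$pixel_size, template$origin),
       year_map = dgx_raster(yr, template$pixel_size, template$origin))
}

#' Read / write reference polygons as GeoJSON
#'
#' A FeatureCollection of Polygon features with properties `dclass` and
#' `event_year`, coordinates in raster pixel space.
#'
#' @param polygons list of [ref_polygon] objects.
#' @param path file path.
#' @return `read_polygons_geojson` returns a list of [ref_polygon];
#'   `write_polygons_geojson` returns `path` invisibly.
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(polygons, function(p) {
    stopifnot(inherits(p, "ref_polygon"))
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(p$geometry)),
                           function(i) p$geometry[i, ]))),
         properties = list(dclass = p$dclass,
                           event_year = p$event_year))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  if (!file.exists(path)) stop("no such GeoJSON file: ", path)
  fc <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("cannot parse GeoJSON file ",
                                          path, ": ", conditionMessage(e)))
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1L]],
                                  function(v) as.numeric(unlist(v))))
    ref_polygon(ring, f$properties$dclass, f$properties$event_year)
  })
}
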