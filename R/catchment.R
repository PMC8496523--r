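# Catchment areas: network reachability turned into per-facility
# service-area polygons (buffered covered segments), plus the
# straight-line disc baseline they replace.

#' Build the network catchment area of one facility
#'
#' Snaps the facility to the network, computes cutoff-bounded
#' reachability, and polygonizes the covered edge segments as the
#' dissolved union of their `buffer_m` neighbourhoods (a disc of
#' radius `buffer_m` at the snap point is always included). A facility
#' anchored to a node with no mode-traversable edges yields a plain
#' disc at the snap point.
#'
#' @param network A [road_network()].
#' @param facility A list or one-row data frame with `id`, `x`, `y`.
#' @param cutoff_m Travel-distance cutoff in meters (e.g. 5000 for the
#'   5 km walking threshold).
#' @param mode Travel mode.
#' @param buffer_m Polygonization buffer radius (default half a 100 m
#'   grid cell).
#' @param max_snap_m Maximum facility-to-network snap distance.
#' @return A `catchment` object: `facility_id`, `cutoff_m`, `mode`,
#'   `buffer_m`, `snap`, `segments` (covered segments) and `polygon`
#'   (a `geo_polygon`).
#' @export
build_catchment <- function(network, facility, cutoff_m, mode = "walk",
                            buffer_m = 50, max_snap_m = 500) {
  stopifnot(cutoff_m > 0, buffer_m > 0)
  snap <- snap_facility(network, facility$x, facility$y, mode, max_snap_m)
  tree <- reachability(network, snap, cutoff_m, mode)
  segs <- covered_segments(network, tree)
  if (length(segs) == 0) {
    poly <- geo_disc(snap$snapped_x, snap$snapped_y, buffer_m)
  } else {
    geom <- do.call(rbind, lapply(segs, segment_geometry))
    geom <- rbind(geom, seg_mat(snap$snapped_x, snap$snapped_y,
                                snap$snapped_x, snap$snapped_y))
    poly <- geo_capsules(geom, buffer_m)
  }
  structure(list(facility_id = as.character(facility$id),
                 cutoff_m = cutoff_m, mode = mode, buffer_m = buffer_m,
                 snap = snap, tree = tree, segments = segs, polygon = poly),
            class = "catchment")
}

#' @export
print.catchment <- function(x, ...) {
  cov_len <- sum(vapply(x$segments, function(s) sum(s$intervals[, 2] - s$intervals[, 1]),
                        numeric(1)))
  cat(sprintf("catchment %s: cutoff %g m (%s), %d covered segments, %.1f km network covered\n",
              x$facility_id, x$cutoff_m, x$mode, length(x$segments), cov_len / 1000))
  invisible(x)
}

#' Build catchments for a batch of facilities
#'
#' Per-facility failures (typically unsnappable facilities) are
#' collected, not raised, so one bad point never aborts a run.
#'
#' @param network A [road_network()].
#' @param facilities Data frame with columns `id`, `x`, `y` (extra
#'   columns such as `name`/`group` are carried along elsewhere).
#' @inheritParams build_catchment
#' @return List with `catchments` (named by facility id) and `skipped`
#'   (data frame `facility_id`, `reason`).
#' @export
build_all_catchments <- function(network, facilities, cutoff_m, mode = "walk",
                                 buffer_m = 50, max_snap_m = 500) {
  catchments <- list()
  skipped <- data.frame(facility_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(facilities))) {
    fac <- facilities[i, ]
    res <- tryCatch(
      build_catchment(network, fac, cutoff_m, mode, buffer_m, max_snap_m),
      microcatch_error = function(e) e
    )
    if (inherits(res, "catchment")) {
      catchments[[as.character(fac$id)]] <- res
    } else {
      skipped <- rbind(skipped, data.frame(facility_id = as.character(fac$id),
                                           reason = conditionMessage(res),
                                           stringsAsFactors = FALSE))
    }
  }
  list(catchments = catchments, skipped = skipped)
}

#' Straight-line (Euclidean disc) catchment baseline
#'
#' The conventional buffer that network catchments replace: a disc of
#' radius `cutoff_m` around the facility, ignoring the transport
#' network. Provided for comparison only.
#'
#' @param facility List or one-row data frame with `id`, `x`, `y`.
#' @param cutoff_m Disc radius (meters), > 0.
#' @return A `catchment` object whose polygon is a [geo_disc()].
#' @export
straight_line_catchment <- function(facility, cutoff_m) {
  if (!is.finite(cutoff_m) || cutoff_m <= 0) {
    mc_stop("invalid_cutoff", "cutoff_m must be a positive distance")
  }
  structure(list(facility_id = as.character(facility$id),
                 cutoff_m = cutoff_m, mode = "straight_line",
                 buffer_m = 0,
                 snap = NULL, tree = NULL, segments = list(),
                 polygon = geo_disc(facility$x, facility$y, cutoff_m)),
            class = "catchment")
}

#' Export catchment polygons as a GeoJSON FeatureCollection
#'
#' Coordinates are the working planar meters, carried as-is.
#'
#' @param catchments List of `catchment` objects.
#' @param path Output .geojson path.
#' @export
catchments_to_geojson <- function(catchments, path) {
  features <- lapply(catchments, function(ct) {
    rings <- geo_rings(ct$polygon)
    closed <- lapply(rings, function(r) {
      m <- rbind(r, r[1L, , drop = FALSE])
      lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L]))
    })
    # group rings into polygons: each CCW outer ring with its CW holes
    signs <- vapply(rings, ring_signed_area, numeric(1)) > 0
    polys <- list()
    for (i in seq_along(rings)) {
      if (signs[i]) polys[[length(polys) + 1L]] <- list(closed[[i]])
      else if (length(polys) > 0) {
        polys[[length(polys)]] <- c(polys[[length(polys)]], list(closed[[i]]))
      }
    }
    geometry <- if (length(polys) == 1) {
      list(type = "Polygon", coordinates = polys[[1]])
    } else {
      list(type = "MultiPolygon", coordinates = polys)
    }
    list(type = "Feature",
         properties = list(facility_id = ct$facility_id,
                           cutoff_m = ct$cutoff_m, mode = ct$mode,
                           buffer_m = ct$buffer_m),
         geometry = geometry)
  })
  fc <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
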