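# Minimal GeoJSON Point FeatureCollection I/O (planar coordinates
# carried as-is; CRS handling is out of scope).

#' Write a point table as a GeoJSON FeatureCollection
#' @param df Data frame with `x`, `y` and attribute columns.
#' @param path Output path.
#' @param properties Attribute columns to keep as feature properties.
#' @export
write_points_geojson <- function(df, path, properties = setdiff(names(df), c("x", "y"))) {
  properties <- intersect(properties, names(df))
  features <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, properties, drop = FALSE])
    props <- lapply(props, function(v) if (is.na(v)) NULL else v)
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10, null = "null")
  invisible(path)
}

#' Read a GeoJSON Point FeatureCollection into a data frame
#' @param path GeoJSON path.
#' @return Data frame with `x`, `y` and one column per property.
#' @export
read_points_geojson <- function(path) {
  if (!file.exists(path)) mc_stop("io_error", sprintf("file not found: %s", path))
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    mc_stop("format_error", "expected a GeoJSON FeatureCollection")
  }
  rows <- lapply(fc$features, function(f) {
    if (!identical(f$geometry$type, "Point")) {
      mc_stop("format_error", "expected Point geometries")
    }
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    c(list(x = as.numeric(f$geometry$coordinates[[1]]),
           y = as.numeric(f$geometry$coordinates[[2]])), props)
  })
  if (length(rows) == 0) return(data.frame(x = numeric(), y = numeric()))
  cols <- unique(unlist(lapply(rows, names)))
  out <- lapply(cols, function(cn) {
    vals <- lapply(rows, function(r) {
      v <- r[[cn]]
      if (is.null(v) || length(v) == 0) NA else v
    })
    if (cn %in% c("x", "y")) as.numeric(unlist(vals))
    else as.character(unlist(vals))
  })
  names(out) <- cols
  data.frame(out, stringsAsFactors = FALSE)
}
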