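# Gridded population data model and zonal extraction.
#
# A population grid holds one integer raster per age-band x sex stratum
# (WorldPop-style). Counts are persons per cell; row 1 is the
# northernmost row, matching Esri ASCII grid row order. NA marks
# nodata cells (consistent across strata).

stratum_key <- function(age_band, sex) paste(age_band, sex, sep = ".")

#' Construct a stratified population grid
#'
#' @param strata Named list of nrows-by-ncols numeric matrices of
#'   non-negative integer counts, one per stratum; names are
#'   `"<age_band>.<sex>"` keys (see `strata_info`). Row 1 is the
#'   northernmost row.
#' @param xll,yll Lower-left corner of the grid (meters).
#' @param cell_size_m Cell edge length (meters).
#' @param strata_info Data frame with columns `age_band`, `sex`
#'   describing each stratum, in the order of `strata`. Defaults to a
#'   parse of the stratum names.
#' @param nodata_value Sentinel written to .asc files for NA cells.
#' @return A `population_grid` object with a recomputed `total` layer.
#' @export
population_grid <- function(strata, xll, yll, cell_size_m,
                            strata_info = NULL, nodata_value = -9999) {
  if (length(strata) == 0) mc_stop("validation_error", "at least one stratum is required")
  dims <- lapply(strata, dim)
  if (length(unique(dims)) != 1) {
    mc_stop("format_error", "all strata must have identical dimensions")
  }
  if (is.null(names(strata)) || anyDuplicated(names(strata))) {
    mc_stop("validation_error", "strata must have unique names")
  }
  if (is.null(strata_info)) {
    parts <- strsplit(names(strata), ".", fixed = TRUE)
    strata_info <- data.frame(
      age_band = vapply(parts, function(p) paste(p[-length(p)], collapse = "."), ""),
      sex = vapply(parts, function(p) p[length(p)], ""),
      stringsAsFactors = FALSE
    )
  }
  strata <- lapply(strata, function(m) {
    storage.mode(m) <- "double"
    m
  })
  na_mask <- Reduce(`|`, lapply(strata, is.na))
  for (k in seq_along(strata)) {
    bad <- is.na(strata[[k]]) != na_mask
    if (any(bad)) mc_stop("validation_error", "nodata cells differ across strata")
    if (any(strata[[k]] < 0, na.rm = TRUE)) {
      mc_stop("validation_error", sprintf("negative counts in stratum '%s'", names(strata)[k]))
    }
  }
  total <- Reduce(`+`, strata)
  structure(list(
    ncols = ncol(total), nrows = nrow(total),
    xll = xll, yll = yll, cell_size_m = cell_size_m,
    nodata_value = nodata_value,
    strata = strata, strata_info = strata_info, total = total
  ), class = "population_grid")
}

#' @export
print.population_grid <- function(x, ...) {
  cat(sprintf("population_grid: %d x %d cells of %g m, %d strata, %s persons\n",
              x$nrows, x$ncols, x$cell_size_m, length(x$strata),
              format(sum(x$total, na.rm = TRUE), big.mark = ",")))
  invisible(x)
}

# Cell-center coordinates. Row 1 = north.
grid_cell_centers <- function(grid) {
  cs <- grid$cell_size_m
  list(
    x = grid$xll + (seq_len(grid$ncols) - 0.5) * cs,
    y = grid$yll + (grid$nrows - seq_len(grid$nrows) + 0.5) * cs
  )
}

# Expand centers for a block of rows/cols; returns vectors aligned with
# matrix indexing m[rows, cols] flattened column-major.
expand_centers <- function(grid, rows, cols) {
  ctr <- grid_cell_centers(grid)
  list(
    px = rep(ctr$x[cols], each = length(rows)),
    py = rep(ctr$y[rows], times = length(cols)),
    row = rep(rows, times = length(cols)),
    col = rep(cols, each = length(rows))
  )
}

# ---- Esri ASCII grid I/O --------------------------------------------

read_asc <- function(path) {
  if (!file.exists(path)) mc_stop("io_error", sprintf("raster file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    mc_stop("format_error", sprintf("missing ASCII grid header keys in %s", path))
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr) {
    mc_stop("format_error",
            sprintf("%s: expected %d values, found %d", path, nc * nr, length(vals)))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  list(m = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = nodata)
}

write_asc <- function(m, path, xll, yll, cellsize, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  m[is.na(m)] <- nodata
  writeLines(apply(format(m, trim = TRUE, scientific = FALSE),
                   1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a stratified population grid from a manifest
#'
#' The manifest CSV has columns `file,age_band,sex`, one row per
#' stratum raster (Esri ASCII grid, paths relative to the manifest).
#' The total layer is recomputed from the strata, never read from disk.
#'
#' @param manifest_path Path to manifest.csv.
#' @return A [population_grid()].
#' @export
read_grid <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    mc_stop("io_error", sprintf("manifest not found: %s", manifest_path))
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("file", "age_band", "sex") %in% names(man))) {
    mc_stop("format_error", "manifest must have columns file, age_band, sex")
  }
  dir <- dirname(manifest_path)
  strata <- list()
  hdr_ref <- NULL
  for (i in seq_len(nrow(man))) {
    path <- file.path(dir, man$file[i])
    r <- read_asc(path)
    hdr <- c(nrow(r$m), ncol(r$m), r$xll, r$yll, r$cellsize)
    if (is.null(hdr_ref)) {
      hdr_ref <- hdr
    } else if (!isTRUE(all.equal(hdr, hdr_ref, tolerance = 1e-9))) {
      mc_stop("format_error",
              sprintf("raster header of %s differs from the first stratum", man$file[i]))
    }
    strata[[stratum_key(man$age_band[i], man$sex[i])]] <- r$m
  }
  population_grid(strata, xll = hdr_ref[3], yll = hdr_ref[4],
                  cell_size_m = hdr_ref[5],
                  strata_info = man[, c("age_band", "sex")],
                  nodata_value = read_asc(file.path(dir, man$file[1]))$nodata)
}

#' Write a population grid as per-stratum ASCII rasters plus manifest
#'
#' @param grid A [population_grid()].
#' @param out_dir Output directory (created if absent).
#' @param prefix File-name prefix for the rasters.
#' @return Invisibly, the manifest path.
#' @export
write_grid <- function(grid, out_dir, prefix = "pop") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(grid$strata))
  for (k in seq_along(grid$strata)) {
    fn <- sprintf("%s_%s_%s.asc", prefix,
                  gsub("[^0-9A-Za-z+]+", "", grid$strata_info$age_band[k]),
                  grid$strata_info$sex[k])
    write_asc(grid$strata[[k]], file.path(out_dir, fn),
              grid$xll, grid$yll, grid$cell_size_m, grid$nodata_value)
    files[k] <- fn
  }
  man <- data.frame(file = files,
                    age_band = grid$strata_info$age_band,
                    sex = grid$strata_info$sex)
  man_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE)
  invisible(man_path)
}

#' Write a 0/1 mask as an ASCII raster
#' @param mask Logical matrix (row 1 = north). @param grid The grid the
#'   mask refers to. @param path Output .asc path.
#' @export
write_mask_asc <- function(mask, grid, path) {
  m <- matrix(as.numeric(mask), nrow = grid$nrows)
  write_asc(m, path, grid$xll, grid$yll, grid$cell_size_m, grid$nodata_value)
}

# ---- zonal extraction ------------------------------------------------

# rows/cols of cells whose bbox intersects the polygon bbox
bbox_cells <- function(grid, bb) {
  cs <- grid$cell_size_m
  c0 <- max(1L, 1L + floor((bb[1] - grid$xll) / cs))
  c1 <- min(grid$ncols, 1L + floor((bb[3] - grid$xll) / cs))
  top <- grid$yll + grid$nrows * cs
  r0 <- max(1L, 1L + floor((top - bb[4]) / cs))
  r1 <- min(grid$nrows, 1L + floor((top - bb[2]) / cs))
  if (c0 > c1 || r0 > r1) return(NULL)
  list(rows = r0:r1, cols = c0:c1)
}

#' Population inside a polygon (zonal statistics)
#'
#' `rule = "center"` counts a cell fully when its center lies inside
#' the polygon (boundary inside); this is integer-exact and partitions
#' cells. `rule = "fraction"` weights each cell count by the fraction
#' of the cell area intersecting the polygon, rounding only the final
#' per-stratum aggregates.
#'
#' @param grid A [population_grid()].
#' @param polygon A `geo_polygon`.
#' @param rule `"center"` or `"fraction"`.
#' @return A `zonal_result` list: `population_total`,
#'   `population_by_stratum`, `n_cells`, `rule`.
#' @export
zonal_population <- function(grid, polygon, rule = c("center", "fraction")) {
  rule <- match.arg(rule)
  if (!inherits(polygon, "geo_polygon")) {
    mc_stop("geometry_error", "polygon must be a geo_polygon object")
  }
  zero <- stats::setNames(numeric(length(grid$strata)), names(grid$strata))
  cells <- bbox_cells(grid, geo_bbox(polygon))
  if (is.null(cells)) {
    return(structure(list(population_total = 0,
                          population_by_stratum = zero,
                          n_cells = 0L, rule = rule), class = "zonal_result"))
  }
  if (rule == "center") {
    ec <- expand_centers(grid, cells$rows, cells$cols)
    inside <- geo_contains(polygon, ec$px, ec$py)
    idx <- cbind(ec$row[inside], ec$col[inside])
    valid <- !is.na(grid$total[idx])
    idx <- idx[valid, , drop = FALSE]
    by_stratum <- vapply(grid$strata, function(m) sum(m[idx]), numeric(1))
    structure(list(population_total = sum(by_stratum),
                   population_by_stratum = by_stratum,
                   n_cells = nrow(idx), rule = rule), class = "zonal_result")
  } else {
    rings <- geo_rings(polygon)
    cs <- grid$cell_size_m
    ctr <- grid_cell_centers(grid)
    by_stratum <- zero
    n_cells <- 0L
    for (row in cells$rows) {
      for (col in cells$cols) {
        if (is.na(grid$total[row, col])) next
        x0 <- ctr$x[col] - cs / 2; y0 <- ctr$y[row] - cs / 2
        w <- polygon_rect_area(rings, x0, y0, x0 + cs, y0 + cs) / (cs * cs)
        if (w <= 0) next
        w <- min(w, 1)
        n_cells <- n_cells + 1L
        for (k in seq_along(grid$strata)) {
          by_stratum[k] <- by_stratum[k] + w * grid$strata[[k]][row, col]
        }
      }
    }
    by_stratum <- round_half_away(by_stratum)
    structure(list(population_total = sum(by_stratum),
                   population_by_stratum = by_stratum,
                   n_cells = n_cells, rule = rule), class = "zonal_result")
  }
}

#' Cells (and population) covered by no polygon
#'
#' Center rule: a cell is uncovered when its center lies inside none of
#' the polygons. Together with the union coverage this partitions the
#' grid exactly.
#'
#' @param grid A [population_grid()].
#' @param polygons List of `geo_polygon`s (possibly empty/overlapping).
#' @return List with `mask` (logical matrix, TRUE = uncovered),
#'   `population_total` and `population_by_stratum` over uncovered
#'   non-nodata cells.
#' @export
uncovered_cells <- function(grid, polygons) {
  covered <- matrix(FALSE, grid$nrows, grid$ncols)
  for (poly in polygons) {
    cells <- bbox_cells(grid, geo_bbox(poly))
    if (is.null(cells)) next
    ec <- expand_centers(grid, cells$rows, cells$cols)
    inside <- geo_contains(poly, ec$px, ec$py)
    covered[cbind(ec$row[inside], ec$col[inside])] <- TRUE
  }
  mask <- !covered
  idx <- which(mask & !is.na(grid$total), arr.ind = TRUE)
  by_stratum <- vapply(grid$strata, function(m) sum(m[idx]), numeric(1))
  list(mask = mask,
       population_total = sum(by_stratum),
       population_by_stratum = by_stratum)
}
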