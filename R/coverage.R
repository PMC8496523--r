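# Coverage analytics: link the gridded population to facilities via
# their catchments, identify underserved cells, assign case points and
# compute per-facility case rates.

check_catchment_set <- function(catchments) {
  if (length(catchments) == 0) return(invisible(NULL))
  co <- unique(vapply(catchments, function(c) c$cutoff_m, numeric(1)))
  mo <- unique(vapply(catchments, function(c) c$mode, character(1)))
  if (length(co) != 1 || length(mo) != 1) {
    mc_stop("configuration_error", "catchments must share one cutoff and mode")
  }
  invisible(NULL)
}

#' Default cell-to-facility distance rule for exclusive assignment
#'
#' Returns a function `f(px, py, catchment)` giving, per point, the
#' Euclidean distance to the nearest point on the catchment's covered
#' segments plus that point's network distance to the source. Points
#' farther than `buffer_m` from every covered segment fall back to the
#' plain Euclidean distance to the facility snap point.
#'
#' @return A vectorized distance function.
#' @export
catchment_distance_lookup <- function() {
  function(px, py, catchment) {
    segs <- catchment$segments
    snap <- catchment$snap
    euclid_snap <- sqrt((px - snap$snapped_x)^2 + (py - snap$snapped_y)^2)
    if (length(segs) == 0) return(euclid_snap)
    # flatten all covered sub-segments with enough bookkeeping to map a
    # foot point back to its metric offset along the parent edge
    geom <- list(); meta <- list()
    for (si in seq_along(segs)) {
      cs <- segs[[si]]
      g <- segment_geometry(cs)
      for (k in seq_len(nrow(g))) {
        geom[[length(geom) + 1L]] <- g[k, , drop = FALSE]
        meta[[length(meta) + 1L]] <- list(si = si,
                                          t0 = cs$intervals[k, 1],
                                          t1 = cs$intervals[k, 2])
      }
    }
    seg <- do.call(rbind, geom)
    hit <- nearest_on_segments(px, py, seg)
    d <- euclid_snap
    near <- hit$dist <= catchment$buffer_m + 1e-9
    for (i in which(near)) {
      m <- meta[[hit$index[i]]]
      cs <- segs[[m$si]]
      s <- seg[hit$index[i], ]
      glen <- sqrt((s[3] - s[1])^2 + (s[4] - s[2])^2)
      f <- if (glen > 0) hit$offset_m[i] / glen else 0
      t <- m$t0 + f * (m$t1 - m$t0)
      d[i] <- hit$dist[i] + segment_network_distance(cs, t)
    }
    d
  }
}

# per-catchment logical coverage matrix over cell centers
coverage_mask <- function(grid, polygon) {
  m <- matrix(FALSE, grid$nrows, grid$ncols)
  cells <- bbox_cells(grid, geo_bbox(polygon))
  if (is.null(cells)) return(m)
  ec <- expand_centers(grid, cells$rows, cells$cols)
  inside <- geo_contains(polygon, ec$px, ec$py)
  m[cbind(ec$row[inside], ec$col[inside])] <- TRUE
  m
}

sum_strata_cells <- function(grid, idx) {
  vapply(grid$strata, function(m) sum(m[idx], na.rm = TRUE), numeric(1))
}

#' Link population to facilities through their catchments
#'
#' Under `independent` assignment each facility is credited with the
#' full (center-rule) population of its own polygon, so people inside
#' overlapping catchments are counted once per facility. Under
#' `exclusive` assignment every covered cell is credited to exactly
#' one covering facility — the one with the smallest cell-to-facility
#' distance per `distance_lookup`, ties broken by smallest facility
#' id — so facility populations plus the underserved population
#' partition the grid total exactly.
#'
#' @param catchments List of `catchment` objects sharing cutoff and
#'   mode.
#' @param grid A [population_grid()].
#' @param assignment `"independent"` or `"exclusive"`.
#' @param distance_lookup Required for `exclusive`: a function
#'   `f(px, py, catchment)` returning per-point distances (see
#'   [catchment_distance_lookup()]).
#' @return A `coverage_result`: `per_facility` data frame
#'   (facility_id, population_total, n_cells, one column per stratum),
#'   `underserved_total`, `underserved_by_stratum`, `underserved_mask`,
#'   `assignment`, `cutoff_m`, `mode`.
#' @export
compute_coverage <- function(catchments, grid,
                             assignment = c("independent", "exclusive"),
                             distance_lookup = NULL) {
  assignment <- match.arg(assignment)
  check_catchment_set(catchments)
  keys <- names(grid$strata)
  fids <- vapply(catchments, function(c) c$facility_id, character(1))
  if (length(fids) > 0 && anyDuplicated(fids)) {
    mc_stop("configuration_error", "duplicate facility ids in catchment set")
  }
  und <- uncovered_cells(grid, lapply(catchments, function(c) c$polygon))
  if (assignment == "independent") {
    rows <- lapply(catchments, function(ct) {
      z <- zonal_population(grid, ct$polygon, rule = "center")
      c(list(facility_id = ct$facility_id,
             population_total = z$population_total, n_cells = z$n_cells),
        as.list(z$population_by_stratum))
    })
  } else {
    if (is.null(distance_lookup)) {
      mc_stop("configuration_error",
              "exclusive assignment requires a distance_lookup (see catchment_distance_lookup())")
    }
    ord <- order(fids)
    best_d <- matrix(Inf, grid$nrows, grid$ncols)
    owner <- matrix(NA_integer_, grid$nrows, grid$ncols)
    ctr <- grid_cell_centers(grid)
    # iterate in descending id order so that on exact distance ties the
    # smallest facility_id (processed last) takes the cell
    for (oi in rev(ord)) {
      ct <- catchments[[oi]]
      cm <- coverage_mask(grid, ct$polygon)
      idx <- which(cm, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      d <- distance_lookup(ctr$x[idx[, 2]], ctr$y[idx[, 1]], ct)
      upd <- d <= best_d[idx]
      best_d[idx[upd, , drop = FALSE]] <- d[upd]
      owner[idx[upd, , drop = FALSE]] <- oi
    }
    rows <- lapply(seq_along(catchments), function(oi) {
      idx <- which(owner == oi & !is.na(grid$total), arr.ind = TRUE)
      by_s <- sum_strata_cells(grid, idx)
      c(list(facility_id = catchments[[oi]]$facility_id,
             population_total = sum(by_s), n_cells = nrow(idx)),
        as.list(by_s))
    })
  }
  per_facility <- if (length(rows) == 0) {
    stats::setNames(
      data.frame(matrix(numeric(0), ncol = 3 + length(keys))),
      c("facility_id", "population_total", "n_cells", keys))
  } else {
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  }
  per_facility <- per_facility[order(per_facility$facility_id), , drop = FALSE]
  rownames(per_facility) <- NULL
  structure(list(per_facility = per_facility,
                 underserved_total = und$population_total,
                 underserved_by_stratum = und$population_by_stratum,
                 underserved_mask = und$mask,
                 assignment = assignment,
                 cutoff_m = if (length(catchments)) catchments[[1]]$cutoff_m else NA_real_,
                 mode = if (length(catchments)) catchments[[1]]$mode else NA_character_),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("coverage_result (%s): %d facilities, %s covered, %s underserved\n",
              x$assignment, nrow(x$per_facility),
              format(sum(x$per_facility$population_total), big.mark = ","),
              format(x$underserved_total, big.mark = ",")))
  invisible(x)
}

#' Population outside every catchment (underserved areas)
#'
#' @param catchments List of `catchment` objects.
#' @param grid A [population_grid()].
#' @return List with `population_total`, `population_by_stratum` and
#'   `mask` (TRUE = center inside no catchment), suitable for export
#'   with [write_mask_asc()].
#' @export
identify_underserved <- function(catchments, grid) {
  uncovered_cells(grid, lapply(catchments, function(c) c$polygon))
}

#' Assign case points to facilities (exclusive rule)
#'
#' Each point lying inside at least one catchment polygon is assigned
#' to the covering facility with the smallest `distance_lookup`
#' distance (ties by smallest facility id); points outside all
#' polygons get `NA`.
#'
#' @param cases Data frame with `x`, `y` columns.
#' @param catchments List of `catchment` objects.
#' @param distance_lookup Distance function, default
#'   [catchment_distance_lookup()].
#' @return `cases` with an `assigned_facility` column.
#' @export
assign_cases <- function(cases, catchments,
                         distance_lookup = catchment_distance_lookup()) {
  cases$assigned_facility <- rep(NA_character_, nrow(cases))
  if (nrow(cases) == 0 || length(catchments) == 0) return(cases)
  check_catchment_set(catchments)
  fids <- vapply(catchments, function(c) c$facility_id, character(1))
  best_d <- rep(Inf, nrow(cases))
  for (oi in rev(order(fids))) {
    ct <- catchments[[oi]]
    inside <- geo_contains(ct$polygon, cases$x, cases$y)
    if (!any(inside)) next
    d <- rep(Inf, nrow(cases))
    d[inside] <- distance_lookup(cases$x[inside], cases$y[inside], ct)
    upd <- inside & d <= best_d
    best_d[upd] <- d[upd]
    cases$assigned_facility[upd] <- ct$facility_id
  }
  cases
}

#' Per-facility case rates
#'
#' @param assigned_cases Output of [assign_cases()].
#' @param coverage A [compute_coverage()] result on the same
#'   catchments.
#' @param rate_basis Persons per rate unit (default 100,000).
#' @return Data frame `facility_id`, `cases`, `population`, `rate`
#'   (NA when the population is 0), `rate_basis`.
#' @export
case_rates <- function(assigned_cases, coverage, rate_basis = 1e5) {
  pf <- coverage$per_facility
  assigned <- assigned_cases$assigned_facility
  assigned <- assigned[!is.na(assigned)]
  unknown <- setdiff(unique(assigned), pf$facility_id)
  if (length(unknown) > 0) {
    mc_stop("consistency_error",
            sprintf("cases assigned to facilities absent from coverage: %s",
                    paste(unknown, collapse = ", ")))
  }
  counts <- table(factor(assigned, levels = pf$facility_id))
  out <- data.frame(facility_id = pf$facility_id,
                    cases = as.integer(counts),
                    population = pf$population_total,
                    stringsAsFactors = FALSE)
  out$rate <- ifelse(out$population > 0,
                     out$cases / out$population * rate_basis, NA_real_)
  out$rate_basis <- rate_basis
  out
}
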