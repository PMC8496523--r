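# Seeded synthetic inputs: settlement-clustered stratified population
# grids, connected transport networks (perturbed lattice with diagonal
# shortcuts), facilities near dense areas, and case points inside
# catchments. These emulate the statistical structure of gridded
# population products, OSM-like networks and facility registries so
# the full pipeline is testable offline.

#' Default age/sex pyramid (WorldPop-style bands)
#'
#' Age bands 0, 1-4, 5-9, ..., 80+ crossed with sex f/m. Proportions
#' follow a stylized declining age structure (geometric decay over
#' 5-year bands) with an even sex split, normalized to sum to 1.
#'
#' @return Data frame `age_band`, `sex`, `proportion`.
#' @export
default_pyramid <- function() {
  bands <- c("0", "1-4", paste(seq(5, 75, 5), seq(9, 79, 5), sep = "-"), "80+")
  widths <- c(1, 4, rep(5, 15), 10)
  decay <- 0.97 ^ (c(0, cumsum(widths))[seq_along(bands)])
  w <- widths * decay
  props <- rep(w / sum(w) / 2, times = 2)
  data.frame(age_band = rep(bands, 2),
             sex = rep(c("f", "m"), each = length(bands)),
             proportion = props,
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-data generators
#'
#' @param seed Master seed; the network, grid, facility and case
#'   generators draw from independent sub-streams derived from it.
#' @param extent `c(xmin, ymin, xmax, ymax)` in meters; truncated to a
#'   whole number of cells.
#' @param cell_size_m Population-grid cell edge (meters).
#' @param n_settlements Number of Gaussian settlement clusters.
#' @param settlement_amplitude Expected peak persons/cell of each
#'   settlement (scalar or per-settlement vector).
#' @param settlement_sigma_m Settlement spread (meters; scalar or
#'   vector).
#' @param background_rate Expected background persons/cell.
#' @param pyramid Data frame `age_band`, `sex`, `proportion` summing
#'   to 1.
#' @param n_network_nodes Nodes of the synthetic transport network.
#' @param n_facilities Facilities to place.
#' @param case_rate_per_1000 Expected cases per 1,000 catchment
#'   residents.
#' @param max_snap_m Facilities are placed within this distance of the
#'   network.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         extent = c(0, 0, 6000, 6000),
                         cell_size_m = 100,
                         n_settlements = 4L,
                         settlement_amplitude = 40,
                         settlement_sigma_m = 500,
                         background_rate = 0.05,
                         pyramid = default_pyramid(),
                         n_network_nodes = 250L,
                         n_facilities = 6L,
                         case_rate_per_1000 = 10,
                         max_snap_m = 500) {
  if (length(extent) != 4 || extent[3] <= extent[1] || extent[4] <= extent[2]) {
    mc_stop("invalid_config", "extent must be c(xmin, ymin, xmax, ymax) with positive area")
  }
  if (cell_size_m <= 0) mc_stop("invalid_config", "cell_size_m must be positive")
  if ((extent[3] - extent[1]) < cell_size_m || (extent[4] - extent[2]) < cell_size_m) {
    mc_stop("invalid_config", "extent must contain at least one whole cell")
  }
  if (abs(sum(pyramid$proportion) - 1) > 1e-9) {
    mc_stop("invalid_config", "pyramid proportions must sum to 1")
  }
  if (n_settlements < 0 || n_network_nodes < 0 || n_facilities < 0 ||
      background_rate < 0 || case_rate_per_1000 < 0) {
    mc_stop("invalid_config", "counts and rates must be non-negative")
  }
  if (any(settlement_amplitude <= 0) || any(settlement_sigma_m <= 0)) {
    mc_stop("invalid_config", "settlement amplitude and sigma must be positive")
  }
  structure(list(seed = seed, extent = extent, cell_size_m = cell_size_m,
                 n_settlements = as.integer(n_settlements),
                 settlement_amplitude = rep_len(settlement_amplitude,
                                                max(1L, n_settlements)),
                 settlement_sigma_m = rep_len(settlement_sigma_m,
                                              max(1L, n_settlements)),
                 background_rate = background_rate, pyramid = pyramid,
                 n_network_nodes = as.integer(n_network_nodes),
                 n_facilities = as.integer(n_facilities),
                 case_rate_per_1000 = case_rate_per_1000,
                 max_snap_m = max_snap_m),
            class = "synth_config")
}

# settlement centers are drawn in their own sub-stream so the grid can
# be regenerated without shifting the network or facilities
settlement_centers <- function(config) {
  with_seed(substream_seed(config$seed, 2L), {
    n <- config$n_settlements
    ex <- config$extent
    data.frame(x = stats::runif(n, ex[1], ex[3]),
               y = stats::runif(n, ex[2], ex[4]),
               amplitude = config$settlement_amplitude[seq_len(n)],
               sigma = config$settlement_sigma_m[seq_len(n)])
  })
}

# Poisson rate surface lambda(cell) over the truncated grid
lambda_surface <- function(config) {
  ex <- config$extent
  cs <- config$cell_size_m
  ncols <- floor((ex[3] - ex[1]) / cs)
  nrows <- floor((ex[4] - ex[2]) / cs)
  cx <- ex[1] + (seq_len(ncols) - 0.5) * cs
  cy <- ex[2] + (nrows - seq_len(nrows) + 0.5) * cs  # row 1 = north
  lam <- matrix(config$background_rate, nrows, ncols)
  if (config$n_settlements > 0) {
    st <- settlement_centers(config)
    for (k in seq_len(nrow(st))) {
      d2 <- outer((cy - st$y[k])^2, (cx - st$x[k])^2, `+`)
      lam <- lam + st$amplitude[k] * exp(-d2 / (2 * st$sigma[k]^2))
    }
  }
  lam
}

#' Generate a stratified synthetic population grid
#'
#' Cell totals are Poisson with rate `background_rate` plus a sum of
#' Gaussian settlement kernels; each total is split across the age/sex
#' pyramid by a multinomial draw, so strata sum to the total in every
#' cell. Deterministic for a fixed config.
#'
#' @param config A [synth_config()].
#' @return A [population_grid()].
#' @export
generate_population_grid <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lam <- lambda_surface(config)
  pyr <- config$pyramid
  keys <- stratum_key(pyr$age_band, pyr$sex)
  with_seed(substream_seed(config$seed, 2L), {
    # skip the settlement-center draws so the totals stream is aligned
    # with settlement_centers() reuse of the same sub-stream
    if (config$n_settlements > 0) stats::runif(2 * config$n_settlements)
    totals <- matrix(stats::rpois(length(lam), as.vector(lam)),
                     nrow = nrow(lam), ncol = ncol(lam))
    strata <- lapply(keys, function(k) matrix(0, nrow(lam), ncol(lam)))
    names(strata) <- keys
    pos <- which(totals > 0)
    for (j in pos) {
      split <- stats::rmultinom(1L, totals[j], pyr$proportion)[, 1L]
      for (k in seq_along(keys)) strata[[k]][j] <- split[k]
    }
    population_grid(strata, xll = config$extent[1], yll = config$extent[2],
                    cell_size_m = config$cell_size_m,
                    strata_info = pyr[, c("age_band", "sex")])
  })
}

#' Generate a synthetic transport network
#'
#' A jittered lattice with nearest-neighbour road edges, random edge
#' dropout and random diagonal shortcuts, rewired until the largest
#' connected component holds at least 90% of nodes. Shortest paths
#' over such a network differ measurably from straight lines, which is
#' what network catchments are for. Edge classes/modes: roads
#' (walk|drive), paths (walk), ferry lines (ferry), railways (drive).
#'
#' @param config A [synth_config()].
#' @return A [road_network()] with Euclidean edge lengths.
#' @export
generate_road_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_network_nodes
  if (n == 0) {
    return(road_network(data.frame(node_id = character(), x = numeric(),
                                   y = numeric()), NULL))
  }
  ex <- config$extent
  w <- ex[3] - ex[1]; h <- ex[4] - ex[2]
  with_seed(substream_seed(config$seed, 1L), {
    mc <- max(1L, round(sqrt(n * w / h)))
    mr <- ceiling(n / mc)
    sx <- w / mc; sy <- h / mr
    ij <- expand.grid(i = seq_len(mc), j = seq_len(mr))  # i = col, j = row
    ij <- ij[order(ij$j, ij$i), ][seq_len(n), ]
    x <- ex[1] + (ij$i - 0.5) * sx + stats::runif(n, -0.3, 0.3) * sx
    y <- ex[2] + (ij$j - 0.5) * sy + stats::runif(n, -0.3, 0.3) * sy
    nodes <- data.frame(node_id = sprintf("n%04d", seq_len(n)), x = x, y = y)
    key <- function(i, j) ifelse(j >= 1 & j <= mr & i >= 1 & i <= mc,
                                 (j - 1) * mc + i, NA)
    u <- integer(0); v <- integer(0)
    for (d in list(c(1, 0), c(0, 1))) {
      a <- key(ij$i, ij$j); b <- key(ij$i + d[1], ij$j + d[2])
      ok <- !is.na(b) & b <= n
      u <- c(u, a[ok]); v <- c(v, b[ok])
    }
    keep <- stats::runif(length(u)) < 0.9
    u <- u[keep]; v <- v[keep]
    # diagonal shortcuts
    a <- key(ij$i, ij$j); b <- key(ij$i + 1, ij$j + 1)
    ok <- which(!is.na(b) & b <= n & stats::runif(length(b)) < 0.15)
    u <- c(u, a[ok]); v <- c(v, b[ok])
    # rewire until the largest component holds >= 90% of nodes
    repeat {
      g <- igraph::graph_from_edgelist(cbind(u, v), directed = FALSE)
      g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
      comp <- igraph::components(g)
      if (max(comp$csize) >= 0.9 * n || comp$no == 1) break
      big <- which.max(comp$csize)
      other <- which(comp$membership != big)
      main <- which(comp$membership == big)
      # connect the globally nearest cross-component node pair
      d2 <- outer(x[other], x[main], `-`)^2 + outer(y[other], y[main], `-`)^2
      hit <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
      u <- c(u, other[hit[1]]); v <- c(v, main[hit[2]])
    }
    ne <- length(u)
    cls <- sample(c("road", "path", "ferry_line", "railway"), ne,
                  replace = TRUE, prob = c(0.72, 0.25, 0.02, 0.01))
    modes <- c(road = "walk|drive", path = "walk",
               ferry_line = "ferry", railway = "drive")[cls]
    edges <- data.frame(edge_id = sprintf("e%04d", seq_len(ne)),
                        u = nodes$node_id[u], v = nodes$node_id[v],
                        length_m = NA_real_, modes = unname(modes),
                        edge_class = unname(cls))
    road_network(nodes, edges)
  })
}

#' Place facilities proportional to local population density
#'
#' Samples cells with probability proportional to their population
#' (uniform when the grid is empty), jitters the point inside the
#' cell, and pulls any point farther than `max_snap_m` from the
#' network onto it. Facilities are labelled into three `zone_*` groups
#' by x-position terciles (the Table-2-style grouping key).
#'
#' @param network A [road_network()] (non-empty if `n_facilities` > 0).
#' @param grid A [population_grid()].
#' @param config A [synth_config()].
#' @return Data frame `id`, `name`, `group`, `x`, `y`.
#' @export
generate_facilities <- function(network, grid, config) {
  stopifnot(inherits(config, "synth_config"))
  nf <- config$n_facilities
  if (nf == 0) {
    return(data.frame(id = character(), name = character(), group = character(),
                      x = numeric(), y = numeric(), stringsAsFactors = FALSE))
  }
  if (nrow(network$edges) == 0) {
    mc_stop("invalid_config", "cannot place facilities on an empty network")
  }
  seg <- edge_coords(network, seq_len(nrow(network$edges)))
  ctr <- grid_cell_centers(grid)
  with_seed(substream_seed(config$seed, 3L), {
    wts <- as.vector(grid$total)
    wts[is.na(wts)] <- 0
    if (sum(wts) == 0) wts <- rep(1, length(wts))
    cells <- sample.int(length(wts), nf, replace = TRUE, prob = wts)
    rows <- (cells - 1L) %% grid$nrows + 1L
    cols <- (cells - 1L) %/% grid$nrows + 1L
    cs <- grid$cell_size_m
    x <- ctr$x[cols] + stats::runif(nf, -0.4, 0.4) * cs
    y <- ctr$y[rows] + stats::runif(nf, -0.4, 0.4) * cs
    hit <- nearest_on_segments(x, y, seg)
    far <- hit$dist > config$max_snap_m
    if (any(far)) {
      for (i in which(far)) {
        s <- seg[hit$index[i], ]
        L <- sqrt((s[3] - s[1])^2 + (s[4] - s[2])^2)
        f <- if (L > 0) hit$offset_m[i] / L else 0
        px <- s[1] + f * (s[3] - s[1]); py <- s[2] + f * (s[4] - s[2])
        shift <- config$max_snap_m * 0.25 / hit$dist[i]
        x[i] <- px + (x[i] - px) * shift
        y[i] <- py + (y[i] - py) * shift
      }
    }
    ex <- config$extent
    tercile <- findInterval(x, ex[1] + (ex[3] - ex[1]) * c(1, 2) / 3) + 1L
    data.frame(id = sprintf("fac_%03d", seq_len(nf)),
               name = sprintf("Health facility %d", seq_len(nf)),
               group = sprintf("zone_%d", tercile),
               x = x, y = y, stringsAsFactors = FALSE)
  })
}

#' Generate case points inside catchment areas
#'
#' Per catchment, the number of cases is Poisson with mean
#' `case_rate_per_1000 x population / 1000` (population by the center
#' rule); points are placed uniformly inside the catchment polygon by
#' rejection sampling. Deterministic for a fixed config.
#'
#' @param catchments List of `catchment` objects.
#' @param grid A [population_grid()].
#' @param config A [synth_config()].
#' @return Data frame `x`, `y`, `origin_facility` (the generating
#'   catchment) with `assigned_facility` initialized to NA.
#' @export
generate_case_points <- function(catchments, grid, config) {
  stopifnot(inherits(config, "synth_config"))
  empty <- data.frame(x = numeric(), y = numeric(),
                      origin_facility = character(),
                      assigned_facility = character(),
                      stringsAsFactors = FALSE)
  if (length(catchments) == 0 || config$case_rate_per_1000 == 0) return(empty)
  with_seed(substream_seed(config$seed, 4L), {
    out <- list()
    for (ct in catchments) {
      pop <- zonal_population(grid, ct$polygon, rule = "center")$population_total
      n <- stats::rpois(1L, config$case_rate_per_1000 * pop / 1000)
      if (n == 0) next
      bb <- geo_bbox(ct$polygon)
      px <- numeric(0); py <- numeric(0)
      while (length(px) < n) {
        m <- max(32L, 2L * (n - length(px)))
        cx <- stats::runif(m, bb[1], bb[3])
        cy <- stats::runif(m, bb[2], bb[4])
        ok <- geo_contains(ct$polygon, cx, cy)
        px <- c(px, cx[ok]); py <- c(py, cy[ok])
      }
      out[[length(out) + 1L]] <- data.frame(
        x = px[seq_len(n)], y = py[seq_len(n)],
        origin_facility = ct$facility_id,
        assigned_facility = NA_character_, stringsAsFactors = FALSE)
    }
    if (length(out) == 0) empty else do.call(rbind, out)
  })
}

#' Write a full synthetic scene to disk in the pipeline's input formats
#'
#' Produces nodes.csv/edges.csv, per-stratum .asc rasters plus
#' manifest.csv, facilities.geojson and (when catchments are supplied)
#' cases.geojson.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory.
#' @param cutoff_m,mode,buffer_m Catchment parameters used only when
#'   `with_cases = TRUE`.
#' @param with_cases Also build catchments and emit case points.
#' @return Invisibly, a named list of the files written.
#' @export
write_synthetic_inputs <- function(config, out_dir, with_cases = FALSE,
                                   cutoff_m = 2500, mode = "walk",
                                   buffer_m = config$cell_size_m / 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  network <- generate_road_network(config)
  grid <- generate_population_grid(config)
  facilities <- generate_facilities(network, grid, config)
  write_network(network, file.path(out_dir, "nodes.csv"),
                file.path(out_dir, "edges.csv"))
  manifest <- write_grid(grid, out_dir)
  write_points_geojson(facilities, file.path(out_dir, "facilities.geojson"),
                       c("id", "name", "group"))
  files <- list(nodes = file.path(out_dir, "nodes.csv"),
                edges = file.path(out_dir, "edges.csv"),
                manifest = manifest,
                facilities = file.path(out_dir, "facilities.geojson"))
  if (with_cases && nrow(facilities) > 0) {
    built <- build_all_catchments(network, facilities, cutoff_m, mode,
                                  buffer_m, config$max_snap_m)
    cases <- generate_case_points(built$catchments, grid, config)
    write_points_geojson(cases, file.path(out_dir, "cases.geojson"),
                         c("origin_facility", "assigned_facility"))
    files$cases <- file.path(out_dir, "cases.geojson")
  }
  invisible(files)
}
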