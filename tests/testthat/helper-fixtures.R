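# Shared fixtures and independent oracles. Oracles are deliberately
# naive (enumeration / scalar loops) so they share no code path with
# the implementation they check.

# chain A --3000m-- B --3000m-- C laid out on the x axis
chain_network <- function() {
  road_network(
    data.frame(node_id = c("A", "B", "C"), x = c(0, 3000, 6000), y = 0),
    data.frame(edge_id = c("eAB", "eBC"), u = c("A", "B"), v = c("B", "C"),
               length_m = c(3000, 3000), modes = "walk", edge_class = "road")
  )
}

# triangle with stored lengths decoupled from layout: AB = AC = 2000,
# BC = 5000
triangle_network <- function() {
  road_network(
    data.frame(node_id = c("A", "B", "C"),
               x = c(0, -1500, 1500), y = c(0, 1500, 1500)),
    data.frame(edge_id = c("eAB", "eAC", "eBC"),
               u = c("A", "A", "B"), v = c("B", "C", "C"),
               length_m = c(2000, 2000, 5000), modes = "walk",
               edge_class = "road")
  )
}

# uniform single-stratum grid: every cell holds `fill` persons
flat_grid <- function(nrows, ncols, cell = 100, fill = 1, xll = 0, yll = 0) {
  population_grid(list("0-99.f" = matrix(fill, nrows, ncols)),
                  xll = xll, yll = yll, cell_size_m = cell)
}

small_pyramid <- function() {
  data.frame(age_band = c("0-14", "0-14", "15+", "15+"),
             sex = c("f", "m", "f", "m"),
             proportion = c(0.2, 0.2, 0.3, 0.3))
}

small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, extent = c(0, 0, 2000, 2000), cell_size_m = 100,
               n_settlements = 2, settlement_amplitude = 25,
               settlement_sigma_m = 300, background_rate = 0.05,
               pyramid = small_pyramid(), n_network_nodes = 60,
               n_facilities = 3, case_rate_per_1000 = 10)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# random star-shaped simple polygon (vertices sorted by angle)
random_star_polygon <- function(cx, cy, rmin, rmax, n = 9) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  geo_ringpoly(cbind(cx + r * cos(th), cy + r * sin(th)))
}

# ---- oracles ---------------------------------------------------------

# classic scalar pnpoly crossing test (boundary not special-cased;
# test polygons keep cell centers off their edges)
oracle_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ring[i, 2] > py) != (ring[j, 2] > py)) {
      xin <- ring[j, 1] + (py - ring[j, 2]) / (ring[i, 2] - ring[j, 2]) *
        (ring[i, 1] - ring[j, 1])
      if (px < xin) inside <- !inside
    }
    j <- i
  }
  inside
}

# shortest path by exhaustive simple-path enumeration (DFS)
oracle_shortest <- function(node_ids, edge_df, src) {
  best <- stats::setNames(rep(Inf, length(node_ids)), node_ids)
  best[src] <- 0
  rec <- function(cur, dist, visited) {
    inc <- which(edge_df$u == cur | edge_df$v == cur)
    for (i in inc) {
      nxt <- if (edge_df$u[i] == cur) edge_df$v[i] else edge_df$u[i]
      if (nxt %in% visited) next
      d <- dist + edge_df$length_m[i]
      if (d < best[nxt]) best[nxt] <<- d
      rec(nxt, d, c(visited, nxt))
    }
  }
  rec(src, 0, src)
  best
}

# hand BFS connectivity check (keeps the oracle free of igraph)
oracle_connected <- function(node_ids, edge_df) {
  if (length(node_ids) == 0) return(TRUE)
  seen <- node_ids[1]
  repeat {
    nxt <- unique(c(edge_df$v[edge_df$u %in% seen],
                    edge_df$u[edge_df$v %in% seen]))
    grown <- union(seen, nxt)
    if (length(grown) == length(seen)) break
    seen <- grown
  }
  length(seen) == length(node_ids)
}

# random connected network of n nodes with Euclidean edge lengths
random_connected_network <- function(n, p = 0.45, span = 5000) {
  repeat {
    x <- stats::runif(n, 0, span)
    y <- stats::runif(n, 0, span)
    ids <- sprintf("n%02d", seq_len(n))
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p
    if (!any(keep)) next
    pr <- pairs[, keep, drop = FALSE]
    edges <- data.frame(
      edge_id = sprintf("e%03d", seq_len(ncol(pr))),
      u = ids[pr[1, ]], v = ids[pr[2, ]],
      length_m = sqrt((x[pr[1, ]] - x[pr[2, ]])^2 + (y[pr[1, ]] - y[pr[2, ]])^2),
      modes = "walk", edge_class = "road", stringsAsFactors = FALSE)
    if (oracle_connected(ids, edges)) {
      return(road_network(data.frame(node_id = ids, x = x, y = y), edges))
    }
  }
}

# a network_location sitting exactly on a node, via an incident edge
location_at_node <- function(network, node_id) {
  i <- match(node_id, network$nodes$node_id)
  snap_facility(network, network$nodes$x[i], network$nodes$y[i],
                mode = "walk", max_snap_m = 1)
}

# small ready-made scene for coverage tests
make_scene <- function(seed, cutoff_m = 800, n_facilities = 3) {
  cfg <- small_config(seed = seed, n_facilities = n_facilities)
  network <- generate_road_network(cfg)
  grid <- generate_population_grid(cfg)
  facilities <- generate_facilities(network, grid, cfg)
  built <- build_all_catchments(network, facilities, cutoff_m, "walk",
                                buffer_m = 50, max_snap_m = cfg$max_snap_m)
  list(config = cfg, network = network, grid = grid,
       facilities = facilities, catchments = built$catchments,
       skipped = built$skipped)
}
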