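# Transport network: undirected planar graph with per-edge travel
# modes, plus facility snapping and cutoff-bounded shortest-path
# reachability (the service-area engine).

TRAVEL_MODES <- c("walk", "drive", "ferry")
EDGE_CLASSES <- c("road", "path", "ferry_line", "railway", "river")

#' Construct and validate a road network
#'
#' @param nodes Data frame with columns `node_id`, `x`, `y` (meters,
#'   projected).
#' @param edges Data frame with columns `edge_id`, `u`, `v`,
#'   `length_m`, `modes` (|-separated subset of walk/drive/ferry) and
#'   `edge_class`. Missing `length_m` is filled with the Euclidean
#'   endpoint distance.
#' @return A `road_network` object.
#' @export
road_network <- function(nodes, edges) {
  nodes <- data.frame(node_id = as.character(nodes$node_id),
                      x = as.numeric(nodes$x), y = as.numeric(nodes$y),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$node_id)) mc_stop("validation_error", "duplicate node ids")
  if (any(!is.finite(nodes$x)) || any(!is.finite(nodes$y))) {
    mc_stop("validation_error", "node coordinates must be finite")
  }
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(edge_id = character(), u = character(), v = character(),
                        length_m = numeric(), modes = character(),
                        edge_class = character(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(edge_id = as.character(edges$edge_id),
                        u = as.character(edges$u), v = as.character(edges$v),
                        length_m = if ("length_m" %in% names(edges))
                          as.numeric(edges$length_m) else NA_real_,
                        modes = as.character(edges$modes),
                        edge_class = if ("edge_class" %in% names(edges))
                          as.character(edges$edge_class) else "road",
                        stringsAsFactors = FALSE)
    if (anyDuplicated(edges$edge_id)) mc_stop("validation_error", "duplicate edge ids")
    dangling <- setdiff(c(edges$u, edges$v), nodes$node_id)
    if (length(dangling) > 0) {
      mc_stop("validation_error",
              sprintf("edge endpoints not in node table: %s",
                      paste(sort(dangling), collapse = ", ")))
    }
    if (any(edges$u == edges$v)) mc_stop("validation_error", "self-loop edges are not allowed")
    iu <- match(edges$u, nodes$node_id)
    iv <- match(edges$v, nodes$node_id)
    eu <- sqrt((nodes$x[iu] - nodes$x[iv])^2 + (nodes$y[iu] - nodes$y[iv])^2)
    edges$length_m[is.na(edges$length_m)] <- eu[is.na(edges$length_m)]
    if (any(edges$length_m <= 0)) {
      mc_stop("validation_error",
              sprintf("non-positive edge lengths: %s",
                      paste(edges$edge_id[edges$length_m <= 0], collapse = ", ")))
    }
    mode_list <- strsplit(edges$modes, "|", fixed = TRUE)
    ok <- vapply(mode_list, function(m) length(m) > 0 && all(m %in% TRAVEL_MODES),
                 logical(1))
    if (!all(ok)) {
      mc_stop("validation_error",
              sprintf("invalid mode sets on edges: %s",
                      paste(edges$edge_id[!ok], collapse = ", ")))
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("road_network: %d nodes, %d edges (%.1f km total)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_m) / 1000))
  invisible(x)
}

#' Read a network from node/edge CSV files
#'
#' `nodes.csv` has header `node_id,x,y`; `edges.csv` has header
#' `edge_id,u,v,length_m,modes,edge_class` with `modes` a |-separated
#' list (e.g. `walk|drive`) and `length_m` optionally empty.
#'
#' @param nodes_path,edges_path CSV paths.
#' @return A [road_network()].
#' @export
load_network <- function(nodes_path, edges_path) {
  for (p in c(nodes_path, edges_path)) {
    if (!file.exists(p)) mc_stop("io_error", sprintf("file not found: %s", p))
  }
  nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE,
                           colClasses = c(node_id = "character"))
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE,
                           colClasses = c(edge_id = "character", u = "character",
                                          v = "character"))
  road_network(nodes, edges)
}

#' Write a network to node/edge CSV files
#' @param network A [road_network()]. @param nodes_path,edges_path
#'   Output CSV paths.
#' @export
write_network <- function(network, nodes_path, edges_path) {
  utils::write.csv(network$nodes, nodes_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(network$edges, edges_path, row.names = FALSE, quote = FALSE)
  invisible(c(nodes_path, edges_path))
}

# indices of edges traversable by `mode`
mode_edges <- function(network, mode) {
  if (nrow(network$edges) == 0) return(integer(0))
  which(vapply(strsplit(network$edges$modes, "|", fixed = TRUE),
               function(m) mode %in% m, logical(1)))
}

# endpoint coordinates for a set of edge rows
edge_coords <- function(network, eidx) {
  iu <- match(network$edges$u[eidx], network$nodes$node_id)
  iv <- match(network$edges$v[eidx], network$nodes$node_id)
  seg_mat(network$nodes$x[iu], network$nodes$y[iu],
          network$nodes$x[iv], network$nodes$y[iv])
}

#' Snap a point to the nearest mode-traversable edge
#'
#' Minimizes the point-to-segment Euclidean distance over all edges
#' traversable by `mode`; distance ties are broken by smallest
#' `edge_id`. If no traversable edge lies within `max_snap_m` but a
#' network node does, the point anchors to that node (degenerate
#' location with `edge_id = NA`); otherwise an `unreachable_facility`
#' error is raised.
#'
#' @param network A [road_network()].
#' @param x,y Point coordinates (meters).
#' @param mode Travel mode (`"walk"`, `"drive"`, `"ferry"`).
#' @param max_snap_m Maximum allowed snap distance (meters).
#' @return A `network_location`: `edge_id`, `offset_m`, `snapped_x`,
#'   `snapped_y`, `snap_distance_m` (plus `node_id` for node anchors).
#' @export
snap_facility <- function(network, x, y, mode = "walk", max_snap_m = 500) {
  eidx <- mode_edges(network, mode)
  if (length(eidx) > 0) {
    seg <- edge_coords(network, eidx)
    best_d <- Inf; best <- NULL
    for (i in seq_along(eidx)) {
      hit <- nearest_on_segments(x, y, seg[i, , drop = FALSE])
      d <- hit$dist
      eid <- network$edges$edge_id[eidx[i]]
      if (d < best_d - 1e-12 ||
          (abs(d - best_d) <= 1e-12 && !is.null(best) && eid < best$edge_id)) {
        t <- hit$offset_m
        L <- network$edges$length_m[eidx[i]]
        geom_len <- sqrt((seg[i, 3] - seg[i, 1])^2 + (seg[i, 4] - seg[i, 2])^2)
        frac <- if (geom_len > 0) t / geom_len else 0
        best_d <- d
        best <- list(edge_id = eid, offset_m = frac * L,
                     snapped_x = seg[i, 1] + frac * (seg[i, 3] - seg[i, 1]),
                     snapped_y = seg[i, 2] + frac * (seg[i, 4] - seg[i, 2]),
                     snap_distance_m = d)
      }
    }
    if (best_d <= max_snap_m) {
      return(structure(best, class = "network_location"))
    }
  }
  # node fallback: isolated (for this mode) but present locations
  if (nrow(network$nodes) > 0) {
    dn <- sqrt((network$nodes$x - x)^2 + (network$nodes$y - y)^2)
    j <- which.min(dn)
    if (dn[j] <= max_snap_m) {
      return(structure(list(edge_id = NA_character_, offset_m = 0,
                            node_id = network$nodes$node_id[j],
                            snapped_x = network$nodes$x[j],
                            snapped_y = network$nodes$y[j],
                            snap_distance_m = dn[j]),
                       class = "network_location"))
    }
  }
  mc_stop("unreachable_facility",
          sprintf("no traversable edge or node within %g m of (%g, %g)",
                  max_snap_m, x, y))
}

#' Cutoff-bounded shortest-path distances from a network location
#'
#' The source edge is split at `offset_m` into two traversable
#' half-edges joined at a temporary virtual node; single-source
#' shortest paths are computed over edges traversable by `mode` and
#' truncated at `cutoff_m`. The off-network snap gap is not part of
#' the distance budget.
#'
#' @param network A [road_network()].
#' @param source A `network_location` from [snap_facility()].
#' @param cutoff_m Distance cutoff (meters), > 0.
#' @param mode Travel mode.
#' @return A `reachability_tree`: `source`, `cutoff_m`, `mode` and
#'   `node_distance` (named vector over nodes with distance <= cutoff).
#' @export
reachability <- function(network, source, cutoff_m, mode = "walk") {
  stopifnot(inherits(source, "network_location"), cutoff_m > 0)
  eidx <- mode_edges(network, mode)
  nd <- numeric(0)
  if (is.na(source$edge_id)) {
    # node-anchored source: reachable set grows from that node
    if (length(eidx) > 0) {
      nd <- shortest_from(network, eidx, seeds = source$node_id, seed_d = 0)
    } else if (!is.null(source$node_id)) {
      nd <- stats::setNames(0, source$node_id)
    }
  } else {
    erow <- match(source$edge_id, network$edges$edge_id)
    L <- network$edges$length_m[erow]
    seeds <- c(network$edges$u[erow], network$edges$v[erow])
    seed_d <- c(source$offset_m, L - source$offset_m)
    nd <- shortest_from(network, eidx, seeds, seed_d)
  }
  nd <- nd[nd <= cutoff_m]
  structure(list(source = source, cutoff_m = cutoff_m, mode = mode,
                 node_distance = nd), class = "reachability_tree")
}

# Dijkstra over the mode subgraph from virtual seeds: seeds are node
# ids with initial distances seed_d (the two half-edge lengths of the
# split source edge, or 0 for a node anchor).
shortest_from <- function(network, eidx, seeds, seed_d) {
  e <- network$edges[eidx, , drop = FALSE]
  vids <- unique(c(network$nodes$node_id, "..src.."))
  g <- igraph::make_empty_graph(n = length(vids), directed = FALSE)
  igraph::V(g)$name <- vids
  from <- c(e$u, rep("..src..", length(seeds)))
  to <- c(e$v, seeds)
  w <- c(e$length_m, seed_d)
  keep <- is.finite(w)
  g <- igraph::add_edges(g, rbind(from[keep], to[keep]))
  igraph::E(g)$weight <- w[keep]
  d <- igraph::distances(g, v = "..src..", weights = igraph::E(g)$weight)[1, ]
  d <- d[names(d) != "..src.."]
  d[is.finite(d)]
}

#' Covered sub-segments of every traversable edge
#'
#' For an edge (u, v) of length L, coverage enters from each endpoint
#' with budget `cutoff - d(endpoint)`: from u it spans
#' `[0, min(L, cutoff - d(u))]` and from v `[max(0, L - (cutoff -
#' d(v))), L]` (negative budgets contribute nothing); the reported
#' coverage is the union. The source edge is additionally covered on
#' `[offset - cutoff, offset + cutoff]` clipped to `[0, L]`.
#'
#' @param network A [road_network()].
#' @param tree A [reachability()] result.
#' @return List of `covered_segment` objects: `edge_id`, `intervals`
#'   (k-by-2 matrix of meter ranges), endpoint coordinates and the
#'   endpoint distances needed to evaluate network distance at any
#'   covered point.
#' @export
covered_segments <- function(network, tree) {
  eidx <- mode_edges(network, tree$mode)
  out <- list()
  cutoff <- tree$cutoff_m
  nd <- tree$node_distance
  src_edge <- tree$source$edge_id
  for (i in eidx) {
    eid <- network$edges$edge_id[i]
    L <- network$edges$length_m[i]
    du <- nd[network$edges$u[i]]
    dv <- nd[network$edges$v[i]]
    du <- if (length(du) == 1 && !is.na(du)) du else Inf
    dv <- if (length(dv) == 1 && !is.na(dv)) dv else Inf
    ivs <- matrix(numeric(0), ncol = 2)
    bu <- cutoff - du
    bv <- cutoff - dv
    if (bu >= 0) ivs <- rbind(ivs, c(0, min(L, bu)))
    if (bv >= 0) ivs <- rbind(ivs, c(max(0, L - bv), L))
    is_src <- !is.na(src_edge) && identical(eid, src_edge)
    if (is_src) {
      off <- tree$source$offset_m
      ivs <- rbind(ivs, c(max(0, off - cutoff), min(L, off + cutoff)))
    }
    ivs <- union_intervals(ivs)
    if (nrow(ivs) == 0) next
    iu <- match(network$edges$u[i], network$nodes$node_id)
    iv <- match(network$edges$v[i], network$nodes$node_id)
    out[[length(out) + 1L]] <- structure(list(
      edge_id = eid, intervals = ivs, length_m = L,
      ax = network$nodes$x[iu], ay = network$nodes$y[iu],
      bx = network$nodes$x[iv], by = network$nodes$y[iv],
      d_u = du, d_v = dv,
      source_offset_m = if (is_src) tree$source$offset_m else NA_real_
    ), class = "covered_segment")
  }
  out
}

# merge possibly-overlapping [a, b] rows into disjoint sorted intervals
union_intervals <- function(ivs) {
  ivs <- ivs[ivs[, 2] > ivs[, 1] + 1e-12, , drop = FALSE]
  if (nrow(ivs) <= 1) return(ivs)
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  out <- ivs[1, , drop = FALSE]
  for (i in 2:nrow(ivs)) {
    last <- nrow(out)
    if (ivs[i, 1] <= out[last, 2] + 1e-12) {
      out[last, 2] <- max(out[last, 2], ivs[i, 2])
    } else {
      out <- rbind(out, ivs[i, , drop = FALSE])
    }
  }
  out
}

# straight sub-segment geometry of covered intervals, as a seg_mat
segment_geometry <- function(cs) {
  L <- cs$length_m
  geom_len <- sqrt((cs$bx - cs$ax)^2 + (cs$by - cs$ay)^2)
  lerp <- function(t) {
    f <- if (L > 0) t / L else 0
    c(cs$ax + f * (cs$bx - cs$ax), cs$ay + f * (cs$by - cs$ay))
  }
  do.call(rbind, lapply(seq_len(nrow(cs$intervals)), function(k) {
    p <- lerp(cs$intervals[k, 1]); q <- lerp(cs$intervals[k, 2])
    seg_mat(p[1], p[2], q[1], q[2])
  }))
}

# network distance (to the source) of a point at metric offset t along
# the edge of a covered segment
segment_network_distance <- function(cs, t, cutoff_m) {
  d <- pmin(cs$d_u + t, cs$d_v + (cs$length_m - t))
  if (!is.na(cs$source_offset_m)) d <- pmin(d, abs(t - cs$source_offset_m))
  d
}
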