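# helper: a hand-made catchment whose polygon is an explicit ring,
# for precise overlap scenarios
ring_catchment <- function(id, ring, snap_x, snap_y, cutoff = 1000) {
  structure(list(facility_id = id, cutoff_m = cutoff, mode = "walk",
                 buffer_m = 50,
                 snap = structure(list(edge_id = NA_character_, offset_m = 0,
                                       snapped_x = snap_x, snapped_y = snap_y,
                                       snap_distance_m = 0),
                                  class = "network_location"),
                 tree = NULL, segments = list(),
                 polygon = geo_ringpoly(ring)),
            class = "catchment")
}

test_that("one all-covering catchment absorbs the grid; none leaves it underserved", {
  grid <- flat_grid(6, 6, cell = 100, fill = 4)
  big <- ring_catchment("f1", cbind(c(-10, 700, 700, -10), c(-10, -10, 700, 700)),
                        300, 300)
  cov <- compute_coverage(list(big), grid)
  expect_equal(cov$per_facility$population_total, sum(grid$total))
  expect_equal(cov$underserved_total, 0)
  und <- identify_underserved(list(), grid)
  expect_equal(und$population_total, sum(grid$total))
})

test_that("co-located catchments: independent double-counts, exclusive tie-breaks by id", {
  grid <- flat_grid(6, 6, cell = 100, fill = 2)
  ring <- cbind(c(-10, 700, 700, -10), c(-10, -10, 700, 700))
  a <- ring_catchment("fa", ring, 300, 300)
  b <- ring_catchment("fb", ring, 300, 300)
  ind <- compute_coverage(list(a, b), grid, "independent")
  expect_equal(ind$per_facility$population_total, rep(sum(grid$total), 2))
  exc <- compute_coverage(list(a, b), grid, "exclusive",
                          catchment_distance_lookup())
  pf <- exc$per_facility
  expect_equal(pf$population_total[pf$facility_id == "fa"], sum(grid$total))
  expect_equal(pf$population_total[pf$facility_id == "fb"], 0)
  expect_error(compute_coverage(list(a, b), grid, "exclusive"),
               class = "configuration_error")
})

test_that("exclusive assignment equals a brute-force nearest-covering scan", {
  lookup <- catchment_distance_lookup()
  for (seed in c(3, 11)) {
    scene <- make_scene(seed = seed, cutoff_m = 900)
    grid <- scene$grid
    exc <- compute_coverage(scene$catchments, grid, "exclusive", lookup)
    ctr <- microcatch:::grid_cell_centers(grid)
    fids <- vapply(scene$catchments, function(c) c$facility_id, "")
    oracle_pop <- setNames(numeric(length(fids)), sort(fids))
    for (row in seq_len(grid$nrows)) for (col in seq_len(grid$ncols)) {
      px <- ctr$x[col]; py <- ctr$y[row]
      best <- NULL; best_d <- Inf
      for (fid in sort(fids)) {  # ascending id: ties keep the first
        ct <- scene$catchments[[fid]]
        if (!geo_contains(ct$polygon, px, py)) next
        d <- lookup(px, py, ct)
        if (d < best_d - 1e-12) { best_d <- d; best <- fid }
      }
      if (!is.null(best)) {
        oracle_pop[best] <- oracle_pop[best] + grid$total[row, col]
      }
    }
    expect_equal(exc$per_facility$population_total,
                 unname(oracle_pop[exc$per_facility$facility_id]))
  }
})

test_that("exclusive coverage conserves the grid total exactly as integers", {
  lookup <- catchment_distance_lookup()
  for (seed in 1:8) {
    scene <- make_scene(seed = seed, cutoff_m = 800)
    exc <- compute_coverage(scene$catchments, scene$grid, "exclusive", lookup)
    expect_identical(sum(exc$per_facility$population_total) + exc$underserved_total,
                     sum(scene$grid$total))
    # independent never reports less than exclusive for any facility
    ind <- compute_coverage(scene$catchments, scene$grid, "independent")
    m <- merge(ind$per_facility[, c("facility_id", "population_total")],
               exc$per_facility[, c("facility_id", "population_total")],
               by = "facility_id", suffixes = c("_ind", "_exc"))
    expect_true(all(m$population_total_ind >= m$population_total_exc))
  }
})

test_that("case assignment follows the exclusive rule point by point", {
  left <- ring_catchment("L", cbind(c(0, 400, 400, 0), c(0, 0, 600, 600)), 100, 300)
  right <- ring_catchment("R", cbind(c(300, 700, 700, 300), c(0, 0, 600, 600)), 600, 300)
  pts <- data.frame(x = c(100, 650, 350, 1000), y = c(300, 300, 300, 300))
  got <- assign_cases(pts, list(left, right))
  expect_equal(got$assigned_facility, c("L", "R", "L", NA))
  # the overlap point at x = 350 is nearer L's snap (100) than R's (600)
  # brute-force check across a grid of overlap points
  lookup <- catchment_distance_lookup()
  ov <- expand.grid(x = seq(310, 390, 20), y = seq(50, 550, 100))
  got2 <- assign_cases(ov, list(left, right), lookup)
  for (i in seq_len(nrow(ov))) {
    dl <- lookup(ov$x[i], ov$y[i], left)
    dr <- lookup(ov$x[i], ov$y[i], right)
    expect_equal(got2$assigned_facility[i], if (dl <= dr) "L" else "R")
  }
})

test_that("case rates follow the stated arithmetic and flag mismatches", {
  grid <- flat_grid(10, 10, cell = 100, fill = 100)  # 10,000 persons
  big <- ring_catchment("f1", cbind(c(-10, 1100, 1100, -10), c(-10, -10, 1100, 1100)),
                        500, 500)
  cov <- compute_coverage(list(big), grid)
  cases <- data.frame(x = runif(5, 100, 900), y = runif(5, 100, 900))
  rates <- case_rates(assign_cases(cases, list(big)), cov, rate_basis = 1e5)
  expect_equal(rates$rate, 5 / 10000 * 1e5)  # 50 per 100,000
  none <- case_rates(data.frame(x = numeric(), y = numeric(),
                                assigned_facility = character()), cov)
  expect_equal(none$cases, 0L)
  expect_equal(none$rate, 0)
  stray <- data.frame(x = 1, y = 1, assigned_facility = "ghost")
  expect_error(case_rates(stray, cov), class = "consistency_error")
  # zero-population facility: missing rate, not a division error
  empty_cov <- compute_coverage(
    list(ring_catchment("f2", cbind(c(5e4, 5e4 + 10, 5e4 + 10), c(0, 0, 10)), 5e4, 0)),
    grid)
  r0 <- case_rates(data.frame(x = numeric(), y = numeric(),
                              assigned_facility = character()), empty_cov)
  expect_true(is.na(r0$rate))
})

test_that("independent populations and underserved totals are monotone in cutoff", {
  scene <- make_scene(seed = 10, cutoff_m = 500)
  net <- scene$network
  fac <- scene$facilities
  res <- lapply(c(500, 1000, 1600), function(cut) {
    built <- build_all_catchments(net, fac, cut, buffer_m = 50,
                                  max_snap_m = scene$config$max_snap_m)
    compute_coverage(built$catchments, scene$grid, "independent")
  })
  for (i in 1:2) {
    m <- merge(res[[i]]$per_facility, res[[i + 1]]$per_facility,
               by = "facility_id", suffixes = c("_lo", "_hi"))
    expect_true(all(m$population_total_lo <= m$population_total_hi))
    expect_gte(res[[i]]$underserved_total, res[[i + 1]]$underserved_total)
  }
})
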