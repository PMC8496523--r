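# build a coverage_result directly from per-facility totals
fake_coverage <- function(pops, strata_share = c("kids.f" = 0.5, "kids.m" = 0.5)) {
  pf <- data.frame(facility_id = sprintf("f%03d", seq_along(pops)),
                   population_total = pops,
                   n_cells = rep(1L, length(pops)),
                   stringsAsFactors = FALSE)
  for (k in names(strata_share)) pf[[k]] <- pops * strata_share[[k]]
  structure(list(per_facility = pf, underserved_total = 0,
                 underserved_by_stratum = numeric(0),
                 underserved_mask = matrix(FALSE, 1, 1),
                 assignment = "independent", cutoff_m = 5000, mode = "walk"),
            class = "coverage_result")
}

test_that("group summaries report N, total, rounded mean, sample SD, extremes", {
  cov <- fake_coverage(c(100, 5, 5, 5))
  groups <- c(f001 = "solo", f002 = "trio", f003 = "trio", f004 = "trio")
  s <- summarize_by_group(cov, groups)
  solo <- s[s$group == "solo", ]
  expect_equal(solo$n_facilities, 1)
  expect_equal(solo$population_total, 100)
  expect_equal(solo$mean_population, 100)
  expect_true(is.na(solo$sd_population))
  expect_equal(c(solo$min_population, solo$max_population), c(100, 100))
  trio <- s[s$group == "trio", ]
  expect_equal(trio$sd_population, 0)
  expect_error(summarize_by_group(cov, groups[-1]), class = "consistency_error")
})

test_that("summary mean/SD equal an independent two-pass computation", {
  set.seed(77)
  pops <- round(rlnorm(1000, 9, 1))
  cov <- fake_coverage(pops)
  s <- summarize_by_group(cov, setNames(rep("all", 1000),
                                        cov$per_facility$facility_id))
  mean2 <- sum(pops) / length(pops)
  sd2 <- sqrt(sum((pops - mean2)^2) / (length(pops) - 1))
  expect_equal(s$mean_population, sign(mean2) * floor(abs(mean2) + 0.5))
  expect_equal(s$sd_population, sign(sd2) * floor(abs(sd2) + 0.5))
})

test_that("pooling a single row is the identity and empty input errors", {
  one <- summarize_by_group(fake_coverage(c(10, 20)),
                            c(f001 = "g", f002 = "g"))
  pooled <- combine_group_summaries(one)
  expect_equal(pooled[, -1], one[, -1], ignore_attr = TRUE)
  expect_error(combine_group_summaries(one[0, ]), class = "invalid_input")
})

test_that("pooled summaries match direct computation on concatenated raw values", {
  set.seed(42)
  a <- round(runif(40, 100, 9000))
  b <- round(runif(25, 2000, 60000))
  rows <- data.frame(group = c("A", "B"),
                     n_facilities = c(40, 25),
                     population_total = c(sum(a), sum(b)),
                     mean_population = NA, # display fields unused by pooling
                     sd_population = c(sd(a), sd(b)),
                     min_population = c(min(a), min(b)),
                     max_population = c(max(a), max(b)))
  pooled <- combine_group_summaries(rows)
  all_v <- c(a, b)
  expect_equal(attr(pooled, "mean_raw"), mean(all_v), tolerance = 1e-9)
  expect_equal(attr(pooled, "sd_raw"), sd(all_v), tolerance = 1e-9)
  expect_equal(pooled$min_population, min(all_v))
  expect_equal(pooled$max_population, max(all_v))
})

test_that("pooling is associative over partitions of the same facility set", {
  set.seed(8)
  v <- round(runif(60, 50, 5000))
  grp <- rep(c("a", "b", "c"), each = 20)
  mk_row <- function(idx, g) data.frame(
    group = g, n_facilities = length(idx), population_total = sum(v[idx]),
    mean_population = NA, sd_population = sd(v[idx]),
    min_population = min(v[idx]), max_population = max(v[idx]))
  rows3 <- rbind(mk_row(1:20, "a"), mk_row(21:40, "b"), mk_row(41:60, "c"))
  direct <- combine_group_summaries(rows3)
  ab <- combine_group_summaries(rows3[1:2, ], label = "ab")
  ab_row <- ab; ab_row$sd_population <- attr(ab, "sd_raw")
  nested <- combine_group_summaries(rbind(ab_row, rows3[3, ]))
  expect_equal(attr(nested, "mean_raw"), attr(direct, "mean_raw"), tolerance = 1e-9)
  expect_equal(attr(nested, "sd_raw"), attr(direct, "sd_raw"), tolerance = 1e-9)
  expect_equal(attr(direct, "mean_raw"), mean(v), tolerance = 1e-9)
  expect_equal(attr(direct, "sd_raw"), sd(v), tolerance = 1e-9)
})

test_that("resource estimation follows the dose/vial/team formulas", {
  cov <- fake_coverage(c(2000), strata_share = c("kids.f" = 0.25, "kids.m" = 0.25,
                                                 "adults.f" = 0.25, "adults.m" = 0.25))
  a <- resource_assumptions(c("kids.f", "kids.m"), doses_per_person = 2,
                            wastage_fraction = 0.1, vial_doses = 10,
                            team_daily_throughput = 200, campaign_days = 5)
  plan <- estimate_resources(cov, a)
  expect_equal(plan$target_population, 1000)
  expect_equal(plan$doses_needed, 2000)
  expect_equal(plan$vials_needed, 220)
  expect_equal(plan$teams_needed, 2)
  # zero target -> zero everything
  z <- estimate_resources(fake_coverage(0), resource_assumptions("kids.f"))
  expect_equal(unname(unlist(z[, -1])), rep(0, 4))
  expect_error(resource_assumptions(character(0)), class = "configuration_error")
})

test_that("resource totals are additive and monotone in the target population", {
  set.seed(3)
  cov <- fake_coverage(round(runif(20, 0, 30000)))
  a <- resource_assumptions(c("kids.f", "kids.m"), doses_per_person = 1.5,
                            wastage_fraction = 0.15, vial_doses = 20,
                            team_daily_throughput = 120, campaign_days = 7)
  plan <- estimate_resources(cov, a)
  tot <- attr(plan, "totals")
  expect_equal(unname(tot["doses_needed"]), sum(plan$doses_needed))
  expect_equal(unname(tot["vials_needed"]), sum(plan$vials_needed))
  expect_equal(unname(tot["teams_needed"]), sum(plan$teams_needed))
  ord <- order(plan$target_population)
  expect_true(all(diff(plan$doses_needed[ord]) >= 0))
  expect_true(all(diff(plan$vials_needed[ord]) >= 0))
  expect_true(all(diff(plan$teams_needed[ord]) >= 0))
})

test_that("written reports round-trip and tolerate empty coverage", {
  dir <- withr::local_tempdir()
  cov <- fake_coverage(c(120, 250, 30))
  s <- summarize_by_group(cov, setNames(c("g1", "g1", "g2"),
                                        cov$per_facility$facility_id))
  plan <- estimate_resources(cov, resource_assumptions(c("kids.f", "kids.m")))
  write_report(s, cov, plan, dir)
  back <- read.csv(file.path(dir, "report.csv"))
  expect_equal(back$group, s$group)
  expect_equal(back$n_facilities, s$n_facilities)
  expect_equal(back$population_total, s$population_total)
  expect_equal(back$mean_population, s$mean_population)
  sections <- read.csv(file.path(dir, "microplan_sections.csv"))
  expect_equal(nrow(sections), 6)
  # empty coverage: header-only CSVs, no crash
  dir2 <- withr::local_tempdir()
  empty <- compute_coverage(list(), flat_grid(2, 2))
  write_report(NULL, empty, NULL, dir2)
  expect_equal(nrow(read.csv(file.path(dir2, "coverage.csv"))), 0)
})

test_that("identical seeded runs produce byte-identical reports", {
  dir <- withr::local_tempdir()
  cfg <- small_config(seed = 4)
  files <- write_synthetic_inputs(cfg, file.path(dir, "in"))
  out <- lapply(c("r1", "r2"), function(d)
    run_microplan(files$nodes, files$edges, files$facilities, files$manifest,
                  out_dir = file.path(dir, d), cutoff_m = 900, buffer_m = 50,
                  max_snap_m = cfg$max_snap_m))
  for (f in c("report.csv", "coverage.csv", "underserved.csv")) {
    expect_identical(readBin(file.path(dir, "r1", f), "raw", 1e6),
                     readBin(file.path(dir, "r2", f), "raw", 1e6))
  }
})
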