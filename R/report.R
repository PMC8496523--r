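# Microplan reporting: grouped per-facility population summaries
# (Table-2-style rows), pooling of sub-group summaries, and campaign
# resource estimation.

#' Grouped summary of per-facility catchment populations
#'
#' One row per group: number of facilities, total population, mean
#' (rounded to the nearest integer, half away from zero), sample SD
#' (divisor N-1, rounded; NA when N < 2), minimum and maximum.
#'
#' @param coverage A [compute_coverage()] result.
#' @param facility_groups Named character vector (facility_id ->
#'   group label) or a data frame with columns `facility_id`/`id` and
#'   `group`. Every facility in `coverage` must have a label.
#' @return A `group_summary` data frame sorted by group label.
#' @export
summarize_by_group <- function(coverage, facility_groups) {
  pf <- coverage$per_facility
  if (is.data.frame(facility_groups)) {
    idc <- if ("facility_id" %in% names(facility_groups)) "facility_id" else "id"
    facility_groups <- stats::setNames(as.character(facility_groups$group),
                                       as.character(facility_groups[[idc]]))
  }
  labels <- facility_groups[pf$facility_id]
  if (any(is.na(labels))) {
    mc_stop("consistency_error",
            sprintf("facilities without a group label: %s",
                    paste(pf$facility_id[is.na(labels)], collapse = ", ")))
  }
  out <- lapply(sort(unique(labels)), function(g) {
    v <- pf$population_total[labels == g]
    data.frame(group = g,
               n_facilities = length(v),
               population_total = sum(v),
               mean_population = round_half_away(mean(v)),
               sd_population = if (length(v) >= 2)
                 round_half_away(stats::sd(v)) else NA_real_,
               min_population = min(v),
               max_population = max(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Pool group summaries into one combined row
#'
#' Combines rows by total counts and the pooled sample variance
#' `s^2 = (sum (n_i - 1) s_i^2 + sum n_i (m_i - m)^2) / (N - 1)` with
#' group means `m_i` reconstructed from totals. Rows with `n = 1`
#' (missing SD) contribute zero within-group sum of squares. This is
#' exactly the arithmetic that links the per-continent rows of a
#' Table-2-style report to its pooled Total row.
#'
#' @param rows A `group_summary` data frame (>= 1 row).
#' @param label Group label for the combined row.
#' @return One-row `group_summary`.
#' @export
combine_group_summaries <- function(rows, label = "Total") {
  if (is.null(rows) || nrow(rows) == 0) {
    mc_stop("invalid_input", "no group summaries to combine")
  }
  if (nrow(rows) == 1) {
    out <- rows
    out$group <- label
    m <- rows$population_total / rows$n_facilities
    out$mean_population <- round_half_away(m)
    attr(out, "mean_raw") <- m
    attr(out, "sd_raw") <- rows$sd_population
    return(out)
  }
  n <- rows$n_facilities
  tot <- rows$population_total
  if (any(n < 1)) mc_stop("invalid_input", "group sizes must be >= 1")
  N <- sum(n)
  Tt <- sum(tot)
  mi <- tot / n
  m <- Tt / N
  s <- ifelse(is.na(rows$sd_population), 0, rows$sd_population)
  within <- sum((n - 1) * s^2)
  between <- sum(n * (mi - m)^2)
  s2 <- (within + between) / (N - 1)
  out <- data.frame(group = label,
                    n_facilities = N,
                    population_total = Tt,
                    mean_population = round_half_away(m),
                    sd_population = if (N >= 2) round_half_away(sqrt(s2)) else NA_real_,
                    min_population = min(rows$min_population),
                    max_population = max(rows$max_population),
                    stringsAsFactors = FALSE)
  # unrounded pooled statistics, for chaining/verification
  attr(out, "mean_raw") <- m
  attr(out, "sd_raw") <- sqrt(s2)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Campaign resource assumptions
#'
#' @param target_strata Character vector of stratum keys
#'   (`"<age_band>.<sex>"`) the campaign targets, or a data frame with
#'   `age_band`, `sex` columns. Must be non-empty.
#' @param doses_per_person Doses per targeted person (> 0).
#' @param wastage_fraction Expected dose wastage (>= 0, e.g. 0.1).
#' @param vial_doses Doses per vial (positive integer).
#' @param team_daily_throughput Doses one team delivers per day.
#' @param campaign_days Campaign duration in days.
#' @return A validated `resource_assumptions` list.
#' @export
resource_assumptions <- function(target_strata,
                                 doses_per_person = 1,
                                 wastage_fraction = 0.1,
                                 vial_doses = 10L,
                                 team_daily_throughput = 150L,
                                 campaign_days = 5L) {
  if (is.data.frame(target_strata)) {
    target_strata <- stratum_key(target_strata$age_band, target_strata$sex)
  }
  if (length(target_strata) == 0) {
    mc_stop("configuration_error", "target_strata must be non-empty")
  }
  if (doses_per_person <= 0 || wastage_fraction < 0 || vial_doses < 1 ||
      team_daily_throughput < 1 || campaign_days < 1) {
    mc_stop("configuration_error", "invalid resource assumption values")
  }
  structure(list(target_strata = as.character(target_strata),
                 doses_per_person = doses_per_person,
                 wastage_fraction = wastage_fraction,
                 vial_doses = as.integer(vial_doses),
                 team_daily_throughput = as.integer(team_daily_throughput),
                 campaign_days = as.integer(campaign_days)),
            class = "resource_assumptions")
}

#' Estimate campaign resources per facility
#'
#' Per facility: `target` is the covered population summed over the
#' target strata; `doses = ceil(target x doses_per_person)`;
#' `vials = ceil(doses x (1 + wastage) / vial_doses)`;
#' `teams = ceil(doses / (team_daily_throughput x campaign_days))`.
#'
#' @param coverage A [compute_coverage()] result.
#' @param assumptions A [resource_assumptions()].
#' @return A `resource_plan` data frame with per-facility rows and a
#'   `totals` attribute of campaign-wide sums.
#' @export
estimate_resources <- function(coverage, assumptions) {
  stopifnot(inherits(assumptions, "resource_assumptions"))
  pf <- coverage$per_facility
  missing <- setdiff(assumptions$target_strata, names(pf))
  if (length(missing) > 0) {
    mc_stop("configuration_error",
            sprintf("target strata absent from coverage: %s",
                    paste(missing, collapse = ", ")))
  }
  target <- if (nrow(pf) == 0) numeric(0) else
    rowSums(pf[, assumptions$target_strata, drop = FALSE])
  doses <- ceiling(target * assumptions$doses_per_person)
  vials <- ceiling(doses * (1 + assumptions$wastage_fraction) / assumptions$vial_doses)
  teams <- ceiling(doses / (assumptions$team_daily_throughput * assumptions$campaign_days))
  plan <- data.frame(facility_id = pf$facility_id,
                     target_population = target,
                     doses_needed = doses,
                     vials_needed = vials,
                     teams_needed = teams,
                     stringsAsFactors = FALSE)
  attr(plan, "totals") <- c(target_population = sum(target),
                            doses_needed = sum(doses),
                            vials_needed = sum(vials),
                            teams_needed = sum(teams))
  attr(plan, "assumptions") <- assumptions
  class(plan) <- c("resource_plan", "data.frame")
  plan
}

# The non-computed microplan sections, emitted as placeholders so a
# written report always shows the full six-section structure.
microplan_section_template <- function() {
  data.frame(
    section = c("resource_estimation", "cold_chain_logistics", "operations",
                "supervision", "recording_reporting", "monitoring_framework"),
    status = c("computed", rep("template", 5)),
    stringsAsFactors = FALSE
  )
}

#' Write the microplan report bundle
#'
#' Writes `report.csv` (grouped Table-2-style summary), `coverage.csv`,
#' `resources.csv` (when a plan is given), `catchments.geojson` and
#' `underserved.asc`/`underserved.csv` (when catchments/grid are
#' given), `microplan_sections.csv` and a `run_manifest.json` echoing
#' the configuration. Rewriting with identical inputs is byte-identical.
#'
#' @param summaries A `group_summary` data frame (may be NULL).
#' @param coverage A `coverage_result` (may be NULL).
#' @param plan A `resource_plan` (may be NULL).
#' @param out_dir Output directory (created if absent).
#' @param catchments Optional list of catchments for GeoJSON export.
#' @param grid Optional [population_grid()] for the underserved mask.
#' @param config Optional named list echoed into the run manifest.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(summaries, coverage, plan, out_dir,
                         catchments = NULL, grid = NULL, config = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) mc_stop("io_error", sprintf("cannot create %s", out_dir))
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    files <<- c(files, p)
  }
  if (is.null(summaries)) {
    summaries <- data.frame(group = character(), n_facilities = integer(),
                            population_total = numeric(), mean_population = numeric(),
                            sd_population = numeric(), min_population = numeric(),
                            max_population = numeric())
  }
  wr(summaries, "report.csv")
  if (!is.null(coverage)) {
    pf <- coverage$per_facility
    pf <- cbind(data.frame(facility_id = pf$facility_id,
                           assignment = rep(coverage$assignment, nrow(pf)),
                           cutoff_m = rep(coverage$cutoff_m, nrow(pf))),
                pf[, setdiff(names(pf), "facility_id"), drop = FALSE])
    wr(pf, "coverage.csv")
    und <- data.frame(stratum = c(names(coverage$underserved_by_stratum), "total"),
                      population = c(coverage$underserved_by_stratum,
                                     coverage$underserved_total))
    wr(und, "underserved.csv")
    if (!is.null(grid)) {
      p <- file.path(out_dir, "underserved.asc")
      write_mask_asc(coverage$underserved_mask, grid, p)
      files <- c(files, p)
    }
  }
  if (!is.null(plan)) wr(as.data.frame(plan), "resources.csv")
  wr(microplan_section_template(), "microplan_sections.csv")
  if (!is.null(catchments) && length(catchments) > 0) {
    p <- file.path(out_dir, "catchments.geojson")
    catchments_to_geojson(catchments, p)
    files <- c(files, p)
  }
  manifest <- list(
    package = "microcatch",
    package_version = as.character(utils::packageVersion("microcatch")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config
  )
  p <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE, null = "null")
  files <- c(files, p)
  invisible(files)
}

#' Run the full microplanning pipeline on files
#'
#' Loads a network (node/edge CSVs), facilities (GeoJSON points with
#' `id`, `name`, `group`) and a stratified population grid (manifest),
#' builds all catchments, computes coverage and underserved totals,
#' summarizes by the grouping attribute and writes the report bundle.
#'
#' @param nodes,edges Network CSV paths.
#' @param facilities Facilities GeoJSON path.
#' @param manifest Population-grid manifest CSV path.
#' @param out_dir Output directory.
#' @param cutoff_m,mode,buffer_m,max_snap_m Catchment parameters.
#' @param assignment `"independent"` or `"exclusive"`.
#' @param group_by Facility property used as grouping key.
#' @param assumptions Optional [resource_assumptions()] for
#'   resources.csv.
#' @param cases Optional case-point GeoJSON path; when given, cases
#'   are assigned and rates.csv is written.
#' @param rate_basis Persons per rate unit for rates.csv.
#' @return Invisibly, a list with `catchments`, `skipped`, `coverage`,
#'   `summaries`, `plan`, `rates` and `files`.
#' @export
run_microplan <- function(nodes, edges, facilities, manifest, out_dir,
                          cutoff_m = 5000, mode = "walk", buffer_m = 50,
                          max_snap_m = 500,
                          assignment = c("independent", "exclusive"),
                          group_by = "group", assumptions = NULL,
                          cases = NULL, rate_basis = 1e5) {
  assignment <- match.arg(assignment)
  network <- load_network(nodes, edges)
  fac <- read_points_geojson(facilities)
  if (!"id" %in% names(fac)) mc_stop("format_error", "facilities need an 'id' property")
  grid <- read_grid(manifest)
  built <- build_all_catchments(network, fac, cutoff_m, mode, buffer_m, max_snap_m)
  lookup <- if (assignment == "exclusive") catchment_distance_lookup() else NULL
  coverage <- compute_coverage(built$catchments, grid, assignment, lookup)
  groups <- if (group_by %in% names(fac)) {
    stats::setNames(as.character(fac[[group_by]]), as.character(fac$id))
  } else {
    stats::setNames(rep("all", nrow(fac)), as.character(fac$id))
  }
  summaries <- if (nrow(coverage$per_facility) > 0) {
    summarize_by_group(coverage, groups)
  } else NULL
  plan <- if (!is.null(assumptions)) estimate_resources(coverage, assumptions) else NULL
  config <- list(nodes = basename(nodes), edges = basename(edges),
                 facilities = basename(facilities), manifest = basename(manifest),
                 cutoff_m = cutoff_m, mode = mode, buffer_m = buffer_m,
                 max_snap_m = max_snap_m, assignment = assignment,
                 group_by = group_by,
                 skipped_facilities = built$skipped$facility_id)
  files <- write_report(summaries, coverage, plan, out_dir,
                        catchments = built$catchments, grid = grid,
                        config = config)
  rates <- NULL
  if (!is.null(cases)) {
    pts <- read_points_geojson(cases)
    assigned <- assign_cases(pts, built$catchments, catchment_distance_lookup())
    rates <- case_rates(assigned, coverage, rate_basis)
    p <- file.path(out_dir, "rates.csv")
    utils::write.csv(rates, p, row.names = FALSE, na = "")
    write_points_geojson(assigned, file.path(out_dir, "cases_assigned.geojson"))
    files <- c(files, p, file.path(out_dir, "cases_assigned.geojson"))
  }
  invisible(list(catchments = built$catchments, skipped = built$skipped,
                 coverage = coverage, summaries = summaries, plan = plan,
                 rates = rates, files = files))
}
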