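#' Assemble and validate a harvest dataset
#'
#' Bundles the per-report table and the region registry into a validated
#' `harvest_data` object, the input to every estimator in the package. A
#' report is one hunting team's annual return for one species: the team's
#' hunting area (ha) and its harvest count. The registry defines the spatial
#' hierarchy: every hunting management precinct (HMP) belongs to exactly one
#' county and has a known total huntable area.
#'
#' Identifiers are treated as opaque strings and never used arithmetically.
#' One `harvest_data` instance carries exactly one species' counts.
#'
#' Validation is strict: non-positive areas, negative or non-integer harvest
#' counts, reports in unregistered HMPs, HMPs assigned to the wrong county,
#' and reported area exceeding an HMP's huntable area are all hard errors
#' naming the offending rows (silent clipping would make the unreported area
#' negative downstream).
#'
#' @param reports Data frame with columns `report_id`, `county_id`, `hmp_id`,
#'   `area_ha` (positive, hectares) and `harvest` (non-negative integer).
#' @param registry Data frame with columns `county_id`, `hmp_id`,
#'   `huntable_area_ha` (positive) and optionally `excluded` (0/1 flag for
#'   HMPs outside the estimation scope, e.g. above the tree line or urban).
#' @param species Species label carried along for reporting.
#' @return A `harvest_data` object: a list with tibbles `reports` and
#'   `registry` plus the `species` label.
#' @examples
#' reg <- tibble::tibble(county_id = "c1", hmp_id = "h1",
#'                       huntable_area_ha = 1000, excluded = 0)
#' rep <- tibble::tibble(report_id = "r1", county_id = "c1", hmp_id = "h1",
#'                       area_ha = 300, harvest = 2L)
#' harvest_data(rep, reg)
#' @export
harvest_data <- function(reports, registry, species = "species") {
  req_rep <- c("report_id", "county_id", "hmp_id", "area_ha", "harvest")
  req_reg <- c("county_id", "hmp_id", "huntable_area_ha")
  miss <- setdiff(req_rep, names(reports))
  if (length(miss) > 0) {
    abort(paste0("reports table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  miss <- setdiff(req_reg, names(registry))
  if (length(miss) > 0) {
    abort(paste0("registry table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  registry <- as_tibble(registry)
  if (!"excluded" %in% names(registry)) registry$excluded <- 0L
  registry <- registry %>%
    mutate(across(c("county_id", "hmp_id"), as.character),
           huntable_area_ha = as.numeric(.data$huntable_area_ha),
           excluded = as.integer(.data$excluded))
  reports <- as_tibble(reports) %>%
    mutate(across(c("report_id", "county_id", "hmp_id"), as.character),
           area_ha = as.numeric(.data$area_ha))

  if (anyDuplicated(registry$hmp_id) > 0) {
    dup <- registry$hmp_id[duplicated(registry$hmp_id)]
    abort(paste0("each HMP must belong to exactly one county; duplicated: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad <- which(!is.finite(registry$huntable_area_ha) |
                 registry$huntable_area_ha <= 0)
  if (length(bad) > 0) {
    abort(paste0("registry huntable_area_ha must be positive; offending row(s): ",
                 paste(bad, collapse = ", ")))
  }

  bad <- which(!is.finite(reports$area_ha) | reports$area_ha <= 0)
  if (length(bad) > 0) {
    abort(paste0("report area_ha must be positive; offending report(s): ",
                 paste(reports$report_id[bad], collapse = ", ")))
  }
  h <- reports$harvest
  bad <- which(!is.finite(as.numeric(h)) | as.numeric(h) < 0 |
                 as.numeric(h) != round(as.numeric(h)))
  if (length(bad) > 0) {
    abort(paste0("harvest must be a non-negative integer; offending report(s): ",
                 paste(reports$report_id[bad], collapse = ", ")))
  }
  reports$harvest <- as.integer(round(as.numeric(h)))

  unknown <- which(!reports$hmp_id %in% registry$hmp_id)
  if (length(unknown) > 0) {
    abort(paste0("report(s) in HMP(s) absent from registry: ",
                 paste(reports$report_id[unknown], collapse = ", ")))
  }
  county_of <- setNames(registry$county_id, registry$hmp_id)
  mism <- which(reports$county_id != county_of[reports$hmp_id])
  if (length(mism) > 0) {
    abort(paste0("report county_id disagrees with registry for report(s): ",
                 paste(reports$report_id[mism], collapse = ", ")))
  }

  tot <- reports %>%
    group_by(.data$hmp_id) %>%
    summarise(reported = sum(.data$area_ha), .groups = "drop") %>%
    left_join(registry, by = "hmp_id")
  over <- tot %>% filter(.data$reported > .data$huntable_area_ha * (1 + 1e-9))
  if (nrow(over) > 0) {
    abort(paste0("reported area exceeds huntable area in HMP(s): ",
                 paste(over$hmp_id, collapse = ", ")))
  }

  structure(list(reports = reports, registry = registry, species = species),
            class = "harvest_data")
}

#' @export
print.harvest_data <- function(x, ...) {
  cat("<harvest_data> species:", x$species, "\n")
  cat(" ", nrow(x$reports), "reports in",
      length(unique(x$reports$hmp_id)), "of", nrow(x$registry), "HMPs,",
      length(unique(x$registry$county_id)), "counties\n")
  cov <- sum(x$reports$area_ha) / sum(x$registry$huntable_area_ha)
  cat("  reported area covers", sprintf("%.1f%%", 100 * cov),
      "of huntable area\n")
  invisible(x)
}

#' Read a harvest dataset from delimited text files
#'
#' Reads the comma-delimited reports file (header
#' `report_id,county_id,hmp_id,area_ha,harvest`) and registry file (header
#' `county_id,hmp_id,huntable_area_ha,excluded`) and validates them with
#' [harvest_data()]. Row order is preserved.
#'
#' @param reports_path,registry_path Paths to the delimited text files.
#' @inheritParams harvest_data
#' @return A validated `harvest_data` object.
#' @export
read_harvest_data <- function(reports_path, registry_path,
                              species = "species") {
  if (!file.exists(reports_path)) abort(paste0("no such file: ", reports_path))
  if (!file.exists(registry_path)) abort(paste0("no such file: ", registry_path))
  rep <- readr::read_csv(reports_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character(),
                                                 area_ha = readr::col_double(),
                                                 harvest = readr::col_double()))
  reg <- readr::read_csv(registry_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character(),
                                                 huntable_area_ha = readr::col_double(),
                                                 excluded = readr::col_double()))
  harvest_data(rep, reg, species = species)
}

#' Write a harvest dataset to delimited text files
#'
#' Inverse of [read_harvest_data()]; a load-write-load round trip is the
#' identity on all fields.
#'
#' @param data A `harvest_data` object.
#' @param reports_path,registry_path Output file paths.
#' @return `data`, invisibly.
#' @export
write_harvest_data <- function(data, reports_path, registry_path) {
  stopifnot(inherits(data, "harvest_data"))
  readr::write_csv(data$reports, reports_path)
  readr::write_csv(data$registry, registry_path)
  invisible(data)
}

#' Unreported area per HMP
#'
#' The unreported area of an HMP is its total huntable area minus the summed
#' area of its reports: the area for which harvest must be extrapolated.
#' Reported plus unreported area equals huntable area exactly, and the
#' dataset validator guarantees the difference is non-negative.
#'
#' @param data A `harvest_data` object.
#' @param hmp_id Optional HMP identifier(s); default all registered HMPs.
#' @return A tibble with columns `county_id`, `hmp_id`, `huntable_area_ha`,
#'   `reported_area_ha`, `unreported_area_ha`.
#' @examples
#' d <- simulate_harvest_data(seed = 1)$data
#' unreported_area(d)
#' @export
unreported_area <- function(data, hmp_id = NULL) {
  stopifnot(inherits(data, "harvest_data"))
  if (!is.null(hmp_id)) {
    unknown <- setdiff(hmp_id, data$registry$hmp_id)
    if (length(unknown) > 0) {
      abort(paste0("unknown HMP(s): ", paste(unknown, collapse = ", ")))
    }
  }
  out <- data$registry %>%
    left_join(data$reports %>%
                group_by(hmp_id = .data$hmp_id) %>%
                summarise(reported_area_ha = sum(.data$area_ha),
                          .groups = "drop"),
              by = "hmp_id") %>%
    mutate(reported_area_ha = coalesce(.data$reported_area_ha, 0),
           unreported_area_ha = pmax(.data$huntable_area_ha -
                                       .data$reported_area_ha, 0)) %>%
    select("county_id", "hmp_id", "huntable_area_ha", "reported_area_ha",
           "unreported_area_ha")
  if (!is.null(hmp_id)) out <- out %>% filter(.data$hmp_id %in% !!hmp_id)
  out
}

#' Apply the species exclusion rules
#'
#' Drops (a) every county whose reports all record zero harvest of the focal
#' species — the species is taken to be absent there — and (b) every HMP
#' flagged `excluded` in the registry (precincts for which no harvest is
#' estimated). Reports located in dropped units are removed along with the
#' units. The operation is idempotent.
#'
#' @param data A `harvest_data` object.
#' @return A filtered `harvest_data` object; the dropped units are attached
#'   as attribute `"dropped"` (a tibble with columns `level` and `unit_id`).
#'   If nothing is retained an empty dataset is returned with a warning.
#' @export
apply_species_exclusions <- function(data) {
  stopifnot(inherits(data, "harvest_data"))
  reg <- data$registry
  rep <- data$reports

  excl_hmp <- reg$hmp_id[reg$excluded == 1L]
  reg2 <- reg %>% filter(.data$excluded != 1L)
  rep2 <- rep %>% filter(!.data$hmp_id %in% excl_hmp)

  zero_counties <- rep2 %>%
    group_by(.data$county_id) %>%
    summarise(all_zero = all(.data$harvest == 0L), .groups = "drop") %>%
    filter(.data$all_zero) %>%
    pull(.data$county_id)
  # counties with no reports at all are also unusable downstream
  no_report <- setdiff(reg2$county_id, rep2$county_id)
  drop_cty <- union(zero_counties, no_report)

  reg3 <- reg2 %>% filter(!.data$county_id %in% drop_cty)
  rep3 <- rep2 %>% filter(!.data$county_id %in% drop_cty)

  dropped <- bind_rows(
    tibble(level = "hmp", unit_id = excl_hmp),
    tibble(level = "county", unit_id = drop_cty)
  )
  if (nrow(reg3) == 0) {
    warn("all units excluded; returning an empty dataset")
  }
  out <- structure(list(reports = rep3, registry = reg3,
                        species = data$species),
                   class = "harvest_data")
  attr(out, "dropped") <- dropped
  out
}

# Integer indexing shared by the model-fitting code: counties 1..L in sorted
# order, HMPs 1..K in sorted order, each report mapped to its HMP/county.
hb_index <- function(data) {
  reg <- data$registry %>% arrange(.data$county_id, .data$hmp_id)
  counties <- sort(unique(reg$county_id))
  hmps <- reg$hmp_id
  cty_of_hmp <- match(reg$county_id, counties)
  list(
    counties = counties,
    hmps = hmps,
    n_county = length(counties),
    n_hmp = length(hmps),
    cty_of_hmp = cty_of_hmp,
    hmp_of_report = match(data$reports$hmp_id, hmps),
    cty_of_report = match(data$reports$county_id, counties)
  )
}
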