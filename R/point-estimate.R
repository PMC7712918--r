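#' Per-HMP harvest rate of the linear baseline
#'
#' The rate used by the currently deployed extrapolation method: total
#' reported harvest over total reported area of the HMP; for an HMP with no
#' reports, the same ratio over its whole county. A county without any
#' report has no defined rate and is an error (such counties are excluded
#' from estimation upstream).
#'
#' @param data A `harvest_data` object.
#' @param hmp_id Optional HMP identifier(s); default all registered HMPs.
#' @return A tibble with columns `county_id`, `hmp_id`, `nu` (animals per
#'   ha) and `source` (`"hmp"` or `"county"` fallback).
#' @export
harvest_rate <- function(data, hmp_id = NULL) {
  stopifnot(inherits(data, "harvest_data"))
  hmp_tab <- data$reports %>%
    group_by(hmp_id = .data$hmp_id) %>%
    summarise(K = sum(.data$harvest), A = sum(.data$area_ha), .groups = "drop")
  cty_tab <- data$reports %>%
    group_by(county_id = .data$county_id) %>%
    summarise(Kc = sum(.data$harvest), Ac = sum(.data$area_ha), .groups = "drop")
  out <- data$registry %>%
    select("county_id", "hmp_id") %>%
    left_join(hmp_tab, by = "hmp_id") %>%
    left_join(cty_tab, by = "county_id")
  no_cty <- out %>% filter(is.na(.data$Ac) | .data$Ac <= 0)
  if (nrow(no_cty) > 0) {
    abort(paste0("county without reports, rate undefined: ",
                 paste(unique(no_cty$county_id), collapse = ", ")))
  }
  out <- out %>%
    mutate(source = if_else(!is.na(.data$A) & .data$A > 0, "hmp", "county"),
           nu = if_else(.data$source == "hmp", .data$K / .data$A,
                        .data$Kc / .data$Ac)) %>%
    select("county_id", "hmp_id", "nu", "source")
  if (!is.null(hmp_id)) {
    unknown <- setdiff(hmp_id, out$hmp_id)
    if (length(unknown) > 0) {
      abort(paste0("unknown HMP(s): ", paste(unknown, collapse = ", ")))
    }
    out <- out[match(hmp_id, out$hmp_id), ]
  }
  out
}

#' Linear point estimate of total harvest
#'
#' The deterministic baseline estimator: each HMP's total harvest is its
#' reported harvest plus its rate ([harvest_rate()]) times its unreported
#' area, aggregated to county and national totals. The estimator carries no
#' uncertainty measure, is exactly scale-equivariant in areas, and inherits
#' the full sensitivity of the ratio to low reporting (an HMP whose only
#' reports record zero harvest gets estimate zero; a tiny report with one
#' animal extrapolates to the whole HMP).
#'
#' @param data A `harvest_data` object.
#' @return A tibble with columns `level` (`"hmp"`, `"county"`, `"nation"`),
#'   `unit_id` (`NA` for the national row) and `estimate` (animals). County
#'   rows sum the HMP rows and the national row sums the county rows
#'   exactly.
#' @examples
#' reg <- tibble::tibble(county_id = "c1", hmp_id = "h1",
#'                       huntable_area_ha = 100000)
#' rep <- tibble::tibble(report_id = "r1", county_id = "c1", hmp_id = "h1",
#'                       area_ha = 20, harvest = 1L)
#' point_estimate(harvest_data(rep, reg)) # extrapolates 1 animal to 5000
#' @export
point_estimate <- function(data) {
  stopifnot(inherits(data, "harvest_data"))
  per_hmp <- harvest_rate(data) %>%
    left_join(unreported_area(data), by = c("county_id", "hmp_id")) %>%
    left_join(data$reports %>%
                group_by(hmp_id = .data$hmp_id) %>%
                summarise(reported = sum(.data$harvest), .groups = "drop"),
              by = "hmp_id") %>%
    mutate(reported = coalesce(as.numeric(.data$reported), 0),
           estimate = .data$reported + .data$nu * .data$unreported_area_ha)
  per_cty <- per_hmp %>%
    group_by(unit_id = .data$county_id) %>%
    summarise(estimate = sum(.data$estimate), .groups = "drop")
  bind_rows(
    per_hmp %>% transmute(level = "hmp", unit_id = .data$hmp_id,
                          estimate = .data$estimate),
    per_cty %>% mutate(level = "county", .before = 1),
    tibble(level = "nation", unit_id = NA_character_,
           estimate = sum(per_cty$estimate))
  )
}
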