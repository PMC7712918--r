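#' Sample team areas that tile an unreported area
#'
#' Draws hypothetical non-reporting team areas from
#' `Log-Normal(log(m), s)` recursively until their cumulative sum reaches
#' the unreported area `U`, then truncates the overshooting team's area so
#' the sample sums to `U` exactly. The truncated area is used as that
#' team's exposure when its harvest is sampled, which keeps the expected
#' total harvest over the partition exactly `mu * U` under the Poisson
#' model (thinning invariance). Uses the current R RNG state.
#'
#' @param m Log-normal median team area (ha), positive.
#' @param s Log-scale SD, positive.
#' @param U Unreported area (ha), non-negative.
#' @return Numeric vector of team areas summing to `U`; empty if `U = 0`.
#' @export
sample_team_areas <- function(m, s, U) {
  stopifnot(is.finite(m), m > 0, is.finite(s), s > 0, is.finite(U), U >= 0)
  if (U <= 0) return(numeric(0))
  out <- numeric(0)
  tot <- 0
  # draw in growing blocks; expected count is U / E[Log-Normal]
  block <- max(8L, ceiling(1.5 * U / exp(log(m) + s^2 / 2)))
  while (tot < U) {
    a <- rlnorm(block, log(m), s)
    cs <- tot + cumsum(a)
    if (cs[length(cs)] >= U) {
      i <- which(cs >= U)[1]
      out <- c(out, a[seq_len(i)])
      out[length(out)] <- U - (if (i > 1) cs[i - 1] else tot)
      return(out)
    }
    out <- c(out, a)
    tot <- cs[length(cs)]
  }
  out
}

#' Sample one team's harvest under a harvest model
#'
#' Team harvest is Poisson given the team's rate. For models without
#' overdispersion the rate is deterministic, `mu * A` (times the
#' relative-area adjustment `(A/m_bar)^phi` when the model includes it);
#' for models with overdispersion the rate is first drawn from a Gamma with
#' shape `alpha` and mean `mu * A` (times the adjustment), i.e. scale
#' `mean / alpha`. Vectorized over `area`. Uses the current R RNG state.
#'
#' @param spec A `harvest_model_spec`.
#' @param mu Average harvest rate of the HMP (animals per ha).
#' @param alpha Gamma shape of the HMP (ignored unless `spec$alpha`).
#' @param phi Relative-area exponent (ignored unless `spec$phi`).
#' @param area Team area(s), ha.
#' @param m_bar Typical team area of the HMP (required iff `spec$phi`).
#' @return Integer vector of sampled harvest counts, one per area.
#' @export
sample_team_harvest <- function(spec, mu, alpha = Inf, phi = 0, area,
                                m_bar = NULL) {
  stopifnot(inherits(spec, "harvest_model_spec"))
  n <- length(area)
  if (n == 0) return(integer(0))
  stopifnot(all(area > 0), mu > 0)
  mean_h <- mu * area
  if (spec$phi) {
    if (is.null(m_bar)) abort("m_bar is required for models including phi")
    mean_h <- mean_h * area_effect(area, m_bar, phi)
  }
  if (spec$alpha) {
    if (!is.finite(alpha) || alpha <= 0) {
      abort("models including alpha need a finite positive shape")
    }
    theta <- rgamma(n, shape = alpha, scale = mean_h / alpha)
    as.integer(rpois(n, theta))
  } else {
    as.integer(rpois(n, mean_h))
  }
}

#' Posterior-predictive harvest on unreported area
#'
#' For each of `n_sims` predictive samples, pairs one uniformly drawn area
#' posterior draw with one uniformly drawn harvest posterior draw
#' (independently, with replacement), tiles every HMP's unreported area
#' with team areas from the area draw ([sample_team_areas()]), samples each
#' team's harvest from the harvest draw under the fitted model
#' ([sample_team_harvest()]), and sums to HMP totals. County and national
#' totals are exact sums of the HMP totals within each sample.
#'
#' @param area_fit An `area_fit` for the same region registry.
#' @param harvest_fit A `harvest_fit`.
#' @param data The `harvest_data` defining reported and unreported area.
#' @param n_sims Number of predictive samples.
#' @param seed Integer seed; reproducible.
#' @param target_area Optional override of the area to predict for: a
#'   tibble with columns `hmp_id` and `unreported_area_ha`. Used by the
#'   train/validation workflow, which predicts the area covered by the
#'   held-out reports instead of the huntable remainder.
#' @return A `harvest_prediction` object: a tibble of per-sample HMP totals
#'   (`sim`, `county_id`, `hmp_id`, `kappa`, `n_teams`) with the model
#'   name, `n_sims` and seed attached as attributes.
#' @export
predict_unreported <- function(area_fit, harvest_fit, data, n_sims = 1000,
                               seed = 1, target_area = NULL) {
  stopifnot(inherits(area_fit, "area_fit"),
            inherits(harvest_fit, "harvest_fit"),
            inherits(data, "harvest_data"), n_sims >= 1)
  ua <- unreported_area(data)
  if (!is.null(target_area)) {
    unknown <- setdiff(target_area$hmp_id, ua$hmp_id)
    if (length(unknown) > 0) {
      abort(paste0("unknown HMP(s) in target_area: ",
                   paste(unknown, collapse = ", ")))
    }
    ua <- ua %>%
      select(-"unreported_area_ha") %>%
      left_join(target_area %>% select("hmp_id", "unreported_area_ha"),
                by = "hmp_id") %>%
      mutate(unreported_area_ha = coalesce(.data$unreported_area_ha, 0))
  }
  missing_a <- setdiff(ua$hmp_id, colnames(area_fit$m))
  missing_h <- setdiff(ua$hmp_id, colnames(harvest_fit$mu))
  if (length(missing_a) > 0 || length(missing_h) > 0) {
    abort(paste0("posterior lacks HMP(s): ",
                 paste(union(missing_a, missing_h), collapse = ", ")))
  }
  spec <- harvest_fit$spec
  cty_of <- setNames(ua$county_id, ua$hmp_id)
  set.seed(as.integer(seed %% 2147483647L))
  na_draws <- nrow(area_fit$m)
  nh_draws <- nrow(harvest_fit$mu)
  ai <- sample.int(na_draws, n_sims, replace = TRUE)
  hi <- sample.int(nh_draws, n_sims, replace = TRUE)

  res <- vector("list", n_sims)
  for (q in seq_len(n_sims)) {
    kq <- integer(nrow(ua))
    nt <- integer(nrow(ua))
    for (j in seq_len(nrow(ua))) {
      U <- ua$unreported_area_ha[j]
      if (U <= 0) next
      k_id <- ua$hmp_id[j]
      areas <- sample_team_areas(area_fit$m[ai[q], k_id],
                                 area_fit$s[ai[q], cty_of[[k_id]]], U)
      nt[j] <- length(areas)
      kq[j] <- sum(sample_team_harvest(
        spec, mu = harvest_fit$mu[hi[q], k_id],
        alpha = harvest_fit$alpha[hi[q], k_id],
        phi = harvest_fit$phi_draws[hi[q]],
        area = areas,
        m_bar = if (spec$phi) harvest_fit$m_bar[[k_id]]))
    }
    res[[q]] <- tibble(sim = q, county_id = ua$county_id, hmp_id = ua$hmp_id,
                       kappa = kq, n_teams = nt)
  }
  out <- bind_rows(res)
  attr(out, "model") <- spec$name
  attr(out, "n_sims") <- n_sims
  attr(out, "seed") <- seed
  class(out) <- c("harvest_prediction", class(out))
  out
}

# Per-sample totals of a prediction at a given level.
prediction_totals <- function(pred, level = c("nation", "county", "hmp"),
                              unit_id = NULL) {
  level <- match.arg(level)
  g <- switch(level, nation = pred %>% mutate(unit_id = NA_character_),
              county = pred %>% mutate(unit_id = .data$county_id),
              hmp = pred %>% mutate(unit_id = .data$hmp_id))
  if (!is.null(unit_id)) {
    if (!unit_id %in% g$unit_id) abort(paste0("unknown unit: ", unit_id))
    g <- g %>% filter(.data$unit_id == !!unit_id)
  }
  g %>%
    group_by(.data$sim, .data$unit_id) %>%
    summarise(kappa = sum(.data$kappa), .groups = "drop")
}

# Reported harvest at a given level.
reported_totals <- function(data, level, unit_id = NULL) {
  g <- switch(level,
              nation = data$reports %>% mutate(unit_id = NA_character_),
              county = data$reports %>% mutate(unit_id = .data$county_id),
              hmp = data$reports %>% mutate(unit_id = .data$hmp_id))
  tot <- g %>%
    group_by(.data$unit_id) %>%
    summarise(reported = sum(.data$harvest), .groups = "drop")
  units <- switch(level, nation = tibble(unit_id = NA_character_),
                  county = distinct(data$registry, unit_id = .data$county_id),
                  hmp = distinct(data$registry, unit_id = .data$hmp_id))
  out <- units %>% left_join(tot, by = "unit_id") %>%
    mutate(reported = coalesce(.data$reported, 0L))
  if (!is.null(unit_id)) out <- out %>% filter(.data$unit_id %in% !!unit_id)
  out
}

#' Summarise predicted total harvest
#'
#' Total harvest of a unit is its observed reported harvest plus the
#' predicted harvest of its unreported area; this returns the posterior
#' predictive median and a central credibility interval of that total.
#' Interval endpoints use the inverse-empirical-CDF quantile (type 1), i.e.
#' order statistics of the samples; the median averages the two central
#' order statistics when the sample count is even.
#'
#' @param pred A `harvest_prediction`.
#' @param data The `harvest_data` the prediction was made for.
#' @param level `"nation"`, `"county"` or `"hmp"`.
#' @param unit_id Optional single unit at that level.
#' @param probs Lower/upper interval probabilities in (0, 1).
#' @return A tibble with columns `level`, `unit_id`, `reported`, `median`,
#'   `lower`, `upper`.
#' @export
summarise_harvest <- function(pred, data, level = c("nation", "county", "hmp"),
                              unit_id = NULL, probs = c(0.025, 0.975)) {
  stopifnot(inherits(pred, "harvest_prediction"),
            inherits(data, "harvest_data"),
            all(probs > 0), all(probs < 1), length(probs) == 2)
  level <- match.arg(level)
  totals <- prediction_totals(pred, level, unit_id)
  rep_tab <- reported_totals(data, level, unit_id)
  totals %>%
    group_by(.data$unit_id) %>%
    summarise(median = median(.data$kappa),
              lower = unname(quantile(.data$kappa, min(probs), type = 1)),
              upper = unname(quantile(.data$kappa, max(probs), type = 1)),
              .groups = "drop") %>%
    right_join(rep_tab, by = "unit_id") %>%
    transmute(level = level, unit_id = .data$unit_id,
              reported = .data$reported,
              median = .data$reported + .data$median,
              lower = .data$reported + .data$lower,
              upper = .data$reported + .data$upper)
}
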