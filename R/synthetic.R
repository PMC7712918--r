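#' Configuration of the synthetic-data generator
#'
#' Defines a ground-truth scenario with exactly the generative structure
#' the models assume: log-normal team areas with county/HMP random effects
#' and county-specific log-scale spread, Gamma-Poisson team harvests with
#' HMP/county random effects on the log-rate, an optional rate-variability
#' association, an optional power effect of relative team area on the
#' per-area rate, and independent reporting with a fixed coverage
#' probability.
#'
#' The default scenario — 4 counties of 6 HMPs with 25 teams each and 30%
#' reporting coverage — is the package's standard desk-scale test bed:
#' large enough for all top-level parameters to be identifiable, small
#' enough that a reduced-length MCMC fit takes seconds. The default
#' parameter values describe a moderately common, moderately variable
#' quarry species (typical team area ~400 ha, average rate ~1 animal per
#' 100 ha, county effects larger than HMP effects, team-level rates more
#' variable than exponential, harvest rate per area decreasing with team
#' area); the methods vignette motivates each choice.
#'
#' @param n_counties,hmps_per_county,teams_per_hmp Region layout.
#' @param coverage Probability a team reports, in (0, 1]; independent of
#'   its harvest unless `reporting_bias` is nonzero.
#' @param W,T_sd,t_sd,u,z Area-model truth: nationwide log team area,
#'   county/HMP effect SDs, log intra-HMP spread intercept and its county
#'   SD.
#' @param omega,tau,sigma Harvest-model truth: nationwide log rate and
#'   county/HMP effect SDs.
#' @param upsilon,gamma Log shape intercept and rate-variability
#'   association; set `upsilon = Inf` for Poisson (no overdispersion)
#'   truth.
#' @param phi Relative-area effect on the per-area rate.
#' @param reporting_bias Robustness knob, default off (0): log-odds shift
#'   of reporting per harvested animal, breaking the
#'   reporting-independent-of-harvest assumption on purpose.
#' @return A `truth_config` list.
#' @export
truth_config <- function(n_counties = 4, hmps_per_county = 6,
                         teams_per_hmp = 25, coverage = 0.3,
                         W = 6, T_sd = 0.8, t_sd = 0.4, u = -0.7, z = 0.2,
                         omega = -4.6, tau = 0.5, sigma = 0.4,
                         upsilon = 0, gamma = 0.3, phi = -0.3,
                         reporting_bias = 0) {
  stopifnot(n_counties >= 1, hmps_per_county >= 1, teams_per_hmp >= 1,
            coverage > 0, coverage <= 1,
            T_sd >= 0, t_sd >= 0, z >= 0, tau >= 0, sigma >= 0)
  structure(as.list(environment()), class = "truth_config")
}

#' Draw ground-truth parameters and a region registry
#'
#' Samples county and HMP effects for the area and harvest models from
#' their hierarchical Normal distributions at the configured truth values
#' and assembles a registry whose huntable areas are provisionally set to
#' `teams_per_hmp` times the expected team area (rounded up);
#' [generate_reports()] later replaces them with the exact sum of the
#' generated team areas so that the true unreported harvest is known
#' exactly.
#'
#' @param config A [truth_config()].
#' @param seed Integer seed; the same seed reproduces the same truth.
#' @return A list with `area_params` (W, L, C, T_sd, t_sd, u, v, z),
#'   `harvest_params` (omega, lambda, chi, tau, sigma, upsilon, gamma,
#'   phi), per-HMP `m`, `mu`, `alpha`, per-county `s`, and the provisional
#'   `registry`.
#' @export
generate_truth <- function(config, seed = 1) {
  stopifnot(inherits(config, "truth_config"))
  set.seed(as.integer(seed %% 2147483647L))
  cf <- config
  counties <- sprintf("c%02d", seq_len(cf$n_counties))
  hmps <- as.vector(t(outer(seq_len(cf$n_counties), seq_len(cf$hmps_per_county),
                            function(l, k) sprintf("c%02d_h%02d", l, k))))
  cty_of_hmp <- rep(seq_len(cf$n_counties), each = cf$hmps_per_county)

  L <- setNames(rnorm(cf$n_counties, 0, cf$T_sd), counties)
  C <- setNames(rnorm(length(hmps), 0, cf$t_sd), hmps)
  v <- setNames(rnorm(cf$n_counties, 0, cf$z), counties)
  lambda <- setNames(rnorm(cf$n_counties, 0, cf$tau), counties)
  chi <- setNames(rnorm(length(hmps), 0, cf$sigma), hmps)

  m <- setNames(exp(cf$W + L[cty_of_hmp] + C), hmps)
  s <- setNames(exp(cf$u + v), counties)
  eta <- chi + lambda[cty_of_hmp]
  mu <- setNames(exp(eta + cf$omega), hmps)
  alpha <- if (is.infinite(cf$upsilon)) {
    setNames(rep(Inf, length(hmps)), hmps)
  } else {
    setNames(exp(cf$upsilon + cf$gamma * eta), hmps)
  }

  expected_area <- exp(cf$W + L[cty_of_hmp] + C + (s[cty_of_hmp]^2) / 2)
  registry <- tibble(
    county_id = counties[cty_of_hmp], hmp_id = hmps,
    huntable_area_ha = ceiling(cf$teams_per_hmp * expected_area),
    excluded = 0L
  )
  list(
    area_params = list(W = cf$W, L = L, C = C, T_sd = cf$T_sd,
                       t_sd = cf$t_sd, u = cf$u, v = v, z = cf$z),
    harvest_params = list(omega = cf$omega, lambda = lambda, chi = chi,
                          tau = cf$tau, sigma = cf$sigma,
                          upsilon = cf$upsilon, gamma = cf$gamma,
                          phi = cf$phi),
    m = m, s = s, mu = mu, alpha = alpha,
    registry = registry, config = cf
  )
}

#' Generate a report table from a ground truth
#'
#' Draws every team's area from `Log-Normal(log m_kl, s_l)` and its harvest
#' from the full mechanism — a Gamma(shape `alpha_kl`, mean
#' `mu_kl * A * (A/m_kl)^phi`) team rate followed by a Poisson count
#' (reduced mechanisms are obtained by `phi = 0`, `gamma = 0` or
#' `upsilon = Inf` in the truth). Each team then reports with probability
#' `coverage`, independently of its harvest (unless the `reporting_bias`
#' knob is on). Only reporting teams enter the returned dataset; the full
#' team table, including non-reporters, is returned separately so the true
#' unreported harvest is known. Registry huntable areas are set to the
#' exact per-HMP sum of all generated team areas.
#'
#' The relative-area effect is applied against the HMP's true log-normal
#' median area `m_kl` (the estimand of the fitted typical area).
#'
#' @param truth Output of [generate_truth()].
#' @param seed Integer seed.
#' @return A list: `data` (a validated `harvest_data` of the reporting
#'   teams), `teams` (tibble of all teams: `hmp_id`, `county_id`,
#'   `area_ha`, `harvest`, `reported`), and `truth` (passed through).
#' @export
generate_reports <- function(truth, seed = 1) {
  set.seed(as.integer(seed %% 2147483647L))
  cf <- truth$config
  reg <- truth$registry
  teams <- purrr::map_dfr(seq_len(nrow(reg)), function(j) {
    k_id <- reg$hmp_id[j]
    A <- rlnorm(cf$teams_per_hmp, log(truth$m[[k_id]]),
                truth$s[[reg$county_id[j]]])
    mean_h <- truth$mu[[k_id]] * A * (A / truth$m[[k_id]])^cf$phi
    a_k <- truth$alpha[[k_id]]
    K <- if (is.infinite(a_k)) {
      rpois(cf$teams_per_hmp, mean_h)
    } else {
      rnbinom(cf$teams_per_hmp, size = a_k, mu = mean_h)
    }
    tibble(hmp_id = k_id, county_id = reg$county_id[j],
           area_ha = A, harvest = as.integer(K))
  })
  p_rep <- plogis(qlogis(cf$coverage) + cf$reporting_bias * teams$harvest)
  teams$reported <- runif(nrow(teams)) < p_rep
  teams$report_id <- sprintf("t%05d", seq_len(nrow(teams)))

  reg$huntable_area_ha <- teams %>%
    group_by(.data$hmp_id) %>%
    summarise(tot = sum(.data$area_ha), .groups = "drop") %>%
    pull(.data$tot, name = .data$hmp_id) %>%
    `[`(reg$hmp_id) %>% unname()

  reporters <- teams %>%
    filter(.data$reported) %>%
    select("report_id", "county_id", "hmp_id", "area_ha", "harvest")
  data <- harvest_data(reporters, reg, species = "synthetic")
  list(data = data, teams = teams, truth = truth)
}

#' Simulate a complete synthetic harvest dataset
#'
#' Convenience wrapper: [generate_truth()] then [generate_reports()] with
#' seeds derived from `seed`.
#'
#' @param config A [truth_config()]; default scenario if omitted.
#' @param seed Integer seed.
#' @return See [generate_reports()].
#' @examples
#' sim <- simulate_harvest_data(seed = 42)
#' sim$data
#' sum(sim$teams$harvest[!sim$teams$reported]) # true unreported harvest
#' @export
simulate_harvest_data <- function(config = truth_config(), seed = 1) {
  truth <- generate_truth(config, seed = seed)
  generate_reports(truth, seed = seed + 1L)
}

#' Parameter-recovery and prediction-calibration experiment
#'
#' Loops generate -> fit (area model + one harvest model) -> predict over
#' replicate seeds and reports, per replicate: whether each top-level
#' harvest parameter's 95% central posterior interval covers the
#' generating value, and the national-total prediction (median and 95%
#' interval) against the exactly known true total harvest, alongside the
#' linear point estimate.
#'
#' @param config A [truth_config()].
#' @param model Harvest model code to fit (see [model_spec()]).
#' @param seeds Integer vector of replicate seeds.
#' @param control Sampler settings used for both models in each replicate.
#' @param n_sims Predictive samples per replicate; `0` skips the prediction
#'   stage (parameter recovery only).
#' @param conf_level Credibility level of the intervals.
#' @return A list of tibbles: `parameters` (replicate, parameter, truth,
#'   lower, upper, covered) and `totals` (replicate, truth, reported,
#'   median, lower, upper, covered, point_estimate).
#' @export
recovery_experiment <- function(config = truth_config(), model = "magp",
                                seeds = 1:20,
                                control = mcmc_control(2, 3000, 1000, 2),
                                n_sims = 500, conf_level = 0.95) {
  spec <- model_spec(model)
  a <- (1 - conf_level) / 2
  pars <- c("omega", "tau", "sigma",
            if (spec$alpha) "upsilon", if (spec$gamma) "gamma",
            if (spec$phi) "phi")
  par_rows <- list()
  tot_rows <- list()
  for (sd_i in seeds) {
    sim <- simulate_harvest_data(config, seed = sd_i)
    d <- apply_species_exclusions(sim$data)
    af <- suppressWarnings(fit_area(d, control = control, seed = sd_i))
    mb <- typical_area(af)
    hf <- suppressWarnings(fit_harvest(d, spec, m_bar = mb,
                                       control = control, seed = sd_i))
    tt <- tidy(hf, conf_level = conf_level)
    truth_vals <- unlist(sim$truth$harvest_params[pars])
    tt <- tt %>%
      filter(.data$term %in% pars) %>%
      mutate(replicate = sd_i, truth = truth_vals[.data$term],
             covered = .data$truth >= .data$conf.low &
               .data$truth <= .data$conf.high)
    par_rows[[length(par_rows) + 1]] <-
      tt %>% select("replicate", parameter = "term", "truth",
                    lower = "conf.low", upper = "conf.high", "covered")

    if (n_sims == 0) next
    pred <- predict_unreported(af, hf, d, n_sims = n_sims, seed = sd_i)
    ns <- summarise_harvest(pred, d, level = "nation",
                            probs = c(a, 1 - a))
    retained <- sim$teams %>% filter(.data$hmp_id %in% d$registry$hmp_id)
    truth_total <- sum(retained$harvest)
    pe <- point_estimate(d) %>% filter(.data$level == "nation")
    tot_rows[[length(tot_rows) + 1]] <- tibble(
      replicate = sd_i, truth = truth_total, reported = ns$reported,
      median = ns$median, lower = ns$lower, upper = ns$upper,
      covered = truth_total >= ns$lower & truth_total <= ns$upper,
      point_estimate = pe$estimate
    )
  }
  list(parameters = bind_rows(par_rows), totals = bind_rows(tot_rows))
}
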