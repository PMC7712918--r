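#' Specify one of the six harvest models
#'
#' The harvest-model family is indexed by three switches: `alpha` adds
#' Gamma-distributed team-specific rates within each HMP (overdispersion),
#' `gamma` adds an association between an HMP's average rate and its
#' variability (only meaningful together with `alpha`), and `phi` adds a
#' power effect of a team's relative area on its per-area rate. The six
#' legal combinations are coded `"m0"`, `"ma"`, `"mag"`, `"mp"`, `"map"`
#' and `"magp"` (`a` = alpha, `g` = gamma, `p` = phi).
#'
#' @param model Model code, one of `"m0"`, `"ma"`, `"mag"`, `"mp"`, `"map"`,
#'   `"magp"`; alternatively supply the switches directly.
#' @param alpha,gamma,phi Logical switches (ignored when `model` is given).
#' @return A `harvest_model_spec` object.
#' @examples
#' model_spec("magp")
#' model_spec(alpha = TRUE, phi = TRUE) # same as "map"
#' @export
model_spec <- function(model = NULL, alpha = FALSE, gamma = FALSE,
                       phi = FALSE) {
  codes <- list(m0 = c(FALSE, FALSE, FALSE), ma = c(TRUE, FALSE, FALSE),
                mag = c(TRUE, TRUE, FALSE), mp = c(FALSE, FALSE, TRUE),
                map = c(TRUE, FALSE, TRUE), magp = c(TRUE, TRUE, TRUE))
  if (!is.null(model)) {
    model <- match.arg(model, names(codes))
    fl <- codes[[model]]
    alpha <- fl[1]; gamma <- fl[2]; phi <- fl[3]
  }
  if (gamma && !alpha) {
    abort("the rate-variability association (gamma) requires the overdispersion component (alpha)")
  }
  name <- names(codes)[vapply(codes, function(fl) {
    all(fl == c(alpha, gamma, phi))
  }, logical(1))]
  structure(list(alpha = alpha, gamma = gamma, phi = phi, name = name),
            class = "harvest_model_spec")
}

#' @export
print.harvest_model_spec <- function(x, ...) {
  cat("<harvest_model_spec>", x$name,
      "(alpha:", x$alpha, "gamma:", x$gamma, "phi:", x$phi, ")\n")
  invisible(x)
}

#' Relative-area effect on the expected harvest
#'
#' The multiplicative adjustment `delta = (A / m_bar)^phi` of a team's
#' expected harvest, where `A` is the team's area and `m_bar` the typical
#' team area of its HMP (see [typical_area()]). `phi = 0` means no effect;
#' `phi < 0` means the per-area harvest rate decreases with team area.
#'
#' @param area_ha Team area(s), positive.
#' @param m_bar Typical team area of the HMP, positive.
#' @param phi Exponent.
#' @return `(area_ha / m_bar)^phi`, vectorized.
#' @export
area_effect <- function(area_ha, m_bar, phi) {
  if (any(!is.finite(area_ha)) || any(area_ha <= 0)) abort("area_ha must be positive")
  if (any(!is.finite(m_bar)) || any(m_bar <= 0)) abort("m_bar must be positive")
  (area_ha / m_bar)^phi
}

#' Poisson log-likelihood of one report
#'
#' Log-pmf of harvest count `k` under a Poisson with mean
#' `mu * area_ha * delta`: the uniform-rate likelihood used by models
#' without the overdispersion component.
#'
#' @param k Non-negative integer count(s).
#' @param mu Average harvest rate (animals per ha), positive.
#' @param area_ha Team area (ha), positive.
#' @param delta Relative-area adjustment, positive; default 1.
#' @return Log-likelihood, vectorized.
#' @export
poisson_loglik <- function(k, mu, area_ha, delta = 1) {
  if (any(mu <= 0) || any(delta <= 0)) abort("mu and delta must be positive")
  dpois(k, lambda = mu * area_ha * delta, log = TRUE)
}

#' Gamma-Poisson (negative binomial) log-likelihood of one report
#'
#' Log-pmf of harvest count `k` under the Gamma-Poisson mixture with mean
#' `m = mu * area_ha * delta` and shape `alpha`:
#' `lgamma(k + alpha) - lgamma(k + 1) - lgamma(alpha) +
#'  alpha * log(alpha / (alpha + m)) + k * log(m / (alpha + m))`.
#' This is the likelihood of models with team-level rate heterogeneity; the
#' Poisson likelihood is its limiting case as `alpha -> Inf` (an infinite
#' `alpha` is accepted and dispatched to [poisson_loglik()]).
#'
#' @inheritParams poisson_loglik
#' @param alpha Shape parameter, positive (may be `Inf`).
#' @return Log-likelihood, vectorized.
#' @export
gamma_poisson_loglik <- function(k, mu, alpha, area_ha, delta = 1) {
  if (any(mu <= 0) || any(delta <= 0) || any(alpha <= 0)) {
    abort("mu, alpha and delta must be positive")
  }
  m <- mu * area_ha * delta
  n <- max(length(k), length(m), length(alpha))
  k <- rep_len(k, n)
  m <- rep_len(m, n)
  alpha <- rep_len(alpha, n)
  inf <- is.infinite(alpha)
  out <- numeric(n)
  out[inf] <- dpois(k[inf], lambda = m[inf], log = TRUE)
  out[!inf] <- dnbinom(k[!inf], size = alpha[!inf], mu = m[!inf], log = TRUE)
  out
}

#' Per-HMP mean rate and shape implied by a parameter setting
#'
#' Evaluates the linear predictors of a harvest model: the average rate
#' `mu_kl = exp(chi_kl + lambda_l + omega)` and, when overdispersion is
#' included, the shape `alpha_kl = exp(upsilon + gamma * (chi_kl +
#' lambda_l))` (`gamma` forced to 0 unless the association component is in
#' the model; `alpha` is `Inf` for purely Poisson models).
#'
#' @param params Named list with `omega`, `lambda` (named by county), `chi`
#'   (named by HMP), and as applicable `upsilon`, `gamma`.
#' @param spec A `harvest_model_spec`.
#' @param data A `harvest_data` object supplying the HMP-county hierarchy.
#' @return A tibble with columns `county_id`, `hmp_id`, `mu`, `alpha`.
#' @export
linear_predictors <- function(params, spec, data) {
  stopifnot(inherits(spec, "harvest_model_spec"),
            inherits(data, "harvest_data"))
  idx <- hb_index(data)
  if (!all(idx$hmps %in% names(params$chi)) ||
      !all(idx$counties %in% names(params$lambda))) {
    abort("params must name every registered HMP (chi) and county (lambda)")
  }
  eta <- params$chi[idx$hmps] + params$lambda[idx$counties[idx$cty_of_hmp]]
  mu <- exp(eta + params$omega)
  alpha <- if (spec$alpha) {
    g <- if (spec$gamma) params$gamma else 0
    exp((params$upsilon %||% 0) + g * eta)
  } else {
    rep(Inf, idx$n_hmp)
  }
  tibble(county_id = idx$counties[idx$cty_of_hmp], hmp_id = idx$hmps,
         mu = unname(mu), alpha = unname(alpha))
}

#' Maximum-likelihood harvest rate of a set of reports
#'
#' The pooled ML estimate under the uniform-rate Poisson model: total
#' harvest divided by total reported area. This is also the per-HMP rate of
#' the linear point-estimate baseline.
#'
#' @param reports A data frame with columns `harvest` and `area_ha` (e.g.
#'   the `reports` element of a `harvest_data`).
#' @return Total harvest / total area (animals per ha).
#' @export
ml_rate <- function(reports) {
  if (nrow(reports) == 0 || sum(reports$area_ha) <= 0) {
    abort("need at least one report with positive area")
  }
  sum(reports$harvest) / sum(reports$area_ha)
}

#' Over-dispersed initial values for one harvest-model chain
#'
#' Draws chain-starting values around empirical log harvest/area ratios:
#' the national intercept near the mean of county log-ratios, county
#' effects near their county's log-ratio residual, HMP effects near the
#' HMP residual when the HMP recorded at least one harvested animal and
#' from Normal(0, 0.5) otherwise, `gamma`, `phi`, `upsilon` from
#' Normal(0, 1) and the SDs `tau`, `sigma` from Gamma(5, 5). Zero-harvest
#' log-ratios (which would be `-Inf`) fall back to the Normal(0, 0.5) rule
#' at both HMP and county level.
#'
#' @param data A `harvest_data` object.
#' @param spec A `harvest_model_spec`.
#' @param seed Integer seed.
#' @return Named list with `omega`, `lambda` (named by county), `chi`
#'   (named by HMP), `tau`, `sigma`, and (per `spec`) `upsilon`, `gamma`,
#'   `phi`.
#' @export
seed_chain <- function(data, spec, seed = 1) {
  stopifnot(inherits(data, "harvest_data"),
            inherits(spec, "harvest_model_spec"))
  idx <- hb_index(data)
  rep_tab <- data$reports
  set.seed(as.integer(seed %% 2147483647L))

  cty_sum <- rep_tab %>%
    group_by(county_id = .data$county_id) %>%
    summarise(K = sum(.data$harvest), A = sum(.data$area_ha), .groups = "drop")
  cty_sum <- cty_sum[match(idx$counties, cty_sum$county_id), ]
  if (any(is.na(cty_sum$A)) || any(cty_sum$A <= 0)) {
    abort("every county needs at least one report with positive area")
  }
  log_ratio_cty <- log(cty_sum$K / cty_sum$A)
  ok <- is.finite(log_ratio_cty)
  # all-zero datasets are excluded upstream; if a split still produced one,
  # anchor the intercept at one animal over the total reported area
  center <- if (any(ok)) mean(log_ratio_cty[ok]) else log(1 / sum(cty_sum$A))

  omega0 <- rnorm(1, center, 1)
  lambda0 <- ifelse(ok, rnorm(idx$n_county, log_ratio_cty - omega0, 0.5),
                    rnorm(idx$n_county, 0, 0.5))
  hmp_sum <- rep_tab %>%
    group_by(hmp_id = .data$hmp_id) %>%
    summarise(K = sum(.data$harvest), A = sum(.data$area_ha), .groups = "drop")
  hmp_sum <- hmp_sum[match(idx$hmps, hmp_sum$hmp_id), ]
  has_harvest <- !is.na(hmp_sum$K) & hmp_sum$K > 0
  resid <- suppressWarnings(
    log(hmp_sum$K / hmp_sum$A) - lambda0[idx$cty_of_hmp] - omega0)
  chi0 <- rnorm(idx$n_hmp, ifelse(has_harvest, resid, 0), 0.5)

  out <- list(omega = omega0,
              lambda = setNames(lambda0, idx$counties),
              chi = setNames(chi0, idx$hmps),
              tau = rgamma(1, 5, 5), sigma = rgamma(1, 5, 5))
  if (spec$alpha) out$upsilon <- rnorm(1, 0, 1)
  if (spec$gamma) out$gamma <- rnorm(1, 0, 1)
  if (spec$phi) out$phi <- rnorm(1, 0, 1)
  out
}

#' Joint log posterior density of a harvest model
#'
#' Evaluates, up to an additive constant, the log posterior of the chosen
#' harvest model: the Poisson or Gamma-Poisson likelihood of every report
#' at mean `mu_kl * A_r * delta_r`, the hierarchical Normal densities of
#' the county and HMP effects (`lambda_l ~ Normal(0, tau)`,
#' `chi_kl ~ Normal(0, sigma)`), and the configured top-level priors.
#' As in [area_log_density()], `params` may use the centered effects
#' (`lambda`, `chi`) or the standard-Normal primitives (`lambda_star`,
#' `chi_star`), which are scaled by `tau` and `sigma` respectively before
#' evaluation, so both parameterizations agree exactly.
#'
#' @param params Named list: `omega`, `tau`, `sigma`, effect vectors as
#'   above, and as applicable `upsilon`, `gamma`, `phi`.
#' @param data A `harvest_data` object.
#' @param spec A `harvest_model_spec`.
#' @param priors Prior configuration.
#' @param m_bar Named vector (or tibble from [typical_area()]) of typical
#'   team areas; required iff `spec$phi`.
#' @return The joint log density up to a constant.
#' @export
harvest_log_density <- function(params, data, spec,
                                priors = default_priors(), m_bar = NULL) {
  stopifnot(inherits(data, "harvest_data"),
            inherits(spec, "harvest_model_spec"))
  idx <- hb_index(data)
  p <- params
  if (p$tau <= 0 || p$sigma <= 0) return(-Inf)
  if (is.null(p[["lambda"]])) p$lambda <- setNames(p$tau * p$lambda_star[idx$counties], idx$counties)
  if (is.null(p[["chi"]])) p$chi <- setNames(p$sigma * p$chi_star[idx$hmps], idx$hmps)
  lp_tab <- linear_predictors(p, spec, data)
  mb <- check_m_bar(m_bar, spec, idx)
  A <- data$reports$area_ha
  delta <- if (spec$phi) {
    area_effect(A, mb[data$reports$hmp_id], p$phi)
  } else rep(1, length(A))
  ll <- sum(gamma_poisson_loglik(data$reports$harvest,
                                 mu = lp_tab$mu[idx$hmp_of_report],
                                 alpha = lp_tab$alpha[idx$hmp_of_report],
                                 area_ha = A, delta = delta))
  lp <- sum(dnorm(p$lambda[idx$counties], 0, p$tau, log = TRUE)) +
    sum(dnorm(p$chi[idx$hmps], 0, p$sigma, log = TRUE)) +
    prior_logdens(priors, "omega", p$omega) +
    prior_logdens(priors, "tau", p$tau) +
    prior_logdens(priors, "sigma", p$sigma)
  if (spec$alpha) lp <- lp + prior_logdens(priors, "upsilon", p$upsilon)
  if (spec$gamma) lp <- lp + prior_logdens(priors, "gamma", p$gamma)
  if (spec$phi) lp <- lp + prior_logdens(priors, "phi", p$phi)
  ll + lp
}

# Normalize m_bar input (tibble from typical_area() or named vector) to a
# named vector covering every registered HMP; NULL allowed iff !spec$phi.
check_m_bar <- function(m_bar, spec, idx) {
  if (!spec$phi) return(NULL)
  if (is.null(m_bar)) abort("m_bar is required for models including phi")
  if (is.data.frame(m_bar)) m_bar <- setNames(m_bar$m_bar, m_bar$hmp_id)
  missing <- setdiff(idx$hmps, names(m_bar))
  if (length(missing) > 0) {
    abort(paste0("m_bar lacks HMP(s): ", paste(missing, collapse = ", ")))
  }
  m_bar[idx$hmps]
}

harvest_model_bugs <- function(spec) {
  lik <- if (spec$alpha) "
    K[r] ~ dnegbin(pnb[r], alpha[hmp[r]])
    pnb[r] <- alpha[hmp[r]] / (alpha[hmp[r]] + mn[r])" else "
    K[r] ~ dpois(mn[r])"
  dl <- if (spec$phi) " * pow(A[r] / mbar[hmp[r]], phi)" else ""
  alpha_def <- if (spec$alpha) {
    if (spec$gamma) "alpha[k] <- exp(upsilon + gamma * eta[k])"
    else "alpha[k] <- exp(upsilon)"
  } else ""
  extra_priors <- paste(
    if (spec$alpha) "upsilon ~ dnorm(pu_loc, pu_prec)" else "",
    if (spec$gamma) "gamma ~ dnorm(pg_loc, pg_prec)" else "",
    if (spec$phi) "phi ~ dnorm(pp_loc, pp_prec)" else "",
    sep = "\n  ")
  paste0("
model {
  for (r in 1:N) {", lik, "
    mn[r] <- mu[hmp[r]] * A[r]", dl, "
  }
  for (k in 1:KH) {
    chi_star[k] ~ dnorm(0, 1)
    chi[k] <- sigma * chi_star[k]
    eta[k] <- chi[k] + lambda[cty[k]]
    mu[k] <- exp(eta[k] + omega)
    ", alpha_def, "
  }
  for (l in 1:NL) {
    lambda_star[l] ~ dnorm(0, 1)
    lambda[l] <- tau * lambda_star[l]
  }
  omega ~ dnorm(po_loc, po_prec)
  tau ~ dlnorm(ptau_loc, ptau_prec)
  sigma ~ dlnorm(psig_loc, psig_prec)
  ", extra_priors, "
}")
}

#' Fit a hierarchical harvest model
#'
#' Samples the posterior of one of the six harvest models (see
#' [model_spec()]) by MCMC, using the non-centered parameterization of the
#' county and HMP effects and the over-dispersed chain seeding of
#' [seed_chain()] (a fresh draw per chain). The pointwise log-likelihood of
#' every report under every kept draw is stored for cross-validation.
#'
#' Convergence is reported via split-Rhat and effective sample size of the
#' top-level parameters; split-Rhat above 1.05 triggers a warning, as does
#' a large spread of per-chain mean log-likelihood (a symptom of a chain
#' stuck in a local mode, best addressed by refitting with a new seed).
#'
#' @param data A `harvest_data` object that has passed
#'   [apply_species_exclusions()].
#' @param spec A `harvest_model_spec`.
#' @param priors Prior configuration, see [default_priors()].
#' @param m_bar Typical team areas from [typical_area()]; required iff the
#'   model includes `phi`.
#' @param control Sampler settings, see [mcmc_control()].
#' @param seed Integer seed; identical seed and settings give identical
#'   draws.
#' @return A `harvest_fit` object: pooled draws of the top-level
#'   parameters, effect matrices, per-draw derived `mu_kl` and `alpha_kl`
#'   (draws x HMPs), the draws x reports pointwise log-likelihood matrix,
#'   and diagnostics. The input data, spec, priors and settings are stored
#'   so the fit can be reproduced or refit leaving one report out.
#' @examples
#' \donttest{
#' d <- simulate_harvest_data(seed = 1)$data
#' ctl <- mcmc_control(2, 2000, 500, 1)
#' fit <- fit_harvest(d, model_spec("ma"), control = ctl, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_harvest <- function(data, spec, priors = default_priors(), m_bar = NULL,
                        control = mcmc_control(), seed = 1) {
  stopifnot(inherits(data, "harvest_data"),
            inherits(spec, "harvest_model_spec"))
  if (nrow(data$reports) == 0) abort("dataset has no reports")
  idx <- hb_index(data)
  mb <- check_m_bar(m_bar, spec, idx)
  pr <- function(nm) prior_get(priors, nm)
  jd <- list(
    N = nrow(data$reports), K = data$reports$harvest,
    A = data$reports$area_ha, hmp = idx$hmp_of_report,
    KH = idx$n_hmp, NL = idx$n_county, cty = idx$cty_of_hmp,
    po_loc = pr("omega")$location, po_prec = pr("omega")$scale^-2,
    ptau_loc = pr("tau")$location, ptau_prec = pr("tau")$scale^-2,
    psig_loc = pr("sigma")$location, psig_prec = pr("sigma")$scale^-2
  )
  if (spec$phi) {
    jd$mbar <- unname(mb)
    jd$pp_loc <- pr("phi")$location; jd$pp_prec <- pr("phi")$scale^-2
  }
  if (spec$alpha) {
    jd$pu_loc <- pr("upsilon")$location; jd$pu_prec <- pr("upsilon")$scale^-2
  }
  if (spec$gamma) {
    jd$pg_loc <- pr("gamma")$location; jd$pg_prec <- pr("gamma")$scale^-2
  }

  init_seeds <- chain_seeds(seed + 1L, control$chains)
  inits_fun <- function(chain) {
    ini <- seed_chain(data, spec, seed = init_seeds[chain])
    out <- list(omega = ini$omega, tau = ini$tau, sigma = ini$sigma,
                lambda_star = unname(ini$lambda) / ini$tau,
                chi_star = unname(ini$chi) / ini$sigma)
    if (spec$alpha) out$upsilon <- ini$upsilon
    if (spec$gamma) out$gamma <- ini$gamma
    if (spec$phi) out$phi <- ini$phi
    out
  }

  top <- c("omega", "tau", "sigma",
           if (spec$alpha) "upsilon", if (spec$gamma) "gamma",
           if (spec$phi) "phi")
  monitors <- c(top, "lambda", "chi")
  samples <- run_jags(harvest_model_bugs(spec), jd, monitors, control, seed,
                      inits_fun = inits_fun)

  diag <- mcmc_diagnostics(samples, top)
  warn_convergence(diag, 1.05, paste0("harvest model ", spec$name))

  draws <- pool_draws(samples)
  col_or <- function(stem, n) if (n == 1) stem else paste0(stem, "[", seq_len(n), "]")
  lam <- as.matrix(draws[, col_or("lambda", idx$n_county), drop = FALSE])
  chi <- as.matrix(draws[, col_or("chi", idx$n_hmp), drop = FALSE])
  colnames(lam) <- idx$counties
  colnames(chi) <- idx$hmps
  eta <- chi + lam[, idx$cty_of_hmp, drop = FALSE]
  mu <- exp(eta + draws$omega)
  colnames(mu) <- idx$hmps
  alpha <- if (spec$alpha) {
    g <- if (spec$gamma) draws$gamma else 0
    a <- exp(draws$upsilon + g * eta)
    colnames(a) <- idx$hmps
    a
  } else {
    matrix(Inf, nrow(draws), idx$n_hmp, dimnames = list(NULL, idx$hmps))
  }
  phi_draws <- if (spec$phi) draws$phi else rep(0, nrow(draws))

  loglik <- pointwise_loglik_matrix(data, idx, spec, mu, alpha, phi_draws, mb)
  colnames(loglik) <- data$reports$report_id

  # stuck-chain check: per-chain mean total log-likelihood far apart
  tot_ll <- rowSums(loglik)
  ch_means <- tapply(tot_ll, draws$.chain, mean)
  ch_sds <- tapply(tot_ll, draws$.chain, sd)
  if (length(ch_means) > 1 &&
      (max(ch_means) - min(ch_means)) > 4 * max(mean(ch_sds, na.rm = TRUE), 1e-8)) {
    warn(paste0("harvest model ", spec$name,
                ": chains disagree in mean log-likelihood; a chain may be ",
                "stuck in a local mode - refit with a different seed"))
  }

  structure(list(
    draws = draws %>% select(".chain", ".iteration", ".draw", all_of(top)),
    effects = list(lambda = lam, chi = chi),
    mu = mu, alpha = alpha, phi_draws = phi_draws,
    loglik = loglik, diagnostics = diag,
    spec = spec, m_bar = mb, index = idx,
    data = data, priors = priors, control = control, seed = seed
  ), class = "harvest_fit")
}

# draws x reports pointwise log-likelihood, vectorized over draws.
pointwise_loglik_matrix <- function(data, idx, spec, mu, alpha, phi_draws, mb) {
  n_draw <- nrow(mu)
  N <- nrow(data$reports)
  out <- matrix(NA_real_, n_draw, N)
  A <- data$reports$area_ha
  K <- data$reports$harvest
  for (r in seq_len(N)) {
    k_idx <- idx$hmp_of_report[r]
    m_r <- mu[, k_idx] * A[r]
    if (spec$phi) m_r <- m_r * (A[r] / mb[[idx$hmps[k_idx]]])^phi_draws
    out[, r] <- if (spec$alpha) {
      dnbinom(K[r], size = alpha[, k_idx], mu = m_r, log = TRUE)
    } else {
      dpois(K[r], lambda = m_r, log = TRUE)
    }
  }
  out
}

#' @export
print.harvest_fit <- function(x, ...) {
  cat("<harvest_fit>", x$spec$name, "-", nrow(x$draws), "draws,",
      x$control$chains, "chains;", ncol(x$loglik), "reports\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @method tidy harvest_fit
#' @export
tidy.harvest_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  x$draws %>%
    select(-".chain", -".iteration", -".draw") %>%
    tidyr::pivot_longer(everything(), names_to = "term") %>%
    group_by(.data$term) %>%
    summarise(estimate = median(.data$value),
              std.error = sd(.data$value),
              conf.low = quantile(.data$value, a),
              conf.high = quantile(.data$value, 1 - a),
              .groups = "drop") %>%
    left_join(x$diagnostics, by = c(term = "parameter"))
}

#' @method glance harvest_fit
#' @export
glance.harvest_fit <- function(x, ...) {
  tibble(model = x$spec$name, n_draws = nrow(x$draws),
         chains = x$control$chains, n_reports = ncol(x$loglik),
         max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
         min_ess = min(x$diagnostics$ess, na.rm = TRUE),
         lpd = sum(log(colMeans(exp(x$loglik)))))
}
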