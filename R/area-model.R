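#' Joint log posterior density of the hunting-area model
#'
#' Evaluates, up to an additive constant, the log posterior of the
#' hierarchical log-normal model of hunting-team areas:
#' `A_r ~ Log-Normal(log(m_kl), s_l)` with `m_kl = exp(W + L_l + C_kl)` and
#' `s_l = exp(u + v_l)`, county effects `L_l ~ Normal(0, T)`, HMP effects
#' `C_kl ~ Normal(0, t)`, and `v_l ~ Normal(0, z)`, plus the configured
#' top-level priors.
#'
#' `params` may be supplied in the centered parameterization (`L`, `C`, `v`)
#' or the non-centered one (`L_star`, `C_star`, `v_star`, each a standard
#' Normal primitive scaled by its SD). Primitives are first mapped to the
#' centered effects (`L = T_sd * L_star`, etc.), so both parameterizations
#' evaluate the identical mathematical density.
#'
#' @param params Named list: `W`, `T_sd`, `t_sd`, `u`, `z`, and either
#'   `L`, `v` (named by county) and `C` (named by HMP) or their `_star`
#'   primitives.
#' @param data A `harvest_data` object.
#' @param priors Prior configuration tibble, see [default_priors()].
#' @return A single finite number (for finite inputs): the joint log density
#'   up to a constant.
#' @export
area_log_density <- function(params, data, priors = default_priors()) {
  stopifnot(inherits(data, "harvest_data"))
  if (nrow(data$reports) == 0) abort("dataset has no reports")
  idx <- hb_index(data)
  p <- params
  if (is.null(p[["L"]])) p$L <- setNames(p$T_sd * p$L_star[idx$counties], idx$counties)
  if (is.null(p[["C"]])) p$C <- setNames(p$t_sd * p$C_star[idx$hmps], idx$hmps)
  if (is.null(p[["v"]])) p$v <- setNames(p$z * p$v_star[idx$counties], idx$counties)
  if (p$T_sd <= 0 || p$t_sd <= 0 || p$z <= 0) return(-Inf)

  L <- p[["L"]][idx$counties]
  C <- p[["C"]][idx$hmps]
  v <- p[["v"]][idx$counties]
  log_m <- p$W + L[idx$cty_of_hmp] + C
  s <- exp(p$u + v)

  ll <- sum(dlnorm(data$reports$area_ha,
                   meanlog = log_m[idx$hmp_of_report],
                   sdlog = s[idx$cty_of_report], log = TRUE))
  lp <- sum(dnorm(L, 0, p$T_sd, log = TRUE)) +
    sum(dnorm(C, 0, p$t_sd, log = TRUE)) +
    sum(dnorm(v, 0, p$z, log = TRUE)) +
    prior_logdens(priors, "W", p$W) +
    prior_logdens(priors, "T", p$T_sd) +
    prior_logdens(priors, "t", p$t_sd) +
    prior_logdens(priors, "u", p$u) +
    prior_logdens(priors, "z", p$z)
  ll + lp
}

area_model_bugs <- "
model {
  for (r in 1:N) {
    A[r] ~ dlnorm(log_m[hmp[r]], prec_s[cty_r[r]])
  }
  for (k in 1:KH) {
    C_star[k] ~ dnorm(0, 1)
    C[k] <- t_sd * C_star[k]
    log_m[k] <- W + L[cty[k]] + C[k]
  }
  for (l in 1:NL) {
    L_star[l] ~ dnorm(0, 1)
    L[l] <- T_sd * L_star[l]
    v_star[l] ~ dnorm(0, 1)
    v[l] <- z * v_star[l]
    s[l] <- exp(u + v[l])
    prec_s[l] <- pow(s[l], -2)
  }
  W ~ dnorm(pW_loc, pW_prec)
  T_sd ~ dlnorm(pT_loc, pT_prec)
  t_sd ~ dlnorm(pt_loc, pt_prec)
  u ~ dnorm(pu_loc, pu_prec)
  z ~ dlnorm(pz_loc, pz_prec)
}"

#' Fit the hierarchical hunting-area model
#'
#' Samples the posterior of the log-normal area model (see
#' [area_log_density()]) by MCMC, using the non-centered parameterization of
#' the county, HMP and variability effects and the sampler's default
#' initialization. Every county in `data` must have at least one report;
#' counties violating this should have been removed upstream with
#' [apply_species_exclusions()].
#'
#' @param data A `harvest_data` object.
#' @param priors Prior configuration, see [default_priors()].
#' @param control Sampler settings, see [mcmc_control()].
#' @param seed Integer seed; identical seed and settings give identical draws.
#' @return An `area_fit` object holding the pooled post-warmup draws of the
#'   top-level parameters and effects, per-draw derived `m_kl` (matrix draws
#'   x HMPs) and `s_l` (draws x counties), and split-Rhat/ESS diagnostics.
#'   A warning is emitted if split-Rhat of any top-level parameter exceeds
#'   1.01.
#' @examples
#' \donttest{
#' d <- simulate_harvest_data(seed = 1)$data
#' fit <- fit_area(d, control = mcmc_control(2, 1500, 500, 1), seed = 1)
#' glance(fit)
#' }
#' @export
fit_area <- function(data, priors = default_priors(),
                     control = mcmc_control(), seed = 1) {
  stopifnot(inherits(data, "harvest_data"))
  if (nrow(data$reports) == 0) abort("dataset has no reports")
  idx <- hb_index(data)
  no_rep <- setdiff(seq_len(idx$n_county), unique(idx$cty_of_report))
  if (length(no_rep) > 0) {
    abort(paste0("county with no reports (exclude upstream): ",
                 paste(idx$counties[no_rep], collapse = ", ")))
  }
  pr <- function(nm) prior_get(priors, nm)
  jd <- list(
    N = nrow(data$reports), A = data$reports$area_ha,
    hmp = idx$hmp_of_report, cty_r = idx$cty_of_report,
    KH = idx$n_hmp, NL = idx$n_county, cty = idx$cty_of_hmp,
    pW_loc = pr("W")$location, pW_prec = pr("W")$scale^-2,
    pT_loc = pr("T")$location, pT_prec = pr("T")$scale^-2,
    pt_loc = pr("t")$location, pt_prec = pr("t")$scale^-2,
    pu_loc = pr("u")$location, pu_prec = pr("u")$scale^-2,
    pz_loc = pr("z")$location, pz_prec = pr("z")$scale^-2
  )
  monitors <- c("W", "T_sd", "t_sd", "u", "z", "L", "C", "v")
  samples <- run_jags(area_model_bugs, jd, monitors, control, seed)

  top <- c("W", "T_sd", "t_sd", "u", "z")
  diag <- mcmc_diagnostics(samples, intersect(top, colnames(as.matrix(samples[[1]]))))
  warn_convergence(diag, 1.01, "area model")

  draws <- pool_draws(samples)
  col_or <- function(stem, n) {
    if (n == 1) stem else paste0(stem, "[", seq_len(n), "]")
  }
  Lm <- as.matrix(draws[, col_or("L", idx$n_county), drop = FALSE])
  Cm <- as.matrix(draws[, col_or("C", idx$n_hmp), drop = FALSE])
  vm <- as.matrix(draws[, col_or("v", idx$n_county), drop = FALSE])
  colnames(Lm) <- colnames(vm) <- idx$counties
  colnames(Cm) <- idx$hmps
  m <- exp(draws$W + Lm[, idx$cty_of_hmp, drop = FALSE] + Cm)
  colnames(m) <- idx$hmps
  s <- exp(draws$u + vm)
  colnames(s) <- idx$counties

  structure(list(
    draws = draws %>% select(".chain", ".iteration", ".draw", all_of(top)),
    effects = list(L = Lm, C = Cm, v = vm),
    m = m, s = s,
    diagnostics = diag, index = idx,
    control = control, priors = priors, seed = seed,
    species = data$species
  ), class = "area_fit")
}

#' @export
print.area_fit <- function(x, ...) {
  cat("<area_fit>", nrow(x$draws), "draws,",
      x$control$chains, "chains;", x$index$n_hmp, "HMPs,",
      x$index$n_county, "counties\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Typical hunting-team area per HMP
#'
#' The typical team area of an HMP is defined as the posterior median (over
#' pooled chains) of `m_kl`, the log-normal median of team areas in that
#' HMP. It is computed once from the area posterior and passed to every
#' harvest model that includes the relative-area effect, so the area model
#' need not be refit per species.
#'
#' @param fit An `area_fit` object.
#' @param hmp_id Optional HMP identifier(s); default all.
#' @return A tibble with columns `hmp_id` and `m_bar` (ha).
#' @export
typical_area <- function(fit, hmp_id = NULL) {
  stopifnot(inherits(fit, "area_fit"))
  out <- tibble(hmp_id = colnames(fit$m),
                m_bar = unname(apply(fit$m, 2, median)))
  if (!is.null(hmp_id)) {
    unknown <- setdiff(hmp_id, out$hmp_id)
    if (length(unknown) > 0) {
      abort(paste0("unknown HMP(s): ", paste(unknown, collapse = ", ")))
    }
    out <- out[match(hmp_id, out$hmp_id), ]
  }
  out
}

#' @method tidy area_fit
#' @export
tidy.area_fit <- function(x, conf_level = 0.95, ...) {
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

#' @method glance area_fit
#' @export
glance.area_fit <- function(x, ...) {
  tibble(n_draws = nrow(x$draws), chains = x$control$chains,
         n_hmp = x$index$n_hmp, n_county = x$index$n_county,
         max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
         min_ess = min(x$diagnostics$ess, na.rm = TRUE))
}
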