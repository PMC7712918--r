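#' Split reports into training and validation sets
#'
#' Randomly partitions the reports by permutation: the training set receives
#' `round(fraction * n)` reports and the validation set the rest, so the
#' sizes are deterministic given `n` (an exact half split at the default).
#' No stratification is applied. Both halves share the full registry.
#'
#' @param data A `harvest_data` object with at least 2 reports.
#' @param fraction Training fraction in (0, 1); default 0.5.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return A list with `harvest_data` elements `train` and `validation`;
#'   their report sets are disjoint and their union is the input.
#' @export
split_reports <- function(data, fraction = 0.5, seed = 1) {
  stopifnot(inherits(data, "harvest_data"))
  if (!(fraction > 0 && fraction < 1)) abort("fraction must be in (0, 1)")
  n <- nrow(data$reports)
  if (n < 2) abort("need at least 2 reports to split")
  set.seed(as.integer(seed %% 2147483647L))
  n_train <- round(fraction * n)
  if (n_train == 0 || n_train == n) abort("split would leave one set empty")
  idx <- sample.int(n, n_train)
  mk <- function(rows) {
    structure(list(reports = data$reports[rows, , drop = FALSE],
                   registry = data$registry, species = data$species),
              class = "harvest_data")
  }
  list(train = mk(sort(idx)), validation = mk(setdiff(seq_len(n), idx)))
}

#' Posterior predictive mass at an observed harvest
#'
#' Scores how much probability a predictive distribution assigns to the
#' harvest actually observed. When at least `cutoff` predictive samples hit
#' the observed count exactly, the PPM is the empirical mass (count / Q).
#' Below the cutoff, sampling noise would dominate, so the mass is instead
#' estimated by jittered kernel density estimation for discrete data: each
#' sample is jittered with a uniform draw on [-0.5, 0.5), a Gaussian KDE is
#' fit to the jittered sample, and the density is evaluated at the observed
#' integer.
#'
#' @param pred A `harvest_prediction`.
#' @param data Optional `harvest_data` supplying the observed harvest when
#'   `observed` is omitted.
#' @param level,unit_id Aggregation level and unit scored.
#' @param observed Observed harvest on the predicted area (non-negative
#'   integer). If `NULL`, the reported harvest of the unit in `data` is
#'   used (the train/validation workflow predicts the validation half's
#'   area and scores its reported harvest).
#' @param cutoff Minimum number of samples at the observed value for the
#'   empirical branch; default 10,000 (as a count, not a fraction).
#' @param bw KDE bandwidth for the jittered branch: a number or a
#'   [stats::bw.nrd0()]-style rule name; default `"nrd0"`.
#' @param jitter_seed Seed for the jittering noise.
#' @return A one-row tibble: `level`, `unit_id`, `observed`, `ppm`,
#'   `method` (`"empirical-mass"` or `"jittered-kde"`),
#'   `samples_at_observed`.
#' @export
ppm <- function(pred, data = NULL, level = c("nation", "county", "hmp"),
                unit_id = NULL, observed = NULL, cutoff = 10000,
                bw = "nrd0", jitter_seed = 1) {
  stopifnot(inherits(pred, "harvest_prediction"))
  level <- match.arg(level)
  totals <- prediction_totals(pred, level, unit_id)
  if (is.null(observed)) {
    if (is.null(data)) abort("supply either `observed` or `data`")
    observed <- reported_totals(data, level, unit_id)$reported[1]
  }
  stopifnot(is.finite(observed), observed >= 0, observed == round(observed))
  x <- totals$kappa
  Q <- length(x)
  if (Q == 0) abort("prediction has no samples")
  hits <- sum(x == observed)
  if (hits >= cutoff) {
    p <- hits / Q
    method <- "empirical-mass"
  } else {
    set.seed(as.integer(jitter_seed %% 2147483647L))
    xj <- x + runif(Q, -0.5, 0.5)
    h <- if (is.character(bw)) {
      switch(bw, nrd0 = stats::bw.nrd0(xj), nrd = stats::bw.nrd(xj),
             SJ = stats::bw.SJ(xj), abort("unknown bandwidth rule"))
    } else bw
    if (!is.finite(h) || h <= 0) h <- 0.5 # degenerate sample fallback
    # exact Gaussian-KDE evaluation at the observed integer
    p <- mean(dnorm(observed, mean = xj, sd = h))
    method <- "jittered-kde"
  }
  tibble(level = level,
         unit_id = totals$unit_id[1] %||% NA_character_,
         observed = as.integer(observed), ppm = p, method = method,
         samples_at_observed = hits)
}

# --- Pareto-smoothed importance sampling ------------------------------------

# Generalized Pareto fit to exceedances (profile posterior-mean estimator
# with a weakly informative prior on the shape, which stabilizes small
# tails). Returns shape k (positive = heavy tail) and scale sigma.
gpd_fit <- function(x, wip = TRUE) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || x[n] <= 0) return(list(k = NA_real_, sigma = NA_real_))
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_j <- vapply(theta, function(b) mean(log1p(-b * x)), numeric(1))
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(l_j - l_j[j])), numeric(1))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  if (wip) k <- k * n / (n + 10) + 0.5 * 10 / (n + 10)
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Smooth one vector of log importance ratios; returns the smoothed log
# weights (normalized to max 0) and the Pareto-k diagnostic.
psis_smooth <- function(lr, tail_frac = 0.2, min_tail = 5) {
  S <- length(lr)
  lr <- lr - max(lr)
  if (sd(lr) < 1e-12) return(list(lw = lr, k = -Inf))
  M <- min(S - 1L, max(min_tail, ceiling(tail_frac * S)))
  ord <- order(lr)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lr[ord[S - M]]
  exc <- exp(lr[tail_ids]) - exp(cutoff)
  fit <- gpd_fit(exc)
  if (!is.finite(fit$k)) return(list(lw = lr, k = NA_real_))
  p <- (rank(lr[tail_ids], ties.method = "first") - 0.5) / M
  sm <- log(vapply(p, gpd_quantile, numeric(1), k = fit$k,
                   sigma = fit$sigma) + exp(cutoff))
  lr[tail_ids] <- pmin(sm, 0)
  list(lw = lr - max(lr), k = fit$k)
}

#' PSIS-LOO cross-validation from pointwise log-likelihoods
#'
#' Approximates exact leave-one-out cross-validation by importance
#' sampling: for each report, the importance ratios are the reciprocals of
#' its per-draw likelihood, the largest 20% of ratios (at least 5) are
#' replaced by expected order statistics of a generalized Pareto
#' distribution fitted to them (Pareto smoothing), and the report's
#' out-of-sample log predictive density is the log of the smoothed
#' weighted average of its likelihood. The fitted Pareto shape `k` is the
#' reliability diagnostic: values above 0.7 flag reports whose
#' approximation should be replaced by an exact refit
#' ([loo_with_refits()]).
#'
#' @param x A `harvest_fit`, or a draws x reports matrix of pointwise
#'   log-likelihoods (finite entries).
#' @param ... Unused.
#' @return A `loo_result`: list with `elpd` (sum of pointwise values),
#'   `pointwise` tibble (`report_id`, `elpd_i`, `pareto_k`), and
#'   `n_refit = 0`.
#' @export
psis_loo <- function(x, ...) UseMethod("psis_loo")

#' @export
psis_loo.harvest_fit <- function(x, ...) {
  psis_loo(x$loglik, ...)
}

#' @export
psis_loo.matrix <- function(x, ...) {
  if (!all(is.finite(x))) abort("pointwise log-likelihood matrix must be finite")
  if (nrow(x) < 100) {
    warn("fewer than 100 draws; PSIS-LOO may be unstable")
  }
  ids <- colnames(x) %||% as.character(seq_len(ncol(x)))
  res <- lapply(seq_len(ncol(x)), function(i) {
    ll <- x[, i]
    sm <- psis_smooth(-ll)
    lw <- sm$lw
    # log weighted mean of exp(ll): logsumexp(lw + ll) - logsumexp(lw)
    elpd_i <- log_sum_exp(lw + ll) - log_sum_exp(lw)
    c(elpd_i, sm$k)
  })
  res <- do.call(rbind, res)
  out <- list(elpd = sum(res[, 1]),
              pointwise = tibble(report_id = ids, elpd_i = res[, 1],
                                 pareto_k = res[, 2]),
              n_refit = 0L)
  class(out) <- "loo_result"
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.loo_result <- function(x, ...) {
  cat("<loo_result> ELPD:", round(x$elpd, 2), "over",
      nrow(x$pointwise), "reports;",
      sum(is.finite(x$pointwise$pareto_k) & x$pointwise$pareto_k > 0.7),
      "report(s) with Pareto k > 0.7;", x$n_refit, "exact refit(s)\n")
  invisible(x)
}

#' PSIS-LOO with exact refits for unreliable reports
#'
#' Runs [psis_loo()] on a fitted harvest model and then, for every report
#' whose Pareto shape diagnostic exceeds `k_threshold` (default 0.7),
#' refits the model on the data without that report and replaces the
#' report's pointwise value with its exact log predictive density (the log
#' of its likelihood averaged over the refit draws).
#'
#' @param fit A `harvest_fit` (it carries its data, priors and settings, so
#'   refits are self-contained).
#' @param k_threshold Pareto-k above which a report is refit exactly.
#' @param control Optional sampler settings for the refits; defaults to the
#'   settings of `fit`.
#' @param seed Seed for the refit chains.
#' @return A `loo_result` with `n_refit` recording the number of exact
#'   refits.
#' @export
loo_with_refits <- function(fit, k_threshold = 0.7, control = NULL,
                            seed = 1) {
  stopifnot(inherits(fit, "harvest_fit"))
  base <- psis_loo(fit)
  flagged <- which(is.finite(base$pointwise$pareto_k) &
                     base$pointwise$pareto_k > k_threshold)
  if (length(flagged) == 0) return(base)
  control <- control %||% fit$control
  for (i in flagged) {
    sub <- structure(list(reports = fit$data$reports[-i, , drop = FALSE],
                          registry = fit$data$registry,
                          species = fit$data$species),
                     class = "harvest_data")
    refit <- fit_harvest(sub, fit$spec, priors = fit$priors,
                         m_bar = fit$m_bar, control = control,
                         seed = seed + i)
    base$pointwise$elpd_i[i] <- exact_lpd(refit, fit$data$reports[i, ])
  }
  base$elpd <- sum(base$pointwise$elpd_i)
  base$n_refit <- length(flagged)
  base
}

# Exact log predictive density of one held-out report under a fit.
exact_lpd <- function(fit, report) {
  k_id <- report$hmp_id
  if (!k_id %in% colnames(fit$mu)) {
    abort(paste0("held-out report's HMP absent from fit: ", k_id))
  }
  m_r <- fit$mu[, k_id] * report$area_ha
  if (fit$spec$phi) {
    m_r <- m_r * (report$area_ha / fit$m_bar[[k_id]])^fit$phi_draws
  }
  ll <- if (fit$spec$alpha) {
    dnbinom(report$harvest, size = fit$alpha[, k_id], mu = m_r, log = TRUE)
  } else {
    dpois(report$harvest, lambda = m_r, log = TRUE)
  }
  log_sum_exp(ll) - log(length(ll))
}

#' Compare models by expected log predictive density
#'
#' Tabulates ELPD differences of several LOO results against the
#' best-scoring model, with the standard error of each difference computed
#' from the per-report pointwise differences
#' (`se = sqrt(n * var(pointwise diffs))`). Differences beyond two standard
#' errors are conventionally taken as meaningful for well-behaved samples,
#' and beyond four as conservative evidence; both flags are reported. All
#' results must cover the identical report set.
#'
#' @param ... Named `loo_result` objects, or a single named list of them.
#' @return A tibble sorted by ELPD with columns `model`, `elpd`,
#'   `elpd_diff`, `se_diff`, `beyond_2se`, `beyond_4se`.
#' @export
compare_elpd <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && !inherits(dots[[1]], "loo_result")) dots <- dots[[1]]
  if (length(dots) < 2) abort("need at least two loo_result objects")
  if (is.null(names(dots)) || any(names(dots) == "")) {
    names(dots) <- paste0("model", seq_along(dots))
  }
  ref_ids <- sort(dots[[1]]$pointwise$report_id)
  for (d in dots) {
    if (!identical(sort(d$pointwise$report_id), ref_ids)) {
      abort("all models must be evaluated on the identical report set")
    }
  }
  elpds <- vapply(dots, function(d) d$elpd, numeric(1))
  best <- names(dots)[which.max(elpds)]
  pw <- function(d) d$pointwise$elpd_i[order(d$pointwise$report_id)]
  pw_best <- pw(dots[[best]])
  n <- length(pw_best)
  out <- purrr::map_dfr(names(dots), function(nm) {
    diffs <- pw(dots[[nm]]) - pw_best
    se <- if (nm == best) 0 else sqrt(n * var(diffs))
    tibble(model = nm, elpd = elpds[[nm]], elpd_diff = sum(diffs),
           se_diff = se)
  }) %>%
    arrange(desc(.data$elpd)) %>%
    mutate(beyond_2se = abs(.data$elpd_diff) > 2 * .data$se_diff &
             .data$model != best,
           beyond_4se = abs(.data$elpd_diff) > 4 * .data$se_diff &
             .data$model != best)
  out
}

#' Ratio of predictive performance against a reference model
#'
#' The per-unit ratio `ppm_reduced / ppm_full`, binned at factors
#' 0.05, 0.5, 2 and 20 for reporting: ratios in (0.5, 2) mean comparable
#' performance, ratios below mean the reduced model does worse.
#'
#' @param ppm_reduced,ppm_full Tibbles from [ppm()] over the same units.
#' @return A tibble with `unit_id`, `ratio`, and an ordered `bin` factor.
#' @export
ppm_ratio <- function(ppm_reduced, ppm_full) {
  stopifnot(identical(ppm_reduced$unit_id, ppm_full$unit_id))
  breaks <- c(0, 0.05, 0.5, 2, 20, Inf)
  tibble(unit_id = ppm_reduced$unit_id,
         ratio = ppm_reduced$ppm / ppm_full$ppm) %>%
    mutate(bin = cut(.data$ratio, breaks = breaks, right = FALSE,
                     labels = c("<0.05", "0.05-0.5", "0.5-2", "2-20", ">20"),
                     ordered_result = TRUE))
}
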