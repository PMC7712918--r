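test_that("report splitting is an exact, reproducible partition", {
  sim <- simulate_harvest_data(truth_config(n_counties = 2,
                                            hmps_per_county = 2,
                                            teams_per_hmp = 10,
                                            coverage = 1), seed = 50)
  d <- sim$data
  sp <- split_reports(d, fraction = 0.5, seed = 4)
  n <- nrow(d$reports)
  expect_equal(nrow(sp$train$reports), round(0.5 * n))
  expect_equal(nrow(sp$validation$reports), n - round(0.5 * n))
  expect_length(intersect(sp$train$reports$report_id,
                          sp$validation$reports$report_id), 0)
  expect_setequal(c(sp$train$reports$report_id,
                    sp$validation$reports$report_id),
                  d$reports$report_id)
  sp2 <- split_reports(d, fraction = 0.5, seed = 4)
  expect_identical(sp$train$reports, sp2$train$reports)
  expect_error(split_reports(d, fraction = 0), "in \\(0, 1\\)")
  d1 <- harvest_data(d$reports[1, ], d$registry)
  expect_error(split_reports(d1), "at least 2")
})

test_that("PPM uses the empirical mass above the cutoff and KDE below", {
  reg <- tibble::tibble(county_id = "c1", hmp_id = "h1",
                        huntable_area_ha = 1e5, excluded = 0L)
  mk_pred <- function(kappa) {
    p <- tibble::tibble(sim = seq_along(kappa), county_id = "c1",
                        hmp_id = "h1", kappa = kappa, n_teams = 1L)
    class(p) <- c("harvest_prediction", class(p))
    p
  }
  # all samples equal the observation: mass 1, empirical branch
  p1 <- ppm(mk_pred(rep(5L, 50)), level = "hmp", unit_id = "h1",
            observed = 5, cutoff = 10)
  expect_equal(p1$ppm, 1)
  expect_equal(p1$method, "empirical-mass")
  expect_equal(p1$samples_at_observed, 50L)

  # Poisson(1) samples, observed 0: mass ~ exp(-1) on the empirical branch
  set.seed(51)
  x <- rpois(2e5, 1)
  p2 <- ppm(mk_pred(x), level = "hmp", unit_id = "h1", observed = 0,
            cutoff = 10000)
  expect_equal(p2$method, "empirical-mass")
  expect_equal(p2$ppm, exp(-1), tolerance = 0.005 / exp(-1))

  # below the cutoff the method switches exactly
  p3 <- ppm(mk_pred(x), level = "hmp", unit_id = "h1", observed = 0,
            cutoff = sum(x == 0) + 1L)
  expect_equal(p3$method, "jittered-kde")
  p4 <- ppm(mk_pred(x), level = "hmp", unit_id = "h1", observed = 0,
            cutoff = sum(x == 0))
  expect_equal(p4$method, "empirical-mass")

  # the KDE branch is a density: values over the integer grid sum to ~1
  set.seed(52)
  y <- rpois(5000, 40)
  dens <- vapply(0:120, function(k) {
    ppm(mk_pred(y), level = "hmp", unit_id = "h1", observed = k,
        cutoff = 1e9)$ppm
  }, 0)
  expect_equal(sum(dens), 1, tolerance = 0.02)
  # far outside the support the estimate is non-negative and tiny
  far <- ppm(mk_pred(y), level = "hmp", unit_id = "h1", observed = 500,
             cutoff = 1e9)
  expect_gte(far$ppm, 0)
  expect_lt(far$ppm, 1e-6)
})

test_that("PSIS-LOO matches a closed-form conjugate leave-one-out oracle", {
  # conjugate toy: K_i ~ Poisson(mu * A_i), mu ~ Gamma(a, b); the exact
  # LOO predictive of observation i is negative binomial with the
  # posterior of the remaining observations
  a <- 2; b <- 300
  A <- c(120, 340, 80, 510, 260)
  set.seed(53)
  K <- rpois(5, 0.01 * A)
  exact_loo <- sum(vapply(1:5, function(i) {
    shape <- a + sum(K[-i])
    rate <- b + sum(A[-i])
    dnbinom(K[i], size = shape, prob = rate / (rate + A[i]), log = TRUE)
  }, 0))
  set.seed(54)
  mu_draws <- rgamma(4000, shape = a + sum(K), rate = b + sum(A))
  ll <- vapply(1:5, function(i) dpois(K[i], mu_draws * A[i], log = TRUE),
               numeric(4000))
  colnames(ll) <- paste0("r", 1:5)
  res <- psis_loo(ll)
  expect_lt(abs(res$elpd - exact_loo), 0.1)
  expect_true(all(res$pointwise$pareto_k < 0.7))
  # the LOO penalty is non-negative: ELPD below in-sample lpd
  in_sample <- sum(log(colMeans(exp(ll))))
  expect_lte(res$elpd, in_sample)
})

test_that("PSIS-LOO handles degenerate weights and is shift-invariant", {
  ll_const <- matrix(-1.234, nrow = 300, ncol = 3,
                     dimnames = list(NULL, c("a", "b", "c")))
  suppressWarnings(res <- psis_loo(ll_const))
  expect_equal(res$pointwise$elpd_i, rep(-1.234, 3))
  expect_true(all(res$pointwise$pareto_k <= 0))

  set.seed(55)
  ll <- matrix(rnorm(500 * 4, -2, 0.7), 500, 4,
               dimnames = list(NULL, paste0("r", 1:4)))
  res1 <- psis_loo(ll)
  ll_shift <- sweep(ll, 2, c(1, -3, 0.5, 2), "+")
  res2 <- psis_loo(ll_shift)
  expect_equal(res1$pointwise$pareto_k, res2$pointwise$pareto_k,
               tolerance = 1e-10)
  expect_error(psis_loo(matrix(c(1, NA), 2, 1)), "finite")
})

test_that("exact refits replace flagged reports and exhaustive refits agree", {
  cfg <- truth_config(n_counties = 2, hmps_per_county = 2,
                      teams_per_hmp = 10, coverage = 0.5, upsilon = Inf,
                      phi = 0)
  sim <- simulate_harvest_data(cfg, seed = 60)
  d <- apply_species_exclusions(sim$data)
  ctl <- fast_ctl(2, 1600, 600)
  fit <- suppressWarnings(fit_harvest(d, model_spec("m0"), control = ctl,
                                      seed = 6))
  base <- psis_loo(fit)
  # nothing flagged: refit pass returns the identical result
  if (all(base$pointwise$pareto_k <= 0.7, na.rm = TRUE)) {
    same <- loo_with_refits(fit, k_threshold = 0.7, seed = 1)
    expect_identical(same$pointwise, base$pointwise)
    expect_equal(same$n_refit, 0L)
  }
  # force refits for every report: exact LOO should agree with PSIS within
  # Monte Carlo error for reports PSIS considers reliable
  all_refit <- suppressWarnings(
    loo_with_refits(fit, k_threshold = -Inf, control = ctl, seed = 2))
  expect_equal(all_refit$n_refit, nrow(d$reports))
  ok <- base$pointwise$pareto_k < 0.7
  mc_se <- 2 * sd(base$pointwise$elpd_i[ok] -
                    all_refit$pointwise$elpd_i[ok])
  expect_lt(max(abs(base$pointwise$elpd_i[ok] -
                      all_refit$pointwise$elpd_i[ok])), max(0.3, 3 * mc_se))
})

test_that("ELPD comparison reproduces brute-force difference arithmetic", {
  mk_loo <- function(vals) {
    structure(list(elpd = sum(vals),
                   pointwise = tibble::tibble(
                     report_id = paste0("r", seq_along(vals)),
                     elpd_i = vals, pareto_k = 0),
                   n_refit = 0L), class = "loo_result")
  }
  a <- mk_loo(c(-1.0, -2.0, -0.5))
  b <- mk_loo(c(-1.4, -2.1, -1.0))
  cmp <- compare_elpd(full = a, reduced = b)
  expect_equal(cmp$elpd_diff[cmp$model == "full"], 0)
  expect_equal(cmp$se_diff[cmp$model == "full"], 0)
  diffs <- c(-0.4, -0.1, -0.5)
  expect_equal(cmp$elpd_diff[cmp$model == "reduced"], sum(diffs))
  expect_equal(cmp$se_diff[cmp$model == "reduced"],
               sqrt(3 * var(diffs)))
  # identical pointwise values give zero difference
  cmp2 <- compare_elpd(m1 = a, m2 = mk_loo(c(-1.0, -2.0, -0.5)))
  expect_equal(cmp2$elpd_diff, c(0, 0))
  # differences are measured against the best model and are invariant to
  # argument order (pairwise antisymmetry collapses onto the best row)
  cmp_ab <- compare_elpd(a = a, b = b)
  cmp_ba <- compare_elpd(b = b, a = a)
  expect_equal(cmp_ab$elpd_diff[cmp_ab$model == "b"], b$elpd - a$elpd)
  expect_equal(cmp_ab[order(cmp_ab$model), ], cmp_ba[order(cmp_ba$model), ])
  # mismatched report sets are rejected
  cc <- mk_loo(c(-1, -2))
  expect_error(compare_elpd(a = a, c = cc), "identical report set")
})

test_that("PPM ratios bin at the reporting thresholds", {
  mk <- function(p) tibble::tibble(unit_id = paste0("u", seq_along(p)),
                                   ppm = p)
  rr <- ppm_ratio(mk(c(0.01, 0.2, 0.5, 3, 30) * 0.1),
                  mk(rep(0.1, 5)))
  expect_equal(as.character(rr$bin),
               c("<0.05", "0.05-0.5", "0.5-2", "2-20", ">20"))
})
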