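test_that("model specification enforces the six legal combinations", {
  expect_equal(model_spec("m0")$name, "m0")
  expect_equal(model_spec("magp"), model_spec(alpha = TRUE, gamma = TRUE,
                                              phi = TRUE))
  expect_error(model_spec(gamma = TRUE), "requires the overdispersion")
  expect_error(model_spec("bogus"))
  specs <- c("m0", "ma", "mag", "mp", "map", "magp")
  expect_equal(vapply(specs, function(s) model_spec(s)$name, ""),
               setNames(specs, specs))
})

test_that("relative-area effect follows its closed form", {
  expect_equal(area_effect(123, 456, 0), 1)
  expect_equal(area_effect(789, 789, -0.7), 1)
  expect_equal(area_effect(4 * 300, 300, -0.5), 0.5)
  expect_equal(area_effect(c(100, 400), 200, 1), c(0.5, 2))
  expect_error(area_effect(-1, 200, 1), "positive")
  expect_error(area_effect(100, 0, 1), "positive")
})

test_that("Poisson likelihood matches closed forms and the aggregation identity", {
  expect_equal(poisson_loglik(0, mu = 0.01, area_ha = 300), -3)
  # independent oracle on random cases
  set.seed(5)
  for (i in 1:20) {
    k <- rpois(1, 3)
    mu <- rexp(1, 10)
    A <- runif(1, 10, 1000)
    del <- exp(rnorm(1, 0, 0.3))
    m <- mu * A * del
    expect_equal(poisson_loglik(k, mu, A, del),
                 k * log(m) - m - lgamma(k + 1), tolerance = 1e-10)
  }
  # the product of per-report Poisson pmfs and the single pmf of the summed
  # count at the summed exposure have identical derivative in mu:
  # d/dmu sum_r log Poiss(K_r | mu A_r) = sum(K)/mu - sum(A)
  K <- c(2L, 0L, 5L)
  A <- c(100, 250, 400)
  mu0 <- 0.007
  eps <- 1e-6
  num_deriv <- (sum(poisson_loglik(K, mu0 + eps, A)) -
                  sum(poisson_loglik(K, mu0 - eps, A))) / (2 * eps)
  expect_equal(num_deriv, sum(K) / mu0 - sum(A), tolerance = 1e-4)
  agg_deriv <- (poisson_loglik(sum(K), mu0 + eps, sum(A)) -
                  poisson_loglik(sum(K), mu0 - eps, sum(A))) / (2 * eps)
  expect_equal(num_deriv, agg_deriv, tolerance = 1e-4)
})

test_that("Gamma-Poisson likelihood matches quadrature and its Poisson limit", {
  # quadrature oracle: integrate Poisson(K | theta) over theta ~
  # Gamma(shape alpha, mean mu * A * delta)
  mixture_quadrature <- function(k, mu, alpha, A, delta = 1) {
    m <- mu * A * delta
    f <- function(th) dpois(k, th) * dgamma(th, shape = alpha,
                                            scale = m / alpha)
    log(stats::integrate(f, 0, Inf, rel.tol = 1e-12)$value)
  }
  set.seed(6)
  for (i in 1:10) {
    k <- rpois(1, 2)
    mu <- rexp(1, 5)
    alpha <- rlnorm(1, 0, 1)
    A <- runif(1, 5, 50)
    expect_equal(gamma_poisson_loglik(k, mu, alpha, A),
                 mixture_quadrature(k, mu, alpha, A), tolerance = 1e-8)
  }
  # K = 0 closed form
  expect_equal(gamma_poisson_loglik(0, 0.01, 2, 100),
               2 * log(2 / (2 + 1)))
  # Poisson limit at alpha = 1e8
  for (k in c(0L, 3L, 20L)) {
    for (m in c(0.3, 5)) {
      expect_equal(gamma_poisson_loglik(k, m, 1e8, 1),
                   poisson_loglik(k, m, 1), tolerance = 1e-5)
    }
  }
  # pmf sums to 1 over the count support
  for (alpha in c(0.5, 3)) {
    expect_equal(sum(exp(gamma_poisson_loglik(0:2000, 0.02, alpha, 500))),
                 1, tolerance = 1e-8)
  }
})

test_that("linear predictors follow the hierarchy and the gamma switch", {
  d <- tiny_data()
  pars <- list(omega = -4, lambda = c(cA = 0, cB = 0),
               chi = c(h1 = 0, h2 = 0, h3 = 0),
               upsilon = 0.5, gamma = 1.2)
  lp0 <- linear_predictors(pars, model_spec("m0"), d)
  expect_equal(lp0$mu, rep(exp(-4), 3))
  expect_true(all(is.infinite(lp0$alpha)))

  pars2 <- pars
  pars2$lambda <- c(cA = 0.8, cB = -0.2)
  pars2$chi <- c(h1 = 0.3, h2 = 0, h3 = 0)
  lpg <- linear_predictors(pars2, model_spec("mag"), d)
  # positive gamma and positive eta push alpha above exp(upsilon)
  expect_gt(lpg$alpha[lpg$hmp_id == "h1"], exp(0.5))
  expect_equal(lpg$mu[lpg$hmp_id == "h1"], exp(0.3 + 0.8 - 4))
  # without the association, alpha is exp(upsilon) regardless of effects
  lpa <- linear_predictors(pars2, model_spec("ma"), d)
  expect_equal(lpa$alpha, rep(exp(0.5), 3))
  expect_error(linear_predictors(list(omega = 0, lambda = c(cA = 0),
                                      chi = c(h1 = 0)),
                                 model_spec("m0"), d), "every registered")
})

test_that("the ML rate is the ratio of totals and maximizes the likelihood", {
  expect_equal(ml_rate(tibble::tibble(harvest = c(2, 3),
                                      area_ha = c(100, 400))), 0.01)
  expect_equal(ml_rate(tibble::tibble(harvest = c(0, 0),
                                      area_ha = c(50, 50))), 0)
  expect_error(ml_rate(tibble::tibble(harvest = integer(0),
                                      area_ha = numeric(0))), "at least one")
  # grid-search oracle: the ratio maximizes the pooled Poisson likelihood
  set.seed(7)
  K <- rpois(6, 4)
  A <- runif(6, 50, 500)
  grid <- seq(1e-5, 0.2, by = 1e-6)
  ll <- vapply(grid, function(m) sum(dpois(K, m * A, log = TRUE)), 0)
  expect_equal(ml_rate(tibble::tibble(harvest = K, area_ha = A)),
               grid[which.max(ll)], tolerance = 1e-4)
})

test_that("chain seeding is deterministic and guards zero-harvest units", {
  d <- tiny_data()
  s1 <- seed_chain(d, model_spec("magp"), seed = 9)
  s2 <- seed_chain(d, model_spec("magp"), seed = 9)
  expect_identical(s1, s2)
  expect_named(s1, c("omega", "lambda", "chi", "tau", "sigma", "upsilon",
                     "gamma", "phi"))
  expect_true(all(is.finite(unlist(s1))))
  expect_true(s1$tau > 0 && s1$sigma > 0)
  s0 <- seed_chain(d, model_spec("m0"), seed = 9)
  expect_false(any(c("upsilon", "gamma", "phi") %in% names(s0)))

  # when all county ratios are equal, the intercept seed centers on log r:
  # empirical distribution over many seeds
  dr <- one_hmp_data(areas = c(100, 100), harvests = c(1, 1)) # r = 0.01
  oms <- vapply(1:400, function(s) seed_chain(dr, model_spec("m0"), s)$omega,
                0)
  expect_equal(mean(oms), log(0.01), tolerance = 3 * 1 / sqrt(400))
  expect_equal(sd(oms), 1, tolerance = 0.15)

  # an HMP with zero harvest gets the Normal(0, 0.5) fallback for chi
  dz <- tiny_data() # h2 has zero harvest
  chis <- vapply(1:400, function(s) {
    seed_chain(dz, model_spec("m0"), s)$chi[["h2"]]
  }, 0)
  expect_true(all(is.finite(chis)))
  expect_equal(mean(chis), 0, tolerance = 3 * 0.5 / sqrt(400))
  expect_equal(sd(chis), 0.5, tolerance = 0.1)
})

test_that("harvest log density agrees across parameterizations and nests", {
  d <- tiny_data()
  pars <- list(omega = -4.2, tau = 0.5, sigma = 0.35,
               lambda = c(cA = 0.4, cB = -0.3),
               chi = c(h1 = 0.2, h2 = -0.1, h3 = 0.05),
               upsilon = 0.3, gamma = 0.7, phi = -0.25)
  mb <- c(h1 = 250, h2 = 500, h3 = 1200)
  spec <- model_spec("magp")
  pars_nc <- pars
  pars_nc$lambda <- NULL
  pars_nc$chi <- NULL
  pars_nc$lambda_star <- c(cA = 0.4, cB = -0.3) / pars$tau
  pars_nc$chi_star <- c(h1 = 0.2, h2 = -0.1, h3 = 0.05) / pars$sigma
  expect_equal(harvest_log_density(pars, d, spec, m_bar = mb),
               harvest_log_density(pars_nc, d, spec, m_bar = mb),
               tolerance = 1e-12)

  # with gamma = 0 and phi = 0 the full model's density differs from the
  # overdispersion-only model exactly by the two extra prior terms
  pars0 <- pars
  pars0$gamma <- 0
  pars0$phi <- 0
  pr <- default_priors()
  extra <- dnorm(0, 0, pr$scale[pr$parameter == "gamma"], log = TRUE) +
    dnorm(0, 0, pr$scale[pr$parameter == "phi"], log = TRUE)
  expect_equal(harvest_log_density(pars0, d, spec, m_bar = mb),
               harvest_log_density(pars0[setdiff(names(pars0),
                                                 c("gamma", "phi"))],
                                   d, model_spec("ma")) + extra,
               tolerance = 1e-12)
  expect_error(harvest_log_density(pars, d, spec), "m_bar")
})

test_that("per-draw pointwise likelihoods are proper probabilities", {
  sim <- simulate_harvest_data(truth_config(n_counties = 2,
                                            hmps_per_county = 3,
                                            teams_per_hmp = 10,
                                            coverage = 0.5), seed = 21)
  d <- apply_species_exclusions(sim$data)
  fit <- suppressWarnings(fit_harvest(d, model_spec("ma"),
                                      control = fast_ctl(2, 1200, 400),
                                      seed = 2))
  expect_equal(dim(fit$loglik), c(nrow(fit$draws), nrow(d$reports)))
  expect_true(all(fit$loglik <= 0))
  expect_true(all(is.finite(fit$loglik)))
  # reproducibility of the full fit
  fit2 <- suppressWarnings(fit_harvest(d, model_spec("ma"),
                                       control = fast_ctl(2, 1200, 400),
                                       seed = 2))
  expect_identical(fit$draws, fit2$draws)
  expect_identical(fit$loglik, fit2$loglik)
  # fixed-parameter pmf sums to ~1 over counts for a sampled draw/report
  mu1 <- fit$mu[7, 1]
  a1 <- fit$alpha[7, 1]
  A1 <- d$reports$area_ha[1]
  expect_equal(sum(exp(gamma_poisson_loglik(0:5000, mu1, a1, A1))), 1,
               tolerance = 1e-8)
})
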