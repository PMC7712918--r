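test_that("sampled team areas tile the unreported area exactly", {
  expect_identical(sample_team_areas(500, 0.5, 0), numeric(0))
  set.seed(31)
  for (i in 1:50) {
    U <- runif(1, 10, 50000)
    a <- sample_team_areas(exp(runif(1, 4, 7)), runif(1, 0.2, 1.5), U)
    expect_true(all(a > 0))
    expect_equal(sum(a), U, tolerance = 1e-9)
  }
  # renewal-theory check: expected team count ~ U / E[team area]
  m <- 400; s <- 0.6; U <- 2e5
  mean_area <- exp(log(m) + s^2 / 2)
  set.seed(32)
  counts <- vapply(1:1000, function(i) length(sample_team_areas(m, s, U)), 0)
  expect_equal(mean(counts), U / mean_area, tolerance = 0.05)
})

test_that("team harvest sampling matches the model moments", {
  set.seed(33)
  # degenerate mean: zero harvest
  expect_true(all(sample_team_harvest(model_spec("m0"), mu = 1e-12,
                                      area = rep(1e-6, 100)) == 0L))
  # overdispersed model: mean mu*A, variance mu*A + (mu*A)^2 / alpha
  mu <- 0.02; A <- 500; alpha <- 1.5; n <- 1e5
  x <- sample_team_harvest(model_spec("ma"), mu = mu, alpha = alpha,
                           area = rep(A, n))
  m_true <- mu * A
  v_true <- m_true + m_true^2 / alpha
  se_mean <- sqrt(v_true / n)
  expect_equal(mean(x), m_true, tolerance = 3 * se_mean / m_true)
  expect_equal(var(x), v_true, tolerance = 0.05)
  # phi = 0 reduces the area-effect model to the baseline: same pmf
  set.seed(34)
  x0 <- sample_team_harvest(model_spec("m0"), mu = mu, area = rep(A, n))
  xp <- sample_team_harvest(model_spec("mp"), mu = mu, phi = 0,
                            area = rep(A, n), m_bar = 123)
  tab <- table(factor(x0, levels = 0:max(x0, xp)),
               dnn = NULL)
  p_ref <- dpois(0:max(x0, xp), m_true)
  suppressWarnings({
    pval <- stats::chisq.test(table(factor(xp, levels = 0:max(x0, xp))),
                              p = p_ref / sum(p_ref))$p.value
  })
  expect_gt(pval, 0.01)
  expect_error(sample_team_harvest(model_spec("mp"), mu = 1, phi = 1,
                                   area = 10), "m_bar")
})

test_that("posterior-predictive totals conserve structure and the Poisson mean", {
  reg <- tiny_data()$registry
  d <- tiny_data()
  af <- fake_area_fit(m = c(150, 300, 500), s = c(0.5, 0.4), registry = reg)
  mu <- c(0.01, 0.02, 0.004)
  hf <- fake_harvest_fit(model_spec("m0"), mu = mu, registry = reg)
  pred <- predict_unreported(af, hf, d, n_sims = 3000, seed = 41)
  # aggregation identities hold exactly per draw
  nat <- pred %>% dplyr::group_by(sim) %>%
    dplyr::summarise(k = sum(kappa))
  cty <- pred %>% dplyr::group_by(sim, county_id) %>%
    dplyr::summarise(k = sum(kappa), .groups = "drop") %>%
    dplyr::group_by(sim) %>% dplyr::summarise(k = sum(k))
  expect_equal(nat$k, cty$k)
  expect_true(all(pred$kappa >= 0))
  expect_true(all(pred$kappa == round(pred$kappa)))

  # with point-mass parameters under the baseline model, the HMP total is
  # exactly Poisson(mu * U) by thinning invariance: check the mean
  U <- unreported_area(d)
  for (j in 1:3) {
    k_id <- U$hmp_id[j]
    lam <- mu[j] * U$unreported_area_ha[j]
    kap <- pred$kappa[pred$hmp_id == k_id]
    expect_equal(mean(kap), lam, tolerance = 3 * sqrt(lam / 3000) / lam)
  }

  # full coverage: all predictive totals are zero
  full <- one_hmp_data(areas = c(600, 400), harvests = c(1, 2),
                       huntable = 1000)
  af1 <- fake_area_fit(m = 500, s = 0.5, registry = full$registry)
  hf1 <- fake_harvest_fit(model_spec("m0"), mu = 0.01,
                          registry = full$registry)
  pred1 <- predict_unreported(af1, hf1, full, n_sims = 50, seed = 1)
  expect_true(all(pred1$kappa == 0))
  expect_true(all(pred1$n_teams == 0))

  # reproducibility
  pred2 <- predict_unreported(af, hf, d, n_sims = 100, seed = 7)
  pred3 <- predict_unreported(af, hf, d, n_sims = 100, seed = 7)
  expect_equal(as.data.frame(pred2), as.data.frame(pred3))
})

test_that("larger unreported area stochastically increases the total", {
  reg <- tiny_data()$registry
  d <- tiny_data()
  af <- fake_area_fit(m = c(150, 300, 500), s = c(0.5, 0.4), registry = reg)
  hf <- fake_harvest_fit(model_spec("m0"), mu = c(0.01, 0.02, 0.004),
                         registry = reg)
  pred_small <- predict_unreported(af, hf, d, n_sims = 400, seed = 3)
  dbig <- d
  dbig$registry$huntable_area_ha <- d$registry$huntable_area_ha * 3
  pred_big <- predict_unreported(af, hf, dbig, n_sims = 400, seed = 3)
  tot <- function(p) p %>% dplyr::group_by(sim) %>%
    dplyr::summarise(k = sum(kappa)) %>% dplyr::pull(k)
  expect_gt(mean(tot(pred_big)), mean(tot(pred_small)))
})

test_that("summaries add reported harvest and use order-statistic intervals", {
  reg <- tiny_data()$registry
  d <- tiny_data()
  # constant predictive samples: all quantiles collapse to reported + c
  pred <- tibble::tibble(sim = rep(1:10, each = 3),
                         county_id = rep(reg$county_id, 10),
                         hmp_id = rep(reg$hmp_id, 10),
                         kappa = 7L, n_teams = 1L)
  class(pred) <- c("harvest_prediction", class(pred))
  s <- summarise_harvest(pred, d, "nation")
  expect_equal(s$median, sum(d$reports$harvest) + 21)
  expect_equal(s$lower, s$median)
  expect_equal(s$upper, s$median)

  # uniform samples 0..999 on one unit: interval by inverse-ECDF quantiles
  pred2 <- tibble::tibble(sim = 1:1000, county_id = "cA", hmp_id = "h1",
                          kappa = sample(0:999), n_teams = 1L)
  class(pred2) <- c("harvest_prediction", class(pred2))
  s2 <- summarise_harvest(pred2, d, "hmp", unit_id = "h1")
  rep_h1 <- 5
  expect_equal(s2$lower - rep_h1, 24) # 25th order statistic of 0..999
  expect_equal(s2$upper - rep_h1, 974)
  expect_equal(s2$median - rep_h1, 499.5) # midpoint of a symmetric sample
  expect_error(summarise_harvest(pred2, d, "hmp", unit_id = "h9"),
               "unknown unit")
})
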