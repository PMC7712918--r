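# Shared fixtures: everything is built in code at test time.

# Hand-sized dataset: 2 counties, 3 HMPs, known numbers used across tests.
tiny_data <- function() {
  registry <- tibble::tibble(
    county_id = c("cA", "cA", "cB"),
    hmp_id = c("h1", "h2", "h3"),
    huntable_area_ha = c(1000, 2000, 5000),
    excluded = 0L
  )
  reports <- tibble::tibble(
    report_id = paste0("r", 1:5),
    county_id = c("cA", "cA", "cA", "cB", "cB"),
    hmp_id = c("h1", "h1", "h2", "h3", "h3"),
    area_ha = c(300, 200, 500, 1000, 1500),
    harvest = c(2L, 3L, 0L, 10L, 5L)
  )
  harvest_data(reports, registry, species = "toy")
}

# Single-county single-HMP dataset with configurable totals.
one_hmp_data <- function(areas, harvests, huntable = sum(areas) * 4) {
  n <- length(areas)
  harvest_data(
    tibble::tibble(report_id = paste0("r", seq_len(n)), county_id = "c1",
                   hmp_id = "h1", area_ha = areas,
                   harvest = as.integer(harvests)),
    tibble::tibble(county_id = "c1", hmp_id = "h1",
                   huntable_area_ha = huntable, excluded = 0L)
  )
}

# Reduced sampler settings for unit tests.
fast_ctl <- function(chains = 2, iter = 1500, warmup = 500, thin = 1) {
  mcmc_control(chains, iter, warmup, thin)
}

# Fabricated posterior objects with point-mass (or given) draws, for
# exercising the prediction machinery under exactly known parameters.
fake_area_fit <- function(m, s, registry) {
  idx <- hb_index_public(registry)
  n_draw <- if (is.matrix(m)) nrow(m) else 1L
  mm <- if (is.matrix(m)) m else matrix(m, n_draw, length(m), byrow = TRUE)
  ss <- if (is.matrix(s)) s else matrix(s, n_draw, length(s), byrow = TRUE)
  colnames(mm) <- idx$hmps
  colnames(ss) <- idx$counties
  structure(list(m = mm, s = ss, index = idx), class = "area_fit")
}

fake_harvest_fit <- function(spec, mu, alpha = NULL, phi = 0, m_bar = NULL,
                             registry) {
  idx <- hb_index_public(registry)
  n_draw <- if (is.matrix(mu)) nrow(mu) else 1L
  mum <- if (is.matrix(mu)) mu else matrix(mu, n_draw, length(mu), byrow = TRUE)
  colnames(mum) <- idx$hmps
  am <- if (is.null(alpha)) {
    matrix(Inf, n_draw, length(idx$hmps))
  } else if (is.matrix(alpha)) alpha else {
    matrix(alpha, n_draw, length(alpha), byrow = TRUE)
  }
  colnames(am) <- idx$hmps
  structure(list(spec = spec, mu = mum, alpha = am,
                 phi_draws = rep(phi, n_draw), m_bar = m_bar, index = idx),
            class = "harvest_fit")
}

# Index helper mirroring the package-internal ordering, from a registry.
hb_index_public <- function(registry) {
  reg <- registry[order(registry$county_id, registry$hmp_id), ]
  counties <- sort(unique(reg$county_id))
  list(counties = counties, hmps = reg$hmp_id,
       cty_of_hmp = match(reg$county_id, counties))
}

# Chi-square goodness-of-fit of counts against a Poisson(lambda) pmf,
# pooling tail bins so every expected count is at least 5.
poisson_gof_pvalue <- function(x, lambda) {
  n <- length(x)
  kmax <- max(x)
  probs <- dpois(0:kmax, lambda)
  probs <- c(probs, 1 - sum(probs)) # right tail
  expected <- n * probs
  obs <- c(tabulate(x + 1L, nbins = kmax + 1L), 0)
  # pool from the right until all expected >= 5
  while (length(expected) > 2 && expected[length(expected)] < 5) {
    k <- length(expected)
    expected[k - 1] <- expected[k - 1] + expected[k]
    obs[k - 1] <- obs[k - 1] + obs[k]
    expected <- expected[-k]; obs <- obs[-k]
  }
  keep <- expected >= 5
  stat <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  df <- sum(keep) - 1
  stats::pchisq(stat, df, lower.tail = FALSE)
}
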