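#' MCMC sampler settings
#'
#' Default settings follow the analysis protocol the package implements:
#' 4 chains of 30,000 iterations each including a 5,000-iteration warmup,
#' with thinning that keeps every 5th post-warmup draw (i.e. 80% of draws
#' discarded, keeping output files small). All settings are overridable;
#' the test suite and the worked examples run at much reduced scale.
#'
#' @param chains Number of chains.
#' @param iter Total iterations per chain, including warmup.
#' @param warmup Iterations discarded as warmup (adaptation + burn-in).
#' @param thin Keep every `thin`-th post-warmup draw.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, iter = 30000, warmup = 5000, thin = 5) {
  stopifnot(chains >= 1, warmup >= 2, iter > warmup, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin)),
            class = "mcmc_control")
}

# Derive one sub-seed per chain from the user-facing seed, reproducibly and
# below 2^31 so they remain valid R/JAGS integers.
chain_seeds <- function(seed, chains) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% 2147483647L))
  sample.int(2147483646L, chains)
}

# Run a JAGS model and return pooled draws plus per-chain structure.
# inits_fun(chain_index) may supply model-parameter initial values; RNG type
# and seed are always set per chain so runs are reproducible.
run_jags <- function(model_string, data, monitors, control, seed,
                     inits_fun = NULL) {
  seeds <- chain_seeds(seed, control$chains)
  inits <- lapply(seq_len(control$chains), function(i) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = seeds[i])
    if (!is.null(inits_fun)) ini <- c(ini, inits_fun(i))
    ini
  })
  n_adapt <- min(1000L, control$warmup %/% 2L)
  n_burn <- control$warmup - n_adapt
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = control$chains,
                          n.adapt = n_adapt, quiet = TRUE)
  if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
  out <- rjags::coda.samples(jm, variable.names = monitors,
                             n.iter = control$iter - control$warmup,
                             thin = control$thin, progress.bar = "none")
  out
}

# Split-Rhat (rank-free version of the standard potential scale reduction
# factor): each chain is split in half before computing between/within
# variances, so within-chain drift also registers.
split_rhat <- function(x) {
  # x: iterations x chains matrix of one parameter's draws
  n <- nrow(x)
  half <- n %/% 2L
  if (half < 2) return(NA_real_)
  halves <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W < 1e-300) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Diagnostics table for a coda mcmc.list restricted to `pars`.
mcmc_diagnostics <- function(samples, pars) {
  mat <- lapply(samples, function(ch) as.matrix(ch)[, pars, drop = FALSE])
  ess <- coda::effectiveSize(samples)[pars]
  tibble(
    parameter = pars,
    rhat = vapply(pars, function(p) {
      split_rhat(vapply(mat, function(ch) ch[, p], numeric(nrow(mat[[1]]))))
    }, numeric(1)),
    ess = unname(ess)
  )
}

# Pool an mcmc.list into a draws tibble with .chain/.iteration columns.
pool_draws <- function(samples) {
  bind_rows(lapply(seq_along(samples), function(i) {
    d <- as_tibble(as.matrix(samples[[i]]))
    d$.chain <- i
    d$.iteration <- seq_len(nrow(d))
    d
  })) %>% mutate(.draw = row_number())
}

# Warn if split-Rhat of any top-level parameter exceeds the tolerance.
warn_convergence <- function(diag, tol, where) {
  bad <- diag %>% filter(is.finite(.data$rhat), .data$rhat > tol)
  if (nrow(bad) > 0) {
    warn(paste0(where, ": split-Rhat > ", tol, " for ",
                paste(bad$parameter, collapse = ", "),
                "; consider longer chains"))
  }
  invisible(diag)
}
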