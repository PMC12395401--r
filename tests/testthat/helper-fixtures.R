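# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

girls_targets <- c(atgv = 8.41, tgv = 5.85, aphv = 11.30, phv = 8.38)
boys_targets <- c(atgv = 11.19, tgv = 5.43, aphv = 13.55, phv = 9.52)

girls_curve <- function() fixture("girls_curve",
  calibrate_reference(girls_targets, s = 1.2, t0 = 6, H0 = 113))

boys_curve <- function() fixture("boys_curve",
  calibrate_reference(boys_targets, s = 1.1, t0 = 6, H0 = 115))

# a small girls cohort and its MAP fit, for unit tests
small_sim <- function() fixture("small_sim",
  simulate_cohort(girls_curve(), generator_config(n_subjects = 24, sex = "F", seed = 301)))

small_cohort <- function() fixture("small_cohort",
  apply_inclusion_filter(small_sim()$cohort)$cohort)

small_fit <- function() fixture("small_fit",
  fit_map(small_cohort(), sitar_config(df = 5)))

# a short two-chain posterior sample on a mid-sized cohort
mcmc_sim <- function() fixture("mcmc_sim",
  simulate_cohort(girls_curve(), generator_config(n_subjects = 40, sex = "F", seed = 21)))

mcmc_fit <- function() fixture("mcmc_fit", suppressWarnings(
  sample_posterior(apply_inclusion_filter(mcmc_sim()$cohort)$cohort,
                   sitar_config(df = 5, chains = 2, iterations = 600,
                                warmup = 300, seed = 99))))

# independent type-7 quantile (sort-based, linear interpolation), used as
# an oracle against stats::quantile-based code paths
quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
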