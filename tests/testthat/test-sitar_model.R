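test_that("the age transform and its inverse agree", {
  expect_equal(transform_age(12, 11, 0, 0), 1)
  expect_equal(transform_age(13, 11, 1, log(2)), 0.5)
  set.seed(11)
  for (k in 1:100) {
    x <- runif(1, 5, 20); zeta <- rnorm(1, 0, 1); gam <- rnorm(1, 0, 0.3)
    u <- transform_age(x, 11.5, zeta, gam)
    expect_equal(11.5 + zeta + u * exp(gam), x, tolerance = 1e-12)
  }
})

test_that("predicted height composes size, timing and intensity correctly", {
  set.seed(3)
  basis <- build_basis(runif(100, -5, 5), df = 5)
  pop <- list(alpha0 = 150, beta = rnorm(5, 0, 3), zeta0 = 0.2, gamma0 = -0.05)
  x <- runif(50, 6, 17)
  # zero effects give the population curve; size shifts additively
  base <- predict_height(pop, c(0, 0, 0), basis, 11.5, x)
  expect_equal(predict_height(pop, c(3, 0, 0), basis, 11.5, x), base + 3)
  # independent composition oracle
  ef <- c(-1.2, 0.4, 0.08)
  direct <- vapply(x, function(xx) {
    u <- (xx - 11.5 - pop$zeta0 - ef[2]) * exp(-(pop$gamma0 + ef[3]))
    pop$alpha0 + ef[1] + sum(eval_basis(basis, u, 0) * pop$beta)
  }, numeric(1))
  expect_equal(predict_height(pop, ef, basis, 11.5, x), direct, tolerance = 1e-10)
})

test_that("log likelihood equals independent per-record summation", {
  # single record, zero residual, unit sigma: standard normal at 0
  one <- growth_cohort(data.frame(id = "a", sex = "F", age = 10, stature = 140))
  basis <- build_basis(seq(-4, 4, length.out = 50), df = 5)
  ef <- matrix(0, 1, 3, dimnames = list("a", NULL))
  pop0 <- list(alpha0 = 140, beta = rep(0, 5), zeta0 = 0, gamma0 = 0, sigma = 1)
  expect_equal(log_likelihood(one, list(pop = pop0, effects = ef), basis, 10),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  # doubling sigma under zero residuals costs n log 2
  co <- small_cohort()
  n <- nrow(co)
  ids <- unique(co$id)
  ef2 <- matrix(0, length(ids), 3, dimnames = list(ids, NULL))
  popz <- list(alpha0 = 0, beta = rep(0, 5), zeta0 = 0, gamma0 = 0, sigma = 1)
  co0 <- co; co0$stature <- rep(100, n)
  pop100 <- popz; pop100$alpha0 <- 100
  l1 <- log_likelihood(co0, list(pop = pop100, effects = ef2), basis, mean(co$age))
  pop200 <- pop100; pop200$sigma <- 2
  l2 <- log_likelihood(co0, list(pop = pop200, effects = ef2), basis, mean(co$age))
  expect_equal(l2 - l1, -n * log(2), tolerance = 1e-10)
  # brute-force oracle on a random 30-record cohort
  set.seed(9)
  co30 <- growth_cohort(data.frame(
    id = rep(sprintf("s%d", 1:6), each = 5), sex = "F",
    age = rep(seq(8, 14, length.out = 5), 6) + runif(30, 0, 0.2),
    stature = runif(30, 120, 170)
  ))
  pop <- list(alpha0 = 145, beta = rnorm(5, 0, 2), zeta0 = 0.3,
              gamma0 = 0.05, sigma = 0.8)
  ef30 <- matrix(rnorm(18, 0, 0.3), 6, 3,
                 dimnames = list(sprintf("s%d", 1:6), NULL))
  xb <- mean(co30$age)
  got <- log_likelihood(co30, list(pop = pop, effects = ef30), basis, xb)
  brute <- 0
  for (r in seq_len(30)) {
    e <- ef30[co30$id[r], ]
    u <- (co30$age[r] - xb - pop$zeta0 - e[2]) * exp(-(pop$gamma0 + e[3]))
    mu <- pop$alpha0 + e[1] + sum(eval_basis(basis, u, 0) * pop$beta)
    brute <- brute + dnorm(co30$stature[r], mu, pop$sigma, log = TRUE)
  }
  expect_equal(got, brute, tolerance = 1e-10)
  # a subject without effects is a contract error
  expect_error(
    log_likelihood(co30, list(pop = pop, effects = ef30[1:5, ]), basis, xb),
    class = "sitargrowth_contract_error"
  )
})

test_that("the prior is zero-centred, unimodal and decomposes by term", {
  scales <- list(mean_y = 150, sd_y = 12, sd_x = 3)
  base <- list(
    pop = list(alpha0 = 150, beta = rep(0, 5), zeta0 = 0, gamma0 = 0, sigma = 1),
    sds = c(1, 0.5, 0.1), corr = diag(3)
  )
  lp0 <- log_prior(base, scales)
  # mode of the zeta0 component at zero, monotone decay in |gamma0|
  for (z in c(-1, -0.5, 0.5, 1)) {
    p <- base; p$pop$zeta0 <- z
    expect_lt(log_prior(p, scales), lp0)
  }
  prev <- lp0
  for (g in c(0.5, 1, 2)) {
    p <- base; p$pop$gamma0 <- g
    expect_lt(log_prior(p, scales), prev)
    prev <- log_prior(p, scales)
  }
  # total equals the sum of its components
  comp <- attr(lp0, "components")
  expect_equal(sum(comp), as.numeric(lp0))
  # domain boundaries yield -Inf, not exceptions
  p <- base; p$pop$sigma <- -1
  expect_identical(log_prior(p, scales), -Inf)
  p <- base; p$corr <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_identical(log_prior(p, scales), -Inf)
})

test_that("MAP fitting is deterministic and rejects degenerate cohorts", {
  co <- small_cohort()
  f1 <- small_fit()
  f2 <- fit_map(co, sitar_config(df = 5))
  expect_equal(f1$sampler_meta$objective, f2$sampler_meta$objective,
               tolerance = 1e-8)
  expect_equal(f1$draws$pop, f2$draws$pop)
  one <- growth_cohort(data.frame(id = "a", sex = "F",
                                  age = 7:16 + 0.5, stature = seq(120, 165, 5)))
  expect_error(fit_map(one, sitar_config(df = 5)),
               class = "sitargrowth_config_error")
  both <- growth_cohort(data.frame(
    id = rep(c("a", "b"), each = 5), sex = rep(c("F", "M"), each = 5),
    age = rep(8:12, 2), stature = c(seq(125, 145, 5), seq(127, 147, 5))
  ))
  expect_error(fit_map(both, sitar_config(df = 5)),
               class = "sitargrowth_config_error")
})

test_that("MAP recovers a low-noise cohort generated from the model itself", {
  # SITAR-truth generation: shared spline shape, zero random effects,
  # near-noise-free measurements.  The generating spline uses exactly the
  # basis the fit will build (knots at quantiles of x - mean(x)), with
  # coefficients projected from a realistic height curve, so the truth is
  # representable in the fitted model's own family.
  set.seed(4)
  ages <- seq(6.5, 16.5, by = 1)
  ids <- sprintf("s%02d", 1:12)
  x <- rep(ages, length(ids))
  xb <- mean(x)
  basis <- build_basis(x - xb, df = 5)
  B <- eval_basis(basis, x - xb, 0)
  co_ols <- lm.fit(cbind(1, B), reference_height(girls_curve(), x))$coefficients
  pop <- list(alpha0 = co_ols[[1]], beta = unname(co_ols[-1]),
              zeta0 = 0, gamma0 = 0)
  # 0.01 cm jitter only regularizes the residual SD; at stature scale the
  # cohort is effectively noise-free
  y <- predict_height(pop, c(0, 0, 0), basis, xb, x) + rnorm(length(x), 0, 0.01)
  co <- growth_cohort(data.frame(id = rep(ids, each = length(ages)),
                                 sex = "F", age = x, stature = y))
  fit <- fit_map(co, sitar_config(df = 5))
  d <- fit$draws$pop[1, ]
  expect_lt(abs(d[["zeta0"]]), 1e-2)
  expect_lt(abs(d[["gamma0"]]), 1e-2)
  # fitted mean curve tracks the generating curve
  xs <- seq(7, 16, by = 0.25)
  pred <- predict_height(sitargrowth:::.draw_pop(fit, 1), c(0, 0, 0),
                         fit$basis, fit$x_bar, xs)
  truth <- predict_height(pop, c(0, 0, 0), basis, xb, xs)
  expect_lt(sqrt(mean((pred - truth)^2)), 0.05)
})

test_that("posterior sampling honours its draw-count and seed contracts", {
  fit <- mcmc_fit()
  expect_equal(n_draws(fit), 2 * (600 - 300))
  expect_equal(length(fit$sampler_meta$chain_id), 600)
  # identical seed, identical data: identical draw sequence
  fit2 <- suppressWarnings(
    sample_posterior(apply_inclusion_filter(mcmc_sim()$cohort)$cohort,
                     sitar_config(df = 5, chains = 2, iterations = 600,
                                  warmup = 300, seed = 99)))
  expect_identical(fit$draws$pop, fit2$draws$pop)
  expect_identical(fit$draws$effects, fit2$draws$effects)
  # missing seed is rejected
  expect_error(sample_posterior(small_cohort(), sitar_config(df = 5, seed = NULL)),
               class = "sitargrowth_config_error")
})

test_that("posterior mean landmarks sit near generator truth and the MAP", {
  fit <- mcmc_fit()
  lm <- population_landmarks(fit)
  draws <- attr(lm, "draws")
  aphv <- lm$estimate[lm$landmark == "aphv"]
  sd_aphv <- sd(draws[, 3])
  truth <- girls_targets[["aphv"]]
  expect_lt(abs(aphv - truth), 2 * sd_aphv + 0.25)
  map_aphv <- population_landmarks(
    fit_map(apply_inclusion_filter(mcmc_sim()$cohort)$cohort, sitar_config(df = 5))
  )$estimate[3]
  expect_lt(abs(aphv - map_aphv), 2 * sd_aphv + 0.15)
})

test_that("posterior predictive replicates preserve the design and the mean", {
  fit <- small_fit()
  pp <- posterior_predict(fit, n_replicates = 1, seed = 5)
  expect_equal(nrow(pp$replicates), nrow(fit$data))
  # sigma -> 0 limit: replicates equal noise-free predictions
  fit0 <- fit
  fit0$draws$pop[1, "sigma"] <- 1e-12
  pp0 <- posterior_predict(fit0, n_replicates = 1, seed = 5)
  pop <- sitargrowth:::.draw_pop(fit, 1)
  ei <- fit$draws$effects[1, , ]
  rownames(ei) <- fit$subject_ids
  pred <- vapply(seq_len(nrow(fit$data)), function(r) {
    predict_height(pop, ei[fit$data$id[r], ], fit$basis, fit$x_bar,
                   fit$data$age[r])
  }, numeric(1))
  expect_equal(unname(drop(pp0$replicates)), unname(pred), tolerance = 1e-9)
  # law of large numbers against the posterior-mean prediction
  fitm <- mcmc_fit()
  ppm <- posterior_predict(fitm, n_replicates = 200, seed = 6)
  mean_rep <- rowMeans(ppm$replicates)
  mean_pred <- rowMeans(vapply(pp_idx <- ppm$draw_index, function(d) {
    popd <- sitargrowth:::.draw_pop(fitm, d)
    eid <- fitm$draws$effects[d, , ]
    rownames(eid) <- fitm$subject_ids
    ez <- eid[fitm$data$id, ]
    u <- transform_age(fitm$data$age, fitm$x_bar, popd$zeta0 + ez[, 2],
                       popd$gamma0 + ez[, 3])
    popd$alpha0 + ez[, 1] + drop(eval_basis(fitm$basis, u, 0) %*% popd$beta)
  }, numeric(nrow(fitm$data))))
  sigma_bar <- mean(fitm$draws$pop[, "sigma"])
  mc_err <- 4 * sigma_bar / sqrt(length(ppm$draw_index))
  expect_lt(max(abs(mean_rep - mean_pred)), mc_err + 0.2)
  # more replicates than draws is a contract error
  expect_error(posterior_predict(small_fit(), n_replicates = 2),
               class = "sitargrowth_contract_error")
})

test_that("a saved fit reloads to an identical analysis", {
  fit <- small_fit()
  d <- withr::local_tempdir()
  save_sitar_fit(fit, d)
  fit2 <- load_sitar_fit(d)
  expect_equal(fit2$draws$pop, fit$draws$pop, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(fit2$x_bar, fit$x_bar)
  lm1 <- population_landmarks(fit)
  lm2 <- population_landmarks(fit2)
  expect_equal(lm1$estimate, lm2$estimate, tolerance = 1e-9)
})
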