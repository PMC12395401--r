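# The SITAR model: likelihood, priors, MAP and MCMC estimation.
#
# Model: y_ij = alpha0 + alpha_i + sum_k beta_k h_k(u_ij) + eps_ij,
#        u_ij = (x_ij - x_bar - zeta0 - zeta_i) * exp(-(gamma0 + gamma_i)),
#        eps_ij ~ N(0, sigma^2),
# with per-subject effects (alpha_i, zeta_i, gamma_i) drawn from a
# zero-mean trivariate normal with SDs (sd_alpha, sd_zeta, sd_gamma) and a
# 3x3 correlation matrix.  gamma is intensity/tempo: it scales the age axis,
# so velocity scales by exp(-gamma_total) via the chain rule.
#
# Estimation works in an unconstrained parameterization: log scales for
# sigma and the random-effect SDs, canonical partial correlations (tanh of
# unconstrained reals) for the correlation matrix, and non-centred subject
# effects (effects = C z_i with C = diag(SDs) %*% chol(R), z_i ~ N(0, I)).
# Priors are weakly regularizing and scaled to the data (SD of stature, SD
# of age); the correlation prior is LKJ(2), imposed exactly through its
# C-vine Beta representation on the partial correlations.

#' Model and sampler configuration
#'
#' @param df Spline degrees of freedom (number of basis columns).
#' @param chains,iterations,warmup MCMC design: `iterations` is the total
#'   per-chain count including warmup; stored draws are
#'   `chains * (iterations - warmup)`.
#' @param seed Integer seed for stochastic estimation.
#' @param prior_scale Multiplier applied to every prior scale
#'   hyperparameter (used by prior-sensitivity sweeps).
#' @param priors Optional explicit prior list overriding the data-scaled
#'   defaults (see [sitar_default_priors()]).
#' @param rhat_threshold,ess_threshold Convergence flags: warn when split
#'   R-hat exceeds / bulk ESS falls below these.
#' @param map_maxit Iteration cap for the MAP optimizer.
#' @export
sitar_config <- function(df = 5, chains = 2, iterations = 6000, warmup = 3000,
                         seed = NULL, prior_scale = 1, priors = NULL,
                         rhat_threshold = 1.01, ess_threshold = 400,
                         map_maxit = 6000) {
  if (warmup >= iterations)
    sg_error("warmup must be below iterations", "sitargrowth_config_error")
  if (prior_scale <= 0)
    sg_error("prior_scale must be > 0", "sitargrowth_config_error")
  structure(
    list(df = df, chains = chains, iterations = iterations, warmup = warmup,
         seed = seed, prior_scale = prior_scale, priors = priors,
         rhat_threshold = rhat_threshold, ess_threshold = ess_threshold,
         map_maxit = map_maxit),
    class = "sitar_config"
  )
}

#' Default data-scaled priors
#'
#' Weakly regularizing priors scaled to the fitted cohort:
#' `alpha0 ~ N(mean stature, (2 SDy)^2)`, `beta_k ~ N(0, (5 SDy)^2)`,
#' `zeta0 ~ N(0, SDx^2)`, `gamma0 ~ N(0, 1.5^2)`,
#' `sigma ~ half-t(3, SDy)`, `sd_alpha ~ half-N(SDy)`,
#' `sd_zeta ~ half-N(SDx)`, `sd_gamma ~ half-N(0.5)`, correlation `LKJ(2)`.
#'
#' @param mean_y,sd_y Mean and SD of stature (cm) in the fitted cohort.
#' @param sd_x SD of age (years) in the fitted cohort.
#' @param scale Common multiplier on all scale hyperparameters.
#' @export
sitar_default_priors <- function(mean_y, sd_y, sd_x, scale = 1) {
  list(
    alpha0 = c(mean_y, 2 * sd_y * scale),
    beta = c(0, 5 * sd_y * scale),
    zeta0 = c(0, sd_x * scale),
    gamma0 = c(0, 1.5 * scale),
    sigma = c(df = 3, scale = sd_y * scale),
    sd_alpha = sd_y * scale,
    sd_zeta = sd_x * scale,
    sd_gamma = 0.5 * scale,
    lkj_eta = 2
  )
}

#' SITAR age transform
#'
#' `u = (x - x_bar - zeta_total) * exp(-gamma_total)`; strictly increasing
#' in `x` with slope `exp(-gamma_total)`.
#'
#' @param x Age in years.
#' @param x_bar Centering constant (mean age of measurement).
#' @param zeta_total Timing shift in years (population + individual).
#' @param gamma_total Log intensity (population + individual).
#' @export
transform_age <- function(x, x_bar, zeta_total, gamma_total) {
  (x - x_bar - zeta_total) * exp(-gamma_total)
}

#' Predicted (noise-free) stature
#'
#' `alpha0 + alpha_i + beta %*% h(u)` with `u` from [transform_age()].
#'
#' @param pop List with `alpha0`, `beta`, `zeta0`, `gamma0`.
#' @param effects Numeric vector `c(alpha, zeta, gamma)` for one subject
#'   (zeros give the population mean curve).
#' @param basis An `ncs_basis`.
#' @param x_bar Centering constant in years.
#' @param x Ages at which to predict.
#' @export
predict_height <- function(pop, effects = c(0, 0, 0), basis, x_bar, x) {
  u <- transform_age(x, x_bar, pop$zeta0 + effects[2], pop$gamma0 + effects[3])
  drop(pop$alpha0 + effects[1] + eval_basis(basis, u, 0) %*% pop$beta)
}

# ---- internal model context ------------------------------------------------

.model_context <- function(cohort, config) {
  stopifnot(inherits(cohort, "growth_cohort"))
  if (length(unique(cohort$sex)) > 1)
    sg_error("cohort contains both sexes; fit each sex separately",
             "sitargrowth_config_error")
  ids <- unique(cohort$id)
  if (length(ids) < 2)
    sg_error("at least 2 subjects are required (random-effect SDs are unidentifiable otherwise)",
             "sitargrowth_config_error")
  idx <- match(cohort$id, ids)
  x <- cohort$age
  y <- cohort$stature
  x_bar <- mean(x)
  basis <- build_basis(x - x_bar, df = config$df)
  scales <- list(mean_y = mean(y), sd_y = stats::sd(y), sd_x = stats::sd(x))
  priors <- config$priors %||%
    sitar_default_priors(scales$mean_y, scales$sd_y, scales$sd_x,
                         scale = config$prior_scale)
  K <- config$df
  list(
    x = x, y = y, idx = idx, ids = ids, n_subj = length(ids),
    n_rec = length(y), x_bar = x_bar, basis = basis, K = K,
    scales = scales, priors = priors, sex = cohort$sex[1]
  )
}

# parameter vector layout: alpha0, beta(K), zeta0, gamma0,
# log sigma, log sd_alpha, log sd_zeta, log sd_gamma, y_corr(3), z(3n)
.theta_index <- function(K, n) {
  npop <- K + 10
  list(
    alpha0 = 1L, beta = 1L + seq_len(K), zeta0 = K + 2L, gamma0 = K + 3L,
    lsig = K + 4L, lsds = K + 4L + 1:3, ycorr = K + 7L + 1:3,
    pop = seq_len(npop), z = npop + seq_len(3L * n), npop = npop
  )
}

# lower Cholesky of the correlation matrix from canonical partial
# correlations z = tanh(y)
.corr_chol <- function(zc) {
  L <- matrix(0, 3, 3)
  L[1, 1] <- 1
  L[2, 1] <- zc[1]; L[2, 2] <- sqrt(1 - zc[1]^2)
  L[3, 1] <- zc[2]
  L[3, 2] <- zc[3] * sqrt(1 - zc[2]^2)
  L[3, 3] <- sqrt((1 - zc[2]^2) * (1 - zc[3]^2))
  L
}

.unpack <- function(theta, ix, n) {
  zc <- tanh(theta[ix$ycorr])
  sds <- exp(theta[ix$lsds])
  L <- .corr_chol(zc)
  list(
    alpha0 = theta[ix$alpha0], beta = theta[ix$beta],
    zeta0 = theta[ix$zeta0], gamma0 = theta[ix$gamma0],
    sigma = exp(theta[ix$lsig]), sds = sds, zc = zc, L = L,
    C = diag(sds) %*% L,
    Z = matrix(theta[ix$z], n, 3)
  )
}

# LKJ(eta) on a 3x3 correlation via independent scaled Betas on the CPCs,
# plus the tanh Jacobian; exact including normalization up to a constant
.lp_cpc <- function(zc, ycorr, eta) {
  b <- c(eta + 0.5, eta + 0.5, eta)
  sum(stats::dbeta((zc + 1) / 2, b, b, log = TRUE)) +
    sum(log1p(-zc^2))  # d tanh(y)/dy = 1 - zc^2
}

.lp_half_normal <- function(x, scale) {
  # density on x > 0; log(2) constant dropped
  stats::dnorm(x, 0, scale, log = TRUE)
}

.lp_half_t <- function(x, df, scale) {
  stats::dt(x / scale, df, log = TRUE) - log(scale)
}

# Negative log posterior in the unconstrained parameterization.
#
# Two parameterizations of the subject effects are supported.  The MCMC
# sampler works non-centred (theta's z-block holds standardized deviates
# z_i, effects = C z_i with prior z ~ N(0, I)), which gives good sampler
# geometry.  The MAP optimizer works centred (the z-block holds the
# effects themselves, penalized by the trivariate normal with its
# -n log|Sigma|/2 term): the non-centred JOINT mode is degenerate --
# inflating the scales shrinks the z-penalty without a log-determinant
# counterweight -- whereas the centred mode pins the scales to the
# realized effect spread.
.make_objective <- function(ctx, centred = FALSE) {
  ix <- .theta_index(ctx$K, ctx$n_subj)
  pr <- ctx$priors
  x <- ctx$x; y <- ctx$y; idx <- ctx$idx
  n <- ctx$n_subj; N <- ctx$n_rec
  basis <- ctx$basis; x_bar <- ctx$x_bar

  effects_of <- function(up) if (centred) up$Z else up$Z %*% t(up$C)

  predparts <- function(up) {
    E <- effects_of(up)  # n x 3: alpha, zeta, gamma
    gamma_tot <- up$gamma0 + E[idx, 3]
    u <- (x - x_bar - up$zeta0 - E[idx, 2]) * exp(-gamma_tot)
    B0 <- eval_basis(basis, u, 0)
    pred <- up$alpha0 + E[idx, 1] + drop(B0 %*% up$beta)
    list(E = E, u = u, B0 = B0, pred = pred, gamma_tot = gamma_tot)
  }

  effect_penalty <- function(up) {
    if (centred) {
      # -0.5 sum e' Sigma^-1 e - n log|C|,  Sigma = C C'
      Cinv <- forwardsolve(up$C, diag(3))
      W <- up$Z %*% t(Cinv)   # rows are C^-1 e_i
      -0.5 * sum(W^2) - n * sum(log(diag(up$C)))
    } else {
      -0.5 * sum(up$Z^2)
    }
  }

  logpost <- function(theta) {
    up <- .unpack(theta, ix, n)
    pp <- predparts(up)
    r <- y - pp$pred
    ll <- -N * log(up$sigma) - 0.5 * sum(r^2) / up$sigma^2
    lp <- stats::dnorm(up$alpha0, pr$alpha0[1], pr$alpha0[2], log = TRUE) +
      sum(stats::dnorm(up$beta, pr$beta[1], pr$beta[2], log = TRUE)) +
      stats::dnorm(up$zeta0, pr$zeta0[1], pr$zeta0[2], log = TRUE) +
      stats::dnorm(up$gamma0, pr$gamma0[1], pr$gamma0[2], log = TRUE) +
      .lp_half_t(up$sigma, pr$sigma[["df"]], pr$sigma[["scale"]]) + theta[ix$lsig] +
      .lp_half_normal(up$sds[1], pr$sd_alpha) + theta[ix$lsds[1]] +
      .lp_half_normal(up$sds[2], pr$sd_zeta) + theta[ix$lsds[2]] +
      .lp_half_normal(up$sds[3], pr$sd_gamma) + theta[ix$lsds[3]] +
      .lp_cpc(up$zc, theta[ix$ycorr], pr$lkj_eta) +
      effect_penalty(up)
    ll + lp
  }

  nlp <- function(theta) -logpost(theta)

  grad_nlp <- function(theta) {
    up <- .unpack(theta, ix, n)
    pp <- predparts(up)
    r <- y - pp$pred
    w <- r / up$sigma^2                 # dll/dpred
    B1 <- eval_basis(basis, pp$u, 1)
    g1 <- drop(B1 %*% up$beta)          # d pred / d u
    egam <- exp(-pp$gamma_tot)
    d_zeta <- -egam * g1                # d pred / d zeta_total
    d_gam <- -pp$u * g1                 # d pred / d gamma_total
    g <- numeric(length(theta))
    g[ix$alpha0] <- sum(w) - (up$alpha0 - pr$alpha0[1]) / pr$alpha0[2]^2
    g[ix$beta] <- drop(crossprod(pp$B0, w)) - (up$beta - pr$beta[1]) / pr$beta[2]^2
    g[ix$zeta0] <- sum(w * d_zeta) - (up$zeta0 - pr$zeta0[1]) / pr$zeta0[2]^2
    g[ix$gamma0] <- sum(w * d_gam) - (up$gamma0 - pr$gamma0[1]) / pr$gamma0[2]^2
    GE <- cbind(
      rowsum(w, idx, reorder = TRUE),
      rowsum(w * d_zeta, idx, reorder = TRUE),
      rowsum(w * d_gam, idx, reorder = TRUE)
    )
    if (centred) {
      Cinv <- forwardsolve(up$C, diag(3))
      g[ix$z] <- as.vector(GE - (up$Z %*% t(Cinv)) %*% Cinv)
    } else {
      g[ix$z] <- as.vector(GE %*% up$C) - theta[ix$z]
    }
    # scale and correlation block: central finite differences
    h <- 1e-6
    for (j in c(ix$lsig, ix$lsds, ix$ycorr)) {
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      g[j] <- (logpost(tp) - logpost(tm)) / (2 * h)
    }
    -g
  }

  list(nlp = nlp, grad = grad_nlp, ix = ix, ctx = ctx, logpost = logpost,
       predparts = predparts, centred = centred)
}

.start_theta <- function(ctx) {
  ix <- .theta_index(ctx$K, ctx$n_subj)
  B0 <- eval_basis(ctx$basis, ctx$x - ctx$x_bar, 0)
  fit <- stats::lm.fit(cbind(1, B0), ctx$y)
  res <- fit$residuals
  theta <- numeric(ix$npop + 3 * ctx$n_subj)
  theta[ix$alpha0] <- fit$coefficients[1]
  theta[ix$beta] <- fit$coefficients[-1]
  theta[ix$zeta0] <- 0
  theta[ix$gamma0] <- 0
  subj_mean_res <- tapply(res, ctx$idx, mean)
  theta[ix$lsig] <- log(max(stats::sd(res), 1e-2))
  theta[ix$lsds] <- log(pmax(c(stats::sd(subj_mean_res), 0.3, 0.08), 1e-3))
  theta[ix$ycorr] <- 0
  theta
}

# assemble one natural-scale draw row from unpacked parameters
.pop_row <- function(up, K) {
  R <- up$L %*% t(up$L)
  c(
    alpha0 = unname(up$alpha0),
    stats::setNames(up$beta, paste0("beta_", seq_len(K))),
    zeta0 = unname(up$zeta0), gamma0 = unname(up$gamma0),
    sigma = unname(up$sigma),
    sd_alpha = unname(up$sds[1]), sd_zeta = unname(up$sds[2]),
    sd_gamma = unname(up$sds[3]),
    corr_az = R[1, 2], corr_ag = R[1, 3], corr_zg = R[2, 3]
  )
}

.new_sitar_fit <- function(ctx, pop, effects, config, meta, convergence = NULL) {
  structure(
    list(
      basis = ctx$basis, x_bar = ctx$x_bar, sex = ctx$sex,
      subject_ids = ctx$ids, K = ctx$K,
      draws = list(pop = pop, effects = effects),
      data = data.frame(id = ctx$ids[ctx$idx], age = ctx$x, stature = ctx$y,
                        stringsAsFactors = FALSE),
      scales = ctx$scales, priors = ctx$priors, config = config,
      sampler_meta = meta, convergence = convergence
    ),
    class = "sitar_fit"
  )
}

#' @export
print.sitar_fit <- function(x, ...) {
  cat(sprintf("SITAR fit (%s): %d subjects, %d records, df = %d, %d draw(s)\n",
              x$sampler_meta$method, length(x$subject_ids), nrow(x$data),
              x$K, nrow(x$draws$pop)))
  cat("posterior means of population parameters:\n")
  print(round(colMeans(x$draws$pop), 4))
  invisible(x)
}

#' Number of posterior draws in a fit
#' @param fit A `sitar_fit`.
#' @export
n_draws <- function(fit) nrow(fit$draws$pop)

# ---- public likelihood / prior (natural scale) -----------------------------

#' SITAR log likelihood
#'
#' Sum over all records of the normal log density of the residual
#' (stature minus predicted height) with SD `sigma`.
#'
#' @param cohort A [growth_cohort()] (single sex).
#' @param params List with `pop` (containing `alpha0`, `beta`, `zeta0`,
#'   `gamma0`, `sigma`) and `effects`, a matrix with one row per subject
#'   (rownames = subject ids) and columns alpha, zeta, gamma.
#' @param basis An `ncs_basis`.
#' @param x_bar Centering constant.
#' @export
log_likelihood <- function(cohort, params, basis, x_bar) {
  stopifnot(inherits(cohort, "growth_cohort"))
  pop <- params$pop
  if (pop$sigma <= 0)
    sg_error("sigma must be > 0", "sitargrowth_contract_error")
  ef <- params$effects
  miss <- setdiff(unique(cohort$id), rownames(ef))
  if (length(miss) > 0)
    sg_error(paste("subjects missing effects:", paste(miss, collapse = ", ")),
             "sitargrowth_contract_error")
  ei <- ef[cohort$id, , drop = FALSE]
  u <- transform_age(cohort$age, x_bar, pop$zeta0 + ei[, 2], pop$gamma0 + ei[, 3])
  pred <- pop$alpha0 + ei[, 1] + drop(eval_basis(basis, u, 0) %*% pop$beta)
  sum(stats::dnorm(cohort$stature, pred, pop$sigma, log = TRUE))
}

#' SITAR log prior
#'
#' Sum of the log prior densities of the population parameters, residual
#' SD, random-effect SDs and correlation matrix; returns `-Inf` at domain
#' boundaries (non-positive sigma/SDs, non-positive-definite correlation)
#' rather than erroring.  The per-component terms are attached as the
#' `"components"` attribute.
#'
#' @param params List with `pop` (as in [log_likelihood()]), `sds`
#'   (length-3: alpha, zeta, gamma) and `corr` (3x3 correlation matrix).
#' @param scales List with `mean_y`, `sd_y`, `sd_x` of the fitted data.
#' @param priors Optional prior list; defaults to
#'   [sitar_default_priors()] at the given scales.
#' @export
log_prior <- function(params, scales, priors = NULL) {
  pr <- priors %||% sitar_default_priors(scales$mean_y, scales$sd_y, scales$sd_x)
  pop <- params$pop
  sds <- params$sds
  R <- params$corr
  if (pop$sigma <= 0 || any(sds < 0)) return(-Inf)
  ev <- tryCatch(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) -1)
  if (any(ev <= 0) || any(abs(diag(R) - 1) > 1e-12)) return(-Inf)
  comp <- c(
    alpha0 = stats::dnorm(pop$alpha0, pr$alpha0[1], pr$alpha0[2], log = TRUE),
    beta = sum(stats::dnorm(pop$beta, pr$beta[1], pr$beta[2], log = TRUE)),
    zeta0 = stats::dnorm(pop$zeta0, pr$zeta0[1], pr$zeta0[2], log = TRUE),
    gamma0 = stats::dnorm(pop$gamma0, pr$gamma0[1], pr$gamma0[2], log = TRUE),
    sigma = .lp_half_t(pop$sigma, pr$sigma[["df"]], pr$sigma[["scale"]]),
    sd_alpha = .lp_half_normal(sds[1], pr$sd_alpha),
    sd_zeta = .lp_half_normal(sds[2], pr$sd_zeta),
    sd_gamma = .lp_half_normal(sds[3], pr$sd_gamma),
    corr = (pr$lkj_eta - 1) * determinant(R, logarithm = TRUE)$modulus[1]
  )
  out <- sum(comp)
  attr(out, "components") <- comp
  out
}

# ---- MAP -------------------------------------------------------------------

#' Fit the SITAR model by posterior-mode optimization
#'
#' Jointly maximizes log likelihood plus log prior over the population
#' parameters, variance components and all per-subject effects (in the
#' non-centred parameterization), using `nlminb` with an analytic gradient
#' for the location parameters and subject effects.  Deterministic for a
#' given cohort and configuration.
#'
#' @param cohort A single-sex [growth_cohort()], normally after
#'   [apply_inclusion_filter()].
#' @param config A [sitar_config()].
#' @return A `sitar_fit` with a single draw (the posterior mode).
#' @export
fit_map <- function(cohort, config = sitar_config()) {
  ctx <- .model_context(cohort, config)
  obj <- .make_objective(ctx, centred = TRUE)
  ix <- obj$ix
  theta0 <- .start_theta(ctx)
  # Stage 1: curve, sigma and effects with the variance/correlation block
  # frozen at its start values (a fixed ridge), so the effects populate
  # before the scales are free to move -- the joint mode is otherwise
  # reachable only through a funnel that collapses the scales.
  free <- setdiff(seq_along(theta0), c(ix$lsds, ix$ycorr))
  th <- theta0
  opt1 <- stats::nlminb(
    theta0[free],
    function(p) { th[free] <- p; obj$nlp(th) },
    gradient = function(p) { th[free] <- p; obj$grad(th)[free] },
    control = list(iter.max = config$map_maxit, eval.max = 4 * config$map_maxit)
  )
  theta1 <- theta0
  theta1[free] <- opt1$par
  # re-initialize scales and correlation from the realized effect moments
  E1 <- matrix(theta1[ix$z], ctx$n_subj, 3)
  theta1[ix$lsds] <- log(pmax(apply(E1, 2, stats::sd), 1e-3))
  R1 <- suppressWarnings(stats::cor(E1))
  if (anyNA(R1)) R1 <- diag(3)
  cpc <- c(R1[1, 2], R1[1, 3],
           (R1[2, 3] - R1[1, 2] * R1[1, 3]) /
             sqrt(max((1 - R1[1, 2]^2) * (1 - R1[1, 3]^2), 1e-10)))
  theta1[ix$ycorr] <- atanh(pmin(pmax(cpc, -0.99), 0.99))
  # Stage 2: full joint optimization
  opt <- stats::nlminb(theta1, obj$nlp, gradient = obj$grad,
                       control = list(iter.max = config$map_maxit,
                                      eval.max = 4 * config$map_maxit))
  gnorm <- sqrt(sum(obj$grad(opt$par)^2))
  if (opt$iterations >= config$map_maxit && gnorm > 1)
    sg_error(sprintf("MAP did not converge after %d iterations (objective %.4f, |grad| %.3g)",
                     opt$iterations, opt$objective, gnorm),
             "sitargrowth_convergence_error",
             trace = opt)
  up <- .unpack(opt$par, obj$ix, ctx$n_subj)
  pop <- matrix(.pop_row(up, ctx$K), nrow = 1,
                dimnames = list(NULL, names(.pop_row(up, ctx$K))))
  E <- matrix(opt$par[obj$ix$z], ctx$n_subj, 3)  # centred: effects directly
  effects <- array(E, dim = c(1, ctx$n_subj, 3),
                   dimnames = list(NULL, ctx$ids, c("alpha", "zeta", "gamma")))
  meta <- list(method = "map", seed = config$seed, objective = opt$objective,
               grad_norm = gnorm, convergence = opt$convergence,
               iterations = opt$iterations, message = opt$message,
               theta = opt$par)
  .new_sitar_fit(ctx, pop, effects, config, meta)
}

# ---- MCMC ------------------------------------------------------------------

#' Sample the SITAR posterior
#'
#' Adaptive Metropolis-within-Gibbs: the population/variance block uses a
#' multivariate random-walk proposal whose covariance is adapted to the
#' empirical posterior covariance during warmup; the per-subject
#' (non-centred) effect triples are updated jointly with per-subject
#' adaptive step sizes, exploiting their conditional independence.  Chains
#' start from the posterior mode plus a small dispersed jitter.  Split
#' R-hat and bulk ESS are computed per population parameter; threshold
#' violations attach a warning to the fit rather than erroring.
#'
#' @inheritParams fit_map
#' @return A `sitar_fit` with `chains * (iterations - warmup)` draws.
#' @export
sample_posterior <- function(cohort, config = sitar_config()) {
  if (is.null(config$seed))
    sg_error("sampler seed is mandatory", "sitargrowth_config_error")
  ctx <- .model_context(cohort, config)
  obj <- .make_objective(ctx)
  ix <- obj$ix
  n <- ctx$n_subj
  map_fit <- fit_map(cohort, config)
  theta_map <- map_fit$sampler_meta$theta
  # MAP theta is centred: convert the effect block to standardized deviates
  up_map <- .unpack(theta_map, ix, n)
  E_map <- matrix(theta_map[ix$z], n, 3)
  theta_map[ix$z] <- as.vector(E_map %*% t(forwardsolve(up_map$C, diag(3))))

  n_keep <- config$iterations - config$warmup
  kept_pop <- matrix(NA_real_, config$chains * n_keep, 10 + ctx$K)
  kept_E <- array(NA_real_, dim = c(config$chains * n_keep, n, 3))
  chain_id <- integer(config$chains * n_keep)
  accept_pop <- numeric(config$chains)

  # likelihood-coupled block: curve location parameters and the residual
  # SD.  The random-effect scales and correlations are updated separately
  # in centred form (see below), which sidesteps the funnel coupling
  # between scales and standardized effects.
  blocks <- list(c(ix$alpha0, ix$beta, ix$zeta0, ix$gamma0, ix$lsig))
  scale_idx <- c(ix$lsds, ix$ycorr)
  pr <- ctx$priors
  # conditional log density of the scale/correlation block given the
  # centred effects E: the likelihood does not involve it, so this is the
  # trivariate-normal density of E plus the priors (with transform
  # Jacobians) -- cheap, no likelihood evaluation
  scale_conditional <- function(sv, E) {
    sds <- exp(sv[1:3])
    zc <- tanh(sv[4:6])
    L <- .corr_chol(zc)
    C <- diag(sds) %*% L
    W <- E %*% t(forwardsolve(C, diag(3)))
    -0.5 * sum(W^2) - n * sum(log(diag(C))) +
      .lp_half_normal(sds[1], pr$sd_alpha) + sv[1] +
      .lp_half_normal(sds[2], pr$sd_zeta) + sv[2] +
      .lp_half_normal(sds[3], pr$sd_gamma) + sv[3] +
      .lp_cpc(zc, sv[4:6], pr$lkj_eta)
  }
  # precondition each block with its curvature at the mode: the proposal
  # covariance starts at the inverse block Hessian of the negative log
  # posterior (falling back to a diagonal if not positive definite)
  block_chol <- lapply(blocks, function(b) {
    d <- length(b)
    h <- 1e-4
    f0 <- obj$nlp(theta_map)
    H <- matrix(0, d, d)
    for (a in seq_len(d)) {
      for (bb in a:d) {
        tpp <- theta_map; tpp[b[a]] <- tpp[b[a]] + h; tpp[b[bb]] <- tpp[b[bb]] + h
        tpm <- theta_map; tpm[b[a]] <- tpm[b[a]] + h; tpm[b[bb]] <- tpm[b[bb]] - h
        tmp <- theta_map; tmp[b[a]] <- tmp[b[a]] - h; tmp[b[bb]] <- tmp[b[bb]] + h
        tmm <- theta_map; tmm[b[a]] <- tmm[b[a]] - h; tmm[b[bb]] <- tmm[b[bb]] - h
        H[a, bb] <- H[bb, a] <-
          (obj$nlp(tpp) - obj$nlp(tpm) - obj$nlp(tmp) + obj$nlp(tmm)) / (4 * h^2)
      }
    }
    ch <- tryCatch(t(chol(solve(H))), error = function(e) NULL)
    if (is.null(ch)) {
      hd <- pmax(diag(H), 1e-4)
      ch <- diag(1 / sqrt(hd), d)
    }
    ch
  })

  set.seed(config$seed)
  row <- 0L
  for (ch in seq_len(config$chains)) {
    theta <- theta_map + stats::rnorm(length(theta_map), 0, 0.02)
    lp_cur <- obj$logpost(theta)
    # per-block adaptation state: proposal Cholesky, log step scale,
    # running moments of the block draws
    bstate <- c(
      lapply(seq_along(blocks), function(bi) {
        d <- length(blocks[[bi]])
        list(chol = block_chol[[bi]], log_s = log(2.38 / sqrt(d)),
             mean = numeric(d), cov = matrix(0, d, d), n = 0, acc = 0)
      }),
      # state for the centred scale/correlation block
      list(list(chol = diag(0.05, 6), log_s = 0,
                mean = numeric(6), cov = matrix(0, 6, 6), n = 0, acc = 0))
    )
    s_z <- rep(0.25, n)
    n_acc_pop <- 0
    for (it in seq_len(config$iterations)) {
      # -- population sub-blocks
      for (bi in seq_along(blocks)) {
        b <- blocks[[bi]]; st <- bstate[[bi]]
        prop <- theta
        prop[b] <- theta[b] +
          exp(st$log_s) * drop(st$chol %*% stats::rnorm(length(b)))
        lp_prop <- obj$logpost(prop)
        acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur
        if (acc) { theta <- prop; lp_cur <- lp_prop }
        if (it <= config$warmup) {
          gain <- min(0.5, 5 / sqrt(it))
          st$log_s <- st$log_s + gain * ((if (acc) 1 else 0) - 0.25) * 0.2
          xb <- theta[b]
          st$n <- st$n + 1
          delta <- xb - st$mean
          st$mean <- st$mean + delta / st$n
          st$cov <- st$cov + tcrossprod(delta, xb - st$mean)
          if (st$n >= 500 && it %% 25 == 0) {
            S <- st$cov / (st$n - 1)
            st$chol <- tryCatch(
              t(chol(S + diag(1e-12 + 1e-6 * mean(diag(S)), length(b)))),
              error = function(e) st$chol
            )
          }
        } else if (acc) n_acc_pop <- n_acc_pop + 1
        bstate[[bi]] <- st
      }
      # -- scale/correlation block, centred (ASIS interweaving): hold the
      # effects E fixed, update the scales against their closed-form
      # conditional, then map the standardized deviates back
      up <- .unpack(theta, ix, n)
      E_cur <- up$Z %*% t(up$C)
      sv <- theta[scale_idx]
      lp_sv <- scale_conditional(sv, E_cur)
      st <- bstate[[2]]
      svp <- sv + exp(st$log_s) * drop(st$chol %*% stats::rnorm(6))
      lp_svp <- scale_conditional(svp, E_cur)
      acc_s <- is.finite(lp_svp) && log(stats::runif(1)) < lp_svp - lp_sv
      if (acc_s) {
        theta[scale_idx] <- svp
        up <- .unpack(theta, ix, n)
        theta[ix$z] <- as.vector(E_cur %*% t(forwardsolve(up$C, diag(3))))
        lp_cur <- obj$logpost(theta)
      }
      if (it <= config$warmup) {
        gain <- min(0.5, 5 / sqrt(it))
        st$log_s <- st$log_s + gain * ((if (acc_s) 1 else 0) - 0.25) * 0.2
        xb <- theta[scale_idx]
        st$n <- st$n + 1
        delta <- xb - st$mean
        st$mean <- st$mean + delta / st$n
        st$cov <- st$cov + tcrossprod(delta, xb - st$mean)
        if (st$n >= 100 && it %% 25 == 0) {
          S <- st$cov / (st$n - 1)
          st$chol <- tryCatch(
            t(chol(S + diag(1e-12 + 1e-6 * mean(diag(S)), 6))),
            error = function(e) st$chol
          )
        }
      }
      bstate[[2]] <- st
      # -- subject-effect block (conditionally independent given pop)
      up <- .unpack(theta, ix, n)
      Z <- up$Z
      Zp <- Z + matrix(stats::rnorm(3 * n), n, 3) * s_z
      lp_z_cur <- .subject_logpost(Z, up, ctx)
      lp_z_prop <- .subject_logpost(Zp, up, ctx)
      acc_i <- log(stats::runif(n)) < lp_z_prop - lp_z_cur
      if (any(acc_i)) {
        Z[acc_i, ] <- Zp[acc_i, ]
        theta[ix$z] <- as.vector(Z)
        lp_cur <- lp_cur + sum((lp_z_prop - lp_z_cur)[acc_i])
      }
      if (it <= config$warmup) {
        eta <- min(0.5, 5 / sqrt(it))
        s_z <- pmin(2, pmax(1e-3, s_z * exp(eta * (ifelse(acc_i, 1, 0) - 0.3) * 0.2)))
      } else {
        row <- row + 1L
        upk <- .unpack(theta, ix, n)
        kept_pop[row, ] <- .pop_row(upk, ctx$K)
        kept_E[row, , ] <- upk$Z %*% t(upk$C)
        chain_id[row] <- ch
      }
    }
    accept_pop[ch] <- n_acc_pop / (2 * (config$iterations - config$warmup))
  }
  colnames(kept_pop) <- names(.pop_row(.unpack(theta_map, ix, n), ctx$K))
  dimnames(kept_E) <- list(NULL, ctx$ids, c("alpha", "zeta", "gamma"))

  conv <- .convergence_table(kept_pop, chain_id, config)
  meta <- list(method = "mcmc", seed = config$seed, chains = config$chains,
               iterations = config$iterations, warmup = config$warmup,
               chain_id = chain_id, accept_pop = accept_pop)
  fit <- .new_sitar_fit(ctx, kept_pop, kept_E, config, meta, convergence = conv)
  if (any(conv$flag, na.rm = TRUE))
    warning(sprintf("convergence flags raised for: %s",
                    paste(conv$parameter[conv$flag], collapse = ", ")))
  fit
}

# per-subject log posterior contributions (likelihood + z prior), up to
# constants shared between current and proposed states
.subject_logpost <- function(Z, up, ctx) {
  E <- Z %*% t(up$C)
  gamma_tot <- up$gamma0 + E[ctx$idx, 3]
  u <- (ctx$x - ctx$x_bar - up$zeta0 - E[ctx$idx, 2]) * exp(-gamma_tot)
  pred <- up$alpha0 + E[ctx$idx, 1] +
    drop(eval_basis(ctx$basis, u, 0) %*% up$beta)
  r <- ctx$y - pred
  drop(rowsum(-0.5 * r^2 / up$sigma^2, ctx$idx, reorder = TRUE)) -
    0.5 * rowSums(Z^2)
}

.convergence_table <- function(pop, chain_id, config) {
  params <- colnames(pop)
  chains <- sort(unique(chain_id))
  tab <- do.call(rbind, lapply(params, function(p) {
    m <- vapply(chains, function(ch) pop[chain_id == ch, p],
                numeric(sum(chain_id == chains[1])))
    rh <- if (length(chains) >= 2) split_rhat(m) else NA_real_
    es <- bulk_ess(m)
    data.frame(parameter = p, rhat = rh, ess_bulk = es,
               stringsAsFactors = FALSE)
  }))
  tab$flag <- (!is.na(tab$rhat) & tab$rhat > config$rhat_threshold) |
    (!is.na(tab$ess_bulk) & tab$ess_bulk < config$ess_threshold)
  tab
}

# ---- posterior predictive --------------------------------------------------

#' Simulate replicate datasets from the posterior predictive distribution
#'
#' For each replicate one posterior draw is selected (evenly spaced through
#' the stored draws) and stature is simulated as predicted height plus
#' normal noise with that draw's sigma, at the original (subject, age)
#' design points.
#'
#' @param fit A `sitar_fit`.
#' @param n_replicates Number of replicate datasets (must not exceed the
#'   number of stored draws).
#' @param seed Integer seed.
#' @return List with `replicates` (a records x n_replicates matrix),
#'   `draw_index` and `design` (id, age of each row).
#' @export
posterior_predict <- function(fit, n_replicates = 100, seed = 1) {
  stopifnot(inherits(fit, "sitar_fit"))
  nd <- n_draws(fit)
  if (nd < n_replicates)
    sg_error(sprintf("fit has %d draws, fewer than n_replicates = %d", nd, n_replicates),
             "sitargrowth_contract_error")
  draw_index <- unique(round(seq(1, nd, length.out = n_replicates)))
  set.seed(seed)
  sim <- vapply(draw_index, function(d) {
    pop <- .draw_pop(fit, d)
    ei <- fit$draws$effects[d, , ]
    if (is.null(dim(ei))) ei <- matrix(ei, ncol = 3)
    rownames(ei) <- fit$subject_ids
    ez <- ei[fit$data$id, , drop = FALSE]
    u <- transform_age(fit$data$age, fit$x_bar,
                       pop$zeta0 + ez[, 2], pop$gamma0 + ez[, 3])
    pred <- pop$alpha0 + unname(ez[, 1]) +
      drop(eval_basis(fit$basis, u, 0) %*% pop$beta)
    unname(pred + stats::rnorm(length(pred), 0, pop$sigma))
  }, numeric(nrow(fit$data)))
  list(replicates = sim, draw_index = draw_index,
       design = fit$data[, c("id", "age")])
}

# extract one draw's population parameters as a list
.draw_pop <- function(fit, d) {
  row <- fit$draws$pop[d, ]
  list(
    alpha0 = unname(row[["alpha0"]]),
    beta = unname(row[paste0("beta_", seq_len(fit$K))]),
    zeta0 = unname(row[["zeta0"]]), gamma0 = unname(row[["gamma0"]]),
    sigma = unname(row[["sigma"]])
  )
}

# ---- fit serialization -----------------------------------------------------

#' Save / load a SITAR fit as plain text
#'
#' Draws are written as CSV (population columns then flattened effects),
#' the spline basis as JSON, and metadata (x_bar, subject ids, sampler
#' settings, data) as JSON, so a fit can be reloaded and evaluated
#' identically.
#'
#' @param fit A `sitar_fit`.
#' @param dir Directory to write into (created if needed).
#' @export
save_sitar_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eff <- fit$draws$effects
  nd <- dim(eff)[1]
  flat <- matrix(eff, nrow = nd)
  colnames(flat) <- as.vector(outer(fit$subject_ids, c("alpha", "zeta", "gamma"),
                                    function(i, p) paste0(p, "_i[", i, "]")))
  utils::write.csv(cbind(fit$draws$pop, flat),
                   file.path(dir, "draws.csv"), row.names = FALSE)
  basis_to_json(fit$basis, file.path(dir, "basis.json"))
  meta <- list(
    x_bar = fit$x_bar, sex = fit$sex, subject_ids = fit$subject_ids,
    K = fit$K, scales = fit$scales, sampler_meta = fit$sampler_meta["method"],
    seed = fit$sampler_meta$seed,
    chain_id = fit$sampler_meta$chain_id,
    config = unclass(fit$config)[c("df", "chains", "iterations", "warmup",
                                   "prior_scale")],
    data = fit$data
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @rdname save_sitar_fit
#' @export
load_sitar_fit <- function(dir) {
  draws <- utils::read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  basis <- basis_from_json(file.path(dir, "basis.json"))
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  ids <- meta$subject_ids
  K <- meta$K
  popcols <- c("alpha0", paste0("beta_", seq_len(K)), "zeta0", "gamma0",
               "sigma", "sd_alpha", "sd_zeta", "sd_gamma",
               "corr_az", "corr_ag", "corr_zg")
  pop <- as.matrix(draws[, popcols])
  nd <- nrow(pop)
  eff <- array(NA_real_, dim = c(nd, length(ids), 3),
               dimnames = list(NULL, ids, c("alpha", "zeta", "gamma")))
  for (p in c("alpha", "zeta", "gamma"))
    eff[, , p] <- as.matrix(draws[, paste0(p, "_i[", ids, "]")])
  structure(
    list(
      basis = basis, x_bar = meta$x_bar, sex = meta$sex, subject_ids = ids,
      K = K, draws = list(pop = pop, effects = eff),
      data = meta$data, scales = meta$scales,
      config = do.call(sitar_config, meta$config),
      sampler_meta = list(method = meta$sampler_meta$method, seed = meta$seed,
                          chain_id = meta$chain_id),
      convergence = NULL
    ),
    class = "sitar_fit"
  )
}
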