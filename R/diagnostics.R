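# Posterior predictive checks, convergence diagnostics, and the
# measurement-count / prior-scale sensitivity analyses.

#' Density-overlap posterior predictive check
#'
#' Gaussian kernel density estimates of the observed stature values and
#' each replicate dataset on a shared grid; the per-replicate statistic is
#' the overlap coefficient `integral of min(f_obs, f_rep)`, in [0, 1].
#' The bandwidth is Silverman's rule on the observed sample and is shared
#' by the replicates, so overlap differences reflect the data rather than
#' bandwidth adaptation.
#'
#' @param observed Numeric vector of observed values (>= 30).
#' @param replicates Matrix (rows = design points, columns = replicates)
#'   or list of numeric vectors.
#' @return A `ppc_result`: list with `overlap` (mean), `per_replicate`,
#'   `grid`, `f_obs`, `f_rep` (grid x replicate matrix).
#' @export
ppc_density_overlap <- function(observed, replicates) {
  if (is.list(replicates)) replicates <- do.call(cbind, replicates)
  replicates <- as.matrix(replicates)
  if (length(observed) < 30)
    sg_error("need at least 30 observed values", "sitargrowth_contract_error")
  if (ncol(replicates) < 1)
    sg_error("need at least one replicate", "sitargrowth_contract_error")
  if (stats::sd(observed) == 0)
    sg_error("observed sample is degenerate (constant)",
             "sitargrowth_degenerate_error")
  if (any(apply(replicates, 2, stats::sd) == 0))
    sg_error("a replicate sample is degenerate (constant)",
             "sitargrowth_degenerate_error")
  bw <- stats::bw.nrd0(observed)
  lo <- min(observed, replicates) - 3 * bw
  hi <- max(observed, replicates) + 3 * bw
  grid <- seq(lo, hi, length.out = 512)
  f_obs <- stats::density(observed, bw = bw, from = lo, to = hi, n = 512)$y
  f_rep <- apply(replicates, 2, function(r)
    stats::density(r, bw = bw, from = lo, to = hi, n = 512)$y)
  per <- apply(f_rep, 2, function(f) trapz(grid, pmin(f_obs, f)))
  structure(
    list(overlap = mean(per), per_replicate = per,
         grid = grid, f_obs = f_obs, f_rep = f_rep),
    class = "ppc_result"
  )
}

#' Export PPC density grids as CSV
#'
#' Columns `x,f_obs,f_rep_mean,f_rep_low,f_rep_high` (the replicate band is
#' the pointwise 68% interval), so the usual density-overlay figure can be
#' regenerated from the export.
#'
#' @param ppc A [ppc_density_overlap()] result.
#' @param path Output path.
#' @export
write_ppc_csv <- function(ppc, path) {
  band <- apply(ppc$f_rep, 1, ci68)
  out <- data.frame(
    x = ppc$grid, f_obs = ppc$f_obs,
    f_rep_mean = rowMeans(ppc$f_rep),
    f_rep_low = band[1, ], f_rep_high = band[2, ]
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# ---- convergence -----------------------------------------------------------

#' Split R-hat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, from the usual between/within variance decomposition.
#'
#' @param draws Matrix with one column per chain (equal lengths).
#' @return Scalar R-hat (`NA` for degenerate inputs where all draws are
#'   identical; `Inf` when within-chain variance is zero but chains
#'   differ).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  split <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(half), j], draws[half + seq_len(half), j])))
  m <- ncol(split); nn <- nrow(split)
  mu_j <- colMeans(split)
  s2_j <- apply(split, 2, stats::var)
  W <- mean(s2_j)
  B <- nn * stats::var(mu_j)
  if (W == 0) return(if (B == 0) NA_real_ else Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Bulk effective sample size
#'
#' Rank-normalizes the draws, splits each chain in half, and estimates ESS
#' from the chain-averaged autocorrelations using Geyer's initial monotone
#' positive sequence.
#'
#' @param draws Matrix with one column per chain.
#' @return Scalar effective sample size.
#' @export
bulk_ess <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  split <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(half), j], draws[half + seq_len(half), j])))
  # rank-normalize jointly
  r <- matrix(stats::qnorm((rank(split) - 0.375) / (length(split) + 0.25)),
              nrow(split), ncol(split))
  nn <- nrow(r); m <- ncol(r)
  if (stats::sd(r) == 0 || nn < 4) return(NA_real_)
  # chain-wise autocovariances (biased, denominator nn), averaged over chains
  acov <- function(x) {
    x <- x - mean(x)
    vapply(0:(nn - 1), function(l)
      sum(x[seq_len(nn - l)] * x[seq_len(nn - l) + l]) / nn, numeric(1))
  }
  ac <- rowMeans(vapply(seq_len(m), function(j) acov(r[, j]), numeric(nn)))
  W <- mean(apply(r, 2, stats::var))
  B_over_n <- if (m > 1) stats::var(colMeans(r)) else 0
  var_plus <- W * (nn - 1) / nn + B_over_n
  rho <- 1 - (W - ac) / var_plus  # rho[1] is lag 0
  # Geyer paired sums p_t = rho(2t) + rho(2t+1), initial positive monotone
  max_t <- floor(nn / 2) - 1
  p <- numeric(0)
  for (t in 0:max_t) {
    pt <- rho[2 * t + 1] + rho[2 * t + 2]
    if (t > 0 && pt < 0) break
    p <- c(p, pt)
  }
  p <- cummin(p)
  tau <- max(-1 + 2 * sum(p), 1 / log10(nn * m))
  ess <- nn * m / tau
  min(ess, nn * m * log10(nn * m))
}

#' Convergence report for a fit
#'
#' Split R-hat and bulk ESS per population parameter, with flags when
#' R-hat exceeds or ESS falls below the configured thresholds.  For a
#' single-chain or MAP fit, R-hat is marked unavailable.
#'
#' @param fit A `sitar_fit`.
#' @return Data frame `parameter`, `rhat`, `ess_bulk`, `flag`.
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "sitar_fit"))
  if (!is.null(fit$convergence)) return(fit$convergence)
  if (fit$sampler_meta$method != "mcmc" || is.null(fit$sampler_meta$chain_id)) {
    return(data.frame(parameter = colnames(fit$draws$pop), rhat = NA_real_,
                      ess_bulk = NA_real_, flag = FALSE,
                      stringsAsFactors = FALSE))
  }
  .convergence_table(fit$draws$pop, fit$sampler_meta$chain_id, fit$config)
}

# ---- sensitivity -----------------------------------------------------------

#' Sensitivity of landmarks to the minimum measurement count
#'
#' For each threshold `m`, restricts the cohort to subjects with at least
#' `m` records, refits (MAP by default), and extracts the population
#' landmarks; reports per-threshold estimates and the SD across thresholds
#' of each landmark's point estimate.  Thresholds leaving fewer than
#' `min_subjects` subjects are skipped with a log entry.
#'
#' @param cohort A single-sex [growth_cohort()].
#' @param thresholds Integer vector of minimum measurement counts; `0`
#'   (or 1) reproduces the unrestricted fit.
#' @param config A [sitar_config()].
#' @param method `"map"` or `"mcmc"`.
#' @param min_subjects Smallest refit cohort allowed (default 10).
#' @param search_window Optional landmark window shared by all refits.
#' @return A `sensitivity_result`: list with `table` (threshold,
#'   n_subjects, atgv, tgv, aphv, phv), `dispersion` (SD across thresholds
#'   per landmark) and `skipped`.
#' @export
sensitivity_by_min_measurements <- function(cohort,
                                            thresholds = c(4:11, 1),
                                            config = sitar_config(),
                                            method = c("map", "mcmc"),
                                            min_subjects = 10,
                                            search_window = NULL) {
  method <- match.arg(method)
  if (length(thresholds) == 0)
    sg_error("thresholds must be non-empty", "sitargrowth_config_error")
  counts <- table(cohort$id)
  rows <- list(); skipped <- integer(0)
  for (m in sort(thresholds)) {
    keep <- names(counts)[counts >= m]
    if (length(keep) < min_subjects) {
      message(sprintf("threshold %d skipped: only %d subjects", m, length(keep)))
      skipped <- c(skipped, m)
      next
    }
    sub <- cohort[cohort$id %in% keep, , drop = FALSE]
    class(sub) <- c("growth_cohort", "data.frame")
    fit <- if (method == "map") fit_map(sub, config) else
      sample_posterior(sub, config)
    lm <- population_landmarks(fit, search_window)
    est <- stats::setNames(lm$estimate, lm$landmark)
    rows[[length(rows) + 1]] <- data.frame(
      threshold = m, n_subjects = length(keep),
      atgv = est[["atgv"]], tgv = est[["tgv"]],
      aphv = est[["aphv"]], phv = est[["phv"]]
    )
  }
  if (length(rows) == 0)
    sg_error("every threshold was skipped", "sitargrowth_config_error")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  stopifnot(!is.unsorted(rev(tab$n_subjects)))  # counts weakly decrease in m
  disp <- vapply(c("atgv", "tgv", "aphv", "phv"),
                 function(l) stats::sd(tab[[l]]), numeric(1))
  structure(list(table = tab, dispersion = disp, skipped = skipped),
            class = "sensitivity_result")
}

#' Prior-scale sensitivity sweep
#'
#' Refits with every prior scale hyperparameter multiplied by each factor
#' and reports the population landmark estimates and their shifts relative
#' to factor 1.
#'
#' @param cohort A single-sex [growth_cohort()].
#' @param factors Positive multipliers (1 is added if absent).
#' @param config Base [sitar_config()].
#' @param search_window Optional landmark window shared by all refits.
#' @return Data frame `factor`, landmark estimates, and `d_*` shifts
#'   relative to the default prior.
#' @export
prior_sensitivity_sweep <- function(cohort, factors = c(0.5, 1, 2),
                                    config = sitar_config(),
                                    search_window = NULL) {
  if (any(factors <= 0))
    sg_error("prior scalings must be > 0", "sitargrowth_config_error")
  factors <- sort(unique(c(1, factors)))
  rows <- lapply(factors, function(f) {
    cf <- config
    cf$prior_scale <- config$prior_scale * f
    fit <- fit_map(cohort, cf)
    lm <- population_landmarks(fit, search_window)
    est <- stats::setNames(lm$estimate, lm$landmark)
    data.frame(factor = f, atgv = est[["atgv"]], tgv = est[["tgv"]],
               aphv = est[["aphv"]], phv = est[["phv"]])
  })
  tab <- do.call(rbind, rows)
  base <- tab[tab$factor == 1, ]
  for (l in c("atgv", "tgv", "aphv", "phv"))
    tab[[paste0("d_", l)]] <- tab[[l]] - base[[l]]
  rownames(tab) <- NULL
  tab
}
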