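# Velocity curves and pubertal growth landmarks.
#
# Differentiating the SITAR prediction with respect to age gives the
# velocity curve
#
#   v(x) = exp(-gamma_total) * sum_k beta_k h_k'(u(x)),
#
# since the age transform u(x) has slope exp(-gamma_total) and the size
# parameters vanish under differentiation.  Four landmarks are extracted
# per curve: the pubertal peak (APHV, PHV) and the pre-spurt takeoff
# (ATGV, TGV), defined as the local velocity minimum immediately preceding
# the peak -- the standard auxological definition.  Because a spline fitted
# over a truncated age range may be monotone before the spurt, the takeoff
# falls back to the window-edge minimum with a `boundary` flag.

#' Velocity of a SITAR curve
#'
#' @param pop List with `beta`, `zeta0`, `gamma0` (and optionally
#'   `alpha0`, unused).
#' @param effects Numeric `c(alpha, zeta, gamma)`; zeros give the
#'   population curve.
#' @param basis An `ncs_basis`.
#' @param x_bar Centering constant (years).
#' @param x Ages (years).
#' @return Velocity in cm/year at each `x`.
#' @export
velocity <- function(pop, effects = c(0, 0, 0), basis, x_bar, x) {
  gt <- pop$gamma0 + effects[3]
  u <- transform_age(x, x_bar, pop$zeta0 + effects[2], gt)
  exp(-gt) * drop(eval_basis(basis, u, 1) %*% pop$beta)
}

# analytic acceleration dv/dx = exp(-2 gamma) * beta . h''(u)
.acceleration <- function(pop, effects, basis, x_bar, x) {
  gt <- pop$gamma0 + effects[3]
  u <- transform_age(x, x_bar, pop$zeta0 + effects[2], gt)
  exp(-2 * gt) * drop(eval_basis(basis, u, 2) %*% pop$beta)
}

# refine a bracketed zero of `fd` (a derivative function) to ~1e-8
.refine_root <- function(fd, lo, hi) {
  stats::uniroot(fd, c(lo, hi), tol = 1e-9)$root
}

#' Locate the pubertal peak of a velocity curve
#'
#' The highest interior local maximum of the curve over `search_window`
#' (an acceleration zero-crossing from positive to negative), bracketed on
#' a dense grid and refined by root-finding on the derivative (the
#' analytic acceleration when `accel` is supplied, a central difference
#' otherwise) to better than 1e-6 years.  Restricting to stationary maxima
#' keeps the search on the pubertal spurt even when velocity is still
#' declining from its childhood values at the window edge.
#'
#' @param vfun Function age -> velocity (vectorized).
#' @param search_window Length-2 numeric age interval.
#' @param accel Optional function age -> dv/dx.
#' @param n_grid Grid resolution used to bracket the maximum.
#' @return List with `age`, `velocity`.
#' @export
find_peak <- function(vfun, search_window, accel = NULL, n_grid = 801) {
  lo <- search_window[1]; hi <- search_window[2]
  if (!(lo < hi))
    sg_error("empty search window", "sitargrowth_contract_error")
  grid <- seq(lo, hi, length.out = n_grid)
  v <- vfun(grid)
  # interior local maxima: v lower on both sides
  maxima <- which(diff(sign(diff(v))) < 0) + 1
  if (length(maxima) == 0)
    sg_error(sprintf("no interior velocity maximum in [%.3g, %.3g] (curve is monotone)",
                     lo, hi),
             "sitargrowth_landmark_error")
  j <- maxima[which.max(v[maxima])]
  fd <- accel %||% function(x) {
    h <- 1e-6
    (vfun(x + h) - vfun(x - h)) / (2 * h)
  }
  age <- if (fd(grid[j - 1]) > 0 && fd(grid[j + 1]) < 0) {
    .refine_root(fd, grid[j - 1], grid[j + 1])
  } else {
    stats::optimize(vfun, c(grid[j - 1], grid[j + 1]),
                    maximum = TRUE, tol = 1e-9)$maximum
  }
  list(age = age, velocity = vfun(age))
}

#' Locate the takeoff preceding a peak
#'
#' The last local minimum of velocity (acceleration zero-crossing from
#' negative to positive) before `peak_age`; if the curve has no interior
#' local minimum on the window, returns the window-edge minimum flagged
#' with `boundary = TRUE`.
#'
#' @inheritParams find_peak
#' @param peak_age Age of the peak bounding the search from above.
#' @return List with `age`, `velocity`, `boundary`.
#' @export
find_takeoff <- function(vfun, peak_age, search_window, accel = NULL,
                         n_grid = 801) {
  lo <- search_window[1]
  hi <- min(search_window[2], peak_age)
  if (!(lo < hi))
    sg_error("empty takeoff search window", "sitargrowth_contract_error")
  grid <- seq(lo, hi, length.out = n_grid)
  v <- vfun(grid)
  # interior local minima: v higher on both sides
  interior <- which(diff(sign(diff(v))) > 0) + 1
  if (length(interior) > 0) {
    j <- max(interior)  # last minimum before the peak
    fd <- accel %||% function(x) {
      h <- 1e-6
      (vfun(x + h) - vfun(x - h)) / (2 * h)
    }
    age <- if (fd(grid[j - 1]) < 0 && fd(grid[j + 1]) > 0) {
      .refine_root(fd, grid[j - 1], grid[j + 1])
    } else {
      stats::optimize(vfun, c(grid[j - 1], grid[j + 1]), tol = 1e-9)$minimum
    }
    list(age = age, velocity = vfun(age), boundary = FALSE)
  } else {
    j <- which.min(v)
    list(age = grid[j], velocity = v[j], boundary = j %in% c(1, n_grid))
  }
}

# landmarks of one draw's curve (population or individual); returns NULL on
# landmark failure
.draw_landmarks <- function(pop, effects, basis, x_bar, window) {
  vf <- function(x) velocity(pop, effects, basis, x_bar, x)
  af <- function(x) .acceleration(pop, effects, basis, x_bar, x)
  pk <- tryCatch(find_peak(vf, window, accel = af), error = function(e) NULL)
  if (is.null(pk)) return(NULL)
  to <- find_takeoff(vf, pk$age, window, accel = af)
  c(atgv = to$age, tgv = to$velocity, aphv = pk$age, phv = pk$velocity,
    boundary = as.numeric(to$boundary))
}

#' Default landmark search window of a fit
#'
#' Ages at the 5th-95th percentile of the observed measurement ages;
#' landmark search on the extrapolated linear spline tails is refused.
#'
#' @param fit A `sitar_fit`.
#' @export
default_search_window <- function(fit) {
  unname(stats::quantile(fit$data$age, c(0.05, 0.95), type = 7))
}

#' Population growth landmarks with 68% credible intervals
#'
#' For every posterior draw the population velocity curve's four landmarks
#' are computed (individual effects zero); the point estimate is the mean
#' over draws and the interval the central 68% (16th-84th percentile).
#' Draws whose landmark search fails are dropped and counted.
#'
#' @param fit A `sitar_fit`.
#' @param search_window Length-2 age interval; defaults to
#'   [default_search_window()].
#' @return A `growth_landmarks` data frame: one row per landmark with
#'   `estimate`, `ci68_low`, `ci68_high`, plus attributes `n_draws_used`,
#'   `n_failed` and `boundary_frac`.
#' @export
population_landmarks <- function(fit, search_window = NULL) {
  stopifnot(inherits(fit, "sitar_fit"))
  window <- search_window %||% default_search_window(fit)
  nd <- n_draws(fit)
  rows <- matrix(NA_real_, nd, 5)
  for (d in seq_len(nd)) {
    lm <- .draw_landmarks(.draw_pop(fit, d), c(0, 0, 0), fit$basis, fit$x_bar, window)
    if (!is.null(lm)) rows[d, ] <- lm
  }
  ok <- !is.na(rows[, 1])
  if (mean(ok) < 0.9)
    sg_error(sprintf("landmark search failed in %.0f%% of draws",
                     100 * mean(!ok)),
             "sitargrowth_landmark_error")
  rows <- rows[ok, , drop = FALSE]
  out <- do.call(rbind, lapply(1:4, function(k) {
    s <- rows[, k]
    ci <- if (nrow(rows) > 1) ci68(s) else c(s, s)
    data.frame(landmark = c("atgv", "tgv", "aphv", "phv")[k],
               estimate = mean(s), ci68_low = ci[1], ci68_high = ci[2],
               stringsAsFactors = FALSE)
  }))
  attr(out, "n_draws_used") <- sum(ok)
  attr(out, "n_failed") <- sum(!ok)
  attr(out, "boundary_frac") <- mean(rows[, 5])
  attr(out, "draws") <- rows[, 1:4, drop = FALSE]
  class(out) <- c("growth_landmarks", "data.frame")
  out
}

#' Individual growth landmarks
#'
#' Per subject and posterior draw, the landmarks of the individual velocity
#' curve via the closed-form mapping from the population curve's
#' transformed-age landmarks: with `u*` the peak of
#' `g(u) = sum_k beta_k h_k'(u)`,
#' `APHV_i = x_bar + zeta0 + zeta_i + u* exp(gamma0 + gamma_i)` and
#' `PHV_i = exp(-(gamma0 + gamma_i)) g(u*)` (same for the takeoff).  Point
#' estimates are posterior means.
#'
#' @inheritParams population_landmarks
#' @return A data frame, one row per subject (`id`, `atgv`, `tgv`, `aphv`,
#'   `phv`, `boundary_frac`), with per-draw samples in the `"draws"`
#'   attribute (list of n_draws x n_subjects matrices).
#' @export
individual_landmarks <- function(fit, search_window = NULL) {
  stopifnot(inherits(fit, "sitar_fit"))
  window <- search_window %||% default_search_window(fit)
  nd <- n_draws(fit)
  n <- length(fit$subject_ids)
  draws <- list(atgv = matrix(NA_real_, nd, n), tgv = matrix(NA_real_, nd, n),
                aphv = matrix(NA_real_, nd, n), phv = matrix(NA_real_, nd, n))
  boundary <- numeric(nd)
  failed <- 0L
  for (d in seq_len(nd)) {
    pop <- .draw_pop(fit, d)
    # landmarks of g(u) on the population transformed-age window
    g <- function(u) drop(eval_basis(fit$basis, u, 1) %*% pop$beta)
    gacc <- function(u) drop(eval_basis(fit$basis, u, 2) %*% pop$beta)
    uwin <- transform_age(window, fit$x_bar, pop$zeta0, pop$gamma0)
    pk <- tryCatch(find_peak(g, uwin, accel = gacc), error = function(e) NULL)
    if (is.null(pk)) { failed <- failed + 1L; next }
    to <- find_takeoff(g, pk$age, uwin, accel = gacc)
    boundary[d] <- to$boundary
    ei <- fit$draws$effects[d, , ]
    if (is.null(dim(ei))) ei <- matrix(ei, ncol = 3)
    eg <- exp(pop$gamma0 + ei[, 3])
    shift <- fit$x_bar + pop$zeta0 + ei[, 2]
    draws$aphv[d, ] <- shift + pk$age * eg
    draws$phv[d, ] <- pk$velocity / eg
    draws$atgv[d, ] <- shift + to$age * eg
    draws$tgv[d, ] <- to$velocity / eg
  }
  if (failed / nd > 0.1)
    sg_error(sprintf("landmark search failed in %d of %d draws", failed, nd),
             "sitargrowth_landmark_error")
  ok <- !is.na(draws$aphv[, 1])
  out <- data.frame(
    id = fit$subject_ids,
    atgv = colMeans(draws$atgv[ok, , drop = FALSE]),
    tgv = colMeans(draws$tgv[ok, , drop = FALSE]),
    aphv = colMeans(draws$aphv[ok, , drop = FALSE]),
    phv = colMeans(draws$phv[ok, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  out$boundary_frac <- mean(boundary[ok])
  attr(out, "draws") <- lapply(draws, function(m) m[ok, , drop = FALSE])
  attr(out, "n_draws_used") <- sum(ok)
  out
}

#' Export landmark tables as CSV
#'
#' @param pop_lm A [population_landmarks()] table (or `NULL`).
#' @param ind_lm An [individual_landmarks()] table (or `NULL`).
#' @param sex Sex label recorded in the export.
#' @param path Output CSV path.
#' @export
write_landmarks_csv <- function(pop_lm = NULL, ind_lm = NULL, sex, path) {
  rows <- list()
  if (!is.null(pop_lm)) {
    rows[[1]] <- data.frame(
      level = "pop", id = NA_character_, sex = sex,
      landmark = pop_lm$landmark, estimate = pop_lm$estimate,
      ci68_low = pop_lm$ci68_low, ci68_high = pop_lm$ci68_high,
      n_draws_used = attr(pop_lm, "n_draws_used"),
      boundary_flag = attr(pop_lm, "boundary_frac") > 0,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(ind_lm)) {
    dr <- attr(ind_lm, "draws")
    long <- do.call(rbind, lapply(c("atgv", "tgv", "aphv", "phv"), function(l) {
      ci <- apply(dr[[l]], 2, ci68)
      data.frame(
        level = "id", id = ind_lm$id, sex = sex, landmark = l,
        estimate = ind_lm[[l]], ci68_low = ci[1, ], ci68_high = ci[2, ],
        n_draws_used = attr(ind_lm, "n_draws_used"),
        boundary_flag = ind_lm$boundary_frac > 0,
        stringsAsFactors = FALSE
      )
    }))
    rows[[length(rows) + 1]] <- long
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
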