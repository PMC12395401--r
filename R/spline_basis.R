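# Natural cubic spline basis on the transformed-age scale.
#
# The SITAR mean curve is sum_k beta_k h_k(u), where u is the transformed
# age.  The h_k are natural cubic splines: twice continuously differentiable
# piecewise cubics constrained to be linear beyond the boundary knots.  The
# basis is built with the standard truncated-power construction (no
# intercept column; the model's size intercept absorbs the constant):
#
#   h_1(u)     = u
#   h_{k+1}(u) = d_k(u) - d_{M-1}(u),   k = 1, ..., M-2
#   d_k(u)     = [ (u - xi_k)_+^3 - (u - xi_M)_+^3 ] / (xi_M - xi_k)
#
# with knots xi_1 < ... < xi_M (boundary knots first and last).  All three
# derivative orders are available analytically; the second derivative
# vanishes identically outside the boundary knots.

#' Build a natural cubic spline basis
#'
#' Places boundary knots at the range of `u_values` and `df - 1` interior
#' knots at equally spaced quantiles, and returns a basis object that can be
#' evaluated (value, first or second derivative) at any real `u`,
#' extrapolating linearly beyond the boundaries.
#'
#' @param u_values Numeric vector of transformed ages used to place knots.
#' @param df Number of basis columns K (no intercept column); the basis has
#'   `df - 1` interior knots.
#' @return An object of class `ncs_basis` with elements `boundary_knots`,
#'   `interior_knots` and `df`.
#' @export
build_basis <- function(u_values, df = 5) {
  if (!is.numeric(u_values) || anyNA(u_values) || any(!is.finite(u_values)))
    sg_error("u_values must be finite numeric", "sitargrowth_config_error")
  if (df < 2)
    sg_error("df must be >= 2", "sitargrowth_config_error")
  ux <- sort(unique(u_values))
  if (length(ux) < df + 2)
    sg_error(
      sprintf("need at least df + 2 = %d distinct u_values, got %d",
              df + 2, length(ux)),
      "sitargrowth_config_error"
    )
  boundary <- range(ux)
  probs <- seq_len(df - 1) / df
  interior <- unname(stats::quantile(u_values, probs = probs, type = 7))
  if (any(diff(interior) <= 0) ||
      interior[1] <= boundary[1] || interior[df - 1] >= boundary[2])
    sg_error("interior knots are not strictly increasing strictly inside the boundary knots",
             "sitargrowth_config_error")
  structure(
    list(boundary_knots = boundary, interior_knots = interior, df = df),
    class = "ncs_basis"
  )
}

# truncated cubic power and its derivatives
.tp3 <- function(u, knot, deriv) {
  d <- pmax(u - knot, 0)
  switch(as.character(deriv),
    "0" = d^3,
    "1" = 3 * d^2,
    "2" = 6 * d
  )
}

#' Evaluate a natural cubic spline basis
#'
#' @param basis An `ncs_basis` object from [build_basis()].
#' @param u Numeric vector of transformed ages (extrapolation allowed).
#' @param deriv Derivative order: 0 (value), 1 or 2.
#' @return A `length(u) x df` matrix, one column per basis function.
#' @export
eval_basis <- function(basis, u, deriv = 0) {
  stopifnot(inherits(basis, "ncs_basis"))
  if (!deriv %in% c(0, 1, 2))
    sg_error("deriv must be 0, 1 or 2", "sitargrowth_config_error")
  knots <- c(basis$boundary_knots[1], basis$interior_knots, basis$boundary_knots[2])
  M <- length(knots)
  out <- matrix(0, length(u), basis$df)
  out[, 1] <- switch(as.character(deriv), "0" = u, "1" = 1, "2" = 0)
  xiM <- knots[M]
  dlast <- (.tp3(u, knots[M - 1], deriv) - .tp3(u, xiM, deriv)) / (xiM - knots[M - 1])
  for (k in seq_len(M - 2)) {
    dk <- (.tp3(u, knots[k], deriv) - .tp3(u, xiM, deriv)) / (xiM - knots[k])
    out[, k + 1] <- dk - dlast
  }
  out
}

#' Serialize a basis to JSON
#'
#' The JSON carries `boundary_knots`, `interior_knots` and `df`, enough to
#' reconstruct the basis exactly with [basis_from_json()].
#'
#' @param basis An `ncs_basis` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
basis_to_json <- function(basis, path = NULL) {
  stopifnot(inherits(basis, "ncs_basis"))
  js <- jsonlite::toJSON(unclass(basis), digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname basis_to_json
#' @param json JSON string or file path written by [basis_to_json()].
#' @export
basis_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(
    list(
      boundary_knots = as.numeric(x$boundary_knots),
      interior_knots = as.numeric(x$interior_knots),
      df = as.integer(x$df)
    ),
    class = "ncs_basis"
  )
}
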