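# DBC10% as a function of residence time. Diffusion into the binding gel
# phase makes the capacity grow with residence time towards a plateau; a
# two-parameter saturation form DBC(tau) = dmax * tau / (k_half + tau)
# captures that shape. The functional form is a modeling choice — the
# measurements provide only anchor points — so a piecewise-linear
# interpolation mode over the anchors is offered alongside the fit.

#' Measured DBC-vs-residence-time anchors
#'
#' @param residence_time_min Residence times in minutes (> 0, unique).
#' @param dbc10_g_per_l Measured DBC10% values in g/L (> 0).
#' @return A data.frame of class `dbc_anchors`.
#' @export
dbc_anchors <- function(residence_time_min, dbc10_g_per_l) {
  check_number(residence_time_min, "residence_time_min", positive = TRUE, len1 = FALSE)
  check_number(dbc10_g_per_l, "dbc10_g_per_l", positive = TRUE, len1 = FALSE)
  if (length(residence_time_min) != length(dbc10_g_per_l)) {
    cs_abort("Anchor vectors must have equal length.", "invalid_input")
  }
  if (anyDuplicated(residence_time_min)) {
    cs_abort("Anchor residence times must be unique.", "invalid_input")
  }
  o <- order(residence_time_min)
  structure(
    data.frame(residence_time_min = residence_time_min[o],
               dbc10_g_per_l = dbc10_g_per_l[o]),
    class = c("dbc_anchors", "data.frame")
  )
}

sat_form <- function(tau, dmax, k_half) dmax * tau / (k_half + tau)

# exact two-point solution of the saturation form
sat_solve2 <- function(t1, d1, t2, d2) {
  den <- d1 * t2 - d2 * t1
  if (den <= 0) return(NULL)  # non-increasing data: no valid saturation pair
  k <- t1 * t2 * (d2 - d1) / den
  if (k < 0) return(NULL)
  c(dmax = d1 * (k + t1) / t1, k_half = k)
}

#' Fit the saturation model DBC(tau) = dmax * tau / (k_half + tau)
#'
#' With exactly two anchors the fit is the exact algebraic solution; with
#' more, least squares starting from the first/last-anchor algebraic
#' solution (refined by Nelder-Mead then BFGS). Identical anchor values fit
#' a constant (`dmax = value`, `k_half = 0`).
#'
#' @param anchors A [dbc_anchors()] data.frame (or any data.frame with the
#'   same columns), at least two rows.
#' @return An object of class `dbc_rt_model` with `mode =
#'   "saturation_fit"`, `dmax`, `k_half`, the anchors and the residuals.
#' @examples
#' fit_dbc_rt(dbc_anchors(c(0.1, 2), c(35.2, 50.1)))
#' @export
fit_dbc_rt <- function(anchors) {
  if (is.data.frame(anchors) && !inherits(anchors, "dbc_anchors")) {
    anchors <- dbc_anchors(anchors$residence_time_min, anchors$dbc10_g_per_l)
  }
  stopifnot(inherits(anchors, "dbc_anchors"))
  tau <- anchors$residence_time_min
  d <- anchors$dbc10_g_per_l
  if (length(tau) < 2) {
    cs_abort("At least two anchors are needed to fit the model.",
             "insufficient_data")
  }

  if (diff(range(d)) == 0) {
    par <- c(dmax = d[1], k_half = 0)
  } else {
    n <- length(tau)
    start <- sat_solve2(tau[1], d[1], tau[n], d[n])
    if (is.null(start)) {
      start <- c(dmax = max(d), k_half = stats::median(tau))
    }
    ssq <- function(p) {
      if (p[1] <= 0 || p[2] < 0) return(Inf)
      sum((d - sat_form(tau, p[1], p[2]))^2)
    }
    par <- start
    if (n > 2 && ssq(start) > 0) {
      par <- stats::optim(par, ssq, method = "Nelder-Mead",
                          control = list(reltol = 1e-14, maxit = 5000))$par
      par <- stats::optim(par, ssq, method = "BFGS",
                          control = list(reltol = 1e-14, maxit = 500))$par
    }
    names(par) <- c("dmax", "k_half")
  }

  structure(
    list(mode = "saturation_fit", anchors = anchors,
         dmax = unname(par["dmax"]), k_half = unname(par["k_half"]),
         residuals = d - sat_form(tau, par["dmax"], par["k_half"])),
    class = "dbc_rt_model"
  )
}

#' Piecewise-linear DBC-vs-residence-time model
#'
#' Interpolates between anchors exactly; outside the anchor range the value
#' is clamped to the nearest anchor (no extrapolation).
#'
#' @param anchors A [dbc_anchors()] data.frame, at least one row.
#' @return A `dbc_rt_model` with `mode = "interpolate"`.
#' @export
dbc_rt_interpolator <- function(anchors) {
  if (is.data.frame(anchors) && !inherits(anchors, "dbc_anchors")) {
    anchors <- dbc_anchors(anchors$residence_time_min, anchors$dbc10_g_per_l)
  }
  stopifnot(inherits(anchors, "dbc_anchors"))
  structure(
    list(mode = "interpolate", anchors = anchors,
         dmax = NA_real_, k_half = NA_real_,
         residuals = rep(0, nrow(anchors))),
    class = "dbc_rt_model"
  )
}

#' @export
print.dbc_rt_model <- function(x, ...) {
  if (x$mode == "saturation_fit") {
    cat(sprintf(
      "<dbc_rt_model> DBC(tau) = %.4g * tau / (%.4g + tau), %d anchors, max |resid| %.3g\n",
      x$dmax, x$k_half, nrow(x$anchors), max(abs(x$residuals))))
  } else {
    cat(sprintf("<dbc_rt_model> piecewise-linear over %d anchors\n",
                nrow(x$anchors)))
  }
  invisible(x)
}

#' Evaluate a DBC-vs-residence-time model
#'
#' @param model A `dbc_rt_model`.
#' @param residence_time_min Residence time(s) in minutes (> 0).
#' @return DBC10% in g/L (vectorized over `residence_time_min`).
#' @export
dbc_at <- function(model, residence_time_min) {
  stopifnot(inherits(model, "dbc_rt_model"))
  check_number(residence_time_min, "residence_time_min", positive = TRUE,
               len1 = FALSE)
  if (model$mode == "interpolate") {
    if (nrow(model$anchors) == 1) {
      return(rep(model$anchors$dbc10_g_per_l, length(residence_time_min)))
    }
    stats::approx(model$anchors$residence_time_min,
                  model$anchors$dbc10_g_per_l,
                  xout = residence_time_min, rule = 2)$y
  } else {
    sat_form(residence_time_min, model$dmax, model$k_half)
  }
}
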