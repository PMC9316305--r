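#' Breakthrough curve container
#'
#' Outlet product concentration versus cumulative applied volume recorded
#' while overloading a device. Concentrations may be absolute (g/L) or
#' already normalized to the feed concentration C0.
#'
#' @param volume_ml Strictly increasing cumulative applied volume, mL.
#' @param outlet Outlet concentration, g/L (or C/C0 if `normalized`).
#' @param c0 Feed concentration, g/L (> 0).
#' @param void_volume_ml System void volume V0, mL (>= 0); subtracted in the
#'   10%-breakthrough capacity only.
#' @param normalized Is `outlet` already C/C0?
#' @return An object of class `breakthrough_curve`.
#' @export
breakthrough_curve <- function(volume_ml, outlet, c0, void_volume_ml = 0,
                               normalized = FALSE) {
  check_number(c0, "c0", positive = TRUE)
  check_number(void_volume_ml, "void_volume_ml", nonneg = TRUE)
  if (length(volume_ml) != length(outlet) || length(volume_ml) < 2) {
    cs_abort("`volume_ml` and `outlet` must be equal-length vectors (n >= 2).",
             "invalid_parameter")
  }
  if (any(diff(volume_ml) <= 0)) {
    cs_abort("`volume_ml` must be strictly increasing.", "invalid_parameter")
  }
  if (any(outlet < 0)) {
    cs_abort("Outlet concentrations must be >= 0.", "invalid_parameter")
  }
  cc0 <- if (normalized) outlet else outlet / c0
  if (any(cc0 > 1.2)) {
    cs_abort("Normalized outlet exceeds 1.2; not a plausible breakthrough curve.",
             "invalid_parameter")
  }
  structure(
    list(volume_ml = as.numeric(volume_ml), outlet = as.numeric(outlet),
         c0 = c0, void_volume_ml = void_volume_ml, normalized = normalized),
    class = "breakthrough_curve"
  )
}

# normalized outlet C/C0
curve_cc0 <- function(curve) {
  if (curve$normalized) curve$outlet else curve$outlet / curve$c0
}

#' Total dynamic binding capacity from pre-breakthrough loading
#'
#' DBC = V0% * C0 / V_membrane, where V0% is the largest applied volume at
#' which no product is measurable in the flowthrough. Matching the
#' fraction-wise measurement procedure (flowthrough collected in discrete
#' fractions), V0% is by default the last sample strictly below the
#' detection limit; `mode = "interpolate"` instead interpolates the limit
#' crossing on the curve. No void correction is applied here.
#'
#' @param curve A [breakthrough_curve()].
#' @param device A [device()].
#' @param detection_limit Outlet concentration (g/L) below which product
#'   counts as undetectable; default 1% of C0.
#' @param mode `"fraction"` (default) or `"interpolate"`.
#' @return Total DBC in g per L of stationary phase.
#' @export
dbc_total <- function(curve, device, detection_limit = 0.01 * curve$c0,
                      mode = c("fraction", "interpolate")) {
  stopifnot(inherits(curve, "breakthrough_curve"), inherits(device, "capture_device"))
  mode <- match.arg(mode)
  check_number(detection_limit, "detection_limit", positive = TRUE)
  conc <- if (curve$normalized) curve$outlet * curve$c0 else curve$outlet
  above <- conc >= detection_limit
  if (above[1]) {
    cs_abort("Curve starts above the detection limit: no pre-breakthrough region.",
             "no_prebreakthrough")
  }
  v0pct <- if (!any(above)) {
    utils::tail(curve$volume_ml, 1)
  } else if (mode == "fraction") {
    curve$volume_ml[which(above)[1] - 1L]
  } else {
    i <- which(above)[1]
    stats::approx(conc[(i - 1):i], curve$volume_ml[(i - 1):i],
                  xout = detection_limit)$y
  }
  v0pct * curve$c0 / device$stationary_phase_volume_ml
}

#' Volume at 10% breakthrough
#'
#' First upward crossing of C/C0 = 0.1, with linear interpolation between
#' the bracketing samples. On a non-monotone (noisy) curve with several
#' crossings the first is used and a warning is issued.
#'
#' @param curve A [breakthrough_curve()].
#' @return V10% in mL.
#' @export
find_v10 <- function(curve) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  cc0 <- curve_cc0(curve)
  v <- curve$volume_ml
  if (cc0[1] >= 0.1) {
    cs_abort("Curve starts at or above 10% breakthrough; no upward crossing.",
             "no_breakthrough")
  }
  up <- which(cc0[-length(cc0)] < 0.1 & cc0[-1] >= 0.1)
  if (!length(up)) {
    cs_abort("Curve never reaches 10% breakthrough.", "no_breakthrough")
  }
  if (length(up) > 1) {
    warning("Multiple 10% crossings; using the first.", call. = FALSE)
  }
  i <- up[1]
  if (cc0[i + 1] == 0.1) return(v[i + 1])
  v[i] + (0.1 - cc0[i]) / (cc0[i + 1] - cc0[i]) * (v[i + 1] - v[i])
}

#' Dynamic binding capacity at 10% breakthrough
#'
#' DBC10% = (V10% - V0) * C0 / V_membrane, with V0 the system void volume
#' carried on the curve.
#'
#' @param curve A [breakthrough_curve()].
#' @param device A [device()].
#' @return DBC10% in g per L of stationary phase.
#' @export
dbc10 <- function(curve, device) {
  stopifnot(inherits(curve, "breakthrough_curve"), inherits(device, "capture_device"))
  v10 <- find_v10(curve)
  if (v10 < curve$void_volume_ml) {
    cs_abort("V10% is below the void volume; curve and void are inconsistent.",
             "invalid_curve")
  }
  (v10 - curve$void_volume_ml) * curve$c0 / device$stationary_phase_volume_ml
}

#' Pool an elution peak by UV threshold
#'
#' Collects the eluate between the first upward crossing of the threshold
#' and the next downward crossing (the "100-100 mAU" pooling rule), with
#' linear interpolation at both edges.
#'
#' @param trace Data.frame with a volume column (first column or `volume`/
#'   `volume_mv`/`volume_ml`) and a signal column (second column or
#'   `uv_mau`).
#' @param threshold Pooling threshold in the signal's units (mAU).
#' @return An object of class `elution_pool` with `start_volume`,
#'   `end_volume`, `pooled_volume` in the trace's volume units.
#' @export
pool_elution <- function(trace, threshold = 100) {
  stopifnot(is.data.frame(trace), nrow(trace) >= 2)
  vcol <- intersect(c("volume", "volume_mv", "volume_ml"), names(trace))
  scol <- intersect("uv_mau", names(trace))
  v <- if (length(vcol)) trace[[vcol[1]]] else trace[[1]]
  s <- if (length(scol)) trace[[scol[1]]] else trace[[2]]
  check_number(threshold, "threshold", positive = TRUE)
  above <- s >= threshold
  if (!any(above)) {
    cs_abort("Signal never reaches the pooling threshold.", "empty_pool")
  }
  i1 <- which(above)[1]
  start <- if (i1 == 1L) v[1] else {
    v[i1 - 1] + (threshold - s[i1 - 1]) / (s[i1] - s[i1 - 1]) * (v[i1] - v[i1 - 1])
  }
  after <- which(!above & seq_along(s) > i1)
  end <- if (!length(after)) {
    warning("Signal still above threshold at end of trace; pooling to last sample.",
            call. = FALSE)
    utils::tail(v, 1)
  } else {
    j <- after[1]
    v[j - 1] + (s[j - 1] - threshold) / (s[j - 1] - s[j]) * (v[j] - v[j - 1])
  }
  structure(
    list(start_volume = start, end_volume = end, pooled_volume = end - start),
    class = "elution_pool"
  )
}
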