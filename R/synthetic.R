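# Synthetic chromatography data. Breakthrough curves follow the
# Thomas/logistic adsorption model, chosen over Bohart-Adams or Yoon-Nelson
# because it gives closed-form breakthrough volumes usable as independent
# oracles; the forms are interchangeable for sigmoidal curves of this kind.

#' Thomas-model parameters for a synthetic breakthrough curve
#'
#' The outlet profile is the logistic solution of the Thomas adsorption
#' model: C/C0 = 1 / (1 + exp\[(k_th/Q) (q0 Vm - C0 (V - V0))\]), with
#' saturation capacity `q0` (g/L), rate constant `k_th` (L/g/min), feed
#' concentration `c0` (g/L), volumetric flow `flow` (mL/min), stationary
#' phase volume `v_m` (mL) and system void `void` (mL). Noise is additive
#' Gaussian on the outlet concentration, truncated at zero.
#'
#' @param q0 Saturation capacity, g per L stationary phase (> 0).
#' @param k_th Thomas rate constant, L/g/min (> 0).
#' @param c0 Feed concentration, g/L (> 0).
#' @param flow Volumetric flow rate, mL/min (> 0).
#' @param v_m Stationary-phase volume, mL (> 0).
#' @param void System void volume, mL (>= 0).
#' @param grid_step Volume sampling step, mL (> 0).
#' @param noise_sd Outlet-concentration noise SD, g/L (>= 0).
#' @param seed Optional integer seed for the noise.
#' @return A list of class `thomas_params`.
#' @export
thomas_params <- function(q0, k_th, c0 = 1, flow = 6, v_m = 1.2, void = 0,
                          grid_step = 1, noise_sd = 0, seed = NULL) {
  for (nm in c("q0", "k_th", "c0", "flow", "v_m", "grid_step")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  check_number(void, "void", nonneg = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(q0 = q0, k_th = k_th, c0 = c0, flow = flow, v_m = v_m,
                 void = void, grid_step = grid_step, noise_sd = noise_sd,
                 seed = seed),
            class = "thomas_params")
}

#' Closed-form 10%-breakthrough volume and capacity of a Thomas curve
#'
#' Setting C/C0 = 0.1 in the logistic Thomas solution gives
#' V10 = V0 + (q0 Vm - Q ln(9)/k_th) / C0, hence
#' DBC10% = q0 - Q ln(9)/(k_th Vm). These serve as independent oracles for
#' the curve-based estimators.
#'
#' @param p A [thomas_params()].
#' @return Volume in mL (`thomas_v10`) or capacity in g/L (`thomas_dbc10`).
#' @export
thomas_v10 <- function(p) {
  stopifnot(inherits(p, "thomas_params"))
  p$void + (p$q0 * p$v_m - p$flow * log(9) / p$k_th) / p$c0
}

#' @rdname thomas_v10
#' @export
thomas_dbc10 <- function(p) {
  stopifnot(inherits(p, "thomas_params"))
  p$q0 - p$flow * log(9) / (p$k_th * p$v_m)
}

#' Simulate a Thomas-model breakthrough curve
#'
#' Samples the logistic Thomas profile on a regular volume grid from zero
#' to just past saturation (C/C0 ~ 0.999), adds truncated Gaussian noise if
#' requested, and returns a [breakthrough_curve()] carrying `c0` and the
#' void volume. Bit-reproducible for a fixed seed.
#'
#' @param p A [thomas_params()].
#' @return A [breakthrough_curve()].
#' @examples
#' dbc10(simulate_breakthrough(thomas_params(q0 = 42.9, k_th = 30)),
#'       device("m", 1.2))
#' @export
simulate_breakthrough <- function(p) {
  stopifnot(inherits(p, "thomas_params"))
  v_max <- p$void + (p$q0 * p$v_m + p$flow * log(999) / p$k_th) / p$c0
  v <- seq(0, v_max + p$grid_step, by = p$grid_step)
  cc0 <- 1 / (1 + exp((p$k_th / p$flow) * (p$q0 * p$v_m - p$c0 * (v - p$void))))
  outlet <- cc0 * p$c0
  if (p$noise_sd > 0) {
    outlet <- with_local_seed(p$seed, {
      pmax(0, outlet + stats::rnorm(length(outlet), sd = p$noise_sd))
    })
    outlet <- pmin(outlet, 1.19 * p$c0)
  }
  breakthrough_curve(v, outlet, c0 = p$c0, void_volume_ml = p$void)
}

#' Simulate a one-cycle UV / pressure trace
#'
#' Builds the volume-indexed trace of a full bind-elute cycle from a
#' resolved recipe: flowthrough plateau during load (unbound impurities),
#' exponential decay to baseline during wash, a Gaussian elution peak whose
#' area is controllable, a small regeneration peak, and per-phase pressure
#' plateaus proportional to flow rate. Zero load density gives a flat
#' baseline. Reproducible for a fixed seed.
#'
#' @param recipe A [recipe()].
#' @param feed A [feed()].
#' @param device A [device()].
#' @param peak_params Optional list overriding defaults:
#'   `load_plateau_mau` (default 500 * titer), `elution_area_mau_mv`
#'   (default 150 * loaded mass density), `elution_sd_mv` (0.8),
#'   `elution_offset_mv` (2), `regen_peak_fraction` (0.05),
#'   `pressure_plateau_bar` (1.3, at the highest flow),
#'   `uv_noise_mau` (0), `pressure_noise_bar` (0), `grid_step_mv` (0.05).
#' @param seed Optional integer seed.
#' @param load_density_g_per_l Load density resolving the load volume
#'   (default 30).
#' @return A data.frame: `volume_mv`, `phase`, `uv_mau`, `pressure_bar`.
#' @export
simulate_cycle_trace <- function(recipe, feed, device, peak_params = list(),
                                 seed = NULL, load_density_g_per_l = 30) {
  stopifnot(inherits(recipe, "capture_recipe"), inherits(device, "capture_device"))
  check_number(load_density_g_per_l, "load_density_g_per_l", nonneg = TRUE)
  pp <- utils::modifyList(list(
    load_plateau_mau = 500 * feed$titer_g_per_l,
    elution_area_mau_mv = 150 * load_density_g_per_l,
    elution_sd_mv = 0.8,
    elution_offset_mv = 2,
    regen_peak_fraction = 0.05,
    pressure_plateau_bar = 1.3,
    uv_noise_mau = 0,
    pressure_noise_bar = 0,
    grid_step_mv = 0.05
  ), peak_params)
  if (load_density_g_per_l == 0) {
    pp$load_plateau_mau <- 0
    pp$elution_area_mau_mv <- 0
  }

  bd <- cycle_breakdown(recipe, device, feed, yield = 1,
                        load_density_g_per_l = load_density_g_per_l)
  ph <- bd$phases
  bounds <- cumsum(c(0, ph$volume_mv))
  v <- seq(0, utils::tail(bounds, 1), by = pp$grid_step_mv)
  idx <- pmin(findInterval(v, bounds, rightmost.closed = TRUE), nrow(ph))
  phase_name <- ph$name[idx]
  rel <- v - bounds[idx]

  uv <- numeric(length(v))
  h_elu <- pp$elution_area_mau_mv / (pp$elution_sd_mv * sqrt(2 * pi))
  for (i in seq_len(nrow(ph))) {
    sel <- idx == i
    if (!any(sel)) next
    r <- rel[sel]
    uv[sel] <- switch(ph$name[i],
      load = pp$load_plateau_mau / (1 + exp(-(r - 1.5) / 0.3)),
      wash = pp$load_plateau_mau * exp(-r / 0.7),
      elution = h_elu *
        exp(-0.5 * ((r - pp$elution_offset_mv) / pp$elution_sd_mv)^2),
      regeneration = pp$regen_peak_fraction * h_elu *
        exp(-0.5 * ((r - 1) / 0.5)^2),
      0
    )
  }
  press <- pp$pressure_plateau_bar * ph$flow_rate_mv_min[idx] /
    max(ph$flow_rate_mv_min)

  if (pp$uv_noise_mau > 0 || pp$pressure_noise_bar > 0) {
    noise <- with_local_seed(seed, list(
      uv = stats::rnorm(length(v), sd = pp$uv_noise_mau),
      pr = stats::rnorm(length(v), sd = pp$pressure_noise_bar)
    ))
    uv <- pmax(0, uv + noise$uv)
    press <- pmax(0, press + noise$pr)
  }

  data.frame(volume_mv = v, phase = phase_name, uv_mau = uv,
             pressure_bar = press, stringsAsFactors = FALSE)
}

#' Trapezoidal integral of a trace signal over a volume window
#'
#' @param trace Data.frame with a volume column and a signal column (as in
#'   [simulate_cycle_trace()] output).
#' @param from,to Integration bounds in the trace's volume units.
#' @param signal Signal column name (default `"uv_mau"`).
#' @return The integral in signal-units times volume-units.
#' @export
integrate_signal <- function(trace, from = -Inf, to = Inf, signal = "uv_mau") {
  vcol <- intersect(c("volume_mv", "volume_ml", "volume"), names(trace))[1]
  v <- trace[[vcol]]
  s <- trace[[signal]]
  keep <- v >= from & v <= to
  v <- v[keep]; s <- s[keep]
  if (length(v) < 2) return(0)
  sum(diff(v) * (s[-1] + s[-length(s)]) / 2)
}

#' Draw a synthetic feed within stated ranges
#'
#' Uniform draws of titer and impurity levels within the given bounds,
#' reproducible for a fixed seed. Default impurity bounds span the levels
#' reported for the harvested cell culture fluids of this process family.
#'
#' @param seed Integer seed.
#' @param titer_range Titer bounds, g/L.
#' @param hcp_range Host cell protein bounds, ppm.
#' @param hcdna_range Host cell DNA bounds, ppm.
#' @return A [feed()].
#' @export
generate_feed <- function(seed = NULL, titer_range = c(2.25, 4.3),
                          hcp_range = c(10305, 54004),
                          hcdna_range = c(2320, 4750)) {
  for (r in list(titer_range, hcp_range, hcdna_range)) {
    if (length(r) != 2 || r[1] > r[2]) {
      cs_abort("Ranges must be length-2 with lower <= upper.",
               "invalid_parameter")
    }
  }
  draws <- with_local_seed(seed, c(
    stats::runif(1, titer_range[1], titer_range[2]),
    stats::runif(1, hcp_range[1], hcp_range[2]),
    stats::runif(1, hcdna_range[1], hcdna_range[2])
  ))
  feed(titer_g_per_l = draws[1], hcp_ppm = draws[2], hcdna_ppm = draws[3])
}
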