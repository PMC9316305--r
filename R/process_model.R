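#' Chromatography device description
#'
#' A device is the stationary phase (membrane or packed resin bed) plus the
#' geometry needed to convert between absolute volumes and stationary-phase
#' volumes. All recipe volumes are expressed as dimensionless multiples of
#' `stationary_phase_volume_ml` (MV for membranes, CV for resin columns), so
#' every cycle-level quantity computed from a recipe is invariant to device
#' size by construction.
#'
#' @param name Device label.
#' @param stationary_phase_volume_ml Membrane/resin bed volume in mL (> 0).
#' @param kind `"membrane"` or `"resin"`.
#' @param bed_height_mm Optional bed height in mm (> 0).
#' @param void_volume_ml System void volume in mL (>= 0); used as the V0
#'   correction of the 10%-breakthrough capacity.
#' @return An object of class `capture_device`.
#' @examples
#' device("prototype", 1.2, kind = "membrane", bed_height_mm = 4)
#' @export
device <- function(name, stationary_phase_volume_ml,
                   kind = c("membrane", "resin"),
                   bed_height_mm = NULL, void_volume_ml = 0) {
  kind <- match.arg(kind)
  check_number(stationary_phase_volume_ml, "stationary_phase_volume_ml", positive = TRUE)
  check_number(void_volume_ml, "void_volume_ml", nonneg = TRUE)
  if (!is.null(bed_height_mm)) check_number(bed_height_mm, "bed_height_mm", positive = TRUE)
  structure(
    list(
      name = as.character(name)[1],
      stationary_phase_volume_ml = stationary_phase_volume_ml,
      bed_height_mm = bed_height_mm,
      void_volume_ml = void_volume_ml,
      kind = kind
    ),
    class = "capture_device"
  )
}

#' @export
print.capture_device <- function(x, ...) {
  cat(sprintf("<capture_device> %s (%s), V = %g mL, void = %g mL\n",
              x$name, x$kind, x$stationary_phase_volume_ml, x$void_volume_ml))
  invisible(x)
}

#' Feed (harvested cell culture fluid) description
#'
#' @param titer_g_per_l Product (mAb) concentration in g/L (> 0).
#' @param hcp_ppm Optional host cell protein level, ng per mg product.
#' @param hcdna_ppm Optional host cell DNA level, ng per mg product.
#' @param aggregate_fraction Optional aggregate fraction in \[0, 1\].
#' @return An object of class `capture_feed`.
#' @export
feed <- function(titer_g_per_l, hcp_ppm = NULL, hcdna_ppm = NULL,
                 aggregate_fraction = NULL) {
  check_number(titer_g_per_l, "titer_g_per_l", positive = TRUE)
  if (!is.null(hcp_ppm)) check_number(hcp_ppm, "hcp_ppm", nonneg = TRUE)
  if (!is.null(hcdna_ppm)) check_number(hcdna_ppm, "hcdna_ppm", nonneg = TRUE)
  if (!is.null(aggregate_fraction)) {
    check_number(aggregate_fraction, "aggregate_fraction", nonneg = TRUE)
    if (aggregate_fraction > 1) {
      cs_abort("`aggregate_fraction` must be in [0, 1].", "invalid_parameter")
    }
  }
  structure(
    list(titer_g_per_l = titer_g_per_l, hcp_ppm = hcp_ppm,
         hcdna_ppm = hcdna_ppm, aggregate_fraction = aggregate_fraction),
    class = "capture_feed"
  )
}

PHASE_NAMES <- c("equilibration", "load", "wash", "elution",
                 "regeneration", "re_equilibration")

#' Recipe phase
#'
#' One step of a bind-elute cycle. Volumes are in stationary-phase volumes
#' (MV); flow rates in MV/min, so duration = volume / flow_rate in minutes.
#' The load phase may omit its volume (`NA`): it is resolved at run time from
#' the load density and feed titer. Hold-until phases (e.g. "regenerate until
#' pH >= 12.3, then 4 MV more") carry their trigger as metadata but must be
#' resolved to a fixed deterministic volume before simulation, since no pH
#' transient model is part of the cycle model.
#'
#' @param name One of `r paste(PHASE_NAMES, collapse = ", ")`.
#' @param volume_mv Phase volume in MV (>= 0; `NA` allowed for load only).
#' @param flow_rate_mv_min Flow rate in MV/min (> 0).
#' @param hold_rule Optional list `list(trigger =, extra_volume_mv =)`
#'   recording the hold-until semantics the fixed volume resolves.
#' @return An object of class `capture_phase`.
#' @export
phase <- function(name, volume_mv, flow_rate_mv_min, hold_rule = NULL) {
  name <- match.arg(name, PHASE_NAMES)
  check_number(flow_rate_mv_min, "flow_rate_mv_min", positive = TRUE)
  if (is.na(volume_mv)) {
    if (name != "load") {
      cs_abort("Only the load phase may leave `volume_mv` unresolved (NA).",
               "invalid_parameter")
    }
  } else {
    check_number(volume_mv, "volume_mv", nonneg = TRUE)
  }
  if (!is.null(hold_rule)) {
    if (!is.list(hold_rule) || is.null(hold_rule$trigger)) {
      cs_abort("`hold_rule` must be a list with a `trigger` element.",
               "invalid_parameter")
    }
  }
  structure(
    list(name = name, volume_mv = volume_mv,
         flow_rate_mv_min = flow_rate_mv_min, hold_rule = hold_rule),
    class = "capture_phase"
  )
}

#' Chromatography recipe
#'
#' An ordered list of phases with exactly one load phase, plus the rule that
#' sets the load density as a fraction of the measured 10%-breakthrough
#' dynamic binding capacity (industry practice: 80%).
#'
#' @param phases List of [phase()] objects, exactly one named `"load"`.
#' @param load_fraction_of_dbc Fraction of DBC10% applied as load density,
#'   in (0, 1]; default 0.8.
#' @return An object of class `capture_recipe`.
#' @export
recipe <- function(phases, load_fraction_of_dbc = 0.8) {
  if (!length(phases) || !all(vapply(phases, inherits, TRUE, "capture_phase"))) {
    cs_abort("`phases` must be a non-empty list of capture_phase objects.",
             "invalid_recipe")
  }
  nm <- vapply(phases, `[[`, "", "name")
  if (sum(nm == "load") != 1L) {
    cs_abort("A recipe must contain exactly one load phase.", "invalid_recipe")
  }
  check_number(load_fraction_of_dbc, "load_fraction_of_dbc", positive = TRUE)
  if (load_fraction_of_dbc > 1) {
    cs_abort("`load_fraction_of_dbc` must be in (0, 1].", "invalid_parameter")
  }
  structure(
    list(phases = phases, load_fraction_of_dbc = load_fraction_of_dbc),
    class = "capture_recipe"
  )
}

#' @export
print.capture_recipe <- function(x, ...) {
  cat(sprintf("<capture_recipe> %d phases, load = %.0f%% of DBC10%%\n",
              length(x$phases), 100 * x$load_fraction_of_dbc))
  for (p in x$phases) {
    cat(sprintf("  %-16s %6s MV @ %g MV/min\n", p$name,
                ifelse(is.na(p$volume_mv), "<run>", format(p$volume_mv)),
                p$flow_rate_mv_min))
  }
  invisible(x)
}

#' Replace the load-phase flow rate of a recipe
#'
#' Used by flow-rate sweeps: the residence time during load (1/flow) sets
#' both the achievable binding capacity and the load-phase duration.
#'
#' @param x A [recipe()].
#' @param flow_rate_mv_min New load flow rate in MV/min (> 0).
#' @return The modified recipe.
#' @export
set_load_flow <- function(x, flow_rate_mv_min) {
  stopifnot(inherits(x, "capture_recipe"))
  check_number(flow_rate_mv_min, "flow_rate_mv_min", positive = TRUE)
  i <- which(vapply(x$phases, `[[`, "", "name") == "load")
  x$phases[[i]]$flow_rate_mv_min <- flow_rate_mv_min
  x
}

#' Residence time from flow rate
#'
#' The residence time tau is the time fluid spends in the stationary phase;
#' with flow in stationary-phase volumes per minute, tau = 1/flow. The
#' membrane's reference condition of 5 MV/min corresponds to 0.2 min (12 s).
#'
#' @param flow_rate_mv_min Flow rate in MV/min (> 0).
#' @return Residence time in minutes.
#' @examples
#' residence_time(5)   # 0.2 min = 12 s
#' @export
residence_time <- function(flow_rate_mv_min) {
  check_number(flow_rate_mv_min, "flow_rate_mv_min", positive = TRUE, len1 = FALSE)
  1 / flow_rate_mv_min
}

#' Feed volume needed to reach a load density
#'
#' @param load_density_g_per_l Target load in g product per L stationary
#'   phase (> 0).
#' @param titer_g_per_l Feed titer in g/L (> 0).
#' @return Load volume in MV.
#' @examples
#' load_volume(34.4, 3.12)
#' @export
load_volume <- function(load_density_g_per_l, titer_g_per_l) {
  check_number(load_density_g_per_l, "load_density_g_per_l", positive = TRUE)
  check_number(titer_g_per_l, "titer_g_per_l", positive = TRUE)
  load_density_g_per_l / titer_g_per_l
}

#' Deterministic cycle breakdown
#'
#' Computes per-phase durations and buffer volumes for one bind-elute cycle.
#' Each phase takes volume / flow_rate minutes. The load volume is resolved
#' from the load density (either given directly, or as
#' `load_fraction_of_dbc * dbc10`) and the feed titer. Feed is not buffer:
#' the buffer tally excludes the load phase.
#'
#' @param recipe A [recipe()].
#' @param device A [device()] (carried for unit conversion at I/O
#'   boundaries; cycle times do not depend on it).
#' @param feed A [feed()].
#' @param dbc10 Dynamic binding capacity at 10% breakthrough, g/L (> 0).
#'   Required unless `load_density_g_per_l` is given.
#' @param yield Step yield fraction in (0, 1]; the eluted mass per litre of
#'   stationary phase is `load density * yield`.
#' @param include_regeneration If `FALSE`, the regeneration phase contributes
#'   zero time and volume (used for cycles that skip cleaning).
#' @param load_density_g_per_l Optional direct load density override, g/L.
#' @return An object of class `cycle_breakdown` with elements `phases` (a
#'   data.frame of name, volume_mv, flow_rate_mv_min, duration_min,
#'   buffer_volume_mv), `total_time_min`, `load_volume_mv`,
#'   `loaded_mass_per_l`, `eluted_mass_per_l`, `yield`.
#' @examples
#' d <- device("m", 1.2)
#' r <- membrane_recipe()
#' cycle_breakdown(r, d, feed(3.12), load_density_g_per_l = 34.4, yield = 0.947)
#' @export
cycle_breakdown <- function(recipe, device, feed, dbc10 = NULL, yield = 0.947,
                            include_regeneration = TRUE,
                            load_density_g_per_l = NULL) {
  if (!inherits(recipe, "capture_recipe")) {
    cs_abort("`recipe` must be a capture_recipe.", "invalid_recipe")
  }
  stopifnot(inherits(device, "capture_device"), inherits(feed, "capture_feed"))
  check_number(yield, "yield", positive = TRUE)
  if (yield > 1) cs_abort("`yield` must be in (0, 1].", "invalid_parameter")
  if (is.null(load_density_g_per_l)) {
    check_number(dbc10, "dbc10", positive = TRUE)
    load_density_g_per_l <- recipe$load_fraction_of_dbc * dbc10
  } else {
    check_number(load_density_g_per_l, "load_density_g_per_l", nonneg = TRUE)
  }

  nm <- vapply(recipe$phases, `[[`, "", "name")
  vol <- vapply(recipe$phases, `[[`, 0, "volume_mv")
  flow <- vapply(recipe$phases, `[[`, 0, "flow_rate_mv_min")

  lv <- if (load_density_g_per_l > 0) {
    load_volume(load_density_g_per_l, feed$titer_g_per_l)
  } else 0
  vol[nm == "load"] <- lv
  if (!include_regeneration) vol[nm == "regeneration"] <- 0

  dur <- vol / flow
  buf <- ifelse(nm == "load", 0, vol)

  structure(
    list(
      phases = data.frame(
        name = nm, volume_mv = vol, flow_rate_mv_min = flow,
        duration_min = dur, buffer_volume_mv = buf,
        stringsAsFactors = FALSE
      ),
      total_time_min = sum(dur),
      load_volume_mv = lv,
      loaded_mass_per_l = load_density_g_per_l,
      eluted_mass_per_l = load_density_g_per_l * yield,
      yield = yield,
      include_regeneration = include_regeneration,
      device = device,
      titer_g_per_l = feed$titer_g_per_l
    ),
    class = "cycle_breakdown"
  )
}

#' @export
print.cycle_breakdown <- function(x, ...) {
  cat("<cycle_breakdown>\n")
  print(x$phases, row.names = FALSE)
  cat(sprintf("total: %.2f min; load %.2f MV; eluted %.2f g/L (yield %.1f%%)\n",
              x$total_time_min, x$load_volume_mv, x$eluted_mass_per_l,
              100 * x$yield))
  invisible(x)
}

#' Average cycle time under reduced regeneration frequency
#'
#' When the caustic regeneration (CIP) phase runs only every k-th cycle, the
#' average cycle time over a k-cycle block is
#' `((k - 1) * t_no_regen + t_full) / k`.
#'
#' @param full Cycle breakdown including regeneration.
#' @param no_regen The same cycle with the regeneration phase skipped.
#' @param k Regeneration interval in cycles (integer >= 1).
#' @return Average cycle time in minutes.
#' @export
amortized_cycle_time <- function(full, no_regen, k) {
  stopifnot(inherits(full, "cycle_breakdown"), inherits(no_regen, "cycle_breakdown"))
  check_number(k, "k", positive = TRUE)
  if (k < 1 || k != round(k)) {
    cs_abort("`k` must be a positive integer.", "invalid_parameter")
  }
  ((k - 1) * no_regen$total_time_min + full$total_time_min) / k
}

#' Buffer consumption per gram of purified product
#'
#' Sum of the non-load phase volumes (feed is not buffer), converted to
#' litres via the device volume, divided by the eluted mass in grams. Both
#' numerator and denominator scale with device size, so the result depends
#' only on the MV-denominated recipe and the eluted mass density.
#'
#' @param breakdown A [cycle_breakdown()].
#' @param device A [device()].
#' @return Buffer use in L per g of eluted product.
#' @export
buffer_per_gram <- function(breakdown, device) {
  stopifnot(inherits(breakdown, "cycle_breakdown"), inherits(device, "capture_device"))
  buffer_mv <- sum(breakdown$phases$buffer_volume_mv)
  if (buffer_mv == 0) return(0)
  if (breakdown$eluted_mass_per_l <= 0) {
    cs_abort("Eluted mass is zero; buffer per gram is undefined.", "invalid_state")
  }
  vm_l <- device$stationary_phase_volume_ml / 1000
  (buffer_mv * vm_l) / (breakdown$eluted_mass_per_l * vm_l)
}
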