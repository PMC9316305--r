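# Volumetric productivity: PR = m_eluted / (V_stationary * t_cycle), here
# carried per litre of stationary phase so PR = eluted_mass_per_l / hours.
# Expressing recipes in MV makes PR independent of absolute device size.

#' Productivity of one cycle condition
#'
#' @param breakdown A [cycle_breakdown()].
#' @param cycle_time_min Optional override of the cycle time (e.g. an
#'   amortized average, or a measured value consumed as data).
#' @return An object of class `productivity_result` with `pr_g_per_l_h`,
#'   `cycle_time_min`, `eluted_mass_per_l`.
#' @examples
#' d <- device("m", 1.2)
#' bd <- cycle_breakdown(membrane_recipe(), d, feed(3.12),
#'                       load_density_g_per_l = 34.4, yield = 0.947)
#' productivity(bd)
#' @export
productivity <- function(breakdown, cycle_time_min = NULL) {
  stopifnot(inherits(breakdown, "cycle_breakdown"))
  t_min <- cycle_time_min %||% breakdown$total_time_min
  if (t_min <= 0) {
    cs_abort("Cycle time must be positive to compute productivity.",
             "invalid_state")
  }
  structure(
    list(pr_g_per_l_h = breakdown$eluted_mass_per_l / (t_min / 60),
         cycle_time_min = t_min,
         eluted_mass_per_l = breakdown$eluted_mass_per_l,
         condition = list(titer = breakdown$titer_g_per_l,
                          yield = breakdown$yield)),
    class = "productivity_result"
  )
}

#' @export
print.productivity_result <- function(x, ...) {
  cat(sprintf("<productivity_result> %.1f g/L/h (cycle %.2f min, eluted %.2f g/L)\n",
              x$pr_g_per_l_h, x$cycle_time_min, x$eluted_mass_per_l))
  invisible(x)
}

# PR for one (titer, load flow) condition with regeneration every k-th cycle
pr_condition <- function(titer, load_flow, dbc10, recipe, device,
                         yield = 0.947, regen_every_k = 1L,
                         load_density_g_per_l = NULL) {
  rec <- set_load_flow(recipe, load_flow)
  fd <- feed(titer)
  full <- cycle_breakdown(rec, device, fd, dbc10 = dbc10, yield = yield,
                          load_density_g_per_l = load_density_g_per_l)
  t_avg <- if (regen_every_k > 1) {
    nr <- cycle_breakdown(rec, device, fd, dbc10 = dbc10, yield = yield,
                          include_regeneration = FALSE,
                          load_density_g_per_l = load_density_g_per_l)
    amortized_cycle_time(full, nr, regen_every_k)
  } else {
    full$total_time_min
  }
  list(breakdown = full, cycle_time_min = t_avg,
       pr = full$eluted_mass_per_l / (t_avg / 60))
}

#' Productivity sweep over feed titers and load flow rates
#'
#' For every grid cell the binding capacity is taken from the DBC(tau)
#' model at tau = 1/flow, the cycle is rebuilt with that load flow and
#' density (`load_fraction_of_dbc * DBC10%`), and the amortized
#' productivity is computed.
#'
#' @param titers Feed titers, g/L.
#' @param load_flows Load flow rates, MV/min.
#' @param model A `dbc_rt_model`.
#' @param recipe,device Recipe and device for the non-load phases.
#' @param yield Step yield fraction (default 0.947).
#' @param regen_every_k Regeneration interval in cycles (default 1).
#' @return A data.frame of class `sweep_grid` in long form: `titer_g_per_l`,
#'   `load_flow_mv_min`, `residence_time_min`, `dbc10_g_per_l`,
#'   `cycle_time_min`, `pr_g_per_l_h`.
#' @export
sweep_productivity <- function(titers, load_flows, model, recipe, device,
                               yield = 0.947, regen_every_k = 1L) {
  if (!length(titers) || !length(load_flows)) {
    cs_abort("Sweep grids must be non-empty.", "invalid_parameter")
  }
  check_number(titers, "titers", positive = TRUE, len1 = FALSE)
  check_number(load_flows, "load_flows", positive = TRUE, len1 = FALSE)
  grid <- expand.grid(titer_g_per_l = titers, load_flow_mv_min = load_flows,
                      KEEP.OUT.ATTRS = FALSE)
  tau <- residence_time(grid$load_flow_mv_min)
  dbc <- dbc_at(model, tau)
  res <- mapply(function(ti, fl, db) {
    r <- pr_condition(ti, fl, db, recipe, device, yield, regen_every_k)
    c(r$cycle_time_min, r$pr)
  }, grid$titer_g_per_l, grid$load_flow_mv_min, dbc)
  out <- cbind(grid,
               data.frame(residence_time_min = tau, dbc10_g_per_l = dbc,
                          cycle_time_min = res[1, ], pr_g_per_l_h = res[2, ]))
  class(out) <- c("sweep_grid", "data.frame")
  attr(out, "regen_every_k") <- regen_every_k
  out
}

#' Optimal load flow rate for a given titer
#'
#' Argmax of productivity over a candidate flow grid; ties are broken
#' toward the higher flow (shorter residence time). The default candidate
#' grid spans the flows of practical interest, 1-10 MV/min.
#'
#' @param titer Feed titer, g/L.
#' @param candidate_flows Candidate load flows, MV/min.
#' @param model A `dbc_rt_model`.
#' @inheritParams sweep_productivity
#' @return A list with `flow_mv_min` and the corresponding `result`
#'   (`productivity_result`).
#' @export
optimal_flow <- function(titer, candidate_flows = c(1, 2, 3, 5, 10), model,
                         recipe, device, yield = 0.947, regen_every_k = 1L) {
  if (!length(candidate_flows)) {
    cs_abort("At least one candidate flow is required.", "invalid_parameter")
  }
  grid <- sweep_productivity(titer, candidate_flows, model, recipe, device,
                             yield, regen_every_k)
  best_pr <- max(grid$pr_g_per_l_h)
  best_flow <- max(grid$load_flow_mv_min[grid$pr_g_per_l_h == best_pr])
  row <- grid[grid$load_flow_mv_min == best_flow, ][1, ]
  r <- pr_condition(titer, best_flow, row$dbc10_g_per_l, recipe, device,
                    yield, regen_every_k)
  list(flow_mv_min = best_flow, result = productivity(r$breakdown, r$cycle_time_min))
}

#' Productivity versus regeneration frequency
#'
#' Evaluates PR with the regeneration phase executed every k-th cycle for
#' each k. PR is affine in 1/k through the cycle time, so it increases with
#' k with strictly diminishing increments towards the no-regeneration limit.
#'
#' @param condition List with `titer`, `load_flow`, and either `dbc10` or
#'   `load_density_g_per_l`, plus `recipe`, `device` and optionally `yield`.
#' @param k_values Integer regeneration intervals (>= 1).
#' @return A data.frame: `regen_every_k`, `cycle_time_min`, `pr_g_per_l_h`.
#' @export
regen_frequency_curve <- function(condition, k_values) {
  if (any(k_values < 1) || any(k_values != round(k_values))) {
    cs_abort("`k_values` must be integers >= 1.", "invalid_parameter")
  }
  rows <- lapply(k_values, function(k) {
    r <- pr_condition(condition$titer, condition$load_flow,
                      condition$dbc10 %||% NULL,
                      condition$recipe, condition$device,
                      yield = condition$yield %||% 0.947,
                      regen_every_k = k,
                      load_density_g_per_l = condition$load_density_g_per_l %||% NULL)
    data.frame(regen_every_k = k, cycle_time_min = r$cycle_time_min,
               pr_g_per_l_h = r$pr)
  })
  do.call(rbind, rows)
}

#' Compare two device/recipe conditions
#'
#' Side-by-side cycle time, productivity and buffer consumption for two
#' fully specified conditions (e.g. membrane versus resin), with the
#' productivity fold change. A condition may supply `cycle_time_min` to use
#' a measured cycle time instead of the recipe reconstruction.
#'
#' @param condition_a,condition_b Lists with `label`, `recipe`, `device`,
#'   `titer`, either `dbc10` or `load_density_g_per_l`, `yield`, and
#'   optionally `cycle_time_min`.
#' @return A list with a `table` data.frame (one row per condition) and
#'   `pr_fold` = PR_a / PR_b.
#' @export
compare_devices <- function(condition_a, condition_b) {
  one <- function(cond) {
    bd <- cycle_breakdown(cond$recipe, cond$device, feed(cond$titer),
                          dbc10 = cond$dbc10 %||% NULL,
                          yield = cond$yield %||% 0.947,
                          load_density_g_per_l = cond$load_density_g_per_l %||% NULL)
    pr <- productivity(bd, cycle_time_min = cond$cycle_time_min %||% NULL)
    data.frame(
      label = cond$label %||% cond$device$name,
      cycle_time_min = pr$cycle_time_min,
      eluted_mass_per_l = bd$eluted_mass_per_l,
      pr_g_per_l_h = pr$pr_g_per_l_h,
      buffer_l_per_g = buffer_per_gram(bd, cond$device),
      stringsAsFactors = FALSE
    )
  }
  tab <- rbind(one(condition_a), one(condition_b))
  list(table = tab, pr_fold = tab$pr_g_per_l_h[1] / tab$pr_g_per_l_h[2])
}
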