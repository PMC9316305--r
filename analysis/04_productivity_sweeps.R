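#!/usr/bin/env Rscript
# Productivity as a function of feed titer, load flow rate and regeneration
# frequency, plus the per-flow optimum. Writes:
#   results/productivity_sweep.csv  - titer x flow grid
#   results/optimal_flow.csv        - best flow per titer
#   results/printed_conditions.csv - printed-condition productivities
#   results/regen_frequency.csv     - PR vs regeneration interval

suppressPackageStartupMessages(library(capturesim))
dir.create("results", showWarnings = FALSE)

dev <- device("membrane-prototype", 1.2, kind = "membrane", bed_height_mm = 4)
rec <- membrane_recipe("sweep")
anchors <- read_dbc_anchors(
  system.file("extdata", "dbc_anchors.csv", package = "capturesim"))
model <- dbc_rt_interpolator(anchors)

titers <- c(0.5, 1, 2, 3, 5, 8, 10)
flows <- c(1, 2, 3, 5, 10)
grid <- sweep_productivity(titers, flows, model, rec, dev, yield = 0.947)
write.csv(grid, "results/productivity_sweep.csv",
          row.names = FALSE, quote = FALSE)

opt <- do.call(rbind, lapply(titers, function(ti) {
  o <- optimal_flow(ti, flows, model, rec, dev, yield = 0.947)
  data.frame(titer_g_per_l = ti, best_flow_mv_min = o$flow_mv_min,
             pr_g_per_l_h = o$result$pr_g_per_l_h)
}))
write.csv(opt, "results/optimal_flow.csv", row.names = FALSE, quote = FALSE)
cat("Optimal load flow shifts down as titer rises:\n")
print(opt, row.names = FALSE)

# the three printed conditions, with regeneration each vs every 7th cycle
conds <- list(list(titer = 1, flow = 10, dbc10 = 35.2),
              list(titer = 5, flow = 5, dbc10 = 40.1),
              list(titer = 10, flow = 3, dbc10 = 43.1))
t7 <- do.call(rbind, lapply(conds, function(cc) {
  rc <- regen_frequency_curve(
    list(titer = cc$titer, load_flow = cc$flow, dbc10 = cc$dbc10,
         yield = 0.947, recipe = rec, device = dev), c(1, 7))
  data.frame(titer_g_per_l = cc$titer, load_flow_mv_min = cc$flow,
             dbc10_g_per_l = cc$dbc10,
             pr_each_cycle = rc$pr_g_per_l_h[1],
             pr_every_7th = rc$pr_g_per_l_h[2])
}))
write.csv(t7, "results/printed_conditions.csv",
          row.names = FALSE, quote = FALSE)
cat("\nPrinted-condition productivities (g/L/h), regeneration each vs every 7th cycle:\n")
print(t7, row.names = FALSE)

rc <- regen_frequency_curve(
  list(titer = 10, load_flow = 3, dbc10 = 43.1, yield = 0.947,
       recipe = rec, device = dev), 1:12)
write.csv(rc, "results/regen_frequency.csv", row.names = FALSE, quote = FALSE)
cat(sprintf(
  "\nRegeneration every 7th instead of every cycle raises PR by %.1f%% at titer 10;\ngains beyond k = 7 are marginal (k = 12 adds only %.1f%% more).\n",
  100 * (rc$pr_g_per_l_h[7] / rc$pr_g_per_l_h[1] - 1),
  100 * (rc$pr_g_per_l_h[12] / rc$pr_g_per_l_h[7] - 1)))
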