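#!/usr/bin/env Rscript
# Generate synthetic Thomas-model breakthrough curves at the membrane's
# working point and estimate total DBC and DBC10% from them, checking the
# estimators against the closed-form oracles. Writes:
#   results/breakthrough_curve.csv  - one noise-free example curve
#   results/breakthrough_dbc.csv    - estimates vs closed form over a grid

suppressPackageStartupMessages(library(capturesim))
dir.create("results", showWarnings = FALSE)
set.seed(101)

dev <- device("membrane-prototype", 1.2, kind = "membrane", bed_height_mm = 4)

# example curve at the study's capacity scale (DBC10% ~ 42.9 g/L)
p <- thomas_params(q0 = 43.5, k_th = 60, c0 = 1.0, flow = 6, v_m = 1.2,
                   grid_step = 0.25)
curve <- simulate_breakthrough(p)
write_chromatogram(
  data.frame(volume_ml = curve$volume_ml,
             concentration_g_per_l = curve$outlet),
  "results/breakthrough_curve.csv")

rows <- list()
for (q0 in c(30, 35, 40, 43.5, 50)) {
  for (noise in c(0, 0.02)) {
    pq <- thomas_params(q0 = q0, k_th = 60, c0 = 1.0, flow = 6, v_m = 1.2,
                        grid_step = 0.25, noise_sd = noise, seed = 101)
    cv <- suppressWarnings(simulate_breakthrough(pq))
    rows[[length(rows) + 1]] <- data.frame(
      q0 = q0, noise_sd = noise,
      dbc10_estimate = dbc10(cv, dev),
      dbc10_closed_form = thomas_dbc10(pq),
      dbc_total_estimate = dbc_total(cv, dev)
    )
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/breakthrough_dbc.csv", row.names = FALSE, quote = FALSE)

err <- max(abs(tab$dbc10_estimate - tab$dbc10_closed_form)[tab$noise_sd == 0])
cat(sprintf(
  "Estimated DBC10%% on %d synthetic curves; max |error| vs closed form on\nnoise-free curves: %.3f g/L (grid-step bound %.3f g/L).\n",
  nrow(tab), err, 1.0 * 0.25 / 1.2))
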