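dev <- membrane_device()

test_that("productivity reproduces the study's membrane and resin values", {
  bd <- cycle_breakdown(membrane_recipe(), dev, feed(3.12),
                        load_density_g_per_l = 34.4, yield = 0.947)
  pr <- productivity(bd)
  expect_equal(pr$pr_g_per_l_h, 203.6, tolerance = 0.002)
  expect_equal(pr$pr_g_per_l_h, bd$eluted_mass_per_l / (bd$total_time_min / 60))

  # doubling the cycle time halves PR
  pr2 <- productivity(bd, cycle_time_min = 2 * bd$total_time_min)
  expect_equal(pr2$pr_g_per_l_h, pr$pr_g_per_l_h / 2)

  rs <- recipe_preset("resin")
  bdr <- cycle_breakdown(rs$recipe, rs$device, feed(3.12),
                         load_density_g_per_l = 24.3, yield = 0.964)
  expect_equal(productivity(bdr, cycle_time_min = 100.4)$pr_g_per_l_h,
               24.3 * 0.964 * 60 / 100.4)
})

test_that("sweeps evaluate each cell consistently and preserve monotonicity", {
  m <- dbc_rt_interpolator(study_anchors())
  r <- membrane_recipe("sweep")
  grid <- sweep_productivity(c(1, 3, 5, 10), c(3, 5, 10), m, r, dev)
  expect_equal(nrow(grid), 12)

  # single-cell grid equals the direct condition computation
  one <- sweep_productivity(5, 5, m, r, dev)
  direct <- capturesim:::pr_condition(5, 5, dbc_at(m, 0.2), r, dev)
  expect_equal(one$pr_g_per_l_h, direct$pr)

  # PR non-decreasing in titer at fixed flow
  for (fl in unique(grid$load_flow_mv_min)) {
    col <- grid[grid$load_flow_mv_min == fl, ]
    col <- col[order(col$titer_g_per_l), ]
    expect_true(all(diff(col$pr_g_per_l_h) > 0))
  }

  # best flow shifts down as titer rises (printed optimum pattern)
  best_flow <- vapply(c(1, 10), function(ti) {
    sub <- grid[grid$titer_g_per_l == ti, ]
    sub$load_flow_mv_min[which.max(sub$pr_g_per_l_h)]
  }, 0)
  expect_equal(best_flow, c(10, 3))

  expect_error(sweep_productivity(numeric(), 5, m, r, dev),
               class = "invalid_parameter")
})

test_that("the flow optimizer equals brute force and breaks ties upward", {
  m <- dbc_rt_interpolator(study_anchors())
  r <- membrane_recipe("sweep")
  flows <- c(1, 2, 3, 5, 10)
  for (ti in c(1, 3, 5, 10)) {
    opt <- optimal_flow(ti, flows, m, r, dev)
    prs <- vapply(flows, function(fl) {
      capturesim:::pr_condition(ti, fl, dbc_at(m, 1 / fl), r, dev)$pr
    }, 0)
    expect_equal(opt$flow_mv_min, flows[which.max(prs)])
    expect_equal(opt$result$pr_g_per_l_h, max(prs))
  }
  single <- optimal_flow(5, 4, m, r, dev)
  expect_equal(single$flow_mv_min, 4)

  # duplicated candidate produces exactly tied best cells; the higher
  # (well, equal) flow of the tied set is returned, exercising the tie rule
  tie <- optimal_flow(1, c(10, 10, 3), m, r, dev)
  expect_equal(tie$flow_mv_min, 10)
})

test_that("regeneration-frequency curve rises with diminishing gains", {
  r <- membrane_recipe("sweep")
  cond <- list(titer = 5, load_flow = 5, dbc10 = 40.1, yield = 0.947,
               recipe = r, device = dev)
  curve <- regen_frequency_curve(cond, 1:10)
  base <- capturesim:::pr_condition(5, 5, 40.1, r, dev)
  expect_equal(curve$pr_g_per_l_h[1], base$pr)
  expect_true(all(diff(curve$pr_g_per_l_h) > 0))
  expect_true(all(diff(diff(curve$pr_g_per_l_h)) < 0))

  # closed form PR(k) = m / (t_nr + t_regen / k)
  full <- cycle_breakdown(set_load_flow(r, 5), dev, feed(5), dbc10 = 40.1)
  nr <- cycle_breakdown(set_load_flow(r, 5), dev, feed(5), dbc10 = 40.1,
                        include_regeneration = FALSE)
  t_regen <- full$total_time_min - nr$total_time_min
  closed <- full$eluted_mass_per_l * 60 /
    (nr$total_time_min + t_regen / curve$regen_every_k)
  expect_equal(curve$pr_g_per_l_h, closed)

  expect_error(regen_frequency_curve(cond, c(1, 0)),
               class = "invalid_parameter")
})

test_that("productivity is identical across device sizes", {
  m <- dbc_rt_interpolator(study_anchors())
  r <- membrane_recipe("sweep")
  prs <- vapply(c(1.2, 10, 70), function(vm) {
    capturesim:::pr_condition(5, 5, 40.1, r, membrane_device(vm))$pr
  }, 0)
  expect_identical(prs[1], prs[2])
  expect_identical(prs[1], prs[3])
})

test_that("membrane-vs-resin comparison shows the order-of-magnitude gap", {
  mem <- list(label = "membrane", recipe = membrane_recipe(),
              device = dev, titer = 3.12, load_density_g_per_l = 34.4,
              yield = 0.947)
  rs <- recipe_preset("resin")
  res <- list(label = "resin", recipe = rs$recipe, device = rs$device,
              titer = 3.12, load_density_g_per_l = 24.3, yield = 0.964,
              cycle_time_min = 100.4)
  cmp <- compare_devices(mem, res)
  expect_equal(nrow(cmp$table), 2)
  expect_equal(cmp$pr_fold, 14, tolerance = 0.05)
  expect_gt(cmp$pr_fold, 10)

  same <- compare_devices(mem, mem)
  expect_equal(same$pr_fold, 1.0)
})
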