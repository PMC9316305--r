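test_that("residence time is the reciprocal of the flow rate", {
  expect_equal(residence_time(5), 0.2)     # 12 s at the membrane load flow
  expect_equal(residence_time(10), 0.1)
  expect_equal(residence_time(3), 1 / 3, tolerance = 1e-12)
  expect_true(all(diff(residence_time(c(1, 2, 5, 10))) < 0))
  expect_error(residence_time(0), class = "invalid_parameter")
  expect_error(residence_time(-2), class = "invalid_parameter")
})

test_that("load volume converts load density and titer consistently", {
  expect_equal(load_volume(34.4, 3.12), 34.4 / 3.12)
  expect_equal(load_volume(28.16, 1.0), 28.16)
  expect_equal(load_volume(34.4, 3.12) * 3.12, 34.4)
  expect_error(load_volume(34.4, 0), class = "invalid_parameter")
})

test_that("the membrane cycling recipe reconstructs the printed cycle time", {
  bd <- cycle_breakdown(membrane_recipe(), membrane_device(), feed(3.12),
                        load_density_g_per_l = 34.4, yield = 0.947)
  # 5/10 + (34.4/3.12)/5 + 12/10 + 12/5 + 9/5 + 15/10
  expect_equal(bd$total_time_min,
               0.5 + (34.4 / 3.12) / 5 + 1.2 + 2.4 + 1.8 + 1.5)
  expect_equal(bd$total_time_min, 9.6, tolerance = 0.01)
  expect_equal(bd$total_time_min, sum(bd$phases$duration_min))
  expect_equal(bd$eluted_mass_per_l, 34.4 * 0.947)
})

test_that("cycle breakdown handles degenerate and regeneration-free cycles", {
  zero <- recipe(list(
    phase("equilibration", 0, 1), phase("load", NA, 1), phase("wash", 0, 1)
  ))
  bd0 <- cycle_breakdown(zero, membrane_device(), feed(1),
                         load_density_g_per_l = 0)
  expect_equal(bd0$total_time_min, 0)

  r <- membrane_recipe()
  full <- cycle_breakdown(r, membrane_device(), feed(3.12), dbc10 = 42.9)
  nr <- cycle_breakdown(r, membrane_device(), feed(3.12), dbc10 = 42.9,
                        include_regeneration = FALSE)
  regen_min <- 9 / 5
  expect_equal(full$total_time_min - nr$total_time_min, regen_min)
  expect_equal(nr$phases$volume_mv[nr$phases$name == "regeneration"], 0)
  # load density resolved from the 80%-of-DBC10 rule
  expect_equal(full$loaded_mass_per_l, 0.8 * 42.9)
})

test_that("the sweep-preset recipe at titer 10 gives the derived cycle time", {
  bd <- cycle_breakdown(set_load_flow(membrane_recipe("sweep"), 3),
                        membrane_device(), feed(10), dbc10 = 43.1)
  # 0.5 + (0.8*43.1/10)/3 + 1.2 + 2.4 + 10/5 + 16/10
  expect_equal(bd$total_time_min, 8.849, tolerance = 1e-3)
})

test_that("a recipe without a load phase is rejected", {
  expect_error(recipe(list(phase("wash", 5, 1))), class = "invalid_recipe")
  expect_error(
    recipe(list(phase("load", NA, 1), phase("load", NA, 1))),
    class = "invalid_recipe")
})

test_that("amortized cycle time interpolates between full and regen-free cycles", {
  r <- set_load_flow(membrane_recipe("sweep"), 3)
  full <- cycle_breakdown(r, membrane_device(), feed(10), dbc10 = 43.1)
  nr <- cycle_breakdown(r, membrane_device(), feed(10), dbc10 = 43.1,
                        include_regeneration = FALSE)
  expect_equal(amortized_cycle_time(full, nr, 1), full$total_time_min)
  # regeneration phase is 10 MV at 5 MV/min = 2.0 min
  expect_equal(amortized_cycle_time(full, nr, 7),
               ((6 * (full$total_time_min - 2)) + full$total_time_min) / 7)
  expect_equal(amortized_cycle_time(full, nr, 7), 7.135, tolerance = 1e-3)
  ks <- 1:20
  ts <- vapply(ks, function(k) amortized_cycle_time(full, nr, k), 0)
  expect_true(all(diff(ts) < 0))
  # affine in 1/k: second differences in 1/k vanish
  expect_equal(ts, nr$total_time_min + (full$total_time_min - nr$total_time_min) / ks)
  expect_error(amortized_cycle_time(full, nr, 0), class = "invalid_parameter")
})

test_that("buffer per gram reproduces the recipe-sum reconstructions", {
  # sweep preset: 5 + 12 + 12 + 10 + 16 = 55 MV of buffer
  bd <- cycle_breakdown(membrane_recipe("sweep"), membrane_device(), feed(3.12),
                        load_density_g_per_l = 34.4, yield = 0.947)
  expect_equal(buffer_per_gram(bd, membrane_device()), 55 / (34.4 * 0.947))
  expect_equal(buffer_per_gram(bd, membrane_device()), 1.69, tolerance = 0.005)

  # resin: 5 + 6 + 12 + 2 + 6 = 31 CV
  rs <- recipe_preset("resin")
  bdr <- cycle_breakdown(rs$recipe, rs$device, feed(3.12),
                         load_density_g_per_l = 24.3, yield = 0.964)
  expect_equal(buffer_per_gram(bdr, rs$device), 31 / (24.3 * 0.964))
  expect_equal(buffer_per_gram(bdr, rs$device), 1.32, tolerance = 0.005)

  no_buffer <- recipe(list(phase("load", NA, 5)))
  bd0 <- cycle_breakdown(no_buffer, membrane_device(), feed(1),
                         load_density_g_per_l = 10)
  expect_equal(buffer_per_gram(bd0, membrane_device()), 0)
})

test_that("cycle quantities are invariant to device size and feed is not buffer", {
  for (vm in c(1.2, 10, 70)) {
    bd <- cycle_breakdown(membrane_recipe(), membrane_device(vm), feed(3.12),
                          dbc10 = 42.9)
    if (vm == 1.2) ref <- bd
    expect_identical(bd$total_time_min, ref$total_time_min)
    expect_identical(bd$phases$volume_mv, ref$phases$volume_mv)
  }
  expect_equal(ref$phases$buffer_volume_mv[ref$phases$name == "load"], 0)
})

test_that("load-phase duration falls with titer at fixed density and flow", {
  durs <- vapply(c(1, 2, 5, 10), function(ti) {
    bd <- cycle_breakdown(membrane_recipe(), membrane_device(), feed(ti),
                          load_density_g_per_l = 34.4)
    bd$phases$duration_min[bd$phases$name == "load"]
  }, 0)
  expect_true(all(diff(durs) < 0))
})
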