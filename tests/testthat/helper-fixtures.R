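# shared fixtures: reference devices, recipes and study conditions

membrane_device <- function(vm_ml = 1.2) {
  device("membrane-prototype", vm_ml, kind = "membrane", bed_height_mm = 4)
}

resin_device <- function() {
  device("resin-column", 1.0, kind = "resin")
}

# the three titer/flow/DBC conditions of the productivity comparison table
study_conditions <- function() {
  list(
    list(titer = 1,  load_flow = 10, dbc10 = 35.2),
    list(titer = 5,  load_flow = 5,  dbc10 = 40.1),
    list(titer = 10, load_flow = 3,  dbc10 = 43.1)
  )
}

# exact algebraic two-point solution of d = dmax * tau / (k + tau),
# independent of the fitting code
solve_saturation_2pt <- function(t1, d1, t2, d2) {
  k <- t1 * t2 * (d2 - d1) / (d1 * t2 - d2 * t1)
  c(dmax = d1 * (k + t1) / t1, k_half = k)
}

study_anchors <- function() {
  dbc_anchors(c(0.1, 0.2, 1 / 3, 2), c(35.2, 40.1, 43.1, 50.1))
}
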