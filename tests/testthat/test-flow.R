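two_outlet_table <- function(L_right = 3, L_left = 3, d = 0.8) {
  data.frame(
    id = c("root", "R", "L"),
    parent_id = c("", "root", "root"),
    generation = c(0L, 1L, 1L),
    length_cm = c(10, L_right, L_left),
    diameter_cm = c(1.56, d, d),
    dx = c(0, 0.5, -0.5), dy = 0, dz = c(-1, -0.8, -0.8),
    lobe = c("none", "RLL", "LLL"),
    region = NA, stringsAsFactors = FALSE)
}

test_that("breathing waveform: half-sine with pi/2 peak-to-mean ratio", {
  cyc <- breathing_cycle()
  expect_equal(cyc$peak_flow, cyc$mean_inspiratory_flow * pi / 2,
               tolerance = 1e-13)
  expect_equal(signif(waveform_flow(cyc, 1), 3), 9.42)
  expect_equal(waveform_flow(cyc, 0), 0)
  expect_equal(waveform_flow(cyc, 3), -cyc$peak_flow)
  # integrates to zero over a period; |Q| averages to the mean over inhalation
  dt <- 0.01
  tt <- seq(0, 4 - dt, by = dt) + dt / 2
  expect_lt(abs(mean(waveform_flow(cyc, tt))), 1e-12)
  inh <- tt[tt < 2]
  expect_equal(mean(abs(waveform_flow(cyc, inh))), 6, tolerance = 1e-3)
})

test_that("Poiseuille resistance: direct arithmetic, linearity, d^4 law", {
  gas <- gas_properties()
  expected <- 128 * gas$viscosity * 0.10 / (pi * 0.0156^4)
  expect_equal(poiseuille_resistance(0.10, 0.0156), expected)
  expect_equal(expected, 1.231e3, tolerance = 1e-3)
  expect_equal(poiseuille_resistance(0.2, 0.0156),
               2 * poiseuille_resistance(0.1, 0.0156))
  expect_equal(poiseuille_resistance(0.1, 0.0078),
               16 * poiseuille_resistance(0.1, 0.0156))
  expect_error(poiseuille_resistance(0.1, 0), "diameter")
})

test_that("Reynolds number: zero flow and direct arithmetic", {
  expect_equal(reynolds_number(0, 1, 1), 0)
  # circular pipe d = 1 cm at 6 L/min with default air
  gas <- gas_properties()
  csa <- pi * 0.5^2
  U <- 6 / 60000 / (csa * 1e-4)
  expect_equal(reynolds_number(6, csa, 1),
               gas$density * U * 0.01 / gas$viscosity)
  expect_equal(reynolds_number(6, csa, 1), 872, tolerance = 0.01)
})

test_that("equal-pressure split: symmetry and the parallel-resistor law", {
  sym <- build_tree(two_outlet_table())
  sol <- solve_steady(sym, 6)
  q <- stats::setNames(sol$branches$flow_lpm, sol$branches$id)
  expect_equal(unname(q["R"]), unname(q["L"]))
  expect_equal(unname(q["R"]), 3)

  # right branch twice the length -> resistances 2:1 -> flows 1/3 : 2/3
  asym <- build_tree(two_outlet_table(L_right = 6, L_left = 3))
  sola <- solve_steady(asym, 6)
  fr <- sola$fractions
  expect_equal(unname(fr["R"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(fr["L"]), 2 / 3, tolerance = 1e-12)
})

test_that("the packaged characteristic tree reproduces the ventilation split", {
  tree <- char_tree_cache()
  sol <- solve_steady(tree, 6)
  lv <- lobar_ventilation(sol)
  expect_equal(lv$right, 0.57, tolerance = 0.01)
  expect_equal(unname(lv$lobes),
               unname(reference_lobar_fractions()[names(lv$lobes)]),
               tolerance = 1e-9)
})

test_that("mass is conserved at every node of every snapshot", {
  tree <- char_tree_cache()
  series <- solve_transient(tree, breathing_cycle(), dt = 0.25)
  worst <- max(vapply(series$solutions, flow_residuals, 0, tree = tree))
  expect_lt(worst, 1e-10)
})

test_that("pure-Poiseuille solutions scale linearly with the inlet flow", {
  tree <- char_tree_cache()
  off <- loss_config(pedley = FALSE, K_bifurcation = 0, K_larynx = 0)
  s1 <- solve_steady(tree, 2, losses = off)
  s3 <- solve_steady(tree, 6, losses = off)
  expect_equal(3 * s1$branches$flow_lpm, s3$branches$flow_lpm,
               tolerance = 1e-12)
  expect_equal(3 * s1$node_pressure, s3$node_pressure, tolerance = 1e-12)
})

test_that("lobar-fractions mode pins the configured split exactly", {
  tree <- char_tree_cache()
  want <- c(RUL = 0.25, RML = 0.05, RLL = 0.30, LUL = 0.22, LLL = 0.18)
  sol <- solve_steady(tree, 6, bc = outlet_bc("lobar_fractions", want))
  lv <- lobar_ventilation(sol)
  expect_equal(lv$lobes[names(want)], want, tolerance = 1e-12)
  expect_lt(flow_residuals(sol, tree), 1e-12)
  # equal-pressure fractions sum to one
  expect_equal(sum(lobar_ventilation(solve_steady(tree, 6))$lobes), 1,
               tolerance = 1e-12)
})

test_that("transient series is quasi-steady and sign-mirrored", {
  tree <- char_tree_cache()
  cyc <- breathing_cycle()
  series <- solve_transient(tree, cyc, dt = 0.5)
  at <- function(t) series$solutions[[which(series$times == t)]]
  peak <- solve_steady(tree, cyc$peak_flow, time = 1)
  expect_equal(at(1)$branches$flow_lpm, peak$branches$flow_lpm)
  expect_equal(at(2)$branches$flow_lpm, rep(0, nrow(tree$branches)))
  # exhalation mirrors inhalation: Q(T - t) = -Q(t)
  expect_equal(at(3.5)$branches$flow_lpm, -at(0.5)$branches$flow_lpm,
               tolerance = 1e-12)
  expect_error(solve_transient(tree, cyc, dt = 0.3), "divide")
})

test_that("node pressures match a dense linear-system oracle on small trees", {
  for (tab in list(two_outlet_table(),
                   two_outlet_table(L_right = 7, L_left = 2, d = 0.9),
                   make_weibel_table(tree_recipe(max_generation = 2,
                                                 mode = "weibel_symmetric")))) {
    tree <- build_tree(tab)
    off <- loss_config(pedley = FALSE, K_bifurcation = 0, K_larynx = 0)
    sol <- solve_steady(tree, 6, losses = off)
    oracle <- dense_pressure_oracle(tree, 6)
    got <- sol$node_pressure[paste0("node_", names(oracle))]
    expect_equal(unname(got), unname(oracle), tolerance = 1e-9)
  }
})

test_that("pressure drops follow the Poiseuille identity on a single tube", {
  solo <- build_tree(make_weibel_table(tree_recipe(max_generation = 0,
                                                   mode = "weibel_symmetric")))
  off <- loss_config(pedley = FALSE, K_bifurcation = 0, K_larynx = 0)
  sol <- solve_steady(solo, 6, losses = off)
  R <- poiseuille_resistance(0.10, 0.0156)
  expect_equal(pressure_drop(sol, "trachea_inlet", "node_g0"),
               R * 6 / 60000, tolerance = 1e-12)
  zero <- solve_steady(solo, 0, losses = off)
  expect_equal(pressure_drop(zero, "trachea_inlet", "node_g0"), 0)
  expect_error(pressure_drop(sol, "nope", "node_g0"), "unknown node")
})

test_that("the glottis is the Reynolds hotspot of the upper airway at peak flow", {
  tree <- char_tree_cache()
  sol <- solve_steady(tree, breathing_cycle()$peak_flow, time = 1)
  re <- stats::setNames(sol$upper$reynolds, sol$upper$name)
  expect_equal(names(which.max(re)), "larynx")
  expect_gt(unname(re["larynx"]), 1000)
})
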