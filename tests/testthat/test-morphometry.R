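test_that("carinal radius is the daughter-radius sum times the curvature ratio", {
  expect_equal(carinal_radius(0.4, 0.4, 0.1), 0.08)
  expect_equal(carinal_radius(0, 0, 0.1), 0)
  expect_equal(carinal_radius(0.55, 0.45, 0.1), 0.1)
  expect_error(carinal_radius(-0.1, 0.4), "radii")
  # symmetric in (R_A, R_B), linear in c_c
  for (i in 1:20) {
    ra <- i * 0.03; rb <- 1 / i
    expect_identical(carinal_radius(ra, rb, 0.1), carinal_radius(rb, ra, 0.1))
    expect_equal(carinal_radius(ra, rb, 0.2), 2 * carinal_radius(ra, rb, 0.1))
  }
})

test_that("transition zone starts at the configured fraction of the parent length", {
  expect_equal(transition_zone(1.0), 0.8)
  expect_equal(transition_zone(2.5), 2.0)
  expect_equal(transition_zone(list(length_cm = 3), bifurcation_spec(transition_fraction = 0.5)),
               1.5)
  expect_error(bifurcation_spec(transition_fraction = 1), "transition_fraction")
  expect_error(transition_zone(0), "length")
})

test_that("C-shape area matches a 2D integration oracle and its limits", {
  spec <- trachea_spec(diameter = 1.56, posterior_cut_offset = 0.65)
  expect_equal(c_shape_area(spec), cut_disk_area_numeric(1.56, 0.65, n = 20000),
               tolerance = 1e-6)
  expect_equal(c_shape_area(spec), 1.8352, tolerance = 1e-4)
  # offset = 0: half the circle; offset = r: full circle (flagged)
  expect_equal(c_shape_area(2, 0), pi / 2)
  expect_warning(full <- c_shape_area(2, 1), "degenerate")
  expect_equal(full, pi)
  # monotone increasing in the cut offset; segment non-negative
  offs <- seq(0.05, 0.75, by = 0.05)
  areas <- vapply(offs, function(h) c_shape_area(1.56, h), 0)
  expect_true(all(diff(areas) > 0))
  expect_true(all(areas <= pi * 0.78^2))
})

test_that("build_tree assembles valid trees and flags structural defects", {
  tree <- char_tree_cache()
  expect_equal(nrow(terminal_branches(tree)), 64L)
  expect_equal(tree$max_generation, 6L)
  expect_setequal(unique(terminal_branches(tree)$lobe),
                  c("RUL", "RML", "RLL", "LUL", "LLL"))

  # degenerate: trachea only
  solo <- make_weibel_table(tree_recipe(max_generation = 0,
                                        mode = "weibel_symmetric"))
  t0 <- build_tree(solo)
  expect_equal(t0$max_generation, 0L)
  expect_equal(nrow(terminal_branches(t0)), 1L)

  # structural errors
  tab <- make_weibel_table(tree_recipe(max_generation = 2,
                                       mode = "weibel_symmetric"))
  orphan <- tab
  orphan$parent_id[orphan$id == "g0R"] <- "missing"
  expect_error(build_tree(orphan), "orphan")
  onechild <- tab[tab$id != "g0LL", ]   # drop one leaf: parent keeps 1 child
  expect_error(build_tree(onechild), "children")
  twisted <- tab
  twisted$generation[twisted$id == "g0R"] <- 2L
  expect_error(build_tree(twisted), "generation")
})

test_that("symmetric tables satisfy the diameter law to 1e-10 for any exponent", {
  for (xn in c(2, 2.5, 3)) {
    tab <- make_weibel_table(tree_recipe(max_generation = 4,
                                         mode = "weibel_symmetric", x_n = xn))
    tree <- build_tree(tab, bif_spec = bifurcation_spec(x_n = xn))
    res <- tree$branches$diameter_law_residual
    expect_lt(max(res, na.rm = TRUE), 1e-10)
    # child/parent ratio is 2^(-1/x_n)
    b <- tree$branches
    kid <- b[!is.na(b$parent_id), ]
    ratio <- kid$diameter_cm / b[kid$parent_id, "diameter_cm"]
    expect_equal(ratio, rep(2^(-1 / xn), nrow(kid)), tolerance = 1e-12)
  }
})

test_that("ring annotations cover trachea and main bronchi at the step spacing", {
  tree <- char_tree_cache()  # trachea 10 cm
  ringed <- add_rings(tree, ring_spec(step_p = 5, width_L = 3))
  expect_equal(ring_count(ringed, "T"), 20L)
  expect_gt(ring_count(ringed, "RMB"), 0L)
  expect_equal(ring_count(ringed, "RULr"), 0L)  # generation 2: no rings
  # disabled rings leave the tree unchanged
  off <- add_rings(tree, ring_spec(enabled = FALSE))
  expect_identical(off$ring_annotations, tree$ring_annotations)
  expect_error(ring_spec(step_p = 3, width_L = 3), "width")
})

test_that("morphometry CSV dialect round-trips through read/write", {
  tab <- make_weibel_table(tree_recipe(max_generation = 3,
                                       mode = "weibel_symmetric"))
  f <- tempfile(fileext = ".csv")
  write_morphometry(tab, f)
  back <- read_morphometry(f)
  expect_equal(back$id, tab$id)
  expect_equal(back$diameter_cm, tab$diameter_cm, tolerance = 1e-12)
  tree <- build_tree(back)
  expect_equal(nrow(terminal_branches(tree)), 8L)
})
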