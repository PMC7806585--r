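test_that("symmetric generator: node counts, exact diameter law, determinism", {
  tab <- make_weibel_table(tree_recipe(max_generation = 6,
                                       mode = "weibel_symmetric"))
  expect_equal(nrow(tab), 127L)
  expect_equal(sum(!tab$id %in% tab$parent_id), 64L)
  tab2 <- make_weibel_table(tree_recipe(max_generation = 6,
                                        mode = "weibel_symmetric",
                                        seed = 999))
  expect_identical(tab, tab2)   # symmetric mode ignores the seed
  # every generated table builds without structural errors
  for (g in 0:4) {
    expect_s3_class(build_tree(make_weibel_table(
      tree_recipe(max_generation = g, mode = "weibel_symmetric"))),
      "airway_tree")
  }
})

test_that("characteristic generator: 64 labelled terminals, target split, fixture identity", {
  tab <- make_characteristic_table()
  term <- tab[!tab$id %in% tab$parent_id, ]
  expect_equal(nrow(term), 64L)
  expect_setequal(unique(term$lobe), c("RUL", "RML", "RLL", "LUL", "LLL"))
  expect_equal(sum(reference_lobar_fractions()), 1)

  tree <- build_tree(tab)
  lv <- lobar_ventilation(solve_steady(tree, 6))
  expect_gt(lv$right, 0.55)
  expect_lt(lv$right, 0.59)

  # packaged fixture is content-addressed: byte-identical to the generator
  fixture <- system.file("extdata", "characteristic_tree.csv",
                         package = "airwaydep")
  tmp <- tempfile(fileext = ".csv")
  write_morphometry(tab, tmp)
  expect_identical(readLines(tmp), readLines(fixture))
  expect_equal(unname(tools::md5sum(fixture)),
               "675031d7e91e69e4c645a9629bedf904")
})

test_that("mirror symmetry: the symmetric fixture yields mirrored flow and transport", {
  tree <- weibel_tree(4)
  sol <- solve_steady(tree, 6)
  lv <- lobar_ventilation(sol)
  expect_equal(lv$right, lv$left, tolerance = 1e-12)
  # per-branch flows mirror between the R and L subtrees
  q <- stats::setNames(sol$branches$flow_lpm, sol$branches$id)
  rs <- grep("^g0R", names(q), value = TRUE)
  expect_equal(unname(q[rs]), unname(q[sub("^g0R", "g0L", rs)]),
               tolerance = 1e-12)
  rec <- transport(tree, 6, make_injection(), particle_spec(7))
  expect_equal(sum(rec$escaped[c("RUL", "RML", "RLL")]),
               sum(rec$escaped[c("LUL", "LLL")]), tolerance = 1e-12)
})

test_that("disk injection: support, determinism, mean radius", {
  inj <- make_injection(2720, 2.16, 0, seed = 3)
  r <- sqrt(inj$positions$x_cm^2 + inj$positions$y_cm^2)
  expect_true(all(r <= 1.08))
  inj2 <- make_injection(2720, 2.16, 0, seed = 3)
  expect_identical(inj$positions, inj2$positions)
  # mean radius of a uniform disk is 2R/3; allow 2 standard errors
  se <- (1.08 * sqrt(1 / 2 - 4 / 9)) / sqrt(2720)
  expect_lt(abs(mean(r) - 2 * 1.08 / 3), 2 * se)
  # the injection sampler must not disturb the global RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); make_injection(10, seed = 99); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("morphometry perturbation: identity, determinism, split stability", {
  tab <- make_characteristic_table()
  expect_identical(perturb_morphometry(tab, 0), tab)
  p1 <- perturb_morphometry(tab, 0.05, seed = 4)
  p2 <- perturb_morphometry(tab, 0.05, seed = 4)
  expect_identical(p1, p2)
  expect_true(all(p1$diameter_cm > 0))

  # 5% geometric noise moves the right-lung share by < 5 points (100 seeds)
  shares <- vapply(1:100, function(s) {
    pt <- perturb_morphometry(tab, 0.05, seed = s)
    lobar_ventilation(solve_steady(build_tree(pt), 6))$right
  }, 0)
  expect_true(all(abs(shares - 0.57) < 0.05))
})
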