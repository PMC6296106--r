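test_that("orientation metrics pin the eccentricity convention", {
  # all points on the Y axis: eccentricity 1, radial 1, ratio_y 1
  rows <- c(list(list(1, "soma", 0, 0, 0, -1)),
            lapply(2:21, function(i) list(i, "axon", 0, (i - 1) * 5, 0, i - 1)))
  m <- orientation_metrics(toy_neuron(rows), "axon")
  expect_equal(unname(m["eccentricity"]), 1)
  expect_equal(unname(m["radial"]), 1)
  expect_equal(unname(m["ratio_y"]), 1)
  expect_gt(m["y_mean"], 0)
  expect_gt(m["y_std_mean"], 0)

  # uniform circle: eccentricity ~ 0
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  rows <- c(list(list(1, "soma", 100, 0, 0, -1)),
            lapply(seq_along(th), function(i)
              list(i + 1, "axon", 100 * cos(th[i]), 100 * sin(th[i]), 0, i)))
  m2 <- orientation_metrics(toy_neuron(rows), "axon")
  expect_lt(m2["eccentricity"], 0.05)
  expect_true(all(is.na(orientation_metrics(toy_neuron(
    list(list(1, "soma", 0, 0, 0, -1))), "axon"))))
})

test_that("orientation metrics are stable under resampling refinement", {
  n <- generate_neuron(default_templates()$MC, seed = 31)
  m1 <- orientation_metrics(n, "axon", step = 1)
  m2 <- orientation_metrics(n, "axon", step = 0.5)
  expect_equal(m1, m2, tolerance = 1e-3)
})

test_that("grid metrics count occupied cells and bifurcation spread", {
  # straight 100-um vertical branch on a 20-um grid: 5 cells of 400 um^2
  rows <- c(list(list(1, "soma", 10, 0, 0, -1)),
            lapply(1:100, function(i) list(i + 1, "axon", 10, i, 0, i)))
  n <- toy_neuron(rows)
  m <- grid_metrics(n, "axon", cell_size = 20)
  expect_equal(unname(m["grid_area"]), 5 * 400)
  expect_true(is.na(m["density_bifs"]))  # fewer than 2 bifurcations

  # duplicated overlaid arbor: same area, doubled occupancy
  rows2 <- c(rows, lapply(1:100, function(i)
    list(i + 101, "axon", 10, i, 0, if (i == 1) 1 else i + 100)))
  m2 <- grid_metrics(toy_neuron(rows2), "axon", cell_size = 20)
  expect_equal(unname(m2["grid_area"]), unname(m["grid_area"]))
  expect_equal(unname(m2["grid_mean"]), 2 * unname(m["grid_mean"]),
               tolerance = 0.02)

  # two bifurcations 50 um apart
  rows3 <- list(list(1, "soma", 0, 0, 0, -1), list(2, "axon", 0, 5, 0, 1),
                list(3, "axon", 3, 10, 0, 2), list(4, "axon", -3, 10, 0, 2),
                list(5, "axon", 0, 55, 0, 2),
                list(6, "axon", 3, 60, 0, 5), list(7, "axon", -3, 60, 0, 5))
  m3 <- grid_metrics(toy_neuron(rows3), "axon")
  expect_equal(unname(m3["density_bifs"]), 50)
})

test_that("laminar Monte Carlo matches closed-form uniform-offset geometry", {
  model <- laminar_model(thickness_sd = rep(0, 5))  # deterministic layers
  t23 <- model$thickness_mean[model$layer == "L2/3"]

  # arbor top exactly half the home thickness above the soma: the soma
  # offset is uniform, so P(reach L1) = 1/2
  rows <- c(list(list(1, "soma", 0, 0, 0, -1)),
            lapply(seq_len(ceiling(t23 / 2)), function(i)
              list(i + 1, "axon", 0, i * t23 / 2 / ceiling(t23 / 2), 2 * (i %% 2), i)))
  n <- toy_neuron(rows, home_layer = "L2/3")
  nd <- 2000
  m <- laminar_metrics(n, model, n_draws = nd, seed = 4)
  expect_equal(unname(m["l1_prob"]), 0.5,
               tolerance = 3 * sqrt(0.25 / nd) / 0.5)

  # single point at the soma: nothing crosses
  pt <- toy_neuron(list(list(1, "soma", 0, 0, 0, -1),
                        list(2, "axon", 0, 0, 0, 1)), home_layer = "L4")
  m0 <- laminar_metrics(pt, model, n_draws = 500, seed = 1)
  expect_equal(unname(m0["translaminar"]), 0)
  expect_equal(unname(m0["l1_prob"]), 0)

  # arbor spanning far beyond the cortex: certain reach
  big <- toy_neuron(list(list(1, "soma", 0, 0, 0, -1),
                         list(2, "axon", 0, -30000, 0, 1),
                         list(3, "axon", 0, 30000, 0, 2)), home_layer = "L5")
  mb <- laminar_metrics(big, laminar_model(), n_draws = 300, seed = 2)
  expect_equal(unname(mb["translaminar"]), 1)
  expect_equal(unname(mb["l1_prob"]), 1)
  expect_error(laminar_metrics(toy_neuron(list(list(1, "soma", 0, 0, 0, -1),
                                               list(2, "axon", 0, 9, 0, 1)),
                                          home_layer = "L9"),
                               laminar_model()), "home layer")
})

test_that("reach probability is monotone in arbor height", {
  model <- laminar_model()
  probs <- vapply(c(100, 300, 500, 700, 900), function(h) {
    rows <- c(list(list(1, "soma", 0, 0, 0, -1)),
              lapply(1:10, function(i) list(i + 1, "axon", 0, i * h / 10,
                                            3 * (i %% 2), i)))
    n <- toy_neuron(rows, home_layer = "L2/3")
    laminar_metrics(n, model, n_draws = 800, seed = 7)[["l1_prob"]]
  }, 1)
  expect_true(all(diff(probs) >= 0))
})

test_that("Monte-Carlo laminar estimates converge with more draws", {
  n <- generate_neuron(default_templates()$MC, seed = 17)
  m1 <- laminar_metrics(n, laminar_model(), n_draws = 1000, seed = 5)
  m2 <- laminar_metrics(n, laminar_model(), n_draws = 2000, seed = 6)
  p <- m1[["l1_prob"]]
  se <- sqrt(max(p * (1 - p), 0.01) / 1000)
  expect_lt(abs(m2[["l1_prob"]] - p), 3 * se + 1e-9)
})

test_that("dendritic polarity distinguishes bipolar from multipolar", {
  # two stems at +Y and -Y
  bi <- toy_neuron(list(list(1, "soma", 0, 0, 0, -1),
                        list(2, "axon", 0, 5, 0, 1), list(3, "axon", 0, 25, 5, 2),
                        list(4, "dendrite", 0, 8, 0, 1),
                        list(5, "dendrite", 0, 30, 0, 4),
                        list(6, "dendrite", 0, -8, 0, 1),
                        list(7, "dendrite", 0, -30, 0, 6)))
  m <- dendrite_polarity_metrics(bi)
  expect_equal(unname(m["d.insert.eccentricity"]), 1)
  expect_equal(unname(m["d.insert.radial"]), 1)
  expect_equal(unname(m["d.multipolar"]), 0)

  # four stems N/E/S/W
  multi <- toy_neuron(list(list(1, "soma", 0, 0, 0, -1),
                           list(2, "axon", 0, 5, 0, 1), list(3, "axon", 0, 25, 5, 2),
                           list(4, "dendrite", 0, 8, 0, 1),
                           list(5, "dendrite", 8, 0, 0, 1),
                           list(6, "dendrite", 0, -8, 0, 1),
                           list(7, "dendrite", -8, 0, 0, 1)))
  m2 <- dendrite_polarity_metrics(multi)
  expect_equal(unname(m2["d.insert.eccentricity"]), 0, tolerance = 1e-9)
  expect_equal(unname(m2["d.multipolar"]), 1)

  # coincident arbors: zero displacement
  co <- toy_neuron(list(list(1, "soma", 0, 0, 0, -1),
                        list(2, "axon", 0, 5, 0, 1), list(3, "axon", 0, 15, 0, 2),
                        list(4, "dendrite", 0, 5, 0, 1),
                        list(5, "dendrite", 0, 15, 0, 4)))
  expect_equal(unname(dendrite_polarity_metrics(co)["d.displaced"]), 0,
               tolerance = 1e-9)
})

test_that("pattern metrics count short vertical terminals and axon origin", {
  n <- toy_neuron(list(list(1, "soma", 0, 0, 0, -1),
                       list(2, "axon", 0, 10, 0, 1),
                       list(3, "axon", 0, 20, 0, 2),
                       list(4, "axon", 0, -10, 0, 3),   # 30 um straight down
                       list(5, "axon", 30, 20, 0, 3)))  # 30 um horizontal
  m <- pattern_metrics(n)
  expect_equal(unname(m["short_vertical_terminals"]), 1)
  expect_equal(unname(m["short_vertical_frac"]), 0.5)
  expect_equal(unname(m["axon_origin"]), 1)  # root directly above centroid
})
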