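test_that("branch metrics follow hand-computed toy values", {
  n <- toy_bifurcating()
  m <- branch_metrics(n, "axon")
  # branches: root chain 20 um, two children of ~14.14 um each
  expect_equal(unname(m["N_stems"]), 1)
  expect_equal(unname(m["terminal_degree"]), 2)
  expect_equal(unname(m["N_bifurcations"]), 1)
  expect_equal(unname(m["length.avg"]), (20 + 2 * sqrt(200)) / 3)
  expect_equal(unname(m["total_length"]), 30 + 2 * sqrt(200))  # incl. stem
  expect_equal(unname(m["height"]), 30)    # axon Y in [10, 40]
  expect_equal(unname(m["width"]), 20)
  expect_true(all(is.na(branch_metrics(n, "axon", branches = list()))))
})

test_that("distance metrics: straight arbors and the L-shaped path", {
  # straight radial chain: path distance equals Euclidean everywhere
  rows <- c(list(list(1, "soma", 0, 0, 0, -1)),
            lapply(2:11, function(i) list(i, "axon", 0, (i - 1) * 4, 0, i - 1)))
  n <- toy_neuron(rows)
  m <- distance_metrics(n, "axon")
  expect_equal(unname(m["path_dist.avg"]), unname(m["euclidean_dist.avg"]))
  expect_equal(unname(m["path_dist.max"]), unname(m["euclidean_dist.max"]))

  # 10 up then 10 right: terminal path 20, Euclidean 14.142
  rows <- list(list(1, "soma", 0, 0, 0, -1), list(2, "axon", 0, 0, 0, 1),
               list(3, "axon", 0, 10, 0, 2), list(4, "axon", 10, 10, 0, 3))
  nL <- toy_neuron(rows)
  mL <- distance_metrics(nL, "axon")
  expect_equal(unname(mL["path_dist.max"]), 20)
  expect_equal(unname(mL["euclidean_dist.max"]), sqrt(200), tolerance = 1e-6)
  expect_true(all(is.na(distance_metrics(nL, "dendrite"))))
})

test_that("remote bifurcation, tilt and torque conventions", {
  # children ending at (10,0,0) and (0,10,0) from a bifurcation at origin
  rows <- list(list(1, "soma", 0, -10, 0, -1), list(2, "axon", 0, -5, 0, 1),
               list(3, "axon", 0, 0, 0, 2),
               list(4, "axon", 10, 0, 0, 3), list(5, "axon", 0, 10, 0, 3))
  n <- toy_neuron(rows)
  m <- angle_metrics(n, "axon")
  expect_equal(unname(m["remote_bifurcation_angle.avg"]), 90)

  # collinear children: 0 degrees
  rows2 <- list(list(1, "soma", 0, -10, 0, -1), list(2, "axon", 0, 0, 0, 1),
                list(3, "axon", 5, 5, 0, 2), list(4, "axon", 10, 10, 0, 2))
  expect_equal(unname(angle_metrics(toy_neuron(rows2),
                                    "axon")["remote_bifurcation_angle.avg"]),
               0, tolerance = 1e-5)

  # parent along +Y, symmetric children at +/-45 degrees: tilt 135 each
  rows3 <- list(list(1, "soma", 0, 0, 0, -1), list(2, "axon", 0, 10, 0, 1),
                list(3, "axon", 0, 20, 0, 2),
                list(4, "axon", 10, 30, 0, 3), list(5, "axon", -10, 30, 0, 3))
  m3 <- angle_metrics(toy_neuron(rows3), "axon")
  expect_equal(unname(m3["remote_tilt_angle.avg"]), 135)
  expect_true(is.na(angle_metrics(toy_bifurcating(),
                                  "dendrite")["remote_bifurcation_angle.avg"]))
})

test_that("partition asymmetry formula and the balanced tree", {
  # (l, r) = (3, 1): asymmetry 1 at the root bifurcation
  rows <- list(list(1, "soma", 0, 0, 0, -1), list(2, "axon", 0, 2, 0, 1),
               list(3, "axon", -4, 6, 0, 2), # left subtree with 3 tips
               list(4, "axon", -6, 8, 0, 3), list(5, "axon", -2, 8, 0, 3),
               list(6, "axon", -7, 10, 0, 4), list(7, "axon", -5, 10, 0, 4),
               list(8, "axon", 4, 6, 0, 2))  # right: single tip
  n <- toy_neuron(rows)
  pa <- topology_metrics(n, "axon")
  # bifurcations: root (3 vs 1 -> 1), left inner (2 vs 1 -> 1), and the
  # deepest (1 vs 1 -> 0)
  expect_equal(unname(pa["partition_asymmetry.avg"]), mean(c(1, 1, 0)))

  # full balanced binary tree with 8 tips: all 7 bifurcations at 0
  build_balanced <- function(depth) {
    rows <- list(list(1, "soma", 0, 0, 0, -1), list(2, "axon", 0, 2, 0, 1))
    nid <- 2
    level <- list(list(id = 2, x = 0))
    for (d in seq_len(depth)) {
      nxt <- list()
      for (p in level) {
        for (s in c(-1, 1)) {
          nid <- nid + 1
          rows[[length(rows) + 1]] <-
            list(nid, "axon", p$x + s * 2^(depth - d), d * 4 + 2, 0, p$id)
          nxt[[length(nxt) + 1]] <- list(id = nid, x = p$x + s * 2^(depth - d))
        }
      }
      level <- nxt
    }
    toy_neuron(rows)
  }
  bal <- build_balanced(3)
  expect_equal(unname(topology_metrics(bal, "axon")["partition_asymmetry.avg"]), 0)
})

test_that("terminal branch length and tortuosity", {
  n <- toy_bifurcating()
  m <- terminal_branch_metrics(n, "axon")
  expect_equal(unname(m["t.tortuosity.avg"]), 1)  # straight terminals
  expect_equal(unname(m["t.length.avg"]), sqrt(200))
  expect_equal(unname(m["t.length.med"]), sqrt(200))
  expect_equal(unname(m["t.remote_bifurcation_angle.avg"]),
               unname(angle_metrics(n, "axon")["remote_bifurcation_angle.avg"]))

  # finely discretized half circle: tortuosity -> pi / 2
  th <- seq(0, pi, length.out = 200)
  rows <- c(list(list(1, "soma", -50, 0, 0, -1)),
            lapply(seq_along(th), function(i)
              list(i + 1, "axon", -50 * cos(th[i]), 50 * sin(th[i]), 0,
                   i)))
  half <- toy_neuron(rows)
  m2 <- terminal_branch_metrics(half, "axon")
  expect_equal(unname(m2["t.tortuosity.avg"]), pi / 2, tolerance = 0.01)
})

test_that("summaries agree with a first-principles oracle on random trees", {
  for (seed in 1:20) {
    n <- random_tree(sample(10:30, 1), seed)
    o <- oracle_arbor_stats(n, "axon")
    br <- decompose_branches(n, "axon")
    bm <- branch_metrics(n, "axon", br)
    expect_equal(unname(bm["N_stems"]), o$n_stems)
    expect_equal(unname(bm["terminal_degree"]), o$terminal_degree)
    expect_equal(sort(vapply(br, `[[`, 1, "length")), o$branch_lengths)
    expect_equal(unname(bm["total_length"]),
                 sum(process_segments(n, "axon")$length))
    dm <- distance_metrics(n, "axon")
    expect_equal(unname(dm["euclidean_dist.max"]), o$euclid_max)
    tm <- topology_metrics(n, "axon", br)
    if (length(o$partition_asymmetry) > 0) {
      expect_equal(unname(tm["partition_asymmetry.avg"]),
                   mean(o$partition_asymmetry))
    }
    am <- angle_metrics(n, "axon", br)
    if (length(o$remote_angles) > 0) {
      expect_equal(unname(am["remote_bifurcation_angle.avg"]),
                   mean(o$remote_angles), tolerance = 1e-8)
    }
  }
})

test_that("metric and topological summaries are rotation invariant", {
  inv <- c("length.avg", "length.sd", "length.med", "length.max",
           "total_length", "N_stems", "N_bifurcations", "terminal_degree")
  n <- random_tree(30, 42)
  r <- rotate_neuron(n, axis = c(1, 2, 3), deg = 53)
  expect_equal(branch_metrics(r, "axon")[inv], branch_metrics(n, "axon")[inv])
  expect_equal(distance_metrics(r, "axon"), distance_metrics(n, "axon"),
               tolerance = 1e-8)
  expect_equal(angle_metrics(r, "axon"), angle_metrics(n, "axon"),
               tolerance = 1e-8)
  expect_equal(topology_metrics(r, "axon"), topology_metrics(n, "axon"))
})

test_that("collinear subdivision leaves length and distance metrics fixed", {
  n <- toy_bifurcating()
  s <- subdivide_segments(n)
  keep <- c("length.avg", "length.sd", "length.med", "length.max",
            "total_length", "N_stems", "N_bifurcations", "terminal_degree")
  expect_equal(branch_metrics(s, "axon")[keep], branch_metrics(n, "axon")[keep],
               tolerance = 1e-12)
  expect_equal(distance_metrics(s, "axon"), distance_metrics(n, "axon"),
               tolerance = 1e-9)
  expect_equal(angle_metrics(s, "axon"), angle_metrics(n, "axon"),
               tolerance = 1e-12)
})

test_that("angles, tortuosities and lengths respect their ranges", {
  for (seed in 1:5) {
    n <- generate_neuron(default_templates()$LBC, seed = seed)
    am <- angle_metrics(n, "axon")
    expect_true(am["remote_bifurcation_angle.avg"] >= 0 &&
                am["remote_bifurcation_angle.avg"] <= 180)
    expect_true(am["remote_tilt_angle.avg"] >= 0 &&
                am["remote_tilt_angle.avg"] <= 180)
    expect_true(am["torque_angle.avg"] >= 0 && am["torque_angle.avg"] <= 180)
    tb <- terminal_branch_metrics(n, "axon")
    expect_gte(tb["t.tortuosity.avg"], 1)
    expect_gte(branch_metrics(n, "axon")["length.avg"], 0)
  }
})
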