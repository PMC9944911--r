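test_that("branch probability reduces to the flow fraction at sigma = 1", {
  set.seed(1)
  fa <- runif(200, 0, 5); fb <- runif(200, 0, 5)
  expect_equal(branch_probability(fa, fb, 1), fa / (fa + fb), tolerance = 1e-12)
  expect_equal(branch_probability(3, 1, 1), 0.75, tolerance = 1e-12)
})

test_that("branch probability handles sharpness and atanh limits", {
  expect_equal(branch_probability(3, 1, 1.25), 0.79790720946894,
               tolerance = 1e-10)
  expect_identical(branch_probability(0, 2, 1.5), 0)
  expect_identical(branch_probability(2, 0, 1.5), 1)
  expect_error(branch_probability(0, 0), "zero")
  # always a probability, and p_A + p_B = 1
  set.seed(2)
  fa <- c(runif(100, 0, 10), 0, 1e-12, 1e12)
  fb <- c(runif(100, 0, 10), 1, 1e12, 1e-12)
  for (s in c(1, 1.25, 3, 20)) {
    p <- branch_probability(fa, fb, s)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(p + branch_probability(fb, fa, s), rep(1, length(p)),
                 tolerance = 1e-9)
  }
})

test_that("routing rules: lodge when too wide, larger branch when one is too narrow", {
  expect_identical(choose_branch(2.0, c(1.5, 1.2), c(1, 1))$action, "lodge")
  # larger branch deterministically, regardless of flows
  for (i in 1:10)
    expect_identical(choose_branch(1.3, c(1.5, 1.2), c(1e-6, 100))$child, 1L)
  # Monte Carlo branch choice follows the flows (binomial check)
  set.seed(3)
  picks <- replicate(1e4, choose_branch(0.1, c(1.5, 1.2), c(1, 1))$child)
  expect_lt(abs(mean(picks == 1) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("remobilization arithmetic matches linear dissolution", {
  # full dissolution of a 2.67 mm embolus: 5 and 10 days
  expect_equal(remobilization_time(2.67, 0, 0.533)$time / 24,
               2.67 / 0.533, tolerance = 1e-12)
  expect_equal(round(remobilization_time(2.67, 0, 0.533)$time / 24), 5)
  expect_equal(round(remobilization_time(2.67, 0, 0.267)$time / 24), 10)
  expect_equal(remobilization_time(1.0, 0.8, 0.533)$time, 9.00562851782364,
               tolerance = 1e-10)
  expect_identical(remobilization_time(1.0, 1.0, 0.533)$time, 0)
  expect_identical(remobilization_time(1.0, 0.5, 0)$time, Inf)
})

test_that("tiny emboli exit with no infarct; oversized emboli block everything", {
  tr <- small_tree(); pm <- small_map()
  tiny <- simulate_stroke(tr, 1e-5, transport_config(Delta = 0), perfusion = pm,
                          seed = 1)
  expect_identical(tiny$status, "exited")
  expect_identical(tiny$infarct_pct, 0)

  big <- simulate_stroke(tr, 6, transport_config(Delta = 0), perfusion = pm,
                         seed = 1)
  expect_identical(big$status, "lodged")
  expect_identical(big$lodge_site, tr$root)
  expect_equal(big$infarct_pct, 100, tolerance = 1e-9)
  expect_equal(sum(big$territory_pct), 100, tolerance = 1e-9)
})

test_that("an embolus barely above the terminal scale dissolves before tau", {
  tr <- small_tree(); pm <- small_map()
  dmin <- min(tr$seg$diameter)
  out <- simulate_stroke(tr, dmin * 1.05, transport_config(Delta = 0.533),
                         perfusion = pm, seed = 4)
  expect_identical(out$infarct_pct, 0)   # cleared well inside the 4 h window
  expect_identical(out$status, "exited")
})

test_that("stroke simulation replays identically and clock methods agree", {
  tr <- small_tree(); pm <- small_map()
  for (d in c(0.4, 1.1, 2.3)) {
    a <- simulate_stroke(tr, d, transport_config(), perfusion = pm, seed = 11)
    b <- simulate_stroke(tr, d, transport_config(), perfusion = pm, seed = 11)
    g <- simulate_stroke(tr, d, transport_config(), perfusion = pm, seed = 11,
                         clock_method = "general")
    expect_identical(a$lesioned, b$lesioned)
    expect_identical(a$trajectory, b$trajectory)
    expect_identical(sort(a$lesioned), sort(g$lesioned))
    expect_equal(a$infarct_pct, g$infarct_pct, tolerance = 1e-12)
  }
})

test_that("lodge sites move strictly distally with non-increasing diameter", {
  tr <- small_tree()
  idx <- tr$index
  for (seed in 1:5) {
    out <- simulate_stroke(tr, 1.8, transport_config(), seed = seed)
    traj <- out$trajectory
    expect_true(all(diff(traj$time) >= 0))
    expect_true(all(diff(traj$diameter) <= 1e-12))
    lodges <- traj$segment[traj$event == "lodge"]
    if (length(lodges) > 1) {
      for (k in 2:length(lodges)) {
        expect_gt(idx$tin[lodges[k]], idx$tin[lodges[k - 1]])
        expect_lte(idx$tin[lodges[k]], idx$tout[lodges[k - 1]])
      }
    }
  }
})

test_that("leaf-arrival frequencies follow flow fractions at sigma = 1", {
  tree <- random_binary_tree(8, seed = 77)
  fl <- solve_flows(tree)
  leaves <- which(tree$index$n_children == 0L)
  exits <- integer(0)
  for (i in 1:4000) {
    out <- simulate_stroke(tree, 1e-9, transport_config(Delta = 0), seed = i,
                           keep_trajectory = FALSE)
    exits[i] <- out$trajectory$segment[out$trajectory$event == "exit"]
  }
  obs <- tabulate(factor(exits, levels = leaves), nbins = length(leaves))
  p <- fl$flow[leaves] / sum(fl$flow[leaves])
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 1e-3)
})

test_that("mean infarct volume is non-decreasing in embolus diameter", {
  tr <- small_tree(); ph <- small_phantom(); pm <- small_map()
  co <- run_cohort(tr, ph, diameters = c(0.5, 1, 1.5, 2, 2.5, 3), n = 40,
                   config = transport_config(), master_seed = 9, perfusion = pm)
  m <- tapply(co$infarct_pct, co$diameter, mean)
  expect_true(all(diff(m) >= 0))
})
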