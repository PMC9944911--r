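test_that("cohorts are reproducible with deterministic per-run seeds", {
  tr <- small_tree(); ph <- small_phantom(); pm <- small_map()
  one <- run_cohort(tr, ph, diameters = 1.2, n = 1, master_seed = 4,
                    perfusion = pm)
  expect_identical(nrow(one), 1L)

  a <- run_cohort(tr, ph, diameters = c(0.8, 1.6), n = 5, master_seed = 21,
                  perfusion = pm)
  b <- run_cohort(tr, ph, diameters = c(0.8, 1.6), n = 5, master_seed = 21,
                  perfusion = pm)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(nrow(a), 10L)

  tiny <- run_cohort(tr, ph, distribution = size_distribution("delta", diameter = 1e-5),
                     n = 6, config = transport_config(Delta = 0),
                     master_seed = 3, perfusion = pm)
  expect_true(all(tiny$infarct_pct == 0))
  expect_true(all(tiny$status == "exited"))

  too_big <- size_distribution("flat", min = 0.1, max = 10)
  expect_error(run_cohort(tr, ph, distribution = too_big, n = 2, perfusion = pm),
               "input vessel")
})

test_that("the offset power-law fit recovers noise-free coefficients exactly", {
  d0 <- 4
  d <- diameter_grid(0.3, 3.5, 30)
  dat <- data.frame(diameter = rep(d, each = 3),
                    infarct_pct = 52.4 * ((rep(d, each = 3) - 0.0888) / d0)^3.145)
  fit <- fit_power_law(dat, d0 = d0, tau = 4, Delta = 0.533)
  expect_equal(fit$a, 52.4, tolerance = 1e-6)
  expect_equal(fit$b, 3.145, tolerance = 1e-6)
  expect_equal(fit$d_prime, 0.0888, tolerance = 1e-4)
})

test_that("fitting requires informative cohorts", {
  flat <- data.frame(diameter = c(0.5, 1, 2), infarct_pct = 0)
  expect_error(fit_power_law(flat, d0 = 4, tau = 4, Delta = 0.533),
               "nonzero mean infarct")
})

test_that("the inverted law sizes emboli from infarct volumes", {
  fit <- structure(list(a = 52.4, b = 3.145, d_prime = 0.0888, d0 = 4,
                        tau = 4, Delta = 0.533, se = c(a = NA, b = NA, d_prime = NA)),
                   class = "power_law_fit")
  # infarct = a with no offset returns d0
  expect_equal(embolus_diameter_from_volume(52.4, fit, tau = 0, Delta = 0), 4)
  expect_equal(embolus_diameter_from_volume(6.55, fit),
               4 * (6.55 / 52.4)^(1 / 3.145) + 4 * 0.533 / 24,
               tolerance = 1e-12)
  expect_equal(round(embolus_diameter_from_volume(6.55, fit), 3), 2.154)
  # forward law then inverse law is the identity
  d <- seq(0.5, 3.4, by = 0.3)
  y <- fit$a * ((d - fit$tau * fit$Delta / 24) / fit$d0)^fit$b
  expect_equal(embolus_diameter_from_volume(y, fit), d, tolerance = 1e-12)
  expect_error(embolus_diameter_from_volume(0, fit), "positive")
})

test_that("size distributions validate their parameters", {
  expect_error(size_distribution("delta"), "diameter")
  expect_error(size_distribution("flat", min = 2, max = 1), "min")
  flat <- size_distribution("flat", min = 0.1, max = 2.67)
  set.seed(1)
  dd <- strokesim:::sample_diameters(flat, 1000)
  expect_true(all(dd > 0.1 & dd <= 2.67))
})

test_that("overlap maps are probabilities supported on the brain", {
  tr <- small_tree(); ph <- small_phantom(); pm <- small_map()
  om1 <- overlap_map(tr, ph, size_distribution("delta", diameter = 1.5), n = 1,
                     master_seed = 2, perfusion = pm)
  expect_true(all(om1$prob %in% c(0, 1)))

  om <- overlap_map(tr, ph, size_distribution("flat", min = 0.5, max = 2.67),
                    n = 50, master_seed = 2, perfusion = pm)
  expect_true(all(om$prob >= 0 & om$prob <= 1))
  outside <- ph$tissue == 0L
  expect_true(all(om$prob[outside] == 0))
})

test_that("territory summaries identify blocked hemispheres and quiet cohorts", {
  tr <- small_tree(); ph <- small_phantom(); pm <- small_map()
  quiet <- run_cohort(tr, ph, distribution = size_distribution("delta", diameter = 1e-5),
                      n = 4, config = transport_config(Delta = 0),
                      master_seed = 5, perfusion = pm)
  ts <- territory_lesion_summary(quiet)
  expect_true(all(ts$lesion_frequency == 0))
  expect_true(all(ts$mean_lesion_pct == 0))

  # between the CoW cascade and the trunk diameter: the embolus passes the
  # join, then blocks one whole hemisphere permanently
  hemi <- run_cohort(tr, ph, diameters = 3.8, n = 4,
                     config = transport_config(Delta = 0),
                     master_seed = 6, perfusion = pm)
  expect_true(all(abs(hemi$infarct_pct - 50) < 1))
  ts2 <- territory_lesion_summary(hemi)
  blocked <- ts2$lesion_frequency[ts2$lesion_frequency > 0]
  expect_identical(length(blocked), 3L)   # the three territories of one side
  expect_true(all(blocked == 1))
})

test_that("fits at the two dissolution rates agree on a and b", {
  tr <- small_tree(); ph <- small_phantom(); pm <- small_map()
  d <- diameter_grid(0.5, 3.1, 15)
  f <- lapply(c(0.533, 0.267), function(Delta) {
    co <- run_cohort(tr, ph, diameters = d, n = 15,
                     config = transport_config(Delta = Delta),
                     master_seed = 31, perfusion = pm)
    fit_power_law(co, d_prime = 4 * Delta / 24)
  })
  expect_lt(abs(f[[1]]$a - f[[2]]$a) / f[[1]]$a, 0.2)
  expect_lt(abs(f[[1]]$b - f[[2]]$b) / f[[1]]$b, 0.15)
})
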