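test_that("ischaemia clocks implement the continuous zero-flow criterion", {
  tr <- small_tree()
  n <- length(tr$index$terminals)
  ones <- rep(1, n); zeros <- rep(0, n)

  # zero flow on [0, 3.9] then restored: longest run 3.9 h, no lesion at tau 4
  cl <- leaf_clocks(tr)
  cl <- record_flow_interval(cl, 0, 3.9, zeros)
  cl <- record_flow_interval(cl, 3.9, 10, ones)
  expect_identical(length(lesioned_terminals(cl, 4)), 0L)
  expect_equal(max(cl$longest), 3.9)

  # zero flow on [0, 4.0]: lesion at the threshold
  cl <- leaf_clocks(tr)
  cl <- record_flow_interval(cl, 0, 4.0, zeros)
  cl <- record_flow_interval(cl, 4.0, 5, ones)
  expect_identical(lesioned_terminals(cl, 4), tr$index$terminals)

  # two disjoint 3 h runs separated by restored flow: not continuous
  cl <- leaf_clocks(tr)
  cl <- record_flow_interval(cl, 0, 3, zeros)
  cl <- record_flow_interval(cl, 3, 4, ones)
  cl <- record_flow_interval(cl, 4, 7, zeros)
  cl <- record_flow_interval(cl, 7, 8, ones)
  expect_identical(length(lesioned_terminals(cl, 4)), 0L)

  # an open run at the horizon counts once it reaches tau
  cl <- leaf_clocks(tr)
  cl <- record_flow_interval(cl, 0, 6, zeros)
  expect_identical(lesioned_terminals(cl, 4), tr$index$terminals)
  expect_identical(length(lesioned_terminals(cl, Inf)), 0L)

  # fresh clocks: no lesions
  expect_identical(length(lesioned_terminals(leaf_clocks(tr), 4)), 0L)

  # chronology is enforced
  cl <- record_flow_interval(leaf_clocks(tr), 0, 5, zeros)
  expect_error(record_flow_interval(cl, 2, 3, ones), "out-of-order")
})

test_that("voxel ownership partitions the brain and volumes are consistent", {
  tr <- small_tree(); ph <- small_phantom()
  pm <- small_map()
  expect_identical(length(pm$site_of_voxel), length(ph$brain_idx))
  expect_true(all(pm$site_of_voxel >= 1 & pm$site_of_voxel <= nrow(tr$sites)))
  expect_equal(sum(pm$vol_site), ph$brain_vol)
  expect_equal(sum(pm$vol_terminal), ph$brain_vol)
})

test_that("infarct volume percentages cover the limiting cases", {
  tr <- small_tree(); ph <- small_phantom(); pm <- small_map()
  term <- tr$index$terminals
  expect_identical(infarct_volume_percent(integer(0), ph, tr, pm), 0)
  expect_equal(infarct_volume_percent(term, ph, tr, pm), 100, tolerance = 1e-12)

  # one hemisphere's terminals own half the brain (mirror symmetry)
  right <- term[tr$seg$hemi[term] == "R"]
  expect_lt(abs(infarct_volume_percent(right, ph, tr, pm) - 50), 1)
})

test_that("infarct volume tracks the demand fraction for permanent occlusions", {
  tr <- small_tree(); ph <- small_phantom(); pm <- small_map()
  idx <- tr$index
  demand <- tabulate(tr$site_segment, nrow(tr$seg))
  total <- sum(demand)
  # territory trunks and a few large main branches
  set.seed(5)
  cand <- which(tr$seg$gen == "main" & idx$depth >= 3 & idx$depth <= 6 &
                  idx$n_children == 2L)
  for (s in c(which(!is.na(tr$seg$territory))[1], sample(cand, 5))) {
    distal <- which(idx$tin >= idx$tin[s] & idx$tin <= idx$tout[s])
    les <- intersect(distal, tr$index$terminals)
    vol <- infarct_volume_percent(les, ph, tr, pm)
    dem <- 100 * sum(demand[distal]) / total
    expect_lt(abs(vol - dem), 2)
  }
})

test_that("lesion masks complement to the brain mask and mirror across hemispheres", {
  tr <- small_tree(); ph <- small_phantom(); pm <- small_map()
  term <- tr$index$terminals
  expect_true(all(lesion_mask(integer(0), ph, tr, pm) == 0L))

  some <- term[seq(1, length(term), by = 3)]
  rest <- setdiff(term, some)
  m1 <- lesion_mask(some, ph, tr, pm)
  m2 <- lesion_mask(rest, ph, tr, pm)
  expect_identical((m1 | m2), ph$tissue > 0)
  expect_identical(sum(m1 & m2), 0L)

  right <- term[tr$seg$hemi[term] == "R"]
  left <- term[tr$seg$hemi[term] == "L"]
  mr <- lesion_mask(right, ph, tr, pm)
  ml <- lesion_mask(left, ph, tr, pm)
  nx <- ph$dim[1]
  expect_identical(ml, mr[nx:1, , ])
})
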