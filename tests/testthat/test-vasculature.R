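test_that("Murray root diameter reproduces the printed d0 and closed forms", {
  d0 <- compute_root_diameter(c(3.1, 2.7, 2.6, 1.5), 3.2)
  expect_equal(round(d0), 4)          # printed value
  expect_equal(d0, 4.02722344509753, tolerance = 1e-12)
  expect_equal(compute_root_diameter(2.2, 3.2), 2.2)
  expect_equal(compute_root_diameter(c(1.7, 1.7), 2.9), 2^(1 / 2.9) * 1.7)
  expect_error(compute_root_diameter(numeric(0)), "no branch")
  expect_error(compute_root_diameter(c(1, -1)), "positive")
})

test_that("leaf budgets are apportioned by demand share", {
  expect_identical(strokesim:::apportion_leaves(4096, c(0.75, 0.25)),
                   c(3072L, 1024L))
  b <- strokesim:::apportion_leaves(100, c(5, 3, 1, 0.01))
  expect_identical(sum(b), 100L)
  expect_true(all(b >= 1L))
})

test_that("hemisphere growth respects budgets, Murray law and demand scaling", {
  ph <- small_phantom()
  sites <- sample_perfusion_sites(ph, 2000, rng_seed = 3)
  right <- sites[sites$x > 0, ]
  hemi <- grow_hemisphere_tree(right, n_leaves = 128, rng_seed = 5)
  expect_s3_class(hemi, "vascular_tree")
  expect_identical(nrow(hemi$seg), 2L * 128L)  # trunk + cascade + 2L-4

  # Murray conservation at every bifurcation
  idx <- hemi$index
  bif <- which(idx$n_children == 2L)
  dg <- hemi$seg$diameter^hemi$gamma
  rel <- abs(dg[bif] - dg[idx$child1[bif]] - dg[idx$child2[bif]]) / dg[bif]
  expect_lt(max(rel), 1e-9)

  # demand distal to a main vessel = (d / d_root)^gamma exactly
  trunk <- which(hemi$seg$role == "trunk")
  total <- sum(tabulate(hemi$site_segment, nrow(hemi$seg)))
  mid <- sample(which(idx$n_children == 2L), 20)
  for (s in mid) {
    distal <- which(idx$tin >= idx$tin[s] & idx$tin <= idx$tout[s])
    frac <- sum(tabulate(hemi$site_segment, nrow(hemi$seg))[distal]) / total
    expect_equal((hemi$seg$diameter[s] / hemi$seg$diameter[trunk])^hemi$gamma,
                 frac, tolerance = 1e-9)
  }

  # deterministic given seed
  hemi2 <- grow_hemisphere_tree(right, n_leaves = 128, rng_seed = 5)
  expect_equal(hemi$seg, hemi2$seg)

  # more leaves than sites errors, naming the starved territory
  expect_error(grow_hemisphere_tree(right, n_leaves = nrow(right) + 10),
               "territory")
})

test_that("symmetrization mirrors geometry exactly and doubles the main tree", {
  ph <- small_phantom()
  sites <- sample_perfusion_sites(ph, 1200, rng_seed = 13)
  hemi <- grow_hemisphere_tree(sites[sites$x > 0, ], n_leaves = 64, rng_seed = 2)
  n <- nrow(hemi$seg)
  tree <- symmetrize(hemi)
  expect_identical(nrow(tree$seg), 2L * n + 1L)
  expect_identical(sum(tree$seg$role == "input"), 1L)

  r <- seq_len(n); l <- r + n
  expect_identical(tree$seg$x1[l], -tree$seg$x1[r])
  expect_identical(tree$seg$x0[l], -tree$seg$x0[r])
  expect_identical(tree$seg$diameter[l], tree$seg$diameter[r])
  expect_identical(tree$seg$hemi[r], rep("R", n))
  expect_identical(tree$seg$hemi[l], rep("L", n))

  # site territory labels swap L/R
  ns <- nrow(hemi$sites)
  expect_identical(sub("-R$", "", tree$sites$territory[seq_len(ns)]),
                   sub("-L$", "", tree$sites$territory[seq_len(ns) + ns]))

  # input obeys Murray over the two trunks
  input <- which(tree$seg$role == "input")
  trunkd <- tree$seg$diameter[tree$seg$role == "trunk"][1]
  expect_equal(tree$seg$diameter[input], 2^(1 / tree$gamma) * trunkd,
               tolerance = 1e-12)

  # fragments crossing the plane are rejected
  bad <- hemi
  bad$seg$x1[10] <- -1
  expect_error(symmetrize(bad), "sagittal")
})

test_that("appended subtrees have exact diameter ratios and segment counts", {
  tr <- small_tree()
  expect_identical(sum(tr$seg$gen == "appended"), 62L * 512L)  # 62 per main leaf

  # each appended generation multiplies diameter by 2^(-1/gamma) exactly
  app <- which(tr$seg$gen == "appended")
  par <- tr$seg$parent[app]
  expect_equal(tr$seg$diameter[app],
               tr$seg$diameter[par] * 2^(-1 / tr$gamma), tolerance = 1e-12)

  # closed form: a 44 um leaf yields 14.9 um terminals after 5 generations
  expect_equal(44 * 2^(-5 / 3.2), 14.8968110163058, tolerance = 1e-10)

  # generations = 0 is the identity
  ph <- small_phantom()
  sites <- sample_perfusion_sites(ph, 800, rng_seed = 21)
  hemi <- grow_hemisphere_tree(sites[sites$x > 0, ], n_leaves = 32, rng_seed = 1)
  tree <- symmetrize(hemi)
  expect_identical(append_terminal_subtrees(tree, generations = 0)$seg, tree$seg)
})

test_that("diameter scaling hits the configured d0 and composes", {
  tr <- small_tree()
  trunk <- which(tr$seg$role == "trunk")[1]
  expect_equal(tr$seg$diameter[trunk], compute_root_diameter(), tolerance = 1e-12)
  doubled <- tr
  doubled$seg$diameter <- doubled$seg$diameter * 2
  rescaled <- scale_diameters(doubled)
  expect_equal(rescaled$seg$diameter, tr$seg$diameter, tolerance = 1e-12)
})

test_that("validation reports structural violations and passes default trees", {
  tr <- small_tree()
  expect_identical(nrow(validate_tree(tr)), 0L)

  bad <- tr
  bad$seg$diameter[100] <- -bad$seg$diameter[100]
  v <- validate_tree(bad)
  expect_true(any(v$check == "diameter" & v$segment == 100))

  cyc <- tr
  cyc$seg$parent[tr$root] <- 200L  # root now points into the tree: cycle
  expect_true(any(validate_tree(cyc)$check %in% c("connectivity", "root")))
})
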