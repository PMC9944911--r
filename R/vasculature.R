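#' Murray-law root diameter
#'
#' Combines branch diameters through the bifurcation exponent:
#' `(sum(d_i^gamma))^(1/gamma)`. With the printed diameters of the four
#' major cerebral arteries (MCA 3.1, PCA 2.7, ACA 2.6, CA 1.5 mm) and
#' `gamma = 3.2` this gives the circle-of-Willis input diameter
#' d0 = 4.03 mm (4 mm to the nearest millimetre).
#'
#' @param branch_diameters Positive diameters in mm.
#' @param gamma Bifurcation exponent (> 0).
#' @return The root diameter in mm.
#' @export
compute_root_diameter <- function(branch_diameters = BRANCH_DIAMETERS,
                                  gamma = 3.2) {
  if (length(branch_diameters) == 0) stopf("no branch diameters supplied")
  if (any(branch_diameters <= 0)) stopf("branch diameters must be positive")
  if (gamma <= 0) stopf("gamma must be positive")
  sum(branch_diameters^gamma)^(1 / gamma)
}

territory_group <- function(sites) {
  g <- sub("-[LR]$", "", as.character(sites$territory))
  g[g == "PCAcereb"] <- "PCA"
  g[sites$cerebellum] <- "CA"
  g
}

# largest-remainder apportionment of n leaves by demand weight, >= 1 each
apportion_leaves <- function(n, weights) {
  share <- n * weights / sum(weights)
  base <- pmax(1L, floor(share))
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(share - floor(share), decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(share - floor(share))
    for (i in ord) {
      if (rem == 0) break
      if (base[i] > 1L) { base[i] <- base[i] - 1L; rem <- rem + 1L }
    }
  }
  as.integer(base)
}

new_tree <- function(seg, sites, site_segment, gamma, branch_diameters,
                     seed = NULL, config = list(), d0 = NA_real_,
                     hemisphere = FALSE, symmetric = FALSE) {
  tree <- structure(list(seg = seg, sites = sites,
                         site_segment = site_segment,
                         gamma = gamma, branch_diameters = branch_diameters,
                         d0 = d0, seed = seed, config = config,
                         config_hash = config_hash(config),
                         hemisphere = hemisphere, symmetric = symmetric),
                    class = "vascular_tree")
  finalize_tree(tree)
}

# rebuild the navigation index: children, depth, Euler tour, terminals
finalize_tree <- function(tree) {
  tree$seg$parent <- as.integer(tree$seg$parent)
  tree$site_segment <- as.integer(tree$site_segment)
  seg <- tree$seg
  n <- nrow(seg)
  root <- which(is.na(seg$parent))
  if (length(root) != 1) stopf("tree must have exactly one root")
  idx <- .tree_index(seg$parent, root)
  terminals <- which(idx$n_children == 0L)
  terminals <- terminals[order(idx$tin[terminals])]
  tree$root <- root
  tree$index <- list(child1 = idx$child1, child2 = idx$child2,
                     n_children = idx$n_children, depth = idx$depth,
                     tin = idx$tin, tout = idx$tout,
                     order = order(idx$depth), terminals = terminals,
                     term_tin = idx$tin[terminals])
  tree
}

# bottom-up Murray diameters: leaf diameter ~ demand^(1/gamma).
# d^gamma of a segment equals the summed demand of terminals in its subtree,
# computed from the Euler-tour contiguity of subtrees (fully vectorised).
murray_diameters <- function(seg, index, gamma, leaf_demand) {
  term <- index$terminals                 # sorted by tin
  csum <- cumsum(leaf_demand[term])
  lo <- findInterval(index$tin - 1L, index$term_tin) + 1L
  hi <- findInterval(index$tout, index$term_tin)
  dg <- ifelse(hi >= lo, csum[hi] - c(0, csum)[lo], 0)
  dg^(1 / gamma)
}

#' Grow one hemisphere of the arterial tree
#'
#' Constructive growth on the perfusion sites of one hemisphere (x > 0).
#' Sites are grouped into the MCA, PCA, ACA and CA (cerebellar) territories;
#' each territory receives a leaf budget proportional to its demand share
#' (largest-remainder apportionment). Within a territory, a seeded random
#' ordering of anchor sites is inserted sequentially: each new site becomes a
#' leaf attached by a side-branch bifurcation at the nearest point of the
#' existing territory tree, which reproduces the asymmetric side-branching
#' morphology of real arterial trees. Remaining sites are assigned to their
#' nearest leaf and contribute to its demand. Territory roots are joined by a
#' strictly binary circle-of-Willis cascade ((MCA,PCA),(ACA,CA)) fed by a
#' single hemisphere trunk, so a hemisphere with L leaves has exactly 2L
#' segments. Diameters are assigned bottom-up by flow conservation
#' `d_parent^gamma = d_a^gamma + d_b^gamma` with leaf diameters proportional
#' to demand^(1/gamma).
#'
#' @param sites Perfusion sites of one hemisphere (all x > 0), as returned by
#'   [sample_perfusion_sites()].
#' @param cow_center Circle-of-Willis entry point (mm, on the mid-sagittal
#'   plane).
#' @param n_leaves Total leaf budget for the hemisphere (segment count 2 *
#'   `n_leaves`).
#' @param gamma Bifurcation exponent.
#' @param rng_seed Seed for the insertion order; growth is deterministic
#'   given seed and sites.
#' @param branch_diameters Printed territory artery diameters (recorded on
#'   the tree; the configured d0 is their Murray combination).
#' @return A `vascular_tree` fragment (one hemisphere, unscaled diameters).
#' @export
grow_hemisphere_tree <- function(sites, cow_center = c(0, 0, -40),
                                 n_leaves = 4096, gamma = 3.2,
                                 rng_seed = NULL,
                                 branch_diameters = BRANCH_DIAMETERS) {
  if (nrow(sites) == 0) stopf("no perfusion sites supplied")
  if (any(sites$x <= 0)) stopf("hemisphere sites must lie strictly in x > 0")
  if (n_leaves < 1) stopf("n_leaves must be >= 1")
  grp <- territory_group(sites)
  groups <- intersect(c("MCA", "PCA", "ACA", "CA"), unique(grp))
  if (length(groups) == 0) stopf("no territory groups in sites")
  demand <- vapply(groups, function(g) sum(sites$weight[grp == g]), numeric(1))
  budgets <- apportion_leaves(n_leaves, demand)
  names(budgets) <- groups
  counts <- vapply(groups, function(g) sum(grp == g), numeric(1))
  short <- budgets > counts
  if (any(short))
    stopf("territory %s has %d sites but needs %d leaves",
          groups[short][1], counts[short][1], budgets[short][1])

  # CoW cascade geometry: trunk -> H -> (J1 -> (MCA, PCA), J2 -> (ACA, CA))
  E0 <- c(0, cow_center[2], cow_center[3])
  E1 <- E0 + c(5, 0, 0)
  E2 <- E1 + c(4, 0, 0)
  seg_rows <- list()
  add_seg <- function(prox, dist, parent, territory, role, hemi = "R") {
    seg_rows[[length(seg_rows) + 1]] <<- data.frame(
      parent = parent, x0 = prox[1], y0 = prox[2], z0 = prox[3],
      x1 = dist[1], y1 = dist[2], z1 = dist[3],
      diameter = NA_real_, length = max(sqrt(sum((dist - prox)^2)), 1e-6),
      territory = territory, hemi = hemi, gen = "main", role = role,
      stringsAsFactors = FALSE)
    length(seg_rows)
  }
  id_trunk <- add_seg(E0, E1, NA_integer_, NA_character_, "trunk")
  pair_point <- function(gs) {
    sel <- grp %in% gs
    ctr <- c(mean(sites$x[sel]), mean(sites$y[sel]), mean(sites$z[sel]))
    u <- ctr - E2
    E2 + 5 * u / max(sqrt(sum(u^2)), 1e-9)
  }
  # junction layout depends on how many territories are present
  attach_at <- list(); attach_parent <- list()
  if (length(groups) == 1) {
    id_h <- add_seg(E1, E2, id_trunk, NA_character_, "junction")
    attach_at[[groups[1]]] <- E2; attach_parent[[groups[1]]] <- id_h
  } else if (length(groups) == 2) {
    id_h <- add_seg(E1, E2, id_trunk, NA_character_, "junction")
    for (g in groups) { attach_at[[g]] <- E2; attach_parent[[g]] <- id_h }
  } else {
    id_h <- add_seg(E1, E2, id_trunk, NA_character_, "junction")
    p1 <- groups[1:2]; p2 <- groups[-(1:2)]
    id_j1 <- add_seg(E2, pair_point(p1), id_h, NA_character_, "junction")
    for (g in p1) { attach_at[[g]] <- as.numeric(seg_rows[[id_j1]][, c("x1", "y1", "z1")])
                    attach_parent[[g]] <- id_j1 }
    if (length(p2) == 1) {
      attach_at[[p2]] <- E2; attach_parent[[p2]] <- id_h
    } else {
      id_j2 <- add_seg(E2, pair_point(p2), id_h, NA_character_, "junction")
      for (g in p2) { attach_at[[g]] <- as.numeric(seg_rows[[id_j2]][, c("x1", "y1", "z1")])
                      attach_parent[[g]] <- id_j2 }
    }
  }
  base <- do.call(rbind, seg_rows)

  site_order <- with_seed(rng_seed, sample.int(nrow(sites)))
  all_seg <- list(base)
  offset <- nrow(base)
  site_segment <- integer(nrow(sites))
  leaf_extra <- list()
  for (g in groups) {
    sel <- site_order[grp[site_order] == g]
    anchors <- sel[seq_len(budgets[[g]])]
    extras <- sel[-seq_len(budgets[[g]])]
    xyz <- as.matrix(sites[anchors, c("x", "y", "z")])
    grown <- .grow_cco(attach_at[[g]], xyz, 0.05)
    ns <- nrow(grown$prox)
    segs <- data.frame(
      parent = ifelse(is.na(grown$parent), attach_parent[[g]],
                      grown$parent + offset),
      x0 = grown$prox[, 1], y0 = grown$prox[, 2], z0 = grown$prox[, 3],
      x1 = grown$dist[, 1], y1 = grown$dist[, 2], z1 = grown$dist[, 3],
      diameter = NA_real_,
      length = pmax(sqrt(rowSums((grown$dist - grown$prox)^2)), 1e-6),
      territory = g, hemi = "R", gen = "main", role = "vessel",
      stringsAsFactors = FALSE)
    is_leaf <- !is.na(grown$site)
    site_segment[anchors[grown$site[is_leaf]]] <- which(is_leaf) + offset
    if (length(extras) > 0) {
      leaf_xyz <- xyz[grown$site[is_leaf], , drop = FALSE]
      cell <- max((diff(range(leaf_xyz[, 1])) + 1) / 20, 1)
      nn <- .nn_index_grid(leaf_xyz, as.matrix(sites[extras, c("x", "y", "z")]), cell)
      site_segment[extras] <- (which(is_leaf)[nn]) + offset
    }
    all_seg[[length(all_seg) + 1]] <- segs
    offset <- offset + ns
  }
  seg <- do.call(rbind, all_seg)
  rownames(seg) <- NULL

  tree <- new_tree(seg, sites, site_segment, gamma, branch_diameters,
                   seed = rng_seed, hemisphere = TRUE,
                   config = list(n_leaves = n_leaves, gamma = gamma,
                                 cow_center = cow_center))
  leaf_demand <- numeric(nrow(seg))
  tab <- tabulate(site_segment, nbins = nrow(seg))
  leaf_demand[] <- tab
  tree$seg$diameter <- murray_diameters(tree$seg, tree$index, gamma, leaf_demand)
  tree
}

#' Mirror a hemisphere about the sagittal plane and join at a single input
#'
#' Creates the left hemisphere as an exact mirror copy (x -> -x, territory
#' labels swapped L/R) and joins both hemisphere trunks under a single input
#' segment on the mid-sagittal plane with diameter `2^(1/gamma)` times the
#' trunk diameter, so flow conservation holds at the join. The main tree
#' below the input has twice the hemisphere's segment count.
#'
#' @param hemisphere A `vascular_tree` fragment from [grow_hemisphere_tree()]
#'   lying entirely in x >= 0.
#' @return A symmetric `vascular_tree`.
#' @export
symmetrize <- function(hemisphere) {
  stopifnot(inherits(hemisphere, "vascular_tree"))
  if (!isTRUE(hemisphere$hemisphere)) stopf("tree is not a hemisphere fragment")
  seg <- hemisphere$seg
  if (min(seg$x0, seg$x1) < -1e-9)
    stopf("hemisphere fragment crosses the mid-sagittal plane")
  n <- nrow(seg)
  left <- seg
  left$x0 <- -left$x0; left$x1 <- -left$x1
  left$hemi <- "L"
  left$parent <- left$parent + n
  right_root <- which(is.na(seg$parent))

  input_len <- 10
  root_prox <- c(seg$x0[right_root], seg$y0[right_root], seg$z0[right_root])
  input <- data.frame(parent = NA_integer_,
                      x0 = 0, y0 = root_prox[2], z0 = root_prox[3] - input_len,
                      x1 = 0, y1 = root_prox[2], z1 = root_prox[3],
                      diameter = 2^(1 / hemisphere$gamma) * seg$diameter[right_root],
                      length = input_len, territory = NA_character_,
                      hemi = "C", gen = "main", role = "input",
                      stringsAsFactors = FALSE)
  seg2 <- rbind(seg, left, input)
  input_id <- 2L * n + 1L
  seg2$parent[right_root] <- input_id
  seg2$parent[right_root + n] <- input_id

  sites <- hemisphere$sites
  mirror_sites <- sites
  mirror_sites$x <- -mirror_sites$x
  swap <- function(s) {
    out <- sub("-R$", "-TMP", s)
    out <- sub("-L$", "-R", out)
    sub("-TMP$", "-L", out)
  }
  mirror_sites$territory <- swap(as.character(sites$territory))
  sites2 <- rbind(sites, mirror_sites)
  rownames(sites2) <- NULL
  site_segment2 <- c(hemisphere$site_segment, hemisphere$site_segment + n)

  new_tree(seg2, sites2, site_segment2, hemisphere$gamma,
           hemisphere$branch_diameters, seed = hemisphere$seed,
           config = hemisphere$config, d0 = hemisphere$d0,
           hemisphere = FALSE, symmetric = TRUE)
}

#' Append symmetric terminal subtrees to every main-tree leaf
#'
#' Each main-tree leaf gains a symmetric binary subtree of `generations`
#' levels (default 5, giving 32 terminal vessels and 62 appended segments per
#' leaf). Each generation multiplies the diameter by `2^(-1/gamma)` exactly
#' and the length by `length_ratio`. The leaf's perfusion sites are
#' partitioned over the terminals by continued principal-axis bisection;
#' terminals beyond the site count inherit the leaf position and carry no
#' tissue volume.
#'
#' @param tree A `vascular_tree`.
#' @param generations Number of bifurcation generations to append (0 leaves
#'   the tree unchanged).
#' @param gamma Bifurcation exponent (defaults to the tree's).
#' @param length_ratio Per-generation length factor (space-filling default
#'   `2^(-1/3)`; lengths only enter resistances).
#' @return The augmented `vascular_tree`.
#' @export
append_terminal_subtrees <- function(tree, generations = 5,
                                     gamma = tree$gamma,
                                     length_ratio = 2^(-1 / 3)) {
  stopifnot(inherits(tree, "vascular_tree"))
  if (generations < 0) stopf("generations must be >= 0")
  if (generations == 0) return(tree)
  seg <- tree$seg
  leaves <- which(tree$index$n_children == 0L)
  L <- length(leaves)
  u <- cbind(seg$x1 - seg$x0, seg$y1 - seg$y0, seg$z1 - seg$z0)[leaves, , drop = FALSE]
  nu <- sqrt(rowSums(u^2)); nu[nu < 1e-9] <- 1
  u <- u / nu
  # orthonormal frame per leaf
  ref <- ifelse(abs(u[, 3]) < 0.9, 3, 1)
  e <- matrix(0, L, 3); e[cbind(seq_len(L), ref)] <- 1
  p <- cbind(u[, 2] * e[, 3] - u[, 3] * e[, 2],
             u[, 3] * e[, 1] - u[, 1] * e[, 3],
             u[, 1] * e[, 2] - u[, 2] * e[, 1])
  p <- p / sqrt(rowSums(p^2))
  q <- cbind(u[, 2] * p[, 3] - u[, 3] * p[, 2],
             u[, 3] * p[, 1] - u[, 1] * p[, 3],
             u[, 1] * p[, 2] - u[, 2] * p[, 1])

  blocks <- list()
  offset <- nrow(seg)
  prev_ids <- matrix(leaves, nrow = L)            # gen 0 = the leaves
  prev_tip <- cbind(seg$x1, seg$y1, seg$z1)[leaves, , drop = FALSE]
  prev_tips <- list(prev_tip)                      # one matrix per branch col
  for (k in seq_len(generations)) {
    nb <- 2^k
    dk_k <- seg$diameter[leaves] * 2^(-k / gamma)
    lk_k <- pmax(seg$length[leaves] * length_ratio^k, 1e-6)
    parent_mat <- prev_ids[, rep(seq_len(nb / 2), each = 2), drop = FALSE]
    ids <- matrix(offset + seq_len(L * nb), nrow = L)
    rows <- vector("list", nb)
    tips <- vector("list", nb)
    for (b in seq_len(nb)) {
      side <- if (b %% 2 == 1) 1 else -1
      perp <- if (k %% 2 == 1) p else q
      dir <- u + 0.45 * side * perp
      dir <- dir / sqrt(rowSums(dir^2))
      start <- prev_tips[[ceiling(b / 2)]]
      tip <- start + dir * lk_k
      rows[[b]] <- data.frame(
        parent = parent_mat[, b],
        x0 = start[, 1], y0 = start[, 2], z0 = start[, 3],
        x1 = tip[, 1], y1 = tip[, 2], z1 = tip[, 3],
        diameter = dk_k, length = lk_k,
        territory = seg$territory[leaves], hemi = seg$hemi[leaves],
        gen = "appended", role = "vessel", stringsAsFactors = FALSE)
      tips[[b]] <- tip
    }
    # ids are column-major over (leaf, branch); rbind(rows) lays the block out
    # in the same order, so id (b-1)*L + i matches row (b-1)*L + i.
    blocks[[k]] <- do.call(rbind, rows)
    prev_ids <- ids
    prev_tips <- tips
    offset <- offset + L * nb
  }
  seg2 <- rbind(seg, do.call(rbind, blocks))
  rownames(seg2) <- NULL

  # partition each leaf's sites over its terminals by continued bisection
  site_segment <- tree$site_segment
  xyz <- as.matrix(tree$sites[, c("x", "y", "z")])
  first_new <- nrow(seg) + 1L
  # terminal ids of leaf i: last generation ids matrix row i
  term_ids <- prev_ids
  by_leaf <- split(seq_along(site_segment), factor(site_segment, levels = leaves))
  for (i in seq_len(L)) {
    s <- by_leaf[[i]]
    if (length(s) == 0) next
    sets <- list(s)
    for (k in seq_len(generations)) {
      nxt <- vector("list", 2 * length(sets))
      for (j in seq_along(sets)) {
        ss <- sets[[j]]
        if (length(ss) <= 1) { nxt[[2 * j - 1]] <- ss; nxt[[2 * j]] <- integer(0) }
        else {
          pts <- xyz[ss, , drop = FALSE]
          ctr <- colMeans(pts)
          cv <- crossprod(sweep(pts, 2, ctr))
          ax <- eigen(cv, symmetric = TRUE)$vectors[, 1]
          pr <- as.numeric(pts %*% ax)
          ord2 <- order(pr, ss)
          half <- ceiling(length(ss) / 2)
          nxt[[2 * j - 1]] <- ss[ord2[seq_len(half)]]
          nxt[[2 * j]] <- ss[ord2[-seq_len(half)]]
        }
      }
      sets <- nxt
    }
    for (b in seq_along(sets))
      if (length(sets[[b]]) > 0) site_segment[sets[[b]]] <- term_ids[i, b]
  }

  tree$seg <- seg2
  tree$site_segment <- site_segment
  finalize_tree(tree)
}

#' Scale all diameters so the hemisphere root matches the configured d0
#'
#' Multiplies every diameter by one global constant so that the
#' circle-of-Willis level diameter (the hemisphere trunk) equals
#' `target_d0`, the Murray combination of the configured territory artery
#' diameters by default. Records `d0` on the tree.
#'
#' @param tree A `vascular_tree`.
#' @param target_d0 Target trunk diameter in mm.
#' @return The rescaled tree.
#' @export
scale_diameters <- function(tree,
                            target_d0 = compute_root_diameter(
                              tree$branch_diameters, tree$gamma)) {
  stopifnot(inherits(tree, "vascular_tree"))
  trunk <- which(tree$seg$role == "trunk")[1]
  if (is.na(trunk)) trunk <- tree$root
  s <- target_d0 / tree$seg$diameter[trunk]
  tree$seg$diameter <- tree$seg$diameter * s
  tree$d0 <- target_d0
  tree
}

#' Build the full default vasculature
#'
#' One-call pipeline: sample perfusion sites on the phantom, grow the right
#' hemisphere, mirror and join ([symmetrize()]), append terminal subtrees and
#' scale diameters to the configured d0. Deterministic given `seed`.
#'
#' @param phantom A [build_phantom()] result.
#' @param leaves_per_hemisphere Main-tree leaf budget per hemisphere
#'   (default 4096, i.e. 8192 main segments per hemisphere and 16,384 after
#'   symmetrization, excluding the joining input).
#' @param sites_per_leaf Average perfusion sites sampled per leaf.
#' @param generations Appended-subtree generations (default 5 -> 32
#'   terminals per leaf).
#' @param gamma Bifurcation exponent.
#' @param branch_diameters Territory artery diameters (mm).
#' @param grey_white_demand_ratio Grey:white metabolic demand ratio.
#' @param seed Master seed for site sampling and growth.
#' @param cow_center Circle-of-Willis entry point.
#' @return A finalized, scaled `vascular_tree`.
#' @export
build_vasculature <- function(phantom,
                              leaves_per_hemisphere = 4096,
                              sites_per_leaf = 4,
                              generations = 5,
                              gamma = 3.2,
                              branch_diameters = BRANCH_DIAMETERS,
                              grey_white_demand_ratio = 3,
                              seed = 1,
                              cow_center = c(0, 0, -40)) {
  n_sample <- 2L * as.integer(leaves_per_hemisphere * sites_per_leaf)
  sites <- sample_perfusion_sites(phantom, n_sample,
                                  grey_white_demand_ratio,
                                  rng_seed = derive_seed(seed, 1))
  right <- sites[sites$x > 0, , drop = FALSE]
  rownames(right) <- NULL
  hemi <- grow_hemisphere_tree(right, cow_center = cow_center,
                               n_leaves = leaves_per_hemisphere,
                               gamma = gamma, rng_seed = derive_seed(seed, 2),
                               branch_diameters = branch_diameters)
  tree <- symmetrize(hemi)
  tree <- append_terminal_subtrees(tree, generations = generations, gamma = gamma)
  tree <- scale_diameters(tree)
  tree$seed <- seed
  tree$config <- list(leaves_per_hemisphere = leaves_per_hemisphere,
                      sites_per_leaf = sites_per_leaf,
                      generations = generations, gamma = gamma,
                      branch_diameters = branch_diameters,
                      grey_white_demand_ratio = grey_white_demand_ratio,
                      seed = seed, cow_center = cow_center,
                      phantom = phantom$config)
  tree$config_hash <- config_hash(tree$config)
  tree
}

#' @export
print.vascular_tree <- function(x, ...) {
  n_main <- sum(x$seg$gen == "main" & x$seg$role != "input")
  n_app <- sum(x$seg$gen == "appended")
  cat("vascular_tree:", nrow(x$seg), "segments (", n_main, "main,", n_app,
      "appended ),", length(x$index$terminals), "terminals\n")
  cat("  gamma =", x$gamma, "; d0 =", format(x$d0, digits = 4),
      "mm; diameters", format(min(x$seg$diameter) * 1000, digits = 3), "um -",
      format(max(x$seg$diameter), digits = 3), "mm\n")
  invisible(x)
}

#' Validate structural invariants of a vascular tree
#'
#' Report-only checks: connectivity and acyclicity, binary branching (a
#' single-child pass-through is allowed only for the hemisphere trunk and
#' joining input), positive diameters and lengths, Murray flow conservation
#' at every bifurcation, and exact mirror symmetry of the main tree for
#' symmetrized trees.
#'
#' @param tree A `vascular_tree`.
#' @param tol Relative tolerance for Murray conservation.
#' @return A data.frame of violations (zero rows if the tree is valid).
#' @export
validate_tree <- function(tree, tol = 1e-9) {
  v <- list()
  add <- function(check, segment, message)
    v[[length(v) + 1]] <<- data.frame(check = check, segment = segment,
                                      message = message)
  seg <- tree$seg
  roots <- which(is.na(seg$parent))
  if (length(roots) != 1) {
    add("root", NA_integer_,
        sprintf("tree has %d roots; exactly one required", length(roots)))
    return(do.call(rbind, v))
  }
  idx <- tryCatch(.tree_index(seg$parent, roots),
                  error = function(e) e)
  if (inherits(idx, "error")) {
    add("connectivity", NA_integer_, conditionMessage(idx))
    return(do.call(rbind, v))
  }
  if (sum(is.na(seg$parent)) != 1)
    add("root", NA_integer_, "tree must have exactly one root")
  bad <- which(seg$diameter <= 0 | is.na(seg$diameter))
  for (i in bad) add("diameter", i, sprintf("segment %d: non-positive diameter", i))
  bad <- which(seg$length <= 0 | is.na(seg$length))
  for (i in bad) add("length", i, sprintf("segment %d: non-positive length", i))
  one <- which(idx$n_children == 1L & !seg$role %in% c("trunk", "input"))
  for (i in one) add("branching", i, sprintf("segment %d: single child", i))
  bif <- which(idx$n_children == 2L)
  dg <- seg$diameter^tree$gamma
  rel <- abs(dg[bif] - (dg[idx$child1[bif]] + dg[idx$child2[bif]])) / dg[bif]
  for (i in bif[rel > tol])
    add("murray", i, sprintf("segment %d: flow conservation violated", i))
  if (isTRUE(tree$symmetric)) {
    main <- which(seg$gen == "main" & seg$role != "input")
    n <- length(main) / 2
    r <- main[seq_len(n)]; l <- main[seq_len(n) + n]
    if (any(abs(seg$x0[r] + seg$x0[l]) > 1e-9) ||
        any(abs(seg$x1[r] + seg$x1[l]) > 1e-9) ||
        any(abs(seg$y1[r] - seg$y1[l]) > 1e-9) ||
        any(abs(seg$diameter[r] - seg$diameter[l]) > 1e-9))
      add("symmetry", NA_integer_, "main tree is not mirror-symmetric")
  }
  if (length(v) == 0)
    data.frame(check = character(0), segment = integer(0), message = character(0))
  else do.call(rbind, v)
}
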