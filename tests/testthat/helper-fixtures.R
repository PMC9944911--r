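# Shared fixtures, memoized across test files within a session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

small_phantom <- function() {
  fixture("ph4", build_phantom(phantom_config(spacing = 4)))
}

# 256 leaves/hemisphere, full 5 appended generations: fast but deep enough
# for transport and trial properties
small_tree <- function() {
  fixture("tr256", build_vasculature(small_phantom(),
                                     leaves_per_hemisphere = 256,
                                     sites_per_leaf = 4, generations = 5,
                                     seed = 7))
}

small_map <- function() fixture("pm256", perfusion_map(small_tree(), small_phantom()))

# full-scale fixtures used by the acceptance tests
full_phantom <- function() fixture("ph2", build_phantom(phantom_config(spacing = 2)))
full_tree <- function() {
  fixture("tr4096", build_vasculature(full_phantom(),
                                      leaves_per_hemisphere = 4096,
                                      sites_per_leaf = 4, generations = 5,
                                      seed = 42))
}
full_map <- function() fixture("pm4096", perfusion_map(full_tree(), full_phantom()))

# random strictly binary tree with arbitrary diameters/lengths (valid for the
# flow solver; not Murray-consistent on purpose)
random_binary_tree <- function(n_leaves, seed) {
  set.seed(seed)
  parent <- NA_integer_
  for (k in seq_len(n_leaves - 1)) {
    idx <- strokesim:::.tree_index(parent, 1L)
    leaves <- which(idx$n_children == 0L)
    pick <- if (length(leaves) == 1) leaves else sample(leaves, 1)
    parent <- c(parent, pick, pick)
  }
  n <- length(parent)
  seg <- data.frame(parent = parent,
                    x0 = 0, y0 = 0, z0 = 0,
                    x1 = runif(n), y1 = runif(n), z1 = runif(n),
                    diameter = runif(n, 0.6, 1.6),
                    length = runif(n, 0.5, 2),
                    territory = NA_character_, hemi = "R",
                    gen = "main", role = "vessel",
                    stringsAsFactors = FALSE)
  strokesim:::new_tree(seg, sites = data.frame(), site_segment = integer(0),
                       gamma = 3.2, branch_diameters = BRANCH_DIAMETERS)
}

# dense nodal-pressure oracle: terminals grounded, input_flow injected at the
# inlet node; occlusions as near-infinite resistances
kirchhoff_flows <- function(tree, occlusions = integer(0), input_flow = 1) {
  seg <- tree$seg
  n <- nrow(seg)
  R <- seg$length / seg$diameter^4
  R[occlusions] <- 1e14 * max(R)
  term <- which(tree$index$n_children == 0L)
  unknown <- c(0L, setdiff(seq_len(n), term))  # node 0 = inlet
  m <- length(unknown)
  G <- matrix(0, m, m); rhs <- numeric(m)
  rhs[1] <- input_flow
  nid <- function(node) match(node, unknown)
  for (i in seq_len(n)) {
    g <- 1 / R[i]
    u <- if (is.na(seg$parent[i])) 0L else seg$parent[i]
    iu <- nid(u); iv <- nid(i)
    if (!is.na(iu)) G[iu, iu] <- G[iu, iu] + g
    if (!is.na(iv)) G[iv, iv] <- G[iv, iv] + g
    if (!is.na(iu) && !is.na(iv)) {
      G[iu, iv] <- G[iu, iv] - g
      G[iv, iu] <- G[iv, iu] - g
    }
  }
  p <- numeric(n + 1)  # node pressures, index node+1; terminals stay 0
  p[unknown + 1L] <- solve(G, rhs)
  flow <- numeric(n)
  for (i in seq_len(n)) {
    u <- if (is.na(seg$parent[i])) 0L else seg$parent[i]
    flow[i] <- (p[u + 1L] - p[i + 1L]) / R[i]
  }
  flow
}
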