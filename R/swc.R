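#' Write a vascular tree as SWC plus a JSON attribute sidecar
#'
#' Geometry goes to `<path>.swc` (node 1 is the root's proximal vertex;
#' node i+1 is segment i's distal endpoint with radius = diameter/2 and a
#' type code equal to the territory index in [TERRITORY_LEVELS], 0 for
#' trunk/junction/input segments). Everything SWC cannot carry (gamma, d0,
#' territory/generation/role labels, explicit lengths, perfusion sites and
#' their terminal assignment, seed, config hash) goes to `<path>.json`.
#' `read_tree(write_tree(tree))` reproduces all fields up to float
#' round-trip.
#'
#' @param tree A `vascular_tree`.
#' @param path Base path (an `.swc` extension is stripped).
#' @return Invisibly, the two file paths.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "vascular_tree"))
  base <- sub("\\.swc$", "", path)
  seg <- tree$seg
  n <- nrow(seg)
  code <- integer(n)
  lab <- ifelse(is.na(seg$territory) | seg$hemi == "C", NA,
                paste0(sub("^PCA$", "PCAcereb", seg$territory), "-", seg$hemi))
  code <- match(lab, TERRITORY_LEVELS)
  code[is.na(code)] <- 0L
  root <- tree$root
  lines <- c(
    "# strokesim vascular tree (id type x y z radius parent)",
    sprintf("1 1 %.17g %.17g %.17g %.17g -1",
            seg$x0[root], seg$y0[root], seg$z0[root], seg$diameter[root] / 2),
    sprintf("%d %d %.17g %.17g %.17g %.17g %d",
            seq_len(n) + 1L, code, seg$x1, seg$y1, seg$z1, seg$diameter / 2,
            ifelse(is.na(seg$parent), 1L, seg$parent + 1L)))
  writeLines(lines, paste0(base, ".swc"))

  sidecar <- list(
    format = "strokesim-tree", version = 1L,
    gamma = tree$gamma, d0 = tree$d0,
    branch_diameters = as.list(tree$branch_diameters),
    seed = tree$seed, config_hash = tree$config_hash,
    hemisphere = isTRUE(tree$hemisphere), symmetric = isTRUE(tree$symmetric),
    segments = list(territory = seg$territory, hemi = seg$hemi,
                    gen = seg$gen, role = seg$role, length = seg$length),
    sites = tree$sites, site_segment = tree$site_segment)
  jsonlite::write_json(sidecar, paste0(base, ".json"),
                       digits = NA, auto_unbox = TRUE, na = "null",
                       null = "null")
  invisible(c(paste0(base, ".swc"), paste0(base, ".json")))
}

#' Read a vascular tree written by [write_tree()]
#'
#' @param path Base path or `.swc` path; the `.json` sidecar must sit next
#'   to it.
#' @return A `vascular_tree`.
#' @export
read_tree <- function(path) {
  base <- sub("\\.swc$", "", path)
  swc_path <- paste0(base, ".swc"); json_path <- paste0(base, ".json")
  if (!file.exists(swc_path)) stopf("SWC file not found: %s", swc_path)
  if (!file.exists(json_path))
    stopf("missing JSON sidecar next to SWC: %s", json_path)
  raw <- readLines(swc_path)
  body <- which(!grepl("^\\s*(#|$)", raw))
  if (length(body) == 0) stopf("%s: empty SWC file", swc_path)
  parts <- strsplit(trimws(raw[body]), "\\s+")
  bad <- which(lengths(parts) != 7)
  if (length(bad))
    stopf("%s line %d: expected 7 SWC columns", swc_path, body[bad[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 7, byrow = TRUE)
  nas <- which(rowSums(is.na(m)) > 0)
  if (length(nas))
    stopf("%s line %d: non-numeric SWC field", swc_path, body[nas[1]])
  ids <- as.integer(m[, 1]); par <- as.integer(m[, 7])
  pos <- match(par, ids)
  orphan <- which(par != -1 & is.na(pos))
  if (length(orphan))
    stopf("%s line %d: parent id %d not defined", swc_path, body[orphan[1]],
          par[orphan[1]])
  if (sum(par == -1) != 1) stopf("%s: SWC must have exactly one root node", swc_path)

  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (!identical(side$format, "strokesim-tree"))
    stopf("%s: not a strokesim tree sidecar", json_path)

  seg_nodes <- which(par != -1)             # every non-root node is a segment
  n <- length(seg_nodes)
  node_of_seg <- seg_nodes
  seg_of_node <- match(seq_len(nrow(m)), node_of_seg)  # node row -> segment id
  parent_seg <- seg_of_node[pos[seg_nodes]]            # NA when parent is node 1
  sa <- side$segments
  if (length(sa$territory) != n)
    stopf("%s: sidecar has %d segments, SWC has %d", json_path,
          length(sa$territory), n)
  seg <- data.frame(
    parent = parent_seg,
    x0 = m[pos[seg_nodes], 3], y0 = m[pos[seg_nodes], 4], z0 = m[pos[seg_nodes], 5],
    x1 = m[seg_nodes, 3], y1 = m[seg_nodes, 4], z1 = m[seg_nodes, 5],
    diameter = 2 * m[seg_nodes, 6],
    length = as.numeric(sa$length),
    territory = as.character(sa$territory), hemi = as.character(sa$hemi),
    gen = as.character(sa$gen), role = as.character(sa$role),
    stringsAsFactors = FALSE)
  sites <- as.data.frame(side$sites)
  tree <- new_tree(seg, sites, as.integer(side$site_segment),
                   gamma = side$gamma,
                   branch_diameters = unlist(side$branch_diameters),
                   seed = side$seed, d0 = side$d0 %||% NA_real_,
                   hemisphere = isTRUE(side$hemisphere),
                   symmetric = isTRUE(side$symmetric))
  tree$config_hash <- side$config_hash
  tree
}
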