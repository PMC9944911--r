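#' Per-terminal ischaemia clocks
#'
#' Tracks, for every terminal vessel, the start of the current continuous
#' zero-flow interval and the longest completed zero-flow interval.
#'
#' @param tree A `vascular_tree`.
#' @return An object of class `leaf_clocks`.
#' @export
leaf_clocks <- function(tree) {
  n <- length(tree$index$terminals)
  structure(list(terminals = tree$index$terminals,
                 cur_start = rep(NA_real_, n),
                 longest = numeric(n),
                 t_last = 0),
            class = "leaf_clocks")
}

#' Record one piecewise-constant flow interval on the ischaemia clocks
#'
#' Flow is piecewise constant between events. Terminals with zero flow over
#' `[t_start, t_end]` accumulate (a new zero-flow run opens at `t_start` if
#' none is open); terminals with positive flow close any open run at
#' `t_start`. Intervals must be supplied in chronological order.
#'
#' @param clocks A [leaf_clocks()] object.
#' @param t_start,t_end Interval bounds in hours, `t_end >= t_start >=`
#'   the previous interval's end.
#' @param leaf_flows Numeric vector of terminal flows aligned with
#'   `clocks$terminals` (see [terminal_flows()]).
#' @return The updated clocks.
#' @export
record_flow_interval <- function(clocks, t_start, t_end, leaf_flows) {
  stopifnot(inherits(clocks, "leaf_clocks"))
  if (length(leaf_flows) != length(clocks$terminals))
    stopf("leaf_flows must have one entry per terminal")
  if (t_end < t_start) stopf("interval end precedes its start")
  if (t_start < clocks$t_last - 1e-12)
    stopf("out-of-order interval: starts at %g before previous end %g",
          t_start, clocks$t_last)
  pos <- leaf_flows > 0
  closing <- pos & !is.na(clocks$cur_start)
  if (any(closing)) {
    clocks$longest[closing] <- pmax(clocks$longest[closing],
                                    t_start - clocks$cur_start[closing])
    clocks$cur_start[closing] <- NA_real_
  }
  opening <- !pos & is.na(clocks$cur_start)
  clocks$cur_start[opening] <- t_start
  clocks$t_last <- t_end
  clocks
}

#' Terminals whose longest continuous zero-flow interval reaches tau
#'
#' Open zero-flow runs are closed at the last recorded time, so an interval
#' still open at the simulation horizon counts if it already reaches `tau`.
#'
#' @param clocks A [leaf_clocks()] object.
#' @param tau Ischaemia threshold in hours.
#' @return Integer ids of lesioned terminal segments.
#' @export
lesioned_terminals <- function(clocks, tau) {
  stopifnot(inherits(clocks, "leaf_clocks"))
  eff <- clocks$longest
  open <- !is.na(clocks$cur_start)
  eff[open] <- pmax(eff[open], clocks$t_last - clocks$cur_start[open])
  clocks$terminals[eff >= tau]
}

#' Map brain voxels to owning terminals
#'
#' Every brain voxel is assigned to its nearest perfusion site (Euclidean
#' distance, ties to the lowest site index) and through it to the terminal
#' segment that owns the site, partitioning the brain among terminals.
#' Precomputed once per (tree, phantom) pair and reused across a cohort.
#'
#' @param tree A `vascular_tree` whose sites were sampled on `phantom`.
#' @param phantom The [build_phantom()] result.
#' @return An object of class `perfusion_map` with per-voxel site ids,
#'   per-site and per-terminal tissue volumes, and per-territory volumes.
#' @export
perfusion_map <- function(tree, phantom) {
  stopifnot(inherits(tree, "vascular_tree"), inherits(phantom, "brain_phantom"))
  xyz <- as.matrix(tree$sites[, c("x", "y", "z")])
  cell <- max((phantom$brain_vol / nrow(xyz))^(1 / 3) * 1.5, phantom$spacing)
  site_of_voxel <- .nn_index_grid(xyz, phantom$brain_xyz, cell)
  vol_site <- tabulate(site_of_voxel, nbins = nrow(xyz)) * phantom$voxel_vol
  terminal_of_site <- tree$site_segment
  vol_terminal <- numeric(nrow(tree$seg))
  agg <- rowsum(vol_site, terminal_of_site)
  vol_terminal[as.integer(rownames(agg))] <- agg[, 1]
  site_territory <- as.character(tree$sites$territory)
  structure(list(site_of_voxel = site_of_voxel,
                 terminal_of_site = terminal_of_site,
                 vol_site = vol_site,
                 vol_terminal = vol_terminal,
                 site_territory = site_territory,
                 brain_vol = phantom$brain_vol,
                 dim = phantom$dim, brain_idx = phantom$brain_idx,
                 affine = phantom$affine),
            class = "perfusion_map")
}

# infarct % and per-territory breakdown for a lesioned-terminal set
lesion_volumes <- function(lesioned, perfusion) {
  les_flag <- logical(length(perfusion$vol_terminal))
  les_flag[lesioned] <- TRUE
  sel <- les_flag[perfusion$terminal_of_site]
  pct <- setNames(numeric(length(TERRITORY_LEVELS)), TERRITORY_LEVELS)
  if (any(sel)) {
    agg <- rowsum(perfusion$vol_site[sel], perfusion$site_territory[sel])
    pct[rownames(agg)] <- 100 * agg[, 1] / perfusion$brain_vol
  }
  list(infarct_pct = 100 * sum(perfusion$vol_terminal[lesioned]) / perfusion$brain_vol,
       territory_pct = pct)
}

#' Infarct volume as a percentage of brain volume
#'
#' The volume of all voxels owned by lesioned terminals, as a percentage of
#' total brain volume.
#'
#' @param lesioned Integer ids of lesioned terminal segments.
#' @param phantom The phantom (used to build `perfusion` if not supplied).
#' @param tree The vascular tree.
#' @param perfusion Optional precomputed [perfusion_map()].
#' @return Infarct volume in percent (0..100).
#' @export
infarct_volume_percent <- function(lesioned, phantom, tree, perfusion = NULL) {
  if (is.null(perfusion)) perfusion <- perfusion_map(tree, phantom)
  lesion_volumes(lesioned, perfusion)$infarct_pct
}

#' Voxel mask of a lesion
#'
#' @inheritParams infarct_volume_percent
#' @return A uint8 array of the phantom's dimensions: 1 where the voxel is
#'   owned by a lesioned terminal, 0 elsewhere.
#' @export
lesion_mask <- function(lesioned, phantom, tree, perfusion = NULL) {
  if (is.null(perfusion)) perfusion <- perfusion_map(tree, phantom)
  les_flag <- logical(length(perfusion$vol_terminal))
  les_flag[lesioned] <- TRUE
  sel <- les_flag[perfusion$terminal_of_site[perfusion$site_of_voxel]]
  mask <- array(0L, perfusion$dim)
  mask[perfusion$brain_idx[sel]] <- 1L
  mask
}

#' Write a lesion mask as NIfTI
#'
#' @param mask A [lesion_mask()] array.
#' @param phantom The phantom providing the affine.
#' @param path Output `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_lesion_nifti <- function(mask, phantom, path) {
  RNifti::writeNifti(nifti_image(mask, phantom), path)
  invisible(path)
}
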