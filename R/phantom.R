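#' Perfusion-territory labels used by the phantom
#'
#' Six territories: anterior (ACA), middle (MCA) and fused posterior +
#' cerebellar (PCAcereb) cerebral artery territories, for the left and right
#' hemispheres. Integer codes 1..6 index this vector; 0 marks voxels outside
#' the brain.
#'
#' @export
TERRITORY_LEVELS <- c("ACA-L", "ACA-R", "MCA-L", "MCA-R",
                      "PCAcereb-L", "PCAcereb-R")

#' Default printed diameters of the major cerebral arteries (mm)
#'
#' Middle (MCA), posterior (PCA), anterior (ACA) cerebral and cerebellar (CA)
#' arteries. Their Murray-law combination with exponent `gamma` gives the
#' circle-of-Willis input diameter `d0` (see [compute_root_diameter()]).
#'
#' @export
BRANCH_DIAMETERS <- c(MCA = 3.1, PCA = 2.7, ACA = 2.6, CA = 1.5)

#' Phantom configuration
#'
#' Parameters of the synthetic brain volume: an ellipsoidal cerebrum with a
#' grey-matter shell and white-matter core, plus a posterior-inferior
#' cerebellar ellipsoid whose exclusive volume realises the cerebellar-artery
#' territory (fused with PCA in the labels, as in the vascular model).
#'
#' @param semi_axes Cerebrum ellipsoid semi-axes in mm (x right, y anterior,
#'   z superior; RAS world coordinates, mid-sagittal plane at x = 0).
#' @param grey_fraction Fraction of each ellipsoid's volume occupied by the
#'   outer grey-matter shell.
#' @param cerebellum_center,cerebellum_semi_axes Centre (mm) and semi-axes of
#'   the cerebellar ellipsoid.
#' @param territory_fractions Named per-hemisphere demand/volume fractions for
#'   MCA, PCA, ACA and CA; must sum to 1. Defaults to the Murray-law shares
#'   `d_i^gamma / sum(d^gamma)` of the printed artery diameters.
#' @param gamma Bifurcation exponent used for the default territory fractions.
#' @param spacing Isotropic voxel spacing in mm.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(semi_axes = c(70, 85, 60),
                           grey_fraction = 0.5,
                           cerebellum_center = c(0, -58, -50),
                           cerebellum_semi_axes = c(40, 28, 22),
                           territory_fractions = NULL,
                           gamma = 3.2,
                           spacing = 2) {
  if (any(semi_axes <= 0) || any(cerebellum_semi_axes <= 0))
    stopf("degenerate geometry: ellipsoid semi-axes must be positive")
  if (spacing <= 0) stopf("voxel spacing must be positive")
  if (grey_fraction <= 0 || grey_fraction >= 1)
    stopf("grey_fraction must lie in (0, 1)")
  if (is.null(territory_fractions)) {
    w <- BRANCH_DIAMETERS^gamma
    territory_fractions <- w / sum(w)
  }
  territory_fractions <- territory_fractions[c("MCA", "PCA", "ACA", "CA")]
  if (anyNA(territory_fractions) ||
      abs(sum(territory_fractions) - 1) > 1e-8)
    stopf("territory fractions must be named MCA/PCA/ACA/CA and sum to 1")
  structure(list(semi_axes = semi_axes, grey_fraction = grey_fraction,
                 cerebellum_center = cerebellum_center,
                 cerebellum_semi_axes = cerebellum_semi_axes,
                 territory_fractions = territory_fractions,
                 gamma = gamma, spacing = spacing),
            class = "phantom_config")
}

#' Build the voxelised brain phantom
#'
#' Voxelises the two-ellipsoid brain on a grid that is exactly symmetric
#' about the mid-sagittal plane (no voxel centre lies on x = 0), labels each
#' brain voxel grey or white, and partitions each hemisphere into the three
#' territory labels by angular sectors: MCA lateral, ACA anterior-medial,
#' PCA posterior-inferior, with the cerebellum fused into the PCA territory.
#' Sector thresholds are data-driven quantiles so the realised per-territory
#' volume fractions match the configuration up to voxelisation.
#'
#' @param config A [phantom_config()].
#' @return An object of class `brain_phantom` with per-voxel `tissue`
#'   (0 outside, 1 grey, 2 white) and `territory` (0 or 1..6, see
#'   [TERRITORY_LEVELS]) arrays, the voxel->world affine, and cached brain
#'   voxel coordinates.
#' @export
build_phantom <- function(config = phantom_config()) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  h <- config$spacing
  a <- config$semi_axes; cb <- config$cerebellum_center; cs <- config$cerebellum_semi_axes
  ext <- pmax(a, abs(cb) + cs) + h
  nd <- 2L * as.integer(ceiling(ext / h))  # even counts, centres at +-(k-1/2)h
  centers <- lapply(1:3, function(d) (seq_len(nd[d]) - nd[d] / 2 - 0.5) * h)

  X <- centers[[1]][slice.index(array(0, nd), 1)]
  Y <- centers[[2]][slice.index(array(0, nd), 2)]
  Z <- centers[[3]][slice.index(array(0, nd), 3)]
  q_cer <- (X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2
  q_cb <- ((X - cb[1]) / cs[1])^2 + ((Y - cb[2]) / cs[2])^2 + ((Z - cb[3]) / cs[3])^2
  in_cer <- q_cer <= 1
  in_cb <- q_cb <= 1
  brain <- in_cer | in_cb
  if (!any(brain)) stopf("degenerate geometry: phantom contains no brain voxels")

  shell <- (1 - config$grey_fraction)^(1 / 3)
  grey <- (in_cer & sqrt(q_cer) > shell) | (!in_cer & in_cb & sqrt(q_cb) > shell)
  tissue <- array(0L, nd)
  tissue[brain] <- ifelse(grey[brain], 1L, 2L)

  cb_only <- in_cb & !in_cer

  # territory sectors (scores are mirror-invariant: |x| and (y, z) only)
  territory <- array(0L, nd)
  fr <- config$territory_fractions
  idx_cer <- which(in_cer)
  lat <- abs(X[idx_cer] / a[1]) / sqrt(pmax(q_cer[idx_cer], 1e-12))
  psi <- atan2(Z[idx_cer] / a[3], Y[idx_cer] / a[2])
  dpsi <- abs(((psi - (-2.5) + pi) %% (2 * pi)) - pi)  # distance to posterior-inferior

  right <- X[idx_cer] > 0
  n_hemi <- sum(X > 0 & brain)            # per-hemisphere brain voxels
  n_cb_hemi <- sum(X > 0 & cb_only)
  n_mca <- round(fr[["MCA"]] * n_hemi)
  n_aca <- round(fr[["ACA"]] * n_hemi)
  n_cer_hemi <- sum(right)
  n_pca <- n_cer_hemi - n_mca - n_aca
  if (n_pca < 0)
    stopf("cerebellum too large for the configured PCA+CA territory fraction")

  thr_lat <- sort(lat[right], decreasing = TRUE)[n_mca]
  is_mca <- lat >= thr_lat
  rest_right <- right & !is_mca
  thr_psi <- sort(dpsi[rest_right])[min(n_pca, sum(rest_right))]
  is_pca <- !is_mca & dpsi <= thr_psi

  lab <- integer(length(idx_cer))
  lab[is_mca] <- ifelse(right[is_mca], 4L, 3L)
  lab[is_pca] <- ifelse(right[is_pca], 6L, 5L)
  rest <- lab == 0L
  lab[rest] <- ifelse(right[rest], 2L, 1L)
  territory[idx_cer] <- lab
  territory[cb_only] <- ifelse(X[cb_only] > 0, 6L, 5L)

  origin <- vapply(centers, `[`, numeric(1), 1L)
  affine <- diag(c(h, h, h, 1))
  affine[1:3, 4] <- origin

  brain_idx <- which(brain)
  brain_xyz <- cbind(X[brain_idx], Y[brain_idx], Z[brain_idx])
  structure(list(tissue = tissue, territory = territory,
                 cerebellum = array(cb_only, nd),
                 spacing = h, dim = nd, origin = origin, affine = affine,
                 config = config, brain_idx = brain_idx, brain_xyz = brain_xyz,
                 voxel_vol = h^3, brain_vol = length(brain_idx) * h^3),
            class = "brain_phantom")
}

#' @export
print.brain_phantom <- function(x, ...) {
  cat("brain_phantom:", paste(x$dim, collapse = " x "), "voxels at",
      x$spacing, "mm;", length(x$brain_idx), "brain voxels (",
      format(x$brain_vol / 1000, digits = 4), "cm^3 )\n")
  invisible(x)
}

#' Sample perfusion sites on the phantom
#'
#' Sites are drawn with probability proportional to per-voxel metabolic
#' demand (grey voxels weighted by `grey_white_demand_ratio`), then jittered
#' uniformly within their voxel, so every site lies inside a brain voxel.
#' Sites drive vascular-tree growth and define voxel ownership of terminals.
#'
#' @param phantom A [build_phantom()] result.
#' @param n_sites Number of sites (0 returns an empty table).
#' @param grey_white_demand_ratio Relative demand of grey vs white matter.
#' @param rng_seed Integer seed; identical seeds give identical site lists.
#' @return A data.frame with world coordinates, tissue class, territory
#'   label, cerebellum flag and unit demand weight per site.
#' @export
sample_perfusion_sites <- function(phantom, n_sites,
                                   grey_white_demand_ratio = 3,
                                   rng_seed = NULL) {
  stopifnot(inherits(phantom, "brain_phantom"))
  if (grey_white_demand_ratio <= 0) stopf("demand ratio must be positive")
  if (n_sites < 0) stopf("n_sites must be non-negative")
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      tissue = character(0), territory = character(0),
                      cerebellum = logical(0), weight = numeric(0),
                      voxel = integer(0))
  if (n_sites == 0) return(empty)
  if (length(phantom$brain_idx) == 0) stopf("phantom has no brain voxels")
  tis <- phantom$tissue[phantom$brain_idx]
  w <- ifelse(tis == 1L, grey_white_demand_ratio, 1)
  with_seed(rng_seed, {
    pick <- sample.int(length(phantom$brain_idx), n_sites, replace = TRUE, prob = w)
    jit <- matrix(runif(3 * n_sites, -phantom$spacing / 2, phantom$spacing / 2),
                  ncol = 3)
    vox <- phantom$brain_idx[pick]
    data.frame(x = phantom$brain_xyz[pick, 1] + jit[, 1],
               y = phantom$brain_xyz[pick, 2] + jit[, 2],
               z = phantom$brain_xyz[pick, 3] + jit[, 3],
               tissue = ifelse(tis[pick] == 1L, "grey", "white"),
               territory = TERRITORY_LEVELS[phantom$territory[vox]],
               cerebellum = phantom$cerebellum[vox],
               weight = 1, voxel = vox)
  })
}

# world-coordinate centre of given linear voxel indices
voxel_centers <- function(phantom, idx) {
  ij <- arrayInd(idx, phantom$dim)
  sweep((ij - 1) * phantom$spacing, 2, phantom$origin, `+`)
}

nifti_image <- function(arr, phantom, datatype = "uint8") {
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::qform(img) <- structure(phantom$affine, code = 2L)
  RNifti::sform(img) <- structure(phantom$affine, code = 2L)
  img
}

#' Write phantom label volumes as NIfTI
#'
#' Writes `tissue.nii.gz` and `territory.nii.gz` uint8 label volumes with the
#' phantom affine (RAS, mm).
#'
#' @param phantom A [build_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("tissue.nii.gz", "territory.nii.gz"))
  RNifti::writeNifti(nifti_image(phantom$tissue, phantom), paths[1])
  RNifti::writeNifti(nifti_image(phantom$territory, phantom), paths[2])
  invisible(paths)
}
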