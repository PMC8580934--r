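#' Physical volume of a mask in cm^3
#'
#' In-set voxel count times the anisotropic voxel volume
#' (spacing_1 x spacing_2 x spacing_3 mm^3), converted to cm^3. Lesion
#' dimensions are reported in cm^3 throughout because cohorts scanned at
#' multiple centres mix voxel sizes (in-plane 0.86-1.27 mm, slice 2.5-3 mm),
#' so voxel counts are not comparable across femurs.
#'
#' @param mask A [label_mask()].
#' @return Volume in cm^3 (double).
#' @export
mask_volume <- function(mask) {
  stopifnot_mask(mask)
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' 3-D Dice coefficient between two segmentations
#'
#' The volumetric Sorensen-Dice coefficient `2|A n B| / (|A| + |B|)`.
#' It is computed on voxel counts: voxel volume cancels in the ratio, so the
#' result is exact and independent of spacing. A value of 1 means identical
#' segmentations, 0 means disjoint ones.
#'
#' When exactly one mask is empty the formula gives 0 and that value is
#' returned. When both are empty the coefficient is undefined (0/0); this is
#' an error rather than a silent 1, because a pair with no segmentation on
#' either side carries no agreement information and treating it as perfect
#' agreement would inflate reliability summaries.
#'
#' @param a,b [label_mask()] objects on the same grid
#'   (see [validate_same_grid()]).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  validate_same_grid(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L) {
    stop("Dice undefined for two empty segmentations", call. = FALSE)
  }
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Non-overlapping segmentation volume in cm^3
#'
#' The volume of the symmetric difference between two segmentations,
#' `|A| + |B| - 2|A n B|`, in cm^3. It is 0 exactly when the masks are
#' identical, and equals `(|A| + |B|) (1 - Dice)`. Unlike the Dice
#' coefficient it is defined for two empty masks (0 cm^3).
#'
#' @inheritParams dice_coefficient
#' @return Non-overlap volume in cm^3.
#' @export
non_overlap_volume <- function(a, b) {
  validate_same_grid(a, b)
  n <- sum(a$voxels) + sum(b$voxels) - 2L * sum(a$voxels & b$voxels)
  n * prod(a$spacing) / 1000
}

#' Compare one pair of segmentations
#'
#' Computes all pairwise agreement quantities for a pair of masks on a shared
#' grid: Dice coefficient, both volumes, intersection volume, non-overlapping
#' volume, and the mean segmentation volume `(|A| + |B|) / 2` used for size
#' stratification.
#'
#' @inheritParams dice_coefficient
#' @return A one-row tibble with columns `dice`, `volume_a`, `volume_b`,
#'   `volume_intersection`, `non_overlap_volume`, `mean_volume`
#'   (volumes in cm^3).
#' @examples
#' a <- label_mask(array(rep(c(TRUE, FALSE), c(100, 100)), c(10, 10, 2)), c(1, 1, 1))
#' compare_pair(a, a)
#' @export
compare_pair <- function(a, b) {
  validate_same_grid(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L) {
    stop("Dice undefined for two empty segmentations", call. = FALSE)
  }
  ni <- sum(a$voxels & b$voxels)
  vox <- prod(a$spacing) / 1000
  tibble::tibble(
    dice = 2 * ni / (na + nb),
    volume_a = na * vox,
    volume_b = nb * vox,
    volume_intersection = ni * vox,
    non_overlap_volume = (na + nb - 2L * ni) * vox,
    mean_volume = (na + nb) / 2 * vox
  )
}

# 26-neighbourhood offsets: the 13 lexicographically positive halves of the
# 3^3 - 1 neighbour steps (the other half gives the same undirected edges).
half_offsets_26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  g[keep, , drop = FALSE]
})

# Label connected in-set voxels (26-connectivity). Returns an integer array of
# component ids (0 = background).
label_components <- function(voxels) {
  d <- dim(voxels)
  n_in <- sum(voxels)
  lab <- array(0L, d)
  if (n_in == 0L) return(lab)
  idx_map <- array(0L, d)
  idx_map[voxels] <- seq_len(n_in)

  edges <- vector("list", nrow(half_offsets_26))
  for (k in seq_len(nrow(half_offsets_26))) {
    o <- half_offsets_26[k, ]
    a1 <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    a2 <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    a3 <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    src <- idx_map[a1 - o[1], a2 - o[2], a3 - o[3], drop = FALSE]
    dst <- idx_map[a1, a2, a3, drop = FALSE]
    both <- src > 0L & dst > 0L
    if (any(both)) edges[[k]] <- rbind(src[both], dst[both])
  }
  edges <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = n_in, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, as.vector(edges))
  memb <- igraph::components(g)$membership
  lab[voxels] <- as.integer(memb)
  lab
}

#' Count connected lesion components in a mask
#'
#' Number of connected in-set components under 26-connectivity (voxels
#' touching by face, edge or corner belong to one component). Used as a
#' disagreement diagnostic: operators sometimes render what one of them sees
#' as a single lesion as several separate components. Agreement metrics are
#' unaffected, because all lesions of a femur are merged before the Dice
#' coefficient is computed.
#'
#' @param mask A [label_mask()].
#' @return Integer component count (0 for an empty mask).
#' @export
count_components <- function(mask) {
  stopifnot_mask(mask)
  if (!any(mask$voxels)) return(0L)
  max(label_components(mask$voxels))
}
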