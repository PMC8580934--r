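#' Configuration of a synthetic reliability cohort
#'
#' Defines the study conditions emulated by the synthetic-cohort generator:
#' a 54-femur cohort (19 osteolytic, 17 osteoblastic, 18 mixed) segmented by
#' two operators in two sessions each. Lesion volumes are drawn from per-type
#' log-normal distributions moment-matched to published cohort means/SDs
#' (see [reference_cohort_summary()]); log-normal rather than normal because
#' the published SDs are of the same order as the means, so a normal model
#' would produce negative volumes.
#'
#' Agreement is controlled by per-femur target Dice levels: an inter-operator
#' target drawn around `target_dice`, intra-operator targets boosted above it
#' by `intra_boost` (operators are more consistent with themselves than with
#' each other, and operator II more so than operator I), and a size effect
#' `size_dice_slope` that raises targets for lesions larger than
#' `size_pivot` and lowers them for smaller ones (larger lesions are easier
#' to delineate consistently).
#'
#' @param n_per_type Femur counts for (osteolytic, osteoblastic, mixed).
#' @param grid_shape Voxel grid dimensions of each synthetic scan.
#' @param spacing Voxel spacing in mm (in-plane, in-plane, slice).
#' @param volume_mean,volume_sd Per-type lesion-volume mean and SD in cm^3,
#'   in the order (osteolytic, osteoblastic, mixed).
#' @param target_dice Mean inter-operator Dice target in (0, 1): one global
#'   value or three per-type values (osteolytic, osteoblastic, mixed).
#' @param dice_dispersion SD of the per-femur inter-operator Dice target
#'   around `target_dice` (targets are clipped to `[0.08, 0.97]`).
#' @param intra_boost Named additive boosts (`I`, `II`) of the intra-operator
#'   Dice targets over the femur's inter-operator target; must be >= 0.
#' @param size_dice_slope Dice-target increase per doubling of lesion volume
#'   relative to `size_pivot`; 0 switches the size effect off.
#' @param size_pivot Volume (cm^3) at which the size effect is neutral.
#' @param split_probability Probability per femur that one randomly chosen
#'   operator/session mask renders the lesion as two separate components
#'   (count disagreement), implemented as a thin planar gap.
#' @param volume_jitter SD of the log-normal jitter applied to each observed
#'   mask's voxel budget around the reference volume (operators disagree on
#'   lesion extent, not only on boundary placement).
#' @param roughness Surface roughness of the reference lesion (relative
#'   amplitude of smooth noise added to the ellipsoidal implicit surface).
#' @param noise_sigma_mm Correlation length (mm) of all boundary-noise
#'   fields.
#' @param dice_tol Calibration tolerance: per-femur achieved Dice is bisected
#'   to within this distance of its target (doubled for targets < 0.3, where
#'   Dice responds very steeply to noise amplitude).
#' @param seed Integer RNG seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_type = c(osteolytic = 19L, osteoblastic = 17L, mixed = 18L),
                             grid_shape = c(96L, 96L, 160L),
                             spacing = c(0.98, 0.98, 3.0),
                             volume_mean = c(osteolytic = 14.48, osteoblastic = 33.35, mixed = 41.2),
                             volume_sd = c(osteolytic = 13.83, osteoblastic = 32.42, mixed = 27.47),
                             target_dice = 0.52,
                             dice_dispersion = 0.15,
                             intra_boost = c(I = 0.04, II = 0.19),
                             size_dice_slope = 0.07,
                             size_pivot = 20,
                             split_probability = 0.1,
                             volume_jitter = 0.12,
                             roughness = 0.25,
                             noise_sigma_mm = 4,
                             dice_tol = 0.03,
                             seed = 1L) {
  n_per_type <- as.integer(n_per_type)
  if (length(n_per_type) != 3L || any(n_per_type < 0)) {
    stop("`n_per_type` must be 3 non-negative counts", call. = FALSE)
  }
  names(n_per_type) <- cohort_lesion_types
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8)) {
    stop("`grid_shape` must be 3 dimensions of at least 8 voxels", call. = FALSE)
  }
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive mm values", call. = FALSE)
  }
  if (any(volume_mean <= 0)) stop("`volume_mean` must be positive", call. = FALSE)
  if (any(volume_sd < 0)) stop("`volume_sd` must be non-negative", call. = FALSE)
  names(volume_mean) <- names(volume_sd) <- cohort_lesion_types
  if (!length(target_dice) %in% c(1L, 3L) || any(target_dice <= 0) ||
      any(target_dice > 1)) {
    stop("`target_dice` must be one global value or three per-type values in (0, 1]",
         call. = FALSE)
  }
  target_dice <- rep(as.double(target_dice), length.out = 3L)
  names(target_dice) <- cohort_lesion_types
  if (any(intra_boost < 0) || !all(c("I", "II") %in% names(intra_boost))) {
    stop("`intra_boost` must be non-negative values named I and II", call. = FALSE)
  }
  if (dice_dispersion < 0) stop("`dice_dispersion` must be >= 0", call. = FALSE)
  if (split_probability < 0 || split_probability > 1) {
    stop("`split_probability` must be in [0, 1]", call. = FALSE)
  }
  if (volume_jitter < 0) stop("`volume_jitter` must be >= 0", call. = FALSE)
  if (size_pivot <= 0) stop("`size_pivot` must be positive", call. = FALSE)
  if (dice_tol <= 0) stop("`dice_tol` must be positive", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  structure(list(
    n_per_type = n_per_type, grid_shape = grid_shape, spacing = spacing,
    volume_mean = volume_mean, volume_sd = volume_sd,
    target_dice = target_dice, dice_dispersion = dice_dispersion,
    intra_boost = intra_boost[c("I", "II")],
    size_dice_slope = size_dice_slope, size_pivot = size_pivot,
    split_probability = split_probability, volume_jitter = volume_jitter,
    roughness = roughness,
    noise_sigma_mm = noise_sigma_mm, dice_tol = dice_tol, seed = seed
  ), class = "synthetic_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw a lesion volume for a lesion type
#'
#' One positive draw from the log-normal distribution whose parameters are
#' moment-matched to the configured mean and SD for that type
#' (`sdlog^2 = log(1 + cv^2)`, `meanlog = log(mean) - sdlog^2 / 2`).
#' In the degenerate `sd = 0` limit all draws equal the mean.
#'
#' @param lesion_type One of `"osteolytic"`, `"osteoblastic"`, `"mixed"`.
#' @param config A [synthetic_config()].
#' @param n Number of draws.
#' @return Volumes in cm^3.
#' @export
sample_lesion_volume <- function(lesion_type, config = synthetic_config(), n = 1) {
  lesion_type <- match.arg(lesion_type, cohort_lesion_types)
  m <- config$volume_mean[[lesion_type]]
  s <- config$volume_sd[[lesion_type]]
  if (m <= 0) stop("configured mean volume must be positive", call. = FALSE)
  if (s == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# Largest lesion volume (cm^3) that fits in the grid with crop margins.
# The crop window spans 2 * ceiling((extent * 1.15 + margin) / spacing) + 1
# voxels per axis, so the sphere radius is backed out of that bound.
grid_capacity_cm3 <- function(grid_shape, spacing, margin_mm) {
  r <- min(((grid_shape - 3) / 2) * spacing - margin_mm) / 1.15
  if (r <= 0) return(0)
  0.95 * (4 / 3) * pi * r^3 / 1000
}

# Build an ellipsoid-plus-roughness implicit field on a crop window of the
# grid. The reference mask is the strict super-level set {field > 0}; the
# level is chosen so the in-set voxel count matches the requested volume.
# Returns field (crop array), offset (1-based corner of the crop in the full
# grid), and the reference mask (crop logical array, one connected component).
make_reference_field <- function(volume_cm3, grid_shape, spacing,
                                 roughness, sigma_vox, margin_mm = 10) {
  v_mm3 <- volume_cm3 * 1000
  target_n <- round(v_mm3 / prod(spacing))
  if (target_n < 20) {
    stop("requested volume (", signif(volume_cm3, 3),
         " cm^3) spans fewer than 20 voxels at this spacing", call. = FALSE)
  }
  r0 <- (3 * v_mm3 / (4 * pi))^(1 / 3)
  half_extent <- grid_shape * spacing / 2
  if (r0 * 1.15 + margin_mm > min(half_extent)) {
    stop("requested volume (", signif(volume_cm3, 3),
         " cm^3) is too large for the grid", call. = FALSE)
  }

  ratios <- stats::runif(3, 0.5, 2)
  rot <- random_rotation()
  rough <- roughness
  for (attempt in 1:12) {
    axes <- r0 * ratios / prod(ratios)^(1 / 3)
    # Half-extent of the rotated ellipsoid along each grid axis.
    ext <- sqrt(colSums((t(rot) * axes)^2))
    half <- ceiling((ext * 1.15 + margin_mm) / spacing)
    if (all(2 * half + 1 <= grid_shape)) {
      crop_dim <- 2L * half + 1L
      lo <- purrr::map2_int(as.integer(half), grid_shape - 2L * as.integer(half),
                            ~ .x + sample.int(.y, 1))
      centre_idx <- as.integer(half) + 1L  # crop-local centre voxel
      co <- purrr::map(1:3, function(ax) (seq_len(crop_dim[ax]) - centre_idx[ax]) * spacing[ax])
      # q(x) = || diag(1/axes) R^T x ||^2 on the crop grid, fully vectorised.
      n_crop <- prod(crop_dim)
      X <- cbind(rep(co[[1]], times = crop_dim[2] * crop_dim[3]),
                 rep(rep(co[[2]], each = crop_dim[1]), times = crop_dim[3]),
                 rep(co[[3]], each = crop_dim[1] * crop_dim[2]))
      Y <- X %*% rot
      q <- array((Y[, 1] / axes[1])^2 + (Y[, 2] / axes[2])^2 + (Y[, 3] / axes[3])^2,
                 dim = crop_dim)
      base <- 1 - q
      for (noise_try in 1:5) {
        field <- base + rough * noise_field(crop_dim, sigma_vox)
        level <- sort(as.vector(field), decreasing = TRUE)[target_n]
        field <- field - level
        mask <- field > 0
        # Surface noise can detach small satellite specks; push them just
        # below the surface so the reference stays a single connected blob.
        lab <- label_components(mask)
        if (max(lab) > 1L) {
          big <- which.max(tabulate(lab[lab > 0L]))
          specks <- mask & lab != big
          field[specks] <- -1e-3
          mask <- mask & lab == big
        }
        if (abs(sum(mask) - target_n) <= max(1, 0.05 * target_n)) {
          return(list(field = field, mask = mask,
                      offset = lo - as.integer(half),
                      crop_dim = crop_dim))
        }
        rough <- rough * 0.75
      }
    }
    ratios <- ratios^0.7  # shrink towards a sphere until the crop fits
  }
  stop("could not realise a connected reference lesion of ",
       signif(volume_cm3, 3), " cm^3 on this grid", call. = FALSE)
}

#' Generate a synthetic reference lesion
#'
#' A connected, roughly ellipsoidal blob with random axis ratios in
#' `[0.5, 2]`, random orientation and a noise-roughened surface, whose volume
#' matches the request to within 5%. This is the generator's hidden ground
#' truth: real reliability studies have none (it is impossible to know which
#' operator's segmentation is closest to the true lesion), so the reference
#' is a testing device only and is never consumed by the analysis pipeline.
#'
#' @param volume_cm3 Requested lesion volume in cm^3.
#' @param grid_shape,spacing Grid dimensions and voxel spacing (mm).
#' @param roughness,noise_sigma_mm Surface-roughness amplitude and
#'   correlation length, as in [synthetic_config()].
#' @return A [label_mask()] on the full grid.
#' @export
generate_reference_lesion <- function(volume_cm3,
                                      grid_shape = c(96L, 96L, 160L),
                                      spacing = c(0.98, 0.98, 3.0),
                                      roughness = 0.25, noise_sigma_mm = 4) {
  sigma_vox <- noise_sigma_mm / spacing
  ref <- make_reference_field(volume_cm3, as.integer(grid_shape), spacing,
                              roughness, sigma_vox)
  label_mask(embed_crop(ref$mask, as.integer(grid_shape), ref$offset), spacing)
}

embed_crop <- function(crop, grid_shape, offset) {
  full <- array(FALSE, grid_shape)
  d <- dim(crop)
  full[offset[1]:(offset[1] + d[1] - 1),
       offset[2]:(offset[2] + d[2] - 1),
       offset[3]:(offset[3] + d[3] - 1)] <- crop
  full
}

dice_counts <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(0)
  2 * sum(a & b) / s
}

# Bisect a noise amplitude so that `measure(amplitude)` (a Dice value,
# monotone non-increasing in the amplitude) lands within tol of target,
# then refine once by secant interpolation across the final bracket (plain
# bisection would stop at the first midpoint inside the tolerance, which
# sits below the target more often than above because Dice falls steeply at
# small amplitudes). Returns list(amplitude, achieved). If even amplitude 0
# is below the target, the closest attainable point (0) is returned.
bisect_amplitude <- function(measure, target, tol, hi0 = 0.25, max_hi = 64) {
  d0 <- measure(0)
  if (d0 <= target + tol) return(list(amplitude = 0, achieved = d0))
  lo <- 0; d_lo <- d0
  hi <- hi0; d_hi <- measure(hi)
  while (d_hi > target && hi < max_hi) {
    lo <- hi; d_lo <- d_hi
    hi <- hi * 2
    d_hi <- measure(hi)
  }
  best_a <- hi; best_d <- d_hi
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    d <- measure(mid)
    if (abs(d - target) < abs(best_d - target)) { best_a <- mid; best_d <- d }
    if (d > target) { lo <- mid; d_lo <- d } else { hi <- mid; d_hi <- d }
    if (abs(d - target) <= tol) break
  }
  if (d_lo > d_hi) {
    a_sec <- lo + (d_lo - target) * (hi - lo) / (d_lo - d_hi)
    d_sec <- measure(a_sec)
    if (abs(d_sec - target) < abs(best_d - target)) {
      best_a <- a_sec; best_d <- d_sec
    }
  }
  list(amplitude = best_a, achieved = best_d)
}

#' Perturb a mask towards a target Dice agreement
#'
#' Produces a boundary-perturbed rendition of a reference segmentation whose
#' Dice coefficient with the reference is close to `target`. The mask is
#' first relaxed to a smooth implicit field (Gaussian smoothing of the
#' occupancy), a spatially correlated noise field is added, and the noise
#' amplitude is bisected until the measured Dice is within the tolerance
#' (`tol` for targets >= 0.3, `2 * tol` below, where Dice responds very
#' steeply). Spatially correlated noise displaces whole stretches of boundary
#' coherently, mimicking operator disagreement on unclear lesion boundaries;
#' independent voxel flips would not.
#'
#' @param reference A non-empty [label_mask()].
#' @param target Target Dice in (0, 1]; `1` returns the reference unchanged.
#' @param tol Calibration tolerance (default 0.03).
#' @param noise_sigma_mm Noise correlation length in mm.
#' @return A [label_mask()] with attribute `achieved_dice`.
#' @export
perturb_to_target_dice <- function(reference, target, tol = 0.03,
                                   noise_sigma_mm = 4) {
  stopifnot_mask(reference)
  if (!any(reference$voxels)) stop("reference mask is empty", call. = FALSE)
  if (target <= 0 || target > 1) stop("`target` must be in (0, 1]", call. = FALSE)
  if (target == 1) {
    out <- reference
    attr(out, "achieved_dice") <- 1
    return(out)
  }
  tol_eff <- if (target < 0.3) 2 * tol else tol
  spacing <- reference$spacing
  sigma_vox <- noise_sigma_mm / spacing
  grid_shape <- dim(reference$voxels)

  # Crop to the reference bounding box plus room to grow.
  idx <- which(reference$voxels, arr.ind = TRUE)
  pad <- pmax(4L, ceiling(3 * sigma_vox))
  lo <- pmax(1L, apply(idx, 2, min) - pad)
  hi <- pmin(grid_shape, apply(idx, 2, max) + pad)
  crop <- reference$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  field <- gaussian_smooth_3d(array(as.double(crop), dim(crop)),
                              pmax(sigma_vox / 2, 0.7)) - 0.5
  noise <- noise_field(dim(crop), sigma_vox)
  ref_crop <- crop
  n_ref <- sum(ref_crop)
  # Volume-preserving perturbation: the perturbed mask is the top-|A| voxels
  # of (field + a * noise), so the noise displaces the boundary without
  # inflating the segmentation, and Dice can be driven arbitrarily low.
  level_set <- function(a) {
    g <- field + a * noise
    g >= kth_largest(as.vector(g), n_ref)
  }
  measure <- function(a) dice_counts(ref_crop, level_set(a))
  fit <- bisect_amplitude(measure, target, tol_eff)
  if (abs(fit$achieved - target) > tol_eff) {
    stop(sprintf("could not reach target Dice %.3g; closest achieved %.3g",
                 target, fit$achieved), call. = FALSE)
  }
  out <- label_mask(embed_crop(level_set(fit$amplitude), grid_shape, lo), spacing)
  attr(out, "achieved_dice") <- fit$achieved
  out
}

# Plane-gap parameters for splitting a component: returns a logical crop-shaped
# "remove" array, or NULL if the plane misses the component.
plane_slab <- function(voxels, centre, normal, offset, width) {
  d <- dim(voxels)
  proj <- array(0, d)
  for (ax in 1:3) {
    ramp <- (seq_len(d[ax]) - centre[ax]) * normal[ax]
    perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    proj <- proj + aperm(array(ramp, d[perm]), order(perm))
  }
  abs(proj - offset) < width / 2
}

#' Split one lesion component in two with a planar gap
#'
#' Carves a thin, empty, plane-like gap through the largest connected
#' component of the mask so that the component count increases by exactly
#' one, removing less than 10% of the mask's voxels. This emulates count
#' disagreement between operators: one operator segments a single lesion
#' where the other sees two separate ones. Because agreement is computed on
#' per-femur unions, the Dice coefficient is robust to this kind of
#' disagreement (the split mask retains > 90% of the voxels).
#'
#' @param mask A [label_mask()] whose largest component has at least 100
#'   voxels.
#' @param max_attempts Number of random plane orientations/offsets to try.
#' @return The split [label_mask()].
#' @export
split_lesion <- function(mask, max_attempts = 30) {
  stopifnot_mask(mask)
  lab <- label_components(mask$voxels)
  n_comp <- max(lab)
  if (n_comp == 0L) stop("mask is empty", call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sizes[big] < 100) {
    stop("largest component has ", sizes[big],
         " voxels; need at least 100 to split", call. = FALSE)
  }
  comp <- lab == big
  idx <- which(comp, arr.ind = TRUE)
  centre <- colMeans(idx)
  for (i in seq_len(max_attempts)) {
    # Axis-aligned planes need only a single-voxel layer to break
    # 26-connectivity; oblique ones need a slab as wide as |n|_1. Prefer the
    # thin cuts, and cut off-centre, so that less than 10% of the mask goes.
    if (i %% 2 == 1L) {
      normal <- c(0, 0, 0)
      normal[sample.int(3, 1)] <- 1
    } else {
      normal <- stats::rnorm(3)
      normal <- normal / sqrt(sum(normal^2))
    }
    width <- sum(abs(normal)) + 0.05
    span <- as.vector((idx - matrix(centre, nrow(idx), 3, byrow = TRUE)) %*% normal)
    q <- stats::quantile(span, c(0.2, 0.35, 0.65, 0.8))
    offset <- if (stats::runif(1) < 0.5) stats::runif(1, q[1], q[2]) else
      stats::runif(1, q[3], q[4])
    slab <- plane_slab(mask$voxels, centre, normal, offset, width) & comp
    n_removed <- sum(slab)
    if (n_removed == 0 || n_removed >= 0.1 * sum(mask$voxels)) next
    cand <- mask$voxels & !slab
    if (max(label_components(cand)) == n_comp + 1L) {
      return(label_mask(cand, mask$spacing))
    }
  }
  stop("could not split the component into exactly two parts after ",
       max_attempts, " attempts", call. = FALSE)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Generate the four observed masks of one femur on a crop window.
#
# Model: every observed mask is a super-level set of the shared reference
# field plus an operator-systematic noise field (persistent across sessions)
# plus a session-specific noise field:
#   M[o, s] = { F + alpha * O[o] + beta[o] * S[o, s] > 0 }.
# The operator amplitude alpha is bisected on the mean of the two
# inter-operator session Dice values, and each beta[o] on that operator's
# intra Dice, so the realised agreement matches the femur's targets. An
# optional planar gap (count disagreement) is part of the thresholded mask
# during calibration, so it does not bias the achieved Dice.
generate_femur <- function(config, femur_id, lesion_type, femur_seed) {
  with_seed(femur_seed, {
    cap <- grid_capacity_cm3(config$grid_shape, config$spacing, margin_mm = 10)
    vol <- sample_lesion_volume(lesion_type, config)
    clamped <- vol > cap
    if (clamped) vol <- cap

    size_term <- config$size_dice_slope * log2(vol / config$size_pivot)
    t_inter <- clip(stats::rnorm(1, config$target_dice[[lesion_type]] + size_term,
                                 config$dice_dispersion), 0.08, 0.97)
    # Intra targets must exceed the inter target: inter disagreement contains
    # the session noise that drives intra disagreement, so an intra target at
    # or below the inter target is unattainable in this model.
    boost <- pmax(stats::rnorm(2, config$intra_boost, config$dice_dispersion / 3),
                  0.03)
    t_intra <- clip(t_inter + boost, 0.10, 0.985)
    names(t_intra) <- c("I", "II")

    sigma_vox <- config$noise_sigma_mm / config$spacing
    # Very low Dice targets need room for the masks to drift apart: the
    # attainable floor scales with lesion volume over crop volume, so widen
    # the crop for strongly disagreeing femurs — but never beyond what the
    # grid can hold around a sphere of the requested volume.
    margin_mm <- if (t_inter < 0.35) 18 else 10
    r0 <- (3 * vol * 1000 / (4 * pi))^(1 / 3)
    margin_fit <- min((config$grid_shape - 3) / 2 * config$spacing) -
      1.15 * r0 - max(config$spacing)
    margin_mm <- max(2, min(margin_mm, margin_fit))
    ref <- make_reference_field(vol, config$grid_shape, config$spacing,
                                config$roughness, sigma_vox,
                                margin_mm = margin_mm)
    crop_dim <- ref$crop_dim

    O <- list(I = noise_field(crop_dim, sigma_vox),
              II = noise_field(crop_dim, sigma_vox))
    S <- list(I = list(noise_field(crop_dim, sigma_vox),
                       noise_field(crop_dim, sigma_vox)),
              II = list(noise_field(crop_dim, sigma_vox),
                        noise_field(crop_dim, sigma_vox)))

    split_victim <- NULL
    slab <- NULL
    if (stats::runif(1) < config$split_probability) {
      split_victim <- c(sample(c("I", "II"), 1), sample(c("1", "2"), 1))
      idx <- which(ref$mask, arr.ind = TRUE)
      centre <- colMeans(idx)
      normal <- stats::rnorm(3)
      normal <- normal / sqrt(sum(normal^2))
      width <- sum(abs(normal)) + 0.3
      span <- as.vector((idx - matrix(centre, nrow(idx), 3, byrow = TRUE)) %*% normal)
      offset <- stats::runif(1, stats::quantile(span, 0.35), stats::quantile(span, 0.65))
      slab <- plane_slab(ref$mask, centre, normal, offset, width)
    }

    # Per-mask voxel budgets: operators (and sessions) disagree on lesion
    # extent, so each observed mask gets a log-normally jittered volume.
    # Femurs with high agreement targets necessarily agree on volume too
    # (Dice bounds the volume ratio), so the jitter shrinks with the
    # tightest pairwise target.
    n_ref <- sum(ref$mask)
    jitter_sd <- config$volume_jitter * min(1, 1.5 * (1 - max(t_intra, t_inter)))
    n_obs <- round(n_ref * exp(stats::rnorm(4, 0, jitter_sd)))
    names(n_obs) <- c("I1", "I2", "II1", "II2")

    # Observed masks are volume-preserving level sets of the perturbed field:
    # the top-n voxels of F + alpha * O[op] + beta * S[op, session]. Keeping
    # the voxel budget fixed lets the noise amplitude drive Dice towards 0
    # without ballooning the segmentation.
    make_mask <- function(op, se, alpha, beta) {
      g <- ref$field + alpha * O[[op]] + beta * S[[op]][[as.integer(se)]]
      m <- g >= kth_largest(as.vector(g), n_obs[[paste0(op, se)]])
      if (!is.null(split_victim) && split_victim[1] == op && split_victim[2] == se) {
        m <- m & !slab
      }
      m
    }

    tol <- config$dice_tol
    alpha <- 0
    beta <- c(I = 0, II = 0)
    inter_dice <- function(a) {
      (dice_counts(make_mask("I", "1", a, beta[["I"]]),
                   make_mask("II", "1", a, beta[["II"]])) +
       dice_counts(make_mask("I", "2", a, beta[["I"]]),
                   make_mask("II", "2", a, beta[["II"]]))) / 2
    }
    t_eff_inter <- if (t_inter < 0.3) 2 * tol else tol
    for (pass in 1:2) {
      for (op in c("I", "II")) {
        t_eff <- if (t_intra[[op]] < 0.3) 2 * tol else tol
        fit <- bisect_amplitude(function(b) {
          dice_counts(make_mask(op, "1", alpha, b), make_mask(op, "2", alpha, b))
        }, t_intra[[op]], t_eff)
        beta[[op]] <- fit$amplitude
      }
      fit <- bisect_amplitude(inter_dice, t_inter, t_eff_inter)
      alpha <- fit$amplitude
      if (abs(fit$achieved - t_inter) <= t_eff_inter) break
    }
    # If the inter target is still unattainable (session noise alone already
    # pushes agreement below it), trade intra accuracy for inter accuracy:
    # shrink the session amplitudes and recalibrate the operator amplitude.
    # Intra agreement then sits above its target, preserving intra > inter.
    relax <- 0
    while (fit$achieved < t_inter - t_eff_inter && relax < 4) {
      beta <- beta * 0.75
      fit <- bisect_amplitude(inter_dice, t_inter, t_eff_inter)
      alpha <- fit$amplitude
      relax <- relax + 1
    }

    masks <- list()
    for (op in c("I", "II")) for (se in c("1", "2")) {
      m <- make_mask(op, se, alpha, beta[[op]])
      if (!any(m)) m <- ref$mask  # degenerate amplitude blew the mask away
      masks[[paste0(op, se)]] <- label_mask(m, config$spacing)
    }

    achieved <- c(
      inter_1 = dice_counts(masks[["I1"]]$voxels, masks[["II1"]]$voxels),
      inter_2 = dice_counts(masks[["I2"]]$voxels, masks[["II2"]]$voxels),
      intra_I = dice_counts(masks[["I1"]]$voxels, masks[["I2"]]$voxels),
      intra_II = dice_counts(masks[["II1"]]$voxels, masks[["II2"]]$voxels)
    )

    truth <- tibble::tibble(
      femur_id = femur_id, lesion_type = lesion_type,
      volume_cm3 = vol, volume_clamped = clamped,
      target_inter = t_inter,
      target_intra_I = t_intra[["I"]], target_intra_II = t_intra[["II"]],
      achieved_inter_1 = achieved[["inter_1"]],
      achieved_inter_2 = achieved[["inter_2"]],
      achieved_intra_I = achieved[["intra_I"]],
      achieved_intra_II = achieved[["intra_II"]],
      alpha = alpha, beta_I = beta[["I"]], beta_II = beta[["II"]],
      split_mask = if (is.null(split_victim)) NA_character_ else
        paste0(split_victim[1], ":", split_victim[2]),
      seed = femur_seed
    )
    list(masks = masks, offset = ref$offset, truth = truth)
  })
}

cohort_plan <- function(config) {
  types <- rep(cohort_lesion_types, times = config$n_per_type)
  n <- length(types)
  if (!n) stop("empty cohort: all counts in `n_per_type` are zero", call. = FALSE)
  femur_seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, n))
  tibble::tibble(
    femur_id = sprintf("F%02d", seq_len(n)),
    lesion_type = types,
    femur_seed = femur_seeds
  )
}

#' Generate a synthetic reliability cohort
#'
#' Generates the full synthetic study defined by a [synthetic_config()]:
#' for every femur a hidden reference lesion and four observed segmentations
#' (2 operators x 2 sessions) whose pairwise Dice agreement is calibrated to
#' the femur's targets. With `dir` set, masks are written as NIfTI files
#' together with `manifest.csv` (the [load_cohort()] dialect),
#' `truth.csv` (every generation parameter and achieved Dice per femur) and
#' a `config.yaml` echo; otherwise masks are returned in memory as a `mask`
#' list-column.
#'
#' The generation is a pure function of the configuration (including its
#' seed): the same config yields byte-identical manifests and truth tables.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory.
#' @return A list with `cohort` (a tibble usable by
#'   [assemble_study_table()]) and `truth` (the generation truth table).
#' @export
generate_cohort <- function(config = synthetic_config(), dir = NULL) {
  plan <- cohort_plan(config)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  }
  records <- list(); truths <- list()
  for (i in seq_len(nrow(plan))) {
    fem <- generate_femur(config, plan$femur_id[i], plan$lesion_type[i],
                          plan$femur_seed[i])
    truths[[i]] <- fem$truth
    for (op in c("I", "II")) for (se in c("1", "2")) {
      crop <- fem$masks[[paste0(op, se)]]
      full <- label_mask(embed_crop(crop$voxels, config$grid_shape, fem$offset),
                         config$spacing)
      rec <- tibble::tibble(femur_id = plan$femur_id[i], operator = op,
                            session = se, lesion_type = plan$lesion_type[i])
      if (is.null(dir)) {
        rec$mask_path <- NA_character_
        rec$mask <- list(full)
      } else {
        rel <- file.path("masks", sprintf("%s_op%s_s%s.nii.gz",
                                          plan$femur_id[i], op, se))
        write_mask(full, file.path(dir, rel))
        rec$mask_path <- rel
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  cohort <- dplyr::bind_rows(records)
  truth <- dplyr::bind_rows(truths)
  if (!is.null(dir)) {
    write_manifest(cohort, file.path(dir, "manifest.csv"))
    readr::write_csv(truth, file.path(dir, "truth.csv"))
    cfg <- config
    cfg$n_per_type <- as.list(cfg$n_per_type)
    cfg$intra_boost <- as.list(cfg$intra_boost)
    cfg$volume_mean <- as.list(cfg$volume_mean)
    cfg$volume_sd <- as.list(cfg$volume_sd)
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
    cohort <- validate_cohort(cohort, dir = dir)
  } else {
    cohort$complete <- TRUE
  }
  list(cohort = cohort, truth = truth)
}

#' Simulate a cohort and compute its study table in one pass
#'
#' Streaming equivalent of [generate_cohort()] followed by
#' [assemble_study_table()]: each femur's four masks are generated, compared,
#' and discarded, so a full-size cohort never has to be held in memory or
#' written to disk. Numerically identical to the two-step route for the same
#' configuration.
#'
#' @param config A [synthetic_config()].
#' @return A list with `study` (a `segrel_study` table) and `truth`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  plan <- cohort_plan(config)
  pairings <- list(
    inter_1 = c("I1", "II1", "inter"), inter_2 = c("I2", "II2", "inter"),
    intra_I = c("I1", "I2", "intra"), intra_II = c("II1", "II2", "intra")
  )
  rows <- list(); truths <- list()
  for (i in seq_len(nrow(plan))) {
    fem <- generate_femur(config, plan$femur_id[i], plan$lesion_type[i],
                          plan$femur_seed[i])
    truths[[i]] <- fem$truth
    for (set in names(pairings)) {
      p <- pairings[[set]]
      cmp <- compare_pair(fem$masks[[p[1]]], fem$masks[[p[2]]])
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(femur_id = plan$femur_id[i],
                       lesion_type = plan$lesion_type[i],
                       kind = p[3], set = set), cmp)
    }
  }
  study <- dplyr::bind_rows(rows)
  class(study) <- c("segrel_study", class(study))
  list(study = study, truth = dplyr::bind_rows(truths))
}
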