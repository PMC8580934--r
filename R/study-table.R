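comparison_set_levels <- c("inter_1", "inter_2", "intra_I", "intra_II")

#' Merge all lesion masks of one femur/operator/session into a union mask
#'
#' Operators do not necessarily agree on the number of lesions within a
#' femur: one may segment a single large lesion where the other draws two
#' smaller ones. Agreement is therefore always measured per femur on the
#' voxelwise union of all lesions an operator segmented in that femur, which
#' makes the Dice coefficient insensitive to split/merge disagreement.
#'
#' @param masks A list of [label_mask()] objects on one shared grid.
#' @return A single [label_mask()]: the voxelwise union.
#' @export
merge_lesions_per_femur <- function(masks) {
  if (!length(masks)) stop("no masks to merge", call. = FALSE)
  for (m in masks) stopifnot_mask(m)
  out <- masks[[1]]$voxels
  for (m in masks[-1]) {
    validate_same_grid(masks[[1]], m)
    out <- out | m$voxels
  }
  label_mask(out, masks[[1]]$spacing)
}

fetch_mask <- function(row) {
  if (!is.null(row$mask[[1]]) && is_label_mask(row$mask[[1]])) return(row$mask[[1]])
  read_mask(row$mask_path[[1]])
}

#' Assemble the per-femur comparison table of a reliability study
#'
#' For every complete femur (all four operator x session segmentations
#' present) this builds the four standard comparisons of a two-operator,
#' two-session design:
#'
#' * `inter_1`: operator I vs operator II, first session;
#' * `inter_2`: operator I vs operator II, second session;
#' * `intra_I`: operator I, session 1 vs session 2;
#' * `intra_II`: operator II, session 1 vs session 2.
#'
#' Pairs in which both segmentations are empty carry no agreement information
#' and are dropped with a warning. Incomplete femurs contribute no rows.
#'
#' @param cohort A cohort tibble from [load_cohort()] or
#'   [generate_cohort()]: one row per (femur, operator, session) with either
#'   a `mask` list-column of [label_mask()] objects or a `mask_path` column
#'   of NIfTI paths.
#' @param components If `TRUE`, also count connected components of each mask
#'   (columns `n_components_a`, `n_components_b`) as a split/merge
#'   disagreement diagnostic. Off by default; it does not affect any metric.
#' @return A tibble of class `segrel_study` with one row per femur and
#'   comparison set: `femur_id`, `lesion_type`, `kind` (`inter`/`intra`),
#'   `set` (one of `inter_1`, `inter_2`, `intra_I`, `intra_II`) and the
#'   [compare_pair()] columns.
#' @export
assemble_study_table <- function(cohort, components = FALSE) {
  cohort <- tibble::as_tibble(cohort)
  if (!"mask" %in% names(cohort)) cohort$mask <- vector("list", nrow(cohort))
  if ("complete" %in% names(cohort)) cohort <- cohort[cohort$complete, ]

  pairings <- tibble::tibble(
    set = comparison_set_levels,
    kind = c("inter", "inter", "intra", "intra"),
    op_a = c("I", "I", "I", "II"), se_a = c("1", "2", "1", "1"),
    op_b = c("II", "II", "I", "II"), se_b = c("1", "2", "2", "2")
  )

  rows <- list()
  for (fid in unique(cohort$femur_id)) {
    fem <- cohort[cohort$femur_id == fid, ]
    masks <- list()
    for (i in seq_len(nrow(fem))) {
      masks[[paste(fem$operator[i], fem$session[i])]] <- fetch_mask(fem[i, ])
    }
    for (j in seq_len(nrow(pairings))) {
      p <- pairings[j, ]
      a <- masks[[paste(p$op_a, p$se_a)]]
      b <- masks[[paste(p$op_b, p$se_b)]]
      if (!any(a$voxels) && !any(b$voxels)) {
        warning(sprintf("femur %s, %s: both segmentations empty; pair excluded",
                        fid, p$set), call. = FALSE)
        next
      }
      cmp <- compare_pair(a, b)
      if (components) {
        cmp$n_components_a <- count_components(a)
        cmp$n_components_b <- count_components(b)
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(femur_id = fid, lesion_type = fem$lesion_type[1],
                       kind = p$kind, set = p$set),
        cmp
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(femur_id = character(), lesion_type = character(),
                   kind = character(), set = character(), dice = double(),
                   volume_a = double(), volume_b = double(),
                   volume_intersection = double(), non_overlap_volume = double(),
                   mean_volume = double())
  class(out) <- c("segrel_study", class(out))
  out
}
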