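#' Read a binary lesion mask from a NIfTI file
#'
#' Loads a 3-D NIfTI volume and binarises it: any nonzero stored value maps
#' to in-set. Voxel spacing is taken from the header (`pixdim`), in mm.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3-D volume.
#' @return A [label_mask()].
#' @seealso [write_mask()] for the inverse operation.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected 3-D volume in ", path, "; file has ", length(d),
         " dimensions", call. = FALSE)
  }
  sp <- RNifti::pixdim(img)
  if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0)) {
    stop("header spacing (pixdim) must be 3 strictly positive values in ",
         path, "; got (", paste(signif(sp, 6), collapse = ", "), ")",
         call. = FALSE)
  }
  label_mask(as.array(img) != 0, spacing = as.double(sp))
}

#' Write a binary mask to a NIfTI file
#'
#' Stores occupancy as `uint8` (0/1) with the mask's spacing in the header,
#' so that `read_mask(write_mask(m, path))` reproduces voxels and spacing
#' exactly.
#'
#' @param mask A [label_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot_mask(mask)
  arr <- array(as.integer(mask$voxels), dim = dim(mask$voxels))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

cohort_operators <- c("I", "II")
cohort_sessions <- c("1", "2")
cohort_lesion_types <- c("osteolytic", "osteoblastic", "mixed")

#' Load and validate a cohort manifest
#'
#' A reliability cohort is described by a CSV manifest with one row per
#' segmentation: columns `femur_id`, `operator` (`I`/`II`), `session`
#' (`1`/`2`), `lesion_type` (`osteolytic`/`osteoblastic`/`mixed`) and
#' `mask_path`. A femur is *complete* when all four (operator, session)
#' combinations are present; every paired statistic in the analysis needs all
#' four segmentations, so incomplete femurs are flagged and later excluded
#' (with a warning) rather than imputed.
#'
#' @param manifest Path to the manifest CSV. Relative `mask_path` entries are
#'   resolved against the manifest's directory.
#' @return A tibble with one row per segmentation record, columns as in the
#'   manifest plus a logical `complete` column, ordered by femur, operator,
#'   session.
#' @export
load_cohort <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest, call. = FALSE)
  rec <- readr::read_csv(manifest, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("femur_id", "operator", "session", "lesion_type", "mask_path")
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  validate_cohort(dplyr::select(rec, dplyr::all_of(needed)), dir = dirname(manifest))
}

# Shared validation for manifests and in-memory cohorts (generator output).
validate_cohort <- function(rec, dir = NULL) {
  rec <- tibble::as_tibble(rec)
  for (col in c("operator", "session", "lesion_type")) {
    rec[[col]] <- as.character(rec[[col]])
  }
  bad_op <- setdiff(unique(rec$operator), cohort_operators)
  if (length(bad_op)) {
    stop("unknown operator value(s): ", paste(bad_op, collapse = ", "),
         " (expected I or II)", call. = FALSE)
  }
  bad_se <- setdiff(unique(rec$session), cohort_sessions)
  if (length(bad_se)) {
    stop("unknown session value(s): ", paste(bad_se, collapse = ", "),
         " (expected 1 or 2)", call. = FALSE)
  }
  bad_ty <- setdiff(unique(rec$lesion_type), cohort_lesion_types)
  if (length(bad_ty)) {
    stop("unknown lesion_type value(s): ", paste(bad_ty, collapse = ", "),
         " (expected osteolytic, osteoblastic or mixed)", call. = FALSE)
  }

  key <- paste(rec$femur_id, rec$operator, rec$session, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- rec[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate record for femur %s, operator %s, session %s",
                 dup$femur_id, dup$operator, dup$session), call. = FALSE)
  }

  type_per_femur <- tapply(rec$lesion_type, rec$femur_id,
                           function(x) length(unique(x)))
  if (any(type_per_femur > 1)) {
    stop("conflicting lesion_type within femur ",
         names(type_per_femur)[type_per_femur > 1][1], call. = FALSE)
  }

  if (!is.null(dir) && "mask_path" %in% names(rec)) {
    rel <- !grepl("^(/|[A-Za-z]:)", rec$mask_path)
    rec$mask_path[rel] <- file.path(dir, rec$mask_path[rel])
  }

  n_combo <- tapply(key, rec$femur_id, length)
  complete_ids <- names(n_combo)[n_combo == 4L]
  rec$complete <- rec$femur_id %in% complete_ids
  if (any(!rec$complete)) {
    inc <- unique(rec$femur_id[!rec$complete])
    warning("femur(s) with fewer than 4 segmentations excluded from paired analyses: ",
            paste(inc, collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(rec, .data$femur_id, .data$operator, .data$session)
}

#' Write a cohort manifest CSV
#'
#' @param cohort A tibble with columns `femur_id`, `operator`, `session`,
#'   `lesion_type`, `mask_path`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  cols <- c("femur_id", "operator", "session", "lesion_type", "mask_path")
  readr::write_csv(dplyr::select(tibble::as_tibble(cohort), dplyr::all_of(cols)), path)
  invisible(path)
}
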