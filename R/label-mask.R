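#' Construct a binary label mask
#'
#' A `label_mask` is a 3-D binary occupancy array together with its voxel
#' spacing in millimetres. It is the elementary object of every overlap
#' computation in the package: the two segmentations compared by
#' [dice_coefficient()] and [non_overlap_volume()] are both label masks on
#' the same voxel grid.
#'
#' Any nonzero value in `voxels` is treated as in-set: stored label values
#' (1, 3, 255, ...) are collapsed to occupancy on construction. This matches
#' the analysis convention that all lesions within a femur are merged before
#' agreement is measured, so distinct label ids carry no information here.
#'
#' @param voxels A 3-D `logical` or `numeric` array. Nonzero / `TRUE` means
#'   the voxel belongs to the segmentation.
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm, in
#'   array index order (first, second, third dimension). All components must
#'   be strictly positive.
#' @return An object of class `label_mask`: a list with elements `voxels`
#'   (logical 3-D array) and `spacing` (double, mm).
#' @examples
#' m <- label_mask(array(c(1, 0, 0, 1), c(2, 2, 1)), spacing = c(1, 1, 2.5))
#' mask_volume(m)
#' @export
label_mask <- function(voxels, spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3-D array; got ",
         if (is.array(voxels)) paste0(length(dim(voxels)), "-D") else class(voxels)[1],
         call. = FALSE)
  }
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || anyNA(spacing)) {
    stop("`spacing` must be 3 finite voxel edge lengths in mm", call. = FALSE)
  }
  if (any(spacing <= 0)) {
    bad <- which(spacing <= 0)[1]
    stop("`spacing` must be strictly positive; axis ", bad, " is ",
         spacing[bad], call. = FALSE)
  }
  if (!is.logical(voxels)) {
    storage.mode(voxels) <- "double"
    voxels <- voxels != 0
  }
  if (anyNA(voxels)) stop("`voxels` contains missing values", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_mask> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, %d in-set (%.4g cm^3)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$voxels), mask_volume(x)))
  invisible(x)
}

#' @export
dim.label_mask <- function(x) dim(x$voxels)

#' Test whether an object is a label mask
#' @param x Any object.
#' @return `TRUE` for objects created by [label_mask()] or [read_mask()].
#' @export
is_label_mask <- function(x) inherits(x, "label_mask")

stopifnot_mask <- function(x, arg = deparse(substitute(x))) {
  if (!is_label_mask(x)) {
    stop("`", arg, "` must be a label_mask (see ?label_mask)", call. = FALSE)
  }
  invisible(x)
}

#' Check that two masks live on the same voxel grid
#'
#' Overlap metrics are exact voxel-set operations and are only meaningful
#' when both segmentations annotate the same image grid (same dimensions and
#' same voxel spacing). No resampling or registration is performed by this
#' package: paired segmentations of one femur come from the same CT scan and
#' therefore share a grid by construction.
#'
#' @param a,b `label_mask` objects.
#' @param tol Spacing tolerance in mm per axis (default `1e-6`).
#' @return Invisibly `TRUE` if the grids match; otherwise an error naming the
#'   offending axis.
#' @export
validate_same_grid <- function(a, b, tol = 1e-6) {
  stopifnot_mask(a)
  stopifnot_mask(b)
  da <- dim(a$voxels); db <- dim(b$voxels)
  if (!identical(da, db)) {
    ax <- which(da != db)[1]
    stop(sprintf("grid shape mismatch on axis %d: %d vs %d voxels", ax, da[ax], db[ax]),
         call. = FALSE)
  }
  dsp <- abs(a$spacing - b$spacing)
  if (any(dsp > tol)) {
    ax <- which(dsp > tol)[1]
    stop(sprintf("voxel spacing mismatch on axis %d: %.6g vs %.6g mm", ax,
                 a$spacing[ax], b$spacing[ax]), call. = FALSE)
  }
  invisible(TRUE)
}
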