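#' Volumetric label mask with physical spacing
#'
#' The geometric substrate for all radius and volume computation: a 3D
#' integer label grid (0 = background, 1 = artery, 2 = vein; a plain binary
#' mask uses 1 for all foreground) together with the voxel spacing in mm
#' along each axis and the world position of voxel (1,1,1).
#'
#' World position of voxel index (i,j,k) (1-based) is
#' `origin + (i-1, j-1, k-1) * spacing`. Direction cosines are not modeled:
#' radii and volumes are rotation-invariant, so all computation happens in
#' index/spacing space.
#'
#' @param labels 3D integer array with values in \{0, 1, 2\}.
#' @param spacing Numeric length-3, voxel edge lengths in mm, all > 0.
#' @param origin Numeric length-3, world coordinate (mm) of the first voxel.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L))
  if (length(bad))
    stop("unexpected label value(s): ", paste(bad, collapse = ", "),
         " (allowed: 0, 1, 2)", call. = FALSE)
  structure(list(labels = labels, spacing = spacing, origin = origin),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$labels)
  n <- mask_foreground_count(x)
  cat(sprintf("<voxel_mask> %d x %d x %d, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  foreground: %d voxels (artery %d, vein %d)\n",
              n, sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

#' @export
dim.voxel_mask <- function(x) dim(x$labels)

#' Number of foreground voxels in a mask
#'
#' @param mask A [voxel_mask()].
#' @param compartment `"all"`, `"artery"` or `"vein"`.
#' @return Integer count.
#' @export
mask_foreground_count <- function(mask, compartment = "all") {
  sum(compartment_select(mask, compartment))
}

#' Volume of one voxel in mL
#'
#' @param mask A [voxel_mask()].
#' @return `prod(spacing)` in mm^3 divided by 1000 (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(mask) prod(mask$spacing) / 1000

# Logical 3D array: which voxels belong to the requested compartment.
compartment_select <- function(mask, compartment = c("all", "artery", "vein")) {
  compartment <- match.arg(compartment)
  switch(compartment,
         all    = mask$labels > 0L,
         artery = mask$labels == 1L,
         vein   = mask$labels == 2L)
}

# 1-based voxel index matrix (n x 3) -> world coordinates (mm).
index_to_world <- function(mask, idx) {
  sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

stopifnot_same_grid <- function(a, b, what = "mask") {
  if (!identical(dim(a$labels), dim(b$labels)) ||
      max(abs(a$spacing - b$spacing)) > 1e-6)
    stop(what, " is not on the same grid (shape/spacing mismatch)",
         call. = FALSE)
  invisible(TRUE)
}
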