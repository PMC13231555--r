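#' Read a vessel mask from NIfTI or NRRD
#'
#' Reads a 3D label volume and normalizes it to the package's convention:
#' 0 = background, 1 = artery, 2 = vein. A plain binary mask (values 0/1)
#' is treated as all-artery unless `binary_as` says otherwise. Any other
#' nonzero value is an error unless `remap` translates it.
#'
#' Voxel spacing is taken from the file header, in mm. NIfTI volumes with a
#' non-axis-aligned orientation are accepted with a warning; all computation
#' is done in index/spacing space since radii and volumes are
#' rotation-invariant.
#'
#' @param path Path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @param dialect `"auto"` (from the extension), `"nifti"` or `"nrrd"`.
#' @param binary_as Label to assign to the foreground of a 0/1 mask
#'   (`"artery"` or `"vein"`).
#' @param remap Optional named integer vector mapping file values to
#'   \{0,1,2\}, e.g. `c("3" = 1, "4" = 2)`.
#' @return A [voxel_mask()].
#' @export
read_mask <- function(path, dialect = c("auto", "nifti", "nrrd"),
                      binary_as = c("artery", "vein"), remap = NULL) {
  dialect <- match.arg(dialect)
  binary_as <- match.arg(binary_as)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto")
    dialect <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"

  if (dialect == "nifti") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("could not parse NIfTI file ",
                                             path, ": ", conditionMessage(e),
                                             call. = FALSE))
    arr <- as.array(img)
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
      arr <- array(arr, dim = dim(arr)[1:3])
    if (length(dim(arr)) != 3L)
      stop("expected a 3D volume, got ", length(dim(arr)), " dimensions",
           call. = FALSE)
    spacing <- RNifti::pixdim(img)[1:3]
    xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
    origin <- c(0, 0, 0)
    if (!is.null(xf) && all(dim(xf) == c(4, 4))) {
      origin <- xf[1:3, 4]
      rot <- abs(xf[1:3, 1:3])
      if (any(rot[!diag(3)] > 1e-4 * max(rot)))
        warning("non-axis-aligned orientation ignored; computing in ",
                "index/spacing space", call. = FALSE)
    }
  } else {
    nr <- tryCatch(read_nrrd(path),
                   error = function(e) stop("could not parse NRRD file ",
                                            path, ": ", conditionMessage(e),
                                            call. = FALSE))
    arr <- nr$data
    spacing <- nr$spacing
    origin <- ifelse(is.na(nr$origin), 0, nr$origin)
  }

  vals <- round(arr)
  if (max(abs(arr - vals), na.rm = TRUE) > 1e-6)
    stop("mask contains non-integer values", call. = FALSE)
  if (!is.null(remap)) {
    from <- as.numeric(names(remap))
    for (i in seq_along(from)) vals[arr == from[i]] <- remap[[i]]
  }
  present <- unique(as.vector(vals))
  bad <- setdiff(present, c(0, 1, 2))
  if (length(bad))
    stop("unexpected label value(s) in ", path, ": ",
         paste(bad, collapse = ", "),
         " (supply `remap` to translate them)", call. = FALSE)
  if (setequal(present[present != 0], 1) && binary_as == "vein")
    vals[vals == 1] <- 2
  voxel_mask(array(as.integer(vals), dim = dim(arr)),
             spacing = spacing, origin = origin)
}

#' Write a vessel mask to NIfTI or NRRD
#'
#' The on-disk file round-trips through [read_mask()] to an equal mask:
#' identical labels and shape, spacing within float tolerance.
#'
#' @param mask A [voxel_mask()].
#' @param path Output path; the extension picks the format when
#'   `dialect = "auto"`.
#' @inheritParams read_mask
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, dialect = c("auto", "nifti", "nrrd")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(mask, "voxel_mask"))
  if (dialect == "auto")
    dialect <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  if (dialect == "nifti") {
    write_volume_nifti(mask$labels, path, mask$spacing, mask$origin,
                       datatype = "uint8")
  } else {
    write_nrrd(mask$labels, path, mask$spacing, mask$origin, type = "uint8")
  }
  invisible(path)
}

# Shared NIfTI writer for label and float volumes.
write_volume_nifti <- function(arr, path, spacing, origin,
                               datatype = c("uint8", "float")) {
  datatype <- match.arg(datatype)
  img <- RNifti::asNifti(arr)
  sf <- diag(c(spacing, 1))
  sf[1:3, 4] <- origin
  img <- RNifti::asNifti(img, reference = list(pixdim = c(1, spacing, rep(1, 4))))
  RNifti::sform(img) <- structure(sf, code = 2L)
  RNifti::qform(img) <- structure(sf, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a subject metadata table
#'
#' Expects a CSV with header `id,group,age,sex,height_cm,weight_kg` (or a
#' JSON array of objects with those keys). `group` must be `patient` or
#' `control`; `sex` must be `male` or `female`. Body surface area is not
#' read: it is computed from height and weight by [compute_bsa()].
#'
#' @param path CSV or JSON file path.
#' @return A data.frame of class `subject_table` with columns `id`, `group`,
#'   `age`, `sex`, `height_cm`, `weight_kg` and `bsa` (all `NA` until
#'   [compute_bsa()] fills it).
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  as_subject_table(df)
}

#' Validate a data.frame of subjects
#'
#' @param df Data.frame with columns `id`, `group`, `age`, `sex`,
#'   `height_cm`, `weight_kg`.
#' @return The validated `subject_table`.
#' @export
as_subject_table <- function(df) {
  need <- c("id", "group", "age", "sex", "height_cm", "weight_kg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df)) {
    badg <- !df$group %in% c("patient", "control")
    if (any(badg))
      stop("invalid group value in row(s) ", paste(which(badg), collapse = ", "),
           " (expected 'patient' or 'control')", call. = FALSE)
    bads <- !df$sex %in% c("male", "female")
    if (any(bads))
      stop("invalid sex value in row(s) ", paste(which(bads), collapse = ", "),
           call. = FALSE)
    badh <- !is.finite(df$height_cm) | df$height_cm <= 0
    badw <- !is.finite(df$weight_kg) | df$weight_kg <= 0
    if (any(badh | badw))
      stop("nonpositive height/weight in row(s) ",
           paste(which(badh | badw), collapse = ", "), call. = FALSE)
    if (anyDuplicated(df$id))
      stop("duplicate subject id(s): ",
           paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
           call. = FALSE)
  }
  df <- df[c(need, intersect("bsa", names(df)))]
  if (is.null(df$bsa)) df$bsa <- rep(NA_real_, nrow(df))
  class(df) <- c("subject_table", "data.frame")
  df
}

#' Export a radius field (and provenance) as volumes
#'
#' Writes the per-voxel radius in mm as a float volume (background 0) and,
#' optionally, the provenance map as a uint8 volume
#' (0 = background, 1 = centerline, 2 = constrained, 3 = fallback).
#'
#' @param field A `radius_field` from [propagate_radius()].
#' @param mask The source [voxel_mask()].
#' @param path Output path for the radius volume (`.nii`, `.nii.gz`, `.nrrd`).
#' @param provenance_path Optional output path for the provenance map.
#' @return `path`, invisibly.
#' @export
write_radius_field <- function(field, mask, path, provenance_path = NULL) {
  stopifnot(inherits(field, "radius_field"))
  arr <- field$radius
  arr[is.na(arr)] <- 0
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(arr, path, mask$spacing, mask$origin, type = "double")
  } else {
    write_volume_nifti(arr, path, mask$spacing, mask$origin, datatype = "float")
  }
  if (!is.null(provenance_path)) {
    prov <- field$provenance_codes
    if (grepl("\\.nrrd$", provenance_path, ignore.case = TRUE)) {
      write_nrrd(prov, provenance_path, mask$spacing, mask$origin, type = "uint8")
    } else {
      write_volume_nifti(prov, provenance_path, mask$spacing, mask$origin,
                         datatype = "uint8")
    }
  }
  invisible(path)
}
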