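#' Diameter bins for vessel-volume stratification
#'
#' The five diameter groups 0.8–1.6, 1.6–2.4, 2.4–3.2, 3.2–4.0 and > 4.0 mm,
#' each with a strict lower and an inclusive upper boundary, plus the
#' sub-threshold interval (0, 0.8] that is reported separately and excluded
#' from headline totals (0.8 mm is the minimum diameter reliably resolved
#' on CT pulmonary angiography).
#'
#' @param edges Ordered interior thresholds in mm.
#' @return A `diameter_bins` object with `breaks`, `labels` and the
#'   sub-threshold label.
#' @export
diameter_bins <- function(edges = c(0.8, 1.6, 2.4, 3.2, 4.0)) {
  stopifnot(length(edges) >= 1, all(diff(edges) > 0), all(edges > 0))
  k <- length(edges)
  labels <- c("sub_threshold",
              paste0(format(edges[-k], trim = TRUE), "-",
                     format(edges[-1], trim = TRUE), "mm"),
              paste0(">", format(edges[k], trim = TRUE), "mm"))
  structure(list(edges = edges,
                 breaks = c(0, edges, Inf),
                 labels = labels),
            class = "diameter_bins")
}

#' Assign diameters to bins
#'
#' Membership uses the strict-lower / inclusive-upper rule: a diameter of
#' exactly 1.6 mm falls in 0.8–1.6 mm; exactly 0.8 mm falls in the
#' sub-threshold bin.
#'
#' @param diameter_mm Numeric vector of diameters (mm), all > 0.
#' @param bins A [diameter_bins()].
#' @return Factor with the bins' labels.
#' @export
bin_of_diameter <- function(diameter_mm, bins = diameter_bins()) {
  stopifnot(inherits(bins, "diameter_bins"))
  cut(diameter_mm, breaks = bins$breaks, labels = bins$labels, right = TRUE)
}

#' Body surface area by the DuBois formula
#'
#' `BSA(m^2) = Weight(kg)^0.425 x Height(cm)^0.725 x 0.007184`.
#'
#' @param subjects A `subject_table` (from [read_subjects()] /
#'   [as_subject_table()]); its `bsa` column is filled. Alternatively pass
#'   `height_cm` and `weight_kg` directly to get a numeric vector.
#' @param height_cm,weight_kg Used when `subjects` is missing.
#' @return The `subject_table` with `bsa` filled, or a numeric vector.
#' @export
compute_bsa <- function(subjects = NULL, height_cm = NULL, weight_kg = NULL) {
  if (!is.null(subjects)) {
    stopifnot(inherits(subjects, "data.frame"))
    subjects$bsa <- compute_bsa(height_cm = subjects$height_cm,
                                weight_kg = subjects$weight_kg)
    return(subjects)
  }
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive and finite", call. = FALSE)
  weight_kg^0.425 * height_cm^0.725 * 0.007184
}

#' Diameter-binned vessel volumes from a radius field
#'
#' Each foreground voxel contributes its voxel volume (mm^3 / 1000 = mL) to
#' the diameter bin containing its propagated diameter `d = 2 * radius`, in
#' its compartment (artery / vein). Headline totals sum the supra-threshold
#' bins only: `IPVVa` (artery), `IPVVv` (vein) and `TIPVV = IPVVa + IPVVv`.
#' The sub-threshold bin (d <= 0.8 mm) is reported separately; set
#' `include_subthreshold = TRUE` to fold it into the totals.
#'
#' @param field A `radius_field` covering the mask's foreground.
#' @param mask The source [voxel_mask()].
#' @param bins A [diameter_bins()].
#' @param roi Optional lung-ROI [voxel_mask()] on the same grid; only
#'   foreground voxels inside the ROI are counted (used e.g. to exclude
#'   hilar vessels).
#' @param include_subthreshold Include the sub-threshold bin in totals.
#' @return A `volume_report`: `bins` data.frame (compartment, bin, voxel
#'   count, volume_ml), `totals` (TIPVV/IPVVa/IPVVv, mL), bookkeeping
#'   (voxel volume, fallback fraction, whether an ROI was applied).
#' @export
bin_volumes <- function(field, mask, bins = diameter_bins(), roi = NULL,
                        include_subthreshold = FALSE) {
  stopifnot(inherits(field, "radius_field"), inherits(mask, "voxel_mask"))
  if (!identical(dim(field$radius), dim(mask$labels)))
    stop("radius field and mask have different shapes", call. = FALSE)
  sel <- mask$labels > 0L
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "voxel_mask"))
    stopifnot_same_grid(roi, mask, "roi")
    sel <- sel & roi$labels > 0L
  }
  if (any(sel & is.na(field$radius)))
    stop("radius field does not cover the selected foreground", call. = FALSE)
  vv <- voxel_volume_ml(mask)
  lab <- mask$labels[sel]
  bin <- bin_of_diameter(2 * field$radius[sel], bins)
  counts <- table(compartment = factor(lab, levels = c(1L, 2L),
                                       labels = c("artery", "vein")),
                  bin = bin)
  tab <- as.data.frame(counts, responseName = "voxels",
                       stringsAsFactors = FALSE)
  tab$compartment <- as.character(tab$compartment)
  tab$bin <- as.character(tab$bin)
  all_tab <- data.frame(compartment = "all", bin = bins$labels,
                        voxels = as.vector(counts["artery", ] + counts["vein", ]),
                        stringsAsFactors = FALSE)
  tab <- rbind(tab, all_tab)
  tab$voxels <- as.numeric(tab$voxels)
  tab$volume_ml <- tab$voxels * vv
  tab$bin <- factor(tab$bin, levels = bins$labels)
  tab <- tab[order(match(tab$compartment, c("artery", "vein", "all")),
                   tab$bin), ]
  rownames(tab) <- NULL

  supra <- if (include_subthreshold) bins$labels else
    setdiff(bins$labels, "sub_threshold")
  tot <- function(cc) sum(tab$volume_ml[tab$compartment == cc &
                                          tab$bin %in% supra])
  ipvva <- tot("artery")
  ipvvv <- tot("vein")
  structure(list(
    bins = tab,
    totals = c(TIPVV = ipvva + ipvvv, IPVVa = ipvva, IPVVv = ipvvv),
    subthreshold_ml = c(
      artery = sum(tab$volume_ml[tab$compartment == "artery" &
                                   tab$bin == "sub_threshold"]),
      vein = sum(tab$volume_ml[tab$compartment == "vein" &
                                 tab$bin == "sub_threshold"])),
    include_subthreshold = include_subthreshold,
    voxel_volume_ml = vv,
    foreground_voxels = sum(sel),
    fallback_fraction = field$fallback_fraction,
    roi_applied = !is.null(roi),
    normalized = FALSE,
    bin_labels = bins$labels), class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat("<volume_report>",
      if (x$roi_applied) "(ROI applied)" else "(whole mask)", "\n")
  t <- x$totals
  cat(sprintf("  TIPVV %.2f mL | IPVVa %.2f mL | IPVVv %.2f mL\n",
              t["TIPVV"], t["IPVVa"], t["IPVVv"]))
  if (isTRUE(x$normalized))
    cat(sprintf("  normalized (BSA %.2f m^2): TIPVV %.2f mL/m^2\n",
                x$bsa, x$totals_per_m2["TIPVV"]))
  print(x$bins, ...)
  invisible(x)
}

#' Normalize a volume report by body surface area
#'
#' Divides every volume by the subject's BSA (DuBois), yielding mL per m^2;
#' raw values are retained alongside. Normalization is linear, so it
#' commutes with summation over bins.
#'
#' @param report A `volume_report` from [bin_volumes()].
#' @param subject A one-row `subject_table` (or any list with `bsa`), with
#'   `bsa` already computed via [compute_bsa()].
#' @return The report with `volume_ml_per_m2` columns and normalized totals
#'   added.
#' @export
normalize_report <- function(report, subject) {
  stopifnot(inherits(report, "volume_report"))
  bsa <- subject$bsa
  if (is.null(bsa) || length(bsa) != 1L || !is.finite(bsa) || bsa <= 0)
    stop("subject has no computed BSA; run compute_bsa() first", call. = FALSE)
  report$bins$volume_ml_per_m2 <- report$bins$volume_ml / bsa
  report$totals_per_m2 <- report$totals / bsa
  report$subthreshold_ml_per_m2 <- report$subthreshold_ml / bsa
  report$bsa <- bsa
  report$subject_id <- if (!is.null(subject$id)) subject$id else NA_character_
  report$normalized <- TRUE
  report
}

#' Color-code a vessel mask by diameter or compartment
#'
#' `by_diameter` labels: 1 = 0.8 < d <= 3.2 mm (red), 2 = 3.2 < d <= 4.0 mm
#' (yellow), 3 = d > 4.0 mm (blue), 4 = d <= 0.8 mm (gray, sub-threshold).
#' `by_compartment` labels: 1 = artery (red), 2 = vein (blue). The color
#' map is returned alongside and written as a JSON sidecar by
#' [write_label_volume()].
#'
#' @param field A `radius_field` (needed for `by_diameter`).
#' @param mask The source [voxel_mask()].
#' @param scheme `"by_diameter"` or `"by_compartment"`.
#' @return A `label_volume`: list with `labels` (3D integer array),
#'   `spacing`, `origin` and `colormap` (named label -> color).
#' @export
color_code <- function(field = NULL, mask,
                       scheme = c("by_diameter", "by_compartment")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(mask, "voxel_mask"))
  labels <- array(0L, dim = dim(mask$labels))
  if (scheme == "by_compartment") {
    labels[] <- mask$labels
    colormap <- c("1" = "red", "2" = "blue")
  } else {
    stopifnot(inherits(field, "radius_field"))
    sel <- mask$labels > 0L
    d <- 2 * field$radius[sel]
    code <- ifelse(d <= 0.8, 4L, ifelse(d <= 3.2, 1L, ifelse(d <= 4.0, 2L, 3L)))
    labels[sel] <- code
    colormap <- c("1" = "red", "2" = "yellow", "3" = "blue", "4" = "gray")
  }
  structure(list(labels = labels, spacing = mask$spacing,
                 origin = mask$origin, colormap = colormap),
            class = "label_volume")
}

#' Write a color-coded label volume with its JSON color map
#'
#' @param lv A `label_volume` from [color_code()].
#' @param path Output volume path (`.nii`, `.nii.gz` or `.nrrd`).
#' @param colormap_path Path for the JSON color-map sidecar; default is
#'   `path` with a `.colormap.json` suffix.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(lv, path, colormap_path = NULL) {
  stopifnot(inherits(lv, "label_volume"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(lv$labels, path, lv$spacing, lv$origin, type = "uint8")
  } else {
    write_volume_nifti(lv$labels, path, lv$spacing, lv$origin,
                       datatype = "uint8")
  }
  if (is.null(colormap_path))
    colormap_path <- paste0(sub("\\.(nii\\.gz|nii|nrrd)$", "", path,
                                ignore.case = TRUE), ".colormap.json")
  jsonlite::write_json(as.list(lv$colormap), colormap_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
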