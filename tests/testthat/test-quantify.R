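test_that("DuBois BSA reproduces worked values and its power-law structure", {
  expect_equal(round(compute_bsa(height_cm = 164, weight_kg = 66), 2), 1.72)
  expect_equal(round(compute_bsa(height_cm = 170, weight_kg = 70), 2), 1.81)
  # scaling weight by 2^(1/0.425) doubles BSA exactly
  b1 <- compute_bsa(height_cm = 160, weight_kg = 60)
  b2 <- compute_bsa(height_cm = 160, weight_kg = 60 * 2^(1 / 0.425))
  expect_equal(b2, 2 * b1, tolerance = 1e-12)
  expect_error(compute_bsa(height_cm = -160, weight_kg = 60), "positive")

  subj <- as_subject_table(data.frame(
    id = "s1", group = "control", age = 45, sex = "male",
    height_cm = 164, weight_kg = 66))
  expect_equal(round(compute_bsa(subj)$bsa, 2), 1.72)
})

test_that("bin boundaries follow the strict-lower/inclusive-upper rule", {
  b <- diameter_bins()
  d <- c(0.5, 0.8, 0.8 + 1e-9, 1.6, 1.6 + 1e-9, 2.4, 3.2, 4.0, 4.0 + 1e-9, 9)
  expect_equal(as.character(bin_of_diameter(d, b)),
               c("sub_threshold", "sub_threshold", "0.8-1.6mm", "0.8-1.6mm",
                 "1.6-2.4mm", "1.6-2.4mm", "2.4-3.2mm", "3.2-4.0mm",
                 ">4mm", ">4mm"))
})

make_uniform_field <- function(dims, spacing, diameter, label = 1L) {
  lab <- array(label, dim = dims)
  m <- voxel_mask(lab, spacing = spacing)
  radius <- array(diameter / 2, dim = dims)
  field <- structure(list(radius = radius,
                          provenance = array(2L, dim = dims),
                          fallback_fraction = 0, compartment = "all"),
                     class = "radius_field")
  list(mask = m, field = field)
}

test_that("bin volumes follow direct voxel arithmetic", {
  u <- make_uniform_field(c(10, 10, 10), c(0.5, 0.5, 0.5), diameter = 2.0)
  rep <- bin_volumes(u$field, u$mask)
  tab <- rep$bins[rep$bins$compartment == "artery", ]
  expect_equal(tab$volume_ml[tab$bin == "1.6-2.4mm"], 1000 * 0.125 / 1000)
  expect_equal(sum(tab$volume_ml[tab$bin != "1.6-2.4mm"]), 0)
  expect_equal(unname(rep$totals["IPVVa"]), 0.125)
  expect_equal(unname(rep$totals["TIPVV"]), 0.125)
})

test_that("volumes are conserved and totals are additive", {
  ph <- make_tree(root_radius_mm = 3, depth = 2L, seed = 2L, label = 1L)
  # relabel half the tree as vein to exercise both compartments
  lab <- ph$mask$labels
  zcut <- dim(lab)[3] %/% 2
  lab[, , seq_len(zcut)][lab[, , seq_len(zcut)] > 0] <- 2L
  m <- voxel_mask(lab, spacing = ph$mask$spacing)
  rf <- vessel_radius_field(m)
  rep <- bin_volumes(rf, m)

  per_comp <- split(rep$bins, rep$bins$compartment)
  # integer voxel counts add up exactly
  expect_identical(sum(per_comp$artery$voxels) + sum(per_comp$vein$voxels),
                   as.numeric(mask_foreground_count(m)))
  expect_identical(per_comp$all$voxels,
                   per_comp$artery$voxels + per_comp$vein$voxels)
  # volume conservation including the sub-threshold bin
  expect_equal(sum(per_comp$all$volume_ml),
               mask_foreground_count(m) * voxel_volume_ml(m),
               tolerance = 1e-12)
  # additivity of headline totals
  expect_identical(unname(rep$totals["TIPVV"]),
                   unname(rep$totals["IPVVa"] + rep$totals["IPVVv"]))

  # sub-threshold voxels are excluded from totals unless asked for
  rep_in <- bin_volumes(rf, m, include_subthreshold = TRUE)
  expect_equal(unname(rep_in$totals["TIPVV"]),
               unname(rep$totals["TIPVV"] + sum(rep$subthreshold_ml)),
               tolerance = 1e-12)
})

test_that("binned volumes match a ground-truth oracle up to boundary voxels", {
  # segment diameters 2.8, 2.0 and 1.4 mm sit mid-bin, away from the bin
  # edges, so only boundary/junction voxels can land in a different bin
  # than the analytic truth
  ph <- make_tree(root_radius_mm = 1.4, depth = 2L, scale = 0.715,
                  root_length_mm = 15, spacing = c(0.5, 0.5, 0.5), seed = 6L)
  rf <- vessel_radius_field(ph$mask)
  rep <- bin_volumes(rf, ph$mask)
  # oracle: bin the analytic per-voxel truth instead of the propagated field
  fg <- ph$mask$labels > 0
  truth_bins <- table(bin_of_diameter(2 * ph$truth$radius[fg]))
  got_bins <- with(rep$bins[rep$bins$compartment == "all", ],
                   setNames(voxels, as.character(bin)))
  mismatch <- sum(abs(got_bins[names(truth_bins)] - as.numeric(truth_bins))) / 2
  expect_lt(mismatch / sum(fg), 0.25)  # only boundary/junction voxels move
})

test_that("normalization divides by BSA and commutes with summation", {
  u <- make_uniform_field(c(8, 8, 8), c(1, 1, 1), diameter = 3)
  rep <- bin_volumes(u$field, u$mask)
  subj <- compute_bsa(as_subject_table(data.frame(
    id = "s9", group = "control", age = 50, sex = "female",
    height_cm = 164, weight_kg = 66)))
  norm <- normalize_report(rep, subj)
  expect_equal(norm$totals_per_m2, norm$totals / subj$bsa)
  expect_equal(sum(norm$bins$volume_ml_per_m2[norm$bins$compartment == "all"]),
               sum(norm$bins$volume_ml[norm$bins$compartment == "all"]) / subj$bsa,
               tolerance = 1e-12)
  # raw 86 mL over BSA 1.72 -> 50 mL/m^2
  expect_equal(86 / subj$bsa, 50, tolerance = 0.01)
  expect_error(normalize_report(rep, list(bsa = NULL)), "BSA")
})

test_that("a +0.4 mm radius shift never moves volume to a lower bin", {
  ph <- make_tree(root_radius_mm = 2.5, depth = 1L, seed = 3L)
  rf <- vessel_radius_field(ph$mask)
  rep1 <- bin_volumes(rf, ph$mask)
  rf2 <- rf
  rf2$radius <- rf$radius + 0.4
  rep2 <- bin_volumes(rf2, ph$mask)
  b <- diameter_bins()$labels
  v1 <- with(rep1$bins[rep1$bins$compartment == "all", ],
             setNames(voxels, as.character(bin)))[b]
  v2 <- with(rep2$bins[rep2$bins$compartment == "all", ],
             setNames(voxels, as.character(bin)))[b]
  # cumulative count from the top bin down can only grow
  expect_true(all(rev(cumsum(rev(v2))) >= rev(cumsum(rev(v1)))))
})

test_that("an ROI restricts the counted voxels and must share the grid", {
  u <- make_uniform_field(c(6, 6, 6), c(1, 1, 1), diameter = 3)
  roi_lab <- array(0L, c(6, 6, 6)); roi_lab[1:3, , ] <- 1L
  roi <- voxel_mask(roi_lab)
  rep <- bin_volumes(u$field, u$mask, roi = roi)
  expect_equal(rep$foreground_voxels, 3 * 36)
  bad_roi <- voxel_mask(array(1L, c(5, 6, 6)))
  expect_error(bin_volumes(u$field, u$mask, roi = bad_roi), "grid")
})

test_that("diameter color coding uses the red/yellow/blue bands", {
  dims <- c(4, 4, 4)
  lab <- array(1L, dims)
  m <- voxel_mask(lab)
  mk <- function(d) structure(list(radius = array(d / 2, dims)),
                              class = "radius_field")
  expect_true(all(color_code(mk(5), m)$labels == 3L))     # > 4 mm: blue
  expect_true(all(color_code(mk(3.2), m)$labels == 1L))   # 3.2 exactly: red
  expect_true(all(color_code(mk(3.5), m)$labels == 2L))   # yellow band
  expect_true(all(color_code(mk(0.5), m)$labels == 4L))   # sub-threshold
  cm <- color_code(mk(5), m)$colormap
  expect_identical(cm[["1"]], "red")
  expect_identical(cm[["3"]], "blue")

  lab2 <- lab; lab2[1:2, , ] <- 2L
  m2 <- voxel_mask(lab2)
  cc <- color_code(mask = m2, scheme = "by_compartment")
  expect_identical(cc$labels, m2$labels)
  expect_identical(cc$colormap[["2"]], "blue")
})

test_that("label volumes are written with a JSON color-map sidecar", {
  ph <- make_cylinder(2.2, 10)
  rf <- vessel_radius_field(ph$mask)
  lv <- color_code(rf, ph$mask)
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_label_volume(lv, f)
  back <- ipvv:::read_nrrd(f)
  expect_equal(array(as.integer(back$data), dim(lv$labels)), lv$labels)
  cmap <- jsonlite::fromJSON(paste0(sub("\\.nrrd$", "", f), ".colormap.json"))
  expect_identical(cmap[["1"]], "red")
})
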