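# Independent brute-force references for the compiled geometry kernels.
# These deliberately re-derive each quantity from first principles (O(N*M)
# scans) and are only run on small inputs.

# Exhaustive EDT: min over all background voxel centers, physical spacing.
brute_edt <- function(mask, compartment = "all") {
  fg <- ipvv:::compartment_select(mask, compartment)
  dims <- dim(mask$labels)
  out <- array(NA_real_, dim = dims)
  bg_idx <- arrayInd(which(!fg), dims)
  fg_idx <- arrayInd(which(fg), dims)
  if (nrow(fg_idx) == 0) return(out)
  stopifnot(nrow(bg_idx) > 0)
  sp <- mask$spacing
  for (i in seq_len(nrow(fg_idx))) {
    dx <- (fg_idx[i, 1] - bg_idx[, 1]) * sp[1]
    dy <- (fg_idx[i, 2] - bg_idx[, 2]) * sp[2]
    dz <- (fg_idx[i, 3] - bg_idx[, 3]) * sp[3]
    out[fg_idx[i, 1], fg_idx[i, 2], fg_idx[i, 3]] <-
      sqrt(min(dx * dx + dy * dy + dz * dz))
  }
  out
}

# Exhaustive constrained nearest-neighbour propagation with the same
# candidate rule and tie-breaks as the production kernel: candidates are
# centerline points with dist < radius (strict); nearest wins; distance
# ties prefer the larger radius, then the smaller centerline list position;
# no candidate -> globally nearest centerline point (fallback).
brute_propagate <- function(mask, centerline, compartment = "all") {
  fg <- ipvv:::compartment_select(mask, compartment)
  dims <- dim(mask$labels)
  lin_fg <- which(fg)
  vox <- arrayInd(lin_fg, dims)
  dd <- as.numeric(dims)
  cl_lin <- (centerline$points[, 1] - 1) +
    dd[1] * ((centerline$points[, 2] - 1) + dd[2] * (centerline$points[, 3] - 1)) + 1
  sp <- mask$spacing
  r <- centerline$radius
  radius <- array(NA_real_, dim = dims)
  prov <- array(0L, dim = dims)
  for (i in seq_along(lin_fg)) {
    pos <- match(lin_fg[i], cl_lin)
    if (!is.na(pos)) {
      radius[lin_fg[i]] <- r[pos]
      prov[lin_fg[i]] <- 1L
      next
    }
    ax <- (vox[i, 1] - centerline$points[, 1]) * sp[1]
    ay <- (vox[i, 2] - centerline$points[, 2]) * sp[2]
    az <- (vox[i, 3] - centerline$points[, 3]) * sp[3]
    d2 <- ax * ax + ay * ay + az * az
    pick <- function(cand) cand[order(d2[cand], -r[cand], cand)][1]
    cand <- which(d2 < r * r)
    if (length(cand)) {
      j <- pick(cand)
      radius[lin_fg[i]] <- r[j]
      prov[lin_fg[i]] <- 2L
    } else {
      j <- pick(seq_along(r))
      radius[lin_fg[i]] <- r[j]
      prov[lin_fg[i]] <- 3L
    }
  }
  list(radius = radius, provenance = prov)
}

# Random blob mask: union of a few random balls, guaranteed background rim.
random_blob_mask <- function(seed, max_fg = 1e4) {
  set.seed(seed)
  sp <- sample(list(c(1, 1, 1), c(0.5, 0.5, 0.5), c(0.8, 0.8, 1.2)), 1)[[1]]
  kind <- sample(c("cylinder", "bent", "tree"), 1)
  ph <- switch(kind,
    cylinder = make_cylinder(runif(1, max(sp), 2.5), runif(1, 8, 25),
                             spacing = sp,
                             axis = rnorm(3) + c(0, 0, 0.5)),
    bent = make_bent_tube(runif(1, max(sp), 2), runif(1, 6, 15), spacing = sp),
    tree = {
      lo <- max(sp) / 0.7^2 + 0.05
      make_tree(root_radius_mm = runif(1, lo, lo + 0.8),
                depth = 2L, scale = 0.7, root_length_mm = runif(1, 6, 12),
                spacing = sp, seed = seed + 1000L)
    })
  if (mask_foreground_count(ph$mask) > max_fg) return(random_blob_mask(seed + 1))
  ph$mask
}

expect_radius_fields_identical <- function(fast, brute) {
  expect_identical(fast$provenance, brute$provenance)
  expect_identical(fast$radius, brute$radius)
}
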