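# Synthetic tubular phantoms with analytically known radii. Every phantom
# is the union of capsules (cylinders with hemispherical caps): a voxel is
# foreground iff its center lies within `radius` of some axis segment, the
# binary-mask analogue of a segmentation output. Ground truth carries, for
# each foreground voxel, the radius of the nearest generating segment
# (distance ties resolved toward the larger radius).

# Vectorized point-to-segment distance: P is n x 3, a and b length-3.
dist_point_segment <- function(P, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((P[, 1] - a[1])^2 + (P[, 2] - a[2])^2 + (P[, 3] - a[3])^2))
  }
  t <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2] +
          (P[, 3] - a[3]) * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  dx <- P[, 1] - (a[1] + t * ab[1])
  dy <- P[, 2] - (a[2] + t * ab[2])
  dz <- P[, 3] - (a[3] + t * ab[3])
  sqrt(dx^2 + dy^2 + dz^2)
}

# Rasterize a set of capsule segments onto a voxel grid sized to fit them
# with a background margin. segments: list of list(a =, b =, radius =).
rasterize_capsules <- function(segments, spacing, margin_vox = 2L) {
  stopifnot(length(segments) >= 1L)
  rads <- vapply(segments, `[[`, numeric(1), "radius")
  if (any(rads < max(spacing)))
    stop("sub-voxel tube: segment radius ", format(min(rads)),
         " mm < max spacing ", format(max(spacing)),
         " mm", call. = FALSE)
  ends <- do.call(rbind, lapply(segments, function(s) rbind(s$a, s$b)))
  rr <- rep(rads, each = 2)
  lo <- apply(ends - rr, 2, min) - margin_vox * spacing
  hi <- apply(ends + rr, 2, max) + margin_vox * spacing
  dims <- pmax(as.integer(ceiling((hi - lo) / spacing)) + 1L, 3L)
  origin <- lo

  bestd <- array(Inf, dim = dims)
  bestr <- array(NA_real_, dim = dims)
  fg <- array(FALSE, dim = dims)

  ax <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ay <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  az <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]

  for (s in segments) {
    pad <- s$radius + max(spacing)
    sub <- list(
      which(ax >= min(s$a[1], s$b[1]) - pad & ax <= max(s$a[1], s$b[1]) + pad),
      which(ay >= min(s$a[2], s$b[2]) - pad & ay <= max(s$a[2], s$b[2]) + pad),
      which(az >= min(s$a[3], s$b[3]) - pad & az <= max(s$a[3], s$b[3]) + pad))
    if (!all(lengths(sub) > 0)) next
    P <- as.matrix(expand.grid(ax[sub[[1]]], ay[sub[[2]]], az[sub[[3]]],
                               KEEP.OUT.ATTRS = FALSE))
    d <- dist_point_segment(P, s$a, s$b)
    idx <- as.matrix(expand.grid(sub[[1]], sub[[2]], sub[[3]],
                                 KEEP.OUT.ATTRS = FALSE))
    lin <- idx[, 1] + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1))
    inside <- d <= s$radius
    fg[lin[inside]] <- TRUE
    better <- d < bestd[lin] |
      (d == bestd[lin] & (is.na(bestr[lin]) | s$radius > bestr[lin]))
    bl <- lin[better]
    bestd[bl] <- d[better]
    bestr[bl] <- s$radius
  }
  truth_radius <- array(NA_real_, dim = dims)
  truth_radius[fg] <- bestr[fg]
  list(fg = fg, truth_radius = truth_radius, origin = origin, dims = dims)
}

phantom_result <- function(ras, spacing, segments, label = 1L) {
  labels <- array(0L, dim = ras$dims)
  labels[ras$fg] <- as.integer(label)
  mask <- voxel_mask(labels, spacing = spacing, origin = ras$origin)
  truth <- structure(list(
    radius = ras$truth_radius,
    centerline = lapply(segments, function(s) rbind(s$a, s$b)),
    segments = segments), class = "phantom_truth")
  list(mask = mask, truth = truth)
}

#' Straight-cylinder phantom with known radius
#'
#' @param radius_mm Tube radius in mm; must be at least `max(spacing)`
#'   (sub-voxel tubes are rejected).
#' @param length_mm Axis length in mm.
#' @param spacing Voxel spacing (mm), length 3.
#' @param axis Direction of the tube axis (any nonzero vector).
#' @param label Foreground label (1 = artery, 2 = vein).
#' @return List with `mask` (a [voxel_mask()]) and `truth` (per-voxel true
#'   radius array aligned with the mask, plus the analytic centerline).
#' @export
make_cylinder <- function(radius_mm, length_mm, spacing = c(1, 1, 1),
                          axis = c(0, 0, 1), label = 1L) {
  stopifnot(radius_mm > 0, length_mm > 0)
  axis <- axis / sqrt(sum(axis^2))
  a <- c(0, 0, 0)
  b <- axis * length_mm
  segs <- list(list(a = a, b = b, radius = radius_mm))
  phantom_result(rasterize_capsules(segs, spacing), spacing, segs, label)
}

#' Bent-tube phantom (90-degree elbow)
#'
#' Two perpendicular straight legs of equal radius joined at a corner,
#' approximating a right-angle vessel bend.
#'
#' @inheritParams make_cylinder
#' @param leg_mm Length of each leg in mm.
#' @export
make_bent_tube <- function(radius_mm, leg_mm, spacing = c(1, 1, 1),
                           label = 1L) {
  stopifnot(radius_mm > 0, leg_mm > 0)
  corner <- c(0, 0, 0)
  segs <- list(
    list(a = c(0, 0, -leg_mm), b = corner, radius = radius_mm),
    list(a = corner, b = c(leg_mm, 0, 0), radius = radius_mm))
  phantom_result(rasterize_capsules(segs, spacing), spacing, segs, label)
}

#' Random bifurcating vessel-tree phantom
#'
#' A binary tree of tapering capsule segments: each child's radius is the
#' parent's times `scale`, its direction a random deflection of the
#' parent's. Topology and geometry are fully determined by `seed`.
#'
#' @param root_radius_mm Radius of the trunk segment in mm.
#' @param depth Number of branching generations (0 = a single straight
#'   segment, identical to [make_cylinder()]).
#' @param scale Child/parent radius ratio in (0, 1].
#' @param root_length_mm Trunk length in mm; child lengths shrink by
#'   `length_scale` per generation.
#' @param length_scale Child/parent length ratio.
#' @param spacing Voxel spacing (mm).
#' @param seed Integer seed fixing the tree exactly.
#' @param label Foreground label.
#' @return As [make_cylinder()]; `truth$segments` lists every generating
#'   segment with its radius.
#' @export
make_tree <- function(root_radius_mm = 3, depth = 2L, scale = 0.7,
                      root_length_mm = 20, length_scale = 0.8,
                      spacing = c(1, 1, 1), seed = 1L, label = 1L) {
  stopifnot(root_radius_mm > 0, depth >= 0L, scale > 0, scale <= 1)
  leaf_r <- root_radius_mm * scale^depth
  if (leaf_r < max(spacing))
    stop("leaf radius ", format(leaf_r), " mm is below max spacing ",
         format(max(spacing)), " mm; reduce `depth` (or raise `scale`)",
         call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  segs <- list()
  grow <- function(p0, dir, r, len, level) {
    p1 <- p0 + dir * len
    segs[[length(segs) + 1L]] <<- list(a = p0, b = p1, radius = r)
    if (level >= depth) return(invisible())
    for (child in 1:2) {
      # deflect by 25-45 degrees at a random azimuth around the parent axis
      theta <- runif(1, 25, 45) * pi / 180
      phi <- runif(1, 0, 2 * pi)
      u <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- u - sum(u * dir) * dir
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
              dir[3] * e1[1] - dir[1] * e1[3],
              dir[1] * e1[2] - dir[2] * e1[1])
      newdir <- cos(theta) * dir +
        sin(theta) * (cos(phi + pi * (child - 1)) * e1 +
                        sin(phi + pi * (child - 1)) * e2)
      newdir <- newdir / sqrt(sum(newdir^2))
      grow(p1, newdir, r * scale, len * length_scale, level + 1L)
    }
  }
  grow(c(0, 0, 0), c(0, 0, 1), root_radius_mm, root_length_mm, 0L)
  phantom_result(rasterize_capsules(segs, spacing), spacing, segs, label)
}
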