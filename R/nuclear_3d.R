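#' Otsu threshold of an intensity sample
#'
#' Histogram-based threshold minimizing intra-class variance
#' (equivalently maximizing between-class variance), computed on
#' `nbins` equal-width bins between the sample range.
#'
#' @param x numeric vector or array of intensities.
#' @param nbins number of histogram bins.
#' @return the threshold value (voxels strictly above it are foreground).
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  r <- range(x)
  if (diff(r) == 0) stop("constant image: Otsu threshold undefined")
  edges <- seq(r[1], r[2], length.out = nbins + 1L)
  bin <- pmin(nbins, pmax(1L, findInterval(x, edges, rightmost.closed = TRUE)))
  h <- tabulate(bin, nbins)
  w <- h / sum(h)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(w)
  mu_cum <- cumsum(w * mids)
  mu_T <- mu_cum[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nbins)
  between[valid] <- (mu_T * w0[valid] - mu_cum[valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(between)
  edges[k + 1L]
}

new_nucleus_mask <- function(mask, voxel_size) {
  idx <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(idx)
  surf <- surface_voxels(mask)
  sidx <- which(surf, arr.ind = TRUE)
  radius <- mean(sqrt(rowSums(sweep(sidx, 2, centroid)^2)))
  structure(list(mask = mask, centroid = centroid, surface = surf,
                 radius_vox = radius, radius_um = radius * voxel_size,
                 voxel_size = voxel_size, rim = NULL,
                 lamin_radius_vox = NA_real_, flagged_fraction = NA_real_,
                 usable = TRUE),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat("<nucleus_mask> ", sum(x$mask), " voxels, radius ",
      round(x$radius_vox, 2), " vox (", round(x$radius_um, 3), " um)",
      if (!is.na(x$flagged_fraction))
        paste0(", ", round(100 * x$flagged_fraction, 1), "% edge flagged"),
      if (!x$usable) " [UNUSABLE]", "\n", sep = "")
  invisible(x)
}

#' Segment the nucleus from the DAPI channel
#'
#' Otsu threshold on the whole stack, retain the largest 6-connected
#' foreground component, and fill holes slice by slice (background
#' regions of a z-slice not connected to the slice border become
#' foreground).
#'
#' @param stack a `nucleus_stack`, or a 3D numeric array of DAPI
#'   intensities.
#' @param voxel_size physical voxel size when `stack` is a bare array.
#' @return a `nucleus_mask` with centroid and mean surface-to-centroid
#'   radius.
#' @export
segment_nucleus <- function(stack, voxel_size = NULL) {
  if (inherits(stack, "nucleus_stack")) {
    img <- stack$dapi
    if (is.null(voxel_size)) voxel_size <- stack$voxel_size
  } else {
    img <- stack
    if (is.null(voxel_size)) voxel_size <- 1
  }
  stopifnot(length(dim(img)) == 3L)
  thr <- otsu_threshold(img)
  fg <- img > thr
  if (!any(fg)) stop("no foreground voxels above the Otsu threshold")
  lab <- cpp_label6(as.logical(fg), dim(img))
  sizes <- tabulate(lab)
  keep <- which.max(sizes)
  mask <- array(lab == keep, dim = dim(img))
  mask <- fill_holes_slicewise(mask)
  new_nucleus_mask(mask, voxel_size)
}

# Fill holes per z-slice: complement components that do not touch the
# slice border are interior holes.
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  for (z in seq_len(d[3])) {
    sl <- mask[, , z]
    if (!any(sl)) next
    comp <- cpp_label6(as.logical(!sl), c(d[1], d[2], 1L))
    comp <- array(comp, dim = c(d[1], d[2]))
    border_labels <- unique(c(comp[1, ], comp[d[1], ], comp[, 1], comp[, d[2]]))
    border_labels <- setdiff(border_labels, 0L)
    hole <- !sl & !(comp %in% border_labels)
    dim(hole) <- c(d[1], d[2])
    sl[hole] <- TRUE
    mask[, , z] <- sl
  }
  mask
}

#' Refine and flag the DAPI boundary against the lamin rim
#'
#' The lamin channel is Otsu-thresholded, filled per slice, and reduced
#' to a single-voxel rim (boundary of the filled region in each
#' z-slice).  Rim voxels farther than `tolerance` voxels from the
#' nearest DAPI surface voxel are flagged; a nucleus with more than 10%
#' of its rim flagged is marked unusable.  The DAPI mask geometry is
#' kept; refinement is a consistency check and records the lamin-derived
#' radius alongside the DAPI one.
#'
#' @param nucleus a `nucleus_mask` from [segment_nucleus()].
#' @param lamin 3D lamin intensity array (or a `nucleus_stack`).
#' @param tolerance maximum accepted rim-to-edge deviation, voxels.
#' @return the `nucleus_mask` with `rim`, `lamin_radius_vox`,
#'   `flagged_fraction` and `usable` filled in.
#' @export
refine_boundary <- function(nucleus, lamin, tolerance = 2) {
  stopifnot(inherits(nucleus, "nucleus_mask"))
  if (inherits(lamin, "nucleus_stack")) lamin <- lamin$lamin
  d <- dim(nucleus$mask)
  stopifnot(identical(dim(lamin), d))
  thr <- tryCatch(otsu_threshold(lamin), error = function(e) NULL)
  if (is.null(thr)) {
    warning("empty lamin rim: refinement skipped")
    return(nucleus)
  }
  lm <- array(lamin > thr, dim = d)
  if (!any(lm)) {
    warning("empty lamin rim: refinement skipped")
    return(nucleus)
  }
  lm <- fill_holes_slicewise(lm)
  # single-voxel rim per slice: boundary (4-connectivity) of the filled
  # lamin region within each z-plane
  rim <- array(FALSE, dim = d)
  for (z in seq_len(d[3])) {
    sl <- lm[, , z]
    if (!any(sl)) next
    er <- sl
    er[-1, ] <- er[-1, ] & sl[-d[1], ]
    er[-d[1], ] <- er[-d[1], ] & sl[-1, ]
    er[, -1] <- er[, -1] & sl[, -d[2]]
    er[, -d[2]] <- er[, -d[2]] & sl[, -1]
    rim[, , z] <- sl & !er
  }
  if (!any(rim)) {
    warning("empty lamin rim: refinement skipped")
    return(nucleus)
  }
  # distance from each rim voxel to the nearest DAPI surface voxel
  dmap <- sqrt(cpp_sqedt(as.logical(nucleus$surface), d))
  dev <- array(dmap, dim = d)[rim]
  nucleus$rim <- rim
  nucleus$flagged_fraction <- mean(dev > tolerance)
  nucleus$usable <- nucleus$flagged_fraction <= 0.10
  ridx <- which(rim, arr.ind = TRUE)
  nucleus$lamin_radius_vox <-
    mean(sqrt(rowSums(sweep(ridx, 2, nucleus$centroid)^2)))
  nucleus
}

#' Distance-to-boundary map of a nucleus mask
#'
#' Euclidean distance transform of the inside region with respect to the
#' outside: every inside voxel receives its distance (in voxels) to the
#' nearest outside voxel — the distance to the closest point on the
#' nuclear boundary; outside voxels are 0.
#'
#' @param nucleus a `nucleus_mask` or a logical 3D array.
#' @return 3D numeric array of distances.
#' @export
distance_map <- function(nucleus) {
  mask <- if (inherits(nucleus, "nucleus_mask")) nucleus$mask else nucleus
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- sqrt(cpp_sqedt(as.logical(!mask), dim(mask)))
  array(d, dim = dim(mask))
}

#' Mean surface-to-centroid radius of a mask
#'
#' @param nucleus a `nucleus_mask` or logical 3D array.
#' @param voxel_size micrometres per voxel for the physical radius.
#' @return list with `radius_vox` and `radius_um`.
#' @export
estimate_radius <- function(nucleus, voxel_size = NULL) {
  if (inherits(nucleus, "nucleus_mask")) {
    if (is.null(voxel_size)) voxel_size <- nucleus$voxel_size
    return(list(radius_vox = nucleus$radius_vox,
                radius_um = nucleus$radius_vox * voxel_size))
  }
  if (is.null(voxel_size)) voxel_size <- 1
  nm <- new_nucleus_mask(nucleus, voxel_size)
  list(radius_vox = nm$radius_vox, radius_um = nm$radius_um)
}

#' Distances of FISH-signal voxels to the nuclear boundary
#'
#' The FISH channel is thresholded (Otsu restricted to voxels inside the
#' mask, unless a numeric threshold is given); only signal voxels inside
#' the nucleus are counted, and the per-nucleus mean voxel distance is
#' normalized by the nuclear radius.
#'
#' Otsu is reliable for signals occupying more than about 1% of the
#' nucleus; for very compact spots its between-class criterion can
#' prefer splitting the background noise, so the `"halfmax"` rule
#' (threshold halfway between the in-mask median and maximum) is
#' provided and recommended for small spots.
#'
#' @param stack a `nucleus_stack` (or 3D FISH array).
#' @param nucleus a `nucleus_mask`.
#' @param dmap precomputed [distance_map()] (computed when `NULL`).
#' @param threshold `"otsu"`, `"halfmax"`, or a numeric intensity
#'   cut-off.
#' @param locus,nucleus_id labels carried into the result.
#' @return a `fish_measurement`: voxel distances, their mean, the radius
#'   and the normalized mean distance (0 = boundary, 1 = centroid).
#' @export
extract_fish_distances <- function(stack, nucleus, dmap = NULL,
                                   threshold = "otsu", locus = "locus",
                                   nucleus_id = 1L) {
  fish <- if (inherits(stack, "nucleus_stack")) stack$fish else stack
  stopifnot(inherits(nucleus, "nucleus_mask"),
            identical(dim(fish), dim(nucleus$mask)))
  if (is.null(dmap)) dmap <- distance_map(nucleus)
  inside_vals <- fish[nucleus$mask]
  thr <- if (identical(threshold, "otsu")) otsu_threshold(inside_vals)
         else if (identical(threshold, "halfmax"))
           (median(inside_vals) + max(inside_vals)) / 2
         else as.numeric(threshold)
  sel <- nucleus$mask & fish > thr
  if (!any(sel))
    stop("no FISH voxels inside the nucleus: nucleus excluded")
  dists <- dmap[sel]
  m <- mean(dists)
  structure(list(locus = locus, nucleus_id = nucleus_id,
                 distances_vox = dists, mean_vox = m,
                 radius_vox = nucleus$radius_vox,
                 normalized = normalize_distance(m, nucleus$radius_vox),
                 n_voxels = length(dists), usable = nucleus$usable),
            class = "fish_measurement")
}

#' Normalize a boundary distance by the nuclear radius
#'
#' 0 at the boundary, 1 at the centroid; values are not clamped, so
#' voxelization can produce values slightly above 1 near the centre.
#'
#' @param distance distance(s) to the boundary, voxels.
#' @param radius nuclear radius, voxels; must be positive.
#' @return `distance / radius`.
#' @export
normalize_distance <- function(distance, radius) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  distance / radius
}

#' Run the full single-nucleus measurement chain
#'
#' Segmentation, optional lamin refinement, distance map, FISH voxel
#' extraction — the same voxel pipeline for simulated reference nuclei
#' and real measurements.
#'
#' @param stack a `nucleus_stack`.
#' @param refine run [refine_boundary()] against the lamin channel.
#' @param tolerance rim deviation tolerance, voxels.
#' @inheritParams extract_fish_distances
#' @return a `fish_measurement`.
#' @export
measure_nucleus <- function(stack, refine = FALSE, tolerance = 2,
                            threshold = "otsu", locus = "locus",
                            nucleus_id = 1L) {
  nuc <- segment_nucleus(stack)
  if (refine) nuc <- refine_boundary(nuc, stack, tolerance = tolerance)
  dmap <- distance_map(nuc)
  extract_fish_distances(stack, nuc, dmap, threshold = threshold,
                         locus = locus, nucleus_id = nucleus_id)
}
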