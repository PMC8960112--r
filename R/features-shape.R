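# Shape and cardiac-anatomy features computed on label masks.
#
# All physical quantities use the mask spacing (slice_mm, row_mm, col_mm):
# volumes in ml, areas in mm^2, thicknesses in mm.  Features of absent
# structures are NA (missing), never silently zero.

mask_phase <- function(mask, phase) {
  lab <- if (inherits(mask, "label_mask")) mask$labels else mask
  stopifnot(phase >= 1, phase <= dim(lab)[4])
  out <- lab[, , , phase, drop = FALSE]
  dim(out) <- dim(out)[1:3]
  out
}

#' Structure volume in ml
#'
#' Voxel count times physical voxel volume.
#'
#' @param mask A [label_mask()] (or 4D label array).
#' @param structure Structure name (see [label_convention()]) or label value.
#' @param phase Cardiac phase (1-based).
#' @param spacing `(slice_mm, row_mm, col_mm)`.
#' @return Volume in ml (0 for an empty structure).
#' @export
structure_volume <- function(mask, structure, phase, spacing) {
  lab <- mask_phase(mask, phase)
  n <- sum(lab == structure_label(structure))
  n * prod(spacing) / 1000
}

#' Structure surface area in mm^2
#'
#' Area of the triangulated 0.5-level isosurface of the binary structure
#' volume (marching cubes with Taubin smoothing; see the methods vignette for
#' the mesher's numerical behaviour).
#'
#' @inheritParams structure_volume
#' @param smooth_iterations Taubin smoothing passes (default 10; 0 disables).
#' @return Area in mm^2, or `NA` for an empty structure (missing, not zero).
#' @export
structure_surface_area <- function(mask, structure, phase, spacing,
                                   smooth_iterations = 10) {
  lab <- mask_phase(mask, phase)
  bin <- lab == structure_label(structure)
  if (!any(bin)) return(NA_real_)
  mesh_area(mesh_binary(bin, spacing, smooth_iterations))
}

#' Structure sphericity
#'
#' `(36 pi V^2)^(1/3) / A`: 1 for a ball, smaller for any other shape.
#'
#' @inheritParams structure_surface_area
#' @return Dimensionless sphericity in (0, 1], `NA` if the structure is empty.
#' @export
structure_sphericity <- function(mask, structure, phase, spacing,
                                 smooth_iterations = 10) {
  V <- structure_volume(mask, structure, phase, spacing) * 1000  # mm^3
  if (V == 0) return(NA_real_)
  A <- structure_surface_area(mask, structure, phase, spacing, smooth_iterations)
  (36 * pi * V^2)^(1 / 3) / A
}

slice_centroid <- function(sl, value, spacing) {
  idx <- which(sl == value, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  c(mean(idx[, 1] - 1) * spacing[2], mean(idx[, 2] - 1) * spacing[3])
}

# Walk rays from `origin` (mm) at `angles`; return for each angle the radii
# (mm) at which the label run changes, based on nearest-neighbour sampling.
ray_profile <- function(sl, origin, angle, spacing, step, r_max) {
  r <- seq(step, r_max, by = step)
  rr <- round(origin[1] / spacing[2] + (r / spacing[2]) * sin(angle)) + 1
  cc <- round(origin[2] / spacing[3] + (r / spacing[3]) * cos(angle)) + 1
  ok <- rr >= 1 & rr <= nrow(sl) & cc >= 1 & cc <= ncol(sl)
  lab <- rep(NA_integer_, length(r))
  lab[ok] <- sl[cbind(rr[ok], cc[ok])]
  list(r = r, lab = lab)
}

#' Interventricular septum thickness
#'
#' The septum axis is the ray from the LV blood-pool centroid towards the RV
#' blood-pool centroid.  For rays within +/- 30 degrees of that axis the
#' radial wall thickness is the distance between the endocardial and
#' epicardial crossings; the septum thickness is the mean over the sector.
#' The relative value normalizes by the LV epicardial diameter measured along
#' the septum axis through the LV centroid.
#'
#' @inheritParams structure_volume
#' @param slice Slice index (1-based).
#' @param half_angle_deg Sector half-angle (default 30).
#' @return List with `septum_thickness_mm` and `relative_septum_thickness`;
#'   both `NA` when LV myocardium, LV pool or RV pool is absent on the slice.
#' @export
septum_thickness <- function(mask, phase, slice, spacing, half_angle_deg = 30) {
  lab4 <- mask_phase(mask, phase)
  sl <- lab4[, , slice]
  conv <- label_convention()
  lv_c <- slice_centroid(sl, conv[["lv_bloodpool"]], spacing)
  rv_c <- slice_centroid(sl, conv[["rv_bloodpool"]], spacing)
  if (is.null(lv_c) || is.null(rv_c) || !any(sl == conv[["lv_myocardium"]])) {
    return(list(septum_thickness_mm = NA_real_, relative_septum_thickness = NA_real_))
  }
  axis <- atan2(rv_c[1] - lv_c[1], rv_c[2] - lv_c[2])
  step <- 0.25 * min(spacing[2], spacing[3])
  r_max <- sqrt((nrow(sl) * spacing[2])^2 + (ncol(sl) * spacing[3])^2)
  angles <- axis + seq(-half_angle_deg, half_angle_deg, by = 2) * pi / 180
  wall <- vapply(angles, function(a) {
    pr <- ray_profile(sl, lv_c, a, spacing, step, r_max)
    in_pool <- pr$lab == conv[["lv_bloodpool"]]
    i_endo <- which(!in_pool)[1]          # first sample beyond the pool
    if (is.na(i_endo) || i_endo < 2) return(NA_real_)
    after <- pr$lab[i_endo:length(pr$lab)]
    n_myo <- which(after != conv[["lv_myocardium"]])[1] - 1
    if (is.na(n_myo) || n_myo < 1) return(NA_real_)
    n_myo * step
  }, 0)
  if (all(is.na(wall))) {
    return(list(septum_thickness_mm = NA_real_, relative_septum_thickness = NA_real_))
  }
  th <- mean(wall, na.rm = TRUE)
  epi_r <- vapply(c(axis, axis + pi), function(a) {
    pr <- ray_profile(sl, lv_c, a, spacing, step, r_max)
    inside <- pr$lab %in% c(conv[["lv_bloodpool"]], conv[["lv_myocardium"]])
    i_out <- which(!inside)[1]
    if (is.na(i_out)) return(NA_real_)
    (i_out - 1) * step
  }, 0)
  diam <- sum(epi_r)
  list(septum_thickness_mm = th,
       relative_septum_thickness = if (is.finite(diam) && diam > 0) th / diam else NA_real_)
}

# Longest closed 0.5-level contour of a binary slice, in mm coordinates.
# Returned as an n x 2 matrix (closed implicitly; last point != first).
slice_contour <- function(bin, spacing) {
  if (sum(bin) < 3) return(NULL)
  cl <- grDevices::contourLines(x = (seq_len(nrow(bin)) - 1) * spacing[2],
                                y = (seq_len(ncol(bin)) - 1) * spacing[3],
                                z = bin * 1, levels = 0.5)
  if (!length(cl)) return(NULL)
  best <- cl[[which.max(vapply(cl, function(p) length(p$x), 0))]]
  pts <- cbind(best$x, best$y)
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), , drop = FALSE]
  pts
}

# Circular moving-average smoothing of a closed polyline (suppresses the
# half-voxel staircase of marching squares before perimeter measurement).
smooth_contour <- function(pts, window = 5) {
  n <- nrow(pts)
  if (n < window) return(pts)
  half <- (window - 1) %/% 2
  idx <- outer(seq_len(n), -half:half, "+")
  idx <- ((idx - 1) %% n) + 1
  cbind(rowMeans(matrix(pts[idx, 1], n)), rowMeans(matrix(pts[idx, 2], n)))
}

closed_perimeter <- function(pts) {
  d <- pts[c(2:nrow(pts), 1), ] - pts
  sum(sqrt(rowSums(d^2)))
}

#' Endocardial tortuosity of the LV on a slice
#'
#' Ratio of the endocardial contour perimeter to the perimeter of its convex
#' hull (>= 1; 1 for convex contours).  The marching-squares contour is
#' lightly smoothed before measurement so that a digitized circle scores ~1.
#'
#' @inheritParams septum_thickness
#' @param structure Structure whose boundary is traced (default LV blood pool).
#' @return Dimensionless tortuosity >= 1 (up to numerical tolerance), `NA` if
#'   the structure is absent on the slice.
#' @export
lv_tortuosity <- function(mask, phase, slice, spacing, structure = "lv_bloodpool") {
  lab4 <- mask_phase(mask, phase)
  bin <- lab4[, , slice] == structure_label(structure)
  pts <- slice_contour(bin, spacing)
  if (is.null(pts) || nrow(pts) < 8) return(NA_real_)
  pts <- smooth_contour(pts)
  hull <- grDevices::chull(pts)
  closed_perimeter(pts) / closed_perimeter(pts[hull, , drop = FALSE])
}

#' Box-counting (Minkowski-Bouligand) fractal dimension of a boundary
#'
#' Boundary pixels are structure pixels with at least one 4-neighbour outside
#' the structure.  N(eps) boxes of size eps in {1, 2, 4, 8, 16} pixels are
#' counted and the dimension is the least-squares slope of
#' log N(eps) ~ log(1/eps).
#'
#' @inheritParams septum_thickness
#' @param structure Structure name or label value.
#' @return Dimensionless fractal dimension, `NA` if the structure is absent.
#' @export
fractal_dimension <- function(mask, structure, phase, slice) {
  lab4 <- mask_phase(mask, phase)
  bin <- lab4[, , slice] == structure_label(structure)
  if (!any(bin)) return(NA_real_)
  pad <- matrix(FALSE, nrow(bin) + 2, ncol(bin) + 2)
  pad[2:(nrow(bin) + 1), 2:(ncol(bin) + 1)] <- bin
  inner <- pad[2:(nrow(bin) + 1), 2:(ncol(bin) + 1)] &
    pad[1:nrow(bin), 2:(ncol(bin) + 1)] & pad[3:(nrow(bin) + 2), 2:(ncol(bin) + 1)] &
    pad[2:(nrow(bin) + 1), 1:ncol(bin)] & pad[2:(nrow(bin) + 1), 3:(ncol(bin) + 2)]
  boundary <- which(bin & !inner, arr.ind = TRUE)
  if (nrow(boundary) < 2) return(NA_real_)
  eps <- c(1, 2, 4, 8, 16)
  n_box <- vapply(eps, function(e) {
    nrow(unique(cbind((boundary[, 1] - 1) %/% e, (boundary[, 2] - 1) %/% e)))
  }, 0)
  keep <- n_box > 0
  stats::coef(stats::lm(log(n_box[keep]) ~ log(1 / eps[keep])))[[2]]
}

#' Global function parameters from an LV volume curve
#'
#' EDV/ESV are the curve extrema (first occurrence on ties), per the usual
#' cine convention; EF = (EDV - ESV) / EDV.
#'
#' @param volume_curve Numeric vector of LV blood-pool volumes (ml) per phase,
#'   or a [feature_curve()].
#' @return List with `edv_ml`, `esv_ml`, `ef`, `ed_phase`, `es_phase`
#'   (1-based phases).
#' @export
function_parameters <- function(volume_curve) {
  v <- if (inherits(volume_curve, "feature_curve")) volume_curve$values else volume_curve
  stopifnot(is.numeric(v), length(v) >= 1)
  edv <- max(v); esv <- min(v)
  list(edv_ml = edv, esv_ml = esv,
       ef = if (edv > 0) (edv - esv) / edv else 0,
       ed_phase = which.max(v), es_phase = which.min(v))
}
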