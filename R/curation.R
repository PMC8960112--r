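# Segmentation curation operators.
#
# Three correction mechanisms, each producing new sessions (append-only
# provenance): sparse-to-dense shape-based slice interpolation on signed
# distance transforms, motion-compensated temporal propagation of contours
# through a demons-style deformation field, and boolean consistency
# enforcement between the anatomical regions (the epicardial region is
# authoritative: the LV blood pool is clipped to it, the RV blood pool is
# excluded from it, the myocardium is the remainder).
#
# Contours are ordered closed polylines in voxel coordinates (row, col) on
# one (phase, slice); conversion to/from masks uses even-odd rasterization
# and marching-squares extraction (round-trip tolerance 0.5 voxel).

#' Create a contour object
#'
#' @param structure One of `lv_endo`, `lv_epi`, `rv_endo`.
#' @param phase,slice 1-based indices.
#' @param points `n x 2` matrix of (row, col) voxel coordinates, ordered,
#'   closed implicitly (first point is not repeated); at least 3 points and
#'   non-self-intersecting.
#' @param corrected Manual-correction flag.
#' @return Object of class `cmr_contour`.
#' @export
cmr_contour <- function(structure = c("lv_endo", "lv_epi", "rv_endo"), phase, slice,
                    points, corrected = FALSE) {
  structure <- match.arg(structure)
  points <- as.matrix(points)
  if (nrow(points) < 3 || ncol(points) != 2) stop2("contour needs >= 3 (row, col) points")
  if (!polygon_is_simple(points)) stop2("contour polygon is self-intersecting")
  base::structure(list(structure = structure, phase = as.integer(phase),
                       slice = as.integer(slice), points = points,
                       corrected = isTRUE(corrected)),
                  class = "cmr_contour")
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) && ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_is_simple <- function(pts) {
  n <- nrow(pts)
  if (n > 400) return(TRUE)  # validation skipped for very dense contours
  nxt <- c(2:n, 1)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (segments_intersect(pts[i, ], pts[nxt[i], ], pts[j, ], pts[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Rasterize a closed polygon to a binary slice (even-odd rule)
#'
#' @param points `n x 2` (row, col) voxel coordinates.
#' @param dim `(rows, cols)` of the output.
#' @return Logical matrix; pixel centers at integer coordinates.
#' @export
rasterize_polygon <- function(points, dim) {
  out <- matrix(FALSE, dim[1], dim[2])
  rr <- max(1, floor(min(points[, 1]))):min(dim[1], ceiling(max(points[, 1])))
  cc <- max(1, floor(min(points[, 2]))):min(dim[2], ceiling(max(points[, 2])))
  if (!length(rr) || !length(cc)) return(out)
  py <- rep(rr, times = length(cc))          # row = y
  px <- rep(cc, each = length(rr))           # col = x
  inside <- rep(FALSE, length(py))
  n <- nrow(points)
  for (e in seq_len(n)) {
    y1 <- points[e, 1]; x1 <- points[e, 2]
    j <- if (e == n) 1 else e + 1
    y2 <- points[j, 1]; x2 <- points[j, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xi <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- px[crosses] < xi
      inside[crosses][flip] <- !inside[crosses][flip]
    }
  }
  out[cbind(py[inside], px[inside])] <- TRUE
  out
}

#' Extract the outer 0.5-level contour of a binary slice
#'
#' Marching squares; the longest contour is returned, in voxel coordinates.
#'
#' @param bin Logical matrix.
#' @return `n x 2` (row, col) matrix, or `NULL` if no contour exists.
#' @export
mask_to_contour_points <- function(bin) {
  if (sum(bin) < 1) return(NULL)
  cl <- grDevices::contourLines(x = seq_len(nrow(bin)), y = seq_len(ncol(bin)),
                                z = bin * 1, levels = 0.5)
  if (!length(cl)) return(NULL)
  best <- cl[[which.max(vapply(cl, function(p) length(p$x), 0))]]
  pts <- cbind(best$x, best$y)
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), , drop = FALSE]
  pts
}

signed_distance <- function(bin) {
  fg <- EBImage::imageData(EBImage::distmap(EBImage::Image(bin * 1)))
  bg <- EBImage::imageData(EBImage::distmap(EBImage::Image((!bin) * 1)))
  fg - bg
}

#' Shape-based interpolation of a structure across slices
#'
#' For every slice lying between two annotated neighbours, the structure
#' region is replaced by the zero super-level set of the linearly
#' interpolated signed distance transforms of the bounding annotated slices.
#' Annotated slices are unchanged.  Interpolation runs per structure on the
#' binary mask; run [enforce_consistency()] afterwards to restore joint
#' validity if needed.
#'
#' @param mask A [label_mask()] or 4D label array.
#' @param structure Structure name or label value.
#' @param phase Cardiac phase (1-based).
#' @param annotated_slices Slice indices treated as ground truth (>= 2 that
#'   contain the structure).
#' @return A new [label_mask()].
#' @export
interpolate_slices <- function(mask, structure, phase, annotated_slices) {
  lab4 <- if (inherits(mask, "label_mask")) mask$labels else mask
  lv <- structure_label(structure)
  annotated_slices <- sort(unique(as.integer(annotated_slices)))
  has <- vapply(annotated_slices, function(s) any(lab4[, , s, phase] == lv), TRUE)
  if (sum(has) < 2) stop2("need >= 2 annotated slices containing the structure")
  annotated_slices <- annotated_slices[has]
  out <- lab4
  sdf_cache <- lapply(annotated_slices, function(s) signed_distance(lab4[, , s, phase] == lv))
  for (k in seq_len(length(annotated_slices) - 1)) {
    s0 <- annotated_slices[k]; s1 <- annotated_slices[k + 1]
    if (s1 - s0 < 2) next
    d0 <- sdf_cache[[k]]; d1 <- sdf_cache[[k + 1]]
    for (s in (s0 + 1):(s1 - 1)) {
      w <- (s - s0) / (s1 - s0)
      region <- ((1 - w) * d0 + w * d1) >= 0
      sl <- out[, , s, phase]
      sl[sl == lv] <- 0L
      sl[region] <- lv
      out[, , s, phase] <- sl
    }
  }
  label_mask(out)
}

gauss2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) + m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc + m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

warp2d <- function(m, ur, uc) {
  nr <- nrow(m); nc <- ncol(m)
  r <- matrix(seq_len(nr), nr, nc) + ur
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) + uc
  matrix(bilinear_sample(m, as.vector(r), as.vector(c)), nr, nc)
}

resize2d <- function(m, nr, nc) {
  EBImage::imageData(EBImage::resize(EBImage::Image(m), w = nr, h = nc,
                                     filter = "bilinear"))
}

demons_2d <- function(fixed, moving, levels = c(4, 2, 1),
                      iterations = c(60, 40, 20), sigma_fluid = 1,
                      sigma_elastic = 1, alpha = 2.5) {
  ur <- NULL; uc <- NULL
  for (li in seq_along(levels)) {
    f <- levels[li]
    nr <- max(8, floor(nrow(fixed) / f)); nc <- max(8, floor(ncol(fixed) / f))
    fx <- resize2d(if (f > 1) gauss2d(fixed, f / 2) else fixed, nr, nc)
    mv <- resize2d(if (f > 1) gauss2d(moving, f / 2) else moving, nr, nc)
    if (is.null(ur)) {
      ur <- matrix(0, nr, nc); uc <- matrix(0, nr, nc)
    } else {
      scale_r <- nr / nrow(ur); scale_c <- nc / ncol(uc)
      ur <- resize2d(ur, nr, nc) * scale_r
      uc <- resize2d(uc, nr, nc) * scale_c
    }
    iscale <- max(abs(fx - mean(fx)), 1e-8)
    for (it in seq_len(iterations[li])) {
      w <- warp2d(mv, ur, uc)
      diff <- fx - w
      gr <- (rbind(w[-1, , drop = FALSE], w[nrow(w), ]) -
             rbind(w[1, ], w[-nrow(w), , drop = FALSE])) / 2
      gc <- (cbind(w[, -1, drop = FALSE], w[, ncol(w)]) -
             cbind(w[, 1], w[, -ncol(w), drop = FALSE])) / 2
      g2 <- gr^2 + gc^2
      denom <- g2 + (alpha * diff / iscale)^2 * iscale^2
      denom[denom < 1e-9] <- Inf
      dur <- diff * gr / denom
      duc <- diff * gc / denom
      cap <- 1  # voxels per iteration, keeps the update diffeomorphic-ish
      dur <- pmin(pmax(dur, -cap), cap); duc <- pmin(pmax(duc, -cap), cap)
      dur <- gauss2d(dur, sigma_fluid); duc <- gauss2d(duc, sigma_fluid)
      ur <- gauss2d(ur + dur, sigma_elastic)
      uc <- gauss2d(uc + duc, sigma_elastic)
    }
  }
  nr <- nrow(fixed); nc <- ncol(fixed)
  list(ur = resize2d(ur, nr, nc) * nr / nrow(ur),
       uc = resize2d(uc, nr, nc) * nc / ncol(uc))
}

#' Estimate the deformation field between two cardiac phases
#'
#' Multi-resolution, Gaussian-regularized demons-style intensity
#' registration, computed per slice (through-plane motion is not modelled:
#' short-axis slices are thick).  The returned field maps phase-`t`
#' coordinates to phase-`t+1`: a tissue point at voxel `x` in `image_t` is
#' found at `x + u(x)` in `image_t1`.  Identical inputs give an exactly zero
#' field.
#'
#' @param image_t,image_t1 3D arrays `[row, col, slice]` on the same grid.
#' @param levels,iterations Multi-resolution schedule (coarse to fine).
#' @return Object of class `deformation_field`: list with `ur`, `uc`
#'   (4D-free: arrays `[row, col, slice]` of row/col displacements, voxels).
#' @export
estimate_deformation <- function(image_t, image_t1, levels = c(4, 2, 1),
                                 iterations = c(60, 40, 20)) {
  if (!identical(dim(image_t), dim(image_t1))) {
    stop2("image grids differ: [%s] vs [%s]",
          paste(dim(image_t), collapse = "x"), paste(dim(image_t1), collapse = "x"))
  }
  if (length(dim(image_t)) == 2L) {
    dim(image_t) <- c(dim(image_t), 1L); dim(image_t1) <- dim(image_t)
  }
  S <- dim(image_t)[3]
  ur <- array(0, dim(image_t)); uc <- array(0, dim(image_t))
  for (s in seq_len(S)) {
    # with fixed = image_t and moving = image_t1 the solution u satisfies
    # image_t(x) = image_t1(x + u(x)), i.e. u is the forward map t -> t+1
    res <- demons_2d(fixed = image_t[, , s], moving = image_t1[, , s],
                     levels = levels, iterations = iterations)
    ur[, , s] <- res$ur
    uc[, , s] <- res$uc
  }
  base::structure(list(ur = ur, uc = uc), class = "deformation_field")
}

#' The identity deformation field for a grid
#' @param dim 3D grid dimensions `[row, col, slice]`.
#' @return A zero `deformation_field`.
#' @export
identity_field <- function(dim) {
  base::structure(list(ur = array(0, dim), uc = array(0, dim)),
                  class = "deformation_field")
}

#' Propagate a contour through a chain of deformation fields
#'
#' Contour points are advected through the composed fields, one target phase
#' per field; after each step the contour is rasterized and re-extracted from
#' the outer boundary of the rasterized region, which resolves any
#' self-intersections and keeps the simple-polygon invariant.
#'
#' @param contour A [cmr_contour()] at phase `t`.
#' @param field_chain List of `deformation_field`s; field `k` maps phase
#'   `t+k-1` to `t+k`.
#' @param grid_dim `(rows, cols)` of the mask grid.
#' @return List of propagated [cmr_contour()]s (flagged `corrected = FALSE`,
#'   attribute `origin = "propagated"`), one per field in the chain.
#' @export
propagate_contour <- function(contour, field_chain, grid_dim) {
  stopifnot(inherits(contour, "cmr_contour"))
  if (inherits(field_chain, "deformation_field")) field_chain <- list(field_chain)
  out <- list()
  pts <- contour$points
  phase <- contour$phase
  for (k in seq_along(field_chain)) {
    fld <- field_chain[[k]]
    s <- contour$slice
    dr <- bilinear_sample(fld$ur[, , s], pts[, 1], pts[, 2])
    dc <- bilinear_sample(fld$uc[, , s], pts[, 1], pts[, 2])
    pts <- cbind(pts[, 1] + dr, pts[, 2] + dc)
    # rasterize + re-extract to restore a clean simple polygon
    bin <- rasterize_polygon(pts, grid_dim)
    if (any(bin)) {
      repts <- mask_to_contour_points(bin)
      if (!is.null(repts) && nrow(repts) >= 3) pts <- repts
    }
    phase <- phase + 1L
    cc <- cmr_contour(contour$structure, phase, s, pts, corrected = FALSE)
    attr(cc, "origin") <- "propagated"
    out[[k]] <- cc
  }
  out
}

#' Enforce boolean consistency between cardiac regions
#'
#' The epicardial region is authoritative: the LV blood pool is intersected
#' with it, the RV blood pool is subtracted from it, and the myocardium is
#' the epicardial region minus the blood pool.  Given a label mask, the
#' epicardial region is the hole-filled myocardium (restricted to previously
#' labelled voxels, so total labelled volume never increases); given
#' explicit (possibly overlapping) regions use [consistent_labels()].  The
#' operator is idempotent.
#'
#' @param mask A [label_mask()] or 4D label array.
#' @param phases,slices Subsets to process (default: all).
#' @return A new [label_mask()].
#' @export
enforce_consistency <- function(mask, phases = NULL, slices = NULL) {
  lab4 <- if (inherits(mask, "label_mask")) mask$labels else mask
  conv <- label_convention()
  phases <- phases %||% seq_len(dim(lab4)[4])
  slices <- slices %||% seq_len(dim(lab4)[3])
  for (p in phases) for (s in slices) {
    sl <- lab4[, , s, p]
    myo <- sl == conv[["lv_myocardium"]]
    if (!any(myo)) next
    pool <- sl == conv[["lv_bloodpool"]]
    rv <- sl == conv[["rv_bloodpool"]]
    labelled <- myo | pool | rv
    epi <- (EBImage::imageData(EBImage::fillHull(EBImage::Image(myo * 1))) > 0.5 &
              labelled) | myo
    new_pool <- pool & epi
    new_rv <- rv & !epi
    new_sl <- matrix(0L, nrow(sl), ncol(sl))
    new_sl[new_rv] <- conv[["rv_bloodpool"]]
    new_sl[epi & !new_pool] <- conv[["lv_myocardium"]]
    new_sl[new_pool] <- conv[["lv_bloodpool"]]
    lab4[, , s, p] <- new_sl
  }
  label_mask(lab4)
}

#' Combine possibly overlapping anatomical regions into a consistent mask
#'
#' Precedence follows the epicardial-region-authoritative rule:
#' `lv_bloodpool = endo & epi`, `myocardium = epi & !lv_bloodpool`,
#' `rv_bloodpool = rv & !epi`.
#'
#' @param endo,epi,rv Logical matrices (LV endocardial region, LV epicardial
#'   region, RV endocardial region).
#' @return Integer label matrix using [label_convention()].
#' @export
consistent_labels <- function(endo, epi, rv) {
  conv <- label_convention()
  out <- matrix(0L, nrow(epi), ncol(epi))
  pool <- endo & epi
  out[rv & !epi] <- conv[["rv_bloodpool"]]
  out[epi & !pool] <- conv[["lv_myocardium"]]
  out[pool] <- conv[["lv_bloodpool"]]
  out
}

contour_region_name <- function(structure) {
  switch(structure, lv_endo = "endo", lv_epi = "epi", rv_endo = "rv")
}

#' Apply contour corrections to a session
#'
#' Each edit replaces the corresponding anatomical region on its (phase,
#' slice); the slice labels are rebuilt with [consistent_labels()].  The
#' result is a new session with `origin = "corrected"` and per-contour
#' correction flags set exactly on the edited (phase, slice, structure)
#' triples; the input session is untouched.
#'
#' @param session A `cmr_session`.
#' @param edits List of [cmr_contour()]s.
#' @return A new `cmr_session` (unattached; see [attach_session()]).
#' @export
apply_correction <- function(session, edits) {
  stopifnot(inherits(session, "cmr_session"), length(edits) >= 1)
  lab4 <- session$mask$labels
  conv <- label_convention()
  flags <- list()
  for (ed in edits) {
    stopifnot(inherits(ed, "cmr_contour"))
    sl <- lab4[, , ed$slice, ed$phase]
    regions <- list(
      endo = sl == conv[["lv_bloodpool"]],
      epi = (EBImage::imageData(EBImage::fillHull(EBImage::Image(
        (sl == conv[["lv_myocardium"]] | sl == conv[["lv_bloodpool"]]) * 1))) > 0.5),
      rv = sl == conv[["rv_bloodpool"]])
    regions[[contour_region_name(ed$structure)]] <-
      rasterize_polygon(ed$points, dim(sl))
    lab4[, , ed$slice, ed$phase] <- consistent_labels(regions$endo, regions$epi,
                                                      regions$rv)
    flags[[length(flags) + 1]] <- data.frame(phase = ed$phase, slice = ed$slice,
                                             structure = ed$structure,
                                             corrected = TRUE)
  }
  pcc <- unique(do.call(rbind, flags))
  sid <- paste0("s_", substr(content_hash(list(lab4, "corrected", session$case_id,
                                               session$session_id)), 1, 16))
  base::structure(list(session_id = sid, case_id = session$case_id,
                       mask = label_mask(lab4), origin = "corrected",
                       per_contour_corrected = pcc, certainty = NULL,
                       landmarks = NULL),
                  class = "cmr_session")
}

#' Attach an existing session object to a case (append-only)
#' @param case A `cmr_case`.
#' @param session A `cmr_session` for that case.
#' @return The updated case.
#' @export
attach_session <- function(case, session) {
  stopifnot(inherits(session, "cmr_session"),
            identical(session$case_id, case$case_id))
  mdim <- dim(session$mask$labels)
  ok <- any(vapply(case$images, function(im) identical(dim(im$voxels), mdim), TRUE))
  if (!ok) stop2("session mask grid does not match case images")
  case$sessions <- c(case$sessions, setNames(list(session), session$session_id))
  case
}
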