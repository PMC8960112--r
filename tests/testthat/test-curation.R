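test_that("signed-distance slice interpolation behaves like the analytic SDF", {
  n <- 64; g <- grid_coords(n)
  D <- sqrt(outer(g^2, g^2, "+"))
  lab <- array(0L, c(n, n, 3, 1))
  lab[, , 1, 1][D <= 10] <- 3L
  lab[, , 3, 1][D <= 20] <- 3L
  out <- interpolate_slices(lab, "lv_bloodpool", 1, c(1, 3))
  mid <- out$labels[, , 2, 1] == 3L
  expect_gte(dice(mid, D <= 15), 0.95)   # radius interpolates linearly
  # annotated slices are untouched
  expect_identical(out$labels[, , 1, 1], lab[, , 1, 1])
  expect_identical(out$labels[, , 3, 1], lab[, , 3, 1])

  # identical bounding slices reproduce themselves in between
  lab2 <- lab; lab2[, , 3, 1] <- lab[, , 1, 1]
  out2 <- interpolate_slices(lab2, "lv_bloodpool", 1, c(1, 3))
  expect_identical(out2$labels[, , 2, 1], lab2[, , 1, 1])

  # translated copies: intermediate centroid at the midpoint (+/- 1 px)
  lab3 <- array(0L, c(n, n, 3, 1))
  lab3[, , 1, 1][D <= 10] <- 3L
  D2 <- sqrt(outer(g^2, (g - 10)^2, "+"))
  lab3[, , 3, 1][D2 <= 10] <- 3L
  out3 <- interpolate_slices(lab3, "lv_bloodpool", 1, c(1, 3))
  idx <- which(out3$labels[, , 2, 1] == 3L, arr.ind = TRUE)
  expect_equal(mean(idx[, 2]), (n + 1) / 2 + 5, tolerance = 1)

  # symmetry: swapping the bounding slices' roles gives the same intermediate
  lab_sw <- lab
  lab_sw[, , 1, 1] <- lab[, , 3, 1]; lab_sw[, , 3, 1] <- lab[, , 1, 1]
  out_sw <- interpolate_slices(lab_sw, "lv_bloodpool", 1, c(1, 3))
  expect_identical(out_sw$labels[, , 2, 1], out$labels[, , 2, 1])

  expect_error(interpolate_slices(lab, "lv_bloodpool", 1, c(1)), ">= 2")
})

test_that("demons registration honours its accuracy contract", {
  tex <- smooth_texture(96, seed = 1)
  f <- array(tex, c(96, 96, 1))
  # identical images: exactly zero field
  fld <- estimate_deformation(f, f)
  expect_lte(max(abs(fld$ur), abs(fld$uc)), 0.1)
  # known translation of 3 px: median recovered within 0.5 px in the interior
  mv <- array(0, c(96, 96, 1)); mv[4:96, , 1] <- tex[1:93, ]
  fld2 <- estimate_deformation(f, mv)
  expect_lt(abs(median(fld2$ur[20:76, 20:76, 1]) - 3), 0.5)
  expect_lt(abs(median(fld2$uc[20:76, 20:76, 1])), 0.5)
  # smooth synthetic warp of <= 5 px: mean endpoint error <= 1.5 px in a band
  g <- grid_coords(96)
  amp <- 4
  wr <- outer(sin(pi * (1:96) / 96), sin(pi * (1:96) / 96)) * amp
  src_r <- matrix(1:96, 96, 96) + wr
  src_c <- matrix(1:96, 96, 96, byrow = TRUE)
  warped <- matrix(cardioloop:::bilinear_sample(tex, as.vector(src_r),
                                                as.vector(src_c)), 96, 96)
  fld3 <- estimate_deformation(array(warped, c(96, 96, 1)), f)
  band <- 25:70
  epe <- sqrt((fld3$ur[band, band, 1] - wr[band, band])^2 +
                fld3$uc[band, band, 1]^2)
  expect_lte(mean(epe), 1.5)
  expect_error(estimate_deformation(f, array(0, c(48, 48, 1))), "grids differ")
})

test_that("contour propagation preserves shape through fields", {
  n <- 64; g <- grid_coords(n)
  D <- sqrt(outer(g^2, g^2, "+"))
  bin <- D <= 15
  pts <- mask_to_contour_points(bin)
  ct <- cmr_contour("lv_endo", 1, 1, pts)
  # identity fields: contours unchanged up to rasterization (<= 0.5 px)
  ids <- replicate(3, identity_field(c(n, n, 1)), simplify = FALSE)
  out <- propagate_contour(ct, ids, c(n, n))
  expect_length(out, 3)
  for (k in 1:3) {
    expect_equal(out[[k]]$phase, 1 + k)
    expect_false(out[[k]]$corrected)
    expect_equal(attr(out[[k]], "origin"), "propagated")
    d <- as.matrix(dist(rbind(out[[k]]$points, ct$points)))
    np <- nrow(out[[k]]$points)
    h <- max(apply(d[1:np, -(1:np), drop = FALSE], 1, min),
             apply(d[-(1:np), 1:np, drop = FALSE], 2, min))
    expect_lte(h, 0.5 + 1e-9)
  }
  # uniform translation fields translate the contour, shape-preserving
  tr <- identity_field(c(n, n, 1)); tr$ur[] <- 2; tr$uc[] <- 1
  out_t <- propagate_contour(ct, list(tr), c(n, n))
  moved <- out_t[[1]]$points
  ref <- cbind(ct$points[, 1] + 2, ct$points[, 2] + 1)
  d <- as.matrix(dist(rbind(moved, ref)))
  np <- nrow(moved)
  h <- max(apply(d[1:np, -(1:np), drop = FALSE], 1, min),
           apply(d[-(1:np), 1:np, drop = FALSE], 2, min))
  expect_lte(h, 1)
})

test_that("propagation tracks phantom contraction with high overlap", {
  cfg <- phantom_config(n_cases = 1, phases = 8, slices = 3, grid = c(96, 96),
                        spacing_mm = c(8, 1.5, 1.5), seed = 13,
                        class_mix = c(NOR = 1))
  gen <- generate_cohort(cfg)
  case <- cohort_cases(gen$cohort)[[1]]
  vox <- case$images[[1]]$voxels
  lab <- case$sessions[[1]]$mask$labels
  s <- 2
  pts <- mask_to_contour_points(lab[, , s, 1] == 3L)
  # the field chain below is built for this single slice, so the contour
  # indexes slice 1 of those one-slice fields
  ct <- cmr_contour("lv_endo", 1, 1, pts)
  fields <- lapply(1:3, function(p) {
    estimate_deformation(vox[, , s, p, drop = TRUE] |> array(c(96, 96, 1)),
                         vox[, , s, p + 1, drop = TRUE] |> array(c(96, 96, 1)))
  })
  out <- propagate_contour(ct, fields, c(96, 96))
  for (k in 1:3) {
    prop <- rasterize_polygon(out[[k]]$points, c(96, 96))
    expect_gte(dice(prop, lab[, , s, 1 + k] == 3L), 0.9)
  }
})

test_that("consistency enforcement clips, reassigns, and is idempotent", {
  n <- 80; g <- grid_coords(n)
  D <- sqrt(outer(g^2, g^2, "+"))
  # endo disc protruding beyond the epi ring
  sl <- matrix(0L, n, n)
  sl[D <= 25 & D > 15] <- 2L
  Dp <- sqrt(outer(g^2, (g - 15)^2, "+"))  # pool shifted right by 15
  sl[Dp <= 15] <- 3L
  lab <- array(0L, c(n, n, 1, 1)); lab[, , 1, 1] <- sl
  fixed <- enforce_consistency(lab)
  sl2 <- fixed$labels[, , 1, 1]
  myo_fill <- EBImage::imageData(EBImage::fillHull(EBImage::Image((sl == 2L) * 1))) > 0.5
  expect_equal(sum(sl2 == 3L & !myo_fill), 0)          # endo clipped to epi
  expect_lte(sum(sl2 != 0L), sum(sl != 0L))            # volume never increases
  # idempotence
  again <- enforce_consistency(fixed)
  expect_identical(again$labels, fixed$labels)

  # RV drawn into the septal wall: region interface reassigns overlap to myo
  endo <- D <= 15
  epi <- D <= 25
  rv <- sqrt(outer(g^2, (g + 30)^2, "+")) <= 12  # overlaps the epi ring
  out <- consistent_labels(endo, epi, rv)
  expect_equal(sum(out == 1L & epi), 0)                # RV disjoint from epi
  expect_true(all(out[epi & !endo] == 2L))             # overlap now myo
  expect_true(all(out[endo] == 3L))

  # already-consistent phantom masks are unchanged
  gen <- generate_cohort(tiny_phantom_config(n_cases = 1, seed = 19))
  lab0 <- cohort_cases(gen$cohort)[[1]]$sessions[[1]]$mask$labels
  expect_identical(enforce_consistency(lab0)$labels, lab0)
})

test_that("consistency enforcement survives random perturbations", {
  gen <- generate_cohort(tiny_phantom_config(n_cases = 1, seed = 47))
  lab0 <- cohort_cases(gen$cohort)[[1]]$sessions[[1]]$mask$labels
  set.seed(101)
  for (i in 1:25) {
    lab <- lab0
    p <- sample(dim(lab)[4], 1); s <- sample(dim(lab)[3], 1)
    sl <- lab[, , s, p]
    # random structure translated by a random offset, overwriting labels
    v <- sample(c(1L, 2L, 3L), 1)
    d <- sample(-6:6, 2, replace = TRUE)
    src <- which(sl == v, arr.ind = TRUE)
    if (!nrow(src)) next
    dst <- src + matrix(d, nrow(src), 2, byrow = TRUE)
    keep <- dst[, 1] >= 1 & dst[, 1] <= nrow(sl) & dst[, 2] >= 1 & dst[, 2] <= ncol(sl)
    sl[src] <- 0L
    sl[dst[keep, , drop = FALSE]] <- v
    lab[, , s, p] <- sl
    fixed <- enforce_consistency(lab, phases = p, slices = s)
    sl2 <- fixed$labels[, , s, p]
    myo_fill <- EBImage::imageData(EBImage::fillHull(EBImage::Image((sl2 == 2L) * 1))) > 0.5
    expect_equal(sum(sl2 == 3L & !(myo_fill | sl2 == 2L)), 0)  # endo inside epi
    expect_equal(sum(sl2 == 1L & (sl2 == 2L | sl2 == 3L)), 0)
    expect_lte(sum(fixed$labels != 0L), sum(lab != 0L))        # no growth
    expect_identical(enforce_consistency(fixed, phases = p, slices = s)$labels,
                     fixed$labels)                             # idempotent
  }
})

test_that("apply_correction flags exactly the touched contours", {
  gen <- generate_cohort(tiny_phantom_config(n_cases = 1, seed = 53))
  case <- cohort_cases(gen$cohort)[[1]]
  sess <- latest_session(case)
  bin <- sess$mask$labels[, , 2, 1] == 3L
  pts <- mask_to_contour_points(bin)
  # move the endo contour outward a little (simulated expert edit)
  ctr <- colMeans(pts)
  pts2 <- sweep(sweep(pts, 2, ctr), 2, c(1.08, 1.08), "*")
  pts2 <- sweep(pts2, 2, ctr, "+")
  edit <- cmr_contour("lv_endo", 1, 2, pts2, corrected = TRUE)
  new_sess <- apply_correction(sess, list(edit))
  expect_equal(new_sess$origin, "corrected")
  expect_equal(nrow(new_sess$per_contour_corrected), 1)
  expect_equal(new_sess$per_contour_corrected$structure, "lv_endo")
  expect_true(all(new_sess$per_contour_corrected$corrected))
  # original untouched; other slices copied unchanged
  expect_identical(sess$mask$labels, cohort_cases(gen$cohort)[[1]]$sessions[[1]]$mask$labels)
  expect_identical(new_sess$mask$labels[, , 3, ], sess$mask$labels[, , 3, ])
  # the edited slice's pool grew
  expect_gt(sum(new_sess$mask$labels[, , 2, 1] == 3L), sum(bin))
  # attaching keeps both sessions
  case2 <- attach_session(case, new_sess)
  expect_length(case2$sessions, 2)
})

test_that("correcting a corrupted slice removes the volume-curve discontinuity", {
  gen <- generate_cohort(tiny_phantom_config(n_cases = 1, seed = 59))
  case <- cohort_cases(gen$cohort)[[1]]
  sess <- latest_session(case)
  bad <- inject_corruption(sess, "mask_dropout",
                           params = list(structure = "lv_bloodpool", slice = 3))
  area_jump <- function(s) {
    areas <- vapply(seq_len(dim(s$mask$labels)[3]),
                    function(sl) sum(s$mask$labels[, , sl, 1] == 3L), 0)
    max(abs(diff(areas)))
  }
  jump_bad <- area_jump(bad)
  # expert replaces the dropped slice with the true contour
  pts <- mask_to_contour_points(sess$mask$labels[, , 3, 1] == 3L)
  fixed <- apply_correction(bad, list(cmr_contour("lv_endo", 1, 3, pts)))
  expect_lt(area_jump(fixed), jump_bad)
})
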