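test_that("volumes follow voxel arithmetic and analytic shapes", {
  # 1000 voxels at 1 mm iso = 1 ml
  bin <- array(FALSE, c(10, 10, 10)); bin[1:10, 1:10, 1:10] <- TRUE
  expect_equal(structure_volume(mask4(bin), "lv_bloodpool", 1, c(1, 1, 1)), 1)
  # digitized ellipsoid within 2% of 4/3 pi abc
  a <- 20; b <- 15; c <- 10
  E <- outer(outer((grid_coords(45) / a)^2, (grid_coords(35) / b)^2, "+"),
             (grid_coords(25) / c)^2, "+") <= 1
  v <- structure_volume(mask4(E), "lv_bloodpool", 1, c(1, 1, 1)) * 1000
  expect_lt(abs(v - 4 / 3 * pi * a * b * c) / (4 / 3 * pi * a * b * c), 0.02)
  # empty structure is exactly 0 ml
  expect_equal(structure_volume(mask4(E), "rv_bloodpool", 1, c(1, 1, 1)), 0)
})

test_that("surface area matches analytic values and scales with spacing^2", {
  ball <- digitized_ball(10)
  A <- structure_surface_area(mask4(ball), "lv_bloodpool", 1, c(1, 1, 1))
  expect_lt(abs(A - 4 * pi * 100) / (4 * pi * 100), 0.03)
  # doubling all spacings quadruples the area (exactly)
  A2 <- structure_surface_area(mask4(ball), "lv_bloodpool", 1, c(2, 2, 2))
  expect_equal(A2 / A, 4, tolerance = 1e-9)
  # a single voxel meshes to the octahedron of area sqrt(3) (documented
  # behaviour of the midpoint marching-cubes mesher; no smoothing below 30
  # vertices)
  vox <- array(FALSE, c(3, 3, 3)); vox[2, 2, 2] <- TRUE
  expect_equal(structure_surface_area(mask4(vox), "lv_bloodpool", 1, c(1, 1, 1)),
               sqrt(3), tolerance = 1e-9)
  # empty structure: missing value, not zero
  expect_true(is.na(structure_surface_area(mask4(ball), "rv_bloodpool", 1,
                                           c(1, 1, 1))))
})

test_that("sphericity is 1 for balls, (pi/6)^(1/3) for cubes, low for pancakes", {
  ball <- digitized_ball(10)
  expect_equal(structure_sphericity(mask4(ball), "lv_bloodpool", 1, c(1, 1, 1)),
               1, tolerance = 0.05)
  cube <- array(FALSE, c(26, 26, 26)); cube[4:23, 4:23, 4:23] <- TRUE
  expect_equal(structure_sphericity(mask4(cube), "lv_bloodpool", 1, c(1, 1, 1)),
               (pi / 6)^(1 / 3), tolerance = 0.05)
  pan <- array(FALSE, c(26, 26, 5)); pan[4:23, 4:23, 3] <- TRUE
  expect_lt(structure_sphericity(mask4(pan), "lv_bloodpool", 1, c(1, 1, 1)), 0.6)
})

test_that("septum thickness recovers constructed shell geometry", {
  sl <- shell_slice(r_endo = 30, r_epi = 40)
  lab <- array(0L, c(dim(sl), 1, 1)); lab[, , 1, 1] <- sl
  st <- septum_thickness(lab, 1, 1, c(1, 1, 1))
  expect_equal(st$septum_thickness_mm, 10, tolerance = 0.5)
  expect_equal(st$relative_septum_thickness, 10 / 80, tolerance = 0.01)
  # in-plane rotation by 90 degrees leaves the measurement unchanged
  n <- nrow(sl)
  lab90 <- array(0L, c(n, n, 1, 1)); lab90[, , 1, 1] <- t(sl)[n:1, ]
  st90 <- septum_thickness(lab90, 1, 1, c(1, 1, 1))
  expect_equal(st90$septum_thickness_mm, st$septum_thickness_mm, tolerance = 0.5)
  # RV absent -> missing value
  sl_norv <- sl; sl_norv[sl_norv == 1L] <- 0L
  lab2 <- array(0L, c(dim(sl), 1, 1)); lab2[, , 1, 1] <- sl_norv
  expect_true(is.na(septum_thickness(lab2, 1, 1, c(1, 1, 1))$septum_thickness_mm))
})

test_that("tortuosity is 1 for convex contours and large for stars", {
  g <- grid_coords(41); D <- sqrt(outer(g^2, g^2, "+"))
  circ <- array(0L, c(41, 41, 1, 1)); circ[, , 1, 1][D <= 15] <- 3L
  expect_equal(lv_tortuosity(circ, 1, 1, c(1, 1, 1)), 1, tolerance = 0.03)
  # 5-point star, inner/outer 10/20: analytic perimeter/hull ratio = 1.13
  g2 <- grid_coords(61)
  th <- atan2(outer(g2, rep(1, 61)), outer(rep(1, 61), g2))
  D2 <- sqrt(outer(g2^2, g2^2, "+"))
  star <- array(0L, c(61, 61, 1, 1))
  star[, , 1, 1][D2 <= 10 + 10 * (0.5 + 0.5 * cos(5 * th))] <- 3L
  expect_gt(lv_tortuosity(star, 1, 1, c(1, 1, 1)), 1.1)
  # spikier star (inner radius ~4): analytic ratio ~1.44
  spiky <- array(0L, c(61, 61, 1, 1))
  spiky[, , 1, 1][D2 <= 4 + 16 * (0.5 + 0.5 * cos(5 * th))] <- 3L
  expect_gt(lv_tortuosity(spiky, 1, 1, c(1, 1, 1)), 1.3)
  # hull perimeter minimality: never < 1 - eps, over assorted masks
  set.seed(7)
  for (i in 1:10) {
    blob <- array(0L, c(41, 41, 1, 1))
    rr <- 8 + 6 * runif(1)
    blob[, , 1, 1][sqrt(outer((g - round(runif(1, -5, 5)))^2,
                              (g - round(runif(1, -5, 5)))^2, "+")) <= rr] <- 3L
    expect_gte(lv_tortuosity(blob, 1, 1, c(1, 1, 1)), 1 - 0.02)
  }
})

test_that("box-counting dimension separates lines from prefractals", {
  lab <- array(0L, c(64, 64, 1, 1)); lab[32, , 1, 1] <- 2L
  expect_equal(fractal_dimension(lab, "lv_myocardium", 1, 1), 1, tolerance = 0.1)
  # smooth closed contour (square boundary) stays near 1
  sq <- array(0L, c(64, 64, 1, 1)); sq[16:48, 16:48, 1, 1] <- 2L
  expect_equal(fractal_dimension(sq, "lv_myocardium", 1, 1), 1, tolerance = 0.15)
  # Koch-like prefractal (3 iterations, dimension log4/log3 ~ 1.26)
  koch_segments <- function(p1, p2, depth) {
    if (depth == 0) return(list(rbind(p1, p2)))
    d <- (p2 - p1) / 3
    a <- p1 + d; b <- p1 + 2 * d
    rot <- matrix(c(cos(-pi / 3), sin(-pi / 3), -sin(-pi / 3), cos(-pi / 3)), 2)
    peak <- a + as.vector(rot %*% d)
    c(koch_segments(p1, a, depth - 1), koch_segments(a, peak, depth - 1),
      koch_segments(peak, b, depth - 1), koch_segments(b, p2, depth - 1))
  }
  segs <- koch_segments(c(100, 10), c(100, 250), 3)
  lab2 <- array(0L, c(128, 128, 1, 1))
  for (sg in segs) {
    t <- seq(0, 1, length.out = 40)
    pts <- cbind(sg[1, 1] + t * (sg[2, 1] - sg[1, 1]),
                 sg[1, 2] + t * (sg[2, 2] - sg[1, 2])) / 2
    pts <- round(pts)
    keep <- pts[, 1] >= 1 & pts[, 1] <= 128 & pts[, 2] >= 1 & pts[, 2] <= 128
    lab2[, , 1, 1][pts[keep, , drop = FALSE]] <- 2L
  }
  expect_gt(fractal_dimension(lab2, "lv_myocardium", 1, 1), 1.15)
})

test_that("function parameters follow the curve extrema convention", {
  fp <- function_parameters(c(100, 80, 40, 60, 95))
  expect_equal(fp$edv_ml, 100); expect_equal(fp$esv_ml, 40)
  expect_equal(fp$ef, 0.6)
  expect_equal(fp$ed_phase, 1); expect_equal(fp$es_phase, 3)
  # constant curve: EF 0
  expect_equal(function_parameters(rep(70, 5))$ef, 0)
  # ties resolve to the first occurrence
  fp2 <- function_parameters(c(50, 90, 40, 90, 40))
  expect_equal(fp2$ed_phase, 2); expect_equal(fp2$es_phase, 3)
  # phantom EF recovery against the programmed truth
  gen <- generate_cohort(tiny_phantom_config(n_cases = 2, seed = 31))
  tab <- extract_feature_table(gen$cohort, "fast")
  expect_lt(max(abs(tab$lv.ef - gen$truth$ef)), 0.03)
})
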