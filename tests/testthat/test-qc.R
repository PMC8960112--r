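toy_table <- function(values, feature = "lv_myocardium.septum_thickness.mean") {
  tab <- data.frame(row_id = paste0("c", seq_along(values), "::s"),
                    case_id = paste0("c", seq_along(values)),
                    session_id = "s", class_label = "NOR",
                    stringsAsFactors = FALSE)
  tab[[feature]] <- values
  structure(tab, class = c("feature_table", "data.frame"))
}

test_that("robust z-scores flag exactly the extreme case", {
  tab <- toy_table(c(1:9, 100))
  rep <- feature_outliers(tab, features = "lv_myocardium.septum_thickness.mean")
  expect_true(rep$flagged[["c10"]])
  expect_equal(sum(rep$flagged), 1)
  # hand computation: median 5.5, MAD(constant=1.4826) of {4.5,...,94.5}
  z10 <- (100 - 5.5) / (1.4826 * median(abs(c(1:9, 100) - 5.5)))
  expect_equal(rep$flags$score[rep$flags$case_id == "c10"], abs(z10))
  expect_gt(z10, 25)

  # all-identical values: MAD 0, warning, nothing flagged
  expect_warning(rep0 <- feature_outliers(toy_table(rep(7, 10)),
                                          features = "lv_myocardium.septum_thickness.mean"),
                 "zero MAD")
  expect_equal(sum(rep0$flagged), 0)

  # infinite threshold: empty report
  rep_inf <- feature_outliers(tab, features = "lv_myocardium.septum_thickness.mean",
                              z_threshold = Inf)
  expect_equal(sum(rep_inf$flagged), 0)
})

test_that("flags are monotone in threshold and affine-invariant", {
  set.seed(4)
  vals <- c(rnorm(20), 8, -9)
  tab <- toy_table(vals)
  f <- "lv_myocardium.septum_thickness.mean"
  thresholds <- c(1, 2, 3, 5, 10)
  flagged <- lapply(thresholds, function(th) {
    names(which(feature_outliers(tab, features = f, z_threshold = th)$flagged))
  })
  for (k in seq_len(length(thresholds) - 1)) {
    expect_true(all(flagged[[k + 1]] %in% flagged[[k]]))
  }
  # monotone affine transform of the column leaves flags unchanged
  tab2 <- tab; tab2[[f]] <- 3.7 * tab2[[f]] - 11
  expect_identical(feature_outliers(tab, features = f)$flagged,
                   feature_outliers(tab2, features = f)$flagged)
})

test_that("slice misalignment scores the phantom geometry as designed", {
  gen <- generate_cohort(tiny_phantom_config(n_cases = 1, seed = 61))
  sess <- latest_session(cohort_cases(gen$cohort)[[1]])
  clean <- slice_misalignment(sess, c(8, 2, 2))
  expect_lt(clean$score, 0.2)     # apex taper only
  expect_false(clean$flag)

  # shifting a slice by about one pool radius trips the 0.5 threshold
  lab <- sess$mask$labels
  r_eq_px <- sqrt(sum(lab[, , 3, 1] == 3L) / pi)
  shifted <- inject_corruption(sess, "slice_shift",
                               params = list(d = c(round(r_eq_px), 0), slice = 3))
  m <- slice_misalignment(shifted, c(8, 2, 2))
  expect_gte(m$score, 0.5)
  expect_true(m$flag)

  # dropout is caught by the area-jump rule
  dropped <- inject_corruption(sess, "mask_dropout",
                               params = list(structure = "lv_bloodpool", slice = 3))
  md <- slice_misalignment(dropped, c(8, 2, 2))
  expect_equal(md$max_area_jump, 1)
  expect_true(md$flag)

  # single-slice mask: no adjacent pairs, score 0, unflagged
  lab1 <- lab[, , 3, , drop = FALSE]
  img1 <- image_volume(cohort_cases(gen$cohort)[[1]]$images[[1]]$voxels[, , 3, , drop = FALSE],
                       c(8, 2, 2))
  case1 <- cmr_case("single", list(img1))
  case1 <- add_session(case1, label_mask(lab1), "automatic")
  s1 <- slice_misalignment(latest_session(case1), c(8, 2, 2))
  expect_equal(s1$score, 0)
  expect_false(s1$flag)
})

test_that("worklists are ordered, deterministic and empty without flags", {
  expect_equal(nrow(build_worklist(outlier_report(
    data.frame(case_id = character(), rule = character(), feature = character(),
               score = numeric(), threshold = numeric()), c("a", "b")))), 0)

  flags <- data.frame(case_id = c("b", "a", "c", "a"),
                      rule = "feature_range", feature = "f",
                      score = c(5, 7, 5, 4), threshold = 3,
                      stringsAsFactors = FALSE)
  rep <- outlier_report(flags, c("a", "b", "c", "d"))
  wl1 <- build_worklist(rep)
  wl2 <- build_worklist(rep)
  expect_identical(wl1, wl2)
  expect_equal(wl1$case_id, c("a", "b", "c"))  # by score desc, ties by id
  expect_equal(wl1$n_flags, c(2L, 1L, 1L))
})

test_that("corruption-free cohorts stay below a 10% false-positive rate", {
  cfg <- phantom_config(n_cases = 60, phases = 6, slices = 6, grid = c(72, 72),
                        spacing_mm = c(8, 2.1, 2.1), seed = 314)
  gen <- generate_cohort(cfg)
  tab <- suppressMessages(extract_feature_table(gen$cohort, "standard"))
  wl <- build_worklist(feature_outliers(tab), cohort_misalignment(gen$cohort))
  expect_lte(nrow(wl) / 60, 0.10)
})

test_that("the pcp rendering writes a vector-graphics file", {
  gen <- generate_cohort(tiny_phantom_config(n_cases = 3, seed = 67))
  tab <- extract_feature_table(gen$cohort, "fast")
  path <- file.path(withr::local_tempdir(), "pcp.svg")
  pcp_plot(tab, features = c("lv_bloodpool.volume.mean",
                             "lv_myocardium.septum_thickness.mean",
                             "lv.ef"), file = path)
  expect_true(file.exists(path) || file.exists(sub("svg$", "pdf", path)))
})
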