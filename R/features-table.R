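# Feature curves and the cohort feature table.
#
# Time-resolved features are computed once per cardiac phase (a FeatureCurve)
# and aggregated with minimum, maximum, median and arithmetic mean; the
# cohort FeatureTable holds one row per (case, session) with the aggregated
# feature columns, clinical scalars, the class label and the session id for
# provenance.

#' Create a feature curve
#'
#' @param name Feature name, `"<structure>.<feature>"`.
#' @param values One scalar per cardiac phase (NA = missing).
#' @param units Unit string (`""` for dimensionless).
#' @return Object of class `feature_curve` with `aggregates` (min, max,
#'   median, mean, computed over non-missing phases).
#' @export
feature_curve <- function(name, values, units = "") {
  stopifnot(is.character(name), is.numeric(values))
  agg <- curve_aggregates(values)
  structure(list(name = name, values = as.numeric(values), units = units,
                 aggregates = agg), class = "feature_curve")
}

curve_aggregates <- function(values) {
  if (all(is.na(values))) {
    return(c(min = NA_real_, max = NA_real_, median = NA_real_, mean = NA_real_))
  }
  c(min = min(values, na.rm = TRUE), max = max(values, na.rm = TRUE),
    median = median(values, na.rm = TRUE), mean = mean(values, na.rm = TRUE))
}

#' @export
print.feature_curve <- function(x, ...) {
  cat(sprintf("<feature_curve> %s [%s], %d phases; mean %.4g\n", x$name,
              x$units, length(x$values), x$aggregates[["mean"]]))
  invisible(x)
}

#' Feature presets
#'
#' `standard` is the full documented preset (shape, cardiac, GLCM, NGTDM and
#' first-order families over LV blood pool, LV myocardium and RV blood pool);
#' `fast` is a reduced preset without mesh-based shape features, intended for
#' large simulation sweeps.
#'
#' @param preset `"standard"` or `"fast"`, or a data frame with columns
#'   `feature`, `structure`, `group`, `units` (returned unchanged).
#' @return Data frame describing one feature curve per row.
#' @export
feature_preset <- function(preset = "standard") {
  if (is.data.frame(preset)) return(preset)
  fs <- function(feature, structure, group, units) {
    data.frame(feature = feature, structure = structure, group = group,
               units = units, stringsAsFactors = FALSE)
  }
  structures <- c("lv_bloodpool", "lv_myocardium", "rv_bloodpool")
  standard <- rbind(
    fs("volume", structures, "shape", "ml"),
    fs("surface_area", structures, "shape", "mm2"),
    fs("sphericity", structures, "shape", ""),
    fs("glcm_contrast", c("lv_myocardium", "lv_bloodpool"), "glcm", ""),
    fs("glcm_difference_entropy", c("lv_myocardium", "lv_bloodpool"), "glcm", "bits"),
    fs("glcm_cluster_tendency", c("lv_myocardium", "lv_bloodpool"), "glcm", ""),
    fs("ngtdm_coarseness", c("lv_myocardium", "lv_bloodpool"), "ngtdm", ""),
    fs("ngtdm_complexity", c("lv_myocardium", "lv_bloodpool"), "ngtdm", ""),
    fs("septum_thickness", "lv_myocardium", "cardiac", "mm"),
    fs("relative_septum_thickness", "lv_myocardium", "cardiac", ""),
    fs("tortuosity", "lv_bloodpool", "shape", ""),
    fs("fractal_dimension", "lv_myocardium", "shape", ""),
    fs("intensity_mean", c("lv_myocardium", "lv_bloodpool"), "first_order", "au"),
    fs("intensity_sd", c("lv_myocardium", "lv_bloodpool"), "first_order", "au"))
  fast <- rbind(
    fs("volume", structures, "shape", "ml"),
    fs("glcm_contrast", "lv_myocardium", "glcm", ""),
    fs("glcm_cluster_tendency", "lv_myocardium", "glcm", ""),
    fs("ngtdm_coarseness", "lv_bloodpool", "ngtdm", ""),
    fs("septum_thickness", "lv_myocardium", "cardiac", "mm"),
    fs("relative_septum_thickness", "lv_myocardium", "cardiac", ""),
    fs("intensity_mean", c("lv_myocardium", "lv_bloodpool"), "first_order", "au"),
    fs("intensity_sd", "lv_myocardium", "first_order", "au"))
  switch(preset, standard = standard, fast = fast,
         stop2("unknown feature preset '%s'", preset))
}

# Mean over slices, NA-aware; NA when nothing is computable.
slice_mean <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)

#' Compute feature curves for one session
#'
#' @param case A `cmr_case`.
#' @param session A `cmr_session` of that case (default: latest).
#' @param feature_set Preset name or data frame (see [feature_preset()]).
#' @param smooth_iterations Mesh smoothing passes for surface-based features.
#' @return Named list of [feature_curve()] objects, plus attribute
#'   `function_parameters` (EDV/ESV/EF from the LV volume curve).
#' @export
extract_feature_curves <- function(case, session = NULL, feature_set = "standard",
                                   smooth_iterations = 10) {
  session <- session %||% latest_session(case)
  spec <- feature_preset(feature_set)
  img <- case$images[[1]]
  vox <- img$voxels; lab <- session$mask$labels
  spacing <- img$spacing
  P <- dim(lab)[4]; S <- dim(lab)[3]
  curves <- list()
  set_curve <- function(structure, feature, units, values) {
    nm <- paste0(structure, ".", feature)
    curves[[nm]] <<- feature_curve(nm, values, units)
  }
  per_slice <- function(fn) vapply(seq_len(S), fn, 0)
  # memoize the GLCM/NGTDM bundles: several curve rows share one computation
  cache <- new.env(parent = emptyenv())
  glcm_c <- function(st, p) {
    k <- paste0("g", st, p)
    if (is.null(cache[[k]])) cache[[k]] <- glcm_features(vox, lab, st, p)
    cache[[k]]
  }
  ngtdm_c <- function(st, p) {
    k <- paste0("n", st, p)
    if (is.null(cache[[k]])) cache[[k]] <- ngtdm_features(vox, lab, st, p)
    cache[[k]]
  }
  area_c <- function(st, p) {
    k <- paste0("a", st, p)
    if (is.null(cache[[k]])) {
      cache[[k]] <- structure_surface_area(lab, st, p, spacing, smooth_iterations)
    }
    cache[[k]]
  }
  sphericity_c <- function(st, p) {
    V <- structure_volume(lab, st, p, spacing) * 1000
    if (V == 0) return(NA_real_)
    (36 * pi * V^2)^(1 / 3) / area_c(st, p)
  }
  septum_c <- function(p) {
    k <- paste0("s", p)
    if (is.null(cache[[k]])) {
      res <- lapply(seq_len(S), function(s) septum_thickness(lab, p, s, spacing))
      cache[[k]] <- list(
        abs = slice_mean(vapply(res, `[[`, 0, "septum_thickness_mm")),
        rel = slice_mean(vapply(res, `[[`, 0, "relative_septum_thickness")))
    }
    cache[[k]]
  }

  for (r in seq_len(nrow(spec))) {
    feat <- spec$feature[r]; st <- spec$structure[r]; un <- spec$units[r]
    vals <- vapply(seq_len(P), function(p) {
      switch(feat,
        volume = structure_volume(lab, st, p, spacing),
        surface_area = area_c(st, p),
        sphericity = sphericity_c(st, p),
        glcm_contrast = glcm_c(st, p)[["contrast"]],
        glcm_difference_entropy = glcm_c(st, p)[["difference_entropy"]],
        glcm_cluster_tendency = glcm_c(st, p)[["cluster_tendency"]],
        ngtdm_coarseness = ngtdm_c(st, p)[["coarseness"]],
        ngtdm_complexity = ngtdm_c(st, p)[["complexity"]],
        septum_thickness = septum_c(p)$abs,
        relative_septum_thickness = septum_c(p)$rel,
        tortuosity = slice_mean(per_slice(function(s)
          lv_tortuosity(lab, p, s, spacing, structure = st))),
        fractal_dimension = slice_mean(per_slice(function(s)
          fractal_dimension(lab, st, p, s))),
        intensity_mean = first_order_features(vox, lab, st, p)[["mean"]],
        intensity_sd = first_order_features(vox, lab, st, p)[["sd"]],
        stop2("unknown feature '%s'", feat))
    }, 0)
    set_curve(st, feat, un, vals)
  }
  lv_vol <- curves[["lv_bloodpool.volume"]]
  if (!is.null(lv_vol)) {
    attr(curves, "function_parameters") <- function_parameters(lv_vol)
  }
  curves
}

#' Extract the cohort feature table
#'
#' One row per (case, selected session): aggregated feature curves (four
#' aggregate columns per curve), global function parameters, clinical
#' scalars, class label and provenance ids.  Deterministic column order;
#' missing features are `NA` and reported via `message()`, never silently 0.
#'
#' @param cohort A `cmr_cohort`.
#' @param feature_set Preset name or data frame (see [feature_preset()]).
#' @param clinical_keys Clinical scalars to copy into the table.
#' @param sessions Optional named character vector `case_id -> session_id`
#'   selecting a specific session (default: latest per case).
#' @param smooth_iterations Mesh smoothing passes for surface-based features.
#' @param verbose Log one line per case.
#' @return A `feature_table` (data frame) with attribute `schema`.
#' @export
extract_feature_table <- function(cohort, feature_set = "standard",
                                  clinical_keys = c("height_cm", "weight_kg"),
                                  sessions = NULL, smooth_iterations = 10,
                                  verbose = FALSE) {
  cases <- cohort_cases(cohort)
  stopifnot(length(cases) >= 1)
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    if (!length(case$sessions)) stop2("case '%s' has no sessions", case$case_id)
    session <- if (!is.null(sessions) && case$case_id %in% names(sessions)) {
      case$sessions[[sessions[[case$case_id]]]]
    } else latest_session(case)
    if (verbose) message("extracting ", case$case_id, " (", session$session_id, ")")
    rows[[i]] <- feature_row(case, session, feature_set, clinical_keys,
                             smooth_iterations)
  }
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$row_id)) stop2("duplicated (case, session) rows")
  n_missing <- sum(is.na(tab[, feature_columns(tab)]))
  if (n_missing > 0) {
    message(sprintf("feature table: %d missing values (absent structures)", n_missing))
  }
  schema <- feature_schema(feature_set, clinical_keys)
  structure(tab, schema = schema, class = c("feature_table", "data.frame"))
}

feature_row <- function(case, session, feature_set, clinical_keys,
                        smooth_iterations = 10) {
  curves <- extract_feature_curves(case, session, feature_set, smooth_iterations)
  vals <- unlist(unname(lapply(curves, function(cv) {
    setNames(cv$aggregates, paste0(cv$name, ".", names(cv$aggregates)))
  })))
  fp <- attr(curves, "function_parameters")
  if (!is.null(fp)) {
    vals <- c(vals, lv.edv_ml = fp$edv_ml, lv.esv_ml = fp$esv_ml, lv.ef = fp$ef)
  }
  clin <- setNames(vapply(clinical_keys, function(k) {
    v <- case$clinical[[k]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, 0), clinical_keys)
  out <- data.frame(row_id = paste0(case$case_id, "::", session$session_id),
                    case_id = case$case_id, session_id = session$session_id,
                    class_label = case$class_label %||% NA_character_,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(t(c(clin, vals))))
}

feature_schema <- function(feature_set, clinical_keys) {
  spec <- feature_preset(feature_set)
  agg <- c("min", "max", "median", "mean")
  rows <- do.call(rbind, lapply(seq_len(nrow(spec)), function(r) {
    data.frame(column = paste0(spec$structure[r], ".", spec$feature[r], ".", agg),
               structure = spec$structure[r], feature = spec$feature[r],
               aggregate = agg, units = spec$units[r], group = spec$group[r],
               stringsAsFactors = FALSE)
  }))
  fp <- data.frame(column = c("lv.edv_ml", "lv.esv_ml", "lv.ef"),
                   structure = "lv_bloodpool",
                   feature = c("edv", "esv", "ef"), aggregate = "none",
                   units = c("ml", "ml", ""), group = "cardiac",
                   stringsAsFactors = FALSE)
  cl <- data.frame(column = clinical_keys, structure = "patient",
                   feature = clinical_keys, aggregate = "none",
                   units = c(height_cm = "cm", weight_kg = "kg")[clinical_keys],
                   group = "clinical", stringsAsFactors = FALSE)
  rbind(rows, fp, cl)
}

#' Names of the numeric feature columns of a feature table
#' @param table A `feature_table` (or compatible data frame).
#' @return Character vector of feature/clinical column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("row_id", "case_id", "session_id", "class_label"))
}

#' Write / read a feature table as CSV with a sidecar schema
#'
#' The schema (column, structure, feature, aggregate, units, group) is
#' written as `<path>.schema.json`.  Missing values use the token `NA`.
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @return `path` (write) or the `feature_table` (read).
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "NA")
  schema <- attr(table, "schema")
  if (!is.null(schema)) {
    jsonlite::write_json(schema, paste0(path, ".schema.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  schema_path <- paste0(path, ".schema.json")
  schema <- if (file.exists(schema_path)) {
    jsonlite::fromJSON(schema_path)
  } else NULL
  structure(tab, schema = schema, class = c("feature_table", "data.frame"))
}
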