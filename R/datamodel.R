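# Hierarchical cohort data model: Patient > Study > Case > {ImageVolume, Session}.
#
# The model mirrors the DICOM patient/study hierarchy and keeps every
# segmentation in an append-only Session so that any derived feature value is
# traceable back to the exact mask that produced it.  Voxel grids are R arrays
# indexed [row, col, slice, phase]; physical spacing is (slice_mm, row_mm,
# col_mm).  Voxel indices are 1-based in R code, physical coordinate =
# (index - 1) * spacing; slice 1 is the most basal slice by file order.

#' Create an image volume
#'
#' @param voxels Numeric array indexed `[row, col, slice, phase]`; a 3D array
#'   is promoted to a single-phase 4D array.
#' @param spacing Numeric vector `(slice_mm, row_mm, col_mm)`, strictly
#'   positive.
#' @param modality One of `"cine"`, `"lge"`, `"other"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, modality = c("cine", "lge", "other")) {
  modality <- match.arg(modality)
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L) stop2("voxels must be a 3D or 4D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop2("spacing must be 3 strictly positive values (slice_mm, row_mm, col_mm)")
  }
  structure(list(voxels = voxels, spacing = spacing,
                 phase_count = dim(voxels)[4L], modality_tag = modality),
            class = "image_volume")
}

#' Create a label mask
#'
#' @param labels Integer array indexed `[row, col, slice, phase]` (3D promoted
#'   to single phase).  Only values of [label_convention()] may occur.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels) {
  if (length(dim(labels)) == 3L) dim(labels) <- c(dim(labels), 1L)
  if (length(dim(labels)) != 4L) stop2("labels must be a 3D or 4D array")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(label_convention()))
  if (length(bad)) stop2("unknown label value(s): %s", paste(sort(bad), collapse = ", "))
  structure(list(labels = labels, label_convention = label_convention()),
            class = "label_mask")
}

#' Create a case
#'
#' @param case_id Case identifier string.
#' @param images List of [image_volume()] objects.
#' @param clinical Named list of clinical scalars (e.g. `height_cm`,
#'   `weight_kg`).
#' @param class_label Optional categorical class label.
#' @param label_set Optional character vector of admissible class labels.
#' @param annotations Free-form named list.
#' @return An object of class `cmr_case` with an empty session list.
#' @export
cmr_case <- function(case_id, images, clinical = list(), class_label = NULL,
                     label_set = NULL, annotations = list()) {
  if (inherits(images, "image_volume")) images <- list(images)
  stopifnot(length(images) >= 1L, all(vapply(images, inherits, TRUE, "image_volume")))
  if (!is.null(class_label) && !is.null(label_set) && !class_label %in% label_set) {
    stop2("class_label '%s' not in declared label set", class_label)
  }
  structure(list(case_id = as.character(case_id), images = images,
                 clinical = clinical, class_label = class_label,
                 label_set = label_set, annotations = annotations,
                 sessions = list()),
            class = "cmr_case")
}

#' Wrap cases into the Patient/Study hierarchy
#'
#' @param cases List of [cmr_case()] objects.
#' @param patient_ids,study_ids Optional id vectors (default: one patient and
#'   one study per case, derived from the case id).
#' @return An object of class `cmr_cohort`.
#' @export
cmr_cohort <- function(cases, patient_ids = NULL, study_ids = NULL) {
  stopifnot(all(vapply(cases, inherits, TRUE, "cmr_case")))
  ids <- vapply(cases, `[[`, "", "case_id")
  if (anyDuplicated(ids)) stop2("duplicated case_id in cohort")
  patient_ids <- patient_ids %||% paste0("pat_", ids)
  study_ids <- study_ids %||% paste0("study_", ids)
  if (anyDuplicated(patient_ids)) stop2("patient_id must be unique within a cohort")
  patients <- mapply(function(case, pid, sid) {
    structure(list(patient_id = pid,
                   studies = list(structure(list(study_id = sid, cases = list(case)),
                                            class = "cmr_study"))),
              class = "cmr_patient")
  }, cases, patient_ids, study_ids, SIMPLIFY = FALSE)
  structure(list(patients = patients), class = "cmr_cohort")
}

#' Flatten a cohort to its list of cases
#' @param cohort A `cmr_cohort`.
#' @return Named list of `cmr_case` objects.
#' @export
cohort_cases <- function(cohort) {
  stopifnot(inherits(cohort, "cmr_cohort"))
  cases <- unlist(lapply(cohort$patients, function(p) {
    unlist(lapply(p$studies, `[[`, "cases"), recursive = FALSE)
  }), recursive = FALSE)
  names(cases) <- vapply(cases, `[[`, "", "case_id")
  cases
}

# Replace a case (by id) inside the nested hierarchy, preserving structure.
set_cohort_case <- function(cohort, case) {
  for (i in seq_along(cohort$patients)) {
    for (j in seq_along(cohort$patients[[i]]$studies)) {
      for (k in seq_along(cohort$patients[[i]]$studies[[j]]$cases)) {
        if (cohort$patients[[i]]$studies[[j]]$cases[[k]]$case_id == case$case_id) {
          cohort$patients[[i]]$studies[[j]]$cases[[k]] <- case
          return(cohort)
        }
      }
    }
  }
  stop2("case '%s' not found in cohort", case$case_id)
}

#' Attach a segmentation session to a case
#'
#' Sessions are append-only: adding a session never modifies an existing one.
#' The session id is content-addressed (hash of mask content, origin, case id
#' and per-case sequence number), so identical inputs yield identical ids and
#' provenance is collision-free and reproducible.
#'
#' @param case A `cmr_case`.
#' @param mask A [label_mask()] whose grid matches one of the case's images.
#' @param origin One of `"automatic"`, `"manual"`, `"corrected"`.
#' @param per_contour_corrected Optional data frame with columns `phase`,
#'   `slice`, `structure`, `corrected`; required non-empty (with at least one
#'   `TRUE`) when `origin == "corrected"`.
#' @param certainty Optional per-voxel probability array (pass-through).
#' @param landmarks Optional free-form point list (pass-through).
#' @return The updated case; retrieve the new session with [latest_session()].
#' @export
add_session <- function(case, mask, origin = c("automatic", "manual", "corrected"),
                        per_contour_corrected = NULL, certainty = NULL,
                        landmarks = NULL) {
  origin <- match.arg(origin)
  stopifnot(inherits(case, "cmr_case"), inherits(mask, "label_mask"))
  mdim <- dim(mask$labels)
  ok <- any(vapply(case$images, function(im) identical(dim(im$voxels), mdim), TRUE))
  if (!ok) {
    idim <- dim(case$images[[1]]$voxels)
    stop2("mask dimensions [%s] do not match case image dimensions [%s]",
          paste(mdim, collapse = "x"), paste(idim, collapse = "x"))
  }
  if (origin == "corrected") {
    if (is.null(per_contour_corrected) || !any(per_contour_corrected$corrected)) {
      stop2("origin = 'corrected' requires at least one corrected contour flag")
    }
  }
  if (is.null(per_contour_corrected)) {
    per_contour_corrected <- data.frame(phase = integer(), slice = integer(),
                                        structure = character(), corrected = logical())
  }
  sid <- paste0("s_", substr(content_hash(list(mask$labels, origin, case$case_id,
                                               length(case$sessions))), 1, 16))
  session <- structure(list(session_id = sid, case_id = case$case_id, mask = mask,
                            origin = origin,
                            per_contour_corrected = per_contour_corrected,
                            certainty = certainty, landmarks = landmarks),
                       class = "cmr_session")
  case$sessions <- c(case$sessions, setNames(list(session), sid))
  case
}

#' Most recently added session of a case
#' @param case A `cmr_case`.
#' @return A `cmr_session` (error if the case has none).
#' @export
latest_session <- function(case) {
  if (!length(case$sessions)) stop2("case '%s' has no sessions", case$case_id)
  case$sessions[[length(case$sessions)]]
}

#' Look up a session by id anywhere in a cohort
#' @param cohort A `cmr_cohort`.
#' @param session_id Session id string.
#' @return The `cmr_session`, or error if unknown.
#' @export
find_session <- function(cohort, session_id) {
  for (case in cohort_cases(cohort)) {
    if (session_id %in% names(case$sessions)) return(case$sessions[[session_id]])
  }
  stop2("unknown session id '%s'", session_id)
}

#' Resolve the provenance of a feature-table row
#'
#' Maps a row id emitted by [extract_feature_table()] back to the exact
#' case/session that produced it.
#'
#' @param feature_row_id Row id string (`"<case_id>::<session_id>"`).
#' @param cohort The cohort the table was extracted from.
#' @return List with `case_id`, `session_id`, `origin`.
#' @export
resolve_provenance <- function(feature_row_id, cohort) {
  parts <- strsplit(feature_row_id, "::", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop2("malformed feature row id '%s'", feature_row_id)
  cases <- cohort_cases(cohort)
  if (!parts[1] %in% names(cases)) stop2("unknown case id '%s'", parts[1])
  case <- cases[[parts[1]]]
  if (!parts[2] %in% names(case$sessions)) {
    stop2("unknown session id '%s' for case '%s'", parts[2], parts[1])
  }
  s <- case$sessions[[parts[2]]]
  list(case_id = s$case_id, session_id = s$session_id, origin = s$origin)
}

#' @export
print.cmr_cohort <- function(x, ...) {
  cases <- cohort_cases(x)
  ns <- sum(vapply(cases, function(cc) length(cc$sessions), 1L))
  cat(sprintf("<cmr_cohort> %d patients, %d cases, %d sessions\n",
              length(x$patients), length(cases), ns))
  invisible(x)
}

#' @export
print.cmr_session <- function(x, ...) {
  d <- dim(x$mask$labels)
  cat(sprintf("<cmr_session> %s (case %s, origin %s, grid %s)\n",
              x$session_id, x$case_id, x$origin, paste(d, collapse = "x")))
  invisible(x)
}
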