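# Cohort serialization: NIfTI volumes + a JSON manifest.
#
# On disk a cohort is a directory with one image NIfTI and one mask NIfTI per
# session, plus `manifest.json` listing cases, file paths, clinical scalars,
# class labels and session provenance.  NIfTI arrays are stored with axis
# order (row, col, slice, phase) — i.e. the 4th NIfTI dimension is cardiac
# phase — and pixdim (row_mm, col_mm, slice_mm).  This order is enforced on
# load.

nifti_write <- function(arr, spacing, path) {
  # spacing is internal order (slice, row, col); NIfTI pixdim follows axes.
  img <- RNifti::asNifti(arr, pixdim = c(spacing[2], spacing[3], spacing[1], 1)[seq_along(dim(arr))])
  RNifti::writeNifti(img, path)
  invisible(path)
}

nifti_read <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (!length(dim(arr)) %in% c(3L, 4L)) stop2("%s: expected 3D or 4D NIfTI", path)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  pd <- RNifti::pixdim(img)
  list(voxels = arr, spacing = c(pd[3], pd[1], pd[2]))
}

#' Write a cohort to a directory
#'
#' @param cohort A `cmr_cohort`.
#' @param dir Output directory (created if missing).
#' @param truth Optional phantom truth table, written as `truth.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format = "cardioloop-cohort", version = 1L, cases = list())
  for (case in cohort_cases(cohort)) {
    img <- case$images[[1]]
    img_path <- file.path(dir, paste0(case$case_id, "_image.nii.gz"))
    nifti_write(img$voxels, img$spacing, img_path)
    sessions <- lapply(case$sessions, function(s) {
      mask_path <- file.path(dir, paste0(case$case_id, "_", s$session_id, "_mask.nii.gz"))
      nifti_write(s$mask$labels, img$spacing, mask_path)
      list(session_id = s$session_id, origin = s$origin,
           mask = basename(mask_path),
           per_contour_corrected = s$per_contour_corrected)
    })
    manifest$cases[[length(manifest$cases) + 1L]] <- list(
      case_id = case$case_id,
      patient_id = paste0("pat_", case$case_id),
      image = basename(img_path),
      modality = img$modality_tag,
      spacing = img$spacing,
      clinical = case$clinical,
      class_label = case$class_label,
      label_set = case$label_set,
      sessions = unname(sessions))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(truth)) write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a cohort from a manifest
#'
#' Reads the manifest and all referenced NIfTI volumes, validates grid shapes
#' and the label convention, and rebuilds the session hierarchy with its
#' original session ids and provenance flags.
#'
#' @param manifest_path Path to `manifest.json` (or to the cohort directory).
#' @param fail_fast If `TRUE` (default) the first invalid case aborts the
#'   load; otherwise invalid cases are skipped with a warning.
#' @param verbose Log one line per loaded file.
#' @return A `cmr_cohort`.
#' @export
load_cohort <- function(manifest_path, fail_fast = TRUE, verbose = FALSE) {
  if (dir.exists(manifest_path)) manifest_path <- file.path(manifest_path, "manifest.json")
  if (!file.exists(manifest_path)) stop2("manifest not found: %s", manifest_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (!identical(m$format, "cardioloop-cohort")) stop2("not a cohort manifest: %s", manifest_path)
  base <- dirname(manifest_path)
  cases <- list()
  for (entry in m$cases) {
    case <- tryCatch({
      img_path <- file.path(base, entry$image)
      if (verbose) message("loading ", img_path)
      nif <- nifti_read(img_path)
      img <- image_volume(nif$voxels, unlist(entry$spacing), entry$modality %||% "cine")
      case <- cmr_case(entry$case_id, list(img),
                       clinical = lapply(entry$clinical, identity),
                       class_label = entry$class_label,
                       label_set = unlist(entry$label_set))
      for (s in entry$sessions) {
        msk_path <- file.path(base, s$mask)
        if (verbose) message("loading ", msk_path)
        marr <- nifti_read(msk_path)$voxels
        if (!identical(dim(marr), dim(img$voxels))) {
          stop2("%s: mask grid [%s] does not match image grid [%s]", msk_path,
                paste(dim(marr), collapse = "x"), paste(dim(img$voxels), collapse = "x"))
        }
        pcc <- if (length(s$per_contour_corrected)) {
          do.call(rbind, lapply(s$per_contour_corrected, as.data.frame))
        } else NULL
        case <- add_session(case, label_mask(marr), s$origin,
                            per_contour_corrected = pcc)
        # preserve the original id so provenance survives the round trip
        names(case$sessions)[length(case$sessions)] <- s$session_id
        case$sessions[[length(case$sessions)]]$session_id <- s$session_id
      }
      case
    }, error = function(e) {
      if (fail_fast) stop2("case '%s': %s", entry$case_id, conditionMessage(e))
      warning(sprintf("skipping case '%s': %s", entry$case_id, conditionMessage(e)))
      NULL
    })
    if (!is.null(case)) cases[[length(cases) + 1L]] <- case
  }
  cmr_cohort(cases)
}
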