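# Automated outlier detection over the cohort feature table and the mask
# geometry — a scriptable surrogate for interactive parallel-coordinates
# brushing: instead of an expert excluding extreme feature ranges by hand,
# robust z-scores flag them, and a slice-misalignment score flags the
# geometric failure mode visible as surface discontinuities.

default_watch_features <- function(table) {
  # the feature axes typically brushed: myocardial texture, septum thickness,
  # LV tortuosity, blood-pool coarseness — mean and max aggregates
  pats <- c("lv_myocardium.glcm_cluster_tendency", "lv_myocardium.glcm_contrast",
            "lv_myocardium.ngtdm_complexity", "lv_bloodpool.ngtdm_coarseness",
            "lv_myocardium.septum_thickness", "lv_bloodpool.tortuosity")
  cols <- unlist(lapply(pats, function(p) paste0(p, c(".mean", ".max"))))
  intersect(cols, names(table))
}

#' Robust feature-range outlier detection
#'
#' Per feature, robust z = (x - median) / (1.4826 * MAD); a case is flagged
#' when |z| exceeds the threshold on any watched feature.  Features with
#' MAD = 0 are skipped with a warning.  Flags are invariant to monotone
#' affine transforms of a feature column, and lowering the threshold never
#' unflags a case.
#'
#' @param table A `feature_table`.
#' @param features Columns to watch (default: the standard brushed axes
#'   present in the table).
#' @param z_threshold Robust z threshold (default 3).
#' @return Object of class `outlier_report`: data frame `flags` (case_id,
#'   rule, feature, score, threshold), logical `flagged` per case, `summary`.
#' @export
feature_outliers <- function(table, features = NULL, z_threshold = 3.0) {
  features <- features %||% default_watch_features(table)
  features <- intersect(features, names(table))
  flags <- list()
  for (f in features) {
    x <- table[[f]]
    med <- median(x, na.rm = TRUE)
    madv <- mad(x, na.rm = TRUE)  # 1.4826 * median absolute deviation
    if (!is.finite(madv) || madv == 0) {
      warning(sprintf("feature '%s' has zero MAD; skipped", f))
      next
    }
    z <- (x - med) / madv
    hit <- which(!is.na(z) & abs(z) > z_threshold)
    if (length(hit)) {
      flags[[length(flags) + 1]] <- data.frame(
        case_id = table$case_id[hit], rule = "feature_range", feature = f,
        score = abs(z[hit]), threshold = z_threshold, stringsAsFactors = FALSE)
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(case_id = character(), rule = character(), feature = character(),
               score = numeric(), threshold = numeric(), stringsAsFactors = FALSE)
  outlier_report(flags, unique(table$case_id))
}

outlier_report <- function(flags, all_cases) {
  flagged <- setNames(all_cases %in% flags$case_id, all_cases)
  base::structure(list(flags = flags, flagged = flagged,
                       summary = list(n_cases = length(all_cases),
                                      n_flagged = sum(flagged),
                                      n_flags = nrow(flags))),
                  class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d/%d cases flagged (%d flags)\n",
              x$summary$n_flagged, x$summary$n_cases, x$summary$n_flags))
  invisible(x)
}

#' Slice-misalignment score of a segmentation session
#'
#' At end-diastole (the phase maximizing LV blood-pool volume), the score is
#' the maximum over adjacent slice pairs of the LV blood-pool centroid
#' displacement divided by the pool's equivalent radius (resolution
#' independent).  The maximum inter-slice area jump ratio
#' `1 - min(a1, a2) / max(a1, a2)` is reported alongside and also flags
#' (it catches slice dropout, which has no centroid to displace).
#'
#' @param session A `cmr_session`.
#' @param spacing `(slice_mm, row_mm, col_mm)`.
#' @param threshold Centroid-shift flag threshold (default 0.5).
#' @param area_jump_threshold Area-ratio flag threshold (default 0.6).
#' @return List with `score`, `max_area_jump`, `flag`, `ed_phase`, `case_id`.
#' @export
slice_misalignment <- function(session, spacing = c(1, 1, 1), threshold = 0.5,
                               area_jump_threshold = 0.6) {
  lab4 <- session$mask$labels
  conv <- label_convention()
  P <- dim(lab4)[4]; S <- dim(lab4)[3]
  pool_count <- vapply(seq_len(P), function(p) sum(lab4[, , , p] == conv[["lv_bloodpool"]]), 0)
  ed <- which.max(pool_count)
  structures <- c("lv_bloodpool", "lv_myocardium", "rv_bloodpool")
  cents <- vector("list", S)
  areas <- matrix(0, S, length(structures), dimnames = list(NULL, structures))
  for (s in seq_len(S)) {
    sl <- lab4[, , s, ed]
    cents[s] <- list(slice_centroid(sl, conv[["lv_bloodpool"]], spacing))
    for (st in structures) {
      areas[s, st] <- sum(sl == conv[[st]]) * spacing[2] * spacing[3]
    }
  }
  score <- 0; max_jump <- 0
  if (S >= 2) {
    for (s in seq_len(S - 1)) {
      # area discontinuities are monitored on all structures (endocardial and
      # epicardial surfaces both betray misalignment/dropout failures)
      for (st in structures) {
        a1 <- areas[s, st]; a2 <- areas[s + 1, st]
        if (a1 > 0 || a2 > 0) {
          max_jump <- max(max_jump, 1 - min(a1, a2) / max(a1, a2))
        }
      }
      if (!is.null(cents[[s]]) && !is.null(cents[[s + 1]])) {
        disp <- sqrt(sum((cents[[s]] - cents[[s + 1]])^2))
        r_eq <- sqrt(mean(areas[s:(s + 1), "lv_bloodpool"]) / pi)
        if (r_eq > 0) score <- max(score, disp / r_eq)
      }
    }
  }
  list(case_id = session$case_id, score = score, max_area_jump = max_jump,
       flag = score > threshold || max_jump > area_jump_threshold,
       ed_phase = ed)
}

#' Misalignment report for a whole cohort
#'
#' @param cohort A `cmr_cohort`.
#' @inheritParams slice_misalignment
#' @return An `outlier_report` with rules `slice_misalignment` /
#'   `area_jump`.
#' @export
cohort_misalignment <- function(cohort, threshold = 0.5, area_jump_threshold = 0.6) {
  cases <- cohort_cases(cohort)
  flags <- list()
  for (case in cases) {
    sp <- case$images[[1]]$spacing
    m <- slice_misalignment(latest_session(case), sp, threshold, area_jump_threshold)
    if (m$score > threshold) {
      flags[[length(flags) + 1]] <- data.frame(
        case_id = case$case_id, rule = "slice_misalignment", feature = "lv_bloodpool_centroid",
        score = m$score, threshold = threshold, stringsAsFactors = FALSE)
    }
    if (m$max_area_jump > area_jump_threshold) {
      flags[[length(flags) + 1]] <- data.frame(
        case_id = case$case_id, rule = "area_jump", feature = "lv_bloodpool_area",
        score = m$max_area_jump, threshold = area_jump_threshold,
        stringsAsFactors = FALSE)
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(case_id = character(), rule = character(), feature = character(),
               score = numeric(), threshold = numeric(), stringsAsFactors = FALSE)
  outlier_report(flags, vapply(cases, `[[`, "", "case_id"))
}

#' Build the correction worklist from outlier reports
#'
#' Union of flagged cases over all reports, ordered by maximum flag score
#' descending; ties broken deterministically by case id.
#'
#' @param ... `outlier_report` objects.
#' @return Data frame with `case_id`, `max_score`, `n_flags`, `reasons`.
#' @export
build_worklist <- function(...) {
  reports <- list(...)
  flags <- do.call(rbind, lapply(reports, `[[`, "flags"))
  if (is.null(flags) || !nrow(flags)) {
    return(data.frame(case_id = character(), max_score = numeric(),
                      n_flags = integer(), reasons = character(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(flags, flags$case_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(case_id = d$case_id[1], max_score = max(d$score),
               n_flags = nrow(d),
               reasons = paste(unique(paste0(d$rule, ":", d$feature)),
                               collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$max_score, out$case_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Static parallel-coordinates plot of a feature table
#'
#' Non-interactive rendering of the brushing view: one polyline per case over
#' min-max scaled feature axes, coloured by class, worklist cases
#' highlighted.
#'
#' @param table A `feature_table`.
#' @param features Feature columns to draw (default: watched axes).
#' @param highlight Case ids drawn in red on top.
#' @param file Optional SVG (or PDF) output path.
#' @return Invisibly, the scaled matrix that was drawn.
#' @export
pcp_plot <- function(table, features = NULL, highlight = character(), file = NULL) {
  features <- features %||% default_watch_features(table)
  features <- intersect(features, names(table))
  stopifnot(length(features) >= 2)
  X <- as.matrix(table[, features])
  rng <- apply(X, 2, range, na.rm = TRUE)
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, pmax(rng[2, ] - rng[1, ], 1e-12), "/")
  if (!is.null(file)) {
    if (grepl("[.]svg$", file) && capabilities("cairo")) {
      grDevices::svg(file, width = 9, height = 5)
    } else {
      grDevices::pdf(sub("[.]svg$", ".pdf", file), width = 9, height = 5)
    }
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  cls <- factor(table$class_label %||% rep("?", nrow(table)))
  cols <- grDevices::hcl.colors(max(2, nlevels(cls)), "Dark 3")[as.integer(cls)]
  graphics::matplot(t(Xs), type = "l", lty = 1, col = grDevices::adjustcolor(cols, 0.5),
                    xaxt = "n", ylab = "scaled value", xlab = "")
  graphics::axis(1, at = seq_along(features), labels = features, las = 2, cex.axis = 0.5)
  hi <- which(table$case_id %in% highlight)
  if (length(hi)) {
    graphics::matlines(t(Xs[hi, , drop = FALSE]), lty = 1, lwd = 2, col = "red")
  }
  invisible(Xs)
}
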