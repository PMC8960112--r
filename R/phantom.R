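# Synthetic short-axis cardiac phantom generator.
#
# Geometry is a stack of discs: on every slice the LV is a pair of concentric
# circles (endocardium / epicardium) whose radius tapers linearly by 40% from
# base to apex, and the RV blood pool is a crescent formed by a disc adjacent
# to the LV at a fixed angular position, clipped away from the epicardium.
# Contraction scales the endocardial radius by 1 - cf * w(t) where w rises
# sinusoidally from 0 at end-diastole (phase 1) to 1 at end-systole
# (phase round(0.4 * phases)), so the programmed ejection fraction is
# EF = 1 - (1 - cf)^2.  The epicardial radius follows so that the per-slice
# myocardial ring area is conserved over the cycle.  Intensities are
# Gaussian: blood pool mean 400, myocardium mean 150, background mean 80,
# with configurable texture and global noise SDs.  The SCAR class adds a 60
# degree transmural wedge at the inferior wall with blood-pool-level
# intensity, emulating LGE hyperenhancement.
#
# Disease classes differ only through the geometry priors (documented
# synthetic choices, not clinical claims): DCM dilates the LV cavity and
# thins the wall, HCM thickens the wall, RVA enlarges the RV, SCAR adds the
# bright wedge.  Per-case RNG streams are derived from (seed, case index) so
# cohorts are stable under changes of n_cases.

phantom_classes <- c("NOR", "DCM", "HCM", "RVA", "SCAR")

#' Default per-class geometry priors of the phantom
#'
#' Gaussian `c(mean, sd)` priors for LV endocardial radius, wall thickness,
#' RV scale and contraction fraction, per disease class.  Synthetic defaults
#' (documented in the methods vignette), not clinical claims.
#'
#' @return Named list of per-class prior lists.
#' @export
default_geometry_priors <- function() {
  list(
    NOR  = list(lv_endo_radius_mm = c(25, 2.0), wall_thickness_mm = c(8, 1.0),
                rv_scale = c(1.0, 0.05), contraction_fraction = c(0.33, 0.02)),
    DCM  = list(lv_endo_radius_mm = c(33, 2.5), wall_thickness_mm = c(6, 0.8),
                rv_scale = c(1.0, 0.05), contraction_fraction = c(0.15, 0.02)),
    HCM  = list(lv_endo_radius_mm = c(20, 2.0), wall_thickness_mm = c(15, 1.5),
                rv_scale = c(1.0, 0.05), contraction_fraction = c(0.35, 0.02)),
    RVA  = list(lv_endo_radius_mm = c(25, 2.0), wall_thickness_mm = c(8, 1.0),
                rv_scale = c(1.5, 0.08), contraction_fraction = c(0.30, 0.02)),
    SCAR = list(lv_endo_radius_mm = c(25, 2.0), wall_thickness_mm = c(8, 1.0),
                rv_scale = c(1.0, 0.05), contraction_fraction = c(0.25, 0.02)))
}

#' Phantom cohort configuration
#'
#' @param n_cases Number of cases.
#' @param class_mix Named proportions over `NOR, DCM, HCM, RVA, SCAR`
#'   (must sum to 1).
#' @param phases Cardiac phases per cycle (>= 2; default 25).
#' @param slices Short-axis slices (default 10).
#' @param grid `(rows, cols)` in-plane grid (default `c(128, 128)`).
#' @param spacing_mm `(slice_mm, row_mm, col_mm)` voxel spacing
#'   (default `c(8, 1.5, 1.5)`).
#' @param seed Integer seed; all phantom randomness derives from it.
#' @param geometry_priors Per-class list of `c(mean, sd)` priors for
#'   `lv_endo_radius_mm`, `wall_thickness_mm`, `rv_scale`,
#'   `contraction_fraction`.
#' @param intensity List with `bloodpool_mean`, `myo_mean`, `background_mean`,
#'   `texture_sd`, `noise_sd`.
#' @param corruption List with `rate` (fraction of corrupted cases) and
#'   `types` (mix over `slice_shift`, `mask_dilate`, `mask_dropout`).
#' @return A validated object of class `phantom_config`.
#' @export
phantom_config <- function(n_cases = 100,
                           class_mix = c(NOR = 0.25, DCM = 0.25, HCM = 0.25,
                                         RVA = 0.25, SCAR = 0),
                           phases = 25L, slices = 10L, grid = c(128L, 128L),
                           spacing_mm = c(8.0, 1.5, 1.5), seed = 1L,
                           geometry_priors = default_geometry_priors(),
                           intensity = list(bloodpool_mean = 400, myo_mean = 150,
                                            background_mean = 80,
                                            texture_sd = 30, noise_sd = 10),
                           corruption = list(rate = 0,
                                             types = c(slice_shift = 1/3,
                                                       mask_dilate = 1/3,
                                                       mask_dropout = 1/3))) {
  class_mix <- unlist(class_mix)          # tolerate JSON-sourced configs
  grid <- as.integer(unlist(grid))
  spacing_mm <- as.numeric(unlist(spacing_mm))
  if (is.list(corruption$types)) corruption$types <- unlist(corruption$types)
  geometry_priors <- lapply(geometry_priors, function(p) lapply(p, unlist))
  cfg <- structure(list(n_cases = as.integer(n_cases), class_mix = class_mix,
                        phases = as.integer(phases), slices = as.integer(slices),
                        grid = as.integer(grid), spacing_mm = as.numeric(spacing_mm),
                        seed = as.integer(seed), geometry_priors = geometry_priors,
                        intensity = intensity, corruption = corruption),
                   class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is_count(cfg$n_cases) && cfg$n_cases >= 1, "n_cases must be a positive integer")
  chk(all(names(cfg$class_mix) %in% phantom_classes),
      "class_mix names must be among NOR, DCM, HCM, RVA, SCAR")
  chk(abs(sum(cfg$class_mix) - 1) < 1e-8, "class_mix proportions must sum to 1")
  chk(all(cfg$class_mix >= 0), "class_mix proportions must be non-negative")
  chk(cfg$phases >= 2, "phases must be >= 2")
  chk(cfg$slices >= 1, "slices must be >= 1")
  chk(length(cfg$grid) == 2 && all(cfg$grid >= 16), "grid must be (rows, cols) >= 16")
  chk(length(cfg$spacing_mm) == 3 && all(cfg$spacing_mm > 0),
      "spacing_mm must be 3 positive values")
  gp <- cfg$geometry_priors
  for (cl in names(gp)) {
    for (f in c("lv_endo_radius_mm", "wall_thickness_mm", "rv_scale",
                "contraction_fraction")) {
      chk(!is.null(gp[[cl]][[f]]) && gp[[cl]][[f]][1] > 0,
          sprintf("%s prior for %s must be positive", f, cl))
    }
  }
  if (all(c("HCM", "NOR") %in% names(gp))) {
    chk(gp$HCM$wall_thickness_mm[1] > gp$NOR$wall_thickness_mm[1],
        "HCM wall thickness prior mean must exceed NOR's")
    chk(gp$DCM$lv_endo_radius_mm[1] > gp$NOR$lv_endo_radius_mm[1],
        "DCM LV endo radius prior mean must exceed NOR's")
    chk(gp$RVA$rv_scale[1] > 1, "RVA rv_scale prior mean must exceed 1")
  }
  chk(cfg$corruption$rate >= 0 && cfg$corruption$rate <= 1,
      "corruption rate must be in [0, 1]")
  chk(abs(sum(cfg$corruption$types) - 1) < 1e-8 || cfg$corruption$rate == 0,
      "corruption type mix must sum to 1")
  if (length(problems)) {
    stop2("invalid phantom config:\n  - %s", paste(problems, collapse = "\n  - "))
  }
  invisible(cfg)
}

# Contraction weight: 0 at ED (t = 0), 1 at ES, back to 0 at cycle end.
contraction_weight <- function(phases) {
  t <- seq_len(phases) - 1
  t_es <- max(1L, round(0.4 * phases))
  theta <- ifelse(t <= t_es, pi * t / t_es, pi * (phases - t) / (phases - t_es))
  sin(theta / 2)^2
}

#' Programmed ejection fraction for a contraction fraction
#' @param contraction_fraction Endocardial radius reduction at end-systole.
#' @return `1 - (1 - contraction_fraction)^2`.
#' @export
programmed_ef <- function(contraction_fraction) 1 - (1 - contraction_fraction)^2

# Sample per-case geometry parameters from the class priors.
sample_case_params <- function(class, priors) {
  p <- priors[[class]]
  draw <- function(f, lo = 1e-3, hi = Inf) {
    min(max(rnorm(1, p[[f]][1], p[[f]][2]), lo), hi)
  }
  list(class = class,
       lv_endo_radius_mm = draw("lv_endo_radius_mm", lo = 5),
       wall_thickness_mm = draw("wall_thickness_mm", lo = 2),
       rv_scale = draw("rv_scale", lo = 0.3),
       contraction_fraction = draw("contraction_fraction", lo = 0.02, hi = 0.8))
}

# Build the 4D image and mask for one case from its geometry parameters.
# Returns list(image, labels, truth) where truth holds the programmed values.
build_phantom_case <- function(params, cfg, rng_seed) {
  set.seed(rng_seed)
  rows <- cfg$grid[1]; cols <- cfg$grid[2]
  S <- cfg$slices; P <- cfg$phases
  sp <- cfg$spacing_mm  # (slice, row, col)
  r_base <- params$lv_endo_radius_mm
  wall <- params$wall_thickness_mm
  cf <- params$contraction_fraction
  taper <- 1 - 0.4 * (seq_len(S) - 1) / max(1, S - 1)
  w <- contraction_weight(P)
  scale_t <- 1 - cf * w

  # LV centre placed right of the image centre so the RV crescent fits left.
  c_row <- (rows / 2) * sp[2]
  c_col <- (cols / 2 + 0.12 * cols) * sp[3]
  X <- matrix((seq_len(rows) - 1) * sp[2], rows, cols)          # row coordinate, mm
  Y <- matrix((seq_len(cols) - 1) * sp[3], rows, cols, byrow = TRUE)
  D_lv <- sqrt((X - c_row)^2 + (Y - c_col)^2)
  ang <- atan2(X - c_row, Y - c_col)  # 0 = +col axis, pi/2 = +row (inferior)

  labels <- array(0L, c(rows, cols, S, P))
  image <- array(0, c(rows, cols, S, P))
  gap <- 1.5
  mu_bg <- cfg$intensity$background_mean
  tex <- cfg$intensity$texture_sd
  noise <- cfg$intensity$noise_sd
  r_endo_ed <- r_base * taper
  r_epi_ed <- r_endo_ed + wall  # constant ED wall thickness along the stack
  scar_wedge <- abs(ang - pi / 2) <= (pi / 6)  # 60 deg inferior sector

  for (p in seq_len(P)) {
    r_endo <- r_endo_ed * scale_t[p]
    r_epi <- sqrt(r_endo^2 + r_epi_ed^2 - r_endo_ed^2)  # ring area conserved
    for (s in seq_len(S)) {
      r_rv <- params$rv_scale * 0.75 * r_endo[s]
      c_rv_col <- c_col - (r_epi[s] + 0.35 * r_rv)
      D_rv <- sqrt((X - c_row)^2 + (Y - c_rv_col)^2)
      lab <- matrix(0L, rows, cols)
      lab[D_rv <= r_rv & D_lv > r_epi[s] + gap] <- 1L
      lab[D_lv <= r_epi[s] & D_lv > r_endo[s]] <- 2L
      lab[D_lv <= r_endo[s]] <- 3L
      mu <- matrix(mu_bg, rows, cols)
      mu[lab == 1L | lab == 3L] <- cfg$intensity$bloodpool_mean
      mu[lab == 2L] <- cfg$intensity$myo_mean
      if (params$class == "SCAR") {
        mu[lab == 2L & scar_wedge] <- cfg$intensity$bloodpool_mean
      }
      image[, , s, p] <- mu + rnorm(rows * cols, 0, tex) +
        rnorm(rows * cols, 0, noise)
      labels[, , s, p] <- lab
    }
  }

  vol_ml <- function(sc) sum(pi * (r_endo_ed * sc)^2) * sp[1] / 1000
  edv <- vol_ml(max(scale_t)); esv <- vol_ml(min(scale_t))
  truth <- list(class = params$class,
                lv_endo_radius_mm = r_base, wall_thickness_mm = wall,
                rv_scale = params$rv_scale, contraction_fraction = cf,
                edv_ml = edv, esv_ml = esv, ef = (edv - esv) / edv,
                ed_phase = which.max(scale_t), es_phase = which.min(scale_t),
                wall_by_phase = sqrt((r_base * scale_t)^2 +
                                     (r_base + wall)^2 - r_base^2) - r_base * scale_t)
  list(image = image, labels = labels, truth = truth)
}

#' Generate a phantom cohort
#'
#' Deterministic given `config$seed`.  Every case carries a 4D cine image and
#' one automatic session holding the true segmentation, unless the case was
#' selected for corruption (at `config$corruption$rate`), in which case the
#' session holds the corrupted mask and the true mask is retained in the
#' truth record.
#'
#' @param config A [phantom_config()].
#' @return List with `cohort` (a `cmr_cohort`) and `truth` (a data frame, one
#'   row per case, with programmed volumes, EF, wall thickness and any
#'   injected corruption; attributes `wall_by_phase` (matrix) and
#'   `true_masks` (named list of uncorrupted [label_mask()]s for corrupted
#'   cases)).
#' @export
generate_cohort <- function(config) {
  validate_phantom_config(config)
  n <- config$n_cases
  cases <- vector("list", n)
  rows <- list(); wall_mat <- NULL; true_masks <- list()
  classes <- names(config$class_mix)[config$class_mix > 0]
  mix <- config$class_mix[classes]
  for (i in seq_len(n)) {
    rs <- derive_seed(config$seed, i)
    set.seed(rs)
    cl <- sample(classes, 1, prob = mix)
    params <- sample_case_params(cl, config$geometry_priors)
    built <- build_phantom_case(params, config, derive_seed(rs, 1))
    case_id <- sprintf("case_%03d", i)
    img <- image_volume(built$image, config$spacing_mm,
                        if (cl == "SCAR") "lge" else "cine")
    # clinical covariates: loosely class-linked height/weight, mildly noisy
    set.seed(derive_seed(rs, 2))
    clinical <- list(height_cm = round(rnorm(1, 172, 9), 1),
                     weight_kg = round(rnorm(1, 80, 12), 1))
    case <- cmr_case(case_id, list(img), clinical = clinical, class_label = cl,
                     label_set = phantom_classes)
    case <- add_session(case, label_mask(built$labels), "automatic")

    corr <- list(type = NA_character_, phase = NA_integer_, slice = NA_integer_,
                 structure = NA_character_)
    set.seed(derive_seed(rs, 3))
    if (runif(1) < config$corruption$rate) {
      kind <- sample(names(config$corruption$types), 1,
                     prob = config$corruption$types)
      true_session <- latest_session(case)
      corrupted <- inject_corruption(true_session, kind,
                                     seed = derive_seed(rs, 4))
      info <- attr(corrupted, "corruption")
      corr <- list(type = kind, phase = info$phase %||% NA_integer_,
                   slice = info$slice %||% NA_integer_,
                   structure = info$structure %||% NA_character_)
      case$sessions <- setNames(list(corrupted), corrupted$session_id)
      true_masks[[case_id]] <- true_session$mask
    }
    cases[[i]] <- case
    rows[[i]] <- data.frame(case_id = case_id, class = cl,
                            lv_endo_radius_mm = built$truth$lv_endo_radius_mm,
                            wall_thickness_mm = built$truth$wall_thickness_mm,
                            rv_scale = built$truth$rv_scale,
                            contraction_fraction = built$truth$contraction_fraction,
                            edv_ml = built$truth$edv_ml, esv_ml = built$truth$esv_ml,
                            ef = built$truth$ef,
                            ed_phase = built$truth$ed_phase,
                            es_phase = built$truth$es_phase,
                            corruption_type = corr$type,
                            corruption_phase = corr$phase,
                            corruption_slice = corr$slice,
                            corruption_structure = corr$structure,
                            stringsAsFactors = FALSE)
    wall_mat <- rbind(wall_mat, built$truth$wall_by_phase)
  }
  truth <- do.call(rbind, rows)
  rownames(wall_mat) <- truth$case_id
  attr(truth, "wall_by_phase") <- wall_mat
  attr(truth, "true_masks") <- true_masks
  list(cohort = cmr_cohort(cases), truth = truth)
}

#' Inject a segmentation corruption into a session
#'
#' Returns a new automatic session with the corrupted mask; the input session
#' is untouched.  Kinds: `slice_shift` translates one slice's labels by `d`
#' voxels (all phases, emulating a misaligned acquisition), `mask_dilate`
#' morphologically dilates one structure at one phase, `mask_dropout` erases
#' one structure on one slice (all phases).
#'
#' @param session A `cmr_session`.
#' @param kind One of `slice_shift`, `mask_dilate`, `mask_dropout`.
#' @param params List of kind-specific parameters: `d` (shift, voxels,
#'   default `c(10, 0)`), `slice`, `phase`, `structure`, `radius` (dilation,
#'   default 3).
#' @param seed Integer seed for the unspecified choices.
#' @return A new `cmr_session`; the applied corruption is recorded in
#'   `attr(, "corruption")`.
#' @export
inject_corruption <- function(session, kind = c("slice_shift", "mask_dilate",
                                                "mask_dropout"),
                              params = list(), seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  lab <- session$mask$labels
  d4 <- dim(lab)
  S <- d4[3]; P <- d4[4]
  info <- list(kind = kind)
  if (kind == "slice_shift") {
    d <- params$d %||% c(10, 0)
    if (any(abs(d) >= d4[1:2])) stop2("shift (%s) larger than grid", paste(d, collapse = ","))
    slice <- params$slice %||% sample(max(2, S %/% 3):max(2, 2 * S %/% 3), 1)
    for (p in seq_len(P)) {
      sl <- lab[, , slice, p]
      out <- matrix(0L, d4[1], d4[2])
      src_r <- seq_len(d4[1]) - d[1]; src_c <- seq_len(d4[2]) - d[2]
      ok_r <- src_r >= 1 & src_r <= d4[1]; ok_c <- src_c >= 1 & src_c <= d4[2]
      out[ok_r, ok_c] <- sl[src_r[ok_r], src_c[ok_c]]
      lab[, , slice, p] <- out
    }
    info$slice <- slice; info$d <- d
  } else if (kind == "mask_dilate") {
    structure_name <- params$structure %||% sample(c("lv_bloodpool", "lv_myocardium"), 1)
    lv <- structure_label(structure_name)
    radius <- params$radius %||% 3
    phase <- params$phase %||% sample(seq_len(P), 1)
    brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
    for (s in seq_len(S)) {
      bin <- lab[, , s, phase] == lv
      dil <- EBImage::dilate(EBImage::Image(bin * 1), brush) > 0.5
      sl <- lab[, , s, phase]
      sl[dil] <- lv
      lab[, , s, phase] <- sl
    }
    info$structure <- structure_name; info$phase <- phase; info$radius <- radius
  } else { # mask_dropout
    structure_name <- params$structure %||% sample(c("lv_bloodpool", "lv_myocardium",
                                                     "rv_bloodpool"), 1)
    lv <- structure_label(structure_name)
    slice <- params$slice %||% sample(seq_len(S), 1)
    for (p in seq_len(P)) {
      sl <- lab[, , slice, p]
      sl[sl == lv] <- 0L
      lab[, , slice, p] <- sl
    }
    info$structure <- structure_name; info$slice <- slice
  }
  new_session <- structure(list(
    session_id = paste0("s_", substr(content_hash(list(lab, "automatic",
                                                       session$case_id, kind)), 1, 16)),
    case_id = session$case_id, mask = label_mask(lab), origin = "automatic",
    per_contour_corrected = session$per_contour_corrected,
    certainty = NULL, landmarks = NULL), class = "cmr_session")
  attr(new_session, "corruption") <- info
  new_session
}
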