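# Plain-text serialization of cohorts.
#
# Dialects:
#  * eyes.csv       — per-eye header: eye_id, laterality, scale_um_per_unit,
#                     bmo_plane_depth_um
#  * landmarks.csv  — one row per point: eye_id, point_role
#                     (margin/fovea/trunk/ppa), x_um, y_um, depth_um
#                     (margin rows keep their polygon order)
#  * exams.csv      — one row per exam: eye_id, visit, 52 pattern-deviation
#                     category columns named pd_x{+/-x}_y{+/-y}, md_db,
#                     psd_prob, ght, fixation_loss_rate, false_pos_rate,
#                     false_neg_rate
#  * covariates.csv — per-eye clinical covariates
#  * manifest.json  — generator configuration and seed
# Missing values are empty fields. write_* / read_* round-trip exactly.

pd_column_names <- function(grid = build_grid_242()) {
  sc <- grid[!grid$blind_spot, ]
  sprintf("pd_x%+d_y%+d", sc$x, sc$y)
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write landmark records to the landmark CSV dialect
#'
#' @param records List of [landmark_record()] objects.
#' @param eyes_path,landmarks_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_landmarks <- function(records, eyes_path, landmarks_path) {
  eyes <- do.call(rbind, lapply(records, function(r) data.frame(
    eye_id = r$eye_id, laterality = r$laterality,
    scale_um_per_unit = r$scale_um_per_unit,
    bmo_plane_depth_um = r$bmo_plane_depth_um, stringsAsFactors = FALSE)))
  pts <- do.call(rbind, lapply(records, function(r) {
    rows <- data.frame(eye_id = r$eye_id, point_role = "margin",
                       x_um = r$bmo_margin[, 1L], y_um = r$bmo_margin[, 2L],
                       depth_um = NA_real_, stringsAsFactors = FALSE)
    add <- function(role, p, depth = NA_real_) {
      if (is.null(p)) return(NULL)
      data.frame(eye_id = r$eye_id, point_role = role, x_um = p[1L],
                 y_um = p[2L], depth_um = depth, stringsAsFactors = FALSE)
    }
    rbind(rows, add("fovea", r$fovea),
          add("trunk", r$trunk, r$trunk_depth_um),
          add("ppa", r$ppa_max_point))
  }))
  write_csv_plain(eyes, eyes_path)
  write_csv_plain(pts, landmarks_path)
  invisible(c(eyes_path, landmarks_path))
}

#' Read landmark records from the landmark CSV dialect
#'
#' @param eyes_path,landmarks_path CSV paths written by
#'   [write_landmarks()].
#' @return List of [landmark_record()] objects, in `eyes_path` order.
#' @export
read_landmarks <- function(eyes_path, landmarks_path) {
  eyes <- utils::read.csv(eyes_path, stringsAsFactors = FALSE)
  pts <- utils::read.csv(landmarks_path, stringsAsFactors = FALSE)
  needed <- c("eye_id", "point_role", "x_um", "y_um")
  if (!all(needed %in% names(pts)))
    stop_lcshift("landmark CSV ", landmarks_path, " lacks columns: ",
                 paste(setdiff(needed, names(pts)), collapse = ", "))
  lapply(seq_len(nrow(eyes)), function(i) {
    e <- eyes[i, ]
    p <- pts[pts$eye_id == e$eye_id, ]
    if (!nrow(p)) stop_lcshift("no landmarks for eye ", e$eye_id,
                               " in ", landmarks_path)
    margin <- as.matrix(p[p$point_role == "margin", c("x_um", "y_um")])
    one <- function(role) {
      q <- p[p$point_role == role, ]
      if (!nrow(q)) NULL else c(q$x_um[1L], q$y_um[1L])
    }
    trunk_row <- p[p$point_role == "trunk", ]
    landmark_record(
      eye_id = e$eye_id, laterality = e$laterality,
      bmo_margin = margin, fovea = one("fovea"), trunk = one("trunk"),
      ppa_max_point = one("ppa"),
      trunk_depth_um = if (nrow(trunk_row)) trunk_row$depth_um[1L] else NA_real_,
      bmo_plane_depth_um = e$bmo_plane_depth_um,
      scale_um_per_unit = e$scale_um_per_unit)
  })
}

#' Write visual field series to the exam CSV dialect
#'
#' @param series List of [eye_series()] objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_exams <- function(series, path) {
  grid <- build_grid_242()
  cols <- pd_column_names(grid)
  rows <- do.call(rbind, lapply(series, function(s) {
    do.call(rbind, lapply(s$exams, function(e) {
      pd <- as.list(e$pd[!grid$blind_spot])
      names(pd) <- cols
      cbind(data.frame(eye_id = e$eye_id, visit = e$visit,
                       stringsAsFactors = FALSE),
            as.data.frame(pd, check.names = FALSE, optional = TRUE),
            data.frame(md_db = e$md_db, psd_prob = e$psd_prob, ght = e$ght,
                       fixation_loss_rate = e$fixation_loss_rate,
                       false_pos_rate = e$false_pos_rate,
                       false_neg_rate = e$false_neg_rate,
                       stringsAsFactors = FALSE))
    }))
  }))
  write_csv_plain(rows, path)
  invisible(path)
}

#' Read visual field series from the exam CSV dialect
#'
#' @param path CSV written by [write_exams()].
#' @param covariates Optional covariate data.frame with an `eye_id` column;
#'   matched rows are attached to each series.
#' @return List of [eye_series()] objects, one per eye.
#' @export
read_exams <- function(path, covariates = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- pd_column_names()
  if (!all(cols %in% names(df)))
    stop_lcshift("exam CSV ", path, " lacks pattern-deviation columns")
  lapply(split(df, df$eye_id)[unique(df$eye_id)], function(d) {
    exams <- lapply(seq_len(nrow(d)), function(i) {
      vf_exam(eye_id = d$eye_id[i], visit = d$visit[i],
              pd = as.integer(unlist(d[i, cols], use.names = FALSE)),
              md_db = d$md_db[i], psd_prob = d$psd_prob[i], ght = d$ght[i],
              fixation_loss_rate = d$fixation_loss_rate[i],
              false_pos_rate = d$false_pos_rate[i],
              false_neg_rate = d$false_neg_rate[i])
    })
    cov <- if (!is.null(covariates))
      covariates[covariates$eye_id == d$eye_id[1L], , drop = FALSE]
    eye_series(exams, covariates = cov)
  })
}

#' Serialize a simulated cohort to a directory
#'
#' Writes `eyes.csv`, `landmarks.csv`, `covariates.csv`, `exams.csv`,
#' `truth.csv` (synthetic ground truth) and `manifest.json` (configuration
#' and seed). With a fixed seed the files are byte-identical across runs.
#'
#' @param sim An object from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "lcshift_cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landmarks(sim$records, file.path(dir, "eyes.csv"),
                  file.path(dir, "landmarks.csv"))
  write_csv_plain(sim$covariates, file.path(dir, "covariates.csv"))
  write_exams(sim$series, file.path(dir, "exams.csv"))
  write_csv_plain(sim$truth, file.path(dir, "truth.csv"))
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `records`, `series`, `covariates`, `truth` (or `NULL`
#'   if absent), `manifest`.
#' @export
read_cohort <- function(dir) {
  req <- file.path(dir, c("eyes.csv", "landmarks.csv", "covariates.csv",
                          "exams.csv"))
  missing <- req[!file.exists(req)]
  if (length(missing))
    stop_lcshift("cohort directory ", dir, " lacks: ",
                 paste(basename(missing), collapse = ", "))
  covariates <- utils::read.csv(file.path(dir, "covariates.csv"),
                                stringsAsFactors = FALSE)
  records <- read_landmarks(file.path(dir, "eyes.csv"),
                            file.path(dir, "landmarks.csv"))
  series <- read_exams(file.path(dir, "exams.csv"), covariates)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  list(records = records, series = series, covariates = covariates,
       truth = truth, manifest = manifest)
}
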