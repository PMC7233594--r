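# Pipeline orchestration: landmarks -> geometry -> visual field
# classification -> cohort assembly -> statistics -> report bundle.

#' Pipeline configuration
#'
#' Exactly one of `input_dir` (a cohort directory in the package's CSV/JSON
#' dialects) or `simulate` (a [sim_config()]) must be given.
#'
#' @param input_dir Cohort directory to read, or `NULL`.
#' @param simulate A [sim_config()] to generate the cohort, or `NULL`.
#' @param cluster_rule `"methods"` (default) or `"abstract"`.
#' @param adjacency Lattice connectivity for clusters, 8 (default) or 4.
#' @param confirm_n Consecutive reliable exams confirming a defect
#'   (default 2).
#' @param alpha Significance level for the tree (default 0.05).
#' @param n_perm Permutations for the tree tests (default 999 at pipeline
#'   scale).
#' @param screen_threshold Univariate screening threshold (default 0.20).
#' @param center_method BMO centre definition, `"centroid"` or
#'   `"vertex_mean"`.
#' @param out_dir Report output directory, or `NULL` for no files.
#' @param seed Seed for the analysis-stage randomness (tree permutations,
#'   per-subject eye selection).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = NULL,
                            cluster_rule = c("methods", "abstract"),
                            adjacency = 8L, confirm_n = 2L, alpha = 0.05,
                            n_perm = 999L, screen_threshold = 0.20,
                            center_method = "centroid",
                            out_dir = NULL, seed = 1L) {
  if (is.null(input_dir) == is.null(simulate))
    stop_lcshift("exactly one of input_dir or simulate must be given")
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  structure(list(input_dir = input_dir, simulate = simulate,
                 cluster_rule = match.arg(cluster_rule),
                 adjacency = as.integer(adjacency),
                 confirm_n = as.integer(confirm_n), alpha = alpha,
                 n_perm = as.integer(n_perm),
                 screen_threshold = screen_threshold,
                 center_method = center_method,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Eligibility filter for cohort inputs
#'
#' Applies the inclusion rules: myopia (axial length >= 24.0 mm),
#' high-tension criterion (highest IOP > 21 mmHg), follow-up >= 2 years,
#' and an optional `quality_ok` flag. When a subject contributes both eyes,
#' one is selected by a seeded draw keyed by the subject id. Every
#' exclusion is logged with the triggering rule; missing required
#' covariates exclude the eye with reason `"missing <name>"`.
#'
#' @param covariates data.frame with columns `eye_id`, `axial_length`,
#'   `iop_max`, `followup_years` and optionally `subject_id`,
#'   `quality_ok`.
#' @param seed Seed for the per-subject eye selection.
#' @return List with `kept` (eye ids), `log` (data.frame eye_id, rule).
#' @export
exclusion_filter <- function(covariates, seed = 1L) {
  stopifnot(is.data.frame(covariates), "eye_id" %in% names(covariates))
  log <- data.frame(eye_id = character(), rule = character(),
                    stringsAsFactors = FALSE)
  note <- function(id, rule)
    rbind(log, data.frame(eye_id = id, rule = rule, stringsAsFactors = FALSE))
  keep <- rep(TRUE, nrow(covariates))
  for (i in seq_len(nrow(covariates))) {
    row <- covariates[i, ]
    for (v in c("axial_length", "iop_max", "followup_years")) {
      if (is.null(row[[v]]) || is.na(row[[v]])) {
        log <- note(row$eye_id, paste("missing", v)); keep[i] <- FALSE; break
      }
    }
    if (!keep[i]) next
    if (row$axial_length < 24.0) {
      log <- note(row$eye_id, "axial length < 24.0 mm (myopia criterion)")
      keep[i] <- FALSE
    } else if (row$iop_max <= 21) {
      log <- note(row$eye_id, "highest IOP <= 21 mmHg (high-tension criterion)")
      keep[i] <- FALSE
    } else if (row$followup_years < 2) {
      log <- note(row$eye_id, "follow-up < 2 years")
      keep[i] <- FALSE
    } else if (!is.null(row$quality_ok) && !is.na(row$quality_ok) &&
               !row$quality_ok) {
      log <- note(row$eye_id, "poor image quality")
      keep[i] <- FALSE
    }
  }
  kept <- covariates[keep, , drop = FALSE]
  # one eye per subject, seeded choice keyed by subject id
  if ("subject_id" %in% names(kept) && anyDuplicated(kept$subject_id)) {
    sel <- unlist(lapply(split(seq_len(nrow(kept)), kept$subject_id),
                         function(idx) {
      if (length(idx) == 1L) return(idx)
      sid <- kept$subject_id[idx[1L]]
      key <- sum(utf8ToInt(sid) * seq_along(utf8ToInt(sid))) %% 1000003L
      pick <- with_seed(substream_seed(seed, key, 3L),
                        sample.int(length(idx), 1L))
      drop <- idx[-pick]
      log <<- rbind(log, data.frame(
        eye_id = kept$eye_id[drop],
        rule = "fellow eye of selected study eye", stringsAsFactors = FALSE))
      idx[pick]
    }))
    kept <- kept[sort(sel), , drop = FALSE]
  }
  list(kept = kept$eye_id, log = log)
}

#' Run the full analysis pipeline
#'
#' Generates or loads the cohort, applies the eligibility filter, measures
#' the optic nerve head geometry of every eye, classifies the initial and
#' final hemisphere of visual field defect, assembles the cohort table, and
#' runs the statistical stage: a shift-group-stratified summary table,
#' logistic screens for initial inferior defect, initial bi-hemispheric
#' defect and final single-hemisphere defect, and the conditional inference
#' tree for the initial hemisphere. Deterministic under a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `lcshift_report`; when `config$out_dir` is set,
#'   the report is also written there as CSV/JSON/SVG/text files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop_lcshift("[", what, "] ", conditionMessage(e)))
  }
  inputs <- stage("load", {
    if (!is.null(config$simulate)) {
      sim <- simulate_cohort(config$simulate)
      list(records = sim$records, series = sim$series,
           covariates = sim$covariates, truth = sim$truth)
    } else read_cohort(config$input_dir)
  })
  filt <- stage("exclusion", exclusion_filter(inputs$covariates, config$seed))
  keep_ids <- filt$kept
  exclusions <- filt$log
  rec_ids <- vapply(inputs$records, `[[`, character(1L), "eye_id")
  ser_ids <- vapply(inputs$series, `[[`, character(1L), "eye_id")

  geom <- stage("geometry", {
    measure_cohort(inputs$records[rec_ids %in% keep_ids],
                   center_method = config$center_method)
  })
  rule <- cluster_rule(config$cluster_rule)
  vf <- stage("vf-classification", {
    grid <- build_grid_242()
    rows <- lapply(inputs$series[ser_ids %in% keep_ids], function(s) {
      rel <- sum(vapply(s$exams, function(e)
        suppressWarnings(is_reliable(e)), logical(1L)))
      init <- if (rel >= 2L)
        initial_hemisphere(s, rule, config$confirm_n, grid, config$adjacency)
      else "undetermined"
      fin <- if (rel >= 2L)
        suppressWarnings(final_hemisphere(s, rule, config$confirm_n, grid,
                                          config$adjacency))
      else "none"
      md_final <- {
        rexams <- Filter(function(e) suppressWarnings(is_reliable(e)), s$exams)
        if (length(rexams)) rexams[[length(rexams)]]$md_db else NA_real_
      }
      data.frame(eye_id = s$eye_id, n_reliable_exams = rel,
                 initial_hemisphere = init, final_hemisphere = fin,
                 md_final_db = md_final, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  unreliable_eyes <- vf$eye_id[vf$n_reliable_exams < 2L]
  if (length(unreliable_eyes)) {
    exclusions <- rbind(exclusions, data.frame(
      eye_id = unreliable_eyes, rule = "fewer than 2 reliable exams",
      stringsAsFactors = FALSE))
    vf <- vf[!vf$eye_id %in% unreliable_eyes, , drop = FALSE]
    geom <- geom[!geom$eye_id %in% unreliable_eyes, , drop = FALSE]
  }
  cohort <- stage("assembly", {
    out <- merge(geom, inputs$covariates, by = "eye_id", sort = FALSE)
    out <- merge(out, vf, by = "eye_id", sort = FALSE)
    out[order(out$eye_id), , drop = FALSE]
  })
  stats_out <- stage("statistics", cohort_statistics(cohort, config))
  report <- structure(list(
    cohort = cohort, exclusions = exclusions, config = config,
    table1 = stats_out$table1,
    logistic_initial_inferior = stats_out$logistic_initial_inferior,
    logistic_initial_bihemi = stats_out$logistic_initial_bihemi,
    logistic_final_single = stats_out$logistic_final_single,
    ctree = stats_out$ctree,
    truth = inputs$truth
  ), class = "lcshift_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

group_rows <- function(x, g, labels = c("A", "B", "C")) {
  lapply(labels, function(l) {
    xi <- x[g == l & !is.na(x)]
    if (length(xi) >= 2L)
      group_summary(l, length(xi), mean(xi), stats::sd(xi))
    else NULL
  })
}

summarize_continuous <- function(x, g) {
  gs <- Filter(Negate(is.null), group_rows(x, g))
  p <- NA_real_
  test <- NA_character_
  if (length(gs) >= 3L) {
    p <- anova_from_summary(gs)$p_value
    test <- "anova"
  } else if (length(gs) == 2L) {
    p <- two_sample_t(gs[[1L]], gs[[2L]])$p_value
    test <- "t"
  }
  stats_by <- vapply(c("A", "B", "C"), function(l) {
    xi <- x[g == l & !is.na(x)]
    if (!length(xi)) return(NA_character_)
    sprintf("%.2f±%.2f (n=%d)", mean(xi), stats::sd(xi), length(xi))
  }, character(1L))
  c(stats_by, p = format(p, digits = 4), test = test)
}

cohort_statistics <- function(cohort, config) {
  g <- cohort$shift_group
  cont_vars <- c(age = "age", iop = "iop_max", axial = "axial_length",
                 md0 = "md0_db", md_final = "md_final_db",
                 followup = "followup_years", bmo_area = "bmo_area_mm2",
                 shift_index = "shift_index", lcd = "lcd_um",
                 abs_alpha = NA, beta_ppa = "beta_deg")
  tab1 <- do.call(rbind, lapply(names(cont_vars), function(nm) {
    x <- if (nm == "abs_alpha") abs(cohort$alpha_deg) else cohort[[cont_vars[nm]]]
    row <- summarize_continuous(x, g)
    data.frame(variable = nm, group_A = row[1L], group_B = row[2L],
               group_C = row[3L], p_value = row["p"], test = row["test"],
               stringsAsFactors = FALSE)
  }))
  cat_row <- function(nm, flag) {
    tab <- table(factor(g, levels = c("A", "B", "C")), flag)
    p <- tryCatch(chisq_test(as.matrix(tab))$p_value, error = function(e) NA_real_)
    counts <- vapply(c("A", "B", "C"), function(l)
      sprintf("%d/%d", sum(flag & g == l, na.rm = TRUE), sum(g == l)),
      character(1L))
    data.frame(variable = nm, group_A = counts[1L], group_B = counts[2L],
               group_C = counts[3L], p_value = format(p, digits = 4),
               test = "chisq", stringsAsFactors = FALSE)
  }
  tab1 <- rbind(tab1,
                cat_row("female", cohort$sex == "female"),
                cat_row("bihemi_initial", cohort$initial_hemisphere == "bi"),
                cat_row("bihemi_final", cohort$final_hemisphere == "bi"))

  # Table-2-style: initial inferior defect (among single-hemisphere onsets)
  single <- cohort[cohort$initial_hemisphere %in% c("superior", "inferior"), ]
  cand2 <- data.frame(age = single$age, iop_max = single$iop_max,
                      axial_length = single$axial_length,
                      bmo_area_mm2 = single$bmo_area_mm2,
                      md0_db = single$md0_db, lcd_um = single$lcd_um,
                      beta_deg = single$beta_deg,
                      shift_index = single$shift_index,
                      alpha_deg = single$alpha_deg)
  fit2 <- screen_and_fit(cand2, single$initial_hemisphere == "inferior",
                         threshold = config$screen_threshold)
  # Table-3-style: initial bi-hemispheric defect
  det <- cohort[cohort$initial_hemisphere != "undetermined", ]
  cand3 <- data.frame(age = det$age, iop_max = det$iop_max,
                      axial_length = det$axial_length,
                      bmo_area_mm2 = det$bmo_area_mm2, md0_db = det$md0_db,
                      lcd_um = det$lcd_um, shift_index = det$shift_index,
                      abs_alpha_deg = abs(det$alpha_deg))
  fit3 <- screen_and_fit(cand3, det$initial_hemisphere == "bi",
                         threshold = config$screen_threshold)
  # Table-4-style: final defect restricted to a single hemisphere
  fin <- cohort[cohort$final_hemisphere %in%
                  c("superior", "inferior", "bi"), ]
  cand4 <- data.frame(age = fin$age, iop_max = fin$iop_max,
                      axial_length = fin$axial_length,
                      bmo_area_mm2 = fin$bmo_area_mm2,
                      md_final_db = fin$md_final_db, lcd_um = fin$lcd_um,
                      shift_index = fin$shift_index,
                      obliqueness_deg = fin$obliqueness_deg,
                      followup_years = fin$followup_years)
  fit4 <- screen_and_fit(cand4, fin$final_hemisphere != "bi",
                         threshold = config$screen_threshold)
  # conditional inference tree on eyes with a measurable trunk angle
  tre_dat <- cohort[!is.na(cohort$alpha_deg) &
                      cohort$initial_hemisphere %in%
                        c("superior", "inferior", "bi"),
                    c("alpha_deg", "md0_db", "age", "iop_max", "axial_length",
                      "initial_hemisphere")]
  tre <- if (nrow(tre_dat) >= 20L)
    ctree_fit(tre_dat[, 1:5], tre_dat$initial_hemisphere,
              alpha = config$alpha, n_perm = config$n_perm,
              seed = config$seed)
  else NULL
  list(table1 = tab1, logistic_initial_inferior = fit2,
       logistic_initial_bihemi = fit3, logistic_final_single = fit4,
       ctree = tre)
}

#' @export
print.lcshift_report <- function(x, ...) {
  cat("lcshift pipeline report\n")
  cat("  cohort:", nrow(x$cohort), "eyes;", nrow(x$exclusions),
      "exclusion(s)\n")
  cat("  shift groups:",
      paste(names(table(x$cohort$shift_group)),
            table(x$cohort$shift_group), sep = "=", collapse = " "), "\n")
  cat("  initial hemisphere:",
      paste(names(table(x$cohort$initial_hemisphere)),
            table(x$cohort$initial_hemisphere), sep = "=", collapse = " "),
      "\n")
  cat("  final hemisphere:",
      paste(names(table(x$cohort$final_hemisphere)),
            table(x$cohort$final_hemisphere), sep = "=", collapse = " "),
      "\n\n")
  cat("Initial inferior defect screen:\n")
  print(x$logistic_initial_inferior)
  if (!is.null(x$ctree)) {
    cat("\n")
    print(x$ctree)
  }
  invisible(x)
}

screen_to_df <- function(fit) {
  u <- fit$univariate
  u$stage <- "univariate"
  out <- u[, c("stage", "term", "estimate", "se", "or", "ci_lower",
               "ci_upper", "p_value", "n")]
  if (!is.null(fit$multivariate)) {
    m <- fit$multivariate$coefficients
    m <- m[m$term != "(Intercept)", , drop = FALSE]
    m$stage <- "multivariate"
    m$n <- fit$multivariate$n
    out <- rbind(out, m[, names(out)])
  }
  out
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) writeLines(
    "pipeline failed before all outputs were written",
    file.path(dir, "FAILED")))
  write_csv_plain(report$cohort, file.path(dir, "cohort.csv"))
  write_csv_plain(report$exclusions, file.path(dir, "exclusions.csv"))
  write_csv_plain(report$table1, file.path(dir, "table1_by_shift_group.csv"))
  write_csv_plain(screen_to_df(report$logistic_initial_inferior),
                  file.path(dir, "logistic_initial_inferior.csv"))
  write_csv_plain(screen_to_df(report$logistic_initial_bihemi),
                  file.path(dir, "logistic_initial_bihemi.csv"))
  write_csv_plain(screen_to_df(report$logistic_final_single),
                  file.path(dir, "logistic_final_single.csv"))
  if (!is.null(report$ctree))
    writeLines(format(report$ctree), file.path(dir, "ctree.txt"))
  write_polar_svg(report$cohort, file.path(dir, "polar_alpha.svg"))
  summary <- list(
    n_eyes = nrow(report$cohort),
    n_excluded = nrow(report$exclusions),
    shift_groups = as.list(table(report$cohort$shift_group)),
    initial_hemisphere = as.list(table(report$cohort$initial_hemisphere)),
    final_hemisphere = as.list(table(report$cohort$final_hemisphere)),
    seed = report$config$seed,
    cluster_rule = report$config$cluster_rule,
    adjacency = report$config$adjacency,
    confirm_n = report$config$confirm_n)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(dir)
}
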