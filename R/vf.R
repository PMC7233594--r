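# Humphrey 24-2 pattern-deviation maps and the defect-cluster rule.
#
# Pattern-deviation categories are coded as integers:
#   0 = within normal limits, 1 = p < 5%, 2 = p < 2%, 3 = p < 1%, 4 = p < 0.5%
# Maps are stored in right-eye orientation (+x temporal field, +y superior).

PD_LEVELS <- c("normal", "p<5%", "p<2%", "p<1%", "p<0.5%")

.lcshift_cache <- new.env(parent = emptyenv())

#' Canonical Humphrey 24-2 test grid
#'
#' Builds the 54-point 24-2 layout in right-eye orientation (degrees of
#' visual angle, +x temporal, +y superior, 6-degree spacing, two extra
#' points at 27 degrees nasally). The two points at the physiologic blind
#' spot (15, +/-3) are flagged and never scored; the remaining 52 points
#' split 26/26 across the superior and inferior hemifields.
#'
#' @return `data.frame` with columns `x`, `y`, `hemifield`
#'   (`"superior"`/`"inferior"`) and `blind_spot` (logical), one row per
#'   test point, in a fixed deterministic order.
#' @export
build_grid_242 <- function() {
  if (!is.null(.lcshift_cache$grid242)) return(.lcshift_cache$grid242)
  row_x <- list(
    `21` = c(-9, -3, 3, 9),
    `15` = c(-15, -9, -3, 3, 9, 15),
    `9`  = c(-21, -15, -9, -3, 3, 9, 15, 21),
    `3`  = c(-27, -21, -15, -9, -3, 3, 9, 15, 21)
  )
  pts <- do.call(rbind, lapply(c(21, 15, 9, 3, -3, -9, -15, -21), function(y) {
    x <- row_x[[as.character(abs(y))]]
    data.frame(x = x, y = y)
  }))
  pts$hemifield <- ifelse(pts$y > 0, "superior", "inferior")
  pts$blind_spot <- pts$x == 15 & abs(pts$y) == 3
  rownames(pts) <- NULL
  .lcshift_cache$grid242 <- pts
  pts
}

#' Construct a single visual field exam
#'
#' @param eye_id Identifier.
#' @param visit Visit ordinal or time (numeric; exams sort by it).
#' @param pd Integer vector of pattern-deviation categories (0-4, see
#'   details) of length 54 in grid order, with blind-spot entries ignored,
#'   or length 52 covering only scoreable points.
#' @param md_db Mean deviation (dB).
#' @param psd_prob Pattern standard deviation probability in (0, 1].
#' @param ght Glaucoma hemifield test flag: `"within"`, `"borderline"` or
#'   `"outside"`.
#' @param fixation_loss_rate,false_pos_rate,false_neg_rate Reliability
#'   indices in \[0, 1\].
#' @return Object of class `vf_exam`.
#' @export
vf_exam <- function(eye_id, visit, pd, md_db = NA_real_, psd_prob = NA_real_,
                    ght = c("within", "borderline", "outside"),
                    fixation_loss_rate = NA_real_, false_pos_rate = NA_real_,
                    false_neg_rate = NA_real_) {
  ght <- match.arg(ght)
  grid <- build_grid_242()
  pd <- as.integer(pd)
  if (length(pd) == 52L) {
    full <- rep(NA_integer_, 54L)
    full[!grid$blind_spot] <- pd
    pd <- full
  }
  if (length(pd) != 54L)
    stop_lcshift("pd must have 52 or 54 entries, got ", length(pd))
  pd[grid$blind_spot] <- NA_integer_
  sc <- pd[!grid$blind_spot]
  if (any(is.na(sc)) || any(sc < 0L | sc > 4L))
    stop_lcshift("pattern-deviation categories must be 0..4 for all 52 scoreable points")
  rates <- c(fixation_loss_rate, false_pos_rate, false_neg_rate)
  if (any(!is.na(rates) & (rates < 0 | rates > 1)))
    stop_lcshift("reliability rates must lie in [0, 1]")
  structure(list(
    eye_id = as.character(eye_id)[1L], visit = as.numeric(visit)[1L],
    pd = pd, md_db = as.numeric(md_db)[1L], psd_prob = as.numeric(psd_prob)[1L],
    ght = ght, fixation_loss_rate = as.numeric(fixation_loss_rate)[1L],
    false_pos_rate = as.numeric(false_pos_rate)[1L],
    false_neg_rate = as.numeric(false_neg_rate)[1L]
  ), class = "vf_exam")
}

#' Reliability filter for a visual field exam
#'
#' An exam is reliable when fixation losses are <= 20% and both
#' false-positive and false-negative error rates are <= 25% (inclusive
#' thresholds). Missing rates make the exam unreliable, with a warning.
#'
#' @param exam A [vf_exam()].
#' @return Logical scalar.
#' @export
is_reliable <- function(exam) {
  stopifnot(inherits(exam, "vf_exam"))
  r <- c(exam$fixation_loss_rate, exam$false_pos_rate, exam$false_neg_rate)
  if (any(is.na(r))) {
    warning("missing reliability index; exam treated as unreliable", call. = FALSE)
    return(FALSE)
  }
  r[1L] <= 0.20 && r[2L] <= 0.25 && r[3L] <= 0.25
}

#' Defect-cluster rule
#'
#' The default (`"methods"`) rule qualifies a cluster of >= 3 connected
#' abnormal points each at p < 5%, at least one of which reaches p < 1%.
#' The `"abstract"` variant requires >= 3 connected points all at p < 0.5%.
#'
#' @param name `"methods"` or `"abstract"`; ignored when the threshold
#'   arguments are given explicitly.
#' @param abnormal_min Minimum category (0-4) counting as abnormal.
#' @param strict_min Category threshold for the stricter-point requirement.
#' @param strict_count How many cluster points must reach `strict_min`.
#' @param min_size Minimum cluster size.
#' @return Object of class `cluster_rule`.
#' @export
cluster_rule <- function(name = c("methods", "abstract"), abnormal_min = NULL,
                         strict_min = NULL, strict_count = NULL,
                         min_size = NULL) {
  name <- match.arg(name)
  def <- if (name == "methods")
    list(abnormal_min = 1L, strict_min = 3L, strict_count = 1L, min_size = 3L)
  else
    list(abnormal_min = 4L, strict_min = 4L, strict_count = 0L, min_size = 3L)
  out <- list(
    name = name,
    abnormal_min = as.integer(abnormal_min %||% def$abnormal_min),
    strict_min = as.integer(strict_min %||% def$strict_min),
    strict_count = as.integer(strict_count %||% def$strict_count),
    min_size = as.integer(min_size %||% def$min_size)
  )
  with(out, {
    if (is.na(abnormal_min) || abnormal_min < 1L || abnormal_min > 4L ||
        is.na(strict_min) || strict_min < abnormal_min || strict_min > 4L ||
        is.na(strict_count) || strict_count < 0L ||
        is.na(min_size) || min_size < 1L)
      stop_lcshift("invalid cluster rule parameters")
  })
  structure(out, class = "cluster_rule")
}

# Neighbour index list for the 24-2 lattice under 8- or 4-connectivity
# (6-degree spacing; diagonals included for 8-connectivity).
grid_neighbours <- function(grid, adjacency = 8L) {
  adjacency <- as.integer(adjacency)
  if (!adjacency %in% c(4L, 8L)) stop_lcshift("adjacency must be 4 or 8")
  key <- paste0("nb", adjacency, "_", nrow(grid))
  if (identical(grid, .lcshift_cache$grid242) &&
      !is.null(.lcshift_cache[[key]]))
    return(.lcshift_cache[[key]])
  n <- nrow(grid)
  dx <- outer(grid$x, grid$x, `-`); dy <- outer(grid$y, grid$y, `-`)
  adj <- if (adjacency == 8L)
    abs(dx) <= 6 & abs(dy) <= 6 & !(dx == 0 & dy == 0)
  else
    (abs(dx) == 6 & dy == 0) | (dx == 0 & abs(dy) == 6)
  nb <- lapply(seq_len(n), function(i) which(adj[i, ]))
  if (identical(grid, .lcshift_cache$grid242)) .lcshift_cache[[key]] <- nb
  nb
}

#' Find qualifying defect clusters on a pattern-deviation map
#'
#' Computes maximal connected components of abnormal points on the 24-2
#' lattice and keeps those satisfying the cluster rule. Components are
#' computed separately within each hemifield (clusters never span the
#' horizontal meridian) unless `confine_hemifield = FALSE`; blind-spot
#' points never count and never bridge components. Clusters are returned in
#' deterministic order: superior hemifield first, then by smallest point
#' index.
#'
#' @param exam A [vf_exam()].
#' @param grid Grid from [build_grid_242()].
#' @param rule A [cluster_rule()].
#' @param adjacency 8 (default, includes diagonals) or 4.
#' @param confine_hemifield Keep clusters within one hemifield (default
#'   `TRUE`; the hemifield-agnostic variant serves the diagnostic
#'   glaucomatous-defect criterion).
#' @return List of integer vectors of grid row indices, each with a
#'   `hemifield` attribute (`NA` when not confined and mixed).
#' @export
find_clusters <- function(exam, grid = build_grid_242(),
                          rule = cluster_rule("methods"), adjacency = 8L,
                          confine_hemifield = TRUE) {
  stopifnot(inherits(exam, "vf_exam"), inherits(rule, "cluster_rule"))
  nb <- grid_neighbours(grid, adjacency)
  abnormal <- !grid$blind_spot & !is.na(exam$pd) & exam$pd >= rule$abnormal_min
  comps <- list()
  seen <- rep(FALSE, nrow(grid))
  groups <- if (confine_hemifield) split(seq_len(nrow(grid)), grid$hemifield)
            else list(all = seq_len(nrow(grid)))
  for (g in groups) {
    allowed <- rep(FALSE, nrow(grid)); allowed[g] <- TRUE
    for (s in g) {
      if (!abnormal[s] || seen[s]) next
      queue <- s; seen[s] <- TRUE; comp <- integer()
      while (length(queue)) {
        i <- queue[1L]; queue <- queue[-1L]
        comp <- c(comp, i)
        for (j in nb[[i]]) {
          if (abnormal[j] && allowed[j] && !seen[j]) {
            seen[j] <- TRUE
            queue <- c(queue, j)
          }
        }
      }
      comp <- sort(comp)
      if (length(comp) >= rule$min_size &&
          sum(exam$pd[comp] >= rule$strict_min) >= rule$strict_count) {
        hemi <- unique(grid$hemifield[comp])
        attr(comp, "hemifield") <- if (length(hemi) == 1L) hemi else NA_character_
        comps[[length(comps) + 1L]] <- comp
      }
    }
  }
  ord <- order(vapply(comps, function(co) attr(co, "hemifield") != "superior",
                      logical(1L)),
               vapply(comps, min, integer(1L)))
  comps[ord]
}

#' Hemifield involvement call for one exam
#'
#' @inheritParams find_clusters
#' @return Object of class `hemisphere_call`: list with `label`
#'   (`"none"`, `"superior"`, `"inferior"` or `"bi"`) and `clusters`.
#' @export
hemifield_call <- function(exam, grid = build_grid_242(),
                           rule = cluster_rule("methods"), adjacency = 8L) {
  cl <- find_clusters(exam, grid, rule, adjacency)
  hemis <- unique(vapply(cl, attr, character(1L), "hemifield"))
  label <- if (length(cl) == 0L) "none"
  else if (all(c("superior", "inferior") %in% hemis)) "bi"
  else hemis[1L]
  structure(list(label = label, clusters = cl), class = "hemisphere_call")
}

#' @export
print.hemisphere_call <- function(x, ...) {
  cat("<hemisphere_call>", x$label, "—", length(x$clusters),
      "qualifying cluster(s)\n")
  invisible(x)
}

#' Glaucomatous visual field defect criteria
#'
#' An exam shows a glaucomatous defect when any of: (1) the glaucoma
#' hemifield test is outside normal limits; (2) a qualifying cluster of
#' three connected abnormal points (p < 5%, one at p < 1%) exists anywhere
#' on the map (hemifield-agnostic); (3) the pattern standard deviation
#' probability is below 5%.
#'
#' @inheritParams find_clusters
#' @return Logical scalar.
#' @export
is_glaucomatous_defect <- function(exam, grid = build_grid_242(),
                                   adjacency = 8L) {
  stopifnot(inherits(exam, "vf_exam"))
  if (identical(exam$ght, "outside")) return(TRUE)
  if (length(find_clusters(exam, grid, cluster_rule("methods"),
                           adjacency, confine_hemifield = FALSE)) > 0L)
    return(TRUE)
  !is.na(exam$psd_prob) && exam$psd_prob < 0.05
}

# ---- longitudinal series ---------------------------------------------------

#' Bundle one eye's longitudinal exams and covariates
#'
#' @param exams List of [vf_exam()] objects for one eye (any order; sorted
#'   by visit).
#' @param covariates Optional named list / one-row data.frame of clinical
#'   covariates.
#' @return Object of class `eye_series`.
#' @export
eye_series <- function(exams, covariates = NULL) {
  stopifnot(length(exams) > 0L,
            all(vapply(exams, inherits, logical(1L), "vf_exam")))
  ids <- unique(vapply(exams, `[[`, character(1L), "eye_id"))
  if (length(ids) != 1L)
    stop_lcshift("exams mix eye ids: ", paste(ids, collapse = ", "))
  exams <- exams[order(vapply(exams, `[[`, numeric(1L), "visit"))]
  structure(list(eye_id = ids, exams = exams, covariates = covariates),
            class = "eye_series")
}

# hemifield presence matrix over reliable exams, in chronological order
reliable_presence <- function(series, rule, grid, adjacency) {
  rel <- Filter(function(e) suppressWarnings(is_reliable(e)), series$exams)
  pres <- t(vapply(rel, function(e) {
    cl <- find_clusters(e, grid, rule, adjacency)
    hemis <- vapply(cl, attr, character(1L), "hemifield")
    c(superior = "superior" %in% hemis, inferior = "inferior" %in% hemis)
  }, logical(2L)))
  pres
}

#' Initial hemisphere of visual field defect
#'
#' Scans the reliable exams in chronological order. A hemifield's defect is
#' established once its qualifying cluster appears in `confirm_n`
#' consecutive reliable exams. The first hemifield to establish names the
#' initial defect; if both establish at the same exam (including when both
#' are present from the initial examination) the eye is classified as
#' bi-hemispheric.
#'
#' @param series An [eye_series()].
#' @param rule A [cluster_rule()].
#' @param confirm_n Consecutive reliable exams required (default 2).
#' @param grid,adjacency Grid and connectivity, as in [find_clusters()].
#' @return `"superior"`, `"inferior"`, `"bi"` or `"undetermined"`.
#' @export
initial_hemisphere <- function(series, rule = cluster_rule("methods"),
                               confirm_n = 2L, grid = build_grid_242(),
                               adjacency = 8L) {
  stopifnot(inherits(series, "eye_series"))
  pres <- reliable_presence(series, rule, grid, adjacency)
  if (nrow(pres) < 2L) {
    warning("fewer than 2 reliable exams; initial hemisphere undetermined",
            call. = FALSE)
    return("undetermined")
  }
  confirm_n <- max(1L, as.integer(confirm_n))
  est <- vapply(c("superior", "inferior"), function(h) {
    run <- 0L
    for (i in seq_len(nrow(pres))) {
      run <- if (pres[i, h]) run + 1L else 0L
      if (run >= confirm_n) return(i)
    }
    NA_integer_
  }, integer(1L))
  if (all(is.na(est))) return("undetermined")
  if (all(!is.na(est)) && est[["superior"]] == est[["inferior"]]) return("bi")
  names(est)[which.min(est)]
}

#' Final hemisphere of visual field defect
#'
#' Applies the cluster rule to the last `confirm_n` reliable exams: a
#' hemifield counts only when its qualifying cluster is present in all of
#' them. Both hemifields give `"bi"`, neither gives `"none"`.
#'
#' @inheritParams initial_hemisphere
#' @return `"none"`, `"superior"`, `"inferior"` or `"bi"`.
#' @export
final_hemisphere <- function(series, rule = cluster_rule("methods"),
                             confirm_n = 2L, grid = build_grid_242(),
                             adjacency = 8L) {
  stopifnot(inherits(series, "eye_series"))
  pres <- reliable_presence(series, rule, grid, adjacency)
  confirm_n <- max(1L, as.integer(confirm_n))
  if (nrow(pres) < max(2L, confirm_n)) {
    warning("fewer than ", max(2L, confirm_n),
            " reliable exams; final hemisphere set to \"none\"", call. = FALSE)
    return("none")
  }
  tail_pres <- pres[seq(nrow(pres) - confirm_n + 1L, nrow(pres)), , drop = FALSE]
  sup <- all(tail_pres[, "superior"]); inf <- all(tail_pres[, "inferior"])
  if (sup && inf) "bi" else if (sup) "superior" else if (inf) "inferior" else "none"
}
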