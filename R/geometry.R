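# Planar geometry of optic nerve head landmarks.
#
# All measurements live in the plane of the Bruch's membrane opening (BMO):
# coordinates are planar projections in micrometres with +y superior; axial
# depths are separate scalars. Angular conventions follow right-eye
# orientation: the nasal horizontal midline (the ray from the BMO centre away
# from the fovea) is 0 deg for the vascular-trunk angle, the temporal midline
# (towards the fovea) is 0 deg for the parapapillary-atrophy angle, and
# positive angles are superior in both frames.

#' Construct a per-eye landmark record
#'
#' Bundles one eye's planar optic nerve head landmarks: the delineated BMO
#' margin polygon, the fovea, the central retinal vascular trunk (absent when
#' the trunk lies outside the BMO), the point of maximal beta-zone
#' parapapillary atrophy width, and the axial depths needed for lamina
#' cribrosa depth. Coordinates are multiplied by `scale_um_per_unit` at
#' construction so that everything downstream works in micrometres.
#'
#' @param eye_id Identifier, coerced to character.
#' @param laterality `"right"` or `"left"`.
#' @param bmo_margin Numeric matrix (>= 8 rows, 2 columns) of ordered margin
#'   points forming a simple closed polygon.
#' @param fovea Length-2 numeric point, outside the margin polygon.
#' @param trunk Length-2 numeric point inside/on the margin, or `NULL` when
#'   the trunk is outside the BMO (severe shift convention).
#' @param ppa_max_point Length-2 numeric point, or `NULL` if there is no
#'   beta-zone parapapillary atrophy.
#' @param trunk_depth_um Axial depth of the trunk emergence (um), `NA` if
#'   unmeasured or the trunk is absent.
#' @param bmo_plane_depth_um Reference depth of the BMO plane at the trunk's
#'   position (um).
#' @param scale_um_per_unit Micrometres per coordinate unit (1 if the
#'   coordinates are already in um).
#' @param validate Set `FALSE` to skip the polygon/containment checks
#'   (internal use).
#' @return An object of class `landmark_record`.
#' @export
landmark_record <- function(eye_id, laterality, bmo_margin, fovea,
                            trunk = NULL, ppa_max_point = NULL,
                            trunk_depth_um = NA_real_,
                            bmo_plane_depth_um = 0,
                            scale_um_per_unit = 1,
                            validate = TRUE) {
  laterality <- as.character(laterality)
  if (length(laterality) != 1L || !laterality %in% c("right", "left"))
    stop_lcshift("unknown laterality ", deparse(laterality),
                 ": must be \"right\" or \"left\"")
  if (!is_scalar_number(scale_um_per_unit) || scale_um_per_unit <= 0)
    stop_lcshift("scale_um_per_unit must be a positive number")
  bmo_margin <- as_point_matrix(bmo_margin, "bmo_margin") * scale_um_per_unit
  fovea <- as_point(fovea, "fovea") * scale_um_per_unit
  if (!is.null(trunk)) trunk <- as_point(trunk, "trunk") * scale_um_per_unit
  if (!is.null(ppa_max_point))
    ppa_max_point <- as_point(ppa_max_point, "ppa_max_point") * scale_um_per_unit
  rec <- structure(list(
    eye_id = as.character(eye_id)[1L],
    laterality = laterality,
    scale_um_per_unit = 1,
    bmo_margin = bmo_margin,
    fovea = fovea,
    trunk = trunk,
    ppa_max_point = ppa_max_point,
    trunk_depth_um = as.numeric(trunk_depth_um)[1L],
    bmo_plane_depth_um = as.numeric(bmo_plane_depth_um)[1L]
  ), class = "landmark_record")
  if (validate) validate_landmark_record(rec)
  rec
}

as_point <- function(p, what) {
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p)))
    stop_lcshift(what, " must be a finite length-2 numeric point")
  p
}

as_point_matrix <- function(m, what) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (ncol(m) != 2L || any(!is.finite(m)))
    stop_lcshift(what, " must be a finite n x 2 numeric matrix")
  m
}

validate_landmark_record <- function(rec) {
  m <- rec$bmo_margin
  if (nrow(m) < 8L)
    stop_lcshift("bmo_margin needs at least 8 points, got ", nrow(m))
  if (!polygon_is_simple(m))
    stop_lcshift("bmo_margin is self-intersecting: not a simple polygon")
  if (point_in_polygon(rec$fovea, m))
    stop_lcshift("fovea lies inside the BMO margin polygon")
  if (!is.null(rec$trunk) &&
      !point_in_polygon(rec$trunk, m, on_boundary_ok = TRUE))
    stop_lcshift("trunk is present but lies outside the BMO margin polygon")
  invisible(rec)
}

# ---- polygon primitives ----------------------------------------------------

polygon_signed_area <- function(m) {
  x <- m[, 1L]; y <- m[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Area centroid of the BMO margin polygon
#'
#' The BMO centre is the area centroid of the closed polygon through the
#' delineated margin points (shoelace formula), invariant under cyclic
#' reordering of the vertices.
#'
#' @param margin Numeric matrix of ordered polygon vertices (n x 2).
#' @return Length-2 numeric centroid.
#' @export
bmo_centroid <- function(margin) {
  m <- as_point_matrix(margin, "margin")
  if (!polygon_is_simple(m))
    stop_lcshift("margin is self-intersecting: centroid undefined")
  # translate to improve conditioning for far-from-origin polygons
  ref <- colMeans(m)
  x <- m[, 1L] - ref[1L]; y <- m[, 2L] - ref[2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps)
    stop_lcshift("degenerate polygon with zero area")
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a) + ref
}

# Even-odd point-in-polygon test; points on the boundary count as inside
# when on_boundary_ok.
point_in_polygon <- function(p, m, on_boundary_ok = FALSE, tol = 1e-9) {
  n <- nrow(m)
  x <- m[, 1L]; y <- m[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  # boundary check: distance from p to each segment
  ex <- xn - x; ey <- yn - y
  len2 <- ex^2 + ey^2
  t <- pmin(1, pmax(0, ((p[1L] - x) * ex + (p[2L] - y) * ey) / pmax(len2, tol)))
  d2 <- (x + t * ex - p[1L])^2 + (y + t * ey - p[2L])^2
  scale <- max(1, sqrt(max(len2)))
  if (any(d2 <= (tol * scale)^2)) return(on_boundary_ok)
  crosses <- ((y > p[2L]) != (yn > p[2L])) &
    (p[1L] < x + (p[2L] - y) * (xn - x) / (yn - y))
  sum(crosses) %% 2L == 1L
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(q2 - q1, p1 - q1)
  d2 <- cross2(q2 - q1, p2 - q1)
  d3 <- cross2(p2 - p1, q1 - p1)
  d4 <- cross2(p2 - p1, q2 - p1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1L], b[1L]) <= c[1L] && c[1L] <= max(a[1L], b[1L]) &&
      min(a[2L], b[2L]) <= c[2L] && c[2L] <= max(a[2L], b[2L])
  }
  (d1 == 0 && on_seg(q1, q2, p1)) || (d2 == 0 && on_seg(q1, q2, p2)) ||
    (d3 == 0 && on_seg(p1, p2, q1)) || (d4 == 0 && on_seg(p1, p2, q2))
}

cross2 <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

polygon_is_simple <- function(m) {
  n <- nrow(m)
  if (n < 3L) return(FALSE)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip adjacent edges (shared vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(m[i, ], m[idx(i + 1L), ],
                             m[j, ], m[idx(j + 1L), ])) return(FALSE)
    }
  }
  TRUE
}

# Distance from `center` to the polygon boundary along unit direction `dir`:
# exact ray/segment intersection against the piecewise-linear closed margin,
# first intersection outward from the centre.
ray_polygon_distance <- function(center, dir, margin, tol = 1e-12) {
  m <- as_point_matrix(margin, "margin")
  p1 <- m
  p2 <- m[c(seq_len(nrow(m))[-1L], 1L), , drop = FALSE]
  ex <- p2[, 1L] - p1[, 1L]; ey <- p2[, 2L] - p1[, 2L]
  wx <- p1[, 1L] - center[1L]; wy <- p1[, 2L] - center[2L]
  det <- dir[2L] * ex - dir[1L] * ey
  ok <- abs(det) > tol
  t <- (wy * ex - wx * ey) / det       # distance along the ray
  u <- (dir[1L] * wy - dir[2L] * wx) / det  # position along the edge
  hit <- ok & t > tol & u >= -1e-9 & u <= 1 + 1e-9
  if (!any(hit))
    stop_lcshift("ray from the BMO centre failed to intersect the margin ",
                 "polygon (center = ", paste(signif(center, 6), collapse = ", "),
                 "; dir = ", paste(signif(dir, 6), collapse = ", "), ")")
  min(t[hit])
}

# ---- orientation -----------------------------------------------------------

mirror_x_about <- function(pts, cx) {
  if (is.null(pts)) return(NULL)
  if (is.matrix(pts)) {
    pts[, 1L] <- 2 * cx - pts[, 1L]
    pts
  } else {
    pts[1L] <- 2 * cx - pts[1L]
    pts
  }
}

#' Normalize a landmark record to right-eye orientation
#'
#' Right eyes are returned unchanged. Left eyes are mirrored about the
#' vertical axis through the BMO centroid, which swaps nasal/temporal raw
#' coordinates while preserving superior/inferior, so that all angular
#' measurements share right-eye semantics. The returned record is flagged as
#' right-oriented, making the operation idempotent.
#'
#' @param rec A [landmark_record()].
#' @return A `landmark_record` in right-eye orientation.
#' @export
to_right_eye_orientation <- function(rec) {
  stopifnot(inherits(rec, "landmark_record"))
  if (rec$laterality == "right") return(rec)
  cx <- bmo_centroid(rec$bmo_margin)[1L]
  rec$bmo_margin <- mirror_x_about(rec$bmo_margin, cx)
  rec$fovea <- mirror_x_about(rec$fovea, cx)
  rec$trunk <- mirror_x_about(rec$trunk, cx)
  rec$ppa_max_point <- mirror_x_about(rec$ppa_max_point, cx)
  rec$laterality <- "right"
  rec
}

#' Fovea-BMO reference axis
#'
#' Unit vector from the BMO centre towards the fovea: the temporal reference
#' direction. Its negation is the nasal 0-deg ray for the vascular trunk
#' angle; the vector itself is the temporal 0-deg ray for the
#' parapapillary-atrophy angle.
#'
#' @param center BMO centre (length-2).
#' @param fovea Fovea position (length-2).
#' @return Unit length-2 vector pointing temporally.
#' @export
fobmo_axis <- function(center, fovea) {
  v <- as_point(fovea, "fovea") - as_point(center, "center")
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps)
    stop_lcshift("fovea and BMO centre coincide: reference axis undefined")
  v / n
}

# Signed angle (degrees, (-180, 180]) from reference ray `ref` to vector `v`,
# positive when `v` lies on the superior (+y) side of the reference line.
# Works for either temporal orientation of the raw x axis.
signed_angle_deg <- function(ref, v) {
  ref <- ref / sqrt(sum(ref^2))
  nv <- sqrt(sum(v^2))
  v <- v / nv
  ang <- atan2(cross2(ref, v), sum(ref * v)) * 180 / pi
  # orient the sign so that "counter-clockwise from ref" means "towards superior"
  if (cross2(ref, c(0, 1)) < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Angular deviation of the vascular trunk
#'
#' Signed angle of the BMO-centre-to-trunk ray from the nasal horizontal
#' midline, in right-eye orientation; positive values indicate a superiorly
#' located trunk. Returns `NA` when the trunk is absent (outside the BMO).
#'
#' @param center BMO centre.
#' @param trunk Trunk position or `NULL` when absent.
#' @param nasal_ray Unit vector of the nasal reference ray
#'   (`-fobmo_axis(...)`).
#' @return Angle in degrees in (-180, 180], or `NA`.
#' @export
angular_deviation <- function(center, trunk, nasal_ray) {
  if (is.null(trunk)) return(NA_real_)
  v <- as_point(trunk, "trunk") - as_point(center, "center")
  if (sqrt(sum(v^2)) < 1e-9) {
    warning("trunk coincides with the BMO centre; angular deviation set to 0",
            call. = FALSE)
    return(0)
  }
  signed_angle_deg(nasal_ray, v)
}

#' Shift index of the vascular trunk
#'
#' Ratio a/b where a is the distance from the BMO centre to the trunk and b
#' the distance from the centre to the margin polygon along the same ray.
#' By convention the index is exactly 1 when the trunk lies outside the BMO
#' (absent trunk). The result is clipped to \[0, 1\].
#'
#' @param center BMO centre.
#' @param trunk Trunk position or `NULL` when absent.
#' @param margin Ordered margin polygon (n x 2 matrix) containing `center`.
#' @return Shift index in \[0, 1\].
#' @export
shift_index <- function(center, trunk, margin) {
  if (is.null(trunk)) return(1)
  center <- as_point(center, "center")
  trunk <- as_point(trunk, "trunk")
  v <- trunk - center
  a <- sqrt(sum(v^2))
  if (a < 1e-9) return(0)
  b <- ray_polygon_distance(center, v / a, margin)
  min(1, max(0, a / b))
}

#' Angular location of maximal beta-zone parapapillary atrophy width
#'
#' Signed angle of the centre-to-PPA-point ray from the temporal horizontal
#' midline, positive superior, in right-eye orientation.
#'
#' @param center BMO centre.
#' @param ppa_point Point of maximal beta-zone PPA width, or `NULL` if no
#'   beta-zone PPA (returns `NA`).
#' @param temporal_ray Unit temporal reference ray (`fobmo_axis(...)`).
#' @return Angle in degrees in (-180, 180], or `NA`.
#' @export
ppa_angular_location <- function(center, ppa_point, temporal_ray) {
  if (is.null(ppa_point)) return(NA_real_)
  v <- as_point(ppa_point, "ppa_point") - as_point(center, "center")
  if (sqrt(sum(v^2)) < 1e-9)
    stop_lcshift("ppa_max_point coincides with the BMO centre")
  signed_angle_deg(temporal_ray, v)
}

#' Obliqueness of the vascular trunk deviation
#'
#' Absolute in-quadrant angle of the trunk from the horizontal: the angular
#' deviation folded into its quadrant, so 0 means a fully horizontal and 90 a
#' fully vertical deviation. Used when modelling visual field defects that
#' stay restricted to a single hemisphere.
#'
#' @param alpha_deg Angular deviation in degrees, (-180, 180].
#' @return Degrees in \[0, 90\]; `NA` if `alpha_deg` is `NA`.
#' @export
obliqueness <- function(alpha_deg) {
  a <- ((alpha_deg + 180) %% 360) - 180   # wrap to (-180, 180]
  a[!is.na(a) & a == -180] <- 180
  out <- 90 - abs(abs(a) - 90)
  out[is.na(alpha_deg)] <- NA_real_
  out
}

#' Classify the extent of lamina cribrosa shift
#'
#' Shift groups: `"A"` (mild, shift index < 0.5), `"B"` (moderate,
#' 0.5 <= index < 1) and `"C"` (severe, index = 1, i.e. trunk outside the
#' BMO). Values within `1e-9` of 1 count as 1.
#'
#' @param shift_index Numeric vector of shift indices in \[0, 1\].
#' @return Character vector of `"A"`, `"B"`, `"C"`.
#' @export
classify_shift_group <- function(shift_index) {
  if (any(!is.finite(shift_index) | shift_index < 0 | shift_index > 1 + 1e-9))
    stop_lcshift("shift_index values must lie in [0, 1]")
  ifelse(shift_index >= 1 - 1e-9, "C", ifelse(shift_index >= 0.5, "B", "A"))
}

#' Lamina cribrosa depth at the vascular trunk
#'
#' Axial distance of the trunk emergence from the BMO reference plane,
#' floored at zero (a negative difference indicates an annotation above the
#' plane and triggers a warning).
#'
#' @param bmo_plane_depth_um BMO plane reference depth (um).
#' @param trunk_depth_um Trunk emergence depth (um).
#' @return Depth in um (>= 0), `NA` if either input is missing.
#' @export
lcd <- function(bmo_plane_depth_um, trunk_depth_um) {
  if (is.na(bmo_plane_depth_um) || is.na(trunk_depth_um)) return(NA_real_)
  d <- trunk_depth_um - bmo_plane_depth_um
  if (d < 0) {
    warning("trunk depth above the BMO plane; lamina cribrosa depth floored at 0",
            call. = FALSE)
    d <- 0
  }
  d
}

# ---- per-eye summary -------------------------------------------------------

#' Measure all optic nerve head geometry for one eye
#'
#' Normalizes the record to right-eye orientation and derives the full
#' geometry summary: angular deviation, shift index and group, beta-zone PPA
#' angle, obliqueness, lamina cribrosa depth and BMO area.
#'
#' @param rec A [landmark_record()].
#' @param center_method `"centroid"` (polygon area centroid, default) or
#'   `"vertex_mean"` for the arithmetic mean of the margin points.
#' @return One-row `data.frame` with columns `eye_id`, `alpha_deg`,
#'   `shift_index`, `shift_group`, `beta_deg`, `obliqueness_deg`, `lcd_um`,
#'   `bmo_area_mm2`.
#' @export
measure_onh <- function(rec, center_method = c("centroid", "vertex_mean")) {
  stopifnot(inherits(rec, "landmark_record"))
  center_method <- match.arg(center_method)
  rec <- to_right_eye_orientation(rec)
  margin <- rec$bmo_margin
  center <- if (center_method == "centroid") bmo_centroid(margin)
            else colMeans(margin)
  temporal <- fobmo_axis(center, rec$fovea)
  nasal <- -temporal
  alpha <- angular_deviation(center, rec$trunk, nasal)
  si <- shift_index(center, rec$trunk, margin)
  grp <- classify_shift_group(si)
  if (grp == "C") alpha <- NA_real_
  beta <- ppa_angular_location(center, rec$ppa_max_point, temporal)
  data.frame(
    eye_id = rec$eye_id,
    alpha_deg = alpha,
    shift_index = si,
    shift_group = grp,
    beta_deg = beta,
    obliqueness_deg = obliqueness(alpha),
    lcd_um = lcd(rec$bmo_plane_depth_um, rec$trunk_depth_um),
    bmo_area_mm2 = abs(polygon_signed_area(margin)) * 1e-6,
    stringsAsFactors = FALSE
  )
}

#' Measure geometry for a list of eyes
#'
#' @param records List of [landmark_record()] objects.
#' @param ... Passed to [measure_onh()].
#' @return `data.frame` with one row per eye.
#' @export
measure_cohort <- function(records, ...) {
  do.call(rbind, lapply(records, measure_onh, ...))
}

#' @export
print.landmark_record <- function(x, ...) {
  cat("<landmark_record> eye", x$eye_id, "(", x$laterality, "eye )\n")
  cat("  BMO margin:", nrow(x$bmo_margin), "points; trunk:",
      if (is.null(x$trunk)) "absent (outside BMO)" else
        paste0("(", paste(signif(x$trunk, 5), collapse = ", "), ") um"), "\n")
  cat("  fovea: (", paste(signif(x$fovea, 5), collapse = ", "), ") um\n")
  invisible(x)
}
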