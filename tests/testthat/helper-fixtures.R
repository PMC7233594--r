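# Fixtures built in code: margins, records, pattern-deviation maps.

circle_margin <- function(r = 750, n = 24, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# star-shaped polygon around `center` (random radii): always simple
random_star_polygon <- function(n = 12, center = c(0, 0),
                                r_range = c(400, 1000)) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_range[1], r_range[2])
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

right_eye_record <- function(trunk = c(300, 0), margin = circle_margin(),
                             fovea = c(-4700, 0), ppa = NULL,
                             trunk_depth = 546, plane_depth = 0, ...) {
  landmark_record("eyeR", "right", margin, fovea = fovea, trunk = trunk,
                  ppa_max_point = ppa, trunk_depth_um = trunk_depth,
                  bmo_plane_depth_um = plane_depth, ...)
}

# exam with the given grid rows set to the given categories; reliable by
# default
make_exam <- function(levels = integer(0), idx = integer(0), eye = "e1",
                      visit = 0, ght = "within", psd_prob = 0.5,
                      fl = 0, fp = 0, fn = 0, md = -2) {
  pd <- rep(0L, 54L)
  pd[idx] <- as.integer(levels)
  vf_exam(eye, visit, pd, md_db = md, psd_prob = psd_prob, ght = ght,
          fixation_loss_rate = fl, false_pos_rate = fp, false_neg_rate = fn)
}

# grid row index at coordinates (x, y)
gp <- function(x, y, grid = build_grid_242()) {
  i <- which(grid$x == x & grid$y == y)
  stopifnot(length(i) == 1L)
  i
}

# random pattern-deviation map: each scoreable point abnormal with prob p,
# severity uniform over 1..4
random_exam <- function(p = 0.12, eye = "r", visit = 0) {
  grid <- build_grid_242()
  pd <- rep(0L, 54L)
  sc <- which(!grid$blind_spot)
  hit <- sc[stats::runif(length(sc)) < p]
  pd[hit] <- sample(1:4, length(hit), replace = TRUE)
  vf_exam(eye, visit, pd, md_db = -3, psd_prob = 0.5, ght = "within",
          fixation_loss_rate = 0, false_pos_rate = 0, false_neg_rate = 0)
}

# exact-moment sample: n values with sample mean m and sample sd s
raw_with_moments <- function(n, m, s) {
  x <- stats::rnorm(n)
  as.numeric(scale(x)) * s + m
}

rigid_motion <- function(pts, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  if (is.matrix(pts)) t(R %*% t(pts)) + rep(shift, each = nrow(pts))
  else drop(R %*% pts) + shift
}
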