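# Optic nerve head landmark geometry: orientation, centroid, angles,
# shift index, derived measures.

test_that("right-eye records pass through orientation unchanged; left eyes mirror correctly", {
  rec <- right_eye_record()
  expect_identical(to_right_eye_orientation(rec), rec)

  # left eye raw frame: temporal (towards fovea) is +x
  marginL <- circle_margin()
  recL <- landmark_record("eyeL", "left", marginL, fovea = c(4700, 0),
                          trunk = c(100, 50), trunk_depth_um = 500)
  recR <- to_right_eye_orientation(recL)
  expect_equal(recR$laterality, "right")
  # trunk stays 100 um temporal (towards the fovea) and 50 um superior
  expect_equal(recR$trunk, c(-100, 50))
  expect_equal(recR$fovea, c(-4700, 0))
  # idempotent on the result
  expect_identical(to_right_eye_orientation(recR), recR)
  # the raw reflection is an involution
  cx <- bmo_centroid(marginL)[1]
  pts <- cbind(runif(5, -500, 500), runif(5, -500, 500))
  expect_equal(lcshift:::mirror_x_about(lcshift:::mirror_x_about(pts, cx), cx),
               pts)
  expect_error(landmark_record("x", "os", circle_margin(), c(-4700, 0)),
               "laterality")
})

test_that("left-eye record and its hand-built right-eye mirror give identical geometry", {
  set.seed(42)
  margin <- random_star_polygon(24)
  trunk <- c(150, -220)
  ppa <- c(-1100, -240)
  recR <- landmark_record("m1", "right", margin, fovea = c(-4700, -420),
                          trunk = trunk, ppa_max_point = ppa,
                          trunk_depth_um = 520, bmo_plane_depth_um = 30)
  mir <- function(p) if (is.matrix(p)) cbind(-p[, 1], p[, 2]) else c(-p[1], p[2])
  recL <- landmark_record("m1", "left", mir(margin), fovea = mir(c(-4700, -420)),
                          trunk = mir(trunk), ppa_max_point = mir(ppa),
                          trunk_depth_um = 520, bmo_plane_depth_um = 30)
  expect_equal(measure_onh(recL), measure_onh(recR), tolerance = 1e-9)
})

test_that("BMO centroid matches shoelace oracle and symmetry cases", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
              c(0, 0.75), c(0, 0.5), c(0, 0.25), c(0, 0.1))
  expect_equal(bmo_centroid(sq), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(bmo_centroid(circle_margin(600, 24, c(10, -3))), c(10, -3),
               tolerance = 1e-9)
  # independent shoelace oracle, no recentering
  shoelace <- function(m) {
    x <- m[, 1]; y <- m[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    a <- sum(x * yn - xn * y) / 2
    c(sum((x + xn) * (x * yn - xn * y)), sum((y + yn) * (x * yn - xn * y))) /
      (6 * a)
  }
  set.seed(7)
  for (i in 1:25) {
    m <- random_star_polygon(sample(8:20, 1), center = runif(2, -2000, 2000))
    expect_equal(bmo_centroid(m), shoelace(m), tolerance = 1e-9)
    shift <- sample(nrow(m), 1)
    cyc <- m[c(shift:nrow(m), seq_len(shift - 1L)), ]
    expect_equal(bmo_centroid(cyc), bmo_centroid(m), tolerance = 1e-9)
  }
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1),
               c(-0.2, 0.8), c(-0.3, 0.6), c(-0.3, 0.4), c(-0.2, 0.2))
  expect_error(bmo_centroid(bow), "self-intersecting")
})

test_that("fovea-BMO axis is the unit temporal direction and rotates with the landmarks", {
  expect_equal(fobmo_axis(c(0, 0), c(-3000, 0)), c(-1, 0))
  v <- fobmo_axis(c(0, 0), c(-3000, -300))
  expect_equal(sqrt(sum(v^2)), 1)
  expect_equal(atan2(v[2], v[1]), atan2(-300, -3000))
  expect_error(fobmo_axis(c(1, 2), c(1, 2)), "coincide")
  set.seed(1)
  for (i in 1:10) {
    th <- runif(1, -pi, pi)
    c0 <- runif(2, -100, 100); f0 <- c0 + runif(2, -3000, 3000)
    a0 <- fobmo_axis(c0, f0)
    a1 <- fobmo_axis(rigid_motion(c0, th, c(5, 9)),
                     rigid_motion(f0, th, c(5, 9)))
    expect_equal(a1, rigid_motion(a0, th, c(0, 0)), tolerance = 1e-12)
  }
})

test_that("angular deviation follows the nasal-zero, superior-positive convention", {
  nasal <- c(1, 0)  # right-eye frame, fovea temporal at -x
  expect_equal(angular_deviation(c(0, 0), c(500, 0), nasal), 0)
  expect_equal(angular_deviation(c(0, 0), c(0, 500), nasal), 90)
  expect_equal(angular_deviation(c(0, 0), c(400, -400), nasal), -45)
  expect_true(is.na(angular_deviation(c(0, 0), NULL, nasal)))
  expect_warning(a0 <- angular_deviation(c(0, 0), c(0, 0), nasal),
                 "coincides")
  expect_equal(a0, 0)
  # tilted reference: sign decided by the superior side of the line
  nasal2 <- c(cos(0.1), sin(0.1))
  expect_gt(angular_deviation(c(0, 0), c(500, 200), nasal2), 0)
  expect_lt(angular_deviation(c(0, 0), c(500, -200), nasal2), 0)
})

test_that("shift index: circle closed form, absent-trunk convention, clipping", {
  m <- circle_margin(750)
  expect_equal(shift_index(c(0, 0), c(0, 0), m), 0)
  expect_equal(shift_index(c(0, 0), c(300, 0), m), 0.4, tolerance = 1e-9)
  expect_equal(shift_index(c(0, 0), NULL, m), 1)
  # closed form a/r for many directions on a fine circle
  mf <- circle_margin(820, 4096)
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 10, 800); th <- runif(1, -pi, pi)
    expect_equal(shift_index(c(0, 0), a * c(cos(th), sin(th)), mf),
                 min(1, a / 820), tolerance = 1e-6)
  }
  # convex polygons: exact ray/segment value vs an independent
  # crossing-number bisection oracle along the ray
  inside_oracle <- function(p, m) {
    # textbook even-odd crossing count, written independently
    n <- nrow(m); cross <- 0L
    for (k in seq_len(n)) {
      a1 <- m[k, ]; a2 <- m[if (k == n) 1L else k + 1L, ]
      if ((a1[2] > p[2]) != (a2[2] > p[2])) {
        xint <- a1[1] + (p[2] - a1[2]) * (a2[1] - a1[1]) / (a2[2] - a1[2])
        if (p[1] < xint) cross <- cross + 1L
      }
    }
    cross %% 2L == 1L
  }
  set.seed(4)
  for (i in 1:8) {
    hull_pts <- cbind(runif(40, -900, 900), runif(40, -900, 900))
    m2 <- hull_pts[chull(hull_pts), ]
    ctr <- colMeans(m2)
    th <- runif(1, -pi, pi); dir <- c(cos(th), sin(th))
    lo <- 0; hi <- 4000
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (inside_oracle(ctr + mid * dir, m2)) lo <- mid else hi <- mid
    }
    b_oracle <- (lo + hi) / 2
    a <- 0.7 * b_oracle
    expect_equal(shift_index(ctr, ctr + a * dir, m2), a / b_oracle,
                 tolerance = 1e-6)
  }
})

test_that("alpha, shift index and beta are invariant to rigid motions of all landmarks", {
  set.seed(11)
  for (i in 1:10) {
    margin <- random_star_polygon(24)
    trunk <- c(120, 180); fovea <- c(-4700, -350); ppa <- c(-900, -600)
    th <- runif(1, -pi / 6, pi / 6); sh <- runif(2, -4000, 4000)
    g0 <- local({
      ctr <- bmo_centroid(margin)
      tmp <- fobmo_axis(ctr, fovea)
      c(angular_deviation(ctr, trunk, -tmp),
        shift_index(ctr, trunk, margin),
        ppa_angular_location(ctr, ppa, tmp))
    })
    g1 <- local({
      m2 <- rigid_motion(margin, th, sh)
      ctr <- bmo_centroid(m2)
      tmp <- fobmo_axis(ctr, rigid_motion(fovea, th, sh))
      c(angular_deviation(ctr, rigid_motion(trunk, th, sh), -tmp),
        shift_index(ctr, rigid_motion(trunk, th, sh), m2),
        ppa_angular_location(ctr, rigid_motion(ppa, th, sh), tmp))
    })
    expect_equal(g1, g0, tolerance = 1e-9)
  }
})

test_that("PPA angular location uses the temporal-zero, superior-positive convention", {
  temporal <- c(-1, 0)
  expect_equal(ppa_angular_location(c(0, 0), c(-900, 0), temporal), 0)
  expect_equal(ppa_angular_location(c(0, 0), c(0, -900), temporal), -90)
  expect_true(is.na(ppa_angular_location(c(0, 0), NULL, temporal)))
  expect_error(ppa_angular_location(c(0, 0), c(0, 0), temporal), "coincides")
  # double mirroring leaves beta unchanged
  recL <- landmark_record("b", "left", circle_margin(), fovea = c(4700, 0),
                          trunk = c(100, 50), ppa_max_point = c(850, -320))
  g1 <- measure_onh(recL)
  cx <- bmo_centroid(recL$bmo_margin)[1]
  recL2 <- recL
  for (f in c("bmo_margin", "fovea", "trunk", "ppa_max_point"))
    recL2[[f]] <- lcshift:::mirror_x_about(
      lcshift:::mirror_x_about(recL2[[f]], cx), cx)
  expect_equal(measure_onh(recL2), g1, tolerance = 1e-9)
})

test_that("obliqueness folds the angle into its quadrant", {
  expect_equal(obliqueness(90), 90)
  expect_equal(obliqueness(0), 0)
  expect_equal(obliqueness(-135), 45)
  expect_true(is.na(obliqueness(NA_real_)))
  a <- runif(40, -180, 180)
  expect_equal(obliqueness(a), obliqueness(-a))
  expect_equal(obliqueness(a), obliqueness(180 - a))
  expect_equal(obliqueness(a), obliqueness(a + 360))
  expect_true(all(obliqueness(a) >= 0 & obliqueness(a) <= 90))
})

test_that("shift groups follow the A/B/C thresholds", {
  expect_equal(classify_shift_group(c(0.25, 0.68, 1.0, 0, 0.4999, 0.5)),
               c("A", "B", "C", "A", "A", "B"))
  expect_equal(classify_shift_group(1 - 1e-12), "C")
  expect_error(classify_shift_group(1.2), "\\[0, 1\\]")
  expect_error(classify_shift_group(-0.1), "\\[0, 1\\]")
})

test_that("lamina cribrosa depth is the plane-to-trunk distance, floored at zero", {
  expect_equal(lcd(0, 546), 546)
  expect_equal(lcd(100, 100), 0)
  expect_equal(lcd(50, 581), 531)
  expect_true(is.na(lcd(NA, 500)))
  expect_true(is.na(lcd(0, NA)))
  expect_warning(z <- lcd(100, 80), "floored")
  expect_equal(z, 0)
})

test_that("measure_onh assembles a consistent geometry summary", {
  rec <- right_eye_record(trunk = c(0, 300), ppa = c(-850, -100))
  g <- measure_onh(rec)
  expect_equal(g$alpha_deg, 90, tolerance = 1e-9)
  expect_equal(g$shift_index, 0.4, tolerance = 1e-9)
  expect_equal(g$shift_group, "A")
  expect_equal(g$lcd_um, 546)
  # area of the inscribed regular 24-gon with circumradius 750 um
  expect_equal(g$bmo_area_mm2, 0.5 * 24 * 0.75^2 * sin(2 * pi / 24),
               tolerance = 1e-9)
  expect_equal(g$obliqueness_deg, 90)
  # severe shift: trunk absent => group C, alpha missing
  recC <- right_eye_record(trunk = NULL, trunk_depth = NA)
  gC <- measure_onh(recC)
  expect_equal(gC$shift_index, 1)
  expect_equal(gC$shift_group, "C")
  expect_true(is.na(gC$alpha_deg))
  # record validation
  expect_error(landmark_record("x", "right", circle_margin(),
                               fovea = c(100, 0)), "fovea")
  expect_error(landmark_record("x", "right", circle_margin(),
                               fovea = c(-4700, 0), trunk = c(2000, 0)),
               "outside")
})
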