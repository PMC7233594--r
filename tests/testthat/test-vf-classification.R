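# 24-2 grid construction, cluster rule, hemifield calls and longitudinal
# hemisphere determination.

test_that("the 24-2 grid has the canonical layout", {
  g <- build_grid_242()
  expect_equal(nrow(g), 54)
  expect_equal(sum(g$blind_spot), 2)
  expect_equal(sort(g$y[g$blind_spot]), c(-3, 3))
  expect_true(all(g$x[g$blind_spot] == 15))
  expect_equal(sum(g$hemifield == "superior" & !g$blind_spot), 26)
  expect_equal(sum(g$hemifield == "inferior" & !g$blind_spot), 26)
  expect_true(all(abs(g$x) <= 27 & abs(g$y) <= 21))
})

test_that("reliability thresholds are inclusive", {
  expect_true(is_reliable(make_exam(fl = 0.20, fp = 0.25, fn = 0.25)))
  expect_false(is_reliable(make_exam(fl = 0.21)))
  expect_false(is_reliable(make_exam(fp = 0.26)))
  expect_false(is_reliable(make_exam(fn = 0.26)))
  expect_warning(r <- is_reliable(make_exam(fl = NA)), "missing")
  expect_false(r)
})

test_that("cluster rule accepts qualifying components only", {
  idx3 <- c(gp(-9, 9), gp(-3, 9), gp(3, 9))
  ex <- make_exam(c(1L, 1L, 3L), idx3)
  cl <- find_clusters(ex)
  expect_length(cl, 1)
  expect_equal(as.integer(cl[[1]]), sort(idx3))
  expect_equal(attr(cl[[1]], "hemifield"), "superior")
  # the same three points without any p<1% point do not qualify
  expect_length(find_clusters(make_exam(c(1L, 1L, 2L), idx3)), 0)
  # two points never qualify
  expect_length(find_clusters(make_exam(c(4L, 4L), idx3[1:2])), 0)
  # 2 superior + 1 inferior connected across the meridian: no cluster
  mer <- c(gp(-9, 3), gp(-9, -3), gp(-3, 3))
  expect_length(find_clusters(make_exam(c(4L, 4L, 4L), mer)), 0)
  # but the hemifield-agnostic variant sees one
  expect_length(find_clusters(make_exam(c(4L, 4L, 4L), mer),
                              confine_hemifield = FALSE), 1)
  # abstract rule: all points must reach p<0.5%
  abs_rule <- cluster_rule("abstract")
  expect_length(find_clusters(make_exam(c(4L, 4L, 3L), idx3), rule = abs_rule), 0)
  expect_length(find_clusters(make_exam(c(4L, 4L, 4L), idx3), rule = abs_rule), 1)
  # the blind spot at (15,3) never bridges: (21,3) stays apart from
  # (9,3),(3,3), so no size-3 component forms
  bs <- c(gp(21, 3), gp(9, 3), gp(3, 3))
  expect_length(find_clusters(make_exam(c(4L, 4L, 4L), bs)), 0)
  expect_error(cluster_rule("methods", abnormal_min = 9), "invalid")
})

test_that("4- and 8-connectivity differ on diagonal-only contact", {
  diag_idx <- c(gp(-9, 9), gp(-3, 15), gp(3, 21))
  ex <- make_exam(c(4L, 4L, 4L), diag_idx)
  expect_length(find_clusters(ex, adjacency = 8L), 1)
  expect_length(find_clusters(ex, adjacency = 4L), 0)
})

test_that("cluster finding equals exhaustive component enumeration on random maps", {
  set.seed(2024)
  rule <- cluster_rule("methods")
  for (i in 1:150) {
    ex <- random_exam(p = runif(1, 0.05, 0.3))
    adjc <- sample(c(4L, 8L), 1)
    mine <- find_clusters(ex, rule = rule, adjacency = adjc)
    orac <- oracle_clusters(ex, rule, adjacency = adjc)
    expect_identical(cluster_key(mine), cluster_key(orac))
  }
})

test_that("escalating any point's category never removes a qualifying cluster", {
  set.seed(91)
  for (i in 1:40) {
    ex <- random_exam(p = 0.15)
    before <- find_clusters(ex)
    cov_before <- unique(unlist(before))
    j <- sample(which(!build_grid_242()$blind_spot), 1)
    ex$pd[j] <- min(4L, ex$pd[j] + sample(1:3, 1))
    after <- find_clusters(ex)
    cov_after <- unique(unlist(after))
    expect_true(all(cov_before %in% cov_after))
  }
})

test_that("hemifield call labels none/superior/inferior/bi", {
  sup <- c(gp(-9, 9), gp(-3, 9), gp(3, 9))
  inf <- c(gp(-9, -9), gp(-3, -9), gp(3, -9))
  expect_equal(hemifield_call(make_exam(c(1L, 3L, 1L), sup))$label, "superior")
  expect_equal(hemifield_call(make_exam(c(1L, 3L, 1L), inf))$label, "inferior")
  expect_equal(hemifield_call(make_exam(rep(c(1L, 3L, 1L), 2), c(sup, inf)))$label,
               "bi")
  expect_equal(hemifield_call(make_exam())$label, "none")
})

test_that("glaucomatous-defect criteria: GHT, cluster, PSD probability", {
  expect_true(is_glaucomatous_defect(make_exam(ght = "outside")))
  expect_true(is_glaucomatous_defect(make_exam(psd_prob = 0.04)))
  expect_false(is_glaucomatous_defect(make_exam(psd_prob = 0.5)))
  two <- make_exam(c(4L, 4L), c(gp(-9, 9), gp(-3, 9)))
  expect_false(is_glaucomatous_defect(two))
  three <- make_exam(c(1L, 1L, 3L), c(gp(-9, 9), gp(-3, 9), gp(3, 9)))
  expect_true(is_glaucomatous_defect(three))
})

test_that("initial hemisphere requires repetition and flags bi at simultaneous establishment", {
  sup <- c(gp(-9, 9), gp(-3, 9), gp(3, 9))
  inf <- c(gp(-9, -9), gp(-3, -9), gp(3, -9))
  e_sup <- function(v) make_exam(c(1L, 3L, 1L), sup, visit = v)
  e_both <- function(v) make_exam(rep(c(1L, 3L, 1L), 2), c(sup, inf), visit = v)
  e_none <- function(v) make_exam(visit = v)

  s1 <- eye_series(list(e_sup(1), e_sup(2), e_both(3), e_both(4)))
  expect_equal(initial_hemisphere(s1), "superior")
  s2 <- eye_series(list(e_both(1), e_both(2), e_both(3)))
  expect_equal(initial_hemisphere(s2), "bi")
  s3 <- eye_series(list(e_none(1), e_none(2)))
  expect_equal(initial_hemisphere(s3), "undetermined")
  expect_warning(r <- initial_hemisphere(eye_series(list(e_sup(1)))),
                 "fewer than 2")
  expect_equal(r, "undetermined")
  # a single unreliable exam between confirmations resets nothing it shouldn't
  e_unrel <- make_exam(rep(c(1L, 3L, 1L), 2), c(sup, inf), visit = 2, fl = 0.5)
  s4 <- eye_series(list(e_sup(1), e_unrel, e_sup(3)))
  expect_equal(initial_hemisphere(s4), "superior")
  # established label is invariant to appending later exams
  s5 <- eye_series(list(e_sup(1), e_sup(2)))
  lab5 <- initial_hemisphere(s5)
  s6 <- eye_series(list(e_sup(1), e_sup(2), e_both(3), e_both(4), e_both(5)))
  expect_equal(initial_hemisphere(s6), lab5)
})

test_that("final hemisphere reads the last confirm_n reliable exams", {
  sup <- c(gp(-9, 9), gp(-3, 9), gp(3, 9))
  inf <- c(gp(-9, -9), gp(-3, -9), gp(3, -9))
  e_sup <- function(v) make_exam(c(1L, 3L, 1L), sup, visit = v)
  e_inf <- function(v) make_exam(c(1L, 3L, 1L), inf, visit = v)
  e_both <- function(v) make_exam(rep(c(1L, 3L, 1L), 2), c(sup, inf), visit = v)

  expect_equal(final_hemisphere(eye_series(list(e_sup(1), e_both(2), e_both(3)))),
               "bi")
  expect_equal(final_hemisphere(eye_series(list(e_sup(1), e_inf(2), e_inf(3)))),
               "inferior")
  expect_equal(final_hemisphere(eye_series(list(e_sup(1), e_sup(2), e_inf(3)))),
               "none")
  expect_warning(r <- final_hemisphere(eye_series(list(e_sup(1)))), "fewer")
  expect_equal(r, "none")
})
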