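# Synthetic cohort generator: determinism, substreams, truth structure,
# moment recovery, closed-loop label recovery, serialization round trips.

noiseless <- function(n = 30, seed = 5, ...) {
  sim_config(n_eyes = n, seed = seed, fp_point_prob = 0,
             unreliable_prob = 0, md_noise_sd = 0, ...)
}

test_that("a fixed seed reproduces the cohort exactly and substreams are stable", {
  cfg <- sim_config(n_eyes = 6, seed = 31)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$covariates, s2$covariates)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$records[[3]]$bmo_margin, s2$records[[3]]$bmo_margin)
  # adding eyes never perturbs earlier eyes
  cfg_big <- sim_config(n_eyes = 9, seed = 31)
  s3 <- simulate_cohort(cfg_big)
  expect_identical(s3$covariates[1:6, ], s1$covariates)
  expect_identical(s3$records[[5]]$trunk, s1$records[[5]]$trunk)
  expect_identical(s3$series[[2]]$exams[[1]]$pd, s1$series[[2]]$exams[[1]]$pd)
})

test_that("severe shift draws produce absent-trunk records and the stated propensities", {
  cfg <- sim_config(n_eyes = 2, seed = 1)
  found_severe <- FALSE
  for (i in 1:300) {
    e <- simulate_eye(cfg, i)
    if (e$truth$shift_index_true == 1) {
      found_severe <- TRUE
      expect_null(e$record$trunk)
      expect_true(is.na(e$truth$alpha_true_deg))
      expect_equal(measure_onh(e$record)$shift_group, "C")
      break
    }
  }
  expect_true(found_severe)
  # logistic evaluation of the inferior-onset propensity at alpha = -60
  cfg2 <- sim_config(n_eyes = 2, seed = 1,
                     alpha_mix = list(p_superior = 0, superior = c(0, 1e-6),
                                      inferior = c(-60, 1e-6)),
                     severe_prob = 0)
  e2 <- simulate_eye(cfg2, 4)
  expect_equal(e2$truth$p_inferior,
               plogis(log(0.83) * e2$truth$alpha_true_deg))
  expect_gt(e2$truth$p_inferior, 0.5)
})

test_that("a null trunk effect decouples onset hemisphere from the trunk angle", {
  cfg <- sim_config(n_eyes = 2, seed = 77, effect_logodds_per_degree = 0,
                    severe_prob = 0)
  eyes <- lapply(1:800, function(i) simulate_eye(cfg, i))
  tr <- do.call(rbind, lapply(eyes, function(e) as.data.frame(e$truth)))
  tr <- tr[tr$initial != "bi", ]
  expect_true(all(tr$p_inferior == 0.5))
  tab <- table(tr$alpha_true_deg > 0, tr$initial)
  expect_gt(chisq_test(as.matrix(tab))$p_value, 0.01)
})

test_that("the measured geometry recovers the drawn angle and shift index", {
  cfg <- sim_config(n_eyes = 2, seed = 13)
  for (i in 1:25) {
    e <- simulate_eye(cfg, i)
    g <- measure_onh(e$record)
    if (e$truth$shift_index_true < 1) {
      expect_equal(g$alpha_deg, e$truth$alpha_true_deg, tolerance = 1e-6)
      expect_equal(g$shift_index, e$truth$shift_index_true, tolerance = 1e-6)
    } else {
      expect_equal(g$shift_index, 1)
    }
  }
  # laterality mixing exercises the mirroring path transparently
  cfgL <- sim_config(n_eyes = 2, seed = 13, laterality_mix = TRUE)
  lats <- vapply(1:40, function(i) simulate_eye(cfgL, i)$record$laterality,
                 character(1))
  expect_setequal(unique(lats), c("right", "left"))
  for (i in which(lats == "left")[1:5]) {
    e <- simulate_eye(cfgL, i)
    g <- measure_onh(e$record)
    if (e$truth$shift_index_true < 1)
      expect_equal(g$alpha_deg, e$truth$alpha_true_deg, tolerance = 1e-6)
  }
})

test_that("truncated covariate draws reproduce the configured moments within 1%", {
  cfg <- sim_config(n_eyes = 2, seed = 3)
  tp <- cfg$trunc_params
  set.seed(1234)
  targets <- list(age = c(54.7, 14.2, 20), axial = c(25.5, 1.3, 24),
                  iop = c(25.2, 4.1, 21), followup = c(5.0, 2.7, 2))
  for (nm in names(targets)) {
    x <- lcshift:::rnorm_trunc(1e5, tp[[nm]][1], tp[[nm]][2], targets[[nm]][3])
    expect_lt(abs(mean(x) - targets[[nm]][1]) / targets[[nm]][1], 0.01)
    expect_lt(abs(sd(x) - targets[[nm]][2]) / targets[[nm]][2], 0.01)
    expect_gte(min(x), targets[[nm]][3])
  }
})

test_that("visual field series realize the true onset structure", {
  cfg <- noiseless(seed = 41)
  sim <- simulate_cohort(cfg)
  for (i in seq_len(cfg$n_eyes)) {
    truth <- sim$truth[i, ]
    first <- sim$series[[i]]$exams[[1]]
    call1 <- hemifield_call(first)$label
    if (truth$initial == "bi") expect_equal(call1, "bi")
    else expect_equal(call1, truth$initial)
  }
  # with no false positives, the opposite hemifield stays silent until the
  # true second onset
  sup_eyes <- which(sim$truth$initial == "superior")
  for (i in sup_eyes[1:min(5, length(sup_eyes))]) {
    for (e in sim$series[[i]]$exams) {
      if (e$visit < sim$truth$second_onset_year[i]) {
        lab <- hemifield_call(e)$label
        expect_true(lab %in% c("superior"))
      }
    }
  }
})

test_that("noiseless closed-loop classification recovers every true label", {
  cfg <- noiseless(n = 50, seed = 8)
  sim <- simulate_cohort(cfg)
  init <- vapply(sim$series, function(s) initial_hemisphere(s), character(1))
  fin <- vapply(sim$series, function(s) final_hemisphere(s), character(1))
  expect_equal(init, sim$truth$initial,
               ignore_attr = TRUE)
  expect_equal(fin, sim$truth$final, ignore_attr = TRUE)
  # bi at onset stays bi under the generator's non-improving series
  bi0 <- sim$truth$initial == "bi"
  expect_true(all(fin[bi0] == "bi"))
})

test_that("label recovery degrades gracefully under measurement noise", {
  cfg <- sim_config(n_eyes = 50, seed = 9, fp_point_prob = 0.02,
                    unreliable_prob = 0.1)
  sim <- simulate_cohort(cfg)
  init <- vapply(sim$series, function(s)
    suppressWarnings(initial_hemisphere(s)), character(1))
  expect_gte(mean(init == sim$truth$initial), 0.9)
})

test_that("cohort serialization round-trips and is byte-stable under a fixed seed", {
  cfg <- sim_config(n_eyes = 7, seed = 17)
  sim <- simulate_cohort(cfg)
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  write_cohort(sim, d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  back <- read_cohort(d1)
  expect_equal(back$covariates, sim$covariates)
  expect_equal(length(back$records), 7)
  expect_equal(back$records[[2]]$bmo_margin, sim$records[[2]]$bmo_margin,
               tolerance = 1e-9)
  expect_equal(back$records[[2]]$trunk, sim$records[[2]]$trunk,
               tolerance = 1e-9)
  s_back <- back$series[[3]]; s_orig <- sim$series[[3]]
  expect_equal(length(s_back$exams), length(s_orig$exams))
  expect_identical(s_back$exams[[1]]$pd, s_orig$exams[[1]]$pd)
  # geometry measured after the round trip matches
  expect_equal(measure_cohort(back$records), measure_cohort(sim$records),
               tolerance = 1e-6)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the requested cohort size appears in all outputs", {
  cfg <- sim_config(n_eyes = 81, seed = 2)
  sim <- simulate_cohort(cfg)
  expect_length(sim$records, 81)
  expect_length(sim$series, 81)
  expect_equal(nrow(sim$covariates), 81)
  expect_equal(nrow(sim$truth), 81)
  d <- file.path(tempdir(), "coh81")
  write_cohort(sim, d)
  expect_equal(nrow(utils::read.csv(file.path(d, "covariates.csv"))), 81)
  expect_equal(length(unique(utils::read.csv(file.path(d, "exams.csv"),
                                             check.names = FALSE)$eye_id)), 81)
  unlink(d, recursive = TRUE)
})
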