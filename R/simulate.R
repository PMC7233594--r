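# Synthetic cohort generator.
#
# Emulates a myopic high-tension glaucoma cohort: per-eye optic nerve head
# landmarks (near-elliptical BMO polygon, fovea, vascular trunk placed at a
# drawn angular deviation and shift index), clinical covariates matching the
# cohort moments, and longitudinal 24-2 pattern-deviation series with a
# configurable ground-truth dependence of the onset hemifield on the trunk's
# angular deviation and of bi-hemispheric onset on baseline severity.
#
# Randomness is organised as per-eye substreams keyed by eye index (stage 1:
# landmarks/covariates/truth, stage 2: visual field series), so adding an
# eye never perturbs earlier eyes.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions of the modelled cohort: 81 eyes,
#' age 54.7 +/- 14.2 years, axial length 25.5 +/- 1.3 mm (truncated at
#' >= 24 mm), highest IOP 25.2 +/- 4.1 mmHg (truncated at > 21), baseline
#' mean deviation -8.11 +/- 5.85 dB, follow-up 5.0 +/- 2.7 years (truncated
#' at >= 2), a superior-biased two-component mixture for the trunk angle, a
#' beta-distributed shift index with a point mass at 1 (trunk outside the
#' BMO), and a per-degree inferior-onset log-odds of log(0.83).
#'
#' @param n_eyes Number of eyes.
#' @param seed Base seed for all substreams.
#' @param age_mean_sd,axial_mean_sd,iop_mean_sd,md0_mean_sd,followup_mean_sd
#'   Length-2 (mean, sd) vectors for the covariate draws.
#' @param female_prob Probability of female sex.
#' @param alpha_mix Superior-biased mixture for the trunk angle (degrees):
#'   list with `p_superior` and (mean, sd) pairs `superior`, `inferior`.
#' @param shift_beta_params Shape parameters of the beta distribution of
#'   the shift index below 1.
#' @param severe_prob Point mass at shift index 1 (trunk outside BMO).
#' @param severe_bi_prob Probability that a severe-shift eye starts
#'   bi-hemispheric.
#' @param effect_logodds_per_degree True per-degree log-odds of inferior
#'   onset (default `log(0.83)`).
#' @param onset_intercept Intercept of the inferior-onset logit.
#' @param bihemi_intercept,bihemi_md_slope Logit of bi-hemispheric onset as
#'   a function of baseline MD (slope < 0: worse MD, more bi-hemispheric).
#' @param bihemi_conversion_per_year Yearly hazard of the second hemifield
#'   becoming involved during follow-up.
#' @param lcd_mean_sd Lamina cribrosa depth (um).
#' @param bmo_radius_um Mean ellipse semi-axes (um) of the BMO margin
#'   (temporal-nasal, superior-inferior); defaults give an area near
#'   2.6 mm^2.
#' @param bmo_jitter_um Radial vertex jitter (um) of the 24-point margin.
#' @param fovea_dist_um BMO-centre-to-fovea distance (um).
#' @param fobmo_tilt_deg Mean inferior tilt of the fovea-BMO axis (degrees,
#'   negative = fovea below the horizontal).
#' @param ppa_prob Probability that the eye has beta-zone parapapillary
#'   atrophy.
#' @param visits_per_year,min_visits Visual field testing frequency.
#' @param progression_db_per_year Mean deviation decline per year (dB).
#' @param md_noise_sd Per-visit MD measurement noise (dB).
#' @param fp_point_prob Probability that a normal point shows an isolated
#'   false-positive abnormality on one exam.
#' @param unreliable_prob Probability that an exam fails the reliability
#'   criteria.
#' @param laterality_mix If `TRUE`, half the eyes are generated as left
#'   eyes (stored in raw left-eye coordinates) to exercise the mirroring
#'   path.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_eyes = 81L, seed = 1L,
                       age_mean_sd = c(54.7, 14.2),
                       axial_mean_sd = c(25.5, 1.3),
                       iop_mean_sd = c(25.2, 4.1),
                       md0_mean_sd = c(-8.11, 5.85),
                       followup_mean_sd = c(5.0, 2.7),
                       female_prob = 25 / 81,
                       alpha_mix = list(p_superior = 0.55,
                                        superior = c(40, 35),
                                        inferior = c(-35, 30)),
                       shift_beta_params = c(1.5, 1.6),
                       severe_prob = 6 / 81,
                       severe_bi_prob = 2 / 3,
                       effect_logodds_per_degree = log(0.83),
                       onset_intercept = 0,
                       bihemi_intercept = -5.1,
                       bihemi_md_slope = -0.35,
                       bihemi_conversion_per_year = 0.07,
                       lcd_mean_sd = c(540, 155),
                       bmo_radius_um = c(950, 870),
                       bmo_jitter_um = 15,
                       fovea_dist_um = 4700,
                       fobmo_tilt_deg = -7,
                       ppa_prob = 0.85,
                       visits_per_year = 2,
                       min_visits = 4L,
                       progression_db_per_year = 0.5,
                       md_noise_sd = 0.3,
                       fp_point_prob = 0.01,
                       unreliable_prob = 0.05,
                       laterality_mix = FALSE) {
  cfg <- as.list(environment())
  for (nm in c("age_mean_sd", "axial_mean_sd", "iop_mean_sd", "md0_mean_sd",
               "followup_mean_sd", "lcd_mean_sd"))
    if (cfg[[nm]][2L] <= 0) stop_lcshift(nm, " sd must be > 0")
  for (nm in c("female_prob", "severe_prob", "severe_bi_prob", "ppa_prob",
               "fp_point_prob", "unreliable_prob"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop_lcshift(nm, " must be a probability in [0, 1]")
  # pre-truncation parameters whose lower-truncated draws reproduce the
  # configured cohort moments
  cfg$trunc_params <- list(
    age = trunc_normal_params(age_mean_sd[1L], age_mean_sd[2L], 20),
    axial = trunc_normal_params(axial_mean_sd[1L], axial_mean_sd[2L], 24),
    iop = trunc_normal_params(iop_mean_sd[1L], iop_mean_sd[2L], 21),
    followup = trunc_normal_params(followup_mean_sd[1L],
                                   followup_mean_sd[2L], 2),
    lcd = trunc_normal_params(lcd_mean_sd[1L], lcd_mean_sd[2L], 0))
  structure(cfg, class = "sim_config")
}

# Exact inverse-CDF sampling from a lower-truncated normal; stable even when
# the truncation point sits far in the parent distribution's tail.
rnorm_trunc <- function(n, mean, sd, lower = -Inf) {
  if (!is.finite(lower)) return(stats::rnorm(n, mean, sd))
  p_tail <- stats::pnorm(lower, mean, sd, lower.tail = FALSE)
  u <- stats::runif(n)
  pmax(lower, stats::qnorm(u * p_tail, mean, sd, lower.tail = FALSE))
}

# Moments of a normal truncated below at `a`.
trunc_normal_moments <- function(mu, sigma, a) {
  al <- (a - mu) / sigma
  lam <- exp(stats::dnorm(al, log = TRUE) -
               stats::pnorm(al, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + al * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Pre-truncation (mu, sigma) whose truncated-at-`a` distribution has the
# target mean and sd, so lower-bounded covariate draws reproduce the
# configured cohort moments.
trunc_normal_params <- function(target_mean, target_sd, a) {
  if (!is.finite(a) || (a - target_mean) / target_sd < -6)
    return(c(target_mean, target_sd))
  obj <- function(p) {
    if (p[2L] <= 0) return(1e10)
    mo <- trunc_normal_moments(p[1L], p[2L], a)
    (mo[1L] - target_mean)^2 / target_sd^2 + (mo[2L] / target_sd - 1)^2
  }
  fit <- stats::optim(c(target_mean, target_sd), obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  fit$par
}

# near-elliptical BMO margin polygon: 24 vertices (one per radial scan),
# radial jitter; returns closed-polygon vertex matrix (not repeated).
make_bmo_margin <- function(radius, jitter_sd, n_vertices = 24L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r_jit <- stats::rnorm(n_vertices, 0, jitter_sd)
  cbind((radius[1L] + r_jit) * cos(theta),
        (radius[2L] + r_jit) * sin(theta))
}

#' Simulate one eye: landmarks, covariates and ground truth
#'
#' Draws clinical covariates from the configured truncated normals, the
#' trunk angular deviation from the superior-biased mixture and the shift
#' index from its beta/point-mass distribution; builds the BMO margin
#' polygon, fovea and trunk landmarks (trunk absent when the shift index is
#' 1); and records the true onset labels: inferior-onset propensity
#' `plogis(onset_intercept + effect_logodds_per_degree * alpha)` and
#' bi-hemispheric propensity `plogis(bihemi_intercept + bihemi_md_slope *
#' md0)`.
#'
#' @param config A [sim_config()].
#' @param eye_index Eye index (keys the random substream).
#' @return List with `record` ([landmark_record()]), `covariates` (one-row
#'   data.frame) and `truth` (list with `alpha_true_deg`,
#'   `shift_index_true`, `p_inferior`, `p_bihemi`, `initial`, `final`,
#'   `second_onset_year`).
#' @export
simulate_eye <- function(config, eye_index) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, eye_index, 1L), {
    tp <- config$trunc_params
    age <- rnorm_trunc(1, tp$age[1], tp$age[2], lower = 20)
    sex <- if (stats::runif(1) < config$female_prob) "female" else "male"
    axial <- rnorm_trunc(1, tp$axial[1], tp$axial[2], lower = 24.0)
    iop <- rnorm_trunc(1, tp$iop[1], tp$iop[2], lower = 21 + 1e-6)
    md0 <- stats::rnorm(1, config$md0_mean_sd[1], config$md0_mean_sd[2])
    followup <- rnorm_trunc(1, tp$followup[1], tp$followup[2], lower = 2)
    lcd_true <- rnorm_trunc(1, tp$lcd[1], tp$lcd[2], lower = 0)
    # trunk position
    mix <- config$alpha_mix
    comp <- stats::runif(1) < mix$p_superior
    alpha <- if (comp) stats::rnorm(1, mix$superior[1], mix$superior[2])
             else stats::rnorm(1, mix$inferior[1], mix$inferior[2])
    alpha <- ((alpha + 180) %% 360) - 180
    if (alpha == -180) alpha <- 180
    severe <- stats::runif(1) < config$severe_prob
    si <- if (severe) 1 else
      stats::rbeta(1, config$shift_beta_params[1], config$shift_beta_params[2])
    # margin + axis
    margin <- make_bmo_margin(config$bmo_radius_um, config$bmo_jitter_um)
    tilt <- stats::rnorm(1, config$fobmo_tilt_deg, 2)
    phi <- (180 - tilt) * pi / 180           # fovea direction (temporal, tilted)
    center <- bmo_centroid(margin)
    fovea <- center + config$fovea_dist_um * c(cos(phi), sin(phi))
    nasal <- -fobmo_axis(center, fovea)
    # trunk at the drawn angle/shift, measured from the polygon centroid
    trunk <- NULL
    if (!severe) {
      ang <- alpha * pi / 180
      dir <- c(cos(ang) * nasal[1] - sin(ang) * nasal[2],
               sin(ang) * nasal[1] + cos(ang) * nasal[2])
      b <- ray_polygon_distance(center, dir, margin)
      trunk <- center + si * b * dir
    }
    has_ppa <- stats::runif(1) < config$ppa_prob
    ppa <- NULL
    beta_true <- NA_real_
    if (has_ppa) {
      beta_true <- stats::rnorm(1, -20, 50)
      beta_true <- ((beta_true + 180) %% 360) - 180
      angb <- beta_true * pi / 180
      temporal <- -nasal
      dirb <- c(cos(angb) * temporal[1] - sin(angb) * temporal[2],
                sin(angb) * temporal[1] + cos(angb) * temporal[2])
      bb <- ray_polygon_distance(center, dirb, margin)
      ppa <- center + 1.25 * bb * dirb
    }
    plane_depth <- stats::runif(1, 0, 100)
    laterality <- "right"
    if (config$laterality_mix && stats::runif(1) < 0.5) laterality <- "left"
    # truth
    p_bi <- stats::plogis(config$bihemi_intercept + config$bihemi_md_slope * md0)
    if (severe) p_bi <- max(p_bi, config$severe_bi_prob)
    p_inf <- if (severe) 0.5 else
      stats::plogis(config$onset_intercept +
                      config$effect_logodds_per_degree * alpha)
    u_bi <- stats::runif(1); u_hemi <- stats::runif(1)
    initial <- if (u_bi < p_bi) "bi" else
      if (u_hemi < p_inf) "inferior" else "superior"
    second_onset <- if (initial == "bi") 0 else
      stats::rexp(1, rate = max(config$bihemi_conversion_per_year, 1e-12))
    # the converted hemifield counts as a final defect when it is visible in
    # the last two scheduled exams of the follow-up
    h <- 1 / config$visits_per_year
    t_max <- h * floor(followup / h)
    final <- if (initial == "bi" || second_onset <= t_max - h) "bi" else initial
    rec <- landmark_record(
      eye_id = sprintf("eye%03d", eye_index), laterality = "right",
      bmo_margin = margin, fovea = fovea, trunk = trunk, ppa_max_point = ppa,
      trunk_depth_um = if (severe) NA_real_ else plane_depth + lcd_true,
      bmo_plane_depth_um = plane_depth)
    if (laterality == "left") {
      cx <- bmo_centroid(rec$bmo_margin)[1L]
      rec$bmo_margin <- mirror_x_about(rec$bmo_margin, cx)
      rec$fovea <- mirror_x_about(rec$fovea, cx)
      rec$trunk <- mirror_x_about(rec$trunk, cx)
      rec$ppa_max_point <- mirror_x_about(rec$ppa_max_point, cx)
      rec$laterality <- "left"
    }
    covar <- data.frame(
      eye_id = rec$eye_id, subject_id = sprintf("subj%03d", eye_index),
      age = age, sex = sex, iop_max = iop, axial_length = axial,
      md0_db = md0, followup_years = followup, quality_ok = TRUE,
      stringsAsFactors = FALSE)
    truth <- list(eye_id = rec$eye_id, alpha_true_deg = if (severe) NA_real_ else alpha,
                  shift_index_true = si, p_inferior = p_inf, p_bihemi = p_bi,
                  initial = initial, final = final,
                  second_onset_year = second_onset)
    list(record = rec, covariates = covar, truth = truth)
  })
}

# deterministic per-hemifield cluster template: connected points on the
# 24-2 lattice near the arcuate region, grown from a seed point
hemifield_cluster <- function(grid, hemifield, size, nb) {
  cand <- which(grid$hemifield == hemifield & !grid$blind_spot)
  # seed in the nasal-step / arcuate area
  seed_pool <- cand[abs(grid$x[cand]) <= 15 & abs(grid$y[cand]) >= 9]
  s <- seed_pool[sample.int(length(seed_pool), 1L)]
  comp <- s
  while (length(comp) < size) {
    fringe <- setdiff(unique(unlist(nb[comp])), comp)
    fringe <- fringe[fringe %in% cand]
    if (!length(fringe)) break
    comp <- c(comp, fringe[sample.int(length(fringe), 1L)])
  }
  sort(comp)
}

#' Simulate one eye's longitudinal visual field series
#'
#' Builds per-visit pattern-deviation maps: a qualifying cluster is seeded
#' in the onset hemifield(s) from the first visit (both for bi-hemispheric
#' truth), the second hemifield is added from the true second-onset time
#' for progressing eyes, isolated false-positive points are sprinkled at
#' `fp_point_prob`, and a fraction `unreliable_prob` of exams fails the
#' reliability criteria. MD declines by `progression_db_per_year`.
#'
#' @param truth,covariates Outputs of [simulate_eye()].
#' @param config A [sim_config()].
#' @param eye_index Eye index (keys the random substream).
#' @return List of [vf_exam()] objects in visit order.
#' @export
simulate_vf_series <- function(truth, covariates, config, eye_index) {
  stopifnot(inherits(config, "sim_config"))
  grid <- build_grid_242()
  nb <- grid_neighbours(grid, 8L)
  with_seed(substream_seed(config$seed, eye_index, 2L), {
    fu <- covariates$followup_years
    times <- seq(0, fu, by = 1 / config$visits_per_year)
    if (length(times) < config$min_visits)
      times <- seq(0, fu, length.out = config$min_visits)
    hemis0 <- switch(truth$initial,
                     bi = c("superior", "inferior"),
                     superior = "superior", inferior = "inferior")
    second <- setdiff(c("superior", "inferior"), hemis0)
    clusters <- list(
      superior = hemifield_cluster(grid, "superior", sample(4:6, 1L), nb),
      inferior = hemifield_cluster(grid, "inferior", sample(4:6, 1L), nb))
    scoreable <- which(!grid$blind_spot)
    exams <- vector("list", length(times))
    for (v in seq_along(times)) {
      t <- times[v]
      active <- hemis0
      if (length(second) && truth$second_onset_year <= t)
        active <- c(active, second)
      pd <- rep(0L, 54L)
      for (h in active) {
        idx <- clusters[[h]]
        lev <- rep(1L, length(idx))
        nstrict <- max(2L, round(length(idx) / 2))
        lev[seq_len(nstrict)] <- 4L
        extra <- idx[lev == 1L]
        if (length(extra))
          lev[lev == 1L] <- sample(1:3, length(extra), replace = TRUE)
        pd[idx] <- pmax(pd[idx], lev)
      }
      if (config$fp_point_prob > 0) {
        fp <- scoreable[stats::runif(length(scoreable)) < config$fp_point_prob]
        pd[fp] <- pmax(pd[fp], 1L)
      }
      unreliable <- stats::runif(1) < config$unreliable_prob
      fl <- if (unreliable) 0.30 else stats::runif(1, 0, 0.15)
      fp_rate <- stats::runif(1, 0, 0.15)
      fn_rate <- stats::runif(1, 0, 0.15)
      md <- covariates$md0_db - config$progression_db_per_year * t +
        stats::rnorm(1, 0, config$md_noise_sd)
      defect <- length(active) > 0L
      exams[[v]] <- vf_exam(
        eye_id = truth$eye_id, visit = t, pd = pd,
        md_db = md, psd_prob = if (defect) 0.04 else 0.5,
        ght = if (defect) "outside" else "within",
        fixation_loss_rate = fl, false_pos_rate = fp_rate,
        false_neg_rate = fn_rate)
    }
    exams
  })
}

#' Simulate a full cohort
#'
#' @param config A [sim_config()].
#' @return Object of class `lcshift_cohort_sim`: lists `records`, `series`
#'   ([eye_series()] per eye), data.frames `covariates` and `truth`, and
#'   the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  eyes <- lapply(seq_len(config$n_eyes), function(i) simulate_eye(config, i))
  records <- lapply(eyes, `[[`, "record")
  covariates <- do.call(rbind, lapply(eyes, `[[`, "covariates"))
  truth <- do.call(rbind, lapply(eyes, function(e)
    as.data.frame(e$truth, stringsAsFactors = FALSE)))
  series <- lapply(seq_len(config$n_eyes), function(i) {
    exams <- simulate_vf_series(eyes[[i]]$truth, eyes[[i]]$covariates,
                                config, i)
    eye_series(exams, covariates = eyes[[i]]$covariates)
  })
  structure(list(records = records, series = series, covariates = covariates,
                 truth = truth, config = config),
            class = "lcshift_cohort_sim")
}

#' @export
print.lcshift_cohort_sim <- function(x, ...) {
  cat("<lcshift_cohort_sim>", length(x$records), "eyes, seed",
      x$config$seed, "\n")
  cat("  true initial hemispheres:",
      paste(names(table(x$truth$initial)), table(x$truth$initial),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}
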