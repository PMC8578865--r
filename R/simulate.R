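#' Configuration for the synthetic two-trial generator
#'
#' The generator emulates a single-arm observational trial ("trial1": 15
#' patients, symptom scales on days 0/7/14/28, blood on days 0/7/28, 11
#' healthy controls) and a two-arm randomized trial ("trial2": 18 patients
#' per arm, scales on days 0/4/7/14/28, blood on days 0/4/28, 4 subjects per
#' arm missing all blood draws). Patients carry a latent neuroplasticity
#' trait and a latent response gain; see the methods vignette for the full
#' generative model. All defaults are calibrated only to reproduce the
#' qualitative structure such data exhibit (patients below controls in
#' BDNF, a negative baseline BDNF--HAMD correlation, NI autocorrelation
#' across visits, early-enhancement/response coupling in the active arm) —
#' absolute BDNF levels are assay-dependent placeholders.
#'
#' @param seed Integer seed; the dataset is a deterministic function of
#'   (config, seed).
#' @param n_per_arm Patients per arm, or `NULL` for the trial default
#'   (15 in trial 1, 18 per arm in trial 2).
#' @param n_controls Healthy controls (default 11).
#' @param control_bdnf_mean,control_bdnf_sd Healthy-control serum BDNF in
#'   pg/ml.
#' @param patient_bdnf_deficit Mean pg/ml by which patient baseline BDNF
#'   falls below the control mean.
#' @param hamd_baseline_mean,hamd_baseline_sd Pre-truncation mean and
#'   between-subject SD of baseline HAMD-24; baselines are resampled until
#'   they meet the enrollment floor.
#' @param enrollment_floor Minimum baseline HAMD-24 (default 20).
#' @param trait_sd SD of the stable per-subject neuroplasticity trait, in
#'   NI units (pg/ml per HAMD-24 point). The trait shifts the subject's NI
#'   at every visit, inducing the NI autocorrelation.
#' @param trait_coupling Fraction in \[0, 1\]: magnitude of the negative
#'   correlation between the trait and baseline symptom severity; this is
#'   what links low BDNF to high HAMD-24 at every visit.
#' @param response_ni_gain Dimensionless coupling of the per-subject
#'   response gain into the NI trajectory: a subject's mean NI change from
#'   baseline is scaled by `1 + response_ni_gain * (gain - 1)`. This is the
#'   knob that makes early NI enhancement predictive of final response.
#' @param measurement_sd_hamd Visit-level HAMD-24 noise (score points).
#' @param measurement_sd_bdnf Visit-level BDNF noise (pg/ml), carried in
#'   the index scale as `measurement_sd_bdnf / E[baseline HAMD]`.
#' @param missing_bdnf Named list: number of patients per arm whose blood
#'   draws all failed, per trial.
#' @param arm_profiles Nested list `trial -> arm -> list(hamd_change,
#'   bdnf_change, response_sd)`. `hamd_change` and `bdnf_change` are named
#'   numeric vectors of mean changes from baseline (names are visit days);
#'   `response_sd` is the SD of the subject response gain (gain 1 = the
#'   arm-average response).
#' @param schedule Named list `trial -> list(scale_days, blood_days)`.
#' @return A list with class `"generator_config"`.
#' @seealso [simulate_trial()], [simulate_controls()], [simulate_study()],
#'   [expected_structure()]
#' @export
generator_config <- function(
    seed = 20210427L,
    n_per_arm = NULL,
    n_controls = 11L,
    control_bdnf_mean = 24000,
    control_bdnf_sd = 3500,
    patient_bdnf_deficit = 8000,
    hamd_baseline_mean = 26,
    hamd_baseline_sd = 4,
    enrollment_floor = 20,
    trait_sd = 180,
    trait_coupling = 0.9,
    response_ni_gain = 2,
    measurement_sd_hamd = 1.5,
    measurement_sd_bdnf = 2000,
    missing_bdnf = list(trial1 = 1L, trial2 = 4L),
    arm_profiles = NULL,
    schedule = NULL) {
  if (is.null(arm_profiles)) {
    arm_profiles <- list(
      trial1 = list(
        yueju = list(
          hamd_change = c(`7` = -5, `14` = -10, `28` = -17),
          bdnf_change = c(`7` = 4000, `28` = 6000),
          response_sd = 0.3
        )
      ),
      trial2 = list(
        yueju = list(
          hamd_change = c(`4` = -8, `7` = -12, `14` = -16, `28` = -19),
          bdnf_change = c(`4` = 2000, `28` = 6000),
          response_sd = 0.3
        ),
        escitalopram = list(
          hamd_change = c(`4` = -4, `7` = -6, `14` = -7, `28` = -8),
          bdnf_change = c(`4` = 0, `28` = 0),
          response_sd = 0.2
        )
      )
    )
  }
  if (is.null(schedule)) {
    schedule <- list(
      trial1 = list(scale_days = c(0L, 7L, 14L, 28L), blood_days = c(0L, 7L, 28L)),
      trial2 = list(scale_days = c(0L, 4L, 7L, 14L, 28L), blood_days = c(0L, 4L, 28L))
    )
  }
  cfg <- list(
    seed = as.integer(seed), n_per_arm = n_per_arm, n_controls = n_controls,
    control_bdnf_mean = control_bdnf_mean, control_bdnf_sd = control_bdnf_sd,
    patient_bdnf_deficit = patient_bdnf_deficit,
    hamd_baseline_mean = hamd_baseline_mean, hamd_baseline_sd = hamd_baseline_sd,
    enrollment_floor = enrollment_floor,
    trait_sd = trait_sd, trait_coupling = trait_coupling,
    response_ni_gain = response_ni_gain,
    measurement_sd_hamd = measurement_sd_hamd,
    measurement_sd_bdnf = measurement_sd_bdnf,
    missing_bdnf = missing_bdnf,
    arm_profiles = arm_profiles, schedule = schedule
  )
  stopifnot(
    cfg$trait_coupling >= 0, cfg$trait_coupling <= 1,
    cfg$trait_sd >= 0, cfg$measurement_sd_hamd >= 0,
    cfg$measurement_sd_bdnf >= 0, cfg$hamd_baseline_sd >= 0,
    cfg$control_bdnf_sd >= 0
  )
  structure(cfg, class = "generator_config")
}

# raw moments 1..4 of a normal(0, sd_w) truncated to [lower, Inf)
truncnorm_moments <- function(sd_w, lower) {
  if (sd_w == 0) {
    if (lower > 0) rlang::abort("degenerate truncation: lower bound above the point mass")
    return(c(mu1 = 0, mu2 = 0, mu3 = 0, mu4 = 0))
  }
  a <- lower / sd_w
  lam <- stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  m1 <- lam
  m2 <- 1 + a * lam
  m3 <- lam * (2 + a^2)
  m4 <- 3 * (1 + a * lam) + a^3 * lam
  c(mu1 = sd_w * m1, mu2 = sd_w^2 * m2, mu3 = sd_w^3 * m3, mu4 = sd_w^4 * m4)
}

# All closed-form population quantities implied by a generator config, for
# one trial. Internal work-horse shared by expected_structure() and the
# sampler (the sampler uses the per-day NI means/loadings computed here).
ni_population_params <- function(config, trial) {
  sig_s <- config$hamd_baseline_sd
  sig_h <- config$measurement_sd_hamd
  sig_w2 <- sig_s^2 + sig_h^2
  sig_w <- sqrt(sig_w2)
  h0 <- config$hamd_baseline_mean
  tau <- config$trait_sd
  cc <- config$trait_coupling
  psi <- config$response_ni_gain
  mom <- truncnorm_moments(sig_w, config$enrollment_floor - h0)
  mu1 <- mom[["mu1"]]; mu2 <- mom[["mu2"]]
  mu3 <- mom[["mu3"]]; mu4 <- mom[["mu4"]]
  varZ <- mu2 - mu1^2
  cov_ts <- -cc * tau * sig_s
  b <- if (sig_w2 > 0) cov_ts / sig_w2 else 0
  a_s <- if (sig_w2 > 0) sig_s^2 / sig_w2 else 0
  var_t_perp <- tau^2 - b^2 * sig_w2
  var_t_cond <- b^2 * varZ + var_t_perp
  E_t <- b * mu1
  E_s <- a_s * mu1
  cov_ts_cond <- b * a_s * varZ + (cov_ts - b * a_s * sig_w2)
  E_ts <- cov_ts_cond + E_t * E_s
  E_H0 <- h0 + mu1
  sig_n <- config$measurement_sd_bdnf / E_H0
  mu_b0 <- config$control_bdnf_mean - config$patient_bdnf_deficit
  m0 <- (mu_b0 - b * (h0 * mu1 + mu2)) / E_H0
  C_t <- h0 * E_t + E_ts
  A <- m0 * (h0 + E_s) + C_t
  hbar_base <- h0 + E_s
  # baseline BDNF-HAMD correlation (continuous core)
  E_Y <- E_H0
  E_B0 <- m0 * (h0 + mu1) + b * (h0 * mu1 + mu2)
  E_B0Y <- m0 * (h0^2 + 2 * h0 * mu1 + mu2) + b * (h0^2 * mu1 + 2 * h0 * mu2 + mu3)
  cov_b0_h0 <- E_B0Y - E_B0 * E_Y
  sig_u2 <- var_t_perp + sig_n^2
  varP <- (m0 + b * h0)^2 * varZ + b^2 * (mu4 - mu2^2) +
    2 * (m0 + b * h0) * b * (mu3 - mu1 * mu2)
  varQ <- sig_u2 * (h0^2 + 2 * h0 * mu1 + mu2)
  var_B0 <- varP + varQ
  cor_b0_h0 <- if (var_B0 > 0 && varZ > 0) cov_b0_h0 / sqrt(var_B0 * varZ) else NA_real_
  sched <- config$schedule[[trial]]
  arms <- config$arm_profiles[[trial]]
  solve_delta <- function(L, sg) {
    if (sg == 0) return(L)
    disc <- 1 + 2 * sg^2 * L
    if (disc < 0) {
      rlang::abort("hamd_change too large for this response_sd (no attainable mean)")
    }
    (-1 + sqrt(disc)) / sg^2
  }
  arm_params <- lapply(names(arms), function(arm) {
    prof <- arms[[arm]]
    sg <- prof$response_sd
    scale_days <- sched$scale_days
    delta <- stats::setNames(numeric(length(scale_days)), scale_days)
    for (d in as.character(scale_days[scale_days > 0])) {
      dh <- prof$hamd_change[[d]]
      if (is.null(dh)) rlang::abort(paste0("no hamd_change for day ", d))
      Mtarget <- (E_H0 + dh) / hbar_base
      if (Mtarget <= 0) rlang::abort("hamd_change drives the mean below zero")
      delta[[d]] <- solve_delta(log(Mtarget), sg)
    }
    blood_days <- sort(sched$blood_days)
    early_blood <- min(blood_days[blood_days > 0])
    m_d <- stats::setNames(numeric(length(blood_days)), blood_days)
    beta_d <- gamma_d <- m_d
    for (d in as.character(blood_days)) {
      if (d == "0") {
        m_d[[d]] <- m0; beta_d[[d]] <- 1; gamma_d[[d]] <- 0
        next
      }
      targetB <- mu_b0 + prof$bdnf_change[[d]]
      del <- delta[[d]]
      M <- exp(del + del^2 * sg^2 / 2)
      if (as.integer(d) <= early_blood) {
        # gain loading tied to the subject's own NI change: gamma = psi*(m_d - m0)
        denom <- A * M / m0 + psi * del * sg^2 * M * hbar_base
        m_d[[d]] <- (targetB + m0 * psi * del * sg^2 * M * hbar_base) / denom
        gamma_d[[d]] <- psi * (m_d[[d]] - m0)
      } else {
        # beyond the early visit the gain loading saturates at its early value;
        # the late index is dominated by the trait-proportional amplification
        gamma_d[[d]] <- gamma_d[[as.character(early_blood)]]
        m_d[[d]] <- (targetB - gamma_d[[d]] * del * sg^2 * M * hbar_base) * m0 / (A * M)
      }
      beta_d[[d]] <- m_d[[d]] / m0
    }
    mean_hamd <- stats::setNames(
      c(E_H0, E_H0 + prof$hamd_change[as.character(scale_days[scale_days > 0])]),
      scale_days)
    mean_bdnf <- stats::setNames(
      c(mu_b0, mu_b0 + prof$bdnf_change[as.character(blood_days[blood_days > 0])]),
      blood_days)
    # population correlation of NI between blood-day pairs
    vr <- beta_d^2 * var_t_cond + gamma_d^2 * sg^2 + sig_n^2
    pairs_ <- utils::combn(as.character(blood_days), 2)
    ni_cor <- tibble(
      day_from = as.integer(pairs_[1, ]), day_to = as.integer(pairs_[2, ]),
      correlation = vapply(seq_len(ncol(pairs_)), function(i) {
        d1 <- pairs_[1, i]; d2 <- pairs_[2, i]
        cv <- beta_d[[d1]] * beta_d[[d2]] * var_t_cond +
          gamma_d[[d1]] * gamma_d[[d2]] * sg^2
        cv / sqrt(vr[[d1]] * vr[[d2]])
      }, numeric(1))
    )
    mean_ni <- beta_d * (m0 + E_t)
    list(arm = arm, response_sd = sg, delta = delta, m_d = m_d,
         beta_d = beta_d, gamma_d = gamma_d, ni_var = vr, ni_cor = ni_cor,
         mean_hamd = mean_hamd, mean_bdnf = mean_bdnf, mean_ni = mean_ni)
  })
  names(arm_params) <- names(arms)
  list(
    sig_s = sig_s, sig_h = sig_h, sig_w = sig_w, h0 = h0, tau = tau,
    coupling = cc, psi = psi, cov_ts = cov_ts, b = b, a_s = a_s,
    var_t_perp = var_t_perp, var_t_cond = var_t_cond, E_H0 = E_H0,
    sig_n = sig_n, m0 = m0, mu_b0 = mu_b0, E_B0 = E_B0,
    cor_baseline_bdnf_hamd = cor_b0_h0, sd_baseline_bdnf = sqrt(var_B0),
    arm = arm_params, schedule = sched
  )
}

#' Closed-form population structure implied by a generator configuration
#'
#' Returns the analytic (no-simulation) population values the generator's
#' latent linear-Gaussian core implies, conditional on the enrollment
#' truncation: mean baseline BDNF per group, the population correlation of
#' baseline BDNF with baseline HAMD-24, and the population NI correlation
#' between every pair of blood-draw visits per arm. These are the oracle
#' values against which parameter-recovery simulations are checked. The
#' formulas describe the continuous core of the model; integer rounding of
#' scale scores and the rare score floors are the only departures in the
#' emitted data.
#'
#' @param config A [generator_config()].
#' @param trial `"trial1"` or `"trial2"`.
#' @return A list with `mean_bdnf_baseline_patients`, `mean_bdnf_controls`,
#'   `mean_hamd_baseline`, `cor_baseline_bdnf_hamd`, `sd_baseline_bdnf`,
#'   `mean_ni_baseline`, `ni_correlations` (tibble `arm, day_from, day_to,
#'   correlation`) and `means` (tibble `arm, day, mean_hamd, mean_bdnf,
#'   mean_ni`).
#' @export
expected_structure <- function(config, trial = c("trial2", "trial1")) {
  trial <- match.arg(trial)
  p <- ni_population_params(config, trial)
  ni_cor <- dplyr::bind_rows(lapply(p$arm, function(ap) {
    dplyr::mutate(ap$ni_cor, arm = ap$arm, .before = 1)
  }))
  means <- dplyr::bind_rows(lapply(p$arm, function(ap) {
    days <- as.integer(names(ap$mean_hamd))
    tibble(arm = ap$arm, day = days,
           mean_hamd = unname(ap$mean_hamd),
           mean_bdnf = unname(ap$mean_bdnf[as.character(days)]),
           mean_ni = unname(ap$mean_ni[as.character(days)]))
  }))
  list(
    mean_bdnf_baseline_patients = p$E_B0,
    mean_bdnf_controls = config$control_bdnf_mean,
    mean_hamd_baseline = p$E_H0,
    cor_baseline_bdnf_hamd = p$cor_baseline_bdnf_hamd,
    sd_baseline_bdnf = p$sd_baseline_bdnf,
    mean_ni_baseline = p$m0,
    ni_correlations = ni_cor,
    means = means
  )
}

# draw the latent triple (severity s, trait t, baseline visit noise e_h0),
# rejecting until the observed continuous baseline meets the floor
draw_latents <- function(p, floor_) {
  sig_s <- p$sig_s
  repeat {
    s <- stats::rnorm(1, 0, sig_s)
    t_mean <- if (sig_s > 0) (p$cov_ts / sig_s^2) * s else 0
    t_var <- p$tau^2 - (if (sig_s > 0) p$cov_ts^2 / sig_s^2 else 0)
    tr <- stats::rnorm(1, t_mean, sqrt(max(0, t_var)))
    e_h0 <- stats::rnorm(1, 0, p$sig_h)
    if (p$h0 + s + e_h0 >= floor_) {
      return(list(s = s, trait = tr, e_h0 = e_h0))
    }
  }
}

#' Simulate one patient
#'
#' Draws a subject's latent severity, neuroplasticity trait and response
#' gain, then emits one record per scheduled visit. Uses the current R RNG
#' stream; [simulate_trial()] seeds it. Exposed mainly for inspection and
#' testing; most users want [simulate_trial()].
#'
#' @param config A [generator_config()].
#' @param trial `"trial1"` or `"trial2"`.
#' @param arm Arm name present in the trial's profiles.
#' @param subject_id Identifier for the emitted rows.
#' @return A tibble of visit records for the subject.
#' @export
simulate_subject <- function(config, trial, arm, subject_id = "S01") {
  p <- ni_population_params(config, trial)
  simulate_subject_impl(config, p, trial, arm, subject_id)
}

simulate_subject_impl <- function(config, p, trial, arm, subject_id) {
  ap <- p$arm[[arm]]
  if (is.null(ap)) rlang::abort(paste0("arm '", arm, "' not in trial profiles"))
  lat <- draw_latents(p, config$enrollment_floor)
  g <- stats::rnorm(1, 1, ap$response_sd)
  sched <- p$schedule
  days <- sched$scale_days
  improvement <- exp(ap$delta[as.character(days)] * g) # 1 at baseline
  hamd_cont <- ifelse(
    days == 0,
    p$h0 + lat$s + lat$e_h0,
    (p$h0 + lat$s) * improvement + stats::rnorm(length(days), 0, p$sig_h)
  )
  hamd <- pmin(SCALE_MAX[["hamd24"]], pmax(0, round(hamd_cont)))
  qids <- pmin(27, pmax(0, round(
    (16 + 0.55 * lat$s) * improvement + stats::rnorm(length(days), 0, 1.2))))
  qids[days == 0] <- max(5, qids[days == 0]) # enrollment requires QIDS >= 5
  phq <- pmin(27, pmax(0, round(
    (17 + 0.5 * lat$s) * improvement + stats::rnorm(length(days), 0, 1.3))))
  bdnf <- rep(NA_real_, length(days))
  for (d in sched$blood_days) {
    i <- which(days == d)
    key <- as.character(d)
    ni <- ap$beta_d[[key]] * (p$m0 + lat$trait) +
      ap$gamma_d[[key]] * (g - 1) + stats::rnorm(1, 0, p$sig_n)
    # physical floors: the index and the assay cannot go below ~1
    bdnf[i] <- max(1, max(ni, 1) * max(hamd[i], 0.5))
  }
  tibble(
    subject_id = subject_id, trial = trial, arm = arm, day = as.integer(days),
    hamd24 = as.numeric(hamd), qids_sr16 = as.numeric(qids),
    phq9 = as.numeric(phq), bdnf = bdnf
  )
}

#' Simulate a full trial dataset
#'
#' Emits a validated long-format patient table for one trial: records only
#' on the scheduled days of each modality, the configured number of
#' randomly chosen patients per arm missing *all* blood draws (whole-subject
#' missingness, as when a blood draw fails), every patient meeting the
#' enrollment floor at day 0. Identical `(config, seed)` give a
#' bit-identical dataset.
#'
#' @param config A [generator_config()].
#' @param trial `"trial1"` or `"trial2"`.
#' @return A validated trial tibble (see [read_trial_table()] for columns).
#' @export
simulate_trial <- function(config, trial = c("trial2", "trial1")) {
  trial <- match.arg(trial)
  set.seed(config$seed + switch(trial, trial1 = 1L, trial2 = 2L))
  p <- ni_population_params(config, trial)
  arms <- names(config$arm_profiles[[trial]])
  n_default <- switch(trial, trial1 = 15L, trial2 = 18L)
  n_arm <- config$n_per_arm %||% n_default
  n_miss <- config$missing_bdnf[[trial]] %||% 0L
  if (n_arm <= n_miss) rlang::abort("n_per_arm must exceed missing_bdnf")
  out <- list()
  for (arm in arms) {
    tag <- toupper(substr(arm, 1, 1))
    ids <- sprintf("%s_%s%03d", switch(trial, trial1 = "T1", trial2 = "T2"),
                   tag, seq_len(n_arm))
    rows <- lapply(ids, function(id) simulate_subject_impl(config, p, trial, arm, id))
    arm_tbl <- dplyr::bind_rows(rows)
    if (n_miss > 0) {
      drop_ids <- sample(ids, n_miss)
      arm_tbl$bdnf[arm_tbl$subject_id %in% drop_ids] <- NA_real_
    }
    out[[arm]] <- arm_tbl
  }
  dat <- dplyr::bind_rows(out)
  validate_trial_data(dat)
  attr(dat, "seed") <- config$seed
  dat
}

#' Simulate the healthy-control BDNF table
#'
#' @param config A [generator_config()].
#' @return A tibble `subject_id, arm, bdnf` with `n_controls` rows; BDNF
#'   floored at 1 pg/ml.
#' @export
simulate_controls <- function(config) {
  set.seed(config$seed + 3L)
  tibble(
    subject_id = sprintf("HC%03d", seq_len(config$n_controls)),
    arm = "healthy_control",
    bdnf = pmax(1, stats::rnorm(config$n_controls, config$control_bdnf_mean,
                                config$control_bdnf_sd))
  )
}

#' Simulate the complete study bundle
#'
#' Both trials plus the healthy-control table, each from its own sub-seed of
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list `trial1`, `trial2`, `controls`.
#' @export
simulate_study <- function(config = generator_config()) {
  list(
    trial1 = simulate_trial(config, "trial1"),
    trial2 = simulate_trial(config, "trial2"),
    controls = simulate_controls(config)
  )
}
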