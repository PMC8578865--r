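test_that("the generator is a deterministic function of (config, seed)", {
  cfg <- generator_config(seed = 99L)
  a <- simulate_trial(cfg, "trial2")
  b <- simulate_trial(cfg, "trial2")
  expect_identical(dplyr::as_tibble(a), dplyr::as_tibble(b))
  expect_identical(simulate_controls(cfg), simulate_controls(cfg))
  c2 <- simulate_trial(generator_config(seed = 100L), "trial2")
  expect_false(identical(dplyr::as_tibble(a), dplyr::as_tibble(c2)))
})

test_that("trial shapes match the study designs", {
  cfg <- generator_config(seed = 2L)
  t2 <- simulate_trial(cfg, "trial2")
  expect_equal(length(unique(t2$subject_id)), 36)
  for (arm in c("yueju", "escitalopram")) {
    sub <- t2[t2$arm == arm, ]
    expect_equal(length(unique(sub$subject_id)), 18)
    expect_equal(sort(unique(sub$day)), c(0, 4, 7, 14, 28))
    # blood on 0/4/28 only, and exactly 4 subjects lost all draws
    expect_true(all(is.na(sub$bdnf[sub$day %in% c(7, 14)])))
    with_blood <- unique(sub$subject_id[!is.na(sub$bdnf)])
    expect_equal(length(with_blood), 14)
    per_day <- table(sub$day[!is.na(sub$bdnf)])
    expect_equal(unname(per_day[c("0", "4", "28")]), rep(14L, 3),
                 ignore_attr = TRUE)
  }
  t1 <- simulate_trial(cfg, "trial1")
  expect_equal(length(unique(t1$subject_id)), 15)
  expect_equal(sort(unique(t1$day)), c(0, 7, 14, 28))
  expect_equal(length(unique(t1$subject_id[!is.na(t1$bdnf)])), 14)
  ctl <- simulate_controls(cfg)
  expect_equal(nrow(ctl), 11)
  expect_true(all(ctl$bdnf > 0))
  # output passes the ingestion validator by construction
  expect_silent(validate_trial_data(t2))
})

test_that("every emitted patient meets the enrollment floor at baseline", {
  for (seed in c(1L, 17L, 533L)) {
    cfg <- generator_config(seed = seed)
    t2 <- simulate_trial(cfg, "trial2")
    expect_true(all(t2$hamd24[t2$day == 0] >= 20))
    expect_true(all(t2$qids_sr16[t2$day == 0] >= 5))
    out <- apply_enrollment(t2)
    expect_equal(nrow(exclusion_report(out)), 0)
  }
})

test_that("a minimal two-subject configuration still validates", {
  cfg <- generator_config(seed = 8L, n_per_arm = 2L,
                          missing_bdnf = list(trial1 = 0L, trial2 = 0L))
  t2 <- simulate_trial(cfg, "trial2")
  expect_equal(length(unique(t2$subject_id)), 4)
  expect_silent(validate_trial_data(t2))
  expect_true(all(!is.na(t2$bdnf[t2$day %in% c(0, 4, 28)])))
})

test_that("the noiseless limit collapses each arm to identical subjects", {
  prof <- list(trial2 = list(yueju = list(
    hamd_change = c(`4` = -6, `7` = -8, `14` = -10, `28` = -12),
    bdnf_change = c(`4` = 1000, `28` = 2000),
    response_sd = 0
  )))
  cfg <- generator_config(seed = 4L, n_per_arm = 5L,
                          hamd_baseline_sd = 0, hamd_baseline_mean = 26,
                          trait_sd = 0, trait_coupling = 0,
                          measurement_sd_hamd = 0, measurement_sd_bdnf = 0,
                          missing_bdnf = list(trial1 = 0L, trial2 = 0L),
                          arm_profiles = prof)
  t2 <- simulate_trial(cfg, "trial2")
  per_day_sd <- tapply(t2$hamd24, t2$day, sd)
  expect_true(all(per_day_sd == 0))
  expect_true(all(tapply(t2$bdnf[!is.na(t2$bdnf)],
                         t2$day[!is.na(t2$bdnf)], sd) == 0))
})

test_that("with only trait variance the NI autocorrelation is exactly 1", {
  prof <- list(trial2 = list(yueju = list(
    hamd_change = c(`4` = -6, `7` = -8, `14` = -10, `28` = -12),
    bdnf_change = c(`4` = 1000, `28` = 2000),
    response_sd = 0
  )))
  cfg <- generator_config(seed = 4L, n_per_arm = 40L,
                          trait_sd = 120, trait_coupling = 0,
                          measurement_sd_bdnf = 0,
                          missing_bdnf = list(trial1 = 0L, trial2 = 0L),
                          arm_profiles = prof)
  es <- expected_structure(cfg, "trial2")
  expect_equal(es$ni_correlations$correlation, rep(1, 3))
  t2 <- simulate_trial(cfg, "trial2")
  nit <- ni_table(t2)
  w <- tidyr::pivot_wider(nit[, c("subject_id", "day", "ni")],
                          names_from = "day", values_from = "ni")
  expect_equal(cor(w$`0`, w$`4`), 1, tolerance = 1e-12)
  expect_equal(cor(w$`0`, w$`28`), 1, tolerance = 1e-12)
})

test_that("zero deficit equalizes patient and control baseline means", {
  cfg <- generator_config(patient_bdnf_deficit = 0)
  es <- expected_structure(cfg, "trial2")
  expect_equal(es$mean_bdnf_baseline_patients, es$mean_bdnf_controls)
})

test_that("analytic population values match an independent Monte-Carlo oracle", {
  # the oracle re-implements the continuous latent model from its definition
  cfg <- generator_config()
  p <- plastidx:::ni_population_params(cfg, "trial2")
  n <- 1e5
  withr::with_seed(613, {
    s <- rnorm(n, 0, p$sig_s)
    tt <- rnorm(n, (p$cov_ts / p$sig_s^2) * s,
                sqrt(p$tau^2 - p$cov_ts^2 / p$sig_s^2))
    e0 <- rnorm(n, 0, p$sig_h)
    keep <- (p$h0 + s + e0) >= cfg$enrollment_floor
    s <- s[keep]; tt <- tt[keep]; e0 <- e0[keep]
    m <- sum(keep)
    for (arm in c("yueju", "escitalopram")) {
      ap <- p$arm[[arm]]
      g <- rnorm(m, 1, ap$response_sd)
      ni <- sapply(c("0", "4", "28"), function(d) {
        ap$beta_d[[d]] * (p$m0 + tt) + ap$gamma_d[[d]] * (g - 1) +
          rnorm(m, 0, p$sig_n)
      })
      H0 <- p$h0 + s + e0
      B0 <- ni[, "0"] * H0
      # mean baseline BDNF
      se_mean <- sd(B0) / sqrt(m)
      expect_lt(abs(mean(B0) - p$E_B0), 3 * se_mean)
      # baseline BDNF-HAMD correlation
      r_bh <- cor(B0, H0)
      se_r <- (1 - r_bh^2) / sqrt(m)
      expect_lt(abs(r_bh - p$cor_baseline_bdnf_hamd), 3 * se_r)
      # NI autocorrelation for every visit pair
      an <- ap$ni_cor
      for (i in seq_len(nrow(an))) {
        r_mc <- cor(ni[, as.character(an$day_from[i])],
                    ni[, as.character(an$day_to[i])])
        se <- (1 - r_mc^2) / sqrt(m)
        expect_lt(abs(r_mc - an$correlation[i]), 3 * se)
      }
    }
  })
})

test_that("directional defaults: falling HAMD in both arms, BDNF rising only under yueju", {
  cfg <- generator_config(seed = 20L, n_per_arm = 500L)
  t2 <- simulate_trial(cfg, "trial2")
  for (arm in c("yueju", "escitalopram")) {
    mh <- tapply(t2$hamd24[t2$arm == arm], t2$day[t2$arm == arm], mean)
    expect_true(all(diff(mh[as.character(c(0, 4, 7, 14, 28))]) < 0))
  }
  y <- t2[t2$arm == "yueju" & !is.na(t2$bdnf), ]
  e <- t2[t2$arm == "escitalopram" & !is.na(t2$bdnf), ]
  wide_y <- tidyr::pivot_wider(y[, c("subject_id", "day", "bdnf")],
                               names_from = "day", values_from = "bdnf")
  wide_e <- tidyr::pivot_wider(e[, c("subject_id", "day", "bdnf")],
                               names_from = "day", values_from = "bdnf")
  ty <- welch_t_test(wide_y$`28`, wide_y$`0`)
  expect_gt(ty$mean_a - ty$mean_b, 0)
  expect_lt(ty$p_value, 0.05) # rise is real at n = 500
  te <- welch_t_test(wide_e$`28`, wide_e$`0`)
  expect_gt(te$p_value, 0.05) # flat: no detectable change even at n = 500
})
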