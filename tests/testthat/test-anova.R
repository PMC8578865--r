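test_that("no time effect gives zero time SS and F", {
  m <- cbind(c(1, 5, 9), c(1, 5, 9), c(1, 5, 9))
  res <- rm_anova_oneway(m)
  expect_equal(unname(res$ss[["time"]]), 0)
  expect_equal(res$f_stat, 0)
})

test_that("the SS decomposition matches the brute-force oracle", {
  m3 <- matrix(c(4, 7, 2, 9, 1, 5, 6, 8, 3), nrow = 3) # fixed integer matrix
  res <- rm_anova_oneway(m3)
  expect_equal(res$ss, brute_rm_ss(m3), tolerance = 1e-12)
  withr::with_seed(31, {
    for (i in 1:15) {
      n <- sample(3:12, 1); k <- sample(2:6, 1)
      m <- matrix(rnorm(n * k, 10, 3), n, k)
      res <- rm_anova_oneway(m)
      expect_equal(res$ss, brute_rm_ss(m), tolerance = 1e-10)
      expect_true(all(res$ss >= -1e-12))
    }
  })
})

test_that("the F test agrees with the base-R within-subject decomposition", {
  withr::with_seed(32, {
    n <- 8; k <- 4
    m <- matrix(rnorm(n * k, 20, 4), n, k)
    res <- rm_anova_oneway(m)
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(n), k)),
                     time = factor(rep(seq_len(k), each = n)))
    ref <- summary(aov(y ~ time + Error(subj / time), data = df))
    tab <- ref[["Error: subj:time"]][[1]]
    expect_equal(res$f_stat, tab["time", "F value"], tolerance = 1e-10)
    expect_equal(res$p_uncorrected, tab["time", "Pr(>F)"], tolerance = 1e-10)
  })
})

test_that("a two-level within factor reproduces the squared paired t", {
  withr::with_seed(33, {
    for (i in 1:10) {
      n <- sample(3:15, 1)
      m <- cbind(rnorm(n, 10), rnorm(n, 12))
      res <- rm_anova_oneway(m)
      expect_equal(res$epsilon, 1) # 2 levels are always spherical
      tt <- t.test(m[, 2], m[, 1], paired = TRUE)
      expect_equal(res$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(res$p_gg, tt$p.value, tolerance = 1e-10)
    }
  })
})

test_that("the sphericity correction factor behaves analytically", {
  # compound symmetry -> exactly 1
  cs <- matrix(0.4, 4, 4); diag(cs) <- 1.5
  expect_equal(gg_epsilon(cs), 1)
  expect_equal(gg_epsilon(diag(2) * 3), 1) # k = 2 forced
  # one dominant component after double centering pushes epsilon to 1/(k-1);
  # oracle: direct evaluation of the definition on the same matrix
  v <- c(3, -1, -1, -1)
  sig <- 10 * outer(v, v) + diag(4) * 1e-3
  k <- 4
  ctr <- sig - outer(rowMeans(sig), rep(1, k)) - outer(rep(1, k), rowMeans(sig)) + mean(sig)
  direct <- sum(diag(ctr))^2 / ((k - 1) * sum(ctr^2))
  expect_equal(gg_epsilon(sig), max(1 / 3, min(1, direct)))
  expect_lt(gg_epsilon(sig), 0.34)
  # bounds on random covariance matrices
  withr::with_seed(34, {
    for (i in 1:20) {
      k <- sample(2:6, 1)
      x <- matrix(rnorm(20 * k), 20, k)
      e <- gg_epsilon(cov(x))
      expect_gte(e, 1 / (k - 1))
      expect_lte(e, 1)
    }
  })
  expect_error(gg_epsilon(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("estimated epsilon approaches 1 from below under true sphericity", {
  withr::with_seed(35, {
    eps <- replicate(300, {
      m <- matrix(rnorm(12 * 4), 12, 4) # iid: spherical population
      gg_epsilon(cov(m))
    })
    expect_true(all(eps <= 1))
    expect_gt(mean(eps), 0.75)
    expect_lt(mean(eps), 1)
  })
})

test_that("split-plot SS match brute-force summation on a small fixture", {
  m <- matrix(c(10, 12, 20, 23,
                8, 11, 15, 19,
                6, 9, 11, 14), nrow = 4) # 4 subjects x 3 times
  grp <- c("a", "a", "b", "b")
  res <- mixed_anova(m, grp)
  # brute force over definitions
  grand <- mean(m)
  subj_m <- rowMeans(m); col_m <- colMeans(m)
  grp_m <- tapply(subj_m, grp, mean)
  ss_total <- sum((m - grand)^2)
  ss_bs <- 3 * sum((subj_m - grand)^2)
  ss_grp <- 3 * 2 * sum((grp_m - grand)^2)
  cell <- apply(m, 2, function(cl) tapply(cl, grp, mean))
  ss_cells <- 2 * sum((cell - grand)^2)
  ss_time <- 4 * sum((col_m - grand)^2)
  ss_int <- ss_cells - ss_grp - ss_time
  eff <- res$effects
  expect_equal(eff$ss[eff$effect == "group"], ss_grp, tolerance = 1e-10)
  expect_equal(eff$ss[eff$effect == "subjects_within"], ss_bs - ss_grp, tolerance = 1e-10)
  expect_equal(eff$ss[eff$effect == "time"], ss_time, tolerance = 1e-10)
  expect_equal(eff$ss[eff$effect == "group_time"], ss_int, tolerance = 1e-10)
  expect_equal(sum(eff$ss), ss_total, tolerance = 1e-10)
})

test_that("split-plot F values agree with the base-R Error-stratum fit", {
  withr::with_seed(36, {
    n_per <- 5; k <- 4
    m <- rbind(matrix(rnorm(n_per * k, 20), n_per, k),
               matrix(rnorm(n_per * k, 24), n_per, k))
    grp <- rep(c("a", "b"), each = n_per)
    res <- mixed_anova(m, grp)
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(2 * n_per), k)),
                     time = factor(rep(seq_len(k), each = 2 * n_per)),
                     grp = factor(rep(grp, k)))
    ref <- summary(aov(y ~ grp * time + Error(subj), data = df))
    btab <- ref[["Error: subj"]][[1]]
    wtab <- ref[["Error: Within"]][[1]]
    eff <- res$effects
    expect_equal(eff$f_stat[eff$effect == "group"], btab["grp", "F value"],
                 tolerance = 1e-10)
    expect_equal(eff$f_stat[eff$effect == "time"], wtab["time", "F value"],
                 tolerance = 1e-10)
    expect_equal(eff$f_stat[eff$effect == "group_time"], wtab["grp:time", "F value"],
                 tolerance = 1e-10)
  })
})

test_that("exchangeable groups and parallel profiles null the right effects", {
  withr::with_seed(37, {
    base <- matrix(rnorm(6 * 3, 15), 6, 3)
    m <- rbind(base, base) # two identical groups
    grp <- rep(c("a", "b"), each = 6)
    res <- mixed_anova(m, grp)
    eff <- res$effects
    expect_equal(eff$f_stat[eff$effect == "group"], 0, tolerance = 1e-10)
    expect_equal(eff$ss[eff$effect == "group_time"], 0, tolerance = 1e-10)
    # shifting one group by a constant: still no interaction
    m2 <- rbind(base, base + 5)
    res2 <- mixed_anova(m2, grp)
    expect_equal(res2$effects$ss[res2$effects$effect == "group_time"], 0,
                 tolerance = 1e-8)
    expect_gt(res2$effects$f_stat[res2$effects$effect == "group"], 1)
  })
})

test_that("SS components are non-negative and total on random fixtures", {
  withr::with_seed(38, {
    for (i in 1:10) {
      g1 <- sample(2:6, 1); g2 <- sample(2:6, 1); k <- sample(2:5, 1)
      m <- matrix(rnorm((g1 + g2) * k, 10, 2), g1 + g2, k)
      grp <- rep(c("a", "b"), c(g1, g2))
      res <- mixed_anova(m, grp)
      expect_true(all(res$effects$ss >= -1e-10))
      expect_equal(sum(res$effects$ss), res$ss_total, tolerance = 1e-8)
    }
  })
})

test_that("invalid designs are rejected", {
  m <- matrix(rnorm(12), 4, 3)
  expect_error(mixed_anova(m, c("a", "a", "a", "b")), "at least 2 subjects")
  expect_error(mixed_anova(m, rep("a", 4)), "at least 2 groups")
  m[2, 2] <- NA
  expect_error(rm_anova_oneway(m), "missing")
  expect_error(mixed_anova(m, c("a", "a", "b", "b")), "missing")
})
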