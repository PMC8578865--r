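test_that("a well-formed table reads with all records and a clean report", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(path)
  dat <- read_trial_table(path, expected_trial = "trial2")
  expect_equal(nrow(dat), 6)
  expect_equal(dat$subject_id[1], "S01") # row order preserved
  rep <- load_report(dat)
  expect_equal(rep$value[rep$field == "missing_bdnf"], 0)
  expect_equal(sum(rep$value[grepl("unparseable", rep$field)]), 0)
})

test_that("missing-value tokens parse to NA and are counted", {
  for (token in c("NA", "nan", "NaN", "")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_toy_csv(path, bdnf_s1_d0 = token)
    dat <- read_trial_table(path)
    expect_true(is.na(dat$bdnf[dat$subject_id == "S01" & dat$day == 0]))
    expect_equal(load_report(dat)$value[load_report(dat)$field == "missing_bdnf"], 1)
  }
  # a genuinely unparseable cell is missing *and* counted as unparseable
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(path, bdnf_s1_d0 = "not-a-number")
  dat <- read_trial_table(path)
  expect_true(is.na(dat$bdnf[dat$subject_id == "S01" & dat$day == 0]))
  rep <- load_report(dat)
  expect_equal(rep$value[rep$field == "unparseable_bdnf_pg_ml"], 1)
})

test_that("schema and integrity violations are errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,trial,arm,day,hamd24,qids_sr16,phq9",
               "S01,trial2,yueju,0,25,16,17"), path)
  expect_error(read_trial_table(path), "bdnf_pg_ml")

  path2 <- withr::local_tempfile(fileext = ".csv")
  lines <- readLines(write_toy_csv(withr::local_tempfile(fileext = ".csv")))
  writeLines(c(lines, lines[2]), path2) # duplicate (S01, day 0)
  expect_error(read_trial_table(path2), "duplicate")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,trial,arm,day,hamd24,qids_sr16,phq9,bdnf_pg_ml",
               "S01,trial2,yueju,0,25,16,17,15000",
               "S01,trial2,yueju,3,20,13,14,16000"), path3)
  expect_error(read_trial_table(path3), "schedule")

  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,trial,arm,day,hamd24,qids_sr16,phq9,bdnf_pg_ml",
               "S01,trial2,yueju,0,90,16,17,15000"), path4)
  expect_error(read_trial_table(path4), "hamd24")
})

test_that("write-then-read round trip is exact, including missingness", {
  cfg <- generator_config(seed = 7L)
  dat <- simulate_trial(cfg, "trial2")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(dat, path)
  back <- read_trial_table(path, "trial2")
  for (col in c("subject_id", "trial", "arm", "day", "hamd24",
                "qids_sr16", "phq9", "bdnf")) {
    expect_identical(back[[col]], dat[[col]], label = col)
  }
})

test_that("enrollment excludes whole subjects at an inclusive threshold", {
  dat <- toy_trial(list(A = c(`0` = 19, `28` = 10),
                        B = c(`0` = 20, `28` = 10),
                        C = c(`0` = 30, `28` = 10)))
  out <- apply_enrollment(dat, enrollment_criteria())
  expect_setequal(unique(out$subject_id), c("B", "C")) # 20 retained: >= is inclusive
  rep <- exclusion_report(out)
  expect_equal(rep$subject_id, "A")
  expect_match(rep$reason, "hamd24 < 20")
  expect_false("A" %in% out$subject_id) # all of A's rows removed

  # no-op when everyone qualifies, and idempotent
  out2 <- apply_enrollment(out, enrollment_criteria())
  expect_equal(dplyr::as_tibble(out2), dplyr::as_tibble(out), ignore_attr = TRUE)
  expect_equal(nrow(exclusion_report(out2)), 0)
})

test_that("enrollment also applies the QIDS floor", {
  dat <- toy_trial(list(A = c(`0` = 25), B = c(`0` = 25)))
  dat$qids_sr16[dat$subject_id == "A"] <- 3
  dat$qids_sr16[dat$subject_id == "B"] <- 5
  out <- apply_enrollment(dat)
  expect_setequal(unique(out$subject_id), "B")
  expect_match(exclusion_report(out)$reason, "qids_sr16 < 5")
})

test_that("complete-case subsetting is per-analysis and idempotent", {
  cfg <- generator_config(seed = 3L)
  dat <- simulate_trial(cfg, "trial2")
  arm <- dat[dat$arm == "yueju", ]
  # 18 subjects, 4 missing all BDNF -> 14 with complete blood
  cc <- complete_cases(arm, "bdnf", c(0, 4, 28))
  expect_equal(length(unique(cc$subject_id)), 14)
  # enrollment guarantees the baseline scale, so this is the identity
  cc2 <- complete_cases(arm, "hamd24", 0)
  expect_setequal(unique(cc2$subject_id), unique(arm$subject_id))
  # idempotence and monotone subject counts
  expect_equal(complete_cases(cc, "bdnf", c(0, 4, 28)), cc)
  expect_lte(length(unique(cc$subject_id)), length(unique(arm$subject_id)))
  expect_error(complete_cases(arm, "serotonin", 0), "unknown variable")
})

test_that("a subject missing one visit's BDNF is dropped only when that visit is requested", {
  dat <- toy_trial(
    list(A = c(`0` = 25, `4` = 20, `28` = 10), B = c(`0` = 26, `4` = 21, `28` = 11)),
    bdnf = list(A = c(`0` = 15000, `4` = 15500, `28` = NA),
                B = c(`0` = 14000, `4` = 14100, `28` = 14500))
  )
  expect_setequal(unique(complete_cases(dat, "bdnf", c(0, 4))$subject_id), c("A", "B"))
  expect_setequal(unique(complete_cases(dat, "bdnf", c(0, 4, 28))$subject_id), "B")
})
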