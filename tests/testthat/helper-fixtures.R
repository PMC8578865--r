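# Small programmatic fixtures shared across test files.

# a well-formed 2-subject x 3-day trial-2 fragment written to a temp CSV
write_toy_csv <- function(path, bdnf_s1_d0 = "15000") {
  lines <- c(
    "subject_id,trial,arm,day,hamd24,qids_sr16,phq9,bdnf_pg_ml",
    paste0("S01,trial2,yueju,0,25,16,17,", bdnf_s1_d0),
    "S01,trial2,yueju,4,20,13,14,16000",
    "S01,trial2,yueju,28,8,6,7,21000",
    "S02,trial2,escitalopram,0,28,18,19,14000",
    "S02,trial2,escitalopram,4,24,15,16,14500",
    "S02,trial2,escitalopram,28,19,12,13,14200"
  )
  writeLines(lines, path)
  path
}

# in-memory toy trial table; hamd is a named list subject -> c(day = score)
toy_trial <- function(hamd, arm = "yueju", trial = "trial2", bdnf = NULL) {
  rows <- list()
  for (sid in names(hamd)) {
    days <- as.integer(names(hamd[[sid]]))
    b <- if (!is.null(bdnf) && sid %in% names(bdnf)) {
      bdnf[[sid]][as.character(days)]
    } else rep(NA_real_, length(days))
    rows[[sid]] <- tibble::tibble(
      subject_id = sid, trial = trial, arm = arm, day = days,
      hamd24 = as.numeric(hamd[[sid]]), qids_sr16 = NA_real_,
      phq9 = NA_real_, bdnf = as.numeric(b)
    )
  }
  dplyr::bind_rows(rows)
}

# brute-force two-way (subject x condition) SS decomposition by direct
# summation over the definitions -- the RM-ANOVA oracle
brute_rm_ss <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ss_total <- 0; ss_subj <- 0; ss_time <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) ss_total <- ss_total + (m[i, j] - g)^2
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(m[i, ]) - g)^2
  for (j in seq_len(k)) ss_time <- ss_time + n * (mean(m[, j]) - g)^2
  c(subjects = ss_subj, time = ss_time, error = ss_total - ss_subj - ss_time,
    total = ss_total)
}

# direct-summation Pearson oracle with closed-form t and p
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  r <- sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, p = 2 * pt(-abs(t), n - 2))
}

# pair-counting AUC written independently (loop form) for cross-checks
loop_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
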