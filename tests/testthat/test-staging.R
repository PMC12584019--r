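overall_fixture_cohort <- function() {
  fx <- reference_fixtures()$overall
  cohort_from_confusion_fixture(fx$spec)
}

test_that("forced stepwise run reproduces the reference two-step analysis", {
  x <- overall_fixture_cohort()
  m <- run_stepwise(x, forced_cutoffs = c(`3` = 192, `2` = 135))
  executed <- m$audit[!is.na(m$audit$cutoff), ]

  expect_identical(executed$n_remaining, c(270L, 165L))
  expect_identical(executed$cutoff, c(192L, 135L))
  expect_identical(executed$tp, c(12L, 19L))
  expect_identical(executed$fp, c(93L, 63L))
  expect_identical(executed$tn, c(162L, 79L))
  expect_identical(executed$fn, c(3L, 4L))
  # remaining-sample recursion: 270 - (12 + 93) = 165
  expect_identical(executed$n_remaining[2],
                   executed$n_remaining[1] - (executed$tp[1] + executed$fp[1]))
  expect_identical(m$cutoffs, c(135L, 192L))
  expect_true(all(executed$forced))
})

test_that("free search on a fixture cohort beats or matches the printed Youden", {
  # the printed cutoff's Youden is a lower bound for the maximized Youden
  x <- overall_fixture_cohort()
  best <- optimal_cutoff_youden(x$clinfit_admission, x$td_level >= 3)
  printed <- metrics_from_confusion(confusion(12, 93, 162, 3))
  expect_gte(best$youden, printed$youden)
})

test_that("noise-free planted thresholds are recovered exactly", {
  p <- simulation_params(n = 5000, td_thresholds = c(120, 150, 200),
                         td_noise = 0, seed = 17)
  m <- run_stepwise(simulate_cohort(p))
  expect_identical(sort(m$cutoffs), c(120L, 150L, 200L))
  expect_identical(length(m$stage_names), 4L)
  # every executed step is a perfect separation
  executed <- m$audit[!is.na(m$audit$cutoff), ]
  expect_true(all(executed$youden == 1))
})

test_that("stage assignment follows the [c_k, c_{k+1}) band convention", {
  x <- overall_fixture_cohort()
  m <- run_stepwise(x, forced_cutoffs = c(`3` = 192, `2` = 135))
  expect_identical(
    as.character(assign_stage(c(0, 134, 135, 191, 192, 300), m)),
    c("light", "light", "moderate", "moderate", "high", "high"))
  expect_error(assign_stage(301, m), class = "clinstage_validation_error")

  dist <- stage_distribution(x, m)
  expect_identical(dist$n, c(83L, 82L, 105L))
  expect_equal(dist$pct, c(30.7, 30.4, 38.9))
  expect_identical(sum(dist$n), nrow(x))
})

test_that("stage distribution partitions any cohort under any model", {
  for (seed in 1:5) {
    x <- simulate_cohort(simulation_params(n = 400, seed = seed))
    m <- suppressWarnings(run_stepwise(x))
    stages <- assign_stage(x$clinfit_admission, m)
    expect_false(anyNA(stages))
    expect_identical(sum(stage_distribution(x, m)$n), nrow(x))
    # retained cutoffs strictly increase and respect the separation rule
    if (length(m$cutoffs) > 1) {
      expect_true(all(diff(m$cutoffs) >= m$criteria$min_separation))
    }
    # remaining-sample recursion along the executed audit rows
    executed <- m$audit[!is.na(m$audit$cutoff), ]
    if (nrow(executed) > 1) {
      expect_identical(executed$n_remaining[-1],
                       executed$n_remaining[-nrow(executed)] -
                         (executed$tp[-nrow(executed)] + executed$fp[-nrow(executed)]))
    }
  }
})

test_that("degenerate class sizes are skipped and yield a 1-stage model", {
  x <- toy_cohort(c(rep(50, 9), 280), td = c(rep(0, 9), 3))
  expect_warning(m <- run_stepwise(x), "1-stage")
  expect_identical(length(m$cutoffs), 0L)
  expect_identical(m$stage_names, "all")
  expect_true(all(grepl("skipped", m$audit$reason)))
  expect_identical(as.character(unique(assign_stage(x$clinfit_admission, m))), "all")

  expect_error(run_stepwise(toy_cohort(c(10, 20), td = c(1, 1))),
               class = "clinstage_staging_error")
})

test_that("retention drops weak comparisons and merges close cutoffs", {
  # two well-separated perfect thresholds plus one weak comparison:
  # the TD1/TD2 split is assigned at random so the TD>=2 step cannot
  # discriminate beyond fishing noise
  withr::with_seed(42, {
    n <- 2000
    adm <- as.integer(round(runif(n, 0, 300)))
    td <- as.integer(latent_td_level(adm, c(80, 150, 220)))
    mid <- td %in% c(1, 2)
    td[mid] <- sample(c(1L, 2L), sum(mid), replace = TRUE)
  })
  x <- toy_cohort(adm, td = td)
  m <- run_stepwise(x)
  dropped <- m$audit[!m$audit$retained & !is.na(m$audit$cutoff), ]
  expect_gte(nrow(dropped), 1)
  expect_true(all(grepl("dropped|merged", dropped$reason)))
  expect_true(all(m$audit$youden[m$audit$retained] >= 0.3))
  expect_true(all(m$audit$auc[m$audit$retained] >= 0.6))

  # merge rule: planted thresholds 10 points apart both separate perfectly
  # (Youden 1), so the merge loop fires and drops the lower cutoff on the tie
  p <- simulation_params(n = 4000, td_thresholds = c(60, 150, 160),
                         td_noise = 0, seed = 13)
  m2 <- run_stepwise(simulate_cohort(p))
  expect_identical(sort(m2$cutoffs), c(60L, 160L))
  merged <- m2$audit[!m2$audit$retained & !is.na(m2$audit$cutoff), ]
  expect_identical(merged$cutoff, 150L)
  expect_true(all(grepl("merged", merged$reason)))
})

test_that("excluded candidates are honoured and overrides are audited", {
  p <- simulation_params(n = 3000, td_thresholds = c(120, 150, 200),
                         td_noise = 0, seed = 8)
  x <- simulate_cohort(p)
  m <- run_stepwise(x, excluded_candidates = list(`3` = 200L))
  step3 <- m$audit[m$audit$upper_level == 3, ]
  expect_false(step3$cutoff == 200)
  m_forced <- run_stepwise(x, forced_cutoffs = c(`3` = 250))
  expect_true(m_forced$audit$forced[m_forced$audit$upper_level == 3])
})
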