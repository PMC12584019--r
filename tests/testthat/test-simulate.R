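test_that("simulation is deterministic given the seed and matches configured moments", {
  p <- simulation_params(n = 5000, td_thresholds = c(135, 160, 192),
                         td_noise = 0.05, seed = 21)
  x1 <- simulate_cohort(p)
  x2 <- simulate_cohort(p)
  expect_identical(as.data.frame(x1), as.data.frame(x2))

  # law-of-large-numbers check against configured admission moments
  expect_lt(abs(mean(x1$clinfit_admission) - 165.3), 3)
  expect_lt(abs(sd(x1$clinfit_admission) - 59.4), 3)
  expect_lt(abs(mean(x1$age_years) - 62.9), 1.5)
  expect_lt(abs(mean(x1$sex == "male") - 0.541), 0.05)

  # a different seed gives a different cohort
  x3 <- simulate_cohort(simulation_params(n = 5000, td_thresholds = c(135, 160, 192),
                                          td_noise = 0.05, seed = 22))
  expect_false(identical(x1$clinfit_admission, x3$clinfit_admission))
})

test_that("noise-free TD levels are the exact step function of the planted thresholds", {
  p <- simulation_params(n = 2000, td_thresholds = c(120, 150, 200),
                         td_noise = 0, seed = 5)
  x <- simulate_cohort(p)
  expect_identical(x$td_level,
                   as.integer(latent_td_level(x$clinfit_admission, c(120, 150, 200))))
  # band definition: a score exactly at t3 is TD3, just below t1 is TD0
  expect_identical(latent_td_level(c(199, 200, 119, 120, 0, 300), c(120, 150, 200)),
                   c(2L, 3L, 0L, 1L, 0L, 3L))
})

test_that("default generator marginals emulate the reference cohort", {
  x <- simulate_cohort(simulation_params(seed = 1))
  expect_identical(nrow(x), 270L)
  s <- describe_cohort(x)
  td0 <- s$categorical$pct[s$categorical$block == "td_level" &
                             s$categorical$level == "0"]
  expect_lt(abs(td0 - 34.4), 6)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params(td_thresholds = c(150, 140, 200)),
               class = "clinstage_param_error")
  expect_error(simulation_params(td_noise = 0.7), class = "clinstage_param_error")
  expect_error(simulation_params(diagnosis_props = c(stroke = 1)),
               class = "clinstage_param_error")
  expect_error(simulation_params(n = 0), class = "clinstage_param_error")
})

test_that("simulation params round-trip through YAML and JSON configs", {
  p <- simulation_params(n = 50, td_thresholds = c(100, 150, 250), seed = 9)
  yml <- withr::local_tempfile(fileext = ".yaml")
  as_config <- unclass(p)
  as_config$diagnosis_props <- as.list(as_config$diagnosis_props)  # YAML map
  yaml::write_yaml(as_config, yml)
  expect_identical(unclass(read_simulation_params(yml)), unclass(p))
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(as_config, js, auto_unbox = TRUE, digits = NA)
  expect_equal(unclass(read_simulation_params(js)), unclass(p))
})

test_that("fixture cohorts reproduce every confusion cell of their spec", {
  fixtures <- reference_fixtures()
  for (name in names(fixtures)) {
    fx <- fixtures[[name]]
    x <- do.call(cohort_from_confusion_fixture,
                 c(list(spec = fx$spec), fx$demographics))
    expect_identical(nrow(x), as.integer(sum(fx$spec[1, c("tp", "fp", "tn", "fn")])),
                     label = sprintf("%s cohort size", name))
    forced <- setNames(fx$spec$cutoff, as.character(fx$spec$upper_level))
    m <- suppressWarnings(run_stepwise(x, forced_cutoffs = forced))
    executed <- m$audit[!is.na(m$audit$cutoff), ]
    expect_identical(executed$cutoff, as.integer(fx$spec$cutoff),
                     label = sprintf("%s cutoffs", name))
    for (cell in c("tp", "fp", "tn", "fn")) {
      expect_identical(executed[[cell]], as.integer(fx$spec[[cell]]),
                       label = sprintf("%s %s", name, cell))
    }
    # fixture output always passes cohort validation (construction succeeded)
    expect_s3_class(x, "clinstage_cohort")
  }
})

test_that("minimal and inconsistent fixture specs behave per contract", {
  # single step, perfectly separated pair
  x <- cohort_from_confusion_fixture(confusion_fixture_spec(
    data.frame(cutoff = 150, tp = 1, fp = 0, tn = 1, fn = 0)))
  expect_identical(nrow(x), 2L)
  cm <- confusion_at_cutoff(x$clinfit_admission, x$td_level >= 3, 150)
  expect_equal(unclass(cm)[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 0L, tn = 1L, fn = 0L))

  # violated remaining-sample identity names the broken recursion
  expect_error(
    confusion_fixture_spec(data.frame(
      cutoff = c(200, 100), tp = c(5, 1), fp = c(5, 1),
      tn = c(10, 1), fn = c(0, 1))),
    class = "clinstage_fixture_error")
  expect_error(
    confusion_fixture_spec(data.frame(
      cutoff = c(200, 100), tp = c(5, 1), fp = c(5, 1),
      tn = c(10, 1), fn = c(0, 1))),
    "remaining-sample identity")

  # cutoffs must strictly decrease
  expect_error(
    confusion_fixture_spec(data.frame(
      cutoff = c(100, 200), tp = c(1, 1), fp = c(1, 1),
      tn = c(3, 1), fn = c(0, 0))),
    "strictly decrease")

  # a step that cannot absorb carried higher-level positives is rejected
  expect_error(
    cohort_from_confusion_fixture(confusion_fixture_spec(data.frame(
      cutoff = c(200, 100), tp = c(0, 1), fp = c(2, 3),
      tn = c(4, 2), fn = c(3, 1)))),
    class = "clinstage_fixture_error")
})
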