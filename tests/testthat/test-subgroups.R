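test_that("subgroup sample sizes partition the cohort within each factor", {
  x <- simulate_cohort(simulation_params(n = 600, seed = 31))
  res <- suppressWarnings(run_subgroups(x, stratification_plan(), include_overall = TRUE))
  factors <- vapply(res, function(r) r$factor, character(1))
  ns <- vapply(res, function(r) r$n, numeric(1))
  for (f in c("sex", "age", "diagnosis")) {
    expect_identical(as.integer(sum(ns[factors == f])), nrow(x), label = f)
  }
  expect_identical(as.integer(ns[["overall"]]), nrow(x))
})

test_that("a single all-inclusive stratum equals the full-cohort run", {
  x <- simulate_cohort(simulation_params(n = 800, seed = 32,
                                         td_thresholds = c(120, 160, 210),
                                         td_noise = 0.05))
  res <- suppressWarnings(
    run_subgroups(x, stratification_plan("sex"), include_overall = TRUE))
  direct <- suppressWarnings(run_stepwise(x))
  expect_identical(res$overall$model$cutoffs, direct$cutoffs)
  expect_equal(as.data.frame(res$overall$model$audit), as.data.frame(direct$audit))
})

test_that("identical planted thresholds are recovered in every stratum", {
  p <- simulation_params(n = 6000, td_thresholds = c(120, 150, 200),
                         td_noise = 0, seed = 33)
  x <- simulate_cohort(p)
  res <- run_subgroups(x, stratification_plan(c("sex", "age")),
                       include_overall = FALSE)
  for (r in res) {
    expect_identical(sort(r$model$cutoffs), c(120L, 150L, 200L),
                     label = r$stratum)
  }
})

test_that("sex/age/diagnosis fixture cohorts reproduce their printed step cells", {
  fixtures <- reference_fixtures()
  for (name in c("male", "female", "age_lt65", "age_ge65",
                 "stroke", "msk", "cancer")) {
    fx <- fixtures[[name]]
    x <- do.call(cohort_from_confusion_fixture,
                 c(list(spec = fx$spec), fx$demographics))
    forced <- setNames(fx$spec$cutoff, as.character(fx$spec$upper_level))
    m <- suppressWarnings(run_stepwise(x, forced_cutoffs = forced))
    executed <- m$audit[!is.na(m$audit$cutoff), ]
    expect_identical(executed[, c("tp", "fp", "tn", "fn")],
                     tibble::as_tibble(lapply(fx$spec[, c("tp", "fp", "tn", "fn")],
                                              as.integer)),
                     label = name)
  }
  # spot checks against the printed subgroup metrics
  male1 <- metrics_from_confusion(confusion(4, 12, 126, 4))
  expect_equal(round_half_up(male1$specificity, 3), 0.913)
  lt65 <- metrics_from_confusion(confusion(4, 13, 119, 0))
  expect_equal(round_half_up(lt65$specificity, 3), 0.902)
})

test_that("degenerate strata yield 1-stage models with warnings, not failures", {
  x <- toy_cohort(c(200, 100, 150, 120, 210, 90), td = c(2, 0, 1, 0, 2, 1),
                  diagnosis = c(rep("stroke", 5), "cancer"))
  expect_warning(
    res <- run_subgroups(x, stratification_plan("diagnosis"),
                         include_overall = FALSE),
    "1-stage|no cutoff")
  expect_identical(length(res$cancer$model$cutoffs), 0L)

  expect_error(run_subgroups(x, stratification_plan("ward")),
               class = "clinstage_plan_error")
})

test_that("collate_cutoffs builds summary, detail and dropped tables", {
  x <- simulate_cohort(simulation_params(n = 2000, seed = 35,
                                         td_thresholds = c(120, 160, 210),
                                         td_noise = 0.05))
  res <- suppressWarnings(run_subgroups(x, stratification_plan("sex")))
  col <- collate_cutoffs(res)
  expect_identical(col$summary$stratum, c("overall", "male", "female"))
  expect_true(all(col$detail$stratum %in% col$summary$stratum))
  expect_true(all(c("sensitivity", "specificity", "auc", "youden", "exploratory")
                  %in% names(col$detail)))
  # detail rows ascend in cutoff within stratum
  for (s in unique(col$detail$stratum)) {
    expect_false(is.unsorted(col$detail$cutoff[col$detail$stratum == s]))
  }
  # single stratum accepted; 1-stage stratum yields an empty cutoff list + marker
  single <- collate_cutoffs(res$overall)
  expect_identical(nrow(single$summary), 1L)
  sparse <- toy_cohort(c(rep(50, 9), 280), td = c(rep(0, 9), 3))
  res1 <- suppressWarnings(run_subgroups(sparse, stratification_plan("sex"),
                                         include_overall = FALSE))
  col1 <- collate_cutoffs(res1)
  expect_true(any(col1$summary$warning == "no cutoff retained"))
  expect_identical(col1$summary$cutoffs[col1$summary$warning != ""], "")
})
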