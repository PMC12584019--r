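# Exact confusion-matrix fixtures: cohorts constructed so that the
# stepwise procedure, run with the fixture's cutoffs forced, reproduces
# every TP/FP/TN/FN cell of a published staging table.

#' Specify a multi-step confusion-matrix fixture
#'
#' Each step belongs to one dichotomy of the stepwise procedure (positives
#' = TD level at or above `upper_level`, evaluated on the sample remaining
#' after the previous step excluded its predicted positives). Internal
#' consistency is enforced: cutoffs strictly decrease across steps, upper
#' levels strictly decrease, and each step's total equals the previous
#' step's total minus its predicted positives (tp + fp) — the
#' remaining-sample recursion.
#'
#' @param steps data frame with one row per step and columns `cutoff`,
#'   `tp`, `fp`, `tn`, `fn`; optional `upper_level` (default descending
#'   from 3) and `label` (default `"L vs L-1"`).
#' @return a `clinstage_fixture_spec`.
#' @export
#' @examples
#' confusion_fixture_spec(data.frame(
#'   cutoff = c(192, 135),
#'   tp = c(12, 19), fp = c(93, 63), tn = c(162, 79), fn = c(3, 4)
#' ))
confusion_fixture_spec <- function(steps) {
  steps <- tibble::as_tibble(steps)
  required <- c("cutoff", "tp", "fp", "tn", "fn")
  missing_cols <- setdiff(required, names(steps))
  if (length(missing_cols) > 0) {
    stopf("fixture spec missing column(s): %s", paste(missing_cols, collapse = ", "),
          class = "clinstage_fixture_error")
  }
  k <- nrow(steps)
  if (k < 1) stopf("fixture spec needs at least one step", class = "clinstage_fixture_error")
  if (!("upper_level" %in% names(steps))) {
    steps$upper_level <- seq(3L, by = -1L, length.out = k)
  }
  if (!("label" %in% names(steps))) {
    steps$label <- sprintf("TD>=%d vs TD<%d", steps$upper_level, steps$upper_level)
  }
  counts <- as.matrix(steps[c("tp", "fp", "tn", "fn")])
  if (any(counts < 0) || any(counts != floor(counts))) {
    stopf("confusion counts must be non-negative integers",
          class = "clinstage_fixture_error")
  }
  if (k > 1 && any(diff(steps$cutoff) >= 0)) {
    stopf("cutoffs must strictly decrease across steps",
          class = "clinstage_fixture_error")
  }
  if (k > 1 && any(diff(steps$upper_level) >= 0)) {
    stopf("upper levels must strictly decrease across steps",
          class = "clinstage_fixture_error")
  }
  if (any(steps$upper_level < 1 | steps$upper_level > 3)) {
    stopf("upper levels must lie in 1-3", class = "clinstage_fixture_error")
  }
  totals <- rowSums(counts)
  if (k > 1) {
    carried <- totals[-k] - (steps$tp[-k] + steps$fp[-k])
    bad <- which(carried != totals[-1])
    if (length(bad) > 0) {
      stopf(paste0("remaining-sample identity violated between steps %d and %d: ",
                   "%d - (%d + %d) = %d but step %d totals %d"),
            bad[1], bad[1] + 1L, totals[bad[1]], steps$tp[bad[1]], steps$fp[bad[1]],
            carried[bad[1]], bad[1] + 1L, totals[bad[1] + 1L],
            class = "clinstage_fixture_error")
    }
  }
  structure(steps, class = c("clinstage_fixture_spec", class(steps)))
}

#' Build a cohort that reproduces a confusion fixture exactly
#'
#' Constructs integer scores and TD labels such that running
#' [run_stepwise()] with the fixture's cutoffs forced reproduces every
#' TP/FP/TN/FN cell. Predicted positives of step k get a score midway
#' inside the band \[cutoff_k, cutoff_{k-1}) (the top band is open at
#' 300), predicted negatives of the final step a score midway in
#' \[0, cutoff_K) — mid-band placement is robust to off-by-one threshold
#' convention changes. TD labels are minimal: step-k true positives sit
#' at the dichotomy's upper level, false positives one level below; true
#' positives missed at a step (its FN) keep their higher level and are
#' carried into the later steps' cells, so a spec whose later steps
#' cannot absorb them is rejected.
#'
#' Only the confusion cells (and hence stage counts) are controlled; TD
#' marginals and demographics of the fixture are not those of any real
#' cohort. Demographics are constant filler, settable for subgroup
#' fixtures.
#'
#' @param spec a [confusion_fixture_spec()].
#' @param sex,diagnosis,age_years constant demographic filler values.
#' @param provenance provenance label for the cohort.
#' @return a [cohort()] with `sum(tp1 + fp1 + tn1 + fn1)` patients.
#' @export
cohort_from_confusion_fixture <- function(spec, sex = "male",
                                          diagnosis = "other",
                                          age_years = 63,
                                          provenance = "confusion fixture") {
  if (!inherits(spec, "clinstage_fixture_spec")) spec <- confusion_fixture_spec(spec)
  k_steps <- nrow(spec)
  score <- integer(0)
  td <- integer(0)
  # true positives missed so far: TD labels (all >= current upper level)
  # that must be spent in later steps' true-positive cells
  debt <- integer(0)
  upper_bound <- 301L  # exclusive top of the current score band

  mid_band <- function(lo, hi) {  # integer in [lo, hi)
    as.integer(min(lo + (hi - lo) %/% 2L, SCORE_MAX))
  }

  for (k in seq_len(k_steps)) {
    st <- spec[k, ]
    lvl <- st$upper_level
    n_true_pos <- st$tp + st$fn
    if (length(debt) > n_true_pos) {
      stopf(paste0("step %d (%s) has %d true positives but %d higher-level ",
                   "positives are carried from earlier steps"),
            k, st$label, n_true_pos, length(debt),
            class = "clinstage_fixture_error")
    }
    # labels for this step's true positives: spend carried labels first
    tp_labels <- c(debt, rep(lvl, n_true_pos - length(debt)))
    pos_score <- mid_band(st$cutoff, upper_bound)
    # predicted positives finalized now: tp true positives + fp negatives
    score <- c(score, rep(pos_score, st$tp + st$fp))
    td <- c(td, tp_labels[seq_len(st$tp)], rep(lvl - 1L, st$fp))
    debt <- tp_labels[seq_len(st$fn) + st$tp]  # missed positives carry on
    if (k == k_steps) {
      neg_score <- mid_band(0L, st$cutoff)
      score <- c(score, rep(neg_score, st$fn + st$tn))
      td <- c(td, debt, rep(max(lvl - 1L, 0L), st$tn))
      debt <- integer(0)
    }
    upper_bound <- as.integer(st$cutoff)
  }

  n <- length(score)
  cohort(
    tibble::tibble(
      patient_id = sprintf("F%05d", seq_len(n)),
      age_years = age_years, sex = sex, diagnosis = diagnosis,
      clinfit_admission = score, clinfit_discharge = NA_integer_,
      td_level = as.integer(td)
    ),
    provenance = provenance
  )
}

#' Reference staging fixtures
#'
#' Confusion-matrix specifications of the reference ClinFIT staging
#' analysis: the overall two-step model (cutoffs 192 then 135) and the
#' sex, age-band and diagnosis subgroup models, as printed in the study
#' tables. Each entry carries the fixture spec plus the demographic
#' filler describing its stratum, so [cohort_from_confusion_fixture()]
#' can rebuild a cohort on which the forced stepwise run reproduces every
#' cell.
#'
#' @return named list; each element has `spec` (a
#'   [confusion_fixture_spec()]) and `demographics` (filler values for
#'   the stratum).
#' @export
#' @examples
#' fx <- reference_fixtures()$overall
#' cohort_from_confusion_fixture(fx$spec)
reference_fixtures <- function() {
  fx <- function(cutoffs, tp, fp, tn, fn, labels, sex = "male",
                 diagnosis = "other", age_years = 63) {
    list(
      spec = confusion_fixture_spec(tibble::tibble(
        cutoff = cutoffs, tp = tp, fp = fp, tn = tn, fn = fn,
        upper_level = c(3L, 2L), label = labels
      )),
      demographics = list(sex = sex, diagnosis = diagnosis,
                          age_years = age_years)
    )
  }
  two_labels <- c("high vs moderate", "moderate vs light")
  list(
    overall   = fx(c(192, 135), c(12, 19), c(93, 63), c(162, 79), c(3, 4), two_labels),
    male      = fx(c(232, 156), c(4, 18), c(12, 48), c(126, 59), c(4, 5), two_labels,
                   sex = "male"),
    female    = fx(c(175, 134), c(7, 6), c(55, 22), c(62, 34), c(0, 0), two_labels,
                   sex = "female"),
    age_lt65  = fx(c(232, 173), c(4, 16), c(13, 27), c(119, 69), c(0, 7), two_labels,
                   age_years = 50),
    age_ge65  = fx(c(175, 157), c(9, 5), c(60, 9), c(63, 48), c(2, 3), two_labels,
                   age_years = 75),
    stroke    = fx(c(175, 162), c(9, 2), c(42, 3), c(38, 33), c(0, 0), two_labels,
                   diagnosis = "stroke"),
    msk       = fx(c(261, 173), c(1, 13), c(0, 11), c(55, 27), c(1, 5), two_labels,
                   diagnosis = "msk"),
    cancer    = fx(c(241, 134), c(2, 5), c(4, 33), c(57, 19), c(0, 0), two_labels,
                   diagnosis = "cancer"),
    # The "other"-diagnosis model involved a manual threshold substitution
    # (167 replaced by 128/193), so its two printed steps do not satisfy the
    # remaining-sample recursion (61 - 20 = 41 remaining, but the second
    # step totals 36) and cannot form one sequential fixture; each step is
    # therefore a standalone one-step fixture.
    other_high_vs_moderate = list(
      spec = confusion_fixture_spec(tibble::tibble(
        cutoff = 193, tp = 1, fp = 19, tn = 40, fn = 1,
        upper_level = 3L, label = "high vs moderate")),
      demographics = list(sex = "male", diagnosis = "other", age_years = 63)
    ),
    other_moderate_vs_light = list(
      spec = confusion_fixture_spec(tibble::tibble(
        cutoff = 128, tp = 12, fp = 10, tn = 10, fn = 4,
        upper_level = 2L, label = "moderate vs light")),
      demographics = list(sex = "male", diagnosis = "other", age_years = 63)
    )
  )
}
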