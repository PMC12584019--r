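# Subgroup re-derivation of staging models and cross-stratum collation.

#' Stratification plan for subgroup analyses
#'
#' Strata are analysed marginally, one factor at a time (sex; age band
#' below/at-or-above the boundary; diagnosis group) — no
#' cross-classification, which would explode sparsity.
#'
#' @param factors subset of `c("sex", "age", "diagnosis")`.
#' @param age_boundary years; 65 by default, the boundary being inclusive
#'   in the older band.
#' @return a `clinstage_strat_plan`.
#' @export
stratification_plan <- function(factors = c("sex", "age", "diagnosis"),
                                age_boundary = 65) {
  supported <- c("sex", "age", "diagnosis")
  unknown <- setdiff(factors, supported)
  if (length(factors) == 0 || length(unknown) > 0) {
    stopf("factors must be a non-empty subset of %s (got: %s)",
          paste(supported, collapse = ", "), paste(unknown, collapse = ", "),
          class = "clinstage_plan_error")
  }
  structure(list(factors = factors, age_boundary = age_boundary),
            class = "clinstage_strat_plan")
}

stratum_splits <- function(x, plan) {
  out <- list()
  for (f in plan$factors) {
    values <- switch(f,
      sex = as.character(x$sex),
      diagnosis = as.character(x$diagnosis),
      age = ifelse(x$age_years >= plan$age_boundary,
                   sprintf("age>=%d", plan$age_boundary),
                   sprintf("age<%d", plan$age_boundary))
    )
    level_order <- switch(f,
      sex = SEX_LEVELS,
      diagnosis = DIAGNOSIS_LEVELS,
      age = c(sprintf("age<%d", plan$age_boundary),
              sprintf("age>=%d", plan$age_boundary))
    )
    for (lv in intersect(level_order, unique(values))) {
      out[[lv]] <- list(factor = f, level = lv, rows = which(values == lv))
    }
  }
  out
}

#' Derive staging models within demographic/diagnostic strata
#'
#' Applies [run_stepwise()] independently within each stratum of the
#' plan, with identical criteria. Strata too sparse for any comparison
#' yield 1-stage models with warnings, not failures. Per-stratum forced
#' cutoffs or excluded candidates reproduce documented manual overrides.
#'
#' @param x a [cohort()].
#' @param plan a [stratification_plan()].
#' @param criteria a [retention_criteria()].
#' @param include_overall also run the procedure on the full cohort,
#'   keyed `"overall"` (default `TRUE`).
#' @param overrides optional named list keyed by stratum label (or
#'   `"overall"`); each element a list with `forced_cutoffs` and/or
#'   `excluded_candidates` passed through to [run_stepwise()].
#' @return named list of `clinstage_subgroup_result`: `stratum`,
#'   `factor`, `n`, `model`.
#' @export
run_subgroups <- function(x, plan = stratification_plan(),
                          criteria = retention_criteria(),
                          include_overall = TRUE, overrides = NULL) {
  stopifnot(inherits(x, "clinstage_cohort"), inherits(plan, "clinstage_strat_plan"))
  splits <- stratum_splits(x, plan)
  if (include_overall) {
    splits <- c(list(overall = list(factor = "overall", level = "overall",
                                    rows = seq_len(nrow(x)))),
                splits)
  }
  lapply(splits, function(s) {
    sub <- x[s$rows, ]
    attr(sub, "provenance") <- sprintf("%s [%s]",
                                       attr(x, "provenance") %||% "unspecified",
                                       s$level)
    ov <- overrides[[s$level]] %||% list()
    model <- tryCatch(
      run_stepwise(sub, criteria,
                   forced_cutoffs = ov$forced_cutoffs,
                   excluded_candidates = ov$excluded_candidates),
      clinstage_staging_error = function(e) {
        warnf("stratum %s: %s; returning a 1-stage model", s$level, conditionMessage(e))
        structure(list(cutoffs = integer(0), stage_names = "all",
                       n = nrow(sub), criteria = criteria,
                       audit = tibble::tibble()),
                  class = "clinstage_staging_model")
      }
    )
    structure(list(stratum = s$level, factor = s$factor, n = nrow(sub),
                   model = model),
              class = "clinstage_subgroup_result")
  })
}

#' Collate retained cutoffs across strata
#'
#' Builds the cross-subgroup comparison: one summary row per stratum
#' (sample size, retained cutoffs ascending), a detail table with one row
#' per stratum-cutoff carrying Se/Sp/AUC/Youden, and an audit appendix of
#' skipped or dropped candidates. Steps whose positive class had fewer
#' than 10 members are flagged `exploratory`.
#'
#' @param results list of subgroup results from [run_subgroups()] (a
#'   single result is accepted).
#' @return a `clinstage_cutoff_collation`: list of tibbles `summary`,
#'   `detail`, `dropped`.
#' @export
collate_cutoffs <- function(results) {
  if (inherits(results, "clinstage_subgroup_result")) results <- list(results)
  if (length(results) == 0) stopf("no subgroup results to collate")
  summaries <- list(); details <- list(); dropped <- list()
  for (r in results) {
    m <- r$model
    summaries[[length(summaries) + 1]] <- tibble::tibble(
      stratum = r$stratum, n = r$n, n_stages = length(m$cutoffs) + 1L,
      cutoffs = if (length(m$cutoffs)) paste(m$cutoffs, collapse = ", ") else "",
      warning = if (length(m$cutoffs) == 0) "no cutoff retained" else ""
    )
    if (nrow(m$audit) > 0) {
      kept <- m$audit[m$audit$retained, ]
      if (nrow(kept) > 0) {
        details[[length(details) + 1]] <- tibble::tibble(
          stratum = r$stratum, label = kept$label, cutoff = kept$cutoff,
          n_step = kept$n_remaining,
          sensitivity = kept$sensitivity, specificity = kept$specificity,
          accuracy = kept$accuracy, auc = kept$auc, youden = kept$youden,
          exploratory = (kept$tp + kept$fn) < 10
        )[order(kept$cutoff), ]
      }
      gone <- m$audit[!m$audit$retained, ]
      if (nrow(gone) > 0) {
        dropped[[length(dropped) + 1]] <- tibble::tibble(
          stratum = r$stratum, label = gone$label, cutoff = gone$cutoff,
          reason = gone$reason
        )
      }
    }
  }
  structure(list(summary = dplyr::bind_rows(summaries),
                 detail = dplyr::bind_rows(details),
                 dropped = dplyr::bind_rows(dropped)),
            class = "clinstage_cutoff_collation")
}

#' @export
print.clinstage_cutoff_collation <- function(x, ...) {
  cat("Retained cutoffs by stratum\n")
  print(x$summary)
  if (nrow(x$dropped) > 0) {
    cat(sprintf("(%d skipped/dropped candidate(s); see $dropped)\n", nrow(x$dropped)))
  }
  invisible(x)
}
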