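# The stepwise staging procedure: sequential high-to-low ROC comparisons
# with exclusion after each retained cutoff, retention/merge filtering,
# and the resulting staging model.

#' Retention and merge criteria for candidate cutoffs
#'
#' A derived cutoff is kept only if its comparison discriminates: AUC at
#' least `min_auc` and Youden index at least `min_youden`. Surviving
#' cutoffs closer together than `min_separation` points (default 15, 5%
#' of the 0-300 scale) are merged by dropping the weaker member.
#' `min_class_size` is the smallest class allowed in a step's dichotomy;
#' the default 2 lets steps with as few as two positives run (such steps
#' are flagged exploratory downstream, not suppressed).
#'
#' @param min_separation minimum distance between adjacent retained
#'   cutoffs, in score points.
#' @param min_auc minimum AUC for retention, in \[0.5, 1\].
#' @param min_youden minimum Youden index for retention, in \[0, 1\].
#' @param min_class_size minimum size of either class for a step to run.
#' @return a `clinstage_criteria` list.
#' @export
retention_criteria <- function(min_separation = 15, min_auc = 0.6,
                               min_youden = 0.3, min_class_size = 2) {
  if (min_separation < 0) stopf("min_separation must be non-negative")
  if (min_auc < 0.5 || min_auc > 1) stopf("min_auc must lie in [0.5, 1]")
  if (min_youden < 0 || min_youden > 1) stopf("min_youden must lie in [0, 1]")
  if (!is_count1(min_class_size) || min_class_size < 1) {
    stopf("min_class_size must be a positive integer")
  }
  structure(list(min_separation = min_separation, min_auc = min_auc,
                 min_youden = min_youden, min_class_size = as.integer(min_class_size)),
            class = "clinstage_criteria")
}

#' Derive a staging model by stepwise ROC analysis
#'
#' Walks the TD levels from the highest present level down to 1. At each
#' level L, the remaining sample is dichotomized cumulatively (positives
#' = TD >= L), the Youden-optimal integer cutoff is found
#' ([optimal_cutoff_youden()]), and all remaining patients scoring at or
#' above that cutoff — the predicted positives — are excluded before the
#' next level. Steps whose smaller class is below `min_class_size` are
#' recorded as skipped and cause no exclusion.
#'
#' After the sequential pass, retention filtering drops any cutoff with
#' AUC below `min_auc` or Youden below `min_youden`; then, while any
#' adjacent pair of survivors is closer than `min_separation`, the member
#' with the lower Youden index is dropped (ties: the lower cutoff). A
#' provisionally retained cutoff still causes exclusion for subsequent
#' steps even if later dropped — the audit trail records this; set
#' `reevaluate_after_drop = TRUE` to instead re-run the sequential pass
#' with dropped candidates excluded until the retained set is stable.
#'
#' Manual overrides reproduce judgment calls: `forced_cutoffs` pins the
#' cutoff used at given levels, `excluded_candidates` removes values from
#' the search grid. Overrides are recorded in the audit, never silent.
#'
#' @param x a [cohort()].
#' @param criteria a [retention_criteria()].
#' @param forced_cutoffs optional named numeric vector: names are TD
#'   upper levels ("1"-"3"), values the cutoff to force at that step.
#' @param excluded_candidates optional integer vector (applied at every
#'   step) or named list by TD upper level of cutoff values to exclude
#'   from the search.
#' @param reevaluate_after_drop logical; re-run the sequential pass after
#'   retention drops until stable (off by default, matching the
#'   sequential narrative of the reference analysis).
#' @param stage_names optional character vector of K+1 stage labels,
#'   low to high.
#' @return a `clinstage_staging_model`: `cutoffs` (ascending retained
#'   cutoffs), `stage_names`, `n`, `criteria`, and `audit` (one row per
#'   attempted step: label, level, n_remaining, cutoff, confusion cells,
#'   metrics, `retained`, `reason`, `forced`).
#' @export
run_stepwise <- function(x, criteria = retention_criteria(),
                         forced_cutoffs = NULL, excluded_candidates = NULL,
                         reevaluate_after_drop = FALSE, stage_names = NULL) {
  stopifnot(inherits(x, "clinstage_cohort"))
  if (nrow(x) == 0) stopf("cohort is empty", class = "clinstage_staging_error")
  if (length(unique(x$td_level)) < 2) {
    stopf("need at least 2 distinct TD levels to derive cutoffs",
          class = "clinstage_staging_error")
  }
  banned <- normalize_exclusions(excluded_candidates)
  if (!is.null(forced_cutoffs)) {
    forced_cutoffs <- unlist(forced_cutoffs)
    if (is.null(names(forced_cutoffs))) {
      stopf("forced_cutoffs must be named by TD upper level, e.g. c(`3` = 192)")
    }
  }
  drop_set <- integer(0)  # candidates banned by re-evaluation rounds
  repeat {
    audit <- stepwise_pass(x, criteria, forced_cutoffs, banned, drop_set)
    audit <- apply_retention(audit, criteria)
    newly_dropped <- audit$cutoff[!audit$retained & !is.na(audit$cutoff)]
    newly_dropped <- setdiff(newly_dropped, drop_set)
    if (!reevaluate_after_drop || length(newly_dropped) == 0) break
    drop_set <- c(drop_set, newly_dropped)
  }

  cutoffs <- sort(audit$cutoff[audit$retained])
  k <- length(cutoffs)
  if (k == 0) {
    warnf("no cutoff survived the retention criteria; returning a 1-stage model")
  }
  if (is.null(stage_names)) stage_names <- default_stage_names(k)
  if (length(stage_names) != k + 1) {
    stopf("stage_names must have %d entries for %d cutoffs", k + 1, k)
  }
  structure(list(cutoffs = cutoffs, stage_names = stage_names,
                 n = nrow(x), criteria = criteria, audit = audit),
            class = "clinstage_staging_model")
}

default_stage_names <- function(k) {
  if (k == 0) return("all")
  if (k == 1) return(c("light", "high"))
  if (k == 2) return(c("light", "moderate", "high"))
  paste0("stage", 0:k)
}

normalize_exclusions <- function(excluded) {
  if (is.null(excluded)) return(list())
  if (is.numeric(excluded)) {
    return(setNames(rep(list(as.integer(excluded)), 3), as.character(1:3)))
  }
  lapply(excluded, as.integer)
}

# One full high-to-low sequential pass. drop_set: cutoffs globally banned
# from the candidate grid (re-evaluation mode).
stepwise_pass <- function(x, criteria, forced_cutoffs, banned, drop_set) {
  remaining <- x
  rows <- list()
  for (lvl in seq(max(x$td_level), 1L)) {
    labels <- remaining$td_level >= lvl
    n_pos <- sum(labels)
    n_neg <- sum(!labels)
    label <- sprintf("TD>=%d vs TD<%d", lvl, lvl)
    if (min(n_pos, n_neg) < criteria$min_class_size) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        label = label, upper_level = lvl, n_remaining = nrow(remaining),
        cutoff = NA_integer_, tp = NA_integer_, fp = NA_integer_,
        tn = NA_integer_, fn = NA_integer_,
        sensitivity = NA_real_, specificity = NA_real_, accuracy = NA_real_,
        youden = NA_real_, auc = NA_real_,
        retained = FALSE, forced = FALSE,
        reason = sprintf("skipped: class sizes %d/%d below minimum %d",
                         n_pos, n_neg, criteria$min_class_size)
      )
      next
    }
    forced <- unname(forced_cutoffs[as.character(lvl)])
    if (length(forced) == 1 && !is.na(forced)) {
      cut <- as.integer(forced)
      cm <- confusion_at_cutoff(remaining$clinfit_admission, labels, cut)
      m <- metrics_from_confusion(cm)
      res <- list(cutoff = cut, sensitivity = m$sensitivity,
                  specificity = m$specificity, accuracy = m$accuracy,
                  youden = m$youden,
                  auc = roc_auc(remaining$clinfit_admission, labels),
                  confusion = cm)
      was_forced <- TRUE
    } else {
      candidates <- setdiff(0:300, c(banned[[as.character(lvl)]], drop_set))
      res <- optimal_cutoff_youden(remaining$clinfit_admission, labels,
                                   candidates = candidates)
      was_forced <- FALSE
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      label = label, upper_level = lvl, n_remaining = nrow(remaining),
      cutoff = res$cutoff,
      tp = res$confusion$tp, fp = res$confusion$fp,
      tn = res$confusion$tn, fn = res$confusion$fn,
      sensitivity = res$sensitivity, specificity = res$specificity,
      accuracy = res$accuracy, youden = res$youden, auc = res$auc,
      retained = TRUE, forced = was_forced, reason = ""
    )
    remaining <- remaining[remaining$clinfit_admission < res$cutoff, ]
  }
  dplyr::bind_rows(rows)
}

# Retention filter + merge loop on the audit of one pass.
apply_retention <- function(audit, criteria) {
  audit$reason[audit$retained == FALSE & audit$reason == ""] <- "skipped"
  executed <- which(audit$retained)
  for (i in executed) {
    if (audit$auc[i] < criteria$min_auc || audit$youden[i] < criteria$min_youden) {
      audit$retained[i] <- FALSE
      audit$reason[i] <- sprintf(
        "dropped: AUC %.3f / Youden %.3f below retention minima (%.2f / %.2f)",
        audit$auc[i], audit$youden[i], criteria$min_auc, criteria$min_youden)
    }
  }
  # merge loop: each iteration removes one cutoff, so it terminates
  repeat {
    idx <- which(audit$retained)
    if (length(idx) < 2) break
    ord <- idx[order(audit$cutoff[idx])]
    gaps <- diff(audit$cutoff[ord])
    close_pair <- which(gaps < criteria$min_separation)
    if (length(close_pair) == 0) break
    a <- ord[close_pair[1]]
    b <- ord[close_pair[1] + 1]
    drop <- if (audit$youden[a] < audit$youden[b]) a
            else if (audit$youden[b] < audit$youden[a]) b
            else if (audit$cutoff[a] < audit$cutoff[b]) a else b
    keep <- if (drop == a) b else a
    audit$retained[drop] <- FALSE
    audit$reason[drop] <- sprintf(
      "merged: within %d points of cutoff %d and lower Youden (%.3f vs %.3f)",
      criteria$min_separation, audit$cutoff[keep], audit$youden[drop],
      audit$youden[keep])
  }
  audit
}

#' @export
print.clinstage_staging_model <- function(x, ...) {
  k <- length(x$cutoffs)
  cat(sprintf("<clinstage_staging_model> %d stage(s) on n = %d\n", k + 1, x$n))
  if (k > 0) {
    bands <- stage_bands(x)
    for (i in seq_len(nrow(bands))) {
      cat(sprintf("  %-10s %s\n", bands$stage[i], bands$band[i]))
    }
  } else {
    cat("  single stage covering the whole 0-300 scale\n")
  }
  dropped <- sum(!x$audit$retained)
  if (dropped > 0) cat(sprintf("  (%d step(s) skipped or dropped; see $audit)\n", dropped))
  invisible(x)
}

stage_bands <- function(model) {
  k <- length(model$cutoffs)
  lo <- c(0L, model$cutoffs)
  hi <- c(model$cutoffs - 1L, SCORE_MAX)
  tibble::tibble(
    stage = model$stage_names,
    band = ifelse(lo == hi, sprintf("%d", lo), sprintf("%d-%d", lo, hi))
  )
}

#' Assign scores to functional stages
#'
#' Stage index = number of retained cutoffs at or below the score, giving
#' bands \[0, c1), \[c1, c2), ..., \[cK, 300\]. For the two-cutoff model
#' (135, 192): below 135 light, 135-191 moderate, 192 and above high.
#'
#' @param score integer score vector, each in 0-300.
#' @param model a staging model from [run_stepwise()].
#' @return factor of stage labels (ordered low to high).
#' @export
#' @examples
#' m <- list(cutoffs = c(135, 192), stage_names = c("light", "moderate", "high"))
#' class(m) <- "clinstage_staging_model"
#' assign_stage(c(0, 134, 135, 191, 192, 300), m)
assign_stage <- function(score, model) {
  stopifnot(inherits(model, "clinstage_staging_model"))
  if (anyNA(score) || any(score < 0 | score > SCORE_MAX)) {
    stopf("scores must lie in 0-%d", SCORE_MAX,
          class = "clinstage_validation_error")
  }
  idx <- findInterval(score, model$cutoffs)  # count of cutoffs <= score
  factor(model$stage_names[idx + 1], levels = model$stage_names, ordered = TRUE)
}

#' Stage distribution of a cohort under a model
#'
#' @param x a [cohort()].
#' @param model a staging model from [run_stepwise()].
#' @return tibble with `stage`, `n`, `pct` (1 decimal); counts sum to the
#'   cohort size.
#' @export
stage_distribution <- function(x, model) {
  stopifnot(inherits(x, "clinstage_cohort"))
  stages <- assign_stage(x$clinfit_admission, model)
  tab <- table(stages)
  tibble::tibble(
    stage = factor(names(tab), levels = model$stage_names, ordered = TRUE),
    n = as.integer(tab),
    pct = round_half_up(100 * as.integer(tab) / nrow(x), 1)
  )
}
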