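# Report rendering: staging and descriptive reports as markdown plus a
# machine-readable JSON twin. Both renderings are produced from one
# rounded data structure, so every number in the markdown equals the
# corresponding JSON field.

fmt3 <- function(x) round_half_up(x, 3)
fmt1 <- function(x) round_half_up(x, 1)

md_table <- function(df) {
  if (nrow(df) == 0) return("(empty table)")
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) ifelse(is.na(col), "", format(col, trim = TRUE, scientific = FALSE))
    else ifelse(is.na(col), "", as.character(col))
  }, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, rule, body), collapse = "\n")
}

audit_presentation <- function(audit) {
  if (nrow(audit) == 0) return(audit)
  tibble::tibble(
    comparison = audit$label, n = audit$n_remaining, cutoff = audit$cutoff,
    tp = audit$tp, fp = audit$fp, tn = audit$tn, fn = audit$fn,
    se = fmt3(audit$sensitivity), sp = fmt3(audit$specificity),
    acc = fmt3(audit$accuracy), auc = fmt3(audit$auc),
    youden = fmt3(audit$youden),
    retained = audit$retained,
    forced = audit$forced,
    reason = audit$reason
  )
}

#' Render a staging report (markdown + JSON)
#'
#' Emits, per stratum: the step table in the published format (cutoff,
#' TP/FP/TN/FN, Se/Sp/Acc/AUC/Youden at 3 decimals, retained and dropped
#' steps with reasons), the stage bands and the stage distribution of the
#' cohort; for subgroup runs, a cross-stratum cutoff summary. A 1-stage
#' outcome is reported with an explicit warning line and an empty cutoff
#' table.
#'
#' @param x the [cohort()] the models were derived on (used for stage
#'   distributions).
#' @param results a staging model from [run_stepwise()] or the list
#'   returned by [run_subgroups()].
#' @param out_dir optional directory; when given, writes
#'   `<basename>.md` and `<basename>.json` there.
#' @param basename file stem used under `out_dir`.
#' @return invisibly, a list with `markdown` (character scalar) and
#'   `data` (the JSON-ready structure).
#' @export
report_staging <- function(x, results, out_dir = NULL, basename = "staging_report") {
  stopifnot(inherits(x, "clinstage_cohort"))
  if (inherits(results, "clinstage_staging_model")) {
    results <- list(overall = structure(
      list(stratum = "overall", factor = "overall", n = results$n, model = results),
      class = "clinstage_subgroup_result"))
  }
  plan_strata <- run_report_strata(x, results)

  data <- list(
    n = nrow(x),
    provenance = attr(x, "provenance") %||% "unspecified",
    criteria = unclass(results[[1]]$model$criteria),
    strata = plan_strata
  )
  lines <- c("# ClinFIT functional staging report", "",
             sprintf("Cohort: n = %d (%s)", data$n, data$provenance),
             sprintf("Retention criteria: separation >= %s points, AUC >= %s, Youden >= %s, min class size %s",
                     data$criteria$min_separation, data$criteria$min_auc,
                     data$criteria$min_youden, data$criteria$min_class_size), "")
  for (s in plan_strata) {
    lines <- c(lines, sprintf("## Stratum: %s (n = %d)", s$stratum, s$n), "")
    if (length(s$cutoffs) == 0) {
      lines <- c(lines, sprintf("WARNING: %s", s$warning), "", "(empty cutoff table)", "")
    } else {
      lines <- c(lines, sprintf("Retained cutoffs: %s",
                                paste(s$cutoffs, collapse = ", ")), "")
    }
    if (nrow(s$steps) > 0) {
      lines <- c(lines, "### Step table", md_table(s$steps), "")
    }
    if (nrow(s$stage_distribution) > 0) {
      lines <- c(lines, "### Stage distribution",
                 md_table(s$stage_distribution), "")
    }
  }
  if (length(plan_strata) > 1) {
    summary_rows <- dplyr::bind_rows(lapply(plan_strata, function(s) {
      tibble::tibble(stratum = s$stratum, n = s$n,
                     n_stages = length(s$cutoffs) + 1L,
                     cutoffs = paste(s$cutoffs, collapse = ", "))
    }))
    lines <- c(lines, "## Cutoffs across strata", md_table(summary_rows), "")
  }
  markdown <- paste(lines, collapse = "\n")
  write_report(markdown, data, out_dir, basename)
  invisible(list(markdown = markdown, data = data))
}

run_report_strata <- function(x, results) {
  lapply(unname(results), function(r) {
    m <- r$model
    steps <- audit_presentation(m$audit)
    dist <- if (nrow(stratum_rows(x, r)) > 0) {
      stage_distribution(stratum_cohort(x, r), m)
    } else {
      tibble::tibble()
    }
    list(
      stratum = r$stratum, n = r$n,
      cutoffs = m$cutoffs,
      stage_names = m$stage_names,
      warning = if (length(m$cutoffs) == 0)
        "no cutoff survived the retention criteria; single-stage model" else "",
      steps = steps,
      stage_distribution = {
        if (nrow(dist)) dist$stage <- as.character(dist$stage)
        dist
      }
    )
  })
}

stratum_rows <- function(x, r) {
  if (r$factor == "overall") return(x)
  stratum_cohort(x, r)
}

stratum_cohort <- function(x, r) {
  rows <- switch(r$factor,
    overall = seq_len(nrow(x)),
    sex = which(as.character(x$sex) == r$stratum),
    diagnosis = which(as.character(x$diagnosis) == r$stratum),
    age = {
      boundary <- as.numeric(sub(".*[<>=]+", "", r$stratum))
      if (grepl(">=", r$stratum)) which(x$age_years >= boundary)
      else which(x$age_years < boundary)
    }
  )
  out <- x[rows, ]
  attr(out, "provenance") <- attr(x, "provenance")
  class(out) <- class(x)
  out
}

#' Render a descriptive report (markdown + JSON)
#'
#' Table-I-style cohort description plus the paired admission-discharge
#' change section. When no discharge scores are available the paired
#' section is replaced by an explicit "not computable" note.
#'
#' @inheritParams report_staging
#' @return invisibly, list with `markdown` and `data`.
#' @export
report_descriptive <- function(x, out_dir = NULL, basename = "descriptive_report") {
  stopifnot(inherits(x, "clinstage_cohort"))
  summ <- describe_cohort(x)
  paired <- tryCatch(paired_change(x), error = function(e) NULL)

  paired_data <- if (is.null(paired)) {
    list(computable = FALSE, note = "paired change not computable (fewer than 2 complete pairs)")
  } else {
    list(computable = TRUE,
         n_pairs = paired$n_pairs, n_excluded = paired$n_excluded,
         mean_admission = fmt1(paired$mean_admission),
         mean_discharge = fmt1(paired$mean_discharge),
         mean_difference = fmt1(paired$mean_difference),
         sd_difference = fmt1(paired$sd_difference),
         t_statistic = fmt3(paired$t_statistic), df = paired$df,
         p_value = fmt3(paired$p_value),
         p_display = if (paired$p_value < 0.001) "< 0.001"
                     else as.character(fmt3(paired$p_value)),
         cohens_d = fmt3(paired$cohens_d),
         d_ci_low = fmt3(paired$d_ci_low), d_ci_high = fmt3(paired$d_ci_high),
         effect_band = paired$effect_band)
  }
  data <- list(
    n = summ$n, provenance = summ$provenance,
    categorical = summ$categorical,
    scores = summ$scores,
    paired_change = paired_data
  )
  lines <- c("# Cohort descriptive report", "",
             sprintf("Cohort: n = %d (%s)", summ$n, summ$provenance), "",
             "## Characteristics", md_table(summ$categorical), "",
             "## Scores", md_table(summ$scores), "",
             "## Admission to discharge change")
  if (!paired_data$computable) {
    lines <- c(lines, paired_data$note, "")
  } else {
    lines <- c(lines, md_table(tibble::as_tibble(
      paired_data[c("n_pairs", "n_excluded", "mean_difference", "sd_difference",
                    "t_statistic", "p_display", "cohens_d", "d_ci_low",
                    "d_ci_high", "effect_band")])), "")
  }
  markdown <- paste(lines, collapse = "\n")
  write_report(markdown, data, out_dir, basename)
  invisible(list(markdown = markdown, data = data))
}

write_report <- function(markdown, data, out_dir, basename) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  writeLines(markdown, file.path(out_dir, paste0(basename, ".md")))
  jsonlite::write_json(data, file.path(out_dir, paste0(basename, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
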