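# Table-I-style descriptive summary of a cohort.

#' Summarize a cohort's demographic and clinical characteristics
#'
#' Counts and percentages by sex, age band (below vs at-or-above the
#' boundary, 65 inclusive in the older band by default), diagnosis group
#' and TD level, plus mean/SD of the admission and discharge ClinFIT
#' scores. Percentages are computed over non-missing values within each
#' block; means and SDs are presented at 1 decimal.
#'
#' For a single record the sample SD is undefined; it is reported as 0.0
#' with a warning rather than `NA` so the summary stays total.
#'
#' @param x a [cohort()].
#' @param age_boundary age in years separating the two bands (default 65,
#'   the conventional working-age/older-adult split).
#' @return a `clinstage_summary`: list of tibbles (`categorical`, one row
#'   per block level with `n` and `pct`; `scores`, mean/SD per timepoint)
#'   with a print method.
#' @export
describe_cohort <- function(x, age_boundary = 65) {
  stopifnot(inherits(x, "clinstage_cohort"))
  if (nrow(x) == 0) stopf("cannot describe an empty cohort")

  block <- function(block_name, values) {
    keep <- !is.na(values)
    tab <- table(values[keep])
    tibble::tibble(
      block = block_name,
      level = names(tab),
      n = as.integer(tab),
      pct = round_half_up(100 * as.integer(tab) / sum(keep), 1)
    )
  }
  age_band <- factor(
    ifelse(x$age_years >= age_boundary,
           sprintf(">=%d", age_boundary), sprintf("<%d", age_boundary)),
    levels = c(sprintf("<%d", age_boundary), sprintf(">=%d", age_boundary))
  )
  categorical <- dplyr::bind_rows(
    block("sex", x$sex),
    block("age_band", age_band),
    block("diagnosis", x$diagnosis),
    block("td_level", factor(x$td_level, levels = 0:3))
  )

  score_row <- function(label, v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      return(tibble::tibble(measure = label, n = 0L, mean = NA_real_, sd = NA_real_))
    }
    s <- if (length(v) == 1) {
      warnf("SD undefined for n = 1 (%s); reporting 0.0", label)
      0
    } else {
      sd(v)
    }
    tibble::tibble(measure = label, n = length(v),
                   mean = round_half_up(mean(v), 1), sd = round_half_up(s, 1))
  }
  scores <- dplyr::bind_rows(
    score_row("clinfit_admission", x$clinfit_admission),
    score_row("clinfit_discharge", x$clinfit_discharge),
    score_row("age_years", x$age_years)
  )

  structure(
    list(n = nrow(x), categorical = categorical, scores = scores,
         age_boundary = age_boundary,
         provenance = attr(x, "provenance") %||% "unspecified"),
    class = "clinstage_summary"
  )
}

#' @export
print.clinstage_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d; %s)\n", x$n, x$provenance))
  for (b in unique(x$categorical$block)) {
    rows <- x$categorical[x$categorical$block == b, ]
    cat(sprintf("  %s: %s\n", b,
                paste(sprintf("%s %d (%.1f%%)", rows$level, rows$n, rows$pct),
                      collapse = ", ")))
  }
  for (i in seq_len(nrow(x$scores))) {
    r <- x$scores[i, ]
    cat(sprintf("  %s: mean %.1f (SD %.1f), n = %d\n",
                r$measure, r$mean, r$sd, r$n))
  }
  invisible(x)
}
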