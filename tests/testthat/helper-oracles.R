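# Independent oracles and small builders shared across tests.

# O(n^2) pair-counting AUC: P(score_pos > score_neg) + 0.5 P(tie)
auc_pairwise <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive Youden search over all 301 integer cutoffs, scalar arithmetic
# only; ties broken toward the smallest cutoff.
youden_exhaustive <- function(scores, labels) {
  labels <- as.logical(labels)
  best_cut <- NA_integer_
  best_j <- -Inf
  for (cut in 0:300) {
    pred <- scores >= cut
    se <- sum(pred & labels) / sum(labels)
    sp <- sum(!pred & !labels) / sum(!labels)
    j <- se + sp - 1
    if (j > best_j) {
      best_j <- j
      best_cut <- cut
    }
  }
  list(cutoff = best_cut, youden = best_j)
}

# random score/label instance with both classes guaranteed
random_instance <- function(n, seed) {
  withr::with_seed(seed, {
    labels <- c(TRUE, FALSE, as.logical(rbinom(n - 2, 1, runif(1, 0.2, 0.8))))
    shift <- runif(1, 0, 80)
    scores <- pmin(pmax(round(rnorm(n, 150 + shift * labels, 60)), 0), 300)
    list(scores = as.integer(scores), labels = sample(labels))
  })
}

# minimal valid cohort from parallel vectors
toy_cohort <- function(admission, td, discharge = NA_integer_,
                       sex = "male", diagnosis = "other", age = 60,
                       provenance = "toy") {
  n <- length(admission)
  cohort(tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    age_years = rep_len(age, n),
    sex = rep_len(sex, n),
    diagnosis = rep_len(diagnosis, n),
    clinfit_admission = as.integer(admission),
    clinfit_discharge = as.integer(rep_len(discharge, n)),
    td_level = as.integer(rep_len(td, n))
  ), provenance = provenance)
}
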