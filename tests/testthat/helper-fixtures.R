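# Shared in-code fixtures: small cohorts, hand-built count objects, and
# an independent brute-force oracle for the patient-vote aggregation
# rules.

# binned_counts with exactly `per_bin` in-range fragments per bin, all
# at one fragment size (deterministic coverage bookkeeping)
flat_counts <- function(n_bins, per_bin, size = 100, sample_id = "S1") {
  m <- matrix(as.integer(per_bin), nrow = n_bins, ncol = 1,
              dimnames = list(as.character(seq_len(n_bins)),
                              as.character(size)))
  binned_counts(sample_id, m, size_window = c(51, 250))
}

tiny_cohort <- function(n_healthy = 6, n_cancer = 6, seed = 42,
                        tumor_fraction = 0.35, bins_per_sample = 24,
                        fragments_per_bin = 1500) {
  generate_cohort(
    cohort_spec(n_healthy, n_cancer, bins_per_sample = bins_per_sample,
                fragments_per_bin = fragments_per_bin, seed = seed),
    cancer_params = profile_model_params(tumor_fraction = tumor_fraction))
}

# Brute-force vote-aggregation oracle, written independently of the
# package implementation: walks patients one by one and counts the
# confusion matrix directly from the stated rules.
oracle_vote_metrics <- function(votes_by_patient, truth,
                                mode = c("consensus", "majority")) {
  mode <- match.arg(mode)
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(votes_by_patient)) {
    v <- votes_by_patient[[i]]   # logical votes, TRUE = cancer
    is_cancer <- truth[i]
    if (mode == "consensus") {
      call <- if (all(v)) "cancer" else if (all(!v)) "healthy" else
        "undefined"
      if (call == "undefined") {
        # error of the patient's true class
        if (is_cancer) fn <- fn + 1 else fp <- fp + 1
        next
      }
    } else {
      call <- if (sum(v) > length(v) / 2) "cancer" else "healthy"
    }
    if (call == "cancer" && is_cancer) tp <- tp + 1
    if (call == "cancer" && !is_cancer) fp <- fp + 1
    if (call == "healthy" && !is_cancer) tn <- tn + 1
    if (call == "healthy" && is_cancer) fn <- fn + 1
  }
  n <- length(votes_by_patient)
  c(accuracy = 100 * (tp + tn) / n,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

# turn per-patient vote patterns into the flat subsample vectors the
# assessment functions consume (probabilities 0.9 / 0.1)
flatten_votes <- function(votes_by_patient, truth) {
  prob <- unlist(lapply(votes_by_patient,
                        function(v) ifelse(v, 0.9, 0.1)))
  labels <- rep(ifelse(truth, "cancer", "healthy"),
                lengths(votes_by_patient))
  pid <- rep(sprintf("P%02d", seq_along(votes_by_patient)),
             lengths(votes_by_patient))
  list(prob = prob, labels = labels, patient_id = pid)
}

# all (n_votes, cancer_votes, truth) single-patient configurations with
# odd vote counts up to 5
single_patient_configs <- function() {
  out <- list()
  for (nv in c(1L, 3L, 5L)) {
    for (cv in 0:nv) {
      for (truth in c(FALSE, TRUE)) {
        out[[length(out) + 1L]] <- list(n = nv, cancer = cv,
                                        truth = truth)
      }
    }
  }
  out
}
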