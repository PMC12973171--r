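# Classification metrics. Cancer is the positive class throughout; the
# decision threshold on predicted probabilities is 0.5, with exact ties
# classified as cancer (sensitivity-favoring, documented).

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling.
#'
#' @param scores Numeric scores, larger = more cancer-like.
#' @param labels Logical or 0/1 vector, `TRUE`/1 = cancer.
#' @return AUROC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auroc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Computed as `sum_k (R_k - R_{k-1}) P_k` over distinct score
#' thresholds in decreasing order, with tied scores processed as one
#' block.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`, or `NA` if no positives.
#' @export
auprc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y)
  if (n1 == 0 || all(y)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)  # block ends
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

threshold_votes <- function(prob, threshold = 0.5) prob >= threshold

confusion_metrics <- function(pred_cancer, true_cancer) {
  tp <- sum(pred_cancer & true_cancer)
  tn <- sum(!pred_cancer & !true_cancer)
  fp <- sum(pred_cancer & !true_cancer)
  fn <- sum(!pred_cancer & true_cancer)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = 100 * (tp + tn) / length(pred_cancer),
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

metrics_set <- function(cm, scores, labels) {
  data.frame(accuracy = cm$accuracy, sensitivity = cm$sensitivity,
             specificity = cm$specificity,
             auroc = auroc(scores, labels), auprc = auprc(scores, labels))
}

#' Subsample-level performance assessment
#'
#' Treats every subsample as an independent prediction: threshold
#' probabilities at 0.5 (ties to cancer) for accuracy / sensitivity /
#' specificity, and use the raw probabilities for AUROC / AUPRC.
#'
#' @param prob Predicted cancer probabilities, one per subsample.
#' @param labels Subsample class labels (`"cancer"`/`"healthy"`, logical
#'   or 0/1).
#' @return One-row `data.frame`: accuracy, sensitivity, specificity (in
#'   percent), auroc, auprc.
#' @export
assess_subsample <- function(prob, labels) {
  y <- normalize_labels(labels)
  cm <- confusion_metrics(threshold_votes(prob), y)
  metrics_set(cm, prob, y)
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "cancer"
  } else {
    as.logical(labels)
  }
}

patient_table <- function(prob, labels, patient_id) {
  stopifnot(length(prob) == length(labels),
            length(prob) == length(patient_id))
  y <- normalize_labels(labels)
  split_idx <- split(seq_along(prob), patient_id)
  data.frame(
    patient_id = names(split_idx),
    true_cancer = vapply(split_idx, function(i) y[i][1], logical(1)),
    n_votes = lengths(split_idx),
    cancer_votes = vapply(split_idx,
                          function(i) sum(threshold_votes(prob[i])),
                          numeric(1)),
    mean_prob = vapply(split_idx, function(i) mean(prob[i]), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Consensus-vote patient-level assessment
#'
#' A patient is classified only if all of its subsample votes agree;
#' otherwise the decision is `"undefined"`. Undefined healthy patients
#' count as false positives and undefined cancer patients as false
#' negatives, so indecision is always penalized. AUROC / AUPRC use the
#' patient score, defined here as the mean subsample probability.
#'
#' @param prob Subsample cancer probabilities.
#' @param labels Subsample class labels.
#' @param patient_id Patient identifier per subsample.
#' @return List with `decisions` (per-patient `data.frame` with
#'   `decision` in healthy/cancer/undefined and `score`) and `metrics`
#'   (one-row `data.frame` as in [assess_subsample()]).
#' @export
assess_consensus <- function(prob, labels, patient_id) {
  pt <- patient_table(prob, labels, patient_id)
  decision <- ifelse(pt$cancer_votes == pt$n_votes, "cancer",
                     ifelse(pt$cancer_votes == 0, "healthy", "undefined"))
  # undefined counts as an error of the patient's true class
  pred_cancer <- ifelse(decision == "undefined", !pt$true_cancer,
                        decision == "cancer")
  cm <- confusion_metrics(pred_cancer, pt$true_cancer)
  decisions <- data.frame(patient_id = pt$patient_id, decision = decision,
                          score = pt$mean_prob,
                          true_class = ifelse(pt$true_cancer, "cancer",
                                              "healthy"),
                          stringsAsFactors = FALSE)
  list(decisions = decisions,
       metrics = metrics_set(cm, pt$mean_prob, pt$true_cancer))
}

#' Majority-of-votes patient-level assessment
#'
#' Each patient is classified by strict majority of an odd number of
#' subsample votes (with 5 subsamples the minimum support for a call is
#' 3/5 = 60%). The patient score used for AUROC / AUPRC is the fraction
#' of cancer votes by default, or the mean subsample probability with
#' `score = "mean_prob"`.
#'
#' @inheritParams assess_consensus
#' @param score Patient score definition: `"vote_fraction"` (default)
#'   or `"mean_prob"`.
#' @return As [assess_consensus()]; decisions are never undefined.
#' @export
assess_majority <- function(prob, labels, patient_id,
                            score = c("vote_fraction", "mean_prob")) {
  score <- match.arg(score)
  pt <- patient_table(prob, labels, patient_id)
  if (any(pt$n_votes %% 2 == 0)) {
    fw_stop("every patient must have an odd number of votes (ties must be impossible)",
            "fragwave_parameter_error")
  }
  frac <- pt$cancer_votes / pt$n_votes
  pred_cancer <- frac > 0.5
  sc <- if (score == "vote_fraction") frac else pt$mean_prob
  cm <- confusion_metrics(pred_cancer, pt$true_cancer)
  decisions <- data.frame(patient_id = pt$patient_id,
                          decision = ifelse(pred_cancer, "cancer",
                                            "healthy"),
                          score = sc,
                          true_class = ifelse(pt$true_cancer, "cancer",
                                              "healthy"),
                          stringsAsFactors = FALSE)
  list(decisions = decisions, metrics = metrics_set(cm, sc, pt$true_cancer))
}
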