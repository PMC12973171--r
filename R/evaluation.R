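#' Patient-grouped stratified train-test split
#'
#' Assigns whole patients to train or test so that no patient's
#' subsamples ever straddle the split, stratifying by class crossed
#' with flowcell (when a `flowcell` column exists) so batch composition
#' stays consistent between the two sides. A stratum with a single
#' patient goes to train with a warning.
#'
#' @param metadata `data.frame` with `patient_id`, `class` and
#'   optionally `flowcell` (one row per patient).
#' @param test_fraction Fraction of patients held out (default 0.25).
#' @param seed Integer seed; the split is reproducible.
#' @return Object of class `split_plan`: `data.frame` `patient_id`,
#'   `class`, `set` (`"train"`/`"test"`), plus attributes.
#' @export
patient_split <- function(metadata, test_fraction = 0.25, seed = 1L) {
  stopifnot(all(c("patient_id", "class") %in% names(metadata)))
  assert_scalar_number(test_fraction, "test_fraction", 0, 0.9)
  md <- metadata[!duplicated(metadata$patient_id), , drop = FALSE]
  strata <- if ("flowcell" %in% names(md)) {
    paste(md$class, md$flowcell, sep = "|")
  } else md$class
  set <- rep("train", nrow(md))
  withr::with_seed(as.integer(seed), {
    for (st in unique(strata)) {
      idx <- which(strata == st)
      if (length(idx) < 2) {
        warning("stratum '", st, "' has a single patient; assigned to train")
        next
      }
      n_test <- round(test_fraction * length(idx))
      if (n_test > 0) set[sample(idx, n_test)] <- "test"
    }
  })
  structure(data.frame(patient_id = md$patient_id, class = md$class,
                       set = set, stringsAsFactors = FALSE),
            test_fraction = test_fraction, seed = as.integer(seed),
            class = c("split_plan", "data.frame"))
}

#' Patient-grouped stratified cross-validation folds
#'
#' @param metadata One row per patient with `patient_id`, `class`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Named integer vector: fold index per patient id.
#' @export
patient_folds <- function(metadata, k = 10, seed = 1L) {
  md <- metadata[!duplicated(metadata$patient_id), , drop = FALSE]
  if (k > nrow(md)) {
    fw_stop(sprintf("k = %d exceeds the number of patients (%d)", k,
                    nrow(md)), "fragwave_parameter_error")
  }
  fold <- setNames(integer(nrow(md)), md$patient_id)
  withr::with_seed(as.integer(seed), {
    for (cl in unique(md$class)) {
      idx <- which(md$class == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

model_seed <- function(base, split_i, retrain_j) {
  # deterministic seed grid; bounded well below .Machine$integer.max
  (as.integer(base) + 2000L + 100L * split_i + retrain_j) %% 2000000000L
}

train_any <- function(X, y, model, seed, dnn = dnn_spec(),
                      stopping = "rule1", groups = NULL) {
  if (model == "dnn") {
    train_dnn(X, y, spec = dnn, stopping = stopping, seed = seed,
              groups = groups)
  } else {
    train_baseline(X, y, kind = model, seed = seed)
  }
}

assess_all_methods <- function(prob, info_test) {
  rbind(
    cbind(method = "subsample",
          assess_subsample(prob, info_test$class)),
    cbind(method = "consensus",
          assess_consensus(prob, info_test$class,
                           info_test$patient_id)$metrics),
    cbind(method = "majority",
          assess_majority(prob, info_test$class,
                          info_test$patient_id)$metrics))
}

summarize_runs <- function(runs) {
  metrics <- c("accuracy", "sensitivity", "specificity", "auroc", "auprc")
  out <- list()
  for (meth in unique(runs$method)) {
    r <- runs[runs$method == meth, , drop = FALSE]
    med <- vapply(metrics, function(m) median(r[[m]], na.rm = TRUE),
                  numeric(1))
    # within-split IQR across retrains = model stochasticity;
    # IQR of split medians = data-composition variability
    per_split <- split(r, r$split)
    iqr_model <- vapply(metrics, function(m) {
      median(vapply(per_split,
                    function(d) IQR(d[[m]], na.rm = TRUE), numeric(1)),
             na.rm = TRUE)
    }, numeric(1))
    iqr_data <- vapply(metrics, function(m) {
      IQR(vapply(per_split,
                 function(d) median(d[[m]], na.rm = TRUE), numeric(1)),
          na.rm = TRUE)
    }, numeric(1))
    out[[meth]] <- data.frame(method = meth, metric = metrics,
                              median = med, iqr_model = iqr_model,
                              iqr_data = iqr_data, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Multi-split, multi-retrain experiment
#'
#' The full evaluation protocol: for each of `n_splits` patient-grouped
#' stratified train-test splits, the cohort is re-augmented with a
#' split-specific seed (so each split sees a different subsample
#' combination), the model is trained `n_retrains` times, and test
#' performance is computed under all three assessment methods
#' (subsample, consensus, majority). Seeds are derived from `base_seed`
#' as: split i uses `base_seed + i` for splitting, `base_seed + 1000 +
#' i` for augmentation, and retrain j uses `base_seed + 2000 + 100 i +
#' j` for training.
#'
#' @param cohort A `fragment_cohort` (or list with `counts`,
#'   `metadata`).
#' @param model `"dnn"`, `"rf"` or `"lr"`. Baseline models are
#'   deterministic enough to be retrained once per split unless
#'   `n_retrains_baseline` says otherwise.
#' @param features `"dwt"`, `"pmf"` or `"benchmark"`.
#' @param n_splits,n_retrains Evaluation grid (defaults 20, 20).
#' @param test_fraction Held-out patient fraction (default 0.25).
#' @param min_fragments Per-subsample fragment floor for augmentation.
#' @param cancer_target,healthy_choices Subsampling policy (see
#'   [plan_cohort_subsampling()]).
#' @param size_range PMF size range.
#' @param dwt [dwt_config()] when `features = "dwt"`.
#' @param dnn [dnn_spec()] when `model = "dnn"`.
#' @param stopping DNN stopping rule.
#' @param base_seed Base of the deterministic seed grid.
#' @param n_retrains_baseline Retrains for lr/rf models (default 1).
#' @return Object of class `experiment_report`: `runs` (one row per
#'   split x retrain x method), `summary` (medians and the two IQR
#'   summaries), `config`, `timing` (seconds per training).
#' @export
run_experiment <- function(cohort, model = c("dnn", "rf", "lr"),
                           features = c("dwt", "pmf", "benchmark"),
                           n_splits = 20, n_retrains = 20,
                           test_fraction = 0.25, min_fragments = 1e6,
                           cancer_target = 5, healthy_choices = c(3, 5),
                           size_range = c(51, 250), dwt = dwt_config(),
                           dnn = dnn_spec(), stopping = "rule1",
                           base_seed = 1L, n_retrains_baseline = 1) {
  model <- match.arg(model)
  features <- match.arg(features)
  md <- cohort$metadata
  plan <- plan_cohort_subsampling(cohort, cancer_target = cancer_target,
                                  healthy_choices = healthy_choices,
                                  min_fragments = min_fragments,
                                  size_range = size_range)
  nr <- if (model == "dnn") n_retrains else n_retrains_baseline
  runs <- list()
  t_train <- numeric(0)
  for (i in seq_len(n_splits)) {
    split <- patient_split(md, test_fraction, seed = as.integer(base_seed) + i)
    aug <- augment_cohort(cohort, plan, min_fragments = min_fragments,
                          size_range = size_range,
                          seed = as.integer(base_seed) + 1000L + i)
    Xall <- featurize_profiles(aug$profiles, kind = features, config = dwt)
    info <- aug$info
    tr <- info$patient_id %in% split$patient_id[split$set == "train"]
    te <- info$patient_id %in% split$patient_id[split$set == "test"]
    for (j in seq_len(nr)) {
      t0 <- proc.time()[["elapsed"]]
      fit <- train_any(Xall[tr, , drop = FALSE], info$class[tr], model,
                       seed = model_seed(base_seed, i, j), dnn = dnn,
                       stopping = stopping,
                       groups = info$patient_id[tr])
      t_train <- c(t_train, proc.time()[["elapsed"]] - t0)
      prob <- predict_prob(fit, Xall[te, , drop = FALSE])
      m <- assess_all_methods(prob, info[te, , drop = FALSE])
      runs[[length(runs) + 1L]] <- cbind(split = i, retrain = j, m)
    }
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  structure(list(runs = runs, summary = summarize_runs(runs),
                 config = list(model = model, features = features,
                               n_splits = n_splits, n_retrains = nr,
                               test_fraction = test_fraction,
                               min_fragments = min_fragments,
                               base_seed = as.integer(base_seed)),
                 timing = list(median_train_s = median(t_train),
                               total_train_s = sum(t_train))),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s/%s, %d splits x %d retrains\n",
              x$config$model, x$config$features, x$config$n_splits,
              x$config$n_retrains))
  s <- x$summary[x$summary$metric == "auroc", ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s median AUROC %.3f (IQR model %.3f, data %.3f)\n",
                s$method[i], s$median[i], s$iqr_model[i], s$iqr_data[i]))
  }
  invisible(x)
}

#' Patient-grouped k-fold cross-validation on one augmented dataset
#'
#' Uses a single fixed augmentation (train and test pooled), assigns
#' patients to stratified folds, and trains `n_retrains` models per
#' fold.
#'
#' @param X Feature matrix of the augmented dataset.
#' @param info Subsample metadata (`patient_id`, `class`) aligned with
#'   `X` rows.
#' @param k Number of folds (default 10).
#' @param n_retrains Model re-trainings per fold (default 1).
#' @param model,dnn,stopping As in [run_experiment()].
#' @param base_seed Seed for fold assignment and training.
#' @return `experiment_report` whose `runs` carry `split` = fold index.
#' @export
cross_validate <- function(X, info, k = 10, n_retrains = 1,
                           model = c("dnn", "rf", "lr"),
                           dnn = dnn_spec(), stopping = "rule1",
                           base_seed = 1L) {
  model <- match.arg(model)
  pat <- data.frame(patient_id = info$patient_id, class = info$class,
                    stringsAsFactors = FALSE)
  fold <- patient_folds(pat, k = k, seed = as.integer(base_seed))
  runs <- list()
  for (f in seq_len(k)) {
    te <- fold[info$patient_id] == f
    tr <- !te
    for (j in seq_len(n_retrains)) {
      fit <- train_any(X[tr, , drop = FALSE], info$class[tr], model,
                       seed = model_seed(base_seed, f, j), dnn = dnn,
                       stopping = stopping,
                       groups = info$patient_id[tr])
      prob <- predict_prob(fit, X[te, , drop = FALSE])
      m <- assess_all_methods(prob, info[te, , drop = FALSE])
      runs[[length(runs) + 1L]] <- cbind(split = f, retrain = j, m)
    }
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  structure(list(runs = runs, summary = summarize_runs(runs),
                 config = list(model = model, k = k,
                               n_retrains = n_retrains,
                               base_seed = as.integer(base_seed)),
                 timing = NULL),
            class = "experiment_report")
}

#' Region-ablation importance analysis
#'
#' Re-scores the classifier after zeroing out each named fragment-size
#' region of the PMF before the wavelet transform, using the same
#' cross-validation folds for the full signal and every ablation.
#' Region importance is ranked by the drop in median majority-vote
#' CV AUROC relative to the full signal.
#'
#' @param augmented An `augmented_set` from [augment_cohort()].
#' @param regions An [ablation_regions()] list.
#' @param k,n_retrains,model,dnn,stopping,base_seed As in
#'   [cross_validate()].
#' @param dwt [dwt_config()] applied to the (possibly ablated) signals.
#' @return List: `auroc` (data.frame signal x fold x retrain AUROC,
#'   majority method), `ranking` (signals by median AUROC drop),
#'   `reports` (full `experiment_report` per signal).
#' @export
ablation_experiment <- function(augmented, regions = ablation_regions(),
                                k = 10, n_retrains = 1,
                                model = c("dnn", "rf", "lr"),
                                dwt = dwt_config(), dnn = dnn_spec(),
                                stopping = "rule1", base_seed = 1L) {
  model <- match.arg(model)
  signals <- c("full", names(regions))
  reports <- list()
  for (sig in signals) {
    profs <- if (sig == "full") augmented$profiles else
      lapply(augmented$profiles, ablate_region, region = sig,
             regions = regions)
    X <- featurize_profiles(profs, kind = "dwt", config = dwt)
    reports[[sig]] <- cross_validate(X, augmented$info, k = k,
                                     n_retrains = n_retrains,
                                     model = model, dnn = dnn,
                                     stopping = stopping,
                                     base_seed = base_seed)
  }
  auroc_tab <- do.call(rbind, lapply(signals, function(sig) {
    r <- reports[[sig]]$runs
    r <- r[r$method == "majority", c("split", "retrain", "auroc")]
    cbind(signal = sig, r)
  }))
  med <- vapply(signals, function(sig) {
    median(auroc_tab$auroc[auroc_tab$signal == sig], na.rm = TRUE)
  }, numeric(1))
  drop <- med["full"] - med
  ranking <- data.frame(signal = signals, median_auroc = med,
                        auroc_drop = drop, row.names = NULL)
  ranking <- ranking[order(-ranking$auroc_drop), ]
  list(auroc = auroc_tab, ranking = ranking, reports = reports)
}
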