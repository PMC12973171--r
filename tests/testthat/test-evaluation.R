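test_that("patient splits are grouped, stratified, and reproducible", {
  md <- data.frame(patient_id = sprintf("P%02d", 1:8),
                   class = rep(c("healthy", "cancer"), each = 4),
                   stringsAsFactors = FALSE)
  sp <- patient_split(md, 0.25, seed = 3)
  expect_equal(sum(sp$set == "test"), 2)
  expect_equal(as.integer(table(sp$class[sp$set == "test"])), c(1L, 1L))
  expect_length(intersect(sp$patient_id[sp$set == "train"],
                          sp$patient_id[sp$set == "test"]), 0)
  expect_identical(sp, patient_split(md, 0.25, seed = 3))
  expect_false(identical(sp$set, patient_split(md, 0.25, seed = 4)$set))
})

test_that("a 153-patient cohort at fraction 0.25 holds out 38 patients", {
  md <- data.frame(
    patient_id = sprintf("P%03d", 1:153),
    class = rep(c("healthy", "cancer"), c(80, 73)),
    stringsAsFactors = FALSE)
  sp <- patient_split(md, 0.25, seed = 1)
  expect_equal(sum(sp$set == "test"), 38)
  expect_equal(sum(sp$set == "test" & sp$class == "healthy"), 20)
  expect_equal(sum(sp$set == "test" & sp$class == "cancer"), 18)
})

test_that("singleton strata fall back to train with a warning", {
  md <- data.frame(patient_id = c("A", "B", "C"),
                   class = c("healthy", "healthy", "cancer"),
                   stringsAsFactors = FALSE)
  expect_warning(sp <- patient_split(md, 0.5, seed = 1), "single patient")
  expect_equal(sp$set[sp$patient_id == "C"], "train")
})

test_that("cross-validation folds partition patients without leakage", {
  md <- data.frame(patient_id = sprintf("P%02d", 1:20),
                   class = rep(c("healthy", "cancer"), each = 10),
                   stringsAsFactors = FALSE)
  fold <- patient_folds(md, k = 10, seed = 2)
  expect_equal(as.integer(table(fold)), rep(2L, 10))
  expect_error(patient_folds(md, k = 30), class = "fragwave_parameter_error")
})

test_that("AUROC and AUPRC match the reference implementation and null behavior", {
  withr::with_seed(11, {
    y <- runif(300) < 0.4
    s <- runif(300) + y * 0.7
  })
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  # hand-enumerated average precision on a small case
  # scores 0.9(+) 0.8(-) 0.7(+) 0.6(+): AP = 1/3*(1 + 2/3 + 3/4)
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, TRUE)),
               (1 + 2 / 3 + 3 / 4) / 3)
  withr::with_seed(12, {
    y0 <- rep(c(TRUE, FALSE), 1000)
    s0 <- runif(2000)
  })
  expect_equal(auroc(s0, y0), 0.5, tolerance = 0.05)
  expect_true(is.na(auroc(1:3, c(TRUE, TRUE, TRUE))))
})

test_that("subsample assessment thresholds at 0.5 with ties to cancer", {
  m <- assess_subsample(c(0.9, 0.8, 0.1, 0.2), c("cancer", "cancer",
                                                 "healthy", "healthy"))
  expect_equal(m$accuracy, 100)
  expect_equal(m$auroc, 1)

  labels <- c("cancer", "cancer", "cancer", "healthy", "healthy")
  m2 <- assess_subsample(rep(0.5, 5), labels)
  expect_equal(m2$accuracy, 100 * mean(labels == "cancer"))
})

test_that("consensus calls require unanimity and penalize indecision", {
  r <- assess_consensus(rep(0.9, 5), rep("cancer", 5), rep("P1", 5))
  expect_equal(r$decisions$decision, "cancer")

  r2 <- assess_consensus(c(0.9, 0.9, 0.1, 0.9, 0.9), rep("cancer", 5),
                         rep("P1", 5))
  expect_equal(r2$decisions$decision, "undefined")
  expect_equal(r2$metrics$sensitivity, 0)  # the undefined cancer case is a FN

  # 2 healthy (one undefined) + 2 cancer correct:
  # specificity 50, sensitivity 100, accuracy 75
  prob <- c(0.1, 0.1, 0.1,   0.1, 0.9, 0.1,   0.9, 0.9, 0.9,  0.9, 0.9, 0.9)
  labels <- rep(c("healthy", "healthy", "cancer", "cancer"), each = 3)
  pid <- rep(c("H1", "H2", "C1", "C2"), each = 3)
  r3 <- assess_consensus(prob, labels, pid)
  expect_equal(r3$metrics$specificity, 50)
  expect_equal(r3$metrics$sensitivity, 100)
  expect_equal(r3$metrics$accuracy, 75)
})

test_that("majority voting uses strict majority of odd votes with vote-fraction scores", {
  r <- assess_majority(c(0.9, 0.9, 0.1, 0.9, 0.9), rep("cancer", 5),
                       rep("P1", 5))
  expect_equal(r$decisions$decision, "cancer")
  expect_equal(r$decisions$score, 0.8)

  r2 <- assess_majority(c(0.1, 0.2, 0.9), rep("healthy", 3), rep("P1", 3))
  expect_equal(r2$decisions$decision, "healthy")
  expect_equal(r2$decisions$score, 1 / 3)

  expect_error(assess_majority(c(0.9, 0.1), rep("cancer", 2), rep("P1", 2)),
               class = "fragwave_parameter_error")
})

test_that("vote aggregation matches exhaustive enumeration on every per-patient configuration", {
  # The confusion matrices of both methods are sums of per-patient
  # outcomes, so agreement on every (n_votes, cancer_votes, truth)
  # configuration plus additivity (checked below on random cohorts)
  # covers all multi-patient vote patterns.
  for (cfg in single_patient_configs()) {
    votes <- list(rep(c(TRUE, FALSE), c(cfg$cancer, cfg$n - cfg$cancer)))
    flat <- flatten_votes(votes, cfg$truth)
    cons <- assess_consensus(flat$prob, flat$labels, flat$patient_id)
    maj <- assess_majority(flat$prob, flat$labels, flat$patient_id)
    for (m in c("accuracy", "sensitivity", "specificity")) {
      expect_equal(cons$metrics[[m]],
                   unname(oracle_vote_metrics(votes, cfg$truth,
                                              "consensus")[m]))
      expect_equal(maj$metrics[[m]],
                   unname(oracle_vote_metrics(votes, cfg$truth,
                                              "majority")[m]))
    }
    # a defined consensus decision always equals the majority decision
    if (cons$decisions$decision != "undefined") {
      expect_identical(cons$decisions$decision, maj$decisions$decision)
    }
  }
})

test_that("vote aggregation matches the brute-force oracle on random multi-patient cohorts", {
  withr::with_seed(99, {
    for (rep_i in 1:300) {
      n_pat <- sample(2:4, 1)
      votes <- lapply(seq_len(n_pat), function(i) {
        nv <- sample(c(1, 3, 5), 1)
        sample(c(TRUE, FALSE), nv, replace = TRUE)
      })
      truth <- sample(c(TRUE, FALSE), n_pat, replace = TRUE)
      flat <- flatten_votes(votes, truth)
      cons <- assess_consensus(flat$prob, flat$labels, flat$patient_id)
      maj <- assess_majority(flat$prob, flat$labels, flat$patient_id)
      oc <- oracle_vote_metrics(votes, truth, "consensus")
      om <- oracle_vote_metrics(votes, truth, "majority")
      expect_equal(c(cons$metrics$accuracy, cons$metrics$sensitivity,
                     cons$metrics$specificity), unname(oc))
      expect_equal(c(maj$metrics$accuracy, maj$metrics$sensitivity,
                     maj$metrics$specificity), unname(om))
      # undefined accounting
      n_unan <- sum(vapply(votes, function(v)
        all(v) || all(!v), logical(1)))
      expect_equal(sum(cons$decisions$decision == "undefined"),
                   n_pat - n_unan)
    }
  })
})

test_that("a small experiment grid is structurally sound and seed-replayable", {
  co <- tiny_cohort(n_healthy = 6, n_cancer = 6, seed = 17)
  rep1 <- suppressWarnings(
    run_experiment(co, model = "lr", features = "benchmark",
                   n_splits = 2, n_retrains = 2, min_fragments = 3000,
                   base_seed = 9))
  expect_equal(nrow(rep1$runs), 2 * 1 * 3)  # baselines retrain once
  expect_true(all(c("subsample", "consensus", "majority") %in%
                  rep1$runs$method))
  # medians lie within per-run ranges
  s <- rep1$summary
  for (meth in unique(s$method)) {
    r <- rep1$runs[rep1$runs$method == meth, ]
    expect_gte(s$median[s$method == meth & s$metric == "auroc"],
               min(r$auroc))
    expect_lte(s$median[s$method == meth & s$metric == "auroc"],
               max(r$auroc))
  }
  rep2 <- suppressWarnings(
    run_experiment(co, model = "lr", features = "benchmark",
                   n_splits = 2, n_retrains = 2, min_fragments = 3000,
                   base_seed = 9))
  expect_identical(rep1$runs, rep2$runs)
})

test_that("cross-validation reports fold metrics without patient leakage", {
  co <- tiny_cohort(n_healthy = 6, n_cancer = 6, seed = 19)
  aug <- augment_cohort(co, 3, min_fragments = 3000, seed = 2)
  X <- featurize_profiles(aug$profiles, "benchmark")
  cv <- cross_validate(X, aug$info, k = 4, model = "lr", base_seed = 5)
  expect_equal(sort(unique(cv$runs$split)), 1:4)
  expect_true(all(is.finite(cv$runs$accuracy)))
  fold <- patient_folds(data.frame(patient_id = aug$info$patient_id,
                                   class = aug$info$class), k = 4,
                        seed = 5)
  expect_equal(length(fold), 12)
})
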