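test_that("rule 1 stops on a converged, stable loss window", {
  expect_true(stopping_rule_1(c(0.5, 0.3, 0.090, 0.091, 0.089, 0.090, 0.090)))
  # low mean but unstable window
  expect_false(stopping_rule_1(c(0.03, 0.07, 0.04, 0.06, 0.05)))
  # window not filled yet
  expect_false(stopping_rule_1(c(0.01, 0.01, 0.01)))
  # stable but not low enough
  expect_false(stopping_rule_1(c(0.2, 0.2, 0.2, 0.2, 0.2)))
})

test_that("rule 2 stops after five consecutive increases and rolls back five epochs", {
  dec <- stopping_rule_2(c(0.5, 0.4, 0.41, 0.42, 0.43, 0.44, 0.45))
  expect_true(dec$stop)
  expect_equal(dec$rollback_epoch, 2)
  # monotone decreasing never stops
  expect_false(stopping_rule_2(seq(1, 0.1, length.out = 50))$stop)
  # a streak of 4 broken by a decrease resets
  expect_false(stopping_rule_2(c(0.5, 0.51, 0.52, 0.53, 0.54, 0.50))$stop)
})

make_separable <- function(n_per_class = 60, p = 6, shift = 3, seed = 2) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
               matrix(rnorm(n_per_class * p, mean = shift), n_per_class))
    list(X = X, y = rep(c("healthy", "cancer"), each = n_per_class))
  })
}

test_that("training is deterministic given the seed and rejects bad input", {
  d <- make_separable()
  a <- train_dnn(d$X, d$y, dnn_spec(max_epochs = 30), seed = 5)
  b <- train_dnn(d$X, d$y, dnn_spec(max_epochs = 30), seed = 5)
  expect_identical(a$loss_history, b$loss_history)
  expect_identical(a$par, b$par)
  c_ <- train_dnn(d$X, d$y, dnn_spec(max_epochs = 30), seed = 6)
  expect_false(identical(a$loss_history, c_$loss_history))

  bad <- d$X; bad[1, 1] <- NA
  expect_error(train_dnn(bad, d$y), class = "fragwave_input_error")
  expect_error(train_dnn(d$X, d$y[-1]), class = "fragwave_input_error")
})

test_that("the network separates well-separated classes and rule 1 usually fires early", {
  d <- make_separable()
  # dropout off: the training-loss trajectory is smooth, so the
  # convergence rule can be exercised without stochastic loss jitter
  spec <- dnn_spec(dropout_rate = 0)
  fired <- 0; n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    fit <- train_dnn(d$X, d$y, spec, seed = s)
    expect_equal(auroc(predict_prob(fit, d$X), d$y == "cancer"), 1)
    if (!is.na(fit$stopped_at) && fit$stopped_at < fit$spec$max_epochs) {
      fired <- fired + 1
    }
  }
  expect_gte(fired, n_seeds - 1)
})

test_that("shuffled labels yield chance-level held-out discrimination", {
  d <- make_separable(n_per_class = 80)
  aurocs <- vapply(1:3, function(s) {
    y_perm <- withr::with_seed(100 + s, sample(d$y))
    tr <- c(1:60, 81:140); te <- setdiff(seq_along(y_perm), tr)
    fit <- train_dnn(d$X[tr, ], y_perm[tr], dnn_spec(max_epochs = 150),
                     seed = s)
    auroc(predict_prob(fit, d$X[te, ]), y_perm[te] == "cancer")
  }, numeric(1))
  expect_true(all(aurocs > 0.25 & aurocs < 0.75))
  expect_gt(mean(aurocs), 0.35)
  expect_lt(mean(aurocs), 0.65)
})

test_that("rule 2 training stops on rising validation loss and keeps a rollback state", {
  d <- make_separable(n_per_class = 40)
  fit <- train_dnn(d$X, d$y, dnn_spec(max_epochs = 100),
                   stopping = "rule2", seed = 3)
  expect_true(!is.null(fit$val_loss_history))
  expect_true(all(predict_prob(fit, d$X) >= 0 & predict_prob(fit, d$X) <= 1))
})

test_that("baseline models separate benchmark features of distinct classes", {
  profs <- function(tf, n, seed) {
    withr::with_seed(seed, {
      lapply(seq_len(n), function(i) {
        base <- make_class_pmf(profile_model_params(tumor_fraction = tf))
        noisy <- as.integer(rmultinom(1, 30000, base$values))
        compute_pmf(setNames(noisy, base$sizes))
      })
    })
  }
  tr_p <- c(profs(0, 25, 1), profs(0.3, 25, 2))
  te_p <- c(profs(0, 15, 3), profs(0.3, 15, 4))
  ytr <- rep(c("healthy", "cancer"), each = 25)
  yte <- rep(c("healthy", "cancer"), each = 15)
  Xtr <- featurize_profiles(tr_p, "benchmark")
  Xte <- featurize_profiles(te_p, "benchmark")

  rf <- train_baseline(Xtr, ytr, "rf", seed = 1)
  expect_gt(auroc(predict_prob(rf, Xte), yte == "cancer"), 0.9)
  lr <- train_baseline(Xtr, ytr, "lr", seed = 1)
  expect_gt(auroc(predict_prob(lr, Xte), yte == "cancer"), 0.9)

  # identical class distributions: chance-level
  null_tr <- c(profs(0, 25, 5), profs(0, 25, 6))
  null_te <- c(profs(0, 15, 7), profs(0, 15, 8))
  rf0 <- train_baseline(featurize_profiles(null_tr, "benchmark"), ytr,
                        "rf", seed = 1)
  a0 <- auroc(predict_prob(rf0, featurize_profiles(null_te, "benchmark")),
              yte == "cancer")
  expect_gt(a0, 0.25); expect_lt(a0, 0.75)
})

test_that("degenerate inputs: constant columns train, single-class labels do not", {
  d <- make_separable(n_per_class = 30)
  Xc <- cbind(d$X, constant = 1)
  expect_s3_class(train_baseline(Xc, d$y, "rf", seed = 1), "trained_model")
  expect_s3_class(train_dnn(Xc, d$y, dnn_spec(max_epochs = 10), seed = 1),
                  "trained_model")
  expect_error(train_baseline(d$X, rep("cancer", nrow(d$X)), "rf"),
               class = "fragwave_input_error")
})
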