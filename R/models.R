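#' Feed-forward network specification
#'
#' The classifier is a densely connected feed-forward network with
#' three hidden layers of 64, 32 and 16 neurons, leaky-ReLU activations
#' and per-layer dropout, trained full-batch with Adam on a binary
#' cross-entropy loss for at most 400 epochs. Dropout rate, learning
#' rate and the leaky-ReLU slope are conventional defaults surfaced
#' here as configuration.
#'
#' @param hidden_sizes Hidden layer widths (exactly three).
#' @param leaky_slope Negative-side slope of the leaky ReLU.
#' @param dropout_rate Dropout probability per hidden layer.
#' @param learning_rate Adam step size.
#' @param max_epochs Hard cap on training epochs (default 400).
#' @param batch_size Minibatch size; `Inf` (default) trains full-batch.
#' @return Object of class `dnn_spec`.
#' @export
dnn_spec <- function(hidden_sizes = c(64, 32, 16), leaky_slope = 0.01,
                     dropout_rate = 0.2, learning_rate = 1e-3,
                     max_epochs = 400, batch_size = Inf) {
  if (length(hidden_sizes) != 3L) {
    fw_stop("the network has exactly three hidden layers",
            "fragwave_parameter_error")
  }
  assert_scalar_number(leaky_slope, "leaky_slope", 0, 1)
  assert_scalar_number(dropout_rate, "dropout_rate", 0, 0.95)
  assert_scalar_number(learning_rate, "learning_rate", 1e-8)
  assert_scalar_number(max_epochs, "max_epochs", 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 leaky_slope = leaky_slope, dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = batch_size),
            class = "dnn_spec")
}

#' Training-loss convergence stopping rule ("rule 1")
#'
#' Stop when the training loss averaged over the last `window` epochs
#' drops below `loss_threshold` while its relative range
#' (`(max - min) / mean`) over the same window does not exceed
#' `relative_range_threshold`. Never stops before the window is filled.
#'
#' @param loss_history Numeric vector of per-epoch training losses.
#' @param window Number of trailing epochs examined (default 5).
#' @param loss_threshold Mean-loss threshold (default 0.1).
#' @param relative_range_threshold Maximum relative range (default
#'   0.15).
#' @return `TRUE` if training should stop.
#' @export
stopping_rule_1 <- function(loss_history, window = 5,
                            loss_threshold = 0.1,
                            relative_range_threshold = 0.15) {
  if (length(loss_history) < window) return(FALSE)
  last <- tail(loss_history, window)
  m <- mean(last)
  m < loss_threshold && (max(last) - min(last)) / m <= relative_range_threshold
}

#' Validation-loss early stopping ("rule 2")
#'
#' Stop after the validation loss has increased for `patience`
#' consecutive epochs; the model state from `patience` epochs before
#' the stop is the one to keep.
#'
#' @param val_loss_history Numeric vector of per-epoch validation
#'   losses.
#' @param patience Number of consecutive strict increases (default 5).
#' @return List `stop` (logical) and `rollback_epoch` (epoch index of
#'   the checkpoint to restore, `NA` when not stopping).
#' @export
stopping_rule_2 <- function(val_loss_history, patience = 5) {
  n <- length(val_loss_history)
  if (n < patience + 1) return(list(stop = FALSE, rollback_epoch = NA_integer_))
  inc <- diff(tail(val_loss_history, patience + 1)) > 0
  if (all(inc)) list(stop = TRUE, rollback_epoch = n - patience)
  else list(stop = FALSE, rollback_epoch = NA_integer_)
}

lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# numerically stable binary cross-entropy from logits
bce_from_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

mlp_init <- function(input_dim, hidden_sizes) {
  dims <- c(input_dim, hidden_sizes, 1L)
  W <- list(); b <- list()
  for (k in seq_len(length(dims) - 1L)) {
    W[[k]] <- matrix(rnorm(dims[k] * dims[k + 1L],
                           sd = sqrt(2 / dims[k])),
                     dims[k], dims[k + 1L])
    b[[k]] <- numeric(dims[k + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, spec, dropout = FALSE) {
  nl <- length(par$W)
  a <- X
  cache <- list(a0 = X, z = vector("list", nl), a = vector("list", nl),
                mask = vector("list", nl))
  for (k in seq_len(nl)) {
    z <- sweep(a %*% par$W[[k]], 2, par$b[[k]], "+")
    cache$z[[k]] <- z
    if (k < nl) {
      a <- lrelu(z, spec$leaky_slope)
      if (dropout && spec$dropout_rate > 0) {
        mask <- matrix(runif(length(a)) >= spec$dropout_rate,
                       nrow(a), ncol(a)) / (1 - spec$dropout_rate)
        a <- a * mask
        cache$mask[[k]] <- mask
      }
      cache$a[[k]] <- a
    } else {
      a <- z  # output logits
    }
  }
  cache$logits <- as.numeric(a)
  cache
}

mlp_backward <- function(par, cache, y, spec) {
  nl <- length(par$W)
  n <- length(y)
  gW <- vector("list", nl); gb <- vector("list", nl)
  p <- 1 / (1 + exp(-cache$logits))
  delta <- matrix((p - y) / n, n, 1)
  for (k in rev(seq_len(nl))) {
    a_prev <- if (k == 1) cache$a0 else cache$a[[k - 1]]
    gW[[k]] <- crossprod(a_prev, delta)
    gb[[k]] <- colSums(delta)
    if (k > 1) {
      delta <- delta %*% t(par$W[[k]])
      if (!is.null(cache$mask[[k - 1]])) delta <- delta * cache$mask[[k - 1]]
      delta <- delta * lrelu_grad(cache$z[[k - 1]], spec$leaky_slope)
    }
  }
  list(W = gW, b = gb)
}

adam_state <- function(par) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(par$W), vW = zero_like(par$W),
       mb = zero_like(par$b), vb = zero_like(par$b), t = 0)
}

adam_update <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (k in seq_along(par$W)) {
    st$mW[[k]] <- beta1 * st$mW[[k]] + (1 - beta1) * grad$W[[k]]
    st$vW[[k]] <- beta2 * st$vW[[k]] + (1 - beta2) * grad$W[[k]]^2
    par$W[[k]] <- par$W[[k]] -
      lr * (st$mW[[k]] / bc1) / (sqrt(st$vW[[k]] / bc2) + eps)
    st$mb[[k]] <- beta1 * st$mb[[k]] + (1 - beta1) * grad$b[[k]]
    st$vb[[k]] <- beta2 * st$vb[[k]] + (1 - beta2) * grad$b[[k]]^2
    par$b[[k]] <- par$b[[k]] -
      lr * (st$mb[[k]] / bc1) / (sqrt(st$vb[[k]] / bc2) + eps)
  }
  list(par = par, st = st)
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1  # constant columns pass through
  list(mu = mu, sd = sd)
}

apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

#' Train the feed-forward network
#'
#' Features are z-scored with statistics fitted on the training rows
#' only (leakage-safe); training runs until the chosen stopping rule
#' fires or `max_epochs` is reached. With `stopping = "rule2"` a
#' validation fraction is split off (patient-grouped when `groups` is
#' given) and the returned parameters are the checkpoint from five
#' epochs before the stop.
#'
#' @param X Numeric feature matrix (rows = subsamples).
#' @param y Labels (`"cancer"`/`"healthy"`, logical or 0/1).
#' @param spec A [dnn_spec()].
#' @param stopping `"rule1"` (training-loss convergence, default) or
#'   `"rule2"` (validation-loss early stopping).
#' @param seed Integer seed; training is deterministic given the seed.
#' @param groups Optional grouping vector (e.g. patient ids) used for
#'   the rule-2 validation split.
#' @param val_fraction Fraction split off for rule 2 (default 0.1).
#' @return Object of class `trained_model` (kind `"dnn"`) with the
#'   fitted parameters, the scaler, and the full `loss_history`
#'   (plus `val_loss_history` under rule 2).
#' @export
train_dnn <- function(X, y, spec = dnn_spec(), stopping = c("rule1", "rule2"),
                      seed = 1L, groups = NULL, val_fraction = 0.1) {
  stopping <- match.arg(stopping)
  X <- as.matrix(X)
  if (any(!is.finite(X))) {
    fw_stop("feature matrix contains non-finite values",
            "fragwave_input_error")
  }
  y <- as.numeric(normalize_labels(y))
  if (nrow(X) != length(y)) {
    fw_stop("feature rows and labels differ in length",
            "fragwave_input_error")
  }

  withr::with_seed(as.integer(seed), {
    val_idx <- integer(0)
    if (stopping == "rule2") {
      if (!is.null(groups)) {
        gs <- unique(groups)
        vg <- sample(gs, max(1, round(val_fraction * length(gs))))
        val_idx <- which(groups %in% vg)
      } else {
        val_idx <- sample(nrow(X), max(1, round(val_fraction * nrow(X))))
      }
    }
    tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
    sc <- fit_scaler(X[tr_idx, , drop = FALSE])
    Xtr <- apply_scaler(X[tr_idx, , drop = FALSE], sc)
    ytr <- y[tr_idx]
    Xval <- if (length(val_idx)) apply_scaler(X[val_idx, , drop = FALSE], sc)
    yval <- y[val_idx]

    par <- mlp_init(ncol(X), spec$hidden_sizes)
    st <- adam_state(par)
    loss_hist <- numeric(0)
    val_hist <- numeric(0)
    checkpoints <- list()  # ring buffer of the last 6 states (rule 2)
    stopped_at <- NA_integer_

    n <- nrow(Xtr)
    bs <- min(spec$batch_size, n)
    for (epoch in seq_len(spec$max_epochs)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      batch_losses <- numeric(0)
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        cache <- mlp_forward(par, Xtr[idx, , drop = FALSE], spec,
                             dropout = TRUE)
        batch_losses <- c(batch_losses,
                          bce_from_logits(cache$logits, ytr[idx]))
        grad <- mlp_backward(par, cache, ytr[idx], spec)
        upd <- adam_update(par, grad, st, spec$learning_rate)
        par <- upd$par; st <- upd$st
      }
      loss_hist <- c(loss_hist, mean(batch_losses))

      if (stopping == "rule1") {
        if (stopping_rule_1(loss_hist)) { stopped_at <- epoch; break }
      } else {
        vl <- bce_from_logits(mlp_forward(par, Xval, spec)$logits, yval)
        val_hist <- c(val_hist, vl)
        checkpoints <- c(checkpoints, list(par))
        if (length(checkpoints) > 6) checkpoints <- tail(checkpoints, 6)
        dec <- stopping_rule_2(val_hist)
        if (dec$stop) {
          par <- checkpoints[[max(1, length(checkpoints) - 5)]]
          stopped_at <- epoch
          break
        }
      }
    }

    structure(list(kind = "dnn", par = par, scaler = sc, spec = spec,
                   stopping = stopping, seed = as.integer(seed),
                   loss_history = loss_hist,
                   val_loss_history = if (length(val_hist)) val_hist,
                   stopped_at = stopped_at),
              class = "trained_model")
  })
}

#' Train a baseline classifier
#'
#' @param X Numeric feature matrix.
#' @param y Labels (`"cancer"`/`"healthy"`, logical or 0/1).
#' @param kind `"lr"` (logistic regression via `stats::glm`) or `"rf"`
#'   (random forest, 500 trees).
#' @param seed Integer seed (random forest).
#' @return Object of class `trained_model`.
#' @export
train_baseline <- function(X, y, kind = c("lr", "rf"), seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  y <- normalize_labels(y)
  if (length(unique(y)) < 2) {
    fw_stop("training labels contain a single class",
            "fragwave_input_error")
  }
  colnames(X) <- make.names(colnames(X) %||%
                              paste0("f", seq_len(ncol(X))), unique = TRUE)
  fit <- withr::with_seed(as.integer(seed), {
    if (kind == "lr") {
      d <- data.frame(y = as.numeric(y), X, check.names = FALSE)
      suppressWarnings(glm(y ~ ., data = d, family = binomial()))
    } else {
      randomForest::randomForest(x = X, y = factor(y, c(FALSE, TRUE)),
                                 ntree = 500)
    }
  })
  structure(list(kind = kind, fit = fit, features = colnames(X),
                 seed = as.integer(seed)),
            class = "trained_model")
}

#' Predicted cancer probabilities
#'
#' Pure function of the trained model and its input.
#'
#' @param model A `trained_model`.
#' @param X Feature matrix with the training-time columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, X) {
  stopifnot(inherits(model, "trained_model"))
  X <- as.matrix(X)
  if (model$kind == "dnn") {
    Xs <- apply_scaler(X, model$scaler)
    z <- mlp_forward(model$par, Xs, model$spec)$logits
    1 / (1 + exp(-z))
  } else if (model$kind == "lr") {
    colnames(X) <- model$features
    as.numeric(predict(model$fit,
                       newdata = as.data.frame(X, check.names = FALSE),
                       type = "response"))
  } else {
    colnames(X) <- model$features
    predict(model$fit, newdata = X, type = "prob")[, "TRUE"]
  }
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> kind=%s%s\n", x$kind,
              if (x$kind == "dnn")
                sprintf(", epochs=%d, final loss=%.4f",
                        length(x$loss_history),
                        tail(x$loss_history, 1))
              else ""))
  invisible(x)
}
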