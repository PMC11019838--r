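# Training schedule, combined loss, and the cascade-of-ten ensemble with
# hard-example pass-through.

#' Training configuration
#'
#' Schedule and loss hyper-parameters for one network: Adam at a starting
#' learning rate of 1e-3, at most 15 epochs with early stopping after 7
#' epochs without validation improvement. The loss is
#' `loss_mix * weighted BCE + (1 - loss_mix) * focal Tversky`; the Tversky
#' index weights false negatives by `tversky_alpha` and false positives by
#' `tversky_beta` (`alpha + beta = 1`), and the focal exponent is
#' `tversky_gamma`. The positive class weight defaults to the
#' negatives-to-positives ratio of the training set, recomputed per cascade
#' stage.
#'
#' @param learning_rate Adam learning rate.
#' @param max_epochs Maximum epochs.
#' @param early_stop_patience Epochs without improvement before stopping
#'   (must be < `max_epochs`).
#' @param positive_class_weight Weight on positive-example BCE terms;
#'   `NULL` means `n_neg / n_pos` of the training set.
#' @param tversky_alpha,tversky_beta False-negative / false-positive weights
#'   of the Tversky index (must sum to 1).
#' @param tversky_gamma Focal exponent.
#' @param loss_mix Mixing ratio in \[0, 1\]: 1 = pure weighted BCE, 0 = pure
#'   focal Tversky.
#' @param batch_size Minibatch size.
#' @param decision_threshold Score threshold for a positive call.
#' @param seed Integer seed controlling initialisation and shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, max_epochs = 15L,
                         early_stop_patience = 7L,
                         positive_class_weight = NULL,
                         tversky_alpha = 0.7, tversky_beta = 0.3,
                         tversky_gamma = 0.75, loss_mix = 0.5,
                         batch_size = 32L, decision_threshold = 0.5,
                         seed = 1L) {
  if (early_stop_patience >= max_epochs) {
    stop_invalid("`early_stop_patience` must be smaller than `max_epochs`")
  }
  if (abs(tversky_alpha + tversky_beta - 1) > 1e-8) {
    stop_invalid("`tversky_alpha + tversky_beta` must equal 1")
  }
  if (loss_mix < 0 || loss_mix > 1) stop_invalid("`loss_mix` must be in [0, 1]")
  if (!is.null(positive_class_weight) && positive_class_weight <= 0) {
    stop_invalid("`positive_class_weight` must be positive")
  }
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 positive_class_weight = positive_class_weight,
                 tversky_alpha = tversky_alpha, tversky_beta = tversky_beta,
                 tversky_gamma = tversky_gamma, loss_mix = loss_mix,
                 batch_size = as.integer(batch_size),
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Loss value and gradient with respect to the scores. The focal Tversky term
# is computed on soft scores over the whole batch.
combined_loss_grad <- function(scores, labels, config, pos_weight = 1) {
  n <- length(scores)
  eps <- 1e-12
  s <- pmin(pmax(scores, eps), 1 - eps)
  y <- labels
  w <- ifelse(y == 1, pos_weight, 1)
  bce <- -mean(w * (y * log(s) + (1 - y) * log(1 - s)))
  dbce <- -(w * (y / s - (1 - y) / (1 - s))) / n
  a <- config$tversky_alpha; b <- config$tversky_beta
  g <- config$tversky_gamma
  tp <- sum(s * y)
  fn <- sum((1 - s) * y)
  fp <- sum(s * (1 - y))
  den <- tp + a * fn + b * fp
  if (den < eps) {
    ti <- 1
    dti <- numeric(n)
  } else {
    ti <- tp / den
    dden <- y - a * y + b * (1 - y)
    dti <- (y * den - tp * dden) / den^2
  }
  ft <- (1 - ti)^g
  dft <- if (ti >= 1) numeric(n) else -g * (1 - ti)^(g - 1) * dti
  mix <- config$loss_mix
  list(loss = mix * bce + (1 - mix) * ft,
       dscore = mix * dbce + (1 - mix) * dft)
}

#' Combined weighted BCE + focal Tversky loss
#'
#' `loss_mix * weighted binary cross-entropy + (1 - loss_mix) * focal
#' Tversky`, where the focal Tversky term is `(1 - TI)^gamma` with the
#' Tversky index `TI = TP / (TP + alpha*FN + beta*FP)` computed on soft
#' scores over the batch. At `loss_mix = 1` this reduces to plain weighted
#' BCE, at `loss_mix = 0` to pure focal Tversky.
#'
#' @param scores Scores in (0, 1).
#' @param labels Binary labels (0/1).
#' @param config [train_config()].
#' @param pos_weight Weight applied to positive-example BCE terms.
#' @return Scalar loss.
#' @export
combined_loss <- function(scores, labels, config = train_config(),
                          pos_weight = 1) {
  if (length(scores) == 0L) stop_invalid("empty batch")
  if (length(scores) != length(labels)) stop_invalid("length mismatch")
  if (any(scores <= 0 | scores >= 1)) {
    stop_invalid("scores must lie strictly in (0, 1)")
  }
  combined_loss_grad(scores, labels, config, pos_weight)$loss
}

# Early-stopping bookkeeping: monitors (metric, loss); an epoch improves
# when the metric rises, or ties the best metric with a lower loss. Stop
# after `patience` consecutive epochs without improvement.
early_stopper <- function(patience) {
  best_metric <- -Inf
  best_loss <- Inf
  since <- 0L
  best_epoch <- 0L
  function(epoch, metric, loss) {
    improved <- metric > best_metric + 1e-12 ||
      (abs(metric - best_metric) <= 1e-12 && loss < best_loss - 1e-12)
    if (improved) {
      best_metric <<- metric
      best_loss <<- loss
      best_epoch <<- epoch
      since <<- 0L
    } else {
      since <<- since + 1L
    }
    list(improved = improved, stop = since >= patience,
         best_epoch = best_epoch)
  }
}

binary_metrics <- function(y, pred) {
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else 0
  list(sensitivity = sens, specificity = spec, precision = prec, f1 = f1)
}

#' Train a single network
#'
#' Trains one 1-D CNN for at most `max_epochs` epochs of minibatch Adam,
#' monitoring validation F1 (ties broken by lower validation loss) and
#' stopping early after `early_stop_patience` epochs without improvement.
#' The best-validation parameter state is returned. Deterministic given
#' `config$seed`.
#'
#' @param x_train,x_val Feature matrices (n x 297).
#' @param y_train,y_val Binary labels (1 = CTCC).
#' @param config [train_config()].
#' @param spec [network_spec()].
#' @return List with `net` (best state), `history` (per-epoch data frame),
#'   `stopped_epoch`, `best_epoch`, `pos_weight`.
#' @export
train_one <- function(x_train, y_train, x_val, y_val,
                      config = train_config(), spec = network_spec()) {
  classes <- unique(y_train)
  if (length(classes) < 2L) {
    missing_cls <- if (all(y_train == 1)) "NC (negative)" else "CTCC (positive)"
    stop_invalid("training set contains a single class; missing: ", missing_cls)
  }
  pos_weight <- config$positive_class_weight
  if (is.null(pos_weight)) pos_weight <- sum(y_train == 0) / sum(y_train == 1)
  with_seed(config$seed, {
    net <- cnn_init(spec, seed = stats::runif(1L, 1, .Machine$integer.max))
    state <- adam_init(net)
    stopper <- early_stopper(config$early_stop_patience)
    best_net <- net
    history <- vector("list", config$max_epochs)
    n <- nrow(x_train)
    stopped <- config$max_epochs
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        rows <- idx[start:min(start + config$batch_size - 1L, n)]
        fwd <- cnn_forward(net, x_train[rows, , drop = FALSE], keep_cache = TRUE)
        lg <- combined_loss_grad(fwd$scores, y_train[rows], config, pos_weight)
        grads <- cnn_backward(net, fwd, lg$dscore)
        stepped <- adam_step(net, grads, state, lr = config$learning_rate)
        net <- stepped$net
        state <- stepped$state
        batch_losses <- c(batch_losses, lg$loss)
      }
      val_scores <- cnn_forward(net, x_val)
      val_loss <- combined_loss_grad(val_scores, y_val, config, pos_weight)$loss
      val_pred <- as.integer(val_scores >= config$decision_threshold)
      vm <- binary_metrics(y_val, val_pred)
      history[[epoch]] <- data.frame(
        epoch = epoch, train_loss = mean(batch_losses), val_loss = val_loss,
        val_f1 = vm$f1, val_sensitivity = vm$sensitivity,
        val_specificity = vm$specificity)
      st <- stopper(epoch, vm$f1, val_loss)
      if (st$improved) best_net <- net
      if (st$stop) { stopped <- epoch; break }
    }
    history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
    list(net = best_net, history = history, stopped_epoch = stopped,
         best_epoch = utils::tail(history$epoch[history$val_f1 ==
                                                  max(history$val_f1)], 1L),
         pos_weight = pos_weight)
  })
}

#' Fit a cascaded ensemble of peak classifiers
#'
#' Trains an ordered sequence of up to `n_models` networks. Stage 1 trains
#' on the full training set; each later stage trains only on the previous
#' stage's hard examples — its training-set false positives, false negatives
#' and true positives, with the confidently rejected true negatives dropped
#' — so successive networks learn new boundaries between hard-to-discern NC
#' and CTCC peaks. Class weights are recomputed per stage. If a stage's
#' surviving training set collapses to a single class, the cascade is
#' truncated at the previous stage with a warning.
#'
#' @param x Training feature matrix (n x 297).
#' @param y Binary labels (1 = CTCC).
#' @param x_val,y_val Validation set (fixed across stages). If omitted, a
#'   stratified 20% split of the training data is used.
#' @param config [train_config()].
#' @param n_models Number of cascade stages, in \[1, 10\].
#' @param spec [network_spec()].
#' @return Object of class `peak_cascade`: list with `stages` (trained
#'   networks), `histories`, `stage_sizes` (per-stage training counts),
#'   `config`, `spec`.
#' @seealso [predict.peak_cascade()]
#' @export
cascade_train <- function(x, y, x_val = NULL, y_val = NULL,
                          config = train_config(), n_models = 10L,
                          spec = network_spec()) {
  if (n_models < 1L || n_models > 10L) {
    stop_invalid("`n_models` must be between 1 and 10")
  }
  if (is.null(x_val)) {
    hold <- with_seed(config$seed, {
      pos <- which(y == 1); neg <- which(y == 0)
      c(sample(pos, max(1L, round(0.2 * length(pos)))),
        sample(neg, max(1L, round(0.2 * length(neg)))))
    })
    x_val <- x[hold, , drop = FALSE]; y_val <- y[hold]
    x <- x[-hold, , drop = FALSE]; y <- y[-hold]
  }
  stages <- list()
  histories <- list()
  stage_sizes <- data.frame(stage = integer(0), n_train = integer(0),
                            n_positive = integer(0))
  cur_x <- x; cur_y <- y
  for (k in seq_len(n_models)) {
    if (length(unique(cur_y)) < 2L) {
      warning("cascade truncated at stage ", k - 1L,
              ": surviving training set has a single class")
      break
    }
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    fit <- train_one(cur_x, cur_y, x_val, y_val, cfg_k, spec)
    stages[[k]] <- fit$net
    histories[[k]] <- fit$history
    stage_sizes <- rbind(stage_sizes,
                         data.frame(stage = k, n_train = length(cur_y),
                                    n_positive = sum(cur_y == 1)))
    pred <- as.integer(cnn_forward(fit$net, cur_x) >= config$decision_threshold)
    keep <- !(pred == 0L & cur_y == 0L)   # drop true negatives only
    cur_x <- cur_x[keep, , drop = FALSE]
    cur_y <- cur_y[keep]
  }
  if (length(stages) == 0L) stop_invalid("no cascade stage could be trained")
  structure(list(stages = stages, histories = histories,
                 stage_sizes = stage_sizes, config = config, spec = spec),
            class = "peak_cascade")
}

#' Predict with a cascade ensemble
#'
#' Every example enters stage 1; only examples predicted positive proceed to
#' the next stage, and the final positives are those predicted positive by
#' every stage. The audit records the stage at which each rejected example
#' was dropped.
#'
#' @param object A `peak_cascade`.
#' @param x Feature matrix (n x 297).
#' @param type `"class"` for 0/1 predictions, `"audit"` for the full
#'   per-stage record.
#' @param n_stages Evaluate only the first `n_stages` stages (default all).
#' @param ... Unused.
#' @return For `"class"`, an integer vector. For `"audit"`, a list with
#'   `class`, `drop_stage` (NA for survivors) and `scores` (n x stages,
#'   NA once dropped).
#' @export
predict.peak_cascade <- function(object, x, type = c("class", "audit"),
                                 n_stages = length(object$stages), ...) {
  type <- match.arg(type)
  if (ncol(x) != object$spec$input_length) {
    stop_invalid("feature length ", ncol(x), " != expected ",
                 object$spec$input_length)
  }
  n <- nrow(x)
  n_stages <- min(n_stages, length(object$stages))
  alive <- rep(TRUE, n)
  drop_stage <- rep(NA_integer_, n)
  scores <- matrix(NA_real_, n, n_stages)
  thr <- object$config$decision_threshold
  for (k in seq_len(n_stages)) {
    idx <- which(alive)
    if (length(idx) == 0L) break
    s <- cnn_forward(object$stages[[k]], x[idx, , drop = FALSE])
    scores[idx, k] <- s
    rejected <- idx[s < thr]
    alive[rejected] <- FALSE
    drop_stage[rejected] <- k
  }
  cls <- as.integer(alive)
  if (type == "class") cls
  else list(class = cls, drop_stage = drop_stage, scores = scores)
}

#' @export
print.peak_cascade <- function(x, ...) {
  cat(sprintf("peak_cascade: %d stage(s), input length %d\n",
              length(x$stages), x$spec$input_length))
  print(x$stage_sizes, row.names = FALSE)
  invisible(x)
}

#' @export
summary.peak_cascade <- function(object, ...) {
  cat(sprintf("Cascaded peak classifier with %d stage(s)\n",
              length(object$stages)))
  cat(sprintf("  architecture: %d conv+pool blocks (channels %s), kernel %d, fc %d -> 1\n",
              length(object$spec$channel_widths),
              paste(object$spec$channel_widths, collapse = "-"),
              object$spec$kernel_size, object$spec$fc_in))
  for (k in seq_along(object$stages)) {
    h <- object$histories[[k]]
    best <- h[which.max(h$val_f1), ]
    cat(sprintf("  stage %d: trained on %d (%d positive), best val F1 %.3f at epoch %d\n",
                k, object$stage_sizes$n_train[k],
                object$stage_sizes$n_positive[k], best$val_f1, best$epoch))
  }
  invisible(object)
}

#' Plot cascade training-set sizes and class balance
#'
#' Stage-wise training-set size (log scale) and positive fraction: the
#' hard-example pass-through shrinks the training set while enriching the
#' positive class.
#'
#' @param x A `peak_cascade`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.peak_cascade <- function(x, ...) {
  ss <- x$stage_sizes
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(ss$stage, ss$n_train, type = "b", log = "y",
                 xlab = "cascade stage", ylab = "training examples",
                 main = "Cascade hard-example pass-through", ...)
  graphics::par(new = TRUE)
  graphics::plot(ss$stage, ss$n_positive / ss$n_train, type = "b", lty = 2,
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1), col = 2)
  graphics::axis(4, col.axis = 2)
  graphics::mtext("positive fraction", side = 4, line = 2.5, col = 2)
  invisible(x)
}
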