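CLASSES <- c("RH", "ND")   # column 1 of the score matrix is RH (positive)

#' Stratified hold-out split
#'
#' Disjoint train/validation/test index sets in the given proportions
#' (default 60/20/20), stratified by class: within each class the
#' train and validation counts are rounded to the nearest integer and the
#' remainder goes to the test set, so a 50/50-balanced set of 100 splits
#' 60/20/20 exactly.
#'
#' @param labels Character vector of per-sample class labels.
#' @param ratios Train/validation/test proportions summing to 1.
#' @param seed Integer RNG seed.
#' @param stratify Stratify by class (default TRUE; requires >= 5 samples
#'   per class).
#' @return List of integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
split_dataset <- function(labels, ratios = c(0.6, 0.2, 0.2), seed = 1L,
                          stratify = TRUE) {
  if (abs(sum(ratios) - 1) > 1e-8) {
    stop("split ratios must sum to 1", call. = FALSE)
  }
  set.seed(seed)
  split_one <- function(idx) {
    idx <- sample(idx)
    n <- length(idx)
    n_tr <- round(ratios[1] * n)
    n_va <- round(ratios[2] * n)
    list(train = idx[seq_len(n_tr)],
         val = idx[n_tr + seq_len(n_va)],
         test = idx[(n_tr + n_va + 1):n])
  }
  if (stratify) {
    if (any(table(labels) < 5)) {
      stop("stratified split needs at least 5 samples per class",
           call. = FALSE)
    }
    parts <- lapply(unique(labels), function(cl) {
      split_one(which(labels == cl))
    })
    list(train = sort(unlist(lapply(parts, `[[`, "train"))),
         val = sort(unlist(lapply(parts, `[[`, "val"))),
         test = sort(unlist(lapply(parts, `[[`, "test"))))
  } else {
    split_one(seq_along(labels))
  }
}

#' Build a classifier dataset from epochs or PSD features
#'
#' The \code{"time"} representation feeds ICA-cleaned epochs (channels x
#' samples) to the models; \code{"psd"} feeds the one-sided PSD bins as a
#' channels x frequency image.
#'
#' @param obj An \code{epoch_set} or \code{psd_features}.
#' @param representation \code{"time"} or \code{"psd"} (forced by the
#'   object type).
#' @return List: \code{x} (samples x channels x width array), \code{y}
#'   (labels), \code{representation}.
#' @export
model_dataset <- function(obj, representation = NULL) {
  if (inherits(obj, "epoch_set")) {
    list(x = obj$data, y = obj$labels, representation = "time")
  } else if (inherits(obj, "psd_features")) {
    list(x = obj$values, y = obj$labels, representation = "psd")
  } else {
    stop("expected an epoch_set or psd_features", call. = FALSE)
  }
}

model_init <- function(cfg, seed) {
  if (inherits(cfg, "eegnet_config")) eegnet_init(cfg, seed)
  else recurrent_init(cfg, seed)
}

model_fwd <- function(cfg, params, x, mode) {
  if (inherits(cfg, "eegnet_config")) {
    eegnet_forward(x, cfg, params, mode)
  } else {
    out <- recurrent_forward(x, cfg, params)
    list(scores = out$scores, params = params, cache = out$cache)
  }
}

model_bwd <- function(cfg, params, cache, dscores) {
  if (inherits(cfg, "eegnet_config")) eegnet_backward(dscores, cache)
  else recurrent_backward(dscores, cfg, params, cache)
}

## trainable leaves, shaped like the gradients
trainable_of <- function(cfg, params) {
  if (inherits(cfg, "eegnet_config")) {
    list(conv1 = params$conv1,
         bn1 = params$bn1[c("gamma", "beta")],
         dw = params$dw,
         bn2 = params$bn2[c("gamma", "beta")],
         pw = params$pw,
         bn3 = params$bn3[c("gamma", "beta")],
         dense = params$dense)
  } else {
    params
  }
}

merge_trainable <- function(params, upd) {
  for (nm in names(upd)) {
    if (is.list(upd[[nm]])) {
      params[[nm]] <- merge_trainable(params[[nm]], upd[[nm]])
    } else {
      params[[nm]] <- upd[[nm]]
    }
  }
  params
}

eval_scores <- function(cfg, params, x, chunk = 128L) {
  n <- dim(x)[1]
  out <- NULL
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    sc <- model_fwd(cfg, params, x[s:e, , , drop = FALSE], "eval")$scores
    out <- rbind(out, sc)
  }
  out
}

scores_to_labels <- function(scores) {
  ## ties resolve to ND
  ifelse(scores[, 1] > scores[, 2], "RH", "ND")
}

#' Train a classifier
#'
#' Minimizes class-weighted softmax cross-entropy with Adam. When a
#' validation set is given, the best-validation-accuracy parameters are
#' kept and training stops early after \code{patience} epochs without
#' improvement. Deterministic under \code{seed} (single-threaded BLAS).
#'
#' @param cfg An \code{\link{eegnet_config}} or
#'   \code{\link{recurrent_config}}.
#' @param train,val Datasets from \code{\link{model_dataset}} (\code{val}
#'   optional).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Training epoch cap.
#' @param patience Early-stopping patience (epochs).
#' @param seed Integer RNG seed (initialization, shuffling, dropout).
#' @param verbose Print per-epoch progress.
#' @return List of class \code{trained_model}: \code{config},
#'   \code{params}, \code{history} (per-epoch loss and accuracy),
#'   \code{representation}, \code{classes}, \code{seed}.
#' @export
train_model <- function(cfg, train, val = NULL, lr = 1e-3, batch_size = 32,
                        max_epochs = 100, patience = 10, seed = 1L,
                        verbose = FALSE) {
  stopifnot(inherits(cfg, "model_config"))
  if (length(train$y) == 0) stop("empty training set", call. = FALSE)
  set.seed(seed)
  params <- model_init(cfg, seed)
  y <- match(train$y, CLASSES)
  if (any(is.na(y))) stop("labels must be RH or ND", call. = FALSE)
  ## inverse-frequency class weights, mean 1
  cw <- length(y) / (length(CLASSES) * pmax(tabulate(y, 2), 1))
  tr_view <- trainable_of(cfg, params)
  opt <- adam_init(tr_view)
  n <- length(y)
  best <- list(acc = -Inf, params = params, epoch = 0)
  history <- NULL
  wait <- 0
  for (ep in seq_len(max_epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (s in seq(1, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      if (length(idx) < 2) next   # batch norm needs >= 2 in train mode
      fw <- model_fwd(cfg, params, train$x[idx, , , drop = FALSE], "train")
      params <- fw$params
      ls <- softmax_xent(fw$scores, y[idx], cw)
      if (!is.finite(ls$loss)) {
        stop("training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      }
      losses <- c(losses, ls$loss)
      grads <- model_bwd(cfg, params, fw$cache, ls$dscores)
      upd <- adam_step(trainable_of(cfg, params), grads, opt, lr = lr)
      opt <- upd$state
      params <- merge_trainable(params, upd$params)
    }
    val_acc <- NA_real_
    if (!is.null(val)) {
      pred <- scores_to_labels(eval_scores(cfg, params, val$x))
      val_acc <- mean(pred == val$y)
      if (val_acc > best$acc + 1e-12) {
        best <- list(acc = val_acc, params = params, epoch = ep)
        wait <- 0
      } else {
        wait <- wait + 1
      }
    }
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = mean(losses),
                                val_acc = val_acc))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val_acc %s", ep, mean(losses),
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
    if (!is.null(val) && wait >= patience) break
  }
  if (!is.null(val)) params <- best$params
  structure(list(config = cfg, params = params, history = history,
                 representation = train$representation,
                 classes = CLASSES, seed = seed),
            class = "trained_model")
}

#' Predict class labels
#'
#' Argmax over class scores; exact ties resolve to ND.
#'
#' @param object A \code{trained_model}.
#' @param newdata A \code{\link{model_dataset}} (representation must match
#'   training) or a bare samples x channels x width array.
#' @param ... Unused.
#' @return List: \code{labels} (RH/ND), \code{scores} (samples x 2,
#'   columns RH, ND).
#' @export
predict.trained_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.null(newdata$representation)) {
    if (!identical(newdata$representation, object$representation)) {
      stop("model was trained on '", object$representation,
           "' input but got '", newdata$representation, "'", call. = FALSE)
    }
    x <- newdata$x
  } else {
    x <- newdata
  }
  scores <- eval_scores(object$config, object$params, x)
  colnames(scores) <- CLASSES
  list(labels = scores_to_labels(scores), scores = scores)
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model>", class(x$config)[1],
      sprintf("(%s representation, seed %d)\n", x$representation, x$seed))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epochs, final loss %.4f, best val acc %s\n",
                nrow(x$history), last$train_loss,
                ifelse(all(is.na(x$history$val_acc)), "-",
                       sprintf("%.3f", max(x$history$val_acc, na.rm = TRUE)))))
  }
  invisible(x)
}
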