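#' Train the sweep-category classifier
#'
#' Trains the convolutional network on normalized feature arrays with
#' minibatch Adam, a validation split for early stopping (patience on
#' validation loss, best weights restored) and a fixed seed for
#' reproducibility, then evaluates on the held-out test set.
#'
#' @param train,test lists with `x` (n x statistics x subwindows array)
#'   and `y` (factor with levels neutral/shared/divergent), e.g. from
#'   [featurize_instances()].
#' @param max_epochs training epoch cap (default 100).
#' @param seed RNG seed (initialization, shuffling, validation split).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience in epochs.
#' @param val_frac validation fraction of the training set.
#' @param f1,f2,hidden layer widths.
#' @param weight_decay L2 penalty.
#' @param dropout dropout rate on the dense hidden layer (training
#'   only).
#' @param augment_flip also present every training matrix reversed
#'   along the subwindow axis (valid because the selected site is drawn
#'   symmetrically around the locus centre).
#' @param n_ensemble number of networks trained from different
#'   initialization seeds; posteriors are averaged (default 3).
#' @return object of class `sweep_classifier`: weights, architecture,
#'   class order, feature layout, training history and the test
#'   `report` (confusion matrix, per-class precision/recall, balanced
#'   and neutral-vs-selected accuracy).
#' @export
train_classifier <- function(train, test, max_epochs = 100L, seed = 1L,
                             batch_size = 32L, lr = 3e-4,
                             patience = 25L, val_frac = 0.15,
                             f1 = 96L, f2 = 96L, hidden = 96L,
                             weight_decay = 1e-3, dropout = 0.6,
                             augment_flip = TRUE, n_ensemble = 3L) {
  if (n_ensemble > 1L) {
    members <- lapply(seq_len(n_ensemble), function(k)
      train_classifier(train, test, max_epochs = max_epochs,
                       seed = seed + 101L * (k - 1L),
                       batch_size = batch_size, lr = lr,
                       patience = patience, val_frac = val_frac,
                       f1 = f1, f2 = f2, hidden = hidden,
                       weight_decay = weight_decay, dropout = dropout,
                       augment_flip = augment_flip, n_ensemble = 1L))
    model <- members[[1]]
    model$members <- members
    model$report <- evaluate_classifier(model, test)
    return(model)
  }
  classes <- levels(train$y)
  present <- classes %in% unique(as.character(train$y))
  if (!all(present))
    stop("class missing from training set: ",
         paste(classes[!present], collapse = ", "))
  d <- dim(train$x)
  set.seed(seed)
  par <- cnn_init(C = d[2], L = d[3], n_classes = length(classes),
                  f1 = f1, f2 = f2, hidden = hidden)
  # input standardization: sum-normalized rows of signed statistics can
  # explode when the row sum is near zero; z-score each cell on the
  # training set and clip, storing the transform with the model
  prep <- list(center = apply(train$x, c(2, 3), mean),
               scale = pmax(apply(train$x, c(2, 3), sd), 1e-8),
               clip = 5)
  train <- list(x = prep_apply(prep, train$x), y = train$y)
  test <- list(x = prep_apply(prep, test$x), y = test$y)
  n <- d[1]
  n_val <- max(1L, round(val_frac * n))
  perm <- sample.int(n)
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  Xtr <- train$x[tr_idx, , , drop = FALSE]
  Ytr <- onehot(train$y[tr_idx], length(classes))
  Xval <- train$x[val_idx, , , drop = FALSE]
  Yval <- onehot(train$y[val_idx], length(classes))
  if (augment_flip) {
    # the selected site is drawn symmetrically around the locus centre,
    # so reversing the subwindow axis yields an equally valid instance
    Xtr <- abind_first(Xtr, Xtr[, , rev(seq_len(dim(Xtr)[3])),
                                drop = FALSE])
    Ytr <- rbind(Ytr, Ytr)
  }
  ntr_all <- dim(Xtr)[1]
  st <- adam_init(par)
  best <- list(loss = Inf, par = par, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  ntr <- ntr_all
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(ntr)
    ep_loss <- 0
    nb <- 0L
    for (b0 in seq(1L, ntr, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, ntr)]
      Xb <- Xtr[idx, , , drop = FALSE]
      Yb <- Ytr[idx, , drop = FALSE]
      cache <- cnn_forward(par, Xb, keep = TRUE, dropout = dropout)
      ep_loss <- ep_loss + cross_entropy(cache$probs, Yb)
      nb <- nb + 1L
      grads <- cnn_backward(par, Xb, Yb, cache, weight_decay)
      upd <- adam_step(par, grads, st, lr = lr)
      par <- upd$par
      st <- upd$st
      par$arch <- upd$par$arch
    }
    val_loss <- cross_entropy(cnn_forward(par, Xval), Yval)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                val_loss = val_loss))
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, par = par, epoch = epoch)
    } else if (epoch - best$epoch >= patience) {
      break
    }
  }
  par <- best$par
  model <- structure(
    list(par = par, classes = classes, prep = prep,
         layout = list(stat_names = stat_set_names(), C = d[2], L = d[3]),
         history = history, best_epoch = best$epoch, seed = seed),
    class = "sweep_classifier")
  model$report <- evaluate_classifier(model, test)
  model
}

abind_first <- function(a, b) {
  d <- dim(a)
  out <- array(0, dim = c(d[1] + dim(b)[1], d[2], d[3]))
  out[seq_len(d[1]), , ] <- a
  out[d[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

prep_apply <- function(prep, x) {
  n <- dim(x)[1]
  for (i in seq_len(n)) {
    z <- (x[i, , ] - prep$center) / prep$scale
    x[i, , ] <- pmin(pmax(z, -prep$clip), prep$clip)
  }
  x
}

#' Posterior class probabilities for feature arrays
#' @param model a `sweep_classifier`.
#' @param x n x statistics x subwindows array (layout checked).
#' @return n x classes probability matrix.
#' @export
predict_posteriors <- function(model, x) {
  if (length(dim(x)) == 2L) x <- array(x, dim = c(1L, dim(x)))
  if (dim(x)[2] != model$layout$C || dim(x)[3] != model$layout$L)
    stop("feature layout does not match the trained model")
  if (!is.null(model$members)) {
    p <- Reduce(`+`, lapply(model$members, function(m) {
      xm <- if (is.null(m$prep)) x else prep_apply(m$prep, x)
      cnn_forward(m$par, xm)
    })) / length(model$members)
  } else {
    if (!is.null(model$prep)) x <- prep_apply(model$prep, x)
    p <- cnn_forward(model$par, x)
  }
  colnames(p) <- model$classes
  p
}

#' Evaluate a classifier on a labelled set
#'
#' @param model a `sweep_classifier`.
#' @param test list with `x` and `y`.
#' @return list: confusion matrix, per-class precision/recall, overall,
#'   balanced and neutral-vs-selected binary accuracy.
#' @export
evaluate_classifier <- function(model, test) {
  probs <- predict_posteriors(model, test$x)
  pred <- factor(model$classes[max.col(probs, ties.method = "first")],
                 levels = model$classes)
  truth <- factor(as.character(test$y), levels = model$classes)
  cm <- table(truth = truth, predicted = pred)
  recall <- diag(cm) / pmax(rowSums(cm), 1L)
  precision <- diag(cm) / pmax(colSums(cm), 1L)
  bin_truth <- truth != "neutral"
  bin_pred <- pred != "neutral"
  list(confusion = cm, precision = precision, recall = recall,
       accuracy = mean(pred == truth),
       balanced_accuracy = mean(recall),
       n_correct = sum(pred == truth), n = length(truth),
       binary_accuracy = mean(bin_truth == bin_pred))
}

#' Classify feature matrices into selection categories
#'
#' Applies the trained network to a stream of feature matrices and
#' returns per-window posteriors, the argmax call and its support. A
#' window is asserted to be in a category at the support threshold only
#' when its posterior reaches `support_threshold` (reported per class in
#' the `supported` column for the called class).
#'
#' @param model a `sweep_classifier`.
#' @param features list of `feature_matrix` objects (with `meta`).
#' @param support_threshold posterior needed to assert a call (default
#'   0.99).
#' @return data.frame: window coordinates, class posteriors, `call`,
#'   `support`, `supported`.
#' @export
predict_windows <- function(model, features, support_threshold = 0.99) {
  if (inherits(features, "feature_matrix")) features <- list(features)
  n <- length(features)
  x <- array(0, dim = c(n, model$layout$C, model$layout$L))
  for (i in seq_len(n)) {
    v <- features[[i]]$values
    if (!all(dim(v) == c(model$layout$C, model$layout$L)))
      stop("feature layout does not match the trained model")
    x[i, , ] <- v
  }
  probs <- predict_posteriors(model, x)
  meta <- do.call(rbind, lapply(features, function(f) {
    data.frame(chrom = f$meta$chrom, start = f$meta$start,
               end = f$meta$end, center_start = f$meta$center_start,
               center_end = f$meta$center_end)
  }))
  call_idx <- max.col(probs, ties.method = "first")
  support <- probs[cbind(seq_len(n), call_idx)]
  out <- cbind(meta, as.data.frame(probs))
  names(out)[(ncol(meta) + 1L):ncol(out)] <-
    paste0("p_", model$classes)
  out$call <- model$classes[call_idx]
  out$support <- support
  out$supported <- support >= support_threshold
  out
}

#' Serialize / restore a trained classifier
#'
#' The weights, class order and feature-layout configuration are stored
#' together so a reloaded model refuses mismatched features and
#' reproduces posteriors exactly.
#'
#' @param model a `sweep_classifier`.
#' @param path file path (.rds).
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "sweep_classifier")) stop("not a sweep_classifier")
  m
}
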