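# Training and evaluation protocol: weighted cross-entropy minimized with
# Adam under per-pass augmentation, model selection on a validation set,
# stratified chronological k-fold cross-validation with per-gain noisy
# test sets, per-class/macro metrics, and one-sided Mann-Whitney
# comparison between runs.

#' Training configuration
#'
#' @param max_epochs maximum training passes (default 1000).
#' @param learning_rate Adam step size (default 1e-4).
#' @param batch_size minibatch size (default 128).
#' @param selection_metric validation metric choosing the returned weights:
#'   `"mf1"` (default), `"acc"` or `"loss"`.
#' @param seed integer seed for shuffling and initialization.
#' @return An object of class `wb_train_config`.
#' @export
train_config <- function(max_epochs = 1000L, learning_rate = 1e-4,
                         batch_size = 128L,
                         selection_metric = c("mf1", "acc", "loss"),
                         seed = 1L) {
  stopifnot(max_epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 optimizer = "adam",
                 batch_size = as.integer(batch_size),
                 selection_metric = match.arg(selection_metric),
                 seed = as.integer(seed)),
            class = "wb_train_config")
}

#' Inverse-frequency class weights for the cross-entropy loss
#'
#' Weight of class c is proportional to `1/count_c`, normalized so the
#' weights average to 1; rarer classes contribute more to the loss,
#' counteracting class imbalance.
#'
#' @param counts positive per-class example counts.
#' @return Numeric weights with mean 1.
#' @export
compute_class_weights <- function(counts) {
  if (any(counts <= 0)) stop("missing class: every class needs a positive count")
  w <- 1 / counts
  w / mean(w)
}

#' Random over-sampling to the per-dataset maximum class count
#'
#' Within each (dataset, class) group, examples are duplicated uniformly
#' at random until every class in that dataset reaches the dataset's
#' largest class count. Applied before merging heterogeneous datasets.
#'
#' @param epochs a labeled [wb_epochs()].
#' @param dataset optional character vector tagging each epoch's source
#'   dataset (default: one dataset).
#' @return A [wb_epochs()] with duplicated rows appended.
#' @export
random_oversample <- function(epochs, dataset = NULL) {
  lab <- epochs$info$label
  if (anyNA(lab)) stop("random_oversample requires labeled epochs")
  ds <- if (is.null(dataset)) rep("d", n_epochs(epochs)) else as.character(dataset)
  keep <- seq_len(n_epochs(epochs))
  extra <- integer(0)
  for (d in unique(ds)) {
    di <- which(ds == d)
    counts <- table(lab[di])
    target <- max(counts)
    for (cl in names(counts)) {
      ci <- di[lab[di] == as.integer(cl)]
      deficit <- target - length(ci)
      if (deficit > 0L)
        extra <- c(extra, ci[sample.int(length(ci), deficit, replace = TRUE)])
    }
  }
  epochs[c(keep, extra)]
}

#' Stratified chronological k-fold splits
#'
#' Within each class, epochs are ordered by recording timestamp (ties
#' broken by source id) and partitioned into `k` chronologically
#' contiguous parts of near-equal size, never splitting one source
#' recording across parts so train, validation and test never share a
#' recording. Fold `i` takes part `i` of every class as the test set; of
#' the remaining parts, `val_parts` (taken cyclically after the test
#' part) form the validation set and the rest the training set.
#'
#' @param epochs a labeled [wb_epochs()].
#' @param k number of folds (default 10); must be at least 2.
#' @param val_parts how many of the `k-1` remaining parts per class go to
#'   validation (default 1, i.e. an 8:1 train:validation split at k=10).
#' @return A list of `k` folds, each
#'   `list(fold_id, train, val, test)` of epoch indices.
#' @export
stratified_chrono_kfold <- function(epochs, k = 10L, val_parts = 1L) {
  if (k < 2L) stop("k must be >= 2 (no held-out fold possible otherwise)")
  if (val_parts < 1L || val_parts > k - 2L)
    stop("val_parts must lie in 1..k-2 so at least one part remains for training")
  lab <- epochs$info$label
  if (anyNA(lab)) stop("stratification error: unlabeled epochs present")
  info <- epochs$info
  part_of <- integer(n_epochs(epochs))
  for (cl in sort(unique(lab))) {
    ci <- which(lab == cl)
    if (length(ci) < k)
      stop("stratification error: class ", cl, " has ", length(ci),
           " epochs, fewer than k = ", k)
    ord <- ci[order(info$recorded_at[ci], info$source_id[ci])]
    # contiguous recording blocks; a recording never straddles two parts
    blocks <- split(ord, factor(info$source_id[ord], levels = unique(info$source_id[ord])))
    if (length(blocks) < k)
      stop("stratification error: class ", cl, " has ", length(blocks),
           " source recordings, fewer than k = ", k)
    sizes <- lengths(blocks)
    n <- sum(sizes)
    mids <- cumsum(sizes) - sizes / 2
    bp <- pmin(floor(k * mids / n), k - 1L)
    # guarantee every part nonempty: force strictly increasing coverage
    bp <- cummax(bp)
    if (length(unique(bp)) < k) {
      # fall back to spreading blocks evenly when epoch counts are lumpy
      bp <- floor(k * (seq_along(blocks) - 0.5) / length(blocks))
    }
    for (j in seq_along(blocks)) part_of[blocks[[j]]] <- bp[j]
  }
  lapply(seq_len(k) - 1L, function(i) {
    vp <- (i + seq_len(val_parts)) %% k
    list(fold_id = i,
         train = which(!part_of %in% c(i, vp)),
         val = which(part_of %in% vp),
         test = which(part_of == i))
  })
}

# weighted cross-entropy of predicted probabilities
wce_loss <- function(probs, labels, class_weights) {
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  mean(class_weights[labels + 1L] * -log(pmax(p, 1e-12)))
}

#' Train a classifier
#'
#' End-to-end minibatch gradient descent with the Adam optimizer and a
#' weighted cross-entropy loss. When an augmentation configuration is
#' supplied the training set is regenerated by [augment_set()] on every
#' pass, so the model never sees the same noisy variant twice. After each
#' pass the selection metric is computed on the validation set and the
#' weights from the best pass are returned.
#'
#' @param m an untrained (or warm-started) `wb_classifier`.
#' @param train_set,val_set labeled [wb_epochs()]; `val_set` nonempty.
#' @param pool training-partition [noise_pool()] or `NULL` when
#'   augmentation is disabled.
#' @param aug_cfg an [aug_config()] or `NULL` for no augmentation.
#' @param tcfg a [train_config()].
#' @param verbose print per-pass loss and validation metric.
#' @return The trained `wb_classifier` (weights from the best validation
#'   pass; `training_state` holds the history).
#' @export
train <- function(m, train_set, val_set, pool = NULL, aug_cfg = NULL,
                  tcfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(m, "wb_classifier"), n_epochs(val_set) > 0)
  if (tcfg$max_epochs < 1L) stop("max_epochs must be >= 1 (no training pass)")
  labels <- train_set$info$label
  if (anyNA(labels)) stop("training set must be fully labeled")
  counts <- tabulate(labels + 1L, nbins = m$config$num_class)
  cw <- compute_class_weights(pmax(counts, 1L))
  cw[counts == 0L] <- 0
  adam <- lapply(m$layers, function(l)
    if (!is.null(l$W)) list(mW = l$W * 0, vW = l$W * 0,
                            mb = l$b * 0, vb = l$b * 0) else NULL)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  best <- list(metric = if (tcfg$selection_metric == "loss") Inf else -Inf,
               loss = Inf, layers = m$layers, pass = NA_integer_)
  history <- data.frame(pass = integer(0), loss = numeric(0), val = numeric(0))
  set.seed(tcfg$seed)
  for (pass in seq_len(tcfg$max_epochs)) {
    X <- if (!is.null(aug_cfg) && any(aug_cfg$enable))
      augment_set(train_set, pool, aug_cfg, pass = pass)$samples
    else train_set$samples
    ord <- sample.int(nrow(X))
    pass_loss <- 0; nb <- 0L
    for (s in seq(1L, length(ord), by = tcfg$batch_size)) {
      bi <- ord[s:min(s + tcfg$batch_size - 1L, length(ord))]
      fw <- model_forward(m, X[bi, , drop = FALSE], keep_cache = TRUE)
      loss <- wce_loss(fw$probs, labels[bi], cw)
      if (!is.finite(loss))
        stop("divergence error: non-finite loss at pass ", pass,
             " (learning rate ", tcfg$learning_rate, ")")
      pass_loss <- pass_loss + loss; nb <- nb + 1L
      grads <- model_backward(m, fw$caches, fw$probs, labels[bi], cw)
      step <- step + 1
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (j in seq_along(m$layers)) {
        if (is.null(grads[[j]])) next
        a <- adam[[j]]
        a$mW <- b1 * a$mW + (1 - b1) * grads[[j]]$dW
        a$vW <- b2 * a$vW + (1 - b2) * grads[[j]]$dW^2
        a$mb <- b1 * a$mb + (1 - b1) * grads[[j]]$db
        a$vb <- b2 * a$vb + (1 - b2) * grads[[j]]$db^2
        m$layers[[j]]$W <- m$layers[[j]]$W -
          tcfg$learning_rate * corr * a$mW / (sqrt(a$vW) + eps)
        m$layers[[j]]$b <- m$layers[[j]]$b -
          tcfg$learning_rate * corr * a$mb / (sqrt(a$vb) + eps)
        adam[[j]] <- a
      }
    }
    val_metric <- switch(tcfg$selection_metric,
      loss = wce_loss(predict_proba(m, val_set), val_set$info$label, cw),
      acc = mean(classify(m, val_set) == val_set$info$label),
      mf1 = eval_report(val_set$info$label, classify(m, val_set),
                        m$config$num_class)$mf1)
    history <- rbind(history, data.frame(pass = pass, loss = pass_loss / nb,
                                         val = val_metric))
    # ties on the validation metric break toward lower training loss, so a
    # saturated validation set still tracks continuing optimization
    improved <- if (tcfg$selection_metric == "loss") val_metric < best$metric
                else val_metric > best$metric ||
                     (val_metric == best$metric && pass_loss / nb < best$loss)
    if (improved) best <- list(metric = val_metric, loss = pass_loss / nb,
                               layers = m$layers, pass = pass)
    if (verbose)
      message(sprintf("pass %3d  loss %.4f  val(%s) %.4f", pass,
                      pass_loss / nb, tcfg$selection_metric, val_metric))
  }
  m$layers <- best$layers
  m$training_state <- list(trained = TRUE, best_metric = best$metric,
                           best_pass = best$pass, history = history)
  m
}

#' Evaluation report from true and predicted labels
#'
#' Builds the C x C confusion matrix (rows = true, columns = predicted),
#' per-class one-vs-rest precision/recall/F1, overall accuracy
#' (trace / n) and macro-averaged F1 (unweighted mean of per-class F1).
#' A class absent from both truth and predictions has F1 defined as 0 and
#' is still included in the macro average.
#'
#' @param y_true,y_pred integer labels in `0..num_class-1`.
#' @param num_class number of classes.
#' @return An object of class `wb_eval_report`.
#' @export
eval_report <- function(y_true, y_pred, num_class) {
  if (length(y_true) == 0L) stop("empty test set")
  stopifnot(length(y_true) == length(y_pred))
  C <- as.integer(num_class)
  conf <- matrix(0L, C, C,
                 dimnames = list(true = 0:(C - 1L), pred = 0:(C - 1L)))
  for (i in seq_along(y_true))
    conf[y_true[i] + 1L, y_pred[i] + 1L] <- conf[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  pr <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  re <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(pr + re > 0, 2 * pr * re / (pr + re), 0)
  structure(list(confusion = conf,
                 per_class = data.frame(class = 0:(C - 1L), precision = pr,
                                        recall = re, f1 = f1, support = rowSums(conf)),
                 acc = sum(tp) / length(y_true),
                 mf1 = mean(f1),
                 n = length(y_true)),
            class = "wb_eval_report")
}

#' Evaluate a trained classifier on a labeled test set
#'
#' @param m a `wb_classifier`.
#' @param test_set a labeled [wb_epochs()].
#' @return A [eval_report()].
#' @export
evaluate <- function(m, test_set) {
  if (n_epochs(test_set) == 0L) stop("empty test set")
  if (anyNA(test_set$info$label)) stop("test set must be fully labeled")
  eval_report(test_set$info$label, classify(m, test_set), m$config$num_class)
}

#' @export
print.wb_eval_report <- function(x, ...) {
  cat(sprintf("<wb_eval_report> n = %d, ACC = %.4f, MF1 = %.4f\n",
              x$n, x$acc, x$mf1))
  print(x$per_class, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Export an evaluation report as JSON plus a confusion-matrix CSV
#' @param report a [eval_report()].
#' @param path output JSON path; the confusion matrix is written next to
#'   it with suffix `_confusion.csv`.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path) {
  jsonlite::write_json(list(acc = report$acc, mf1 = report$mf1, n = report$n,
                            per_class = report$per_class),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write.csv(report$confusion, sub("\\.json$", "_confusion.csv", path))
  invisible(path)
}

#' One-sided Mann-Whitney comparison of two runs
#'
#' Tests whether the per-fold metric values in `b` are stochastically
#' larger than those in `a`. The exact null distribution is used when the
#' combined sample size is at most 20 and there are no ties; otherwise
#' the normal approximation with the midrank tie correction. Significance
#' is declared at alpha = 0.05.
#'
#' @param a,b numeric vectors of per-fold metric values (e.g. ACC or MF1).
#' @param alpha significance level (default 0.05).
#' @return `list(u, p_value, significant, method)`.
#' @export
mann_whitney_compare <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) > 0, length(b) > 0)
  use_exact <- (length(a) + length(b)) <= 20L && !any(duplicated(c(a, b)))
  wt <- stats::wilcox.test(b, a, alternative = "greater", exact = use_exact,
                           correct = !use_exact)
  list(u = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < alpha,
       method = if (use_exact) "exact" else "normal approximation (tie-corrected)")
}

#' Dual-microphone noise subtraction
#'
#' Subtracts the far (noise-dominated) microphone signal from the near
#' (wingbeat plus noise) signal, sample by sample. With a unit-gain
#' overlay and identical noise this recovers the clean wingbeat exactly.
#'
#' @param near,far [wb_epochs()] or numeric vectors of identical shape.
#' @return An object matching `near`'s type; labels inherited from `near`.
#' @export
dual_mic_subtract <- function(near, far) {
  ns <- if (inherits(near, "wb_epochs")) near$samples else near
  fs <- if (inherits(far, "wb_epochs")) far$samples else far
  if (!identical(dim(ns), dim(fs)) || length(ns) != length(fs))
    stop("shape mismatch between near and far signals")
  if (inherits(near, "wb_epochs")) {
    out <- near
    out$samples <- ns - fs
    out$info$is_noisy <- FALSE
    return(out)
  }
  ns - fs
}

#' Full cross-validated evaluation under noise overlay
#'
#' Runs the stratified chronological k-fold protocol: for every fold a
#' fresh model is trained (with per-pass augmentation from the training
#' noise pool) and evaluated on that fold's test epochs overlaid with
#' test-pool noise at each gain in `gains` (clean copies kept when
#' `keep_clean`). The per-gain cross-validations are independent and
#' their fold-level predictions are concatenated into one combined
#' report.
#'
#' @param epochs labeled [wb_epochs()] for the whole dataset.
#' @param train_pool,test_pool [noise_pool()]s with disjoint recordings
#'   (or `NULL` to skip overlay on that side).
#' @param model_cfg a [model_config()].
#' @param aug_cfg an [aug_config()] or `NULL`.
#' @param tcfg a [train_config()].
#' @param k number of folds.
#' @param gains gain factors for the noisy test sets (default `c(1, 1.5, 2)`).
#' @param keep_clean keep clean test copies alongside noisy ones.
#' @param verbose print per-fold progress.
#' @return `list(report, fold_metrics, folds)` where `report` is the
#'   combined [eval_report()] and `fold_metrics` a data frame of per-fold,
#'   per-gain ACC/MF1.
#' @export
crossval <- function(epochs, train_pool, test_pool, model_cfg, aug_cfg,
                     tcfg, k = 10L, gains = c(1, 1.5, 2),
                     keep_clean = TRUE, verbose = FALSE) {
  folds <- stratified_chrono_kfold(epochs, k)
  y_true_all <- integer(0); y_pred_all <- integer(0)
  fm <- data.frame()
  for (f in folds) {
    cfg_f <- model_cfg
    cfg_f$seed <- model_cfg$seed + f$fold_id
    m <- build_model(cfg_f)
    m <- train(m, epochs[f$train], epochs[f$val], pool = train_pool,
               aug_cfg = aug_cfg, tcfg = tcfg)
    for (g in gains) {
      test <- if (is.null(test_pool)) epochs[f$test]
              else build_noisy_eval_set(epochs[f$test], test_pool, g, keep_clean)
      rep_g <- evaluate(m, test)
      y_true_all <- c(y_true_all, test$info$label)
      y_pred_all <- c(y_pred_all, classify(m, test))
      fm <- rbind(fm, data.frame(fold = f$fold_id, gain = g,
                                 acc = rep_g$acc, mf1 = rep_g$mf1, n = rep_g$n))
      if (verbose)
        message(sprintf("fold %d g=%.1f: ACC %.3f MF1 %.3f",
                        f$fold_id, g, rep_g$acc, rep_g$mf1))
    }
  }
  list(report = eval_report(y_true_all, y_pred_all, model_cfg$num_class),
       fold_metrics = fm, folds = folds)
}
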