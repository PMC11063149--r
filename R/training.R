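# Seeded stratified splitting, the training loop, and the iterated pipeline.

#' Pipeline run configuration
#'
#' @param holdout_fraction Fraction of observations held out for testing in
#'   each iteration (default 0.375, i.e. 3,750 of 10,000).
#' @param epochs Maximum training epochs per iteration (default 15; training
#'   stops early once `accuracy_target` is reached on the held-out set).
#' @param max_iterations Maximum train/test iterations (default 5).
#' @param accuracy_target Held-out accuracy at which an iteration stops early
#'   (default 0.95).
#' @param convergence_tol Convergence threshold: the pipeline stops when the
#'   best held-out accuracy changes by less than this across two successive
#'   iterations and `accuracy_target` has been met (default 0.005).
#' @param batch_size Mini-batch size (default 16; small batches buy
#'   more optimiser steps per epoch, which matters under tight epoch caps).
#' @param learning_rate Adam learning rate (default 0.01).
#' @param weight_decay Decoupled L2 decay applied to weight matrices
#'   (AdamW-style; default 0.03). Shrinks the many uninformative head weights
#'   that high-dimensional noisy inputs otherwise accumulate.
#' @param seed Master seed; every stochastic stage consumes a seed derived
#'   deterministically from `(seed, iteration, stage)`.
#' @param arch Backbone identifier passed to [build_model()]
#'   (default `"resnet18"`; use `"resnet_small"` for desk-scale pseudo-images).
#' @param pool_grid Adaptive pooling grid override (see [build_model()]).
#' @param attribution_method `"integrated-gradients"` (default) or
#'   `"saliency"`.
#' @param ig_steps Number of path steps for integrated gradients (default 8).
#' @return An object of class `run_config`.
#' @export
run_config <- function(holdout_fraction = 0.375, epochs = 15L,
                       max_iterations = 5L, accuracy_target = 0.95,
                       convergence_tol = 0.005, batch_size = 16L,
                       learning_rate = 0.01, weight_decay = 0.03,
                       seed = 1L, arch = "resnet18",
                       pool_grid = NULL,
                       attribution_method = "integrated-gradients",
                       ig_steps = 8L) {
  structure(list(
    holdout_fraction = check_fraction(holdout_fraction, "holdout_fraction"),
    epochs = check_count(epochs, "epochs"),
    max_iterations = check_count(max_iterations, "max_iterations"),
    accuracy_target = accuracy_target,
    convergence_tol = convergence_tol,
    batch_size = check_count(batch_size, "batch_size"),
    learning_rate = learning_rate,
    weight_decay = weight_decay,
    seed = as.integer(seed),
    arch = arch,
    pool_grid = pool_grid,
    attribution_method = attribution_method,
    ig_steps = check_count(ig_steps, "ig_steps")
  ), class = "run_config")
}

#' Stratified train/test split
#'
#' The held-out set has exactly `round(n_obs * fraction)` members, allocated
#' across classes proportionally (largest-remainder rounding), so per-class
#' test proportions are within one observation of `fraction`. Sampling within
#' classes is reproducible from `seed`.
#'
#' @param n_obs Number of observations.
#' @param labels Integer class codes (0-based), length `n_obs`.
#' @param fraction Held-out fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @examples
#' sp <- split_data(10000, rep(0:1, 5000), 0.375, seed = 1)
#' length(sp$test)  # 3750
#' @export
split_data <- function(n_obs, labels, fraction, seed = 1L) {
  n_obs <- check_count(n_obs, "n_obs")
  fraction <- check_fraction(fraction, "fraction")
  labels <- as.integer(labels)
  if (length(labels) != n_obs) {
    stop("`labels` must have length n_obs", call. = FALSE)
  }
  tab <- table(labels)
  if (any(tab < 2L)) {
    stop("every class needs at least 2 observations; class ",
         names(tab)[which.min(tab)], " has ", min(tab), call. = FALSE)
  }
  total_test <- round(n_obs * fraction)
  if (total_test < 1L || total_test >= n_obs) {
    stop("fraction leaves an empty train or test set", call. = FALSE)
  }
  classes <- as.integer(names(tab))
  ideal <- as.numeric(tab) * fraction
  take <- pmin(floor(ideal), as.numeric(tab) - 1)
  rem <- total_test - sum(take)
  if (rem > 0) {
    pri <- order(ideal - take, decreasing = TRUE)
    for (j in pri) {
      if (rem == 0) break
      if (take[j] < tab[j] - 1) { take[j] <- take[j] + 1; rem <- rem - 1 }
    }
  }
  test <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(j) {
      members <- which(labels == classes[j])
      sample(members, take[j])
    }), use.names = FALSE)
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n_obs), test), test = test)
}

#' Train a model for one iteration
#'
#' Runs up to `config$epochs` epochs of Adam on softmax cross-entropy,
#' evaluating the held-out set after every epoch and stopping early once
#' `config$accuracy_target` is reached. Per-epoch metrics and final
#' per-sample held-out correctness are recorded.
#'
#' @param model A [build_model()] network.
#' @param train_set,test_set Lists with `images` (`side x side x n` array)
#'   and `labels` (0-based integer codes).
#' @param config A [run_config()].
#' @return An object of class `iteration_result`: `metrics` (data frame with
#'   per-epoch `train_loss`, `train_acc`, `test_loss`, `test_acc`),
#'   `predictions` and `correct` on the held-out set, `epochs_run`, and the
#'   trained `model`.
#' @export
train_model <- function(model, train_set, test_set, config = run_config()) {
  stopifnot(inherits(model, "pf_model"))
  xtr <- pf_as_batch(train_set$images)
  ytr <- as.integer(train_set$labels)
  xte <- pf_as_batch(test_set$images)
  yte <- as.integer(test_set$labels)
  n_tr <- dim(xtr)[4L]
  if (n_tr < 1L || dim(xte)[4L] < 1L) {
    stop("train and test sets must be non-empty", call. = FALSE)
  }
  opt <- pf_adam_init(config$learning_rate,
                      weight_decay = config$weight_decay %||% 0)
  bs <- config$batch_size
  metrics <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), test_loss = numeric(0),
                        test_acc = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, "shuffle", ep), sample.int(n_tr))
    tot_loss <- 0; tot_correct <- 0L
    for (start in seq(1L, n_tr, by = bs)) {
      sel <- ord[start:min(start + bs - 1L, n_tr)]
      xb <- xtr[, , , sel, drop = FALSE]
      yb <- ytr[sel]
      fw <- pf_forward(model, xb, train = TRUE, keep = TRUE)
      model$buffers <- fw$buffers
      ls <- pf_softmax_xent(fw$logits, yb)
      if (!is.finite(ls$loss)) {
        stop(sprintf("training loss became non-finite at epoch %d (learning rate %g)",
                     ep, config$learning_rate), call. = FALSE)
      }
      bw <- pf_backward(model, fw$cache, ls$dlogits)
      st <- pf_adam_step(opt, model$params, bw$grads)
      opt <- st$state
      model$params <- st$params
      tot_loss <- tot_loss + ls$loss * length(sel)
      tot_correct <- tot_correct +
        sum(max.col(t(ls$prob), ties.method = "first") - 1L == yb)
    }
    ev <- pf_evaluate(model, xte, yte, bs)
    metrics <- rbind(metrics, data.frame(
      epoch = ep, train_loss = tot_loss / n_tr,
      train_acc = tot_correct / n_tr,
      test_loss = ev$loss, test_acc = ev$acc))
    if (ev$acc >= config$accuracy_target) break
  }
  final <- predict_classes(model, test_set$images, bs)
  structure(list(metrics = metrics,
                 predictions = final$classes,
                 correct = final$classes == yte,
                 epochs_run = nrow(metrics),
                 model = model),
            class = "iteration_result")
}

pf_evaluate <- function(model, x, y, batch_size) {
  n <- dim(x)[4L]
  loss <- 0; correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    end <- min(start + batch_size - 1L, n)
    fw <- pf_forward(model, x[, , , start:end, drop = FALSE], train = FALSE)
    ls <- pf_softmax_xent(fw$logits, y[start:end])
    loss <- loss + ls$loss * (end - start + 1L)
    correct <- correct +
      sum(max.col(t(ls$prob), ties.method = "first") - 1L == y[start:end])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Run the full fold-train-attribute pipeline
#'
#' Filters all-zero rows/columns, log-normalises, folds each observation into
#' a square pseudo-image, then repeats seeded stratified train/test cycles:
#' each iteration trains a freshly initialised network on a fresh split and
#' attributes the correctly classified held-out samples toward their true
#' class. Attribution maps accumulate across iterations (each correct sample
#' weighted equally) and are finally averaged per class and back-mapped to
#' ranked features. Iterating stops early once the best held-out accuracy
#' changes by less than `convergence_tol` between successive iterations while
#' meeting `accuracy_target`; otherwise `max_iterations` cycles run.
#'
#' @param table A labeled [feature_table()] with at least 2 classes.
#' @param config A [run_config()].
#' @param feature_order Optional folding permutation (see
#'   [read_feature_order()]).
#' @return An object of class `pf_run`: `config`, `filter_log`, `fold_spec`,
#'   `iterations` (list of [train_model()] results), `accuracy` (per-iteration
#'   best held-out accuracy with mean and sd), `attribution_summary`,
#'   `ranking`, `feature_names`, `label_names`, `converged_at`.
#' @export
run_pipeline <- function(table, config = run_config(), feature_order = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "run_config"))
  if (is.null(table$labels)) {
    stop("run_pipeline needs a labeled table", call. = FALSE)
  }
  n_classes <- length(unique(table$labels))
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)

  table <- filter_empty(table)
  norm <- log_normalize(table$values)
  ntab <- table
  ntab$values <- norm
  spec <- compute_fold_spec(ncol(norm), order = feature_order)
  imgs <- fold_dataset(ntab, spec)

  iterations <- list()
  attr_sets <- list()
  best_acc <- numeric(0)
  converged_at <- NA_integer_
  for (i in seq_len(config$max_iterations)) {
    sp <- split_data(nrow(norm), table$labels, config$holdout_fraction,
                     seed = derive_seed(config$seed, "split", i))
    model <- build_model(spec$side, n_classes, arch = config$arch,
                         seed = derive_seed(config$seed, "init", i),
                         pool_grid = config$pool_grid)
    iter_cfg <- config
    iter_cfg$seed <- derive_seed(config$seed, "train", i)
    res <- tryCatch(
      train_model(model,
                  list(images = imgs$images[, , sp$train, drop = FALSE],
                       labels = table$labels[sp$train]),
                  list(images = imgs$images[, , sp$test, drop = FALSE],
                       labels = table$labels[sp$test]),
                  iter_cfg),
      error = function(e) stop(sprintf("iteration %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
    res$split <- sp
    iterations[[i]] <- res
    attr_sets[[i]] <- attribute_correct(
      res$model, imgs$images[, , sp$test, drop = FALSE],
      labels = table$labels[sp$test], predictions = res$predictions,
      method = config$attribution_method, ig_steps = config$ig_steps)
    best_acc[i] <- max(res$metrics$test_acc)
    if (i >= 2L &&
        abs(best_acc[i] - best_acc[i - 1L]) < config$convergence_tol &&
        best_acc[i] >= config$accuracy_target) {
      converged_at <- i
      break
    }
  }

  summary <- accumulate_attributions(attr_sets, n_classes = n_classes)
  ranking <- rank_features(summary, spec, table$feature_names)
  structure(list(
    config = config,
    filter_log = table$filter_log,
    fold_spec = spec,
    iterations = iterations,
    accuracy = list(per_iteration = best_acc,
                    mean = mean(best_acc),
                    sd = if (length(best_acc) > 1L) stats::sd(best_acc) else 0),
    attribution_summary = summary,
    ranking = ranking,
    feature_names = table$feature_names,
    label_names = table$label_names,
    converged_at = converged_at
  ), class = "pf_run")
}

#' @export
print.pf_run <- function(x, ...) {
  cat(sprintf("<pf_run> %d iteration(s), fold %dx%d, arch '%s'\n",
              length(x$iterations), x$fold_spec$side, x$fold_spec$side,
              x$config$arch))
  cat(sprintf("  held-out accuracy: %.3f +/- %.3f%s\n", x$accuracy$mean,
              x$accuracy$sd,
              if (!is.na(x$converged_at))
                sprintf(" (converged at iteration %d)", x$converged_at) else ""))
  top <- x$ranking[x$ranking$class == "overall", ][1:min(5, sum(x$ranking$class == "overall")), ]
  cat("  top features:", paste(top$feature_name, collapse = ", "), "\n")
  invisible(x)
}
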