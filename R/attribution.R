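# Gradient-based attribution of correct held-out predictions, per-class
# accumulation, and back-mapping of pixels to ranked features.

pf_supported_methods <- c("integrated-gradients", "saliency")

# gradient of the (summed) true-class logits with respect to the input batch
pf_input_grad <- function(model, x, targets) {
  fw <- pf_forward(model, x, train = FALSE, keep = TRUE)
  dl <- matrix(0, model$n_classes, ncol(fw$logits))
  dl[cbind(targets + 1L, seq_len(ncol(dl)))] <- 1
  pf_backward(model, fw$cache, dl)$dx
}

#' Attribute correctly classified samples to input pixels
#'
#' Computes one attribution map per correctly classified sample, attributed
#' toward its true class; misclassified samples are excluded (with a warning
#' when nothing survives). `"saliency"` is the raw input gradient of the true
#' class score; `"integrated-gradients"` integrates that gradient along the
#' straight path from an all-zero baseline to the input (midpoint rule,
#' `ig_steps` steps) and multiplies by the input.
#'
#' @param model A trained [build_model()] network.
#' @param images Held-out images, `side x side x n` array.
#' @param labels True 0-based class codes.
#' @param predictions Predicted codes for the same images.
#' @param method `"integrated-gradients"` or `"saliency"`.
#' @param ig_steps Path steps for integrated gradients.
#' @param batch_size Mini-batch size.
#' @return An object of class `pf_attributions`: `maps` (array
#'   `side x side x n_correct` of signed scores), `labels` (classes of the
#'   contributing samples) and `method`.
#' @export
attribute_correct <- function(model, images, labels, predictions,
                              method = "integrated-gradients", ig_steps = 8L,
                              batch_size = 64L) {
  if (!is.character(method) || length(method) != 1L ||
      !method %in% pf_supported_methods) {
    stop("unknown attribution method '", paste(method, collapse = ","),
         "'; supported: ", paste(pf_supported_methods, collapse = ", "),
         call. = FALSE)
  }
  if (inherits(images, "pseudo_images")) images <- images$images
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  stopifnot(length(labels) == dim(images)[3L],
            length(predictions) == length(labels))
  keep <- which(predictions == labels)
  d <- dim(images)
  if (length(keep) == 0L) {
    warning("no correctly classified samples; attribution set is empty")
    return(structure(list(maps = array(0, c(d[1L], d[2L], 0L)),
                          labels = integer(0), method = method),
                     class = "pf_attributions"))
  }
  maps <- array(NA_real_, c(d[1L], d[2L], length(keep)))
  for (start in seq(1L, length(keep), by = batch_size)) {
    end <- min(start + batch_size - 1L, length(keep))
    sel <- keep[start:end]
    xb <- pf_as_batch(images[, , sel, drop = FALSE])
    tb <- labels[sel]
    if (method == "saliency") {
      g <- pf_input_grad(model, xb, tb)
    } else {
      acc <- 0
      for (s in seq_len(ig_steps)) {
        alpha <- (s - 0.5) / ig_steps
        acc <- acc + pf_input_grad(model, xb * alpha, tb)
      }
      g <- xb * acc / ig_steps
    }
    dim(g) <- c(d[1L], d[2L], end - start + 1L)   # single channel
    maps[, , start:end] <- g
  }
  structure(list(maps = maps, labels = labels[keep], method = method),
            class = "pf_attributions")
}

#' Accumulate attribution maps per class
#'
#' Element-wise mean of absolute attribution over the contributing samples of
#' each class (absolute values prevent sign cancellation across samples).
#' Classes with no correct samples yield an all-zero matrix flagged in
#' `empty_classes`. Multiple attribution sets (e.g. from successive pipeline
#' iterations) may be supplied as a list; every contributing sample then
#' carries equal weight.
#'
#' @param attributions A `pf_attributions` object or list of them.
#' @param n_classes Number of classes; defaults to `max(labels) + 1`.
#' @return An object of class `attribution_summary`: `per_class_mean` (list of
#'   `side x side` matrices, one per class code), `n_samples_per_class`,
#'   `empty_classes`, `method`.
#' @export
accumulate_attributions <- function(attributions, n_classes = NULL) {
  if (inherits(attributions, "pf_attributions")) {
    attributions <- list(attributions)
  }
  stopifnot(length(attributions) >= 1L)
  method <- attributions[[1L]]$method
  shp <- dim(attributions[[1L]]$maps)[1:2]
  for (a in attributions) {
    if (!identical(dim(a$maps)[1:2], shp)) {
      stop("attribution maps have mismatched shapes", call. = FALSE)
    }
  }
  all_labels <- unlist(lapply(attributions, `[[`, "labels"))
  if (is.null(n_classes)) n_classes <- max(all_labels, -1L) + 1L
  n_classes <- check_count(n_classes, "n_classes", min = 1L)
  sums <- lapply(seq_len(n_classes), function(i) matrix(0, shp[1L], shp[2L]))
  counts <- integer(n_classes)
  for (a in attributions) {
    if (length(a$labels) == 0L) next
    am <- abs(a$maps)
    for (k in 0:(n_classes - 1L)) {
      m <- a$labels == k
      if (!any(m)) next
      sel <- am[, , m, drop = FALSE]
      sums[[k + 1L]] <- sums[[k + 1L]] + rowSums(sel, dims = 2L)
      counts[k + 1L] <- counts[k + 1L] + sum(m)
    }
  }
  means <- lapply(seq_len(n_classes), function(j) {
    if (counts[j] > 0L) sums[[j]] / counts[j] else sums[[j]]
  })
  structure(list(per_class_mean = means, n_samples_per_class = counts,
                 empty_classes = which(counts == 0L) - 1L, method = method),
            class = "attribution_summary")
}

#' Rank features by mean attribution
#'
#' Maps every non-padding pixel of each per-class mean attribution matrix back
#' to its feature via [pixel_to_feature()] and sorts features by mean score,
#' descending, ties broken by ascending feature index. An `"overall"` ranking
#' (per-class means averaged with weights proportional to contributing sample
#' counts, i.e. equal weight per sample) is appended after the per-class
#' rankings.
#'
#' @param summary An [accumulate_attributions()] result.
#' @param spec The [compute_fold_spec()] used to fold the data.
#' @param feature_names Character vector of feature names, length
#'   `spec$n_features`.
#' @return A data frame with columns `class` (label `"0"`, `"1"`, ... or
#'   `"overall"`), `rank`, `feature_name`, `feature_index`, `mean_score`;
#'   exactly `spec$n_features` rows per class.
#' @export
rank_features <- function(summary, spec, feature_names) {
  stopifnot(inherits(summary, "attribution_summary"),
            inherits(spec, "fold_spec"))
  if (length(feature_names) != spec$n_features) {
    stop("feature_names length does not match fold spec", call. = FALSE)
  }
  side <- spec$side
  if (!all(vapply(summary$per_class_mean,
                  function(m) identical(dim(m), c(side, side)), TRUE))) {
    stop(sprintf("attribution summary geometry does not match %dx%d fold",
                 side, side), call. = FALSE)
  }
  counts <- summary$n_samples_per_class
  w <- if (sum(counts) > 0L) counts / sum(counts) else
    rep(1 / length(counts), length(counts))
  overall <- Reduce(`+`, Map(`*`, summary$per_class_mean, w))
  mats <- c(summary$per_class_mean, list(overall))
  cls <- c(as.character(seq_along(summary$per_class_mean) - 1L), "overall")

  # feature index occupying each row-major flattened pixel position
  feat_of_pixel <- spec$order
  out <- vector("list", length(mats))
  for (j in seq_along(mats)) {
    m <- mats[[j]]
    flat <- as.vector(t(m))[seq_len(spec$n_features)]   # row-major, drop padding
    score <- numeric(spec$n_features)
    score[feat_of_pixel] <- flat
    ord <- order(-score, seq_len(spec$n_features))
    out[[j]] <- data.frame(class = cls[j],
                           rank = seq_len(spec$n_features),
                           feature_name = feature_names[ord],
                           feature_index = ord,
                           mean_score = score[ord],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
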