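# Needle-in-a-haystack benchmark generator, seeded pixel shuffles, and toy
# pattern images for fast end-to-end testing.

#' Describe one planted informative feature
#'
#' @param feature_index 1-based column index of the planted feature.
#' @param class_ranges List (one element per class code, starting at class 0)
#'   of numeric `c(low, high)` pairs with `0 <= low < high <= 1`; values for
#'   an observation of class `c` are drawn uniformly from the half-open
#'   interval `[low_c, high_c)`.
#' @return An object of class `informative_feature`.
#' @export
informative_feature <- function(feature_index, class_ranges) {
  feature_index <- check_count(feature_index, "feature_index")
  stopifnot(is.list(class_ranges), length(class_ranges) >= 2L)
  for (r in class_ranges) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] < 0 || r[2L] > 1 ||
        r[1L] >= r[2L]) {
      stop("each class range must be c(low, high) with 0 <= low < high <= 1",
           call. = FALSE)
    }
  }
  structure(list(feature_index = feature_index, class_ranges = class_ranges),
            class = "informative_feature")
}

# The two canonical planted features: class-conditional value ranges
# [0.00, 0.20) vs [0.20, 0.40) and [0.10, 0.20) vs [0.25, 0.35).
canonical_informative <- function(idx1, idx2) {
  list(
    informative_feature(idx1, list(c(0.00, 0.20), c(0.20, 0.40))),
    informative_feature(idx2, list(c(0.10, 0.20), c(0.25, 0.35)))
  )
}

default_informative <- function(n_features) {
  if (n_features >= 17999L + 226L) {
    # canonical placement: 0-based variables 20 and 17,998
    canonical_informative(21L, 17999L)
  } else if (n_features >= 249L) {
    # keep the canonical offsets (21 from the start, 226 from the end)
    canonical_informative(21L, n_features - 226L)
  } else if (n_features >= 6L) {
    canonical_informative(max(2L, floor(n_features / 3)),
                          floor(2 * n_features / 3))
  } else {
    stop("n_features too small to place the two default informative features; supply `informative`",
         call. = FALSE)
  }
}

#' Configuration for the needle-in-a-haystack generator
#'
#' Defaults emulate the canonical benchmark: 10,000 observations of 18,225
#' uniform-random variables in `[0, 1)`, two of which are planted with
#' disjoint class-conditional sub-ranges (variables 20 and 17,998 in 0-based
#' numbering, i.e. columns 21 and 17,999 here): `[0.00, 0.20)` vs
#' `[0.20, 0.40)` and `[0.10, 0.20)` vs `[0.25, 0.35)` for class 0 vs 1.
#'
#' @param n_obs Number of observations (default 10,000).
#' @param n_features Number of features (default 18,225 = 135^2).
#' @param informative List of [informative_feature()] specs; `NULL` plants the
#'   two canonical features (relocated deterministically when `n_features` is
#'   too small for the canonical positions).
#' @param n_classes Number of classes (default 2).
#' @param class_balance Numeric class proportions summing to 1; `NULL` means
#'   equal.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `nihs_config`.
#' @export
nihs_config <- function(n_obs = 10000L, n_features = 18225L,
                        informative = NULL, n_classes = 2L,
                        class_balance = NULL, seed = 1L) {
  n_obs <- check_count(n_obs, "n_obs")
  n_features <- check_count(n_features, "n_features")
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  if (is.null(informative)) informative <- default_informative(n_features)
  if (inherits(informative, "informative_feature")) informative <- list(informative)
  idx <- vapply(informative, function(s) s$feature_index, 1L)
  if (anyDuplicated(idx)) stop("informative feature indices must be distinct",
                               call. = FALSE)
  if (any(idx > n_features)) {
    stop(sprintf("informative feature index %d exceeds n_features = %d",
                 max(idx), n_features), call. = FALSE)
  }
  for (s in informative) {
    if (length(s$class_ranges) != n_classes) {
      stop("each informative feature needs one class range per class",
           call. = FALSE)
    }
  }
  if (is.null(class_balance)) class_balance <- rep(1 / n_classes, n_classes)
  if (length(class_balance) != n_classes || any(class_balance <= 0) ||
      abs(sum(class_balance) - 1) > 1e-8) {
    stop("`class_balance` must be positive proportions summing to 1",
         call. = FALSE)
  }
  structure(list(n_obs = n_obs, n_features = n_features,
                 informative = informative, n_classes = n_classes,
                 class_balance = class_balance, seed = as.integer(seed)),
            class = "nihs_config")
}

# integer class counts by largest remainder, summing exactly to n
balanced_counts <- function(n, props) {
  ideal <- n * props
  cnt <- floor(ideal)
  rem <- n - sum(cnt)
  if (rem > 0) {
    give <- order(ideal - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[give] <- cnt[give] + 1L
  }
  as.integer(cnt)
}

#' Generate a needle-in-a-haystack dataset
#'
#' Every non-informative cell is drawn from `Uniform[0, 1)`; each planted
#' feature's cell for an observation of class `c` is drawn from
#' `Uniform[low_c, high_c)`. With the default ranges the class-conditional
#' supports of the planted features are disjoint, so a single threshold on
#' the first planted feature separates the classes perfectly — the oracle
#' used by the recovery tests.
#'
#' @param config An [nihs_config()].
#' @return A labeled [feature_table()] with columns `V1..VF`; class codes are
#'   0-based with `label_names` `"class_0"`, `"class_1"`, ...
#' @export
generate_nihs <- function(config = nihs_config()) {
  stopifnot(inherits(config, "nihs_config"))
  with_seed(config$seed, {
    n <- config$n_obs; F <- config$n_features; K <- config$n_classes
    counts <- balanced_counts(n, config$class_balance)
    labels <- sample(rep.int(0:(K - 1L), counts))
    values <- matrix(stats::runif(as.numeric(n) * F), n, F)
    for (s in config$informative) {
      v <- numeric(n)
      for (k in 0:(K - 1L)) {
        r <- s$class_ranges[[k + 1L]]
        m <- labels == k
        v[m] <- r[1L] + stats::runif(sum(m)) * (r[2L] - r[1L])
      }
      values[, s$feature_index] <- v
    }
    feature_table(values,
                  feature_names = paste0("V", seq_len(F)),
                  observation_ids = paste0("obs_", seq_len(n)),
                  labels = labels,
                  label_names = paste0("class_", 0:(K - 1L)))
  })
}

#' Apply one seeded pixel permutation to every image
#'
#' Draws a single permutation of flattened pixel positions from `seed` and
#' applies it identically to all images, emulating the dispersed-pattern
#' experiment in which a fixed shuffle leaves class information intact while
#' destroying local structure.
#'
#' @param images A `pseudo_images` object or a `side x side x n` array.
#' @param seed Integer seed for the permutation.
#' @return List with `images` (same type as the input) and `permutation`
#'   (integer vector `perm`; shuffled pixel `q` holds original flattened
#'   pixel `perm[q]`, column-major flattening).
#' @export
shuffle_pixels <- function(images, seed) {
  wrapped <- inherits(images, "pseudo_images")
  arr <- if (wrapped) images$images else images
  if (length(dim(arr)) != 3L || dim(arr)[3L] == 0L) {
    stop("need a non-empty set of images of identical shape", call. = FALSE)
  }
  d <- dim(arr)
  if (d[1L] != d[2L]) stop("images must be square", call. = FALSE)
  npix <- d[1L] * d[2L]
  perm <- with_seed(seed, sample.int(npix))
  flat <- arr
  dim(flat) <- c(npix, d[3L])
  flat <- flat[perm, , drop = FALSE]
  dim(flat) <- d
  out <- if (wrapped) {
    res <- images
    res$images <- flat
    res
  } else {
    flat
  }
  list(images = out, permutation = perm)
}

#' Invert a pixel shuffle
#'
#' @param images Shuffled images (`pseudo_images` or array).
#' @param permutation The permutation returned by [shuffle_pixels()].
#' @return Images with the original pixel order restored.
#' @export
unshuffle_pixels <- function(images, permutation) {
  wrapped <- inherits(images, "pseudo_images")
  arr <- if (wrapped) images$images else images
  d <- dim(arr)
  flat <- arr
  dim(flat) <- c(d[1L] * d[2L], d[3L])
  restored <- flat
  restored[permutation, ] <- flat
  dim(restored) <- d
  if (wrapped) { images$images <- restored; images } else restored
}

# deterministic per-class template: two filled rectangles whose positions are
# a fixed function of the class index
toy_template <- function(class_code, side) {
  tmpl <- matrix(0, side, side)
  h <- max(3L, side %/% 4L)
  span <- side - h
  r1 <- 1L + (class_code * 5L) %% span
  c1 <- 1L + (class_code * 11L + 3L) %% span
  r2 <- 1L + (class_code * 13L + 7L) %% span
  c2 <- 1L + (class_code * 3L + 1L) %% span
  tmpl[r1:(r1 + h - 1L), c1:(c1 + h - 1L)] <- 1
  tmpl[r2:(r2 + h - 1L), c2:(c2 + h - 1L)] <- 1
  tmpl
}

#' Generate labeled toy pattern images
#'
#' Each class is a fixed intensity template (two class-specific rectangles)
#' plus i.i.d. Gaussian noise, clipped to `[0, 1]`. A fast desk-scale stand-in
#' for natural-image benchmarks, used to exercise the trainer and the
#' pixel-shuffle invariance property.
#'
#' @param n_obs Number of images.
#' @param side Image side in pixels (>= 8).
#' @param n_classes Number of classes (>= 2).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @return A `pseudo_images` object with 0-based `labels` (balanced to within
#'   one image per class) and a `templates` field holding the noise-free
#'   class templates.
#' @export
generate_toy_patterns <- function(n_obs, side, n_classes = 2L, noise_sd = 0.1,
                                  seed = 1L) {
  n_obs <- check_count(n_obs, "n_obs")
  side <- check_count(side, "side", min = 8L)
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be a non-negative number", call. = FALSE)
  }
  templates <- lapply(0:(n_classes - 1L), toy_template, side = side)
  with_seed(seed, {
    labels <- sample(rep_len(0:(n_classes - 1L), n_obs))
    images <- array(0, c(side, side, n_obs))
    for (i in seq_len(n_obs)) images[, , i] <- templates[[labels[i] + 1L]]
    if (noise_sd > 0) {
      images <- images + array(stats::rnorm(length(images), 0, noise_sd),
                               dim(images))
      images[images < 0] <- 0
      images[images > 1] <- 1
    }
    structure(list(images = images, labels = labels,
                   observation_ids = paste0("img_", seq_len(n_obs)),
                   spec = NULL, templates = templates),
              class = "pseudo_images")
  })
}

#' Write a generated table to CSV
#'
#' Writes a [feature_table()] with its label column restored, preceded by a
#' `#`-comment line recording the generation seed (skipped transparently by
#' [load_table()]).
#'
#' @param table A labeled [feature_table()].
#' @param path Output path.
#' @param seed Seed to record in the header comment (optional).
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$values)
  names(df) <- table$feature_names
  if (!is.null(table$labels)) {
    lab <- if (!is.null(table$label_names)) {
      table$label_names[table$labels + 1L]
    } else {
      as.character(table$labels)
    }
    df$label <- lab
  }
  con <- file(path, "wt")
  on.exit(close(con), add = TRUE)
  if (!is.null(seed)) writeLines(sprintf("# pixelfold nihs seed=%d", seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
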