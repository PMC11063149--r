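# Normalisation and the bijective vector <-> square pseudo-image mapping.

#' Log-normalise a feature matrix into the unit interval
#'
#' Per column: shift by `-min(column)` when the minimum is negative, apply
#' `log1p`, then min-max rescale to `[0, 1]`. Both maps are monotone, so
#' within-column rank order is preserved; constant columns map to all zeros.
#' `log1p` compresses the heavy right tail typical of expression counts while
#' leaving zeros at zero.
#'
#' @param values Numeric matrix (observations x features), all entries finite.
#' @return A matrix of the same shape with every entry in `[0, 1]`.
#' @export
log_normalize <- function(values) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  cmin <- apply(values, 2L, min)
  neg <- cmin < 0
  if (any(neg)) {
    values[, neg] <- sweep(values[, neg, drop = FALSE], 2L, cmin[neg])
  }
  values <- log1p(values)
  lo <- apply(values, 2L, min)
  hi <- apply(values, 2L, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  values <- sweep(sweep(values, 2L, lo), 2L, rng, `/`)
  if (any(const)) values[, const] <- 0
  values
}

#' Compute the fold geometry for a feature count
#'
#' Chooses the smallest square that holds all features one-per-pixel:
#' `side = ceiling(sqrt(F))`, with `side^2 - F` zero pixels of tail padding.
#' An optional permutation reorders which feature occupies each pixel (for
#' example from an external index file, see [read_feature_order()]).
#'
#' @param n_features Feature count `F` (>= 1).
#' @param order Optional permutation of `1:F`; `order[p]` is the feature
#'   placed at flattened (row-major) pixel position `p`. Identity when `NULL`.
#' @return An object of class `fold_spec` with fields `n_features`, `side`,
#'   `pad_count` and `order`.
#' @examples
#' compute_fold_spec(19319)  # side 139, pad_count 2
#' @export
compute_fold_spec <- function(n_features, order = NULL) {
  n_features <- check_count(n_features, "n_features")
  side <- as.integer(ceiling(sqrt(as.numeric(n_features))))
  # guard against floating-point sqrt on perfect squares
  while ((side - 1L)^2 >= n_features) side <- side - 1L
  while (side^2 < n_features) side <- side + 1L
  if (is.null(order)) {
    order <- seq_len(n_features)
  } else {
    order <- as.integer(order)
    if (length(order) != n_features || anyNA(order) ||
        !identical(sort(order), seq_len(n_features))) {
      stop("`order` must be a permutation of 1:n_features", call. = FALSE)
    }
  }
  structure(list(n_features = n_features, side = side,
                 pad_count = side^2 - n_features, order = order),
            class = "fold_spec")
}

#' @export
print.fold_spec <- function(x, ...) {
  cat(sprintf("<fold_spec> %d features -> %d x %d image (%d padding pixels)%s\n",
              x$n_features, x$side, x$side, x$pad_count,
              if (identical(x$order, seq_len(x$n_features))) "" else ", custom order"))
  invisible(x)
}

#' Fold a feature vector into a square pseudo-image
#'
#' Fills the `side x side` matrix in row-major order: flattened pixel
#' position `p <= F` receives `v[spec$order[p]]`; the trailing
#' `side^2 - F` positions are zero padding.
#'
#' @param v Numeric vector of length `spec$n_features`.
#' @param spec A [compute_fold_spec()] result.
#' @return A `side x side` numeric matrix.
#' @examples
#' fold_vector(c(1, 2, 3), compute_fold_spec(3))  # rbind(c(1,2), c(3,0))
#' @export
fold_vector <- function(v, spec) {
  stopifnot(inherits(spec, "fold_spec"))
  if (length(v) != spec$n_features) {
    stop(sprintf("vector length %d does not match fold spec for %d features",
                 length(v), spec$n_features), call. = FALSE)
  }
  flat <- c(as.numeric(v)[spec$order], numeric(spec$pad_count))
  matrix(flat, spec$side, spec$side, byrow = TRUE)
}

#' Map a pixel back to the feature it encodes
#'
#' The inverse of [fold_vector()]: for pixel `(row, col)` (1-based) the
#' flattened row-major position is `p = (row - 1) * side + col`, which holds
#' feature `spec$order[p]` when `p <= F` and padding otherwise.
#'
#' @param spec A [compute_fold_spec()] result.
#' @param row,col 1-based pixel coordinates in `1:side`.
#' @return The 1-based feature index, or `NA_integer_` for a padding pixel.
#' @export
pixel_to_feature <- function(spec, row, col) {
  stopifnot(inherits(spec, "fold_spec"))
  if (any(row < 1L | row > spec$side) || any(col < 1L | col > spec$side)) {
    stop(sprintf("pixel coordinates out of range 1..%d", spec$side),
         call. = FALSE)
  }
  p <- (as.integer(row) - 1L) * spec$side + as.integer(col)
  out <- rep(NA_integer_, length(p))
  ok <- p <= spec$n_features
  out[ok] <- spec$order[p[ok]]
  if (length(out) == 1L) out[[1L]] else out
}

#' Fold a whole table into a pseudo-image set
#'
#' Applies [fold_vector()] to every observation, producing a single-channel
#' image per row with labels carried through unchanged. The table is expected
#' to be normalised (see [log_normalize()]) so pixel intensities lie in
#' `[0, 1]`, but any finite values are accepted.
#'
#' @param table A [feature_table()].
#' @param spec A [compute_fold_spec()] whose `n_features` matches the table.
#' @return An object of class `pseudo_images`: list with `images` (array
#'   `side x side x n_obs`), `labels`, `observation_ids` and `spec`.
#' @export
fold_dataset <- function(table, spec) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "fold_spec"))
  if (ncol(table$values) != spec$n_features) {
    stop(sprintf("fold spec is for %d features but table has %d",
                 spec$n_features, ncol(table$values)), call. = FALSE)
  }
  n <- nrow(table$values)
  side <- spec$side
  padded <- cbind(table$values[, spec$order, drop = FALSE],
                  matrix(0, n, spec$pad_count))
  flat <- t(padded)                      # side^2 x n, row-major pixel order
  dim(flat) <- c(side, side, n)          # flat[c, r, i] = pixel (r, c)
  images <- aperm(flat, c(2L, 1L, 3L))
  structure(list(images = images, labels = table$labels,
                 observation_ids = table$observation_ids, spec = spec),
            class = "pseudo_images")
}

#' @export
print.pseudo_images <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<pseudo_images> %d images, %d x %d, %s\n", d[3], d[1], d[2],
              if (is.null(x$labels)) "unlabeled" else
                paste0(length(unique(x$labels)), " classes")))
  invisible(x)
}

#' Unfold pseudo-images back to a feature matrix
#'
#' Exact inverse of [fold_dataset()]: recovers the `n_obs x F` matrix from the
#' image array, discarding padding pixels.
#'
#' @param images A `pseudo_images` object or a `side x side x n` array.
#' @param spec Fold spec; defaults to the one stored in `images`.
#' @return Numeric matrix `n_obs x F`.
#' @export
unfold_dataset <- function(images, spec = NULL) {
  if (inherits(images, "pseudo_images")) {
    spec <- spec %||% images$spec
    images <- images$images
  }
  stopifnot(inherits(spec, "fold_spec"), length(dim(images)) == 3L)
  n <- dim(images)[3L]
  flat <- aperm(images, c(2L, 1L, 3L))   # back to row-major flattening
  dim(flat) <- c(spec$side^2, n)
  vals <- t(flat[seq_len(spec$n_features), , drop = FALSE])
  # column p of `vals` holds feature order[p]; invert the permutation
  vals[, order(spec$order), drop = FALSE]
}

#' Read a feature-order index file
#'
#' A two-column delimited file (`feature_name, rank`) defining the folding
#' order: the feature with rank 1 occupies the first pixel, and so on. Every
#' feature of the table must be ranked exactly once.
#'
#' @param path Path to the index file.
#' @param feature_names Feature names of the table the order will be applied
#'   to.
#' @param delimiter Field separator (default `","`).
#' @return An integer permutation usable as the `order` argument of
#'   [compute_fold_spec()].
#' @export
read_feature_order <- function(path, feature_names, delimiter = ",") {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("index file must have columns (feature_name, rank)",
                          call. = FALSE)
  nm <- as.character(df[[1L]]); rk <- as.integer(df[[2L]])
  if (!setequal(nm, feature_names) || length(nm) != length(feature_names)) {
    stop("index file must rank every table feature exactly once", call. = FALSE)
  }
  if (!identical(sort(rk), seq_along(rk))) {
    stop("ranks must be a permutation of 1..F", call. = FALSE)
  }
  match(nm[order(rk)], feature_names)
}
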