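# Network architectures over the dense-array engine.

pf_supported_archs <- c("resnet_small", "resnet18", "linear")

# builder state: accumulates parameter/buffer arrays under unique names
pf_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$params <- list()
  env$buffers <- list()
  env
}

pf_add_conv <- function(bld, name, cin, cout, k, pad = (k - 1L) %/% 2L) {
  sd <- sqrt(2 / (k * k * cin))                      # He initialisation
  bld$params[[paste0(name, ".W")]] <-
    array(stats::rnorm(cout * cin * k * k, 0, sd), c(cout, cin, k, k))
  bld$params[[paste0(name, ".b")]] <- numeric(cout)
  list(type = "conv", k = as.integer(k), pad = as.integer(pad),
       cin = as.integer(cin), cout = as.integer(cout),
       W = paste0(name, ".W"), b = paste0(name, ".b"))
}

pf_add_bn <- function(bld, name, c) {
  bld$params[[paste0(name, ".g")]] <- rep(1, c)
  bld$params[[paste0(name, ".b")]] <- numeric(c)
  bld$buffers[[paste0(name, ".rm")]] <- numeric(c)
  bld$buffers[[paste0(name, ".rv")]] <- rep(1, c)
  list(type = "bn", c = as.integer(c), g = paste0(name, ".g"),
       b = paste0(name, ".b"), rm = paste0(name, ".rm"),
       rv = paste0(name, ".rv"))
}

pf_relu <- list(type = "relu")
pf_pool_half_layer <- list(type = "pool_half")

pf_add_resblock <- function(bld, name, cin, cout) {
  main <- list(
    pf_add_conv(bld, paste0(name, ".conv1"), cin, cout, 3L),
    pf_add_bn(bld, paste0(name, ".bn1"), cout),
    pf_relu,
    pf_add_conv(bld, paste0(name, ".conv2"), cout, cout, 3L),
    pf_add_bn(bld, paste0(name, ".bn2"), cout)
  )
  skip <- if (cin != cout) {
    list(pf_add_conv(bld, paste0(name, ".proj"), cin, cout, 1L, pad = 0L),
         pf_add_bn(bld, paste0(name, ".projbn"), cout))
  }
  list(type = "resblock", main = main, skip = skip)
}

pf_add_linear <- function(bld, name, din, dout) {
  sd <- sqrt(1 / din)
  bld$params[[paste0(name, ".W")]] <-
    matrix(stats::rnorm(dout * din, 0, sd), dout, din)
  bld$params[[paste0(name, ".b")]] <- numeric(dout)
  list(W = paste0(name, ".W"), b = paste0(name, ".b"), din = as.integer(din))
}

#' Build a trainable classifier network
#'
#' All architectures accept single-channel square inputs of any side via
#' adaptive average pooling ahead of the linear classifier head, so the same
#' code path serves e.g. 135x135 and 139x139 pseudo-images. Weight
#' initialisation is fully reproducible from `seed`.
#'
#' Supported architectures:
#' \describe{
#'   \item{`resnet_small`}{Compact residual backbone for one-feature-per-pixel
#'     pseudo-images: a 3x3 stem and two residual blocks (8 channels
#'     throughout), all stride 1 so spatial resolution is preserved;
#'     the raw input is concatenated as an extra channel, and features are
#'     adaptively pooled to a `pool_grid` x `pool_grid` map (default 32)
#'     before the head. Keeping per-pixel resolution matters because with one
#'     feature per pixel the class signal is purely positional.}
#'   \item{`resnet18`}{An 18-weight-layer residual network (stages of widths
#'     64/128/256/512, two blocks each) with average-pool downsampling and a
#'     global 1x1 adaptive pool. The conventional default for large images.}
#'   \item{`linear`}{Adaptive pooling straight to the head: a multinomial
#'     logistic regression on pooled pixels. Useful as a baseline and in
#'     attribution tests.}
#' }
#'
#' @param side Input image side in pixels (>= 16 for the residual
#'   architectures).
#' @param n_classes Number of output classes (>= 2).
#' @param arch Architecture identifier, one of `"resnet_small"`, `"resnet18"`,
#'   `"linear"`.
#' @param seed Integer seed for weight initialisation.
#' @param pool_grid Side of the adaptive pooling grid before the head;
#'   defaults to 32 for `resnet_small`, 1 for `resnet18`, `side` for
#'   `"linear"`.
#' @return An object of class `pf_model`.
#' @export
build_model <- function(side, n_classes, arch = "resnet_small", seed = 1L,
                        pool_grid = NULL) {
  if (!is.character(arch) || length(arch) != 1L ||
      !arch %in% pf_supported_archs) {
    stop("unknown architecture '", paste(arch, collapse = ","),
         "'; supported: ", paste(pf_supported_archs, collapse = ", "),
         call. = FALSE)
  }
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  side <- check_count(side, "side",
                      min = if (arch == "linear") 2L else 16L)
  bld <- pf_builder()
  with_seed(seed, {
    if (arch == "resnet_small") {
      g <- as.integer(pool_grid %||% 32L)
      layers <- list(
        pf_add_conv(bld, "stem", 1L, 8L, 3L),
        pf_add_bn(bld, "stembn", 8L),
        pf_relu,
        pf_add_resblock(bld, "block1", 8L, 8L),
        pf_add_resblock(bld, "block2", 8L, 8L)
      )
      input_skip <- TRUE
      head_c <- 8L + 1L
    } else if (arch == "resnet18") {
      g <- as.integer(pool_grid %||% 1L)
      widths <- c(64L, 128L, 256L, 512L)
      layers <- list(
        pf_add_conv(bld, "stem", 1L, 64L, 7L),
        pf_add_bn(bld, "stembn", 64L),
        pf_relu,
        pf_pool_half_layer,
        pf_pool_half_layer
      )
      cin <- 64L
      for (s in seq_along(widths)) {
        if (s > 1L) layers <- c(layers, list(pf_pool_half_layer))
        layers <- c(layers, list(
          pf_add_resblock(bld, sprintf("s%db1", s), cin, widths[s]),
          pf_add_resblock(bld, sprintf("s%db2", s), widths[s], widths[s])
        ))
        cin <- widths[s]
      }
      input_skip <- FALSE
      head_c <- 512L
    } else { # linear
      g <- as.integer(pool_grid %||% side)
      layers <- list()
      input_skip <- FALSE
      head_c <- 1L
    }
    din <- g * g * head_c
    fc <- pf_add_linear(bld, "fc", din, n_classes)
    # standardise pooled head features (resnet18 keeps the classic bare head)
    head_bn <- if (arch != "resnet18") pf_add_bn(bld, "headbn", din)
    structure(list(arch = arch, layers = layers, input_skip = input_skip,
                   pool_grid = g, fc = fc, head_bn = head_bn,
                   n_classes = n_classes, side = side,
                   params = bld$params, buffers = bld$buffers),
              class = "pf_model")
  })
}

#' @export
print.pf_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<pf_model> arch '%s', %d classes, pool grid %d, %s parameters\n",
              x$arch, x$n_classes, x$pool_grid, format(np, big.mark = ",")))
  invisible(x)
}

# coerce (H, W, N) image stacks to the engine's channel-first (1, H, W, N)
# layout; with a single channel the memory order is unchanged
pf_as_batch <- function(images) {
  d <- dim(images)
  if (length(d) == 4L) return(images)
  stopifnot(length(d) == 3L)
  dim(images) <- c(1L, d[1L], d[2L], d[3L])
  images
}

#' Predict class scores and labels
#'
#' @param model A [build_model()] network.
#' @param images Array `side x side x n` (or `pseudo_images`).
#' @param batch_size Mini-batch size used for the forward passes.
#' @return List with `logits` (`n_classes x n`) and `classes` (0-based codes).
#' @export
predict_classes <- function(model, images, batch_size = 64L) {
  if (inherits(images, "pseudo_images")) images <- images$images
  x <- pf_as_batch(images)
  n <- dim(x)[4L]
  logits <- matrix(NA_real_, model$n_classes, n)
  for (start in seq(1L, n, by = batch_size)) {
    end <- min(start + batch_size - 1L, n)
    fw <- pf_forward(model, x[, , , start:end, drop = FALSE], train = FALSE)
    logits[, start:end] <- fw$logits
  }
  list(logits = logits, classes = max.col(t(logits), ties.method = "first") - 1L)
}
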