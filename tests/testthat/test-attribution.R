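test_that("a single-pixel model concentrates attribution on that pixel", {
  side <- 6
  m <- one_pixel_model(side, row = 3, col = 4, weight = 2)
  set.seed(9)
  imgs <- array(runif(side * side * 5, 0.2, 1), c(side, side, 5))
  preds <- predict_classes(m, imgs)$classes
  labels <- preds  # everything "correct" so all samples contribute
  for (method in c("saliency", "integrated-gradients")) {
    at <- attribute_correct(m, imgs, labels, preds, method = method)
    expect_equal(dim(at$maps), c(side, side, 5))
    for (i in 1:5) {
      mass <- abs(at$maps[, , i])
      expect_gte(mass[3, 4] / sum(mass), 0.99)
    }
  }
  expect_error(attribute_correct(m, imgs, labels, preds, method = "shap"),
               "integrated-gradients, saliency")
})

test_that("integrated gradients of a linear head equals weight times input", {
  side <- 4
  m <- one_pixel_model(side, row = 2, col = 2, weight = 1.5)
  img <- array(runif(16), c(side, side, 1))
  at <- attribute_correct(m, img, labels = 1L, predictions = 1L,
                          method = "integrated-gradients")
  # exact up to the head-standardisation scale (1/sqrt(1 + eps) at init)
  expect_equal(at$maps[2, 2, 1], 1.5 * img[2, 2, 1], tolerance = 1e-4)
})

test_that("misclassified samples are excluded; empty sets warn", {
  side <- 5
  m <- one_pixel_model(side, 1, 1)
  imgs <- array(runif(side * side * 4, 0.1, 1), c(side, side, 4))
  preds <- predict_classes(m, imgs)$classes
  wrong <- 1L - preds
  expect_warning(at <- attribute_correct(m, imgs, wrong, preds), "no correctly")
  expect_equal(dim(at$maps)[3], 0L)
  mixed <- preds; mixed[2] <- 1L - mixed[2]
  at2 <- attribute_correct(m, imgs, mixed, preds, method = "saliency")
  expect_equal(dim(at2$maps)[3], 3L)
  expect_equal(at2$labels, mixed[-2])
})

test_that("accumulation takes class-wise means of absolute values", {
  v <- matrix(rnorm(9), 3)
  mk <- function(maps, labels) structure(
    list(maps = maps, labels = labels, method = "saliency"),
    class = "pf_attributions")
  # two identical maps in one class -> mean equals the map
  a <- mk(array(abs(v), c(3, 3, 2)), c(0L, 0L))
  s <- accumulate_attributions(a, n_classes = 2)
  expect_equal(s$per_class_mean[[1]], abs(v))
  expect_equal(s$n_samples_per_class, c(2L, 0L))
  expect_equal(s$empty_classes, 1)
  # maps v and -v in one class -> mean of absolute values is |v|
  b <- mk(array(c(v, -v), c(3, 3, 2)), c(1L, 1L))
  s2 <- accumulate_attributions(b, n_classes = 2)
  expect_equal(s2$per_class_mean[[2]], abs(v))
  # classes accumulate independently
  c1 <- mk(array(c(v, 5 * v), c(3, 3, 2)), c(0L, 1L))
  c2 <- mk(array(c(v, 50 * v), c(3, 3, 2)), c(0L, 1L))
  expect_identical(accumulate_attributions(c1, 2)$per_class_mean[[1]],
                   accumulate_attributions(c2, 2)$per_class_mean[[1]])
  bad <- list(a, mk(array(0, c(4, 4, 1)), 0L))
  expect_error(accumulate_attributions(bad), "mismatched")
})

test_that("accumulation is invariant to sample order within a class", {
  set.seed(12)
  maps <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  labels <- c(0L, 1L, 0L, 1L, 0L, 1L)
  mk <- function(o) structure(list(maps = maps[, , o], labels = labels[o],
                                   method = "saliency"),
                              class = "pf_attributions")
  s1 <- accumulate_attributions(mk(1:6), 2)
  s2 <- accumulate_attributions(mk(c(5, 3, 1, 6, 2, 4)), 2)
  expect_equal(s1$per_class_mean, s2$per_class_mean)
})

test_that("rank_features excludes padding, breaks ties by index, counts F rows", {
  spec <- compute_fold_spec(3)
  mk_summary <- function(mat) structure(
    list(per_class_mean = list(mat), n_samples_per_class = 1L,
         empty_classes = integer(0), method = "saliency"),
    class = "attribution_summary")
  # uniform scores: ranking ordered purely by feature index
  r <- rank_features(mk_summary(matrix(1, 2, 2)), spec, c("a", "b", "c"))
  r0 <- r[r$class == "0", ]
  expect_equal(nrow(r0), 3L)
  expect_equal(r0$feature_index, 1:3)
  expect_equal(r0$rank, 1:3)
  expect_false(any(is.na(r0$feature_index)))
  # distinct scores rank descending; padding pixel (2,2) never appears
  m2 <- matrix(c(0.1, 0.9, 0.5, 7), 2, byrow = TRUE)
  r2 <- rank_features(mk_summary(m2), spec, c("a", "b", "c"))
  r20 <- r2[r2$class == "0", ]
  expect_equal(r20$feature_name, c("b", "c", "a"))
  expect_equal(r20$mean_score, c(0.9, 0.5, 0.1))
  expect_error(rank_features(mk_summary(matrix(1, 3, 3)), spec,
                             c("a", "b", "c")), "geometry")
})

test_that("scores attach to features, not pixels, under fold permutations", {
  set.seed(77)
  F <- 7
  fname <- paste0("g", 1:F)
  scores <- runif(F)
  ord <- sample(F)
  sp_id <- compute_fold_spec(F)
  sp_pm <- compute_fold_spec(F, order = ord)
  # per-pixel mean maps produced by folding the same per-feature scores
  mk <- function(sp) structure(
    list(per_class_mean = list(fold_vector(scores, sp)),
         n_samples_per_class = 1L, empty_classes = integer(0),
         method = "saliency"),
    class = "attribution_summary")
  r_id <- rank_features(mk(sp_id), sp_id, fname)
  r_pm <- rank_features(mk(sp_pm), sp_pm, fname)
  for (cl in c("0", "overall")) {
    a <- r_id[r_id$class == cl, c("feature_name", "mean_score")]
    b <- r_pm[r_pm$class == cl, c("feature_name", "mean_score")]
    expect_equal(a, b, ignore_attr = TRUE)
  }
})

test_that("a pipeline ranking on separable toy data has F entries per class", {
  tab <- generate_nihs(small_nihs(100, 256, idx = c(4, 200), seed = 41))
  cfg <- run_config(epochs = 2, max_iterations = 1, seed = 15,
                    arch = "resnet_small", pool_grid = 16,
                    attribution_method = "saliency")
  r <- run_pipeline(tab, cfg)
  for (cl in unique(r$ranking$class)) {
    rc <- r$ranking[r$ranking$class == cl, ]
    expect_equal(nrow(rc), 256L)
    expect_equal(sort(rc$feature_index), 1:256)
    expect_equal(rc$rank, 1:256)
  }
})
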