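test_that("split_data is exact, stratified and seeded", {
  labels <- rep(0:1, each = 5000)
  sp <- split_data(10000, labels, 0.375, seed = 1)
  expect_length(sp$test, 3750L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), 1:10000)
  expect_equal(sum(labels[sp$test] == 0), 1875)
  expect_identical(split_data(10000, labels, 0.375, seed = 1), sp)
  expect_false(identical(split_data(10000, labels, 0.375, seed = 2), sp))
})

test_that("split stratification holds within one observation for odd counts", {
  labels <- rep(0:2, c(11, 7, 5))
  sp <- split_data(23, labels, 0.3, seed = 3)
  expect_length(sp$test, round(23 * 0.3))
  for (k in 0:2) {
    nk <- sum(labels == k)
    tk <- sum(labels[sp$test] == k)
    expect_lte(abs(tk - nk * 0.3), 1)
  }
})

test_that("split_data rejects degenerate inputs", {
  expect_error(split_data(10, rep(0:1, 5), 0), "between 0 and 1")
  expect_error(split_data(10, rep(0:1, 5), 1), "between 0 and 1")
  expect_error(split_data(3, c(0, 0, 1), 0.5), "at least 2")
})

test_that("training separates noise-free-ish toy patterns quickly", {
  toy <- generate_toy_patterns(400, 28, 2, noise_sd = 0.05, seed = 11)
  sp <- split_data(400, toy$labels, 0.25, seed = 3)
  m <- build_model(28, 2, arch = "resnet_small", seed = 5)
  cfg <- run_config(epochs = 5, accuracy_target = 0.95, seed = 9,
                    arch = "resnet_small")
  res <- train_model(m,
    list(images = toy$images[, , sp$train], labels = toy$labels[sp$train]),
    list(images = toy$images[, , sp$test], labels = toy$labels[sp$test]),
    cfg)
  expect_gte(max(res$metrics$test_acc), 0.95)
  expect_lte(res$epochs_run, 5L)
  # metric arrays cover exactly the epochs run; correctness flags match
  expect_equal(nrow(res$metrics), res$epochs_run)
  expect_equal(res$correct,
               res$predictions == toy$labels[sp$test])
  expect_true(all(res$metrics$train_acc >= 0 & res$metrics$train_acc <= 1))
})

test_that("permuted labels train to chance-level held-out accuracy", {
  toy <- generate_toy_patterns(240, 16, 2, noise_sd = 0.05, seed = 17)
  set.seed(29)
  shuffled <- sample(toy$labels)
  sp <- split_data(240, shuffled, 0.3, seed = 5)
  m <- build_model(16, 2, arch = "resnet_small", seed = 2, pool_grid = 16)
  cfg <- run_config(epochs = 3, accuracy_target = 0.99, seed = 7,
                    arch = "resnet_small")
  res <- train_model(m,
    list(images = toy$images[, , sp$train], labels = shuffled[sp$train]),
    list(images = toy$images[, , sp$test], labels = shuffled[sp$test]),
    cfg)
  final <- res$metrics$test_acc[res$epochs_run]
  expect_lte(abs(final - 0.5), 0.1)
})

test_that("run_pipeline respects max_iterations and the convergence rule", {
  tab <- generate_nihs(small_nihs(120, 256, idx = c(5, 200), seed = 19))
  cfg1 <- run_config(epochs = 2, max_iterations = 1, seed = 3,
                     arch = "resnet_small", pool_grid = 16,
                     attribution_method = "saliency")
  r1 <- run_pipeline(tab, cfg1)
  expect_length(r1$iterations, 1L)
  # a tolerance of 1 with no accuracy requirement stops right after iteration 2
  cfg2 <- run_config(epochs = 1, max_iterations = 5, convergence_tol = 1.0,
                     accuracy_target = 0, seed = 3, arch = "resnet_small",
                     pool_grid = 16, attribution_method = "saliency")
  r2 <- run_pipeline(tab, cfg2)
  expect_length(r2$iterations, 2L)
  expect_equal(r2$converged_at, 2L)
  expect_length(r2$accuracy$per_iteration, 2L)
})

test_that("iteration splits differ but each is stratified and exhaustive", {
  tab <- generate_nihs(small_nihs(80, 256, idx = c(2, 250), seed = 23))
  cfg <- run_config(epochs = 1, max_iterations = 2, accuracy_target = 2,
                    seed = 11, arch = "resnet_small", pool_grid = 16,
                    attribution_method = "saliency")
  r <- run_pipeline(tab, cfg)
  s1 <- r$iterations[[1]]$split
  s2 <- r$iterations[[2]]$split
  expect_false(identical(s1$test, s2$test))
  for (s in list(s1, s2)) {
    expect_setequal(c(s$train, s$test), 1:80)
    expect_equal(sum(tab$labels[s$test] == 0), sum(tab$labels[s$test] == 1))
  }
})

test_that("signal-free data stays at chance across pipeline iterations", {
  tab <- generate_nihs(nihs_config(n_obs = 160, n_features = 256,
                                   informative = list(), seed = 37))
  cfg <- run_config(epochs = 2, max_iterations = 3, accuracy_target = 2,
                    convergence_tol = 0, seed = 13, arch = "resnet_small",
                    pool_grid = 16, attribution_method = "saliency")
  r <- suppressWarnings(run_pipeline(tab, cfg))
  expect_length(r$iterations, 3L)
  expect_gte(r$accuracy$mean, 0.4)
  expect_lte(r$accuracy$mean, 0.6)
})
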