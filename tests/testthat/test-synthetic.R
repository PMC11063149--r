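test_that("NIHS generator plants class-conditional ranges and uniform noise", {
  cfg <- small_nihs(300, 400, idx = c(21, 174), seed = 9)
  tab <- generate_nihs(cfg)
  expect_equal(dim(tab$values), c(300L, 400L))
  expect_equal(sort(unique(tab$labels)), 0:1)
  expect_equal(sum(tab$labels == 0), 150)
  v20 <- tab$values[, 21]
  expect_true(all(v20[tab$labels == 0] >= 0 & v20[tab$labels == 0] < 0.2))
  expect_true(all(v20[tab$labels == 1] >= 0.2 & v20[tab$labels == 1] < 0.4))
  v2 <- tab$values[, 174]
  expect_true(all(v2[tab$labels == 0] >= 0.10 & v2[tab$labels == 0] < 0.20))
  expect_true(all(v2[tab$labels == 1] >= 0.25 & v2[tab$labels == 1] < 0.35))
  noise <- tab$values[, -c(21, 174)]
  expect_true(all(noise >= 0 & noise < 1))
  # a single threshold on the first planted feature separates perfectly
  expect_equal(mean((v20 >= 0.2) == (tab$labels == 1)), 1.0)
})

test_that("NIHS generation is reproducible from its seed and indices validate", {
  a <- generate_nihs(small_nihs(50, 64, idx = c(3, 9), seed = 4))
  b <- generate_nihs(small_nihs(50, 64, idx = c(3, 9), seed = 4))
  c <- generate_nihs(small_nihs(50, 64, idx = c(3, 9), seed = 5))
  expect_identical(a$values, b$values)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$values, c$values))
  expect_error(nihs_config(n_obs = 10, n_features = 8,
                           informative = list(informative_feature(
                             9, list(c(0, 0.5), c(0.5, 1))))),
               "exceeds n_features")
  expect_error(informative_feature(1, list(c(0.3, 0.2), c(0, 1))), "low < high")
})

test_that("signal-free NIHS carries no class information", {
  cfg <- nihs_config(n_obs = 60, n_features = 40, informative = list(),
                     seed = 21)
  tab <- generate_nihs(cfg)
  expect_true(all(tab$values >= 0 & tab$values < 1))
  # permutation test on the most separating column: observed max |t| should
  # not be extreme relative to label permutations (alpha = 0.01)
  tstat <- function(lab) {
    m0 <- colMeans(tab$values[lab == 0, ])
    m1 <- colMeans(tab$values[lab == 1, ])
    max(abs(m1 - m0))
  }
  obs <- tstat(tab$labels)
  set.seed(33)
  null <- replicate(199, tstat(sample(tab$labels)))
  p <- (1 + sum(null >= obs)) / 200
  expect_gt(p, 0.01)
})

test_that("class balance follows the requested proportions", {
  cfg <- nihs_config(n_obs = 101, n_features = 16, informative = list(),
                     n_classes = 3, class_balance = c(0.5, 0.3, 0.2), seed = 2)
  tab <- generate_nihs(cfg)
  cnt <- as.integer(table(tab$labels))
  expect_equal(sum(cnt), 101L)
  expect_true(all(abs(cnt - 101 * c(0.5, 0.3, 0.2)) <= 1))
})

test_that("pixel shuffling is a seeded bijection applied identically", {
  set.seed(8)
  imgs <- array(runif(6 * 6 * 4), c(6, 6, 4))
  s1 <- shuffle_pixels(imgs, seed = 13)
  s2 <- shuffle_pixels(imgs, seed = 13)
  expect_identical(s1$permutation, s2$permutation)
  expect_identical(s1$images, s2$images)
  # inverse restores exactly; per-image value multiset unchanged
  expect_identical(unshuffle_pixels(s1$images, s1$permutation), imgs)
  for (i in 1:4) {
    expect_equal(sort(as.vector(s1$images[, , i])),
                 sort(as.vector(imgs[, , i])))
  }
  expect_error(shuffle_pixels(array(0, c(3, 3, 0)), 1), "non-empty")
})

test_that("pixel shuffling commutes with per-image monotone intensity maps", {
  set.seed(2)
  imgs <- array(runif(5 * 5 * 3), c(5, 5, 3))
  f <- function(x) sqrt(x)
  a <- shuffle_pixels(f(imgs), seed = 4)$images
  b <- f(shuffle_pixels(imgs, seed = 4)$images)
  expect_equal(a, b)
})

test_that("toy patterns: noise-free classes are identical and template-separable", {
  toy <- generate_toy_patterns(24, 12, n_classes = 3, noise_sd = 0, seed = 6)
  expect_equal(as.integer(table(toy$labels)), rep(8L, 3))
  for (k in 0:2) {
    cls <- which(toy$labels == k)
    for (i in cls) {
      expect_identical(toy$images[, , i], toy$templates[[k + 1]])
    }
  }
  # nearest-template classification is perfect on noise-free images
  toy2 <- generate_toy_patterns(30, 16, n_classes = 2, noise_sd = 0, seed = 3)
  pred <- vapply(seq_len(30), function(i) {
    d <- vapply(toy2$templates, function(tm)
      sum((toy2$images[, , i] - tm)^2), 1.0)
    which.min(d) - 1L
  }, 1L)
  expect_equal(pred, toy2$labels)
  expect_error(generate_toy_patterns(10, 4), "side")
})

test_that("toy patterns are seeded, clipped to [0,1], and balanced within 1", {
  a <- generate_toy_patterns(21, 10, 2, noise_sd = 0.3, seed = 5)
  b <- generate_toy_patterns(21, 10, 2, noise_sd = 0.3, seed = 5)
  expect_identical(a$images, b$images)
  expect_true(all(a$images >= 0 & a$images <= 1))
  cnt <- as.integer(table(a$labels))
  expect_lte(diff(range(cnt)), 1L)
})

test_that("generated tables round-trip through CSV with the seed comment", {
  tab <- generate_nihs(small_nihs(12, 9, idx = c(2, 7), seed = 31))
  tf <- tempfile(fileext = ".csv")
  write_table_csv(tab, tf, seed = 31)
  expect_true(startsWith(readLines(tf, n = 1), "#"))
  back <- load_table(tf, label_column = "label")
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_equal(back$labels, tab$labels)
  expect_equal(back$label_names, c("class_0", "class_1"))
})
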