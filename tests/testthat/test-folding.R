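test_that("log_normalize maps columns into [0,1] with exact endpoints", {
  # ln(1+0) = 0 and ln(1 + (e-1)) = 1, and min-max is then the identity
  out <- log_normalize(matrix(c(0, exp(1) - 1), 2, 1))
  expect_equal(out, matrix(c(0, 1), 2, 1))
  expect_equal(log_normalize(matrix(5, 3, 1)), matrix(0, 3, 1))
})

test_that("log_normalize is monotone per column, bounded, and shifts negatives", {
  set.seed(7)
  v <- cbind(rnorm(20), rexp(20), runif(20, -3, -1), rep(2, 20))
  out <- log_normalize(v)
  expect_true(all(out >= 0 & out <= 1))
  for (j in 1:3) expect_equal(order(out[, j]), order(v[, j]))
  expect_equal(out[, 4], rep(0, 20))
  bad <- v; bad[3, 2] <- NA
  expect_error(log_normalize(bad), "row 3, column 2")
})

test_that("fold geometry is the smallest enclosing square", {
  s <- compute_fold_spec(19319)
  expect_equal(s$side, 139L)
  expect_equal(s$pad_count, 2L)
  expect_equal(compute_fold_spec(18225)$side, 135L)
  expect_equal(compute_fold_spec(18225)$pad_count, 0L)
  expect_equal(compute_fold_spec(10)$side, 4L)
  expect_equal(compute_fold_spec(10)$pad_count, 6L)
  # tightness invariant over a range of F, including perfect squares
  for (f in c(1:17, 35, 36, 37, 99, 100, 101, 4096, 4097)) {
    sp <- compute_fold_spec(f)
    expect_true((sp$side - 1L)^2 < f && f <= sp$side^2)
  }
  expect_error(compute_fold_spec(4, order = c(1, 1, 2, 3)), "permutation")
})

test_that("fold_vector fills row-major with tail padding and honours order", {
  expect_equal(fold_vector(1:4, compute_fold_spec(4)),
               matrix(c(1, 2, 3, 4), 2, byrow = TRUE))
  expect_equal(fold_vector(1:3, compute_fold_spec(3)),
               matrix(c(1, 2, 3, 0), 2, byrow = TRUE))
  expect_equal(fold_vector(1:4, compute_fold_spec(4, order = 4:1)),
               matrix(c(4, 3, 2, 1), 2, byrow = TRUE))
  expect_error(fold_vector(1:5, compute_fold_spec(4)), "does not match")
})

test_that("pixel_to_feature inverts the fold, flagging padding", {
  sp3 <- compute_fold_spec(3)
  expect_true(is.na(pixel_to_feature(sp3, 2, 2)))
  sp4 <- compute_fold_spec(4)
  expect_equal(pixel_to_feature(sp4, 2, 1), 3L)
  expect_error(pixel_to_feature(sp4, 0, 1), "out of range")
  expect_error(pixel_to_feature(sp4, 1, 3), "out of range")
  # full round trip under a random permutation
  set.seed(5)
  sp <- compute_fold_spec(23, order = sample(23))
  img <- fold_vector(seq_len(23), sp)
  for (r in seq_len(sp$side)) {
    for (c in seq_len(sp$side)) {
      f <- pixel_to_feature(sp, r, c)
      if (is.na(f)) expect_identical(img[r, c], 0) else
        expect_identical(img[r, c], as.numeric(f))
    }
  }
})

test_that("fold_dataset and unfold_dataset are exact inverses", {
  set.seed(11)
  for (ord in list(NULL, sample(12))) {
    v <- matrix(runif(60), 5, 12)
    tab <- make_table(v, labels = rep(0:1, c(2, 3)),
                      label_names = c("a", "b"))
    sp <- compute_fold_spec(12, order = ord)
    imgs <- fold_dataset(tab, sp)
    expect_equal(dim(imgs$images), c(4, 4, 5))
    expect_equal(imgs$labels, tab$labels)
    expect_equal(unfold_dataset(imgs), v)
    # padding pixels are exactly zero in every image
    flat <- aperm(imgs$images, c(2, 1, 3))
    dim(flat) <- c(16, 5)
    expect_true(all(flat[13:16, ] == 0))
  }
  expect_error(fold_dataset(make_table(matrix(1, 2, 5)),
                            compute_fold_spec(4)), "fold spec")
})

test_that("folding with a permuted order equals permuting then identity-folding", {
  set.seed(3)
  v <- runif(10)
  ord <- sample(10)
  sp_perm <- compute_fold_spec(10, order = ord)
  sp_id <- compute_fold_spec(10)
  expect_equal(fold_vector(v, sp_perm), fold_vector(v[ord], sp_id))
})

test_that("an all-zero observation folds to an all-zero image", {
  tab <- make_table(rbind(runif(6), 0), labels = NULL)
  imgs <- fold_dataset(tab, compute_fold_spec(6))
  expect_true(all(imgs$images[, , 2] == 0))
})

test_that("read_feature_order turns an index file into a fold permutation", {
  idx <- tiny_csv(c("feature_name,rank", "f2,1", "f3,2", "f1,3"))
  ord <- read_feature_order(idx, c("f1", "f2", "f3"))
  expect_equal(ord, c(2L, 3L, 1L))
  v <- c(f1 = 10, f2 = 20, f3 = 30)
  sp <- compute_fold_spec(3, order = ord)
  expect_equal(fold_vector(v, sp), matrix(c(20, 30, 10, 0), 2, byrow = TRUE))
  bad <- tiny_csv(c("feature_name,rank", "f2,1", "f3,2"))
  expect_error(read_feature_order(bad, c("f1", "f2", "f3")), "exactly once")
})
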