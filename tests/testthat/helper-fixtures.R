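# Shared fixtures, all generated in code.

tiny_csv <- function(lines, ext = ".csv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

# the canonical 3x2 labeled table used in the io tests
tiny_table_file <- function() {
  tiny_csv(c("f1,f2,label", "1,2,a", "3,4,b", "5,6,a"))
}

make_table <- function(values, labels = NULL, label_names = NULL) {
  feature_table(values, labels = labels, label_names = label_names)
}

# small NIHS config with the two canonical range pairs planted at given columns
small_nihs <- function(n_obs, n_features, idx = NULL, seed = 1) {
  inf <- if (!is.null(idx)) {
    list(informative_feature(idx[1], list(c(0.00, 0.20), c(0.20, 0.40))),
         informative_feature(idx[2], list(c(0.10, 0.20), c(0.25, 0.35))))
  }
  nihs_config(n_obs = n_obs, n_features = n_features, informative = inf,
              seed = seed)
}

# build a 'linear' model whose single active head weight reads one pixel of
# the pool grid; with pool_grid = side each grid cell is exactly one pixel
one_pixel_model <- function(side, row, col, weight = 1) {
  m <- build_model(side, 2, arch = "linear", seed = 1, pool_grid = side)
  W <- matrix(0, 2, side * side)
  # head input is the pooled (C=1, gh, gw) map flattened C-first: for C = 1
  # the flat index of grid cell (r, c) is r + (c - 1) * side
  W[2, row + (col - 1) * side] <- weight
  m$params$fc.W <- W
  m$params$fc.b <- c(0, 0)
  m
}
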