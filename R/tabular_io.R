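# Reading, merging, filtering and label-encoding of delimited feature tables.

#' Construct a feature table
#'
#' The canonical in-memory form used throughout the pipeline: a numeric
#' observations x features matrix with unique row/column identifiers and an
#' optional integer class-label vector.
#'
#' @param values Numeric matrix, `n_obs x F`; all entries must be finite.
#' @param feature_names Character vector of unique feature names, length `F`.
#' @param observation_ids Character vector of unique observation ids, length
#'   `n_obs`.
#' @param labels Optional integer vector of 0-based class codes, length
#'   `n_obs`.
#' @param label_names Optional character vector mapping class code `k` to its
#'   original label string (element `k + 1`).
#' @param filter_log Optional list recording rows/columns removed by
#'   [filter_empty()].
#' @return An object of class `feature_table`.
#' @seealso [load_table()], [filter_empty()], [encode_labels()]
#' @export
feature_table <- function(values, feature_names = colnames(values),
                          observation_ids = rownames(values),
                          labels = NULL, label_names = NULL,
                          filter_log = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names)) feature_names <- paste0("V", seq_len(ncol(values)))
  if (is.null(observation_ids)) observation_ids <- paste0("obs_", seq_len(nrow(values)))
  feature_names <- as.character(feature_names)
  observation_ids <- as.character(observation_ids)
  if (length(feature_names) != ncol(values)) {
    stop("`feature_names` length must equal ncol(values)", call. = FALSE)
  }
  if (length(observation_ids) != nrow(values)) {
    stop("`observation_ids` length must equal nrow(values)", call. = FALSE)
  }
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique; duplicated: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(observation_ids)) {
    stop("observation ids must be unique", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at observation '%s', feature '%s'",
                 observation_ids[bad[1L]], feature_names[bad[2L]]), call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values)) {
      stop("`labels` length must equal nrow(values)", call. = FALSE)
    }
    k <- length(label_names %||% unique(labels))
    if (any(labels < 0L) || any(labels >= k)) {
      stop("label codes must lie in [0, n_classes)", call. = FALSE)
    }
  }
  dimnames(values) <- NULL
  structure(
    list(values = values, feature_names = feature_names,
         observation_ids = observation_ids, labels = labels,
         label_names = label_names, filter_log = filter_log),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d observations x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    nm <- if (!is.null(x$label_names)) x$label_names[as.integer(names(tab)) + 1L] else names(tab)
    cat("  classes:", paste(sprintf("%s (%d)", nm, tab), collapse = ", "), "\n")
  } else {
    cat("  unlabeled\n")
  }
  if (!is.null(x$filter_log)) {
    cat(sprintf("  filtered: %d observations, %d features removed\n",
                length(x$filter_log$removed_observations),
                length(x$filter_log$removed_features)))
  }
  invisible(x)
}

#' Read a delimited feature table
#'
#' Reads a CSV/TSV file with a header row into a [feature_table()]. Every
#' non-label column must be numeric; empty cells are read as 0 (and counted in
#' the returned table's `filter_log`). Files ending in `.gz` are decompressed
#' transparently. A first line starting with `#` (as written by the
#' `generate-nihs` CLI subcommand to record the seed) is skipped.
#'
#' @param path Path to the file.
#' @param delimiter Single field-separator character (default `","`).
#' @param label_column Name of the column holding class labels, or `NULL` for
#'   an unlabeled table.
#' @param id_column Optional name of a column holding observation ids; when
#'   absent, row numbers are used.
#' @return A [feature_table()]; when `label_column` is given, labels are
#'   integer codes assigned by [encode_labels()] and `label_names` holds the
#'   original strings.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("f1,f2,label", "1,2,a", "3,4,b", "5,6,a"), tf)
#' tab <- load_table(tf, label_column = "label")
#' tab$labels        # 0 1 0
#' @export
load_table <- function(path, delimiter = ",", label_column = NULL,
                       id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gz <- grepl("\\.gz$", path)
  first <- if (gz) {
    con <- gzfile(path, "rt"); on.exit(close(con), add = TRUE)
    readLines(con, n = 1L)
  } else {
    readLines(path, n = 1L)
  }
  if (length(first) == 0L) stop("empty input file: ", path, call. = FALSE)
  skip <- if (startsWith(first[1L], "#")) 1L else 0L
  df <- if (gz) {
    utils::read.table(gzfile(path), sep = delimiter, header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      skip = skip, comment.char = "")
  } else {
    as.data.frame(data.table::fread(path, sep = delimiter, header = TRUE,
                                    check.names = FALSE, data.table = FALSE,
                                    skip = skip))
  }
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop("empty input file: ", path, call. = FALSE)
  }
  if (anyDuplicated(names(df))) {
    stop("duplicated column names in ", path, call. = FALSE)
  }

  labels <- NULL; label_names <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      stop(sprintf("label column '%s' not found in %s", label_column, path),
           call. = FALSE)
    }
    enc <- encode_labels(as.character(df[[label_column]]))
    labels <- enc$codes
    label_names <- enc$mapping
    df[[label_column]] <- NULL
  }
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) {
      stop(sprintf("id column '%s' not found in %s", id_column, path),
           call. = FALSE)
    }
    ids <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
  }
  if (ncol(df) == 0L) stop("no feature columns left in ", path, call. = FALSE)

  n_empty <- 0L
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.character(col)) {
      blank <- !nzchar(trimws(col))
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !blank)
      if (length(bad)) {
        stop(sprintf(
          "non-numeric value '%s' at row %d, column '%s' (categorical features must be converted to numbers before loading)",
          col[bad[1L]], bad[1L], names(df)[j]), call. = FALSE)
      }
      num[blank] <- 0
      n_empty <- n_empty + sum(blank)
      df[[j]] <- num
    } else if (!is.numeric(col) && !is.logical(col)) {
      stop(sprintf("non-numeric column '%s' (categorical features must be converted to numbers before loading)",
                   names(df)[j]), call. = FALSE)
    }
  }
  vals <- as.matrix(df)
  storage.mode(vals) <- "double"
  miss <- !is.finite(vals)
  if (any(miss)) {
    # empty cells parsed as NA are treated as 0, per the filtering convention
    vals[is.na(vals)] <- 0
    n_empty <- n_empty + sum(miss)
    if (!all(is.finite(vals))) {
      bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-finite value at row %d, column '%s'",
                   bad[1L], colnames(vals)[bad[2L]]), call. = FALSE)
    }
  }
  feature_table(vals, feature_names = colnames(vals), observation_ids = ids,
                labels = labels, label_names = label_names,
                filter_log = list(removed_observations = character(0),
                                  removed_features = character(0),
                                  empty_cells_as_zero = n_empty))
}

#' Merge feature tables by observation id
#'
#' Exact join on observation ids: every table must contain exactly the same
#' set of ids; unmatched ids are an error. Feature columns are concatenated in
#' the order the tables are given.
#'
#' @param tables A list of [feature_table()] objects.
#' @return A single merged [feature_table()]; labels are taken from the first
#'   table that has them (and must agree across tables that do).
#' @export
merge_tables <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  base <- tables[[1L]]
  if (length(tables) == 1L) return(base)
  ids <- base$observation_ids
  vals <- base$values
  fnames <- base$feature_names
  labels <- base$labels; label_names <- base$label_names
  for (k in 2L:length(tables)) {
    tk <- tables[[k]]
    if (!setequal(ids, tk$observation_ids)) {
      missing <- setdiff(ids, tk$observation_ids)
      extra <- setdiff(tk$observation_ids, ids)
      stop(sprintf("observation ids do not match in table %d (missing: %d, unmatched: %d)",
                   k, length(missing), length(extra)), call. = FALSE)
    }
    ord <- match(ids, tk$observation_ids)
    vals <- cbind(vals, tk$values[ord, , drop = FALSE])
    fnames <- c(fnames, tk$feature_names)
    if (is.null(labels) && !is.null(tk$labels)) {
      labels <- tk$labels[ord]; label_names <- tk$label_names
    } else if (!is.null(labels) && !is.null(tk$labels) &&
               !identical(labels, tk$labels[ord])) {
      stop(sprintf("labels disagree between table 1 and table %d", k),
           call. = FALSE)
    }
  }
  feature_table(vals, feature_names = fnames, observation_ids = ids,
                labels = labels, label_names = label_names)
}

#' Drop all-zero observations and features
#'
#' Removes every row whose entries are all zero and every column whose entries
#' are all zero (evaluated simultaneously on the input matrix), leaving all
#' surviving values untouched. The names of removed rows/columns are appended
#' to the table's `filter_log` for reporting. This is the only filtering the
#' pipeline performs: noisy low-variance features are deliberately retained.
#'
#' @param table A [feature_table()].
#' @return The filtered [feature_table()].
#' @export
filter_empty <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  zero_row <- rowSums(v != 0) == 0L
  zero_col <- colSums(v != 0) == 0L
  if (all(zero_row) || all(zero_col)) {
    stop("all observations or all features are empty; nothing to analyse",
         call. = FALSE)
  }
  if (!any(zero_row) && !any(zero_col)) return(table)
  log <- table$filter_log %||% list(removed_observations = character(0),
                                    removed_features = character(0))
  log$removed_observations <- c(log$removed_observations,
                                table$observation_ids[zero_row])
  log$removed_features <- c(log$removed_features,
                            table$feature_names[zero_col])
  feature_table(v[!zero_row, !zero_col, drop = FALSE],
                feature_names = table$feature_names[!zero_col],
                observation_ids = table$observation_ids[!zero_row],
                labels = if (!is.null(table$labels)) table$labels[!zero_row],
                label_names = table$label_names,
                filter_log = log)
}

#' Encode class labels as integer codes
#'
#' Codes are assigned by lexicographic order of the distinct label strings,
#' 0-based, so that runs are reproducible regardless of file row order.
#'
#' @param raw_labels Character vector of class labels.
#' @return A list with `codes` (integer vector, 0-based) and `mapping`
#'   (character vector; element `k + 1` is the label string for code `k`).
#' @examples
#' encode_labels(c("b", "a", "a"))  # codes 1 0 0, mapping c("a", "b")
#' @export
encode_labels <- function(raw_labels) {
  raw_labels <- as.character(raw_labels)
  if (anyNA(raw_labels)) stop("missing values in labels", call. = FALSE)
  lev <- sort(unique(raw_labels))
  if (length(lev) < 2L) {
    stop("need at least 2 distinct labels for a classification task; found ",
         length(lev), call. = FALSE)
  }
  list(codes = match(raw_labels, lev) - 1L, mapping = lev)
}
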