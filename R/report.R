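# Run reports: JSON + CSV + figures, with a checksummed manifest; and the
# command-line front end.

pf_config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg[vapply(cfg, is.null, TRUE)] <- NULL
  cfg
}

#' Write a run report to disk
#'
#' Writes, under `out_dir`: `report.json` (config echo, filter log, fold
#' geometry, per-iteration accuracy summary and the top of each ranking),
#' `ranking.csv` (the full feature ranking), `history.jsonl` (one JSON record
#' per epoch per iteration), `curves.png` (metric curves), one
#' `heatmap_class_<k>.png` per class (mean attribution pseudo-image), and
#' `manifest.csv` listing every written file with its MD5 checksum.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a data frame manifest with columns `file` and `md5`.
#' @export
write_report <- function(result, out_dir) {
  stopifnot(inherits(result, "pf_run"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L) {
    stop("cannot write to directory: ", out_dir, call. = FALSE)
  }
  files <- character(0)

  # full ranking
  ranking_path <- file.path(out_dir, "ranking.csv")
  utils::write.csv(result$ranking, ranking_path, row.names = FALSE,
                   quote = FALSE)
  files <- c(files, ranking_path)

  # epoch-level history as JSON lines
  hist_path <- file.path(out_dir, "history.jsonl")
  con <- file(hist_path, "wt")
  for (i in seq_along(result$iterations)) {
    m <- result$iterations[[i]]$metrics
    for (r in seq_len(nrow(m))) {
      rec <- c(list(iteration = i), as.list(m[r, ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  close(con)
  files <- c(files, hist_path)

  # main JSON report
  top_n <- min(20L, result$fold_spec$n_features)
  rank_head <- result$ranking[result$ranking$rank <= top_n, ]
  report <- list(
    config = pf_config_as_list(result$config),
    filter_log = result$filter_log,
    fold_spec = list(n_features = result$fold_spec$n_features,
                     side = result$fold_spec$side,
                     pad_count = result$fold_spec$pad_count),
    n_iterations = length(result$iterations),
    converged_at = if (is.na(result$converged_at)) NULL else result$converged_at,
    accuracy = list(per_iteration = result$accuracy$per_iteration,
                    mean = result$accuracy$mean, sd = result$accuracy$sd),
    attribution = list(method = result$attribution_summary$method,
                       n_samples_per_class =
                         result$attribution_summary$n_samples_per_class),
    top_features = rank_head
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  files <- c(files, report_path)

  # metric curves
  curves_path <- file.path(out_dir, "curves.png")
  grDevices::png(curves_path, width = 800, height = 500)
  tryCatch({
    graphics::par(mfrow = c(1, 2))
    for (what in c("loss", "acc")) {
      first <- TRUE
      for (i in seq_along(result$iterations)) {
        m <- result$iterations[[i]]$metrics
        ytr <- m[[paste0("train_", what)]]
        yte <- m[[paste0("test_", what)]]
        if (first) {
          rng <- range(unlist(lapply(result$iterations, function(it)
            c(it$metrics[[paste0("train_", what)]],
              it$metrics[[paste0("test_", what)]]))))
          graphics::plot(NULL, xlim = c(1, max(vapply(result$iterations,
            function(it) nrow(it$metrics), 1L))), ylim = rng,
            xlab = "epoch", ylab = what, main = what)
          first <- FALSE
        }
        graphics::lines(m$epoch, ytr, col = "steelblue", lty = i)
        graphics::lines(m$epoch, yte, col = "firebrick", lty = i)
      }
      graphics::legend("topright", legend = c("train", "test"),
                       col = c("steelblue", "firebrick"), lty = 1, bty = "n")
    }
  }, finally = grDevices::dev.off())
  files <- c(files, curves_path)

  # per-class mean attribution heatmaps
  for (k in seq_along(result$attribution_summary$per_class_mean)) {
    hm_path <- file.path(out_dir, sprintf("heatmap_class_%d.png", k - 1L))
    grDevices::png(hm_path, width = 480, height = 480)
    tryCatch({
      m <- result$attribution_summary$per_class_mean[[k]]
      graphics::image(t(m[nrow(m):1, , drop = FALSE]),
                      col = grDevices::hcl.colors(64, "viridis"),
                      axes = FALSE,
                      main = sprintf("mean |attribution|, class %d", k - 1L))
    }, finally = grDevices::dev.off())
    files <- c(files, hm_path)
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

# ---- command line ---------------------------------------------------------

pf_cli_usage <- function() {
  cat("usage: pixelfold <subcommand> [options]\n",
      "subcommands:\n",
      "  generate-nihs  emit a needle-in-a-haystack CSV\n",
      "  fold           fold a table into a cached pseudo-image tensor\n",
      "  train          run the full pipeline and write a report\n",
      "  report         print a summary of a completed run directory\n",
      sep = "")
}

pf_cli_fail <- function(e) {
  message("error: ", conditionMessage(e))
  1L
}

#' Command-line entry point
#'
#' Drives the package from a shell: `generate-nihs`, `fold`, `train` and
#' `report` subcommands (see `inst/cli/pixelfold`). All randomness is
#' governed by `--seed`.
#'
#' @param argv Character vector of command-line arguments (subcommand first).
#' @return Integer exit code: 0 on success, 1 on runtime error, 2 on usage
#'   error.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) < 1L) { pf_cli_usage(); return(2L) }
  sub <- argv[1L]
  rest <- argv[-1L]
  handler <- switch(sub,
    "generate-nihs" = pf_cli_generate,
    "fold" = pf_cli_fold,
    "train" = pf_cli_train,
    "report" = pf_cli_report,
    NULL)
  if (is.null(handler)) {
    message("unknown subcommand: ", sub)
    pf_cli_usage()
    return(2L)
  }
  tryCatch(handler(rest),
           usage_error = function(e) { message(conditionMessage(e)); 2L },
           error = pf_cli_fail)
}

pf_parse <- function(option_list, args, usage) {
  parser <- optparse::OptionParser(option_list = option_list, usage = usage)
  tryCatch(optparse::parse_args(parser, args = args),
           error = function(e) {
             stop(structure(class = c("usage_error", "error", "condition"),
                            list(message = conditionMessage(e), call = NULL)))
           })
}

pf_cli_generate <- function(args) {
  opts <- pf_parse(list(
    optparse::make_option("--n-obs", type = "integer", default = 10000L,
                          dest = "n_obs"),
    optparse::make_option("--n-features", type = "integer", default = 18225L,
                          dest = "n_features"),
    optparse::make_option("--n-classes", type = "integer", default = 2L,
                          dest = "n_classes"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option(c("-o", "--out"), type = "character",
                          default = "nihs.csv")
  ), args, "pixelfold generate-nihs [options]")
  cfg <- nihs_config(n_obs = opts$n_obs, n_features = opts$n_features,
                     n_classes = opts$n_classes, seed = opts$seed)
  tab <- generate_nihs(cfg)
  write_table_csv(tab, opts$out, seed = opts$seed)
  message(sprintf("wrote %d x %d table (+label) to %s",
                  opts$n_obs, opts$n_features, opts$out))
  0L
}

pf_cli_fold <- function(args) {
  opts <- pf_parse(list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--delimiter", type = "character", default = ","),
    optparse::make_option("--label-column", type = "character",
                          default = NULL, dest = "label_column"),
    optparse::make_option("--index", type = "character", default = NULL),
    optparse::make_option(c("-o", "--out"), type = "character",
                          default = "folded")
  ), args, "pixelfold fold --input table.csv [options]")
  if (is.null(opts$input)) stop("--input is required", call. = FALSE)
  tab <- load_table(opts$input, delimiter = opts$delimiter,
                    label_column = opts$label_column)
  tab <- filter_empty(tab)
  ord <- if (!is.null(opts$index)) {
    read_feature_order(opts$index, tab$feature_names)
  }
  spec <- compute_fold_spec(ncol(tab$values), order = ord)
  ntab <- tab
  ntab$values <- log_normalize(tab$values)
  imgs <- fold_dataset(ntab, spec)
  bin_path <- paste0(opts$out, ".bin")
  con <- file(bin_path, "wb")
  writeBin(as.vector(imgs$images), con, size = 8L, endian = "little")
  close(con)
  sidecar <- list(n_obs = dim(imgs$images)[3L], channels = 1L,
                  side = spec$side, n_features = spec$n_features,
                  pad_count = spec$pad_count, order = spec$order,
                  feature_names = tab$feature_names,
                  labels = tab$labels, storage = "float64-little-endian",
                  layout = "side,side,n (column-major)")
  jsonlite::write_json(sidecar, paste0(opts$out, ".json"), auto_unbox = TRUE,
                       digits = NA)
  message(sprintf("wrote %s and %s (%d images, %dx%d)", bin_path,
                  paste0(opts$out, ".json"), dim(imgs$images)[3L],
                  spec$side, spec$side))
  0L
}

pf_cli_train <- function(args) {
  opts <- pf_parse(list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--delimiter", type = "character", default = ","),
    optparse::make_option("--label-column", type = "character",
                          default = "label", dest = "label_column"),
    optparse::make_option("--index", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--epochs", type = "integer", default = 15L),
    optparse::make_option("--max-iterations", type = "integer", default = 5L,
                          dest = "max_iterations"),
    optparse::make_option("--holdout-fraction", type = "double",
                          default = 0.375, dest = "holdout_fraction"),
    optparse::make_option("--arch", type = "character",
                          default = "resnet_small"),
    optparse::make_option("--batch-size", type = "integer", default = 32L,
                          dest = "batch_size"),
    optparse::make_option("--learning-rate", type = "double", default = 1e-3,
                          dest = "learning_rate"),
    optparse::make_option("--attribution", type = "character",
                          default = "integrated-gradients"),
    optparse::make_option("--out-dir", type = "character", default = "run",
                          dest = "out_dir")
  ), args, "pixelfold train --input table.csv [options]")
  if (is.null(opts$input)) stop("--input is required", call. = FALSE)
  tab <- load_table(opts$input, delimiter = opts$delimiter,
                    label_column = opts$label_column)
  ord <- if (!is.null(opts$index)) {
    read_feature_order(opts$index, tab$feature_names)
  }
  cfg <- run_config(holdout_fraction = opts$holdout_fraction,
                    epochs = opts$epochs,
                    max_iterations = opts$max_iterations,
                    seed = opts$seed, arch = opts$arch,
                    batch_size = opts$batch_size,
                    learning_rate = opts$learning_rate,
                    attribution_method = opts$attribution)
  res <- run_pipeline(tab, cfg, feature_order = ord)
  write_report(res, opts$out_dir)
  message(sprintf("run complete: held-out accuracy %.3f +/- %.3f; report in %s",
                  res$accuracy$mean, res$accuracy$sd, opts$out_dir))
  0L
}

pf_cli_report <- function(args) {
  opts <- pf_parse(list(
    optparse::make_option("--run-dir", type = "character", default = "run",
                          dest = "run_dir")
  ), args, "pixelfold report --run-dir DIR")
  path <- file.path(opts$run_dir, "report.json")
  if (!file.exists(path)) stop("no report.json in ", opts$run_dir, call. = FALSE)
  rep <- jsonlite::fromJSON(path)
  cat(sprintf("run of %d iteration(s), fold %dx%d (%d features, %d padding)\n",
              rep$n_iterations, rep$fold_spec$side, rep$fold_spec$side,
              rep$fold_spec$n_features, rep$fold_spec$pad_count))
  cat(sprintf("held-out accuracy: %.4f +/- %.4f\n",
              rep$accuracy$mean, rep$accuracy$sd))
  top <- rep$top_features
  top <- top[top$class == "overall", ]
  cat("top overall features:\n")
  for (r in seq_len(min(10L, nrow(top)))) {
    cat(sprintf("  %2d. %s (%.4g)\n", top$rank[r], top$feature_name[r],
                top$mean_score[r]))
  }
  0L
}
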