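#' Run the end-to-end pipeline
#'
#' Executes the selected stages against one output directory:
#' \describe{
#'   \item{synth}{generate the labelled synthetic dataset and manifest.}
#'   \item{train-sa}{train the scale-adaptive auto-encoder; writes
#'     `sa_model.rds` and `sa_history.csv`.}
#'   \item{train-clf}{train the grading classifier on SA-resized images;
#'     writes `clf_model.rds`, `clf_history.csv` and `split.csv`.}
#'   \item{evaluate}{score the held-out test split; writes `metrics.csv`
#'     (column order `model,tp,tn,fp,fn,precision,sensitivity,f1,specificity,accuracy,auc`),
#'     `confusion.csv` and `roc.csv`.}
#'   \item{cv}{stratified k-fold cross-validation for each configured k;
#'     writes `cv_summary.csv`.}
#' }
#' Stage seeds all derive from the single global seed and are recorded with
#' per-stage timings in `run_log.csv`. A stage whose upstream artifact is
#' missing fails with a dependency error naming the stage to run first.
#'
#' @param config configuration list (see [default_run_config()] /
#'   [parse_run_config()]).
#' @param stages subset of `c("synth", "train-sa", "train-clf", "evaluate",
#'   "cv")`.
#' @param out_dir output directory (default `config$eval$output_dir`).
#' @param verbose print stage progress.
#' @return invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("synth", "train-sa", "train-clf",
                                    "evaluate", "cv"),
                         out_dir = NULL, verbose = TRUE) {
  config <- validate_run_config(merge_config(default_run_config(), config))
  stages <- match.arg(stages, c("synth", "train-sa", "train-clf",
                                "evaluate", "cv"), several.ok = TRUE)
  out_dir <- out_dir %||% config$eval$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data_dir <- file.path(out_dir, "data")
  results <- list()
  log_rows <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  run_stage <- function(stage, seed, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- fn(seed)
    dt <- proc.time()[["elapsed"]] - t0
    log_rows[[stage]] <<- data.frame(stage = stage, seed = seed,
                                     seconds = round(dt, 2))
    say("[%s] done in %.1fs (seed %d)", stage, dt, seed)
    res
  }

  need <- function(path, producer) {
    if (!file.exists(path))
      stop("dependency error: missing artifact '", basename(path),
           "'; run stage '", producer, "' first")
    path
  }

  if ("synth" %in% stages) {
    results$synth <- run_stage("synth", derive_seed(config$seed, 1L), function(seed) {
      sc <- synthetic_config(config$synth$n_per_grade, config$synth$size_range,
                             seed = seed)
      generate_dataset(sc, data_dir)
    })
  }

  manifest_path <- file.path(data_dir, "manifest.csv")

  if ("train-sa" %in% stages) {
    need(manifest_path, "synth")
    results$train_sa <- run_stage("train-sa", derive_seed(config$seed, 2L), function(seed) {
      manifest <- read_manifest(manifest_path)
      n_max <- config$sa$train$max_images
      if (!is.null(n_max) && nrow(manifest) > n_max) {
        old <- local_rng(seed)
        keep <- unlist(lapply(split(seq_len(nrow(manifest)), manifest$grade),
                              function(i) i[sample.int(length(i),
                                                       max(1L, n_max %/% 4L))]))
        restore_rng(old)
        manifest <- manifest[sort(keep), , drop = FALSE]
      }
      imgs <- manifest_images(manifest)
      sa_cfg <- config_to_sa(config)
      model <- build_sa(sa_cfg$arch, seed = seed)
      fit <- train_sa(model, imgs, sa_cfg$train, verbose = verbose)
      saveRDS(fit$model, file.path(out_dir, "sa_model.rds"))
      write_loss_history(fit$history, file.path(out_dir, "sa_history.csv"))
      fit
    })
  }

  if ("train-clf" %in% stages) {
    need(manifest_path, "synth")
    need(file.path(out_dir, "sa_model.rds"), "train-sa")
    results$train_clf <- run_stage("train-clf", derive_seed(config$seed, 4L), function(seed) {
      manifest <- read_manifest(manifest_path)
      sa_model <- readRDS(file.path(out_dir, "sa_model.rds"))
      cfg <- config_to_clf(config)
      fit <- train_classifier(manifest, sa_model, cfg, verbose = verbose)
      saveRDS(fit$model, file.path(out_dir, "clf_model.rds"))
      utils::write.csv(fit$history, file.path(out_dir, "clf_history.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(fit$manifest, file.path(out_dir, "split.csv"),
                       row.names = FALSE, quote = FALSE)
      fit
    })
  }

  if ("evaluate" %in% stages) {
    need(file.path(out_dir, "clf_model.rds"), "train-clf")
    need(file.path(out_dir, "split.csv"), "train-clf")
    results$evaluate <- run_stage("evaluate", derive_seed(config$seed, 6L), function(seed) {
      clf <- readRDS(file.path(out_dir, "clf_model.rds"))
      sa_model <- readRDS(file.path(out_dir, "sa_model.rds"))
      split_df <- utils::read.csv(file.path(out_dir, "split.csv"),
                                  stringsAsFactors = FALSE)
      attr(split_df, "dir") <- normalizePath(data_dir)
      test_df <- split_df[split_df$split == "test", , drop = FALSE]
      if (!nrow(test_df)) test_df <- split_df  # degenerate tiny runs
      imgs <- manifest_images(test_df)
      probs <- t(vapply(imgs, function(im)
        predict_grade(clf, sa_model, im)$probs, numeric(4)))
      pred <- clf$grade_order[max.col(probs, ties.method = "first")]
      cm <- confusion(test_df$grade, pred)
      roc <- roc_auc(grade_one_hot(test_df$grade), probs)
      rep <- micro_metrics(cm, auc = roc$auc)
      row <- metrics_row(paste0("SA + ", clf$backbone$name), cm, rep)
      utils::write.csv(row, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(as.data.frame(cm$matrix),
                       file.path(out_dir, "confusion.csv"), quote = FALSE)
      utils::write.csv(roc$roc, file.path(out_dir, "roc.csv"),
                       row.names = FALSE, quote = FALSE)
      list(confusion = cm, metrics = rep, roc = roc, row = row)
    })
  }

  if ("cv" %in% stages) {
    need(manifest_path, "synth")
    need(file.path(out_dir, "sa_model.rds"), "train-sa")
    results$cv <- run_stage("cv", derive_seed(config$seed, 8L), function(seed) {
      manifest <- read_manifest(manifest_path)
      sa_model <- readRDS(file.path(out_dir, "sa_model.rds"))
      imgs <- manifest_images(manifest)
      cfg <- config_to_clf(config)
      cfg$epochs <- as.integer(config$eval$cv_epochs)
      rows <- list()
      for (k in config$eval$k) {
        cv <- kfold_cv(manifest, k, seed = seed, train_fn = function(tr, va, fold) {
          tr$split <- "train"; va$split <- "val"
          fit <- train_classifier(rbind(tr, va), sa_model, cfg, images = imgs)
          pred <- vapply(va$id, function(id)
            predict_grade(fit$model, sa_model, imgs[[id]])$label, "")
          mean(pred == va$grade)
        })
        rows[[as.character(k)]] <- data.frame(k = k, mean = cv$mean, std = cv$std)
      }
      out <- do.call(rbind, rows)
      utils::write.csv(out, file.path(out_dir, "cv_summary.csv"),
                       row.names = FALSE, quote = FALSE)
      out
    })
  }

  utils::write.csv(do.call(rbind, log_rows), file.path(out_dir, "run_log.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(results)
}
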