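#' Experiment configuration
#'
#' One serializable bundle tying together the synthetic-data settings, the
#' model, the loss, the training protocol and the fold geometry, so every
#' constant of the protocol (batch size 8, 100 epochs, lr 1e-4 with 0.98
#' decay, Tversky 0.7/0.3/1.3, eps 1e-3, weight constant 100, certainty
#' weights 0.5/1.0/1.5) is a named, defaulted key. Accepts a YAML file or
#' a nested list; omitted keys take the defaults of the respective
#' constructors.
#'
#' @param x Path to a YAML file, or a nested list with (optional) entries
#'   `synth`, `model`, `loss`, `train`, `split`.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  cfg <- structure(list(
    synth = do.call(synth_config, x$synth %||% list()),
    model = do.call(model_spec, x$model %||% list()),
    loss = do.call(loss_config, x$loss %||% list()),
    train = do.call(train_config, x$train %||% list()),
    split = utils::modifyList(list(n_test = NULL, k = 7, seed = 1),
                              x$split %||% list())
  ), class = "experiment_config")
  cfg
}

config_hash <- function(config) rlang::hash(unclass_deep(config))

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x[order(names(x))], unclass_deep)
  x
}

#' Run a full experiment
#'
#' Generates (or loads) a dataset, builds the test/fold plan, runs
#' cross-validation and writes all artefacts to a run directory:
#' `config.yaml`, per-fold epoch curves (`curve_fold_i.csv`), the per-fold
#' and fold-averaged summary tables, row-normalised confusion CSVs per
#' checkpoint criterion, and a provenance JSON (seeds, config hash,
#' per-fold class frequencies and weights).
#'
#' @param config An [experiment_config()] (or list/path coercible to one).
#' @param run_dir Output directory for run artefacts.
#' @param dataset_dir Optional existing dataset directory (from
#'   [generate_dataset()]); if `NULL` the dataset is generated under
#'   `run_dir/dataset`.
#' @param overwrite Allow reuse of a non-empty run directory.
#' @param verbose Per-epoch progress lines.
#' @return The `wound_cv` result, invisibly, with the run directory in
#'   attribute `"run_dir"`.
#' @export
run_experiment <- function(config, run_dir, dataset_dir = NULL,
                           overwrite = FALSE, verbose = FALSE) {
  if (!inherits(config, "experiment_config")) {
    config <- experiment_config(config)
  }
  if (dir.exists(run_dir) && length(dir(run_dir)) > 0 && !overwrite) {
    stop("run directory exists and is not empty: ", run_dir)
  }
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(dataset_dir)) {
    dataset_dir <- file.path(run_dir, "dataset")
    ds <- generate_dataset(config$synth, dataset_dir, overwrite = overwrite)
    dataset <- list(images = ds$images, masks = ds$masks,
                    annotations = ds$annotations, manifest = ds$manifest)
  } else {
    if (!file.exists(file.path(dataset_dir, "manifest.json"))) {
      stop("no dataset manifest found in ", dataset_dir)
    }
    dataset <- load_dataset(dataset_dir)
  }
  ids <- names(dataset$images)
  n_test <- config$split$n_test %||% max(2L, round(0.1 * length(ids)))
  plan <- make_splits(ids, n_test = n_test, k = config$split$k,
                      seed = config$split$seed)
  cv <- run_cross_validation(dataset$images, dataset$masks, plan,
                             config$model, config$loss, config$train,
                             verbose = verbose)
  yaml::write_yaml(unclass_deep(config), file.path(run_dir, "config.yaml"))
  for (i in seq_along(cv$folds)) {
    utils::write.csv(cv$folds[[i]]$curve,
                     file.path(run_dir, sprintf("curve_fold_%d.csv", i)),
                     row.names = FALSE)
  }
  utils::write.csv(tidy.wound_cv(cv), file.path(run_dir, "per_fold.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$summary, file.path(run_dir, "summary.csv"),
                   row.names = FALSE)
  for (crit in names(cv$pooled_confusion)) {
    utils::write.csv(normalize_confusion(cv$pooled_confusion[[crit]]),
                     file.path(run_dir,
                               sprintf("confusion_%s.csv", crit)))
  }
  provenance <- list(
    config_hash = config_hash(config),
    dataset_manifest = dataset$manifest,
    split = list(n_test = n_test, k = config$split$k,
                 seed = config$split$seed),
    folds = lapply(cv$folds, function(f) list(
      frequencies = as.list(f$frequencies),
      class_weights = as.list(f$class_weights$w),
      weight_scheme = f$class_weights$scheme
    ))
  )
  jsonlite::write_json(provenance, file.path(run_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(cv, "run_dir") <- run_dir
  invisible(cv)
}

#' Read the artefacts of a completed (or partial) run
#'
#' @param run_dir Run directory written by [run_experiment()].
#' @return List with `summary`, `per_fold`, `curves` (one tibble, with a
#'   `fold` column), and `confusion` (named list of row-normalised
#'   matrices).
#' @export
report_run <- function(run_dir) {
  sf <- file.path(run_dir, "summary.csv")
  if (!file.exists(sf)) stop("no run artefacts in ", run_dir)
  curves <- list()
  for (f in sort(dir(run_dir, pattern = "^curve_fold_\\d+\\.csv$"))) {
    fold <- as.integer(sub("curve_fold_(\\d+)\\.csv", "\\1", f))
    curves[[length(curves) + 1L]] <-
      dplyr::mutate(tibble::as_tibble(
        utils::read.csv(file.path(run_dir, f))), fold = fold)
  }
  confusion <- list()
  for (f in dir(run_dir, pattern = "^confusion_.*\\.csv$")) {
    crit <- sub("^confusion_(.*)\\.csv$", "\\1", f)
    m <- as.matrix(utils::read.csv(file.path(run_dir, f), row.names = 1))
    colnames(m) <- rownames(m)
    confusion[[crit]] <- m
  }
  list(
    summary = tibble::as_tibble(utils::read.csv(sf)),
    per_fold = tibble::as_tibble(
      utils::read.csv(file.path(run_dir, "per_fold.csv"))),
    curves = if (length(curves) > 0) dplyr::bind_rows(curves) else NULL,
    confusion = confusion
  )
}

#' Side-by-side comparison of two runs
#'
#' Joins the fold-averaged summaries of two runs (for example certainty
#' weighting on vs off) and adds delta columns.
#'
#' @param run_a,run_b Run directories.
#' @param labels Length-2 character labels for the two runs.
#' @return A tibble with one row per checkpoint criterion.
#' @export
compare_runs <- function(run_a, run_b, labels = c("a", "b")) {
  sa <- report_run(run_a)$summary
  sb <- report_run(run_b)$summary
  out <- dplyr::inner_join(sa, sb, by = "criterion",
                           suffix = paste0("_", labels))
  out$delta_mpa <- out[[paste0("mean_pixel_accuracy_", labels[2])]] -
    out[[paste0("mean_pixel_accuracy_", labels[1])]]
  out$delta_miou <- out[[paste0("mean_iou_", labels[2])]] -
    out[[paste0("mean_iou_", labels[1])]]
  tibble::as_tibble(out)
}

#' Dataset statistics table for a dataset directory
#'
#' Loads a generated dataset and tabulates per-class region counts and
#' area fractions, separating active classes from the rare, removed ones.
#'
#' @param dataset_dir Dataset directory.
#' @return A `wound_dataset_stats` tibble.
#' @export
stats_for_dataset <- function(dataset_dir) {
  ds <- load_dataset(dataset_dir)
  dataset_stats(ds$annotations, ds$masks)
}
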