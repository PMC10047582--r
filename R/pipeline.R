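#' End-to-end run configuration
#'
#' A fully serializable description of one pipeline run: phantom-cohort
#' design (or a directory of prepared cases), feature extraction settings,
#' classifier(s), distance-correction and sector settings, and the root
#' seed from which every stage seed is derived.  A run is reproducible
#' from its config alone.
#'
#' @param phantom a [phantom_spec()] (ignored when `cohort_dir` given).
#' @param cohort_dir directory with one subdirectory per case as written
#'   by [write_case_bundle()]; `NULL` simulates the cohort instead.
#' @param n_train,n_test cohort sizes when simulating.
#' @param features a [feature_config()].
#' @param algorithms classifier ids for [recur_fit()].
#' @param correction a [correction_config()].
#' @param activation_fraction sector activation rule, see
#'   [sector_labels()].
#' @param neutral_band_deg sector geometry, see [sector_partition()].
#' @param seed root RNG seed.
#' @param out_dir optional output directory; when set, run stages persist
#'   volumes (NIfTI), tables (CSV) and reports (JSON) there.
#' @return a `run_config` object.
#' @export
run_config <- function(phantom = phantom_spec(), cohort_dir = NULL,
                       n_train = 4L, n_test = 2L,
                       features = feature_config(),
                       algorithms = "catboost",
                       correction = correction_config(),
                       activation_fraction = 0.01, neutral_band_deg = 22.5,
                       seed = 1L, out_dir = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(features, "feature_config"),
            inherits(correction, "correction_config"))
  structure(list(version = "1", phantom = phantom, cohort_dir = cohort_dir,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 features = features, algorithms = algorithms,
                 correction = correction,
                 activation_fraction = activation_fraction,
                 neutral_band_deg = neutral_band_deg,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  # named atomic vectors become JSON objects so their names survive the trip
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  take <- function(lst, fun) {
    lst <- lapply(as.list(lst), unlist)
    lst[intersect(names(formals(fun)), names(lst))]
  }
  phantom <- do.call(phantom_spec, take(p$phantom, phantom_spec))
  features <- do.call(feature_config, take(p$features, feature_config))
  correction <- do.call(correction_config, take(p$correction, correction_config))
  run_config(phantom = phantom, cohort_dir = p$cohort_dir,
             n_train = p$n_train, n_test = p$n_test, features = features,
             algorithms = unlist(p$algorithms), correction = correction,
             activation_fraction = p$activation_fraction,
             neutral_band_deg = p$neutral_band_deg, seed = p$seed,
             out_dir = p$out_dir)
}

stage_seed <- function(config, stage) {
  offs <- c(simulate = 101L, undersample = 211L, train = 307L,
            predict = 401L, evaluate = 503L)
  (config$seed * 7919L + offs[[stage]]) %% (.Machine$integer.max - 1L)
}

log_stage <- function(fmt, ...) {
  message(sprintf("[recurmap %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

resolve_cohort <- function(config) {
  if (!is.null(config$cohort_dir)) {
    dirs <- list.dirs(config$cohort_dir, recursive = FALSE)
    if (length(dirs) == 0L) stop("empty cohort directory")
    bundles <- lapply(dirs, read_case_bundle)
    is_test <- grepl("^test", basename(dirs))
    structure(list(train = bundles[!is_test], test = bundles[is_test],
                   spec = config$phantom, seed = config$seed),
              class = "phantom_cohort")
  } else {
    generate_cohort(config$n_train, config$n_test, config$phantom,
                    seed = stage_seed(config, "simulate"))
  }
}

#' Run pipeline stages
#'
#' `run_simulate()` generates (and optionally writes) the phantom cohort;
#' `run_train()` derives labels, extracts training features, balances
#' classes by undersampling and fits the configured classifier(s);
#' `run_predict()` produces the raw map, corrected map, Otsu threshold and
#' predicted labels for one case; `run_evaluate()` scores a cohort of
#' predictions voxelwise and sectorwise; `run_all()` wires the stages
#' together and returns per-case metrics plus the cohort summary
#' (4 algorithms x 2 modes x 6 metrics when all four classifiers are
#' requested).
#'
#' @param config a [run_config()].
#' @param cohort a `phantom_cohort` (resolved from `config` when omitted).
#' @return `run_train()`: list with `models` (named by algorithm),
#'   `balance` report and the training `manifest`.  See the individual
#'   stage docs for the rest.
#' @export
run_simulate <- function(config) {
  cohort <- resolve_cohort(config)
  if (!is.null(config$out_dir) && is.null(config$cohort_dir)) {
    cdir <- file.path(config$out_dir, "cohort")
    for (b in c(cohort$train, cohort$test)) write_case_bundle(b, cdir)
    log_stage("cohort written to %s", cdir)
  }
  cohort
}

extract_cohort <- function(bundles, features, what = "cohort") {
  tabs <- vector("list", length(bundles))
  for (i in seq_along(bundles)) {
    t0 <- Sys.time()
    tabs[[i]] <- build_feature_table(bundles[[i]], features)
    log_stage("extracted %s case %s (%d voxels, %.1fs)", what,
              tabs[[i]]$case_id, nrow(tabs[[i]]$features),
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  tabs
}

#' @rdname run_simulate
#' @export
run_train <- function(config, cohort = NULL) {
  if (is.null(cohort)) cohort <- resolve_cohort(config)
  if (length(cohort$train) == 0L) stop("training cohort is empty")
  tabs <- extract_cohort(cohort$train, config$features, "training")
  x <- do.call(rbind, lapply(tabs, function(t) t$features))
  y <- unlist(lapply(tabs, function(t) {
    if (is.null(t$labels)) stop(sprintf("case %s has no ground truth", t$case_id))
    t$labels
  }))
  before <- c(nonrecurrence = sum(y == 0L), recurrence = sum(y == 1L))
  idx <- undersample(y, seed = stage_seed(config, "undersample"))
  after <- c(nonrecurrence = sum(y[idx] == 0L), recurrence = sum(y[idx] == 1L))
  log_stage("undersampling: %d/%d -> %d/%d voxels",
            before[["recurrence"]], before[["nonrecurrence"]],
            after[["recurrence"]], after[["nonrecurrence"]])
  models <- list()
  for (alg in config$algorithms) {
    t0 <- Sys.time()
    models[[alg]] <- recur_fit(x[idx, , drop = FALSE], y[idx], algorithm = alg,
                               seed = stage_seed(config, "train"))
    log_stage("trained %s (%.1fs)", alg,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  balance <- list(before = as.list(before), after = as.list(after),
                  retained = length(idx))
  manifest <- list(algorithms = config$algorithms,
                   n_features = ncol(x), seed = config$seed,
                   feature_names = colnames(x))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(balance = balance,
                              algorithms = config$algorithms,
                              n_features = ncol(x), seed = config$seed),
                         file.path(config$out_dir, "training_report.json"),
                         auto_unbox = TRUE, digits = NA)
    saveRDS(models, file.path(config$out_dir, "models.rds"))
  }
  list(models = models, balance = balance, manifest = manifest)
}

#' @rdname run_simulate
#' @param model a fitted `recur_model`.
#' @param bundle one `case_bundle`.
#' @param table optional precomputed [build_feature_table()] for the case.
#' @export
run_predict <- function(config, model, bundle, table = NULL) {
  if (mask_count(bundle$peritumor_mask) == 0L) stop("empty peritumor mask")
  if (is.null(table)) table <- build_feature_table(bundle, config$features)
  scores <- predict(model, table$features)
  raw <- probability_map(scores, bundle$peritumor_mask, stage = "raw")
  d <- distance_from_cavity(bundle$cavity_mask, bundle$peritumor_mask)
  corrected <- distance_correction(raw, d, config$correction)
  pl <- predicted_labels(corrected)
  out <- list(case_id = bundle$case_id, raw = raw, corrected = corrected,
              predicted_mask = pl$mask, otsu_threshold = pl$threshold)
  if (!is.null(config$out_dir)) {
    pdir <- file.path(config$out_dir, "predictions", bundle$case_id)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    sel <- bundle$peritumor_mask$data != 0L
    for (nm in c("raw", "corrected")) {
      arr <- out[[nm]]$data
      arr[!sel] <- 0
      write_volume(voxel_grid(arr, bundle$peritumor_mask$spacing,
                              bundle$peritumor_mask$axes),
                   file.path(pdir, paste0(nm, "_probability.nii.gz")))
    }
    write_volume(pl$mask, file.path(pdir, "predicted_labels.nii.gz"))
    jsonlite::write_json(list(case_id = bundle$case_id,
                              otsu_threshold = pl$threshold,
                              correction = unclass(config$correction),
                              n_predicted = mask_count(pl$mask),
                              n_peritumor = sum(sel)),
                         file.path(pdir, "prediction_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @rdname run_simulate
#' @param predictions named list (by algorithm) of lists of
#'   `run_predict()` outputs, one per test case.
#' @export
run_evaluate <- function(config, cohort, predictions) {
  if (length(cohort$test) == 0L) stop("empty test cohort")
  rows <- list()
  for (alg in names(predictions)) {
    preds <- predictions[[alg]]
    for (i in seq_along(cohort$test)) {
      b <- cohort$test[[i]]
      pr <- preds[[i]]
      if (is.null(pr)) {
        log_stage("skipping %s / %s: no prediction", alg, b$case_id)
        next
      }
      truth <- derive_labels(b$peritumor_mask, b$followup_enhancing_mask)
      vm <- voxel_metrics(pr$corrected, pr$predicted_mask, truth,
                          case_id = b$case_id)
      part <- sector_partition(b$peritumor_mask, b$cavity_mask,
                               config$neutral_band_deg)
      sm <- sector_metrics(part, truth, pr$predicted_mask, pr$corrected,
                           config$activation_fraction, case_id = b$case_id)
      both <- rbind(vm, sm)
      both$algorithm <- alg
      rows[[length(rows) + 1L]] <- both
    }
  }
  per_case <- do.call(rbind, rows)
  summary <- aggregate_cohort(per_case)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_case, file.path(config$out_dir, "metrics_per_case.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$out_dir, "metrics_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  list(per_case = per_case, summary = summary)
}

#' @rdname run_simulate
#' @export
run_all <- function(config) {
  cohort <- run_simulate(config)
  trained <- run_train(config, cohort)
  test_tabs <- extract_cohort(cohort$test, config$features, "testing")
  predictions <- lapply(trained$models, function(m)
    lapply(seq_along(cohort$test), function(i)
      run_predict(config, m, cohort$test[[i]], table = test_tabs[[i]])))
  evaluation <- run_evaluate(config, cohort, predictions)
  list(cohort = cohort, models = trained$models, balance = trained$balance,
       predictions = predictions, per_case = evaluation$per_case,
       summary = evaluation$summary)
}
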