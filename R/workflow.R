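#' Germination-rate summary
#'
#' Per-cultivar and overall germination rates from viable/nonviable counts.
#' Rates are `viable / total * 100`, rounded half-up to integer percent; the
#' overall row uses the summed counts.
#'
#' @param table data.frame with columns `cultivar`, `viable`, `nonviable`,
#'   and optionally `total` (checked for consistency when present).
#' @return data.frame with columns `cultivar`, `viable`, `nonviable`,
#'   `total`, `germination_rate`; last row is `Overall`.
#' @export
#' @examples
#' germination_summary(data.frame(cultivar = "cvX", viable = 453, nonviable = 147))
germination_summary <- function(table) {
  req <- c("cultivar", "viable", "nonviable")
  if (!all(req %in% names(table))) stop_param("need columns cultivar, viable, nonviable")
  tab <- table
  tab$total <- tab$viable + tab$nonviable
  if ("total" %in% names(table) && any(table$total != tab$total))
    stop_param("viable + nonviable must equal total")
  if (any(tab$total <= 0)) stop_param("total must be positive")
  if (any(tab$viable < 0 | tab$nonviable < 0)) stop_param("counts must be non-negative")
  tab$germination_rate <- round_half_up(100 * tab$viable / tab$total)
  overall <- data.frame(cultivar = "Overall", viable = sum(tab$viable),
                        nonviable = sum(tab$nonviable), total = sum(tab$total))
  overall$germination_rate <- round_half_up(100 * overall$viable / overall$total)
  rbind(tab[, c("cultivar", "viable", "nonviable", "total", "germination_rate")],
        overall)
}

#' Run configuration for the full pipeline
#'
#' Bundles every knob the pipeline needs so a run is reproducible from the
#' config and seeds alone; serializable to YAML/JSON.
#'
#' @param n_per_class synthetic seeds per class (when simulating).
#' @param cultivars cultivar names for the synthetic generator.
#' @param image_size frame side length.
#' @param feature_config a [feature_bank()].
#' @param sd_gain sd-scaling gain for [enhance_sets()].
#' @param max_k,candidate_pool SFS settings.
#' @param classifiers classifiers to cross-validate.
#' @param folds CV folds.
#' @param rng_seed master seed (data generation, folds).
#' @return List of class `run_config`.
#' @export
run_config <- function(n_per_class = 60L, cultivars = c("cv1", "cv2", "cv3"),
                       image_size = 224L, feature_config = feature_bank(),
                       sd_gain = 0.15, max_k = 20L, candidate_pool = 50L,
                       classifiers = c("lda", "qda", "knn"), folds = 10L,
                       rng_seed = 1L) {
  structure(list(n_per_class = as.integer(n_per_class), cultivars = cultivars,
                 image_size = as.integer(image_size),
                 feature_config = feature_config, sd_gain = sd_gain,
                 max_k = as.integer(max_k), candidate_pool = as.integer(candidate_pool),
                 classifiers = classifiers, folds = as.integer(folds),
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read and write run configurations as YAML
#'
#' A [run_config()] (including its nested [feature_bank()]) round-trips
#' through a plain YAML file, so a run is reproducible from the file and the
#' seeds alone.
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  fc <- x$feature_config
  run_config(n_per_class = x$n_per_class, cultivars = x$cultivars,
             image_size = x$image_size,
             feature_config = feature_bank(
               lbp_radii = fc$lbp_radii,
               gabor_frequencies = fc$gabor_frequencies,
               gabor_orientations = fc$gabor_orientations,
               glcm_levels = fc$glcm_levels,
               glcm_distance = fc$glcm_distance,
               fft_bands = fc$fft_bands),
             sd_gain = x$sd_gain, max_k = x$max_k,
             candidate_pool = x$candidate_pool,
             classifiers = x$classifiers, folds = x$folds,
             rng_seed = x$rng_seed)
}

# strip S3 classes recursively so configs serialize as plain JSON
unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  # small stable checksum (sum of char codes mixed by position)
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full classification pipeline
#'
#' Executes the staged workflow on synthetic data (or supplied images):
#' preprocess (mask + enhance) -> extract 1044 features/seed -> Fisher+SFS
#' feature selection -> stratified 10-fold cross-validation of each
#' classifier on the selected features. Rerunning with the same config is
#' bit-identical. When `out_dir` is given, the selection trace (JSON),
#' accuracy-vs-k curve (CSV + PNG), feature table (CSV), the classifier
#' summary table (CSV) and a model archive are written, each traceable to
#' the config hash recorded in the log.
#'
#' @param config a [run_config()].
#' @param images optional list of labelled [radiograph()] objects; when
#'   `NULL`, a balanced synthetic dataset is generated per the config.
#' @param out_dir optional output directory.
#' @return List of class `pipeline_run`: `trace` ([sfs()] result), `reports`
#'   (one [cross_validate()] report per classifier), `summary` (Mean/UCI/LCI
#'   table), `archive` (model archive list), `config_hash`, `log`.
#' @export
run_pipeline <- function(config = run_config(), images = NULL, out_dir = NULL) {
  t0 <- proc.time()[3]
  log <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf("[%6.1fs] %s", proc.time()[3] - t0, sprintf(fmt, ...))
    log <<- c(log, msg)
    invisible(msg)
  }
  hash <- config_hash(config)
  note("run %s: start", hash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir) && dir.exists(out_dir))
        unlink(list.files(out_dir, pattern = paste0("^", hash), full.names = TRUE))
      stop_param(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 class = "seedxray_stage_error")
    })
  }
  if (is.null(images)) {
    images <- stage("simulate",
                    generate_dataset(config$n_per_class, config$cultivars,
                                     rng_seed = config$rng_seed,
                                     size = config$image_size)$images)
    note("simulate: %d images", length(images))
  }
  ds <- stage("extract", extract_dataset(images, config$feature_config,
                                         s = config$sd_gain))
  note("extract: %d x %d feature table", nrow(ds$features), ncol(ds$features))
  trace <- stage("select",
                 sfs(ds$features, ds$labels,
                     evaluator = cv_evaluator("lda", folds = config$folds,
                                              rng_seed = config$rng_seed),
                     max_k = config$max_k, candidate_pool = config$candidate_pool))
  note("select: best %.1f%% at k=%d", trace$best_accuracy, trace$best_k)
  sel <- trace$features[seq_len(trace$best_k)]
  Xsel <- ds$features[, sel, drop = FALSE]
  reports <- lapply(config$classifiers, function(cl)
    stage(paste0("cv-", cl),
          cross_validate(Xsel, ds$labels, classifier = cl,
                         folds = config$folds, rng_seed = config$rng_seed)))
  names(reports) <- config$classifiers
  summary <- data.frame(classifier = toupper(config$classifiers),
                        mean = vapply(reports, `[[`, numeric(1), "mean"),
                        uci = vapply(reports, `[[`, numeric(1), "uci"),
                        lci = vapply(reports, `[[`, numeric(1), "lci"),
                        row.names = NULL)
  note("cross-validate: %s",
       paste(sprintf("%s %.1f%%", summary$classifier, summary$mean), collapse = ", "))
  scaler <- fit_scaler(Xsel)
  best_cl <- config$classifiers[which.max(summary$mean)]
  final <- switch(best_cl,
                  lda = fit_lda(apply_scaler(scaler, Xsel), ds$labels),
                  qda = fit_qda(apply_scaler(scaler, Xsel), ds$labels),
                  knn = fit_knn(apply_scaler(scaler, Xsel), ds$labels))
  archive <- model_archive(final, scaler, sel, config)
  run <- structure(list(trace = trace, reports = reports, summary = summary,
                        archive = archive, config_hash = hash, log = log),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_run_artifacts(run, ds, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run %s> best k=%d (%.1f%%)\n", x$config_hash,
              x$trace$best_k, x$trace$best_accuracy))
  print(x$summary)
  invisible(x)
}

write_run_artifacts <- function(run, ds, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pre <- function(name) file.path(out_dir, paste0(run$config_hash, "_", name))
  jsonlite::write_json(list(features = run$trace$features,
                            cv_accuracy_at_step = run$trace$cv_accuracy_at_step,
                            best_k = run$trace$best_k,
                            best_accuracy = run$trace$best_accuracy),
                       pre("selection_trace.json"), auto_unbox = TRUE, digits = NA)
  curve <- data.frame(k = seq_along(run$trace$cv_accuracy_at_step),
                      accuracy = run$trace$cv_accuracy_at_step)
  utils::write.csv(curve, pre("accuracy_vs_k.csv"), row.names = FALSE)
  grDevices::png(pre("accuracy_vs_k.png"), width = 720, height = 480)
  graphics::plot(curve$k, curve$accuracy, type = "b", pch = 19,
                 xlab = "Number of selected features",
                 ylab = "CV accuracy (%)", main = "LDA accuracy vs feature count")
  graphics::abline(v = run$trace$best_k, lty = 2)
  grDevices::dev.off()
  utils::write.csv(data.frame(seed_id = rownames(ds$features), label = ds$labels,
                              ds$features, check.names = FALSE),
                   pre("features.csv"), row.names = FALSE)
  utils::write.csv(run$summary, pre("classifier_summary.csv"), row.names = FALSE)
  jsonlite::write_json(run$archive, pre("model_archive.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(run$log, pre("run_log.txt"))
  invisible(out_dir)
}

ARCHIVE_VERSION <- "seedxray-model-1"

# versioned, JSON-serializable trained-model bundle
model_archive <- function(model, scaler, selected, config) {
  params <- if (inherits(model, "seed_lda")) {
    list(type = "lda", classes = model$classes, means = model$means,
         cov_inv = model$cov_inv, priors = model$priors)
  } else if (inherits(model, "seed_qda")) {
    list(type = "qda", classes = model$classes, priors = model$priors,
         fits = lapply(model$fits, function(f)
           list(mean = f$mean, cov_inv = f$cov_inv, logdet = f$logdet)))
  } else if (inherits(model, "seed_knn")) {
    list(type = "knn", classes = model$classes, k = model$k,
         X = model$X, y = model$y)
  } else stop_param("unsupported model type")
  # scaler vectors are stored as named lists so JSON keeps the feature names
  list(version = ARCHIVE_VERSION, selected_features = selected,
       scaler = list(mean = as.list(scaler$mean), sd = as.list(scaler$sd)),
       classifier = params,
       config = unclass_deep(config))
}

restore_model <- function(archive) {
  if (!identical(archive$version, ARCHIVE_VERSION))
    stop_param(sprintf("incompatible archive version '%s'", archive$version))
  p <- archive$classifier
  sel <- unlist(archive$selected_features)
  as_mat <- function(m) {
    m <- do.call(rbind, lapply(m, unlist))
    matrix(as.numeric(m), nrow(m), ncol(m))
  }
  if (p$type == "lda") {
    mu <- as_mat(p$means); ci <- as_mat(p$cov_inv)
    structure(list(classes = unlist(p$classes), means = mu, cov_inv = ci,
                   priors = unlist(p$priors), feature_names = sel),
              class = c("seed_lda", "seed_classifier"))
  } else if (p$type == "qda") {
    fits <- lapply(p$fits, function(f)
      list(mean = unlist(f$mean), cov_inv = as_mat(f$cov_inv),
           logdet = unlist(f$logdet)))
    structure(list(classes = unlist(p$classes), fits = fits,
                   priors = unlist(p$priors), feature_names = sel),
              class = c("seed_qda", "seed_classifier"))
  } else if (p$type == "knn") {
    X <- as_mat(p$X); colnames(X) <- sel
    structure(list(X = X, y = unlist(p$y), k = as.integer(p$k),
                   classes = unlist(p$classes), feature_names = sel),
              class = c("seed_knn", "seed_classifier"))
  } else stop_param("unsupported classifier type in archive")
}

#' Predict classes for new seed images from a model archive
#'
#' Each image is preprocessed with the archived configuration (mask on the
#' max-normalized image, enhancement triplet, 1044 features, archived scaler)
#' and classified with the archived model. A missing or unreadable file
#' yields a per-row error entry; the run continues.
#'
#' @param archive a model archive (list as produced inside [run_pipeline()],
#'   or the path to its JSON file).
#' @param images list of [radiograph()] objects or character paths to PNGs.
#' @return data.frame with `seed_id`, `class`, `score` (winning posterior)
#'   and `error` (NA on success), one row per input.
#' @export
predict_new <- function(archive, images) {
  if (is.character(archive) && length(archive) == 1)
    archive <- jsonlite::read_json(archive)
  model <- restore_model(archive)
  fc <- archive$config$feature_config
  bank <- feature_bank(lbp_radii = unlist(fc$lbp_radii),
                       gabor_frequencies = unlist(fc$gabor_frequencies),
                       gabor_orientations = unlist(fc$gabor_orientations)[1],
                       glcm_levels = unlist(fc$glcm_levels)[1],
                       glcm_distance = unlist(fc$glcm_distance)[1],
                       fft_bands = unlist(fc$fft_bands)[1])
  s <- unlist(archive$config$sd_gain)[1]
  sc <- list(mean = unlist(archive$scaler$mean), sd = unlist(archive$scaler$sd))
  rows <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    tryCatch({
      if (is.character(im)) im <- read_radiograph(im)
      trip <- enhance_sets(im, s = s)
      mk <- compute_mask(radiograph(trip$set_A, im$seed_id, im$cultivar))
      fv <- extract_all(trip, mk, bank, seed_id = im$seed_id)
      x <- (fv[model$feature_names] - sc$mean[model$feature_names]) /
        sc$sd[model$feature_names]
      pr <- predict(model, rbind(x))
      data.frame(seed_id = im$seed_id, class = pr$class[1],
                 score = max(as.numeric(pr[1, -1])), error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(seed_id = if (is.character(im)) basename(im) else
        tryCatch(im$seed_id, error = function(...) sprintf("item%d", i)),
        class = NA_character_, score = NA_real_,
        error = conditionMessage(e), stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
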