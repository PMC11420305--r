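# End-to-end orchestration: simulate -> extract -> fit -> associate.
# Every stage is a package function over files, so a full run is
# reproducible from the configuration and seed alone; the run manifest
# records the config snapshot and an md5 digest of every output file.

#' Read a pipeline configuration file
#'
#' JSON (or YAML, when the yaml package is installed) mirror of
#' [cohort_config()] arguments, plus the optional pipeline fields
#' `lambda` ("auto" or a number), `render_images` (logical: rasterize
#' and re-extract instead of using scene ground truth), and `n_render`
#' (cap on the number of rendered subjects).
#'
#' @param path Path to a .json or .yaml/.yml file.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("configuration error: YAML config needs the yaml package",
           call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

config_from_list <- function(settings) {
  keep <- intersect(names(settings), names(formals(cohort_config)))
  do.call(cohort_config, settings[keep])
}

#' Write the cohort covariate CSV
#'
#' Canonical schema: `subject_id,sex,age,height_cm,axial_length_mm,eye`.
#' Generator-internal columns (latent factor, refraction) are written to
#' a separate `*_truth.csv` next to it so the covariate file matches what
#' a real study would provide.
#'
#' @param subjects Covariate data.frame from [sample_covariates()].
#' @param path Output CSV path.
#' @export
write_cohort_csv <- function(subjects, path) {
  utils::write.csv(subjects[, c("subject_id", "sex", "age", "height_cm",
                                "axial_length_mm", "eye")],
                   path, row.names = FALSE)
  extra <- intersect(c("subject_id", "refraction_d", "latent_factor"),
                     names(subjects))
  if (length(extra) > 1L)
    utils::write.csv(subjects[, extra],
                     sub("\\.csv$", "_truth.csv", path), row.names = FALSE)
  invisible(path)
}

#' Write / read the feature table CSV
#'
#' One row per eye: `subject_id` followed by the 42 feature columns in
#' [feature_names()] order (frozen).
#'
#' @param features n x 42 matrix with subject ids as rownames.
#' @param path CSV path.
#' @export
write_features_csv <- function(features, path) {
  stopifnot(identical(colnames(features), feature_names()))
  df <- data.frame(subject_id = rownames(features), features,
                   row.names = NULL, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, feature_names()])
  rownames(m) <- df$subject_id
  m
}

#' Write a fitted ridge model as JSON
#'
#' Schema: `{lambda, intercept, beta:{name: value},
#' standardization:{name:[mean, sd]}}`.
#'
#' @param model A `ridge_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  st <- model$standardization
  nm <- names(model$beta)
  jsonlite::write_json(list(
    lambda = model$lambda, intercept = model$intercept,
    beta = as.list(model$beta),
    standardization = stats::setNames(
      lapply(seq_along(nm), function(j) c(st$mean[j], st$sd[j])), nm)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

stage_error <- function(stage, e) {
  stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
}

run_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(force(expr), error = function(e) stage_error(stage, e))
  list(value = out, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the full pipeline
#'
#' Executes, in order: cohort simulation (covariates + scenes), feature
#' extraction (either from rendered images or directly from scene ground
#' truth), ridge fitting with LOOCV (the fundus sex index), and the
#' association analyses; writes every stage output under `out_dir` and
#' returns a manifest with digests.  Fails fast with a stage-labelled
#' error.
#'
#' @param config A [cohort_config()], or a settings list (see
#'   [read_config()]).
#' @param out_dir Output directory.
#' @param lambda Ridge penalty: "auto" (10-fold CV on the full data,
#'   single value reused across LOOCV folds) or a number.
#' @param render_images If TRUE, rasterize scenes to PNG + landmark JSON
#'   and run the extractor on them; if FALSE (default) the extraction
#'   stage uses scene ground-truth features, whose agreement with
#'   rendered-image extraction is established by the round-trip tests.
#' @param n_render With `render_images`, cap on how many subjects are
#'   rasterized (NULL = all).
#' @param quiet Suppress progress messages.
#' @return Run manifest (list), invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         lambda = "auto", render_images = FALSE,
                         n_render = NULL, quiet = FALSE) {
  if (!inherits(config, "cohort_config")) {
    settings <- config
    config <- tryCatch(config_from_list(settings),
                       error = function(e) stage_error("simulate", e))
    lambda <- settings$lambda %||% lambda
    render_images <- settings$render_images %||% render_images
    n_render <- settings$n_render %||% n_render
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()

  say("simulate: n = %d subjects (seed %d)", config$n_subjects, config$seed)
  sim <- run_stage("simulate", simulate_cohort(config, scenes = render_images))
  timings$simulate <- sim$seconds
  write_cohort_csv(sim$value$subjects, file.path(out_dir, "cohort.csv"))

  features <- sim$value$features
  if (render_images) {
    ids <- rownames(features)
    if (!is.null(n_render)) ids <- utils::head(ids, n_render)
    img_dir <- file.path(out_dir, "images")
    lm_dir <- file.path(out_dir, "landmarks")
    dir.create(img_dir, showWarnings = FALSE)
    dir.create(lm_dir, showWarnings = FALSE)
    say("extract: rendering %d images and re-extracting", length(ids))
    ex <- run_stage("extract", {
      for (id in ids) {
        rr <- render_image(sim$value$scenes[[id]])
        write_image_png(rr$image, file.path(img_dir, paste0(id, ".png")))
        write_landmarks(rr$landmarks, file.path(lm_dir, paste0(id, ".json")))
        features[id, ] <- extract_features(rr$image, rr$landmarks,
                                           config$diameters)
      }
      features
    })
    features <- ex$value
    timings$extract <- ex$seconds
  } else {
    ex <- run_stage("extract", features)   # ground-truth fidelity
    timings$extract <- ex$seconds
  }
  write_features_csv(features, file.path(out_dir, "features.csv"))

  y <- as.integer(sim$value$subjects$sex == "female")
  if (identical(lambda, "auto")) {
    say("fit: selecting lambda by 10-fold CV")
    lam <- run_stage("fit", as.numeric(select_lambda(features, y)))
    lambda <- lam$value
  }
  say("fit: LOOCV at lambda = %.4g (%d folds)", lambda, nrow(features))
  fit <- run_stage("fit", loocv_index(features, y, lambda,
                                      ids = sim$value$subjects$subject_id))
  timings$fit <- fit$seconds
  res <- fit$value
  utils::write.csv(res$index, file.path(out_dir, "index.csv"),
                   row.names = FALSE)
  write_model_json(res$model, file.path(out_dir, "model.json"))
  say("fit: LOOCV AROC = %.3f", res$aroc)

  assoc <- run_stage("associate",
                     build_report(res$index, sim$value$subjects,
                                  features = features))
  timings$associate <- assoc$seconds
  write_report(assoc$value, file.path(out_dir, "report"))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("fundusindex")),
    seed = config$seed,
    n_subjects = config$n_subjects,
    lambda = lambda,
    loocv_aroc = res$aroc,
    n_loocv_fits = res$n_fits,
    render_images = render_images,
    timings_seconds = timings,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = stats::setNames(as.list(unname(tools::md5sum(files))),
                              sub(paste0(out_dir, "/"), "", files, fixed = TRUE))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
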