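# End-to-end pipeline: simulate -> train -> segment -> evaluate ->
# clinical -> agree, driven by one configuration object with a single
# master seed from which every stage seed is derived.

#' Assemble a full run configuration
#'
#' @param out_dir run directory (created if missing).
#' @param n_with_artifact,n_without cohort sizes for the simulate stage.
#' @param phantom a [phantom_config()] template for the cohort.
#' @param model a [model_spec()].
#' @param train a [train_config()].
#' @param loss a [loss_config()].
#' @param seed master seed; each stage derives its own seed from it, so two
#'   runs with equal configuration are identical.
#' @param data_dir optional existing dataset directory; when given the
#'   simulate stage is skipped and its manifest is used instead.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir, n_with_artifact = 20L, n_without = 20L,
                       phantom = phantom_config(), model = model_spec(),
                       train = train_config(), loss = loss_config(),
                       seed = 1L, data_dir = NULL) {
  structure(list(out_dir = out_dir, n_with_artifact = as.integer(n_with_artifact),
                 n_without = as.integer(n_without), phantom = phantom,
                 model = model, train = train, loss = loss,
                 seed = as.integer(seed), data_dir = data_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys `out_dir`, `n_with_artifact`, `n_without`, `seed`,
#' `data_dir` plus nested blocks `phantom`, `artifact`, `model`, `train`,
#' `augment`, `loss` whose fields mirror the corresponding constructor
#' arguments.
#'
#' @param path YAML file.
#' @param out_dir overrides the configured output directory.
#' @param seed overrides the configured master seed.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  art <- if (!is.null(y$artifact)) do.call(artifact_config, y$artifact)
  ph_args <- y$phantom %||% list()
  if (!is.null(art)) ph_args$artifact <- art
  if (!is.null(ph_args$intensity_means))
    ph_args$intensity_means <- unlist(ph_args$intensity_means)
  tr_args <- y$train %||% list()
  if (!is.null(y$augment)) tr_args$augment <- do.call(augment_params, y$augment)
  run_config(
    out_dir = out_dir %||% y$out_dir %||% stop_cfg("config must set out_dir"),
    n_with_artifact = y$n_with_artifact %||% 20L,
    n_without = y$n_without %||% 20L,
    phantom = do.call(phantom_config, ph_args),
    model = do.call(model_spec, y$model %||% list()),
    train = do.call(train_config, tr_args),
    loss = do.call(loss_config, y$loss %||% list()),
    seed = seed %||% y$seed %||% 1L,
    data_dir = y$data_dir)
}

predict_studies <- function(model, studies) {
  lapply(studies, function(st) {
    list(ed = predict(model, st$ed_image)$labels,
         es = predict(model, st$es_image)$labels)
  })
}

references_of <- function(studies) {
  lapply(studies, function(st) list(ed = st$ed_mask, es = st$es_mask))
}

cohort_clinical <- function(masks, studies) {
  purrr::map_dfr(names(masks), function(id) {
    st <- studies[[id]]
    clinical_parameters(masks[[id]]$ed, masks[[id]]$es,
                        st$pixel_spacing, st$slice_thickness, study_id = id)
  })
}

#' Run the full pipeline
#'
#' Executes, in order: simulate (unless `data_dir` points at an existing
#' cohort), train, segment the test split, evaluate segmentation metrics,
#' derive clinical parameters for automatic and reference masks, and
#' compute the agreement report. Every artifact is written under
#' `out_dir` and a resolved-configuration snapshot is saved alongside.
#'
#' @param config a [run_config()].
#' @param verbose print per-stage progress.
#' @return a list with `manifest`, `fit`, `metrics`, `metrics_summary`,
#'   `clinical_auto`, `clinical_ref`, `agreement`, and the run directory
#'   `out_dir`. Stage failures abort with the stage name.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    tryCatch(expr, error = function(e)
      stop_cfg("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  snapshot <- rapply(unclass(config), unclass, how = "replace")
  jsonlite::write_json(snapshot, file.path(config$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

  manifest <- stage("simulate", {
    if (!is.null(config$data_dir)) read_manifest(config$data_dir)
    else generate_dataset(config$n_with_artifact, config$n_without,
                          file.path(config$out_dir, "dataset"),
                          seed = derive_seed(config$seed, 1L),
                          base_config = config$phantom)
  })

  fit <- stage("train", {
    train_studies <- load_split(manifest, "train")
    val_studies <- load_split(manifest, "val")
    tc <- config$train
    tc$seed <- derive_seed(config$seed, 2L)
    model <- build_model(config$model, seed = derive_seed(config$seed, 3L))
    f <- train_model(model, train_studies, val_studies, tc, config$loss,
                     verbose = verbose)
    save_checkpoint(f, file.path(config$out_dir, "model"))
    f
  })

  test_studies <- stage("segment", load_split(manifest, "test"))
  preds <- stage("segment", {
    p <- predict_studies(fit$model, test_studies)
    pdir <- file.path(config$out_dir, "predictions")
    dir.create(pdir, showWarnings = FALSE)
    for (id in names(p)) {
      st <- test_studies[[id]]
      for (ph in c("ed", "es"))
        write_nifti_stack(p[[id]][[ph]],
                          file.path(pdir, sprintf("%s_%s_pred.nii.gz", id, ph)),
                          st$pixel_spacing, st$slice_thickness, mask = TRUE)
    }
    p
  })

  metrics <- stage("evaluate", {
    spc <- vapply(test_studies, `[[`, 0, "pixel_spacing")
    m <- evaluate_cohort(preds, references_of(test_studies), spacing = spc)
    mdir <- file.path(config$out_dir, "metrics")
    dir.create(mdir, showWarnings = FALSE)
    write.csv(m, file.path(mdir, "per_study_metrics.csv"), row.names = FALSE)
    m
  })
  metrics_summary <- stage("evaluate", {
    s <- summarize_cohort(metrics)
    write.csv(s, file.path(config$out_dir, "metrics", "cohort_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(s, file.path(config$out_dir, "metrics", "cohort_summary.json"),
                         dataframe = "rows", digits = NA)
    s
  })

  clin <- stage("clinical", {
    cdir <- file.path(config$out_dir, "clinical")
    dir.create(cdir, showWarnings = FALSE)
    auto <- cohort_clinical(preds, test_studies)
    ref <- cohort_clinical(references_of(test_studies), test_studies)
    write.csv(auto, file.path(cdir, "params_auto.csv"), row.names = FALSE)
    write.csv(ref, file.path(cdir, "params_ref.csv"), row.names = FALSE)
    list(auto = auto, ref = ref)
  })

  agreement <- stage("agree", {
    a <- agreement_report(clin$auto, clin$ref)
    write.csv(tidy(a), file.path(config$out_dir, "clinical", "agreement.csv"),
              row.names = FALSE)
    a
  })

  list(manifest = manifest, fit = fit, metrics = metrics,
       metrics_summary = metrics_summary, clinical_auto = clin$auto,
       clinical_ref = clin$ref, agreement = agreement,
       out_dir = config$out_dir)
}
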