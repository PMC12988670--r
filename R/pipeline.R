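#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Defaults mirror the
#' reference analysis settings: archetype counts scanned 2-17 under 10-fold
#' cross-validation with 100 restarts; reliability screen thresholds 5 dB /
#' 0.6; family-wise alpha 0.05 Bonferroni-corrected over 43 aspects.
#'
#' @param vf_csv,meta_csv,qol_csv input paths (`qol_csv` optional).
#' @param out_dir output directory for artifacts.
#' @param k fixed number of archetypes; `NULL` selects it by
#'   cross-validation.
#' @param k_min,k_max,folds,restarts,max_iter,tol,penalty archetype engine
#'   settings (see [crossvalidate_k()] and [fit_archetypes()]).
#' @param asym_threshold,corr_threshold neuro-screen thresholds.
#' @param exclude_flagged drop screen-flagged patients instead of only
#'   reporting them.
#' @param alpha,n_tests,adjust_foveal association settings.
#' @param item_map_path YAML item map (`NULL` = shipped default).
#' @param seed top-level seed recorded in every manifest.
#' @param strict abort on any input validation error.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vf_csv, meta_csv, qol_csv = NULL,
                            out_dir = "vfarch_out", k = NULL, k_min = 2L,
                            k_max = 17L, folds = 10L, restarts = 100L,
                            max_iter = 100L, tol = 1e-6, penalty = 200,
                            asym_threshold = 5, corr_threshold = 0.6,
                            exclude_flagged = FALSE, alpha = 0.05,
                            n_tests = 43L, adjust_foveal = TRUE,
                            item_map_path = NULL, seed = 1L,
                            strict = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

write_manifest <- function(out_dir, stage, params, outputs) {
  man <- list(package = "vfarch",
              version = as.character(utils::packageVersion("vfarch")),
              stage = stage, params = params, outputs = outputs)
  jsonlite::write_json(man, file.path(out_dir,
                                      sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Composes the stages end to end: read and validate inputs, reliability
#' filtering and visit selection, neuro screen, binocular integration,
#' model-order selection (when `k` is not fixed), archetype fit,
#' decomposition, and - when questionnaire data is supplied - association
#' and prediction. Every stage writes its artifact plus a JSON manifest
#' recording package version, parameters and seed; a rerun with the same
#' configuration reproduces identical artifacts. A stage failure aborts
#' with the stage name while preserving upstream artifacts.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_vf("pipeline stage '%s' failed: %s (upstream artifacts kept in %s)",
              name, conditionMessage(e), cfg$out_dir))
  }

  # ---- qc: reliability, visit selection, neuro screen
  qc <- stage("qc", {
    meta <- read_meta_csv(cfg$meta_csv)
    vfs <- read_vf_csv(cfg$vf_csv, meta = meta, strict = cfg$strict)
    pairs <- make_pairs(vfs)
    rows <- list(); selected <- list()
    for (pid in names(pairs)) {
      sel <- select_analysis_visit(pairs[[pid]])
      if (is.null(sel)) {
        rows[[pid]] <- data.frame(patient_id = pid, retained = FALSE,
                                  test_date = NA, vertical_asymmetry_db = NA,
                                  interocular_r = NA, flagged = NA)
        next
      }
      scr <- neuro_screen(sel, cfg$asym_threshold, cfg$corr_threshold)
      keep <- !(cfg$exclude_flagged && scr$flagged)
      rows[[pid]] <- data.frame(
        patient_id = pid, retained = keep,
        test_date = format(sel$right$test_date),
        vertical_asymmetry_db = scr$vertical_asymmetry_db,
        interocular_r = scr$interocular_r, flagged = scr$flagged)
      if (keep) selected[[pid]] <- sel
    }
    report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    write.csv(report, file.path(cfg$out_dir, "qc_report.csv"),
              row.names = FALSE)
    write_manifest(cfg$out_dir, "qc",
                   list(seed = cfg$seed, asym_threshold = cfg$asym_threshold,
                        corr_threshold = cfg$corr_threshold,
                        exclude_flagged = cfg$exclude_flagged),
                   "qc_report.csv")
    list(report = report, selected = selected, meta = meta)
  })

  # ---- integrate
  ivfs <- stage("integrate", {
    ivfs <- lapply(qc$selected, integrate_pair)
    write_ivf_csv(ivfs, file.path(cfg$out_dir, "ivf.csv"))
    write_manifest(cfg$out_dir, "integrate", list(seed = cfg$seed), "ivf.csv")
    ivfs
  })
  X <- ivf_matrix(ivfs)

  # ---- model order
  k_use <- cfg$k
  cv <- NULL
  if (is.null(k_use)) {
    cv <- stage("select_k", {
      if (cfg$folds > nrow(X))
        stop_vf("folds (%d) exceeds retained patients (%d)", cfg$folds,
                nrow(X))
      cv <- crossvalidate_k(X, cfg$k_min, cfg$k_max, cfg$folds, cfg$restarts,
                            cfg$max_iter, cfg$tol, cfg$penalty, cfg$seed)
      write.csv(as.data.frame(cv), file.path(cfg$out_dir, "cv.csv"),
                row.names = FALSE)
      cv
    })
    k_use <- as.integer(select_k(cv))
    write_manifest(cfg$out_dir, "select_k",
                   list(seed = cfg$seed, k_min = cfg$k_min, k_max = cfg$k_max,
                        folds = cfg$folds, restarts = cfg$restarts,
                        selected_k = k_use), "cv.csv")
  }

  # ---- fit + decompose
  model <- stage("fit", {
    model <- fit_archetypes(X, k_use, cfg$restarts, cfg$max_iter, cfg$tol,
                            cfg$penalty, cfg$seed)
    write_model(model, file.path(cfg$out_dir, "model.json"))
    write_manifest(cfg$out_dir, "fit",
                   list(seed = cfg$seed, k = k_use, restarts = cfg$restarts,
                        penalty = cfg$penalty, tol = cfg$tol), "model.json")
    model
  })
  weights <- stage("decompose", {
    w <- decompose(model, X)
    w <- cbind(patient_id = rownames(X), w)
    write.csv(w, file.path(cfg$out_dir, "weights.csv"), row.names = FALSE)
    write_manifest(cfg$out_dir, "decompose", list(seed = cfg$seed),
                   "weights.csv")
    w
  })

  assoc <- NULL
  predicted <- NULL
  if (!is.null(cfg$qol_csv)) {
    assoc <- stage("associate", {
      map <- if (is.null(cfg$item_map_path)) default_item_map()
             else read_item_map(cfg$item_map_path)
      qol <- read_qol_csv(cfg$qol_csv)
      scored <- score_items(qol, map)
      aspects <- aspect_scores(scored, map)
      covs <- patient_covariates(qc$meta, ivfs)
      assoc <- fit_association(aspects, weights, covs, cfg$alpha,
                               cfg$n_tests, cfg$adjust_foveal)
      write.csv(assoc$table, file.path(cfg$out_dir, "assoc.csv"),
                row.names = FALSE)
      write_assoc_json(assoc, file.path(cfg$out_dir, "assoc_models.json"))
      write_manifest(cfg$out_dir, "associate",
                     list(seed = cfg$seed, alpha = cfg$alpha,
                          n_tests = cfg$n_tests,
                          adjust_foveal = cfg$adjust_foveal),
                     c("assoc.csv", "assoc_models.json"))
      assoc
    })
    predicted <- stage("predict", {
      covs <- patient_covariates(qc$meta, ivfs)
      nd <- merge(weights, covs, by = "patient_id")
      pred <- predict_qol(assoc, nd)
      write.csv(pred, file.path(cfg$out_dir, "predicted.csv"),
                row.names = FALSE)
      write_manifest(cfg$out_dir, "predict", list(seed = cfg$seed),
                     "predicted.csv")
      pred
    })
  }
  invisible(list(qc = qc$report, ivfs = ivfs, cv = cv, k = k_use,
                 model = model, weights = weights, assoc = assoc,
                 predicted = predicted))
}

# Per-patient covariates for the association stage: age and gender from the
# metadata of the selected visit, binocular foveal sensitivity from the
# integrated field.
patient_covariates <- function(meta, ivfs) {
  ids <- vapply(ivfs, function(v) v$patient_id, character(1))
  fov <- vapply(ivfs, function(v) v$foveal_binoc_db, numeric(1))
  ms <- vapply(ivfs, function(v) v$ivf_ms, numeric(1))
  m1 <- meta[!duplicated(meta$patient_id), ]
  data.frame(patient_id = ids,
             age = m1$age_years[match(ids, m1$patient_id)],
             gender = m1$gender[match(ids, m1$patient_id)],
             foveal_binoc_db = fov, ivf_ms = ms,
             stringsAsFactors = FALSE)
}
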