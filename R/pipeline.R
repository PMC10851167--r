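# End-to-end orchestration: split -> per-phase selection -> MMD adaptation
# of PCP/PVP onto AP -> concatenation fusion -> ESBELM -> evaluation, plus
# the single-phase and simple-concatenation (SC) ablations. All stage seeds
# derive from one global seed; selection, adaptation and the classifier are
# fitted on training rows only.

#' Pipeline run configuration
#'
#' @param test_fraction held-out fraction (default 0.27, ~7:3).
#' @param k selected features per phase (default 200).
#' @param alpha,floor Mann-Whitney prefilter parameters.
#' @param adapt fit MMD adaptation of the source phases (TRUE = M-DAFM,
#'   FALSE = SC).
#' @param epochs,learning_rate adaptation training parameters.
#' @param L,B ESBELM hidden units and ensemble size.
#' @param ard ARD on (sparse Bayesian) or off (plain ridge ELM).
#' @param threshold_mode decision threshold mode, see [fit_esbelm()].
#' @param seed global seed fanned out to stages via [derive_seed()].
#' @return `run_config` list.
#' @export
run_config <- function(test_fraction = 0.27, k = 200L, alpha = 0.05,
                       floor = 500L, adapt = TRUE, epochs = 300L,
                       learning_rate = 5e-3, L = 200L, B = 10L, ard = TRUE,
                       threshold_mode = "fixed", seed = 1L) {
  structure(list(test_fraction = test_fraction, k = as.integer(k),
                 alpha = alpha, floor = as.integer(floor), adapt = adapt,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 L = as.integer(L), B = as.integer(B), ard = ard,
                 threshold_mode = threshold_mode, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param config a [run_config()]; @param path JSON path.
#' @return path (write) or `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj)
}

# shared front half: split + per-phase selection + selected blocks
prepare_blocks <- function(cohort, config) {
  stopifnot(inherits(cohort, "multi_phase_cohort"))
  split <- stratified_split(cohort$patient_ids, cohort$labels,
                            config$test_fraction,
                            derive_seed(config$seed, "split"))
  tr <- match(split$train, cohort$patient_ids)
  te <- match(split$test, cohort$patient_ids)
  y_tr <- cohort$labels[tr]; y_te <- cohort$labels[te]
  sel <- lapply(cohort$features, function(X)
    select_phase_features(X[tr, , drop = FALSE], y_tr,
                          k = config$k, alpha = config$alpha,
                          floor = config$floor))
  blocks <- lapply(names(cohort$features), function(ph) {
    X <- cohort$features[[ph]]
    list(train = apply_selection(sel[[ph]], X[tr, , drop = FALSE]),
         test = apply_selection(sel[[ph]], X[te, , drop = FALSE]))
  })
  names(blocks) <- names(cohort$features)
  list(split = split, y_train = y_tr, y_test = y_te,
       selection = sel, blocks = blocks)
}

fit_and_evaluate <- function(X_train, y_train, X_test, y_test, config,
                             stage_seed) {
  model <- fit_esbelm(X_train, y_train, L = config$L, B = config$B,
                      seed = stage_seed, ard = config$ard,
                      threshold_mode = config$threshold_mode)
  p_tr <- predict_score(model, X_train)
  p_te <- predict_score(model, X_test)
  list(model = model,
       prob = list(train = p_tr, test = p_te),
       report = list(
         train = evaluate_model(p_tr, y_train, model$decision_threshold),
         test = evaluate_model(p_te, y_test, model$decision_threshold)))
}

#' Run the M-DAFM pipeline on a multi-phase cohort
#'
#' @param cohort a `multi_phase_cohort` (from [generate_feature_cohort()] or
#'   assembled from CSV feature tables).
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, predictions, reports and
#'   the run manifest are written there.
#' @return `mdafm_run`: `split`, `selection`, `adaptations`, `model`,
#'   `prob`, `report` (train/test `evaluation_report`s), `manifest`.
#' @export
run_mdafm <- function(cohort, config = run_config(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  prep <- prepare_blocks(cohort, config)
  blocks <- prep$blocks
  adaptations <- list()
  if (config$adapt) {
    for (src in c("PCP", "PVP")) {
      map <- fit_adaptation(blocks[[src]]$train, blocks$AP$train,
                            epochs = config$epochs,
                            learning_rate = config$learning_rate,
                            seed = derive_seed(config$seed, "adaptation"),
                            source_phase = src)
      blocks[[src]]$train <- apply_adaptation(map, blocks[[src]]$train)
      blocks[[src]]$test <- apply_adaptation(map, blocks[[src]]$test)
      adaptations[[src]] <- map
    }
  }
  fused_tr <- fuse(blocks$PCP$train, blocks$AP$train, blocks$PVP$train,
                   adapted = config$adapt)
  fused_te <- fuse(blocks$PCP$test, blocks$AP$test, blocks$PVP$test,
                   adapted = config$adapt)
  fit <- fit_and_evaluate(fused_tr$matrix, prep$y_train, fused_te$matrix,
                          prep$y_test, config,
                          derive_seed(config$seed, "esbelm"))
  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    train_ids = prep$split$train, test_ids = prep$split$test,
    split_hash = rlang::hash(prep$split),
    selection_hash = rlang::hash(lapply(prep$selection,
                                        `[[`, "selected_indices")),
    prediction_hash = rlang::hash(fit$prob),
    adapted = config$adapt,
    elapsed_s = proc.time()[["elapsed"]] - t0,
    versions = list(mdafm = as.character(utils::packageVersion("mdafm")),
                    r = R.version.string))
  run <- structure(list(split = prep$split, y = list(train = prep$y_train,
                                                     test = prep$y_test),
                        selection = prep$selection,
                        adaptations = adaptations, model = fit$model,
                        prob = fit$prob, report = fit$report,
                        manifest = manifest),
                   class = "mdafm_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in c("train", "test")) {
    write.csv(data.frame(patient_id = run$split[[sp]],
                         label = run$y[[sp]],
                         probability = run$prob[[sp]]),
              file.path(out_dir, sprintf("predictions_%s.csv", sp)),
              row.names = FALSE)
    write.csv(run$report[[sp]]$dca,
              file.path(out_dir, sprintf("dca_%s.csv", sp)),
              row.names = FALSE)
  }
  rep <- lapply(run$report, function(r)
    list(auc = round(r$auc, 4), metrics = as.list(r$metrics_rounded),
         counts = unclass(r$counts), n = r$n))
  jsonlite::write_json(rep, file.path(out_dir, "evaluation_report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the ablation study: single phases, SC and M-DAFM on one split
#'
#' Trains PCP-only, AP-only, PVP-only, simple concatenation (SC) and the
#' domain-adapted fusion (M-DAFM) on the same split, selection and classifier
#' seeds, and reports per-model confusion metrics and AUC for both splits
#' plus pairwise test-set NRI of M-DAFM against every other model.
#'
#' @param cohort a `multi_phase_cohort`.
#' @param config a [run_config()].
#' @param n_boot bootstrap resamples for the NRI comparisons (default 500).
#' @return `mdafm_ablation`: `comparison` (data.frame: model, split, AUC and
#'   the five confusion metrics), `nri` (list of `nri_result` vs M-DAFM),
#'   `runs` (per-model fit objects), `split`.
#' @export
run_ablations <- function(cohort, config = run_config(), n_boot = 500L) {
  prep <- prepare_blocks(cohort, config)
  blocks <- prep$blocks
  seed_clf <- derive_seed(config$seed, "esbelm")
  models <- list()
  for (ph in c("PCP", "AP", "PVP"))
    models[[ph]] <- fit_and_evaluate(blocks[[ph]]$train, prep$y_train,
                                     blocks[[ph]]$test, prep$y_test,
                                     config, seed_clf)
  sc_tr <- fuse(blocks$PCP$train, blocks$AP$train, blocks$PVP$train, FALSE)
  sc_te <- fuse(blocks$PCP$test, blocks$AP$test, blocks$PVP$test, FALSE)
  models$SC <- fit_and_evaluate(sc_tr$matrix, prep$y_train, sc_te$matrix,
                                prep$y_test, config, seed_clf)
  adapted <- blocks
  adaptations <- list()
  for (src in c("PCP", "PVP")) {
    map <- fit_adaptation(blocks[[src]]$train, blocks$AP$train,
                          epochs = config$epochs,
                          learning_rate = config$learning_rate,
                          seed = derive_seed(config$seed, "adaptation"),
                          source_phase = src)
    adapted[[src]]$train <- apply_adaptation(map, blocks[[src]]$train)
    adapted[[src]]$test <- apply_adaptation(map, blocks[[src]]$test)
    adaptations[[src]] <- map
  }
  da_tr <- fuse(adapted$PCP$train, adapted$AP$train, adapted$PVP$train, TRUE)
  da_te <- fuse(adapted$PCP$test, adapted$AP$test, adapted$PVP$test, TRUE)
  models$MDAFM <- fit_and_evaluate(da_tr$matrix, prep$y_train, da_te$matrix,
                                   prep$y_test, config, seed_clf)
  comparison <- do.call(rbind, lapply(names(models), function(mn) {
    do.call(rbind, lapply(c("train", "test"), function(sp) {
      r <- models[[mn]]$report[[sp]]
      data.frame(model = mn, split = sp, auc = round(r$auc, 4),
                 t(round(r$metrics, 4)))
    }))
  }))
  nris <- lapply(setdiff(names(models), "MDAFM"), function(mn)
    nri(models$MDAFM$prob$test, models[[mn]]$prob$test, prep$y_test,
        n_boot = n_boot, seed = derive_seed(config$seed, paste0("nri-", mn))))
  names(nris) <- paste0("MDAFM_vs_", setdiff(names(models), "MDAFM"))
  structure(list(comparison = comparison, nri = nris, runs = models,
                 adaptations = adaptations, split = prep$split,
                 selection = prep$selection, config = config),
            class = "mdafm_ablation")
}

#' @export
print.mdafm_ablation <- function(x, ...) {
  print(x$comparison, row.names = FALSE)
  for (nm in names(x$nri)) {
    r <- x$nri[[nm]]
    cat(sprintf("%s: NRI %.4f (%.4f, %.4f), p = %.4g\n",
                nm, r$nri, r$ci_low, r$ci_high, r$p_value))
  }
  invisible(x)
}

#' End-to-end synthetic demo
#'
#' Generates a scaled-down synthetic cohort (same statistical structure as
#' the default world, fewer feature columns so the demo runs in seconds),
#' runs the full ablation study, and writes the comparison table, NRI
#' results, DCA tables and run manifest to `out_dir`.
#'
#' @param seed global seed.
#' @param out_dir output directory (default a tempdir).
#' @param n_patients,n_features cohort size knobs for the demo.
#' @return the `mdafm_ablation`, invisibly; artifacts on disk.
#' @export
mdafm_demo <- function(seed = 7L, out_dir = tempfile("mdafm-demo"),
                       n_patients = 163L, n_features = 400L) {
  cohort <- generate_feature_cohort(synthetic_config(
    n_patients = n_patients, n_features_per_phase = n_features,
    n_latent = 16L, n_informative = 8L, seed = derive_seed(seed, "cohort")))
  config <- run_config(k = 40L, floor = 120L, epochs = 200L, L = 80L, B = 5L,
                       seed = seed)
  ab <- run_ablations(cohort, config, n_boot = 300L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(ab$comparison, file.path(out_dir, "comparison.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(ab$nri, function(r) r[c("nri", "ci_low", "ci_high", "p_value",
                                   "variant", "n_boot")]),
    file.path(out_dir, "nri.json"), auto_unbox = TRUE, digits = NA)
  for (mn in names(ab$runs))
    write.csv(ab$runs[[mn]]$report$test$dca,
              file.path(out_dir, sprintf("dca_test_%s.csv", mn)),
              row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, config = unclass(ab$config),
         split_hash = rlang::hash(ab$split),
         comparison_hash = rlang::hash(ab$comparison)),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(ab)
}
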