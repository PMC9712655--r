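# End-to-end study driver: curation -> descriptors -> selection ->
# standardisation -> fingerprints -> repeated stratified splits ->
# learners (+ GHOST) -> external-validation metrics.

#' Run the QSAR study pipeline on a chemical library
#'
#' Curates the records, computes and selects descriptors, fingerprints the
#' curated set, draws repeated stratified train/test splits, trains the
#' requested learners on each training split, shifts each decision
#' threshold with GHOST, and evaluates on the held-out split.
#'
#' All repeats are reported; `best_repeat` additionally names, per
#' learner, the repeat maximising test MCC. That selection is optimistic
#' (a max over random splits) and is flagged as such rather than reported
#' silently.
#'
#' @param records Data frame (id, smiles, ...) or `synthetic_library`.
#' @param labels Data frame (id, endpoint, active); taken from the library
#'   when `records` is a `synthetic_library`.
#' @param seed Integer master seed for selection, splits, learners and
#'   GHOST.
#' @param learners Character vector from {"rf", "balanced_rf"}.
#' @param n_repeats Number of stratified splits, default 1.
#' @param test_fraction Held-out fraction, default 0.15.
#' @param hyper_grid Hyperparameter grid forwarded to
#'   [train_classifier()]; the default single-row grid (sqrt-p mtry, 300
#'   trees) skips the CV search for speed.
#' @param ghost Logical: apply GHOST threshold shifting (default TRUE).
#' @return List of class `qsar_study`: `curated`, `selected`
#'   (descriptor matrix after selection), `scaler`, `fps`, `splits`,
#'   `results` (data frame: repeat, learner, threshold, SE, SP, Acc,
#'   bAcc, MCC, AUC, n_test), `models` (last repeat's fitted models),
#'   `best_repeat`.
#' @export
run_qsar_study <- function(records, labels = NULL, seed = 1L,
                           learners = c("rf", "balanced_rf"),
                           n_repeats = 1L, test_fraction = 0.15,
                           hyper_grid = NULL, ghost = TRUE) {
  if (inherits(records, "synthetic_library")) {
    labels <- records$labels
    records <- records$records
  }
  stopifnot(is.data.frame(labels))
  cur <- curate_library(records)
  mat <- compute_descriptor_matrix(cur)
  mat <- remove_uninformative(mat)$matrix
  mat <- correlation_cluster_select(mat, seed = seed)$matrix
  mat <- standardize_descriptors(mat)
  scaler <- mat$scaler
  fps <- maccs_fingerprints(mat$smiles, ids = mat$ids)

  lab <- stats::setNames(as.integer(labels$active), labels$id)
  lab <- lab[mat$ids]
  if (is.null(hyper_grid))
    hyper_grid <- data.frame(mtry = max(1L, floor(sqrt(ncol(mat$values)))),
                             ntree = 300L, nodesize = 1L)

  splits <- split_train_test(mat$ids, lab, test_fraction = test_fraction,
                             n_repeats = n_repeats, seed = seed)
  rows <- list()
  models <- list()
  for (r in seq_len(n_repeats)) {
    sp <- splits[[r]]
    tr_mat <- mat
    tr_mat$values <- mat$values[sp$train, , drop = FALSE]
    te_values <- mat$values[sp$test, , drop = FALSE]
    for (ln in learners) {
      model <- train_classifier(tr_mat$values, lab[sp$train], learner = ln,
                                hyper_grid = hyper_grid,
                                seed = seed + r,
                                train_fps = structure(fps[sp$train],
                                                      class = "maccs_fp_set"))
      if (ghost)
        model <- tune_threshold(model, tr_mat$values, seed = seed + r)
      prob <- predict_probability(model, te_values)
      cc <- confusion_counts(as.integer(prob >= model$threshold),
                             lab[sp$test])
      m <- compute_metrics(cc)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, learner = ln, threshold = model$threshold,
        SE = m$SE, SP = m$SP, Acc = m$Acc, bAcc = m$bAcc, MCC = m$MCC,
        AUC = auc_rank(prob, lab[sp$test]), n_test = length(sp$test))
      models[[ln]] <- model
    }
  }
  results <- do.call(rbind, rows)
  best <- vapply(unique(results$learner), function(ln) {
    sub <- results[results$learner == ln, ]
    sub$repeat_id[which.max(sub$MCC)]
  }, numeric(1))
  structure(list(curated = cur, selected = mat, scaler = scaler, fps = fps,
                 labels = lab, splits = splits, results = results,
                 models = models,
                 best_repeat = best),
            class = "qsar_study")
}

#' @export
print.qsar_study <- function(x, ...) {
  cat("QSAR study:", length(x$labels), "chemicals,",
      sum(x$labels), "active\n")
  print(x$results, row.names = FALSE)
  cat("(best repeat per learner is an optimistic max over splits:",
      paste(names(x$best_repeat), x$best_repeat, sep = "=",
            collapse = ", "), ")\n")
  invisible(x)
}
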