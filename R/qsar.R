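# Imbalance-aware binary QSAR classification: stratified repeated splits,
# random-forest and balanced random-forest learners with 10-fold
# cross-validated hyperparameter selection scored by MCC, GHOST decision
# threshold shifting, cross-validation reporting, and confidence-tiered
# prediction combining probability, applicability domain and chemotype
# evidence.

#' Stratified repeated train/test splits
#'
#' Draws `n_repeats` independent stratified splits holding out
#' `test_fraction` of the chemicals, preserving the class ratio within one
#' chemical per class.
#'
#' @param ids Chemical identifiers.
#' @param labels 0/1 labels aligned with `ids`; both classes need at least
#'   two members.
#' @param test_fraction Held-out fraction, default 0.15.
#' @param n_repeats Number of splits, default 5.
#' @param seed Integer seed; split r uses derived seed `seed + r - 1`.
#' @return List of length `n_repeats`; each element has `train` and `test`
#'   id vectors (disjoint, union = all ids).
#' @export
split_train_test <- function(ids, labels, test_fraction = 0.15,
                             n_repeats = 5L, seed = 1L) {
  stopifnot(length(ids) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L)
    stop("need at least two chemicals per class")
  lapply(seq_len(n_repeats), function(r) {
    set.seed(seed + r - 1L, kind = "Mersenne-Twister",
             sample.kind = "Rejection")
    # largest-remainder allocation so the test set totals round(n * frac)
    groups <- split(ids, labels)
    quota <- vapply(groups, length, integer(1)) * test_fraction
    k <- floor(quota)
    extra <- round(sum(quota)) - sum(k)
    if (extra > 0) {
      ord <- order(quota - k, decreasing = TRUE)
      k[ord[seq_len(extra)]] <- k[ord[seq_len(extra)]] + 1L
    }
    k <- pmax(k, 1L)
    test <- unlist(lapply(seq_along(groups), function(gi)
      sample(groups[[gi]], k[gi])), use.names = FALSE)
    list(train = setdiff(ids, test), test = test)
  })
}

.rf_fit <- function(X, y, learner, mtry, ntree, nodesize, seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  yf <- factor(y, levels = c(0, 1))
  args <- list(x = X, y = yf, ntree = ntree, mtry = mtry,
               nodesize = nodesize)
  if (learner == "balanced_rf") {
    nmin <- min(table(yf))
    args$strata <- yf
    args$sampsize <- c(nmin, nmin)
    args$replace <- TRUE
  }
  do.call(randomForest::randomForest, args)
}

.rf_prob <- function(fit, X) {
  unname(stats::predict(fit, X, type = "prob")[, "1"])
}

#' Train an imbalance-aware QSAR classifier
#'
#' Grid-searches the hyperparameter grid by mean 10-fold cross-validated
#' MCC (at the default 0.5 cutoff), then refits the winning configuration
#' on the full training set. The `balanced_rf` learner draws a
#' class-balanced bootstrap per tree (stratified sampling of
#' minority-class size from both classes); `rf` is a plain random forest.
#' Other probability-emitting learners can be plugged in via `fit_fun` /
#' `prob_fun`.
#'
#' @param mat Training `descriptor_matrix` (standardized or raw; frozen
#'   as-is) or plain matrix with rownames.
#' @param labels Named 0/1 vector or data frame (id, active) covering the
#'   training ids.
#' @param learner `"balanced_rf"` (default), `"rf"`, or `"pluggable"`.
#' @param hyper_grid Data frame of candidate hyperparameters (columns
#'   mtry, ntree, nodesize); a single-row grid skips the CV search.
#' @param cv_folds Folds for the hyperparameter search, default 10.
#' @param seed Integer seed.
#' @param train_fps Optional `maccs_fp_set` of the training chemicals,
#'   stored for applicability-domain scoring at prediction time.
#' @param fit_fun,prob_fun For `learner = "pluggable"`: `fit_fun(X, y01)`
#'   returns a fitted state, `prob_fun(state, X)` returns active-class
#'   probabilities.
#' @return Object of class `qsar_model`: fitted state, `threshold`
#'   (0.5 until [ghost_threshold()] is applied), `descriptor_names`,
#'   `train_fps`, CV search results.
#' @export
train_classifier <- function(mat, labels,
                             learner = c("balanced_rf", "rf", "pluggable"),
                             hyper_grid = NULL, cv_folds = 10L, seed = 1L,
                             train_fps = NULL,
                             fit_fun = NULL, prob_fun = NULL) {
  learner <- match.arg(learner)
  X <- if (inherits(mat, "descriptor_matrix")) mat$values else mat
  stopifnot(is.matrix(X), !is.null(rownames(X)))
  if (is.data.frame(labels)) labels <- stats::setNames(labels$active, labels$id)
  y <- as.integer(labels[rownames(X)])
  if (anyNA(y)) stop("labels missing for some training chemicals")
  if (length(unique(y)) < 2L) stop("training set must contain both classes")

  if (learner == "pluggable") {
    if (is.null(fit_fun) || is.null(prob_fun))
      stop("pluggable learner needs fit_fun and prob_fun")
    state <- fit_fun(X, y)
    return(structure(list(learner = learner, fit = state,
                          prob_fun = prob_fun, threshold = 0.5,
                          descriptor_names = colnames(X),
                          train_fps = train_fps, seed = seed,
                          train_ids = rownames(X)),
                     class = "qsar_model"))
  }

  if (is.null(hyper_grid)) {
    p <- ncol(X)
    hyper_grid <- expand.grid(
      mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3)))),
      ntree = 500L, nodesize = c(1L, 5L))
  }
  if (nrow(hyper_grid) == 0L) stop("empty hyperparameter grid")

  cv_results <- NULL
  best <- hyper_grid[1, , drop = FALSE]
  if (nrow(hyper_grid) > 1L) {
    folds <- .stratified_folds(y, cv_folds, seed)
    scores <- vapply(seq_len(nrow(hyper_grid)), function(g) {
      hp <- hyper_grid[g, ]
      mccs <- vapply(seq_len(max(folds)), function(f) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2L) return(NA_real_)
        fit <- .rf_fit(X[tr, , drop = FALSE], y[tr], learner,
                       hp$mtry, hp$ntree, hp$nodesize, seed + f)
        prob <- .rf_prob(fit, X[!tr, , drop = FALSE])
        compute_metrics(confusion_counts(as.integer(prob >= 0.5),
                                         y[!tr]))$MCC
      }, numeric(1))
      mean(mccs, na.rm = TRUE)
    }, numeric(1))
    cv_results <- cbind(hyper_grid, cv_mcc = scores)
    best <- hyper_grid[which.max(scores), , drop = FALSE]
  }
  fit <- .rf_fit(X, y, learner, best$mtry, best$ntree, best$nodesize, seed)
  structure(list(learner = learner, fit = fit, threshold = 0.5,
                 hyperparameters = best, cv_results = cv_results,
                 descriptor_names = colnames(X), train_fps = train_fps,
                 seed = seed, train_ids = rownames(X), train_labels = y),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("QSAR model:", x$learner, "| decision threshold", x$threshold, "|",
      length(x$descriptor_names), "descriptors\n")
  invisible(x)
}

#' Predicted active-class probabilities
#'
#' @param model A `qsar_model`.
#' @param mat Descriptor matrix or plain matrix over the model's frozen
#'   descriptors.
#' @param oob Use out-of-bag votes when scoring the training matrix itself
#'   (random-forest learners only).
#' @return Named numeric probabilities.
#' @export
predict_probability <- function(model, mat, oob = FALSE) {
  X <- if (inherits(mat, "descriptor_matrix")) mat$values else mat
  miss <- setdiff(model$descriptor_names, colnames(X))
  if (length(miss))
    stop("descriptor mismatch; missing: ", paste(miss, collapse = ", "))
  X <- X[, model$descriptor_names, drop = FALSE]
  if (model$learner == "pluggable")
    return(stats::setNames(model$prob_fun(model$fit, X), rownames(X)))
  if (oob) {
    stopifnot(identical(rownames(X), model$train_ids))
    return(stats::setNames(unname(model$fit$votes[, "1"]), rownames(X)))
  }
  stats::setNames(.rf_prob(model$fit, X), rownames(X))
}

.stratified_folds <- function(y, k, seed) {
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' GHOST decision-threshold shifting
#'
#' Generalized threshold shifting for imbalanced classifiers: scans a
#' candidate grid of probability cutoffs and returns the one maximising
#' the median tuning metric over stratified random subsamples of the
#' training set. Ties are broken toward 0.5.
#'
#' @param probabilities Training-set probabilities (out-of-bag
#'   probabilities are recommended for random forests, see
#'   [predict_probability()]).
#' @param labels Training 0/1 labels aligned with `probabilities`.
#' @param candidates Candidate thresholds, default 0.05 to 0.50 by 0.05.
#' @param metric `"MCC"` (default) or `"kappa"`.
#' @param n_draws Number of subsamples, default 50.
#' @param subsample_fraction Fraction drawn per subsample, default 0.2.
#' @param seed Integer seed.
#' @return The selected threshold (an element of `candidates`).
#' @export
ghost_threshold <- function(probabilities, labels,
                            candidates = seq(0.05, 0.50, by = 0.05),
                            metric = c("MCC", "kappa"), n_draws = 50L,
                            subsample_fraction = 0.2, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(length(probabilities) == length(labels), length(candidates) >= 1L)
  y <- as.integer(labels)
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  metric_fun <- if (metric == "MCC") {
    function(cc) compute_metrics(cc)$MCC
  } else {
    .kappa_metric
  }
  scores <- matrix(NA_real_, nrow = n_draws, ncol = length(candidates))
  for (d in seq_len(n_draws)) {
    idx <- unlist(lapply(split(seq_along(y), y), function(g)
      sample(g, max(1L, round(length(g) * subsample_fraction)))),
      use.names = FALSE)
    for (ci in seq_along(candidates)) {
      cc <- confusion_counts(as.integer(probabilities[idx] >= candidates[ci]),
                             y[idx])
      scores[d, ci] <- metric_fun(cc)
    }
  }
  med <- apply(scores, 2, stats::median, na.rm = TRUE)
  best <- which(med == max(med))
  candidates[best[which.min(abs(candidates[best] - 0.5))]]
}

#' Apply a GHOST-selected threshold to a model
#'
#' Convenience wrapper: computes out-of-bag training probabilities, runs
#' [ghost_threshold()], and stores the result in the model.
#'
#' @param model A fitted `qsar_model` (random-forest learners).
#' @param mat The training descriptor matrix.
#' @param ... Passed to [ghost_threshold()].
#' @return The model with an updated `threshold`.
#' @export
tune_threshold <- function(model, mat, ...) {
  prob <- predict_probability(model, mat, oob = TRUE)
  model$threshold <- ghost_threshold(prob, model$train_labels, ...)
  model
}

#' Stratified k-fold cross-validation of a learner
#'
#' @param mat Descriptor matrix (or plain matrix with rownames).
#' @param labels Named 0/1 vector or data frame (id, active).
#' @param learner `"balanced_rf"` or `"rf"`.
#' @param k Folds, default 10; `k` must not exceed the number of
#'   chemicals.
#' @param seed Integer seed.
#' @param threshold Decision cutoff applied to fold probabilities.
#' @param hyper Single-row hyperparameter data frame (mtry, ntree,
#'   nodesize); defaults to sqrt-mtry, 500 trees, nodesize 1.
#' @return List: `per_fold` (data frame of fold metrics), `pooled`
#'   (metrics from summed confusion counts), `auc` (pooled rank AUC).
#' @export
cross_validate <- function(mat, labels, learner = "balanced_rf", k = 10L,
                           seed = 1L, threshold = 0.5, hyper = NULL) {
  X <- if (inherits(mat, "descriptor_matrix")) mat$values else mat
  if (is.data.frame(labels)) labels <- stats::setNames(labels$active, labels$id)
  y <- as.integer(labels[rownames(X)])
  if (k > nrow(X)) stop("more folds than chemicals")
  if (is.null(hyper))
    hyper <- data.frame(mtry = max(1L, floor(sqrt(ncol(X)))), ntree = 500L,
                        nodesize = 1L)
  folds <- .stratified_folds(y, k, seed)
  pooled <- list(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  prob_all <- numeric(length(y))
  per_fold <- vector("list", max(folds))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    fit <- .rf_fit(X[tr, , drop = FALSE], y[tr], learner, hyper$mtry,
                   hyper$ntree, hyper$nodesize, seed + f)
    prob <- .rf_prob(fit, X[!tr, , drop = FALSE])
    prob_all[!tr] <- prob
    cc <- confusion_counts(as.integer(prob >= threshold), y[!tr])
    for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + cc[[nm]]
    m <- compute_metrics(cc)
    per_fold[[f]] <- data.frame(fold = f, SE = m$SE, SP = m$SP,
                                Acc = m$Acc, bAcc = m$bAcc, MCC = m$MCC)
  }
  class(pooled) <- "confusion_counts"
  list(per_fold = do.call(rbind, per_fold),
       pooled = compute_metrics(pooled),
       pooled_counts = pooled,
       auc = auc_rank(prob_all, y))
}

#' Predict with confidence tiers
#'
#' Scores query chemicals with the model and assembles, per chemical: the
#' active-class probability, the active call at the model's decision
#' threshold, the applicability-domain score against the training
#' fingerprints, and the number of significant chemotypes present. For
#' predicted actives a confidence tier is assigned from three criteria —
#' probability above 0.5, AD score at least 0.75, and more than three
#' significant chemotypes present: `high` when all three hold, `medium`
#' for exactly two, `low` otherwise. Predicted inactives get
#' `not_applicable`.
#'
#' @param model A `qsar_model` holding `train_fps`.
#' @param mat Query descriptor matrix over the model's frozen descriptors.
#' @param query_fps `maccs_fp_set` of the query chemicals (same order as
#'   `mat` rows).
#' @param enrichment [chemotype_enrichment()] rows from the training
#'   analysis; chemotypes with p < `sig_cutoff` count as significant.
#' @param chemotypes `chemotype_matrix` covering the query chemicals.
#' @param sig_cutoff Chemotype significance cutoff, default 0.01.
#' @return Data frame of class `prediction_records`: id, probability,
#'   predicted, ad_score, sig_chemotypes, confidence.
#' @export
predict_with_confidence <- function(model, mat, query_fps, enrichment,
                                    chemotypes, sig_cutoff = 0.01) {
  stopifnot(inherits(model, "qsar_model"))
  if (is.null(model$train_fps))
    stop("model carries no training fingerprints; refit with train_fps")
  prob <- predict_probability(model, mat)
  ids <- names(prob)
  stopifnot(identical(ids, names(query_fps)))
  ad <- vapply(query_fps, ad_score, numeric(1), training = model$train_fps)
  sig <- enrichment$chemotype[!enrichment$untestable &
                                !is.na(enrichment$p_value) &
                                enrichment$p_value < sig_cutoff]
  sig <- intersect(sig, colnames(chemotypes$flags))
  n_sig <- if (length(sig) == 0L) rep(0L, length(ids)) else
    rowSums(chemotypes$flags[ids, sig, drop = FALSE])
  predicted <- as.integer(prob >= model$threshold)
  met <- (prob > 0.5) + (ad >= 0.75) + (n_sig > 3)
  confidence <- ifelse(predicted == 0L, "not_applicable",
                       ifelse(met == 3, "high",
                              ifelse(met == 2, "medium", "low")))
  out <- data.frame(id = ids, probability = unname(prob),
                    predicted = predicted, ad_score = unname(ad),
                    sig_chemotypes = unname(n_sig),
                    confidence = confidence, stringsAsFactors = FALSE)
  class(out) <- c("prediction_records", class(out))
  out
}
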