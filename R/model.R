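# CRM regression: dataset assembly from windowed feature series, OLS and
# gradient-boosted tree fits, subject-wise cross-validation, and Gini
# feature importance.

FEATURE_SETS <- list(
  all          = c("PPI", "HRV", "HRDN", "SBP", "DBP", "PP", "PA", "IPA", "SI"),
  vital_signs  = c("PPI", "SBP", "HRV", "SI", "DBP"),
  abp_waveform = c("PPI", "HRDN", "PP", "IPA"),
  hrdn_only    = "HRDN"
)

#' Assemble a modeling dataset from extracted sessions
#'
#' Builds one row per valid feature window across sessions: the selected
#' feature columns, the reference CRM interpolated to the window time, the
#' phase label and signed ramp rate at that time (negative =
#' depressurization, positive = repressurization, 0 elsewhere), and
#' subject/session identifiers. Optionally restricts to one phase and/or
#' applies baseline normalization per session.
#'
#' @param sessions A list of extracted sessions as returned by
#'   [extract_features()]: each element has `features` (a `feature_series`),
#'   `trace` (the protocol), and `meta` (ids and ramp rates).
#' @param feature_set One of `"all"`, `"vital_signs"`, `"abp_waveform"`,
#'   `"hrdn_only"`.
#' @param phase_selection `"full"`, `"depressurization"` or
#'   `"repressurization"`.
#' @param normalization `"none"` or `"baseline"` (divide each feature by its
#'   valid baseline-phase window mean within the session).
#' @return A data frame of class `crm_dataset` with columns `subject_id`,
#'   `session_id`, `phase`, `ramp_rate`, `window_time`, the feature columns,
#'   and `reference_crm`; attribute `feature_names`.
#' @export
assemble_dataset <- function(sessions,
                             feature_set = c("all", "vital_signs",
                                             "abp_waveform", "hrdn_only"),
                             phase_selection = c("full", "depressurization",
                                                 "repressurization"),
                             normalization = c("none", "baseline")) {
  if (length(sessions) == 0L) stop_invalid("`sessions` must be nonempty")
  if (is.character(feature_set) && length(feature_set) == 1L &&
      !feature_set %in% names(FEATURE_SETS))
    stop_invalid("unknown feature_set '%s'; valid names: %s", feature_set,
                 paste(names(FEATURE_SETS), collapse = ", "))
  feature_set <- match.arg(feature_set)
  phase_selection <- match.arg(phase_selection)
  normalization <- match.arg(normalization)
  feats <- FEATURE_SETS[[feature_set]]

  rows <- lapply(sessions, function(s) {
    tab <- s$features
    if (normalization == "baseline") {
      base_end <- max(s$trace$time_s[s$trace$phase == "baseline"])
      tab <- baseline_normalize(tab, base_end)
    }
    keep <- tab$valid & stats::complete.cases(tab[feats])
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) == 0L) return(NULL)
    phase <- phase_at_time(s$trace, tab$window_time)
    rate <- ifelse(phase == "depressurization", -s$meta$down_rate,
                   ifelse(phase == "repressurization", s$meta$up_rate, 0))
    out <- data.frame(
      subject_id = s$meta$subject_id,
      session_id = s$meta$session_id,
      phase = phase,
      ramp_rate = rate,
      window_time = tab$window_time,
      stringsAsFactors = FALSE
    )
    out[feats] <- tab[feats]
    out$reference_crm <- crm_at_time(s$trace, tab$window_time)
    out
  })
  out <- do.call(rbind, rows)
  if (phase_selection != "full") out <- out[out$phase == phase_selection, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feature_names") <- feats
  class(out) <- c("crm_dataset", "data.frame")
  out
}

#' Regressor configuration
#'
#' Hyperparameters of the CRM regressors. The gradient-boosted tree ensemble
#' uses 100 estimators minimizing squared-error loss with no row subsampling;
#' tree depth 3 and learning rate 0.1 are this package's defaults (commonly
#' used boosting defaults -- not prescribed by the study design) and can be
#' changed here.
#'
#' @param model_kind `"gb_tree"` or `"ols"`.
#' @param n_estimators Number of boosting rounds (default 100).
#' @param max_depth Tree depth (default 3).
#' @param learning_rate Shrinkage per round (default 0.1).
#' @param seed Integer seed for the fit.
#' @return A list of class `crm_model_config`.
#' @export
model_config <- function(model_kind = c("gb_tree", "ols"),
                         n_estimators = 100, max_depth = 3,
                         learning_rate = 0.1, seed = 1) {
  model_kind <- match.arg(model_kind)
  structure(list(model_kind = model_kind, n_estimators = n_estimators,
                 max_depth = max_depth, learning_rate = learning_rate,
                 seed = seed),
            class = "crm_model_config")
}

#' Fit a CRM regressor
#'
#' Trains either a gradient-boosted regression tree ensemble (squared-error
#' loss, no bootstrap subsampling of rows or columns, single thread for
#' determinism) or an ordinary-least-squares linear model on the dataset's
#' feature columns. A constant training target yields a constant model with
#' a warning.
#'
#' @param train A `crm_dataset`.
#' @param config A [model_config()].
#' @return A list of class `crm_model` with the fitted engine, the feature
#'   names and the config.
#' @export
fit_model <- function(train, config = model_config()) {
  feats <- attr(train, "feature_names")
  if (is.null(feats)) stop_invalid("`train` must be a crm_dataset")
  if (length(unique(train$subject_id)) < 2L)
    stop_invalid("training data must contain at least 2 subjects")
  y <- train$reference_crm
  const <- FALSE
  if (stats::sd(y) == 0) {
    warning("constant training target; model will predict that constant")
    const <- TRUE
  }
  x <- as.matrix(train[feats])
  if (config$model_kind == "gb_tree") {
    set.seed(config$seed)
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    engine <- xgboost::xgb.train(
      params = list(
        objective = "reg:squarederror",
        eta = config$learning_rate,
        max_depth = config$max_depth,
        subsample = 1, colsample_bytree = 1,
        lambda = 0, alpha = 0,
        base_score = mean(y),
        nthread = 1,
        seed = config$seed
      ),
      data = dtrain, nrounds = config$n_estimators, verbose = 0
    )
  } else {
    df <- data.frame(.crm = y, x, check.names = FALSE)
    engine <- stats::lm(stats::reformulate(sprintf("`%s`", feats), ".crm"),
                        data = df)
  }
  structure(list(engine = engine, features = feats, config = config,
                 constant = if (const) mean(y) else NULL),
            class = "crm_model")
}

#' Predict CRM estimates, clipped to the 0--100% scale
#'
#' @param model A fitted `crm_model`.
#' @param newdata A `crm_dataset` or data frame containing the model's
#'   feature columns.
#' @return Numeric vector of CRM estimates in \[0, 100\].
#' @export
predict_crm <- function(model, newdata) {
  x <- as.matrix(newdata[model$features])
  p <- if (!is.null(model$constant)) {
    rep(model$constant, nrow(x))
  } else if (model$config$model_kind == "gb_tree") {
    stats::predict(model$engine, xgboost::xgb.DMatrix(x))
  } else {
    df <- as.data.frame(x)
    colnames(df) <- model$features
    as.numeric(stats::predict(model$engine, df))
  }
  pmin(pmax(p, 0), 100)
}

#' Gini importance of a gradient-boosted tree model
#'
#' Normalized total decrease in the squared-error split criterion
#' attributable to each feature across all trees of the ensemble. Importances
#' are nonnegative and sum to 1; features never used in a split score 0.
#'
#' @param model A fitted `crm_model` with `model_kind = "gb_tree"`.
#' @return Named numeric vector over the model's features.
#' @export
gini_importance <- function(model) {
  if (!inherits(model, "crm_model") || model$config$model_kind != "gb_tree")
    stop_invalid("Gini importance is defined only for gb_tree models")
  imp <- rep(0, length(model$features))
  names(imp) <- model$features
  if (!is.null(model$constant)) {
    imp[1L] <- 1
    return(imp)
  }
  # total split gain per feature from the tree dump, normalized to sum 1
  tree <- xgboost::xgb.model.dt.tree(model = model$engine)
  splits <- tree[tree$Feature != "Leaf", c("Feature", "Gain")]
  if (nrow(splits) > 0) {
    g <- tapply(splits$Gain, splits$Feature, sum)
    g <- pmax(g, 0)
    imp[names(g)] <- g
    imp <- imp / sum(imp)
  } else {
    imp[1L] <- 1   # degenerate ensemble with no splits
  }
  imp
}

#' Subject-wise k-fold cross-validation
#'
#' Partitions subjects (not rows) into `k` folds -- sorted by id, shuffled
#' with `seed`, dealt round-robin -- so that no subject contributes to both
#' the training and test side of any fold, then fits the model on each
#' training split and predicts the held-out subjects. Per-fold regression
#' metrics, ROC AUCs at the clinical CRM thresholds, and (for tree models)
#' Gini importances are collected and aggregated as mean and SD across
#' folds.
#'
#' @param data A `crm_dataset`.
#' @param k Number of folds (default 5).
#' @param config A [model_config()].
#' @param seed Seed for the fold shuffle.
#' @param auc_thresholds CRM thresholds (percent) for the ROC analyses.
#' @return A list of class `crm_cv`: `folds` (per-fold subject ids,
#'   predictions with row metadata, metrics, importances), `metrics` (mean
#'   and sd of RMSE, R2 and each AUC), `predictions` (pooled rows with
#'   per-row `estimate` from the fold holding that subject out), and
#'   `importance` (fold-mean Gini importances, tree models only).
#' @export
subjectwise_cv <- function(data, k = 5, config = model_config(), seed = 1,
                           auc_thresholds = c(70, 40, 5)) {
  subjects <- sort(unique(data$subject_id))
  if (length(subjects) < k)
    stop_invalid("need at least k = %d subjects, have %d", k, length(subjects))
  set.seed(seed)
  shuffled <- sample(subjects)
  assignment <- rep_len(seq_len(k), length(shuffled))
  fold_of <- stats::setNames(assignment, shuffled)

  folds <- vector("list", k)
  pooled <- vector("list", k)
  for (f in seq_len(k)) {
    test_subj <- names(fold_of)[fold_of == f]
    is_test <- data$subject_id %in% test_subj
    train <- data[!is_test, , drop = FALSE]
    test <- data[is_test, , drop = FALSE]
    attr(train, "feature_names") <- attr(data, "feature_names")
    attr(test, "feature_names") <- attr(data, "feature_names")
    model <- fit_model(train, config)
    est <- predict_crm(model, test)
    rm <- regression_metrics(est, test$reference_crm)
    aucs <- vapply(auc_thresholds, function(thr)
      roc_auc_at_threshold(est, test$reference_crm, thr), numeric(1))
    names(aucs) <- sprintf("auc_%g", auc_thresholds)
    imp <- if (config$model_kind == "gb_tree") gini_importance(model) else NULL
    folds[[f]] <- list(test_subjects = test_subj, rmse = rm$rmse, r2 = rm$r2,
                       aucs = aucs, importance = imp)
    pooled[[f]] <- cbind(test[c("subject_id", "session_id", "phase",
                                "ramp_rate", "window_time", "reference_crm")],
                         estimate = est, fold = f)
  }
  metric_tab <- function(get) {
    v <- vapply(folds, get, numeric(1))
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  }
  metrics <- list(rmse = metric_tab(function(f) f$rmse),
                  r2 = metric_tab(function(f) f$r2))
  for (nm in names(folds[[1]]$aucs))
    metrics[[nm]] <- metric_tab(function(f) f$aucs[[nm]])
  importance <- NULL
  if (config$model_kind == "gb_tree") {
    im <- do.call(rbind, lapply(folds, function(f) f$importance))
    importance <- colMeans(im)
  }
  structure(list(folds = folds, metrics = metrics,
                 predictions = do.call(rbind, pooled),
                 importance = importance, k = k, config = config),
            class = "crm_cv")
}

#' @export
print.crm_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<crm_cv> %d-fold subject-wise cross-validation (%s)\n",
              x$k, x$config$model_kind))
  cat(sprintf("  RMSE %.1f +/- %.1f %%CRM   R2 %.2f +/- %.2f\n",
              m$rmse["mean"], m$rmse["sd"], m$r2["mean"], m$r2["sd"]))
  for (nm in grep("^auc_", names(m), value = TRUE))
    cat(sprintf("  %s: %.3f +/- %.3f\n", nm, m[[nm]]["mean"], m[[nm]]["sd"]))
  invisible(x)
}
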