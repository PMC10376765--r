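# Network C: gradient-boosted-tree stacking of per-ROI risks.
#
# The six per-ROI disorder probabilities are concatenated into a feature
# vector and a gradient-boosted tree classifier (xgboost, logistic loss) maps
# it to the final disorder probability. Risk vectors used to train the
# stacker must come from a fold the ROI classifiers did not train on
# (out-of-fold protocol), otherwise the stacker inherits their optimism.

#' Fusion (stacking) configuration
#'
#' @param n_trees,max_depth,learning_rate,subsample Gradient-boosting
#'   hyperparameters; shallow trees suit the 6-dimensional feature space.
#' @param missing_policy How missing ROI risks (detector misses) enter the
#'   features: `"indicator"` sets the probability to 0.5 and appends six
#'   missingness indicators; `"impute_mean"` uses training means;
#'   `"native"` passes `NA` to the tree learner's default-direction handling.
#' @param monotone Constrain the stacker to be non-decreasing in every risk
#'   probability.
#' @param seed Integer seed.
#' @return Validated config list.
#' @export
fusion_config <- function(n_trees = 200, max_depth = 3, learning_rate = 0.1,
                          subsample = 0.8,
                          missing_policy = c("indicator", "impute_mean",
                                             "native"),
                          monotone = FALSE, seed = 1L) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(n_trees >= 1, max_depth >= 1, learning_rate > 0,
            learning_rate <= 1)
  list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
       learning_rate = learning_rate, subsample = subsample,
       missing_policy = missing_policy, monotone = monotone,
       seed = as.integer(seed))
}

risk_feature_matrix <- function(risk_vectors, config, train_means = NULL) {
  p <- t(vapply(risk_vectors, function(rv) rv$s, numeric(6)))
  m <- t(vapply(risk_vectors, function(rv) as.numeric(rv$missing_mask),
                numeric(6)))
  colnames(p) <- paste0("s_", gsub("[^A-Za-z0-9]", "", risk_classes()))
  colnames(m) <- paste0("miss_", gsub("[^A-Za-z0-9]", "", risk_classes()))
  if (config$missing_policy == "indicator") {
    p[is.na(p)] <- 0.5
    cbind(p, m)
  } else if (config$missing_policy == "impute_mean") {
    mu <- train_means %||% colMeans(p, na.rm = TRUE)
    mu[is.na(mu)] <- 0.5
    for (j in seq_len(ncol(p))) p[is.na(p[, j]), j] <- mu[j]
    p
  } else {
    p
  }
}

#' Train the risk-fusion stacker
#'
#' @param risk_vectors List of `fg_risk_vector`s from a fold not used to
#'   train the ROI classifiers.
#' @param labels Binary vector.
#' @param config From [fusion_config()].
#' @return Object of class `fg_stacker`.
#' @export
train_fusion <- function(risk_vectors, labels, config = fusion_config()) {
  labels <- as.integer(labels)
  if (length(risk_vectors) != length(labels))
    stop("feature/label length mismatch")
  if (min(table(factor(labels, levels = 0:1))) < 2)
    stop("need at least 2 examples per class")
  X <- risk_feature_matrix(risk_vectors, config)
  train_means <- colMeans(t(vapply(risk_vectors, function(rv) rv$s,
                                   numeric(6))), na.rm = TRUE)
  params <- list(objective = "binary:logistic", max_depth = config$max_depth,
                 eta = config$learning_rate, subsample = config$subsample,
                 nthread = 1)
  if (config$monotone)
    params$monotone_constraints <- paste0(
      "(", paste(c(rep(1, 6), rep(0, ncol(X) - 6)), collapse = ","), ")")
  set.seed(config$seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = labels)
  # n_trees caps the rounds; the actual number is chosen by 5-fold
  # cross-validated early stopping, which matters at stacking-fold sizes of
  # a few hundred rows where a fixed deep ensemble overfits noise features
  nrounds <- config$n_trees
  if (length(labels) >= 30) {
    cvp <- c(params, list(eval_metric = "auc"))
    cv <- xgboost::xgb.cv(params = cvp, data = dtrain,
                          nrounds = config$n_trees, nfold = 5,
                          early_stopping_rounds = 20, verbose = 0)
    nrounds <- max(1L, which.max(cv$evaluation_log$test_auc_mean))
  }
  set.seed(config$seed)
  bst <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = nrounds, verbose = 0)
  structure(list(model = bst, config = config,
                 feature_names = colnames(X), train_means = train_means),
            class = "fg_stacker")
}

#' Final disorder probability from a risk vector
#'
#' @param stacker Trained `fg_stacker`.
#' @param risk_vector A `fg_risk_vector` (or list of them).
#' @param detections,heatmaps Optional extras carried into the prediction.
#' @return A `fg_prediction` (list with `probability`, `risk_vector`,
#'   `detections`, `heatmaps`), or a numeric vector for a list input.
#' @export
predict_disorder <- function(stacker, risk_vector, detections = NULL,
                             heatmaps = NULL) {
  single <- inherits(risk_vector, "fg_risk_vector")
  rvs <- if (single) list(risk_vector) else risk_vector
  X <- risk_feature_matrix(rvs, stacker$config, stacker$train_means)
  p <- stats::predict(stacker$model, xgboost::xgb.DMatrix(X))
  if (!single) return(as.numeric(p))
  structure(list(probability = as.numeric(p[1]), risk_vector = risk_vector,
                 detections = detections, heatmaps = heatmaps),
            class = "fg_prediction")
}

#' Choose the decision threshold on validation data
#'
#' `"fixed_0.5"` ignores the labels and returns 0.5. `"youden"` maximizes
#' sensitivity + specificity - 1 over candidate thresholds placed midway
#' between consecutive unique scores (evaluated on validation data only).
#'
#' @param probabilities Validation scores.
#' @param labels Binary labels.
#' @param policy `"fixed_0.5"` or `"youden"`.
#' @return Threshold in (0, 1).
#' @export
choose_operating_point <- function(probabilities, labels,
                                   policy = c("fixed_0.5", "youden")) {
  policy <- match.arg(policy)
  if (policy == "fixed_0.5") return(0.5)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("youden threshold needs both classes in the validation labels")
  u <- sort(unique(probabilities))
  cand <- c(u[1] - 1e-6, (head(u, -1) + u[-1]) / 2, u[length(u)] + 1e-6)
  j <- vapply(cand, function(t) {
    pred <- probabilities >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}
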