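# Stage 5: gradient-boosted regression trees on a ModelInput.
#
# The learner is a leaf-wise histogram GBM (xgboost with
# grow_policy = "lossguide"), configured through the familiar GBM
# vocabulary. The field-location categorical is one-hot encoded with
# a level set shared between training and validation; fits are
# single-threaded and seeded, so identical inputs give identical
# predictions.

#' Gradient-boosting configuration
#'
#' @param num_trees boosting rounds (default 100).
#' @param learning_rate shrinkage (default 0.1).
#' @param max_leaves maximum leaves per tree (default 31, leaf-wise
#'   growth).
#' @param min_data_in_leaf minimum observations per leaf (default 20;
#'   for squared loss this maps exactly onto the hessian-based
#'   minimum-child-weight rule).
#' @param feature_fraction column subsample per tree in (0, 1].
#' @param bagging_fraction row subsample per tree in (0, 1].
#' @param seed integer seed.
#' @param categorical_features names of categorical columns (default
#'   `"Location"`), one-hot encoded before fitting.
#' @return a [GBMConfig-class].
#' @export
gbmConfig <- function(num_trees = 100, learning_rate = 0.1,
                      max_leaves = 31, min_data_in_leaf = 20,
                      feature_fraction = 1.0, bagging_fraction = 1.0,
                      seed = 1, categorical_features = "Location") {
  methods::new("GBMConfig",
               numTrees = as.integer(num_trees),
               learningRate = learning_rate,
               maxLeaves = as.integer(max_leaves),
               minDataInLeaf = as.integer(min_data_in_leaf),
               featureFraction = feature_fraction,
               baggingFraction = bagging_fraction,
               seed = as.integer(seed),
               categoricalFeatures = categorical_features)
}

#' @noRd
featureColumns <- function(tab) {
  setdiff(names(tab), c("Env", "Hybrid", "y"))
}

#' Design matrix: numeric features as-is, categoricals one-hot with a
#' fixed level set.
#' @noRd
designMatrix <- function(tab, cfg, levels_map) {
  cols <- featureColumns(tab)
  pieces <- lapply(cols, function(cl) {
    if (cl %in% cfg@categoricalFeatures) {
      f <- factor(tab[[cl]], levels = levels_map[[cl]])
      mm <- matrix(0, nrow(tab), nlevels(f),
                   dimnames = list(NULL, paste0(cl, "=", levels(f))))
      mm[cbind(seq_len(nrow(tab)), as.integer(f))] <- 1
      mm
    } else {
      matrix(as.numeric(tab[[cl]]), ncol = 1,
             dimnames = list(NULL, cl))
    }
  })
  do.call(cbind, pieces)
}

#' Fit the GBM on training records and predict the validation records
#'
#' @param train,valid `data.frame`s with columns `Env`, `Hybrid`, `y`,
#'   `Location` and identical numeric feature columns (typically
#'   subsets of one [ModelInput-class] table), or [ModelInput-class]
#'   objects.
#' @param cfg a [GBMConfig-class].
#' @param model_kind label stored on the result (e.g. `"G(A)+E"`).
#' @param scheme,rep,fold bookkeeping labels for the CV cell.
#' @return a [PredictionSet-class].
#' @export
fitPredict <- function(train, valid, cfg = gbmConfig(),
                       model_kind = "model", scheme = "none",
                       rep = 1L, fold = 1L) {
  if (methods::is(train, "ModelInput")) train <- train@table
  if (methods::is(valid, "ModelInput")) valid <- valid@table
  if (!nrow(train)) stop("empty training set")
  if (!identical(sort(featureColumns(train)), sort(featureColumns(valid))))
    stop("feature-contract error: training and validation schemas differ")
  if (anyNA(train$y)) stop("training responses must be non-missing")

  levels_map <- lapply(
    stats::setNames(cfg@categoricalFeatures, cfg@categoricalFeatures),
    function(cl) sort(unique(c(train[[cl]], valid[[cl]]))))
  Xtr <- designMatrix(train, cfg, levels_map)
  Xva <- designMatrix(valid[, names(train), drop = FALSE], cfg, levels_map)

  params <- list(objective = "reg:squarederror",
                 eta = cfg@learningRate,
                 max_leaves = cfg@maxLeaves,
                 max_depth = 0L,
                 grow_policy = "lossguide",
                 tree_method = "hist",
                 min_child_weight = cfg@minDataInLeaf,
                 colsample_bytree = cfg@featureFraction,
                 subsample = cfg@baggingFraction,
                 nthread = 1L,
                 seed = cfg@seed)
  set.seed(cfg@seed)
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(Xtr, label = train$y, nthread = 1L),
    nrounds = cfg@numTrees, verbose = 0)
  pred <- stats::predict(booster, xgboost::xgb.DMatrix(Xva, nthread = 1L))

  methods::new("PredictionSet",
               records = data.frame(Env = valid$Env, Hybrid = valid$Hybrid,
                                    y_observed = valid$y,
                                    y_predicted = as.numeric(pred),
                                    stringsAsFactors = FALSE),
               modelKind = model_kind, scheme = scheme,
               rep = as.integer(rep), fold = as.integer(fold))
}
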