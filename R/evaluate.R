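# Running models through a CV plan.

#' Fit and evaluate one model input under a CV plan
#'
#' For every fold-by-repetition cell of the plan, subsets the model
#' input's table to the cell's training and validation keys, fits the
#' GBM and collects the validation predictions.
#'
#' @param input a [ModelInput-class].
#' @param plan a [CVPlan-class].
#' @param cfg a [GBMConfig-class].
#' @param model_kind label for the model (defaults to the input's
#'   kind/GRM tag).
#' @return list of [PredictionSet-class] objects, one per cell.
#' @export
runCV <- function(input, plan, cfg = gbmConfig(), model_kind = NULL) {
  tab <- input@table
  if (is.null(model_kind)) {
    model_kind <- if (input@grmKind == "none") input@kind
                  else sprintf("%s(%s)", input@kind, input@grmKind)
  }
  key <- comboKey(tab$Env, tab$Hybrid)
  out <- list()
  for (r in seq_len(plan@repetitions)) {
    for (f in seq_len(plan@folds)) {
      ts <- trainingSet(plan, r, f)
      vs <- validationSet(plan, r, f)
      tr_keys <- comboKey(ts$Env, ts$Hybrid)
      va_keys <- comboKey(vs$Env, vs$Hybrid)
      train <- tab[key %in% tr_keys, , drop = FALSE]
      valid <- tab[key %in% va_keys, , drop = FALSE]
      out[[length(out) + 1L]] <- fitPredict(
        train, valid, cfg, model_kind = model_kind,
        scheme = plan@scheme, rep = r, fold = f)
    }
  }
  out
}

#' Evaluate several models under one CV plan
#'
#' @param inputs named list of [ModelInput-class] objects (names are
#'   the model tokens).
#' @param plan a [CVPlan-class].
#' @param cfg a [GBMConfig-class].
#' @param tester_of optional hybrid-to-tester map; when given, the
#'   plan's mean tester overlap is included.
#' @param top_frac top fraction for the Coincidence Index.
#' @return list with `predictions` (named list of per-cell
#'   [PredictionSet-class] lists), `metrics` (per-cell accuracy
#'   table), `comparisons` (pairwise dependent-correlation tests,
#'   `NULL` for a single model) and `tester_overlap` (or `NA`).
#' @export
evaluateModels <- function(inputs, plan, cfg = gbmConfig(),
                           tester_of = NULL, top_frac = 0.20) {
  stopifnot(length(inputs) >= 1L, !is.null(names(inputs)))
  preds <- lapply(names(inputs), function(nm)
    runCV(inputs[[nm]], plan, cfg, model_kind = nm))
  names(preds) <- names(inputs)
  metrics <- do.call(rbind, lapply(preds, metricTable, top_frac = top_frac))
  rownames(metrics) <- NULL
  comparisons <- if (length(inputs) >= 2L) compareModels(preds) else NULL
  overlap <- if (!is.null(tester_of)) testerOverlap(plan, tester_of)
             else NA_real_
  list(predictions = preds, metrics = metrics, comparisons = comparisons,
       tester_overlap = overlap)
}
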