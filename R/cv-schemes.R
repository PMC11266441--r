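# Stage 6a: cross-validation plans (CV2, CV1, CV0).
#
# All schemes run `repetitions` repetitions of k-fold CV with
# k = `folds` (defaults 10 x 5). CV2 and CV1 operate on the last two
# trial years; CV0 trains on the earlier years and validates on the
# final year.

#' @noRd
newCVPlan <- function(scheme, assignments, folds, repetitions, seed) {
  methods::new("CVPlan", scheme = scheme, folds = as.integer(folds),
               repetitions = as.integer(repetitions),
               assignments = assignments, seed = as.integer(seed))
}

#' @noRd
schemeYears <- function(blues) {
  sort(unique(envYear(blues$Env)))
}

#' @noRd
bindAssignments <- function(rep, fold, train_df, valid_df) {
  rbind(data.frame(Rep = rep, Fold = fold, Set = "train",
                   train_df, stringsAsFactors = FALSE),
        data.frame(Rep = rep, Fold = fold, Set = "valid",
                   valid_df, stringsAsFactors = FALSE))
}

#' CV2 plan: untested environment-hybrid combinations
#'
#' Sparse testing: per fold, 20% of all environment-hybrid
#' combinations (of the last two trial years) form the validation set
#' and are removed from training. The five validation folds of one
#' repetition partition the combinations.
#'
#' @param blues BLUE table (`Env`, `Hybrid`, `y`).
#' @param seed integer seed.
#' @param folds folds per repetition (default 5).
#' @param repetitions repetitions (default 10).
#' @return a [CVPlan-class].
#' @export
splitCV2 <- function(blues, seed, folds = 5, repetitions = 10) {
  yrs <- schemeYears(blues)
  use <- blues[envYear(blues$Env) %in% utils::tail(yrs, 2), , drop = FALSE]
  combos <- unique(use[, c("Env", "Hybrid")])
  n <- nrow(combos)
  if (n < folds)
    stop(sprintf("need at least %d environment-hybrid combinations", folds))
  set.seed(deriveSeed(seed, "CV2"))
  out <- vector("list", repetitions * folds)
  for (r in seq_len(repetitions)) {
    perm <- sample.int(n)
    sizes <- foldSizes(n, folds)
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    for (f in seq_len(folds)) {
      vidx <- perm[starts[f]:stops[f]]
      out[[(r - 1L) * folds + f]] <- bindAssignments(
        r, f, combos[-vidx, , drop = FALSE], combos[vidx, , drop = FALSE])
    }
  }
  a <- do.call(rbind, out)
  rownames(a) <- NULL
  newCVPlan("CV2", a, folds, repetitions, seed)
}

#' CV1 plan: untested hybrids in known environments
#'
#' Per fold, 20% of the final-year hybrids form the validation set
#' (their final-year records); all records of those hybrids are
#' removed from the training set (records of the last two trial
#' years). The five folds partition the final-year hybrid set.
#'
#' @inheritParams splitCV2
#' @return a [CVPlan-class].
#' @export
splitCV1 <- function(blues, seed, folds = 5, repetitions = 10) {
  yrs <- schemeYears(blues)
  fy <- utils::tail(yrs, 1)
  use <- blues[envYear(blues$Env) %in% utils::tail(yrs, 2), , drop = FALSE]
  fy_rec <- use[envYear(use$Env) == fy, , drop = FALSE]
  hyb <- sort(unique(fy_rec$Hybrid))
  if (length(hyb) < folds)
    stop(sprintf("need at least %d final-year hybrids", folds))
  set.seed(deriveSeed(seed, "CV1"))
  out <- vector("list", repetitions * folds)
  for (r in seq_len(repetitions)) {
    perm <- sample(hyb)
    sizes <- foldSizes(length(hyb), folds)
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    for (f in seq_len(folds)) {
      vh <- perm[starts[f]:stops[f]]
      valid <- fy_rec[fy_rec$Hybrid %in% vh, c("Env", "Hybrid")]
      train <- use[!(use$Hybrid %in% vh), c("Env", "Hybrid")]
      out[[(r - 1L) * folds + f]] <- bindAssignments(r, f, train, valid)
    }
  }
  a <- do.call(rbind, out)
  rownames(a) <- NULL
  newCVPlan("CV1", a, folds, repetitions, seed)
}

#' CV0 plan: known hybrids in a new year
#'
#' Per fold: (1) 20% of the final-year hybrids (those with at least
#' one earlier-year record, i.e. "known" hybrids) form the validation
#' set — their final-year records; (2) the earlier-year records of
#' those hybrids enter the training set; (3) an additional 60% of the
#' remaining hybrids evaluated in the earlier years are sampled and
#' their earlier-year records added to training. No final-year record
#' ever enters training. On a carryover trial design this lands at
#' about an 80:20 train:validation proportion.
#'
#' @inheritParams splitCV2
#' @param extra_frac fraction of remaining earlier-year hybrids added
#'   to training (default 0.6).
#' @return a [CVPlan-class].
#' @export
splitCV0 <- function(blues, seed, folds = 5, repetitions = 10,
                     extra_frac = 0.6) {
  yrs <- schemeYears(blues)
  if (length(yrs) < 2L) stop("CV0 needs at least two trial years")
  fy <- utils::tail(yrs, 1)
  fy_rec <- blues[envYear(blues$Env) == fy, , drop = FALSE]
  past <- blues[envYear(blues$Env) < fy, , drop = FALSE]
  known <- sort(intersect(unique(fy_rec$Hybrid), unique(past$Hybrid)))
  if (length(known) < folds)
    stop(sprintf("need at least %d known final-year hybrids", folds))
  past_hyb <- sort(unique(past$Hybrid))

  set.seed(deriveSeed(seed, "CV0"))
  out <- vector("list", repetitions * folds)
  ratios <- numeric(0)
  for (r in seq_len(repetitions)) {
    perm <- sample(known)
    sizes <- foldSizes(length(known), folds)
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    for (f in seq_len(folds)) {
      vh <- perm[starts[f]:stops[f]]
      valid <- fy_rec[fy_rec$Hybrid %in% vh, c("Env", "Hybrid")]
      pool <- setdiff(past_hyb, vh)
      extra <- sample(pool, round(extra_frac * length(pool)))
      train <- past[past$Hybrid %in% c(vh, extra), c("Env", "Hybrid")]
      ratios <- c(ratios, nrow(train) / (nrow(train) + nrow(valid)))
      out[[(r - 1L) * folds + f]] <- bindAssignments(r, f, train, valid)
    }
  }
  achieved <- 100 * mean(ratios)
  if (abs(achieved - 80) > 5)
    warning(sprintf(
      "CV0 achieved a %.1f:%.1f train:validation proportion (insufficient earlier-year hybrids?)",
      achieved, 100 - achieved))
  a <- do.call(rbind, out)
  rownames(a) <- NULL
  newCVPlan("CV0", a, folds, repetitions, seed)
}

#' Mean training share of a CV plan
#'
#' 100 x n_train / (n_train + n_valid), averaged over all
#' fold-by-repetition cells.
#'
#' @param plan a [CVPlan-class].
#' @return percentage of records allocated to training.
#' @export
trainingShare <- function(plan) {
  a <- assignments(plan)
  cells <- split(a$Set, list(a$Rep, a$Fold), drop = TRUE)
  100 * mean(vapply(cells, function(s) mean(s == "train"), 0))
}

#' Write a CVPlan to JSON (for exact re-runs)
#'
#' @param plan a [CVPlan-class].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
writeCVPlan <- function(plan, path) {
  jsonlite::write_json(
    list(scheme = plan@scheme, folds = plan@folds,
         repetitions = plan@repetitions, seed = plan@seed,
         assignments = plan@assignments),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
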