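# Stage 6b: accuracy and comparison metrics.

#' Pearson prediction accuracy
#'
#' Sample Pearson correlation between observed and predicted yields.
#'
#' @param p a [PredictionSet-class], or a `data.frame` with
#'   `y_observed` and `y_predicted`.
#' @return the correlation in `[-1, 1]`.
#' @export
pearsonAccuracy <- function(p) {
  r <- if (methods::is(p, "PredictionSet")) p@records else p
  ok <- stats::complete.cases(r$y_observed, r$y_predicted)
  x <- r$y_observed[ok]; y <- r$y_predicted[ok]
  if (length(x) < 3L) stop("need at least 3 paired records")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in observed or predicted")
  stats::cor(x, y)
}

#' Coincidence Index of the top fraction
#'
#' CI = (B - R) / (T - R), where T = ceiling(top_frac * N) genotypes
#' are selected from each ranking (largest values first), B is the
#' overlap between the top-observed and top-predicted sets, and
#' R = top_frac * T is the overlap expected by chance. Ties are broken
#' by a stable sort on the id, so the index is deterministic.
#'
#' @param observed,predicted paired numeric vectors.
#' @param top_frac selected fraction in (0, 1) (default 0.20).
#' @param ids optional ids used for overlap and tie-breaking
#'   (defaults to positions).
#' @return the Coincidence Index (1 = identical top sets, 0 = chance).
#' @export
coincidenceIndex <- function(observed, predicted, top_frac = 0.20,
                             ids = NULL) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (top_frac <= 0 || top_frac >= 1) stop("top_frac must be in (0, 1)")
  n <- length(observed)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  T_sel <- ceiling(top_frac * n)
  R_exp <- top_frac * T_sel
  if (abs(T_sel - R_exp) < 1e-12)
    stop("degenerate Coincidence Index: T equals the chance expectation")
  top_obs <- ids[order(-observed, ids)][seq_len(T_sel)]
  top_pred <- ids[order(-predicted, ids)][seq_len(T_sel)]
  B <- length(intersect(top_obs, top_pred))
  (B - R_exp) / (T_sel - R_exp)
}

#' Mean proportion of overlapping testers between training and
#' validation populations
#'
#' For every fold-by-repetition cell of the plan, computes the Jaccard
#' index |W intersect Z| / |W union Z| of the tester sets of the
#' training (W) and validation (Z) hybrids, and averages over all
#' cells.
#'
#' @param plan a [CVPlan-class].
#' @param tester_of named character vector mapping hybrid to tester
#'   (see [testerMap()]).
#' @return the mean overlap proportion in `[0, 1]`.
#' @export
testerOverlap <- function(plan, tester_of) {
  a <- assignments(plan)
  unmapped <- setdiff(unique(a$Hybrid), names(tester_of))
  if (length(unmapped))
    stop("unmapped hybrid(s): ", paste(utils::head(unmapped, 5),
                                       collapse = ", "))
  cells <- split(a, list(a$Rep, a$Fold), drop = TRUE)
  jac <- vapply(cells, function(cell) {
    W <- unique(tester_of[cell$Hybrid[cell$Set == "train"]])
    Z <- unique(tester_of[cell$Hybrid[cell$Set == "valid"]])
    length(intersect(W, Z)) / length(union(W, Z))
  }, 0)
  mean(jac)
}

#' Compare two overlapping dependent correlations (Meng-Rosenthal-Rubin)
#'
#' Tests whether two correlations r1 = cor(y, p1) and r2 = cor(y, p2)
#' that share the variable y (and the same n samples) differ, given
#' the intercorrelation r12 = cor(p1, p2), via Fisher transforms:
#'
#' z = (z1 - z2) * sqrt((n - 3) / (2 (1 - r12) h)),
#' h = (1 - f rbar2) / (1 - rbar2),
#' f = min(1, (1 - r12) / (2 (1 - rbar2))),
#' rbar2 = (r1^2 + r2^2) / 2.
#'
#' The caller applies a Bonferroni correction across the family of
#' model-pair comparisons (see [compareModels()]).
#'
#' @param r1,r2 the two correlations sharing one variable.
#' @param r12 correlation between the two prediction vectors.
#' @param n sample size (>= 4).
#' @return list with `z` and the two-sided `p`.
#' @export
mengTest <- function(r1, r2, r12, n) {
  for (r in c(r1, r2, r12))
    if (abs(r) >= 1)
      stop("Fisher transform overflow: correlations must be inside (-1, 1)")
  if (n < 4) stop("n must be >= 4")
  z1 <- atanh(r1); z2 <- atanh(r2)
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min(1, (1 - r12) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Pairwise accuracy comparisons between models
#'
#' Pools each model's validation predictions (over all folds and
#' repetitions) onto the shared observed BLUEs, computes each pair's
#' dependent-correlation test ([mengTest()]) and applies a Bonferroni
#' correction across the family of pairs.
#'
#' @param predsets named list (one entry per model) of lists of
#'   [PredictionSet-class] objects.
#' @return `data.frame` with columns `model1`, `model2`, `r1`, `r2`,
#'   `r12`, `n`, `meng_z`, `p_raw`, `p_bonferroni`.
#' @export
compareModels <- function(predsets) {
  pooled <- lapply(predsets, function(ps) {
    do.call(rbind, lapply(ps, function(p) {
      r <- predictions(p)
      data.frame(key = paste(r$Env, r$Hybrid, p@rep, p@fold, sep = "\r"),
                 obs = r$y_observed, pred = r$y_predicted,
                 stringsAsFactors = FALSE)
    }))
  })
  models <- names(pooled)
  if (length(models) < 2L) stop("need at least two models to compare")
  pairs <- utils::combn(models, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- pooled[[pr[1]]]; b <- pooled[[pr[2]]]
    m <- merge(a, b, by = "key", suffixes = c("1", "2"))
    r1 <- stats::cor(m$obs1, m$pred1)
    r2 <- stats::cor(m$obs1, m$pred2)
    r12 <- stats::cor(m$pred1, m$pred2)
    mt <- mengTest(r1, r2, r12, nrow(m))
    data.frame(model1 = pr[1], model2 = pr[2], r1 = r1, r2 = r2,
               r12 = r12, n = nrow(m), meng_z = mt$z, p_raw = mt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- stats::p.adjust(out$p_raw, method = "bonferroni")
  out
}

#' Per-cell accuracy metrics of a set of predictions
#'
#' @param predsets list of [PredictionSet-class] objects (one per CV
#'   cell).
#' @param top_frac top fraction for the Coincidence Index.
#' @return `data.frame` with one row per cell: model, scheme, rep,
#'   fold, `pearson_r`, `coincidence_index`.
#' @export
metricTable <- function(predsets, top_frac = 0.20) {
  out <- do.call(rbind, lapply(predsets, function(p) {
    r <- predictions(p)
    data.frame(model = p@modelKind, scheme = p@scheme, rep = p@rep,
               fold = p@fold,
               pearson_r = pearsonAccuracy(p),
               coincidence_index = coincidenceIndex(
                 r$y_observed, r$y_predicted, top_frac,
                 ids = paste(r$Env, r$Hybrid, sep = "\r")),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
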