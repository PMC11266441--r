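# Stage 1: per-environment mixed models -> hybrid BLUEs + diagnostics.
#
# Fixed-hybrid fit:   yield ~ Hybrid + Replicate + (1|Block:Rep) +
#                     (1|Row) + (1|Col), REML via lme4.
# Random-hybrid refit (same terms, Hybrid random) supplies the genetic
# variance and the mean pairwise prediction error variance V-bar(Delta)
# used by the Cullis generalized heritability. The full PEV matrix of
# the hybrid BLUPs is recovered from the mixed-model equations at the
# REML variance estimates.

#' Fit the single-trial model for one environment
#'
#' @param plots plot-table rows for one environment (columns `Env`,
#'   `Hybrid`, `Replicate`, `Block`, `Row`, `Col`, `Yield_Mg_ha`).
#' @param force_zero_variance if `TRUE`, all random variances are fixed
#'   at zero, so the fit collapses to ordinary least squares on the
#'   fixed effects (the zero-variance limit of the mixed model).
#' @param max_iter optimizer evaluation budget for the REML fit;
#'   exceeding it flags the result as non-converged instead of erroring.
#' @return a [SingleTrialFit-class].
#' @details Hybrids with no non-missing plot are dropped with a
#'   warning. Random terms whose grouping factor has fewer than two
#'   levels, or one level per observation (confounded with the
#'   residual), are omitted. A singular fixed-effect design (hybrid
#'   aliased with replicate) raises an estimability error naming the
#'   aliased coefficients.
#' @examples
#' cfg <- simConfig(n_parents = 10, n_markers = 40,
#'                  n_environments_per_year = 1, years = 2020,
#'                  coverage = 1, seed = 3)
#' study <- simulateStudy(cfg)
#' pt <- plotTable(study)
#' fit <- fitSingleTrial(pt[pt$Env == pt$Env[1], ])
#' head(blues(fit))
#' @export
fitSingleTrial <- function(plots, force_zero_variance = FALSE,
                           max_iter = 200) {
  assertColumns(plots, c("Env", "Hybrid", "Replicate", "Block", "Row",
                         "Col", "Yield_Mg_ha"), "plot table")
  env <- unique(plots$Env)
  if (length(env) != 1L)
    stop("fitSingleTrial() expects plots from exactly one environment")

  keep <- !is.na(plots$Yield_Mg_ha)
  dropped <- setdiff(unique(plots$Hybrid), unique(plots$Hybrid[keep]))
  if (length(dropped))
    warning(sprintf("[%s] dropping hybrid(s) with no non-missing plot: %s",
                    env, paste(dropped, collapse = ", ")))
  df <- plots[keep, , drop = FALSE]
  if (length(unique(df$Hybrid)) < 2L)
    stop("need at least 2 hybrids with data to fit a trial model")

  ## canonical plot order: estimates are then exactly invariant to the
  ## order in which plots arrive
  df <- df[order(df$Replicate, df$Block, df$Row, df$Col, df$Hybrid), ,
           drop = FALSE]
  df$Hybrid <- factor(df$Hybrid)
  df$Replicate <- factor(df$Replicate)
  df$RepBlock <- factor(paste(df$Replicate, df$Block, sep = ":"))
  df$Row <- factor(df$Row)
  df$Col <- factor(df$Col)
  df$y <- df$Yield_Mg_ha

  ## estimability of the fixed part
  fixed_rhs <- if (nlevels(df$Replicate) > 1L) "Hybrid + Replicate"
               else "Hybrid"
  X <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs)), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("estimability error: aliased fixed-effect term(s): ",
         paste(aliased, collapse = ", "))
  }

  usable <- function(f) nlevels(f) >= 2L && nlevels(f) < nrow(df)
  re_terms <- c(RepBlock = usable(df$RepBlock), Row = usable(df$Row),
                Col = usable(df$Col))
  re_names <- names(re_terms)[re_terms]
  if (force_zero_variance) re_names <- character()

  vc <- c(block = 0, row = 0, col = 0, resid = 0)
  converged <- TRUE
  n_iter <- 0L

  if (length(re_names)) {
    form <- stats::as.formula(paste(
      "y ~", fixed_rhs, "+",
      paste(sprintf("(1 | %s)", re_names), collapse = " + ")))
    conv_warn <- FALSE
    fit <- withCallingHandlers(
      lme4::lmer(form, data = df, REML = TRUE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.conv.singular = "ignore",
                   optCtrl = list(maxfun = max_iter * 10,
                                  xtol_abs = 1e-10, ftol_abs = 1e-10))),
      warning = function(w) {
        conv_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    converged <- !conv_warn && (fit@optinfo$conv$opt == 0)
    n_iter <- as.integer(fit@optinfo$feval %||% 0L)
    vcs <- as.data.frame(lme4::VarCorr(fit))
    getv <- function(g) {
      v <- vcs$vcov[vcs$grp == g]
      if (length(v)) v else 0
    }
    vc <- c(block = getv("RepBlock"), row = getv("Row"),
            col = getv("Col"), resid = stats::sigma(fit)^2)
    beta <- lme4::fixef(fit)
    fitted_vals <- stats::fitted(fit)
  } else {
    fit <- stats::lm(stats::as.formula(paste("y ~", fixed_rhs)), data = df)
    s2 <- summary(fit)$sigma^2
    vc["resid"] <- if (is.finite(s2)) s2 else 0   # saturated fit: no df left
    beta <- stats::coef(fit)
    fitted_vals <- stats::fitted(fit)
  }

  ## BLUEs on the data scale: fixed-effect prediction per hybrid,
  ## averaged over replicate levels
  grid <- expand.grid(Hybrid = levels(df$Hybrid),
                      Replicate = levels(df$Replicate),
                      KEEP.OUT.ATTRS = FALSE)
  Xg <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs)), grid)
  pred <- as.vector(Xg %*% beta[colnames(Xg)])
  blue <- tapply(pred, grid$Hybrid, mean)
  blue <- stats::setNames(as.numeric(blue), names(blue))

  ## companion random-hybrid refit for sigma2_g and V-bar(Delta)
  sigma_g <- 0
  pev <- 0
  if (!force_zero_variance) {
    rnd <- tryCatch(
      randomHybridRefit(df, fixed_rhs, re_names, max_iter),
      error = function(e) NULL)
    if (!is.null(rnd)) {
      sigma_g <- rnd$sigma_g
      pev <- rnd$pev
    }
  }

  methods::new("SingleTrialFit",
               env = env, blues = blue,
               mu = unname(beta[1]),
               varComponents = vc,
               sigmaG = sigma_g, pev = pev,
               meanFitted = mean(fitted_vals),
               converged = converged, nIter = n_iter,
               dropped = as.character(dropped))
}

#' Random-hybrid refit + full PEV matrix from the mixed-model equations.
#' @noRd
randomHybridRefit <- function(df, fixed_rhs, re_names, max_iter) {
  fixed_part <- if (grepl("Replicate", fixed_rhs)) "Replicate" else "1"
  form <- stats::as.formula(paste(
    "y ~", fixed_part, "+ (1 | Hybrid)",
    if (length(re_names))
      paste("+", paste(sprintf("(1 | %s)", re_names), collapse = " + "))
    else ""))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(
                 calc.derivs = FALSE, check.conv.singular = "ignore",
                 optCtrl = list(maxfun = max_iter * 10,
                                xtol_abs = 1e-10, ftol_abs = 1e-10)))))
  vcs <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vcs$vcov[vcs$grp == g]
    if (length(v)) v else 0
  }
  sigma_g <- getv("Hybrid")
  sigma_e <- stats::sigma(fit)^2
  if (sigma_g < 1e-10) return(list(sigma_g = 0, pev = 0))

  comp <- c(Hybrid = sigma_g,
            stats::setNames(vapply(re_names, getv, 0), re_names))
  comp <- comp[comp > 1e-10]

  X <- stats::model.matrix(stats::as.formula(paste("~", fixed_part)), df)
  Zs <- lapply(names(comp), function(g)
    stats::model.matrix(~ 0 + df[[g]]))
  q_sizes <- vapply(Zs, ncol, 0L)
  Z <- do.call(cbind, Zs)
  lambda <- rep(sigma_e / comp, times = q_sizes)

  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lambda)))
  Cinv <- tryCatch(solve(C), error = function(e)
    solve(C + diag(1e-8, nrow(C))))
  idx <- ncol(X) + seq_len(q_sizes[1])    # hybrid block comes first
  P <- sigma_e * Cinv[idx, idx, drop = FALSE]

  t_h <- nrow(P)
  if (t_h < 2L) return(list(sigma_g = sigma_g, pev = 0))
  trP <- sum(diag(P))
  pev <- ((t_h - 1) * trP - (sum(P) - trP)) / (t_h * (t_h - 1) / 2)
  list(sigma_g = sigma_g, pev = max(0, pev))
}

#' Coefficient of variation of a single-trial fit
#'
#' 100 x sqrt(residual variance) / mean predicted value, in percent.
#'
#' @param fit a [SingleTrialFit-class].
#' @return the CV in percent.
#' @export
coefficientOfVariation <- function(fit) {
  stopifnot(methods::is(fit, "SingleTrialFit"))
  mu <- fit@meanFitted
  if (!is.finite(mu) || abs(mu) < 1e-12)
    stop("undefined CV: mean of predicted values is zero")
  100 * sqrt(fit@varComponents["resid"]) / mu
}

#' Cullis generalized heritability
#'
#' H2 = 1 - V-bar(Delta) / (2 sigma2_g), computed from the
#' random-hybrid refit's genetic variance and mean pairwise prediction
#' error variance, clamped to `[0, 1]` (with a warning if clamping was
#' needed). A zero genetic variance yields 0 with a `degenerate`
#' attribute.
#'
#' @param fit a [SingleTrialFit-class].
#' @return heritability in `[0, 1]`.
#' @export
cullisHeritability <- function(fit) {
  stopifnot(methods::is(fit, "SingleTrialFit"))
  if (fit@sigmaG <= 1e-10)
    return(structure(0, degenerate = TRUE))
  h2 <- 1 - fit@pev / (2 * fit@sigmaG)
  if (h2 < 0 || h2 > 1) {
    warning(sprintf("H2 (%.3f) outside [0, 1]; clamped", h2))
    h2 <- min(1, max(0, h2))
  }
  unname(h2)
}

#' Fit single-trial models for every environment of a study
#'
#' @param plot_table a full plot table (multiple environments).
#' @param ... passed to [fitSingleTrial()].
#' @return list with `fits` (named list of [SingleTrialFit-class]),
#'   `blues` (the phenotypic matrix: `Env`, `Hybrid`, `y`) and
#'   `diagnostics` (per-trial CV%, Cullis H2, variance components,
#'   convergence).
#' @export
fitTrials <- function(plot_table, ...) {
  envs <- unique(plot_table$Env)
  fits <- lapply(envs, function(e)
    fitSingleTrial(plot_table[plot_table$Env == e, , drop = FALSE], ...))
  names(fits) <- envs
  blues_df <- do.call(rbind, lapply(fits, function(f)
    data.frame(Env = f@env, Hybrid = names(f@blues), y = unname(f@blues),
               stringsAsFactors = FALSE)))
  rownames(blues_df) <- NULL
  diagnostics <- do.call(rbind, lapply(fits, function(f) {
    vc <- f@varComponents
    data.frame(Env = f@env, n_hybrids = length(f@blues),
               CV_pct = as.numeric(tryCatch(coefficientOfVariation(f),
                                            error = function(e) NA_real_)),
               H2_Cullis = as.numeric(cullisHeritability(f)),
               var_block = vc[["block"]], var_row = vc[["row"]],
               var_col = vc[["col"]], var_resid = vc[["resid"]],
               sigma2_g = f@sigmaG, pev = f@pev,
               converged = f@converged, stringsAsFactors = FALSE)
  }))
  rownames(diagnostics) <- NULL
  list(fits = fits, blues = blues_df, diagnostics = diagnostics)
}
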