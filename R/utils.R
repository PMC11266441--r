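# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' Keeps independent stages (population, trials, layers, CV reps) on
#' separate, reproducible random streams. Result stays below 2^31 - 1.
#' @noRd
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483587L)
}

#' Environment id helpers: an environment is "<Location>_<Year>" and the
#' field location is the environment name without the year.
#' @noRd
envYear <- function(env) {
  as.integer(sub("^.*_", "", env))
}

#' @noRd
fieldLocation <- function(env) {
  sub("_[0-9]+$", "", env)
}

#' @noRd
comboKey <- function(env, hybrid) paste(env, hybrid, sep = "\r")

#' Center and rescale a vector (or matrix) so its sample variance equals
#' `v` exactly; degenerate inputs (length < 2 or zero spread) map to zeros.
#' @noRd
scaleToVar <- function(x, v) {
  if (v <= 0) {
    x[] <- 0
    return(x)
  }
  xc <- x - mean(x)
  s <- stats::sd(as.vector(xc))
  if (!is.finite(s) || s == 0) {
    x[] <- 0
    return(x)
  }
  xc / s * sqrt(v)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable partition of n shuffled items into k near-equal folds
#' (sizes differ by at most one).
#' @noRd
foldSizes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' @noRd
assertColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
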