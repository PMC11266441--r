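# Stage 2: engineered environmental features -> the environmental matrix.
#
# Default schema (90 features): 63 weather aggregates, 15 EC-SVD
# scores, 6 lagged-yield statistics, 3 soil assays, 2 binned
# coordinates, 1 management flag.

weatherVariables <- c("Rainfall_mm", "Solar_Radiation_Wm2",
                      "Humidity_pct", "Temp_C")
weatherStats <- c("mean", "max", "min", "sd")

#' Default season windows for weather aggregation
#'
#' The whole trial window plus its intersections with the
#' meteorological seasons (spring: Mar-May, summer: Jun-Aug, autumn:
#' Sep-Nov). Windows are derived from the series' own timestamp range.
#' @noRd
defaultSeasonWindows <- function(ts) {
  mo <- as.integer(strftime(ts, "%m", tz = "UTC"))
  list(season = rep(TRUE, length(ts)),
       spring = mo %in% 3:5,
       summer = mo %in% 6:8,
       autumn = mo %in% 9:11)
}

## One whole-season feature is dropped from the 4 x 4 x 4 grid: the
## minimum 30-minute rainfall over the full season is identically zero
## and carries no information.
droppedWeatherFeature <- "Rainfall_mm_season_min"

#' Names of the 63 default weather features
#' @return character vector of feature names
#'   (`<variable>_<window>_<statistic>`).
#' @export
weatherFeatureNames <- function() {
  nm <- as.vector(t(outer(weatherVariables, c("season", "spring",
                                              "summer", "autumn"),
                          paste, sep = "_")))
  nm <- as.vector(outer(weatherStats, nm, function(s, n)
    paste(n, s, sep = "_")))
  sort(setdiff(nm, droppedWeatherFeature))
}

#' Aggregate a 30-minute weather series into seasonal features
#'
#' For each weather variable, season window and summary statistic
#' (mean, max, min, sd) computes the statistic over the window's
#' 30-minute records. Under the default recipe this yields exactly 63
#' named features. A window with zero records produces missing
#' features with a warning.
#'
#' @param series weather records for one environment, with a
#'   `Timestamp` column and the four variable columns; timestamps must
#'   be strictly increasing.
#' @param season_windows optional named list of logical index vectors
#'   over the series rows; defaults to the whole season plus its
#'   meteorological-season intersections.
#' @return named numeric vector of features.
#' @examples
#' cfg <- simConfig(n_parents = 2, n_markers = 10,
#'                  n_environments_per_year = 1, years = 2020, seed = 5)
#' lay <- generateEnvironmentLayers(cfg)
#' feats <- aggregateWeather(lay$weather)
#' length(feats)
#' @export
aggregateWeather <- function(series, season_windows = NULL) {
  assertColumns(series, c("Timestamp", weatherVariables), "weather series")
  if (nrow(series) == 0L) stop("weather series is empty")
  ts <- series$Timestamp
  if (is.unsorted(as.numeric(ts), strictly = TRUE))
    stop("weather timestamps must be strictly increasing")
  if (is.null(season_windows)) season_windows <- defaultSeasonWindows(ts)

  empty <- names(season_windows)[!vapply(season_windows, any, TRUE)]
  for (w in empty)
    warning(sprintf("window '%s' has zero records; its features are set missing",
                    w))

  out <- c()
  for (v in weatherVariables) {
    for (w in names(season_windows)) {
      x <- series[[v]][season_windows[[w]]]
      for (s in weatherStats) {
        nm <- paste(v, w, s, sep = "_")
        if (nm %in% droppedWeatherFeature) next
        out[nm] <- if (length(x) == 0L) NA_real_
                   else switch(s, mean = mean(x), max = max(x),
                               min = min(x), sd = stats::sd(x))
      }
    }
  }
  out[sort(names(out))]
}

#' Lagged historical-yield features for one environment
#'
#' Six summary statistics (mean, min, p25, p50, p75, max) of the
#' previous year's plot yields at the environment's field location.
#' An environment whose location has no prior-year data gets six
#' missing features (with a message).
#'
#' @param history `data.frame` with columns `Location`, `Year`,
#'   `Yield_Mg_ha`.
#' @param location the environment's field location.
#' @param year the environment's year (features use `year - 1`).
#' @return named numeric vector of six features.
#' @export
laggedYieldFeatures <- function(history, location, year) {
  assertColumns(history, c("Location", "Year", "Yield_Mg_ha"), "history")
  nms <- paste0("LagYield_", c("mean", "min", "p25", "p50", "p75", "max"))
  y <- history$Yield_Mg_ha[history$Location == location &
                             history$Year == year - 1]
  y <- y[!is.na(y)]
  if (length(y) == 0L) {
    message(sprintf("no prior-year yield for %s in %d; lagged features missing",
                    location, year - 1L))
    return(stats::setNames(rep(NA_real_, 6L), nms))
  }
  qs <- stats::quantile(y, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  stats::setNames(c(mean(y), min(y), qs, max(y)), nms)
}

#' Bin a coordinate to a floor grid
#'
#' x' = floor(x / s) * s with the true floor (toward minus infinity),
#' so nearby trials collapse onto one grid value. Defaults used for
#' the environmental matrix are s = 1.2 for latitude and s = 3.6 for
#' longitude.
#'
#' @param x coordinate(s) in degrees.
#' @param s step parameter controlling the binning range (> 0).
#' @return binned coordinate(s).
#' @examples
#' binCoordinate(c(39.785, 39.824, 39.927), 1.2)  # all 39.6
#' @export
binCoordinate <- function(x, s) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("invalid step: s must be a positive number")
  q <- x / s
  ## snap quotients a few ulps away from an integer before flooring, so
  ## binning already-binned values is exactly idempotent
  qr <- round(q)
  q <- ifelse(abs(q - qr) < 1e-9, qr, floor(q))
  q * s
}

#' Reduce the crop-model covariates by truncated SVD
#'
#' Uncentered truncated singular value decomposition of the
#' environments x ECs matrix, keeping `k` components (the default 15
#' captures essentially all variance of a low-rank EC layer). Column
#' centering can be toggled. Missing cells must be imputed first.
#'
#' @param ecs numeric matrix, environments x covariates, with Env
#'   rownames.
#' @param k number of components to keep.
#' @param center center columns before the SVD (default `FALSE`).
#' @return list with `scores` (environments x k, columns
#'   `EC_SVD_1..k`) and `explained` (per-component explained-variance
#'   ratios, summing to at most 1).
#' @export
reduceECs <- function(ecs, k = 15, center = FALSE) {
  ecs <- as.matrix(ecs)
  if (anyNA(ecs))
    stop("imputation required: EC matrix has missing cells")
  if (k > min(dim(ecs)))
    stop(sprintf("k = %d exceeds min(n_env, n_ec) = %d", k, min(dim(ecs))))
  X <- if (center) sweep(ecs, 2, colMeans(ecs)) else ecs
  sv <- svd(X)
  sgn <- svdSignConvention(sv$v[, seq_len(k), drop = FALSE])
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k) * rep(sgn, each = nrow(X))
  dimnames(scores) <- list(rownames(ecs), paste0("EC_SVD_", seq_len(k)))
  list(scores = scores, explained = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

#' Column-wise sign convention: make the largest-magnitude loading of
#' each component positive (removes SVD sign ambiguity).
#' @noRd
svdSignConvention <- function(V) {
  apply(V, 2, function(v) {
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  })
}

#' Assemble the environmental matrix from its six feature categories
#'
#' Column-wise concatenation of the per-environment feature blocks,
#' with a manifest recording each feature's category, units and
#' recipe. All blocks must cover exactly the same environments; a key
#' mismatch raises an error listing the offending environments. Under
#' the default schema the result has 90 features
#' (63 + 15 + 6 + 3 + 2 + 1).
#'
#' @param weather_feats environments x weather-feature matrix.
#' @param ec_scores environments x EC-SVD score matrix.
#' @param lagged_feats environments x lagged-yield feature matrix.
#' @param soil `data.frame` with `Env`, `Nitrate_ppm`,
#'   `Nitrogen_lb_ac`, `Calcium_pct`.
#' @param binned_coords environments x 2 matrix of binned latitude and
#'   longitude (columns `Lat_bin`, `Lon_bin`).
#' @param management `data.frame` with `Env`, `Irrigated`.
#' @return an [EnvironmentalMatrix-class].
#' @export
assembleEnvironmentalMatrix <- function(weather_feats, ec_scores,
                                        lagged_feats, soil,
                                        binned_coords, management) {
  soil_m <- as.matrix(soil[, c("Nitrate_ppm", "Nitrogen_lb_ac",
                               "Calcium_pct")])
  rownames(soil_m) <- soil$Env
  mgmt_m <- matrix(management$Irrigated,
                   dimnames = list(management$Env, "Irrigated"))

  blocks <- list(weather = as.matrix(weather_feats),
                 ec_svd = as.matrix(ec_scores),
                 lagged_yield = as.matrix(lagged_feats),
                 soil = soil_m,
                 coordinates = as.matrix(binned_coords),
                 management = mgmt_m)
  keys <- lapply(blocks, rownames)
  all_envs <- sort(unique(unlist(keys)))
  bad <- lapply(keys, function(k) setdiff(all_envs, k))
  offenders <- bad[vapply(bad, length, 0L) > 0L]
  if (length(offenders)) {
    stop("key mismatch between feature sources: ",
         paste(sprintf("%s missing [%s]", names(offenders),
                       vapply(offenders, paste, "", collapse = ", ")),
               collapse = "; "))
  }

  features <- do.call(cbind, lapply(blocks, function(b)
    b[all_envs, , drop = FALSE]))
  colnames(features) <- unlist(lapply(blocks, colnames), use.names = FALSE)

  units <- c(weather = "mixed (mm, W/m2, %, degC)", ec_svd = "score",
             lagged_yield = "Mg/ha", soil = "mixed (ppm, lb/ac, %)",
             coordinates = "degrees", management = "flag")
  recipe <- c(weather = "stat over 30-min records in season window",
              ec_svd = "uncentered truncated SVD of 765 ECs",
              lagged_yield = "summary of previous-year location yield",
              soil = "assay value",
              coordinates = "floor(x/s)*s, s = 1.2 lat / 3.6 lon",
              management = "irrigation flag")
  man <- do.call(rbind, lapply(names(blocks), function(cat)
    data.frame(name = colnames(blocks[[cat]]), category = cat,
               units = units[[cat]], recipe = recipe[[cat]],
               stringsAsFactors = FALSE)))
  rownames(man) <- NULL
  methods::new("EnvironmentalMatrix", features = features, manifest = man)
}

#' Build the environmental matrix of a synthetic study
#'
#' Orchestrates the full stage-2 recipe on a [SyntheticStudy-class]:
#' weather aggregation per environment, EC SVD reduction, lagged-yield
#' statistics, soil assays, coordinate binning and the management
#' flag. With the defaults this yields the 90-feature schema.
#'
#' @param study a [SyntheticStudy-class].
#' @param k_ec number of EC SVD components (default 15).
#' @param s_lat,s_lon binning steps for latitude and longitude.
#' @param season_windows optional window list passed to
#'   [aggregateWeather()].
#' @return an [EnvironmentalMatrix-class].
#' @export
buildEnvironmentalMatrix <- function(study, k_ec = 15, s_lat = 1.2,
                                     s_lon = 3.6, season_windows = NULL) {
  stopifnot(methods::is(study, "SyntheticStudy"))
  envs <- sort(unique(study@plotTable$Env))

  wf <- do.call(rbind, lapply(envs, function(e) {
    aggregateWeather(study@weather[study@weather$Env == e, , drop = FALSE],
                     season_windows)
  }))
  rownames(wf) <- envs

  ec <- reduceECs(study@ecs[envs, , drop = FALSE], k = k_ec)

  lf <- t(vapply(envs, function(e)
    suppressMessages(laggedYieldFeatures(study@history, fieldLocation(e),
                                         envYear(e))),
    numeric(6)))
  rownames(lf) <- envs

  co <- study@coords[match(envs, study@coords$Env), ]
  bc <- cbind(Lat_bin = binCoordinate(co$Latitude, s_lat),
              Lon_bin = binCoordinate(co$Longitude, s_lon))
  rownames(bc) <- envs

  soil <- study@soil[match(envs, study@soil$Env), ]
  mgmt <- study@management[match(envs, study@management$Env), ]

  assembleEnvironmentalMatrix(wf, ec$scores, lf, soil, bc, mgmt)
}
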