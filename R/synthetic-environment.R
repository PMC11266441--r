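# Synthetic environmental layers: weather, soil, crop-model
# covariates, coordinates, management and historical yield.

#' Generate the environmental layers of a synthetic study
#'
#' Produces, for every environment implied by the configuration:
#'
#' * a 30-minute weather series (rainfall, solar radiation, humidity,
#'   air temperature) over the configured planting-to-harvest window,
#'   with a seasonal + diurnal structure and an environment-level
#'   temperature shift driven by the latent environmental index;
#' * a soil assay table (nitrate ppm, nitrogen lb/acre, calcium %);
#' * a 765-column crop-model covariate (EC) matrix built as a low-rank
#'   signal (first factor = the latent index) plus small noise, so a
#'   15-component SVD captures essentially all its variance;
#' * latitude/longitude jittered around a few regional centers (so
#'   coordinate binning collapses nearby trials);
#' * a per-environment management (irrigation) flag;
#' * a location-year historical yield table for lagged features.
#'
#' @param cfg a [simConfig()] object.
#' @param plot_table optional plot table (from [generateTrials()]);
#'   when given, the history table holds its actual plot yields, so
#'   lagged features summarize the study's own previous-year yields.
#'   Otherwise plausible yields are synthesized.
#' @param ec_rank rank of the EC signal (must be <= 15 for the default
#'   SVD truncation to be near-lossless).
#' @param ec_noise_sd relative noise added on top of the EC signal.
#' @return list with `weather`, `soil`, `ecs`, `coords`, `management`,
#'   `history`.
#' @export
generateEnvironmentLayers <- function(cfg, plot_table = NULL,
                                      ec_rank = 12, ec_noise_sd = 0.01) {
  if (!inherits(cfg, "SimConfig")) stop("cfg must come from simConfig()")
  set.seed(deriveSeed(cfg$seed, "layers"))
  et <- envTable(cfg)
  z <- envIndex(cfg)
  n_env <- nrow(et)

  ## --- coordinates: regional centers + jitter, fixed per location ---
  centers <- data.frame(lat = stats::runif(cfg$n_regions, 36, 45),
                        lon = stats::runif(cfg$n_regions, -102, -80))
  locs <- unique(et$Location)
  region <- rep_len(seq_len(cfg$n_regions), length(locs))
  loc_lat <- centers$lat[region] +
    stats::runif(length(locs), -cfg$coord_jitter[1], cfg$coord_jitter[1])
  loc_lon <- centers$lon[region] +
    stats::runif(length(locs), -cfg$coord_jitter[2], cfg$coord_jitter[2])
  names(loc_lat) <- names(loc_lon) <- locs
  coords <- data.frame(Env = et$Env, Location = et$Location,
                       Latitude = loc_lat[et$Location],
                       Longitude = loc_lon[et$Location],
                       stringsAsFactors = FALSE, row.names = NULL)

  ## --- management: irrigation flag, fixed per location ---
  irr <- stats::setNames(stats::rbinom(length(locs), 1L, 0.2), locs)
  management <- data.frame(Env = et$Env, Irrigated = irr[et$Location],
                           stringsAsFactors = FALSE, row.names = NULL)

  ## --- weather: 30-min series per environment ---
  weather <- do.call(rbind, lapply(seq_len(n_env), function(i) {
    simulateWeatherSeries(et$Env[i], et$Year[i], cfg$season, z[i],
                          loc_lat[et$Location[i]])
  }))
  if (cfg$missing_weather_frac > 0) {
    keep <- stats::runif(nrow(weather)) >= cfg$missing_weather_frac
    weather <- weather[keep, , drop = FALSE]
  }
  rownames(weather) <- NULL

  ## --- soil assays ---
  soil <- data.frame(
    Env = et$Env,
    Nitrate_ppm = 20 + 4 * z + stats::rnorm(n_env, 0, 2),
    Nitrogen_lb_ac = 80 + 10 * z + stats::rnorm(n_env, 0, 5),
    Calcium_pct = pmax(0.2, 1.5 + stats::rnorm(n_env, 0, 0.3)),
    stringsAsFactors = FALSE, row.names = NULL)

  ## --- ECs: mean structure + low-rank signal + small noise ---
  r <- min(ec_rank, n_env, 765L)
  base_mean <- stats::rnorm(765, 5, 1)
  U <- cbind(z, matrix(stats::rnorm(n_env * (r - 1)), n_env))[, seq_len(r),
                                                             drop = FALSE]
  V <- matrix(stats::rnorm(765 * r), ncol = r)
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  d <- seq(8, 1, length.out = r)
  ecs <- outer(rep(1, n_env), base_mean) + U %*% (t(V) * d) +
    matrix(stats::rnorm(n_env * 765, 0, ec_noise_sd), n_env)
  dimnames(ecs) <- list(et$Env, sprintf("EC_%03d", seq_len(765)))

  ## --- history: location-year plot yields ---
  if (!is.null(plot_table)) {
    history <- data.frame(Location = fieldLocation(plot_table$Env),
                          Year = envYear(plot_table$Env),
                          Yield_Mg_ha = plot_table$Yield_Mg_ha,
                          stringsAsFactors = FALSE, row.names = NULL)
    history <- history[!is.na(history$Yield_Mg_ha), , drop = FALSE]
  } else {
    history <- do.call(rbind, lapply(seq_len(n_env), function(i) {
      data.frame(Location = et$Location[i], Year = et$Year[i],
                 Yield_Mg_ha = stats::rnorm(40, cfg$intercept + z[i], 1),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(history) <- NULL

  list(weather = weather, soil = soil, ecs = ecs, coords = coords,
       management = management, history = history)
}

#' One environment's 30-minute weather series over the season window.
#' @noRd
simulateWeatherSeries <- function(env, year, season, z_env, lat) {
  start <- as.POSIXct(paste0(year, "-", season[1], " 00:00:00"), tz = "UTC")
  end <- as.POSIXct(paste0(year, "-", season[2], " 23:30:00"), tz = "UTC")
  ts <- seq(start, end, by = "30 min")
  doy <- as.integer(strftime(ts, "%j", tz = "UTC"))
  hod <- as.integer(strftime(ts, "%H", tz = "UTC")) +
    as.integer(strftime(ts, "%M", tz = "UTC")) / 60

  seasonal <- 18 + 8 * sin(pi * (doy - 110) / 160)   # peaks mid-July
  diurnal <- 5 * sin(pi * (hod - 7) / 12)
  temp <- seasonal + diurnal + 2 * z_env + 0.3 * (40 - lat) +
    stats::rnorm(length(ts), 0, 1.5)

  humidity <- pmin(100, pmax(15, 72 - 0.8 * (temp - 20) +
                               stats::rnorm(length(ts), 0, 6)))
  solar <- pmax(0, 850 * sin(pi * (hod - 6) / 14)) *
    (hod >= 6 & hod <= 20) * (1 + 0.05 * z_env) +
    stats::rnorm(length(ts), 0, 10)
  solar <- pmax(0, solar)
  rain_event <- stats::rbinom(length(ts), 1L, 0.02)
  rainfall <- rain_event * stats::rexp(length(ts), rate = 1 / 2)

  data.frame(Env = env, Timestamp = ts,
             Rainfall_mm = rainfall,
             Solar_Radiation_Wm2 = solar,
             Humidity_pct = humidity,
             Temp_C = temp,
             stringsAsFactors = FALSE)
}
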