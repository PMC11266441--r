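# Synthetic plot-level trials with known ground-truth effect values.

#' Generate plot-level trials and ground-truth effects
#'
#' Lays out a modified RCBD per environment (replicates split into
#' incomplete blocks of field rows) and simulates plot yields as
#'
#' yield = intercept + additive + dominance + environment + GxE
#'         + block(rep) + row + col + residual   (Mg/ha)
#'
#' Additive and dominance values come from i.i.d. normal marker
#' effects, rescaled so the realized hybrid-level sample variances hit
#' the configured `v_g_add` / `v_g_dom` exactly. Environment main
#' effects are correlated (`env_index_cor`) with the latent
#' environmental index that also drives the weather and crop-model
#' layers, and the GxE deviation contains a marker-determined
#' reaction-norm component (hybrid slope x environmental index,
#' weight `gxe_index_cor`), so both are learnable from the data the
#' study exposes. Hybrids are assigned to environments with incomplete
#' overlap (`coverage` of the year cohort per environment, but at
#' least one environment per cohort year per hybrid).
#'
#' @param cfg a [simConfig()] object.
#' @param pop result of [generatePopulation()].
#' @return list with `plot_table` (columns `Env`, `Hybrid`,
#'   `Replicate`, `Block`, `Row`, `Col`, `Yield_Mg_ha`) and `truth`
#'   (realized effects: `intercept`, `additive`, `dominance`, `env`,
#'   `gxe`, `block`, `row`, `col`, `residual`, `env_index`).
#' @export
generateTrials <- function(cfg, pop) {
  if (!inherits(cfg, "SimConfig")) stop("cfg must come from simConfig()")
  set.seed(deriveSeed(cfg$seed, "trials"))
  vc <- cfg$var_components
  et <- envTable(cfg)
  z <- envIndex(cfg)

  dos <- dosage(pop$geno)
  hyb <- rownames(dos)
  n_h <- length(hyb)

  ## genetic values, rescaled to the configured variances
  a_eff <- stats::rnorm(ncol(dos))
  Zc <- sweep(dos, 2, colMeans(dos))
  additive <- scaleToVar(as.vector(Zc %*% a_eff), vc$v_g_add)
  het <- (dos == 1) * 1
  hc <- sweep(het, 2, colMeans(het))
  dominance <- scaleToVar(as.vector(hc %*% stats::rnorm(ncol(dos))),
                          vc$v_g_dom)
  names(additive) <- names(dominance) <- hyb

  ## environment main effects: correlated with the latent index
  rho_e <- cfg$env_index_cor
  e_raw <- rho_e * z + sqrt(max(0, 1 - rho_e^2)) * stats::rnorm(length(z))
  env_eff <- scaleToVar(e_raw, vc$v_env)
  names(env_eff) <- et$Env

  ## GxE: marker-determined reaction norm + i.i.d. deviations
  slope <- as.vector(Zc %*% stats::rnorm(ncol(dos)))
  if (stats::sd(slope) > 0) slope <- as.vector(scale(slope)) else slope[] <- 0
  rho_g <- cfg$gxe_index_cor
  rn <- outer(slope, as.vector(z))
  iid <- matrix(stats::rnorm(n_h * length(z)), n_h)
  gxe <- scaleToVar(rho_g * rn + sqrt(max(0, 1 - rho_g^2)) * iid, vc$v_gxe)
  dimnames(gxe) <- list(hyb, et$Env)

  ## environment-by-environment layout and plot effects
  plots <- vector("list", nrow(et))
  blk_eff <- row_eff <- col_eff <- numeric(0)
  for (i in seq_len(nrow(et))) {
    env <- et$Env[i]
    cohort <- pop$hybrids_by_year[[as.character(et$Year[i])]]
    n_take <- max(2L, round(cfg$coverage * length(cohort)))
    take <- sample(cohort, min(n_take, length(cohort)))
    plots[[i]] <- layoutTrial(cfg, env, take)
  }
  ## guarantee every cohort hybrid at least one environment in its year
  for (y in as.character(cfg$years)) {
    idx <- which(et$Year == as.integer(y))
    seen <- unique(unlist(lapply(plots[idx], function(p) p$Hybrid)))
    missing <- setdiff(pop$hybrids_by_year[[y]], seen)
    for (h in missing) {
      j <- sample(idx, 1L)
      plots[[j]] <- addHybridToTrial(cfg, plots[[j]], et$Env[j], h)
    }
  }
  pt <- do.call(rbind, plots)
  rownames(pt) <- NULL

  ## draw block / row / col effects per environment factor level
  bkey <- unique(paste(pt$Env, pt$Replicate, pt$Block, sep = ":"))
  rkey <- unique(paste(pt$Env, pt$Row, sep = ":"))
  ckey <- unique(paste(pt$Env, pt$Col, sep = ":"))
  blk_eff <- stats::setNames(stats::rnorm(length(bkey), 0, sqrt(vc$v_block)), bkey)
  row_eff <- stats::setNames(stats::rnorm(length(rkey), 0, sqrt(vc$v_row)), rkey)
  col_eff <- stats::setNames(stats::rnorm(length(ckey), 0, sqrt(vc$v_col)), ckey)
  resid <- stats::rnorm(nrow(pt), 0, sqrt(vc$v_resid))

  yi <- cfg$intercept +
    additive[pt$Hybrid] + dominance[pt$Hybrid] + env_eff[pt$Env] +
    gxe[cbind(pt$Hybrid, pt$Env)] +
    blk_eff[paste(pt$Env, pt$Replicate, pt$Block, sep = ":")] +
    row_eff[paste(pt$Env, pt$Row, sep = ":")] +
    col_eff[paste(pt$Env, pt$Col, sep = ":")] +
    resid
  pt$Yield_Mg_ha <- as.numeric(yi)

  if (cfg$missing_plot_frac > 0) {
    drop <- sample.int(nrow(pt), round(cfg$missing_plot_frac * nrow(pt)))
    pt$Yield_Mg_ha[drop] <- NA_real_
  }

  list(plot_table = pt,
       truth = list(intercept = cfg$intercept, additive = additive,
                    dominance = dominance, env = env_eff, gxe = gxe,
                    block = blk_eff, row = row_eff, col = col_eff,
                    residual = resid, env_index = z))
}

#' RCBD layout for one environment: each replicate contains every
#' entered hybrid once; replicates are stacked vertically on a
#' field_cols-wide grid and cut into blocks of rows_per_block rows.
#' @noRd
layoutTrial <- function(cfg, env, hybrids_in) {
  n <- length(hybrids_in)
  ncol_f <- cfg$field_cols
  rows_per_rep <- ceiling(n / ncol_f)
  if (cfg$rows_per_block < 1L)
    stop("layout error: rows_per_block must be >= 1")
  out <- vector("list", cfg$reps)
  for (r in seq_len(cfg$reps)) {
    ord <- sample(hybrids_in)
    idx <- seq_len(n)
    row_in_rep <- (idx - 1L) %/% ncol_f + 1L
    row_abs <- row_in_rep + (r - 1L) * rows_per_rep
    col_abs <- (idx - 1L) %% ncol_f + 1L
    blk <- (row_in_rep - 1L) %/% cfg$rows_per_block + 1L
    out[[r]] <- data.frame(Env = env, Hybrid = ord,
                           Replicate = paste0("Rep", r),
                           Block = paste0("B", blk),
                           Row = sprintf("R%02d", row_abs),
                           Col = sprintf("C%02d", col_abs),
                           Yield_Mg_ha = NA_real_,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Append one hybrid to an existing trial (one plot per replicate,
#' placed on the next free grid cell).
#' @noRd
addHybridToTrial <- function(cfg, plot_env, env, hybrid) {
  for (r in unique(plot_env$Replicate)) {
    ss <- plot_env[plot_env$Replicate == r, ]
    row_ids <- as.integer(sub("R", "", ss$Row))
    last_row <- max(row_ids)
    used <- as.integer(sub("C", "", ss$Col[row_ids == last_row]))
    free <- setdiff(seq_len(cfg$field_cols), used)
    if (length(free)) {
      row_new <- last_row; col_new <- min(free)
    } else {
      row_new <- last_row + 1L; col_new <- 1L
    }
    blk <- max(as.integer(sub("B", "", ss$Block)))
    plot_env <- rbind(plot_env,
      data.frame(Env = env, Hybrid = hybrid, Replicate = r,
                 Block = paste0("B", blk),
                 Row = sprintf("R%02d", row_new),
                 Col = sprintf("C%02d", col_new),
                 Yield_Mg_ha = NA_real_, stringsAsFactors = FALSE))
  }
  plot_env
}
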