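# End-to-end orchestration: synthetic (or file-based) study ->
# stand/soil carbon -> OTU QC, rarefaction, diversity, Bray-Curtis ->
# PCoA + envfit + dbRDA -> indicator analysis -> additive-model battery
# (one microbiome predictor per model) -> correlation report.

# QC -> rarefy -> diversity -> relative abundance -> Bray-Curtis -> PCoA
.community_workflow <- function(table, seed) {
  qc <- qc_filter(table)
  rar <- rarefy(qc, depth = "min", seed = seed)
  div <- diversity_metrics(rar)
  rel <- relative_abundance(rar)
  bc <- bray_curtis(rel)
  ord <- pcoa(bc)
  list(qc = qc, rarefied = rar, diversity = div, relabund = rel,
       bray_curtis = bc, ordination = ord,
       dropped_samples = attr(qc, "dropped_samples"))
}

# per-sample environmental frame for envfit / dbrda / models
.env_frame <- function(plots, soils, carbon, soil_stocks) {
  org <- soils[soils$horizon == "organic", ]
  ss_org <- soil_stocks[soil_stocks$horizon == "organic", ]
  ss_min <- soil_stocks[soil_stocks$horizon == "mineral", ]
  env <- data.frame(
    plot_id = plots$plot_id,
    latitude = plots$latitude,
    mat = plots$mat, map = plots$map,
    n_deposition = plots$n_deposition,
    age = plots$age, stems_per_ha = plots$stems_per_ha,
    forest_type = plots$forest_type,
    ph = org$ph[match(plots$plot_id, org$plot_id)],
    clay = org$clay[match(plots$plot_id, org$plot_id)])
  env$soil_c_organic <- ss_org$c_stock[match(plots$plot_id, ss_org$plot_id)]
  env$soil_c_mineral <- ss_min$c_stock[match(plots$plot_id, ss_min$plot_id)]
  env$soil_n <- ss_org$n_stock[match(plots$plot_id, ss_org$plot_id)] +
    ss_min$n_stock[match(plots$plot_id, ss_min$plot_id)]
  env$growth_rate <- carbon$growth_rate[match(plots$plot_id, carbon$plot_id)]
  env$biomass <- carbon$biomass[match(plots$plot_id, carbon$plot_id)]
  env
}

#' Per-horizon soil stocks for a study
#'
#' @param soils soil profile data frame (see [generate_soils()])
#' @return data frame: plot_id, horizon, c_stock, n_stock (t ha^-1)
#' @export
soil_stocks <- function(soils) {
  data.frame(plot_id = soils$plot_id, horizon = soils$horizon,
             c_stock = soil_stock(soils$c_pct, soils$bulk_density, soils$depth),
             n_stock = soil_stock(soils$n_pct, soils$bulk_density, soils$depth))
}

#' Fit the default additive-model battery
#'
#' Every carbon outcome is regressed on the environmental covariate set
#' plus exactly one microbiome predictor (PCoA axis 1 or 2, richness or
#' Shannon diversity of one marker x horizon table), one model per
#' combination. Soil nitrogen stocks are included as a covariate for
#' tree growth models only.
#'
#' @param env per-plot data frame from the pipeline (outcomes +
#'   covariates)
#' @param predictors named list of per-sample microbiome predictor data
#'   frames (`sample` column plus predictor columns)
#' @param outcomes outcome column names
#' @param vif_limit collinearity flag threshold
#' @return data frame, one row per fitted model
#' @export
model_battery <- function(env, predictors,
                          outcomes = c("growth_rate", "biomass",
                                       "soil_c_organic", "soil_c_mineral"),
                          vif_limit = 5) {
  base_cov <- c("n_deposition", "mat", "map", "ph", "clay",
                "stems_per_ha", "age", "forest_type")
  rows <- list()
  for (tab in names(predictors)) {
    pr <- predictors[[tab]]
    pcols <- setdiff(names(pr), "sample")
    dat0 <- merge(env, pr, by.x = "plot_id", by.y = "sample")
    for (out in outcomes) {
      covs <- if (out == "growth_rate") c(base_cov, "soil_n") else base_cov
      for (pc in pcols) {
        fit <- fit_additive_model(dat0, out, pc, covs, vif_limit = vif_limit)
        rows[[length(rows) + 1]] <- data.frame(
          table = tab, outcome = out, predictor = pc, n = fit$n,
          slope = fit$slope, slope_se = fit$slope_se,
          slope_std = fit$slope_std, slope_std_se = fit$slope_std_se,
          p = fit$p, vif_max = max(fit$vif), vif_flag = fit$vif_flag)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete chain on a synthetic study (generated from
#' `config`) or a pre-built study object: stand growth/biomass carbon by
#' allometric bootstrap, soil stocks, per-table community workflow
#' (QC, rarefaction, diversity, Bray-Curtis, PCoA), environmental
#' vector/factor fitting and dbRDA, indicator-species analysis of the
#' fungal tables against tree growth and organic soil carbon, the
#' additive-model battery, and Pearson correlations. Deterministic for
#' a fixed study config (all stage seeds derive from `config$seed`).
#'
#' @param config a [study_config()] (used to generate the study) or an
#'   existing `synthetic_study`
#' @param out_dir optional directory; if given, stage outputs and
#'   `report.json` are written there
#' @param reps bootstrap replicates for stand carbon (default 1000)
#' @param n_perm envfit permutations (default 999)
#' @param envfit_vars variables fitted onto each ordination
#' @param run_indicators run the per-OTU negative-binomial stage
#'   (default TRUE)
#' @return list of class `mycocarbon_report` with elements
#'   `stand_carbon`, `soil_stocks`, `env`, `community`, `envfit`,
#'   `dbrda`, `indicators`, `models`, `correlations`
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL,
                         reps = 1000, n_perm = 999,
                         envfit_vars = c("growth_rate", "biomass", "age",
                                         "stems_per_ha", "forest_type",
                                         "mat", "map", "n_deposition",
                                         "ph", "clay", "soil_c_organic",
                                         "latitude"),
                         run_indicators = TRUE) {
  study <- if (inherits(config, "synthetic_study")) config else
    generate_study(config)
  cfg <- study$config
  seeds <- derive_seeds(cfg$seed + 1L, 8)

  message(sprintf("[carbon] bootstrapping %d plots, %d reps",
                  nrow(study$plots), reps))
  carbon <- stand_carbon(study$inventories,
                         stats::setNames(study$plots$stems_per_ha,
                                         study$plots$plot_id),
                         reps = reps, seed = seeds[1])
  stocks <- soil_stocks(study$soils)
  env <- .env_frame(study$plots, study$soils, carbon, stocks)

  community <- list(); envfit_res <- list(); dbrda_res <- list()
  predictors <- list()
  dbrda_pred <- c("mat", "map", "n_deposition", "ph", "clay", "age",
                  "stems_per_ha", "forest_type", "latitude")
  for (i in seq_along(study$otu_tables)) {
    nm <- names(study$otu_tables)[i]
    wf <- .community_workflow(study$otu_tables[[nm]], seed = seeds[2] + i)
    community[[nm]] <- wf
    ids <- rownames(wf$rarefied$counts)
    env_i <- env[match(ids, env$plot_id), ]
    message(sprintf("[community] %s: %d samples kept (%d dropped), depth %d",
                    nm, length(ids), length(wf$dropped_samples),
                    attr(wf$rarefied, "rarefaction_depth")))
    ef <- envfit_all(wf$ordination, env_i[envfit_vars], n_perm = n_perm,
                     seed = seeds[3] + i)
    envfit_res[[nm]] <- ef
    dbrda_res[[nm]] <- dbrda(wf$bray_curtis, env_i[dbrda_pred])
    predictors[[nm]] <- data.frame(
      sample = ids,
      stats::setNames(data.frame(wf$ordination$points[, 1],
                                 wf$ordination$points[, 2],
                                 wf$diversity$richness,
                                 wf$diversity$shannon),
                      paste0(nm, c("_pcoa1", "_pcoa2", "_richness",
                                   "_shannon"))))
  }

  indicators <- list()
  if (run_indicators) {
    for (nm in c("fungal_organic", "fungal_mineral")) {
      qc <- community[[nm]]$qc
      ids <- rownames(qc$counts)
      env_i <- env[match(ids, env$plot_id), ]
      for (cov in c("growth_rate", "soil_c_organic")) {
        message(sprintf("[indicators] %s vs %s", nm, cov))
        indicators[[paste(nm, cov, sep = ".")]] <-
          indicator_analysis(qc, env_i[[cov]])
      }
    }
  }

  message(sprintf("[models] battery over %d tables x 4 predictors x 4 outcomes",
                  length(predictors)))
  models <- model_battery(env, predictors)

  correlations <- rbind(
    cbind(pair = "growth_biomass", pearson_cor(env$growth_rate, env$biomass)),
    cbind(pair = "growth_soil_c_mineral",
          pearson_cor(env$growth_rate, env$soil_c_mineral)),
    cbind(pair = "growth_soil_c_organic",
          pearson_cor(env$growth_rate, env$soil_c_organic)))

  report <- structure(list(stand_carbon = carbon, soil_stocks = stocks,
                           env = env, community = community,
                           envfit = envfit_res, dbrda = dbrda_res,
                           indicators = indicators, models = models,
                           correlations = correlations, config = cfg),
                      class = "mycocarbon_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.mycocarbon_report <- function(x, ...) {
  cat(sprintf("mycocarbon report: %d plots, %d OTU tables, %d models\n",
              nrow(x$stand_carbon), length(x$community), nrow(x$models)))
  cat(sprintf("  growth-biomass r = %.3f; max VIF = %.2f\n",
              x$correlations$r[x$correlations$pair == "growth_biomass"],
              max(x$models$vif_max)))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes the tabular stage outputs as CSV and a `report.json` summary
#' (standardized slopes, VIF maxima, envfit tables, dbRDA proportions,
#' indicator counts).
#'
#' @param report a [run_pipeline()] result
#' @param dir output directory
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$stand_carbon, file.path(dir, "stand_carbon.csv"),
                   row.names = FALSE)
  utils::write.csv(report$soil_stocks, file.path(dir, "soil_stocks.csv"),
                   row.names = FALSE)
  utils::write.csv(report$models, file.path(dir, "models.csv"),
                   row.names = FALSE)
  for (nm in names(report$envfit))
    utils::write.csv(report$envfit[[nm]],
                     file.path(dir, sprintf("envfit_%s.csv", nm)),
                     row.names = FALSE)
  for (nm in names(report$indicators))
    utils::write.csv(report$indicators[[nm]],
                     file.path(dir, sprintf("indicators_%s.csv", nm)),
                     row.names = FALSE)
  summary <- list(
    models = report$models,
    envfit = lapply(report$envfit, function(e) e[c("variable", "kind",
                                                   "r2", "p")]),
    dbrda_proportion = lapply(report$dbrda, `[[`, "proportion"),
    indicator_counts = lapply(report$indicators,
                              function(r) sum(r$indicator)),
    correlations = report$correlations,
    max_vif = max(report$models$vif_max))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
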