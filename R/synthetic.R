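# Synthetic forest-microbiome studies with the statistical couplings the
# analysis chain assumes: a latent productivity gradient shared between
# tree growth and (partially) tree size, fungal composition loaded on
# that gradient plus broad environmental structure, bacterial
# composition loaded on pH and organic-horizon carbon, and an evenness
# latent that couples microbial richness negatively to organic-horizon
# carbon stocks. One master seed expands into independent substreams per
# generator so the study is reproducible piecewise.

#' Configuration of a synthetic study
#'
#' Defaults are calibrated to the survey conditions the pipeline is
#' meant for: 238 plots across a -2.5..15.5 degC mean-annual-temperature
#' and 443..2082 mm precipitation range, mean stand age 90 years, and a
#' stand productivity range of roughly 0.1-50 t C ha^-1 yr^-1, with a
#' growth-biomass correlation near 0.7.
#'
#' @param n_plots number of plots (>= 2)
#' @param frac_conifer probability a plot is conifer-dominated
#' @param mat_range,map_range climate ranges (degC; mm yr^-1)
#' @param age_mean,age_sd stand age distribution (years, truncated > 20)
#' @param seed master RNG seed
#' @param n_fungal_otus,n_bacterial_otus OTU richness of the regional
#'   species pools
#' @param gradient_loading_fungi_growth SD of per-OTU fungal loadings on
#'   the growth latent (log-abundance units per latent SD)
#' @param gradient_loading_bacteria_ph SD of per-OTU bacterial loadings
#'   on the pH / organic-carbon surrogate
#' @param growth_biomass_latent_corr target Pearson correlation between
#'   pipeline-computed stand growth and biomass, in (-1, 1)
#' @param depth_distribution per-marker lognormal sequencing-depth law,
#'   a list with `meanlog` and `sdlog` per marker; the defaults leave a
#'   few percent of samples below the QC thresholds (5000 reads 16S,
#'   500 reads ITS)
#' @param trees_per_plot expected measured trees per plot (Poisson)
#' @param frac_dead,frac_small,frac_shrink fractions of census records
#'   that are dead, below 5 cm DBH, or shrinking, to exercise the tree
#'   filters
#' @param growth_log_mu,growth_log_sd location/scale of per-tree carbon
#'   growth rates (log kg C yr^-1); `growth_log_sd` is the loading of
#'   the growth latent
#' @param tree_noise_sd within-plot log-scale spread of tree growth
#' @param dbh_meanlog,dbh_sdlog,dbh_size_loading initial-DBH lognormal
#'   and its loading on the size latent
#' @param stems_meanlog,stems_sdlog stem-density lognormal (stems ha^-1)
#' @param env_loading_sd SD of per-OTU loadings on environmental axes
#' @param env_mismatch_sd plot-level noise between each measured
#'   covariate and the microhabitat version of it the community responds
#'   to; bounds how collinear any compositional axis can be with the
#'   measured covariate set
#' @param baseline_sd SD of per-OTU log-baseline abundances
#' @param otu_noise_sd per-sample per-OTU log-abundance noise
#' @param evenness_sd SD of the plot evenness latent (drives richness)
#' @param richness_c_coupling coupling of organic-horizon C stocks to
#'   the evenness latent (positive value = negative richness-C
#'   covariance)
#' @param mineral_c_coupling coupling of mineral-horizon C stocks to the
#'   growth latent
#' @return object of class `study_config`
#' @export
study_config <- function(n_plots = 238,
                         frac_conifer = 0.5,
                         mat_range = c(-2.5, 15.5),
                         map_range = c(443, 2082),
                         age_mean = 90, age_sd = 25,
                         seed = 42,
                         n_fungal_otus = 400,
                         n_bacterial_otus = 600,
                         gradient_loading_fungi_growth = 0.7,
                         gradient_loading_bacteria_ph = 0.5,
                         growth_biomass_latent_corr = 0.7,
                         depth_distribution = list(
                           "16S" = list(meanlog = log(15000), sdlog = 0.6),
                           "ITS" = list(meanlog = log(1500), sdlog = 0.6)),
                         trees_per_plot = 60,
                         frac_dead = 0.05, frac_small = 0.05,
                         frac_shrink = 0.03,
                         growth_log_mu = log(2.2),
                         growth_log_sd = 0.70,
                         tree_noise_sd = 0.6,
                         dbh_meanlog = log(22), dbh_sdlog = 0.30,
                         dbh_size_loading = 0.25,
                         stems_meanlog = log(700), stems_sdlog = 0.35,
                         env_loading_sd = 0.52,
                         env_mismatch_sd = 0.65,
                         baseline_sd = 1.5,
                         otu_noise_sd = 0.8,
                         evenness_sd = 1.0,
                         richness_c_coupling = 0.30,
                         mineral_c_coupling = 0.25) {
  if (n_plots < 2) stop("n_plots must be >= 2")
  stopifnot(mat_range[1] <= mat_range[2], map_range[1] <= map_range[2],
            frac_conifer >= 0, frac_conifer <= 1,
            is.finite(gradient_loading_fungi_growth),
            is.finite(gradient_loading_bacteria_ph),
            abs(growth_biomass_latent_corr) < 1)
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("study_config: %d plots, seed %d, %d fungal / %d bacterial OTUs\n",
              x$n_plots, x$seed, x$n_fungal_otus, x$n_bacterial_otus))
  invisible(x)
}

#' Generate plot-level covariates
#'
#' Climate is uniform over the configured ranges; latitude is a noisy
#' decreasing function of temperature (northern plots are colder);
#' forest type is Bernoulli; age is truncated normal; stem density and
#' nitrogen deposition are lognormal.
#'
#' @param cfg a [study_config()]
#' @param seed substream seed (defaults to the first substream of
#'   `cfg$seed`)
#' @return data frame: plot_id, latitude, mat, map, forest_type, age,
#'   stems_per_ha, n_deposition
#' @export
generate_covariates <- function(cfg, seed = derive_seeds(cfg$seed, 1)) {
  if (cfg$n_plots < 2) stop("n_plots must be >= 2")
  n <- cfg$n_plots
  with_seed(seed, {
    mat <- stats::runif(n, cfg$mat_range[1], cfg$mat_range[2])
    mat_z <- if (diff(cfg$mat_range) > 0)
      (mat - mean(cfg$mat_range)) / (diff(cfg$mat_range) / 4) else rep(0, n)
    data.frame(
      plot_id = sprintf("P%03d", seq_len(n)),
      latitude = pmin(70, pmax(36, 53 - 4.5 * mat_z + stats::rnorm(n, 0, 3))),
      mat = mat,
      map = stats::runif(n, cfg$map_range[1], cfg$map_range[2]),
      forest_type = ifelse(stats::rbinom(n, 1, cfg$frac_conifer) == 1,
                           "conifer", "broadleaf"),
      age = pmax(20, stats::rnorm(n, cfg$age_mean, cfg$age_sd)),
      stems_per_ha = stats::rlnorm(n, cfg$stems_meanlog, cfg$stems_sdlog),
      n_deposition = stats::rlnorm(n, log(10), 0.4))
  })
}

#' Generate one plot's tree census
#'
#' Measured trees get a lognormal initial DBH (location shifted by the
#' plot's size latent) and a target carbon growth rate lognormal in the
#' plot's growth latent; the final DBH is solved from the allometric
#' power law so the census, run back through the allometry, returns
#' exactly the simulated growth. Configurable fractions of dead,
#' sub-5-cm and shrinking records exercise the census filters.
#'
#' @param plot one row of [generate_covariates()] output (needs
#'   `plot_id` and `stems_per_ha`)
#' @param gradient growth-latent value for the plot
#' @param size_latent size-latent value (default 0)
#' @param cfg a [study_config()]
#' @param seed substream seed
#' @param reg allometry used to invert mass to DBH (the registry default
#'   species entry)
#' @return tree data frame (see [filter_trees()] for columns)
#' @export
generate_tree_inventory <- function(plot, gradient, size_latent = 0, cfg,
                                    seed = 1, reg = allometry_registry()) {
  if (!is.finite(plot$stems_per_ha) || plot$stems_per_ha <= 0)
    stop("stems_per_ha must be positive")
  a <- reg$default["a"]; b <- reg$default["b"]
  with_seed(seed, {
    n <- max(15L, stats::rpois(1, cfg$trees_per_plot))
    species <- sample(paste0("SP", 1:6), n, replace = TRUE)
    dbh_i <- pmax(5.1, stats::rlnorm(n, cfg$dbh_meanlog +
                                       cfg$dbh_size_loading * size_latent,
                                     cfg$dbh_sdlog))
    # per-tree carbon growth (kg C / yr); invert allometry for final DBH
    q <- stats::rlnorm(n, cfg$growth_log_mu + cfg$growth_log_sd * gradient,
                       cfg$tree_noise_sd)
    dt <- 5
    mass_i <- a * dbh_i^b
    dbh_f <- ((mass_i + q * dt / 0.5) / a)^(1 / b)
    status <- rep("alive", n)
    # contaminant records, removed by the census filters
    n_dead <- stats::rbinom(1, n, cfg$frac_dead)
    n_small <- stats::rbinom(1, n, cfg$frac_small)
    n_shrink <- stats::rbinom(1, n, cfg$frac_shrink)
    extra <- n_dead + n_small + n_shrink
    if (extra > 0) {
      di <- c(stats::rlnorm(n_dead, cfg$dbh_meanlog, cfg$dbh_sdlog),
              stats::runif(n_small, 1, 4.9),
              stats::rlnorm(n_shrink, cfg$dbh_meanlog, cfg$dbh_sdlog))
      df_ <- c(di[seq_len(n_dead)] * stats::runif(n_dead, 1, 1.1),
               if (n_small) di[n_dead + seq_len(n_small)] *
                 stats::runif(n_small, 1, 1.2),
               if (n_shrink) di[n_dead + n_small + seq_len(n_shrink)] *
                 stats::runif(n_shrink, 0.9, 0.999))
      species <- c(species, sample(paste0("SP", 1:6), extra, replace = TRUE))
      dbh_i <- c(dbh_i, di)
      dbh_f <- c(dbh_f, df_)
      status <- c(status, rep(c("dead", "alive", "alive"),
                              c(n_dead, n_small, n_shrink)))
    }
    m <- length(status)
    data.frame(plot_id = plot$plot_id,
               tree_id = sprintf("%s_T%03d", plot$plot_id, seq_len(m)),
               species = species, status = status,
               dbh_initial = dbh_i, dbh_final = dbh_f,
               year_initial = 2003, year_final = 2003 + dt)
  })
}

#' Generate soil profiles
#'
#' Two horizons per plot. Organic-horizon carbon content rises with the
#' evenness latent (`richness_driver`), producing the negative
#' richness-to-organic-C-stock covariance; mineral-horizon carbon rises
#' with the growth latent. pH is lower under conifers.
#'
#' @param plots data frame from [generate_covariates()]
#' @param gradient growth latent per plot
#' @param richness_driver evenness latent per plot (higher = less even
#'   communities = lower richness); default 0
#' @param cfg a [study_config()]
#' @param seed substream seed
#' @return data frame: plot_id, horizon, c_pct, n_pct, bulk_density,
#'   depth, ph, clay
#' @export
generate_soils <- function(plots, gradient, richness_driver = 0, cfg,
                           seed = 1) {
  n <- nrow(plots)
  gradient <- rep_len(gradient, n)
  richness_driver <- rep_len(richness_driver, n)
  with_seed(seed, {
    ph <- pmin(7.5, pmax(3.5, stats::rnorm(n, 5.6, 0.7) -
                           0.7 * (plots$forest_type == "conifer")))
    clay <- stats::runif(n, 4, 40)
    org_c <- pmin(48, 22 * exp(cfg$richness_c_coupling * richness_driver +
                                 stats::rnorm(n, 0, 0.2)))
    min_c <- 2.5 * exp(cfg$mineral_c_coupling * gradient +
                         stats::rnorm(n, 0, 0.3))
    org <- data.frame(plot_id = plots$plot_id, horizon = "organic",
                      c_pct = org_c, n_pct = org_c / 25,
                      bulk_density = stats::rlnorm(n, log(0.25), 0.15),
                      depth = stats::runif(n, 2, 8),
                      ph = pmax(3.2, ph - 0.3 + stats::rnorm(n, 0, 0.15)),
                      clay = clay * stats::runif(n, 0.2, 0.5))
    mnr <- data.frame(plot_id = plots$plot_id, horizon = "mineral",
                      c_pct = min_c, n_pct = min_c / 15,
                      bulk_density = stats::rlnorm(n, log(1.2), 0.1),
                      depth = 10,
                      ph = ph + stats::rnorm(n, 0.2, 0.15),
                      clay = clay)
    rbind(org, mnr)
  })
}

# synthetic taxonomy: genera recycled over OTUs; fungal genera carry
# guild annotations including compound (hyphen-joined) trophic modes
.synthetic_taxonomy <- function(otu_ids, marker, seed) {
  with_seed(seed, {
    if (marker == "ITS") {
      guild_pool <- c("ectomycorrhizal", "saprotroph", "endophyte",
                      "pathogen", "ectomycorrhizal-saprotroph",
                      "saprotroph-pathogen", "")
      genera <- sprintf("Fungigenus%02d", 1:40)
      guild_map <- stats::setNames(
        sample(guild_pool, length(genera), replace = TRUE,
               prob = c(.2, .25, .1, .1, .08, .07, .2)), genera)
      kingdom <- "Fungi"
    } else {
      genera <- sprintf("Bactgenus%02d", 1:60)
      guild_map <- NULL
      kingdom <- "Bacteria"
    }
    genus <- sample(genera, length(otu_ids), replace = TRUE)
    tax <- data.frame(otu_id = otu_ids, kingdom = kingdom,
                      phylum = paste0(kingdom, "_phylum"),
                      class = "cls", order = "ord", family = "fam",
                      genus = genus)
    list(taxonomy = tax, guild = guild_map)
  })
}

#' Generate one OTU table
#'
#' Per-OTU log abundance is baseline (scaled by the plot evenness
#' latent) + loading x gradient + environmental loadings + noise; a
#' softmax turns log abundances into compositions and a multinomial
#' draw at a lognormal per-sample depth produces integer counts. True
#' per-OTU loadings are recorded for parameter-recovery scoring.
#'
#' @param plots data frame from [generate_covariates()]
#' @param gradient main latent per plot (growth latent for ITS, pH /
#'   organic-carbon surrogate for 16S)
#' @param marker `"16S"` or `"ITS"`
#' @param horizon `"organic"` or `"mineral"`
#' @param cfg a [study_config()]
#' @param seed substream seed
#' @param env optional data frame of standardized per-plot environmental
#'   axes given secondary per-OTU loadings (scale `cfg$env_loading_sd`)
#' @param evenness evenness latent per plot (default 0); scales the
#'   baseline spread, moving realised richness
#' @param loadings optional per-OTU gradient loadings (default drawn
#'   `N(0, sd)` with the marker's configured loading scale)
#' @return an [otu_table()]; attribute `truth` holds the gradient and
#'   environmental loadings
#' @export
generate_otu_table <- function(plots, gradient,
                               marker = c("16S", "ITS"),
                               horizon = c("organic", "mineral"),
                               cfg, seed = 1, env = NULL, evenness = 0,
                               loadings = NULL) {
  marker <- match.arg(marker)
  horizon <- match.arg(horizon)
  n <- nrow(plots)
  if (length(gradient) != n) stop("one gradient value per plot required")
  n_otus <- if (marker == "ITS") cfg$n_fungal_otus else cfg$n_bacterial_otus
  load_sd <- if (marker == "ITS") cfg$gradient_loading_fungi_growth else
    cfg$gradient_loading_bacteria_ph
  prefix <- if (marker == "ITS") "F" else "B"
  otu_ids <- sprintf("%s_OTU%04d", prefix, seq_len(n_otus))
  evenness <- rep_len(evenness, n)
  seeds <- derive_seeds(seed, 3)
  tax <- .synthetic_taxonomy(otu_ids, marker, seeds[1])
  counts <- with_seed(seeds[2], {
    baseline <- stats::rnorm(n_otus, 0, cfg$baseline_sd)
    lam <- if (is.null(loadings)) stats::rnorm(n_otus, 0, load_sd) else
      rep_len(loadings, n_otus)
    E <- if (is.null(env)) matrix(0, n, 0) else
      scale(stats::model.matrix(~ . - 1, data = env))
    if (ncol(E) > 0)
      # communities respond to the microhabitat, not the plot-mean
      # measurement; the mismatch keeps compositional axes from being
      # linear combinations of the measured covariates
      E <- E + matrix(stats::rnorm(length(E), 0, cfg$env_mismatch_sd),
                      nrow(E), ncol(E))
    Gam <- matrix(stats::rnorm(ncol(E) * n_otus, 0, cfg$env_loading_sd),
                  ncol(E), n_otus)
    if (ncol(E) > 0) {
      # pin each environmental axis' realised loading norm so the
      # environmentally structured share of inertia is stable across
      # seeds rather than chi-square distributed
      nrm <- sqrt(rowSums(Gam^2))
      Gam <- Gam * (cfg$env_loading_sd * sqrt(n_otus) / nrm)
    }
    loga <- exp(0.35 * evenness) %o% rep(1, n_otus) *
      matrix(baseline, n, n_otus, byrow = TRUE) +
      gradient %o% lam + E %*% Gam +
      matrix(stats::rnorm(n * n_otus, 0, cfg$otu_noise_sd), n, n_otus)
    probs <- exp(loga - apply(loga, 1, max))
    probs <- probs / rowSums(probs)
    dd <- cfg$depth_distribution[[marker]]
    depths <- pmax(10, round(stats::rlnorm(n, dd$meanlog, dd$sdlog)))
    cts <- t(vapply(seq_len(n), function(i)
      stats::rmultinom(1, depths[i], probs[i, ])[, 1], integer(n_otus)))
    dimnames(cts) <- list(plots$plot_id, otu_ids)
    attr(cts, "truth") <- list(gradient_loadings = lam, baseline = baseline)
    cts
  })
  truth <- attr(counts, "truth")
  attr(counts, "truth") <- NULL
  out <- otu_table(counts, marker = marker, horizon = horizon,
                   taxonomy = tax$taxonomy, guild = tax$guild)
  attr(out, "truth") <- truth
  out
}

#' Generate a complete synthetic study
#'
#' Composes covariates, latent gradients, tree censuses, soils and the
#' four OTU tables (marker x horizon) under independent substreams of
#' one master seed. The latent growth/size correlation is set from
#' `cfg$growth_biomass_latent_corr` through a calibrated map so that
#' the *pipeline-computed* stand growth vs biomass Pearson correlation
#' matches the configured target at the default calibration.
#'
#' @param cfg a [study_config()]
#' @return list of class `synthetic_study`: `plots`, `inventories`
#'   (named list per plot), `soils`, `otu_tables` (named
#'   `fungal_organic`, `fungal_mineral`, `bacterial_organic`,
#'   `bacterial_mineral`), and `truth` (latents and per-table loadings)
#' @export
generate_study <- function(cfg = study_config()) {
  seeds <- derive_seeds(cfg$seed, 9)
  plots <- generate_covariates(cfg, seed = seeds[1])
  n <- cfg$n_plots
  # latents: growth g, size h (correlated), evenness r (independent);
  # the latent correlation is shrunk slightly relative to the target
  # because shared stem density and lognormal upscaling shift the
  # realised product-moment correlation upward
  rho <- min(0.97, 0.93 * cfg$growth_biomass_latent_corr)
  lat <- with_seed(seeds[2], {
    g <- stats::rnorm(n)
    h <- rho * g + sqrt(1 - rho^2) * stats::rnorm(n)
    r <- stats::rnorm(n, 0, cfg$evenness_sd)
    list(g = g, h = h, r = r)
  })
  tree_seeds <- derive_seeds(seeds[3], n)
  inventories <- lapply(seq_len(n), function(i)
    generate_tree_inventory(plots[i, ], lat$g[i], lat$h[i], cfg,
                            seed = tree_seeds[i]))
  names(inventories) <- plots$plot_id
  soils <- generate_soils(plots, lat$g, lat$r, cfg, seed = seeds[4])
  org <- soils[soils$horizon == "organic", ]
  ph_z <- as.numeric(scale(org$ph))
  orgc_z <- as.numeric(scale(soil_stock(org$c_pct, org$bulk_density, org$depth)))
  bact_gradient <- with_seed(seeds[9],
    ((ph_z + orgc_z) / sqrt(2) + stats::rnorm(n, 0, cfg$env_mismatch_sd)) /
      sqrt(1 + cfg$env_mismatch_sd^2))
  # broad environmental structure: loadings spread over all plot-level
  # axes so no single eigen-direction of composition is reducible to one
  # predictor (keeps per-axis collinearity with the covariate set low
  # while total environmentally structured inertia stays realistic)
  env_all <- data.frame(type = as.numeric(plots$forest_type == "conifer"),
                        mat = plots$mat, map = plots$map,
                        ndep = plots$n_deposition, age = plots$age,
                        stems = plots$stems_per_ha, lat = plots$latitude,
                        ph = org$ph, clay = org$clay)
  env_fungi <- env_all
  env_bact <- env_all
  otu_tables <- list(
    fungal_organic = generate_otu_table(plots, lat$g, "ITS", "organic", cfg,
                                        seed = seeds[5], env = env_fungi,
                                        evenness = lat$r),
    fungal_mineral = generate_otu_table(plots, lat$g, "ITS", "mineral", cfg,
                                        seed = seeds[6], env = env_fungi,
                                        evenness = lat$r),
    bacterial_organic = generate_otu_table(plots, bact_gradient, "16S",
                                           "organic", cfg, seed = seeds[7],
                                           env = env_bact, evenness = lat$r),
    bacterial_mineral = generate_otu_table(plots, bact_gradient, "16S",
                                           "mineral", cfg, seed = seeds[8],
                                           env = env_bact, evenness = lat$r))
  truth <- c(lat, list(bacterial_gradient = bact_gradient,
                       loadings = lapply(otu_tables, attr, "truth")))
  structure(list(plots = plots, inventories = inventories, soils = soils,
                 otu_tables = otu_tables, truth = truth, config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d plots, %d OTU tables, seed %d\n",
              nrow(x$plots), length(x$otu_tables), x$config$seed))
  invisible(x)
}
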