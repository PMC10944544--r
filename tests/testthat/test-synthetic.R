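# The synthetic-study generator: determinism, configured ranges,
# latent couplings and the truth record.

test_that("covariates are reproducible and respect configured ranges", {
  cfg <- study_config(n_plots = 50, seed = 3)
  a <- generate_covariates(cfg)
  b <- generate_covariates(cfg)
  expect_identical(a, b)
  expect_true(all(a$mat >= -2.5 & a$mat <= 15.5))
  expect_true(all(a$map >= 443 & a$map <= 2082))
  expect_true(all(a$age > 0 & a$stems_per_ha > 0 & a$n_deposition > 0))
  expect_true(all(a$forest_type %in% c("conifer", "broadleaf")))

  # collapsed interval degenerates to a point mass
  flat <- generate_covariates(study_config(n_plots = 10, seed = 1,
                                           mat_range = c(7, 7)))
  expect_true(all(flat$mat == 7))
  expect_error(study_config(n_plots = 1), "n_plots")
})

test_that("tree generator couples increments to the gradient and seeds filters", {
  cfg <- study_config(seed = 1)
  plot <- data.frame(plot_id = "P001", stems_per_ha = 800)

  # no contaminants: every record survives the census filter
  cfg0 <- study_config(seed = 1, frac_dead = 0, frac_small = 0,
                       frac_shrink = 0)
  tr0 <- generate_tree_inventory(plot, 0, 0, cfg0, seed = 2)
  expect_equal(nrow(filter_trees(tr0)), nrow(tr0))

  # with contaminants some records are filtered
  cfg1 <- study_config(seed = 1, frac_dead = 0.2, frac_small = 0.2,
                       frac_shrink = 0.2)
  tr1 <- generate_tree_inventory(plot, 0, 0, cfg1, seed = 2)
  expect_lt(nrow(filter_trees(tr1)), nrow(tr1))

  # Monte-Carlo: mean increment increases with the gradient
  cfgb <- study_config(seed = 1, trees_per_plot = 12000, frac_dead = 0,
                       frac_small = 0, frac_shrink = 0)
  lo <- generate_tree_inventory(plot, -1, 0, cfgb, seed = 3)
  hi <- generate_tree_inventory(plot, 1, 0, cfgb, seed = 3)
  expect_gt(mean(tree_growth_rate(hi)), mean(tree_growth_rate(lo)))

  expect_error(generate_tree_inventory(
    data.frame(plot_id = "X", stems_per_ha = 0), 0, 0, cfg), "positive")
})

test_that("OTU generator is seeded, gradient-coupled and truth-recording", {
  cfg <- study_config(n_plots = 200, seed = 5, n_fungal_otus = 60)
  plots <- generate_covariates(cfg)
  set.seed(1); g <- rnorm(200)

  t1 <- generate_otu_table(plots, g, "ITS", "organic", cfg, seed = 9)
  t2 <- generate_otu_table(plots, g, "ITS", "organic", cfg, seed = 9)
  expect_identical(t1$counts, t2$counts)
  t3 <- generate_otu_table(plots, g, "ITS", "organic", cfg, seed = 10)
  expect_false(identical(t1$counts, t3$counts))

  # a strongly positive loading produces positive abundance-gradient r
  lam <- rep(0, 60); lam[7] <- 2
  tt <- generate_otu_table(plots, g, "ITS", "organic", cfg, seed = 4,
                           loadings = lam)
  rel <- relative_abundance(tt$counts + 0)
  expect_gt(cor(rel[, 7], g), 0.3)
  expect_equal(attr(tt, "truth")$gradient_loadings, lam)

  # all-zero loadings: no systematic coupling
  t0 <- generate_otu_table(plots, g, "ITS", "organic", cfg, seed = 4,
                           loadings = rep(0, 60))
  rel0 <- relative_abundance(t0$counts + 0)
  rs <- apply(rel0, 2, cor, y = g)
  expect_lt(abs(mean(rs)), 0.05)

  expect_error(generate_otu_table(plots, g[-1], "ITS", "organic", cfg),
               "per plot")
})

test_that("soil generator produces positive supports and configured couplings", {
  cfg <- study_config(n_plots = 500, seed = 6)
  plots <- generate_covariates(cfg)
  set.seed(2); g <- rnorm(500); r <- rnorm(500)
  soils <- generate_soils(plots, g, r, cfg, seed = 3)
  expect_true(all(soils$bulk_density > 0 & soils$depth > 0))
  expect_true(all(soils$c_pct >= 0 & soils$ph > 0))

  st <- soil_stocks(soils)
  org <- st$c_stock[st$horizon == "organic"]
  mnr <- st$c_stock[st$horizon == "mineral"]
  # organic C rises with the evenness latent (so falls with richness);
  # mineral C rises with the growth latent
  expect_gt(cor(org, r), 0.3)
  expect_gt(cor(mnr, g), 0.3)

  # zero couplings: correlations near zero
  cfg0 <- study_config(n_plots = 500, seed = 6, richness_c_coupling = 0,
                       mineral_c_coupling = 0)
  soils0 <- generate_soils(plots, g, r, cfg0, seed = 3)
  st0 <- soil_stocks(soils0)
  expect_lt(abs(cor(st0$c_stock[st0$horizon == "organic"], r)), 0.1)
  expect_lt(abs(cor(st0$c_stock[st0$horizon == "mineral"], g)), 0.1)
})

test_that("a full study is deterministic, complete and file-round-trippable", {
  cfg <- small_config()
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$otu_tables$fungal_organic$counts,
                   s2$otu_tables$fungal_organic$counts)
  expect_identical(s1$plots, s2$plots)

  s3 <- generate_study(small_config(seed = 12))
  expect_false(identical(s1$otu_tables$fungal_organic$counts,
                         s3$otu_tables$fungal_organic$counts))

  expect_equal(nrow(s1$plots), cfg$n_plots)
  expect_length(s1$inventories, cfg$n_plots)
  # every OTU-table sample id resolves to a plot
  for (tab in s1$otu_tables)
    expect_true(all(rownames(tab$counts) %in% s1$plots$plot_id))
  # truth record present
  expect_length(s1$truth$g, cfg$n_plots)
  expect_length(s1$truth$loadings, 4)

  dir <- withr::local_tempdir()
  write_study(s1, dir)
  expect_true(all(file.exists(file.path(dir,
    c("plots.csv", "trees.csv", "soil.csv", "otu_ITS_organic.tsv",
      "otu_16S_mineral.tsv", "taxonomy.tsv", "guilds.tsv", "truth.json")))))
  back <- read_otu_table(file.path(dir, "otu_ITS_organic.tsv"),
                         marker = "ITS", horizon = "organic",
                         taxonomy_path = file.path(dir, "taxonomy.tsv"),
                         guild_path = file.path(dir, "guilds.tsv"))
  expect_equal(back$counts[rownames(s1$otu_tables$fungal_organic$counts), ],
               s1$otu_tables$fungal_organic$counts)
  trees <- read_trees(file.path(dir, "trees.csv"))
  expect_length(trees, cfg$n_plots)
  expect_equal(nrow(read_plots(file.path(dir, "plots.csv"))), cfg$n_plots)
})

test_that("default study spans the calibrated productivity range", {
  study <- generate_study(study_config())
  carbon <- stand_carbon(study$inventories,
                         setNames(study$plots$stems_per_ha,
                                  study$plots$plot_id),
                         reps = 300, seed = 1)
  expect_gte(min(carbon$growth_rate), 0.10)
  expect_lte(max(carbon$growth_rate), 50.11)
  # fungal richness covaries negatively with organic-horizon C stocks
  rar <- rarefy(qc_filter(study$otu_tables$fungal_organic), "min", seed = 1)
  div <- diversity_metrics(rar)
  st <- soil_stocks(study$soils)
  org <- st[st$horizon == "organic", ]
  oc <- org$c_stock[match(div$sample, org$plot_id)]
  expect_lt(cor(div$richness, oc), -0.1)
})
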