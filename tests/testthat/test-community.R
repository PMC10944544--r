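# OTU-table QC, rarefaction, diversity, relative abundance,
# Bray-Curtis and guild aggregation.

test_that("depth filter drops shallow samples, then global singletons", {
  counts <- rbind(S1 = c(a = 5997, b = 2, c = 1),
                  S2 = c(a = 4998, b = 0, c = 1))
  tab <- otu_table(counts, marker = "16S", horizon = "organic")
  out <- qc_filter(tab)
  expect_equal(rownames(out$counts), "S1")     # 6000 kept, 4999 dropped
  expect_equal(attr(out, "dropped_samples"), "S2")
  # after the depth filter c totals 1 (singleton), b totals 2 (kept)
  expect_false("c" %in% colnames(out$counts))
  expect_true("b" %in% colnames(out$counts))
})

test_that("singleton rule counts totals across retained samples", {
  counts <- rbind(S1 = c(a = 600, b = 1, c = 1),
                  S2 = c(a = 600, b = 1, c = 0))
  tab <- otu_table(counts, marker = "ITS", horizon = "organic")
  out <- qc_filter(tab)
  # b totals 2 (split) -> kept; c totals 1 -> removed
  expect_setequal(colnames(out$counts), c("a", "b"))
  # an already-clean table passes through unchanged
  clean <- otu_table(rbind(S1 = c(a = 600, b = 5), S2 = c(a = 700, b = 3)),
                     marker = "ITS", horizon = "organic")
  expect_equal(qc_filter(clean)$counts, clean$counts)
  shallow <- otu_table(rbind(S1 = c(a = 10)), marker = "16S",
                       horizon = "organic")
  expect_error(qc_filter(shallow), "depth threshold")
})

test_that("rarefaction conserves depth and is an identity at full depth", {
  tab <- random_otu_table(n_samples = 5, n_otus = 15, seed = 3)
  depth <- min(rowSums(tab$counts))
  rar <- rarefy(tab, "min", seed = 1)
  expect_true(all(rowSums(rar$counts) == depth))
  expect_true(all(rar$counts <= tab$counts))   # subsample, never invent reads
  # a sample already exactly at depth is untouched
  exact <- otu_table(rbind(S1 = c(a = 3, b = 2), S2 = c(a = 50, b = 50)),
                     marker = "ITS", horizon = "organic")
  r2 <- rarefy(exact, 5, seed = 1)
  expect_equal(r2$counts["S1", ], c(a = 3, b = 2))
  expect_error(rarefy(exact, 6), "S1")
})

test_that("rarefied counts match the hypergeometric mean over replicates", {
  counts <- rbind(S1 = c(a = 400, b = 100, c = 0))
  tab <- otu_table(counts, marker = "ITS", horizon = "organic")
  depth <- 50
  sums <- Reduce(`+`, lapply(1:1000, function(i)
    rarefy(tab, depth, seed = i)$counts))
  expect_equal(as.numeric(sums / 1000),
               depth * c(400, 100, 0) / 500, tolerance = 0.05)
  # richness can only decrease under subsampling
  expect_lte(sum(rarefy(tab, 5, seed = 1)$counts > 0), sum(counts > 0))
})

test_that("richness and Shannon diversity match hand-computed values", {
  counts <- rbind(S1 = c(a = 10, b = 0, c = 0, d = 0),
                  S2 = c(a = 5, b = 5, c = 5, d = 5),
                  S3 = c(a = 4, b = 2, c = 2, d = 0))
  tab <- otu_table(counts, marker = "ITS", horizon = "organic")
  div <- diversity_metrics(tab)
  expect_equal(div$richness, c(1, 4, 3))
  expect_equal(div$shannon[1], 0)
  expect_equal(div$shannon[2], log(4), tolerance = 1e-10)
  expect_equal(div$shannon[3], 1.039721, tolerance = 1e-6)
  expect_true(all(div$shannon <= log(pmax(div$richness, 1)) + 1e-12))
  # log2 option
  expect_equal(diversity_metrics(tab, base = 2)$shannon[2], 2)
})

test_that("relative abundances are row proportions", {
  counts <- rbind(S1 = c(a = 3, b = 1), S2 = c(a = 7, b = 0))
  rel <- relative_abundance(otu_table(counts, "ITS", "organic"))
  expect_equal(unname(rel["S1", ]), c(0.75, 0.25))
  expect_equal(unname(rowSums(rel)), c(1, 1))
  zero <- otu_table(rbind(S1 = c(a = 0)), "ITS", "organic")
  expect_error(relative_abundance(zero), "zero-total")
})

test_that("Bray-Curtis matches its definition and is a [0,1] semimetric", {
  p <- rbind(x = c(0.6, 0.4), y = c(0.2, 0.8))
  d <- bray_curtis(p)
  expect_equal(d["x", "y"], 0.4)
  expect_equal(d["x", "x"], 0)
  disjoint <- rbind(x = c(1, 0), y = c(0, 1))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)
  # property check on random compositions
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rexp(6 * 10), 6, 10,
                dimnames = list(paste0("s", 1:6), paste0("o", 1:10)))
    m <- m / rowSums(m)
    dm <- bray_curtis(m)
    expect_true(isSymmetric(unclass(dm)))
    expect_true(all(dm >= 0 & dm <= 1))
    expect_true(all(diag(dm) == 0))
  }
})

test_that("guild aggregation honours compound labels and pure views", {
  counts <- matrix(5, 2, 4, dimnames = list(c("S1", "S2"),
                                            c("o1", "o2", "o3", "o4")))
  tax <- data.frame(otu_id = colnames(counts), kingdom = "Fungi",
                    phylum = "p", class = "c", order = "o", family = "f",
                    genus = c("Amanita", "Mortierella", "Fusarium", "Mystery"))
  guild_map <- c(Amanita = "ectomycorrhizal",
                 Mortierella = "saprotroph-pathogen",
                 Fusarium = "pathogen")
  tab <- otu_table(counts, "ITS", "organic", taxonomy = tax)
  agg <- aggregate_guilds(tab, guild_map)

  expect_true("o1" %in% colnames(agg$tables$ectomycorrhizal$counts))
  expect_true("o1" %in% colnames(agg$tables$pure_ectomycorrhizal$counts))
  # compound label keeps the hyphen-joined guild and is excluded from pure_*
  expect_true("o2" %in% colnames(agg$tables$`saprotroph-pathogen`$counts))
  expect_false("pure_saprotroph" %in% names(agg$tables))
  expect_true("o4" %in% colnames(agg$tables$unassigned$counts))

  # top-level subsets partition the OTU set
  top <- setdiff(names(agg$tables), grep("^pure_", names(agg$tables),
                                         value = TRUE))
  all_otus <- unlist(lapply(agg$tables[top], function(t) colnames(t$counts)))
  expect_setequal(all_otus, colnames(counts))
  expect_equal(anyDuplicated(all_otus), 0)
  # relative abundances per guild sum to 1 across the partition
  expect_equal(unname(rowSums(agg$relative)), c(1, 1))

  # empty map: everything unassigned
  agg0 <- aggregate_guilds(tab, NULL)
  expect_equal(colnames(agg0$tables$unassigned$counts), colnames(counts))
})
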