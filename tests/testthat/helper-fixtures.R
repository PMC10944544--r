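# small deterministic fixtures shared across test files

# four-tree census exercising every census filter at once
mixed_census <- function() {
  data.frame(
    plot_id = "P1",
    tree_id = paste0("t", 1:4),
    species = "SP1",
    status = c("dead", "alive", "alive", "alive"),
    dbh_initial = c(30, 4, 20, 10),
    dbh_final = c(31, 5, 18, 12),
    year_initial = 2000, year_final = 2005)
}

# random small otu_table with seeded counts
random_otu_table <- function(n_samples = 8, n_otus = 20, marker = "ITS",
                             horizon = "organic", seed = 1, lambda = 30) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus,
                   dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                   sprintf("OTU%03d", seq_len(n_otus))))
  tax <- data.frame(otu_id = colnames(counts), kingdom = "Fungi",
                    phylum = "p", class = "c", order = "o", family = "f",
                    genus = sample(paste0("G", 1:5), n_otus, replace = TRUE))
  otu_table(counts, marker = marker, horizon = horizon, taxonomy = tax)
}

# small study for pipeline-level tests (fast but non-degenerate)
small_config <- function(seed = 11, n_plots = 60) {
  study_config(n_plots = n_plots, seed = seed, n_fungal_otus = 120,
               n_bacterial_otus = 150, trees_per_plot = 25)
}
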