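# OTU-table handling: quality control, rarefaction, alpha diversity,
# relative abundance, Bray-Curtis dissimilarity and fungal guild splits.
# Convention throughout: samples are rows, OTUs are columns (the usual
# community-ecology orientation); on disk tables are transposed (rows =
# OTUs) as produced by amplicon pipelines.

#' Construct an OTU table
#'
#' @param counts integer matrix, samples in rows, OTUs in columns, with
#'   dimnames
#' @param marker `"16S"` or `"ITS"`
#' @param horizon `"organic"` or `"mineral"`
#' @param taxonomy optional data frame with columns `otu_id` and ranked
#'   lineage columns (kingdom..genus)
#' @param guild optional named character vector mapping genus to guild
#'   label (see [aggregate_guilds()])
#' @return object of class `otu_table`
#' @export
otu_table <- function(counts, marker = c("16S", "ITS"),
                      horizon = c("organic", "mineral"),
                      taxonomy = NULL, guild = NULL) {
  marker <- match.arg(marker)
  horizon <- match.arg(horizon)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and OTU colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, marker = marker, horizon = horizon,
                 taxonomy = taxonomy, guild = guild),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, marker %s, horizon %s\n",
              nrow(x$counts), ncol(x$counts), x$marker, x$horizon))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

.replace_counts <- function(table, counts) {
  table$counts <- counts
  if (!is.null(table$taxonomy))
    table$taxonomy <- table$taxonomy[table$taxonomy$otu_id %in% colnames(counts), ,
                                     drop = FALSE]
  table
}

#' Depth and singleton quality control
#'
#' Drops samples whose total sequence count falls below the per-marker
#' threshold (default 5000 for 16S, 500 for ITS), then removes global
#' singletons: OTUs whose total count across the retained samples is
#' exactly 1. OTUs left with zero counts are also dropped.
#'
#' @param table an [otu_table()]
#' @param min_depth_16s,min_depth_its per-marker depth thresholds
#' @param drop_singletons remove OTUs with global count 1 (default TRUE)
#' @return filtered `otu_table`; attributes `dropped_samples` and
#'   `dropped_otus` record the removed identifiers
#' @export
qc_filter <- function(table, min_depth_16s = 5000, min_depth_its = 500,
                      drop_singletons = TRUE) {
  stopifnot(inherits(table, "otu_table"))
  thr <- if (table$marker == "16S") min_depth_16s else min_depth_its
  depth <- rowSums(table$counts)
  keep_s <- depth >= thr
  if (!any(keep_s))
    stop(sprintf("no sample reaches the %s depth threshold of %d",
                 table$marker, thr))
  counts <- table$counts[keep_s, , drop = FALSE]
  tot <- colSums(counts)
  keep_o <- if (drop_singletons) tot >= 2 else tot >= 1
  dropped_o <- colnames(counts)[!keep_o]
  counts <- counts[, keep_o, drop = FALSE]
  out <- .replace_counts(table, counts)
  attr(out, "dropped_samples") <- rownames(table$counts)[!keep_s]
  attr(out, "dropped_otus") <- dropped_o
  out
}

#' Rarefy to a common sequencing depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to `depth`, the classic correction for unequal
#' sequencing effort before diversity comparisons.
#'
#' @param table an [otu_table()]
#' @param depth target depth, or `"min"` (default) for the lowest sample
#'   total in the table
#' @param seed integer seed for the subsampling stream
#' @return rarefied `otu_table`; every sample sums to `depth`. The depth
#'   and seed used are stored in attributes.
#' @export
rarefy <- function(table, depth = "min", seed = 1) {
  stopifnot(inherits(table, "otu_table"))
  totals <- rowSums(table$counts)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  low <- totals < depth
  if (any(low))
    stop(sprintf("rarefaction depth %d exceeds total of sample(s): %s",
                 depth, paste(rownames(table$counts)[low], collapse = ", ")))
  counts <- with_seed(seed, {
    t(apply(table$counts, 1, function(row) {
      reads <- rep.int(seq_along(row), row)
      kept <- tabulate(sample(reads, depth, replace = FALSE),
                       nbins = length(row))
      kept
    }))
  })
  dimnames(counts) <- dimnames(table$counts)
  out <- .replace_counts(table, counts)
  attr(out, "rarefaction_depth") <- depth
  attr(out, "rarefaction_seed") <- seed
  out
}

#' Per-sample richness and Shannon diversity
#'
#' Richness is the count of OTUs with nonzero counts; Shannon diversity
#' is \eqn{H = -\sum p_i \log p_i} over nonzero proportions, in nats by
#' default. Compute on a rarefied table to avoid depth bias.
#'
#' @param table an [otu_table()]
#' @param base logarithm base for Shannon H (`exp(1)` for nats; use 2
#'   for bits)
#' @return data frame: sample, richness, shannon
#' @export
diversity_metrics <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "otu_table"))
  counts <- table$counts
  tot <- rowSums(counts)
  if (any(tot == 0)) warning("all-zero sample(s); richness and H set to 0")
  H <- vapply(seq_len(nrow(counts)), function(i) {
    p <- counts[i, ]
    p <- p[p > 0] / tot[i]
    if (length(p) == 0) return(0)
    -sum(p * log(p, base = base))
  }, numeric(1))
  data.frame(sample = rownames(counts),
             richness = rowSums(counts > 0),
             shannon = H, row.names = NULL)
}

#' Relative abundances
#'
#' @param table an [otu_table()] or a count matrix (samples x OTUs)
#' @return numeric matrix of proportions; each sample row sums to 1
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("cannot normalise a zero-total sample")
  sweep(counts, 1, tot, "/")
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between
#' abundance profiles; 0 for identical profiles, 1 for disjoint support.
#'
#' @param profiles numeric matrix, samples in rows (typically relative
#'   abundances)
#' @return symmetric matrix of class `dist_matrix` with zero diagonal
#' @export
bray_curtis <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) stop("negative abundances")
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1)) {
    xi <- profiles[i, ]
    rest <- (i + 1):n
    num <- rowSums(abs(sweep(profiles[rest, , drop = FALSE], 2, xi)))
    den <- rowSums(sweep(profiles[rest, , drop = FALSE], 2, xi, "+"))
    d[i, rest] <- d[rest, i] <- ifelse(den == 0, 0, num / den)
  }
  class(d) <- c("dist_matrix", "matrix")
  d
}

#' Split an ITS table into fungal functional guilds
#'
#' Guild annotations are made at the genus level. Genera carrying
#' several trophic annotations keep the hyphen-joined compound label
#' (e.g. `ectomycorrhizal-saprotroph`); in addition, `pure_` views
#' collect taxa with exactly one annotation for guilds where a strict
#' single-trophic-mode reading matters (ectomycorrhizal, saprotroph).
#' Genera missing from the map go to `unassigned`.
#'
#' @param table an ITS [otu_table()] whose taxonomy has a `genus` column
#' @param guild_map named character vector genus -> guild label; compound
#'   guilds hyphen-joined. Defaults to the `guild` slot of the table.
#' @param pure_guilds guilds for which a `pure_*` single-annotation view
#'   is also produced
#' @return list with `tables`: named list of `otu_table` subsets (the
#'   non-`pure_` entries partition the OTU set) and `relative`: per
#'   sample x guild relative-abundance matrix over the partition
#' @export
aggregate_guilds <- function(table, guild_map = table$guild,
                             pure_guilds = c("ectomycorrhizal", "saprotroph")) {
  stopifnot(inherits(table, "otu_table"))
  if (table$marker != "ITS") stop("guild aggregation applies to ITS tables")
  if (is.null(table$taxonomy) || is.null(table$taxonomy$genus))
    stop("table lacks genus-level taxonomy")
  genus <- table$taxonomy$genus[match(colnames(table$counts),
                                      table$taxonomy$otu_id)]
  lab <- if (is.null(guild_map)) rep(NA_character_, length(genus)) else
    unname(guild_map[genus])
  lab[is.na(lab) | lab == ""] <- "unassigned"
  subsets <- split(colnames(table$counts), lab)
  tables <- lapply(subsets, function(otus)
    .replace_counts(table, table$counts[, otus, drop = FALSE]))
  for (g in pure_guilds) {            # pure views: single-annotation taxa only
    if (g %in% names(subsets))
      tables[[paste0("pure_", g)]] <- tables[[g]]
  }
  rel_tot <- rowSums(table$counts)
  rel <- vapply(subsets, function(otus)
    rowSums(table$counts[, otus, drop = FALSE]) / pmax(rel_tot, 1),
    numeric(nrow(table$counts)))
  if (is.null(dim(rel))) rel <- matrix(rel, nrow = 1,
                                       dimnames = list(rownames(table$counts),
                                                       names(subsets)))
  list(tables = tables, relative = rel)
}
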