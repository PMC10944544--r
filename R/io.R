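# Plain-text readers and writers for study inputs and outputs. OTU
# tables on disk follow the amplicon convention (rows = OTUs, first
# column the OTU id, remaining columns per-sample counts, tab
# separated); all delimited files are UTF-8 with a header row and '.'
# decimal separator.

#' Write an OTU table as TSV
#'
#' @param table an [otu_table()]
#' @param path output file
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  out <- data.frame(otu_id = colnames(table$counts),
                    t(table$counts), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU table from TSV
#'
#' @param path counts TSV (rows OTUs, first column `otu_id`)
#' @param marker,horizon table labels
#' @param taxonomy_path optional taxonomy TSV (`otu_id` + rank columns)
#' @param guild_path optional guild TSV with columns `genus`, `guild`
#' @return an [otu_table()]
#' @export
read_otu_table <- function(path, marker, horizon, taxonomy_path = NULL,
                           guild_path = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  counts <- t(as.matrix(raw[, -1, drop = FALSE]))
  colnames(counts) <- raw[[1]]
  taxonomy <- if (!is.null(taxonomy_path))
    utils::read.table(taxonomy_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE) else NULL
  guild <- if (!is.null(guild_path)) {
    g <- utils::read.table(guild_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    stats::setNames(g$guild, g$genus)
  } else NULL
  otu_table(counts, marker = marker, horizon = horizon,
            taxonomy = taxonomy, guild = guild)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Produces `plots.csv`, `trees.csv`, `soil.csv`,
#' `otu_<marker>_<horizon>.tsv`, `taxonomy.tsv`, `guilds.tsv` and
#' `truth.json`.
#'
#' @param study a [generate_study()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$plots, file.path(dir, "plots.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, study$inventories),
                   file.path(dir, "trees.csv"), row.names = FALSE)
  utils::write.csv(study$soils, file.path(dir, "soil.csv"), row.names = FALSE)
  tax_all <- list(); guild_all <- list()
  for (nm in names(study$otu_tables)) {
    tab <- study$otu_tables[[nm]]
    write_otu_table(tab, file.path(dir, sprintf("otu_%s_%s.tsv",
                                                tab$marker, tab$horizon)))
    tax_all[[nm]] <- tab$taxonomy
    if (!is.null(tab$guild))
      guild_all[[nm]] <- data.frame(genus = names(tab$guild),
                                    guild = unname(tab$guild))
  }
  utils::write.table(unique(do.call(rbind, tax_all)),
                     file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(guild_all))
    utils::write.table(unique(do.call(rbind, guild_all)),
                       file.path(dir, "guilds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read tree inventories from trees.csv
#'
#' @param path CSV with columns plot_id, tree_id, species, status,
#'   dbh_initial, dbh_final, year_initial, year_final
#' @return named list of per-plot tree data frames
#' @export
read_trees <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split(df, df$plot_id)
}

#' Read plot metadata
#' @param path plots.csv
#' @return data frame
#' @export
read_plots <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Read soil profiles
#' @param path soil.csv
#' @return data frame
#' @export
read_soils <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
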