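# Stand-level carbon accounting from periodic forest inventories:
# tree-level allometric carbon, census filters, bootstrap upscaling to
# stem density, and soil C/N stocks from content x bulk density x depth.

#' Build an allometry registry
#'
#' Species-specific allometric equations relate diameter at breast height
#' (DBH, cm) to aboveground tree mass (kg) through the power law
#' \eqn{mass = a \cdot DBH^b}. The registry maps species codes to their
#' coefficients plus a generic default used (with a warning) for species
#' without a published equation.
#'
#' @param species data frame with columns `species`, `a`, `b` and
#'   optionally `dbh_min`, `dbh_max` (cm, validity range of the fitted
#'   equation). May be `NULL` for a registry containing only the default.
#' @param default_a,default_b coefficients of the fallback equation. The
#'   defaults (`a = 0.25`, `b = 2.4`) are in the mid-range of published
#'   temperate-tree power laws.
#' @return object of class `allometry_registry`
#' @export
allometry_registry <- function(species = NULL, default_a = 0.25, default_b = 2.4) {
  stopifnot(default_a > 0, default_b > 0)
  if (!is.null(species)) {
    stopifnot(is.data.frame(species),
              all(c("species", "a", "b") %in% names(species)),
              all(species$a > 0), all(species$b > 0))
    if (is.null(species$dbh_min)) species$dbh_min <- 0
    if (is.null(species$dbh_max)) species$dbh_max <- Inf
  }
  structure(list(species = species,
                 default = c(a = default_a, b = default_b)),
            class = "allometry_registry")
}

#' @export
print.allometry_registry <- function(x, ...) {
  n <- if (is.null(x$species)) 0L else nrow(x$species)
  cat(sprintf("allometry registry: %d species entries, default a=%.3g b=%.3g\n",
              n, x$default["a"], x$default["b"]))
  invisible(x)
}

.allometry_lookup <- function(species, reg) {
  a <- rep(reg$default["a"], length(species))
  b <- rep(reg$default["b"], length(species))
  if (!is.null(reg$species)) {
    idx <- match(species, reg$species$species)
    hit <- !is.na(idx)
    a[hit] <- reg$species$a[idx[hit]]
    b[hit] <- reg$species$b[idx[hit]]
    if (any(!hit)) {
      warning(sprintf("no allometric equation for species: %s; using default",
                      paste(unique(species[!hit]), collapse = ", ")),
              call. = FALSE)
    }
  }
  list(a = unname(a), b = unname(b))
}

#' Filter a tree census for growth estimation
#'
#' Removes dead trees, trees below the minimum DBH at the first census,
#' and trees that shrank between censuses (measurement error or breakage).
#' Trees with equal first and last DBH are retained as zero growth.
#' The operation is idempotent and preserves input order.
#'
#' @param trees data frame with columns `tree_id`, `species`, `status`
#'   (`"alive"`/`"dead"`), `dbh_initial`, `dbh_final` (cm), `year_initial`,
#'   `year_final`
#' @param min_dbh minimum initial DBH in cm (default 5)
#' @return the filtered data frame; zero rows is allowed and must be
#'   checked by downstream estimators
#' @export
filter_trees <- function(trees, min_dbh = 5) {
  stopifnot(is.data.frame(trees),
            all(c("status", "dbh_initial", "dbh_final") %in% names(trees)))
  keep <- trees$status == "alive" &
    trees$dbh_initial >= min_dbh &
    trees$dbh_final >= trees$dbh_initial
  trees[keep, , drop = FALSE]
}

#' Tree carbon from DBH
#'
#' Applies the species allometric power law and a constant carbon
#' fraction (default 50% of dry mass across species).
#'
#' @param species character vector of species codes
#' @param dbh DBH in cm (nonnegative)
#' @param reg an [allometry_registry()]
#' @param c_fraction carbon fraction of dry mass, default 0.5
#' @return carbon per tree in kg C
#' @export
tree_carbon <- function(species, dbh, reg = allometry_registry(),
                        c_fraction = 0.5) {
  if (any(dbh < 0)) stop("negative DBH")
  ab <- .allometry_lookup(species, reg)
  c_fraction * ab$a * dbh^ab$b
}

#' Tree carbon growth rate
#'
#' Carbon mass difference between last and first census divided by the
#' census interval in years.
#'
#' @inheritParams tree_carbon
#' @param trees filtered tree data frame (see [filter_trees()])
#' @return kg C per year per tree
#' @export
tree_growth_rate <- function(trees, reg = allometry_registry(),
                             c_fraction = 0.5) {
  dt <- trees$year_final - trees$year_initial
  if (any(dt <= 0)) stop("census interval must be positive")
  (tree_carbon(trees$species, trees$dbh_final, reg, c_fraction) -
     tree_carbon(trees$species, trees$dbh_initial, reg, c_fraction)) / dt
}

#' Bootstrap stand-level growth and biomass carbon
#'
#' Not every stem on a plot carries a DBH record, so measured trees are
#' resampled with replacement up to the in situ stem density; each
#' replicate's tree growth rates and final-census carbon are summed and
#' converted to per-hectare tonnes. The mean over replicates (default
#' 1000) is the stand estimate, with the replicate SD as its spread.
#'
#' @param trees tree data frame, already passed through [filter_trees()]
#' @param stems_per_ha in situ stem density (stems per hectare, > 0)
#' @param reg an [allometry_registry()]
#' @param reps bootstrap replicates, default 1000
#' @param c_fraction carbon fraction, default 0.5
#' @param seed optional integer seed for the resampling stream
#' @return list with `growth_rate` and `biomass` (t C ha^-1 yr^-1 and
#'   t C ha^-1), their bootstrap SDs, and `reps`
#' @export
bootstrap_stand_estimate <- function(trees, stems_per_ha,
                                     reg = allometry_registry(),
                                     reps = 1000, c_fraction = 0.5,
                                     seed = NULL) {
  if (nrow(trees) == 0) stop("no trees left after filtering; cannot bootstrap")
  if (!is.finite(stems_per_ha) || stems_per_ha <= 0)
    stop("stems_per_ha must be positive")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  rate_kg <- tree_growth_rate(trees, reg, c_fraction)
  mass_kg <- tree_carbon(trees$species, trees$dbh_final, reg, c_fraction)
  n_draw <- max(1L, round(stems_per_ha))
  n <- nrow(trees)
  # sampling with replacement n_draw stems per replicate == multinomial
  # draw of per-tree multiplicities; summing through the count matrix
  # avoids materialising reps x n_draw index vectors
  counts <- stats::rmultinom(reps, size = n_draw, prob = rep(1 / n, n))
  growth_reps <- as.numeric(crossprod(counts, rate_kg)) / 1000  # kg -> t
  biomass_reps <- as.numeric(crossprod(counts, mass_kg)) / 1000
  list(growth_rate = mean(growth_reps),
       growth_sd = stats::sd(growth_reps),
       biomass = mean(biomass_reps),
       biomass_sd = stats::sd(biomass_reps),
       reps = reps)
}

#' Soil element stock from content, bulk density and depth
#'
#' stock (t ha^-1) = content/100 * bulk density (g cm^-3) * depth (cm)
#' * 100, i.e. an areal density in g cm^-2 scaled to tonnes per hectare.
#'
#' @param pct elemental content in percent of dry mass
#' @param bulk_density g cm^-3
#' @param depth sampling depth, cm
#' @return stock in t ha^-1
#' @export
soil_stock <- function(pct, bulk_density, depth) {
  if (any(pct < 0) || any(bulk_density < 0) || any(depth < 0))
    stop("soil_stock inputs must be nonnegative")
  (pct / 100) * bulk_density * depth * 100
}

#' Stand carbon for a whole study
#'
#' Runs filter, allometry and bootstrap per plot.
#'
#' @param inventories named list of tree data frames (one per plot)
#' @param stems_per_ha named numeric vector of stem densities
#' @param reg an [allometry_registry()]
#' @param reps bootstrap replicates
#' @param seed integer; per-plot resampling seeds are derived from it so
#'   adding plots does not perturb earlier plots
#' @param min_dbh minimum DBH for [filter_trees()]
#' @return data frame: plot_id, growth_rate, growth_sd, biomass,
#'   biomass_sd, n_trees
#' @export
stand_carbon <- function(inventories, stems_per_ha,
                         reg = allometry_registry(), reps = 1000,
                         seed = 1, min_dbh = 5) {
  plots <- names(inventories)
  stopifnot(!is.null(plots), all(plots %in% names(stems_per_ha)))
  seeds <- derive_seeds(seed, length(plots))
  rows <- lapply(seq_along(plots), function(i) {
    tr <- filter_trees(inventories[[i]], min_dbh = min_dbh)
    est <- bootstrap_stand_estimate(tr, stems_per_ha[[plots[i]]], reg,
                                    reps = reps, seed = seeds[i])
    data.frame(plot_id = plots[i], growth_rate = est$growth_rate,
               growth_sd = est$growth_sd, biomass = est$biomass,
               biomass_sd = est$biomass_sd, n_trees = nrow(tr))
  })
  do.call(rbind, rows)
}
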