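#' Published weatherfish diet-study reference tables
#'
#' Summary tables from a gut-content study of weatherfish (*Misgurnus
#' fossilis*) sampled from a lowland drainage canal: 64 fish in two
#' maturity/size classes (33 juveniles, TL <= 12 cm; 26 mature, TL > 12 cm,
#' after excluding 5 empty guts), 25 food categories. These transcribed
#' tables parameterise the synthetic cohort generator and serve as inputs
#' for reconstruction checks; the per-fish raw data are not redistributed
#' here (they live in a public repository, see `weatherfish_study()$dryad`).
#'
#' @return `weatherfish_table1()`: data frame with one row per food
#'   category and per-group `%W` mean/SD/CV, `%FO` and `%IRI` columns
#'   (`NA` where a category was absent from a group's diet).
#' @rdname weatherfish-tables
#' @export
weatherfish_table1 <- function() {
  read.csv(system.file("extdata", "table1_diet_composition.csv",
                       package = "gutshift"),
           check.names = FALSE, stringsAsFactors = FALSE)
}

#' @return `weatherfish_guild_summary()`: the same summaries after
#'   collapsing categories into the five habitat guilds plus `others`.
#' @rdname weatherfish-tables
#' @export
weatherfish_guild_summary <- function() {
  read.csv(system.file("extdata", "table1_guild_summary.csv",
                       package = "gutshift"),
           check.names = FALSE, stringsAsFactors = FALSE)
}

#' @return `weatherfish_guild_map()`: the category-to-guild assignment as a
#'   [guild_map()]; `"others"` is deliberately unmapped (use
#'   `aggregate_by_guild(..., unmapped = "others")`).
#' @rdname weatherfish-tables
#' @export
weatherfish_guild_map <- function() {
  t1 <- weatherfish_table1()
  keep <- !is.na(t1$guild)
  guild_map(t1$category[keep], t1$guild[keep])
}

#' @return `weatherfish_simper()`: published SIMPER decomposition of the
#'   between-class Bray-Curtis dissimilarity (top categories, average
#'   dissimilarity, contribution and cumulative percentages, group means).
#' @rdname weatherfish-tables
#' @export
weatherfish_simper <- function() {
  read.csv(system.file("extdata", "table2_simper.csv", package = "gutshift"),
           check.names = FALSE, stringsAsFactors = FALSE)
}

#' @return `weatherfish_niche()`: published jackknifed niche-breadth indices
#'   per group with permutation p-values.
#' @rdname weatherfish-tables
#' @export
weatherfish_niche <- function() {
  read.csv(system.file("extdata", "table3_niche.csv", package = "gutshift"),
           check.names = FALSE, stringsAsFactors = FALSE)
}

#' @return `weatherfish_dfa()`: list with the published discriminant
#'   analysis of the five habitat food types: per-variable structure
#'   correlations and F-to-remove (`table`), the canonical `eigenvalue`,
#'   overall `wilks`, `f` with `df`, and classification accuracies (%).
#' @rdname weatherfish-tables
#' @export
weatherfish_dfa <- function() {
  tab <- read.csv(system.file("extdata", "table4_dfa.csv", package = "gutshift"),
                  check.names = FALSE, stringsAsFactors = FALSE)
  list(table = tab, eigenvalue = 1.16, wilks = 0.46, f = 12.10,
       df = c(5, 52), accuracy_pct = 87.93,
       accuracy_by_group = c(juvenile = 87.5, mature = 88.5))
}

#' @return `weatherfish_study()`: cohort-level published summaries used as
#'   inputs downstream: sample sizes, gut-content mass and total-length
#'   means/SDs per group, fullness coefficients, ANOSIM R, overlap indices,
#'   and the data-archive DOI.
#' @rdname weatherfish-tables
#' @export
weatherfish_study <- function() {
  list(
    n = c(juvenile = 33, mature = 26),
    n_caught = 64, n_empty = 5,
    gut_mass_mean = c(juvenile = 73.98, mature = 142.65),
    gut_mass_sd   = c(juvenile = 67.04, mature = 100.62),
    tl_mean = c(juvenile = 11.4, mature = 17.3),
    tl_sd   = c(juvenile = 0.71, mature = 1.0),
    fc_mean = c(juvenile = 1.14, mature = 0.72),
    fc_sd   = c(juvenile = 1.11, mature = 0.70),
    anosim_r = 0.22,
    schoener = c(mean = 0.54, se = 0.029),
    horn     = c(mean = 0.75, se = 0.063),
    cluster_misclassified = c(juvenile = 7, mature = 5),
    dryad = "doi:10.5061/dryad.bvq83bk80"
  )
}
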