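#' Food-category to habitat-guild maps
#'
#' Guilds form a closed five-value set: `BE` (benthic), `EP` (epiphytic),
#' `EP_BE` (epiphytic/benthic), `PL` (planktonic, water column), `DE`
#' (detritus). The slash spelling `"EP/BE"` is accepted on input and
#' normalised to `EP_BE`.
#'
#' @param category character vector of food-category names.
#' @param guild character vector of guild codes, same length.
#' @return a `guild_map`: a data frame with columns `category` and `guild`.
#' @examples
#' guild_map(c("Copepoda", "Detritus"), c("PL", "DE"))
#' @export
guild_map <- function(category, guild) {
  category <- as.character(category)
  guild <- gsub("/", "_", as.character(guild), fixed = TRUE)
  if (length(category) != length(guild)) stop("category and guild lengths differ", call. = FALSE)
  if (anyDuplicated(category)) {
    stop("duplicate category in guild map: ",
         paste(unique(category[duplicated(category)]), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(guild), GUILD_LEVELS)
  if (length(bad)) {
    stop("unknown guild(s): ", paste(bad, collapse = ", "),
         "; valid guilds are ", paste(GUILD_LEVELS, collapse = ", "), call. = FALSE)
  }
  structure(data.frame(category = category, guild = guild,
                       stringsAsFactors = FALSE),
            class = c("guild_map", "data.frame"))
}

#' Read a guild map from CSV or YAML
#'
#' CSV files need `category` and `guild` columns (or exactly two columns,
#' taken in that order); YAML files map category names to guild codes.
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml` vs CSV).
#' @return a [guild_map()].
#' @export
read_guild_map <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lst <- yaml::read_yaml(path)
    return(guild_map(names(lst), unlist(lst, use.names = FALSE)))
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("category", "guild") %in% names(df))) {
    if (ncol(df) != 2) stop("guild map CSV needs 'category' and 'guild' columns", call. = FALSE)
    names(df) <- c("category", "guild")
  }
  guild_map(df$category, df$guild)
}

#' Collapse food categories into habitat guilds
#'
#' Sums biomass within guild for each fish; the per-fish total biomass is
#' conserved exactly. Categories missing from the map either raise an error
#' (`unmapped = "error"`, the default) or are pooled into an `"others"`
#' column (`unmapped = "others"`).
#'
#' @param x a [diet_table()].
#' @param map a [guild_map()].
#' @param unmapped how to treat categories absent from the map.
#' @return a `diet_table` whose categories are the guilds present (ordered
#'   BE, EP, EP_BE, PL, DE, then `others`).
#' @export
aggregate_by_guild <- function(x, map, unmapped = c("error", "others")) {
  stopifnot(inherits(x, "diet_table"), inherits(map, "guild_map"))
  unmapped <- match.arg(unmapped)
  cats <- diet_categories(x)
  g <- map$guild[match(cats, map$category)]
  if (anyNA(g)) {
    if (unmapped == "error") {
      stop("unmapped categor(ies): ", paste(cats[is.na(g)], collapse = ", "),
           call. = FALSE)
    }
    g[is.na(g)] <- "others"
  }
  g <- factor(g, levels = c(GUILD_LEVELS, "others"))
  m <- biomass_matrix(x)
  agg <- sapply(levels(g)[levels(g) %in% g],
                function(lv) rowSums(m[, g == lv, drop = FALSE]))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = nrow(m),
                                       dimnames = list(NULL, levels(g)[levels(g) %in% g]))
  out <- cbind(as.data.frame(x, check.names = FALSE)[META_COLUMNS],
               as.data.frame(agg, check.names = FALSE))
  rownames(out) <- NULL
  diet_table(out, categories = colnames(agg))
}
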