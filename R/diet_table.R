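#' Construct a per-fish diet table
#'
#' A diet table is a data frame with one row per fish, the metadata columns
#' `fish_id`, `group`, `tl_cm`, `body_mass_g`, `gut_mass_mg`, and one
#' non-negative biomass column (mg) per food category. Fish whose biomass
#' columns are all zero are retained but flagged as empty guts; every
#' analysis function excludes them from composition-based computations.
#'
#' @param df data frame holding the mandatory metadata columns plus the
#'   category columns.
#' @param categories character vector naming the food-category columns. By
#'   default every non-metadata column is treated as a category.
#' @return A `diet_table` (a validated data frame carrying a `categories`
#'   attribute).
#' @examples
#' df <- data.frame(fish_id = c("F1", "F2"), group = "juvenile",
#'                  tl_cm = c(10.2, 11.5), body_mass_g = c(5.4, 7.1),
#'                  gut_mass_mg = c(10, 8), Copepoda = c(6, 3),
#'                  Detritus = c(4, 5))
#' x <- diet_table(df)
#' is_empty_gut(x)
#' @export
diet_table <- function(df, categories = NULL) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, check.names = FALSE)
  missing_meta <- setdiff(META_COLUMNS, names(df))
  if (length(missing_meta)) {
    stop("missing mandatory column(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(categories)) categories <- setdiff(names(df), META_COLUMNS)
  if (!length(categories)) stop("no food-category columns found", call. = FALSE)
  if (anyDuplicated(categories)) {
    stop("category names must be unique: ",
         paste(unique(categories[duplicated(categories)]), collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(categories, names(df))
  if (length(absent)) {
    stop("category column(s) not present: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  df$fish_id <- as.character(df$fish_id)
  if (anyDuplicated(df$fish_id)) {
    stop("duplicate fish_id: ",
         paste(unique(df$fish_id[duplicated(df$fish_id)]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[categories])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-numeric or missing biomass values", call. = FALSE)
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative biomass for fish '%s', category '%s'",
                 df$fish_id[idx[1]], categories[idx[2]]), call. = FALSE)
  }
  for (col in c("tl_cm", "body_mass_g", "gut_mass_mg")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]]))) stop("non-numeric values in ", col, call. = FALSE)
  }
  if (any(df$tl_cm <= 0)) stop("tl_cm must be positive", call. = FALSE)
  if (any(df$body_mass_g <= 0)) stop("body_mass_g must be positive", call. = FALSE)
  if (any(df$gut_mass_mg < 0)) stop("gut_mass_mg must be non-negative", call. = FALSE)
  df[categories] <- m
  structure(df,
            categories = categories,
            class = unique(c("diet_table", class(df))))
}

#' Read and write diet tables
#'
#' CSV with a header row, canonical column names `fish_id`, `group`,
#' `tl_cm`, `body_mass_g`, `gut_mass_mg`, followed by one biomass column
#' (mg) per food category. `write_diet_table()` emits the same dialect, so
#' a read/write cycle is field-identical.
#'
#' @param path file path of a CSV diet table.
#' @param categories optional explicit list of category columns; by default
#'   every column after the metadata block is a category.
#' @rdname read_diet_table
#' @return `read_diet_table()` returns a validated [diet_table()];
#'   `write_diet_table()` returns `path` invisibly.
#' @export
read_diet_table <- function(path, categories = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  diet_table(df, categories = categories)
}

#' @param x a `diet_table`.
#' @rdname read_diet_table
#' @export
write_diet_table <- function(x, path) {
  stopifnot(inherits(x, "diet_table"))
  df <- as.data.frame(x, check.names = FALSE)
  df <- df[c(META_COLUMNS, diet_categories(x))]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Accessors for diet tables
#'
#' @param x a `diet_table`.
#' @return `diet_categories()` the category names; `biomass_matrix()` the
#'   fish-by-category biomass matrix (mg, rownames = `fish_id`);
#'   `is_empty_gut()` a logical vector flagging fish with no food remains.
#' @rdname diet_table-accessors
#' @export
diet_categories <- function(x) {
  stopifnot(inherits(x, "diet_table"))
  attr(x, "categories")
}

#' @rdname diet_table-accessors
#' @export
biomass_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x, check.names = FALSE)[diet_categories(x)])
  storage.mode(m) <- "double"
  rownames(m) <- x$fish_id
  m
}

#' @rdname diet_table-accessors
#' @export
is_empty_gut <- function(x) {
  rowSums(biomass_matrix(x)) == 0
}

#' Subset a diet table by row, preserving validation and attributes
#'
#' @param x a `diet_table`.
#' @param keep logical or integer row index of fish to keep.
#' @export
subset_fish <- function(x, keep) {
  stopifnot(inherits(x, "diet_table"))
  df <- as.data.frame(x, check.names = FALSE)[keep, , drop = FALSE]
  rownames(df) <- NULL
  diet_table(df, categories = diet_categories(x))
}

#' @export
print.diet_table <- function(x, ...) {
  cat(sprintf("diet_table: %d fish (%d empty guts), %d food categories, groups: %s\n",
              nrow(x), sum(is_empty_gut(x)), length(diet_categories(x)),
              paste(unique(x$group), collapse = ", ")))
  print(utils::head(as.data.frame(x, check.names = FALSE)), ...)
  if (nrow(x) > 6) cat(sprintf("... and %d more fish\n", nrow(x) - 6L))
  invisible(x)
}

# internal: biomass matrix for one group, empty guts dropped
group_matrix <- function(x, group = NULL, drop_empty = TRUE) {
  m <- biomass_matrix(x)
  if (!is.null(group)) {
    sel <- x$group == group
    if (!any(sel)) stop(sprintf("no fish in group '%s'", group), call. = FALSE)
    m <- m[sel, , drop = FALSE]
  }
  if (drop_empty) {
    keep <- rowSums(m) > 0
    if (!any(keep)) {
      stop(if (is.null(group)) "all guts are empty"
           else sprintf("group '%s' contains only empty guts", group),
           call. = FALSE)
    }
    m <- m[keep, , drop = FALSE]
  }
  m
}

#' Diet composition of a group
#'
#' Biomass proportions over food categories, excluding empty guts. Two
#' conventions are supported: `per_fish` (the mean over fish of each fish's
#' own proportion vector; the convention behind per-fish mean +/- SD summary
#' tables) and `pooled` (group-summed biomass, normalised).
#'
#' @param x a `diet_table`.
#' @param group group label to restrict to; `NULL` uses all fish.
#' @param basis `"per_fish"` (default) or `"pooled"`.
#' @return named numeric vector of proportions summing to 1.
#' @export
composition <- function(x, group = NULL, basis = c("per_fish", "pooled")) {
  basis <- match.arg(basis)
  m <- group_matrix(x, group)
  p <- switch(basis,
              per_fish = colMeans(m / rowSums(m)),
              pooled   = colSums(m) / sum(m))
  p
}
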