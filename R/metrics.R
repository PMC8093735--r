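#' Frequency of occurrence per food category
#'
#' Percentage of non-empty guts in a group that contain each category.
#'
#' @param x a [diet_table()].
#' @param group group label; `NULL` uses all fish.
#' @return named numeric vector of percentages in `[0, 100]`.
#' @export
percent_occurrence <- function(x, group = NULL) {
  m <- group_matrix(x, group)
  100 * colMeans(m > 0)
}

#' Diet importance summary (percentage biomass, occurrence, IRI)
#'
#' One row per food category: `%W` with its between-fish SD and coefficient
#' of variation, `%FO`, the Index of Relative Importance `IRI = %FO x %W`
#' (the two-term form for biomass-only data), and `%IRI` normalised to sum
#' to 100. Rows are sorted by decreasing `%IRI`.
#'
#' Under the `per_fish` basis `%W` is the mean of the per-fish biomass
#' percentages (with SD/CV across fish); under `pooled` it is the share of
#' the group-summed biomass, and SD/CV are not defined (`NA`). CV is
#' reported as `NA` when a category's mean is zero.
#'
#' @inheritParams composition
#' @return data frame with columns `category`, `pct_w`, `pct_w_sd`, `cv`,
#'   `pct_fo`, `iri`, `pct_iri`.
#' @export
diet_summary <- function(x, group = NULL, basis = c("per_fish", "pooled")) {
  basis <- match.arg(basis)
  m <- group_matrix(x, group)
  props <- 100 * m / rowSums(m)
  w_mean <- colMeans(props)
  w_sd <- apply(props, 2, sd)
  fo <- 100 * colMeans(m > 0)
  pct_w <- switch(basis, per_fish = w_mean, pooled = 100 * colSums(m) / sum(m))
  iri <- fo * pct_w
  out <- data.frame(
    category = colnames(m),
    pct_w = pct_w,
    pct_w_sd = if (basis == "per_fish") w_sd else NA_real_,
    cv = if (basis == "per_fish") ifelse(w_mean > 0, 100 * w_sd / w_mean, NA_real_)
         else NA_real_,
    pct_fo = fo,
    iri = iri,
    pct_iri = if (sum(iri) > 0) 100 * iri / sum(iri) else iri,
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$pct_iri), , drop = FALSE]
}

#' Gut fullness coefficient
#'
#' FC = 100 x gut-content mass / body mass (gut mass in mg is converted to
#' g internally). Empty guts have FC = 0.
#'
#' @inheritParams percent_occurrence
#' @return list with `per_fish` (fish_id, group, fc) and `summary` (per
#'   group mean, SD, n).
#' @export
fullness <- function(x, group = NULL) {
  stopifnot(inherits(x, "diet_table"))
  df <- as.data.frame(x, check.names = FALSE)
  if (!is.null(group)) df <- df[df$group == group, , drop = FALSE]
  if (!nrow(df)) stop(sprintf("no fish in group '%s'", group), call. = FALSE)
  fc <- 100 * (df$gut_mass_mg / 1000) / df$body_mass_g
  per_fish <- data.frame(fish_id = df$fish_id, group = df$group, fc = fc,
                         stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(per_fish$fc, per_fish$group), function(v) {
    data.frame(mean = mean(v), sd = sd(v), n = length(v))
  }))
  summ <- data.frame(group = rownames(summ), summ, row.names = NULL,
                     stringsAsFactors = FALSE)
  list(per_fish = per_fish, summary = summ)
}

#' Welch's unequal-variance t test
#'
#' Computes the Welch t statistic and Welch-Satterthwaite degrees of
#' freedom, either from two raw sample vectors or directly from printed
#' summary statistics (mean, SD, n per group) -- the latter is what makes
#' published comparisons reproducible from a table alone.
#'
#' @param x,y either raw numeric sample vectors (leave the remaining
#'   arguments `NULL`), or the two group means.
#' @param sd_x,n_x,sd_y,n_y summary statistics when `x` and `y` are means.
#' @return list of class `welch_t` with `statistic`, `df`, `p.value`,
#'   `estimate` (mean difference `x - y`). When both SDs are zero and the
#'   means are equal the statistic is undefined and reported as `NA`.
#' @examples
#' welch_t(73.98, 142.65, sd_x = 67.04, n_x = 33, sd_y = 100.62, n_y = 26)
#' @export
welch_t <- function(x, y, sd_x = NULL, n_x = NULL, sd_y = NULL, n_y = NULL) {
  if (is.null(sd_x)) {
    stopifnot(length(x) >= 2, length(y) >= 2)
    sd_x <- sd(x); n_x <- length(x); x <- mean(x)
    sd_y <- sd(y); n_y <- length(y); y <- mean(y)
  }
  stopifnot(n_x >= 2, n_y >= 2, sd_x >= 0, sd_y >= 0)
  vx <- sd_x^2 / n_x
  vy <- sd_y^2 / n_y
  se <- sqrt(vx + vy)
  if (se == 0) {
    t <- if (x == y) NA_real_ else sign(x - y) * Inf
    df <- NA_real_
  } else {
    t <- (x - y) / se
    df <- (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  }
  p <- if (is.na(t)) NA_real_ else 2 * pt(-abs(t), df)
  t <- unname(t); df <- unname(df); p <- unname(p)
  structure(list(statistic = t, df = df, p.value = p, estimate = unname(x - y)),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch two-sample t: t = %.4f, df = %.2f, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}
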