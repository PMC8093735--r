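#' Bray-Curtis dissimilarity between fish diets
#'
#' `d(x, y) = sum(|x_c - y_c|) / sum(x_c + y_c)`, in `[0, 1]`. By default
#' each fish's biomass row is converted to proportions first (diet
#' *composition*); `scale = "raw"` uses the biomass in mg. Empty guts are
#' excluded (their dissimilarity is undefined).
#'
#' @param x a [diet_table()] or a numeric matrix of non-negative rows.
#' @param scale `"proportions"` (default) or `"raw"`.
#' @return a [stats::dist] object labelled by `fish_id` (or rownames).
#' @export
bray_curtis <- function(x, scale = c("proportions", "raw")) {
  scale <- match.arg(scale)
  if (inherits(x, "diet_table")) {
    m <- group_matrix(x, NULL, drop_empty = TRUE)
  } else {
    m <- as.matrix(x)
    if (any(m < 0)) stop("negative values in input matrix", call. = FALSE)
    if (any(rowSums(m) == 0)) stop("all-zero rows: dissimilarity undefined", call. = FALSE)
  }
  if (nrow(m) < 2) stop("need at least 2 non-empty fish", call. = FALSE)
  if (scale == "proportions") m <- m / rowSums(m)
  vegan::vegdist(m, method = "bray")
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based R statistic,
#' `R = (mean between-group rank - mean within-group rank) / (N(N-1)/4)`,
#' with ties given average ranks, so `R` lies in `[-1, 1]` and is invariant
#' to any monotone transform of the dissimilarities. The p-value comes from
#' random relabelings of the samples; for two groups, when the number of
#' distinct relabelings `choose(N, n1)` does not exceed `n_perm` the full
#' enumeration is used instead (the identity split is counted, so p > 0).
#' With sampled permutations the add-one convention
#' `p = (hits + 1) / (n_perm + 1)` applies.
#'
#' @param d a dissimilarity ([stats::dist] or square matrix), e.g. from
#'   [bray_curtis()].
#' @param grouping group label per sample; at least two groups with at
#'   least two members each.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed, recorded in the result.
#' @return list of class `anosim_result`: `statistic` (R), `p.value`,
#'   `n_perm`, `method` ("exhaustive" or "sampled"), `seed`.
#' @export
anosim <- function(d, grouping, n_perm = 9999, seed = NULL) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  grouping <- as.character(grouping)
  if (length(grouping) != n) stop("grouping length must match the dissimilarity size", call. = FALSE)
  tab <- table(grouping)
  if (length(tab) < 2) stop("at least two groups are required", call. = FALSE)
  if (any(tab < 2)) stop("each group needs at least 2 members", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r <- rank(as.numeric(d))
  # pair index vectors in dist order (column-major lower triangle)
  pj <- rep(seq_len(n - 1), times = (n - 1):1)
  pi_ <- unlist(lapply(seq_len(n - 1), function(j) (j + 1):n))
  denom <- n * (n - 1) / 4
  r_stat <- function(g) {
    w <- g[pi_] == g[pj]
    (mean(r[!w]) - mean(r[w])) / denom
  }
  r_obs <- r_stat(grouping)
  exhaustive <- length(tab) == 2 && choose(n, tab[1]) <= n_perm
  if (exhaustive) {
    lv <- names(tab)
    sets <- combn(n, tab[[1]])
    perm <- apply(sets, 2, function(idx) {
      g <- rep(lv[2], n)
      g[idx] <- lv[1]
      r_stat(g)
    })
    p <- mean(perm >= r_obs - 1e-12)
    n_used <- ncol(sets)
  } else {
    perm <- vapply(seq_len(n_perm), function(k) r_stat(sample(grouping)),
                   numeric(1))
    p <- (sum(perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(statistic = r_obs, p.value = p, n_perm = n_used,
                 method = if (exhaustive) "exhaustive" else "sampled",
                 seed = seed),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d permutations)\n",
              x$statistic, x$p.value, x$method, x$n_perm))
  invisible(x)
}

#' Similarity percentage decomposition (SIMPER)
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-category contributions: for every between-group pair of fish the
#' category term is `|x_c - y_c| / sum(x + y)`; terms are averaged over all
#' pairs (reported x 100, like a percentage-scale dissimilarity), and the
#' per-category averages sum exactly to the mean between-group
#' dissimilarity. Rows are sorted by decreasing contribution with a
#' cumulative percentage.
#'
#' @param x a [diet_table()].
#' @param groups the two group labels; defaults to the groups present.
#' @inheritParams bray_curtis
#' @return data frame of class `simper_table` with columns `category`,
#'   `avg_dissim`, `contribution_pct`, `cumulative_pct`,
#'   `mean_<group>` per group (per-fish mean percentages, or mean raw
#'   biomass under `scale = "raw"`); attributes `overall_dissimilarity`
#'   (in `[0, 1]`) and `degenerate` (TRUE when the groups are identical so
#'   all contributions vanish).
#' @export
simper <- function(x, groups = NULL, scale = c("proportions", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(x, "diet_table"))
  if (is.null(groups)) groups <- unique(as.character(x$group))
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  sub <- subset_fish(x, x$group %in% groups & !is_empty_gut(x))
  m <- biomass_matrix(sub)
  if (scale == "proportions") m <- 100 * m / rowSums(m)
  m1 <- m[sub$group == groups[1], , drop = FALSE]
  m2 <- m[sub$group == groups[2], , drop = FALSE]
  if (!nrow(m1) || !nrow(m2)) stop("both groups need at least one non-empty fish", call. = FALSE)
  acc <- numeric(ncol(m))
  for (i in seq_len(nrow(m1))) {
    diffs <- abs(m2 - matrix(m1[i, ], nrow(m2), ncol(m2), byrow = TRUE))
    denom <- rowSums(m2) + sum(m1[i, ])
    acc <- acc + colSums(diffs / denom)
  }
  avg <- 100 * acc / (nrow(m1) * nrow(m2))
  total <- sum(avg)
  degenerate <- total == 0
  if (degenerate) {
    warning("groups are identical: all SIMPER contributions are zero")
    contrib <- rep(0, length(avg))
  } else {
    contrib <- 100 * avg / total
  }
  out <- data.frame(category = colnames(m), avg_dissim = avg,
                    contribution_pct = contrib, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[[paste0("mean_", groups[1])]] <- colMeans(m1)
  out[[paste0("mean_", groups[2])]] <- colMeans(m2)
  out <- out[order(-out$avg_dissim), , drop = FALSE]
  out$cumulative_pct <- cumsum(out$contribution_pct)
  out <- out[c("category", "avg_dissim", "contribution_pct", "cumulative_pct",
               paste0("mean_", groups))]
  rownames(out) <- NULL
  structure(out, overall_dissimilarity = total / 100, degenerate = degenerate,
            class = c("simper_table", "data.frame"))
}
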