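#' Arcsine square-root transform of a percentage
#'
#' `asin(sqrt(pct/100))`, in radians; the classical variance-stabilising
#' transform for percentage data entering discriminant analysis.
#'
#' @param pct numeric in `[0, 100]`.
#' @return radians in `[0, pi/2]`.
#' @export
arcsine_transform <- function(pct) {
  if (any(!is.finite(pct)) || any(pct < 0 | pct > 100)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  asin(sqrt(pct / 100))
}

#' Per-fish habitat-guild diet profiles
#'
#' Collapses a diet table into per-fish guild percentages (share of each
#' fish's gut-content biomass per guild), the input for clustering and
#' discriminant analysis. Empty guts are excluded by default.
#'
#' @param x a [diet_table()].
#' @param map a [guild_map()]; defaults to the packaged weatherfish map.
#' @param transform `"none"` (clustering convention) or `"arcsine"`
#'   (discriminant-analysis convention).
#' @param exclude guild columns to drop after computing the percentages
#'   (default drops the residual `"others"` bucket, keeping the five named
#'   food types); percentages are computed before dropping, so rows of the
#'   full profile sum to 100.
#' @param include_empty keep empty-gut fish as all-zero profiles.
#' @return list with `profiles` (fish-by-guild matrix, rownames =
#'   `fish_id`) and `labels` (group per fish).
#' @export
guild_profiles <- function(x, map = weatherfish_guild_map(),
                           transform = c("none", "arcsine"),
                           exclude = "others", include_empty = FALSE) {
  transform <- match.arg(transform)
  agg <- aggregate_by_guild(x, map, unmapped = "others")
  keep <- if (include_empty) rep(TRUE, nrow(agg)) else !is_empty_gut(agg)
  agg <- subset_fish(agg, keep)
  m <- biomass_matrix(agg)
  tot <- rowSums(m)
  pct <- 100 * m / ifelse(tot > 0, tot, 1)
  pct <- pct[, setdiff(colnames(pct), exclude), drop = FALSE]
  if (transform == "arcsine") pct <- arcsine_transform(pct)
  list(profiles = pct, labels = as.character(agg$group))
}

# brute-force-verifiable Ward linkage: hclust(ward.D) on squared Euclidean
# distances gives merge heights equal to twice the within-cluster variance
# increment; halve them to report the increments themselves.
ward_linkage <- function(profiles) {
  hc <- hclust(as.dist(dist(profiles)^2), method = "ward.D")
  hc$height <- hc$height / 2
  hc
}

#' Ward clustering of diet profiles with two-cluster cross-tabulation
#'
#' Agglomerative clustering under Ward's minimum-variance criterion on
#' Euclidean distances; merge heights are reported as within-cluster
#' variance (sum-of-squares) increments. The dendrogram is cut into two
#' clusters, each cluster is labelled by its majority group, and the
#' fish falling outside their group's majority cluster are counted.
#'
#' @param profiles numeric matrix, one row per fish (e.g.
#'   `guild_profiles()$profiles`); rownames are fish ids.
#' @param labels group label per fish.
#' @return list of class `cluster_result`: `hclust` (heights = variance
#'   increments), `assignment`, `crosstab` (cluster x group),
#'   `cluster_labels` (majority group per cluster), `misclassified`
#'   (per-group counts), `degenerate` (all profiles identical).
#' @export
ward_two_clusters <- function(profiles, labels) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least 2 fish", call. = FALSE)
  if (!is.null(rownames(profiles)) && anyDuplicated(rownames(profiles))) {
    stop("duplicate fish ids in profiles", call. = FALSE)
  }
  stopifnot(length(labels) == nrow(profiles))
  hc <- ward_linkage(profiles)
  degenerate <- max(hc$height) < 1e-12
  cl <- cutree(hc, k = 2)
  crosstab <- table(cluster = cl, group = labels)
  cluster_labels <- colnames(crosstab)[apply(crosstab, 1, which.max)]
  names(cluster_labels) <- rownames(crosstab)
  predicted <- cluster_labels[as.character(cl)]
  mis <- tapply(predicted != labels, labels, sum)
  structure(list(hclust = hc, assignment = cl, crosstab = crosstab,
                 cluster_labels = cluster_labels,
                 misclassified = mis, degenerate = degenerate),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Ward two-cluster solution",
      if (x$degenerate) "(degenerate: identical profiles)" else "", "\n")
  print(x$crosstab)
  cat("misclassified under majority labelling:",
      paste(sprintf("%s = %d", names(x$misclassified), x$misclassified),
            collapse = ", "), "\n")
  invisible(x)
}

#' Wilks' lambda and its F approximation for a two-group discriminant axis
#'
#' For two groups there is a single canonical root `lambda1` and
#' `Lambda = 1 / (1 + lambda1)`; the exact F statistic is
#' `F = ((1 - Lambda) / Lambda) * (df2 / df1)` with `df1 = p` variables and
#' `df2 = N - p - 1`.
#'
#' @param eigenvalue the canonical eigenvalue `lambda1`.
#' @rdname wilks
#' @export
wilks_from_eigenvalue <- function(eigenvalue) {
  stopifnot(eigenvalue >= 0)
  1 / (1 + eigenvalue)
}

#' @param wilks Wilks' lambda in (0, 1].
#' @param df1,df2 numerator (`p`) and denominator (`N - p - 1`) degrees of
#'   freedom.
#' @return `wilks_f()`: list with `f`, `df1`, `df2`, `p.value`.
#' @rdname wilks
#' @export
wilks_f <- function(wilks, df1, df2) {
  stopifnot(wilks > 0, wilks <= 1)
  f <- (1 - wilks) / wilks * (df2 / df1)
  list(f = f, df1 = df1, df2 = df2, p.value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Two-group canonical discriminant analysis
#'
#' Canonical variate analysis for two groups: the single eigenvalue of the
#' between- vs within-group scatter problem, Wilks' lambda with its exact F
#' test, structure correlations of each variable with the canonical scores,
#' per-variable F-to-remove statistics (`(Lambda_without_v / Lambda - 1) *
#' (N - p - 1)` on 1 and `N - p - 1` df), and a linear classifier with
#' group-proportional priors evaluated by resubstitution.
#'
#' @param profiles numeric matrix of predictor variables (one row per
#'   fish), typically arcsine-transformed guild percentages.
#' @param labels group label per fish; exactly two groups, each with at
#'   least 2 members, and `N > p + 1`.
#' @param priors `"proportional"` (default) or `"equal"` classifier priors.
#' @return list of class `dfa_result` with `eigenvalue`, `wilks`, `f`,
#'   `df`, `p.value`, `structure_corr`, `partial` (per-variable
#'   `wilks_without`, `f_remove`, `p`), `scores` (canonical scores,
#'   oriented so the first group level has the larger mean),
#'   `classification` (2x2 resubstitution table), `accuracy_pct`, and
#'   `accuracy_by_group`.
#' @export
dfa_two_group <- function(profiles, labels, priors = c("proportional", "equal")) {
  priors <- match.arg(priors)
  X <- as.matrix(profiles)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  g <- factor(labels)
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  n_k <- table(g)
  if (any(n_k < 2)) stop("each group needs at least 2 members", call. = FALSE)
  N <- nrow(X)
  p <- ncol(X)
  if (N <= p + 1) stop("need more observations than variables + 1", call. = FALSE)
  lv <- levels(g)
  mu1 <- colMeans(X[g == lv[1], , drop = FALSE])
  mu2 <- colMeans(X[g == lv[2], , drop = FALSE])
  within_sscp <- function(M, grp) {
    Reduce(`+`, lapply(levels(grp), function(l) {
      Z <- scale(M[grp == l, , drop = FALSE], scale = FALSE)
      crossprod(Z)
    }))
  }
  W <- within_sscp(X, g)
  Winv_d <- tryCatch(solve(W, mu1 - mu2), error = function(e) {
    stop("within-group scatter is singular; remove constant or collinear variables",
         call. = FALSE)
  })
  lambda1 <- as.numeric(n_k[1] * n_k[2] / N * crossprod(mu1 - mu2, Winv_d))
  wilks <- 1 / (1 + lambda1)
  ftest <- wilks_f(wilks, p, N - p - 1)
  scores <- as.numeric(X %*% Winv_d)
  if (mean(scores[g == lv[1]]) < mean(scores[g == lv[2]])) scores <- -scores
  structure_corr <- as.numeric(cor(X, scores))
  names(structure_corr) <- colnames(X)
  partial <- do.call(rbind, lapply(seq_len(p), function(v) {
    Xv <- X[, -v, drop = FALSE]
    Wv <- within_sscp(Xv, g)
    dv <- colMeans(Xv[g == lv[1], , drop = FALSE]) -
      colMeans(Xv[g == lv[2], , drop = FALSE])
    lam_v <- as.numeric(n_k[1] * n_k[2] / N * crossprod(dv, solve(Wv, dv)))
    wilks_wo <- 1 / (1 + lam_v)
    f_rem <- (wilks_wo / wilks - 1) * (N - p - 1)
    data.frame(variable = colnames(X)[v], wilks_without = wilks_wo,
               f_remove = f_rem,
               p = pf(f_rem, 1, N - p - 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(partial) <- NULL
  # linear classifier on the pooled within-group covariance
  S_inv_mu <- function(mu) solve(W / (N - 2), mu)
  prior <- if (priors == "proportional") as.numeric(n_k) / N else c(0.5, 0.5)
  disc <- sapply(1:2, function(k) {
    mu <- if (k == 1) mu1 else mu2
    a <- S_inv_mu(mu)
    X %*% a - 0.5 * sum(mu * a) + log(prior[k])
  })
  pred <- factor(lv[max.col(disc)], levels = lv)
  classification <- table(observed = g, predicted = pred)
  acc_by <- 100 * diag(classification) / rowSums(classification)
  structure(list(eigenvalue = lambda1, wilks = wilks, f = ftest$f,
                 df = c(ftest$df1, ftest$df2), p.value = ftest$p.value,
                 structure_corr = structure_corr, partial = partial,
                 scores = scores, classification = classification,
                 accuracy_pct = 100 * sum(diag(classification)) / N,
                 accuracy_by_group = acc_by, priors = priors),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("two-group discriminant analysis: eigenvalue = %.4f, Wilks' lambda = %.4f\n",
              x$eigenvalue, x$wilks))
  cat(sprintf("F(%d, %d) = %.4f, p = %.4g; resubstitution accuracy = %.2f%%\n",
              x$df[1], x$df[2], x$f, x$p.value, x$accuracy_pct))
  tab <- data.frame(structure_corr = round(x$structure_corr, 3),
                    wilks_without = round(x$partial$wilks_without, 3),
                    f_remove = round(x$partial$f_remove, 2),
                    p = signif(x$partial$p, 3))
  print(tab)
  invisible(x)
}
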