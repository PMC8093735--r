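# x * log(x) with the 0 log 0 := 0 convention (natural log)
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Trophic niche breadth indices
#'
#' Given a diet composition vector, computes category richness S, Simpson
#' dominance `D = sum(p^2)`, Levins breadth `B = 1/D`, Shannon diversity
#' `H = -sum(p log p)`, Levins evenness `Ba = (B - 1)/(S - 1)` and Pielou
#' evenness `J = H / log S`. `Ba` and `J` are undefined (`NA`) for S = 1.
#'
#' The logarithm base only rescales `H`; `J` is base-invariant. The default
#' is the natural log, the base consistent with published Shannon values of
#' 2.3-2.5 for diets of about 25 categories (base-10 values could not
#' exceed `log10(25) = 1.4`).
#'
#' @param p non-negative composition vector; normalised internally to sum
#'   to 1. An all-zero vector is an error.
#' @param log_base base of the logarithm for `H` (and the `J` denominator).
#' @return list of class `niche_breadth` with fields `s`, `d`, `b`, `h`,
#'   `ba`, `j`.
#' @examples
#' niche_breadth(c(0.7, 0.3))
#' @export
niche_breadth <- function(p, log_base = exp(1)) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0)) stop("composition must be finite and non-negative", call. = FALSE)
  if (sum(p) == 0) stop("all-zero composition vector", call. = FALSE)
  p <- p / sum(p)
  s <- sum(p > 0)
  d <- sum(p^2)
  b <- 1 / d
  h <- -sum(xlogx(p)) / log(log_base)
  ba <- if (s > 1) (b - 1) / (s - 1) else NA_real_
  j <- if (s > 1) h / (log(s) / log(log_base)) else NA_real_
  structure(list(s = s, d = d, b = b, h = h, ba = ba, j = j),
            class = "niche_breadth")
}

#' @export
print.niche_breadth <- function(x, ...) {
  cat(sprintf("niche breadth: S = %d, D = %.4f, B = %.4f, H = %.4f, Ba = %.4f, J = %.4f\n",
              x$s, x$d, x$b, x$h, x$ba, x$j))
  invisible(x)
}

#' Delete-one jackknife estimate of a statistic
#'
#' Pseudovalues `theta_i = n * theta_hat - (n - 1) * theta_(-i)`; the
#' jackknife mean is their average and the standard error is
#' `sd(pseudovalues) / sqrt(n)`. For a diet table the resampling unit is
#' the individual fish (empty guts are not resampled since no statistic
#' uses them); for a plain numeric vector it is the element.
#'
#' @param x a numeric vector or a [diet_table()].
#' @param statistic function mapping `x` (with one unit removed) to a
#'   single number.
#' @param ... passed on to `statistic`.
#' @return list of class `jackknife_estimate` with `theta_hat`,
#'   `jack_mean`, `se`, `n`, `pseudovalues`.
#' @examples
#' jackknife(c(1, 2, 3), mean)  # se equals sd/sqrt(n) for the mean
#' @export
jackknife <- function(x, statistic, ...) UseMethod("jackknife")

jackknife_core <- function(theta_hat, loo, n) {
  pseudo <- n * theta_hat - (n - 1) * loo
  structure(list(theta_hat = theta_hat, jack_mean = mean(pseudo),
                 se = sd(pseudo) / sqrt(n), n = n, pseudovalues = pseudo),
            class = "jackknife_estimate")
}

#' @export
jackknife.default <- function(x, statistic, ...) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 observations to jackknife", call. = FALSE)
  theta_hat <- statistic(x, ...)
  loo <- vapply(seq_len(n), function(i) statistic(x[-i], ...), numeric(1))
  jackknife_core(theta_hat, loo, n)
}

#' @export
jackknife.diet_table <- function(x, statistic, ...) {
  units <- which(!is_empty_gut(x))
  n <- length(units)
  if (n < 2) stop("need at least 2 non-empty fish to jackknife", call. = FALSE)
  theta_hat <- statistic(x, ...)
  loo <- vapply(units, function(i) {
    tryCatch(statistic(subset_fish(x, setdiff(seq_len(nrow(x)), i)), ...),
             error = function(e) {
               stop(sprintf("statistic undefined after removing fish '%s': %s",
                            x$fish_id[i], conditionMessage(e)), call. = FALSE)
             })
  }, numeric(1))
  jackknife_core(theta_hat, loo, n)
}

#' @export
print.jackknife_estimate <- function(x, ...) {
  cat(sprintf("jackknife (n = %d): estimate = %.4f, jackknife mean = %.4f, se = %.4f\n",
              x$n, x$theta_hat, x$jack_mean, x$se))
  invisible(x)
}

schoener_alpha <- function(px, py) 1 - 0.5 * sum(abs(px - py))

horn_ro <- function(px, py) {
  (sum(xlogx(px + py)) - sum(xlogx(px)) - sum(xlogx(py))) / (2 * log(2))
}

#' Diet overlap between two groups (Schoener and Horn indices)
#'
#' Schoener `alpha = 1 - 0.5 * sum(|p_x - p_y|)` and Horn's
#' information-theoretic `Ro`; both equal 1 for identical compositions and
#' 0 for disjoint ones. Uncertainty is obtained by jackknifing individual
#' fish from the combined two-group sample, recomputing both group
#' compositions at each deletion.
#'
#' @param x a [diet_table()].
#' @param group_x,group_y the two group labels.
#' @inheritParams composition
#' @param jackknife logical; compute delete-one-fish estimates and SEs
#'   (requires at least 2 non-empty fish per group).
#' @return list of class `overlap_result`: `schoener` and `horn`, each a
#'   list with `estimate` and (optionally) `jack_mean`, `se`.
#' @export
diet_overlap <- function(x, group_x, group_y, basis = c("per_fish", "pooled"),
                         jackknife = TRUE) {
  basis <- match.arg(basis)
  stopifnot(inherits(x, "diet_table"))
  both <- subset_fish(x, x$group %in% c(group_x, group_y) & !is_empty_gut(x))
  pair_stat <- function(tab) {
    px <- composition(tab, group_x, basis)
    py <- composition(tab, group_y, basis)
    c(schoener = schoener_alpha(px, py), horn = horn_ro(px, py))
  }
  est <- pair_stat(both)
  out <- list(schoener = list(estimate = est[["schoener"]]),
              horn = list(estimate = est[["horn"]]))
  if (jackknife) {
    if (sum(both$group == group_x) < 2 || sum(both$group == group_y) < 2) {
      stop("jackknife requires at least 2 non-empty fish in each group", call. = FALSE)
    }
    n <- nrow(both)
    loo <- t(vapply(seq_len(n),
                    function(i) pair_stat(subset_fish(both, -i)),
                    numeric(2)))
    for (nm in c("schoener", "horn")) {
      jk <- jackknife_core(est[[nm]], loo[, nm], n)
      out[[nm]]$jack_mean <- jk$jack_mean
      out[[nm]]$se <- jk$se
    }
  }
  structure(c(out, list(groups = c(group_x, group_y), basis = basis)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  fmt <- function(o, name) {
    if (!is.null(o$se))
      sprintf("%s = %.4f (jackknife mean %.4f +/- %.4f se)", name, o$estimate,
              o$jack_mean, o$se)
    else sprintf("%s = %.4f", name, o$estimate)
  }
  cat(sprintf("diet overlap %s vs %s (%s basis):\n  %s\n  %s\n",
              x$groups[1], x$groups[2], x$basis,
              fmt(x$schoener, "Schoener alpha"), fmt(x$horn, "Horn Ro")))
  invisible(x)
}

#' Permutation test for a between-group difference in a diversity index
#'
#' The observed statistic is the absolute difference of the chosen niche
#' index between the two groups' compositions. The null distribution comes
#' from random reassignments of (non-empty) fish to groups with sizes
#' preserved; `p = (number of permutations >= observed + 1) / (n_perm + 1)`.
#' Permutations on which the index is undefined (e.g. evenness of a
#' single-category split) are redrawn, up to a cap of `10 * n_perm` draws.
#'
#' @param x a [diet_table()].
#' @param index one of `"s"`, `"d"`, `"b"`, `"h"`, `"ba"`, `"j"`.
#' @param groups character vector of the two group labels; defaults to the
#'   two groups present.
#' @param n_perm number of permutations (>= 99).
#' @inheritParams composition
#' @param log_base logarithm base for Shannon-based indices.
#' @param seed optional RNG seed.
#' @return list of class `perm_test`: `statistic` (observed absolute
#'   difference), `p.value`, `n_perm`, `index`.
#' @export
diversity_permutation_test <- function(x, index = c("d", "b", "h", "ba", "j", "s"),
                                       groups = NULL, n_perm = 9999,
                                       basis = c("per_fish", "pooled"),
                                       log_base = exp(1), seed = NULL) {
  index <- match.arg(index)
  basis <- match.arg(basis)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(groups)) groups <- unique(as.character(x$group))
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  sub <- subset_fish(x, x$group %in% groups & !is_empty_gut(x))
  m <- biomass_matrix(sub)
  lab <- as.character(sub$group)
  P <- m / rowSums(m)
  comp_rows <- function(rows) {
    switch(basis,
           per_fish = colMeans(P[rows, , drop = FALSE]),
           pooled = colSums(m[rows, , drop = FALSE]) / sum(m[rows, , drop = FALSE]))
  }
  idx_val <- function(rows) {
    nb <- niche_breadth(comp_rows(rows), log_base = log_base)
    as.numeric(nb[[index]])
  }
  is_g1 <- lab == groups[1]
  obs <- abs(idx_val(which(is_g1)) - idx_val(which(!is_g1)))
  if (is.na(obs)) stop("index undefined for the observed split", call. = FALSE)
  n1 <- sum(is_g1)
  n <- length(lab)
  perm <- numeric(n_perm)
  filled <- 0L
  draws <- 0L
  cap <- 10L * n_perm
  while (filled < n_perm && draws < cap) {
    draws <- draws + 1L
    g1 <- sample.int(n, n1)
    v <- abs(idx_val(g1) - idx_val(setdiff(seq_len(n), g1)))
    if (!is.na(v)) {
      filled <- filled + 1L
      perm[filled] <- v
    }
  }
  if (filled < n_perm) {
    warning(sprintf("only %d of %d valid permutations obtained (cap reached)",
                    filled, n_perm))
    perm <- perm[seq_len(filled)]
  }
  p <- (sum(perm >= obs - 1e-12) + 1) / (length(perm) + 1)
  structure(list(statistic = obs, p.value = p, n_perm = length(perm),
                 index = index, groups = groups, basis = basis),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test (%s, %d perms): |diff| = %.4f, p = %.4g\n",
              x$index, x$n_perm, x$statistic, x$p.value))
  invisible(x)
}
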