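# Build a diet table in code from a biomass matrix (rows = fish).
make_diet <- function(biomass, group = "A", fish_id = NULL,
                      tl = 10, body = 5) {
  biomass <- as.matrix(biomass)
  if (is.null(colnames(biomass))) {
    colnames(biomass) <- paste0("cat", seq_len(ncol(biomass)))
  }
  n <- nrow(biomass)
  df <- data.frame(
    fish_id = fish_id %||% sprintf("F%02d", seq_len(n)),
    group = rep_len(group, n),
    tl_cm = rep_len(tl, n),
    body_mass_g = rep_len(body, n),
    gut_mass_mg = rowSums(biomass),
    check.names = FALSE)
  df <- cbind(df, as.data.frame(biomass, check.names = FALSE))
  diet_table(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-group Dirichlet cohort with full presence, for multivariate tests.
make_dirichlet_cohort <- function(n1, n2, mean1, mean2, kappa = 10,
                                  seed = NULL) {
  k <- length(mean1)
  spec <- cohort_spec(
    n_per_group = c(A = n1, B = n2),
    mean_composition = rbind(A = mean1 / sum(mean1), B = mean2 / sum(mean2)),
    occurrence_prob = matrix(1, 2, k, dimnames = list(c("A", "B"), NULL)),
    concentration = kappa,
    gut_mass_meanlog = c(3, 3), gut_mass_sdlog = c(0.5, 0.5),
    empty_prob = 0)
  simulate_cohort(spec, seed = seed)
}

# Greedy brute-force Ward clustering: at each step merge the pair of
# clusters with the smallest within-cluster variance increment
# dSS = nA*nB/(nA+nB) * ||mA - mB||^2. Independent oracle for linkage
# heights.
brute_force_ward_heights <- function(X) {
  X <- as.matrix(X)
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        ma <- colMeans(X[clusters[[a]], , drop = FALSE])
        mb <- colMeans(X[clusters[[b]], , drop = FALSE])
        na <- length(clusters[[a]]); nb <- length(clusters[[b]])
        dss <- na * nb / (na + nb) * sum((ma - mb)^2)
        if (dss < best[1]) best <- c(dss, a, b)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}
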