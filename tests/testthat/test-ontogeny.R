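test_that("the arcsine square-root transform hits its anchor points", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(100), pi / 2)
  expect_equal(arcsine_transform(50), pi / 4)
  expect_error(arcsine_transform(101), "0, 100")
  expect_error(arcsine_transform(-1), "0, 100")
})

test_that("guild profiles are percentages of each fish's gut biomass", {
  gm <- guild_map(c("Copepoda", "Asellus", "Junk"), c("PL", "EP_BE", "BE"))
  x <- make_diet(cbind(Copepoda = c(3, 0), Asellus = c(1, 2), Junk = c(0, 2)),
                 group = c("A", "B"))
  gp <- guild_profiles(x, gm, exclude = character())
  expect_equal(unname(rowSums(gp$profiles)), c(100, 100))
  expect_equal(unname(gp$profiles[1, "PL"]), 75)
  # excluded columns are dropped after the percentages are computed
  gp2 <- guild_profiles(x, gm, exclude = "BE")
  expect_equal(unname(gp2$profiles[2, "EP_BE"]), 50)
})

test_that("Ward linkage heights equal brute-force variance increments", {
  set.seed(15)
  for (n in c(4, 6, 7)) {
    X <- matrix(rnorm(n * 3), n)
    cl <- ward_two_clusters(X, rep(c("A", "B"), length.out = n))
    expect_equal(cl$hclust$height, brute_force_ward_heights(X),
                 tolerance = 1e-10)
    expect_false(is.unsorted(cl$hclust$height))
  }
})

test_that("two-cluster cut recovers well-separated groups and handles ties", {
  set.seed(16)
  X <- rbind(matrix(rnorm(10 * 2, mean = 0, sd = 0.1), 10),
             matrix(rnorm(8 * 2, mean = 5, sd = 0.1), 8))
  labels <- rep(c("juvenile", "mature"), c(10, 8))
  cl <- ward_two_clusters(X, labels)
  expect_equal(unname(cl$misclassified), c(0L, 0L), ignore_attr = TRUE)
  expect_equal(sort(unname(rowSums(cl$crosstab))), c(8, 10))

  # identical profiles: degenerate but deterministic
  Xc <- matrix(1, 5, 2)
  c1 <- ward_two_clusters(Xc, rep(c("A", "B"), length.out = 5))
  c2 <- ward_two_clusters(Xc, rep(c("A", "B"), length.out = 5))
  expect_true(c1$degenerate)
  expect_identical(c1$assignment, c2$assignment)

  rownames(X) <- c(paste0("F", 1:17), "F1")
  expect_error(ward_two_clusters(X, labels), "duplicate")
})

test_that("two-group discriminant analysis satisfies its algebraic identities", {
  set.seed(17)
  n1 <- 20; n2 <- 15; p <- 4
  X <- rbind(matrix(rnorm(n1 * p), n1), matrix(rnorm(n2 * p, 0.8), n2))
  g <- rep(c("A", "B"), c(n1, n2))
  res <- dfa_two_group(X, g)

  expect_equal(res$wilks * (1 + res$eigenvalue), 1, tolerance = 1e-10)
  expect_true(all(abs(res$structure_corr) <= 1))
  expect_equal(res$df, c(p, n1 + n2 - p - 1))

  # F from Wilks equals the two-sample Hotelling T2 F
  S <- ((n1 - 1) * cov(X[g == "A", ]) + (n2 - 1) * cov(X[g == "B", ])) /
    (n1 + n2 - 2)
  d <- colMeans(X[g == "A", ]) - colMeans(X[g == "B", ])
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(S, d))
  F_hotelling <- T2 * (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p)
  expect_equal(res$f, F_hotelling, tolerance = 1e-8)

  # null case: identical group means
  X0 <- rbind(matrix(rnorm(200), 50), matrix(rnorm(200), 50))
  res0 <- dfa_two_group(X0, rep(c("A", "B"), each = 50))
  expect_lt(res0$eigenvalue, 0.2)
  expect_gt(res0$wilks, 0.85)
})

test_that("the discriminant classifier matches an independent LDA and separates distant groups", {
  set.seed(18)
  n <- 60; p <- 3
  delta <- 6 # Mahalanobis distance between the group means
  X <- rbind(matrix(rnorm(n * p), n), sweep(matrix(rnorm(n * p), n), 2,
                                            rep(delta / sqrt(p), p), `+`))
  g <- rep(c("A", "B"), each = n)
  res <- dfa_two_group(X, g)
  # expected misclassification ~ pnorm(-delta/2) = 0.13%
  expect_gt(res$accuracy_pct, 99)

  ref <- MASS::lda(X, grouping = factor(g))
  pred <- predict(ref)$class
  expect_equal(res$accuracy_pct, 100 * mean(pred == g), tolerance = 1e-10)

  # a constant column makes the within scatter singular
  expect_error(dfa_two_group(cbind(X, 1), g), "singular")
})

test_that("F-to-remove follows the partial-Wilks formula", {
  set.seed(19)
  X <- matrix(rnorm(40 * 3), 40)
  X[21:40, 1] <- X[21:40, 1] + 2
  g <- rep(c("A", "B"), each = 20)
  res <- dfa_two_group(X, g)
  n <- 40; p <- 3
  for (v in 1:p) {
    manual <- (res$partial$wilks_without[v] / res$wilks - 1) * (n - p - 1)
    expect_equal(res$partial$f_remove[v], manual, tolerance = 1e-10)
  }
  # removing the informative variable hurts most
  expect_equal(which.max(res$partial$f_remove), 1L)
})

test_that("Wilks helpers reconstruct published-scale statistics", {
  lam <- wilks_from_eigenvalue(1.16)
  expect_equal(lam, 1 / 2.16, tolerance = 1e-12)
  ft <- wilks_f(lam, 5, 52)
  expect_equal(ft$f, 1.16 * 52 / 5, tolerance = 1e-12)
  expect_lt(ft$p.value, 0.001)
})
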