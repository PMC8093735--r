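test_that("niche breadth indices match direct formula evaluation", {
  u <- niche_breadth(rep(0.25, 4))
  expect_equal(u$d, 0.25)
  expect_equal(u$b, 4)
  expect_equal(u$ba, 1)
  expect_equal(u$j, 1)
  expect_equal(u$h, log(4))

  one <- niche_breadth(c(1, 0, 0))
  expect_equal(one$s, 1)
  expect_equal(one$d, 1)
  expect_equal(one$b, 1)
  expect_equal(one$h, 0)
  expect_true(is.na(one$ba) && is.na(one$j))

  p <- niche_breadth(c(0.7, 0.3))
  expect_equal(p$d, 0.58)
  expect_equal(p$b, 1 / 0.58, tolerance = 1e-10)
  expect_equal(p$h, -(0.7 * log(0.7) + 0.3 * log(0.3)), tolerance = 1e-12)
  expect_equal(round(p$h, 4), 0.6109)

  expect_error(niche_breadth(c(0, 0)), "all-zero")
  # B = 1/D holds exactly for any single composition
  set.seed(2)
  for (i in 1:10) {
    q <- runif(6)
    nb <- niche_breadth(q)
    expect_equal(nb$b * nb$d, 1, tolerance = 1e-12)
  }
})

test_that("evenness and Horn overlap are invariant to the logarithm base", {
  set.seed(4)
  q <- runif(8); q <- q / sum(q)
  expect_equal(niche_breadth(q, log_base = exp(1))$j,
               niche_breadth(q, log_base = 10)$j, tolerance = 1e-12)
  x <- make_dirichlet_cohort(4, 4, runif(5) + 0.2, runif(5) + 0.2, seed = 4)
  # Horn Ro is defined through ratios of logs, so the base cancels by
  # construction; check it stays in [0, 1] on random cohorts
  ov <- diet_overlap(x, "A", "B", jackknife = FALSE)
  expect_gte(ov$horn$estimate, 0)
  expect_lte(ov$horn$estimate, 1)
})

test_that("jackknife pseudovalues reproduce closed forms and brute force", {
  jk <- jackknife(c(1, 2, 3), mean)
  expect_equal(jk$jack_mean, 2)
  expect_equal(jk$se, sd(c(1, 2, 3)) / sqrt(3), tolerance = 1e-12)

  const <- jackknife(c(4, 1, 7, 2), function(v) 42)
  expect_equal(const$se, 0)

  # delete-one over fish for a nonlinear statistic, against brute force
  set.seed(5)
  x <- make_dirichlet_cohort(4, 4, c(3, 2, 1), c(1, 2, 3), seed = 5)
  xa <- subset_fish(x, x$group == "A")
  stat <- function(tab) sum(composition(tab, basis = "per_fish")^2)
  jk2 <- jackknife(xa, stat)
  n <- nrow(xa)
  loo <- sapply(seq_len(n), function(i) stat(subset_fish(xa, -i)))
  pseudo <- n * stat(xa) - (n - 1) * loo
  expect_equal(jk2$jack_mean, mean(pseudo), tolerance = 1e-12)
  expect_equal(jk2$se, sd(pseudo) / sqrt(n), tolerance = 1e-12)

  # an empty-gut fish is not a resampling unit
  x_empty <- make_diet(rbind(c(1, 2), c(2, 1), c(0, 0)))
  expect_equal(jackknife(x_empty, stat)$n, 2)
})

test_that("Schoener and Horn overlap behave at the identity, disjoint and hand-worked cases", {
  ident <- make_diet(rbind(c(2, 2), c(1, 1)), group = c("A", "B"))
  ov <- diet_overlap(ident, "A", "B", jackknife = FALSE)
  expect_equal(ov$schoener$estimate, 1)
  expect_equal(ov$horn$estimate, 1, tolerance = 1e-12)

  disj <- make_diet(rbind(c(1, 0), c(0, 1)), group = c("A", "B"))
  ovd <- diet_overlap(disj, "A", "B", jackknife = FALSE)
  expect_equal(ovd$schoener$estimate, 0)
  expect_equal(ovd$horn$estimate, 0, tolerance = 1e-12)

  # p = (0.5, 0.5) vs q = (1, 0): alpha = 0.5, Ro = 0.6887
  mix <- make_diet(rbind(c(5, 5), c(1, 0)), group = c("A", "B"))
  ovm <- diet_overlap(mix, "A", "B", jackknife = FALSE)
  expect_equal(ovm$schoener$estimate, 0.5)
  ro_hand <- (1.5 * log(1.5) + 0.5 * log(0.5) - 2 * 0.5 * log(0.5)) /
    (2 * log(2))
  expect_equal(ovm$horn$estimate, ro_hand, tolerance = 1e-12)
  expect_equal(round(ovm$horn$estimate, 4), 0.6887)
})

test_that("Schoener alpha satisfies the triangle-like bound on random compositions", {
  set.seed(6)
  sa <- function(p, q) 1 - 0.5 * sum(abs(p - q))
  for (i in 1:50) {
    p <- runif(6); p <- p / sum(p)
    q <- runif(6); q <- q / sum(q)
    z <- runif(6); z <- z / sum(z)
    expect_gte(sa(p, z) - (sa(p, q) + sa(q, z) - 1), -1e-12)
  }
})

test_that("overlap jackknife deletes fish from the combined sample", {
  x <- make_dirichlet_cohort(5, 4, c(3, 1, 1), c(1, 1, 3), seed = 9)
  ov <- diet_overlap(x, "A", "B")
  # brute-force the Schoener pseudovalues
  n <- nrow(x)
  loo <- sapply(seq_len(n), function(i) {
    sub <- subset_fish(x, -i)
    px <- composition(sub, "A"); py <- composition(sub, "B")
    1 - 0.5 * sum(abs(px - py))
  })
  pseudo <- n * ov$schoener$estimate - (n - 1) * loo
  expect_equal(ov$schoener$jack_mean, mean(pseudo), tolerance = 1e-12)
  expect_equal(ov$schoener$se, sd(pseudo) / sqrt(n), tolerance = 1e-12)
})

test_that("the diversity permutation test is calibrated and detects real differences", {
  # identical groups (same fish duplicated): the difference is 0, p ~ 1
  m <- rbind(c(5, 3, 2), c(4, 4, 2))
  x0 <- make_diet(rbind(m, m), group = rep(c("A", "B"), each = 2))
  p0 <- diversity_permutation_test(x0, "b", n_perm = 199, seed = 1)
  expect_gt(p0$p.value, 0.5)

  # strongly different dominance structure: small p
  x1 <- make_dirichlet_cohort(12, 12, c(20, 1, 1, 1, 1), c(1, 1, 1, 1, 20),
                              kappa = 50, seed = 2)
  # make group B much more even than A
  xB <- make_diet(matrix(rep(c(1, 1, 1, 1, 1), 12), 12, byrow = TRUE),
                  group = "B", fish_id = sprintf("B%02d", 1:12))
  xA <- subset_fish(x1, x1$group == "A")
  x2 <- diet_table(rbind(as.data.frame(xA), as.data.frame(xB)))
  p1 <- diversity_permutation_test(x2, "d", n_perm = 499, seed = 3)
  expect_lt(p1$p.value, 0.05)

  # the add-one convention bounds p away from 0
  expect_gte(p1$p.value, 1 / 500)
  expect_lte(p0$p.value, 1)
  expect_error(diversity_permutation_test(x0, "b", n_perm = 10), "at least 99")
})
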