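test_that("diet tables validate, flag empty guts, and round-trip through CSV", {
  df <- data.frame(fish_id = c("F1", "F2", "F3"), group = "juvenile",
                   tl_cm = c(10, 11, 12), body_mass_g = c(5, 6, 7),
                   gut_mass_mg = c(10, 5, 0),
                   Copepoda = c(6, 5, 0), Detritus = c(4, 0, 0))
  x <- diet_table(df)
  expect_equal(unname(is_empty_gut(x)), c(FALSE, FALSE, TRUE))
  expect_equal(diet_categories(x), c("Copepoda", "Detritus"))

  path <- withr::local_tempfile(fileext = ".csv")
  write_diet_table(x, path)
  y <- read_diet_table(path)
  expect_equal(as.data.frame(y), as.data.frame(x))
  expect_equal(diet_categories(y), diet_categories(x))

  df_bad <- df; df_bad$Copepoda[2] <- -1
  expect_error(diet_table(df_bad), "negative biomass.*F2.*Copepoda")
  expect_error(diet_table(df[setdiff(names(df), "group")]),
               "missing mandatory column")
  df_dup <- df; df_dup$fish_id <- c("F1", "F1", "F3")
  expect_error(diet_table(df_dup), "duplicate fish_id")
})

test_that("guild maps enforce the closed five-guild set", {
  gm <- guild_map("Copepoda", "PL")
  expect_s3_class(gm, "guild_map")
  expect_equal(gm$guild, "PL")
  expect_error(guild_map("Copepoda", "XX"), "BE, EP, EP_BE, PL, DE")
  expect_error(guild_map(c("Copepoda", "Copepoda"), c("PL", "PL")),
               "duplicate category")
  expect_equal(guild_map("Asellus", "EP/BE")$guild, "EP_BE")

  # CSV and YAML readers agree
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("category,guild", "Copepoda,PL", "Detritus,DE"), csv)
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("Copepoda: PL", "Detritus: DE"), yml)
  expect_equal(read_guild_map(csv), read_guild_map(yml))
})

test_that("the packaged weatherfish map covers the 25 published categories", {
  t1 <- weatherfish_table1()
  expect_equal(nrow(t1), 25)
  gm <- weatherfish_guild_map()
  # "others" is deliberately unmapped; guild counts follow the published
  # habitat column
  expect_equal(nrow(gm), 24)
  expect_equal(as.list(table(gm$guild)),
               list(BE = 5L, DE = 1L, EP = 9L, EP_BE = 4L, PL = 5L))
})

test_that("guild aggregation sums within guild and conserves per-fish totals", {
  gm <- guild_map(c("Copepoda", "Chydoridae", "Asellus"),
                  c("PL", "PL", "EP_BE"))
  x <- make_diet(cbind(Copepoda = c(2, 1), Chydoridae = c(3, 0),
                       Asellus = c(0, 4)))
  agg <- aggregate_by_guild(x, gm)
  expect_equal(unname(biomass_matrix(agg)[1, "PL"]), 5)
  expect_equal(rowSums(biomass_matrix(agg)), rowSums(biomass_matrix(x)))

  # single-category table: aggregation is the identity on totals
  x1 <- make_diet(cbind(Copepoda = c(7, 2)))
  agg1 <- aggregate_by_guild(x1, gm)
  expect_equal(unname(rowSums(biomass_matrix(agg1))), c(7, 2))

  # unmapped category: error in strict mode, pooled under "others" otherwise
  x2 <- make_diet(cbind(Copepoda = 1, Mystery = 1))
  expect_error(aggregate_by_guild(x2, gm), "unmapped.*Mystery")
  agg2 <- aggregate_by_guild(x2, gm, unmapped = "others")
  expect_equal(unname(biomass_matrix(agg2)[1, "others"]), 1)

  # equal mass in all 25 published categories: per-guild biomass counts
  # the categories in each guild (others bucket gets the unmapped one)
  t1 <- weatherfish_table1()
  eq <- matrix(1, 1, 25, dimnames = list(NULL, t1$category))
  x25 <- make_diet(eq)
  agg25 <- aggregate_by_guild(x25, weatherfish_guild_map(), unmapped = "others")
  expect_equal(as.list(biomass_matrix(agg25)[1, ]),
               list(BE = 5, EP = 9, EP_BE = 4, PL = 5, DE = 1, others = 1))
})

test_that("composition supports per-fish and pooled bases", {
  x1 <- make_diet(rbind(c(4, 6)))
  expect_equal(unname(composition(x1, basis = "per_fish")), c(0.4, 0.6))
  expect_equal(unname(composition(x1, basis = "pooled")), c(0.4, 0.6))

  x2 <- make_diet(rbind(c(1, 0), c(0, 1)))
  expect_equal(unname(composition(x2, basis = "per_fish")), c(0.5, 0.5))
  expect_equal(unname(composition(x2, basis = "pooled")), c(0.5, 0.5))

  x3 <- make_diet(rbind(c(9, 1), c(1, 1)))
  expect_equal(unname(composition(x3, basis = "per_fish")), c(0.7, 0.3))
  expect_equal(unname(composition(x3, basis = "pooled")), c(10, 2) / 12)

  # empty guts are excluded; a group of only empty guts is an error
  x4 <- make_diet(rbind(c(4, 6), c(0, 0)))
  expect_equal(unname(composition(x4)), c(0.4, 0.6))
  x5 <- make_diet(rbind(c(0, 0)))
  expect_error(composition(x5), "empty")
})

test_that("per-fish and pooled compositions coincide for proportional diets", {
  set.seed(1)
  base <- runif(6)
  m <- outer(c(1, 3, 0.5, 10), base) # same proportions, different totals
  x <- make_diet(m)
  expect_equal(composition(x, basis = "per_fish"),
               composition(x, basis = "pooled"), tolerance = 1e-12)
})
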