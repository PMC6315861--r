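test_that("class counts are recovered exactly from an expanded presence", {
  cc <- load_class_counts()
  ex <- expand_class_counts(cc$counts)
  tab <- class_count_table(ex$presence, ex$catalog)
  expect_equal(tab$total, unname(cc$printed_totals[tab$cultivar]))
  # per-class recount for one cultivar
  gam <- tab[tab$cultivar == "Gambiaka", ]
  expect_equal(gam$`amino acids`, 120)
  expect_equal(gam$total, 430)
  expect_true(gam$is_max_total)
  expect_true(tab$is_min_total[tab$cultivar == "Njavara"])
  expect_equal(tab$total[tab$cultivar == "Njavara"], 378)
})

test_that("class count edge cases: empty presence and single class", {
  pres <- tibble::tibble(cultivar = c("cv1", "cv2"), a = FALSE, b = FALSE)
  catalog <- make_catalog(c("a", "b"), class = "lipids")
  tab <- class_count_table(pres, catalog)
  expect_equal(tab$lipids, c(0, 0))
  expect_equal(tab$total, c(0, 0))

  pres2 <- all_present(c("cv1", "cv2"), c("a", "b"))
  tab2 <- class_count_table(pres2, catalog)
  expect_equal(tab2$total, tab2$lipids)

  pres3 <- all_present("cv1", "mystery")
  expect_error(class_count_table(pres3, catalog), "mystery")
})

test_that("lipid share statistics follow the documented conventions", {
  tab <- tibble::tibble(
    cultivar = c("x", "y"),
    lipids = c(30, 50),
    total = c(100, 100)
  )
  lf <- lipid_fraction(tab)
  expect_equal(lf$mean_pct, 40)
  expect_equal(lf$headline_pct, 40)

  one <- tibble::tibble(cultivar = "x", lipids = 7, total = 7)
  expect_equal(lipid_fraction(one)$mean_pct, 100)

  withz <- tibble::tibble(cultivar = c("x", "z"), lipids = c(50, 0),
                          total = c(100, 0))
  expect_warning(lfz <- lipid_fraction(withz), "z")
  expect_equal(lfz$n_cultivars, 1)
})

test_that("discriminator breakdown counts distinct metabolites per class", {
  disc <- load_discriminators()
  bd <- discriminator_breakdown(disc, load_discriminator_catalog())
  expect_equal(sum(bd$n), 71)
  expect_equal(bd$n[bd$chemical_class == "lipids"], 33)
  # distinct-metabolite total matches n_distinct of the entry list
  expect_equal(sum(bd$n),
               dplyr::n_distinct(resolve_metabolite(disc$metabolite)))

  empty <- tibble::tibble(metabolite = character(), cultivar = character())
  bd0 <- discriminator_breakdown(empty, load_discriminator_catalog())
  expect_true(all(bd0$n == 0))
})

test_that("ordination explains structure it should and respects symmetry", {
  # rank-1 matrix: first component carries all variance
  u <- c(1, 2, 3, 4)
  v <- exp(seq(-1, 1, length.out = 30))
  s <- make_ab(outer(v, u))
  ord <- ordination_summary(s)
  expect_equal(ord$variance$var_pct[1], 100, tolerance = 1e-8)

  # duplicated cultivars land on identical scores
  m <- matrix(exp(rnorm(60)), nrow = 20)
  s2 <- make_ab(cbind(m, m[, 2]),
                cultivars = c("c1", "c2", "c3", "c2bis"))
  ord2 <- ordination_summary(s2)
  expect_equal(unlist(ord2$scores[ord2$scores$cultivar == "c2", -1]),
               unlist(ord2$scores[ord2$scores$cultivar == "c2bis", -1]),
               tolerance = 1e-9)

  # missing values are rejected with advice
  s3 <- make_ab(matrix(c(1, NA, 2, 3, 4, 5), nrow = 2))
  expect_error(ordination_summary(s3), "impute")
})

test_that("ordination percentages are non-increasing and permutation-invariant", {
  set.seed(31)
  s <- generate_bran(sim_config(n_metabolites = 100, dropout = 0, seed = 31))
  scaled <- median_scale(s$abundance)
  ord <- ordination_summary(scaled)
  expect_true(all(diff(ord$variance$var_pct) <= 1e-9))
  expect_lt(ord$variance$var_pct[1], 100)
  expect_equal(sum(ord$variance$var_pct), 100, tolerance = 1e-9)

  perm <- scaled[sample(nrow(scaled)), ]
  ordp <- ordination_summary(perm)
  expect_equal(ordp$variance$var_pct, ord$variance$var_pct, tolerance = 1e-9)

  g <- glance(ord)
  expect_equal(g$pc1_pct, ord$variance$var_pct[1])
  expect_equal(nrow(tidy(ord)), 17)
})

test_that("plot helpers return ggplot objects", {
  disc <- load_discriminators()
  expect_s3_class(plot_discriminators(disc), "ggplot")
  catd <- load_discriminator_catalog()
  pres <- all_present(unique(disc$cultivar), catd$metabolite)
  rec <- enrich(disc, catd, pres)
  expect_s3_class(plot_pes_heatmap(rec), "ggplot")
  sim <- generate_bran(sim_config(n_metabolites = 40, n_pathways = 10,
                                  dropout = 0, seed = 2))
  ord <- ordination_summary(median_scale(sim$abundance))
  expect_s3_class(autoplot(ord), "ggplot")
})
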