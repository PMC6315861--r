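test_that("median scaling normalizes each metabolite's median to 1", {
  ab <- make_ab(matrix(c(2, 4, 6), nrow = 1))
  expect_equal(unlist(median_scale(ab)[-1], use.names = FALSE),
               c(0.5, 1, 1.5))
  ab1 <- make_ab(matrix(c(1, 1, 1), nrow = 1))
  expect_equal(unlist(median_scale(ab1)[-1], use.names = FALSE), c(1, 1, 1))
  # missing cells are excluded from the median and preserved
  abm <- make_ab(matrix(c(1, 3, NA, 5, 7), nrow = 1))
  expect_equal(unlist(median_scale(abm)[-1], use.names = FALSE),
               c(0.25, 0.75, NA, 1.25, 1.75))
})

test_that("median scaling rejects all-missing rows and is idempotent", {
  abm <- make_ab(matrix(c(NA, NA, 1, 2), nrow = 2, byrow = TRUE),
                 metabolites = c("ghost", "real"))
  expect_error(median_scale(abm), "ghost")

  sim <- generate_bran(sim_config(n_metabolites = 80, dropout = 0.05, seed = 3))
  s1 <- median_scale(sim$abundance)
  s2 <- median_scale(s1)
  expect_equal(as.matrix(s2[-1]), as.matrix(s1[-1]), tolerance = 1e-9)
  meds <- apply(as.matrix(s1[-1]), 1, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(1, nrow(s1)), tolerance = 1e-9)
})

test_that("imputation policies behave as documented", {
  s <- make_ab(matrix(c(0.5, NA, 1.5), nrow = 1))
  filled <- impute_missing(s, "min_impute")
  expect_equal(unlist(filled[-1], use.names = FALSE), c(0.5, 0.5, 1.5))
  expect_equal(impute_missing(s, "skip"), s)
  full <- make_ab(matrix(1:4, nrow = 2))
  expect_equal(impute_missing(full, "min_impute"), full)
})

test_that("z-scores match hand arithmetic under the sample-sd convention", {
  s <- make_ab(matrix(c(1, 1, 1, 1, 3), nrow = 1))
  z <- compute_zscores(s)
  expect_equal(z$mu, rep(1.4, 5))
  expect_equal(z$sigma, rep(0.8944272, 5), tolerance = 1e-6)
  expect_equal(z$z, c(-0.4472136, -0.4472136, -0.4472136, -0.4472136,
                      1.7888544), tolerance = 1e-6)
  # population convention rescales by sqrt((c-1)/c)
  zp <- compute_zscores(s, sigma = "population")
  expect_equal(zp$z, z$z * sqrt(5 / 4), tolerance = 1e-9)
})

test_that("constant rows are flagged with z = 0 and short rows excluded", {
  s <- make_ab(matrix(c(1, 1, 1, 1,
                        1, 2, NA, NA), nrow = 2, byrow = TRUE),
               metabolites = c("flat", "sparse"))
  expect_warning(z <- compute_zscores(s, min_cultivars = 3), "sparse")
  expect_setequal(unique(z$metabolite), "flat")
  expect_true(all(z$constant))
  expect_true(all(z$z == 0))
  expect_equal(attr(z, "excluded"), "sparse")
})

test_that("z-score rows are standardized and obey the single-extreme bound", {
  set.seed(19)
  for (rep in 1:200) {
    s <- make_ab(matrix(exp(rnorm(17, 0, 0.5)), nrow = 1))
    z <- compute_zscores(s)
    expect_equal(mean(z$z), 0, tolerance = 1e-9)
    expect_equal(sd(z$z), 1, tolerance = 1e-9)
    expect_lte(max(abs(z$z)), 16 / sqrt(17) + 1e-9)
  }
})

test_that("z-scores are invariant to per-metabolite positive rescaling", {
  set.seed(5)
  m <- matrix(exp(rnorm(40)), nrow = 4)
  z1 <- compute_zscores(make_ab(m))
  z2 <- compute_zscores(make_ab(m * c(10, 0.01, 3, 1000)))
  expect_equal(z1$z, z2$z, tolerance = 1e-9)
})

test_that("discriminator detection uses a strict threshold and is monotone", {
  s <- make_ab(matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1), nrow = 3),
               metabolites = c("a", "b", "c"))
  z <- compute_zscores(s)
  expect_equal(nrow(find_discriminators(z)), 0)

  set.seed(23)
  s2 <- make_ab(matrix(exp(rnorm(17 * 30, 0, 0.35)), nrow = 30))
  z2 <- compute_zscores(median_scale(s2))
  thresholds <- c(1, 1.5, 2, 2.5, 3)
  sizes <- vapply(thresholds,
                  function(t) nrow(find_discriminators(z2, t)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # strictness: a cell exactly at the threshold is not flagged
  zt <- tibble::tibble(metabolite = "x", cultivar = "c1", z = 2)
  expect_equal(nrow(find_discriminators(zt, 2)), 0)
  zt$z <- 2.0001
  d <- find_discriminators(zt, 2)
  expect_equal(nrow(d), 1)
  expect_equal(d$direction, "high")
  expect_error(find_discriminators(zt, 0), "positive")
})
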