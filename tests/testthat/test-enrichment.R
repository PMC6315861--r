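test_that("the enrichment score reproduces hand-computed values", {
  expect_equal(pes_score(2, 17, 2, 417), 24.5294117647, tolerance = 1e-9)
  expect_equal(pes_score(5, 5, 10, 10), 1)
  expect_equal(pes_score(0, 4, 3, 100), 0)
  # scale-free: common factors on (k, n) and (m, N) cancel
  expect_equal(pes_score(2, 10, 4, 50), pes_score(6, 20, 12, 100))
  expect_error(pes_score(1, 0, 1, 10), "m must")
  expect_error(pes_score(0, 3, 0, 10), "n must")
})

test_that("enrich handles empty and single-record cases", {
  catalog <- make_catalog(c("a", "b"), pathway = c("p1", "p2"))
  pres <- all_present(c("cv1", "cv2"), c("a", "b"))
  empty <- tibble::tibble(metabolite = character(), cultivar = character())
  expect_equal(nrow(enrich(empty, catalog, pres)), 0)

  one <- tibble::tibble(metabolite = "a", cultivar = "cv1")
  rec <- enrich(one, catalog, pres)
  expect_equal(nrow(rec), 1)
  # one discriminator in a one-metabolite pathway with n = 1: score = N/m
  expect_equal(rec$score, rec$N / rec$m)

  unknown <- tibble::tibble(metabolite = "zzz", cultivar = "cv1")
  expect_error(enrich(unknown, catalog, pres), "zzz")
})

test_that("enrich agrees with a brute-force recount on random instances", {
  set.seed(41)
  for (rep in 1:30) {
    n_met <- sample(10:50, 1)
    n_pw <- sample(2:10, 1)
    n_cv <- sample(2:5, 1)
    mets <- sprintf("m%02d", seq_len(n_met))
    cvs <- sprintf("cv%d", seq_len(n_cv))
    catalog <- tibble::tibble(
      metabolite = mets,
      chemical_class = "lipids",
      pathway = sample(sprintf("p%02d", seq_len(n_pw)), n_met, replace = TRUE)
    )
    pres <- tibble::tibble(cultivar = cvs)
    for (m in mets) pres[[m]] <- runif(n_cv) < 0.8
    n_d <- sample(1:8, 1)
    disc <- tibble::tibble(
      metabolite = sample(mets, n_d, replace = TRUE),
      cultivar = sample(cvs, n_d, replace = TRUE)
    )
    for (scope in c("per_cultivar", "global")) {
      got <- enrich(disc, catalog, pres, scope = scope) |>
        dplyr::select(cultivar, pathway, k, m, n, N, score) |>
        dplyr::arrange(cultivar, pathway)
      want <- brute_enrich(disc, catalog, pres, scope) |>
        dplyr::arrange(cultivar, pathway)
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
  }
})

test_that("counts are conserved within a scope unit", {
  set.seed(17)
  mets <- sprintf("m%02d", 1:40)
  catalog <- tibble::tibble(
    metabolite = mets, chemical_class = "lipids",
    pathway = sample(sprintf("p%d", 1:6), 40, replace = TRUE)
  )
  pres <- all_present(c("cv1", "cv2", "cv3"), mets)
  disc <- tibble::tibble(metabolite = sample(mets, 10),
                         cultivar = sample(c("cv1", "cv2", "cv3"), 10,
                                           replace = TRUE))
  rec <- enrich(disc, catalog, pres, keep_zero = TRUE)
  by_unit <- dplyr::summarise(dplyr::group_by(rec, cultivar),
                              sk = sum(k), sm = sum(m),
                              n = n[1], N = N[1])
  expect_equal(by_unit$sk, by_unit$n)
  expect_equal(by_unit$sm, by_unit$N)
})

test_that("select_enriched drops unit scores and sorts by score", {
  rec <- tibble::tibble(
    cultivar = "cv1", pathway = c("a", "b", "c"),
    k = c(2, 1, 1), m = c(4, 5, 10), n = 5, N = c(31, 5, 2),
    score = c(24.8, 1.0, 0.4), p_hyper = NA_real_
  )
  out <- select_enriched(rec)
  expect_equal(out$score, c(24.8, 0.4))
  expect_equal(nrow(select_enriched(rec[rec$k == 0, ])), 0)
})

test_that("the hypergeometric tail is a sane context statistic", {
  catalog <- make_catalog(c("a", "b", "c", "d"), pathway = c("p1", "p1", "p2", "p2"))
  pres <- all_present("cv1", c("a", "b", "c", "d"))
  disc <- tibble::tibble(metabolite = c("a", "b"), cultivar = "cv1")
  rec <- enrich(disc, catalog, pres)
  # both discriminators in p1 out of 2 drawn from 4: p = choose(2,2)/choose(4,2)
  expect_equal(rec$p_hyper[rec$pathway == "p1"], 1 / 6, tolerance = 1e-12)
})
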