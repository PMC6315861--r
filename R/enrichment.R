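#' Pathway enrichment score
#'
#' Fold enrichment of discriminating metabolites in a metabolic pathway:
#' `PES = (k/m) / (n/N)`, where `k` is the number of discriminating
#' metabolites in the pathway, `m` the total metabolites identified in the
#' pathway, `n` the total discriminating metabolites in scope and `N` the
#' total identified metabolites in scope. A score above 1 means the pathway
#' holds more discriminating metabolites than expected from the dataset-wide
#' rate; 0 iff `k = 0`.
#'
#' @param k,m,n,N Integer counts (vectorized; recycled to a common length).
#' @return Numeric vector of scores.
#' @export
#' @examples
#' pes_score(2, 17, 2, 417) # about 24.5
pes_score <- function(k, m, n, N) {
  v <- vctrs_recycle(k, m, n, N)
  k <- v[[1]]; m <- v[[2]]; n <- v[[3]]; N <- v[[4]]
  if (any(m < 1)) abort("m must be >= 1 (empty pathway)")
  if (any(n < 1)) abort("n must be >= 1 (no discriminating metabolites in scope)")
  if (any(N < 1)) abort("N must be >= 1")
  if (any(k < 0 | k > pmin(m, n))) abort("k must satisfy 0 <= k <= min(m, n)")
  (k * N) / (m * n)
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  lapply(xs, rep_len, length.out = len)
}

#' Per-cultivar or global pathway enrichment of a discriminator set
#'
#' Joins a discriminator set with an annotation catalog and a detection
#' matrix and computes [pes_score()] for every pathway holding at least one
#' discriminating metabolite. Under `scope = "per_cultivar"` (the reporting
#' convention for a per-cultivar enrichment figure), `k` and `n` count the
#' cultivar's own distinct discriminating metabolites and `m` and `N` its
#' detected metabolites; under `scope = "global"`, metabolites are pooled
#' (distinct) over all cultivars and `m`, `N` come from the union of detected
#' metabolites. A hypergeometric tail probability is attached for context but
#' takes no part in selection. `k` counts distinct metabolites, never
#' (metabolite, cultivar) pairs.
#'
#' Metabolite names on both sides are resolved through the synonym table, and
#' a cultivar's discriminating metabolites are always counted as detected in
#' it. Detected metabolites absent from the catalog are ignored (they cannot
#' be placed in a pathway).
#'
#' @param disc Discriminator tibble (`metabolite`, `cultivar` columns).
#' @param catalog Annotation catalog (`metabolite`, `chemical_class`,
#'   `pathway`).
#' @param presence Detection matrix from [presence_matrix()].
#' @param scope `"per_cultivar"` (default) or `"global"`.
#' @param keep_zero Keep pathways with `k = 0`? Default `FALSE` (they carry a
#'   score of 0 and are omitted from reports); set `TRUE` to check count
#'   conservation (`sum(k) = n`, `sum(m) = N` within a scope unit).
#' @param synonyms Synonym table for name resolution.
#' @return A tibble of class `bran_pes` with columns `cultivar` (or
#'   `"global"`), `pathway`, `chemical_class`, `k`, `m`, `n`, `N`, `score`,
#'   `p_hyper`.
#' @export
enrich <- function(disc, catalog, presence,
                   scope = c("per_cultivar", "global"),
                   keep_zero = FALSE, synonyms = bran_synonyms()) {
  scope <- match.arg(scope)
  catalog <- validate_catalog(catalog, extra_classes = unique(catalog$chemical_class))
  key <- catalog %>%
    mutate(metabolite = resolve_metabolite(.data$metabolite, synonyms)) %>%
    distinct(.data$metabolite, .keep_all = TRUE)
  disc <- as_tibble(disc) %>%
    mutate(metabolite = resolve_metabolite(.data$metabolite, synonyms))
  unknown <- setdiff(unique(disc$metabolite), key$metabolite)
  if (length(unknown) > 0) {
    abort(paste0(
      "discriminator metabolite(s) missing from the catalog: ",
      paste(unknown, collapse = ", ")
    ))
  }
  det <- presence_long(presence) %>%
    mutate(metabolite = resolve_metabolite(.data$metabolite, synonyms))

  units <- if (scope == "global") "global" else sort(unique(disc$cultivar))
  res <- purrr::map_dfr(units, function(u) {
    if (scope == "global") {
      d_met <- unique(disc$metabolite)
      p_met <- unique(det$metabolite)
    } else {
      d_met <- unique(disc$metabolite[disc$cultivar == u])
      p_met <- det$metabolite[det$cultivar == u]
    }
    p_met <- union(p_met, d_met)            # discriminators count as detected
    p_met <- intersect(p_met, key$metabolite) # only annotated metabolites
    N <- length(p_met)
    n <- length(d_met)
    if (n == 0) return(NULL)
    tab <- key %>%
      filter(.data$metabolite %in% p_met) %>%
      group_by(.data$pathway, .data$chemical_class) %>%
      summarise(
        m = dplyr::n(),
        k = sum(.data$metabolite %in% d_met),
        .groups = "drop"
      ) %>%
      mutate(
        cultivar = u, n = .env$n, N = .env$N,
        score = (.data$k * .data$N) / (.data$m * .data$n),
        p_hyper = phyper(.data$k - 1, .data$m, .data$N - .data$m, .data$n,
                         lower.tail = FALSE)
      )
    tab
  })
  if (nrow(res) == 0) {
    res <- tibble(cultivar = character(), pathway = character(),
                  chemical_class = character(), k = integer(), m = integer(),
                  n = integer(), N = integer(), score = double(),
                  p_hyper = double())
  }
  if (!keep_zero) res <- filter(res, .data$k >= 1)
  res <- res %>%
    select("cultivar", "pathway", "chemical_class", "k", "m", "n", "N",
           "score", "p_hyper") %>%
    arrange(.data$cultivar, dplyr::desc(.data$score))
  class(res) <- c("bran_pes", class(res))
  res
}

#' Select enriched pathway records
#'
#' Keeps records whose score departs from 1 (a pathway scoring exactly 1 has
#' precisely the dataset-wide share of discriminating metabolites and is not
#' reportable) and at least one discriminating metabolite, sorted by
#' decreasing score.
#'
#' @param records `bran_pes` tibble from [enrich()].
#' @param tol Tolerance for "score equals 1" (default 1e-12).
#' @return Filtered, sorted tibble.
#' @export
select_enriched <- function(records, tol = 1e-12) {
  as_tibble(records) %>%
    filter(.data$k >= 1, abs(.data$score - 1) > tol) %>%
    arrange(dplyr::desc(.data$score))
}

#' Export a PES matrix
#'
#' Writes the pathway-by-cultivar score matrix as TSV alongside a long-format
#' companion with the k/m/n/N bookkeeping.
#'
#' @param records `bran_pes` tibble.
#' @param path Output TSV path for the matrix; the long file gains a
#'   `_long.tsv` suffix.
#' @return `path`, invisibly.
#' @export
write_pes <- function(records, path) {
  wide <- as_tibble(records) %>%
    select("pathway", "cultivar", "score") %>%
    tidyr::pivot_wider(names_from = "cultivar", values_from = "score")
  readr::write_tsv(wide, path)
  readr::write_tsv(as_tibble(records), sub("\\.tsv$", "_long.tsv", path))
  invisible(path)
}
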