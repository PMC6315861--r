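#' Per-cultivar class-count table
#'
#' Counts, for every cultivar, the detected metabolites in each chemical
#' class — the bookkeeping behind a "metabolites with confirmed annotation
#' per cultivar" summary table. Cultivars with the largest and smallest
#' totals are flagged (ties all flagged).
#'
#' @param presence Detection matrix from [presence_matrix()].
#' @param catalog Annotation catalog covering every detected metabolite.
#' @param synonyms Synonym table for name resolution.
#' @return A tibble of class `bran_class_counts`: one row per cultivar, one
#'   column per chemical class present in the catalog, plus `total`,
#'   `is_max_total`, `is_min_total`.
#' @export
class_count_table <- function(presence, catalog, synonyms = bran_synonyms()) {
  key <- as_tibble(catalog) %>%
    mutate(metabolite = resolve_metabolite(.data$metabolite, synonyms)) %>%
    distinct(.data$metabolite, .data$chemical_class)
  det <- presence_long(presence) %>%
    mutate(metabolite = resolve_metabolite(.data$metabolite, synonyms))
  unann <- setdiff(unique(det$metabolite), key$metabolite)
  if (length(unann) > 0) {
    abort(paste0(
      "detected metabolite(s) without catalog annotation: ",
      paste(head(unann, 5), collapse = ", "),
      if (length(unann) > 5) ", ..." else ""
    ))
  }
  seen <- unique(key$chemical_class)
  classes <- c(intersect(bran_classes(), seen), setdiff(seen, bran_classes()))
  counts <- det %>%
    left_join(key, by = "metabolite") %>%
    count(.data$cultivar, .data$chemical_class) %>%
    tidyr::pivot_wider(names_from = "chemical_class", values_from = "n",
                       values_fill = 0L)
  for (cl in setdiff(classes, names(counts))) counts[[cl]] <- 0L
  # preserve input cultivar order, include all-zero cultivars
  counts <- tibble(cultivar = presence$cultivar) %>%
    left_join(counts, by = "cultivar") %>%
    mutate(dplyr::across(-"cultivar", ~ tidyr::replace_na(.x, 0L))) %>%
    select("cultivar", dplyr::all_of(classes))
  counts$total <- rowSums(counts[classes])
  counts$is_max_total <- counts$total == max(counts$total)
  counts$is_min_total <- counts$total == min(counts$total)
  class(counts) <- c("bran_class_counts", class(counts))
  counts
}

round_half_up <- function(x) floor(x + 0.5)

#' Mean lipid share of the metabolome
#'
#' Share of each cultivar's detected metabolome that belongs to a given
#' chemical class (lipids by default), averaged across cultivars. The
#' headline figure is the mean of per-cultivar percentages rounded half-up to
#' an integer; the pooled ratio (total class count over total count) is
#' exported alongside since both conventions are in common use.
#'
#' @param counts `bran_class_counts` tibble from [class_count_table()] (any
#'   tibble with the class column and `total` works).
#' @param class Chemical-class column to summarize; default `"lipids"`.
#' @return A one-row tibble: `mean_pct`, `pooled_pct`, `headline_pct`,
#'   `n_cultivars`.
#' @export
lipid_fraction <- function(counts, class = "lipids") {
  if (!class %in% names(counts)) {
    abort(paste0("no '", class, "' column in the class-count table"))
  }
  keep <- counts$total > 0
  if (any(!keep)) {
    warn(paste0(
      "excluding cultivar(s) with zero detected metabolites: ",
      paste(counts$cultivar[!keep], collapse = ", ")
    ))
  }
  shares <- 100 * counts[[class]][keep] / counts$total[keep]
  tibble(
    mean_pct = mean(shares),
    pooled_pct = 100 * sum(counts[[class]][keep]) / sum(counts$total[keep]),
    headline_pct = round_half_up(mean(shares)),
    n_cultivars = sum(keep)
  )
}

#' Per-class breakdown of a discriminator set
#'
#' Tallies the distinct discriminating metabolites per chemical class. A
#' metabolite flagged in several cultivars counts once.
#'
#' @param disc Discriminator tibble (`metabolite` column).
#' @param catalog Annotation catalog covering every discriminator.
#' @param synonyms Synonym table for name resolution.
#' @return A tibble with one row per chemical class of [bran_classes()]
#'   (plus any extra classes in the catalog), columns `chemical_class` and
#'   `n`; classes without discriminators carry 0.
#' @export
discriminator_breakdown <- function(disc, catalog, synonyms = bran_synonyms()) {
  key <- as_tibble(catalog) %>%
    mutate(metabolite = resolve_metabolite(.data$metabolite, synonyms)) %>%
    distinct(.data$metabolite, .data$chemical_class)
  d_met <- unique(resolve_metabolite(as_tibble(disc)$metabolite, synonyms))
  unann <- setdiff(d_met, key$metabolite)
  if (length(unann) > 0) {
    abort(paste0(
      "discriminating metabolite(s) without catalog annotation: ",
      paste(unann, collapse = ", ")
    ))
  }
  classes <- union(bran_classes(), unique(key$chemical_class))
  tab <- key %>%
    filter(.data$metabolite %in% d_met) %>%
    count(.data$chemical_class)
  tibble(chemical_class = classes) %>%
    left_join(tab, by = "chemical_class") %>%
    mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Ordination summary of a scaled abundance table
#'
#' Principal component decomposition of the cultivar-by-metabolite matrix of
#' median-scaled abundances (columns centered; unit-variance scaling
#' optional), reporting the percent variance explained per component and the
#' cultivar scores on the leading components. This is reporting plumbing for
#' "how much cross-cultivar structure is there", not an inferential method.
#'
#' @param s Scaled abundance tibble with no missing values (run
#'   [impute_missing()] with `"min_impute"` first if needed).
#' @param n_components Number of leading components to report scores for.
#' @param scale Logical; scale metabolites to unit variance before the
#'   decomposition (default `FALSE`: the conventional input is median-scaled
#'   without standardization).
#' @return An object of class `bran_ordination` with elements `variance`
#'   (tibble: `component`, `var_pct`) and `scores` (tibble: `cultivar`,
#'   `PC1`, ...).
#' @export
ordination_summary <- function(s, n_components = 2, scale = FALSE) {
  s <- validate_abundance(s)
  m <- abundance_values(s)
  if (anyNA(m)) {
    abort("abundance table has missing values; impute first (impute_missing(policy = 'min_impute'))")
  }
  x <- t(m) # rows = cultivars
  if (nrow(x) < 2) abort("ordination needs at least two cultivars")
  if (scale) {
    keep <- apply(x, 2, sd) > 0
    x <- x[, keep, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = scale)
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  n_components <- min(n_components, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(cultivar = rownames(x)), scores)
  structure(
    list(
      variance = tibble(component = seq_along(var_pct), var_pct = var_pct),
      scores = scores,
      n_components = n_components
    ),
    class = "bran_ordination"
  )
}

#' @export
print.bran_ordination <- function(x, ...) {
  cat("Ordination summary\n")
  v <- head(x$variance, x$n_components)
  cat(paste0(
    sprintf("  PC%d: %.1f%% of variance", v$component, v$var_pct),
    collapse = "\n"
  ), "\n")
  invisible(x)
}

#' Tidy an ordination summary
#'
#' @param x `bran_ordination` object.
#' @param ... Unused.
#' @return The cultivar score tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.bran_ordination <- function(x, ...) x$scores

#' One-row summary of an ordination
#'
#' @param x `bran_ordination` object.
#' @param ... Unused.
#' @return Tibble with the leading components' variance percentages.
#' @exportS3Method generics::glance
#' @export
glance.bran_ordination <- function(x, ...) {
  v <- x$variance$var_pct
  tibble(
    pc1_pct = v[1],
    pc2_pct = if (length(v) >= 2) v[2] else NA_real_,
    n_components = length(v)
  )
}
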