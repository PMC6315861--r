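#' Path to a bundled data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
bran_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "branmet")))
  }
  path <- system.file("extdata", file, package = "branmet")
  if (path == "") abort(paste0("no bundled file named '", file, "'"))
  path
}

#' Bundled per-cultivar class-count reference table
#'
#' Transcription of the published per-cultivar counts of annotated rice bran
#' metabolites by chemical class for the 17-cultivar reference panel,
#' together with the printed per-cultivar totals.
#'
#' @return A list with `counts` (tibble: `chemical_class` + one numeric
#'   column per cultivar) and `printed_totals` (named numeric vector).
#' @export
load_class_counts <- function() {
  tab <- readr::read_tsv(bran_extdata("rice_bran_class_counts.tsv"),
                         col_types = readr::cols(
                           chemical_class = "c", .default = "d"
                         ), progress = FALSE)
  totals <- tab %>% filter(.data$chemical_class == "Total")
  counts <- tab %>% filter(.data$chemical_class != "Total")
  pt <- as.numeric(totals[1, -1])
  names(pt) <- names(totals)[-1]
  list(counts = counts, printed_totals = pt)
}

#' Expand a class-count table into a presence matrix and catalog
#'
#' Builds a synthetic metabolite universe realizing a per-cultivar
#' class-count table exactly: each chemical class gets as many placeholder
#' metabolites as its maximum count across cultivars, each assigned a
#' single placeholder pathway per class, and each cultivar detects the first
#' `k` metabolites of each class. Running [class_count_table()] on the
#' result reproduces the input counts, which makes the reference table's
#' bookkeeping (totals, min/max cultivars, lipid share) recomputable through
#' the same code path used for real data.
#'
#' @param counts Class-count tibble as in `load_class_counts()$counts`.
#' @return A list with `presence` (detection tibble) and `catalog`
#'   (annotation tibble). Metabolite names are synthetic placeholders.
#' @export
expand_class_counts <- function(counts) {
  cultivars <- names(counts)[-1]
  per_class <- purrr::pmap(counts, function(chemical_class, ...) {
    k <- c(...)
    n_max <- max(k)
    if (n_max == 0) return(NULL)
    slug <- gsub("[^a-z]+", "_", tolower(chemical_class))
    mets <- sprintf("%s_%03d", slug, seq_len(n_max))
    list(
      catalog = tibble(metabolite = mets, chemical_class = chemical_class,
                       pathway = paste(chemical_class, "(placeholder)")),
      det = purrr::map_dfr(seq_along(k), function(j) {
        if (k[j] == 0) return(NULL)
        tibble(cultivar = cultivars[j], metabolite = mets[seq_len(k[j])])
      })
    )
  })
  per_class <- purrr::compact(per_class)
  catalog <- purrr::map_dfr(per_class, "catalog")
  det <- purrr::map_dfr(per_class, "det")
  wide <- det %>%
    mutate(x = TRUE) %>%
    tidyr::pivot_wider(names_from = "metabolite", values_from = "x",
                       values_fill = FALSE)
  # keep cultivar order, add metabolite columns never detected anywhere
  wide <- tibble(cultivar = cultivars) %>% left_join(wide, by = "cultivar")
  for (mcol in setdiff(catalog$metabolite, names(wide))) wide[[mcol]] <- FALSE
  wide <- wide %>%
    mutate(dplyr::across(-"cultivar", ~ tidyr::replace_na(.x, FALSE)))
  list(presence = wide, catalog = catalog)
}

#' Bundled cultivar-discriminating metabolite list
#'
#' Transcription of the published list of 71 rice bran metabolites (74
#' metabolite-cultivar entries) flagged by the cross-cultivar Z-score screen
#' on the 17-cultivar reference panel. Z values were not published, so the
#' entries carry only metabolite, cultivar and direction.
#'
#' @return A tibble with columns `metabolite`, `cultivar`, `direction`.
#' @export
load_discriminators <- function() {
  readr::read_tsv(bran_extdata("rice_bran_discriminators.tsv"),
                  col_types = "ccc", progress = FALSE)
}

#' Bundled annotation catalog for the discriminating metabolites
#'
#' Chemical class and metabolic pathway for each of the 71 discriminating
#' metabolites of the reference panel, covering the 15 pathways reported in
#' its enrichment summary. The full 53-pathway vocabulary of the source
#' panel was not published; this catalog ships the 15 pathways the
#' discriminators occupy.
#'
#' @return A validated catalog tibble.
#' @export
load_discriminator_catalog <- function() {
  read_catalog(bran_extdata("rice_bran_discriminator_catalog.tsv"))
}
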