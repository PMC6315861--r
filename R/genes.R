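#' Read a metabolite-to-biosynthetic-gene map
#'
#' Reads a gene map in the layout of the bundled rice fixture curated from
#' the OryzaCyc 4.0 / Plant Metabolic Network database: one row per
#' enumerated gene with the metabolite it is annotated to, its internal
#' database identifier (`GN7F-...`), its MSU locus name (`LOC_Os...`), the
#' precursor and biosynthesis-pathway free text, and two per-metabolite
#' counts. `direct_count` is the printed number of genes specifically
#' annotated to the metabolite's biosynthesis (authoritative even where the
#' source enumerates only the top genes); `common_count` is the bracketed
#' number of genes shared with the generic class pathway, carried as metadata
#' but never summed into headline totals. Metabolites with a known
#' `direct_count` of zero (e.g. myristate) appear with an empty `gene_id`.
#'
#' @param path Path to the TSV (defaults to the bundled rice bran fixture).
#' @return A tibble of class `bran_gene_map`.
#' @export
read_gene_map <- function(path = bran_extdata("rice_bran_gene_map.tsv")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  gm <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("metabolite", "direct_count", "common_count", "gene_id", "locus")
  missing_cols <- setdiff(need, names(gm))
  if (length(missing_cols) > 0) {
    abort(paste0("gene map lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("direct_count", "common_count")) {
    bad <- which(!grepl("^[0-9]+$", gm[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("malformed %s on line %d: '%s'", col, bad[1] + 1L, gm[[col]][bad[1]]))
    }
    gm[[col]] <- as.integer(gm[[col]])
  }
  # an enumerated record must carry a gene id (locus may be absent in the source)
  enumerated <- !is.na(gm$gene_id) & gm$gene_id != ""
  if (any(!enumerated & gm$direct_count > 0)) {
    abort("blank gene rows are only allowed for metabolites with direct_count 0")
  }
  counts <- gm %>% distinct(.data$metabolite, .data$direct_count, .data$common_count)
  inconsistent <- counts$metabolite[duplicated(counts$metabolite)]
  if (length(inconsistent) > 0) {
    abort(paste0(
      "inconsistent direct/common counts for: ", paste(inconsistent, collapse = ", ")
    ))
  }
  class(gm) <- c("bran_gene_map", class(gm))
  gm
}

# one row per metabolite with its printed gene counts
gene_map_counts <- function(gene_map, synonyms = bran_synonyms()) {
  as_tibble(gene_map) %>%
    mutate(metabolite = resolve_metabolite(.data$metabolite, synonyms)) %>%
    distinct(.data$metabolite, .data$direct_count, .data$common_count)
}

#' Link discriminating metabolites to biosynthetic genes
#'
#' Joins a discriminator set to a gene map by canonical metabolite name.
#' A discriminating metabolite is "matched" if it has any record in the map,
#' including metabolites whose printed direct gene count is zero; the
#' headline `total_direct_genes` sums the per-metabolite direct counts over
#' matched metabolites only (bracketed common-gene counts are excluded, as
#' they overlap heavily across metabolites). Unmatched metabolites are
#' reported, not an error: absence from a pathway-genome database is a
#' finding.
#'
#' @param disc Discriminator tibble (`metabolite` column; other columns
#'   ignored).
#' @param gene_map `bran_gene_map` from [read_gene_map()].
#' @param catalog Optional annotation catalog; when given, the report carries
#'   a per-chemical-class breakdown of matched metabolites.
#' @param synonyms Synonym table used to resolve names on both sides.
#' @return An object of class `bran_linkage`: see [tidy.bran_linkage()] and
#'   [glance.bran_linkage()].
#' @export
link_genes <- function(disc, gene_map, catalog = NULL,
                       synonyms = bran_synonyms()) {
  d_met <- unique(resolve_metabolite(as_tibble(disc)$metabolite, synonyms))
  counts <- gene_map_counts(gene_map, synonyms)
  matched <- counts %>% filter(.data$metabolite %in% d_met)
  unmatched <- setdiff(d_met, counts$metabolite)
  by_class <- NULL
  if (!is.null(catalog)) {
    key <- as_tibble(catalog) %>%
      mutate(metabolite = resolve_metabolite(.data$metabolite, synonyms)) %>%
      distinct(.data$metabolite, .data$chemical_class)
    by_class <- matched %>%
      left_join(key, by = "metabolite") %>%
      group_by(.data$chemical_class) %>%
      summarise(n_matched = dplyr::n(),
                direct_genes = sum(.data$direct_count), .groups = "drop")
  }
  structure(
    list(
      matched = arrange(matched, .data$metabolite),
      unmatched = sort(unmatched),
      total_direct_genes = sum(matched$direct_count),
      n_matched = nrow(matched),
      n_unmatched = length(unmatched),
      by_class = by_class
    ),
    class = "bran_linkage"
  )
}

#' @export
print.bran_linkage <- function(x, ...) {
  cat("Metabolite-gene linkage report\n")
  cat(sprintf("  matched metabolites:   %d\n", x$n_matched))
  cat(sprintf("  unmatched metabolites: %d\n", x$n_unmatched))
  cat(sprintf("  total direct genes:    %d\n", x$total_direct_genes))
  invisible(x)
}

#' Tidy a linkage report
#'
#' @param x `bran_linkage` object.
#' @param ... Unused.
#' @return One row per discriminating metabolite with `matched`,
#'   `direct_count` and `common_count` (`NA` for unmatched).
#' @exportS3Method generics::tidy
#' @export
tidy.bran_linkage <- function(x, ...) {
  bind_rows(
    mutate(x$matched, matched = TRUE),
    tibble(metabolite = x$unmatched, direct_count = NA_integer_,
           common_count = NA_integer_, matched = FALSE)
  ) %>% arrange(dplyr::desc(.data$matched), .data$metabolite)
}

#' One-row summary of a linkage report
#'
#' @param x `bran_linkage` object.
#' @param ... Unused.
#' @return Tibble with `n_matched`, `n_unmatched`, `total_direct_genes`.
#' @exportS3Method generics::glance
#' @export
glance.bran_linkage <- function(x, ...) {
  tibble(
    n_matched = x$n_matched,
    n_unmatched = x$n_unmatched,
    total_direct_genes = x$total_direct_genes
  )
}

#' Export a linkage report
#'
#' @param x `bran_linkage` object.
#' @param path Output TSV path; a JSON companion with the summary gains a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_linkage <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  jsonlite::write_json(
    as.list(glance(x)), sub("\\.tsv$", ".json", path),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
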