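#' Read a cultivar-by-metabolite relative abundance table
#'
#' Reads a delimited feature table in the layout produced by global
#' metabolomics platforms after compound identification: one row per
#' metabolite, the first column holding the metabolite name and the remaining
#' columns one cultivar (sample) each. Cell values are unitless
#' ion-intensity-derived relative abundances; an empty cell (or `NA`) means
#' the metabolite was not detected in that cultivar, which is distinct from a
#' measured value of zero.
#'
#' @param path Path to a TSV (default) or CSV file with a header row.
#' @param delim Field delimiter. If `NULL`, inferred from the file extension
#'   (`.csv` is comma, anything else tab).
#' @return A tibble whose first column is `metabolite` (character) and whose
#'   remaining columns are numeric cultivar abundances, validated so that all
#'   present values are non-negative, identifiers are unique, and every
#'   metabolite is detected in at least one cultivar.
#' @export
read_abundance <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- delim %||% infer_delim(path)
  ab <- readr::read_delim(
    path, delim = delim, na = c("", "NA"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(ab) < 2) abort("abundance table needs a metabolite column plus at least one cultivar column")
  names(ab)[1] <- "metabolite"
  ab[-1] <- lapply(ab[-1], as.numeric)
  validate_abundance(ab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

infer_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Validate an abundance table
#'
#' Checks the invariants of the in-memory abundance representation: unique
#' metabolite and cultivar identifiers, no negative values, and at least one
#' detected value per metabolite. Called by [read_abundance()] and before any
#' write; exported because synthetic or hand-built tables should pass through
#' the same gate.
#'
#' @param ab Abundance tibble (`metabolite` column + numeric cultivar columns).
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_abundance <- function(ab) {
  stopifnot(is.data.frame(ab), ncol(ab) >= 2)
  ab <- as_tibble(ab)
  names(ab)[1] <- "metabolite"
  dup_m <- unique(ab$metabolite[duplicated(ab$metabolite)])
  if (length(dup_m) > 0) {
    abort(paste0("duplicated metabolite id(s): ", paste(dup_m, collapse = ", ")))
  }
  cultivars <- names(ab)[-1]
  dup_c <- unique(cultivars[duplicated(cultivars)])
  if (length(dup_c) > 0) {
    abort(paste0("duplicated cultivar id(s): ", paste(dup_c, collapse = ", ")))
  }
  m <- abundance_values(ab)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf(
      "negative abundance for metabolite '%s' in cultivar '%s'",
      ab$metabolite[neg[1, 1]], cultivars[neg[1, 2]]
    ))
  }
  all_missing <- ab$metabolite[rowSums(!is.na(m)) == 0]
  if (length(all_missing) > 0) {
    abort(paste0(
      "metabolite(s) not detected in any cultivar: ",
      paste(all_missing, collapse = ", ")
    ))
  }
  ab
}

# numeric matrix of the value block, rows = metabolites
abundance_values <- function(ab) {
  m <- as.matrix(ab[-1])
  storage.mode(m) <- "double"
  rownames(m) <- ab$metabolite
  m
}

# rebuild an abundance tibble from a value matrix, preserving column order
abundance_from_values <- function(m, template) {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  tibble(metabolite = template$metabolite) %>% dplyr::bind_cols(out)
}

#' Write an abundance table
#'
#' Inverse of [read_abundance()]: missing cells are written as empty strings
#' so that a read/write/read cycle is the identity on valid tables.
#'
#' @param ab Validated abundance tibble.
#' @param path Output path.
#' @param delim Field delimiter; inferred from the extension if `NULL`.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(ab, path, delim = NULL) {
  ab <- validate_abundance(ab)
  delim <- delim %||% infer_delim(path)
  readr::write_delim(ab, path, delim = delim, na = "")
  invisible(path)
}

#' Read a metabolite annotation catalog
#'
#' A catalog assigns each identified metabolite to exactly one chemical class
#' and exactly one metabolic pathway, optionally carrying KEGG / HMDB /
#' PubChem cross-references. The chemical-class vocabulary is the seven-class
#' scheme of [bran_classes()]; additional classes can be whitelisted.
#'
#' @param path Path to a TSV/CSV file with columns `metabolite`,
#'   `chemical_class`, `pathway` and optional `kegg_id`, `hmdb_id`,
#'   `pubchem_id`.
#' @param delim Field delimiter; inferred from the extension if `NULL`.
#' @param extra_classes Character vector of additional allowed class labels.
#' @return A validated catalog tibble.
#' @export
read_catalog <- function(path, delim = NULL, extra_classes = character()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- delim %||% infer_delim(path)
  cat <- readr::read_delim(
    path, delim = delim, na = c("", "NA"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  validate_catalog(cat, extra_classes = extra_classes)
}

#' Validate an annotation catalog
#'
#' @param cat Catalog tibble with `metabolite`, `chemical_class`, `pathway`.
#' @param extra_classes Additional allowed chemical-class labels.
#' @return The validated tibble.
#' @export
validate_catalog <- function(cat, extra_classes = character()) {
  cat <- as_tibble(cat)
  need <- c("metabolite", "chemical_class", "pathway")
  missing_cols <- setdiff(need, names(cat))
  if (length(missing_cols) > 0) {
    abort(paste0("catalog lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  multi <- cat %>%
    distinct(.data$metabolite, .data$pathway) %>%
    count(.data$metabolite) %>%
    filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(paste0(
      "metabolite(s) assigned to more than one pathway: ",
      paste(multi$metabolite, collapse = ", ")
    ))
  }
  dup <- unique(cat$metabolite[duplicated(cat$metabolite)])
  if (length(dup) > 0) {
    abort(paste0("duplicated metabolite id(s) in catalog: ", paste(dup, collapse = ", ")))
  }
  allowed <- c(bran_classes(), extra_classes)
  bad <- setdiff(unique(cat$chemical_class), allowed)
  if (length(bad) > 0) {
    abort(paste0(
      "unknown chemical class label(s): ", paste(bad, collapse = ", "),
      " (use extra_classes= to allow)"
    ))
  }
  if (any(is.na(cat$pathway) | cat$pathway == "")) {
    abort("every catalog record needs a non-empty pathway")
  }
  # a pathway belongs to a single chemical class across the catalog
  pw <- cat %>%
    distinct(.data$pathway, .data$chemical_class) %>%
    count(.data$pathway) %>%
    filter(.data$n > 1)
  if (nrow(pw) > 0) {
    abort(paste0(
      "pathway(s) mapped to more than one chemical class: ",
      paste(pw$pathway, collapse = ", ")
    ))
  }
  cat
}

#' Export a catalog as JSON
#'
#' Provenance-friendly export of an annotation catalog (one object per
#' metabolite record).
#'
#' @param cat Validated catalog tibble.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(cat, path) {
  cat <- validate_catalog(cat, extra_classes = unique(cat$chemical_class))
  jsonlite::write_json(cat, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Detection (presence/absence) matrix of an abundance table
#'
#' Converts an abundance table into a cultivar-by-metabolite logical matrix:
#' `TRUE` where the metabolite was detected (any non-missing value, including
#' zero) in that cultivar. Per-cultivar metabolite counts are the row sums.
#'
#' @param ab Validated abundance tibble.
#' @return A tibble whose first column is `cultivar` and whose remaining
#'   columns are logical, one per metabolite.
#' @export
presence_matrix <- function(ab) {
  ab <- validate_abundance(ab)
  m <- !is.na(abundance_values(ab))
  out <- as_tibble(as.data.frame(t(m), check.names = FALSE))
  tibble(cultivar = colnames(ab)[-1]) %>% dplyr::bind_cols(out)
}

# long (cultivar, metabolite) pairs of detected cells
presence_long <- function(presence) {
  stopifnot(names(presence)[1] == "cultivar")
  presence %>%
    tidyr::pivot_longer(-"cultivar", names_to = "metabolite",
                        values_to = "detected") %>%
    filter(.data$detected) %>%
    select(-"detected")
}
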