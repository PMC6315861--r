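#' Normalize a metabolite name
#'
#' Compound names in metabolomics reports are typeset inconsistently
#' (Greek letters vs. transliterations, stray whitespace, mixed case,
#' typographic primes). `normalize_metabolite()` maps every surface form to a
#' canonical spelling so that tables from different sources can be joined by
#' name: whitespace is trimmed and collapsed, the name is case-folded, Greek
#' letters are transliterated (`α` to `alpha-`, etc.) and typographic
#' primes/quotes become ASCII apostrophes.
#'
#' @param x Character vector of metabolite names.
#' @return Character vector of the same length, normalized.
#' @export
#' @examples
#' normalize_metabolite(c("  Glutamate ", "α-ketoglutarate"))
normalize_metabolite <- function(x) {
  stopifnot(is.character(x))
  out <- trimws(x)
  out <- gsub("[‘’′]", "'", out)
  out <- gsub("α", "alpha", out)
  out <- gsub("β", "beta", out)
  out <- gsub("γ", "gamma", out)
  out <- gsub("δ", "delta", out)
  out <- gsub("µ|μ", "mu", out)
  out <- gsub("\\s+", " ", out)
  tolower(out)
}

#' Bundled metabolite synonym table
#'
#' Curated aliases for compounds that appear under several names in
#' rice bran metabolomics and pathway-database reports (e.g.
#' "glycerophosphorylcholin (sn-glycero-3-phosphocholine)" vs. "GPC",
#' "cis-aconitate" vs. "aconitate", the co-eluting
#' "gamma-tocopherol/beta-tocopherol" pair reported as one entity).
#'
#' @return A tibble with columns `synonym` and `canonical`, both normalized
#'   via [normalize_metabolite()].
#' @export
bran_synonyms <- function() {
  path <- bran_extdata("metabolite_synonyms.tsv")
  syn <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  tibble(
    synonym = normalize_metabolite(syn$synonym),
    canonical = normalize_metabolite(syn$canonical)
  )
}

#' Resolve metabolite names to canonical identifiers
#'
#' Applies [normalize_metabolite()] and then the synonym table, so that any
#' recognized alias collapses onto its canonical name. Unknown names pass
#' through normalized but otherwise untouched.
#'
#' @param x Character vector of metabolite names.
#' @param synonyms Synonym table as returned by [bran_synonyms()]; pass a
#'   custom tibble with `synonym`/`canonical` columns to extend it.
#' @return Character vector of canonical normalized names.
#' @export
#' @examples
#' resolve_metabolite(c("GPC", "cis-Aconitate", "malate"))
resolve_metabolite <- function(x, synonyms = bran_synonyms()) {
  nx <- normalize_metabolite(x)
  idx <- match(nx, synonyms$synonym)
  hit <- !is.na(idx)
  nx[hit] <- synonyms$canonical[idx[hit]]
  nx
}
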