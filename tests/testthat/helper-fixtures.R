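# small in-code fixtures shared across test files

# abundance tibble from a metabolite-by-cultivar matrix (rows named or not)
make_ab <- function(m, metabolites = NULL, cultivars = NULL) {
  metabolites <- metabolites %||% sprintf("m%02d", seq_len(nrow(m)))
  cultivars <- cultivars %||% sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(NULL, cultivars)
  dplyr::bind_cols(
    tibble::tibble(metabolite = metabolites),
    tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a tiny valid catalog over the given metabolites, one class, one pathway each
make_catalog <- function(metabolites, class = "lipids",
                         pathway = paste(class, "pathway")) {
  tibble::tibble(metabolite = metabolites, chemical_class = class,
                 pathway = pathway)
}

# presence tibble where everything listed is detected in every cultivar
all_present <- function(cultivars, metabolites) {
  out <- tibble::tibble(cultivar = cultivars)
  for (m in metabolites) out[[m]] <- TRUE
  out
}

# brute-force per-cell recount of enrichment bookkeeping, independent of
# enrich(): plain loops over sets, no joins
brute_enrich <- function(disc, catalog, presence, scope) {
  det <- list()
  for (i in seq_len(nrow(presence))) {
    cu <- presence$cultivar[i]
    det[[cu]] <- names(presence)[-1][unlist(presence[i, -1])]
  }
  units <- if (scope == "global") "global" else sort(unique(disc$cultivar))
  rows <- list()
  for (u in units) {
    if (u == "global") {
      d_met <- unique(disc$metabolite)
      p_met <- unique(unlist(det))
    } else {
      d_met <- unique(disc$metabolite[disc$cultivar == u])
      p_met <- det[[u]]
    }
    p_met <- intersect(union(p_met, d_met), catalog$metabolite)
    N <- length(p_met); n <- length(d_met)
    for (pw in unique(catalog$pathway)) {
      in_pw <- catalog$metabolite[catalog$pathway == pw]
      m <- length(intersect(p_met, in_pw))
      k <- length(intersect(d_met, in_pw))
      if (k >= 1) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          cultivar = u, pathway = pw, k = k, m = m, n = n, N = N,
          score = (k / m) / (n / N)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
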