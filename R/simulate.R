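#' Configuration for the synthetic rice bran panel generator
#'
#' Collects and validates the parameters of the generative model behind
#' [generate_bran()]: a 17-cultivar by 450-metabolite panel by default, with
#' class proportions matching the observed composition of a rice bran
#' metabolome (lipids ~39%), 53 metabolic pathways each owned by one class,
#' log-normal abundances with a per-metabolite scale, independent per-cell
#' detection dropout, and optional planted single-cultivar abundance shifts
#' expressed in units of the log-abundance standard deviation.
#'
#' @param n_cultivars Number of cultivars (samples). Default 17.
#' @param n_metabolites Number of metabolites. Default 450.
#' @param class_props Named numeric vector of chemical-class proportions
#'   summing to 1. The default mirrors the per-class shares of an annotated
#'   rice bran metabolome.
#' @param n_pathways Total number of metabolic pathways. Default 53.
#' @param sigma_log Standard deviation of the log-abundance noise. Default
#'   0.35.
#' @param dropout Per-cell probability that a detected metabolite is missing
#'   from a cultivar's table, in `[0, 1)`. Default 0.085, calibrated so that
#'   per-cultivar detected totals fall in the 378-430 range typical of an
#'   annotated rice bran panel.
#' @param effects Optional tibble/data.frame of planted shifts with columns
#'   `metabolite` (index in `1:n_metabolites`), `cultivar` (index in
#'   `1:n_cultivars`) and `shift` (log-sigma units; sign sets direction).
#' @param seed Integer seed driving a single pseudo-random stream.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cultivars = 17, n_metabolites = 450,
                       class_props = NULL, n_pathways = 53,
                       sigma_log = 0.35, dropout = 0.085,
                       effects = NULL, seed = 1L) {
  class_props <- class_props %||% c(
    "amino acids" = 0.27, "carbohydrates" = 0.12,
    "cofactors & vitamins" = 0.06, "lipids" = 0.39,
    "nucleotides" = 0.08, "peptides" = 0.02,
    "secondary metabolites" = 0.06
  )
  stopifnot(
    n_cultivars >= 2, n_metabolites >= 1,
    n_pathways >= 1, n_pathways <= n_metabolites,
    sigma_log >= 0, length(seed) == 1
  )
  if (is.null(names(class_props)) || any(names(class_props) == "")) {
    abort("class_props must be a named vector")
  }
  if (abs(sum(class_props) - 1) > 1e-9) abort("class_props must sum to 1")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  if (!is.null(effects)) {
    effects <- as_tibble(effects)
    stopifnot(all(c("metabolite", "cultivar", "shift") %in% names(effects)))
    if (any(effects$metabolite < 1 | effects$metabolite > n_metabolites)) {
      abort("planted effect metabolite index out of range")
    }
    if (any(effects$cultivar < 1 | effects$cultivar > n_cultivars)) {
      abort("planted effect cultivar index out of range")
    }
  }
  structure(
    list(
      n_cultivars = as.integer(n_cultivars),
      n_metabolites = as.integer(n_metabolites),
      class_props = class_props, n_pathways = as.integer(n_pathways),
      sigma_log = sigma_log, dropout = dropout,
      effects = effects, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate a synthetic rice bran panel
#'
#' Draws an abundance table, a matching annotation catalog and a truth table
#' of planted effects from the model described in [sim_config()]. Cell
#' abundances are `scale_i * exp(sigma_log * eps)` with standard normal
#' `eps` and a per-metabolite log-normal scale, so median scaling removes the
#' scale exactly as it does for platform relative abundances. Planted cells
#' are multiplied by `exp(shift * sigma_log)`. Dropout then blanks cells
#' independently; if a metabolite loses every cultivar, its first cell is
#' restored so the table stays valid.
#'
#' @param cfg `sim_config` object.
#' @return A list with elements `abundance` (tibble in [read_abundance()]
#'   layout), `catalog` (annotation tibble), `truth` (tibble of planted
#'   `metabolite`, `cultivar`, `shift`, `direction`) and `config`.
#' @export
generate_bran <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nm <- cfg$n_metabolites
  nc <- cfg$n_cultivars
  met_ids <- sprintf("met%04d", seq_len(nm))
  cul_ids <- sprintf("cv%02d", seq_len(nc))

  # chemical classes by multinomial draw on the configured proportions
  class_counts <- as.vector(rmultinom(1, nm, cfg$class_props))
  classes <- rep(names(cfg$class_props), class_counts)

  # split pathways across classes roughly proportionally, >= 1 per class
  # that received metabolites
  got <- class_counts > 0
  raw <- cfg$class_props[got] / sum(cfg$class_props[got]) * cfg$n_pathways
  n_pw <- pmax(1L, round_half_up(raw))
  while (sum(n_pw) > cfg$n_pathways) n_pw[which.max(n_pw)] <- n_pw[which.max(n_pw)] - 1L
  while (sum(n_pw) < cfg$n_pathways) n_pw[which.max(raw - n_pw)] <- n_pw[which.max(raw - n_pw)] + 1L
  pw_class <- rep(names(cfg$class_props)[got], n_pw)
  pw_ids <- sprintf("%s pathway %02d", pw_class, unlist(lapply(n_pw, seq_len)))
  pathway <- vapply(classes, function(cl) {
    sample(pw_ids[pw_class == cl], 1)
  }, character(1))

  catalog <- tibble(metabolite = met_ids, chemical_class = classes,
                    pathway = unname(pathway))

  scale_i <- exp(rnorm(nm, 0, 1))
  vals <- scale_i * exp(matrix(rnorm(nm * nc, 0, cfg$sigma_log), nm, nc))
  truth <- tibble(metabolite = character(), cultivar = character(),
                  shift = double(), direction = character())
  if (!is.null(cfg$effects) && nrow(cfg$effects) > 0) {
    i <- cfg$effects$metabolite
    j <- cfg$effects$cultivar
    vals[cbind(i, j)] <- vals[cbind(i, j)] * exp(cfg$effects$shift * cfg$sigma_log)
    truth <- tibble(
      metabolite = met_ids[i], cultivar = cul_ids[j],
      shift = cfg$effects$shift,
      direction = ifelse(cfg$effects$shift > 0, "high", "low")
    )
  }
  if (cfg$dropout > 0) {
    drop <- matrix(runif(nm * nc) < cfg$dropout, nm, nc)
    lost <- rowSums(!drop) == 0
    drop[lost, 1] <- FALSE
    vals[drop] <- NA_real_
  }
  dimnames(vals) <- list(met_ids, cul_ids)
  ab <- dplyr::bind_cols(tibble(metabolite = met_ids),
                         as_tibble(as.data.frame(vals, check.names = FALSE)))
  list(abundance = validate_abundance(ab), catalog = catalog,
       truth = truth, config = cfg)
}

#' Score discriminator recovery against a truth table
#'
#' Compares a discriminator set with the planted effects of a synthetic
#' panel. Sensitivity is the fraction of planted (metabolite, cultivar)
#' entries recovered; the false discovery proportion is the fraction of
#' reported entries that were not planted (0 when nothing is reported);
#' direction accuracy is the fraction of recovered entries whose direction
#' matches the planted sign.
#'
#' @param disc Discriminator tibble from [find_discriminators()].
#' @param truth Truth tibble from [generate_bran()].
#' @return A one-row tibble: `sensitivity`, `fdp`, `direction_accuracy`,
#'   `n_planted`, `n_reported`.
#' @export
evaluate_recovery <- function(disc, truth) {
  disc <- as_tibble(disc)
  truth <- as_tibble(truth)
  d_key <- paste(disc$metabolite, disc$cultivar, sep = "\r")
  t_key <- paste(truth$metabolite, truth$cultivar, sep = "\r")
  hit <- t_key %in% d_key
  dir_ok <- if (any(hit)) {
    planted_dir <- truth$direction[hit]
    found_dir <- disc$direction[match(t_key[hit], d_key)]
    mean(planted_dir == found_dir)
  } else {
    NA_real_
  }
  tibble(
    sensitivity = if (nrow(truth) == 0) NA_real_ else mean(hit),
    fdp = if (nrow(disc) == 0) 0 else mean(!(d_key %in% t_key)),
    direction_accuracy = dir_ok,
    n_planted = nrow(truth),
    n_reported = nrow(disc)
  )
}
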