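#' Median-scale an abundance table
#'
#' Divides each metabolite's abundances by that metabolite's median across the
#' cultivars in which it was detected, so that after scaling the per-metabolite
#' median of present values is exactly 1. This is the standard normalization
#' for cross-sample comparison of global metabolomics relative abundances and
#' is the input convention for the Z-score screen. Missing cells stay missing.
#'
#' @param ab Validated abundance tibble ([read_abundance()] layout).
#' @return A tibble of the same shape with median-scaled values.
#' @export
#' @examples
#' ab <- tibble::tibble(metabolite = "m1", a = 2, b = 4, c = 6)
#' median_scale(ab)
median_scale <- function(ab) {
  ab <- validate_abundance(ab)
  m <- abundance_values(ab)
  med <- apply(m, 1, median, na.rm = TRUE)
  bad <- ab$metabolite[!is.finite(med)]
  if (length(bad) > 0) {
    abort(paste0("metabolite(s) with no detected values: ", paste(bad, collapse = ", ")))
  }
  if (any(med == 0)) {
    abort(paste0(
      "metabolite(s) with zero median abundance cannot be median-scaled: ",
      paste(ab$metabolite[med == 0], collapse = ", ")
    ))
  }
  abundance_from_values(m / med, ab)
}

#' Fill missing cells of a scaled table
#'
#' Two policies for cells where a metabolite was not detected:
#' `"skip"` (default) leaves them missing, so downstream Z-scores are computed
#' over present cells only; `"min_impute"` fills each metabolite's missing
#' cells with that metabolite's minimum present value, the convention used by
#' some commercial global-metabolomics pipelines.
#'
#' @param s Scaled (or raw) abundance tibble.
#' @param policy `"skip"` or `"min_impute"`.
#' @return A tibble of the same shape.
#' @export
impute_missing <- function(s, policy = c("skip", "min_impute")) {
  policy <- match.arg(policy)
  s <- validate_abundance(s)
  if (policy == "skip") return(s)
  m <- abundance_values(s)
  rmin <- apply(m, 1, min, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx) > 0) m[idx] <- rmin[idx[, 1]]
  abundance_from_values(m, s)
}

#' Cross-cultivar Z-scores of median-scaled abundances
#'
#' For each metabolite, computes `Z = (x - mu) / sigma` per cultivar, where
#' `mu` and `sigma` are the mean and standard deviation of that metabolite's
#' (median-scaled) abundances across the cultivars in which it was detected.
#' A metabolite whose abundances are constant (`sigma = 0`) gets `Z = 0`
#' everywhere and is flagged; metabolites detected in fewer than
#' `min_cultivars` cultivars are excluded with a warning, since a standard
#' deviation over one or two values carries no discriminating information.
#'
#' @param s Median-scaled abundance tibble, normally from [median_scale()].
#' @param sigma `"sample"` (n-1 denominator, default) or `"population"`
#'   (n denominator).
#' @param min_cultivars Minimum number of present values a metabolite needs to
#'   enter the screen (default 3).
#' @return A tibble of class `bran_zscores` with one row per detected cell:
#'   `metabolite`, `cultivar`, `value`, `mu`, `sigma`, `z`, `constant`.
#'   Excluded metabolites are recorded in the `excluded` attribute.
#' @export
compute_zscores <- function(s, sigma = c("sample", "population"),
                            min_cultivars = 3) {
  sigma <- match.arg(sigma)
  s <- validate_abundance(s)
  m <- abundance_values(s)
  cultivars <- colnames(m)
  n_present <- rowSums(!is.na(m))
  excl <- rownames(m)[n_present < min_cultivars]
  if (length(excl) > 0) {
    warn(paste0(
      "excluding ", length(excl), " metabolite(s) detected in fewer than ",
      min_cultivars, " cultivars: ", paste(head(excl, 5), collapse = ", "),
      if (length(excl) > 5) ", ..." else ""
    ))
    m <- m[n_present >= min_cultivars, , drop = FALSE]
  }
  if (nrow(m) == 0) {
    out <- tibble(metabolite = character(), cultivar = character(),
                  value = double(), mu = double(), sigma = double(),
                  z = double(), constant = logical())
  } else {
    mu <- rowMeans(m, na.rm = TRUE)
    if (sigma == "sample") {
      sdv <- apply(m, 1, sd, na.rm = TRUE)
    } else {
      np <- rowSums(!is.na(m))
      sdv <- sqrt(rowSums((m - mu)^2, na.rm = TRUE) / np)
    }
    constant <- sdv == 0
    z <- (m - mu) / ifelse(sdv == 0, 1, sdv)
    z[constant, ] <- 0
    out <- tibble(
      metabolite = rep(rownames(m), times = ncol(m)),
      cultivar = rep(cultivars, each = nrow(m)),
      value = as.vector(m),
      mu = rep(unname(mu), times = ncol(m)),
      sigma = rep(unname(sdv), times = ncol(m)),
      z = as.vector(z),
      constant = rep(unname(constant), times = ncol(m))
    ) %>%
      filter(!is.na(.data$value)) %>%
      arrange(match(.data$metabolite, rownames(m)))
  }
  attr(out, "excluded") <- excl
  attr(out, "sigma_convention") <- sigma
  class(out) <- c("bran_zscores", class(out))
  out
}

#' Identify cultivar-discriminating metabolites
#'
#' Flags every (metabolite, cultivar) cell whose Z-score exceeds the
#' threshold in absolute value (strictly: `|Z| > threshold`). Such a
#' metabolite's abundance in that cultivar lies more than `threshold`
#' standard deviations from the cross-cultivar mean, marking it as a
#' distinguisher of that cultivar.
#'
#' @param z `bran_zscores` tibble from [compute_zscores()].
#' @param threshold Positive real; default 2.
#' @return A tibble of class `bran_discriminators` with columns `metabolite`,
#'   `cultivar`, `z`, `direction` (`"high"` if `z > 0`, else `"low"`), sorted
#'   by decreasing `|z|`.
#' @export
find_discriminators <- function(z, threshold = 2) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("threshold must be a single positive number")
  }
  stopifnot(all(c("metabolite", "cultivar", "z") %in% names(z)))
  out <- as_tibble(z) %>%
    filter(abs(.data$z) > threshold) %>%
    mutate(direction = ifelse(.data$z > 0, "high", "low")) %>%
    select("metabolite", "cultivar", "z", "direction") %>%
    arrange(dplyr::desc(abs(.data$z)))
  attr(out, "threshold") <- threshold
  class(out) <- c("bran_discriminators", class(out))
  out
}

#' Write a discriminator report
#'
#' Exports the discriminator set as TSV, optionally annotated with chemical
#' class and pathway from a catalog.
#'
#' @param disc Discriminator tibble from [find_discriminators()] or the
#'   bundled list.
#' @param path Output TSV path.
#' @param catalog Optional annotation catalog for class/pathway columns.
#' @return `path`, invisibly.
#' @export
write_discriminators <- function(disc, path, catalog = NULL) {
  out <- as_tibble(disc)
  if (!is.null(catalog)) {
    key <- validate_catalog(catalog, extra_classes = unique(catalog$chemical_class)) %>%
      mutate(.met = resolve_metabolite(.data$metabolite)) %>%
      select(".met", "chemical_class", "pathway")
    out <- out %>%
      mutate(.met = resolve_metabolite(.data$metabolite)) %>%
      left_join(key, by = ".met") %>%
      select(-".met")
  }
  readr::write_tsv(out, path)
  invisible(path)
}
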