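#' Estimate functional-fraction percentages from per-region in-frame rates
#'
#' A variable domain is functional when all three of its CDRs are in frame,
#' so under independence the chain's functional fraction is the product of
#' its three per-region in-frame fractions; the scFv functional fraction is
#' the heavy-chain fraction times the mean of the kappa and lambda
#' fractions (light chains contribute in roughly equal proportion).
#'
#' @param x either a `qc_report`, a tibble with `region` and `in_frame_pct`
#'   columns, or a named numeric vector of nine in-frame percentages
#'   (names `H1`..`L3`).
#' @return tibble with `quantity` (`heavy`, `kappa`, `lambda`, `scfv`) and
#'   `functional_pct`; `NA` where a chain's regions are incomplete.
#' @examples
#' infr <- c(H1 = 91.3, H2 = 89.7, H3 = 90.3, K1 = 92.2, K2 = 91.6,
#'           K3 = 93.2, L1 = 91.5, L2 = 78.7, L3 = 90.7)
#' estimate_functional_fractions(infr)
#' @export
estimate_functional_fractions <- function(x) {
  pct <- in_frame_vector(x)
  chain_fun <- vapply(c("heavy", "kappa", "lambda"), function(ch) {
    prod(pct[chain_regions(ch)] / 100) * 100
  }, numeric(1))
  scfv <- chain_fun[["heavy"]] / 100 * mean(c(chain_fun[["kappa"]], chain_fun[["lambda"]]))
  tibble::tibble(
    quantity = c("heavy", "kappa", "lambda", "scfv"),
    functional_pct = c(unname(chain_fun), scfv)
  )
}

in_frame_vector <- function(x) {
  if (inherits(x, "qc_report")) x <- x$region_stats
  if (is.data.frame(x)) {
    x <- stats::setNames(x$in_frame_pct, x$region)
  }
  out <- stats::setNames(rep(NA_real_, 9), cdr_regions())
  out[intersect(names(x), cdr_regions())] <- x[intersect(names(x), cdr_regions())]
  out
}

#' Estimate PTM-free clone percentages from per-region motif burdens
#'
#' Assuming PTM motifs occur independently across CDRs, the fraction of a
#' chain's domains free of any motif is the product over its three regions
#' of `1 - Total/100`; the scFv-level fractions are reported separately for
#' heavy x kappa and heavy x lambda pairings, together with the complement
#' (clones carrying at least one motif).
#'
#' @param x a named numeric vector of nine total-PTM percentages (names
#'   `H1`..`L3`), a tibble with `region` and `pct` columns (e.g. the
#'   `Total` rows of [ptm_statistics()] output), or a full
#'   [ptm_statistics()] tibble (the `Total` rows are used).
#' @return tibble with `quantity` (`heavy`, `kappa`, `lambda`,
#'   `heavy_kappa`, `heavy_lambda`), `ptm_free_pct` and `at_least_one_pct`.
#' @examples
#' totals <- c(H1 = 1.36, H2 = 5.44, H3 = 5.87, K1 = 3.60, K2 = 3.58,
#'             K3 = 2.32, L1 = 6.16, L2 = 10.48, L3 = 4.81)
#' estimate_ptm_free_fraction(totals)
#' @export
estimate_ptm_free_fraction <- function(x) {
  pct <- total_ptm_vector(x)
  chain_free <- vapply(c("heavy", "kappa", "lambda"), function(ch) {
    prod(1 - pct[chain_regions(ch)] / 100) * 100
  }, numeric(1))
  pair <- c(
    heavy_kappa = chain_free[["heavy"]] / 100 * chain_free[["kappa"]],
    heavy_lambda = chain_free[["heavy"]] / 100 * chain_free[["lambda"]]
  )
  free <- c(chain_free, pair)
  tibble::tibble(
    quantity = names(free),
    ptm_free_pct = unname(free),
    at_least_one_pct = 100 - unname(free)
  )
}

total_ptm_vector <- function(x) {
  if (is.data.frame(x)) {
    if ("motif" %in% names(x)) x <- x[x$motif == "Total", , drop = FALSE]
    x <- stats::setNames(x$pct, x$region)
  }
  out <- stats::setNames(rep(NA_real_, 9), cdr_regions())
  out[intersect(names(x), cdr_regions())] <- x[intersect(names(x), cdr_regions())]
  out
}

#' Reported QC percentages for a constructed library of this design
#'
#' The NGS characterisation of a constructed phage-display scFv library
#' built with this non-combinatorial design reported, per CDR region, the
#' percentage of in-frame sequences and the percentage of sequences
#' carrying at least one PTM motif (for the library and, as a comparator,
#' for natural human antibody CDRs). These printed values are shipped as a
#' worked example for the estimator arithmetic -- the underlying reads are
#' not distributed, so they are inputs here, not outputs.
#'
#' @return list with named numeric vectors `in_frame_pct`,
#'   `total_ptm_library`, `total_ptm_natural` (names `H1`..`L3`).
#' @examples
#' qc <- reported_library_qc()
#' estimate_functional_fractions(qc$in_frame_pct)
#' estimate_ptm_free_fraction(qc$total_ptm_library)
#' @export
reported_library_qc <- function() {
  list(
    in_frame_pct = c(H1 = 91.3, H2 = 89.7, H3 = 90.3,
                     K1 = 92.2, K2 = 91.6, K3 = 93.2,
                     L1 = 91.5, L2 = 78.7, L3 = 90.7),
    total_ptm_library = c(H1 = 1.36, H2 = 5.44, H3 = 5.87,
                          K1 = 3.60, K2 = 3.58, K3 = 2.32,
                          L1 = 6.16, L2 = 10.48, L3 = 4.81),
    total_ptm_natural = c(H1 = 1.09, H2 = 36.70, H3 = 32.92,
                          K1 = 12.55, K2 = 1.23, K3 = 15.56,
                          L1 = 8.08, L2 = 1.13, L3 = 20.70)
  )
}
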