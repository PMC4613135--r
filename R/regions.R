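#' CDR region codes
#'
#' The nine antibody CDRs are labelled by two-character codes: `H1`, `H2`,
#' `H3` (heavy chain), `K1`, `K2`, `K3` (kappa light chain) and `L1`, `L2`,
#' `L3` (lambda light chain). The letter gives the chain, the digit the loop
#' (CDR1, CDR2 or CDR3). All user-facing functions identify regions by these
#' codes.
#'
#' @return `cdr_regions()` returns the nine codes as a character vector;
#'   `cdr_region_info()` returns a tibble with one row per requested code and
#'   columns `region`, `chain` (`"heavy"`, `"kappa"` or `"lambda"`) and
#'   `loop` (integer 1-3).
#' @examples
#' cdr_regions()
#' cdr_region_info(c("H3", "K2"))
#' @export
cdr_regions <- function() {
  c("H1", "H2", "H3", "K1", "K2", "K3", "L1", "L2", "L3")
}

#' @param region character vector of region codes.
#' @rdname cdr_regions
#' @export
cdr_region_info <- function(region = cdr_regions()) {
  region <- assert_region(region)
  chain_of <- c(H = "heavy", K = "kappa", L = "lambda")
  tibble::tibble(
    region = region,
    chain = unname(chain_of[substr(region, 1, 1)]),
    loop = as.integer(substr(region, 2, 2))
  )
}

assert_region <- function(region) {
  region <- toupper(as.character(region))
  bad <- setdiff(region, cdr_regions())
  if (length(bad) > 0) {
    stop("unknown CDR region code(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(cdr_regions(), collapse = ", "), ")",
         call. = FALSE)
  }
  region
}

#' Regions belonging to one chain
#'
#' @param chain `"heavy"`, `"kappa"` or `"lambda"`.
#' @return character vector of the chain's three region codes, CDR1 to CDR3.
#' @examples
#' chain_regions("kappa")
#' @export
chain_regions <- function(chain = c("heavy", "kappa", "lambda")) {
  chain <- match.arg(chain)
  prefix <- c(heavy = "H", kappa = "K", lambda = "L")[[chain]]
  paste0(prefix, 1:3)
}
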