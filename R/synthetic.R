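# Synthetic inputs: fixture germline sets and scaffolds, truth parameters
# for natural-repertoire generation, and an error-bearing read simulator.
# Everything here is generated in code; the fixture sequences are
# synthetic, plausible human-like stand-ins, not real database entries.

#' Fixture germline CDR set
#'
#' A small hand-written germline CDR set with realistic region lengths
#' (e.g. heavy CDR1 of length 5, kappa CDR2 of length 7) used by the
#' synthetic-data generators and the examples. The sequences are synthetic:
#' they resemble human germline CDRs in composition and length but are not
#' claimed to equal any real germline gene. Heavy CDR3 has no germline
#' entries (it has no practical germline ancestor).
#'
#' @return a [germline_set()].
#' @export
demo_germline_set <- function() {
  germline_set(tibble::tribble(
    ~region, ~name, ~sequence,
    "H1", "VH3-a", "SYAMS",
    "H1", "VH3-b", "DYAMH",
    "H1", "VH3-c", "SYGMH",
    "H1", "VH1-d", "GYYWS",
    "H2", "VH3-a", "AISGSGGSTYYADSVKG",
    "H2", "VH3-b", "VISYDGSNKYYADSVKG",
    "H2", "VH1-c", "RIYPSNGYTNYAQKFQG",
    "H2", "VH1-d", "WINPNSGGTNYAQKFQG",
    "K1", "VK1-a", "RASQSISSYLN",
    "K1", "VK1-b", "RASQGIRNDLG",
    "K1", "VK1-c", "QASQDISNYLN",
    "K1", "VK3-d", "RASQSVSSSYLA",
    "K2", "VK1-a", "AASSLQS",
    "K2", "VK1-b", "DASNRAT",
    "K2", "VK3-c", "GASSRAT",
    "K2", "VK3-d", "KASSLES",
    "K3", "VK1-a", "QQSYSTPLT",
    "K3", "VK1-b", "QQANSFPLT",
    "K3", "VK3-c", "QQYNSYPRT",
    "K3", "VK3-d", "QQSYSTPPLT",
    "L1", "VL1-a", "SGDKLGDKYAS",
    "L1", "VL1-b", "SGSSSNIGSNYVY",
    "L1", "VL2-c", "TGTSSDVGGYNYVS",
    "L2", "VL1-a", "GNSNRPS",
    "L2", "VL1-b", "EVSNRPS",
    "L2", "VL2-c", "DVSNRPS",
    "L3", "VL1-a", "AAWDDSLSG",
    "L3", "VL1-b", "QVWDSSSDHV",
    "L3", "VL2-c", "QSYDSSLSGVV"
  ))
}

#' Fixture framework scaffolds
#'
#' One scaffold per chain (heavy, kappa, lambda) with typical human
#' framework lengths; protein sequences are human-framework-like synthetic
#' fixtures and the nucleotide sequences are their deterministic reverse
#' translation under [preferred_codons()]. Replaceable by user scaffolds
#' via [read_frameworks()].
#'
#' @return named list of [framework_scaffold()] objects.
#' @export
demo_scaffolds <- function() {
  fr_protein <- list(
    heavy = c("EVQLLESGGGLVQPGGSLRLSCAAS", "WVRQAPGKGLEWVS",
              "RFTISRDNSKNTLYLQMNSLRAEDTAVYYCAK", "WGQGTLVTVSS"),
    kappa = c("DIQMTQSPSSLSASVGDRVTITC", "WYQQKPGKAPKLLIY",
              "GVPSRFSGSGSGTDFTLTISSLQPEDFATYYC", "FGQGTKVEIK"),
    lambda = c("QSVLTQPPSASGTPGQRVTISC", "WYQQLPGTAPKLLIY",
               "GVPDRFSGSKSGTSASLAISGLRSEDEADYYC", "FGGGTKLTVL")
  )
  lapply(stats::setNames(names(fr_protein), names(fr_protein)), function(ch) {
    framework_scaffold(ch, reverse_translate(fr_protein[[ch]]))
  })
}

#' Specification of a synthetic natural repertoire
#'
#' Bundles the known generating parameters of one region's natural-like
#' repertoire: germline usage frequencies, per-position substitution
#' spectra (a 20 x L matrix per germline whose column sums are the
#' positional mutation rates), the sample size, and -- for heavy CDR3 and
#' light CDR3 -- the positional/tail truth profiles. Profilers run on the
#' generated repertoire should recover these parameters (parameter
#' recovery is part of the test suite).
#'
#' @param region two-character CDR region code.
#' @param usage named numeric usage frequencies (germline names; sums to 1).
#'   Ignored for `H3`.
#' @param spectrum named list of 20 x L substitution-frequency matrices,
#'   one per germline in `usage`. Ignored for `H3`.
#' @param n number of sequences to generate.
#' @param seed integer seed (optional).
#' @param h3_profile an `h3_profile` truth object (required for `H3`).
#' @param tail_profile an `l3_tail_profile` truth object (required for
#'   `K3`/`L3`).
#' @return a `repertoire_spec` object.
#' @export
repertoire_spec <- function(region, usage = NULL, spectrum = NULL, n = 1000L,
                            seed = NULL, h3_profile = NULL, tail_profile = NULL) {
  region <- assert_region(region)
  if (region == "H3") {
    if (is.null(h3_profile)) stop("H3 repertoire spec needs h3_profile", call. = FALSE)
  } else {
    stopifnot(!is.null(usage), !is.null(spectrum))
    if (abs(sum(usage) - 1) > 1e-9) stop("usage must sum to 1", call. = FALSE)
    if (substr(region, 2, 2) == "3" && is.null(tail_profile)) {
      stop("light-chain CDR3 spec needs tail_profile", call. = FALSE)
    }
  }
  structure(
    list(region = region, usage = usage, spectrum = spectrum, n = as.integer(n),
         seed = seed, h3_profile = h3_profile, tail_profile = tail_profile),
    class = "repertoire_spec"
  )
}

# Deterministic truth spectrum for one germline: positional rates in
# [0.03, 0.10], mass split 0.6/0.3/0.1 over three non-germline residues.
truth_spectrum <- function(germline, g_index, head_len = NULL) {
  gl <- chars(germline)
  L <- length(gl)
  m <- matrix(0, nrow = 20L, ncol = L, dimnames = list(AA20, NULL))
  Luse <- head_len %||% L
  for (p in seq_len(Luse)) {
    rate <- 0.03 + 0.07 * (((3L * p + 2L * g_index) %% 5L) / 4)
    targets <- character(0)
    j <- 0L
    while (length(targets) < 3L) {
      cand <- AA20[((5L * p + 3L * g_index + 7L * j) %% 20L) + 1L]
      j <- j + 1L
      if (cand != gl[p] && !cand %in% targets) targets <- c(targets, cand)
    }
    m[targets, p] <- c(0.6, 0.3, 0.1) * rate
  }
  m
}

#' Truth parameters for the demo repertoires
#'
#' `demo_repertoire_spec()` builds a [repertoire_spec()] with fixed,
#' deterministic truth parameters derived from [demo_germline_set()]:
#' geometric germline usage, positional substitution rates between 3% and
#' 10%, and (for CDR3 regions) the [demo_h3_profile()] /
#' [demo_l3_tail_profile()] truths. Default sample sizes follow the
#' natural-repertoire sizes the design analysis is calibrated for:
#' 8,846 heavy, 3,110 kappa and 2,440 lambda sequences per region.
#'
#' @param region two-character CDR region code.
#' @param n sample size (defaults per chain as above).
#' @param seed integer seed (optional).
#' @return a `repertoire_spec`.
#' @export
demo_repertoire_spec <- function(region, n = NULL, seed = NULL) {
  region <- assert_region(region)
  chain <- cdr_region_info(region)$chain
  n <- n %||% c(heavy = 8846L, kappa = 3110L, lambda = 2440L)[[chain]]
  if (region == "H3") {
    return(repertoire_spec(region, n = n, seed = seed, h3_profile = demo_h3_profile()))
  }
  gl <- germlines_for(demo_germline_set(), region)
  gl <- gl[order(names(gl))]
  k <- length(gl)
  w <- 0.5^seq_len(k)
  usage <- stats::setNames(w / sum(w), names(gl))
  tail_prof <- NULL
  head_len <- NULL
  if (substr(region, 2, 2) == "3") {
    tail_prof <- demo_l3_tail_profile(region)
    head_len <- nchar(gl) - tail_prof$tail_len[as.character(nchar(gl))]
  }
  spectrum <- lapply(seq_len(k), function(i) {
    truth_spectrum(gl[[i]], i, head_len = head_len[i])
  })
  names(spectrum) <- names(gl)
  repertoire_spec(region, usage = usage, spectrum = spectrum, n = n,
                  seed = seed, tail_profile = tail_prof)
}

#' Truth positional profile for CDR-H3
#'
#' A fixed `h3_profile` emulating natural heavy CDR3: lengths 9-20 with a
#' mode near 12-13, antibody-like positional amino-acid frequencies with a
#' mild deterministic positional tilt, and a J-segment-like terminal 3-mer
#' unit table (Phe/Met-Asp-Tyr/Val/... consensus).
#'
#' @return an `h3_profile`.
#' @export
demo_h3_profile <- function() {
  lens <- 9:20
  w <- stats::dnorm(lens, mean = 12.5, sd = 2.2)
  length_dist <- stats::setNames(w / sum(w), lens)
  base <- c(A = .06, C = .005, D = .08, E = .04, F = .04, G = .13, H = .02,
            I = .03, K = .04, L = .06, M = .02, N = .05, P = .04, Q = .03,
            R = .08, S = .12, T = .06, V = .06, W = .015, Y = .10)
  base <- base[AA20] / sum(base)
  positional <- lapply(lens, function(L) {
    ncolm <- L - 3L
    m <- vapply(seq_len(ncolm), function(p) {
      f <- base * (1 + 0.2 * cos(p / 2 + L / 3))
      f / sum(f)
    }, numeric(20L))
    rownames(m) <- AA20
    m
  })
  names(positional) <- lens
  terminal_units <- c(
    FDY = 0.22, MDV = 0.14, FDI = 0.10, LDY = 0.09, MDY = 0.08, FDV = 0.08,
    YDY = 0.07, FDS = 0.06, VDY = 0.06, LDV = 0.05, GDY = 0.05
  )
  structure(
    list(length_dist = length_dist, positional = positional,
         terminal_units = terminal_units, terminal_len = 3L, n = NA_integer_),
    class = "h3_profile"
  )
}

#' Truth tail profile for light-chain CDR3
#'
#' Fixed per-length tail positional frequencies emulating the N-terminal
#' part of the J-segment: tails of length 2 for CDRs of length <= 9 and 3
#' otherwise, ending predominantly in Thr/Val.
#'
#' @param region `"K3"` or `"L3"`.
#' @return an `l3_tail_profile`.
#' @export
demo_l3_tail_profile <- function(region = c("K3", "L3")) {
  region <- match.arg(region)
  gl <- germlines_for(demo_germline_set(), region)
  lens <- sort(unique(nchar(gl)))
  rule <- l3_split_rule(lens)
  cols2 <- list(
    c(L = 0.6, P = 0.2, R = 0.1, W = 0.1),
    c(T = 0.85, S = 0.15)
  )
  cols3 <- list(
    c(P = 0.5, L = 0.3, V = 0.2),
    c(L = 0.5, P = 0.3, I = 0.2),
    c(T = 0.8, V = 0.1, S = 0.1)
  )
  tail_positional <- lapply(lens, function(L) {
    cols <- if (rule[[as.character(L)]] == 2L) cols2 else cols3
    m <- matrix(0, nrow = 20L, ncol = length(cols), dimnames = list(AA20, NULL))
    for (q in seq_along(cols)) m[names(cols[[q]]), q] <- cols[[q]]
    m
  })
  names(tail_positional) <- lens
  structure(
    list(region = region, tail_len = rule, tail_positional = tail_positional,
         n = NA_integer_),
    class = "l3_tail_profile"
  )
}

#' Generate a synthetic natural repertoire with known parameters
#'
#' Draws `spec$n` sequences under the spec's truth parameters: a
#' usage-drawn germline with independent per-position substitutions for
#' CDR1/2 regions, the hybrid head+tail model for light CDR3, and the
#' positional model for heavy CDR3. Deterministic under `spec$seed`.
#'
#' @param spec a [repertoire_spec()].
#' @param germlines a [germline_set()]; must contain every germline named
#'   in the spec's usage (not used for `H3`).
#' @return a [cdr_repertoire()].
#' @export
generate_natural_repertoire <- function(spec, germlines = demo_germline_set()) {
  region <- spec$region
  run <- function() {
    if (region == "H3") {
      return(simulate_h3(spec$h3_profile, spec$n))
    }
    glset <- germlines_for(germlines, region)
    missing_g <- setdiff(names(spec$usage), names(glset))
    if (length(missing_g) > 0) {
      stop("usage germline(s) absent from germline set: ",
           paste(missing_g, collapse = ", "), call. = FALSE)
    }
    truth <- structure(
      list(region = region, usage = spec$usage,
           germline_seqs = glset[names(spec$usage)],
           spectrum = spec$spectrum, length_dist = NULL,
           n_assigned = NA_integer_, n_unassigned = NA_integer_),
      class = "shm_profile"
    )
    if (substr(region, 2, 2) == "3") {
      simulate_l3(truth, spec$tail_profile, spec$n)
    } else {
      simulate_germline_cdr(truth, spec$n)
    }
  }
  seqs <- if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
  cdr_repertoire(seqs, region)
}

#' Specification for synthetic library reads
#'
#' Parameters of the error-bearing read simulator: the designed
#' repertoires and scaffolds to draw from, the number of scFv clones
#' (each contributing one heavy-domain and one light-domain read), the
#' per-nucleotide substitution/deletion/insertion probabilities emulating
#' array-synthesis and PCR errors, a per-read premature-stop injection
#' probability, and the `proofread` flag which retains only fully in-frame
#' reads -- emulating the selective outcome of panning single-CDR libraries
#' against an anti-tag antibody.
#'
#' @param designs named list (region code to designed repertoire) covering
#'   the regions of the requested domains.
#' @param scaffolds named list of scaffolds (`heavy`, `kappa`, `lambda`).
#' @param depth number of clones.
#' @param substitution_rate,deletion_rate,insertion_rate per-nucleotide
#'   error probabilities.
#' @param stop_inject_rate per-read probability of replacing one CDR codon
#'   with a premature stop.
#' @param proofread drop reads with any frameshifted segment or internal
#'   stop codon (default `FALSE`).
#' @param cdr_only restrict errors to CDR segments (calibration mode;
#'   default `FALSE`).
#' @param domains which domain reads to emit (`"VH"`, `"VL"` or both).
#' @param light_mix kappa/lambda clone proportions.
#' @param seed integer seed (optional).
#' @return a `read_sim_spec` object.
#' @export
read_sim_spec <- function(designs, scaffolds, depth = 1000L,
                          substitution_rate = 0.002, deletion_rate = 0.002,
                          insertion_rate = 0.001, stop_inject_rate = 0.01,
                          proofread = FALSE, cdr_only = FALSE,
                          domains = c("VH", "VL"),
                          light_mix = c(kappa = 0.5, lambda = 0.5),
                          seed = NULL) {
  stopifnot(
    all(c(substitution_rate, deletion_rate, insertion_rate, stop_inject_rate) >= 0),
    all(c(substitution_rate, deletion_rate, insertion_rate, stop_inject_rate) <= 1)
  )
  domains <- match.arg(domains, several.ok = TRUE)
  structure(
    list(designs = designs, scaffolds = scaffolds, depth = as.integer(depth),
         substitution_rate = substitution_rate, deletion_rate = deletion_rate,
         insertion_rate = insertion_rate, stop_inject_rate = stop_inject_rate,
         proofread = isTRUE(proofread), cdr_only = isTRUE(cdr_only),
         domains = domains, light_mix = light_mix / sum(light_mix), seed = seed),
    class = "read_sim_spec"
  )
}

mutate_segment <- function(s, sub, del, ins) {
  if (sub == 0 && del == 0 && ins == 0) {
    return(list(seq = s, net = 0L))
  }
  ch <- chars(s)
  n <- length(ch)
  bases <- c("A", "C", "G", "T")
  if (sub > 0 && n > 0) {
    hit <- which(stats::runif(n) < sub)
    for (i in hit) ch[i] <- sample(bases[bases != ch[i]], 1L)
  }
  ndel <- 0L
  if (del > 0 && n > 0) {
    keep <- stats::runif(length(ch)) >= del
    ndel <- sum(!keep)
    ch <- ch[keep]
  }
  nins <- 0L
  if (ins > 0 && length(ch) > 0) {
    at <- which(stats::runif(length(ch)) < ins)
    nins <- length(at)
    if (nins > 0) {
      new <- vector("list", length(ch))
      for (i in seq_along(ch)) new[[i]] <- ch[i]
      for (i in at) new[[i]] <- c(new[[i]], sample(bases, 1L))
      ch <- unlist(new)
    }
  }
  list(seq = paste(ch, collapse = ""), net = nins - ndel)
}

#' Generate synthetic library reads
#'
#' Each clone draws one designed CDR per region, is assembled into
#' nucleotide variable domains on the scaffolds, and emits one read per
#' requested domain with per-nucleotide errors applied segment-wise.
#' Premature stops are injected into a random CDR codon at the spec's
#' per-read rate. With `proofread = TRUE`, reads whose segments do not all
#' conserve length modulo 3 or whose frame-0 translation contains an
#' internal stop are discarded (longer CDRs accumulate more indels, so
#' their dropout emerges naturally). Deterministic under `spec$seed`.
#'
#' @param spec a [read_sim_spec()].
#' @return tibble with columns `read_id`, `sequence`, `chain`, `domain`
#'   (`chain` is the truth label, not an annotation).
#' @export
generate_library_reads <- function(spec) {
  if (spec$depth == 0L) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          chain = character(), domain = character()))
  }
  run <- function() generate_reads_impl(spec)
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}

generate_reads_impl <- function(spec) {
  designs <- lapply(spec$designs, function(d) if (is.data.frame(d)) d$sequence else as.character(d))
  depth <- spec$depth
  light_chain <- sample(names(spec$light_mix), depth, replace = TRUE, prob = spec$light_mix)

  pick <- function(region, k) {
    pool <- designs[[region]]
    if (is.null(pool)) stop("no design for region ", region, call. = FALSE)
    pool[sample.int(length(pool), k, replace = TRUE)]
  }

  out_id <- character(0)
  out_seq <- character(0)
  out_chain <- character(0)
  out_domain <- character(0)
  out_ok <- logical(0)

  emit_domain <- function(domain, chain_of_clone, cdr_mat) {
    for (j in seq_len(depth)) {
      chain <- chain_of_clone[j]
      sc <- spec$scaffolds[[chain]]
      segs <- domain_segments_nt(cdr_mat[j, ], sc)
      if (stats::runif(1) < spec$stop_inject_rate) {
        k <- sample(c("CDR1", "CDR2", "CDR3"), 1L)
        ncod <- nchar(segs[[k]]) %/% 3L
        cpos <- (sample.int(ncod, 1L) - 1L) * 3L + 1L
        substr(segs[[k]], cpos, cpos + 2L) <- "TAA"
      }
      net_ok <- TRUE
      for (sname in names(segs)) {
        if (spec$cdr_only && startsWith(sname, "FR")) next
        mut <- mutate_segment(segs[[sname]], spec$substitution_rate,
                              spec$deletion_rate, spec$insertion_rate)
        segs[[sname]] <- mut$seq
        if (mut$net %% 3L != 0L) net_ok <- FALSE
      }
      read <- paste(segs, collapse = "")
      out_id[[length(out_id) + 1L]] <<- sprintf("clone%06d_%s", j, domain)
      out_seq[[length(out_seq) + 1L]] <<- read
      out_chain[[length(out_chain) + 1L]] <<- chain
      out_domain[[length(out_domain) + 1L]] <<- domain
      out_ok[[length(out_ok) + 1L]] <<- net_ok
    }
  }

  if ("VH" %in% spec$domains) {
    h_cdrs <- cbind(pick("H1", depth), pick("H2", depth), pick("H3", depth))
    emit_domain("VH", rep("heavy", depth), h_cdrs)
  }
  if ("VL" %in% spec$domains) {
    l_cdrs <- matrix("", nrow = depth, ncol = 3L)
    for (chain in unique(light_chain)) {
      idx <- which(light_chain == chain)
      regs <- chain_regions(chain)
      for (c3 in 1:3) l_cdrs[idx, c3] <- pick(regs[c3], length(idx))
    }
    emit_domain("VL", light_chain, l_cdrs)
  }

  out <- tibble::tibble(read_id = out_id, sequence = out_seq,
                        chain = out_chain, domain = out_domain)
  if (spec$proofread) {
    aa <- translate_frames(out$sequence)[[1]]
    no_stop <- !grepl("*", aa, fixed = TRUE)
    out <- out[out_ok & no_stop, , drop = FALSE]
  }
  out
}
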