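#' Default design configuration
#'
#' Per-region target totals (CDR-H3 sized to fill two full synthesis pools,
#' 7,836 sequences; K2 and L2 at 1,000; the remaining regions at 1,500), the
#' CDR-H3 length range (9-20), the array-synthesis pool capacity (3,918
#' oligonucleotides per pool) and the PTM policy.
#'
#' @param targets named integer vector of per-region totals; defaults above.
#' @param h3_length_range inclusive CDR-H3 length bounds.
#' @param pool_capacity maximum oligos per synthesis pool.
#' @param ptm a [ptm_policy()].
#' @return a `design_config` list.
#' @export
design_config <- function(targets = NULL,
                          h3_length_range = c(9L, 20L),
                          pool_capacity = 3918L,
                          ptm = ptm_policy()) {
  default <- c(H1 = 1500L, H2 = 1500L, H3 = 7836L,
               K1 = 1500L, K2 = 1000L, K3 = 1500L,
               L1 = 1500L, L2 = 1000L, L3 = 1500L)
  if (!is.null(targets)) {
    default[assert_region(names(targets))] <- as.integer(targets)
  }
  stopifnot(all(default > 0), pool_capacity > 0)
  structure(
    list(targets = default, h3_length_range = as.integer(h3_length_range),
         pool_capacity = as.integer(pool_capacity), ptm = ptm),
    class = "design_config"
  )
}

#' Simulate CDRs from a germline-usage / hypermutation profile
#'
#' A germline ancestor is drawn according to the profile's usage
#' frequencies; then, independently at every position, the germline residue
#' is replaced with probability equal to that position's total substitution
#' frequency, the replacement drawn from the position's substitution
#' distribution.
#'
#' @param profile an `shm_profile` (see [build_shm_profile()]).
#' @param n number of sequences to draw.
#' @return character vector of `n` amino-acid sequences.
#' @export
simulate_germline_cdr <- function(profile, n = 1L) {
  if (length(profile$usage) == 0) stop("profile has empty germline usage", call. = FALSE)
  draw_germline_based(profile$usage, profile$germline_seqs, profile$spectrum, n)
}

draw_germline_based <- function(usage, germline_seqs, spectrum, n,
                                head_only_len = NULL, g_draw = NULL) {
  if (is.null(g_draw)) g_draw <- sample_named(usage, n)
  out <- character(n)
  for (g in sort(unique(g_draw))) {
    idx <- which(g_draw == g)
    gl <- chars(germline_seqs[[g]])
    L <- length(gl)
    Luse <- if (is.null(head_only_len)) L else head_only_len[[g]]
    S <- spectrum[[g]]
    k <- length(idx)
    mat <- matrix(gl[seq_len(Luse)], nrow = k, ncol = Luse, byrow = TRUE)
    rates <- colSums(S)
    for (p in seq_len(Luse)) {
      if (rates[p] <= 0) next
      hit <- stats::runif(k) < rates[p]
      nh <- sum(hit)
      if (nh > 0) {
        mat[hit, p] <- sample(AA20, nh, replace = TRUE, prob = S[, p] / rates[p])
      }
    }
    out[idx] <- apply(mat, 1, paste, collapse = "")
    if (k == 1L) out[idx] <- paste(mat[1, ], collapse = "")
  }
  out
}

#' Simulate CDR-H3 sequences from a positional profile
#'
#' A length is drawn from the profile's length distribution; the first
#' `length - terminal_len` residues are drawn independently from the
#' per-position amino-acid frequencies for that length; the last
#' `terminal_len` residues are drawn as one unit from the terminal-unit
#' frequencies (the J-segment-derived Kabat 100-102 tail for the default
#' unit length of 3).
#'
#' @param profile an `h3_profile` (see [build_h3_profile()]).
#' @param n number of sequences to draw.
#' @return character vector of `n` amino-acid sequences.
#' @export
simulate_h3 <- function(profile, n = 1L) {
  lens <- sample_named(profile$length_dist, n)
  out <- character(n)
  for (L in sort(unique(lens))) {
    idx <- which(lens == L)
    m <- profile$positional[[L]]
    if (is.null(m)) stop("no positional table for drawn length ", L, call. = FALSE)
    k <- length(idx)
    ncolm <- ncol(m)
    head_mat <- matrix("", nrow = k, ncol = ncolm)
    for (p in seq_len(ncolm)) {
      head_mat[, p] <- sample(AA20, k, replace = TRUE, prob = m[, p])
    }
    heads <- if (ncolm > 0) apply(head_mat, 1, paste, collapse = "") else rep("", k)
    if (k == 1L && ncolm > 0) heads <- paste(head_mat[1, ], collapse = "")
    tails <- if (profile$terminal_len > 0) {
      sample_named(profile$terminal_units, k)
    } else {
      rep("", k)
    }
    out[idx] <- paste0(heads, tails)
  }
  out
}

#' Simulate light-chain CDR3 sequences (hybrid head + tail model)
#'
#' A germline ancestor is drawn from the head profile's usage; the first
#' `length - tail_len` positions are simulated exactly as in
#' [simulate_germline_cdr()]; the last `tail_len` residues (the
#' J-segment-derived tail) are drawn per position from the tail profile for
#' the germline's length.
#'
#' @param profile an `shm_profile` for region `K3` or `L3` (the head model).
#' @param tail an `l3_tail_profile` (see [build_l3_tail_profile()]).
#' @param n number of sequences to draw.
#' @return character vector of `n` amino-acid sequences.
#' @export
simulate_l3 <- function(profile, tail, n = 1L) {
  if (length(profile$usage) == 0) stop("profile has empty germline usage", call. = FALSE)
  g_len <- nchar(profile$germline_seqs)
  missing_len <- setdiff(as.character(unique(g_len)), names(tail$tail_positional))
  if (length(missing_len) > 0) {
    stop("no tail table for CDR length(s) ", paste(missing_len, collapse = ", "),
         call. = FALSE)
  }
  head_len <- stats::setNames(
    g_len - tail$tail_len[as.character(g_len)],
    names(profile$germline_seqs)
  )
  g_draw <- sample_named(profile$usage, n)
  heads <- draw_germline_based(profile$usage, profile$germline_seqs,
                               profile$spectrum, n,
                               head_only_len = head_len, g_draw = g_draw)
  drawn_len <- g_len[g_draw]
  out <- character(n)
  for (L in sort(unique(drawn_len))) {
    idx <- which(drawn_len == L)
    tl <- tail$tail_len[[as.character(L)]]
    m <- tail$tail_positional[[as.character(L)]]
    k <- length(idx)
    tail_mat <- matrix("", nrow = k, ncol = tl)
    for (q in seq_len(tl)) {
      tail_mat[, q] <- sample(AA20, k, replace = TRUE, prob = m[, q])
    }
    tails <- apply(tail_mat, 1, paste, collapse = "")
    if (k == 1L) tails <- paste(tail_mat[1, ], collapse = "")
    out[idx] <- paste0(heads[idx], tails)
  }
  out
}

junction_flanks <- function(scaffold, loop, flank) {
  if (is.null(scaffold) || flank == 0L) return(list(left = "", right = ""))
  up <- scaffold$fr_protein[[loop]]
  down <- scaffold$fr_protein[[loop + 1L]]
  list(
    left = substr(up, nchar(up) - flank + 1L, nchar(up)),
    right = substr(down, 1L, flank)
  )
}

#' Design a PTM-filtered CDR repertoire
#'
#' Candidate CDRs are drawn from the region's simulator
#' ([simulate_germline_cdr()] for CDR1/2, [simulate_h3()] for heavy CDR3,
#' [simulate_l3()] for light CDR3); every candidate carrying a PTM liability
#' motif under `policy` -- scanned together with the scaffold's junction
#' residues -- is rejected, and drawing continues until exactly `n_target`
#' accepted sequences (redundancy allowed) have accumulated. Germline head
#' sequences are sanitised (`DG`/`NG` to `SG`) before simulation, mirroring
#' the germline clean-up done before repertoire design.
#'
#' @param profiles a single profile object, or a list with elements `shm`,
#'   `h3`, `l3_tail` as the region requires.
#' @param region two-character CDR region code.
#' @param scaffold a [framework_scaffold()] providing junction flanks, or
#'   `NULL` to scan bare CDRs.
#' @param n_target number of accepted sequences; defaults to the region's
#'   [design_config()] target.
#' @param policy a [ptm_policy()].
#' @param sanitize substitute `DG`/`NG` with `SG` in germline heads before
#'   simulation (default `TRUE`; ignored for CDR-H3).
#' @param seed integer seed for reproducibility (optional).
#' @param max_attempts attempt budget: if no candidate has been accepted
#'   after this many draws, an error reports the rejection diagnostics.
#' @return a [designed_repertoire()].
#' @export
design_repertoire <- function(profiles, region, scaffold = NULL,
                              n_target = NULL, policy = ptm_policy(),
                              sanitize = TRUE, seed = NULL,
                              max_attempts = NULL) {
  region <- assert_region(region)
  if (inherits(profiles, "shm_profile")) profiles <- list(shm = profiles)
  if (inherits(profiles, "h3_profile")) profiles <- list(h3 = profiles)
  n_target <- n_target %||% design_config()$targets[[region]]
  max_attempts <- max_attempts %||% max(10L * n_target, 10000L)
  loop <- as.integer(substr(region, 2, 2))
  fl <- junction_flanks(scaffold, loop, policy$junction_flank)

  sim <- make_simulator(profiles, region, sanitize)

  draw <- function() {
    accepted <- character(0)
    drawn <- 0L
    repeat {
      k <- min(max(2L * (n_target - length(accepted)), 500L), 50000L)
      cand <- sim(k)
      drawn <- drawn + k
      ok <- ptm_clean(cand, region, policy, fl$left, fl$right)
      accepted <- c(accepted, cand[ok])
      if (length(accepted) >= n_target) break
      if (length(accepted) == 0L && drawn >= max_attempts) {
        stop("design_repertoire(", region, "): 0 of ", drawn,
             " candidates passed the PTM policy; check profiles and policy",
             call. = FALSE)
      }
      if (drawn > 1000L * n_target + 100000L) {
        stop("design_repertoire(", region, "): acceptance rate too low (",
             length(accepted), "/", drawn, ")", call. = FALSE)
      }
    }
    accepted[seq_len(n_target)]
  }
  accepted <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  designed_repertoire(accepted, region)
}

make_simulator <- function(profiles, region, sanitize) {
  loop <- substr(region, 2, 2)
  chain <- substr(region, 1, 1)
  if (region == "H3") {
    prof <- profiles$h3
    if (is.null(prof)) stop("CDR-H3 design needs an h3_profile", call. = FALSE)
    return(function(k) simulate_h3(prof, k))
  }
  prof <- profiles$shm
  if (is.null(prof)) stop("region ", region, " needs an shm_profile", call. = FALSE)
  if (sanitize) {
    prof$germline_seqs <- sanitize_seqs(prof$germline_seqs)
  }
  if (loop == "3") {
    tail <- profiles$l3_tail
    if (is.null(tail)) stop("light-chain CDR3 design needs an l3_tail_profile", call. = FALSE)
    return(function(k) simulate_l3(prof, tail, k))
  }
  function(k) simulate_germline_cdr(prof, k)
}
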