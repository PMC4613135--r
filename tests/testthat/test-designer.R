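test_that("germline sanitisation replaces DG/NG dipeptides with SG", {
  gs <- germline_set(data.frame(
    region = c("H2", "K2", "H2"),
    name = c("a", "b", "c"),
    sequence = c("INSDGSST", "AASSLQS", "NGNG")
  ))
  out <- sanitize_germline(gs)
  expect_equal(out$sequence, c("INSSGSST", "AASSLQS", "SGSG"))
})

test_that("the PTM scanner reports motifs, junction hits and exemptions", {
  pol <- ptm_policy()
  # DG inside a CDR-H2-like context
  hits <- scan_ptm("WISPDGG", "H2", pol)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif_kind, "DG")
  expect_equal(hits$seq_start, 5L)

  # NXS/NXT requires X != P
  expect_equal(nrow(scan_ptm("NPS", "H2", pol)), 0L)

  # Met exemption at the 4th residue of CDR-H1 (Kabat H34)
  expect_equal(nrow(scan_ptm("SYAMS", "H1", pol)), 0L)
  # ... but a Met elsewhere in H1 is a hit
  expect_equal(scan_ptm("MYAAS", "H1", pol)$motif_kind, "Met")

  # overlapping motif families are both reported
  ngs <- scan_ptm("NGS", "H2", pol)
  expect_setequal(ngs$motif_kind, c("NG", "glyc"))

  # H3 tail exemption: Met at third-from-last is tolerated
  expect_equal(nrow(scan_ptm("AAAAAAMDV", "H3", pol)), 0L)
  expect_equal(scan_ptm("AAAAAMADV", "H3", pol)$motif_kind, "Met")
})

test_that("junction flanks catch motifs straddling the CDR boundary and ignore flank-only hits", {
  pol <- ptm_policy()
  # CDR ends with N, downstream framework begins with GS: NG straddles
  hits <- scan_ptm("AAAN", "K1", pol, left_flank = "AS", right_flank = "GS")
  expect_true("NG" %in% hits$motif_kind)
  # a Cys entirely inside the flank is not reported
  expect_equal(nrow(scan_ptm("AAAA", "K1", pol, left_flank = "CS", right_flank = "GS")), 0L)
})

test_that("the vectorised hit matrix agrees with the sliding-window oracle", {
  pol <- ptm_policy()
  withr::with_seed(77, {
    for (region in c("H1", "H3", "K2")) {
      seqs <- random_aa(300, if (region == "H1") 5 else 9)
      got <- !cdrforge:::ptm_clean(seqs, region, pol, "AS", "WV")
      exp <- vapply(seqs, oracle_has_ptm, logical(1), region = region,
                    left = "AS", right = "WV", USE.NAMES = FALSE)
      expect_equal(got, exp)
    }
  })
})

test_that("germline-based simulation reproduces degenerate and forced profiles", {
  mk_profile <- function(seq, spectrum) {
    m <- matrix(0, 20, nchar(seq), dimnames = list(AA_LETTERS, NULL))
    if (!is.null(spectrum)) m[spectrum$res, spectrum$pos] <- spectrum$rate
    structure(list(region = "K2", usage = c(g = 1),
                   germline_seqs = c(g = seq), spectrum = list(g = m),
                   length_dist = NULL, n_assigned = 1L, n_unassigned = 0L),
              class = "shm_profile")
  }
  # all substitution rates zero: germline returned unchanged
  p0 <- mk_profile("AASSLQS", NULL)
  expect_equal(unique(simulate_germline_cdr(p0, 50)), "AASSLQS")

  # rate 1.0 toward Y at position 2: position 2 always Y
  p1 <- mk_profile("AASSLQS", list(res = "Y", pos = 2, rate = 1.0))
  out <- simulate_germline_cdr(p1, 50)
  expect_true(all(substr(out, 2, 2) == "Y"))
  expect_true(all(substr(out, 3, 7) == "SSLQS"))

  # rate 0.1 at one position: observed fraction within 3 binomial SE at n = 10,000
  p2 <- mk_profile("AASSLQS", list(res = "Y", pos = 4, rate = 0.1))
  withr::with_seed(42, {
    out2 <- simulate_germline_cdr(p2, 10000)
  })
  frac <- mean(substr(out2, 4, 4) == "Y")
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("H3 simulation draws heads positionally and tails as units", {
  deg <- matrix(0, 20, 9, dimnames = list(AA_LETTERS, NULL))
  deg["G", ] <- 1
  prof <- structure(
    list(length_dist = c("12" = 1.0), positional = list("12" = deg),
         terminal_units = c(FDY = 1.0), terminal_len = 3L, n = 1L),
    class = "h3_profile"
  )
  out <- simulate_h3(prof, 20)
  expect_equal(unique(out), "GGGGGGGGGFDY")

  prof$terminal_units <- c(FDY = 0.5, MDV = 0.5)
  withr::with_seed(7, out2 <- simulate_h3(prof, 10000))
  frac <- mean(endsWith(out2, "MDV"))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("light CDR3 simulation joins germline heads with positional tails", {
  m <- matrix(0, 20, 9, dimnames = list(AA_LETTERS, NULL))
  prof <- structure(
    list(region = "K3", usage = c(g = 1), germline_seqs = c(g = "QQSYSTPLT"),
         spectrum = list(g = m), length_dist = NULL,
         n_assigned = 1L, n_unassigned = 0L),
    class = "shm_profile"
  )
  tailm <- matrix(0, 20, 2, dimnames = list(AA_LETTERS, NULL))
  tailm["L", 1] <- 0.75
  tailm["P", 1] <- 0.25
  tailm["T", 2] <- 1
  tail <- structure(
    list(region = "K3", tail_len = c("9" = 2L),
         tail_positional = list("9" = tailm), n = 1L),
    class = "l3_tail_profile"
  )
  # zero head rates: head equals the germline prefix
  withr::with_seed(5, out <- simulate_l3(prof, tail, 10000))
  expect_true(all(substr(out, 1, 7) == "QQSYSTP"))
  expect_true(all(substr(out, 9, 9) == "T"))
  frac_p <- mean(substr(out, 8, 8) == "P")
  expect_lt(abs(frac_p - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))

  # a germline length without a tail table is an error
  prof2 <- prof
  prof2$germline_seqs <- c(g = "QQSYSTPPLT")
  prof2$spectrum <- list(g = matrix(0, 20, 10, dimnames = list(AA_LETTERS, NULL)))
  expect_error(simulate_l3(prof2, tail, 1), "tail table")
})

test_that("design_repertoire yields the exact target with zero PTM hits and is seed-reproducible", {
  gs <- demo_germline_set()
  sc <- demo_scaffolds()
  nat <- generate_natural_repertoire(demo_repertoire_spec("K1", n = 2000, seed = 9), gs)
  prof <- build_shm_profile(nat, gs)
  d1 <- design_repertoire(prof, "K1", sc$kappa, n_target = 100, seed = 123)
  expect_equal(nrow(d1), 100L)
  expect_s3_class(d1, "designed_repertoire")
  expect_lte(attr(d1, "unique_count"), 100L)

  fl <- cdrforge:::junction_flanks(sc$kappa, 1L, 2L)
  rescanned <- vapply(d1$sequence, oracle_has_ptm, logical(1), region = "K1",
                      left = fl$left, right = fl$right, USE.NAMES = FALSE)
  expect_false(any(rescanned))

  d2 <- design_repertoire(prof, "K1", sc$kappa, n_target = 100, seed = 123)
  expect_identical(d1$sequence, d2$sequence)
  d3 <- design_repertoire(prof, "K1", sc$kappa, n_target = 100, seed = 124)
  expect_false(identical(d1$sequence, d3$sequence))
})

test_that("a policy that rejects every candidate raises a diagnostic error", {
  m <- matrix(0, 20, 7, dimnames = list(AA_LETTERS, NULL))
  prof <- structure(
    list(region = "K2", usage = c(g = 1), germline_seqs = c(g = "CCCCCCC"),
         spectrum = list(g = m), length_dist = NULL,
         n_assigned = 1L, n_unassigned = 0L),
    class = "shm_profile"
  )
  expect_error(
    design_repertoire(prof, "K2", n_target = 10, seed = 1, max_attempts = 2000),
    "0 of"
  )
})

test_that("designed repertoires stay nature-like: mutation load matches the profile expectation", {
  gs <- demo_germline_set()
  nat <- generate_natural_repertoire(demo_repertoire_spec("K2", n = 4000, seed = 21), gs)
  prof <- build_shm_profile(nat, gs)
  # no PTM filtering here: the check is on the simulator itself
  withr::with_seed(22, sims <- simulate_germline_cdr(prof, 4000))
  mm <- mutation_statistics(tibble::tibble(region = "K2", sequence = sims), gs)
  avg <- sum(mm$mean_mutations * mm$n) / sum(mm$n)
  expected <- expected_mutations(prof)
  se <- sqrt(expected / 4000)  # Poisson-binomial scale approximation
  expect_lt(abs(avg - expected), 3 * se + 0.02)
})
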