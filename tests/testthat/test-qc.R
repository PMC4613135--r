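# Shared fixtures: small designed repertoires on the demo scaffolds.
qc_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gs <- demo_germline_set()
    sc <- demo_scaffolds()
    designs <- list()
    for (r in cdr_regions()) {
      ch <- cdr_region_info(r)$chain
      n <- c(heavy = 2000L, kappa = 1200L, lambda = 1000L)[[ch]]
      nat <- generate_natural_repertoire(
        demo_repertoire_spec(r, n = n, seed = 300 + match(r, cdr_regions())), gs
      )
      profs <- if (r == "H3") {
        list(h3 = build_h3_profile(nat))
      } else if (substr(r, 2, 2) == "3") {
        list(shm = build_shm_profile(nat, gs), l3_tail = build_l3_tail_profile(nat))
      } else {
        list(shm = build_shm_profile(nat, gs))
      }
      designs[[r]] <- design_repertoire(profs, r, sc[[ch]], n_target = 250,
                                        seed = 400 + match(r, cdr_regions()))
    }
    cache <<- list(gs = gs, sc = sc, designs = designs)
    cache
  }
})

test_that("error-free reads round-trip through the annotator with all flags true", {
  fx <- qc_fixture()
  spec <- read_sim_spec(fx$designs, fx$sc, depth = 60,
                        substitution_rate = 0, deletion_rate = 0,
                        insertion_rate = 0, stop_inject_rate = 0, seed = 11)
  reads <- generate_library_reads(spec)
  ann <- annotate_reads(reads, fx$sc, fx$designs)
  resolved <- ann[!is.na(ann$cdr_nt_len), ]
  expect_equal(nrow(resolved), nrow(reads) * 3L)
  expect_true(all(resolved$in_frame))
  expect_true(all(resolved$designed_length))
  expect_true(all(resolved$designed_sequence))
  expect_false(any(resolved$has_stop))
  # truth chain labels are recovered
  truth <- reads$chain[match(resolved$read_id, reads$read_id)]
  expect_equal(resolved$chain, truth)
})

test_that("a single-nucleotide deletion inside CDR2 breaks only that region's frame", {
  fx <- qc_fixture()
  cdrs <- vapply(fx$designs[c("H1", "H2", "H3")], function(d) d$sequence[1], "")
  segs <- cdrforge:::domain_segments_nt(cdrs, fx$sc$heavy)
  segs[["CDR2"]] <- paste0(substr(segs[["CDR2"]], 1, 9),
                           substr(segs[["CDR2"]], 11, nchar(segs[["CDR2"]])))
  read <- paste(segs, collapse = "")
  ann <- annotate_reads(read, fx$sc$heavy, fx$designs)
  expect_false(ann$in_frame[ann$region == "H2"])
  expect_true(ann$in_frame[ann$region == "H1"])
  expect_true(ann$in_frame[ann$region == "H3"])
})

test_that("a premature stop codon inside CDR3 sets has_stop and clears in_frame", {
  fx <- qc_fixture()
  cdrs <- vapply(fx$designs[c("H1", "H2", "H3")], function(d) d$sequence[1], "")
  segs <- cdrforge:::domain_segments_nt(cdrs, fx$sc$heavy)
  substr(segs[["CDR3"]], 4, 6) <- "TAG"
  read <- paste(segs, collapse = "")
  ann <- annotate_reads(read, fx$sc$heavy, fx$designs)
  expect_true(all(ann$has_stop))
  expect_false(ann$in_frame[ann$region == "H3"])
  expect_true(ann$in_frame[ann$region == "H1"])
})

test_that("unannotatable reads get chain unknown and all-false flags, not an error", {
  fx <- qc_fixture()
  withr::with_seed(9, junk <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))
  ann <- annotate_reads(junk, fx$sc)
  expect_equal(unique(ann$chain), "unknown")
  expect_true(all(is.na(ann$cdr_nt_len)))
  expect_false(any(ann$in_frame))
})

test_that("the flag hierarchy designed_sequence => designed_length => in_frame always holds", {
  fx <- qc_fixture()
  spec <- read_sim_spec(fx$designs, fx$sc, depth = 120,
                        substitution_rate = 0.004, deletion_rate = 0.004,
                        insertion_rate = 0.002, stop_inject_rate = 0.05, seed = 13)
  reads <- generate_library_reads(spec)
  ann <- annotate_reads(reads, fx$sc, fx$designs)
  expect_true(all(!ann$designed_sequence | ann$designed_length))
  expect_true(all(!ann$designed_length | ann$in_frame))
})

test_that("library summaries compute percentages and coverage by direct counting", {
  # hand-built annotations: 10 resolved H1 rows, 9 in frame
  ann <- tibble::tibble(
    read_id = sprintf("r%02d", 1:10),
    chain = "heavy", frame = 0L, n_anchors = 6L, region = "H1",
    cdr_seq = c(sprintf("SEQ%d", c(1, 1, 2, 2, 3, 3, 4, 4, 4)), NA),
    cdr_nt_len = 15L,
    in_frame = c(rep(TRUE, 9), FALSE),
    designed_length = c(rep(TRUE, 9), FALSE),
    designed_sequence = c(rep(TRUE, 9), FALSE),
    has_stop = FALSE, fr_mutations = 0L, fr_residues = 10L
  )
  ann$cdr_seq <- gsub("SEQ", "AAAA", ann$cdr_seq)  # keep alphabetic
  designs <- list(H1 = paste0("AAAA", 1:5))
  designs$H1 <- c("AAAAG", "AAAAS", "AAAAT", "AAAAV", "AAAAY")
  ann$cdr_seq[1:9] <- rep(c("AAAAG", "AAAAS", "AAAAT", "AAAAV"), c(2, 2, 2, 3))
  rep <- summarize_library(ann, designs)
  h1 <- rep$region_stats[rep$region_stats$region == "H1", ]
  expect_equal(h1$processed, 10L)
  expect_equal(h1$in_frame_pct, 90)
  # 4 of 5 designed unique sequences observed: coverage 80%
  expect_equal(h1$design_coverage_pct, 80)
})

test_that("mutation statistics average Hamming distances to the closest germline", {
  gs <- toy_germlines()
  seqs <- c("AASSLQS",   # 0 mismatches from gC
            "AATSLQS",   # 1
            "AATTLQS",   # 2
            "AASSLQT")   # 1
  mm <- mutation_statistics(tibble::tibble(region = "K2", sequence = seqs), gs)
  expect_equal(mm$mean_mutations, 1.0)
  expect_equal(mm$mutations_per_residue, 1 / 7)
  # H3 is excluded: no germline ancestors to compare with
  both <- mutation_statistics(
    tibble::tibble(region = c("K2", "H3"), sequence = c("AASSLQS", "AAAAAAAAA")), gs
  )
  expect_false("H3" %in% both$region)
})

test_that("framework mutation rates come from compared framework residues", {
  fx <- qc_fixture()
  spec <- read_sim_spec(fx$designs, fx$sc, depth = 40,
                        substitution_rate = 0, deletion_rate = 0,
                        insertion_rate = 0, stop_inject_rate = 0, seed = 15)
  reads <- generate_library_reads(spec)
  ann <- annotate_reads(reads, fx$sc, fx$designs)
  fr <- fr_mutation_rate(ann)
  expect_true(all(fr$mutations_per_residue == 0))
  expect_true(all(fr$fr_residues > 0))
})

test_that("PTM statistics count sequences with at least one hit, once each", {
  pol <- ptm_policy()
  x <- tibble::tibble(
    region = "K1",
    sequence = c("AADGAAA", "AAAAAAA", "AAAAAAA", "AAAAAAA")
  )
  tab <- ptm_statistics(x, pol)
  expect_equal(tab$pct[tab$motif == "DG"], 25)
  expect_equal(tab$pct[tab$motif == "Total"], 25)

  # a sequence with both DG and Met counts once in Total
  y <- tibble::tibble(region = "K1", sequence = c("AADGMAA", "AAAAAAA"))
  taby <- ptm_statistics(y, pol)
  expect_equal(taby$pct[taby$motif == "DG"], 50)
  expect_equal(taby$pct[taby$motif == "Met"], 50)
  expect_equal(taby$pct[taby$motif == "Total"], 50)

  # Total is subadditive relative to the motif rows
  fx <- qc_fixture()
  nat <- generate_natural_repertoire(demo_repertoire_spec("H2", n = 1500, seed = 77), fx$gs)
  tabn <- ptm_statistics(tibble::as_tibble(nat), pol)
  total <- tabn$pct[tabn$motif == "Total"]
  expect_lte(total, sum(tabn$pct[tabn$motif != "Total"]))
  expect_gt(total, 0)

  # designer output is identically zero under its own policy
  tabd <- ptm_statistics(tibble::as_tibble(fx$designs$H2), pol)
  expect_true(all(tabd$pct == 0))
})

test_that("design comparison yields r-squared 1 for proportional counts and ~0 for shuffled ones", {
  fx <- qc_fixture()
  des <- fx$designs$K2
  # observed exactly proportional to the design: every designed sequence twice
  ann <- tibble::tibble(
    read_id = sprintf("r%05d", seq_len(2 * nrow(des))),
    chain = "kappa", frame = 0L, n_anchors = 6L, region = "K2",
    cdr_seq = rep(des$sequence, 2), cdr_nt_len = 21L,
    in_frame = TRUE, designed_length = TRUE, designed_sequence = TRUE,
    has_stop = FALSE, fr_mutations = 0L, fr_residues = 10L
  )
  comp <- compare_design(ann, list(K2 = des))
  expect_equal(comp$r2$r_squared, 1.0)

  # frequencies shuffled against the design: r-squared near zero
  withr::with_seed(19, {
    counts <- stats::rpois(length(unique(des$sequence)), 5) + 1L
    shuffled <- sample(rep(unique(des$sequence), counts))
  })
  ann2 <- ann[seq_along(shuffled), ]
  ann2$cdr_seq <- shuffled
  comp2 <- compare_design(ann2, list(K2 = des))
  expect_lt(comp2$r2$r_squared, 0.35)

  # all observed sequences distinct: redundancy mass entirely at n = 1
  ann3 <- ann[!duplicated(ann$cdr_seq), ]
  comp3 <- compare_design(ann3, list(K2 = des))
  expect_equal(comp3$redundancy$times_seen, 1L)

  # fewer than three shared sequences: undefined marker
  ann4 <- ann[1:2, ]
  comp4 <- compare_design(ann4, list(K2 = des[1:2, ]))
  expect_true(is.na(comp4$r2$r_squared))
})

test_that("plot helpers return ggplot objects", {
  fx <- qc_fixture()
  prof <- demo_h3_profile()
  expect_s3_class(plot_positional_profile(prof), "ggplot")
  expect_s3_class(autoplot(prof), "ggplot")
})
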