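test_that("natural-repertoire generation respects degenerate and known parameters", {
  gs <- demo_germline_set()
  glK2 <- cdrforge:::germlines_for(gs, "K2")
  zero <- lapply(glK2, function(g) {
    matrix(0, 20, nchar(g), dimnames = list(AA_LETTERS, NULL))
  })
  usage <- c(0.7, 0.3)
  names(usage) <- names(glK2)[1:2]
  spec0 <- repertoire_spec("K2", usage = usage, spectrum = zero[names(usage)],
                           n = 500, seed = 4)
  nat0 <- generate_natural_repertoire(spec0, gs)
  # all rates zero: every sequence equals its germline
  expect_true(all(nat0$sequence %in% glK2[names(usage)]))

  # usage recovery: G1 fraction within 3 binomial SE at n = 10,000
  spec1 <- repertoire_spec("K2", usage = usage, spectrum = zero[names(usage)],
                           n = 10000, seed = 5)
  nat1 <- generate_natural_repertoire(spec1, gs)
  frac <- mean(nat1$sequence == glK2[[names(usage)[1]]])
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))

  # unknown usage key is an error
  bad <- repertoire_spec("K2", usage = c(nope = 1),
                         spectrum = list(nope = zero[[1]]), n = 10)
  expect_error(generate_natural_repertoire(bad, gs), "absent")
})

test_that("identical seeds give byte-identical repertoires and reads", {
  gs <- demo_germline_set()
  r1 <- generate_natural_repertoire(demo_repertoire_spec("H2", n = 500, seed = 8), gs)
  r2 <- generate_natural_repertoire(demo_repertoire_spec("H2", n = 500, seed = 8), gs)
  expect_identical(r1$sequence, r2$sequence)

  designs <- list(H1 = c("SYAMS", "DYAMH"), H2 = c("AISGSGGSTYYADSVKG"),
                  H3 = c("ARDRGYSSGWYFDY"))
  sc <- demo_scaffolds()
  spec <- read_sim_spec(designs, sc, depth = 40, seed = 12, domains = "VH")
  expect_identical(generate_library_reads(spec), generate_library_reads(spec))
})

test_that("profile estimation recovers generator parameters (closed loop)", {
  gs <- demo_germline_set()
  spec <- demo_repertoire_spec("K1", n = 10000, seed = 6)
  nat <- generate_natural_repertoire(spec, gs)
  prof <- build_shm_profile(nat, gs)
  # usage within 3 binomial SE
  for (g in names(spec$usage)) {
    p <- spec$usage[[g]]
    expect_lt(abs(prof$usage[[g]] - p), 3 * sqrt(p * (1 - p) / 10000) + 1e-9)
  }
  # per-position substitution rates within 3 SE (conditional n per germline)
  for (g in names(spec$usage)) {
    n_g <- round(spec$usage[[g]] * 10000)
    truth <- spec$spectrum[[g]]
    est <- prof$spectrum[[g]]
    rate_t <- colSums(truth)
    rate_e <- colSums(est)
    se <- sqrt(rate_t * (1 - rate_t) / n_g)
    expect_true(all(abs(rate_e - rate_t) <= 3 * se + 1e-9))
  }
})

test_that("error-free reads classify as 100% designed; proofreading leaves only in-frame reads", {
  gs <- demo_germline_set()
  sc <- demo_scaffolds()
  nat <- generate_natural_repertoire(demo_repertoire_spec("H3", n = 2000, seed = 31), gs)
  designs <- list(
    H1 = design_repertoire(build_shm_profile(
      generate_natural_repertoire(demo_repertoire_spec("H1", n = 1000, seed = 32), gs), gs
    ), "H1", sc$heavy, n_target = 150, seed = 33),
    H2 = design_repertoire(build_shm_profile(
      generate_natural_repertoire(demo_repertoire_spec("H2", n = 1000, seed = 34), gs), gs
    ), "H2", sc$heavy, n_target = 150, seed = 35),
    H3 = design_repertoire(list(h3 = build_h3_profile(nat)), "H3", sc$heavy,
                           n_target = 300, seed = 36)
  )
  clean <- read_sim_spec(designs, sc, depth = 50, substitution_rate = 0,
                         deletion_rate = 0, insertion_rate = 0,
                         stop_inject_rate = 0, seed = 37, domains = "VH")
  ann <- annotate_reads(generate_library_reads(clean), sc$heavy, designs)
  resolved <- ann[!is.na(ann$cdr_nt_len), ]
  expect_equal(mean(resolved$designed_sequence), 1)

  noisy <- read_sim_spec(designs, sc, depth = 150, substitution_rate = 0,
                         deletion_rate = 0.004, insertion_rate = 0,
                         stop_inject_rate = 0.1, proofread = TRUE,
                         seed = 38, domains = "VH", cdr_only = TRUE)
  reads <- generate_library_reads(noisy)
  expect_lt(nrow(reads), 150L)  # some reads were dropped
  ann2 <- annotate_reads(reads, sc$heavy, designs)
  resolved2 <- ann2[!is.na(ann2$cdr_nt_len), ]
  expect_equal(mean(resolved2$in_frame), 1)
})

test_that("depth zero yields an empty read collection", {
  spec <- read_sim_spec(list(H1 = "SYAMS"), demo_scaffolds(), depth = 0)
  expect_equal(nrow(generate_library_reads(spec)), 0L)
})
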