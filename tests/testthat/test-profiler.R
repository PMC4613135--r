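test_that("germline assignment finds the minimal-Hamming equal-length germline", {
  gs <- toy_germlines()
  a <- assign_germline("QSVTS", gs, "K1")
  expect_equal(a$germline_name, "gA")
  expect_equal(a$mismatch_count, 1L)
  expect_equal(a$mismatch_positions[[1]]$position, 4L)
  expect_equal(a$mismatch_positions[[1]]$observed_residue, "T")

  ident <- assign_germline("QDISN", gs, "K1")
  expect_equal(ident$mismatch_count, 0L)

  # no germline of length 6 for K1
  un <- assign_germline("QSVTSA", gs, "K1")
  expect_equal(un$germline_name, "unassigned")
  expect_true(is.na(un$mismatch_count))

  expect_error(assign_germline("", gs, "K1"))
})

test_that("germline assignment agrees with the brute-force Hamming oracle", {
  gs <- demo_germline_set()
  withr::with_seed(101, {
    for (region in c("H1", "K1", "L1")) {
      g <- gs[gs$region == region, ]
      lens <- unique(nchar(g$sequence))
      obs <- unlist(lapply(lens, function(L) random_aa(40, L)))
      got <- assign_germlines(obs, gs, region)
      for (i in seq_along(obs)) {
        exp <- oracle_assign(obs[i], g$name, g$sequence)
        expect_identical(got$germline_name[i], exp$name)
        expect_identical(got$mismatch_count[i], as.integer(exp$mm))
      }
    }
  })
})

test_that("shm profiles count usage and substitutions directly", {
  gs <- toy_germlines()
  # 4 sequences all assigned to gC (AASSLQS), one carrying S->T at position 3
  rep <- cdr_repertoire(c("AASSLQS", "AASSLQS", "AATSLQS", "AASSLQS"), "K2")
  prof <- build_shm_profile(rep, gs)
  expect_equal(unname(prof$usage["gC"]), 1.0)
  expect_equal(unname(prof$spectrum$gC["T", 3]), 0.25)
  expect_equal(sum(prof$spectrum$gC), 0.25)
  expect_equal(sum(prof$usage), 1, tolerance = 1e-12)

  # repertoire identical to one germline: all-zero spectrum
  prof0 <- build_shm_profile(cdr_repertoire(rep("SYAMS", 5), "H1"), gs)
  expect_equal(sum(prof0$spectrum$gH), 0)

  # invariant to input order
  prof_rev <- build_shm_profile(rep[4:1, ], gs)
  expect_equal(prof$usage, prof_rev$usage)
  expect_equal(prof$spectrum, prof_rev$spectrum)

  expect_error(build_shm_profile(cdr_repertoire("AAA", "K2"), gs), "assigned")
})

test_that("unassignable sequences are excluded but counted", {
  gs <- toy_germlines()
  rep <- cdr_repertoire(c("AASSLQS", "AAA"), "K2")
  prof <- build_shm_profile(rep, gs)
  expect_equal(prof$n_assigned, 1L)
  expect_equal(prof$n_unassigned, 1L)
})

test_that("h3 profiles split head positions from pooled terminal units", {
  seqs <- paste0(replicate(10, paste(sample(c("A", "G", "S"), 9, TRUE), collapse = "")), "FDY")
  prof <- build_h3_profile(cdr_repertoire(seqs, "H3"))
  expect_equal(prof$terminal_units, c(FDY = 1.0))
  expect_equal(names(prof$length_dist), "12")
  expect_equal(ncol(prof$positional[["12"]]), 9L)
  expect_true(all(abs(colSums(prof$positional[["12"]]) - 1) < 1e-9))

  # terminal_len = 0: pure positional model, position 9 splits A/C evenly
  rep9 <- cdr_repertoire(c("AAAAAAAAA", "AAAAAAAAC"), "H3")
  p0 <- build_h3_profile(rep9, terminal_len = 0L)
  expect_equal(unname(p0$positional[["9"]]["A", 9]), 0.5)
  expect_equal(unname(p0$positional[["9"]]["C", 9]), 0.5)
  expect_length(p0$terminal_units, 0L)

  expect_error(build_h3_profile(cdr_repertoire("AAAAA", "H3"), c(9, 20)), "length range")
})

test_that("l3 tail profiles follow the split rule and renormalise per column", {
  rep <- cdr_repertoire(c("QQSYSTPLT", "QQSYSTPLT", "QQSYSTPLT", "QQSYSTPPT"), "K3")
  prof <- build_l3_tail_profile(rep)
  m <- prof$tail_positional[["9"]]
  expect_equal(prof$tail_len[["9"]], 2L)
  expect_equal(unname(m["L", 1]), 0.75)
  expect_equal(unname(m["P", 1]), 0.25)
  expect_equal(unname(m["T", 2]), 1.0)
  expect_true(all(abs(colSums(m) - 1) < 1e-9))

  # lengths missing from an explicit rule are excluded with a warning
  rep2 <- cdr_repertoire(c("QQSYSTPLT", "QQSYSTPPLSLQT"), "K3")
  expect_warning(
    prof2 <- build_l3_tail_profile(rep2, split_rule = c("9" = 2L)),
    "excluded"
  )
  expect_equal(names(prof2$tail_positional), "9")
  expect_error(build_l3_tail_profile(cdr_repertoire("SYAMS", "H1")), "light-chain")
})

test_that("profiles round-trip through versioned JSON", {
  gs <- demo_germline_set()
  nat <- generate_natural_repertoire(demo_repertoire_spec("K2", n = 400, seed = 3), gs)
  prof <- build_shm_profile(nat, gs)
  f <- withr::local_tempfile(fileext = ".json")
  write_profile_json(prof, f)
  back <- read_profile_json(f)
  expect_s3_class(back, "shm_profile")
  expect_equal(back$usage, prof$usage)
  expect_equal(back$spectrum, prof$spectrum)
  expect_equal(back$length_dist, prof$length_dist)

  h3 <- demo_h3_profile()
  f2 <- withr::local_tempfile(fileext = ".json")
  write_profile_json(h3, f2)
  h3b <- read_profile_json(f2)
  expect_equal(h3b$terminal_units, h3$terminal_units)
  expect_equal(h3b$positional[["12"]], h3$positional[["12"]])

  tl <- demo_l3_tail_profile("K3")
  f3 <- withr::local_tempfile(fileext = ".json")
  write_profile_json(tl, f3)
  tlb <- read_profile_json(f3)
  expect_equal(tlb$tail_positional, tl$tail_positional)
})

test_that("tidiers return long frequency tables", {
  gs <- demo_germline_set()
  nat <- generate_natural_repertoire(demo_repertoire_spec("H1", n = 300, seed = 5), gs)
  prof <- build_shm_profile(nat, gs)
  td <- tidy(prof)
  expect_true(all(c("germline", "position", "residue", "frequency") %in% names(td)))
  expect_true(all(td$frequency >= 0))
  gl <- glance(prof)
  expect_equal(gl$n_assigned + gl$n_unassigned, 300L)
})
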