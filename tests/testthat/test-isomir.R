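# hairpin with a known mature and a controlled downstream template so the
# decomposition examples are forced: mature at [4, 26), downstream "CAG..."
caller_reference <- function(downstream = "CAGCG") {
  set.seed(3)
  mature <- "TGAGGTAGTAGGTTGTATAGTT"
  hp <- paste0("GGGC", mature, downstream,
               substr(strrep("GCCA", 20), 1, 49 - nchar(downstream)))
  build_reference(
    tibble::tibble(hairpin_id = "hp1", sequence = hp),
    tibble::tibble(mirna_id = "mir-t", hairpin_id = "hp1",
                   start = 4, end = 26, arm = "5p"))
}

call_one <- function(read, ref, ...) {
  call_isomirs(tibble::tibble(sample_id = "s", sequence = read, count = 1L),
               ref, ...)
}

test_that("lenient mapping honours the mismatch cap and reports overhangs", {
  ref <- caller_reference()
  mature <- ref$matures$canonical_seq
  # 3' TT against template CA: reported with 2 terminal mismatches
  al <- map_lenient(tibble::tibble(sequence = paste0(mature, "TT")), ref)
  at0 <- al[al$start == 4, ]
  expect_equal(at0$mismatches, 2L)
  # three scattered mismatches: no alignment at the mature position
  bad <- mature
  for (i in c(3, 10, 17)) substr(bad, i, i) <- "N"
  al2 <- map_lenient(tibble::tibble(sequence = bad), ref)
  expect_false(any(al2$start == 4))
  # exact read: zero mismatches
  al3 <- map_lenient(tibble::tibble(sequence = mature), ref)
  expect_equal(al3$mismatches[al3$start == 4], 0L)
})

test_that("alignment selection prefers fewest mismatches, then 5' offset", {
  ref <- generate_reference(simulation_config(n_hairpins = 4, seed = 41))
  m <- ref$matures[1, ]
  exact <- m$canonical_seq
  sel <- select_alignment(map_lenient(tibble::tibble(sequence = exact), ref),
                          ref)
  expect_equal(sel$mismatches, 0L)
  expect_equal(sel$mirna_id, m$mirna_id)
  expect_equal(sel$start_offset, 0L)
  # empty input stays empty
  empty <- map_lenient(tibble::tibble(sequence = strrep("N", 20)), ref)
  expect_equal(nrow(select_alignment(empty, ref)), 0L)
})

test_that("3' decomposition uses maximal templated extension", {
  ref <- caller_reference("CAGCG")
  mature <- ref$matures$canonical_seq

  # canonical + TTT vs template CAG -> pure U tail, offset 0
  c1 <- call_one(paste0(mature, "TTT"), ref)
  expect_equal(c1$nta3, "TTT")
  expect_equal(c1$tail_class, "U")
  expect_equal(c1$three_templated_offset, 0L)
  expect_equal(c1$five_offset, 0L)

  # canonical + CTT: the C is templated (+1), tail TT
  c2 <- call_one(paste0(mature, "CTT"), ref)
  expect_equal(c2$three_templated_offset, 1L)
  expect_equal(c2$nta3, "TT")
  expect_equal(c2$tail_class, "U")

  # canonical + AA vs template AG (greedy tie toward templated)
  ref2 <- caller_reference("AGGCG")
  m2 <- ref2$matures$canonical_seq
  c3 <- call_one(paste0(m2, "AA"), ref2)
  expect_equal(c3$three_templated_offset, 1L)
  expect_equal(c3$nta3, "A")
  expect_equal(c3$tail_class, "A")

  # 3'-trimmed by 2, no tail
  c4 <- call_one(substr(mature, 1, nchar(mature) - 2), ref)
  expect_equal(c4$three_templated_offset, -2L)
  expect_equal(c4$nta3, "")
  expect_equal(c4$tail_class, "none")

  # 5' nontemplated addition
  c5 <- call_one(paste0("T", mature), ref)  # upstream template is C (GGGC)
  expect_equal(c5$nta5, "T")
  expect_equal(c5$five_offset, 0L)

  # interior mismatch: unclassifiable, dropped
  bad <- mature
  substr(bad, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mature, 11, 11))[1]
  expect_equal(nrow(call_one(bad, ref)), 0L)
})

test_that("count thresholding keeps signatures with summed count >= 2", {
  calls <- tibble::tibble(
    sample_id = "s1",
    sequence = c("x", "y", "z", "z2"),
    count = c(1L, 2L, 1L, 1L),
    mirna_id = c("m1", "m2", "m3", "m3"),
    five_offset = 0L, three_templated_offset = 0L,
    nta5 = "", nta3 = c("T", "T", "A", "A"),
    tail_class = c("U", "U", "A", "A"),
    arm = "5p", hairpin_id = "h", insert_len = 20L)
  kept <- apply_count_threshold(calls, 2)
  expect_false("m1" %in% kept$mirna_id)      # count 1 dropped
  expect_true("m2" %in% kept$mirna_id)       # count 2 kept
  expect_equal(sum(kept$mirna_id == "m3"), 2L)  # 1 + 1 same signature kept
})

test_that("kept calls reconstruct their read byte for byte", {
  cfg <- simulation_config(n_hairpins = 8, mean_depth = 15000, seed = 37,
                           seq_error_rate = 0.001)
  ref <- generate_reference(cfg)
  sim <- simulate_reads(ref, cfg)
  pp <- preprocess_reads(sim$reads, cfg$adapter_seq)
  calls <- call_isomirs(pp, ref)
  hp <- setNames(ref$hairpins$sequence, ref$hairpins$hairpin_id)
  mat <- ref$matures
  one_per_seq <- calls[!duplicated(calls$sequence), ]
  for (i in seq_len(nrow(one_per_seq))) {
    cl <- one_per_seq[i, ]
    m <- mat[mat$mirna_id == cl$mirna_id & mat$hairpin_id == cl$hairpin_id, ]
    t_start <- m$start + cl$five_offset       # 0-based templated start
    t_end <- m$end + cl$three_templated_offset
    templated <- substr(hp[[cl$hairpin_id]], t_start + 1, t_end)
    expect_identical(paste0(cl$nta5, templated, cl$nta3), cl$sequence)
  }
})

test_that("caller matches the brute-force decomposition oracle", {
  ref <- generate_reference(simulation_config(n_hairpins = 5, seed = 43))
  set.seed(43)
  reads <- character(0)
  mat <- ref$matures
  for (i in 1:80) {
    m <- mat[sample(nrow(mat), 1), ]
    hp <- ref$hairpins$sequence[ref$hairpins$hairpin_id == m$hairpin_id]
    a <- m$start + sample(-2:2, 1)
    b <- m$end + sample(-3:2, 1)
    core <- substr(hp, a + 1, min(b, nchar(hp)))
    tail <- c("", "T", "TT", "TTT", "A", "AA", "AT",
              random_dna(2))[sample(8, 1)]
    reads <- c(reads, paste0(core, tail))
  }
  reads <- unique(reads[nchar(reads) >= 12])
  got <- call_isomirs(tibble::tibble(sample_id = "s", sequence = reads,
                                     count = 1L), ref)
  for (r in reads) {
    exp <- oracle_call(r, ref)
    g <- got[got$sequence == r, ]
    if (is.null(exp)) {
      expect_equal(nrow(g), 0L, info = r)
    } else {
      expect_equal(nrow(g), 1L, info = r)
      expect_equal(g$mirna_id, exp$mirna_id, info = r)
      expect_equal(g$five_offset, exp$five_offset, info = r)
      expect_equal(g$three_templated_offset, exp$three_templated_offset,
                   info = r)
      expect_equal(g$nta3, exp$nta3, info = r)
      expect_equal(g$tail_class, exp$tail_class, info = r)
    }
  }
})

test_that("unambiguous simulated isoform classes are called exactly", {
  cfg <- simulation_config(n_hairpins = 8, mean_depth = 20000, seed = 47)
  ref <- generate_reference(cfg)
  sim <- simulate_reads(ref, cfg)
  pp <- preprocess_reads(sim$reads, cfg$adapter_seq)
  calls <- call_isomirs(pp, ref)
  prov <- sim$truth$provenance
  # per-sequence expected call for canonical untailed reads
  canon <- unique(ref$matures$canonical_seq)
  g <- calls[calls$sequence %in% canon & calls$sample_id == "A1", ]
  expect_true(all(g$five_offset == 0 & g$three_templated_offset == 0 &
                    g$nta3 == "" & g$nta5 == ""))
  expect_equal(sort(unique(g$sequence)), sort(canon))
  # canonical 3p reads with 1-2 nt U tails: context {C,G} downstream makes
  # them unambiguous; the call must be exactly (0, 0, tail)
  m3 <- ref$matures[ref$matures$arm == "3p", ]
  for (len in 1:2) {
    tailed <- paste0(m3$canonical_seq, strrep("T", len))
    gt <- calls[calls$sequence %in% tailed & calls$sample_id == "A1", ]
    if (nrow(gt) > 0) {
      expect_true(all(gt$tail_class == "U" & nchar(gt$nta3) == len &
                        gt$three_templated_offset == 0))
    }
  }
})
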