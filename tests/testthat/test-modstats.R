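mk_calls <- function(n_per_class) {
  # synthetic calls table: counts by class combination
  tibble::tibble(
    sample_id = "s1",
    sequence = paste0("seq", seq_len(sum(n_per_class))),
    count = 1L,
    mirna_id = "m1", arm = "5p", hairpin_id = "h1",
    five_offset = rep(c(0L, 0L, 1L, -1L, 0L),
                      n_per_class),
    three_templated_offset = rep(c(-1L, 0L, 0L, 0L, 0L), n_per_class),
    nta5 = rep(c("", "", "", "T", ""), n_per_class),
    nta3 = rep(c("", "TT", "", "", ""), n_per_class),
    tail_class = rep(c("none", "U", "none", "none", "none"), n_per_class),
    insert_len = 20L)
}

test_that("modification frequencies use the assigned-read denominator", {
  # 100 reads: 40 3'-trimmed, 10 3'-added (U), 5 5'-trimmed, 1 5'-added
  calls <- mk_calls(c(40L, 10L, 5L, 1L, 44L))
  prof <- modification_frequencies(calls)
  f <- setNames(prof$frequency, prof$class)
  expect_equal(f[["3'-trim"]], 0.40)
  expect_equal(f[["3'-add"]], 0.10)
  expect_equal(f[["5'-trim"]], 0.05)
  expect_equal(f[["5'-add"]], 0.01)
  expect_true(all(prof$total == 100))
})

test_that("a read with several modifications counts in every class", {
  calls <- tibble::tibble(
    sample_id = "s1", sequence = "x", count = 10L,
    mirna_id = "m", arm = "3p", hairpin_id = "h",
    five_offset = 1L, three_templated_offset = 0L,
    nta5 = "", nta3 = "TTT", tail_class = "U", insert_len = 22L)
  prof <- modification_frequencies(calls)
  f <- setNames(prof$count, prof$class)
  expect_equal(f[["5'-trim"]], 10L)
  expect_equal(f[["3'-add"]], 10L)
  expect_equal(f[["3'-trim"]], 0L)
  # unmodified calls give zero frequencies everywhere
  quiet <- mk_calls(c(0L, 0L, 0L, 0L, 10L))
  expect_true(all(modification_frequencies(quiet)$frequency == 0))
})

test_that("tail histograms recover point-mass length distributions", {
  calls <- mk_calls(c(0L, 20L, 0L, 0L, 80L))
  calls$nta3[calls$tail_class == "U"] <- "TTT"
  h <- tail_length_histogram(calls)
  expect_equal(nrow(h), 1L)
  expect_equal(h$tail_len, 3)
  expect_equal(h$percent, 20)
  expect_equal(h$mono_oligo, "oligo")
  expect_false("A" %in% h$tail_class)
  # histogram mass reconciles with the 3'-add U class count
  expect_equal(sum(h$count), 20L)
})

test_that("arm ratio arithmetic and continuity correction are exact", {
  mk_arm <- function(n5, u5, n3, u3) {
    tibble::tibble(
      sample_id = "s1",
      sequence = paste0("r", seq_len(n5 + n3)),
      count = 1L, mirna_id = "m", hairpin_id = "h",
      arm = rep(c("5p", "3p"), c(n5, n3)),
      five_offset = 0L, three_templated_offset = 0L, nta5 = "",
      nta3 = c(rep(c("TT", ""), c(u5, n5 - u5)),
               rep(c("TT", ""), c(u3, n3 - u3))),
      tail_class = c(rep(c("U", "none"), c(u5, n5 - u5)),
                     rep(c("U", "none"), c(u3, n3 - u3))),
      insert_len = 20L)
  }
  # 3p 2.0% vs 5p 0.2% -> ratio 10
  r <- arm_uridylation_ratio(mk_arm(1000, 2, 1000, 20))
  expect_equal(r$u_ratio, 10)
  # equal rates -> 1
  r2 <- arm_uridylation_ratio(mk_arm(500, 5, 500, 5))
  expect_equal(r2$u_ratio, 1)
  # zero 5p count: raw ratio infinite, corrected finite and large
  r3 <- arm_uridylation_ratio(mk_arm(1000, 0, 1000, 20))
  expect_true(is.infinite(r3$u_ratio))
  expect_equal(r3$u_ratio_corrected, (20.5 / 1000) / (0.5 / 1000))
})

test_that("fragment detection applies the 13-17 nt anchored window", {
  mk <- function(len, five, three) {
    tibble::tibble(sample_id = "s1", sequence = "x", count = 1L,
                   mirna_id = "m1", arm = "5p", hairpin_id = "h",
                   five_offset = five, three_templated_offset = three,
                   nta5 = "", nta3 = "", tail_class = "none",
                   insert_len = len)
  }
  lib <- c(s1 = 1000)
  expect_equal(sum(fragment_counts(mk(15L, 0L, -7L), lib)$count), 1L)
  expect_equal(sum(fragment_counts(mk(18L, 0L, -4L), lib)$count), 0L)
  expect_equal(sum(fragment_counts(mk(15L, 4L, -3L), lib)$count), 0L)
  expect_equal(sum(fragment_counts(mk(20L, 0L, -2L), lib)$count), 0L)
  # fragment reads never enter the +/-2 expression window: offsets <= -3
  # by definition exclude them from assign_to_mature's window
  expect_true(all(fragment_counts(mk(15L, 0L, -7L), lib)$rate <= 1))
})

test_that("fragment fold change is B/A on normalized rates, 1 for no change", {
  samples <- tibble::tibble(sample_id = c("A1", "A2", "B1", "B2"),
                            condition = rep(c("A", "B"), each = 2))
  frag <- tidyr::expand_grid(mirna_id = c("m1", "m2"),
                             sample_id = samples$sample_id)
  frag$library_size <- 1e5
  frag$count <- c(1000, 1000, 6000, 6000,   # m1: B = 6x A
                  2000, 2000, 2000, 2000)   # m2: no change
  frag$rate <- frag$count / frag$library_size
  fc <- fragment_fold_change(frag, samples)
  expect_equal(fc$fold_change[fc$mirna_id == "m2"], 1)
  expect_equal(fc$fold_change[fc$mirna_id == "m1"], 6, tolerance = 0.01)
})

test_that("profile comparison t-tests match the closed form", {
  samples <- tibble::tibble(sample_id = c("A1", "A2", "A3", "B1", "B2", "B3"),
                            condition = rep(c("A", "B"), each = 3))
  vals <- tibble::tibble(
    sample_id = samples$sample_id,
    statistic = "u_oligo",
    value = c(10, 11, 9, 20, 21, 19))
  cmp <- compare_profiles(vals, samples)
  # pooled sd = 1, t = 10 / sqrt(2/3), df = 4
  t_exp <- 10 / sqrt(2 / 3)
  expect_equal(cmp$t, t_exp, tolerance = 1e-10)
  expect_equal(cmp$p, 2 * stats::pt(-t_exp, df = 4), tolerance = 1e-12)
  expect_lt(cmp$p, 0.001)
  expect_equal(cmp$stars, "***")

  # identical replicate vectors -> guarded p = 1
  same <- vals; same$value <- rep(5, 6)
  cmp2 <- compare_profiles(same, samples)
  expect_equal(cmp2$p, 1)
  expect_true(cmp2$zero_variance)
  # constant but unequal -> p = 0 flagged
  const <- vals; const$value <- rep(c(1, 2), each = 3)
  cmp3 <- compare_profiles(const, samples)
  expect_equal(cmp3$p, 0)
  expect_true(is.infinite(cmp3$t))
  expect_error(compare_profiles(vals[c(1, 4), ], samples[c(1, 4), ]),
               "two replicates")
})

test_that("ddCt fold changes follow 2^-ddCt", {
  expect_equal(ddct_fold_change(22, 15, 20, 15), 0.25)
  expect_equal(ddct_fold_change(20, 15, 20, 15), 1.0)
  expect_equal(ddct_fold_change(18, 15, 20, 15), 4.0)
  expect_error(ddct_fold_change(-1, 15, 20, 15))
})

test_that("arm localization of tails reproduces the precursor inference", {
  # tails injected only at the precursor 3' end (3p arm): U-ratio >> 1,
  # A-ratio ~ 1
  cfg3p <- simulation_config(n_hairpins = 10, mean_depth = 30000, seed = 53,
                             nta_u_rate = c("5p" = 0, "3p" = 0.03),
                             nta_a_rate = c("5p" = 0.05, "3p" = 0.05))
  ref <- generate_reference(cfg3p)
  sim <- simulate_reads(ref, cfg3p)
  calls <- call_isomirs(preprocess_reads(sim$reads, cfg3p$adapter_seq), ref)
  r <- arm_uridylation_ratio(apply_count_threshold(calls))
  expect_true(all(r$u_ratio_corrected > 5))
  expect_true(all(r$a_ratio_corrected > 0.5 & r$a_ratio_corrected < 2))

  # tails on mature reads of both arms at equal rates: both ratios ~ 1
  cfg_eq <- simulation_config(n_hairpins = 10, mean_depth = 30000, seed = 59,
                              nta_u_rate = c("5p" = 0.03, "3p" = 0.03),
                              nta_a_rate = c("5p" = 0.05, "3p" = 0.05))
  ref2 <- generate_reference(cfg_eq)
  sim2 <- simulate_reads(ref2, cfg_eq)
  calls2 <- call_isomirs(preprocess_reads(sim2$reads, cfg_eq$adapter_seq),
                         ref2)
  r2 <- arm_uridylation_ratio(apply_count_threshold(calls2))
  expect_true(all(r2$u_ratio_corrected > 0.5 & r2$u_ratio_corrected < 2))
  expect_true(all(r2$a_ratio_corrected > 0.5 & r2$a_ratio_corrected < 2))
})
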