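small_cfg <- function(...) {
  simulation_config(n_hairpins = 8, mean_depth = 5000, seed = 11, ...)
}

test_that("reference generation is deterministic and well-formed", {
  cfg <- small_cfg()
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$hairpins), 8L)
  expect_equal(nrow(r1$matures), 16L)
  expect_true(all(r1$hairpins$length >= 60 & r1$hairpins$length <= 90))
  lens <- r1$matures$end - r1$matures$start
  expect_true(all(lens >= 20 & lens <= 23))

  one <- generate_reference(simulation_config(n_hairpins = 1, seed = 3))
  expect_equal(sort(one$matures$arm), c("3p", "5p"))
})

test_that("mature sequences are pairwise distinct and never substrings", {
  ref <- generate_reference(simulation_config(n_hairpins = 50, seed = 5))
  seqs <- ref$matures$canonical_seq
  expect_equal(anyDuplicated(seqs), 0L)
  for (i in seq_along(seqs)) {
    others <- seqs[-i]
    expect_false(any(grepl(seqs[i], others, fixed = TRUE)),
                 info = paste("mature", i, "is a substring of another"))
  }
})

test_that("read simulation is deterministic and conserves provenance", {
  cfg <- small_cfg()
  ref <- generate_reference(cfg)
  s1 <- simulate_reads(ref, cfg)
  s2 <- simulate_reads(ref, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$reads), nrow(s1$truth$provenance))
  expect_identical(s1$reads$read_id, s1$truth$provenance$read_id)

  # on-disk FASTQ record count equals provenance rows
  dir <- withr::local_tempdir()
  paths <- write_simulation(s1, ref, dir)
  n_rec <- sum(vapply(paths$fastq,
                      function(p) length(readLines(p)) / 4, numeric(1)))
  expect_equal(n_rec, nrow(s1$truth$provenance))
})

test_that("tail switches and length distributions act as configured", {
  cfg0 <- small_cfg(nta_u_rate = c("5p" = 0, "3p" = 0),
                    nta_a_rate = c("5p" = 0, "3p" = 0))
  ref <- generate_reference(cfg0)
  s <- simulate_reads(ref, cfg0)
  expect_equal(sum(s$truth$provenance$tail_class != "none"), 0L)

  cfg3 <- small_cfg(u_length_dist = c(0, 0, 1, 0, 0),
                    nta_u_rate = c("5p" = 0.05, "3p" = 0.2))
  s3 <- simulate_reads(generate_reference(cfg3), cfg3)
  u <- s3$truth$provenance[s3$truth$provenance$tail_class == "U", ]
  expect_gt(nrow(u), 0)
  expect_true(all(u$tail_len == 3L))
})

test_that("per-miRNA read shares follow the true abundances", {
  cfg <- simulation_config(n_hairpins = 10, mean_depth = 40000, seed = 19,
                           de_fraction = 0, bio_sigma = 0)
  ref <- generate_reference(cfg)
  s <- simulate_reads(ref, cfg)
  prov <- s$truth$provenance[s$truth$provenance$sample_id == "A1", ]
  obs <- table(factor(prov$mirna_id, levels = s$truth$mirna$mirna_id))
  chisq <- suppressWarnings(
    stats::chisq.test(obs, p = s$truth$mirna$share_A))
  expect_gt(chisq$p.value, 0.01)
})

test_that("empirical isoform-class frequencies converge to the mix", {
  mix <- c("canonical" = 0.5, "templated+1" = 0.15, "templated+2" = 0.05,
           "trim-1" = 0.2, "trim-2" = 0.1)
  cfg <- simulation_config(n_hairpins = 6, mean_depth = 30000, seed = 23,
                           isoform_mix = mix, fragment_rate = 0)
  s <- simulate_reads(generate_reference(cfg), cfg)
  prov <- s$truth$provenance
  freq <- prop.table(table(prov$isoform_class))[names(mix)]
  n <- nrow(prov)
  # binomial tolerance: 5 sds of each class proportion
  for (cl in names(mix)) {
    tol <- 5 * sqrt(mix[[cl]] * (1 - mix[[cl]]) / n)
    expect_lt(abs(freq[[cl]] - mix[[cl]]), tol)
  }
})

test_that("condition B applies the configured effects", {
  cfg <- simulation_config(n_hairpins = 10, mean_depth = 50000, seed = 31)
  ref <- generate_reference(cfg)
  s <- simulate_reads(ref, cfg)
  prov <- s$truth$provenance
  tm <- s$truth$mirna
  # fragment rate multiplied in B
  fr <- tapply(prov$fragment, substr(prov$sample_id, 1, 1), mean)
  expect_gt(fr[["B"]] / fr[["A"]], 2.5)
  # 3p U rate halved in B, 5p untouched (rates from arm_rates truth)
  ar <- s$truth$arm_rates
  expect_equal(ar$u_rate[ar$condition == "B" & ar$arm == "3p"],
               0.5 * ar$u_rate[ar$condition == "A" & ar$arm == "3p"])
  expect_equal(ar$u_rate[ar$condition == "B" & ar$arm == "5p"],
               ar$u_rate[ar$condition == "A" & ar$arm == "5p"])
  # DE miRNAs shift read share in the configured direction
  de_up <- tm$mirna_id[tm$de & tm$true_log2fc > 0]
  if (length(de_up) > 0) {
    shr <- function(cond, ids) {
      p <- prov[substr(prov$sample_id, 1, 1) == cond, ]
      mean(p$mirna_id %in% ids)
    }
    expect_gt(shr("B", de_up), shr("A", de_up))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(isoform_mix = c(canonical = 0.5)),
               "sum to 1")
  expect_error(simulation_config(u_length_dist = c(1, 1, 0, 0, 0)),
               "sum to 1")
  expect_error(simulation_config(nta_u_rate = c("5p" = -0.1, "3p" = 0)),
               "\\[0, 1\\]")
  cfg <- small_cfg()
  cfg$mean_depth <- 0
  expect_error(simulate_reads(generate_reference(small_cfg()), cfg),
               "mean_depth")
})

test_that("NB count simulator honours effects and dispersion", {
  sim <- simulate_count_matrix(300, 3, log2fc = rep(c(0, 1), c(250, 50)),
                               dispersion = 0, seed = 9)
  expect_equal(dim(sim$counts), c(300L, 6L))
  m <- sim$counts
  ratio <- rowMeans(m[251:300, 4:6]) /
    pmax(rowMeans(m[251:300, 1:3]), 1)
  expect_gt(median(ratio), 1.5)
})
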