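#' Derive a deterministic stage seed from a master seed
#'
#' Each pipeline stage consumes its own RNG stream derived from the master
#' seed and the stage name, so a stage rerun in isolation reproduces its
#' in-pipeline behaviour.
#'
#' @param master Integer master seed.
#' @param stage Stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647)
}

#' Simulation configuration for synthetic small RNA-seq experiments
#'
#' The defaults emulate a two-condition (control `A` vs knockdown `B`)
#' triplicate small RNA-seq design: hairpin-derived reads with a mix of
#' canonical, templated +1/+2 extended and 1-2 nt 3'-trimmed isoforms;
#' nontemplated U-tails strongly biased to the 3p arm (precursor-level
#' tailing) with modal length 3 nt; nontemplated A-tails equally frequent
#' on both arms (mature-level tailing) and predominantly 1 nt; a low rate
#' of 13-17 nt 5'-anchored fragments; and condition-B effects: log2 fold
#' changes of magnitude `de_log2fc` on a `de_fraction` of miRNAs, a
#' multiplier on the 3p U-tail rate, and a multiplier on the fragment
#' rate.
#'
#' @param n_hairpins Number of synthetic pre-miRNA hairpins.
#' @param n_samples_per_condition Replicates per condition.
#' @param mean_depth Mean reads per sample (per-sample depth is jittered
#'   uniformly by `depth_jitter`).
#' @param abundance_sigma Log-normal sd of per-miRNA true abundance.
#' @param isoform_mix Named probabilities over isoform classes
#'   `canonical`, `templated+1`, `templated+2`, `trim-1`, `trim-2`
#'   (must sum to 1).
#' @param nta_u_rate Named per-read U-tail probability by arm
#'   (`5p`, `3p`), condition A.
#' @param nta_a_rate Named per-read A-tail probability by arm.
#' @param u_length_dist,a_length_dist Probabilities over tail lengths
#'   1..5 (each sums to 1).
#' @param fragment_rate Probability a read is emitted as a 13-17 nt
#'   5'-anchored 3'-truncation of the mature, condition A.
#' @param bio_sigma Replicate-level biological variability: per-sample
#'   log-normal jitter (sdlog) on each miRNA's abundance.
#' @param rate_jitter Replicate-level log-normal jitter (sdlog) on the
#'   per-sample U-tail, A-tail and fragment rates.
#' @param de_fraction Fraction of miRNAs differentially expressed in B.
#' @param de_log2fc Magnitude of the true log2 fold change (sign random).
#' @param u_rate_multiplier_B_3p Condition-B multiplier on the 3p U-tail
#'   rate only.
#' @param fragment_multiplier_B Condition-B multiplier on the fragment
#'   rate.
#' @param seq_error_rate Per-base substitution rate in the insert
#'   (never in the adapter).
#' @param adapter_seq 3' adapter ligated after the (tailed) insert.
#' @param read_length Sequencer read length; insert + adapter is
#'   truncated to this many bases.
#' @param depth_jitter Half-width of the uniform relative depth jitter.
#' @param conditions Two condition labels, control first.
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_hairpins = 20,
                              n_samples_per_condition = 3,
                              mean_depth = 200000,
                              abundance_sigma = 1.2,
                              isoform_mix = c("canonical" = 0.60,
                                              "templated+1" = 0.10,
                                              "templated+2" = 0.05,
                                              "trim-1" = 0.15,
                                              "trim-2" = 0.10),
                              nta_u_rate = c("5p" = 0.003, "3p" = 0.03),
                              nta_a_rate = c("5p" = 0.05, "3p" = 0.05),
                              u_length_dist = c(0.10, 0.20, 0.40, 0.20, 0.10),
                              a_length_dist = c(0.70, 0.20, 0.07, 0.02, 0.01),
                              fragment_rate = 0.01,
                              bio_sigma = 0.2,
                              rate_jitter = 0.1,
                              de_fraction = 0.25,
                              de_log2fc = 1,
                              u_rate_multiplier_B_3p = 0.5,
                              fragment_multiplier_B = 4,
                              seq_error_rate = 0,
                              adapter_seq = "TGGAATTCTCGGGTGCCAAGG",
                              read_length = 50,
                              depth_jitter = 0.15,
                              conditions = c("A", "B"),
                              seed = 1) {
  cfg <- list(n_hairpins = n_hairpins,
              n_samples_per_condition = n_samples_per_condition,
              mean_depth = mean_depth,
              abundance_sigma = abundance_sigma,
              isoform_mix = isoform_mix,
              nta_u_rate = nta_u_rate,
              nta_a_rate = nta_a_rate,
              u_length_dist = u_length_dist,
              a_length_dist = a_length_dist,
              fragment_rate = fragment_rate,
              bio_sigma = bio_sigma,
              rate_jitter = rate_jitter,
              de_fraction = de_fraction,
              de_log2fc = de_log2fc,
              u_rate_multiplier_B_3p = u_rate_multiplier_B_3p,
              fragment_multiplier_B = fragment_multiplier_B,
              seq_error_rate = seq_error_rate,
              adapter_seq = dna_normalize(adapter_seq),
              read_length = read_length,
              depth_jitter = depth_jitter,
              conditions = conditions,
              seed = seed)
  probs <- c(isoform_mix, nta_u_rate, nta_a_rate, u_length_dist,
             a_length_dist, fragment_rate, de_fraction, seq_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(isoform_mix) - 1) > 1e-8) stop("isoform_mix must sum to 1")
  if (abs(sum(u_length_dist) - 1) > 1e-8) stop("u_length_dist must sum to 1")
  if (abs(sum(a_length_dist) - 1) > 1e-8) stop("a_length_dist must sum to 1")
  if (length(conditions) != 2) stop("exactly two conditions are supported")
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic hairpin reference
#'
#' Each hairpin is 60-90 nt with a 5p mature starting at position 4
#' (0-based) and a 3p mature ending 2 nt before the hairpin 3' end (the
#' residual Dicer/Drosha overhang), both 20-23 nt. The two templated bases
#' immediately downstream of each mature are drawn from `{C, G}` so that
#' templated +1/+2 extensions can never be confused with nontemplated U-
#' or A-tails. Mature sequences are guaranteed pairwise distinct and not
#' substrings of one another (bounded retries).
#'
#' @param config A [simulation_config()].
#' @param seed Seed (defaults to a stage seed derived from the config).
#' @return A `mirna_reference`.
#' @export
generate_reference <- function(config, seed = stage_seed(config$seed, "reference")) {
  stopifnot(config$n_hairpins >= 1)
  set.seed(seed)
  for (attempt in 1:50) {
    hp <- vector("list", config$n_hairpins)
    mats <- vector("list", config$n_hairpins)
    for (i in seq_len(config$n_hairpins)) {
      L <- sample(60:90, 1)
      s <- strsplit(rand_dna(L), "")[[1]]
      len5 <- sample(20:23, 1)
      len3 <- sample(20:23, 1)
      s5 <- 4L; e5 <- s5 + len5            # 0-based half-open
      e3 <- L - 2L; s3 <- e3 - len3
      # non-A/T context downstream of each mature 3' end
      s[(e5 + 1):(e5 + 2)] <- sample(c("C", "G"), 2, replace = TRUE)
      s[(e3 + 1):(e3 + 2)] <- sample(c("C", "G"), 2, replace = TRUE)
      hid <- sprintf("syn-hp-%03d", i)
      hp[[i]] <- tibble::tibble(hairpin_id = hid,
                                sequence = paste(s, collapse = ""))
      mats[[i]] <- tibble::tibble(
        mirna_id = sprintf("syn-mir-%03d-%s", i, c("5p", "3p")),
        hairpin_id = hid,
        arm = c("5p", "3p"),
        start = c(s5, s3),
        end = c(e5, e3))
    }
    ref <- build_reference(dplyr::bind_rows(hp), dplyr::bind_rows(mats))
    seqs <- ref$matures$canonical_seq
    distinct <- !anyDuplicated(seqs) &&
      !any(vapply(seq_along(seqs), function(i) {
        any(vapply(seq_along(seqs)[-i], function(j) {
          grepl(seqs[[i]], seqs[[j]], fixed = TRUE)
        }, logical(1)))
      }, logical(1)))
    if (distinct) return(ref)
  }
  stop("could not generate pairwise-distinct mature sequences after 50 attempts")
}

tail_string <- function(class, len) {
  ifelse(class == "U", strrep("T", len),
         ifelse(class == "A", strrep("A", len), ""))
}

#' Simulate small RNA-seq reads with complete ground truth
#'
#' Emits, per sample, reads built as mature isoform (per `isoform_mix`) +
#' optional nontemplated 3' tail + 3' adapter (truncated at
#' `read_length`), plus 13-17 nt 5'-anchored fragments at `fragment_rate`.
#' Condition B applies `de_log2fc` to DE-flagged miRNAs,
#' `u_rate_multiplier_B_3p` to the 3p U-tail rate only, and
#' `fragment_multiplier_B` to the fragment rate. Every emitted read has
#' exactly one provenance row in the ground truth.
#'
#' @param reference A `mirna_reference` from [generate_reference()].
#' @param config A [simulation_config()].
#' @param seed Seed (defaults to a stage seed derived from the config).
#' @return A list of class `isotail_sim`: `reads` (tibble `sample_id`,
#'   `read_id`, `sequence`, `quality`), `samples` (sample sheet tibble),
#'   `truth` (list of tibbles `provenance`, `mirna`, `arm_rates`), and the
#'   `config`.
#' @export
simulate_reads <- function(reference, config,
                           seed = stage_seed(config$seed, "reads")) {
  if (config$mean_depth <= 0) stop("mean_depth must be positive")
  set.seed(seed)
  mat <- reference$matures
  hp_seq <- setNames(reference$hairpins$sequence, reference$hairpins$hairpin_id)
  n_mat <- nrow(mat)

  # true abundances and condition-B effects
  w_a <- rlnorm(n_mat, meanlog = 0, sdlog = config$abundance_sigma)
  de <- runif(n_mat) < config$de_fraction
  sign <- ifelse(runif(n_mat) < 0.5, 1, -1)
  lfc <- ifelse(de, sign * config$de_log2fc, 0)
  w_b <- w_a * 2^lfc
  p_a <- w_a / sum(w_a)
  p_b <- w_b / sum(w_b)

  # per-(mature, class) isoform sequences; classes indexed 1..5
  classes <- names(config$isoform_mix)
  hp_of <- hp_seq[mat$hairpin_id]
  iso_seq <- cbind(
    mat$canonical_seq,
    substr(hp_of, mat$start + 1L, mat$end + 1L),
    substr(hp_of, mat$start + 1L, mat$end + 2L),
    substr(mat$canonical_seq, 1L, nchar(mat$canonical_seq) - 1L),
    substr(mat$canonical_seq, 1L, nchar(mat$canonical_seq) - 2L))
  tail_lookup <- rbind("none" = rep("", 5),
                       "U" = strrep("T", 1:5),
                       "A" = strrep("A", 1:5))

  n_rep <- config$n_samples_per_condition
  cond_of_sample <- rep(config$conditions, each = n_rep)
  rep_of_sample <- rep(seq_len(n_rep), times = 2)
  sample_ids <- paste0(cond_of_sample, rep_of_sample)

  frag_rate <- c(config$fragment_rate,
                 min(1, config$fragment_rate * config$fragment_multiplier_B))
  names(frag_rate) <- config$conditions
  u_rate <- rbind(A = config$nta_u_rate,
                  B = c(config$nta_u_rate["5p"],
                        config$nta_u_rate["3p"] * config$u_rate_multiplier_B_3p))
  rownames(u_rate) <- config$conditions
  a_rate <- rbind(config$nta_a_rate, config$nta_a_rate)
  rownames(a_rate) <- config$conditions

  reads_all <- vector("list", length(sample_ids))
  prov_all <- vector("list", length(sample_ids))
  depths <- integer(length(sample_ids))

  for (si in seq_along(sample_ids)) {
    cond <- cond_of_sample[si]
    depth <- as.integer(round(config$mean_depth *
      runif(1, 1 - config$depth_jitter, 1 + config$depth_jitter)))
    depths[si] <- depth
    p <- if (cond == config$conditions[1]) p_a else p_b
    # replicate-level biological variability on composition and rates
    p <- p * exp(rnorm(n_mat, 0, config$bio_sigma))
    p <- p / sum(p)
    u_mult <- exp(rnorm(1, 0, config$rate_jitter))
    a_mult <- exp(rnorm(1, 0, config$rate_jitter))
    f_mult <- exp(rnorm(1, 0, config$rate_jitter))
    mi <- sample.int(n_mat, depth, replace = TRUE, prob = p)
    arm_i <- mat$arm[mi]

    is_frag <- runif(depth) < pmin(1, frag_rate[cond] * f_mult)
    cls <- sample.int(5L, depth, replace = TRUE, prob = config$isoform_mix)
    u_i <- pmin(1, u_rate[cond, arm_i] * u_mult)
    a_i <- pmin(1, a_rate[cond, arm_i] * a_mult)
    r <- runif(depth)
    ttype <- ifelse(r < u_i, "U", ifelse(r < u_i + a_i, "A", "none"))
    tlen <- integer(depth)
    is_u <- ttype == "U"; is_a <- ttype == "A"
    tlen[is_u] <- sample.int(5L, sum(is_u), replace = TRUE,
                             prob = config$u_length_dist)
    tlen[is_a] <- sample.int(5L, sum(is_a), replace = TRUE,
                             prob = config$a_length_dist)
    # fragments carry no tail and no isoform variation
    ttype[is_frag] <- "none"; tlen[is_frag] <- 0L
    frag_len <- integer(depth)
    frag_len[is_frag] <- sample(13:17, sum(is_frag), replace = TRUE)

    insert <- character(depth)
    idx <- !is_frag
    insert[idx] <- paste0(
      iso_seq[cbind(mi[idx], cls[idx])],
      tail_lookup[cbind(match(ttype[idx], c("none", "U", "A")),
                        pmax(tlen[idx], 1L))])
    insert[is_frag] <- substr(mat$canonical_seq[mi[is_frag]], 1L,
                              frag_len[is_frag])

    if (config$seq_error_rate > 0) {
      nerr <- rbinom(depth, nchar(insert), config$seq_error_rate)
      for (k in which(nerr > 0)) {
        ch <- strsplit(insert[k], "")[[1]]
        pos <- sample.int(length(ch), min(nerr[k], length(ch)))
        ch[pos] <- vapply(ch[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
        insert[k] <- paste(ch, collapse = "")
      }
    }

    seqs <- substr(paste0(insert, config$adapter_seq), 1L, config$read_length)
    ids <- sprintf("%s_r%07d", sample_ids[si], seq_len(depth))
    reads_all[[si]] <- tibble::tibble(
      sample_id = sample_ids[si],
      read_id = ids,
      sequence = seqs,
      quality = strrep("I", nchar(seqs)))
    prov_all[[si]] <- tibble::tibble(
      sample_id = sample_ids[si],
      read_id = ids,
      mirna_id = mat$mirna_id[mi],
      arm = arm_i,
      isoform_class = ifelse(is_frag, "fragment", classes[cls]),
      tail_class = ttype,
      tail_len = tlen,
      fragment = is_frag,
      insert_len = nchar(insert))
  }

  samples <- tibble::tibble(sample_id = sample_ids,
                            condition = cond_of_sample,
                            replicate = rep_of_sample,
                            depth = depths)
  truth_mirna <- tibble::tibble(
    mirna_id = mat$mirna_id, arm = mat$arm,
    weight_A = w_a, weight_B = w_b,
    share_A = p_a, share_B = p_b,
    true_log2fc = lfc, de = de,
    fragment_rate_A = frag_rate[1], fragment_rate_B = frag_rate[2])
  arm_rates <- tibble::tibble(
    condition = rep(config$conditions, each = 2),
    arm = rep(c("5p", "3p"), 2),
    u_rate = c(u_rate[1, c("5p", "3p")], u_rate[2, c("5p", "3p")]),
    a_rate = c(a_rate[1, c("5p", "3p")], a_rate[2, c("5p", "3p")]))

  structure(list(reads = dplyr::bind_rows(reads_all),
                 samples = samples,
                 truth = list(provenance = dplyr::bind_rows(prov_all),
                              mirna = truth_mirna,
                              arm_rates = arm_rates),
                 config = config),
            class = "isotail_sim")
}

#' Simulate a negative-binomial count matrix for two conditions
#'
#' Count-level companion to [simulate_reads()] for studying the
#' differential-expression machinery in isolation: per-feature baseline
#' means are drawn log-normally, condition B applies the per-feature
#' `log2fc`, library sizes are jittered, and counts are drawn NB with a
#' common dispersion (`dispersion = 0` gives Poisson).
#'
#' @param n_features Number of features (miRNAs).
#' @param n_per_group Samples per condition.
#' @param log2fc Per-feature true log2 fold change (length 1 or
#'   `n_features`).
#' @param mean_log_mu,mean_log_sigma Log-normal parameters of baseline
#'   means.
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @param size_factor_jitter Half-width of uniform library-size jitter.
#' @param seed Seed.
#' @return List: `counts` (matrix, features x samples, rownames set),
#'   `condition` (character vector), `log2fc` (true effects),
#'   `size_factors` (true per-sample factors).
#' @export
simulate_count_matrix <- function(n_features, n_per_group, log2fc = 0,
                                  mean_log_mu = log(200),
                                  mean_log_sigma = 1,
                                  dispersion = 0.05,
                                  size_factor_jitter = 0.2,
                                  seed = 1) {
  set.seed(seed)
  log2fc <- rep_len(log2fc, n_features)
  mu0 <- rlnorm(n_features, mean_log_mu, mean_log_sigma)
  sf <- runif(2 * n_per_group, 1 - size_factor_jitter,
              1 + size_factor_jitter)
  condition <- rep(c("A", "B"), each = n_per_group)
  mu <- outer(mu0, sf)
  mu[, condition == "B"] <- mu[, condition == "B"] * 2^log2fc
  counts <- matrix(0, n_features, 2 * n_per_group)
  if (dispersion > 0) {
    counts[] <- rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  } else {
    counts[] <- rpois(length(mu), lambda = mu)
  }
  rownames(counts) <- sprintf("mir-%04d", seq_len(n_features))
  colnames(counts) <- paste0(condition, rep(seq_len(n_per_group), 2))
  list(counts = counts, condition = condition, log2fc = log2fc,
       size_factors = sf)
}

#' Write a simulated experiment to disk
#'
#' Emits per-sample FASTQ (Phred+33), the reference FASTA + GFF3, a
#' sample sheet, and the ground-truth tables.
#'
#' @param sim An `isotail_sim` from [simulate_reads()].
#' @param reference The `mirna_reference` the reads were simulated from.
#' @param dir Output directory.
#' @return Invisibly, a list of paths (`fastq`, `reference_fasta`,
#'   `reference_gff`, `sample_sheet`, `truth_dir`).
#' @export
write_simulation <- function(sim, reference, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "reference.fa")
  gff <- file.path(dir, "matures.gff3")
  write_reference(reference, fasta, gff)
  fq <- character(nrow(sim$samples))
  for (i in seq_len(nrow(sim$samples))) {
    sid <- sim$samples$sample_id[i]
    r <- sim$reads[sim$reads$sample_id == sid, ]
    fq[i] <- file.path(dir, paste0(sid, ".fastq"))
    writeLines(as.vector(rbind(paste0("@", r$read_id), r$sequence,
                               "+", r$quality)), fq[i])
  }
  ss <- dplyr::mutate(sim$samples, fastq = fq)
  readr::write_tsv(ss[, c("sample_id", "condition", "replicate", "fastq")],
                   file.path(dir, "sample_sheet.tsv"), progress = FALSE)
  truth_dir <- file.path(dir, "truth")
  write_tables(sim$truth, truth_dir)
  invisible(list(fastq = setNames(fq, sim$samples$sample_id),
                 reference_fasta = fasta, reference_gff = gff,
                 sample_sheet = file.path(dir, "sample_sheet.tsv"),
                 truth_dir = truth_dir))
}
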