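#' Assemble a pipeline configuration
#'
#' Collects paths and the analysis parameters (the low-input small
#' RNA-seq settings by default: +/-2 nt templated window, two-mismatch
#' lenient mapping, modification read-count threshold 2, 13-17 nt
#' fragment window, baseMean cutoff 10, alpha 0.05).
#'
#' @param reference_fasta,reference_gff Hairpin reference paths.
#' @param sample_sheet Sample sheet TSV path.
#' @param out_dir Output directory for result tables.
#' @param adapter 3' adapter sequence.
#' @param min_overlap Adapter prefix match minimum.
#' @param min_q,min_fraction Quality filter parameters.
#' @param min_length Minimum insert length.
#' @param max_length_quant Insert length cap for the quantification
#'   branch (PAGE size selection); the modification branch is uncapped.
#' @param window +/- templated window for mature assignment.
#' @param max_mismatch Lenient-mapping mismatch cap.
#' @param count_threshold Modification-signature read count threshold.
#' @param fragment_min,fragment_max Fragment insert-length window.
#' @param base_mean_cutoff baseMean filter for differential expression.
#' @param alpha Significance threshold.
#' @param seed Master seed (stage seeds are derived from it).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reference_fasta, reference_gff, sample_sheet,
                            out_dir,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            min_overlap = 8, min_q = 20,
                            min_fraction = 0.95, min_length = 12,
                            max_length_quant = 30, window = 2,
                            max_mismatch = 2, count_threshold = 2,
                            fragment_min = 13, fragment_max = 17,
                            base_mean_cutoff = 10, alpha = 0.05,
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(min_overlap >= 1, min_length >= 1, window >= 0,
            count_threshold >= 1, fragment_min <= fragment_max)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipeline_config()] arguments; absent keys take the
#' defaults.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full small RNA-seq analysis pipeline
#'
#' Fixed stage order: reference/sample-sheet loading -> preprocessing ->
#' the two mapping branches (strict quantification with the +/-2 window;
#' lenient isomiR calling) -> modification statistics (frequencies, tail
#' histograms, arm ratios, fragments and fold changes, condition
#' comparisons) -> differential expression -> deterministic TSV outputs
#' plus a run log with per-sample read accounting. Any stage error aborts
#' with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every result object and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  ref <- with_stage("refio", read_hairpin_reference(config$reference_fasta,
                                                    config$reference_gff))
  samples <- with_stage("refio", read_sample_sheet(config$sample_sheet))

  raw <- with_stage("preprocess", purrr::map_dfr(seq_len(nrow(samples)),
    function(i) read_fastq(samples$fastq[i], samples$sample_id[i])))
  quant_collapsed <- with_stage("preprocess", preprocess_reads(
    raw, config$adapter, config$min_overlap, config$min_q,
    config$min_fraction, config$min_length, config$max_length_quant))
  mod_collapsed <- with_stage("preprocess", preprocess_reads(
    raw, config$adapter, config$min_overlap, config$min_q,
    config$min_fraction, config$min_length, Inf))

  cm <- with_stage("quantify",
                   quantify_samples(quant_collapsed, ref, config$window))

  calls <- with_stage("isomir", call_isomirs(mod_collapsed, ref,
                                             config$max_mismatch))
  totals <- assigned_totals(calls)
  kept <- apply_count_threshold(calls, config$count_threshold)

  mod_lib <- mod_collapsed |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  mod_libsizes <- setNames(mod_lib$n, mod_lib$sample_id)

  profile <- with_stage("modstats", modification_frequencies(kept, totals))
  tails <- with_stage("modstats", tail_length_histogram(kept, FALSE, totals))
  tails_arm <- with_stage("modstats",
                          tail_length_histogram(kept, TRUE, totals))
  arm_ratio <- with_stage("modstats", arm_uridylation_ratio(kept))
  fragments <- with_stage("modstats",
                          fragment_counts(calls, mod_libsizes, ref,
                                          config$fragment_min,
                                          config$fragment_max))

  two_groups <- length(unique(samples$condition)) == 2 &&
    all(table(samples$condition) >= 2)
  frag_fc <- comparisons <- de <- NULL
  if (two_groups) {
    frag_fc <- with_stage("modstats",
                          fragment_fold_change(fragments, samples,
                                               size_factors =
                                                 size_factors(cm)))
    stat_values <- dplyr::bind_rows(
      dplyr::transmute(profile, sample_id = .data$sample_id,
                       statistic = .data$class, value = .data$frequency),
      dplyr::transmute(tails, sample_id = .data$sample_id,
                       statistic = paste0(.data$tail_class, "-tail len ",
                                          .data$tail_len),
                       value = .data$percent))
    comparisons <- with_stage("modstats",
                              compare_profiles(stat_values, samples))
    de <- with_stage("diffexp",
                     nb_wald_test(cm, samples$condition[
                       match(colnames(as.matrix(cm)), samples$sample_id)],
                       config$base_mean_cutoff, config$alpha))
  }

  tables <- list(count_matrix = cm,
                 isomir_calls = kept,
                 modification_profile = profile,
                 tail_histogram = tails,
                 tail_histogram_by_arm = tails_arm,
                 arm_ratio = arm_ratio,
                 fragments = fragments,
                 preprocess_log_quant = attr(quant_collapsed,
                                             "preprocess_log"),
                 preprocess_log_mod = attr(mod_collapsed, "preprocess_log"))
  if (!is.null(frag_fc)) tables$fragment_fold_change <- frag_fc
  if (!is.null(comparisons)) tables$comparisons <- comparisons
  if (!is.null(de)) tables$de_results <- tidy(de)
  paths <- with_stage("refio", write_tables(tables, config$out_dir))

  log_lines <- c(
    paste0("isotail ", as.character(utils::packageVersion("isotail"))),
    paste0("seed: ", config$seed),
    paste0("samples: ", paste(samples$sample_id, collapse = ", ")),
    utils::capture.output(as.data.frame(
      attr(mod_collapsed, "preprocess_log"))))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(reference = ref, samples = samples,
                 count_matrix = cm, calls = kept, totals = totals,
                 profile = profile, tails = tails, tails_arm = tails_arm,
                 arm_ratio = arm_ratio, fragments = fragments,
                 fragment_fold_change = frag_fc,
                 comparisons = comparisons, de = de, paths = paths))
}

#' Generate a self-contained synthetic fixture dataset
#'
#' Writes a complete simulated experiment (reference, FASTQ, sample
#' sheet, ground truth) with the default study design: 20 hairpins, two
#' conditions x 3 replicates. Used by the test suite and as a worked
#' example input.
#'
#' @param dir Output directory.
#' @param seed Master seed.
#' @param depth Mean reads per sample (default 50,000 to keep the
#'   fixture small).
#' @return The paths from [write_simulation()] plus `sim` and
#'   `reference`.
#' @export
make_fixture <- function(dir, seed = 101, depth = 50000) {
  cfg <- simulation_config(mean_depth = depth, seed = seed)
  ref <- generate_reference(cfg)
  sim <- simulate_reads(ref, cfg)
  paths <- write_simulation(sim, ref, dir)
  c(paths, list(sim = sim, reference = ref))
}
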