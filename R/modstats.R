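#' Per-sample totals of mature-assigned reads
#'
#' Denominators for modification frequencies: total assigned read counts
#' per sample, overall and by arm. Compute this on unthresholded calls so
#' the denominator is all mature-assigned reads in the modification
#' branch.
#'
#' @param calls Tibble from [call_isomirs()].
#' @return Tibble `sample_id`, `arm` (`5p`, `3p`, or `all`), `total`.
#' @export
assigned_totals <- function(calls) {
  by_arm <- calls |>
    dplyr::group_by(.data$sample_id, .data$arm) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  all <- calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(arm = "all")
  dplyr::bind_rows(by_arm, all)[, c("sample_id", "arm", "total")]
}

mod_class_flags <- function(calls) {
  dplyr::mutate(calls,
    `3'-trim` = .data$three_templated_offset < 0,
    `3'-add` = .data$nta3 != "" | .data$three_templated_offset > 0,
    `5'-trim` = .data$five_offset > 0,
    `5'-add` = .data$nta5 != "" | .data$five_offset < 0)
}

#' Modification-class frequencies per sample
#'
#' Frequencies of the four end-modification classes 3'-trim, 3'-add,
#' 5'-trim, 5'-add. A read contributes to every class it exhibits (a read
#' may be both 5'-trimmed and 3'-tailed). The denominator is all
#' mature-assigned reads in the modification branch; pass `totals`
#' computed on unthresholded calls, otherwise it is derived from `calls`.
#'
#' @param calls Tibble from [call_isomirs()] (normally after
#'   [apply_count_threshold()]).
#' @param totals Optional tibble from [assigned_totals()].
#' @return Tibble `sample_id`, `class`, `count`, `total`, `frequency`.
#' @export
modification_frequencies <- function(calls, totals = NULL) {
  if (is.null(totals)) totals <- assigned_totals(calls)
  denom <- totals[totals$arm == "all", c("sample_id", "total")]
  flagged <- mod_class_flags(calls)
  out <- purrr::map_dfr(c("3'-trim", "3'-add", "5'-trim", "5'-add"),
    function(cl) {
      flagged |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(count = sum(.data$count[.data[[cl]]]),
                         .groups = "drop") |>
        dplyr::mutate(class = cl)
    })
  out <- dplyr::left_join(out, denom, by = "sample_id")
  if (any(is.na(out$total) | out$total == 0)) {
    warning("zero assigned-read denominator for some sample(s); ",
            "frequencies undefined there")
  }
  out$frequency <- out$count / out$total
  out[, c("sample_id", "class", "count", "total", "frequency")]
}

#' Nontemplated tail length histogram
#'
#' Distribution of pure U- and A-tail lengths (1..`max_len`, longer tails
#' binned at `max_len`), as a percentage of all mature-assigned reads.
#' The mono/oligo split is length 1 versus >= 2.
#'
#' @param calls Tibble from [call_isomirs()].
#' @param by_arm Break down by arm as well?
#' @param totals Optional tibble from [assigned_totals()].
#' @param max_len Longest reported tail length bin.
#' @return Tibble `sample_id`, (`arm`), `tail_class`, `tail_len`,
#'   `mono_oligo`, `count`, `percent`.
#' @export
tail_length_histogram <- function(calls, by_arm = FALSE, totals = NULL,
                                  max_len = 5) {
  if (is.null(totals)) totals <- assigned_totals(calls)
  tailed <- calls[calls$tail_class %in% c("U", "A"), , drop = FALSE]
  tailed$tail_len <- pmin(nchar(tailed$nta3), max_len)
  keys <- c("sample_id", if (by_arm) "arm", "tail_class", "tail_len")
  out <- tailed |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  if (by_arm) {
    denom <- totals[totals$arm != "all", c("sample_id", "arm", "total")]
    out <- dplyr::left_join(out, denom, by = c("sample_id", "arm"))
  } else {
    out <- dplyr::left_join(out, totals[totals$arm == "all",
                                        c("sample_id", "total")],
                            by = "sample_id")
  }
  out$percent <- 100 * out$count / out$total
  out$mono_oligo <- ifelse(out$tail_len == 1, "mono", "oligo")
  out[, c(keys, "mono_oligo", "count", "total", "percent")]
}

#' Arm-resolved uridylation (and adenylation) ratio
#'
#' Per sample, the ratio of the 3p-arm U-tail frequency to the 5p-arm
#' U-tail frequency (frequency = U-tailed assigned reads / assigned reads
#' on that arm). A ratio well above 1 indicates tailing of the precursor
#' 3' end, which only the 3p mature inherits; a ratio near 1 indicates
#' tailing of mature miRNAs on both arms. Adenylation is computed
#' identically for contrast. Alongside the raw ratio (infinite when the
#' 5p count is zero) a continuity-corrected companion
#' `((c3p + 0.5)/n3p) / ((c5p + 0.5)/n5p)` is reported.
#'
#' @param calls Tibble from [call_isomirs()].
#' @return Tibble per sample with per-arm rates and `u_ratio`,
#'   `u_ratio_corrected`, `a_ratio`, `a_ratio_corrected`.
#' @export
arm_uridylation_ratio <- function(calls) {
  st <- calls |>
    dplyr::group_by(.data$sample_id, .data$arm) |>
    dplyr::summarise(total = sum(.data$count),
                     u = sum(.data$count[.data$tail_class == "U"]),
                     a = sum(.data$count[.data$tail_class == "A"]),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(st, names_from = "arm",
                             values_from = c("total", "u", "a"),
                             values_fill = 0)
  need <- c("total_5p", "total_3p", "u_5p", "u_3p", "a_5p", "a_3p")
  for (nm in setdiff(need, names(wide))) wide[[nm]] <- 0
  if (any(wide$total_5p == 0 | wide$total_3p == 0)) {
    stop("both arms need a nonzero assigned-read denominator")
  }
  ratio <- function(c3, n3, c5, n5) (c3 / n3) / (c5 / n5)
  corrected <- function(c3, n3, c5, n5) ((c3 + 0.5) / n3) / ((c5 + 0.5) / n5)
  dplyr::mutate(wide,
    u_rate_5p = .data$u_5p / .data$total_5p,
    u_rate_3p = .data$u_3p / .data$total_3p,
    a_rate_5p = .data$a_5p / .data$total_5p,
    a_rate_3p = .data$a_3p / .data$total_3p,
    u_ratio = ratio(.data$u_3p, .data$total_3p, .data$u_5p, .data$total_5p),
    u_ratio_corrected = corrected(.data$u_3p, .data$total_3p,
                                  .data$u_5p, .data$total_5p),
    a_ratio = ratio(.data$a_3p, .data$total_3p, .data$a_5p, .data$total_5p),
    a_ratio_corrected = corrected(.data$a_3p, .data$total_3p,
                                  .data$a_5p, .data$total_5p))
}

#' Count 13-17 nt short fragments per miRNA and sample
#'
#' A fragment is a read of insert length `min_len`..`max_len` whose 5'
#' end lies within 2 nt of a mature 5' end and whose templated 3' end is
#' at least 3 nt inside the canonical 3' end. Rates are normalized by
#' library size.
#'
#' @param calls Tibble from [call_isomirs()] (unthresholded calls
#'   recommended — fragments are individually rare).
#' @param library_sizes Named numeric vector of per-sample library sizes.
#' @param reference Optional `mirna_reference`; when given, the table is
#'   completed with zero rows for every (miRNA, sample).
#' @param min_len,max_len Insert length window (13-17 nt).
#' @param anchor_window 5' end tolerance (2 nt).
#' @param min_inside Minimum 3'-truncation depth (3 nt).
#' @return Tibble `mirna_id`, `sample_id`, `count`, `library_size`,
#'   `rate`.
#' @export
fragment_counts <- function(calls, library_sizes, reference = NULL,
                            min_len = 13, max_len = 17,
                            anchor_window = 2, min_inside = 3) {
  frag <- calls |>
    dplyr::filter(.data$insert_len >= min_len, .data$insert_len <= max_len,
                  abs(.data$five_offset) <= anchor_window,
                  .data$three_templated_offset <= -min_inside) |>
    dplyr::group_by(.data$mirna_id, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  mirnas <- if (!is.null(reference)) reference$matures$mirna_id else
    unique(c(frag$mirna_id, calls$mirna_id))
  grid <- tidyr::expand_grid(mirna_id = mirnas,
                             sample_id = names(library_sizes))
  out <- dplyr::left_join(grid, frag, by = c("mirna_id", "sample_id"))
  out$count[is.na(out$count)] <- 0L
  out$library_size <- unname(library_sizes[out$sample_id])
  out$rate <- out$count / out$library_size
  out
}

#' Per-miRNA fold change of short-fragment rates between conditions
#'
#' Fold change is the ratio of the condition-mean normalized fragment
#' rates, B over A, so that no change equals 1. By default rates are the
#' library-size-normalized `rate` column of [fragment_counts()]; when
#' `size_factors` (median-of-ratios factors from the expression matrix,
#' see [size_factors()]) are supplied, counts are normalized by them
#' instead, which removes the residual compositional skew that
#' asymmetric expression changes leave in plain library sizes and is
#' what makes "no change" sit at 1. A pseudocount of `pseudocount`
#' reads, scaled to rate units, keeps fold changes finite and symmetric
#' for zero counts.
#'
#' @param fragments Tibble from [fragment_counts()].
#' @param samples Tibble `sample_id`, `condition` (two conditions,
#'   control first by factor/sort order).
#' @param pseudocount Pseudocount in read units (default 0.5).
#' @param size_factors Optional named per-sample size factors.
#' @return Tibble `mirna_id`, `rate_A`, `rate_B`, `fold_change`.
#' @export
fragment_fold_change <- function(fragments, samples, pseudocount = 0.5,
                                 size_factors = NULL) {
  conds <- sort(unique(samples$condition))
  if (length(conds) != 2) stop("exactly two conditions required")
  x <- dplyr::left_join(fragments, samples[, c("sample_id", "condition")],
                        by = "sample_id")
  if (!is.null(size_factors)) {
    scale <- mean(fragments$library_size)
    x$rate <- x$count / (unname(size_factors[x$sample_id]) * scale)
  }
  pc <- pseudocount / mean(fragments$library_size)
  means <- x |>
    dplyr::group_by(.data$mirna_id, .data$condition) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "rate")
  tibble::tibble(
    mirna_id = means$mirna_id,
    rate_A = means[[conds[1]]],
    rate_B = means[[conds[2]]],
    fold_change = (means[[conds[2]]] + pc) / (means[[conds[1]]] + pc))
}

star_codes <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Compare per-sample statistics between two conditions by t-test
#'
#' Unpaired two-sided Student's t-test (equal variances) per statistic.
#' When both groups are constant: equal constants give p = 1; unequal
#' constants are reported as p = 0 with an infinite t and a
#' `zero_variance` flag.
#'
#' @param values Long tibble `sample_id`, `statistic`, `value`.
#' @param samples Tibble `sample_id`, `condition` (two conditions, at
#'   least two replicates each).
#' @return Tibble `statistic`, `mean_A`, `mean_B`, `t`, `p`, `stars`,
#'   `zero_variance`.
#' @export
compare_profiles <- function(values, samples) {
  conds <- sort(unique(samples$condition))
  if (length(conds) != 2) stop("exactly two conditions required")
  # a statistic absent in a sample (e.g. a tail-length bin with no reads)
  # is a true zero there, not missing data
  values <- tidyr::complete(values,
                            sample_id = samples$sample_id,
                            statistic = unique(values$statistic),
                            fill = list(value = 0))
  x <- dplyr::left_join(values, samples[, c("sample_id", "condition")],
                        by = "sample_id")
  n_per <- x |>
    dplyr::distinct(.data$sample_id, .data$condition) |>
    dplyr::count(.data$condition)
  if (any(n_per$n < 2) || nrow(n_per) < 2) {
    stop("at least two replicates per condition required")
  }
  x |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(
      mean_A = mean(.data$value[.data$condition == conds[1]]),
      mean_B = mean(.data$value[.data$condition == conds[2]]),
      t = {
        a <- .data$value[.data$condition == conds[1]]
        b <- .data$value[.data$condition == conds[2]]
        if (sd(a) == 0 && sd(b) == 0) {
          if (mean(a) == mean(b)) 0 else Inf * sign(mean(b) - mean(a))
        } else {
          unname(t.test(b, a, var.equal = TRUE)$statistic)
        }
      },
      p = {
        a <- .data$value[.data$condition == conds[1]]
        b <- .data$value[.data$condition == conds[2]]
        if (sd(a) == 0 && sd(b) == 0) {
          if (mean(a) == mean(b)) 1 else 0
        } else {
          t.test(b, a, var.equal = TRUE)$p.value
        }
      },
      zero_variance = {
        a <- .data$value[.data$condition == conds[1]]
        b <- .data$value[.data$condition == conds[2]]
        sd(a) == 0 && sd(b) == 0
      },
      .groups = "drop") |>
    dplyr::mutate(stars = star_codes(.data$p)) |>
    dplyr::select("statistic", "mean_A", "mean_B", "t", "p", "stars",
                  "zero_variance")
}

#' Relative expression fold change by the 2^-ddCt method
#'
#' `fold = 2^-((ct_target_B - ct_ref_B) - (ct_target_A - ct_ref_A))`,
#' i.e. target expression in condition B relative to A, each normalized
#' to a reference gene.
#'
#' @param ct_target_b,ct_ref_b,ct_target_a,ct_ref_a Ct values
#'   (vectorized).
#' @return Numeric fold change(s).
#' @export
ddct_fold_change <- function(ct_target_b, ct_ref_b, ct_target_a, ct_ref_a) {
  stopifnot(all(c(ct_target_b, ct_ref_b, ct_target_a, ct_ref_a) > 0))
  2^-((ct_target_b - ct_ref_b) - (ct_target_a - ct_ref_a))
}
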