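#' Strictly map collapsed reads to hairpins (exact, sense, full length)
#'
#' Reports every exact sense-strand occurrence of each distinct read
#' sequence across all hairpins. No mismatches are tolerated, so tailed
#' reads never enter this branch.
#'
#' @param collapsed Tibble with a `sequence` column (e.g. from
#'   [collapse_reads()]).
#' @param reference A `mirna_reference`.
#' @return Tibble of hits: `sequence`, `hairpin_id`, `start`, `end`
#'   (0-based half-open on the hairpin).
#' @export
map_strict <- function(collapsed, reference) {
  seqs <- unique(collapsed$sequence)
  hits <- align_ungapped_all(seqs, reference$hairpins$sequence, 0L, 0L, 0L, 1L)
  tibble::tibble(
    sequence = seqs[hits$read],
    hairpin_id = reference$hairpins$hairpin_id[hits$hairpin],
    start = hits$start - 1L,
    end = hits$start - 1L + nchar(seqs[hits$read]))
}

#' Assign strict hits to mature miRNAs with the +/-2 nt templated window
#'
#' A hit is assigned to a mature annotation when both of its ends lie
#' independently within `window` nt of the canonical ends:
#' `|start - m.start| <= window` and `|end - m.end| <= window`. This
#' admits up to 2 nt longer (templated) and 2 nt shorter isoforms while
#' excluding short fragments from the expression matrix. A read assigned
#' to the same miRNA via several hairpin loci is kept once.
#'
#' @param hits Tibble from [map_strict()].
#' @param reference A `mirna_reference`.
#' @param window End tolerance in nt (default 2).
#' @return Tibble `sequence`, `mirna_id` (distinct pairs).
#' @export
assign_to_mature <- function(hits, reference, window = 2) {
  dplyr::inner_join(hits, reference$matures, by = "hairpin_id",
                    suffix = c("", ".m"), relationship = "many-to-many") |>
    dplyr::filter(abs(.data$start - .data$start.m) <= window,
                  abs(.data$end - .data$end.m) <= window) |>
    dplyr::distinct(.data$sequence, .data$mirna_id)
}

#' Build the miRNA x sample count matrix
#'
#' Sums collapsed read counts per (miRNA, sample). A read assigned to the
#' same miRNA through multiple loci contributes once; a read assigned to
#' distinct miRNAs contributes once to each. The per-sample library size
#' is the total collapsed count entering mapping.
#'
#' @param collapsed Tibble `sample_id`, `sequence`, `count`.
#' @param assigned Tibble `sequence`, `mirna_id` from
#'   [assign_to_mature()].
#' @param reference A `mirna_reference` (fixes the row set and order).
#' @return A `count_matrix`: tibble with `mirna_id` and one integer
#'   column per sample, with a `library_sizes` attribute.
#' @export
build_count_matrix <- function(collapsed, assigned, reference) {
  samples <- sort(unique(collapsed$sample_id))
  libsize <- collapsed |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  counts <- dplyr::inner_join(collapsed, assigned, by = "sequence",
                              relationship = "many-to-many") |>
    dplyr::group_by(.data$mirna_id, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  wide <- tidyr::pivot_wider(counts, names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  out <- tibble::tibble(mirna_id = reference$matures$mirna_id) |>
    dplyr::left_join(wide, by = "mirna_id")
  for (s in samples) {
    if (!s %in% names(out)) out[[s]] <- 0L
    out[[s]][is.na(out[[s]])] <- 0L
  }
  out <- out[, c("mirna_id", samples)]
  structure(out,
            library_sizes = setNames(libsize$n, libsize$sample_id)[samples],
            class = c("count_matrix", class(out)))
}

#' Map, assign and count in one step
#'
#' Convenience wrapper running [map_strict()], [assign_to_mature()] and
#' [build_count_matrix()].
#'
#' @inheritParams build_count_matrix
#' @inheritParams assign_to_mature
#' @return A `count_matrix`.
#' @export
quantify_samples <- function(collapsed, reference, window = 2) {
  hits <- map_strict(collapsed, reference)
  assigned <- assign_to_mature(hits, reference, window)
  build_count_matrix(collapsed, assigned, reference)
}

#' @export
as.matrix.count_matrix <- function(x, ...) {
  m <- as.matrix(as.data.frame(x[, -1]))
  rownames(m) <- x$mirna_id
  storage.mode(m) <- "double"
  m
}

#' Library sizes of a count matrix
#'
#' @param x A `count_matrix`.
#' @return Named numeric vector of total collapsed counts per sample.
#' @export
library_sizes <- function(x) attr(x, "library_sizes")
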