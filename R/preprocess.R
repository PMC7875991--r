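#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (optionally gzipped).
#' @param sample_id Optional sample label attached to every record.
#' @return Tibble with `sample_id` (if given), `read_id`, `sequence`,
#'   `quality`.
#' @export
read_fastq <- function(path, sample_id = NULL) {
  # readQualityScaledDNAStringSet warns about dropped metadata columns on
  # plain FASTQ input; nothing is lost
  q <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  out <- tibble::tibble(
    read_id = sub("\\s.*$", "", names(q)),
    sequence = as.character(q),
    quality = as.character(Biostrings::quality(q)))
  if (!is.null(sample_id)) {
    out <- tibble::add_column(out, sample_id = sample_id, .before = 1)
  }
  out
}

#' Clip the 3' adapter off raw reads
#'
#' The insert is everything before the leftmost exact match of an adapter
#' prefix of length at least `min_overlap` that either extends to the read
#' end or matches the full adapter. Reads in which no such match exists
#' are flagged adapterless (`adapter_found = FALSE`, `insert = NA`);
#' absence is a value, not an error.
#'
#' @param reads Tibble with a `sequence` column (and optionally
#'   `quality`).
#' @param adapter Adapter sequence (DNA, at least `min_overlap` long).
#' @param min_overlap Minimum adapter prefix length for a match.
#' @return `reads` with added `insert`, `insert_quality` (when `quality`
#'   is present) and `adapter_found` columns.
#' @export
clip_adapter <- function(reads, adapter, min_overlap = 8) {
  stopifnot(min_overlap >= 1, nchar(adapter) >= min_overlap)
  adapter <- dna_normalize(adapter)
  seqs <- reads$sequence
  L <- nchar(seqs)
  alen <- nchar(adapter)
  probe <- substr(adapter, 1, min_overlap)

  valid_at <- function(p, idx) {
    # match length available from p to read end, capped at the adapter length
    k <- pmin(L[idx] - p + 1L, alen)
    ok <- !is.na(p) & k >= min_overlap &
      substr(seqs[idx], p, p + k - 1L) == substr(adapter, 1, k)
    ok & !is.na(ok)
  }

  p <- unname(stringi::stri_locate_first_fixed(seqs, probe)[, 1])
  ok <- valid_at(p, seq_along(seqs))
  # a probe hit that fails validation may be a chance k-mer inside the
  # insert; fall back to scanning all probe occurrences for those reads
  retry <- which(!is.na(p) & !ok)
  if (length(retry)) {
    all_pos <- stringi::stri_locate_all_fixed(seqs[retry], probe)
    for (i in seq_along(retry)) {
      ri <- retry[i]
      for (cand in all_pos[[i]][, 1]) {
        if (is.na(cand)) break
        if (valid_at(cand, ri)) {
          p[ri] <- cand; ok[ri] <- TRUE; break
        }
      }
    }
  }
  reads$insert <- ifelse(ok, substr(seqs, 1L, p - 1L), NA_character_)
  if ("quality" %in% names(reads)) {
    reads$insert_quality <- ifelse(ok, substr(reads$quality, 1L, p - 1L),
                                   NA_character_)
  }
  reads$adapter_found <- ok
  reads
}

#' Quality-filter clipped inserts
#'
#' A read passes when at least `min_fraction` of its insert bases have a
#' Phred quality of at least `min_q` (Phred+33). Empty inserts fail.
#'
#' @param reads Tibble with `insert` and `insert_quality` columns (from
#'   [clip_adapter()]).
#' @param min_fraction Minimum passing-base fraction.
#' @param min_q Phred threshold.
#' @return `reads` with an added logical `pass_quality` column.
#' @export
quality_filter <- function(reads, min_fraction = 0.95, min_q = 20) {
  qual <- reads$insert_quality
  len <- nchar(qual)
  # count bases with Phred < min_q, i.e. ASCII below 33 + min_q
  low_class <- sprintf("[\\x{01}-\\x{%02X}]", 33L + as.integer(min_q) - 1L)
  n_low <- stringi::stri_count_regex(qual, low_class)
  pass <- !is.na(len) & len > 0 & (len - n_low) / len >= min_fraction
  reads$pass_quality <- pass & !is.na(pass)
  reads
}

#' Length-filter clipped inserts
#'
#' A read passes when its adapter was found and the insert length lies in
#' `[min_len, max_len]`. Adapterless reads always fail.
#'
#' @param reads Tibble from [clip_adapter()].
#' @param min_len Minimum insert length (default 12 nt).
#' @param max_len Maximum insert length, or `Inf` for no cap (the
#'   quantification branch uses 30, mirroring PAGE size selection).
#' @return `reads` with an added logical `pass_length` column.
#' @export
length_filter <- function(reads, min_len = 12, max_len = Inf) {
  len <- nchar(reads$insert)
  pass <- reads$adapter_found & !is.na(len) & len >= min_len & len <= max_len
  reads$pass_length <- pass & !is.na(pass)
  reads
}

#' Collapse reads to unique sequences with multiplicities
#'
#' One record per distinct sequence (per sample when a `sample_id` column
#' is present); counts sum to the number of input reads. Output order is
#' deterministic: count descending, then lexicographic.
#'
#' @param reads Tibble with a sequence column (`insert` preferred,
#'   `sequence` otherwise) and optionally `sample_id`.
#' @return Tibble with `sample_id` (if present), `sequence`, `count`.
#' @export
collapse_reads <- function(reads) {
  seq_col <- if ("insert" %in% names(reads)) "insert" else "sequence"
  keys <- c(intersect("sample_id", names(reads)), seq_col)
  out <- dplyr::count(reads, dplyr::across(dplyr::all_of(keys)),
                      name = "count")
  names(out)[names(out) == seq_col] <- "sequence"
  dplyr::arrange(out,
                 dplyr::across(dplyr::any_of("sample_id")),
                 dplyr::desc(.data$count), .data$sequence)
}

#' Preprocess raw reads: clip, quality-filter, length-filter, collapse
#'
#' The fixed pipeline order is clip -> quality -> length -> collapse.
#' Per-sample read accounting is attached as the `preprocess_log`
#' attribute and satisfies `n_in = n_adapterless + n_clipped` and
#' `n_clipped = n_quality_failed + n_length_failed + n_kept`.
#'
#' @param reads Tibble with `sample_id`, `sequence`, `quality`.
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum adapter prefix match length.
#' @param min_q,min_fraction Quality filter parameters.
#' @param min_len,max_len Insert length window; the modification branch
#'   uses `max_len = Inf`, the quantification branch 30.
#' @return Collapsed tibble (`sample_id`, `sequence`, `count`) with a
#'   `preprocess_log` attribute.
#' @export
preprocess_reads <- function(reads, adapter, min_overlap = 8,
                             min_q = 20, min_fraction = 0.95,
                             min_len = 12, max_len = Inf) {
  reads <- clip_adapter(reads, adapter, min_overlap)
  reads <- quality_filter(reads, min_fraction, min_q)
  reads <- length_filter(reads, min_len, max_len)
  keep <- reads$adapter_found & reads$pass_quality & reads$pass_length
  log <- reads |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_in = dplyr::n(),
      n_adapterless = sum(!.data$adapter_found),
      n_clipped = sum(.data$adapter_found),
      n_quality_failed = sum(.data$adapter_found & !.data$pass_quality),
      n_length_failed = sum(.data$adapter_found & .data$pass_quality &
                              !.data$pass_length),
      n_kept = sum(.data$adapter_found & .data$pass_quality &
                     .data$pass_length),
      .groups = "drop")
  stopifnot(all(log$n_in == log$n_adapterless + log$n_clipped),
            all(log$n_clipped ==
                  log$n_quality_failed + log$n_length_failed + log$n_kept))
  out <- collapse_reads(reads[keep, , drop = FALSE])
  log$n_unique <- dplyr::count(out, .data$sample_id)$n[
    match(log$sample_id, dplyr::count(out, .data$sample_id)$sample_id)]
  log$n_unique[is.na(log$n_unique)] <- 0L
  attr(out, "preprocess_log") <- log
  out
}
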