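#' Leniently map collapsed reads to hairpins (end-modification aware)
#'
#' Reports every sense-strand ungapped placement of each distinct read
#' (the all-alignments contract of `bowtie -a`). At each placement the
#' in-template positions split into a leading and a trailing contiguous
#' mismatch run -- the candidate nontemplated 5'/3' additions, each
#' allowed up to `max_tail` bases -- and the core between them, where at
#' most `max_mismatch` mismatches are tolerated (the `-v 2` style
#' residual cap). Terminal runs are exempt from the mismatch cap: they
#' are precisely what end-modification calling classifies as tails, and
#' a plain cap would make fully nontemplated 3-nt tails unmappable. The
#' read 3' end may additionally overhang the hairpin end by up to
#' `max_overhang` bases; overhanging positions carry no template and are
#' never mismatches.
#'
#' @param collapsed Tibble with a `sequence` column.
#' @param reference A `mirna_reference`.
#' @param max_mismatch Mismatch cap on core (non-terminal) positions.
#' @param max_overhang Maximum 3' overhang beyond the hairpin end.
#' @param max_tail Maximum terminal mismatch run length per end.
#' @param min_core Minimum core (templated) length of a placement.
#' @return Tibble `sequence`, `hairpin_id`, `start` (0-based),
#'   `mismatches` (total in-template), `core_mismatches`, `run5`,
#'   `run3`, `overhang`.
#' @export
map_lenient <- function(collapsed, reference, max_mismatch = 2,
                        max_overhang = 6, max_tail = 8, min_core = 8) {
  seqs <- unique(collapsed$sequence)
  hits <- align_ungapped_all(seqs, reference$hairpins$sequence,
                             as.integer(max_mismatch),
                             as.integer(max_overhang),
                             as.integer(max_tail), as.integer(min_core))
  tibble::tibble(
    sequence = seqs[hits$read],
    hairpin_id = reference$hairpins$hairpin_id[hits$hairpin],
    start = hits$start - 1L,
    mismatches = hits$mismatches,
    core_mismatches = hits$core_mismatches,
    run5 = hits$run5,
    run3 = hits$run3,
    overhang = hits$overhang)
}

# implied mature for each (hairpin, start): the annotation on that hairpin
# minimizing |start - mature start|; ties broken toward the smaller start.
implied_mature <- function(alignments, reference) {
  dplyr::inner_join(alignments, reference$matures, by = "hairpin_id",
                    suffix = c("", ".m"), relationship = "many-to-many") |>
    dplyr::mutate(start_offset = .data$start - .data$start.m) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("sequence", "hairpin_id", "start")))) |>
    dplyr::arrange(abs(.data$start_offset), .data$start.m,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Select one alignment per read deterministically
#'
#' Preference order: fewest core (non-terminal) mismatches; then fewest
#' total mismatches; then smallest absolute 5' offset of the implied
#' mature; then lexicographically smallest hairpin id; then smallest
#' start.
#'
#' @param alignments Tibble from [map_lenient()].
#' @param reference A `mirna_reference`.
#' @return One row per `sequence`, with the implied mature columns
#'   (`mirna_id`, `arm`, mature `start.m`/`end`) attached. Sequences with
#'   no alignment are absent.
#' @export
select_alignment <- function(alignments, reference) {
  if (nrow(alignments) == 0) return(alignments[0, ])
  implied_mature(alignments, reference) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::arrange(.data$core_mismatches, .data$mismatches,
                   abs(.data$start_offset), .data$hairpin_id, .data$start,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

# decompose one read given its selected alignment; returns NULL when the
# read is unclassifiable as an end-modification
decompose_read <- function(read, hp_chars, s0, m_start, m_end) {
  rd <- strsplit(read, "")[[1]]
  L <- length(rd)
  hl <- length(hp_chars)
  tpos <- s0 + seq_len(L)            # 1-based template positions
  templ <- ifelse(tpos <= hl, hp_chars[pmin(tpos, hl)], NA_character_)
  match <- !is.na(templ) & rd == templ

  t3 <- 0L
  while (t3 < L && !match[L - t3]) t3 <- t3 + 1L
  t5 <- 0L
  while (t5 < L - t3 && !match[t5 + 1L]) t5 <- t5 + 1L
  if (t5 + t3 >= L) return(NULL)
  core <- match[(t5 + 1L):(L - t3)]
  if (!all(core)) return(NULL)        # unexplained interior mismatch

  nta5 <- if (t5 > 0) substr(read, 1L, t5) else ""
  nta3 <- if (t3 > 0) substr(read, L - t3 + 1L, L) else ""
  list(five_offset = as.integer((s0 + t5) - m_start),
       three_templated_offset = as.integer((s0 + L - t3) - m_end),
       nta5 = nta5, nta3 = nta3)
}

classify_tail <- function(nta3) {
  dplyr::case_when(
    nta3 == "" ~ "none",
    grepl("^T+$", nta3) ~ "U",
    grepl("^A+$", nta3) ~ "A",
    TRUE ~ "mixed")
}

#' Call isomiRs: decompose reads into templated offsets and tails
#'
#' For each distinct read sequence: lenient mapping, deterministic
#' alignment selection, assignment to the implied mature (absent when the
#' smallest |5' start offset| exceeds `max_assign_dist`), and 3'/5'
#' decomposition by maximal templated extension — walking inward from
#' each read end, the contiguous run of template-mismatching bases is the
#' nontemplated addition, and a terminal base matching the template is
#' always attributed to the template. Reads whose remaining core does not
#' match the template exactly are unclassifiable as end modifications and
#' are dropped, so that templated part + tails reconstructs every kept
#' read byte for byte.
#'
#' @param collapsed Tibble `sample_id`, `sequence`, `count`.
#' @param reference A `mirna_reference`.
#' @param max_mismatch,max_overhang,max_tail,min_core Passed to
#'   [map_lenient()].
#' @param max_assign_dist Maximum |5' start offset| for mature
#'   assignment (default 5).
#' @return Tibble of calls, one row per (sample, read sequence):
#'   `sample_id`, `sequence`, `count`, `mirna_id`, `arm`, `hairpin_id`,
#'   `five_offset`, `three_templated_offset`, `nta5`, `nta3`,
#'   `tail_class`, `insert_len`.
#' @export
call_isomirs <- function(collapsed, reference, max_mismatch = 2,
                         max_overhang = 6, max_tail = 8, min_core = 8,
                         max_assign_dist = 5) {
  aln <- map_lenient(collapsed, reference, max_mismatch, max_overhang,
                     max_tail, min_core)
  sel <- select_alignment(aln, reference)
  sel <- sel[abs(sel$start_offset) <= max_assign_dist, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(tibble::tibble(sample_id = character(), sequence = character(),
                          count = integer(), mirna_id = character(),
                          arm = character(), hairpin_id = character(),
                          five_offset = integer(),
                          three_templated_offset = integer(),
                          nta5 = character(), nta3 = character(),
                          tail_class = character(), insert_len = integer()))
  }
  hp_chars <- lapply(setNames(reference$hairpins$sequence,
                              reference$hairpins$hairpin_id),
                     function(s) strsplit(s, "")[[1]])
  dec <- vector("list", nrow(sel))
  for (i in seq_len(nrow(sel))) {
    dec[i] <- list(decompose_read(sel$sequence[i],
                                  hp_chars[[sel$hairpin_id[i]]],
                                  sel$start[i], sel$start.m[i], sel$end[i]))
  }
  keep <- !vapply(dec, is.null, logical(1))
  sel <- sel[keep, , drop = FALSE]
  dec <- dec[keep]
  calls_u <- tibble::tibble(
    sequence = sel$sequence,
    mirna_id = sel$mirna_id,
    arm = sel$arm,
    hairpin_id = sel$hairpin_id,
    five_offset = vapply(dec, `[[`, integer(1), "five_offset"),
    three_templated_offset = vapply(dec, `[[`, integer(1),
                                    "three_templated_offset"),
    nta5 = vapply(dec, `[[`, character(1), "nta5"),
    nta3 = vapply(dec, `[[`, character(1), "nta3"))
  calls_u$tail_class <- classify_tail(calls_u$nta3)
  calls_u$insert_len <- nchar(calls_u$sequence)
  dplyr::inner_join(
    collapsed[, intersect(c("sample_id", "sequence", "count"),
                          names(collapsed))],
    calls_u, by = "sequence") |>
    tibble::as_tibble()
}

#' Keep only modification signatures supported by enough reads
#'
#' A (sample, miRNA, modification signature) is kept when its summed read
#' count reaches `min_count` (default 2, the low-input setting).
#' The signature is (`five_offset`, `three_templated_offset`, `nta5`,
#' `nta3`).
#'
#' @param calls Tibble from [call_isomirs()].
#' @param min_count Minimum summed read count.
#' @return Filtered calls tibble.
#' @export
apply_count_threshold <- function(calls, min_count = 2) {
  calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(intersect("sample_id", names(calls)), "mirna_id", "five_offset",
        "three_templated_offset", "nta5", "nta3")))) |>
    dplyr::filter(sum(.data$count) >= min_count) |>
    dplyr::ungroup()
}
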