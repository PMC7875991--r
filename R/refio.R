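#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Uppercases and converts U to T. All internal sequence handling uses the
#' DNA alphabet so that reads (sequenced as DNA) and references compare
#' directly.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector over `{A,C,G,T,N}`.
#' @export
dna_normalize <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Read a hairpin reference with mature miRNA annotations
#'
#' Loads pre-miRNA (hairpin) sequences from FASTA and mature miRNA
#' annotations from a GFF3 subset (rows of type `miRNA` carrying `ID` and,
#' optionally, `arm` attributes). GFF3 1-based inclusive coordinates are
#' converted to 0-based half-open at this boundary; everything downstream
#' uses 0-based half-open intervals. When the `arm` attribute is absent it
#' is inferred from the mature midpoint: 5' half of the hairpin is 5p, the
#' rest 3p.
#'
#' @param fasta_path Path to the hairpin FASTA (U residues accepted,
#'   stored as T).
#' @param gff_path Path to the GFF3 annotation.
#' @return An object of class `mirna_reference`: a list with tibbles
#'   `hairpins` (`hairpin_id`, `sequence`, `length`) and `matures`
#'   (`mirna_id`, `hairpin_id`, `arm`, `start`, `end`, `canonical_seq`),
#'   coordinates 0-based half-open on the hairpin.
#' @export
read_hairpin_reference <- function(fasta_path, gff_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  hairpins <- tibble::tibble(
    hairpin_id = unname(sub("\\s.*$", "", names(seqs))),
    sequence = unname(dna_normalize(as.character(seqs)))
  )
  hairpins$length <- nchar(hairpins$sequence)

  gff <- rtracklayer::import(gff_path)
  gff <- gff[as.character(gff$type) == "miRNA"]
  mat <- tibble::tibble(
    mirna_id = as.character(gff$ID),
    hairpin_id = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff) - 1L,  # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gff),
    arm = if (!is.null(gff$arm)) as.character(gff$arm) else NA_character_
  )
  build_reference(hairpins, mat)
}

#' Assemble and validate a `mirna_reference`
#'
#' Validates every mature annotation against its hairpin and fills in
#' canonical sequences and missing arms. Used by [read_hairpin_reference()]
#' and by the read simulator.
#'
#' @param hairpins Tibble with `hairpin_id`, `sequence`.
#' @param matures Tibble with `mirna_id`, `hairpin_id`, `start`, `end`
#'   (0-based half-open) and optional `arm`.
#' @return A `mirna_reference` object.
#' @export
build_reference <- function(hairpins, matures) {
  hairpins <- tibble::as_tibble(hairpins)
  hairpins$sequence <- dna_normalize(hairpins$sequence)
  hairpins$length <- nchar(hairpins$sequence)
  if (anyDuplicated(hairpins$hairpin_id)) {
    stop("duplicated hairpin ids in reference")
  }
  if (any(hairpins$length < 40)) {
    stop("hairpin(s) shorter than 40 nt: ",
         paste(hairpins$hairpin_id[hairpins$length < 40], collapse = ", "))
  }
  matures <- tibble::as_tibble(matures)
  if (!"arm" %in% names(matures)) matures$arm <- NA_character_
  missing_hp <- setdiff(matures$hairpin_id, hairpins$hairpin_id)
  if (length(missing_hp)) {
    stop("mature annotation(s) reference missing hairpin(s): ",
         paste(missing_hp, collapse = ", "))
  }
  matures <- dplyr::left_join(
    matures,
    dplyr::select(hairpins, "hairpin_id", hp_seq = "sequence",
                  hp_len = "length"),
    by = "hairpin_id"
  )
  bad <- matures$start < 0 | matures$end > matures$hp_len
  if (any(bad)) {
    stop("mature annotation(s) outside hairpin bounds: ",
         paste(matures$mirna_id[bad], collapse = ", "))
  }
  len <- matures$end - matures$start
  if (any(len < 16 | len > 28)) {
    stop("mature length outside 16..28 nt: ",
         paste(matures$mirna_id[len < 16 | len > 28], collapse = ", "))
  }
  matures$canonical_seq <- substr(matures$hp_seq, matures$start + 1L,
                                  matures$end)
  mid <- (matures$start + matures$end) / 2
  inferred <- ifelse(mid < matures$hp_len / 2, "5p", "3p")
  matures$arm <- ifelse(is.na(matures$arm), inferred, matures$arm)
  if (!all(matures$arm %in% c("5p", "3p"))) {
    stop("arm must be '5p' or '3p'")
  }
  # Non-overlap of matures on one hairpin, and mature 5' ends >= 8 nt apart:
  # this guarantees the +/-2 assignment window is unambiguous.
  per_hp <- split(matures, matures$hairpin_id)
  for (m in per_hp) {
    if (nrow(m) < 2) next
    m <- m[order(m$start), ]
    if (any(m$end[-nrow(m)] > m$start[-1])) {
      stop("overlapping mature annotations on hairpin ", m$hairpin_id[1])
    }
    if (any(diff(m$start) < 8)) {
      stop("mature 5' ends closer than 8 nt on hairpin ", m$hairpin_id[1])
    }
  }
  matures <- dplyr::select(matures, "mirna_id", "hairpin_id", "arm",
                           "start", "end", "canonical_seq")
  structure(list(hairpins = hairpins, matures = matures),
            class = "mirna_reference")
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat("<mirna_reference> ", nrow(x$hairpins), " hairpins, ",
      nrow(x$matures), " mature miRNAs (",
      sum(x$matures$arm == "5p"), " 5p / ",
      sum(x$matures$arm == "3p"), " 3p)\n", sep = "")
  invisible(x)
}

#' Write a `mirna_reference` to FASTA + GFF3
#'
#' Inverse of [read_hairpin_reference()]; internal 0-based half-open
#' coordinates are emitted as GFF3 1-based inclusive.
#'
#' @param reference A `mirna_reference`.
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference <- function(reference, fasta_path, gff_path) {
  seqs <- Biostrings::DNAStringSet(reference$hairpins$sequence)
  names(seqs) <- reference$hairpins$hairpin_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  m <- reference$matures
  gr <- GenomicRanges::GRanges(
    seqnames = m$hairpin_id,
    ranges = IRanges::IRanges(start = m$start + 1L, end = m$end),
    type = "miRNA", ID = m$mirna_id, arm = m$arm
  )
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(fasta_path, gff_path))
}

#' Read collapsed reads in `>serial-count` FASTA dialect
#'
#' The dialect produced by fastx-style collapsers: each header is
#' `>serial-count` where `count` is the read multiplicity.
#'
#' @param path Collapsed FASTA path.
#' @param sample_id Sample label attached to every record.
#' @return Tibble with `sample_id`, `sequence`, `count`.
#' @export
read_collapsed_fasta <- function(path, sample_id) {
  seqs <- Biostrings::readBStringSet(path)
  heads <- names(seqs)
  ok <- grepl("^[0-9]+-[0-9]+$", heads)
  if (!all(ok)) {
    stop("malformed collapsed-FASTA header at record ", which(!ok)[1],
         ": '>", heads[which(!ok)[1]], "' (expected '>serial-count')")
  }
  counts <- as.integer(sub("^[0-9]+-", "", heads))
  if (any(counts < 1)) stop("collapsed read count must be >= 1")
  out <- tibble::tibble(
    sample_id = sample_id,
    sequence = unname(dna_normalize(as.character(seqs))),
    count = counts
  )
  if (any(nchar(out$sequence) < 12)) {
    stop("collapsed read(s) shorter than 12 nt")
  }
  out
}

#' Write collapsed reads in `>serial-count` FASTA dialect
#'
#' @param reads Tibble with `sequence` and `count`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_collapsed_fasta <- function(reads, path) {
  lines <- as.vector(rbind(
    paste0(">", seq_len(nrow(reads)), "-", reads$count),
    reads$sequence
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `condition`, `replicate`, `fastq`.
#'
#' @param path Sample sheet path.
#' @return Tibble, validated (unique sample ids, every condition with at
#'   least one sample).
#' @export
read_sample_sheet <- function(path) {
  ss <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = "c", condition = "c",
                          replicate = "i", fastq = "c"))
  if (anyDuplicated(ss$sample_id)) stop("duplicated sample_id in sample sheet")
  if (length(unique(ss$condition)) < 1) stop("sample sheet has no conditions")
  ss
}

#' Write result tables as deterministic, diffable TSV
#'
#' Each table is written with a fixed column order (as given), rows sorted
#' by all columns left to right, and doubles rounded to 6 significant
#' digits, so that repeated runs produce byte-identical files.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create ", out_dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- tibble::as_tibble(tables[[nm]])
    num <- vapply(tb, is.double, logical(1))
    tb[num] <- lapply(tb[num], signif, digits = 6)
    if (nrow(tb) > 1) {
      tb <- dplyr::arrange(tb, dplyr::across(dplyr::everything()))
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tb, p, progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a TSV written by [write_tables()]
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
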