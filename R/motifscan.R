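#' Read a JASPAR-format position count matrix
#'
#' Parses the plain-text JASPAR layout: a `>ID name` header followed by
#' four rows `A [ 1 2 3 ]` (brackets optional), in A, C, G, T order.
#'
#' @param path Path to the matrix file.
#' @return 4 x L numeric count matrix with rownames A, C, G, T and a
#'   `motif_id` attribute.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- grep("^>", lines)
  if (length(header) != 1 || length(lines) != 5) {
    stop("expected one '>' header and four base rows")
  }
  motif_id <- sub("^>\\s*", "", lines[header])
  rows <- lines[-header]
  parse_row <- function(x) {
    base <- toupper(sub("^\\s*([ACGTacgt]).*$", "\\1", x))
    nums <- gsub("^[^\\[]*\\[|\\]\\s*$", "", x)
    nums <- if (identical(nums, x)) sub("^\\s*[ACGTacgt]\\s*", "", x) else nums
    list(base = base, counts = as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
  }
  parsed <- lapply(rows, parse_row)
  counts <- do.call(rbind, lapply(parsed, `[[`, "counts"))
  rownames(counts) <- vapply(parsed, `[[`, character(1), "base")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(is.na(counts)) || any(counts < 0)) stop("malformed count matrix")
  attr(counts, "motif_id") <- motif_id
  counts
}

#' Build a log-odds position weight matrix from counts
#'
#' `logodds[b, j] = log2(((counts[b, j] + pc) / (colsum_j + 4 pc)) /
#' background[b])`, in bits.
#'
#' @param counts 4 x L non-negative matrix, rows A, C, G, T.
#' @param pseudocount Pseudocount added to every cell (default 0.25).
#' @param background Background base probabilities (sum to 1; uniform by
#'   default).
#' @param motif_id Motif label (taken from `counts` attribute when
#'   present).
#' @return Object of class `pwm`: list with `motif_id`, `counts`,
#'   `background`, `log_odds` (4 x L, bits), `length`, `consensus`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.25,
                            background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                            motif_id = attr(counts, "motif_id") %||%
                              "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1) stop("counts must have at least one column")
  if (any(counts < 0)) stop("counts must be non-negative")
  rownames(counts) <- c("A", "C", "G", "T")
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  colsum <- colSums(counts)
  if (pseudocount == 0 && any(colsum == 0)) {
    stop("all-zero column requires a positive pseudocount")
  }
  prob <- sweep(counts + pseudocount, 2, colsum + 4 * pseudocount, "/")
  lo <- log2(prob / background)
  consensus <- paste(rownames(lo)[apply(lo, 2, which.max)], collapse = "")
  structure(list(motif_id = motif_id, counts = counts,
                 background = background, log_odds = lo,
                 length = ncol(lo), consensus = consensus),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$motif_id, " length ", x$length,
      " consensus ", x$consensus, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' @param x Character vector over `{A,C,G,T,N}`.
#' @return Reverse-complemented character vector.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

score_windows <- function(region, lo) {
  L <- ncol(lo)
  ch <- strsplit(region, "")[[1]]
  idx <- match(ch, c("A", "C", "G", "T"))
  n <- length(idx) - L + 1
  sc <- numeric(n)
  for (j in seq_len(L)) {
    v <- unname(lo[, j])[idx[j:(j + n - 1)]]
    v[is.na(v)] <- min(lo)   # N or unknown base scores as worst case
    sc <- sc + v
  }
  sc
}

#' Scan one region with a PWM on both strands
#'
#' Scores every window on the forward strand and on the reverse
#' complement, and returns the `top_k` hits by score with a deterministic
#' tie-break by (position, strand). Positions are 0-based on the forward
#' region; minus-strand hits report the window's forward-strand position
#' and the strand-oriented matched word.
#'
#' @param region DNA string (length >= motif length).
#' @param pwm A [pwm_from_counts()] object.
#' @param top_k Number of hits to return.
#' @param region_id Label attached to the hits.
#' @return Tibble `region_id`, `position`, `strand`, `score`, `match`.
#' @export
scan_region <- function(region, pwm, top_k = 3, region_id = "region") {
  region <- dna_normalize(region)
  L <- pwm$length
  n <- nchar(region)
  if (n < L) stop("region (", n, " nt) shorter than motif (", L, " nt)")
  fwd <- score_windows(region, pwm$log_odds)
  rc <- revcomp(region)
  rev <- score_windows(rc, pwm$log_odds)
  hits <- tibble::tibble(
    region_id = region_id,
    position = c(seq_along(fwd) - 1L,            # 0-based forward position
                 n - (seq_along(rev) - 1L) - L),
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    score = c(fwd, rev))
  word <- substring(region, hits$position + 1L, hits$position + L)
  hits$match <- ifelse(hits$strand == "+", word, revcomp(word))
  # rank on scores rounded to 1e-9 so floating-point summation noise
  # cannot reorder exact ties; explicit strand rank so locale collation
  # does not decide them either
  hits <- hits[order(-round(hits$score, 9), hits$position,
                     match(hits$strand, c("+", "-"))), ]
  tibble::as_tibble(head(hits, top_k))
}

#' Scan a set of promoter regions, with an empirical shuffle p-value
#'
#' Runs [scan_region()] on each region. When `n_shuffle > 0`, each
#' region's top score is compared with the distribution of top scores of
#' `n_shuffle` base-shuffled copies of that region, giving the empirical
#' p-value `(1 + #{shuffled top >= observed}) / (n_shuffle + 1)` attached
#' to every reported hit of that region (exact for the rank-1 hit,
#' conservative for lower ranks).
#'
#' @param regions Named character vector of DNA strings, or a tibble with
#'   `region_id` and `sequence`.
#' @param pwm A `pwm` object.
#' @param top_k Hits per region.
#' @param n_shuffle Shuffled replicates per region (0 disables).
#' @param seed Seed for the shuffles.
#' @return Tibble of hits with `p_empirical` (NA when `n_shuffle = 0`).
#' @export
scan_promoters <- function(regions, pwm, top_k = 3, n_shuffle = 0,
                           seed = 1) {
  if (is.data.frame(regions)) {
    regions <- setNames(regions$sequence, regions$region_id)
  }
  if (is.null(names(regions))) {
    names(regions) <- paste0("region_", seq_along(regions))
  }
  set.seed(seed)
  out <- purrr::imap_dfr(regions, function(seq, id) {
    hits <- scan_region(seq, pwm, top_k, region_id = id)
    if (n_shuffle > 0) {
      obs <- max(hits$score)
      null_top <- vapply(seq_len(n_shuffle), function(i) {
        sh <- paste(sample(strsplit(dna_normalize(seq), "")[[1]]),
                    collapse = "")
        max(scan_region(sh, pwm, top_k = 1)$score)
      }, numeric(1))
      hits$p_empirical <- (1 + sum(null_top >= obs)) / (n_shuffle + 1)
    } else {
      hits$p_empirical <- NA_real_
    }
    hits
  })
  out
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences (DNA alphabet).
#' @export
read_promoter_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  setNames(dna_normalize(as.character(seqs)), sub("\\s.*$", "", names(seqs)))
}
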