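# Pure-R brute-force oracles, independent of the package's C++/vectorized
# implementation paths. Deliberately naive: enumerate everything, pick by
# the documented rules.

# all ungapped sense placements of `read` on every hairpin: terminal
# contiguous mismatch runs (each <= max_tail) are candidate tails and do
# not count toward the core mismatch cap max_mm; 3' overhang up to max_ov
# carries no template and is never a mismatch
oracle_align <- function(read, reference, max_mm = 2, max_ov = 6,
                         max_tail = 8, min_core = 8) {
  rd <- strsplit(read, "")[[1]]
  L <- length(rd)
  out <- list()
  for (h in seq_len(nrow(reference$hairpins))) {
    hp <- strsplit(reference$hairpins$sequence[h], "")[[1]]
    hl <- length(hp)
    for (s0 in 0:(hl + max_ov - L)) {
      if (s0 < 0) next
      tpos <- s0 + seq_len(L)
      inb <- which(tpos <= hl)
      if (length(inb) < min_core) next
      mism <- rd[inb] != hp[tpos[inb]]
      run5 <- 0
      while (run5 < length(inb) && mism[run5 + 1]) run5 <- run5 + 1
      run3 <- 0
      while (run3 < length(inb) - run5 && mism[length(inb) - run3])
        run3 <- run3 + 1
      core <- if (run5 + run3 < length(inb)) {
        mism[(run5 + 1):(length(inb) - run3)]
      } else logical(0)
      if (length(core) < min_core) next
      if (run5 > max_tail || run3 > max_tail) next
      if (sum(core) > max_mm) next
      out[[length(out) + 1]] <- data.frame(
        sequence = read,
        hairpin_id = reference$hairpins$hairpin_id[h],
        start = s0, mismatches = sum(mism),
        core_mismatches = sum(core),
        overhang = L - length(inb))
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# full brute-force isomiR call for one read: enumerate every alignment,
# pick by (mismatches, |implied five offset|, hairpin_id, start), then
# enumerate every (5' split, 3' split) decomposition and keep the one with
# maximal templated extension at both ends; NULL when unmappable,
# unassignable (|offset| > 5) or not reconstructable
oracle_call <- function(read, reference, max_mm = 2, max_ov = 6,
                        max_assign = 5) {
  al <- oracle_align(read, reference, max_mm, max_ov)
  if (is.null(al)) return(NULL)
  mat <- reference$matures
  al$off <- NA_integer_
  al$mid <- NA_character_
  for (i in seq_len(nrow(al))) {
    mm <- mat[mat$hairpin_id == al$hairpin_id[i], ]
    d <- abs(al$start[i] - mm$start)
    j <- order(d, mm$start)[1]
    al$off[i] <- al$start[i] - mm$start[j]
    al$mid[i] <- mm$mirna_id[j]
  }
  al <- al[order(al$core_mismatches, al$mismatches, abs(al$off),
                 al$hairpin_id, al$start), ]
  best <- al[1, ]
  if (abs(best$off) > max_assign) return(NULL)
  m <- mat[mat$mirna_id == best$mid, ][1, ]
  hp <- strsplit(reference$hairpins$sequence[
    reference$hairpins$hairpin_id == best$hairpin_id], "")[[1]]
  rd <- strsplit(read, "")[[1]]
  L <- length(rd)
  hl <- length(hp)
  # try every split (t5, t3); valid when the core matches the template
  # exactly and the peeled ends are all template mismatches (so that the
  # decomposition is the maximal-templated one, pick smallest t5 + t3)
  best_dec <- NULL
  for (t5 in 0:(L - 1)) {
    for (t3 in 0:(L - 1 - t5)) {
      core <- seq.int(t5 + 1, L - t3)
      if (length(core) == 0) next
      tpos <- best$start + core
      if (any(tpos > hl)) next
      if (any(rd[core] != hp[tpos])) next
      ends <- c(seq_len(t5), if (t3 > 0) seq.int(L - t3 + 1, L))
      tpos_e <- best$start + ends
      templ_e <- ifelse(tpos_e <= hl, hp[pmin(tpos_e, hl)], NA)
      if (any(!is.na(templ_e) & rd[ends] == templ_e)) next
      if (is.null(best_dec) || (t5 + t3) < (best_dec$t5 + best_dec$t3)) {
        best_dec <- list(t5 = t5, t3 = t3)
      }
    }
  }
  if (is.null(best_dec)) return(NULL)
  t5 <- best_dec$t5; t3 <- best_dec$t3
  nta3 <- if (t3 > 0) substr(read, L - t3 + 1, L) else ""
  list(mirna_id = best$mid,
       five_offset = (best$start + t5) - m$start,
       three_templated_offset = (best$start + L - t3) - m$end,
       nta5 = if (t5 > 0) substr(read, 1, t5) else "",
       nta3 = nta3,
       tail_class = if (nta3 == "") "none"
       else if (grepl("^T+$", nta3)) "U"
       else if (grepl("^A+$", nta3)) "A" else "mixed")
}

# brute-force median-of-ratios
oracle_size_factors <- function(m) {
  geo <- apply(m, 1, function(r) prod(r)^(1 / length(r)))
  use <- apply(m, 1, function(r) all(r > 0))
  vapply(seq_len(ncol(m)), function(s) {
    median(m[use, s] / geo[use])
  }, numeric(1))
}

# brute-force BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# brute-force PWM scan: per-window loop on both strands
oracle_scan_top <- function(region, pwm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(region, "")[[1]]
  L <- pwm$length
  n <- length(ch)
  best <- list(score = -Inf)
  for (pos in 0:(n - L)) {
    w <- ch[(pos + 1):(pos + L)]
    sc_f <- sum(pwm$log_odds[cbind(match(w, rownames(pwm$log_odds)),
                                   seq_len(L))])
    wrc <- rev(unname(comp[w]))
    sc_r <- sum(pwm$log_odds[cbind(match(wrc, rownames(pwm$log_odds)),
                                   seq_len(L))])
    # windows visited in (position, strand) order: strictly-better rounded
    # score wins, so the earliest window keeps exact ties
    for (cand in list(list(score = sc_f, position = pos, strand = "+"),
                      list(score = sc_r, position = pos, strand = "-"))) {
      if (round(cand$score, 9) > round(best$score, 9)) best <- cand
    }
  }
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
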