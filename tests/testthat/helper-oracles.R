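# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-derivations (pure R, no shared code paths with the
# package internals beyond exported constructors).

# IUPAC expansion over concrete nucleotides, written out independently
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_base_match <- function(w, p) {
  w %in% c("A", "C", "G", "T") && w %in% ORACLE_IUPAC[[p]]
}

oracle_mismatch <- function(primer, window) {
  p <- strsplit(primer, "")[[1]]
  w <- strsplit(window, "")[[1]]
  stopifnot(length(p) == length(w))
  sum(!mapply(oracle_base_match, w, p))
}

# all concrete expansions of a short IUPAC string
oracle_expand <- function(seq) {
  parts <- ORACLE_IUPAC[strsplit(seq, "")[[1]]]
  apply(expand.grid(parts, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

# exhaustive window scan for a pattern on the plus strand; anchor = positions
# of the pattern that must match exactly ("end" = last 3, "start" = first 3)
oracle_scan <- function(template, pattern, max_mm, anchor = "end",
                        anchor_len = 3) {
  n <- nchar(template); m <- nchar(pattern)
  hits <- data.frame(start = integer(0), mismatches = integer(0))
  if (m > n) return(hits)
  aidx <- if (anchor == "end") (m - anchor_len + 1):m else 1:anchor_len
  for (s in 0:(n - m)) {
    win <- substr(template, s + 1, s + m)
    pch <- strsplit(pattern, "")[[1]]
    wch <- strsplit(win, "")[[1]]
    match_vec <- mapply(oracle_base_match, wch, pch)
    if (!all(match_vec[aidx])) next
    mm <- sum(!match_vec)
    if (mm <= max_mm)
      hits <- rbind(hits, data.frame(start = s, mismatches = mm))
  }
  hits
}

# plain-R reverse complement, independent of Biostrings
oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# classic DP Levenshtein distance
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  na <- length(a); nb <- length(b)
  d <- matrix(0L, na + 1, nb + 1)
  d[, 1] <- 0:na; d[1, ] <- 0:nb
  for (i in seq_len(na))
    for (j in seq_len(nb))
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
  d[na + 1, nb + 1]
}

# longest self-complementary run over all ungapped offsets (direct restating
# of the definition: longest common run between s and revcomp(s))
oracle_self_complement <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  r <- strsplit(oracle_revcomp(seq), "")[[1]]
  n <- length(s)
  best <- 0
  for (off in -(n - 1):(n - 1)) {
    run <- 0
    for (i in seq_len(n)) {
      j <- i - off
      if (j < 1 || j > n) next
      if (s[i] == r[j]) { run <- run + 1; best <- max(best, run) }
      else run <- 0
    }
  }
  best
}

# exhaustive in-silico PCR: every (forward site, reverse site) pairing in
# both orientations, via oracle_scan only
oracle_amplicons <- function(template, assay, max_mm = 2, window = c(80, 300)) {
  out <- list()
  for (set in assay$sets) {
    for (fp in set$forwards) for (rp in set$reverses) {
      f <- fp$sequence; r <- rp$sequence
      # plus orientation
      fs <- oracle_scan(template, f, max_mm, "end")
      rs <- oracle_scan(template, oracle_revcomp(r), max_mm, "start")
      if (nrow(fs) && nrow(rs))
        for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
          len <- rs$start[j] + nchar(r) - fs$start[i]
          if (rs$start[j] >= fs$start[i] + nchar(f) &&
              len >= window[1] && len <= window[2])
            out[[length(out) + 1]] <- substr(template, fs$start[i] + 1,
                                             rs$start[j] + nchar(r))
        }
      # minus orientation
      tmpl_rc <- oracle_revcomp(template)
      fs <- oracle_scan(tmpl_rc, f, max_mm, "end")
      rs <- oracle_scan(tmpl_rc, oracle_revcomp(r), max_mm, "start")
      if (nrow(fs) && nrow(rs))
        for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
          len <- rs$start[j] + nchar(r) - fs$start[i]
          if (rs$start[j] >= fs$start[i] + nchar(f) &&
              len >= window[1] && len <= window[2])
            out[[length(out) + 1]] <- substr(tmpl_rc, fs$start[i] + 1,
                                             rs$start[j] + nchar(r))
        }
    }
  }
  sort(as.character(unlist(out)))
}
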