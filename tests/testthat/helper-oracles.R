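# Independent brute-force oracles used to validate the fuzzy matchers and
# the merger. These deliberately share no code with the package internals:
# plain dynamic programming and exhaustive scans in base R.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Semi-global edit distance: minimal edits (substitutions + indels) to
# align `pattern` fully against any substring of `text`.
oracle_semiglobal_dist <- function(pattern, text) {
  p <- utf8ToInt(pattern)
  t <- utf8ToInt(text)
  m <- length(p)
  n <- length(t)
  if (n == 0L) return(m)
  prev <- rep(0L, n + 1L) # row 0: alignment may start anywhere in text
  js <- 0:n
  for (i in seq_len(m)) {
    cur <- c(i, pmin(prev[1:n] + (p[i] != t), prev[2:(n + 1L)] + 1L))
    cur <- cummin(cur - js) + js # left-to-right gap propagation
    prev <- cur
  }
  min(prev)
}

# Exhaustive overlap scan for a read pair (read2 already reverse
# complemented): returns the best (mismatch ratio, overlap length) over
# all layouts with overlap >= min_overlap, ratio ties broken by longer
# overlap; NULL when no layout qualifies.
oracle_best_overlap <- function(s1, s2, min_overlap) {
  a <- strsplit(s1, NULL)[[1]]
  b <- strsplit(s2, NULL)[[1]]
  l1 <- length(a)
  l2 <- length(b)
  best <- NULL
  if (l1 < min_overlap || l2 < min_overlap) return(NULL)
  for (off in (-(l2 - min_overlap)):(l1 - min_overlap)) {
    start <- max(0L, off)
    end <- min(l1, off + l2)
    olen <- end - start
    if (olen < min_overlap) next
    mm <- sum(a[(start + 1L):end] != b[(start - off + 1L):(end - off)])
    r <- mm / olen
    if (is.null(best) || r < best$ratio - 1e-12 ||
        (abs(r - best$ratio) <= 1e-12 && olen > best$olen)) {
      best <- list(ratio = r, olen = olen, off = off)
    }
  }
  best
}

# Random DNA string(s)
rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# Apply `n_edits` random edits (substitution / insertion / deletion) to a
# sequence; used to probe the error tolerance of the matchers.
perturb_seq <- function(s, n_edits, indels = TRUE) {
  ch <- strsplit(s, NULL)[[1]]
  for (e in seq_len(n_edits)) {
    op <- if (indels) sample(c("sub", "ins", "del"), 1L) else "sub"
    pos <- sample(length(ch), 1L)
    if (op == "sub") {
      ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1L)
    } else if (op == "ins") {
      ch <- append(ch, sample(c("A", "C", "G", "T"), 1L), after = pos)
    } else if (length(ch) > 1L) {
      ch <- ch[-pos]
    }
  }
  paste(ch, collapse = "")
}

# Wrap bare sequences in a read tibble with constant Q30 qualities
as_reads_merge <- function(seqs) {
  tibble::tibble(read_id = sprintf("r%04d", seq_along(seqs)),
                 sequence = seqs,
                 quality = strrep("?", nchar(seqs)))
}

# Run the sequencing chain demux -> merge -> classify on one simulated
# sample and return the recovered ROI splice-form proportions.
recover_proportions <- function(rs, design, diagnostics) {
  dmx <- demultiplex(rs$read2, design, mate = rs$read1)
  a <- dplyr::filter(dmx, !is.na(sample_index))
  m <- merge_pairs(
    tibble::tibble(read_id = a$read_id, sequence = a$mate_sequence,
                   quality = a$mate_quality),
    tibble::tibble(read_id = a$read_id, sequence = a$sequence,
                   quality = a$quality))
  cl <- classify_reads(dplyr::filter(m, status == "merged"), diagnostics)
  tab <- table(factor(cl$species, levels = splice_forms()))
  as.numeric(tab) / sum(tab)
}
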