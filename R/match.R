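# Error-tolerant semi-global matching helpers shared by trimming,
# demultiplexing and classification. Matching is full edit distance
# (substitutions + indels); the allowed error count for a pattern is
# floor(max_error_rate * pattern length).

allowed_errors <- function(max_error_rate, pattern_length) {
  as.integer(floor(max_error_rate * pattern_length))
}

as_dss <- function(x) {
  if (methods::is(x, "DNAStringSet")) x else Biostrings::DNAStringSet(x)
}

# TRUE where `pattern` occurs in the subject within k edits
fuzzy_hit <- function(pattern, subjects, k) {
  subjects <- as_dss(subjects)
  Biostrings::vcountPattern(pattern, subjects, max.mismatch = k,
                            with.indels = k > 0L, fixed = TRUE) > 0L
}

# Minimal k in 0..kmax at which `pattern` hits each subject; NA if none.
# Levelled search: each read is only re-tested while still unresolved.
fuzzy_min_k <- function(pattern, subjects, kmax) {
  subjects <- as_dss(subjects)
  out <- rep(NA_integer_, length(subjects))
  todo <- seq_along(subjects)
  for (k in 0:kmax) {
    if (!length(todo)) break
    hit <- fuzzy_hit(pattern, subjects[todo], k)
    out[todo[hit]] <- k
    todo <- todo[!hit]
  }
  out
}

# Occurrence boundary of `pattern` within k edits, per subject: the end of
# the first occurrence (side = "first_end"), the start of the first
# (side = "first_start") or the start of the last (side = "last_start").
# NA where the pattern does not occur. vmatchPattern does not support
# indels, so the vectorized pass is substitution-only (which covers the
# common case); subjects it misses are re-searched one by one with the
# indel-aware matcher.
fuzzy_boundary <- function(pattern, subjects, k,
                           side = c("first_end", "first_start", "last_start")) {
  side <- match.arg(side)
  subjects <- as_dss(subjects)
  m <- Biostrings::vmatchPattern(pattern, subjects, max.mismatch = k,
                                 fixed = TRUE)
  idx <- if (side == "first_end") Biostrings::endIndex(m) else
    Biostrings::startIndex(m)
  pick <- if (side == "last_start") {
    function(v) if (is.null(v)) NA_integer_ else max(v)
  } else {
    function(v) if (is.null(v)) NA_integer_ else min(v)
  }
  out <- vapply(idx, pick, 1L)
  if (k > 0L && anyNA(out)) {
    for (i in which(is.na(out))) {
      hit <- Biostrings::matchPattern(pattern, subjects[[i]],
                                      max.mismatch = k, with.indels = TRUE,
                                      fixed = TRUE)
      if (length(hit)) {
        out[i] <- switch(side,
                         first_end = min(BiocGenerics::end(hit)),
                         first_start = min(BiocGenerics::start(hit)),
                         last_start = max(BiocGenerics::start(hit)))
      }
    }
  }
  out
}
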