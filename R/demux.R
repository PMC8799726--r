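#' Quality and adapter trimming
#'
#' 3' quality trimming uses the standard running-sum method (subtract the
#' cutoff from each quality, form partial sums from the 3' end, cut at the
#' minimum of the partial sums). Adapter occurrences are then removed by
#' error-tolerant semi-global matching with allowed edits
#' `floor(max_error_rate * adapter length)`; the read is cut at the
#' earliest adapter occurrence. Partial adapters at the very 3' end are
#' removed when an exact prefix of the adapter of at least
#' `min_adapter_overlap` bases terminates the read. Reads are never
#' lengthened.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `quality`).
#' @param quality_cutoff Phred cutoff for 3' quality trimming (0 disables).
#' @param adapters Character vector of adapter sequences (may be empty).
#' @param max_error_rate Allowed adapter error rate (default 0.1).
#' @param min_adapter_overlap Minimum exact 3'-overlap for partial
#'   adapters (default 3).
#' @return The read tibble with trimmed `sequence`/`quality`.
#' @export
trim_reads <- function(reads, quality_cutoff = 0L, adapters = character(),
                       max_error_rate = 0.1, min_adapter_overlap = 3L) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("malformed reads: sequence/quality length mismatch at record(s) ",
         paste(utils::head(which(nchar(reads$sequence) != nchar(reads$quality)), 5L),
               collapse = ", "), call. = FALSE)
  }
  seqs <- reads$sequence
  quals <- reads$quality
  if (quality_cutoff > 0L) {
    keep <- quality_trim_keep_cpp(quals, as.integer(quality_cutoff))
    seqs <- substr(seqs, 1L, keep)
    quals <- substr(quals, 1L, keep)
  }
  for (ad in adapters) {
    ad <- check_dna(ad, "adapter")
    k <- allowed_errors(max_error_rate, nchar(ad))
    nonempty <- which(nchar(seqs) > 0L)
    if (length(nonempty)) {
      start <- fuzzy_boundary(ad, seqs[nonempty], k, "first_start")
      hit <- !is.na(start)
      idx <- nonempty[hit]
      cut <- start[hit] - 1L
      seqs[idx] <- substr(seqs[idx], 1L, pmax(cut, 0L))
      quals[idx] <- substr(quals[idx], 1L, pmax(cut, 0L))
    }
    # exact partial adapter at the 3' end
    for (ov in (nchar(ad) - 1L):min_adapter_overlap) {
      if (ov < min_adapter_overlap) break
      pre <- substr(ad, 1L, ov)
      tail_match <- substr(seqs, nchar(seqs) - ov + 1L, nchar(seqs)) == pre &
        nchar(seqs) >= ov
      seqs[tail_match] <- substr(seqs[tail_match], 1L,
                                 nchar(seqs[tail_match]) - ov)
      quals[tail_match] <- substr(quals[tail_match], 1L, nchar(seqs[tail_match]))
    }
  }
  dplyr::mutate(reads, sequence = seqs, quality = quals)
}

#' Fuzzy internal-barcode demultiplexing
#'
#' Assigns each read to the sample whose internal barcode it carries,
#' tolerating `floor(max_error_rate * barcode length)` edits
#' (substitutions and indels); with 8-nt barcodes at the default error
#' rate 0.15 this allows one edit. A read is assigned to the unique
#' barcode with minimal edit distance within the allowance; ties between
#' barcodes and reads with no qualifying barcode are left unassigned.
#' The partition is exhaustive: every input read appears exactly once in
#' the output.
#'
#' On assignment, the barcode and the preceding quatromer are trimmed from
#' the barcode-bearing read, and (for paired input) the reverse complement
#' of the barcode and everything 3' of it is trimmed from the mate, which
#' removes the read-through tail of short amplicons.
#'
#' @param reads Read tibble of the barcode-bearing mate (read 2 in the
#'   default construct layout).
#' @param design An [amplicon_design()].
#' @param max_error_rate Allowed barcode error rate (default 0.15).
#' @param window `"offset"` (default) searches the first
#'   `quatromer_length + barcode_length + k` bases, where the construct
#'   places the barcode; `"full"` searches the whole read.
#' @param mate Optional read tibble of the other mate (same order).
#' @return A tibble with one row per input read: `read_id`,
#'   `sample_index` (`NA` when unassigned), `barcode`, `n_errors`,
#'   trimmed `sequence`/`quality`, and `mate_sequence`/`mate_quality`
#'   when a mate was supplied. A demultiplexing report is attached as
#'   attribute `"report"` (see [demux_report()]).
#' @export
demultiplex <- function(reads, design, max_error_rate = 0.15,
                        window = c("offset", "full"), mate = NULL) {
  stopifnot(inherits(design, "amplicon_design"))
  window <- match.arg(window)
  if (!length(design$barcodes)) stop("design has no barcodes", call. = FALSE)
  if (max_error_rate < 0 || max_error_rate >= 1) {
    stop("max_error_rate must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(mate) && nrow(mate) != nrow(reads)) {
    stop("mate must have one row per read", call. = FALSE)
  }
  bcs <- design$barcodes
  blen <- nchar(bcs[1])
  k <- allowed_errors(max_error_rate, blen)
  n <- nrow(reads)

  search <- if (window == "offset") {
    substr(reads$sequence, 1L, design$quatromer_length + blen + k)
  } else {
    reads$sequence
  }
  subj <- as_dss(search)
  dist <- matrix(NA_integer_, nrow = n, ncol = length(bcs))
  for (j in seq_along(bcs)) {
    dist[, j] <- fuzzy_min_k(bcs[j], subj, k)
  }
  best <- apply_row_min(dist)
  sample_index <- best$idx        # NA: no hit or tie
  n_errors <- best$val

  out <- tibble::tibble(
    read_id = reads$read_id,
    sample_index = sample_index,
    barcode = ifelse(is.na(sample_index), NA_character_, bcs[sample_index]),
    n_errors = n_errors,
    sequence = reads$sequence,
    quality = reads$quality)

  # trim quatromer + barcode from assigned reads
  assigned <- which(!is.na(sample_index))
  if (length(assigned)) {
    cut_at <- rep(NA_integer_, n)
    for (j in unique(sample_index[assigned])) {
      idx <- assigned[sample_index[assigned] == j]
      cut_at[idx] <- fuzzy_boundary(bcs[j], search[idx], k, "first_end")
    }
    ok <- assigned[!is.na(cut_at[assigned])]
    out$sequence[ok] <- substr(out$sequence[ok], cut_at[ok] + 1L,
                               nchar(out$sequence[ok]))
    out$quality[ok] <- substr(out$quality[ok], cut_at[ok] + 1L,
                              nchar(out$quality[ok]))
  }

  if (!is.null(mate)) {
    out$mate_sequence <- mate$sequence
    out$mate_quality <- mate$quality
    if (length(assigned)) {
      for (j in unique(sample_index[assigned])) {
        idx <- assigned[sample_index[assigned] == j]
        # the read-through tail sits at the 3' end: take the last occurrence
        start <- fuzzy_boundary(revcomp(bcs[j]), mate$sequence[idx], k,
                                "last_start")
        hit <- idx[!is.na(start)]
        s <- start[!is.na(start)]
        out$mate_sequence[hit] <- substr(out$mate_sequence[hit], 1L, s - 1L)
        out$mate_quality[hit] <- substr(out$mate_quality[hit], 1L, s - 1L)
      }
    }
  }

  n_assigned_per_bc <- vapply(seq_along(bcs),
                              function(j) sum(sample_index == j, na.rm = TRUE),
                              1L)
  n_unassigned_total <- sum(is.na(sample_index))
  attr(out, "report") <- tibble::tibble(
    sample_index = seq_along(bcs),
    barcode = bcs,
    n_assigned = n_assigned_per_bc,
    n_unassigned = n_unassigned_total)
  out
}

# row-wise unique argmin over an integer matrix with NAs;
# ties and all-NA rows yield NA
apply_row_min <- function(m) {
  val <- suppressWarnings(apply(m, 1L, min, na.rm = TRUE))
  val[!is.finite(val)] <- NA_integer_
  nmin <- rowSums(m == val, na.rm = TRUE)
  idx <- max.col(-replace(m, is.na(m), .Machine$integer.max), ties.method = "first")
  idx[is.na(val) | nmin != 1L] <- NA_integer_
  val[is.na(idx)] <- NA_integer_
  list(idx = idx, val = as.integer(val))
}

#' Demultiplexing report
#'
#' @param demuxed Output of [demultiplex()].
#' @return Tibble with per-barcode assignment counts and the unassigned
#'   total.
#' @export
demux_report <- function(demuxed) {
  rep <- attr(demuxed, "report")
  if (is.null(rep)) stop("no report attached; not a demultiplex() result",
                         call. = FALSE)
  rep
}
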