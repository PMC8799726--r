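#' Overlap-merge read pairs
#'
#' Reconstructs full amplicon sequences from paired reads by scanning all
#' candidate overlap layouts of at least `min_overlap` bases — including
#' full containment/read-through, where an amplicon shorter than the read
#' length is covered entirely by both mates — and choosing the layout with
#' the smallest mismatch ratio (mismatches / overlap length), ties broken
#' by the longer overlap. A pair merges when the best ratio is at most
#' `max_mismatch_ratio`; the consensus takes the higher-quality base at
#' conflicting positions (read 1's base, with the quality floored, on
#' quality ties). Read 2 is supplied in sequencing orientation and
#' reverse-complemented internally.
#'
#' Amplicon read-through means any barcode/adapter tails must be trimmed
#' before merging (the pipeline enforces trim and demultiplex first).
#'
#' @param read1,read2 Read tibbles in matching order (`read_id`,
#'   `sequence`, `quality`).
#' @param min_overlap Minimum overlap length (default 10).
#' @param max_mismatch_ratio Maximum allowed mismatch ratio in the overlap
#'   (default 0.25).
#' @param single_end If `TRUE`, `read2` is ignored and reads pass through
#'   unchanged with status `"merged"` (single-end libraries need no
#'   merging).
#' @return A tibble: `read_id`, `sequence`, `quality`, `status`
#'   (`"merged"`/`"unmerged"`), `overlap_length`, `mismatch_ratio`.
#'   Unmerged pairs keep `NA` sequences.
#' @export
merge_pairs <- function(read1, read2 = NULL, min_overlap = 10L,
                        max_mismatch_ratio = 0.25, single_end = FALSE) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(read1)))
  if (single_end) {
    return(tibble::tibble(read_id = read1$read_id,
                          sequence = read1$sequence,
                          quality = read1$quality,
                          status = "merged",
                          overlap_length = NA_integer_,
                          mismatch_ratio = NA_real_))
  }
  if (is.null(read2)) stop("read2 is required unless single_end = TRUE", call. = FALSE)
  if (nrow(read2) != nrow(read1)) {
    stop("read1 and read2 must have the same number of rows", call. = FALSE)
  }
  if (!nrow(read1)) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          quality = character(), status = character(),
                          overlap_length = integer(), mismatch_ratio = double()))
  }
  r2rc <- revcomp(read2$sequence)
  q2rev <- strrev(read2$quality)
  res <- merge_pairs_cpp(read1$sequence, read1$quality, r2rc, q2rev,
                         as.integer(min_overlap), max_mismatch_ratio)
  tibble::tibble(
    read_id = read1$read_id,
    sequence = res$sequence,
    quality = res$quality,
    status = ifelse(res$merged, "merged", "unmerged"),
    overlap_length = res$overlap_length,
    mismatch_ratio = res$mismatch_ratio)
}

#' Merge report
#'
#' @param merged Output of [merge_pairs()].
#' @return One-row tibble with `n_merged`, `n_unmerged` and the median
#'   overlap length.
#' @export
merge_report <- function(merged) {
  tibble::tibble(
    n_merged = sum(merged$status == "merged"),
    n_unmerged = sum(merged$status == "unmerged"),
    median_overlap = stats::median(merged$overlap_length, na.rm = TRUE))
}
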