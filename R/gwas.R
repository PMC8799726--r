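#' Harmonize GWAS odds ratios across studies
#'
#' Per-locus allele harmonization of odds ratios reported by multiple
#' studies: a reference orientation is fixed from the newest study's
#' tested (risk) allele; any study that tested the opposite allele has its
#' OR inverted (`OR <- 1/OR`) and alleles swapped. If the reference
#' study's OR is then below 1 the whole locus is flipped so the consensus
#' OR is at least 1. Loci are sorted descending by the median OR across
#' studies (missing studies excluded from the median). Studies whose
#' alleles match the reference in neither orientation are irreconcilable:
#' the offending rows are flagged and excluded.
#'
#' The procedure is idempotent: harmonizing an already-harmonized table
#' returns it unchanged.
#'
#' @param studies Tibble with columns `locus`, `study`, `year`,
#'   `tested_allele`, `other_allele`, `odds_ratio` (> 0).
#' @return Harmonized tibble sorted by descending `median_or`, with the
#'   per-locus `median_or` joined on. Excluded irreconcilable rows are
#'   attached as attribute `"excluded"`.
#' @export
harmonize_odds_ratios <- function(studies) {
  need <- c("locus", "study", "year", "tested_allele", "other_allele",
            "odds_ratio")
  missing <- setdiff(need, names(studies))
  if (length(missing)) {
    stop("studies is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(studies$odds_ratio <= 0)) {
    stop("odds ratios must be positive", call. = FALSE)
  }
  harmonize_locus <- function(d) {
    ref <- d[order(-d$year, d$study), ][1, ]
    ra <- ref$tested_allele; oa <- ref$other_allele
    aligned <- d$tested_allele == ra & d$other_allele == oa
    flipped <- d$tested_allele == oa & d$other_allele == ra
    bad <- !aligned & !flipped
    d$odds_ratio[flipped] <- 1 / d$odds_ratio[flipped]
    d$tested_allele[flipped] <- ra
    d$other_allele[flipped] <- oa
    ref_or <- d$odds_ratio[d$study == ref$study][1]
    if (ref_or < 1) { # flip the whole locus to the risk orientation
      d$odds_ratio[!bad] <- 1 / d$odds_ratio[!bad]
      d$tested_allele[!bad] <- oa
      d$other_allele[!bad] <- ra
    }
    d$irreconcilable <- bad
    d
  }
  out <- studies |>
    dplyr::group_by(.data$locus) |>
    dplyr::group_modify(~ harmonize_locus(.x)) |>
    dplyr::ungroup()
  excluded <- dplyr::filter(out, .data$irreconcilable)
  out <- out |>
    dplyr::filter(!.data$irreconcilable) |>
    dplyr::select(-"irreconcilable") |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(median_or = stats::median(.data$odds_ratio)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$median_or), .data$locus, .data$study)
  attr(out, "excluded") <- dplyr::select(excluded, -"irreconcilable")
  out
}
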