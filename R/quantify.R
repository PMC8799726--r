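#' Pool-average read normalization
#'
#' Accounts for yield differences between sequencing pools: each sample's
#' counts are divided by the average per-sample total read count of its
#' pool, so samples are comparable across pools of different depth.
#'
#' @param counts A count table (`sample_id`, `species`, `raw_count`).
#' @param pools Tibble mapping `sample_id` to `pool_id`; every sample in
#'   `counts` must be assigned.
#' @return The count table with a `normalized_count` column.
#' @export
pool_normalize <- function(counts, pools) {
  stopifnot(all(c("sample_id", "pool_id") %in% names(pools)))
  missing <- setdiff(unique(counts$sample_id), pools$sample_id)
  if (length(missing)) {
    stop("samples without a pool assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  totals <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$raw_count), .groups = "drop") |>
    dplyr::left_join(dplyr::select(pools, "sample_id", "pool_id"),
                     by = "sample_id") |>
    dplyr::group_by(.data$pool_id) |>
    dplyr::mutate(pool_mean = mean(.data$total)) |>
    dplyr::ungroup()
  if (any(totals$pool_mean == 0)) {
    stop("pool(s) with zero total reads: ",
         paste(unique(totals$pool_id[totals$pool_mean == 0]), collapse = ", "),
         call. = FALSE)
  }
  counts |>
    dplyr::left_join(dplyr::select(totals, "sample_id", "pool_mean"),
                     by = "sample_id") |>
    dplyr::mutate(normalized_count = .data$raw_count / .data$pool_mean) |>
    dplyr::select(-"pool_mean")
}

#' Endogenous-control normalization
#'
#' Expresses each species relative to the endogenous control within the
#' same sample: `value = species_count / (control_count /
#' control_volume_fraction)`. When only a fixed fraction of the control
#' PCR was added to the sequencing pool, `control_volume_fraction`
#' rescales the observed control count to full-reaction equivalents (off
#' by default, i.e. 1). Samples with zero control counts are flagged with
#' `NA` values — expression is undefined there, not zero.
#'
#' @param counts A count table; `corrected_count` is used when present,
#'   else `normalized_count`, else `raw_count`.
#' @param control_species Control species name (default `"GUSB"`).
#' @param control_volume_fraction Fraction of the control reaction volume
#'   pooled (in (0, 1], default 1).
#' @return Tibble `sample_id`, `species`, `value`, `log2_value`,
#'   `control_missing` — one row per ROI splice form per sample.
#' @export
control_normalize <- function(counts, control_species = "GUSB",
                              control_volume_fraction = 1.0) {
  if (control_volume_fraction <= 0 || control_volume_fraction > 1) {
    stop("control_volume_fraction must lie in (0, 1]", call. = FALSE)
  }
  col <- intersect(c("corrected_count", "normalized_count", "raw_count"),
                   names(counts))[1]
  ctrl <- counts |>
    dplyr::filter(.data$species == control_species) |>
    dplyr::transmute(.data$sample_id,
                     control = .data[[col]] / control_volume_fraction)
  counts |>
    dplyr::filter(!.data$species %in% c(control_species, "UNASSIGNED")) |>
    dplyr::left_join(ctrl, by = "sample_id") |>
    dplyr::transmute(
      .data$sample_id, .data$species,
      value = ifelse(is.na(.data$control) | .data$control == 0,
                     NA_real_, .data[[col]] / .data$control),
      log2_value = ifelse(!is.na(.data$value) & .data$value > 0,
                          log2(.data$value), NA_real_),
      control_missing = is.na(.data$control) | .data$control == 0)
}

#' Droplet digital PCR concentration estimate
#'
#' The standard Poisson partition estimator: with `n_total` droplets of
#' which `n_positive` fluoresce, the mean occupancy is
#' `lambda = -log((n_total - n_positive) / n_total)` and the template
#' concentration is `lambda / droplet_volume` (copies/uL), scaled by any
#' reaction dilution. The delta-method standard error of `lambda` is
#' `sqrt((exp(lambda) - 1) / n_total)`.
#'
#' @param wells Droplet-well tibble (`well_id`, `channel`, `n_positive`,
#'   `n_total`, `droplet_volume_nl`; a missing volume column defaults to
#'   0.85 nL).
#' @param reaction_dilution Multiplicative dilution factor (default 1).
#' @param on_saturated `"error"` (default) stops on fully positive wells,
#'   which the estimator cannot quantify; `"flag"` marks them `NA`.
#' @return The wells with `lambda`, `lambda_se`, `concentration`
#'   (copies/uL), `below_lod` (no positives) and `saturated` columns.
#' @export
ddpcr_concentration <- function(wells, reaction_dilution = 1.0,
                                on_saturated = c("error", "flag")) {
  on_saturated <- match.arg(on_saturated)
  stopifnot(all(c("n_positive", "n_total") %in% names(wells)))
  if (!"droplet_volume_nl" %in% names(wells)) wells$droplet_volume_nl <- 0.85
  if (any(wells$n_total < 1L) || any(wells$n_positive < 0L) ||
      any(wells$n_positive > wells$n_total)) {
    stop("wells must satisfy 0 <= n_positive <= n_total and n_total >= 1",
         call. = FALSE)
  }
  sat <- wells$n_positive == wells$n_total
  if (any(sat) && on_saturated == "error") {
    stop("saturated well(s) (all droplets positive): ",
         paste(wells$well_id[sat] %||% which(sat), collapse = ", "),
         call. = FALSE)
  }
  lambda <- -log((wells$n_total - wells$n_positive) / wells$n_total)
  lambda[sat] <- NA_real_
  dplyr::mutate(
    wells,
    lambda = lambda,
    lambda_se = sqrt((exp(lambda) - 1) / .data$n_total),
    concentration = lambda / (.data$droplet_volume_nl * 1e-3) *
      reaction_dilution,
    below_lod = .data$n_positive == 0L,
    saturated = sat)
}

#' ddPCR expression normalized to an endogenous control
#'
#' Ratio of target to control concentration from paired wells (duplex or
#' triplex assays read on separate channels).
#'
#' @param target_well,control_well One-row droplet-well tibbles.
#' @param reaction_dilution Dilution applied to both channels.
#' @return One-row tibble `value`, `log2_value`, `flag` (`"ok"`,
#'   `"control_below_lod"`, `"control_saturated"`, `"target_saturated"`).
#' @export
ddpcr_normalized_expression <- function(target_well, control_well,
                                        reaction_dilution = 1.0) {
  tgt <- ddpcr_concentration(target_well, reaction_dilution, "flag")
  ctl <- ddpcr_concentration(control_well, reaction_dilution, "flag")
  flag <- dplyr::case_when(
    ctl$saturated[1] ~ "control_saturated",
    tgt$saturated[1] ~ "target_saturated",
    ctl$below_lod[1] ~ "control_below_lod",
    TRUE ~ "ok")
  value <- if (flag == "ok") tgt$concentration[1] / ctl$concentration[1] else NA_real_
  tibble::tibble(
    value = value,
    log2_value = ifelse(!is.na(value) & value > 0, log2(value), NA_real_),
    flag = flag)
}

#' Fold change between two sample groups
#'
#' @param expr Expression tibble with `sample_id` and `value` columns
#'   (e.g. from [control_normalize()], one species at a time).
#' @param grouping Tibble `sample_id`, `group` with exactly two groups.
#' @param ref Reference group (fold change is other vs `ref`); defaults to
#'   the first group in sort order.
#' @param scale `"geometric"` (default; `2^(mean log2 diff)`, matching
#'   analysis on the log2 scale) or `"arithmetic"` (`mean(B)/mean(A)`).
#' @return One-row tibble `ref`, `alt`, `fold_change`, `n_ref`, `n_alt`.
#' @export
group_fold_change <- function(expr, grouping, ref = NULL,
                              scale = c("geometric", "arithmetic")) {
  scale <- match.arg(scale)
  d <- dplyr::inner_join(expr, grouping, by = "sample_id") |>
    dplyr::filter(!is.na(.data$value))
  groups <- sort(unique(d$group))
  if (length(groups) != 2L) {
    stop("grouping must define exactly two non-empty groups (got ",
         length(groups), ")", call. = FALSE)
  }
  ref <- ref %||% groups[1]
  alt <- setdiff(groups, ref)
  if (!ref %in% groups || length(alt) != 1L) {
    stop("ref must be one of the two groups", call. = FALSE)
  }
  a <- d$value[d$group == ref]
  b <- d$value[d$group == alt]
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  fc <- if (scale == "geometric") {
    if (any(c(a, b) <= 0)) {
      bad <- d$sample_id[d$value <= 0]
      stop("geometric fold change requires positive values; offending ",
           "sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    2^(mean(log2(b)) - mean(log2(a)))
  } else {
    mean(b) / mean(a)
  }
  tibble::tibble(ref = ref, alt = alt, fold_change = fc,
                 n_ref = length(a), n_alt = length(b))
}

#' Cross-platform concordance (Spearman)
#'
#' Rank correlation between paired per-sample measurements from two
#' methods (e.g. amplicon sequencing vs ddPCR), with average ranks for
#' ties; incomplete pairs are dropped listwise.
#'
#' @param x,y Paired numeric vectors.
#' @return One-row tibble `estimate` (Spearman rho), `n`, `p_value`.
#' @export
concordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    stop("need at least 3 complete pairs (have ", length(x), ")", call. = FALSE)
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))$p.value
  tibble::tibble(estimate = rho, n = length(x), p_value = p)
}
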