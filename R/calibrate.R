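#' Estimate PCR bias factors from equimolar spike-in mixtures
#'
#' Within an equimolar mixture every species should contribute an equal
#' read share; the observed share divided by `1/n_species` is that
#' mixture's bias factor for the species. Factors are pooled across
#' mixtures by geometric mean (factors are ratios) and renormalized so
#' their geometric mean over species is 1. A per-species coefficient of
#' variation across mixtures quantifies consistency: ratios that hold
#' across a wide template range are what justifies using the factors as a
#' correction. A least-squares fit of log(factor) on amplicon length is
#' attached as a diagnostic when lengths are available.
#'
#' @param spikein_counts Count table over the mixtures (`sample_id` =
#'   mixture id, `species`, `raw_count`); `UNASSIGNED` rows are ignored.
#' @param manifests A [mixture_manifest()] tibble naming the mixtures.
#' @param species_lengths Optional named vector of amplicon lengths (bp)
#'   for the length diagnostic.
#' @param cv_threshold QC threshold on the per-species factor CV
#'   (default 0.2); exceeding it raises a warning.
#' @return A `bias_model`: `factors` tibble (`species`, `factor`, `cv`,
#'   `n_mixtures_used`), the per-mixture factor matrix, and the optional
#'   length fit. Supports [tidy()], [glance()] and [autoplot()].
#' @export
estimate_bias <- function(spikein_counts, manifests = NULL,
                          species_lengths = NULL, cv_threshold = 0.2) {
  counts <- dplyr::filter(spikein_counts, .data$species != "UNASSIGNED")
  if (!is.null(manifests)) {
    counts <- dplyr::filter(counts, .data$sample_id %in% manifests$mixture_id)
    missing <- setdiff(manifests$mixture_id, counts$sample_id)
    if (length(missing)) {
      stop("no spike-in counts for mixture(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (!nrow(counts)) stop("no usable spike-in counts", call. = FALSE)
  species <- sort(unique(counts$species))
  zero <- dplyr::filter(counts, .data$raw_count == 0L)
  if (nrow(zero)) {
    warning("species with zero count excluded per mixture: ",
            paste(sprintf("%s in %s", zero$species, zero$sample_id),
                  collapse = ", "), call. = FALSE)
  }
  per_mix <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(share = .data$raw_count / sum(.data$raw_count),
                  factor = .data$share * dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$raw_count > 0L)
  pooled <- per_mix |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(cv = stats::sd(.data$factor) / mean(.data$factor),
                     n_mixtures_used = dplyr::n(),
                     factor = exp(mean(log(.data$factor))),
                     .groups = "drop") |>
    dplyr::select("species", "factor", "cv", "n_mixtures_used")
  if (!all(species %in% pooled$species)) {
    stop("all mixtures have zero counts for species: ",
         paste(setdiff(species, pooled$species), collapse = ", "),
         call. = FALSE)
  }
  pooled$factor <- pooled$factor / exp(mean(log(pooled$factor)))
  length_fit <- NULL
  if (!is.null(species_lengths)) {
    len <- species_lengths[pooled$species]
    if (!any(is.na(len)) && length(unique(len)) > 1L) {
      fit <- stats::lm(log(pooled$factor) ~ len)
      length_fit <- stats::setNames(stats::coef(fit), c("intercept", "slope"))
    }
  }
  high <- pooled$species[!is.na(pooled$cv) & pooled$cv > cv_threshold]
  if (length(high)) {
    warning("bias-factor CV across mixtures exceeds ", cv_threshold,
            " for: ", paste(high, collapse = ", "), call. = FALSE)
  }
  fmat <- per_mix |>
    dplyr::select("sample_id", "species", "factor") |>
    tidyr::pivot_wider(names_from = "species", values_from = "factor")
  structure(list(factors = pooled, per_mixture_factors = fmat,
                 length_fit = length_fit, cv_threshold = cv_threshold),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat("<bias_model> ", nrow(x$factors), " species, ",
      nrow(x$per_mixture_factors), " mixtures\n", sep = "")
  print(x$factors)
  if (!is.null(x$length_fit)) {
    cat(sprintf("length fit: log(factor) = %.4f %+.5f * length\n",
                x$length_fit["intercept"], x$length_fit["slope"]))
  }
  invisible(x)
}

#' @rdname estimate_bias
#' @param x A `bias_model`.
#' @param ... Unused.
#' @export
tidy.bias_model <- function(x, ...) x$factors

#' @rdname estimate_bias
#' @export
glance.bias_model <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$factors),
    n_mixtures = nrow(x$per_mixture_factors),
    max_cv = max(x$factors$cv, na.rm = TRUE),
    qc_pass = max(x$factors$cv, na.rm = TRUE) <= x$cv_threshold,
    length_slope = if (is.null(x$length_fit)) NA_real_ else
      unname(x$length_fit["slope"]))
}

#' Correct counts for PCR amplification bias
#'
#' Divides each species' raw count by its bias factor (per-species
#' multiplicative correction); `UNASSIGNED` rows are left untouched.
#'
#' @param counts A count table.
#' @param model A `bias_model` from [estimate_bias()] covering every
#'   species present in `counts`.
#' @return The count table with a `corrected_count` column and
#'   `corrected = TRUE`; `normalized_count`, if present, is rescaled the
#'   same way.
#' @export
apply_bias_correction <- function(counts, model) {
  stopifnot(inherits(model, "bias_model"))
  fac <- stats::setNames(model$factors$factor, model$factors$species)
  present <- setdiff(unique(counts$species), "UNASSIGNED")
  missing <- setdiff(present, names(fac))
  if (length(missing)) {
    stop("bias model has no factor for species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  f <- fac[counts$species]
  f[counts$species == "UNASSIGNED"] <- 1
  out <- dplyr::mutate(counts,
                       corrected_count = .data$raw_count / unname(f),
                       corrected = TRUE)
  if ("normalized_count" %in% names(counts)) {
    out$normalized_count <- counts$normalized_count / unname(f)
  }
  out
}
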