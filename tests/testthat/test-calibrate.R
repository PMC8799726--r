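design <- default_design()
species <- build_templates(design)$species

# classify a spike-in run into a mixture x species count table
spikein_counts <- function(run, diagnostics) {
  cl <- purrr::imap(run$reads, function(r, id) {
    dplyr::mutate(classify_reads(r, diagnostics), sample_id = id)
  })
  count_splice_forms(cl)
}

test_that("unbiased mixtures yield unit factors", {
  ds <- build_diagnostics(design)
  run <- simulate_spikein_run(design, n_reads_per_mixture = 20000,
                              seq_error_rate = 0, seed = 9)
  model <- estimate_bias(spikein_counts(run, ds), default_manifests())
  # multinomial noise on a share of 0.2 at n = 20000, 3 SD on the factor
  sd3 <- 3 * sqrt(0.2 * 0.8 / 20000) / 0.2
  expect_true(all(abs(model$factors$factor - 1) < sd3))
  expect_equal(exp(mean(log(model$factors$factor))), 1, tolerance = 1e-12)
})

test_that("estimated factors recover the geometric-amplification closed form", {
  eff <- setNames(c(1.00, 1.00, 0.98, 0.98, 0.96),
                  c("0-0", "GUSB", "0-L", "M-0", "M-L"))
  bias <- pcr_bias_spec(eff, n_cycles = 32L)
  ds <- build_diagnostics(design)
  run <- simulate_spikein_run(design, bias = bias,
                              n_reads_per_mixture = 30000,
                              seq_error_rate = 0.005, seed = 33)
  model <- estimate_bias(spikein_counts(run, ds), default_manifests())
  truth <- (1 + eff)^32
  truth <- truth / exp(mean(log(truth))) # same normalization constraint
  est <- setNames(model$factors$factor, model$factors$species)
  expect_true(all(abs(est[names(truth)] / truth - 1) < 0.05))
  expect_equal(nrow(model$per_mixture_factors), 5L)
  expect_true(all(!is.na(model$factors$cv)))
})

test_that("factors are invariant to rescaling a mixture's counts", {
  withr::with_seed(3, {
    ct <- tidyr::crossing(sample_id = c("m1", "m2", "m3"),
                          species = species) |>
      dplyr::mutate(raw_count = as.integer(sample(1000:5000, 15)))
  })
  m1 <- suppressWarnings(estimate_bias(ct))  # random counts trip the CV QC
  ct2 <- dplyr::mutate(ct, raw_count = raw_count * 7L)
  m2 <- suppressWarnings(estimate_bias(ct2))
  expect_equal(m1$factors$factor, m2$factors$factor, tolerance = 1e-12)
})

test_that("zero-count species are excluded per mixture with a warning", {
  ct <- tidyr::crossing(sample_id = c("m1", "m2"), species = species) |>
    dplyr::mutate(raw_count = 1000L)
  ct$raw_count[ct$sample_id == "m1" & ct$species == "M-L"] <- 0L
  expect_warning(model <- estimate_bias(ct), "zero count")
  expect_equal(
    model$factors$n_mixtures_used[model$factors$species == "M-L"], 1L)
  # all-zero species is an estimation error
  ct$raw_count[ct$species == "M-L"] <- 0L
  expect_error(suppressWarnings(estimate_bias(ct)), "zero counts")
})

test_that("high cross-mixture variability triggers the QC warning", {
  ct <- tidyr::crossing(sample_id = c("m1", "m2"), species = species) |>
    dplyr::mutate(raw_count = 1000L)
  ct$raw_count[ct$sample_id == "m2" & ct$species == "0-0"] <- 4000L
  expect_warning(estimate_bias(ct), "CV")
})

test_that("bias correction divides by the factor and spares UNASSIGNED", {
  ct <- tibble::tibble(sample_id = "S01",
                       species = c("0-0", "UNASSIGNED"),
                       raw_count = c(100L, 10L))
  model <- structure(
    list(factors = tibble::tibble(
      species = c("0-0", "M-0", "M-L", "0-L", "GUSB"),
      factor = c(2, 1, 1, 1, 0.5), cv = 0, n_mixtures_used = 2L),
      per_mixture_factors = tibble::tibble(sample_id = c("m1", "m2")),
      length_fit = NULL, cv_threshold = 0.2),
    class = "bias_model")
  out <- apply_bias_correction(ct, model)
  expect_equal(out$corrected_count, c(50, 10))
  expect_true(all(out$corrected))
  # unit factors change nothing
  model$factors$factor <- rep(1, 5)
  expect_equal(apply_bias_correction(ct, model)$corrected_count,
               as.numeric(ct$raw_count))
  # a species without a factor is an error
  ct_bad <- dplyr::mutate(ct, species = c("XX", "UNASSIGNED"))
  expect_error(apply_bias_correction(ct_bad, model), "XX")
})

test_that("estimate + correct round-trips a biased equimolar sample", {
  eff <- setNames(c(1.00, 0.99, 0.98, 0.97, 0.96),
                  c("GUSB", "0-0", "0-L", "M-0", "M-L"))
  bias <- pcr_bias_spec(eff, n_cycles = 32L)
  ds <- build_diagnostics(design)
  run <- simulate_spikein_run(design, bias = bias,
                              n_reads_per_mixture = 30000,
                              seq_error_rate = 0, seed = 55)
  model <- estimate_bias(spikein_counts(run, ds), default_manifests())
  # a fresh biased equimolar sample
  fresh <- simulate_readset(design, setNames(rep(0.2, 5), names(eff)),
                            30000, seq_error_rate = 0, bias = bias,
                            barcode_index = 1, seed = 56)
  cl <- classify_reads(as_reads_merge(
    with(build_templates(design),
         setNames(sequence, species))[fresh$truth$species]), ds) |>
    dplyr::mutate(sample_id = "S01")
  corrected <- apply_bias_correction(count_splice_forms(cl), model) |>
    dplyr::filter(species != "UNASSIGNED") |>
    dplyr::mutate(share = corrected_count / sum(corrected_count))
  expect_true(all(abs(corrected$share / 0.2 - 1) < 0.05))
})

test_that("tidy, glance and autoplot expose the model", {
  ds <- build_diagnostics(design)
  run <- simulate_spikein_run(design, n_reads_per_mixture = 5000,
                              seq_error_rate = 0, seed = 77)
  model <- estimate_bias(spikein_counts(run, ds), default_manifests(),
                         species_lengths = design$species_lengths)
  expect_s3_class(tidy(model), "tbl_df")
  expect_named(tidy(model), c("species", "factor", "cv", "n_mixtures_used"))
  g <- glance(model)
  expect_equal(g$n_species, 5L)
  expect_equal(g$n_mixtures, 5L)
  expect_false(is.na(g$length_slope))
  expect_s3_class(autoplot(model), "ggplot")
})
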