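#' PCR amplification-bias specification
#'
#' Models length-dependent PCR bias as deterministic geometric
#' amplification: a template of species s is amplified by
#' `(1 + e_s)^n_cycles`, where `e_s` is the per-cycle efficiency in (0, 1].
#' Longer amplicons typically amplify with lower efficiency, which is the
#' bias the spike-in calibration stage estimates and removes.
#'
#' @param per_cycle_efficiency Named numeric vector, species -> efficiency
#'   in (0, 1].
#' @param n_cycles Number of PCR cycles (default 32).
#' @return An object of class `pcr_bias_spec`.
#' @export
pcr_bias_spec <- function(per_cycle_efficiency, n_cycles = 32L) {
  if (is.null(names(per_cycle_efficiency)) ||
      any(!nzchar(names(per_cycle_efficiency)))) {
    stop("per_cycle_efficiency must be a named vector (species -> efficiency)",
         call. = FALSE)
  }
  if (any(per_cycle_efficiency <= 0 | per_cycle_efficiency > 1)) {
    stop("per-cycle efficiencies must lie in (0, 1]", call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  structure(list(per_cycle_efficiency = per_cycle_efficiency,
                 n_cycles = n_cycles),
            class = "pcr_bias_spec")
}

#' @rdname pcr_bias_spec
#' @param bias A `pcr_bias_spec` (or `NULL` for no bias).
#' @param species Species to return factors for.
#' @return `amplification_factors()` returns the per-species amplification
#'   factors `(1 + e_s)^n_cycles`, normalized to mean 1 over `species`.
#' @export
amplification_factors <- function(bias, species) {
  if (is.null(bias)) return(stats::setNames(rep(1, length(species)), species))
  stopifnot(inherits(bias, "pcr_bias_spec"))
  missing <- setdiff(species, names(bias$per_cycle_efficiency))
  if (length(missing)) {
    stop("bias spec lacks efficiencies for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  f <- (1 + bias$per_cycle_efficiency[species])^bias$n_cycles
  f / mean(f)
}

#' Equimolar spike-in mixture manifests
#'
#' @param mixture_id Mixture identifiers.
#' @param molecules Template molecules per species in each mixture
#'   (mixtures are equimolar across species by construction).
#' @return A tibble with columns `mixture_id` and `molecules`.
#' @export
mixture_manifest <- function(mixture_id, molecules) {
  molecules <- as.integer(molecules)
  if (any(is.na(molecules) | molecules <= 0L)) {
    stop("molecules must be positive integers", call. = FALSE)
  }
  tibble::tibble(mixture_id = as.character(mixture_id), molecules = molecules)
}

#' @rdname mixture_manifest
#' @details `default_manifests()` reproduces the calibration design: five
#'   equimolar mixtures spanning a 16-fold template range, with the lowest
#'   amount replicated (200, 200, 800, 1600 and 3200 molecules).
#' @export
default_manifests <- function() {
  mixture_manifest(
    mixture_id = c("mix200a", "mix200b", "mix800", "mix1600", "mix3200"),
    molecules = c(200L, 200L, 800L, 1600L, 3200L))
}

# constant synthetic quality string (Phred 30)
const_qual <- function(lens) strrep(rawToChar(as.raw(33L + 30L)), lens)

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  ne <- stats::rbinom(length(seqs), nchar(seqs), rate)
  inject_substitutions_cpp(seqs, ne)
}

#' Simulate a barcoded amplicon read set
#'
#' Generates paired (or single-end) reads from one sample's amplicon pool.
#' Each read pair derives from a splice-form template drawn with
#' probability proportional to `proportions * amplification factor`
#' (see [pcr_bias_spec()]). The sequenced construct places the sample's
#' internal barcode and a fresh random quatromer on the reverse-primer
#' side: read 2 begins `[quatromer][barcode][revcomp(template)...]`, and
#' read 1 reads through the template into `revcomp(barcode)` and
#' `revcomp(quatromer)` whenever the amplicon is shorter than the read
#' length. Substitution errors are applied i.i.d. per base.
#'
#' @param design An [amplicon_design()].
#' @param proportions Named numeric vector over species (must sum to 1);
#'   any subset of the design's species.
#' @param n_read_pairs Number of read pairs to emit.
#' @param seq_error_rate Per-base substitution probability in [0, 0.5).
#' @param bias Optional [pcr_bias_spec()].
#' @param read_length Read length (default 300).
#' @param barcode_index Which design barcode this sample carries (1-based).
#' @param sample_id Sample label used in read names.
#' @param paired Emit read 2? Single-end mode emits read 1 only.
#' @param seed Optional integer seed; fixed seed gives byte-identical output.
#' @return A list with tibbles `read1`, `read2` (`NULL` if single-end) and
#'   `truth` (`read_id`, `species`).
#' @export
simulate_readset <- function(design, proportions, n_read_pairs,
                             seq_error_rate = 0.005, bias = NULL,
                             read_length = 300L, barcode_index = 1L,
                             sample_id = "S1", paired = TRUE, seed = NULL) {
  stopifnot(inherits(design, "amplicon_design"))
  n_read_pairs <- as.integer(n_read_pairs)
  if (is.na(n_read_pairs) || n_read_pairs < 0L) {
    stop("n_read_pairs must be a non-negative integer", call. = FALSE)
  }
  if (seq_error_rate < 0 || seq_error_rate >= 0.5) {
    stop("seq_error_rate must lie in [0, 0.5)", call. = FALSE)
  }
  tpl <- build_templates(design)
  unknown <- setdiff(names(proportions), tpl$species)
  if (length(unknown)) {
    stop("proportions name species absent from the design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  run <- function() {
    fac <- amplification_factors(bias, names(proportions))
    p <- proportions * fac
    p <- p / sum(p)
    species <- if (n_read_pairs > 0L) {
      sample(names(proportions), n_read_pairs, replace = TRUE, prob = p)
    } else character(0)
    templates <- stats::setNames(tpl$sequence, tpl$species)[species]
    bc <- design$barcodes[barcode_index]
    quat <- random_dna(n_read_pairs, design$quatromer_length)
    tail1 <- revcomp(paste0(quat, bc))
    r1 <- substr(paste0(templates, tail1), 1L, read_length)
    r1 <- apply_substitutions(unname(r1), seq_error_rate)
    ids <- sprintf("%s_read%06d", sample_id, seq_len(n_read_pairs))
    read1 <- tibble::tibble(read_id = ids, sequence = r1,
                            quality = const_qual(nchar(r1)))
    read2 <- NULL
    if (paired) {
      r2 <- substr(paste0(quat, bc, revcomp(unname(templates))), 1L, read_length)
      r2 <- apply_substitutions(r2, seq_error_rate)
      read2 <- tibble::tibble(read_id = ids, sequence = r2,
                              quality = const_qual(nchar(r2)))
    }
    list(read1 = read1, read2 = read2,
         truth = tibble::tibble(read_id = ids, species = species))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate an equimolar spike-in calibration run
#'
#' Emits one single-end read set per mixture. Within a mixture the five
#' species are present at equal template amounts, so the expected read
#' share of species s is proportional to `molecules * (1 + e_s)^n_cycles`:
#' any departure from a uniform share is the PCR bias the calibration
#' stage estimates.
#'
#' @param design An [amplicon_design()].
#' @param manifests A [mixture_manifest()] tibble.
#' @param bias Optional [pcr_bias_spec()].
#' @param n_reads_per_mixture Reads emitted per mixture.
#' @param seq_error_rate Per-base substitution probability.
#' @param read_length Read length (default 300).
#' @param seed Optional integer seed.
#' @return A list with `reads` (named list of read tibbles, one per
#'   mixture) and `manifest` (tibble `mixture_id`, `species`, `molecules`).
#' @export
simulate_spikein_run <- function(design, manifests = default_manifests(),
                                 bias = NULL, n_reads_per_mixture = 50000L,
                                 seq_error_rate = 0.005, read_length = 300L,
                                 seed = NULL) {
  stopifnot(inherits(design, "amplicon_design"))
  if (!nrow(manifests)) stop("manifests must be non-empty", call. = FALSE)
  tpl <- build_templates(design)
  run <- function() {
    fac <- amplification_factors(bias, tpl$species)
    reads <- purrr::map(seq_len(nrow(manifests)), function(i) {
      p <- fac / sum(fac) # equimolar: molecules cancel within a mixture
      species <- sample(tpl$species, n_reads_per_mixture, replace = TRUE, prob = p)
      seqs <- substr(stats::setNames(tpl$sequence, tpl$species)[species],
                     1L, read_length)
      seqs <- apply_substitutions(unname(seqs), seq_error_rate)
      ids <- sprintf("%s_read%06d", manifests$mixture_id[i],
                     seq_len(n_reads_per_mixture))
      tibble::tibble(read_id = ids, sequence = seqs,
                     quality = const_qual(nchar(seqs)))
    })
    names(reads) <- manifests$mixture_id
    manifest <- tidyr::crossing(manifests, species = tpl$species) |>
      dplyr::arrange(.data$mixture_id, .data$species)
    list(reads = reads, manifest = manifest)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a droplet digital PCR well
#'
#' Partitions a reaction into droplets; each droplet receives a
#' Poisson(lambda) number of template molecules with
#' `lambda = concentration (copies/uL) * droplet volume (nL) / 1000`, and
#' is read as positive when it holds at least one molecule.
#'
#' @param concentration_copies_per_ul Template concentration (copies/uL).
#' @param droplet_volume_nl Droplet volume in nL (default 0.85, the
#'   nominal droplet volume of common instruments).
#' @param n_droplets Number of accepted droplets (default 20000).
#' @param well_id,channel Labels carried into the output.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `well_id`, `channel`, `n_positive`, `n_total`,
#'   `droplet_volume_nl`.
#' @export
simulate_droplets <- function(concentration_copies_per_ul,
                              droplet_volume_nl = 0.85, n_droplets = 20000L,
                              well_id = "A01", channel = "target",
                              seed = NULL) {
  if (concentration_copies_per_ul < 0) stop("concentration must be >= 0", call. = FALSE)
  if (droplet_volume_nl <= 0) stop("droplet_volume_nl must be > 0", call. = FALSE)
  n_droplets <- as.integer(n_droplets)
  if (is.na(n_droplets) || n_droplets < 1L) stop("n_droplets must be >= 1", call. = FALSE)
  lambda <- concentration_copies_per_ul * droplet_volume_nl * 1e-3
  run <- function() {
    n_pos <- sum(stats::rpois(n_droplets, lambda) >= 1L)
    tibble::tibble(well_id = well_id, channel = channel,
                   n_positive = n_pos, n_total = n_droplets,
                   droplet_volume_nl = droplet_volume_nl)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
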