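#' Build splice-junction diagnostic probes
#'
#' Classification is probe-set based: each splice form is recognised by
#' the exon junctions its inclusion pattern realises
#' (`const_left|M`, `const_left|L`, `const_left|const_right`, `M|L`,
#' `M|const_right`, `L|const_right`), each probe spanning `flank` bases on
#' either side of the junction, plus a central probe for the control
#' amplicon. Because the constitutive flanks are shared by all forms,
#' probe sets must be validated as discriminative: classifying the five
#' error-free templates must produce five distinct calls, otherwise the
#' design is rejected with the collision listed.
#'
#' @param design An [amplicon_design()].
#' @param flank Bases on each side of a junction (default 10; minimum 4).
#' @param max_error_rate Error rate at which the discriminativeness
#'   validation runs (default 0.10, the classifier's operating rate).
#' @return A `diagnostic_set`: named probe vector and the form ->
#'   probe-set mapping.
#' @export
build_diagnostics <- function(design, flank = 10L, max_error_rate = 0.10) {
  stopifnot(inherits(design, "amplicon_design"))
  flank <- as.integer(flank)
  if (is.na(flank) || flank < 4L) stop("flank must be >= 4", call. = FALSE)
  segs <- design$segments
  short <- names(segs)[nchar(unlist(segs)) < flank]
  if (length(short)) {
    stop("segment(s) too short for flank ", flank, ": ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  left <- function(s) substr(s, nchar(s) - flank + 1L, nchar(s))
  right <- function(s) substr(s, 1L, flank)
  junction <- function(a, b) paste0(left(segs[[a]]), right(segs[[b]]))
  probes <- c(
    "CL|M"  = junction("const_left", "alt_m"),
    "CL|L"  = junction("const_left", "alt_l"),
    "CL|CR" = junction("const_left", "const_right"),
    "M|L"   = junction("alt_m", "alt_l"),
    "M|CR"  = junction("alt_m", "const_right"),
    "L|CR"  = junction("alt_l", "const_right"))
  ctrl <- design$control_sequence
  mid <- max(1L, (nchar(ctrl) - 2L * flank) %/% 2L)
  probes <- c(probes, "GUSB" = substr(ctrl, mid, mid + 2L * flank - 1L))
  if (any(nchar(probes) < 12L)) {
    stop("diagnostic probes must be at least 12 nt; increase flank", call. = FALSE)
  }
  form_probes <- list(
    "0-0" = "CL|CR",
    "M-0" = c("CL|M", "M|CR"),
    "M-L" = c("CL|M", "M|L", "L|CR"),
    "0-L" = c("CL|L", "L|CR"),
    "GUSB" = "GUSB")
  ds <- structure(list(probes = probes, form_probes = form_probes),
                  class = "diagnostic_set")
  # discriminativeness: the five error-free templates must yield five
  # distinct, correct calls
  tpl <- build_templates(design)
  calls <- classify_reads(
    tibble::tibble(read_id = tpl$species, sequence = tpl$sequence,
                   quality = const_qual(tpl$length)),
    ds, max_error_rate = max_error_rate, both_strands = FALSE)$species
  bad <- tpl$species[calls != tpl$species]
  if (length(bad)) {
    stop("diagnostic set is not discriminative on the design templates; ",
         "misclassified: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ds
}

#' @export
print.diagnostic_set <- function(x, ...) {
  cat("<diagnostic_set> ", length(x$probes), " probes (",
      paste(nchar(x$probes), collapse = "/"), " nt)\n", sep = "")
  for (f in names(x$form_probes)) {
    cat("  ", format(f, width = 5), " <- {",
        paste(x$form_probes[[f]], collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

# hit matrix (reads x probes) at the per-probe allowed error count
probe_hits <- function(seqs, diagnostics, max_error_rate) {
  subj <- as_dss(seqs)
  probes <- diagnostics$probes
  hits <- matrix(FALSE, nrow = length(seqs), ncol = length(probes),
                 dimnames = list(NULL, names(probes)))
  for (j in seq_along(probes)) {
    k <- allowed_errors(max_error_rate, nchar(probes[j]))
    hits[, j] <- fuzzy_hit(probes[j], subj, k)
  }
  hits
}

# map a hit matrix to species calls: a form is called iff the hit set
# equals its probe set exactly (all own probes hit, no foreign probe hit)
calls_from_hits <- function(hits, diagnostics) {
  sig <- apply(hits, 1L, function(h) paste(colnames(hits)[h], collapse = ";"))
  form_sig <- vapply(diagnostics$form_probes, function(p) {
    paste(intersect(names(diagnostics$probes), p), collapse = ";")
  }, "")
  lookup <- stats::setNames(names(form_sig), form_sig)
  out <- unname(lookup[sig])
  out[is.na(out)] <- "UNASSIGNED"
  out
}

#' Classify merged reads into splice forms
#'
#' Each diagnostic probe is searched by semi-global edit-distance match
#' with `floor(max_error_rate * probe length)` allowed errors. A form is
#' called iff all of its probes hit and no probe belonging only to other
#' forms hits; conflicting or empty hit patterns give `"UNASSIGNED"`
#' (chimeric PCR products must not inflate rare forms, so conflicts are
#' never majority-voted). With `both_strands`, reads with no call are
#' retried as reverse complements; a call in the given orientation wins.
#'
#' @param reads Read tibble (merged amplicon reads).
#' @param diagnostics A [build_diagnostics()] set.
#' @param max_error_rate Allowed probe error rate (default 0.10).
#' @param both_strands Also try the reverse complement (default TRUE).
#' @return The read tibble with a `species` column appended.
#' @export
classify_reads <- function(reads, diagnostics, max_error_rate = 0.10,
                           both_strands = TRUE) {
  stopifnot(inherits(diagnostics, "diagnostic_set"))
  n <- nrow(reads)
  if (!n) return(dplyr::mutate(reads, species = character(0)))
  seqs <- reads$sequence
  valid <- !is.na(seqs) & nzchar(seqs)
  species <- rep("UNASSIGNED", n)
  if (any(valid)) {
    hits <- probe_hits(seqs[valid], diagnostics, max_error_rate)
    species[valid] <- calls_from_hits(hits, diagnostics)
    if (both_strands) {
      retry <- valid & species == "UNASSIGNED"
      if (any(retry)) {
        hits_rc <- probe_hits(revcomp(seqs[retry]), diagnostics, max_error_rate)
        species[retry] <- calls_from_hits(hits_rc, diagnostics)
      }
    }
  }
  dplyr::mutate(reads, species = species)
}

#' Tally splice-form counts per sample
#'
#' @param classified A tibble with `sample_id` and `species` columns
#'   (e.g. classified reads with a sample label joined on), or a named
#'   list of classified read tibbles, one per sample.
#' @return A count table: one row per (sample, species) over all species
#'   levels including `UNASSIGNED`, with `raw_count`. Per sample, counts
#'   sum to the number of input reads.
#' @export
count_splice_forms <- function(classified) {
  if (is.list(classified) && !is.data.frame(classified)) {
    classified <- dplyr::bind_rows(classified, .id = "sample_id")
  }
  stopifnot(all(c("sample_id", "species") %in% names(classified)))
  classified |>
    dplyr::mutate(species = factor(.data$species, levels = species_levels())) |>
    dplyr::count(.data$sample_id, .data$species, .drop = FALSE,
                 name = "raw_count") |>
    dplyr::mutate(species = as.character(.data$species)) |>
    tibble::as_tibble()
}

#' Per-sample classification report
#'
#' @param counts A count table from [count_splice_forms()].
#' @return Tibble with per-sample totals, assigned fraction and per-form
#'   fractions of assigned ROI reads.
#' @export
classification_report <- function(counts) {
  counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_reads = sum(.data$raw_count),
      assigned_fraction = sum(.data$raw_count[.data$species != "UNASSIGNED"]) /
        sum(.data$raw_count),
      .groups = "drop")
}
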