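#' Splice-form identifiers
#'
#' The four region-of-interest (ROI) splice forms are named by their
#' inclusion pattern of the two alternatively spliced exons M ("medium") and
#' L ("little"): `"0-0"` (neither), `"M-0"` (M only), `"M-L"` (both) and
#' `"0-L"` (L only). `"GUSB"` is the endogenous-control amplicon and
#' `"UNASSIGNED"` collects reads no classifier call could be made for.
#'
#' @return `splice_forms()` returns the four ROI form labels;
#'   `species_levels()` additionally includes the control and the
#'   unassigned bucket, in canonical order.
#' @export
splice_forms <- function() c("0-0", "M-0", "M-L", "0-L")

#' @rdname splice_forms
#' @export
species_levels <- function() c(splice_forms(), "GUSB", "UNASSIGNED")

segment_roles <- function() {
  c(const_left = "constitutive_left", alt_m = "alternative_M",
    alt_l = "alternative_L", const_right = "constitutive_right")
}

check_dna <- function(x, what, allow_empty = FALSE) {
  x <- toupper(x)
  if (!allow_empty && any(!nzchar(x))) {
    stop(what, " must be a non-empty DNA string", call. = FALSE)
  }
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T}: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Describe an indexed-amplicon locus design
#'
#' An `amplicon_design` is the blueprint of the assay: the constitutive
#' flanks and the two alternatively spliced exons of the ROI, the
#' endogenous-control amplicon, the PCR primers, and the internal-barcode
#' set used for in-amplicon sample multiplexing. Splice-form templates are
#' the concatenation `const_left + (M) + (L) + const_right` according to
#' each form's inclusion pattern.
#'
#' @param const_left,const_right Constitutive flanking exon sequences.
#' @param alt_m,alt_l The alternatively spliced exons M and L.
#' @param barcodes Character vector of internal barcodes (all the same
#'   length, pairwise distinct); the assay multiplexes one sample per
#'   barcode within a pool.
#' @param quatromer_length Length of the random diversity spacer 5' of the
#'   barcode on the indexing oligo (not a UMI). Default 4.
#' @param forward_primer,reverse_primer Primer annealing sequences.
#' @param control_sequence Endogenous-control (GUSB) amplicon sequence.
#' @param species_lengths Optional named integer vector mapping species to
#'   expected amplicon length in bp; checked against the constructed
#'   templates when supplied.
#' @return An object of class `amplicon_design`.
#' @seealso [default_design()], [build_templates()]
#' @export
amplicon_design <- function(const_left, alt_m, alt_l, const_right,
                            barcodes,
                            quatromer_length = 4L,
                            forward_primer = "",
                            reverse_primer = "",
                            control_sequence,
                            species_lengths = NULL) {
  segs <- list(const_left = check_dna(const_left, "const_left"),
               alt_m = check_dna(alt_m, "alt_m"),
               alt_l = check_dna(alt_l, "alt_l"),
               const_right = check_dna(const_right, "const_right"))
  barcodes <- check_dna(barcodes, "barcodes")
  if (length(unique(nchar(barcodes))) != 1L) {
    stop("all barcodes must have the same length", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("barcodes must be pairwise distinct", call. = FALSE)
  }
  quatromer_length <- as.integer(quatromer_length)
  if (is.na(quatromer_length) || quatromer_length < 0L) {
    stop("quatromer_length must be a non-negative integer", call. = FALSE)
  }
  design <- structure(
    list(segments = segs,
         barcodes = barcodes,
         quatromer_length = quatromer_length,
         forward_primer = if (nzchar(forward_primer)) check_dna(forward_primer, "forward_primer") else "",
         reverse_primer = if (nzchar(reverse_primer)) check_dna(reverse_primer, "reverse_primer") else "",
         control_sequence = check_dna(control_sequence, "control_sequence"),
         species_lengths = species_lengths),
    class = "amplicon_design")
  if (!is.null(species_lengths)) {
    tpl <- build_templates(design)
    want <- species_lengths[tpl$species]
    ok <- is.na(want) | want == tpl$length
    if (!all(ok)) {
      stop("species_lengths disagree with constructed template lengths for: ",
           paste(tpl$species[!ok], collapse = ", "), call. = FALSE)
    }
  }
  design
}

#' @export
print.amplicon_design <- function(x, ...) {
  tpl <- build_templates(x)
  cat("<amplicon_design>\n")
  cat("  segments: ",
      paste(sprintf("%s (%d nt)", names(x$segments), nchar(unlist(x$segments))),
            collapse = ", "), "\n", sep = "")
  cat("  barcodes: ", length(x$barcodes), " x ", nchar(x$barcodes[1]),
      " nt, quatromer ", x$quatromer_length, " nt\n", sep = "")
  cat("  species:  ",
      paste(sprintf("%s=%d bp", tpl$species, tpl$length), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Default synthetic locus design
#'
#' A self-contained synthetic design emulating the assay geometry: 16
#' internal 8-nt barcodes (minimum pairwise edit distance 3) with a 4-nt
#' quatromer, and five amplicon species of lengths 125, 156, 210, 219 and
#' 273 bp. Among the five lengths, template additivity
#' (`len("0-0") + len("M-L") == len("M-0") + len("0-L")`) admits exactly one
#' assignment: control 125 bp, 0-0 156 bp, 0-L 210 bp, M-0 219 bp and M-L
#' 273 bp, giving a 63-nt M exon and a 54-nt L exon. The sequences are
#' fixed arbitrary DNA; they carry no biological meaning.
#'
#' @return An [amplicon_design()] object.
#' @export
default_design <- function() {
  amplicon_design(
    const_left  = "TCAGCCTCCACGATAGCCTGTTGACGTCAGGCAACCTTGTGCGTGGTCATAGCTAGGCAATCTAACTCTTGTGAAGAT",
    alt_m       = "CTCGGTGCCTCTTGCTCTTCTGTAAAGTCACCCACCTCTTACTCCTTCGCAGCAAGAAAGGGA",
    alt_l       = "GGCCGAGAACGCAAGGCCTCTGGCGCAAAGCGTACCTATATCCACTGACTTTCA",
    const_right = "ATGTCAACCATCTAAAGGGGAAAAGGCAAGAGGGGCGCGGGTCCCAGAGGCAGGCGCACTGATCTCTTGATTGTGCCA",
    barcodes = c("CTTGTTCG", "TGCTGTTC", "GGCTCGAT", "GTTAGCTA",
                 "AGAGCTTA", "TCGTCCCT", "GTCGATCG", "TCCTACCA",
                 "TCTGAATC", "GTGCAAAT", "AGACTCGT", "GCGTCCTA",
                 "AATATGCG", "TGAGCTCT", "ACTACATC", "GGTAGTCG"),
    quatromer_length = 4L,
    forward_primer = "CAGCGCTGTAGACTCCGAATGA",
    reverse_primer = "CCTTTTTCAACTTTGTCCGCAA",
    control_sequence = paste0(
      "CGAATATTTCTTACTATGACAATTTTATCCGCGAGTCAGAAGCCTCACGCTGGTATCTCAGACACATA",
      "AAGCACCATAGGTGGAGAAATGGGTACGGACAAGGACGATGTCACCCTATTTGCAAA"),
    species_lengths = c("0-0" = 156L, "M-0" = 219L, "M-L" = 273L,
                        "0-L" = 210L, "GUSB" = 125L))
}

#' Construct splice-form templates from a design
#'
#' Builds the error-free amplicon sequence of each splice form by
#' concatenating the exon segments its inclusion pattern selects, plus the
#' control amplicon.
#'
#' @param design An [amplicon_design()].
#' @return A tibble with columns `species`, `sequence` and `length`,
#'   one row per splice form plus the control.
#' @examples
#' build_templates(default_design())
#' @export
build_templates <- function(design) {
  stopifnot(inherits(design, "amplicon_design"))
  segs <- design$segments
  missing <- setdiff(names(segment_roles()), names(segs))
  if (length(missing)) {
    stop("design is missing segment role(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  inc <- list("0-0" = character(0), "M-0" = "alt_m",
              "M-L" = c("alt_m", "alt_l"), "0-L" = "alt_l")
  tpl <- purrr::imap_chr(inc, function(mid, form) {
    paste0(segs$const_left, paste0(unlist(segs[mid]), collapse = ""),
           segs$const_right)
  })
  tibble::tibble(
    species = c(names(inc), "GUSB"),
    sequence = c(unname(tpl), design$control_sequence),
    length = nchar(c(unname(tpl), design$control_sequence)))
}

#' Read or write an amplicon design as YAML
#'
#' The design file is a flat YAML mapping with keys `const_left`, `alt_m`,
#' `alt_l`, `const_right`, `barcodes`, `quatromer_length`,
#' `forward_primer`, `reverse_primer`, `control_sequence` and optionally
#' `species_lengths`.
#'
#' @param path File path.
#' @param design An [amplicon_design()].
#' @return `read_design()` returns an [amplicon_design()];
#'   `write_design()` returns `path` invisibly.
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("const_left", "alt_m", "alt_l", "const_right", "barcodes",
            "control_sequence")
  missing <- setdiff(need, names(y))
  if (length(missing)) {
    stop("design file is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sl <- y$species_lengths
  if (!is.null(sl)) sl <- unlist(sl)
  amplicon_design(
    const_left = y$const_left, alt_m = y$alt_m, alt_l = y$alt_l,
    const_right = y$const_right,
    barcodes = unlist(y$barcodes),
    quatromer_length = y$quatromer_length %||% 4L,
    forward_primer = y$forward_primer %||% "",
    reverse_primer = y$reverse_primer %||% "",
    control_sequence = y$control_sequence,
    species_lengths = sl)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "amplicon_design"))
  y <- c(design$segments,
         list(barcodes = as.list(design$barcodes),
              quatromer_length = design$quatromer_length,
              forward_primer = design$forward_primer,
              reverse_primer = design$reverse_primer,
              control_sequence = design$control_sequence))
  if (!is.null(design$species_lengths)) {
    y$species_lengths <- as.list(design$species_lengths)
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read or write a splice-form count table
#'
#' Count tables are tidy TSV files with one row per (sample, species):
#' columns `sample_id`, `species`, `raw_count` and, once normalized,
#' `normalized_count`.
#'
#' @param path File path.
#' @param counts A count-table tibble.
#' @return `read_count_table()` returns a tibble; `write_count_table()`
#'   returns `path` invisibly.
#' @export
read_count_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    species = readr::col_character(),
                    raw_count = readr::col_integer(),
                    .default = readr::col_double()))
}

#' @rdname read_count_table
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}
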