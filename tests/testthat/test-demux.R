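design <- default_design()

# a read carrying barcode j in the designed position, with given quatromer
bc_read <- function(design, j, payload = "ACGTACGTACGTACGTACGTACGT",
                    quatromer = "ACGT", barcode = NULL) {
  paste0(quatromer, barcode %||% design$barcodes[j], payload)
}

as_reads <- function(seqs) {
  tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)),
                 sequence = seqs,
                 quality = strrep("?", nchar(seqs)))
}

test_that("exact and single-error barcodes assign to the right sample", {
  seqs <- c(bc_read(design, 3),
            bc_read(design, 3, barcode = perturb_seq(design$barcodes[3], 1,
                                                     indels = FALSE)))
  withr::with_seed(5, {
    dmx <- demultiplex(as_reads(seqs), design)
  })
  expect_equal(dmx$sample_index, c(3L, 3L))
  expect_equal(dmx$n_errors[1], 0L)
  # allowed errors at rate 0.15 on 8-nt barcodes is exactly 1
  expect_lte(dmx$n_errors[2], 1L)
  # the quatromer + barcode prefix is removed on assignment
  expect_equal(dmx$sequence[1], "ACGTACGTACGTACGTACGTACGT")
})

test_that("a read equidistant from two barcodes is left unassigned", {
  # two barcodes at edit distance 2; their midpoint is 1 edit from each
  d2 <- amplicon_design("AAAACCCC", "GGGG", "TTTT", "CCCCAAAA",
                        barcodes = c("AAAATTTT", "AAGGTTTT"),
                        control_sequence = "ACGTACGTACGT")
  mid <- "AAGATTTT" # distance 1 from both
  expect_equal(oracle_semiglobal_dist(d2$barcodes[1], mid), 1L)
  expect_equal(oracle_semiglobal_dist(d2$barcodes[2], mid), 1L)
  dmx <- demultiplex(as_reads(paste0("ACGT", mid, "ACGTACGTACGTACGT")), d2)
  expect_true(is.na(dmx$sample_index))
})

test_that("demultiplexing partitions the input exhaustively", {
  withr::with_seed(11, {
    seqs <- c(vapply(1:16, function(j) bc_read(design, j, rand_dna(1, 40)), ""),
              rand_dna(20, 52))
    dmx <- demultiplex(as_reads(seqs), design)
  })
  rep <- demux_report(dmx)
  expect_equal(sum(rep$n_assigned) + rep$n_unassigned[1], length(seqs))
  expect_equal(nrow(dmx), length(seqs))
  # the 16 constructed reads all land on their own barcode
  expect_equal(dmx$sample_index[1:16], 1:16)
})

test_that("zero error rate reduces to exact substring search", {
  withr::with_seed(23, {
    seqs <- c(vapply(1:8, function(j) bc_read(design, j), ""),
              vapply(1:8, function(j) {
                bc_read(design, j,
                        barcode = perturb_seq(design$barcodes[j], 1,
                                              indels = FALSE))
              }, ""),
              rand_dna(30, 52))
    dmx <- demultiplex(as_reads(seqs), design, max_error_rate = 0,
                       window = "full")
  })
  naive <- vapply(seqs, function(s) {
    hits <- which(vapply(design$barcodes,
                         function(b) grepl(b, s, fixed = TRUE), TRUE))
    if (length(hits) == 1L) hits else NA_integer_
  }, 1L, USE.NAMES = FALSE)
  expect_equal(dmx$sample_index, naive)
})

test_that("offset-window and full-read search agree when the barcode is in place", {
  withr::with_seed(31, {
    seqs <- vapply(1:16, function(j) bc_read(design, j, rand_dna(1, 30)), "")
    w <- demultiplex(as_reads(seqs), design, window = "offset")
    f <- demultiplex(as_reads(seqs), design, window = "full")
  })
  expect_equal(w$sample_index, f$sample_index)
})

test_that("fuzzy assignment agrees with the DP edit-distance oracle", {
  withr::with_seed(47, {
    for (rep in 1:200) {
      read <- rand_dna(1, 30)
      dmx <- demultiplex(as_reads(read), design, window = "full")
      d <- vapply(design$barcodes,
                  function(b) oracle_semiglobal_dist(b, read), 1L)
      best <- min(d)
      expected <- if (best <= 1L && sum(d == best) == 1L) which.min(d) else NA_integer_
      expect_equal(dmx$sample_index, unname(expected),
                   info = paste("read:", read))
    }
  })
})

test_that("paired demultiplexing trims the read-through tail from the mate", {
  rs <- simulate_readset(design, c("M-L" = 1), 50, seq_error_rate = 0,
                         barcode_index = 5, seed = 61)
  dmx <- demultiplex(rs$read2, design, mate = rs$read1)
  tpl <- build_templates(design)
  ml <- tpl$sequence[tpl$species == "M-L"]
  expect_true(all(dmx$mate_sequence == ml))
  expect_true(all(dmx$sequence == as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(ml)))))
})

test_that("quality trimming implements the 3' running-sum rule", {
  # qualities 40,40,40,2,2 with cutoff 20: partial sums from the 3' end
  # reach their minimum just before the two low-quality bases
  q <- intToUtf8(33 + c(40, 40, 40, 2, 2), multiple = FALSE)
  reads <- tibble::tibble(read_id = "r1", sequence = "ACGTA", quality = q)
  out <- trim_reads(reads, quality_cutoff = 20)
  expect_equal(out$sequence, "ACG")
  # all qualities above the cutoff: untouched
  out2 <- trim_reads(tibble::tibble(read_id = "r1", sequence = "ACGTA",
                                    quality = strrep("I", 5)),
                     quality_cutoff = 20)
  expect_equal(out2$sequence, "ACGTA")
})

test_that("adapter removal tolerates floor(rate * length) errors", {
  adapter <- "AGATCGGAAGAGC" # 13 nt -> 1 allowed error at rate 0.1
  body <- "ACGTACGTACGTACGTACGT"
  exact <- paste0(body, adapter)
  onesub <- paste0(body, perturb_seq(adapter, 0), "")
  substr(onesub, nchar(body) + 3, nchar(body) + 3) <- "T"
  reads <- as_reads(c(exact, onesub, body))
  expect_equal(oracle_semiglobal_dist(adapter,
                                      substr(onesub, nchar(body) + 1,
                                             nchar(onesub))) <= 1, TRUE)
  out <- trim_reads(reads, adapters = adapter, max_error_rate = 0.1)
  expect_equal(out$sequence[1], body)
  expect_equal(out$sequence[2], body)
  expect_equal(out$sequence[3], body) # nothing to trim
  expect_true(all(nchar(out$sequence) <= nchar(reads$sequence)))
})
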