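test_that("empty and tiny genomes give an empty hit table, not an error", {
  expect_identical(nrow(scan_genome(Biostrings::DNAStringSet(), TEST_PROFILES)),
                   0L)
  expect_identical(nrow(scan_genome(c(s1 = "ACGTACGT"), TEST_PROFILES)), 0L)
})

test_that("a planted consensus and its reverse complement score identically on both strands", {
  fwd <- plant_scaffold(hox_consensus("Antp"), seed = 11)
  rc <- revcomp_chr(fwd$seq)
  genome <- c(plus = fwd$seq, minus = rc)
  hits <- scan_genome(genome, TEST_PROFILES, min_bits = 100)
  expect_identical(nrow(hits), 2L)
  h_plus <- hits[hits$scaffold == "plus", ]
  h_minus <- hits[hits$scaffold == "minus", ]
  expect_identical(h_plus$strand, "+")
  expect_identical(h_minus$strand, "-")
  expect_equal(h_plus$best_bits, h_minus$best_bits)
  len <- nchar(fwd$seq)
  expect_identical(h_minus$start, len - h_plus$end)
  expect_identical(h_minus$end, len - h_plus$start)
  expect_identical(h_plus$protein, h_minus$protein)
})

test_that("reported best_bits equal direct per-residue summation", {
  sc <- plant_scaffold(c(hox_consensus("Ubx"), hox_consensus("lab")),
                       gap = 2000, seed = 5)
  hits <- scan_genome(c(chr = sc$seq), TEST_PROFILES, min_bits = 50)
  expect_identical(nrow(hits), 2L)
  for (i in seq_len(nrow(hits))) {
    direct <- score_protein(TEST_PROFILES, hits$protein[i])
    expect_equal(hits$best_bits[i], max(direct), tolerance = 1e-9)
    for (cl in TEST_PROFILES$classes)
      expect_equal(hits[[paste0("bits_", cl)]][i], unname(direct[cl]),
                   tolerance = 1e-9)
  }
})

test_that("scan equals exhaustive window enumeration on short sequences", {
  for (s in c(2, 9)) {
    cfg <- simulation_config(seed = s, n_scaffolds = 1L,
                             background_length_bp = 1e4,
                             spacer_log_mean = log(600), spacer_log_sd = 0.4,
                             posterior_spacer_log_mean = log(900),
                             posterior_spacer_log_sd = 0.4,
                             divergence = 0.15, event_probs = NO_EVENTS)
    g <- generate_species_genome(cfg)
    chars <- as.character(g$genome)
    got <- scan_genome(g$genome, TEST_PROFILES, min_bits = 104)
    want <- oracle_scan(as.list(chars), TEST_PROFILES, min_bits = 104)
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$start, want$start)
    expect_identical(got$strand, want$strand)
    expect_equal(got$best_bits, want$best_bits, tolerance = 1e-9)
  }
})

test_that("scanning the reverse complement flips strands and mirrors coordinates", {
  cfg <- simulation_config(seed = 21, n_scaffolds = 1L,
                           background_length_bp = 3e4,
                           spacer_log_mean = log(800), spacer_log_sd = 0.3,
                           posterior_spacer_log_mean = log(1200),
                           posterior_spacer_log_sd = 0.3,
                           event_probs = NO_EVENTS)
  g <- generate_species_genome(cfg)
  hits <- scan_genome(g$genome, TEST_PROFILES)
  rc <- Biostrings::reverseComplement(g$genome)
  names(rc) <- names(g$genome)
  hits_rc <- scan_genome(rc, TEST_PROFILES)
  expect_identical(nrow(hits), nrow(hits_rc))
  len <- Biostrings::width(g$genome)[1]
  m <- hits_rc[order(-hits_rc$start), ]
  expect_identical(m$start, len - hits$end)
  expect_identical(m$end, len - hits$start)
  expect_true(all(m$strand != hits$strand))
  expect_equal(m$best_bits, hits$best_bits)
})

test_that("raising min_bits never adds hits", {
  cfg <- simulation_config(seed = 13, n_scaffolds = 1L,
                           background_length_bp = 2e4,
                           spacer_log_mean = log(500), spacer_log_sd = 0.3,
                           posterior_spacer_log_mean = log(700),
                           posterior_spacer_log_sd = 0.3,
                           divergence = 0.25, event_probs = NO_EVENTS)
  g <- generate_species_genome(cfg)
  prev <- NULL
  for (th in c(20, 60, 104, 150, 200)) {
    h <- scan_genome(g$genome, TEST_PROFILES, min_bits = th)
    if (!is.null(prev)) {
      key <- paste(h$scaffold, h$start, h$strand)
      expect_true(all(key %in% prev))
    }
    prev <- paste(h$scaffold, h$start, h$strand)
  }
})

test_that("windows with N-containing codons are rejected; non-IUPAC characters error", {
  sc <- plant_scaffold(hox_consensus("Scr"), seed = 3)
  clean <- scan_genome(c(s1 = sc$seq), TEST_PROFILES)
  expect_identical(nrow(clean), 1L)
  broken <- sc$seq
  substr(broken, sc$starts[1] + 90L, sc$starts[1] + 90L) <- "N"
  expect_identical(nrow(scan_genome(c(s1 = broken), TEST_PROFILES)), 0L)
  bad <- sc$seq
  substr(bad, 11L, 11L) <- "Z"
  expect_error(scan_genome(c(chrA = bad), TEST_PROFILES),
               "non-IUPAC character 'Z' in scaffold 'chrA' at offset 10")
})

test_that("overlapping windows are resolved to a single best hit per homeobox", {
  cfg <- simulation_config(seed = 4, n_scaffolds = 1L,
                           background_length_bp = 2e4,
                           spacer_log_mean = log(500), spacer_log_sd = 0.2,
                           posterior_spacer_log_mean = log(600),
                           posterior_spacer_log_sd = 0.2,
                           event_probs = NO_EVENTS)
  g <- generate_species_genome(cfg)
  # even at a permissive threshold, one planted homeobox = one reported locus
  h <- scan_genome(g$genome, TEST_PROFILES, min_bits = 30)
  expect_identical(nrow(h), 10L)
  expect_identical(sort(h$start), sort(g$truth$loci$start))
})
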