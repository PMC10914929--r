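test_that("the no-event configuration plants exactly the ancestral cluster", {
  cfg <- simulation_config(seed = 3, background_length_bp = 3e4,
                           spacer_log_mean = log(800), spacer_log_sd = 0.3,
                           posterior_spacer_log_mean = log(1500),
                           posterior_spacer_log_sd = 0.3,
                           event_probs = NO_EVENTS, divergence = 0)
  g <- generate_species_genome(cfg)
  truth <- g$truth
  expect_identical(nrow(truth$loci), 10L)
  expect_identical(truth$loci$label, ancestral_order())
  expect_true(all(truth$loci$strand == "+"))
  expect_true(all(truth$loci$scaffold == "scaffold_1"))
  expect_identical(nrow(truth$events), 0L)
  expect_true(all(truth$loci$end - truth$loci$start == 180L))
  # planted ORFs translate to the class consensi at divergence 0
  expect_identical(unname(truth$loci$protein),
                   unname(vapply(ancestral_order(), hox_consensus,
                                 character(1))))
})

test_that("identical (seed, config) runs are byte-identical; different seeds differ", {
  cfg <- simulation_config(seed = 11, background_length_bp = 2e4,
                           spacer_log_mean = log(500), spacer_log_sd = 0.3,
                           posterior_spacer_log_mean = log(900),
                           posterior_spacer_log_sd = 0.3,
                           event_probs = ALL_EVENTS_ON, divergence = 0.1)
  a <- generate_species_genome(cfg)
  b <- generate_species_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  fa <- tempfile(fileext = ".fa"); fb <- tempfile(fileext = ".fa")
  write_genome(a$genome, fa); write_genome(b$genome, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  cfg2 <- simulation_config(seed = 12, background_length_bp = 2e4,
                            spacer_log_mean = log(500), spacer_log_sd = 0.3,
                            posterior_spacer_log_mean = log(900),
                            posterior_spacer_log_sd = 0.3,
                            event_probs = ALL_EVENTS_ON, divergence = 0.1)
  c_ <- generate_species_genome(cfg2)
  expect_false(identical(as.character(a$genome), as.character(c_$genome)))
})

test_that("a forced split partitions the ten labels into two contiguous ancestral blocks", {
  for (s in 1:10) {
    cfg <- simulation_config(seed = s, background_length_bp = 3e4,
                             spacer_log_mean = log(600), spacer_log_sd = 0.3,
                             posterior_spacer_log_mean = log(1000),
                             posterior_spacer_log_sd = 0.3,
                             event_probs = c(split = 1))
    g <- generate_species_genome(cfg, emit_sequence = FALSE)
    truth <- g$truth
    expect_identical(truth$events$kind, "split")
    groups <- split(truth$loci$label, truth$loci$scaffold)
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    expect_identical(length(groups), 2L)
    anc <- ancestral_order()
    sizes <- sort(vapply(groups, length, integer(1)))
    expect_identical(sum(sizes), 10L)
    for (gset in groups) {
      idx <- sort(match(gset, anc))
      expect_identical(idx, seq(min(idx), max(idx)))  # contiguous block
    }
    # the recorded split pair is the ancestral adjacency that was cut
    pair <- strsplit(truth$events$genes, ",")[[1]]
    expect_identical(abs(diff(match(pair, anc))), 1L)
  }
})

test_that("spacer structure reproduces larger posterior intervals", {
  post <- c(); ant <- c()
  for (s in 1:30) {
    cfg <- simulation_config(seed = 400 + s, event_probs = NO_EVENTS,
                             background_length_bp = 2e4,
                             spacer_log_mean = log(2e3), spacer_log_sd = 0.5,
                             posterior_spacer_log_mean = log(1.2e4),
                             posterior_spacer_log_sd = 0.5)
    tr <- generate_species_genome(cfg, emit_sequence = FALSE)$truth
    gaps <- tr$intergenic
    post <- c(post, gaps$distance[gaps$label_a == "Ubx" &
                                    gaps$label_b == "abdA"])
    ant <- c(ant, gaps$distance[gaps$label_a == "Dfd" &
                                  gaps$label_b == "Scr"])
  }
  expect_gt(median(post), median(ant))
})

test_that("cohort generation applies per-order overrides and validates input", {
  manifest <- data.frame(order = c("Diptera", "Diptera", "Orthoptera"),
                         species = c("sp_a", "sp_b", "sp_c"))
  base <- simulation_config(seed = 5, background_length_bp = 2e4,
                            spacer_log_mean = log(1000),
                            spacer_log_sd = 0.3,
                            posterior_spacer_log_mean = log(2000),
                            posterior_spacer_log_sd = 0.3,
                            event_probs = NO_EVENTS)
  coh <- generate_cohort(manifest, base, emit_sequence = FALSE)
  expect_identical(nrow(coh$summary), 3L)
  expect_setequal(names(coh$results), manifest$species)

  expect_error(generate_cohort(manifest[0, ], base), "empty")
  dup <- rbind(manifest, manifest[1, ])
  expect_error(generate_cohort(dup, base), "duplicate species")
  expect_error(generate_cohort(manifest, base,
                               per_order_overrides = list(Hemiptera = list())),
               "unknown order")

  # ten-fold larger spacer scale for Orthoptera inflates planted core spans
  manifest2 <- data.frame(
    order = c(rep("Diptera", 10), rep("Orthoptera", 10)),
    species = paste0("s", 1:20))
  ov <- list(Orthoptera = list(
    spacer_log_mean = log(10 * exp(base$spacer_log_mean)),
    posterior_spacer_log_mean = log(10 * exp(base$posterior_spacer_log_mean))))
  coh2 <- generate_cohort(manifest2, base, per_order_overrides = ov,
                          emit_sequence = FALSE)
  mean_orth <- mean(coh2$summary$core_span_bp[coh2$summary$order ==
                                                "Orthoptera"])
  mean_dip <- mean(coh2$summary$core_span_bp[coh2$summary$order == "Diptera"])
  expect_gt(mean_orth, mean_dip)
})

test_that("cohort file output writes one FASTA and truth pair per species plus a summary", {
  manifest <- data.frame(order = "Diptera", species = c("f1", "f2", "f3"))
  base <- simulation_config(seed = 9, background_length_bp = 2e4,
                            spacer_log_mean = log(400), spacer_log_sd = 0.2,
                            posterior_spacer_log_mean = log(700),
                            posterior_spacer_log_sd = 0.2,
                            event_probs = NO_EVENTS)
  out <- tempfile("cohort")
  generate_cohort(manifest, base, out_dir = out)
  expect_identical(length(list.files(out, pattern = "\\.fa$")), 3L)
  expect_identical(length(list.files(out, pattern = "truth_loci")), 3L)
  expect_identical(length(list.files(out, pattern = "truth_events")), 3L)
  expect_true(file.exists(file.path(out, "cohort_truth_summary.tsv")))
  unlink(out, recursive = TRUE)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(event_probs = c(split = 1.2)), "\\[0, 1\\]")
  expect_error(simulation_config(divergence = 1), "divergence")
  expect_error(simulation_config(gc_content = 0), "gc_content")
  expect_error(simulation_config(zen_expansion_geometric_p = 0), "geometric")
  expect_error(simulation_config(n_scaffolds = 0), "n_scaffolds")
  expect_error(simulation_config(event_probs = c(bogus = 0.5)), "named")
})

test_that("scaffolds grow to fit the cluster rather than truncating it", {
  cfg <- simulation_config(seed = 2, background_length_bp = 1e4,
                           spacer_log_mean = log(5e3), spacer_log_sd = 0.3,
                           posterior_spacer_log_mean = log(2e4),
                           posterior_spacer_log_sd = 0.3,
                           event_probs = NO_EVENTS)
  g <- generate_species_genome(cfg)
  sc1 <- g$truth$scaffold_lengths[["scaffold_1"]]
  expect_gt(sc1, 1e4)  # lengthened beyond the configured minimum
  expect_gte(sc1, max(g$truth$loci$end) + 3L)
  expect_identical(Biostrings::width(g$genome)[[1]], as.integer(sc1))
})
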