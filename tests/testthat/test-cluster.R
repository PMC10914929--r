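test_that("intergenic distance follows the homeobox-edge definition", {
  a <- list(scaffold = "s1", start = 100, end = 280)
  b <- list(scaffold = "s1", start = 1000, end = 1180)
  expect_identical(intergenic_distance(a, b), 720)
  expect_identical(intergenic_distance(b, a), 720)  # symmetric
  overlap <- list(scaffold = "s1", start = 200, end = 380)
  expect_identical(intergenic_distance(a, overlap), 0)
  c_other <- list(scaffold = "s2", start = 100, end = 280)
  expect_error(intergenic_distance(a, c_other),
               class = "hoxatlas_not_coscaffold")
})

test_that("core cluster span is AbdB..Scr extent, undefined when broken up", {
  starts <- c(lab = 1000, pb = 3000, zen = 5000, Dfd = 7000, Scr = 500000,
              ftz = 400000, Antp = 300000, Ubx = 200000, abdA = 100000,
              AbdB = 10000)
  loci <- fake_loci(names(starts), unname(starts))
  core <- core_cluster_size(loci)
  expect_equal(core$span, 500180 - 10000)
  expect_true(is.na(core$reason))

  moved <- fake_loci(names(starts), unname(starts),
                     scaffold = ifelse(names(starts) == "Scr", "s2", "s1"))
  core2 <- core_cluster_size(moved)
  expect_true(is.na(core2$span))
  expect_match(core2$reason, "not co-scaffold")

  lost <- fake_loci(setdiff(names(starts), "ftz"),
                    unname(starts[setdiff(names(starts), "ftz")]))
  core3 <- core_cluster_size(lost)
  expect_true(is.na(core3$span))
  expect_match(core3$reason, "absent: ftz")
})

test_that("computed core span equals the planted truth on clean genomes", {
  for (s in 1:6) {
    cfg <- simulation_config(seed = s, event_probs = NO_EVENTS,
                             background_length_bp = 5e4,
                             spacer_log_mean = log(2000),
                             spacer_log_sd = 0.4,
                             posterior_spacer_log_mean = log(8000),
                             posterior_spacer_log_sd = 0.4)
    g <- generate_species_genome(cfg)
    res <- run_species_analysis(g$genome, "sp", TEST_PROFILES)
    expect_identical(res$model$core_span_bp,
                     core_cluster_size(g$truth$loci)$span)
  }
})

test_that("a 9.6 Mb gap is called a split while a large intact cluster is not", {
  # Drosophila-like configuration: ANT-C .. 9.6 Mb .. BX-C, typical
  # intergenic distances around 0.2 Mb
  starts <- cumsum(c(1e5, rep(2e5, 6), 9.6e6, 2e5, 2e5))
  loci <- fake_loci(ancestral_order(), starts)
  model <- build_cluster_model(loci)
  sp <- model$split_points
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$left_gene, "Antp")
  expect_identical(sp$right_gene, "Ubx")
  expect_identical(sp$reason, "distance_exceeds_threshold")

  # Schistocerca-like: very large but intact (core ~11 Mb over six intervals)
  big <- fake_loci(ancestral_order(), cumsum(c(1e5, rep(1.9e6, 9))))
  expect_identical(nrow(build_cluster_model(big)$split_points), 0L)

  # co-scaffold break: lab on its own scaffold
  lep <- fake_loci(ancestral_order(), starts,
                   scaffold = c("s2", rep("s1", 9)))
  sp2 <- build_cluster_model(lep)$split_points
  expect_true(any(sp2$left_gene == "lab" & sp2$right_gene == "pb" &
                    sp2$reason == "different_scaffold"))
})

test_that("raising split thresholds never increases the split count", {
  set.seed(42)
  for (rep in 1:5) {
    starts <- cumsum(round(runif(10, 5e4, 6e6)))
    loci <- fake_loci(ancestral_order(), starts)
    model <- build_cluster_model(loci)
    counts <- vapply(c(1e6, 5e6, 9e6, 2e7),
                     function(ab) nrow(detect_splits(model, ab, 5)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
    counts_rel <- vapply(c(2, 5, 20, 100),
                         function(m) nrow(detect_splits(model, 1e5, m)),
                         integer(1))
    expect_true(all(diff(counts_rel) <= 0))
  }
})

test_that("per-scaffold span identity: span = sum of gaps + 180 bp per locus", {
  for (s in 1:8) {
    cfg <- simulation_config(seed = 100 + s, event_probs = ALL_EVENTS_ON,
                             background_length_bp = 5e4,
                             spacer_log_mean = log(2000),
                             spacer_log_sd = 0.5,
                             posterior_spacer_log_mean = log(6000),
                             posterior_spacer_log_sd = 0.5)
    g <- generate_species_genome(cfg, emit_sequence = FALSE)
    model <- build_cluster_model(g$truth$loci)
    for (i in seq_len(nrow(model$spans))) {
      sc <- model$spans$scaffold[i]
      gaps <- model$intergenic$distance[model$intergenic$scaffold == sc]
      expect_identical(model$spans$span_bp[i],
                       sum(gaps) + 180L * model$spans$n_loci[i])
    }
  }
})

test_that("cluster models are invariant to scaffold and row input order", {
  starts <- cumsum(c(1e5, rep(2e5, 4)))
  loci <- rbind(fake_loci(c("lab", "pb", "zen"), starts[1:3], scaffold = "s9"),
                fake_loci(c("Dfd", "Scr"), starts[4:5], scaffold = "s1"))
  loci$copy_index <- 1L
  shuffled <- loci[c(4, 1, 5, 3, 2), ]
  m1 <- build_cluster_model(loci)
  m2 <- build_cluster_model(shuffled)
  expect_identical(m1$spans, m2$spans)
  expect_identical(m1$intergenic, m2$intergenic)
  expect_identical(m1$split_points, m2$split_points)
  # single locus on a scaffold spans exactly one homeobox
  single <- fake_loci("Antp", 5000)
  expect_equal(build_cluster_model(single)$spans$span_bp, 180)
})
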