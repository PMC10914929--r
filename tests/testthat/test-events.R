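test_that("breakpoint distance matches adjacency-set enumeration", {
  expect_identical(breakpoint_distance(ancestral_order()), 0L)
  expect_identical(breakpoint_distance(rev(ancestral_order())), 0L)
  lab_moved <- c(ancestral_order()[-1], "lab")
  expect_identical(breakpoint_distance(lab_moved), 1L)
  expect_identical(oracle_breakpoints(lab_moved, ancestral_order()), 1L)
  expect_error(breakpoint_distance(c("lab", "Hox99")), "unknown label")
  expect_error(breakpoint_distance(c("lab", "lab")), "repeated")
  # subset arrangements restrict the reference adjacencies
  expect_identical(breakpoint_distance(c("pb", "Dfd", "Scr")), 0L)
  set.seed(7)
  for (rep in 1:200) {
    obs <- sample(ancestral_order(), sample(3:8, 1))
    expect_identical(breakpoint_distance(obs),
                     oracle_breakpoints(obs, ancestral_order()))
  }
})

test_that("strand runs opposing the consensus orientation become inversion calls", {
  starts <- cumsum(c(1e4, rep(3e4, 9)))
  block <- fake_loci(ancestral_order(), starts,
                     strand = c("-", "-", "-", rep("+", 7)))
  ev <- call_inversions(build_cluster_model(block))
  expect_identical(nrow(ev), 1L)
  expect_setequal(strsplit(ev$genes, ",")[[1]], c("lab", "pb", "zen"))

  single <- fake_loci(ancestral_order(), starts,
                      strand = ifelse(ancestral_order() == "Dfd", "-", "+"))
  ev2 <- call_inversions(build_cluster_model(single))
  expect_identical(ev2$genes, "Dfd")

  none <- fake_loci(ancestral_order(), starts)
  expect_identical(nrow(call_inversions(build_cluster_model(none))), 0L)
})

test_that("inversion calls are invariant under a global strand flip", {
  starts <- cumsum(c(1e4, rep(3e4, 9)))
  strands <- c("+", "-", "-", rep("+", 7))
  fwd <- fake_loci(ancestral_order(), starts, strand = strands)
  L <- max(fwd$end) + 1e4
  flipped <- fwd
  flipped$strand <- ifelse(fwd$strand == "+", "-", "+")
  flipped$start <- L - fwd$end
  flipped$end <- L - fwd$start
  ev_f <- call_inversions(build_cluster_model(fwd))
  ev_r <- call_inversions(build_cluster_model(flipped))
  expect_identical(norm_events(ev_f), norm_events(ev_r))
})

test_that("terminal blocks at the wrong end are called translocations", {
  # lepidopteran pattern: lab at the posterior end
  starts <- cumsum(c(1e4, rep(3e4, 9)))
  lep <- fake_loci(c(ancestral_order()[-1], "lab"), starts)
  ev <- call_translocations(build_cluster_model(lep))
  expect_identical(ev$kind, "translocation")
  expect_identical(ev$genes, "lab")

  # Limnephilidae pattern: pb, zen, Dfd moved next to AbdB
  tri <- fake_loci(c("lab", "Scr", "ftz", "Antp", "Ubx", "abdA", "AbdB",
                     "pb", "zen", "Dfd"), starts)
  ev2 <- call_translocations(build_cluster_model(tri))
  expect_identical(nrow(ev2), 1L)
  expect_setequal(strsplit(ev2$genes, ",")[[1]], c("pb", "zen", "Dfd"))

  # Phryganeidae-like pattern: the same block upstream of lab
  pre <- fake_loci(c("pb", "zen", "Dfd", "lab", "Scr", "ftz", "Antp",
                     "Ubx", "abdA", "AbdB"), starts)
  ev3 <- call_translocations(build_cluster_model(pre))
  expect_identical(nrow(ev3), 1L)
  expect_setequal(strsplit(ev3$genes, ",")[[1]], c("pb", "zen", "Dfd"))

  # ancestral arrangement and a reversed-in-place block yield no calls
  anc <- fake_loci(ancestral_order(), starts)
  expect_identical(nrow(call_translocations(build_cluster_model(anc))), 0L)
  revblock <- fake_loci(c("zen", "pb", "lab", ancestral_order()[4:10]),
                        starts)
  expect_identical(nrow(call_translocations(build_cluster_model(revblock))),
                   0L)
})

test_that("a gene alone on a scaffold with its gap closed elsewhere is a scaffold translocation", {
  starts <- cumsum(c(1e4, rep(3e4, 8)))
  main <- fake_loci(setdiff(ancestral_order(), "Scr"), starts)
  lone <- fake_loci("Scr", 5e4, scaffold = "s7")
  ev <- call_translocations(build_cluster_model(rbind(main, lone)))
  expect_identical(ev$kind, "scaffold_translocation")
  expect_identical(ev$genes, "Scr")

  # a split leaves no closed gap: the terminal gene is NOT a scaffold
  # translocation (it is reported via split detection instead)
  split_main <- fake_loci(ancestral_order()[-1], starts)
  split_lab <- fake_loci("lab", 5e4, scaffold = "s7")
  model <- build_cluster_model(rbind(split_main, split_lab))
  ev2 <- call_translocations(model)
  expect_identical(nrow(ev2), 0L)
  expect_true(any(model$split_points$left_gene == "lab" &
                    model$split_points$reason == "different_scaffold"))
})

test_that("tandem arrays and absences become duplication and loss calls", {
  zens <- fake_loci(c("pb", rep("zen", 5), "Dfd"),
                    cumsum(c(1e4, 3e4, rep(3e3, 4), 3e4)))
  ev <- call_tandem_duplications_and_losses(zens)
  dup <- ev[ev$kind == "tandem_duplication", ]
  expect_identical(dup$genes, "zen")
  expect_match(dup$evidence, "copies=5")
  losses <- ev[ev$kind == "loss", ]
  expect_setequal(strsplit(paste(losses$genes, collapse = ","), ",")[[1]],
                  setdiff(ancestral_order(), c("pb", "zen", "Dfd")))
  expect_true(all(losses$confidence == "needs-verification"))

  full <- fake_loci(ancestral_order(), cumsum(c(1e4, rep(3e4, 9))))
  expect_identical(nrow(call_tandem_duplications_and_losses(full)), 0L)

  # ftz deletion: exactly one loss, flagged
  no_ftz <- fake_loci(setdiff(ancestral_order(), "ftz"),
                      cumsum(c(1e4, rep(3e4, 8))))
  ev3 <- call_tandem_duplications_and_losses(no_ftz)
  expect_identical(ev3$kind, "loss")
  expect_identical(ev3$genes, "ftz")
})

test_that("event calls are invariant to locus input order", {
  set.seed(31)
  loci <- fake_loci(c(ancestral_order()[-1], "lab"),
                    cumsum(c(1e4, rep(3e4, 9))),
                    strand = c(rep("+", 4), "-", rep("+", 5)))
  model1 <- build_cluster_model(loci)
  shuffle <- loci[sample(nrow(loci)), ]
  model2 <- build_cluster_model(shuffle)
  expect_identical(norm_events(call_events(model1, loci)),
                   norm_events(call_events(model2, shuffle)))
})
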