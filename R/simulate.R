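#' Configuration for the synthetic Hox-cluster genome generator
#'
#' Describes one simulated species: a linear cluster of the ten ancestral
#' genes as 60-codon homeodomain ORFs embedded in random background sequence,
#' with log-normally distributed intergenic spacers (larger for the posterior
#' Antp-Ubx, Ubx-abdA and abdA-AbdB intervals, emulating the consistently
#' larger posterior intergenic distances seen across insect orders),
#' per-site amino-acid divergence, and stochastic structural events.
#'
#' @param seed Integer RNG seed; identical (seed, config) pairs yield
#'   byte-identical genomes and truth tables.
#' @param n_scaffolds Number of background scaffolds (>= 1); the cluster is
#'   embedded in the first, the rest are pure background (event-derived
#'   scaffolds are additional).
#' @param background_length_bp Minimum scaffold length in bp. If a spacer
#'   draw would overrun the scaffold, the scaffold is lengthened to fit
#'   (never silently truncated).
#' @param spacer_log_mean,spacer_log_sd Log-normal parameters (bp) for
#'   ordinary (ANT-C-like) intergenic spacers.
#' @param posterior_spacer_log_mean,posterior_spacer_log_sd Log-normal
#'   parameters for the three posterior intervals (Antp-Ubx, Ubx-abdA,
#'   abdA-AbdB).
#' @param array_spacer_log_mean,array_spacer_log_sd Log-normal parameters
#'   for spacers inside a tandem zen/Shx array.
#' @param divergence Per-site amino-acid substitution probability in [0, 1)
#'   applied independently to every planted homeodomain residue.
#' @param event_probs Named probabilities in [0, 1] for the event kinds
#'   `loss`, `tandem_duplication`, `inversion`, `translocation`,
#'   `scaffold_translocation`, `split`. At most one event of each kind is
#'   planted per genome, and events are placed so that they do not obscure
#'   one another (see the package vignette).
#' @param zen_expansion_geometric_p Geometric parameter in (0, 1] for the
#'   number of extra zen-derived copies in a tandem expansion
#'   (`1 + rgeom(p)`, capped at `max_zen_extra`); extra copies are planted
#'   from the ShxA-D subtype consensi in rotation.
#' @param max_zen_extra Cap on extra zen copies.
#' @param gc_content Background GC fraction in (0, 1).
#' @return Object of class `hox_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_scaffolds = 2L,
                              background_length_bp = 1e6,
                              spacer_log_mean = log(2e4),
                              spacer_log_sd = 0.6,
                              posterior_spacer_log_mean = log(1.2e5),
                              posterior_spacer_log_sd = 0.6,
                              array_spacer_log_mean = log(3e3),
                              array_spacer_log_sd = 0.3,
                              divergence = 0,
                              event_probs = c(loss = 0.02,
                                              tandem_duplication = 0.2,
                                              inversion = 0.1,
                                              translocation = 0.15,
                                              scaffold_translocation = 0.05,
                                              split = 0.3),
                              zen_expansion_geometric_p = 0.35,
                              max_zen_extra = 25L,
                              gc_content = 0.35) {
  kinds <- c("loss", "tandem_duplication", "inversion", "translocation",
             "scaffold_translocation", "split")
  ep <- setNames(rep(0, length(kinds)), kinds)
  if (length(event_probs)) {
    if (is.null(names(event_probs)) ||
        !all(names(event_probs) %in% kinds))
      stop("event_probs must be named with kinds: ",
           paste(kinds, collapse = ", "))
    ep[names(event_probs)] <- event_probs
  }
  if (any(ep < 0 | ep > 1)) stop("event probabilities must lie in [0, 1]")
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  if (gc_content <= 0 || gc_content >= 1)
    stop("gc_content must lie in (0, 1)")
  if (zen_expansion_geometric_p <= 0 || zen_expansion_geometric_p > 1)
    stop("zen_expansion_geometric_p must lie in (0, 1]")
  if (n_scaffolds < 1L) stop("n_scaffolds must be >= 1")
  if (background_length_bp < 1e4)
    stop("background_length_bp must be at least 10 kb")
  for (nm in c("spacer_log_sd", "posterior_spacer_log_sd",
               "array_spacer_log_sd"))
    if (get(nm) < 0) stop(nm, " must be non-negative")
  structure(list(seed = as.integer(seed),
                 n_scaffolds = as.integer(n_scaffolds),
                 background_length_bp = background_length_bp,
                 spacer_log_mean = spacer_log_mean,
                 spacer_log_sd = spacer_log_sd,
                 posterior_spacer_log_mean = posterior_spacer_log_mean,
                 posterior_spacer_log_sd = posterior_spacer_log_sd,
                 array_spacer_log_mean = array_spacer_log_mean,
                 array_spacer_log_sd = array_spacer_log_sd,
                 divergence = divergence,
                 event_probs = ep,
                 zen_expansion_geometric_p = zen_expansion_geometric_p,
                 max_zen_extra = as.integer(max_zen_extra),
                 gc_content = gc_content),
            class = c("hox_sim_config", "list"))
}

#' Generate one synthetic genome with a planted Hox cluster
#'
#' Plants the ten ancestral genes in order on the first scaffold as 60-codon
#' homeodomain ORFs (ATG + homeobox + TAA; codons drawn uniformly among
#' synonymous codons), applies structural events in the fixed order
#' loss, tandem duplication, inversion, translocation, scaffold
#' translocation, split, then records everything in a machine-readable truth
#' table. Event placements are constrained to not obscure one another (an
#' inverted block never equals a majority of its final scaffold group, a
#' split never cuts through another event's footprint), keeping the truth
#' table unambiguous.
#'
#' Coordinates are 0-based half-open; a truth locus interval is the 180 bp
#' homeobox itself.
#'
#' @param config A [simulation_config()].
#' @param species Species name recorded in the truth table.
#' @param emit_sequence If `FALSE`, skip sequence realisation and return
#'   `genome = NULL` with an identical truth table (layout and sequence
#'   random draws are staged separately, so the truth is unaffected).
#' @return List with `genome` (named `DNAStringSet` or `NULL`) and `truth`,
#'   an object of class `hox_truth`: list of `loci`, `events`, `intergenic`
#'   (expected homeobox-edge distances), `scaffold_lengths` and `seed`.
#' @export
generate_species_genome <- function(config = simulation_config(),
                                    species = "synthetic_sp",
                                    emit_sequence = TRUE) {
  stopifnot(inherits(config, "hox_sim_config"))
  set.seed(config$seed)

  plan <- .plan_events(config)
  groups <- .build_arrangement(plan)
  plan$split_pair <- attr(groups, "split_pair")
  layout <- .layout_groups(groups, config)
  layout$loci$species <- species
  layout$loci$protein <- .diverge_proteins(layout$loci, config$divergence)

  truth <- structure(list(
    species = species,
    loci = layout$loci[, c("species", "label", "subtype", "scaffold",
                           "start", "end", "strand", "copy_index",
                           "protein")],
    events = .plan_truth_events(species, plan),
    intergenic = layout$intergenic,
    scaffold_lengths = layout$scaffold_lengths,
    seed = config$seed), class = "hox_truth")

  genome <- NULL
  if (emit_sequence)
    genome <- .emit_genome(layout, config)
  list(genome = genome, truth = truth)
}

#' @export
print.hox_truth <- function(x, ...) {
  cat("hoxatlas truth table for", x$species, "—", nrow(x$loci),
      "planted loci,", nrow(x$events), "events\n")
  invisible(x)
}

## ---- event planning -------------------------------------------------------

.plan_events <- function(config) {
  ep <- config$event_probs
  ## one uniform draw per kind, in fixed order, so firing decisions are
  ## reproducible independently of downstream placement draws
  fire <- setNames(runif(length(ep)) < ep, names(ep))

  surv <- HOX_CLASSES
  loss_gene <- NULL
  if (fire[["loss"]]) {
    loss_gene <- sample(surv, 1L)
    surv <- setdiff(surv, loss_gene)
  }

  n_extra <- 0L
  if (fire[["tandem_duplication"]] && "zen" %in% surv) {
    n_extra <- min(1L + rgeom(1L, config$zen_expansion_geometric_p),
                   config$max_zen_extra)
  }

  trans_block <- character()
  if (fire[["translocation"]] && length(surv) >= 5L) {
    t_len <- sample(1:3, 1L)
    trans_block <- surv[seq_len(min(t_len, length(surv) - 2L))]
  }

  inv_block <- character()
  if (fire[["inversion"]]) {
    allowed <- setdiff(intersect(surv, c("Dfd", "Scr", "ftz", "Antp",
                                         "Ubx", "abdA")), trans_block)
    inv_block <- .pick_contiguous_block(surv, allowed, sample(1:3, 1L))
  }

  st_gene <- NULL
  if (fire[["scaffold_translocation"]]) {
    cand <- setdiff(intersect(surv, c("pb", "Dfd", "Scr", "ftz", "Antp",
                                      "Ubx", "abdA")),
                    c(trans_block, inv_block))
    cand <- Filter(function(g) {
      i <- match(g, surv)
      if (i == 1L || i == length(surv)) return(FALSE)
      nb <- surv[c(i - 1L, i + 1L)]
      !any(nb %in% c(trans_block, if (length(inv_block) > 1L) inv_block))
    }, cand)
    if (length(cand)) st_gene <- sample(cand, 1L)
  }

  list(surv = surv, loss_gene = loss_gene, n_extra = n_extra,
       trans_block = trans_block, inv_block = inv_block, st_gene = st_gene,
       want_split = fire[["split"]], split_pair = NULL)
}

## contiguous run of labels (in the order of `surv`) fully inside `allowed`
.pick_contiguous_block <- function(surv, allowed, len) {
  for (L in rev(seq_len(len))) {
    starts <- which(vapply(seq_len(length(surv) - L + 1L), function(i)
      all(surv[i:(i + L - 1L)] %in% allowed), logical(1L)))
    if (length(starts)) {
      i <- if (length(starts) == 1L) starts else sample(starts, 1L)
      return(surv[i:(i + L - 1L)])
    }
  }
  character()
}

.plan_truth_events <- function(species, plan) {
  ev <- .empty_events()
  if (!is.null(plan$loss_gene))
    ev <- rbind(ev, .event_row(species, "loss", plan$loss_gene, "planted"))
  if (plan$n_extra > 0L)
    ev <- rbind(ev, .event_row(species, "tandem_duplication", "zen",
                               sprintf("copies=%d", plan$n_extra + 1L)))
  if (length(plan$inv_block))
    ev <- rbind(ev, .event_row(species, "inversion", plan$inv_block,
                               "planted"))
  if (length(plan$trans_block))
    ev <- rbind(ev, .event_row(species, "translocation", plan$trans_block,
                               "moved_to=posterior_end"))
  if (!is.null(plan$st_gene))
    ev <- rbind(ev, .event_row(species, "scaffold_translocation",
                               plan$st_gene, "planted"))
  if (!is.null(plan$split_pair))
    ev <- rbind(ev, .event_row(species, "split", plan$split_pair,
                               "scaffold_cut"))
  ev
}

## ---- arrangement ----------------------------------------------------------

.build_arrangement <- function(plan) {
  surv <- plan$surv
  loci <- data.frame(label = surv,
                     subtype = ifelse(surv == "zen", "zen", NA_character_),
                     strand = "+", stringsAsFactors = FALSE)
  if (plan$n_extra > 0L) {
    zi <- match("zen", loci$label)
    shx <- rep(ZEN_SUBTYPES[3:6], length.out = plan$n_extra)
    extra <- data.frame(label = "zen", subtype = shx, strand = "+",
                        stringsAsFactors = FALSE)
    loci <- rbind(loci[seq_len(zi), ], extra,
                  loci[-seq_len(zi), , drop = FALSE])
  }
  if (length(plan$inv_block)) {
    idx <- which(loci$label %in% plan$inv_block)
    idx <- seq(min(idx), max(idx))
    loci[idx, ] <- loci[rev(idx), ]
    loci$strand[idx] <- ifelse(loci$strand[idx] == "+", "-", "+")
  }
  if (length(plan$trans_block)) {
    bi <- which(loci$label %in% plan$trans_block)
    loci <- rbind(loci[-bi, , drop = FALSE], loci[bi, , drop = FALSE])
  }
  groups <- list(main = loci)
  if (!is.null(plan$st_gene)) {
    si <- which(groups$main$label == plan$st_gene)
    groups$st <- groups$main[si, , drop = FALSE]
    groups$main <- groups$main[-si, , drop = FALSE]
  }
  if (plan$want_split) {
    pair <- .choose_split_pair(groups$main, plan)
    if (!is.null(pair)) {
      main <- groups$main
      ci <- which(main$label == pair[1L])[1L]
      groups <- c(list(main_a = main[seq_len(ci), , drop = FALSE],
                       main_b = main[-seq_len(ci), , drop = FALSE]),
                  groups[setdiff(names(groups), "main")])
      attr(groups, "split_pair") <- pair
    }
  }
  rownames_reset <- lapply(groups, function(g) { rownames(g) <- NULL; g })
  attr(rownames_reset, "split_pair") <- attr(groups, "split_pair")
  rownames_reset
}

## a split may only cut between two event-free genes that are ancestral
## neighbours (in the present-restricted order), never beside another
## event's footprint, and must leave any inverted run a strict minority of
## its scaffold group
.choose_split_pair <- function(main, plan) {
  labels <- main$label[!duplicated(main$label)]
  n <- length(labels)
  if (n < 4L) return(NULL)
  present <- HOX_CLASSES[HOX_CLASSES %in% c(labels, plan$st_gene)]
  busy <- c(plan$trans_block, plan$inv_block, plan$st_gene,
            if (plan$n_extra > 0L) "zen")
  st_neighbours <- NULL
  if (!is.null(plan$st_gene)) {
    i <- match(plan$st_gene, present)
    st_neighbours <- present[c(i - 1L, i + 1L)]
  }
  cand <- list()
  for (i in seq_len(n - 1L)) {
    a <- labels[i]; b <- labels[i + 1L]
    if (a %in% busy || b %in% busy) next
    if (abs(match(a, present) - match(b, present)) != 1L) next
    if (!is.null(st_neighbours) && all(c(a, b) %in% st_neighbours)) next
    cand[[length(cand) + 1L]] <- c(a, b)
  }
  if (!length(cand)) return(NULL)
  cand <- cand[sample.int(length(cand))]
  for (pair in cand) {
    ci <- which(main$label == pair[1L])[1L]
    pieces <- list(main[seq_len(ci), , drop = FALSE],
                   main[-seq_len(ci), , drop = FALSE])
    ok <- all(vapply(pieces, function(g) {
      n_min <- sum(g$strand == "-")
      n_min == 0L || n_min < nrow(g) - n_min
    }, logical(1L)))
    ## the translocated block must stay grouped with at least as many
    ## unmoved genes (and >= 2), otherwise the block-at-wrong-end call
    ## becomes ambiguous with its complement
    if (length(plan$trans_block)) {
      ok <- ok && all(vapply(pieces, function(g) {
        in_block <- sum(unique(g$label) %in% plan$trans_block)
        rest <- length(unique(g$label)) - in_block
        in_block == 0L || rest >= max(in_block, 2L)
      }, logical(1L)))
    }
    if (ok) return(pair)
  }
  NULL
}

## ---- coordinates and spacers ----------------------------------------------

.spacer_params <- function(label_a, label_b, both_zen, config) {
  if (both_zen)
    return(c(config$array_spacer_log_mean, config$array_spacer_log_sd))
  pair <- sort(c(label_a, label_b))
  posterior <- any(vapply(POSTERIOR_PAIRS, function(p)
    identical(sort(p), pair), logical(1L)))
  if (posterior)
    c(config$posterior_spacer_log_mean, config$posterior_spacer_log_sd)
  else c(config$spacer_log_mean, config$spacer_log_sd)
}

GENE_FOOTPRINT_BP <- HOMEOBOX_BP + 6L  # ATG + 60 codons + TAA

.layout_groups <- function(groups, config) {
  split_pair <- attr(groups, "split_pair")
  all_loci <- list()
  inter <- list()
  scaffold_lengths <- numeric()
  scaffold_id <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (!nrow(g)) next
    scaffold_id <- scaffold_id + 1L
    sc <- paste0("scaffold_", scaffold_id)
    offset <- round(runif(1L, 5e3, 2e4))
    gene_start <- numeric(nrow(g))
    gene_start[1L] <- offset
    if (nrow(g) > 1L) {
      for (i in seq_len(nrow(g) - 1L)) {
        pp <- .spacer_params(g$label[i], g$label[i + 1L],
                             g$label[i] == "zen" && g$label[i + 1L] == "zen",
                             config)
        spacer <- max(1, round(rlnorm(1L, pp[1L], pp[2L])))
        gene_start[i + 1L] <- gene_start[i] + GENE_FOOTPRINT_BP + spacer
      }
    }
    g$scaffold <- sc
    g$gene_start <- as.integer(gene_start)
    g$start <- as.integer(gene_start + 3L)  # homeobox interval
    g$end <- g$start + HOMEOBOX_BP
    last_end <- gene_start[nrow(g)] + GENE_FOOTPRINT_BP
    scaffold_lengths[sc] <- max(config$background_length_bp, last_end + 5e3)
    all_loci[[length(all_loci) + 1L]] <- g
    if (nrow(g) > 1L) {
      i <- seq_len(nrow(g) - 1L)
      inter[[length(inter) + 1L]] <- data.frame(
        scaffold = sc, label_a = g$label[i], label_b = g$label[i + 1L],
        distance = g$start[i + 1L] - g$end[i], stringsAsFactors = FALSE)
    }
  }
  ## pure background scaffolds
  for (k in seq_len(config$n_scaffolds - 1L)) {
    scaffold_id <- scaffold_id + 1L
    scaffold_lengths[paste0("scaffold_", scaffold_id)] <-
      config$background_length_bp
  }
  loci <- do.call(rbind, all_loci)
  loci$copy_index <- stats::ave(seq_len(nrow(loci)), loci$label,
                                FUN = seq_along)
  list(loci = loci,
       intergenic = if (length(inter)) do.call(rbind, inter)
       else data.frame(scaffold = character(), label_a = character(),
                       label_b = character(), distance = numeric()),
       scaffold_lengths = scaffold_lengths,
       split_pair = split_pair)
}

## planted protein: subtype consensus for zen-derived copies, class
## consensus otherwise, then iid per-site substitution
.diverge_proteins <- function(loci, divergence) {
  vapply(seq_len(nrow(loci)), function(i) {
    cls <- if (!is.na(loci$subtype[i]) && loci$subtype[i] != "zen")
      loci$subtype[i] else loci$label[i]
    prot <- strsplit(HOX_CONSENSUS[[cls]], "")[[1]]
    if (divergence > 0) {
      hit <- runif(HOMEODOMAIN_AA) < divergence
      for (p in which(hit))
        prot[p] <- sample(setdiff(AA_ALPHABET, prot[p]), 1L)
    }
    paste(prot, collapse = "")
  }, character(1L))
}

## ---- sequence emission ----------------------------------------------------

.reverse_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

.encode_gene <- function(protein, strand, rev_codons) {
  res <- strsplit(protein, "")[[1]]
  codons <- vapply(res, function(a) {
    opts <- rev_codons[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1L))
  dna <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  if (strand == "-") dna <- .revcomp_chr(dna)
  dna
}

.revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

.random_background <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.emit_genome <- function(layout, config) {
  rev_codons <- .reverse_codon_table()
  seqs <- character(0)
  for (sc in names(layout$scaffold_lengths)) {
    len <- layout$scaffold_lengths[[sc]]
    bg <- .random_background(len, config$gc_content)
    g <- layout$loci[layout$loci$scaffold == sc, , drop = FALSE]
    if (nrow(g)) {
      pieces <- character(0)
      cursor <- 0L
      for (i in seq_len(nrow(g))) {
        gs <- g$gene_start[i]
        pieces <- c(pieces, substr(bg, cursor + 1L, gs),
                    .encode_gene(g$protein[i], g$strand[i], rev_codons))
        cursor <- gs + GENE_FOOTPRINT_BP
      }
      pieces <- c(pieces, substr(bg, cursor + 1L, len))
      bg <- paste(pieces, collapse = "")
    }
    seqs[sc] <- bg
  }
  Biostrings::DNAStringSet(seqs)
}

#' Generate a cohort of synthetic genomes from a species manifest
#'
#' One genome and truth table per manifest row, with per-order configuration
#' overrides (for instance, much larger spacers for Orthoptera, whose real
#' clusters are dramatically expanded). Per-species seeds are derived
#' deterministically from the base seed and the row index.
#'
#' @param manifest Data frame with columns `order` and `species` (an
#'   assembly column is carried through if present); must be non-empty with
#'   unique species names.
#' @param base_config A [simulation_config()] used for every species.
#' @param per_order_overrides Named list: order name -> list of
#'   [simulation_config()] arguments overriding the base for that order.
#'   Unknown order names are an error.
#' @param out_dir If non-`NULL`, write per-species FASTA plus truth TSVs and
#'   a cohort truth summary there and return file paths invisibly.
#' @param emit_sequence Passed to [generate_species_genome()].
#' @return List with `results` (named per-species list of
#'   `generate_species_genome()` outputs) and `summary` (per-species truth
#'   summary data frame).
#' @export
generate_cohort <- function(manifest, base_config = simulation_config(),
                            per_order_overrides = list(),
                            out_dir = NULL, emit_sequence = TRUE) {
  manifest <- as.data.frame(manifest)
  if (!nrow(manifest)) stop("manifest is empty")
  if (!all(c("order", "species") %in% names(manifest)))
    stop("manifest must have 'order' and 'species' columns")
  if (anyDuplicated(manifest$species))
    stop("duplicate species in manifest: ",
         paste(unique(manifest$species[duplicated(manifest$species)]),
               collapse = ", "))
  bad_orders <- setdiff(names(per_order_overrides), manifest$order)
  if (length(bad_orders))
    stop("per_order_overrides reference unknown order(s): ",
         paste(bad_orders, collapse = ", "))

  base_args <- unclass(base_config)
  results <- vector("list", nrow(manifest))
  names(results) <- manifest$species
  for (i in seq_len(nrow(manifest))) {
    args <- base_args
    ov <- per_order_overrides[[manifest$order[i]]]
    if (!is.null(ov)) args <- modifyList(args, ov)
    args$seed <- (base_args$seed + i * 1009L) %% .Machine$integer.max
    cfg <- do.call(simulation_config, args)
    results[[i]] <- generate_species_genome(cfg, manifest$species[i],
                                            emit_sequence = emit_sequence)
  }

  summary <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    tr <- results[[i]]$truth
    core <- core_cluster_size(tr$loci)
    data.frame(species = manifest$species[i], order = manifest$order[i],
               seed = tr$seed, n_loci = nrow(tr$loci),
               n_events = nrow(tr$events),
               core_span_bp = core$span,
               assembly_bp = sum(tr$scaffold_lengths),
               stringsAsFactors = FALSE)
  }))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sp in names(results)) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", sp)
      if (!is.null(results[[sp]]$genome))
        write_genome(results[[sp]]$genome,
                     file.path(out_dir, paste0(safe, ".fa")))
      write_tsv(results[[sp]]$truth$loci,
                file.path(out_dir, paste0(safe, ".truth_loci.tsv")))
      write_tsv(results[[sp]]$truth$events,
                file.path(out_dir, paste0(safe, ".truth_events.tsv")))
    }
    write_tsv(summary, file.path(out_dir, "cohort_truth_summary.tsv"))
  }
  list(results = results, summary = summary)
}
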