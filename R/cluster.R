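#' Intergenic distance between two Hox loci
#'
#' Distance in bp between the homeobox intervals of two loci on the same
#' scaffold: `max(0, max(start_a, start_b) - min(end_a, end_b))`. Distances
#' are measured homeobox edge to homeobox edge because transcript ends cannot
#' be delimited reliably from assembly sequence alone; overlapping intervals
#' clamp to zero. Loci on different scaffolds raise a condition of class
#' `hoxatlas_not_coscaffold` — the caller records a split instead.
#'
#' @param a,b Single-row locus records (any list/data.frame with `scaffold`,
#'   `start`, `end`).
#' @return Non-negative integer distance in bp; symmetric in its arguments.
#' @export
#' @examples
#' a <- list(scaffold = "s1", start = 100, end = 280)
#' b <- list(scaffold = "s1", start = 1000, end = 1180)
#' intergenic_distance(a, b)  # 720
intergenic_distance <- function(a, b) {
  if (a$scaffold[1L] != b$scaffold[1L])
    stop(errorCondition(
      paste0("loci are not co-scaffold ('", a$scaffold[1L], "' vs '",
             b$scaffold[1L], "'); record a split instead"),
      class = c("hoxatlas_not_coscaffold", "error")))
  max(0, max(a$start[1L], b$start[1L]) - min(a$end[1L], b$end[1L]))
}

#' Reconstruct per-species Hox cluster organisation
#'
#' Groups classified loci by scaffold, orders them by start coordinate, and
#' derives adjacent intergenic distances, per-scaffold spans, the core
#' cluster span (AbdB to Scr) and split points.
#'
#' @param loci A `hox_loci` data frame for one species.
#' @param genome_size_bp Total assembly length in bp (sum of scaffold
#'   lengths), carried into cohort summaries; `NA` if unknown.
#' @param config A [hox_run_config()] supplying the split thresholds.
#' @return Object of class `hox_cluster_model`: list with `species`,
#'   `scaffold_groups` (named list of ordered locus data frames),
#'   `intergenic` (scaffold, gene_a, gene_b, distance), `spans` (per-scaffold
#'   span, see [total_cluster_span()]), `core_span_bp` (+ `core_reason` when
#'   undefined), `split_points`, `genome_size_bp` and the thresholds used.
#' @export
build_cluster_model <- function(loci, genome_size_bp = NA_real_,
                                config = hox_run_config()) {
  stopifnot(is.data.frame(loci))
  loci <- loci[order(loci$scaffold, loci$start), , drop = FALSE]
  if (nrow(loci) && any(diff_ok <- duplicated(loci[c("scaffold", "start")])))
    loci <- loci[!diff_ok, , drop = FALSE]
  groups <- split(loci, loci$scaffold)
  groups <- lapply(groups, function(g) {
    g[order(g$start), , drop = FALSE]
  })

  inter <- do.call(rbind, c(lapply(names(groups), function(sc) {
    g <- groups[[sc]]
    if (nrow(g) < 2L) return(NULL)
    i <- seq_len(nrow(g) - 1L)
    data.frame(scaffold = sc,
               gene_a = .locus_id(g[i, ]),
               gene_b = .locus_id(g[i + 1L, ]),
               label_a = g$label[i], label_b = g$label[i + 1L],
               distance = pmax(0L, g$start[i + 1L] - g$end[i]),
               stringsAsFactors = FALSE)
  }), list(data.frame(scaffold = character(), gene_a = character(),
                      gene_b = character(), label_a = character(),
                      label_b = character(), distance = integer()))))

  model <- structure(list(
    species = if (nrow(loci)) loci$species[1L] else "unknown",
    scaffold_groups = groups,
    intergenic = inter,
    genome_size_bp = genome_size_bp,
    config = config), class = "hox_cluster_model")
  model$spans <- total_cluster_span(model)
  core <- core_cluster_size(model)
  model$core_span_bp <- core$span
  model$core_reason <- core$reason
  model$split_points <- detect_splits(model,
                                      config$split_abs_threshold_bp,
                                      config$split_rel_multiplier)
  model
}

.locus_id <- function(rows) paste0(rows$label, ".", rows$copy_index)

#' @export
print.hox_cluster_model <- function(x, ...) {
  cat("hoxatlas cluster model for", x$species, "\n")
  for (sc in names(x$scaffold_groups)) {
    g <- x$scaffold_groups[[sc]]
    cat(sprintf("  %s: %s\n", sc,
                paste0(g$label, ifelse(g$strand == "-", "(-)", ""),
                       collapse = " - ")))
  }
  if (is.na(x$core_span_bp))
    cat("  core span: undefined (", x$core_reason, ")\n", sep = "")
  else cat("  core span (AbdB-Scr):", x$core_span_bp, "bp\n")
  if (nrow(x$split_points))
    cat("  splits:", paste(paste0(x$split_points$left_gene, "|",
                                  x$split_points$right_gene),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Core Hox cluster span (AbdB to Scr)
#'
#' The span `max(end) - min(start)` over all loci labelled AbdB, abdA, Ubx,
#' Antp, ftz or Scr, provided every one of those labels is present and all
#' their loci sit on a single shared scaffold; otherwise the span is
#' undefined and a reason is reported (not an error). This region is the
#' most conserved part of the insect cluster, which makes its size
#' comparable across species.
#'
#' @param model A `hox_cluster_model` (or a `hox_loci` data frame).
#' @return List with `span` (bp, or `NA`) and `reason` (`NA` when defined).
#' @export
core_cluster_size <- function(model) {
  loci <- .model_loci(model)
  core <- loci[loci$label %in% CORE_LABELS, , drop = FALSE]
  missing_labels <- setdiff(CORE_LABELS, core$label)
  if (length(missing_labels))
    return(list(span = NA_real_,
                reason = paste("absent:",
                               paste(missing_labels, collapse = ","))))
  if (length(unique(core$scaffold)) != 1L)
    return(list(span = NA_real_,
                reason = paste("not co-scaffold:",
                               paste(sort(unique(core$scaffold)),
                                     collapse = ","))))
  list(span = max(core$end) - min(core$start), reason = NA_character_)
}

#' Per-scaffold Hox cluster span
#'
#' `max(end) - min(start)` of the homeobox intervals per scaffold group,
#' with the largest reported as the headline span.
#'
#' @param model A `hox_cluster_model` (or `hox_loci` data frame).
#' @return data.frame with `scaffold`, `n_loci`, `span_bp` and a logical
#'   `headline` marking the largest group.
#' @export
total_cluster_span <- function(model) {
  loci <- .model_loci(model)
  if (!nrow(loci))
    return(data.frame(scaffold = character(), n_loci = integer(),
                      span_bp = numeric(), headline = logical()))
  sp <- do.call(rbind, lapply(split(loci, loci$scaffold), function(g)
    data.frame(scaffold = g$scaffold[1L], n_loci = nrow(g),
               span_bp = max(g$end) - min(g$start),
               stringsAsFactors = FALSE)))
  sp <- sp[order(sp$scaffold), , drop = FALSE]
  sp$headline <- seq_len(nrow(sp)) == which.max(sp$span_bp)
  rownames(sp) <- NULL
  sp
}

.model_loci <- function(model) {
  if (inherits(model, "hox_cluster_model")) {
    if (!length(model$scaffold_groups))
      return(data.frame(species = character(), label = character(),
                        scaffold = character(), start = integer(),
                        end = integer(), strand = character()))
    do.call(rbind, c(model$scaffold_groups, list(make.row.names = FALSE)))
  } else model
}

#' Detect split points in a cluster model
#'
#' For every pair of genes adjacent in the ancestral order restricted to the
#' labels present in the species, a split is recorded when the pair is not
#' co-scaffold, or when its intergenic distance exceeds
#' `max(abs_threshold_bp, rel_multiplier * m)` where `m` is the species
#' median of observed adjacent intergenic distances. For multi-copy labels
#' the closest copy pair is used. The absolute default (9 Mb) is calibrated
#' so that the 9.6 Mb ANT-C/BX-C separation seen in Drosophila melanogaster
#' is called a split while the very large but intact Schistocerca clusters
#' (core 10.8-12.2 Mb over six intervals) are not.
#'
#' @param model A `hox_cluster_model`.
#' @param abs_threshold_bp,rel_multiplier Split thresholds (see above).
#' @return data.frame with `left_gene`, `right_gene`, `reason`
#'   (`different_scaffold` or `distance_exceeds_threshold`) and `distance`
#'   (`NA` when not co-scaffold).
#' @export
detect_splits <- function(model,
                          abs_threshold_bp =
                            hox_run_config()$split_abs_threshold_bp,
                          rel_multiplier =
                            hox_run_config()$split_rel_multiplier) {
  loci <- .model_loci(model)
  empty <- data.frame(left_gene = character(), right_gene = character(),
                      reason = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  present <- HOX_CLASSES[HOX_CLASSES %in% loci$label]
  if (length(present) < 2L) return(empty)
  med <- stats::median(model$intergenic$distance)
  threshold <- max(abs_threshold_bp,
                   if (is.na(med)) 0 else rel_multiplier * med)
  out <- empty
  for (k in seq_len(length(present) - 1L)) {
    a <- loci[loci$label == present[k], , drop = FALSE]
    b <- loci[loci$label == present[k + 1L], , drop = FALSE]
    shared <- intersect(a$scaffold, b$scaffold)
    if (!length(shared)) {
      out <- rbind(out, data.frame(left_gene = present[k],
                                   right_gene = present[k + 1L],
                                   reason = "different_scaffold",
                                   distance = NA_real_))
      next
    }
    dmin <- min(vapply(shared, function(sc) {
      ai <- a[a$scaffold == sc, , drop = FALSE]
      bi <- b[b$scaffold == sc, , drop = FALSE]
      min(outer(seq_len(nrow(ai)), seq_len(nrow(bi)), Vectorize(function(i, j)
        intergenic_distance(ai[i, ], bi[j, ]))))
    }, numeric(1L)))
    if (dmin > threshold)
      out <- rbind(out, data.frame(left_gene = present[k],
                                   right_gene = present[k + 1L],
                                   reason = "distance_exceeds_threshold",
                                   distance = dmin))
  }
  rownames(out) <- NULL
  out
}
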