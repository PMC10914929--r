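#' Sample Pearson correlation with explicit degenerate handling
#'
#' @param x,y Equal-length numeric vectors, length >= 3, each with nonzero
#'   variance.
#' @return List with `r` (the correlation, or `NA`) and `reason` (`NA` when
#'   defined; otherwise why the correlation is undefined). Degenerate input
#'   yields a reported reason, never a silent `NaN`.
#' @export
#' @examples
#' pearson_r(1:5, 2 * (1:5) + 1)$r  # 1
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 3L)
    return(list(r = NA_real_, reason = "fewer than 3 observations"))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    return(list(r = NA_real_, reason = "fewer than 3 finite pairs"))
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r = NA_real_, reason = "zero variance"))
  list(r = stats::cor(x, y), reason = NA_character_)
}

#' Copy-number matrix across species
#'
#' Counts loci per (species, class label); zen-derived subtypes roll up into
#' the zen-clade column, so row sums equal the total number of Hox loci
#' annotated per species.
#'
#' @param loci_tables Named list of per-species `hox_loci` data frames (or a
#'   single combined data frame with a `species` column).
#' @return Integer matrix, species x the ten class labels, plus a `total`
#'   attribute-free final column `total`.
#' @export
copy_number_matrix <- function(loci_tables) {
  if (is.data.frame(loci_tables))
    loci_tables <- split(loci_tables, loci_tables$species)
  m <- t(vapply(loci_tables, function(lo)
    vapply(HOX_CLASSES, function(cl) sum(lo$label == cl), integer(1L)),
    integer(length(HOX_CLASSES))))
  colnames(m) <- HOX_CLASSES
  cbind(m, total = as.integer(rowSums(m)))
}

#' Per-order intergenic-distance distributions
#'
#' Five-number summaries per (order, gene pair), following the boxplot
#' convention used for cross-order comparisons of Hox intergenic distances:
#' box between the 25th and 75th percentiles (linear interpolation between
#' closest ranks, R quantile type 7), median line, whiskers to the most
#' extreme values within 1.5 x IQR of the box, points beyond as outliers.
#'
#' @param models Named list of `hox_cluster_model` objects (names = species).
#' @param order_map Named character vector mapping species to insect order.
#' @return data.frame with one row per (order, gene pair): `n`, `q1`,
#'   `median`, `q3`, `whisker_low`, `whisker_high`, `n_outliers`. The pair
#'   label uses the ancestral orientation, e.g. `"Ubx-abdA"`. Metadata
#'   attribute `quartile_type` records the convention.
#' @export
distance_distributions <- function(models, order_map) {
  rows <- list()
  for (sp in names(models)) {
    ord <- order_map[sp]
    if (is.null(ord) || is.na(ord)) ord <- "unknown"
    inter <- models[[sp]]$intergenic
    if (!nrow(inter)) next
    la <- inter$label_a; lb <- inter$label_b
    canon <- la %in% HOX_CLASSES & lb %in% HOX_CLASSES & la != lb
    inter <- inter[canon, , drop = FALSE]
    if (!nrow(inter)) next
    ai <- match(inter$label_a, HOX_CLASSES)
    bi <- match(inter$label_b, HOX_CLASSES)
    pair <- paste(HOX_CLASSES[pmin(ai, bi)], HOX_CLASSES[pmax(ai, bi)],
                  sep = "-")
    rows[[sp]] <- data.frame(order = unname(ord), pair = pair,
                             distance = inter$distance,
                             stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  if (is.null(long))
    return(structure(data.frame(order = character(), pair = character(),
                                n = integer(), q1 = numeric(),
                                median = numeric(), q3 = numeric(),
                                whisker_low = numeric(),
                                whisker_high = numeric(),
                                n_outliers = integer()),
                     quartile_type = 7L))
  out <- do.call(rbind, lapply(
    split(long, list(long$order, long$pair), drop = TRUE), function(g) {
      q <- unname(quantile(g$distance, c(0.25, 0.5, 0.75), type = 7))
      iqr <- q[3] - q[1]
      lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
      inside <- g$distance[g$distance >= lo & g$distance <= hi]
      data.frame(order = g$order[1L], pair = g$pair[1L],
                 n = nrow(g), q1 = q[1], median = q[2], q3 = q[3],
                 whisker_low = min(inside), whisker_high = max(inside),
                 n_outliers = sum(g$distance < lo | g$distance > hi),
                 stringsAsFactors = FALSE)
    }))
  out <- out[order(out$order, out$pair), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, quartile_type = 7L)
}

#' Aggregate per-species models into a cohort summary
#'
#' The cross-species analogues of the headline comparative analyses:
#' per-species core-cluster span, assembly size and Hox copy number; the
#' species x gene copy-number matrix; per-order Pearson correlation of core
#' span against genome size (raw scale, recorded in metadata); and per-order
#' intergenic-distance distributions.
#'
#' @param models Named list of `hox_cluster_model` objects.
#' @param loci_tables Named list of matching `hox_loci` tables.
#' @param order_map Named character vector species -> order (optional; when
#'   absent all species fall in order "unknown").
#' @return Object of class `hox_cohort_summary`: list with `species` (per
#'   species data frame), `copy_numbers`, `distances`, `order_correlations`
#'   and `metadata`.
#' @export
summarise_cohort <- function(models, loci_tables, order_map = NULL) {
  sp <- names(models)
  if (is.null(order_map))
    order_map <- setNames(rep("unknown", length(sp)), sp)
  order_map[setdiff(sp, names(order_map))] <- "unknown"
  order_map[is.na(order_map)] <- "unknown"
  per_species <- do.call(rbind, lapply(sp, function(s) {
    m <- models[[s]]
    data.frame(species = s, order = unname(order_map[s]),
               n_loci = nrow(loci_tables[[s]]),
               core_span_bp = m$core_span_bp,
               core_reason = m$core_reason,
               genome_size_bp = m$genome_size_bp,
               stringsAsFactors = FALSE)
  }))
  cors <- do.call(rbind, lapply(split(per_species, per_species$order),
                                function(g) {
    pr <- pearson_r(g$core_span_bp, g$genome_size_bp)
    data.frame(order = g$order[1L], n_species = nrow(g),
               r_core_vs_genome = pr$r, reason = pr$reason,
               stringsAsFactors = FALSE)
  }))
  rownames(cors) <- NULL
  structure(list(species = per_species,
                 copy_numbers = copy_number_matrix(loci_tables),
                 distances = distance_distributions(models, order_map),
                 order_correlations = cors,
                 metadata = list(correlation_scale = "raw",
                                 quartile_type = 7L)),
            class = "hox_cohort_summary")
}

#' @export
print.hox_cohort_summary <- function(x, ...) {
  cat("hoxatlas cohort summary:", nrow(x$species), "species,",
      length(unique(x$species$order)), "order(s)\n")
  cat("  total Hox loci:", sum(x$copy_numbers[, "total"]), "\n")
  invisible(x)
}
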