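#' Assign homeodomain hits to Hox paralogy classes
#'
#' Each hit's per-class bit scores are rolled up to the ten ancestral
#' classes: the zen-clade score is the maximum over the plain zen profile and
#' any subtype profiles present (bcd, zen2, ShxA-D), so fast-evolving
#' zen-derived copies are still labelled `zen` at this stage (subtype
#' resolution is done separately by [assign_zen_subtypes()]). The label is
#' the arg-max class; exact ties are broken by ancestral order. When the
#' margin over the runner-up is below `min_margin` the hit is flagged
#' `ambiguous` and both candidate labels are retained.
#'
#' Same-label copies within a species are numbered `copy_index` by position
#' (scaffold, then start), and putative duplicates of canonical (non-zen)
#' genes are flagged `needs-verification`, reflecting the single-assembly
#' caution appropriate to such calls.
#'
#' @param hits A `hox_hits` data frame from [scan_genome()].
#' @param profiles The `hox_profiles` the hits were scored with; must contain
#'   every canonical class.
#' @param min_margin Minimum winning margin (bits) for an unambiguous call.
#' @param species Species identifier recorded in the output.
#' @return A `data.frame` (class `hox_loci`) with columns `species`, `label`,
#'   `subtype` (`NA` until subtype assignment), `scaffold`, `start`, `end`,
#'   `strand`, `protein`, `best_bits`, `margin`, `status`, `candidates`,
#'   `copy_index`, `flags`, plus the per-class `bits_` columns.
#' @export
classify_hits <- function(hits, profiles,
                          min_margin = hox_run_config()$min_margin,
                          species = "unknown") {
  stopifnot(inherits(profiles, "hox_profiles"))
  missing_classes <- setdiff(HOX_CLASSES, profiles$classes)
  if (length(missing_classes))
    stop("profile set is missing canonical class(es): ",
         paste(missing_classes, collapse = ", "))

  loci <- as.data.frame(hits)
  n <- nrow(loci)
  canon <- .canonical_scores(loci, profiles)
  if (n) {
    ord <- t(apply(canon, 1L, order, decreasing = TRUE))
    best_i <- ord[, 1L, drop = TRUE]
    second_i <- ord[, 2L, drop = TRUE]
    label <- HOX_CLASSES[best_i]
    margin <- canon[cbind(seq_len(n), best_i)] -
      canon[cbind(seq_len(n), second_i)]
    status <- ifelse(margin < min_margin, "ambiguous", "ok")
    candidates <- ifelse(status == "ambiguous",
                         paste(HOX_CLASSES[best_i], HOX_CLASSES[second_i],
                               sep = "|"),
                         label)
  } else {
    label <- character(); margin <- numeric()
    status <- character(); candidates <- character()
  }
  loci$species <- rep_len(species, n)
  loci$label <- label
  loci$subtype <- rep_len(NA_character_, n)
  loci$margin <- margin
  loci$status <- status
  loci$candidates <- candidates
  loci <- loci[order(loci$scaffold, loci$start), , drop = FALSE]
  loci$copy_index <- stats::ave(seq_len(nrow(loci)), loci$label,
                                FUN = seq_along)
  dup <- loci$label != "zen" &
    stats::ave(seq_len(nrow(loci)), loci$label, FUN = length) > 1L
  loci$flags <- ifelse(dup, "needs-verification", "")
  rownames(loci) <- NULL
  front <- c("species", "label", "subtype", "scaffold", "start", "end",
             "strand", "frame", "protein", "best_bits", "margin", "status",
             "candidates", "copy_index", "flags")
  loci <- loci[, c(front, setdiff(names(loci), front)), drop = FALSE]
  class(loci) <- c("hox_loci", "data.frame")
  loci
}

#' @rdname classify_hits
#' @param hit A single-row `hox_hits` data frame.
#' @export
classify_hit <- function(hit, profiles,
                         min_margin = hox_run_config()$min_margin,
                         species = "unknown") {
  classify_hits(hit[1L, , drop = FALSE], profiles, min_margin, species)
}

## ten-class score matrix with the zen clade rolled up
.canonical_scores <- function(loci, profiles) {
  get_bits <- function(cl) {
    col <- paste0("bits_", cl)
    if (col %in% names(loci)) loci[[col]] else NULL
  }
  zen_cols <- Filter(Negate(is.null), lapply(ZEN_CLADE, get_bits))
  canon <- vapply(HOX_CLASSES, function(cl) {
    if (cl == "zen") do.call(pmax, zen_cols)
    else get_bits(cl) %||% stop("missing bits column for class ", cl)
  }, numeric(nrow(loci)))
  matrix(canon, nrow = nrow(loci), ncol = length(HOX_CLASSES),
         dimnames = list(NULL, HOX_CLASSES))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Diagnostic-residue rule for bicoid
#'
#' The dipteran bcd gene is a zen-derived duplicate recognisable by two
#' homeodomain substitutions relative to the ancestral state: glutamine to
#' lysine at position 50 (Q50K) and methionine to arginine at position 54
#' (M54R). Both residues are required for a positive call.
#'
#' @return List with `positions` (1-based positions within the 60-residue
#'   homeodomain) and the `residues` required there.
#' @export
bcd_diagnostic_rule <- function() {
  list(positions = c(50L, 54L), residues = c("K", "R"))
}

#' Test a homeodomain for the bicoid diagnostic residues
#'
#' @param protein A 60-residue homeodomain protein string.
#' @param rule A rule as returned by [bcd_diagnostic_rule()].
#' @return `TRUE` iff the residue at every rule position matches (K50 and
#'   R54 under the default rule). Intended for zen-clade loci.
#' @export
#' @examples
#' detect_bcd(hox_consensus("bcd"))  # TRUE
#' detect_bcd(hox_consensus("zen"))  # FALSE (ancestral Q50, M54)
detect_bcd <- function(protein, rule = bcd_diagnostic_rule()) {
  if (!is.character(protein) || length(protein) != 1L ||
      nchar(protein) != HOMEODOMAIN_AA)
    stop("protein must be a single string of exactly ",
         HOMEODOMAIN_AA, " residues")
  if (any(rule$positions < 1L | rule$positions > HOMEODOMAIN_AA))
    stop("rule positions must lie in 1..", HOMEODOMAIN_AA)
  res <- substring(protein, rule$positions, rule$positions)
  all(res == rule$residues)
}

#' Resolve zen-clade loci into subtypes
#'
#' Within one species, each zen-labelled locus is assigned the best-scoring
#' subtype profile (bcd, zen2, ShxA-D) when that profile beats the plain zen
#' profile by at least `divergence_cutoff` bits; otherwise the locus keeps
#' the plain `zen` subtype. When several loci remain plain, only the one
#' scoring best against the plain profile keeps subtype `zen`; the rest are
#' marked `zen-derived-unassigned`. Loci carrying the bicoid diagnostic
#' residues (K50 and R54, see [detect_bcd()]) get a `bcd-residues` flag.
#'
#' @param loci A `hox_loci` data frame (one species).
#' @param profiles The `hox_profiles` used for classification. Subtype
#'   profiles absent from the set are simply not considered.
#' @param divergence_cutoff Bits by which a subtype profile must beat the
#'   plain zen profile.
#' @return `loci` with the `subtype` column filled for zen-labelled rows and
#'   flags updated.
#' @export
assign_zen_subtypes <- function(loci, profiles,
                                divergence_cutoff =
                                  hox_run_config()$zen_divergence_cutoff) {
  zi <- which(loci$label == "zen")
  if (!length(zi)) return(loci)
  subtypes <- intersect(ZEN_SUBTYPES, profiles$classes)
  plain <- loci$bits_zen[zi]
  if (length(subtypes)) {
    sub_bits <- as.matrix(loci[zi, paste0("bits_", subtypes), drop = FALSE])
    best_j <- apply(sub_bits, 1L, which.max)
    best_sub <- sub_bits[cbind(seq_along(zi), best_j)]
    assigned <- ifelse(best_sub - plain >= divergence_cutoff,
                       subtypes[best_j], "zen")
  } else {
    assigned <- rep("zen", length(zi))
  }
  plain_rows <- which(assigned == "zen")
  if (length(plain_rows) > 1L) {
    keep <- plain_rows[which.max(plain[plain_rows])]
    assigned[setdiff(plain_rows, keep)] <- "zen-derived-unassigned"
  }
  loci$subtype[zi] <- assigned
  has_bcd <- vapply(loci$protein[zi], detect_bcd, logical(1L))
  loci$flags[zi] <- ifelse(has_bcd,
                           .add_flag(loci$flags[zi], "bcd-residues"),
                           loci$flags[zi])
  loci
}

.add_flag <- function(flags, new) {
  ifelse(flags == "", new, paste(flags, new, sep = ";"))
}
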