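#' Ancestral insect Hox gene order
#'
#' The ten paralogy classes of the ancestral insect Hox cluster, anterior to
#' posterior. All gene-order comparisons in the package are made against this
#' arrangement, with every gene on the same (plus) reference orientation.
#'
#' @return Character vector of the ten class labels.
#' @export
#' @examples
#' ancestral_order()
ancestral_order <- function() HOX_CLASSES

HOX_CLASSES <- c("lab", "pb", "zen", "Dfd", "Scr", "ftz", "Antp", "Ubx",
                 "abdA", "AbdB")

#' zen-derived subtype labels (dipteran bcd/zen2 and lepidopteran ShxA-D)
#' @return Character vector of subtype labels.
#' @export
zen_subtypes <- function() ZEN_SUBTYPES

ZEN_SUBTYPES <- c("bcd", "zen2", "ShxA", "ShxB", "ShxC", "ShxD")

ALL_CLASSES <- c(HOX_CLASSES, ZEN_SUBTYPES)
ZEN_CLADE <- c("zen", ZEN_SUBTYPES)

## genes whose pairwise intervals behave like the posterior (BX-C-like) part
## of the cluster: consistently larger intergenic distances
POSTERIOR_PAIRS <- list(c("Antp", "Ubx"), c("Ubx", "abdA"), c("abdA", "AbdB"))

CORE_LABELS <- c("Scr", "ftz", "Antp", "Ubx", "abdA", "AbdB")

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

HOMEODOMAIN_AA <- 60L
HOMEOBOX_BP <- 180L

## Synthetic per-class homeodomain consensus sequences.
##
## These are NOT curated biological alignments: they are package-designed
## stand-ins built on a canonical Antp-like homeodomain backbone, with
## deterministic class-specific substitutions confined to non-critical
## positions. The invariant third helix (positions 46-56, WFQNRRMK core) is
## kept, so every canonical class carries the ancestral Q at position 50 and
## M at position 54; bcd alone carries the diagnostic K50 and R54. Classes
## differ pairwise at >= 14 positions (>= 6 within the zen clade), enough to
## make profile classification unambiguous at the divergence levels the
## simulator emulates.
HOX_CONSENSUS <- c(
  lab  = "RLRGRQTYWRYQWLDLEKTFHMNEYLLRFRRIEIAHALNLTEREIKIWFQNRRMKWFKFF",
  pb   = "WFRGRQTYMRYQILELTKQFHFNAWLHRIRDIESAHNLKLTERQIKIWFQNRRMKWKKEN",
  zen  = "RKWQRQTYGRYQTLNLMKEFHCNRYLDRSRYIEIAHALHLTKRLIKIWFQNRRMKWKHEY",
  Dfd  = "RDYGTQTYTRYQYLELEKEFHENRYLQRRRRIEIAHKLPLTIRMLKIWFQNRRMKWYTSN",
  Scr  = "WDRARQYYCRWQDLELKKIFHFNPYLNRRRRIEIAHALGLTERQIKIWFQNRRMKWEKFN",
  ftz  = "DDRLRQNYLRYQTLFLEKEFHFNCYLGRRRRIEIAHKLCLTERCSKIWFQNRRMKWKVFR",
  Antp = "RMRGRQYYRRYQGLELLKAFHENRYLSRRRPIERAHALPLTERKIKIWFQNRRMKWFVEN",
  Ubx  = "YDPGMQIYTRGQHLELRKEFHFNRFLIRRRLIEIAHALCLTERNMKIWFQNRRMKWKKEA",
  abdA = "RARGRQRYTRCQTLELEKEFHHNWKLTRRRRIETAHALELTVRSNKIWFQNRRMKWTCEL",
  AbdB = "KKHGLQTYERYQTLELTKEFHHNVYLTRRRHIEQAHALFLTERQIKIWFQNRRMKWEHAA",
  bcd  = "KKEQRQTYGRYQFLNLMKEFHCNRYLDRSRYIEIAHALSLTKRLIKIWFKNRRRKWKHEY",
  zen2 = "RKWHRQTYGRYQTLNLMKCFHCNRYLDRKRYIEIAHALFLTKRLIKIWFQNRRMKWKCEA",
  ShxA = "RAWQRQTYGRYQGLNLQKYFHCNMKLGRSRHIEMAHGLHLTWRLNKIWFQNRRMKWKHEY",
  ShxB = "RTFQGQLYGRYQCLVLLKQFHCNRYLDRSRYIEIAHFLHLTIRWIKIWFQNRRMKWKPEY",
  ShxC = "RKMCRQTYGRYQTLELEKEFHTNQYLGRSRMIEGAHALMLTKRLNKIWFQNRRMKWKTEY",
  ShxD = "NRLQRQTYYRHQTLNLMKEFHWNRYLDRSRYIEQAHALELTKRTSKIWFQNRRMKWKDET"
)

#' Consensus homeodomain sequence for a Hox class or zen subtype
#'
#' @param class A class label: one of `ancestral_order()` or `zen_subtypes()`.
#' @return A 60-residue protein string (the first sequence of the packaged
#'   seed alignment for that class).
#' @export
#' @examples
#' substr(hox_consensus("Antp"), 50, 54)  # ancestral Q50 ... M54
#' substr(hox_consensus("bcd"), 50, 54)   # diagnostic K50 ... R54
hox_consensus <- function(class) {
  class <- match.arg(class, ALL_CLASSES)
  unname(HOX_CONSENSUS[class])
}

## deterministic minor variants used to pad the packaged seed alignments;
## the substituted positions are shared across classes so they carry no
## class-discriminating signal
.seed_variant <- function(seq, which) {
  s <- strsplit(seq, "")[[1]]
  sub_at <- function(s, pos, res, alt) {
    s[pos] <- if (s[pos] == res) alt else res
    s
  }
  if (which == 1L) {
    s <- sub_at(s, 8L, "S", "T")
    s <- sub_at(s, 21L, "G", "A")
  } else {
    s <- sub_at(s, 33L, "D", "E")
    s <- sub_at(s, 43L, "S", "T")
  }
  paste(s, collapse = "")
}

#' Packaged homeodomain seed alignments
#'
#' Three aligned 60-residue sequences per Hox class and zen subtype: the
#' class consensus plus two minor variants (two substitutions each, at
#' positions shared across classes). These synthetic seeds are the package's
#' stand-in for curated per-class homeodomain alignments; [build_profiles()]
#' turns them into position-specific scoring matrices.
#'
#' @param classes Which classes to include (default: all canonical classes
#'   and zen subtypes).
#' @return Named list of character vectors, one per class.
#' @export
#' @examples
#' seeds <- hox_seed_alignments()
#' lengths(seeds)
hox_seed_alignments <- function(classes = ALL_CLASSES) {
  classes <- match.arg(classes, ALL_CLASSES, several.ok = TRUE)
  out <- lapply(classes, function(cl) {
    cons <- HOX_CONSENSUS[[cl]]
    c(cons, .seed_variant(cons, 1L), .seed_variant(cons, 2L))
  })
  names(out) <- classes
  out
}

#' Default thresholds and tuning parameters
#'
#' One place for every tunable threshold in the pipeline, serialisable to and
#' from JSON with [write_run_config()] / [read_run_config()].
#'
#' @param min_bits Six-frame scan acceptance threshold (bits). The default is
#'   calibrated on the synthetic generator: the largest integer threshold
#'   retaining 100% recall of planted loci at per-site divergence 0.2 across
#'   100 seeds (see [calibrate_min_bits()]).
#' @param min_margin Minimum lead (bits) of the best class over the runner-up
#'   before a classification is reported unambiguous.
#' @param zen_divergence_cutoff Excess (bits) a zen-clade locus must score
#'   under a subtype profile, over the plain zen profile, to be assigned that
#'   subtype.
#' @param split_abs_threshold_bp,split_rel_multiplier Split-calling
#'   thresholds: a co-scaffold ancestral neighbour pair is split when its
#'   intergenic distance exceeds
#'   `max(split_abs_threshold_bp, split_rel_multiplier * median distance)`.
#' @param tandem_window_bp Maximum same-scaffold span within which same-label
#'   copies count as one tandem array.
#' @param seed Seed recorded with every run.
#' @return A named list of class `hox_run_config`.
#' @export
hox_run_config <- function(min_bits = 104,
                           min_margin = 5,
                           zen_divergence_cutoff = 10,
                           split_abs_threshold_bp = 9e6,
                           split_rel_multiplier = 5,
                           tandem_window_bp = 1e6,
                           seed = 1L) {
  cfg <- list(min_bits = min_bits, min_margin = min_margin,
              zen_divergence_cutoff = zen_divergence_cutoff,
              split_abs_threshold_bp = split_abs_threshold_bp,
              split_rel_multiplier = split_rel_multiplier,
              tandem_window_bp = tandem_window_bp,
              seed = as.integer(seed))
  num <- cfg[setdiff(names(cfg), "seed")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x) && x > 0, logical(1L))))
    stop("all thresholds must be single finite positive numbers")
  structure(cfg, class = c("hox_run_config", "list"))
}

#' @export
print.hox_run_config <- function(x, ...) {
  cat("hoxatlas run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
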