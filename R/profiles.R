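#' Build per-class position-specific scoring matrices
#'
#' Turns per-class aligned 60-residue homeodomain sets into log-odds
#' position-specific scoring matrices (PSSMs, in bits). For residue `a` at
#' position `p` in a class with `N` seed sequences,
#'
#' \deqn{S(a,p) = \log_2 \frac{(n_{a,p} + \beta\, b_a) / (N + \beta)}{b_a}}
#'
#' where `n` is the observed count, `b` the background frequency and
#' `beta` the pseudocount weight. With `beta > 0` every entry is finite.
#'
#' @param seed_alignments Named list of character vectors; every sequence
#'   must be exactly 60 residues over the 20-letter amino-acid alphabet.
#'   Defaults to the packaged seeds ([hox_seed_alignments()]).
#' @param pseudocount Pseudocount weight `beta` (> 0).
#' @param background Named numeric vector of 20 background amino-acid
#'   frequencies summing to 1; default uniform. A zero frequency is an error.
#' @return An object of class `hox_profiles`: list with `matrices` (one
#'   20 x 60 matrix per class), `classes`, `background`, `pseudocount`, and a
#'   precomputed elementwise `max_matrix` used as a sound prefilter bound by
#'   [scan_genome()].
#' @export
#' @examples
#' p <- build_profiles()
#' dim(p$matrices$Antp)
#' score_protein(p, hox_consensus("Antp"))[["Antp"]]
build_profiles <- function(seed_alignments = hox_seed_alignments(),
                           pseudocount = 1,
                           background = NULL) {
  if (is.null(background))
    background <- setNames(rep(1 / 20, 20L), AA_ALPHABET)
  if (is.null(names(background)) ||
      !setequal(names(background), AA_ALPHABET))
    stop("background must be named by the 20 amino acids")
  background <- background[AA_ALPHABET]
  if (any(background <= 0))
    stop("background frequencies must all be positive")
  if (abs(sum(background) - 1) > 1e-8)
    stop("background frequencies must sum to 1")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  if (is.null(names(seed_alignments)) || anyDuplicated(names(seed_alignments)))
    stop("seed_alignments must be a uniquely named list of classes")

  mats <- lapply(names(seed_alignments), function(cl) {
    seqs <- seed_alignments[[cl]]
    if (length(seqs) < 1L)
      stop("class '", cl, "' has no seed sequences")
    if (any(nchar(seqs) != HOMEODOMAIN_AA))
      stop("ragged alignment for class '", cl,
           "': every seed must be exactly ", HOMEODOMAIN_AA, " residues")
    chars <- do.call(rbind, strsplit(seqs, ""))
    if (!all(chars %in% AA_ALPHABET))
      stop("non-standard residue in seed alignment for class '", cl, "'")
    counts <- vapply(seq_len(HOMEODOMAIN_AA), function(p)
      tabulate(match(chars[, p], AA_ALPHABET), nbins = 20L),
      integer(20L))
    n <- length(seqs)
    freq <- (counts + pseudocount * background) / (n + pseudocount)
    m <- log2(freq / background)
    dimnames(m) <- list(AA_ALPHABET, NULL)
    m
  })
  names(mats) <- names(seed_alignments)

  max_matrix <- Reduce(pmax, mats)
  structure(list(matrices = mats,
                 classes = names(mats),
                 background = background,
                 pseudocount = pseudocount,
                 max_matrix = max_matrix),
            class = "hox_profiles")
}

#' @export
print.hox_profiles <- function(x, ...) {
  cat("hoxatlas profile set:", length(x$matrices),
      "classes x 20 aa x", HOMEODOMAIN_AA, "positions (log-odds, bits)\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  pseudocount:", x$pseudocount, "\n")
  invisible(x)
}

#' Score a 60-residue protein against every profile
#'
#' @param profiles A `hox_profiles` object.
#' @param protein A 60-residue protein string.
#' @return Named numeric vector of bits, one entry per class.
#' @export
score_protein <- function(profiles, protein) {
  stopifnot(inherits(profiles, "hox_profiles"))
  if (nchar(protein) != HOMEODOMAIN_AA)
    stop("protein must be exactly ", HOMEODOMAIN_AA, " residues")
  idx <- match(strsplit(protein, "")[[1]], AA_ALPHABET)
  if (anyNA(idx))
    stop("protein contains a non-standard residue")
  sel <- cbind(idx, seq_len(HOMEODOMAIN_AA))
  vapply(profiles$matrices, function(m) sum(m[sel]), numeric(1L))
}

## indices 1..20 = amino acids, 21 = invalid (stop codon or fuzzy/N codon)
.aa_index <- function(protein_string) {
  map <- rep.int(21L, 128L)
  map[vapply(AA_ALPHABET, utf8ToInt, integer(1L))] <- seq_len(20L)
  map[utf8ToInt(protein_string)]
}
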