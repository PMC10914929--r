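#' Six-frame homeodomain scan of a genome assembly
#'
#' Slides a 60-codon window over all six reading frames of every scaffold and
#' scores the translated window against every class profile. Windows
#' containing a stop codon or a codon with an ambiguous base (N or any other
#' IUPAC ambiguity code) are rejected. A window is reported when its best
#' per-class score reaches `min_bits`; overlapping reported windows
#' (intersecting nucleotide intervals on a scaffold, either strand) are
#' resolved greedily by score, ties broken leftmost then plus strand.
#' Minus-strand hits are reported in forward-strand coordinates.
#'
#' Internally the scan prefilters windows with the elementwise maximum over
#' all class matrices, which bounds every per-class score from above, so the
#' prefilter is exact: the accepted hit set equals exhaustive window
#' enumeration under the stated rules.
#'
#' @param genome A named `DNAStringSet`, a named character vector of
#'   sequences, or a path to a FASTA(.gz) file.
#' @param profiles A `hox_profiles` object from [build_profiles()].
#' @param min_bits Finite acceptance threshold in bits (default from
#'   [hox_run_config()]).
#' @return A `data.frame` (class `hox_hits`) with columns `scaffold`,
#'   `start`, `end` (0-based half-open, `end - start == 180`), `strand`,
#'   `frame` (0-2 on the read strand), `protein`, `best_bits`, and one
#'   `bits_<class>` column per profile. Empty genome gives zero rows.
#' @export
#' @examples
#' p <- build_profiles()
#' cfg <- simulation_config(seed = 1, background_length_bp = 3e4,
#'                          event_probs = c(split = 0, inversion = 0,
#'                                          translocation = 0,
#'                                          scaffold_translocation = 0,
#'                                          tandem_duplication = 0, loss = 0))
#' g <- generate_species_genome(cfg)
#' hits <- scan_genome(g$genome, p)
#' nrow(hits)  # 10 planted homeoboxes
scan_genome <- function(genome, profiles,
                        min_bits = hox_run_config()$min_bits) {
  stopifnot(inherits(profiles, "hox_profiles"))
  if (!is.numeric(min_bits) || length(min_bits) != 1L || !is.finite(min_bits))
    stop("min_bits must be a single finite number")
  genome <- .as_dna(genome, validate = TRUE)

  hit_list <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    hit_list[[i]] <- .scan_scaffold(genome[[i]], names(genome)[i],
                                    profiles, min_bits)
  }
  hits <- do.call(rbind, c(hit_list, list(.empty_hits(profiles))))
  hits <- .resolve_overlaps(hits)
  hits <- hits[order(hits$scaffold, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("hox_hits", "data.frame")
  hits
}

.empty_hits <- function(profiles) {
  base <- data.frame(scaffold = character(), start = integer(),
                     end = integer(), strand = character(),
                     frame = integer(), protein = character(),
                     best_bits = numeric(), stringsAsFactors = FALSE)
  for (cl in profiles$classes) base[[paste0("bits_", cl)]] <- numeric()
  base
}

## coerce to DNAStringSet; character input is validated with a
## scaffold/offset-naming error for non-IUPAC characters
.as_dna <- function(genome, validate = FALSE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(read_genome(genome))
  if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- paste0("scaffold_", seq_along(genome))
    genome <- vapply(genome, toupper, character(1L))
    if (validate) {
      ok <- c(strsplit("ACGTNRYSWKMBDHV", "")[[1]])
      for (nm in names(genome)) {
        chars <- strsplit(genome[[nm]], "")[[1]]
        bad <- which(!chars %in% ok)
        if (length(bad))
          stop("non-IUPAC character '", chars[bad[1L]],
               "' in scaffold '", nm, "' at offset ", bad[1L] - 1L)
      }
    }
    return(Biostrings::DNAStringSet(genome))
  }
  if (is(genome, "DNAStringSet")) {
    if (length(genome) && is.null(names(genome)))
      names(genome) <- paste0("scaffold_", seq_along(genome))
    if (validate && length(genome)) {
      af <- Biostrings::alphabetFrequency(genome)
      bad_cols <- setdiff(colnames(af),
                          strsplit("ACGTNRYSWKMBDHV", "")[[1]])
      bad <- which(rowSums(af[, bad_cols, drop = FALSE]) > 0)
      if (length(bad)) {
        chars <- strsplit(as.character(genome[[bad[1L]]]), "")[[1]]
        off <- which(!chars %in% strsplit("ACGTNRYSWKMBDHV", "")[[1]])[1L]
        stop("non-IUPAC character '", chars[off], "' in scaffold '",
             names(genome)[bad[1L]], "' at offset ", off - 1L)
      }
    }
    return(genome)
  }
  stop("genome must be a DNAStringSet, named character vector or FASTA path")
}

## translate all six frames of one scaffold in a single Biostrings call
## (per-frame S4 dispatch dominates runtime on short scaffolds otherwise)
.six_frames <- function(dna) {
  len <- length(dna)
  strands <- list(`+` = dna, `-` = Biostrings::reverseComplement(dna))
  frames <- list()
  for (strand in names(strands)) {
    for (frame in 0:2) {
      n_codons <- (len - frame) %/% 3L
      if (n_codons < 1L) next
      frames[[paste(strand, frame)]] <-
        Biostrings::subseq(strands[[strand]], start = frame + 1L,
                           width = n_codons * 3L)
    }
  }
  if (!length(frames)) return(character())
  prots <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(frames),
                          if.fuzzy.codon = "X")))
  names(prots) <- names(frames)
  prots
}

.scan_scaffold <- function(dna, scaffold, profiles, min_bits) {
  len <- length(dna)
  if (len < HOMEOBOX_BP) return(NULL)
  prots <- .six_frames(dna)
  out <- list()
  for (key in names(prots)) {
    strand <- substr(key, 1L, 1L)
    frame <- as.integer(substr(key, 3L, 3L))
    prot <- prots[[key]]
    np <- nchar(prot)
    if (np >= HOMEODOMAIN_AA) {
      idx <- .aa_index(prot)
      cand <- .prefilter_windows(idx, profiles$max_matrix, min_bits)
      if (!length(cand)) next
      rows <- .score_candidates(idx, cand, profiles, min_bits)
      if (is.null(rows)) next
      ## window w (1-based, on read strand) -> read-strand nt interval
      rs <- frame + 3L * (rows$window - 1L)
      if (strand == "+") {
        rows$start <- rs
      } else {
        rows$start <- len - (rs + HOMEOBOX_BP)
      }
      rows$end <- rows$start + HOMEOBOX_BP
      rows$scaffold <- scaffold
      rows$strand <- strand
      rows$frame <- frame
      rows$window <- NULL
      out[[length(out) + 1L]] <- rows
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

## sliding-window sums of an upper-bound matrix; exact superset of windows
## whose best per-class score can reach min_bits
.prefilter_windows <- function(idx, max_matrix, min_bits) {
  np <- length(idx)
  nw <- np - HOMEODOMAIN_AA + 1L
  if (nw < 1L) return(integer())
  bound <- rbind(max_matrix, rep.int(-1e9, HOMEODOMAIN_AA))  # row 21: invalid
  .prefilter_windows_cpp(idx, bound, min_bits)
}

.score_candidates <- function(idx, cand, profiles, min_bits) {
  pos <- seq_len(HOMEODOMAIN_AA)
  classes <- profiles$classes
  rows <- lapply(cand, function(w) {
    widx <- idx[w + pos - 1L]
    if (any(widx == 21L)) return(NULL)  # stop or ambiguous codon
    bits <- vapply(profiles$matrices,
                   function(m) sum(m[cbind(widx, pos)]), numeric(1L))
    best <- max(bits)
    if (best < min_bits) return(NULL)
    r <- data.frame(window = w,
                    protein = paste(AA_ALPHABET[widx], collapse = ""),
                    best_bits = best, stringsAsFactors = FALSE)
    for (cl in classes) r[[paste0("bits_", cl)]] <- bits[[cl]]
    r
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

## greedy overlap resolution: highest best_bits wins; ties leftmost, then +
.resolve_overlaps <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  ord <- order(-hits$best_bits, hits$start,
               match(hits$strand, c("+", "-")))
  keep <- logical(nrow(hits))
  for (scaf in unique(hits$scaffold)) {
    rows <- ord[hits$scaffold[ord] == scaf]
    kept_start <- integer(0)
    kept_end <- integer(0)
    for (r in rows) {
      s <- hits$start[r]; e <- hits$end[r]
      if (!length(kept_start) || all(e <= kept_start | s >= kept_end)) {
        keep[r] <- TRUE
        kept_start <- c(kept_start, s)
        kept_end <- c(kept_end, e)
      }
    }
  }
  hits[keep, , drop = FALSE]
}
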