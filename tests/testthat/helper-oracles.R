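# Shared fixtures and independent oracles used across the suite.

TEST_PROFILES <- build_profiles()

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# -- independent translation + exhaustive scan oracle ------------------------
# Deliberately avoids the production code path: manual codon lookup from the
# standard genetic code, window scores by outer-indexed rowSums, and a plain
# re-implementation of the stated filtering/deduplication rules.

oracle_translate <- function(seq_chars, frame) {
  gc <- Biostrings::GENETIC_CODE
  n_codons <- (length(seq_chars) - frame) %/% 3L
  if (n_codons < 1L) return(character())
  starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- paste0(seq_chars[starts], seq_chars[starts + 1L],
                   seq_chars[starts + 2L])
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"  # any codon containing N or another ambiguity code
  unname(aa)
}

oracle_scan <- function(genome_chars, profiles, min_bits) {
  hits <- list()
  for (scaf in names(genome_chars)) {
    fwd <- strsplit(toupper(genome_chars[[scaf]]), "")[[1]]
    len <- length(fwd)
    comp <- chartr("ACGT", "TGCA", rev(fwd))
    for (strand in c("+", "-")) {
      chars <- if (strand == "+") fwd else comp
      for (frame in 0:2) {
        aa <- oracle_translate(chars, frame)
        np <- length(aa)
        nw <- np - 59L
        if (nw < 1L) next
        aa_i <- match(aa, AA20)                 # NA for stop/ambiguous
        # full enumeration: every window's score under every class profile,
        # accumulated position by position (no prefiltering of any kind)
        per_class <- matrix(0, nrow = nw, ncol = length(profiles$matrices),
                            dimnames = list(NULL, names(profiles$matrices)))
        n_bad <- integer(nw)
        for (p in 1:60) {
          slice <- aa_i[p:(p + nw - 1L)]
          n_bad <- n_bad + is.na(slice)
          for (cl in names(profiles$matrices)) {
            v <- profiles$matrices[[cl]][, p][slice]
            v[is.na(v)] <- 0
            per_class[, cl] <- per_class[, cl] + v
          }
        }
        best <- do.call(pmax, as.data.frame(per_class))
        for (w in which(n_bad == 0L & best >= min_bits)) {
          rs <- frame + 3L * (w - 1L)
          start <- if (strand == "+") rs else len - (rs + 180L)
          hits[[length(hits) + 1L]] <- data.frame(
            scaffold = scaf, start = start, end = start + 180L,
            strand = strand, best_bits = best[w],
            protein = paste(AA20[aa_i[w:(w + 59L)]], collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), strand = character(),
                      best_bits = numeric(), protein = character()))
  h <- do.call(rbind, hits)
  # greedy dedup: best bits, then leftmost, then plus strand
  ord <- order(-h$best_bits, h$start, match(h$strand, c("+", "-")))
  keep <- logical(nrow(h))
  for (scaf in unique(h$scaffold)) {
    ks <- integer(); ke <- integer()
    for (r in ord[h$scaffold[ord] == scaf]) {
      s <- h$start[r]; e <- h$end[r]
      if (!length(ks) || all(e <= ks | s >= ke)) {
        keep[r] <- TRUE; ks <- c(ks, s); ke <- c(ke, e)
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$scaffold, h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# -- breakpoint-distance oracle ----------------------------------------------
# Counts ancestral neighbour pairs missing from the observed arrangement by
# explicit string-pair enumeration.
oracle_breakpoints <- function(observed, ancestral) {
  pres <- ancestral[ancestral %in% observed]
  pair_str <- function(ord) {
    if (length(ord) < 2) return(character())
    sapply(seq_len(length(ord) - 1L), function(i)
      paste(sort(c(ord[i], ord[i + 1L])), collapse = "|"))
  }
  sum(!pair_str(pres) %in% pair_str(observed))
}

# -- small construction helpers ----------------------------------------------

# first-codon encoding of a protein, framed ATG ... TAA
make_orf <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  rev_tab <- split(names(gc), unname(gc))
  codons <- vapply(strsplit(protein, "")[[1]],
                   function(a) rev_tab[[a]][1L], character(1))
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# plant ORFs for given proteins at fixed gaps in an A/T-rich background;
# returns list(seq, starts, ends) with homeobox coordinates (0-based)
plant_scaffold <- function(proteins, strands = rep("+", length(proteins)),
                           gap = 500L, lead = 400L, seed = 42L) {
  set.seed(seed)
  pieces <- character(); starts <- integer(); ends <- integer()
  cursor <- 0L
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE,
                                 prob = c(.35, .15, .15, .35)),
                          collapse = "")
  pieces <- c(pieces, bg(lead)); cursor <- lead
  for (i in seq_along(proteins)) {
    orf <- make_orf(proteins[i])
    if (strands[i] == "-") orf <- revcomp_chr(orf)
    starts <- c(starts, cursor + 3L)
    ends <- c(ends, cursor + 3L + 180L)
    pieces <- c(pieces, orf)
    cursor <- cursor + nchar(orf)
    pieces <- c(pieces, bg(gap))
    cursor <- cursor + gap
  }
  list(seq = paste(pieces, collapse = ""), starts = starts, ends = ends)
}

# hand-build a loci table for cluster/event tests
fake_loci <- function(labels, starts, scaffold = "s1",
                      strand = rep("+", length(labels)),
                      species = "spX") {
  scaffold <- rep_len(scaffold, length(labels))
  starts <- as.integer(starts)
  df <- data.frame(species = species, label = labels,
                   subtype = ifelse(labels == "zen", "zen", NA_character_),
                   scaffold = scaffold, start = starts, end = starts + 180L,
                   strand = strand, stringsAsFactors = FALSE)
  df <- df[order(df$scaffold, df$start), ]
  df$copy_index <- stats::ave(seq_len(nrow(df)), df$label, FUN = seq_along)
  df$flags <- ""
  rownames(df) <- NULL
  df
}

# normalised (kind, sorted gene set) view of an event table
norm_events <- function(ev) {
  ev$genes <- vapply(strsplit(ev$genes, ","), function(g)
    paste(sort(g), collapse = ","), character(1))
  ev <- ev[order(ev$kind, ev$genes), c("kind", "genes")]
  rownames(ev) <- NULL
  ev
}

ALL_EVENTS_ON <- c(loss = 1, tandem_duplication = 1, inversion = 1,
                   translocation = 1, scaffold_translocation = 1, split = 1)
NO_EVENTS <- c(loss = 0, tandem_duplication = 0, inversion = 0,
               translocation = 0, scaffold_translocation = 0, split = 0)
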