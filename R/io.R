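#' Read a genome assembly from FASTA
#'
#' @param path FASTA file, optionally gzip-compressed.
#' @return Named `DNAStringSet`. FASTA headers are truncated at the first
#'   whitespace, matching common assembly-annotation practice.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  ## readDNAStringSet silently drops invalid letters with a warning; a
  ## corrupt assembly must be a hard error, not a shortened sequence
  x <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid", conditionMessage(w)))
        stop("invalid sequence characters in ", path, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a genome to FASTA, wrapped at 80 columns
#'
#' @param x A `DNAStringSet` or named character vector.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @export
write_genome <- function(x, path) {
  if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 80L,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname hox_tsv
#' @param x Data frame to write.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Plain TSV readers/writers used for every tabular output
#'
#' All package tables are written with a header, tab-separated, unquoted,
#' and round-trip through these functions.
#'
#' @param path File path.
#' @name hox_tsv
#' @return `read_tsv()`: a data.frame; `write_tsv()`: the path, invisibly.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Convert a locus table to GRanges (and back)
#'
#' Internal coordinates are 0-based half-open; `GRanges` is 1-based
#' inclusive, so conversion adds 1 to starts. The two converters are exact
#' inverses on locus records.
#'
#' @param loci A `hox_loci`-style data frame.
#' @return A `GenomicRanges::GRanges` with locus metadata columns.
#' @export
loci_to_granges <- function(loci) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$scaffold,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand)
  keep <- setdiff(names(loci), c("scaffold", "start", "end", "strand"))
  S4Vectors::mcols(gr) <- loci[, keep, drop = FALSE]
  gr
}

#' @rdname loci_to_granges
#' @param gr A `GRanges` produced by [loci_to_granges()].
#' @export
granges_to_loci <- function(gr) {
  df <- as.data.frame(S4Vectors::mcols(gr), stringsAsFactors = FALSE)
  out <- cbind(data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr) - 1L,
                          end = GenomicRanges::end(gr),
                          strand = as.character(GenomicRanges::strand(gr)),
                          stringsAsFactors = FALSE),
               df)
  out
}

#' Write homeodomain hits or loci as GFF3
#'
#' Features are typed `homeobox_match` with `score` = best bits; coordinates
#' are converted from the internal 0-based half-open convention to the
#' 1-based inclusive GFF3 convention.
#'
#' @param x A `hox_hits` or `hox_loci` data frame.
#' @param path Output file.
#' @export
write_gff3 <- function(x, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$scaffold,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = x$strand)
  S4Vectors::mcols(gr)$source <- "hoxatlas"
  S4Vectors::mcols(gr)$type <- "homeobox_match"
  S4Vectors::mcols(gr)$score <- x$best_bits
  if ("label" %in% names(x)) {
    S4Vectors::mcols(gr)$ID <- paste0(x$label, ".", x$copy_index)
    S4Vectors::mcols(gr)$Name <- ifelse(is.na(x$subtype) | x$subtype == x$label,
                                        x$label, paste0(x$label, "/", x$subtype))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write loci as BED (0-based half-open, matching internal coordinates)
#'
#' @param x A `hox_loci` data frame.
#' @param path Output file.
#' @export
write_bed <- function(x, path) {
  gr <- loci_to_granges(x)
  S4Vectors::mcols(gr) <- NULL
  names(gr) <- if ("label" %in% names(x))
    paste0(x$label, ".", x$copy_index) else rep(".", nrow(x))
  score <- if ("best_bits" %in% names(x))
    pmin(1000L, pmax(0L, as.integer(round(x$best_bits)))) else 0L
  S4Vectors::mcols(gr)$score <- score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Load a species/assembly manifest
#'
#' A three-column TSV (`order`, `species`, `assembly`) listing one genome
#' assembly per species. The packaged fixture
#' (`system.file("extdata", "species_manifest.tsv", package = "hoxatlas")`)
#' is the 244-row survey cohort: 243 insect species from 13 orders plus the
#' collembolan outgroup, with assembly labels stored verbatim.
#'
#' @param path Manifest TSV with header.
#' @return data.frame of class `hox_manifest` with attribute `order_counts`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("manifest is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- tolower(trimws(fields[[1L]]))
  if (length(header) < 2L || header[1L] != "order" ||
      !header[2L] %in% c("species"))
    stop("manifest must start with a header line 'order<TAB>species[<TAB>assembly]'")
  if (length(lines) < 2L) stop("manifest has a header but no rows: ", path)
  rows <- lapply(seq_along(fields)[-1L], function(i) {
    f <- trimws(fields[[i]])
    if (length(f) != length(header) || any(!nzchar(f[1:2])))
      stop("malformed manifest row at line ", i, ": '", lines[i], "'")
    f
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- header
  if (anyDuplicated(out$species))
    stop("duplicate species in manifest: ",
         paste(unique(out$species[duplicated(out$species)]), collapse = ", "))
  counts <- table(out$order)
  structure(out, order_counts = counts,
            class = c("hox_manifest", "data.frame"))
}

#' @export
print.hox_manifest <- function(x, ...) {
  counts <- attr(x, "order_counts")
  cat("hoxatlas species manifest:", nrow(x), "species,",
      length(counts), "orders\n")
  for (o in names(sort(counts, decreasing = TRUE)))
    cat(sprintf("  %-14s %d\n", o, counts[[o]]))
  invisible(x)
}

#' @rdname load_manifest
#' @export
hoxatlas_manifest <- function() {
  load_manifest(system.file("extdata", "species_manifest.tsv",
                            package = "hoxatlas", mustWork = TRUE))
}

#' Serialise a run configuration to JSON (and back, losslessly)
#'
#' @param config A [hox_run_config()].
#' @param path JSON file path.
#' @name run_config_io
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "hox_run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config_io
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- lapply(vals, function(x) if (is.numeric(x)) as.numeric(x) else x)
  do.call(hox_run_config, vals)
}
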