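#' Pairwise p-distances between aligned homeodomain proteins
#'
#' Normalised mismatch count (p-distance) over the fixed 60-column
#' homeodomain frame; a simple, reproducible distance for duplicate-clade
#' grouping of zen/Shx copies.
#'
#' @param proteins Named character vector of equal-length aligned proteins.
#' @return Symmetric numeric matrix of p-distances with zero diagonal.
#' @export
protein_pdistance <- function(proteins) {
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("proteins must be uniquely named")
  if (length(unique(nchar(proteins))) != 1L)
    stop("proteins must be aligned to equal length")
  chars <- do.call(rbind, strsplit(proteins, ""))
  n <- length(proteins)
  d <- matrix(0, n, n, dimnames = list(names(proteins), names(proteins)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- mean(chars[i, ] != chars[j, ])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining with a deterministic tie-break (the
#' lowest-index pair under the input ordering). Additive distances are
#' recovered exactly, including the branch lengths; negative estimated branch
#' lengths are reported as computed, not clamped.
#'
#' This implementation is intentionally self-contained so it can be
#' cross-checked against an independent library implementation in the test
#' suite.
#'
#' @param d Symmetric non-negative numeric matrix (or `dist`) with zero
#'   diagonal, at least 3 taxa, with row/column names.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- neighbor_joining_tree(d)
#' tr$edge.length  # pendant branches 1, 1, 3
neighbor_joining_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("d must be a square matrix or dist object")
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")

  fmt <- function(x) sprintf("%.12g", x)
  nodes <- rownames(d)          # current newick fragment per active node
  repeat {
    r <- nrow(d)
    if (r == 3L) {
      l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
      l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
      l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
      nwk <- paste0("(", nodes[1], ":", fmt(l1), ",",
                    nodes[2], ":", fmt(l2), ",",
                    nodes[3], ":", fmt(l3), ");")
      return(ape::read.tree(text = nwk))
    }
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, `+`)
    diag(q) <- Inf
    ## lowest-index pair among minima (row-major over i < j)
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    new_frag <- paste0("(", nodes[i], ":", fmt(li), ",",
                       nodes[j], ":", fmt(lj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], new_frag)
    rownames(d2) <- colnames(d2) <- as.character(seq_len(r - 1L))
    d <- d2
  }
}

#' Neighbor-joining gene tree of classified loci
#'
#' Convenience wrapper: p-distances over the homeodomain proteins of a locus
#' table, then neighbor joining. Tip labels are `label.copy_index` (with
#' subtype where assigned).
#'
#' @param loci A `hox_loci` data frame with >= 3 rows.
#' @return An `ape::phylo` tree.
#' @export
hox_gene_tree <- function(loci) {
  if (nrow(loci) < 3L) stop("need at least 3 loci for a tree")
  lab <- ifelse(!is.na(loci$subtype) & loci$subtype != "zen",
                loci$subtype, loci$label)
  tips <- make.unique(paste0(lab, ".", loci$copy_index), sep = "_")
  neighbor_joining_tree(protein_pdistance(setNames(loci$protein, tips)))
}
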