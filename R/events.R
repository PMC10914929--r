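#' Breakpoint distance to the ancestral gene order
#'
#' Number of ancestral gene adjacencies (unordered neighbouring pairs,
#' restricted to the labels present) that are absent from an observed
#' arrangement. Orientation-insensitive, so a full reversal of the cluster
#' has distance zero.
#'
#' @param observed Character vector: observed label order (a permutation of
#'   a subset of the ancestral labels, no repeats).
#' @param ancestral The reference order (default [ancestral_order()]).
#' @return Non-negative integer.
#' @export
#' @examples
#' breakpoint_distance(ancestral_order())              # 0
#' breakpoint_distance(rev(ancestral_order()))         # 0
#' breakpoint_distance(c("pb", "zen", "Dfd", "Scr", "ftz", "Antp",
#'                       "Ubx", "abdA", "AbdB", "lab"))  # 1
breakpoint_distance <- function(observed, ancestral = ancestral_order()) {
  unknown <- setdiff(observed, ancestral)
  if (length(unknown))
    stop("unknown label(s) in observed order: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(observed))
    stop("observed order contains repeated labels")
  present <- ancestral[ancestral %in% observed]
  anc_adj <- .adjacency_set(present)
  obs_adj <- .adjacency_set(observed)
  sum(!(anc_adj %in% obs_adj))
}

## canonical string form of the unordered adjacency set of an order
.adjacency_set <- function(ord) {
  if (length(ord) < 2L) return(character())
  a <- ord[-length(ord)]
  b <- ord[-1L]
  paste(pmin(a, b), pmax(a, b), sep = "~")
}

.event_row <- function(species, kind, genes, evidence, confidence = "high") {
  data.frame(species = species, kind = kind,
             genes = paste(genes, collapse = ","),
             evidence = evidence, confidence = confidence,
             stringsAsFactors = FALSE)
}

.empty_events <- function() {
  data.frame(species = character(), kind = character(), genes = character(),
             evidence = character(), confidence = character(),
             stringsAsFactors = FALSE)
}

## canonical loci of a scaffold group in positional order, one row per label
## (multi-copy labels collapsed to their first copy by position)
.group_label_order <- function(g) {
  g <- g[g$label %in% HOX_CLASSES, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  g[!duplicated(g$label), , drop = FALSE]
}

#' Call block inversions from transcriptional orientation
#'
#' Within each scaffold group the consensus orientation is the majority
#' strand of its Hox loci (ties resolved to the strand of AbdB when present,
#' else plus). Each maximal run of loci opposing the consensus is reported as
#' one block inversion.
#'
#' @param model A `hox_cluster_model`.
#' @return Event data.frame (kind `inversion`).
#' @export
call_inversions <- function(model) {
  out <- .empty_events()
  for (sc in names(model$scaffold_groups)) {
    g <- model$scaffold_groups[[sc]]
    g <- g[order(g$start), , drop = FALSE]
    if (!nrow(g)) next
    n_plus <- sum(g$strand == "+")
    n_minus <- nrow(g) - n_plus
    consensus <- if (n_plus > n_minus) "+"
    else if (n_minus > n_plus) "-"
    else if ("AbdB" %in% g$label) g$strand[match("AbdB", g$label)]
    else "+"
    opp <- g$strand != consensus
    if (!any(opp)) next
    runs <- rle(opp)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      block <- g[starts[k]:ends[k], , drop = FALSE]
      out <- rbind(out, .event_row(
        model$species, "inversion", unique(block$label),
        sprintf("scaffold=%s;consensus=%s;n_loci=%d", sc, consensus,
                nrow(block))))
    }
  }
  out
}

#' Call translocated gene blocks against the ancestral order
#'
#' Within each scaffold group, a maximal terminal block of labels that is
#' contiguous in the ancestral order but sits at the wrong end of the
#' arrangement — the anterior-most labels positioned after every other gene
#' (beyond AbdB), or the posterior-most labels positioned before every other
#' gene (before lab) — is reported as one translocation. The flanking
#' ancestral adjacencies of such a block are necessarily broken. Separately,
#' a Hox locus alone on a scaffold while at least two cluster genes are
#' co-scaffold elsewhere is reported as a `scaffold_translocation`, provided
#' its ancestral neighbours (restricted to present labels) are observed
#' adjacent on a common other scaffold — the signature that the gene left a
#' gap behind, distinguishing the event from a plain cluster split.
#'
#' @param model A `hox_cluster_model`.
#' @param ancestral Reference order.
#' @return Event data.frame (kinds `translocation`, `scaffold_translocation`).
#' @export
call_translocations <- function(model, ancestral = ancestral_order()) {
  out <- .empty_events()
  groups <- model$scaffold_groups
  ## positional translocations within multi-gene groups
  for (sc in names(groups)) {
    lo <- .group_label_order(groups[[sc]])
    obs <- lo$label
    if (length(obs) < 3L) next
    ## rank labels within the ancestral order restricted to THIS group, so
    ## that losses or genes residing on other scaffolds do not fake broken
    ## adjacencies inside the group
    group_present <- ancestral[ancestral %in% obs]
    anc <- match(obs, group_present)
    n <- length(obs)
    ## longest terminal block that is ancestrally contiguous, sits at the
    ## wrong end relative to the remaining genes, and has its flanking
    ## observed adjacency broken (a reversed-in-place block keeps an
    ## ancestral adjacency at its inner flank and is therefore excluded)
    suffix_block <- NULL
    for (k in seq_len(n - 1L)) {
      s <- anc[(k + 1L):n]; rest <- anc[1:k]
      boundary_anc <- abs(anc[k] - anc[k + 1L]) == 1L
      if (.is_contiguous(s) && max(rest) > max(s) && !boundary_anc) {
        suffix_block <- s
        break
      }
    }
    prefix_block <- NULL
    for (k in (n - 1L):1L) {
      s <- anc[1:k]; rest <- anc[(k + 1L):n]
      boundary_anc <- abs(anc[k] - anc[k + 1L]) == 1L
      if (.is_contiguous(s) && min(rest) < min(s) && !boundary_anc) {
        prefix_block <- s
        break
      }
    }
    ## a block at one end is equivalently "the complement at the other end";
    ## keep the more parsimonious (smaller) description
    if (!is.null(suffix_block) && !is.null(prefix_block) &&
        length(suffix_block) + length(prefix_block) == n) {
      if (length(prefix_block) < length(suffix_block)) suffix_block <- NULL
      else prefix_block <- NULL
    }
    if (!is.null(suffix_block))
      out <- rbind(out, .event_row(
        model$species, "translocation", group_present[sort(suffix_block)],
        sprintf("scaffold=%s;block_at=posterior_end", sc)))
    if (!is.null(prefix_block))
      out <- rbind(out, .event_row(
        model$species, "translocation", group_present[sort(prefix_block)],
        sprintf("scaffold=%s;block_at=anterior_end", sc)))
  }
  ## scaffold translocations: singleton groups with a closed gap elsewhere
  n_canon <- vapply(groups, function(g) sum(g$label %in% HOX_CLASSES),
                    integer(1L))
  multi <- names(groups)[n_canon >= 2L]
  for (sc in names(groups)[n_canon == 1L]) {
    g <- groups[[sc]]
    gene <- g$label[g$label %in% HOX_CLASSES][1L]
    if (!length(multi)) next
    present <- ancestral[ancestral %in% unlist(lapply(groups, `[[`, "label"))]
    i <- match(gene, present)
    if (is.na(i) || i == 1L || i == length(present)) next
    left <- present[i - 1L]; right <- present[i + 1L]
    closed <- any(vapply(multi, function(m) {
      obs <- .group_label_order(groups[[m]])$label
      li <- match(left, obs); ri <- match(right, obs)
      !is.na(li) && !is.na(ri) && abs(li - ri) == 1L
    }, logical(1L)))
    if (closed)
      out <- rbind(out, .event_row(
        model$species, "scaffold_translocation", gene,
        sprintf("scaffold=%s;gap_closed_between=%s,%s", sc, left, right)))
  }
  out
}

.is_contiguous <- function(idx) {
  length(idx) && (max(idx) - min(idx) + 1L) == length(idx)
}

#' Call tandem duplications and losses
#'
#' At least two same-label loci on one scaffold, spanning no more than
#' `window_bp` and with no different-label Hox locus intervening, form one
#' tandem duplication (copy count reported). Same-label copies failing the
#' window or contiguity condition are reported as a `dispersed` low-confidence
#' duplication note instead. Any ancestral label with zero loci is a loss,
#' always flagged `needs-verification` since absence from a single assembly
#' is weak evidence.
#'
#' @param loci A `hox_loci` data frame (one species).
#' @param ancestral Reference order.
#' @param window_bp Tandem window (default 1 Mb): wide enough to hold the
#'   large lepidopteran Shx arrays, narrow enough to exclude dispersed
#'   copies.
#' @return Event data.frame (kinds `tandem_duplication`, `loss`).
#' @export
call_tandem_duplications_and_losses <- function(loci,
                                                ancestral = ancestral_order(),
                                                window_bp =
                                                  hox_run_config()$tandem_window_bp) {
  out <- .empty_events()
  species <- if (nrow(loci)) loci$species[1L] else "unknown"
  canon <- loci[loci$label %in% ancestral, , drop = FALSE]
  for (lab in unique(canon$label)) {
    rows <- canon[canon$label == lab, , drop = FALSE]
    if (nrow(rows) < 2L) next
    tandem <- FALSE
    if (length(unique(rows$scaffold)) == 1L) {
      span_ok <- (max(rows$end) - min(rows$start)) <= window_bp
      within <- canon[canon$scaffold == rows$scaffold[1L] &
                        canon$start >= min(rows$start) &
                        canon$end <= max(rows$end), , drop = FALSE]
      contiguous <- all(within$label == lab)
      tandem <- span_ok && contiguous
    }
    if (tandem) {
      out <- rbind(out, .event_row(
        species, "tandem_duplication", lab,
        sprintf("copies=%d;scaffold=%s;array_span_bp=%d", nrow(rows),
                rows$scaffold[1L], max(rows$end) - min(rows$start))))
    } else {
      out <- rbind(out, .event_row(
        species, "tandem_duplication", lab,
        sprintf("copies=%d;dispersed", nrow(rows)),
        confidence = "low"))
    }
  }
  for (lab in setdiff(ancestral, canon$label)) {
    out <- rbind(out, .event_row(species, "loss", lab,
                                 "no locus detected in assembly",
                                 confidence = "needs-verification"))
  }
  out
}

#' Call all structural events for one species
#'
#' Orchestrates the event callers against the ancestral ten-gene order:
#' scaffold translocations and positional translocations first, then cluster
#' splits (from the model's split points, excluding ancestral pairs that
#' involve a translocated gene — their displacement is already explained),
#' strand-based block inversions, and tandem duplications/losses. Orientation
#' evidence is reported independently of positional evidence, so one
#' physical block may legitimately yield both an inversion and a
#' translocation call.
#'
#' @param model A `hox_cluster_model`.
#' @param loci The `hox_loci` the model was built from.
#' @param ancestral Reference order.
#' @param config A [hox_run_config()].
#' @return Event data.frame with columns species, kind, genes, evidence,
#'   confidence, ordered by kind then genes.
#' @export
call_events <- function(model, loci, ancestral = ancestral_order(),
                        config = hox_run_config()) {
  trans <- call_translocations(model, ancestral)
  moved <- unique(unlist(strsplit(trans$genes, ",")))
  splits <- model$split_points
  if (nrow(splits)) {
    keep <- !(splits$left_gene %in% moved | splits$right_gene %in% moved)
    splits <- splits[keep, , drop = FALSE]
  }
  split_events <- if (nrow(splits)) do.call(rbind, lapply(
    seq_len(nrow(splits)), function(i) .event_row(
      model$species, "split",
      c(splits$left_gene[i], splits$right_gene[i]),
      sprintf("reason=%s;distance_bp=%s", splits$reason[i],
              ifelse(is.na(splits$distance[i]), "NA",
                     format(splits$distance[i], scientific = FALSE)))))
  ) else .empty_events()
  inv <- call_inversions(model)
  dl <- call_tandem_duplications_and_losses(loci, ancestral,
                                            config$tandem_window_bp)
  ev <- rbind(split_events, inv, trans, dl)
  kind_order <- c("split", "inversion", "translocation",
                  "scaffold_translocation", "tandem_duplication", "loss")
  ev <- ev[order(match(ev$kind, kind_order), ev$genes), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Cross-species event count matrix
#'
#' @param events_list Named list of per-species event data.frames.
#' @return Integer matrix species x event kind.
#' @export
event_matrix <- function(events_list) {
  kinds <- c("split", "inversion", "translocation",
             "scaffold_translocation", "tandem_duplication", "loss")
  m <- t(vapply(events_list, function(ev)
    vapply(kinds, function(k) sum(ev$kind == k), integer(1L)),
    integer(length(kinds))))
  colnames(m) <- kinds
  m
}
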