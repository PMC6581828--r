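#' Assign candidate target genes to peaks
#'
#' A gene is a target of a peak if it overlaps the peak (distance 0), or if
#' the gap between their nearest edges is at most `max_distance` (inclusive)
#' and no other annotated gene span intersects the open genomic interval
#' strictly between those facing edges. Distances are edge-to-edge and
#' strand-agnostic; any overlap with the peak makes a gene a target
#' regardless of other genes. Each gene is reported once with its minimum
#' distance over supporting peaks.
#'
#' @param peaks Peak data.frame with `peak_id`, `chrom`, `start`, `end`.
#' @param genes Gene data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param max_distance Maximum edge-to-edge gap in bp (default 5000).
#' @param context Optional cell-context label recorded per target.
#' @return data.frame with one row per target gene: `gene_id`, `distance`
#'   (bp, 0 if overlapping), `n_peaks`, `peak_ids` (comma-separated),
#'   `context`.
#' @export
assign_targets <- function(peaks, genes, max_distance = 5000, context = NA_character_) {
  hits <- list()
  for (k in seq_len(nrow(peaks))) {
    ps <- peaks$start[k]; pe <- peaks$end[k]
    g <- genes[genes$chrom == peaks$chrom[k], , drop = FALSE]
    if (nrow(g) == 0L) next
    overlap <- g$start <= pe & g$end >= ps
    # gap between nearest edges for non-overlapping genes
    gap <- ifelse(g$start > pe, g$start - pe - 1L,
                  ifelse(g$end < ps, ps - g$end - 1L, 0L))
    cand <- overlap | gap <= max_distance
    for (i in which(cand)) {
      ok <- TRUE
      if (!overlap[i]) {
        # open interval strictly between the facing edges
        if (g$start[i] > pe) { lo <- pe + 1L; hi <- g$start[i] - 1L }
        else { lo <- g$end[i] + 1L; hi <- ps - 1L }
        if (lo <= hi) {
          others <- g[-i, , drop = FALSE]
          ok <- !any(others$start <= hi & others$end >= lo)
        }
      }
      if (ok) {
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id = g$gene_id[i],
          distance = if (overlap[i]) 0L else as.integer(gap[i]),
          peak_id = peaks$peak_id[k], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(gene_id = character(0), distance = integer(0),
                      n_peaks = integer(0), peak_ids = character(0),
                      context = character(0), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hits)
  ids <- sort(unique(h$gene_id))
  out <- data.frame(
    gene_id = ids,
    distance = vapply(ids, function(id) min(h$distance[h$gene_id == id]), integer(1L)),
    n_peaks = vapply(ids, function(id) length(unique(h$peak_id[h$gene_id == id])), integer(1L)),
    peak_ids = vapply(ids, function(id)
      paste(sort(unique(h$peak_id[h$gene_id == id])), collapse = ","), character(1L)),
    context = context, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Exhaustive reference implementation of target assignment
#'
#' Same contract as [assign_targets()], computed by brute force over every
#' (peak, gene, other-gene) triple. Used to generate planted ground truth in
#' the synthetic module and as an independent check of the main
#' implementation; kept deliberately simple.
#'
#' @inheritParams assign_targets
#' @return Same shape as [assign_targets()].
#' @export
assign_targets_bruteforce <- function(peaks, genes, max_distance = 5000,
                                      context = NA_character_) {
  recs <- list()
  for (k in seq_len(nrow(peaks))) {
    for (i in seq_len(nrow(genes))) {
      if (genes$chrom[i] != peaks$chrom[k]) next
      ps <- peaks$start[k]; pe <- peaks$end[k]
      gs <- genes$start[i]; ge <- genes$end[i]
      if (gs <= pe && ge >= ps) {
        recs[[length(recs) + 1L]] <- list(gene = genes$gene_id[i], d = 0L,
                                          peak = peaks$peak_id[k])
        next
      }
      gap <- if (gs > pe) gs - pe - 1L else ps - ge - 1L
      if (gap > max_distance) next
      lo <- if (gs > pe) pe + 1L else ge + 1L
      hi <- if (gs > pe) gs - 1L else ps - 1L
      blocked <- FALSE
      for (j in seq_len(nrow(genes))) {
        if (j == i || genes$chrom[j] != peaks$chrom[k]) next
        if (lo <= hi && genes$start[j] <= hi && genes$end[j] >= lo) {
          blocked <- TRUE
          break
        }
      }
      if (!blocked) {
        recs[[length(recs) + 1L]] <- list(gene = genes$gene_id[i],
                                          d = as.integer(gap),
                                          peak = peaks$peak_id[k])
      }
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(gene_id = character(0), distance = integer(0),
                      n_peaks = integer(0), peak_ids = character(0),
                      context = character(0), stringsAsFactors = FALSE))
  }
  gene <- vapply(recs, `[[`, character(1L), "gene")
  d <- vapply(recs, `[[`, integer(1L), "d")
  pk <- vapply(recs, `[[`, character(1L), "peak")
  ids <- sort(unique(gene))
  data.frame(
    gene_id = ids,
    distance = vapply(ids, function(id) min(d[gene == id]), integer(1L)),
    n_peaks = vapply(ids, function(id) length(unique(pk[gene == id])), integer(1L)),
    peak_ids = vapply(ids, function(id)
      paste(sort(unique(pk[gene == id])), collapse = ","), character(1L)),
    context = context, stringsAsFactors = FALSE, row.names = NULL)
}

#' Count distinct target genes
#'
#' @param targets Target table from [assign_targets()].
#' @return Number of distinct gene ids.
#' @export
count_unique_targets <- function(targets) {
  length(unique(targets$gene_id))
}

#' Write a target table to TSV
#' @param targets Target table.
#' @param path Output path.
#' @export
write_targets_tsv <- function(targets, path) {
  utils::write.table(targets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
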