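normalize_gene_ids <- function(ids, ignore_case = FALSE) {
  ids <- trimws(as.character(ids))
  if (ignore_case) ids <- toupper(ids)
  ids[ids != ""]
}

#' Summarize bound genes by transcription state
#'
#' Intersects the bound (TaDa target) gene set with the transcribed gene set
#' by gene id and reports the fraction of bound genes that are actively
#' transcribed, both exactly and rounded to the nearest percent.
#'
#' @param targets Target table from [assign_targets()] (or a character vector
#'   of bound gene ids).
#' @param calls Transcript call table from [call_transcribed()] (or a
#'   character vector of transcribed gene ids).
#' @param context Cell-context label (e.g. "ISC/EB", "EC").
#' @return A `bound_gene_summary`: list with `context`, `n_bound`,
#'   `n_transcribed_bound`, `fraction` (exact), `percent` (rounded),
#'   `genes` (the bound-and-transcribed ids).
#' @export
summarize_bound_transcribed <- function(targets, calls, context = NA_character_) {
  bound <- if (is.character(targets)) targets else targets$gene_id
  transcribed <- if (is.character(calls)) calls else calls$gene_id[calls$transcribed]
  bound <- unique(normalize_gene_ids(bound))
  transcribed <- unique(normalize_gene_ids(transcribed))
  both <- intersect(bound, transcribed)
  frac <- if (length(bound)) length(both) / length(bound) else 0
  structure(list(context = context,
                 n_bound = length(bound),
                 n_transcribed_bound = length(both),
                 fraction = frac,
                 percent = round(100 * frac),
                 genes = sort(both)),
            class = "bound_gene_summary")
}

#' @export
print.bound_gene_summary <- function(x, ...) {
  cat(x$n_bound, " bound genes (", x$context, "); ",
      x$n_transcribed_bound, " transcribed (", x$percent, "%)\n", sep = "")
  invisible(x)
}

#' Union of bound-and-transcribed genes across cell contexts
#'
#' @param summaries List of `bound_gene_summary` objects (one per context).
#' @return Sorted character vector: genes bound and transcribed in at least
#'   one context.
#' @export
union_bound_transcribed <- function(summaries) {
  sort(unique(unlist(lapply(summaries, function(s) s$genes))))
}

#' Top-N bound genes by a ranking statistic
#'
#' Deterministic ranking: descending score, ties broken by lexicographic
#' gene id. The default statistic is the strongest supporting-peak mean
#' log2 ratio.
#'
#' @param targets Target table with a score column.
#' @param n Number of genes to return (default 250); fewer if unavailable.
#' @param score Numeric vector of ranking scores aligned with `targets`
#'   rows, or the name of a column of `targets`.
#' @param decreasing Rank high scores first (default TRUE; set FALSE for
#'   e.g. minimum-FDR ranking).
#' @return Character vector of gene ids, best first.
#' @export
top_n_bound <- function(targets, n = 250L, score = "max_peak_ratio",
                        decreasing = TRUE) {
  if (is.character(score) && length(score) == 1L) {
    if (!score %in% names(targets)) {
      stop("score column '", score, "' not found in targets")
    }
    score <- targets[[score]]
  }
  stopifnot(length(score) == nrow(targets))
  key <- if (decreasing) -rank(score, ties.method = "min") else
    rank(score, ties.method = "min")
  ord <- order(key, targets$gene_id)
  utils::head(targets$gene_id[ord], n)
}

#' Intersect gene lists with Venn counts
#'
#' Exact set intersection after id normalization (whitespace trimming,
#' optional case folding), with all pairwise and overall overlap counts.
#'
#' @param lists Named list of character vectors of gene ids.
#' @param ignore_case Case-fold ids before comparing (default FALSE).
#' @return List with `intersection` (sorted ids common to all lists),
#'   `n_intersection`, `sizes`, and `pairwise` (matrix of pairwise overlap
#'   counts).
#' @export
intersect_gene_lists <- function(lists, ignore_case = FALSE) {
  if (is.null(names(lists)) || any(names(lists) == "")) {
    names(lists) <- paste0("list", seq_along(lists))
  }
  sets <- lapply(lists, function(x) unique(normalize_gene_ids(x, ignore_case)))
  common <- Reduce(intersect, sets)
  k <- length(sets)
  pw <- matrix(NA_integer_, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  list(intersection = sort(common),
       n_intersection = length(common),
       sizes = vapply(sets, length, integer(1L)),
       pairwise = pw)
}

#' Read a one-id-per-line gene list
#' @param path TSV/plain file, one gene id per line.
#' @return Character vector of ids (trimmed, empties dropped).
#' @export
read_gene_list <- function(path) {
  normalize_gene_ids(readLines(path))
}

#' Write a gene list, one id per line
#' @param ids Character vector.
#' @param path Output path.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
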