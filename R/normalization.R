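#' Normalize fusion against Dam-only counts into a log2 ratio track
#'
#' Per fragment i the normalized log2 ratio is
#' `log2((fusion_i/F + p) / (dam_i/D + p))` with `F`, `D` the library sizes
#' (total counts) and `p` a pseudocount on the normalized (fraction) scale.
#' The symmetric pseudocount keeps every value finite and makes the operation
#' exactly antisymmetric in its two arguments.
#'
#' @param fusion,dam `count_track`s indexed on the same fragment map.
#' @param map The shared `gatc_map`.
#' @param pseudocount Positive pseudocount on the library-normalized scale
#'   (default `1e-6`, roughly one read in a million).
#' @param sample_id,replicate Identifiers for the returned track (default the
#'   fusion library id).
#' @return A `ratio_track`.
#' @export
normalize_ratio <- function(fusion, dam, map, pseudocount = 1e-6,
                            sample_id = fusion$library_id, replicate = 1L) {
  stopifnot(inherits(fusion, "count_track"), inherits(dam, "count_track"))
  if (length(fusion$counts) != length(dam$counts)) {
    stop("fusion and dam tracks are indexed on different fragment maps")
  }
  validate_track_on_map(fusion$counts, map)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (fusion$lib_size == 0 || dam$lib_size == 0) {
    stop("zero library size")
  }
  vals <- log2((fusion$counts / fusion$lib_size + pseudocount) /
               (dam$counts / dam$lib_size + pseudocount))
  ratio_track(vals, map, sample_id = sample_id, replicate = replicate)
}

#' Replicate quality control by pairwise rank correlation
#'
#' Computes the pairwise Spearman correlation matrix between replicate ratio
#' tracks and flags noisy replicates by greedy peeling: while more than two
#' replicates remain unflagged, the replicate with the lowest median
#' correlation to the other unflagged replicates is flagged if that median
#' falls below `min_correlation`. With only two replicates a low correlation
#' cannot be attributed to either one, so nothing is flagged automatically
#' (the matrix is still reported). Flagged replicates should be excluded
#' from consensus peak formation and replicate combination, mirroring the
#' practice of dropping the replicate that disagrees with an otherwise
#' concordant set.
#'
#' @param tracks List of at least two `ratio_track`s on the same map.
#' @param min_correlation Threshold on the median pairwise Spearman
#'   correlation (default 0.6); always recorded in the report.
#' @param sample_id Label for the report.
#' @return A `qc_report`: list with `correlations` (symmetric matrix, unit
#'   diagonal), `flagged` (replicate ids), `min_correlation`, `sample_id`.
#' @export
replicate_qc <- function(tracks, min_correlation = 0.6,
                         sample_id = tracks[[1L]]$sample_id) {
  if (length(tracks) < 2L) stop("replicate QC needs at least 2 replicates")
  n <- length(tracks[[1L]]$values)
  if (!all(vapply(tracks, function(t) length(t$values) == n, logical(1L)))) {
    stop("replicate tracks have differing numbers of fragments")
  }
  reps <- vapply(tracks, function(t) t$replicate, integer(1L))
  mat <- vapply(tracks, function(t) t$values, numeric(n))
  colnames(mat) <- paste0("rep", reps)
  cors <- stats::cor(mat, method = "spearman")
  med_among <- function(active) {
    vapply(active, function(i)
      stats::median(cors[i, setdiff(active, i)]), numeric(1L))
  }
  active <- seq_along(tracks)
  flagged_idx <- integer(0)
  while (length(active) > 2L) {
    meds <- med_among(active)
    worst <- which.min(meds)
    if (meds[worst] >= min_correlation) break
    flagged_idx <- c(flagged_idx, active[worst])
    active <- active[-worst]
  }
  med <- stats::setNames(rep(NA_real_, length(tracks)), colnames(cors))
  med[active] <- med_among(active)
  structure(list(sample_id = sample_id, correlations = cors,
                 median_correlation = med,
                 flagged = reps[flagged_idx],
                 min_correlation = min_correlation),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Replicate QC for '", x$sample_id, "' (min median Spearman rho ",
      x$min_correlation, ")\n", sep = "")
  print(round(x$correlations, 3))
  if (length(x$flagged)) {
    cat("flagged replicates:", paste(x$flagged, collapse = ", "), "\n")
  } else {
    cat("no replicates flagged\n")
  }
  invisible(x)
}

#' Drop QC-flagged replicates from a track list
#'
#' @param tracks List of `ratio_track`s.
#' @param qc A `qc_report` from [replicate_qc()].
#' @return The tracks whose replicate ids were not flagged.
#' @export
keep_qc_passing <- function(tracks, qc) {
  keep <- vapply(tracks, function(t) !(t$replicate %in% qc$flagged), logical(1L))
  tracks[keep]
}
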