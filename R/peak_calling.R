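# Maximal runs of values > threshold within one arm.
# Returns first/last 0-based ordinals, run length and mean for runs >= min_len.
positive_runs <- function(values, threshold = 0, min_len = 2L) {
  pos <- values > threshold
  if (!any(pos)) {
    return(list(first = integer(0), last = integer(0),
                n = integer(0), mean = numeric(0)))
  }
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  firsts <- starts[keep]
  lasts <- ends[keep]
  cs <- c(0, cumsum(values))
  means <- (cs[lasts + 1L] - cs[firsts]) / (lasts - firsts + 1L)
  list(first = firsts - 1L, last = lasts - 1L,
       n = lasts - firsts + 1L, mean = means)
}

empty_peaks <- function() {
  data.frame(peak_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0),
             frag_first = integer(0), frag_last = integer(0),
             n_fragments = integer(0), mean_ratio = numeric(0),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate binding peaks
#'
#' Candidate peaks are maximal runs of two or more consecutive GATC fragments
#' whose log2 ratio exceeds the per-fragment seeding threshold (default 0).
#' Runs never cross arm boundaries. Each candidate is annotated with its
#' fragment span (0-based ordinals within the arm), genomic span, and the
#' mean log2 ratio over its fragments.
#'
#' @param track A `ratio_track`.
#' @param map The `gatc_map` it is indexed on.
#' @param min_fragment_ratio Per-fragment seeding threshold (default 0).
#' @return data.frame of candidate peaks (possibly empty) ordered by genomic
#'   position: `peak_id`, `chrom`, `start`, `end`, `frag_first`, `frag_last`,
#'   `n_fragments`, `mean_ratio`.
#' @export
enumerate_candidate_peaks <- function(track, map, min_fragment_ratio = 0) {
  validate_track_on_map(track$values, map)
  rows_by_arm <- map_arm_rows(map)
  out <- lapply(names(rows_by_arm), function(arm) {
    rows <- rows_by_arm[[arm]]
    runs <- positive_runs(track$values[rows], threshold = min_fragment_ratio)
    if (length(runs$first) == 0L) return(NULL)
    data.frame(chrom = arm,
               start = map$start[rows[runs$first + 1L]],
               end = map$end[rows[runs$last + 1L]],
               frag_first = runs$first, frag_last = runs$last,
               n_fragments = runs$n, mean_ratio = runs$mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty_peaks())
  out <- out[order(match(out$chrom, map_arms(map)), out$start), , drop = FALSE]
  out <- cbind(peak_id = sprintf("peak_%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Tail-count matrix over (length >= L, mean >= r) for a set of runs.
# lengths capped at max(len_grid); ratio bins from findInterval on ratio_grid.
tail_counts <- function(n_frag, mean_ratio, len_max, ratio_grid) {
  nl <- len_max - 1L          # lengths 2..len_max
  nr <- length(ratio_grid)
  m <- matrix(0, nrow = nl, ncol = nr)
  if (length(n_frag)) {
    li <- pmin(n_frag, len_max) - 1L           # 1..nl
    ri <- findInterval(mean_ratio, ratio_grid) # 0..nr
    keep <- ri >= 1L
    if (any(keep)) {
      tab <- table(factor(li[keep], levels = seq_len(nl)),
                   factor(ri[keep], levels = seq_len(nr)))
      m <- matrix(as.numeric(tab), nrow = nl, ncol = nr)
    }
  }
  # reverse cumulative in both dimensions: count of runs with len >= L, mean >= r
  m <- apply(m, 2L, function(col) rev(cumsum(rev(col))))
  if (is.null(dim(m))) m <- matrix(m, nrow = nl)
  t(apply(m, 1L, function(row) rev(cumsum(rev(row)))))
}

#' Permutation-based FDR table for candidate peaks
#'
#' Estimates, for each (peak length, mean-ratio threshold) grid cell, the
#' expected number of equal-or-better peaks (length >= L and mean >= r) under
#' a null in which fragment ratios are permuted within each chromosome arm —
#' preserving the value multiset and the fragment geometry while destroying
#' spatial contiguity. The cell FDR is the ratio of the expected null count
#' to the observed count, clipped to \[0, 1\] and monotonized to be
#' non-increasing in the ratio threshold at fixed length.
#'
#' @param track A `ratio_track` (one replicate).
#' @param map Its `gatc_map`.
#' @param candidates Candidate peaks from [enumerate_candidate_peaks()].
#' @param n_shuffles Number of arm-wise permutations (default 100).
#' @param seed Integer seed; results are deterministic given it.
#' @param ratio_step Grid step for the mean-ratio dimension (default 0.05).
#' @param min_fragment_ratio Seeding threshold used for the candidates.
#' @return A `peak_fdr_table`: list with `fdr`, `expected`, `observed`
#'   matrices over `lengths` x `ratio_grid`, plus `n_shuffles` and `seed`.
#'   Empty candidates give an empty table.
#' @export
estimate_peak_fdr <- function(track, map, candidates, n_shuffles = 100L,
                              seed, ratio_step = 0.05,
                              min_fragment_ratio = 0) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  if (missing(seed)) stop("seed is required")
  if (nrow(candidates) == 0L) {
    return(structure(list(fdr = NULL, expected = NULL, observed = NULL,
                          lengths = integer(0), ratio_grid = numeric(0),
                          n_shuffles = n_shuffles, seed = seed),
                     class = "peak_fdr_table"))
  }
  len_max <- max(candidates$n_fragments)
  r_max <- max(candidates$mean_ratio)
  ratio_grid <- seq(0, ceiling(r_max / ratio_step) * ratio_step,
                    by = ratio_step)
  obs <- tail_counts(candidates$n_fragments, candidates$mean_ratio,
                     len_max, ratio_grid)
  rows_by_arm <- map_arm_rows(map)
  null_sum <- matrix(0, nrow = len_max - 1L, ncol = length(ratio_grid))
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      nulls_n <- integer(0)
      nulls_m <- numeric(0)
      for (rows in rows_by_arm) {
        perm <- sample(track$values[rows])
        runs <- positive_runs(perm, threshold = min_fragment_ratio)
        nulls_n <- c(nulls_n, runs$n)
        nulls_m <- c(nulls_m, runs$mean)
      }
      null_sum <- null_sum + tail_counts(nulls_n, nulls_m, len_max, ratio_grid)
    }
  })
  expected <- null_sum / n_shuffles
  fdr <- expected / pmax(obs, 1)
  fdr[obs == 0] <- 1
  fdr <- pmin(fdr, 1)
  # enforce non-increasing FDR in the ratio threshold at fixed length
  fdr <- t(apply(fdr, 1L, cummin))
  dimnames(fdr) <- dimnames(expected) <- dimnames(obs) <-
    list(length = as.character(2:len_max), ratio = format(ratio_grid))
  structure(list(fdr = fdr, expected = expected, observed = obs,
                 lengths = 2:len_max, ratio_grid = ratio_grid,
                 n_shuffles = n_shuffles, seed = seed),
            class = "peak_fdr_table")
}

#' Look up per-candidate FDRs in a permutation table
#'
#' @param candidates Candidate peaks.
#' @param fdr_table A `peak_fdr_table` built from the same candidates' track.
#' @return `candidates` with an `fdr` column.
#' @export
assign_peak_fdr <- function(candidates, fdr_table) {
  if (nrow(candidates) == 0L) {
    candidates$fdr <- numeric(0)
    return(candidates)
  }
  if (is.null(fdr_table$fdr)) stop("empty FDR table for non-empty candidates")
  len_max <- max(fdr_table$lengths)
  li <- pmin(candidates$n_fragments, len_max) - 1L
  ri <- findInterval(candidates$mean_ratio, fdr_table$ratio_grid)
  ri <- pmin(pmax(ri, 1L), length(fdr_table$ratio_grid))
  candidates$fdr <- fdr_table$fdr[cbind(li, ri)]
  candidates
}

#' Call significant peaks within one replicate
#'
#' Keeps candidates with permutation FDR below `max_fdr` (default 1%) and
#' mean log2 ratio of at least `min_mean_ratio` (default 0.3), ordered by
#' genomic position.
#'
#' @param candidates Candidate peaks (with an `fdr` column, or supply
#'   `fdr_table` to have it filled in).
#' @param fdr_table Optional `peak_fdr_table` used to assign FDRs first.
#' @param max_fdr FDR cutoff, strict (default 0.01).
#' @param min_mean_ratio Mean log2 ratio threshold, inclusive (default 0.3).
#' @return data.frame of significant peaks.
#' @export
call_peaks_replicate <- function(candidates, fdr_table = NULL,
                                 max_fdr = 0.01, min_mean_ratio = 0.3) {
  if (!is.null(fdr_table)) candidates <- assign_peak_fdr(candidates, fdr_table)
  if (is.null(candidates$fdr)) stop("candidates carry no 'fdr' column")
  keep <- candidates$fdr < max_fdr & candidates$mean_ratio >= min_mean_ratio
  out <- candidates[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# global map row indices covered by a peak data.frame
peak_fragment_rows <- function(peaks, map) {
  rows_by_arm <- map_arm_rows(map)
  idx <- integer(0)
  for (k in seq_len(nrow(peaks))) {
    rows <- rows_by_arm[[peaks$chrom[k]]]
    idx <- c(idx, rows[(peaks$frag_first[k]:peaks$frag_last[k]) + 1L])
  }
  idx
}

#' Consensus peaks across replicates
#'
#' A consensus peak is a maximal run of GATC fragments each of which is
#' covered by a significant peak in every replicate; equivalently, replicate
#' peaks must share at least one fragment, and the consensus span is the
#' intersection of the overlapping replicate spans. The consensus mean ratio
#' is the mean over replicates of their overlapping peaks' means, and the
#' consensus FDR is the maximum over all contributing replicate peaks
#' (conservative combination).
#'
#' @param per_replicate List (one element per QC-passing replicate) of
#'   significant peak data.frames from [call_peaks_replicate()].
#' @param map The shared `gatc_map`.
#' @return data.frame of consensus peaks with `fdr` column.
#' @export
consensus_peaks <- function(per_replicate, map) {
  if (length(per_replicate) == 0L) stop("no replicate peak lists supplied")
  covered <- rep(TRUE, nrow(map))
  for (peaks in per_replicate) {
    cov_r <- rep(FALSE, nrow(map))
    cov_r[peak_fragment_rows(peaks, map)] <- TRUE
    covered <- covered & cov_r
  }
  rows_by_arm <- map_arm_rows(map)
  res <- list()
  for (arm in names(rows_by_arm)) {
    rows <- rows_by_arm[[arm]]
    cov <- covered[rows]
    if (!any(cov)) next
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      f0 <- starts[k] - 1L
      f1 <- ends[k] - 1L
      # replicate peaks overlapping this fragment run
      means <- vapply(per_replicate, function(peaks) {
        sel <- peaks$chrom == arm & peaks$frag_first <= f1 & peaks$frag_last >= f0
        mean(peaks$mean_ratio[sel])
      }, numeric(1L))
      fdrs <- unlist(lapply(per_replicate, function(peaks) {
        sel <- peaks$chrom == arm & peaks$frag_first <= f1 & peaks$frag_last >= f0
        peaks$fdr[sel]
      }))
      res[[length(res) + 1L]] <- data.frame(
        chrom = arm,
        start = map$start[rows[f0 + 1L]], end = map$end[rows[f1 + 1L]],
        frag_first = f0, frag_last = f1, n_fragments = f1 - f0 + 1L,
        mean_ratio = mean(means),
        fdr = if (length(fdrs)) max(fdrs) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    out <- empty_peaks()
    out$fdr <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$chrom, map_arms(map)), out$start), , drop = FALSE]
  out <- cbind(peak_id = sprintf("consensus_%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-fragment seeding threshold from a track quantile
#'
#' Candidate peaks seeded from all positive fragments get extended by
#' flanking noise fragments, which dilutes their mean ratio; seeding from
#' the upper tail of the ratio distribution (default the 0.95 quantile, the
#' convention of published DamID peak finders) keeps candidate runs tight
#' around genuinely enriched fragments.
#'
#' @param track A `ratio_track`.
#' @param seed_quantile Quantile of the track values (default 0.95).
#' @return The threshold value.
#' @export
peak_seed_threshold <- function(track, seed_quantile = 0.95) {
  unname(stats::quantile(track$values, seed_quantile))
}

#' Replicate peak calling and consensus in one step
#'
#' For each replicate: seed candidates at the track's `seed_quantile`
#' threshold, estimate permutation FDRs, and keep peaks with FDR below
#' `max_fdr` and mean log2 ratio of at least `min_mean_ratio`; then
#' intersect the replicate calls into consensus peaks.
#'
#' @param tracks List of QC-passing `ratio_track`s.
#' @param map The shared `gatc_map`.
#' @param seed Base seed; replicate k shuffles with `seed + k`.
#' @param n_shuffles Permutations per replicate (default 100).
#' @param seed_quantile Candidate seeding quantile (default 0.95).
#' @param max_fdr,min_mean_ratio Significance thresholds (defaults 0.01, 0.3).
#' @param ratio_step FDR grid step (default 0.05).
#' @return List with `per_replicate` (significant peak data.frames) and
#'   `consensus`.
#' @export
call_peaks <- function(tracks, map, seed, n_shuffles = 100L,
                       seed_quantile = 0.95, max_fdr = 0.01,
                       min_mean_ratio = 0.3, ratio_step = 0.05) {
  per_replicate <- lapply(seq_along(tracks), function(r) {
    thr <- peak_seed_threshold(tracks[[r]], seed_quantile)
    cand <- enumerate_candidate_peaks(tracks[[r]], map, min_fragment_ratio = thr)
    tab <- estimate_peak_fdr(tracks[[r]], map, cand, n_shuffles = n_shuffles,
                             seed = seed + r, ratio_step = ratio_step,
                             min_fragment_ratio = thr)
    call_peaks_replicate(cand, tab, max_fdr = max_fdr,
                         min_mean_ratio = min_mean_ratio)
  })
  list(per_replicate = per_replicate,
       consensus = consensus_peaks(per_replicate, map))
}

#' Export peaks as GFF or BED6
#'
#' GFF records carry the mean log2 ratio in the score column and the FDR as
#' an attribute; BED6 uses 0-based half-open coordinates.
#'
#' @param peaks Peak data.frame.
#' @param path Output path.
#' @param format `"gff"` or `"bed"`.
#' @export
write_peaks <- function(peaks, path, format = c("gff", "bed")) {
  format <- match.arg(format)
  if (nrow(peaks) == 0L) {
    # rtracklayer cannot export empty feature sets with attributes
    writeLines(if (format == "gff") "##gff-version 2" else character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(peaks$start, peaks$end))
  S4Vectors::mcols(gr)$score <- round(peaks$mean_ratio, 6)
  S4Vectors::mcols(gr)$name <- peaks$peak_id
  if (format == "gff") {
    S4Vectors::mcols(gr)$type <- rep("binding_site", length(gr))
    S4Vectors::mcols(gr)$source <- rep("tadacall", length(gr))
    if (!is.null(peaks$fdr)) S4Vectors::mcols(gr)$fdr <- signif(peaks$fdr, 6)
    rtracklayer::export(gr, path, format = "gff2")
  } else {
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}
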