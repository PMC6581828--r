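# Per-arm prefix machinery for length-weighted window means over a
# piecewise-constant ratio track: S(pos) = sum of per-bp ratio up to pos.
arm_prefix <- function(values, starts, ends) {
  lens <- ends - starts + 1L
  list(starts = starts, values = values,
       cumval = c(0, cumsum(values * lens)),
       arm_start = starts[1L], arm_end = ends[length(ends)])
}

prefix_sum_at <- function(pf, pos) {
  # pos may be arm_start - 1 (empty prefix)
  k <- findInterval(pos, pf$starts)
  out <- numeric(length(pos))
  inside <- k >= 1L
  out[inside] <- pf$cumval[k[inside]] +
    pf$values[k[inside]] * (pos[inside] - pf$starts[k[inside]] + 1)
  out
}

window_means <- function(pf, a, b) {
  (prefix_sum_at(pf, b) - prefix_sum_at(pf, a - 1)) / (b - a + 1)
}

track_arm_prefixes <- function(track, map) {
  rows_by_arm <- map_arm_rows(map)
  lapply(rows_by_arm, function(rows)
    arm_prefix(track$values[rows], map$start[rows], map$end[rows]))
}

#' Mean log2 ratio across a transcript
#'
#' Length-weighted mean of fragment ratios over the portion of each GATC
#' fragment overlapping the gene span: each overlapping fragment contributes
#' its ratio weighted by the number of gene bases it covers.
#'
#' @param track A `ratio_track` (e.g. PolII-Dam).
#' @param gene One-row gene data.frame (or list) with `gene_id`, `chrom`,
#'   `start`, `end`.
#' @param map The `gatc_map`.
#' @return The mean log2 ratio (scalar). A gene on an unmapped arm or
#'   covering no fragment is an error.
#' @export
transcript_mean_ratio <- function(track, gene, map) {
  res <- gene_mean_ratios(track,
                          data.frame(gene_id = gene$gene_id, chrom = gene$chrom,
                                     start = gene$start, end = gene$end,
                                     stringsAsFactors = FALSE),
                          map)
  res$mean_ratio[1L]
}

#' Mean log2 ratio for every gene
#'
#' Vectorized version of [transcript_mean_ratio()].
#'
#' @param track A `ratio_track`.
#' @param genes Gene data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @param map The `gatc_map`.
#' @return data.frame `gene_id`, `size`, `mean_ratio`.
#' @export
gene_mean_ratios <- function(track, genes, map) {
  validate_track_on_map(track$values, map)
  pfs <- track_arm_prefixes(track, map)
  n <- nrow(genes)
  out <- numeric(n)
  for (i in seq_len(n)) {
    arm <- genes$chrom[i]
    pf <- pfs[[arm]]
    if (is.null(pf)) stop("gene '", genes$gene_id[i], "' lies on unmapped arm '", arm, "'")
    a <- max(genes$start[i], pf$arm_start)
    b <- min(genes$end[i], pf$arm_end)
    if (a > b) stop("gene '", genes$gene_id[i], "' covers no GATC fragment")
    out[i] <- window_means(pf, a, b)
  }
  data.frame(gene_id = genes$gene_id, size = genes$end - genes$start + 1L,
             mean_ratio = out, stringsAsFactors = FALSE)
}

#' Null frequency table for PolII transcript calling
#'
#' For each chromosome arm the fragment ratios are permuted within the arm
#' (`iterations` times); in each randomized dataset, for each probe size,
#' `samples` windows of that size are placed uniformly at random within the
#' arm, and the frequency of windows whose length-weighted mean ratio meets
#' or exceeds each ratio threshold is recorded. Frequencies are averaged over
#' iterations. The default grids probe ratio thresholds from 0 to 0.75 log2
#' and window sizes from 250 to 2,500 bp, the regime from which the FDR
#' surface is then extrapolated to larger ratios and transcripts.
#'
#' @param track A `ratio_track`.
#' @param map Its `gatc_map`.
#' @param iterations Number of arm-wise permutations (default 10).
#' @param samples Windows sampled per (iteration, size) (default 1000).
#' @param size_grid Window sizes in bp (default 10 log-spaced bins in
#'   \[250, 2500\]). Sizes exceeding an arm are skipped for that arm with a
#'   warning.
#' @param ratio_grid Ratio thresholds (default `seq(0, 0.75, 0.05)`).
#' @param seed Integer seed; output is deterministic given it.
#' @return A `null_freq_table`: `freq` array (arm x size x ratio), `pooled`
#'   matrix (size x ratio, mean over arms), the grids, `iterations`,
#'   `samples`, `seed`.
#' @export
build_null_table <- function(track, map, iterations = 10L, samples = 1000L,
                             size_grid = round(exp(seq(log(250), log(2500),
                                                       length.out = 10L))),
                             ratio_grid = seq(0, 0.75, by = 0.05),
                             seed) {
  if (missing(seed)) stop("seed is required")
  if (!length(size_grid) || !length(ratio_grid)) stop("grids must be non-empty")
  if (is.unsorted(size_grid) || is.unsorted(ratio_grid)) stop("grids must be sorted")
  validate_track_on_map(track$values, map)
  arms <- map_arms(map)
  rows_by_arm <- map_arm_rows(map)
  freq <- array(NA_real_, dim = c(length(arms), length(size_grid), length(ratio_grid)),
                dimnames = list(arm = arms, size = as.character(size_grid),
                                ratio = format(ratio_grid)))
  with_seed(seed, {
    for (arm in arms) {
      rows <- rows_by_arm[[arm]]
      starts <- map$start[rows]; ends <- map$end[rows]
      arm_len <- ends[length(ends)] - starts[1L] + 1L
      valid <- size_grid <= arm_len
      if (!all(valid)) {
        warning("arm '", arm, "' (", arm_len, " bp) shorter than some window sizes; skipped")
      }
      acc <- matrix(0, nrow = length(size_grid), ncol = length(ratio_grid))
      for (it in seq_len(iterations)) {
        perm <- sample(track$values[rows])
        pf <- arm_prefix(perm, starts, ends)
        for (si in which(valid)) {
          s <- size_grid[si]
          a <- pf$arm_start + sample.int(arm_len - s + 1L, samples, replace = TRUE) - 1L
          m <- window_means(pf, a, a + s - 1L)
          acc[si, ] <- acc[si, ] +
            vapply(ratio_grid, function(r) mean(m >= r), numeric(1L))
        }
      }
      f <- acc / iterations
      f[!valid, ] <- NA_real_
      freq[arm, , ] <- f
    }
  })
  pooled <- apply(freq, c(2L, 3L), mean, na.rm = TRUE)
  structure(list(freq = freq, pooled = pooled, size_grid = size_grid,
                 ratio_grid = ratio_grid, iterations = iterations,
                 samples = samples, seed = seed),
            class = "null_freq_table")
}

#' Fit an FDR surface over enrichment and gene size
#'
#' Models the null frequency table as log-linear in the ratio threshold and
#' the log window size, `log f = b0 + b1 * r + b2 * log(s)`, by least squares
#' over the grid cells; cells with zero observed frequency are floored at
#' half the minimum positive frequency so the empty high-ratio tail still
#' informs the fit. The fitted surface extrapolates beyond the training grid
#' (larger ratios, longer transcripts); predictions are clipped to \[0, 1\]
#' and the slope coefficients are constrained non-positive so predictions are
#' monotone non-increasing in both ratio and size.
#'
#' @param table A `null_freq_table`.
#' @param arm Optional arm name; default fits the arm-pooled table.
#' @return An `fdr_surface`: coefficients `b0`, `b1` (per log2 ratio), `b2`
#'   (per log bp), RMSE on the training grid (frequency scale), and the
#'   functional form id. A degenerate all-zero table yields a surface that
#'   predicts 0, with a warning.
#' @export
fit_fdr_surface <- function(table, arm = NULL) {
  f <- if (is.null(arm)) table$pooled else table$freq[arm, , ]
  grid <- expand.grid(s = table$size_grid, r = table$ratio_grid)
  fv <- as.vector(f)
  keep <- !is.na(fv)
  grid <- grid[keep, , drop = FALSE]
  fv <- fv[keep]
  if (!any(fv > 0)) {
    warning("degenerate null table (all zero frequencies); surface predicts 0")
    return(structure(list(coef = c(b0 = -Inf, b1 = 0, b2 = 0), rmse = 0,
                          form = "loglinear", degenerate = TRUE),
                     class = "fdr_surface"))
  }
  floor_val <- min(fv[fv > 0]) / 2
  fv_fit <- pmax(fv, floor_val)
  fit <- stats::lm(log(fv_fit) ~ grid$r + log(grid$s))
  b <- unname(stats::coef(fit))
  if (b[2L] > 0 || b[3L] > 0) {
    warning("non-monotone slope clipped to 0 in FDR surface fit")
    b[2L] <- min(b[2L], 0)
    b[3L] <- min(b[3L], 0)
  }
  pred <- pmin(1, exp(b[1L] + b[2L] * grid$r + b[3L] * log(grid$s)))
  structure(list(coef = c(b0 = b[1L], b1 = b[2L], b2 = b[3L]),
                 rmse = sqrt(mean((pred - fv)^2)),
                 form = "loglinear", degenerate = FALSE),
            class = "fdr_surface")
}

#' Predict FDR from a fitted surface
#'
#' @param surface An `fdr_surface`.
#' @param r Mean log2 ratio(s).
#' @param s Gene/window size(s) in bp.
#' @return FDR values clipped to \[0, 1\].
#' @export
predict_fdr <- function(surface, r, s) {
  if (isTRUE(surface$degenerate)) return(rep(0, max(length(r), length(s))))
  b <- surface$coef
  pmin(1, pmax(0, exp(b[["b0"]] + b[["b1"]] * r + b[["b2"]] * log(s))))
}

#' @export
print.fdr_surface <- function(x, ...) {
  cat("FDR surface (log f = b0 + b1*r + b2*log s):\n")
  print(signif(x$coef, 4))
  cat("training-grid RMSE:", signif(x$rmse, 3), "\n")
  invisible(x)
}

#' Per-replicate transcript calls from one PolII track
#'
#' Computes each gene's mean PolII log2 ratio and its FDR from a surface
#' fitted to that replicate's own randomized null.
#'
#' @param track A PolII `ratio_track`.
#' @param genes Gene data.frame.
#' @param map The `gatc_map`.
#' @param seed Seed for the null randomization.
#' @param ... Passed to [build_null_table()].
#' @return data.frame `gene_id`, `size`, `mean_ratio`, `fdr`.
#' @export
polii_replicate_calls <- function(track, genes, map, seed, ...) {
  tab <- build_null_table(track, map, seed = seed, ...)
  surf <- fit_fdr_surface(tab)
  res <- gene_mean_ratios(track, genes, map)
  res$fdr <- predict_fdr(surf, res$mean_ratio, res$size)
  res
}

#' Combine replicate transcript calls conservatively
#'
#' Each transcript receives the arithmetic mean of its replicate mean ratios
#' and the highest (worst) FDR across replicates; it is flagged transcribed
#' when that combined FDR is below `max_fdr`.
#'
#' @param replicate_calls List of per-replicate data.frames
#'   (`gene_id`, `mean_ratio`, `fdr`) over the same genes.
#' @param max_fdr Transcribed cutoff on the combined FDR (default 0.01).
#' @return data.frame `gene_id`, `mean_ratio` (combined), `fdr` (combined
#'   max), per-replicate columns, `transcribed` flag.
#' @export
call_transcribed <- function(replicate_calls, max_fdr = 0.01) {
  if (length(replicate_calls) < 1L) stop("at least one replicate is required")
  ids <- replicate_calls[[1L]]$gene_id
  for (rc in replicate_calls) {
    if (!identical(sort(rc$gene_id), sort(ids))) {
      stop("replicate calls cover different gene sets")
    }
  }
  means <- vapply(replicate_calls,
                  function(rc) rc$mean_ratio[match(ids, rc$gene_id)],
                  numeric(length(ids)))
  fdrs <- vapply(replicate_calls,
                 function(rc) rc$fdr[match(ids, rc$gene_id)],
                 numeric(length(ids)))
  means <- matrix(means, nrow = length(ids))
  fdrs <- matrix(fdrs, nrow = length(ids))
  out <- data.frame(gene_id = ids,
                    mean_ratio = rowMeans(means),
                    fdr = apply(fdrs, 1L, max),
                    stringsAsFactors = FALSE)
  for (k in seq_along(replicate_calls)) {
    out[[paste0("mean_ratio_rep", k)]] <- means[, k]
    out[[paste0("fdr_rep", k)]] <- fdrs[, k]
  }
  out$transcribed <- out$fdr < max_fdr
  out
}

#' Full transcription-state calling across replicates
#'
#' Runs [polii_replicate_calls()] per replicate (each with its own derived
#' seed) and combines them with [call_transcribed()].
#'
#' @param tracks List of PolII `ratio_track`s (QC-passing replicates).
#' @param genes Gene data.frame.
#' @param map The `gatc_map`.
#' @param seed Base seed; replicate k uses `seed + k`.
#' @param max_fdr Transcribed cutoff (default 0.01).
#' @param ... Passed to [build_null_table()].
#' @return Combined call table from [call_transcribed()].
#' @export
call_transcribed_genes <- function(tracks, genes, map, seed, max_fdr = 0.01, ...) {
  calls <- lapply(seq_along(tracks), function(k) {
    polii_replicate_calls(tracks[[k]], genes, map, seed = seed + k, ...)
  })
  call_transcribed(calls, max_fdr = max_fdr)
}
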