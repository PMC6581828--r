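# Small fixtures built in code; no files on disk.

# A fragment map with explicit fragment lengths per arm.
toy_map <- function(...) {
  arms <- list(...)
  pieces <- lapply(names(arms), function(arm) {
    lens <- arms[[arm]]
    ends <- cumsum(lens)
    data.frame(chrom = arm, start = c(1L, head(ends, -1L) + 1L),
               end = ends, ordinal = seq_along(lens) - 1L,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  tadacall:::new_gatc_map(df, vapply(arms, sum, numeric(1L)))
}

# n fragments of equal length on one arm
uniform_map <- function(n, frag_len = 10L, arm = "chrA") {
  do.call(toy_map, stats::setNames(list(rep(frag_len, n)), arm))
}

toy_genes <- function(ids, chrom, start, end) {
  data.frame(gene_id = ids, chrom = chrom, start = start, end = end,
             strand = "+", size = end - start + 1L, stringsAsFactors = FALSE)
}

toy_peaks <- function(chrom, start, end, frag_first = NA, frag_last = NA,
                      mean_ratio = 1, fdr = 0) {
  data.frame(peak_id = sprintf("p%02d", seq_along(start)), chrom = chrom,
             start = start, end = end, frag_first = frag_first,
             frag_last = frag_last,
             n_fragments = if (all(is.na(frag_first))) NA_integer_ else
               frag_last - frag_first + 1L,
             mean_ratio = mean_ratio, fdr = fdr, stringsAsFactors = FALSE)
}

# independent maximal-positive-run scanner: O(n^2) over all intervals
runs_bruteforce <- function(values, threshold = 0, min_len = 2L) {
  n <- length(values)
  keep <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      seg <- values[i:j]
      if (all(seg > threshold) &&
          (i == 1 || values[i - 1] <= threshold) &&
          (j == n || values[j + 1] <= threshold) &&
          (j - i + 1) >= min_len) {
        keep[[length(keep) + 1L]] <- c(first = i - 1L, last = j - 1L)
      }
    }
  }
  keep
}

# does any called peak share a fragment with the truth interval?
recovered <- function(peaks, chrom, f0, f1) {
  any(peaks$chrom == chrom & peaks$frag_first <= f1 & peaks$frag_last >= f0)
}

truth_recovery <- function(peaks, truth) {
  vapply(seq_len(nrow(truth)), function(i)
    recovered(peaks, truth$chrom[i], truth$frag_first[i], truth$frag_last[i]),
    logical(1L))
}
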