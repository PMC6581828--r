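#' Configuration for a synthetic TaDa experiment
#'
#' Defines the generative model: a multi-arm genome tiled by GATC fragments
#' with geometrically distributed spacing, non-overlapping gene models with
#' log-uniform sizes, planted contiguous binding domains with a fixed log2
#' effect, a subset of transcribed genes carrying elevated PolII-fusion
#' signal, and per-fragment Gaussian log2 noise (optionally routed through
#' overdispersed negative-binomial read counts).
#'
#' @param arms Named numeric vector of arm lengths in bp (default four
#'   9.6 Mb arms, a desk-scale genome on which the default 100 planted
#'   3-fragment domains occupy ~0.2% of fragments, as in real TaDa data
#'   where binding covers a small minority of the genome).
#' @param gatc_spacing Mean GATC fragment length in bp (default 256, the
#'   expected spacing of a 4-mer motif).
#' @param n_genes Number of gene models to place (default 2000).
#' @param gene_size_range Gene sizes are log-uniform over this range in bp
#'   (default 250 to 20,000).
#' @param genes_overlap Allow overlapping gene placement (default FALSE).
#' @param n_peaks Number of planted binding domains (default 100).
#' @param peak_len_fragments Fragments per planted domain (default 3, >= 2).
#' @param peak_effect Planted binding effect in log2 units (default 1.0).
#' @param transcribed_fraction Fraction of genes planted as transcribed
#'   (default 0.3).
#' @param polii_effect Planted PolII enrichment over transcribed gene bodies
#'   in log2 units (default 1.0).
#' @param noise_sd Per-fragment log2 noise standard deviation (default 0.3).
#' @param n_replicates Biological replicates per condition (default 2, the
#'   number of QC-passing replicates a typical TaDa analysis retains).
#' @param observation `"ratio"` generates log2 ratio tracks directly
#'   (effect + Gaussian noise); `"counts"` generates negative-binomial reads
#'   for fusion and Dam-only libraries and derives ratios by
#'   [normalize_ratio()].
#' @param depth Mean reads per average-length fragment for count generation
#'   (default 200).
#' @param nb_size Negative-binomial size (inverse overdispersion; default
#'   50). `Inf` gives noise-free counts equal to their expectation.
#' @param seed Mandatory integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(arms = c(chr2L = 9.6e6, chr2R = 9.6e6,
                                       chr3L = 9.6e6, chr3R = 9.6e6),
                              gatc_spacing = 256,
                              n_genes = 2000L,
                              gene_size_range = c(250, 20000),
                              genes_overlap = FALSE,
                              n_peaks = 100L,
                              peak_len_fragments = 3L,
                              peak_effect = 1.0,
                              transcribed_fraction = 0.3,
                              polii_effect = 1.0,
                              noise_sd = 0.3,
                              n_replicates = 2L,
                              observation = c("ratio", "counts"),
                              depth = 200,
                              nb_size = 50,
                              seed) {
  observation <- match.arg(observation)
  if (missing(seed)) stop("seed is mandatory in a simulation config")
  stopifnot(peak_len_fragments >= 2L, peak_effect >= 0, polii_effect >= 0,
            transcribed_fraction >= 0, transcribed_fraction <= 1,
            noise_sd >= 0, n_replicates >= 1L)
  structure(list(arms = arms, gatc_spacing = gatc_spacing, n_genes = n_genes,
                 gene_size_range = gene_size_range, genes_overlap = genes_overlap,
                 n_peaks = n_peaks, peak_len_fragments = peak_len_fragments,
                 peak_effect = peak_effect,
                 transcribed_fraction = transcribed_fraction,
                 polii_effect = polii_effect, noise_sd = noise_sd,
                 n_replicates = n_replicates, observation = observation,
                 depth = depth, nb_size = nb_size, seed = as.integer(seed)),
            class = "simulation_config")
}

# Geometric fragment lengths (minimum 4 bp, mean = spacing), truncated to the
# arm; short terminal remainders merge into the final fragment.
sim_fragment_map <- function(arms, spacing) {
  p <- 1 / (spacing - 3)
  pieces <- lapply(names(arms), function(arm) {
    len <- arms[[arm]]
    lens <- integer(0)
    while (sum(lens) < len) {
      need <- ceiling((len - sum(lens)) / spacing * 1.3) + 10L
      lens <- c(lens, 4L + stats::rgeom(need, p))
    }
    cut <- which(cumsum(lens) >= len)[1L]
    lens <- lens[seq_len(cut)]
    ends <- cumsum(lens)
    ends[cut] <- len
    starts <- c(1, utils::head(ends, -1L) + 1)
    if (cut > 1L && ends[cut] - starts[cut] + 1 < 4) {
      starts <- starts[-cut]; ends <- ends[-(cut - 1L)]
    }
    data.frame(chrom = arm, start = as.integer(starts), end = as.integer(ends),
               ordinal = seq_along(starts) - 1L, stringsAsFactors = FALSE)
  })
  new_gatc_map(do.call(rbind, pieces), arms)
}

sim_genes <- function(map, cfg) {
  arms <- attr(map, "arm_lengths")
  sizes <- round(exp(stats::runif(cfg$n_genes, log(cfg$gene_size_range[1L]),
                                  log(cfg$gene_size_range[2L]))))
  placed <- list()
  occupied <- lapply(arms, function(...) cbind(start = numeric(0), end = numeric(0)))
  for (i in seq_len(cfg$n_genes)) {
    arm <- sample(names(arms), 1L, prob = arms)
    if (sizes[i] >= arms[[arm]]) next
    for (try in 1:200) {
      s <- sample.int(arms[[arm]] - sizes[i], 1L)
      e <- s + sizes[i] - 1L
      occ <- occupied[[arm]]
      if (cfg$genes_overlap || !any(occ[, "start"] <= e & occ[, "end"] >= s)) {
        occupied[[arm]] <- rbind(occ, c(s, e))
        placed[[length(placed) + 1L]] <- data.frame(
          chrom = arm, start = s, end = e, stringsAsFactors = FALSE)
        break
      }
    }
  }
  g <- do.call(rbind, placed)
  g <- g[order(match(g$chrom, names(arms)), g$start), , drop = FALSE]
  g <- data.frame(gene_id = sprintf("gene_%04d", seq_len(nrow(g))),
                  g, strand = sample(c("+", "-"), nrow(g), replace = TRUE),
                  stringsAsFactors = FALSE)
  g$size <- g$end - g$start + 1L
  rownames(g) <- NULL
  g
}

# pick n non-adjacent runs of run_len fragments; returns truth peak df +
# per-fragment effect vector
sim_peaks <- function(map, n_peaks, run_len, effect) {
  eff <- numeric(nrow(map))
  if (n_peaks == 0L) {
    return(list(peaks = cbind(empty_peaks(), effect = numeric(0)), effect = eff))
  }
  rows_by_arm <- map_arm_rows(map)
  n_frag <- vapply(rows_by_arm, length, integer(1L))
  if (n_peaks * (run_len + 1L) > sum(n_frag)) {
    stop("infeasible geometry: more planted peak fragments than fragments")
  }
  alloc <- round(n_peaks * n_frag / sum(n_frag))
  while (sum(alloc) < n_peaks) alloc[which.max(n_frag)] <- alloc[which.max(n_frag)] + 1L
  while (sum(alloc) > n_peaks) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  res <- list()
  for (ai in seq_along(rows_by_arm)) {
    rows <- rows_by_arm[[ai]]
    taken <- rep(FALSE, length(rows))
    got <- 0L
    attempts <- 0L
    while (got < alloc[ai]) {
      attempts <- attempts + 1L
      if (attempts > 10000L) stop("could not place planted peaks; geometry too dense")
      f0 <- sample.int(length(rows) - run_len + 1L, 1L)
      span <- f0:(f0 + run_len - 1L)
      guard <- max(1L, f0 - 1L):min(length(rows), f0 + run_len)
      if (any(taken[guard])) next
      taken[span] <- TRUE
      eff[rows[span]] <- effect
      res[[length(res) + 1L]] <- data.frame(
        chrom = names(rows_by_arm)[ai],
        start = map$start[rows[span[1L]]], end = map$end[rows[span[run_len]]],
        frag_first = span[1L] - 1L, frag_last = span[run_len] - 1L,
        n_fragments = run_len, effect = effect, stringsAsFactors = FALSE)
      got <- got + 1L
    }
  }
  peaks <- do.call(rbind, res)
  peaks <- peaks[order(match(peaks$chrom, names(rows_by_arm)), peaks$start), , drop = FALSE]
  peaks <- cbind(peak_id = sprintf("true_%05d", seq_len(nrow(peaks))), peaks,
                 stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  list(peaks = peaks, effect = eff)
}

# per-fragment PolII effect: planted effect scaled by the fraction of the
# fragment covered by a transcribed gene body
sim_polii_effect <- function(map, genes, transcribed_ids, effect) {
  eff <- numeric(nrow(map))
  tg <- genes[genes$gene_id %in% transcribed_ids, , drop = FALSE]
  for (i in seq_len(nrow(tg))) {
    sel <- which(map$chrom == tg$chrom[i] & map$start <= tg$end[i] &
                 map$end >= tg$start[i])
    if (!length(sel)) next
    ov <- pmin(map$end[sel], tg$end[i]) - pmax(map$start[sel], tg$start[i]) + 1
    frac <- ov / (map$end[sel] - map$start[sel] + 1)
    eff[sel] <- pmax(eff[sel], effect * frac)
  }
  eff
}

sim_count_pair <- function(map, effect, noise_sd, depth, nb_size, lib_prefix, rep) {
  lens <- map$end - map$start + 1
  base <- depth * lens / mean(lens)
  e <- effect + if (noise_sd > 0) stats::rnorm(nrow(map), 0, noise_sd) else 0
  mu_fus <- base * 2^e
  draw <- function(mu) {
    if (is.infinite(nb_size)) round(mu) else stats::rnbinom(length(mu), mu = mu, size = nb_size)
  }
  list(fusion = count_track(draw(mu_fus), map,
                            library_id = paste0(lib_prefix, "_fusion_rep", rep),
                            condition = "fusion"),
       dam = count_track(draw(base), map,
                         library_id = paste0(lib_prefix, "_dam_rep", rep),
                         condition = "dam_only"))
}

#' Simulate a complete TaDa experiment with planted ground truth
#'
#' Generates a GATC fragment map, a gene annotation, planted binding domains
#' and transcribed genes, and per-replicate tracks for both the TF-fusion
#' and PolII-fusion assays, together with a truth record whose expected
#' target genes are computed by the exhaustive assignment oracle
#' ([assign_targets_bruteforce()]). Fully deterministic given the config
#' seed.
#'
#' @param config A `simulation_config`.
#' @return A `tada_simulation`: list with `map`, `genes`, `tracks`
#'   (`$tf` and `$polii`, each a list of `ratio_track`s per replicate),
#'   `counts` (for `observation = "counts"`; per assay, per replicate,
#'   fusion and Dam-only `count_track`s), `truth` (planted peaks, transcribed
#'   gene ids, expected targets, config echo), and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    map <- sim_fragment_map(config$arms, config$gatc_spacing)
    genes <- sim_genes(map, config)
    pk <- sim_peaks(map, config$n_peaks, config$peak_len_fragments,
                    config$peak_effect)
    n_tr <- round(config$transcribed_fraction * nrow(genes))
    transcribed <- sort(sample(genes$gene_id, n_tr))
    pol_eff <- sim_polii_effect(map, genes, transcribed, config$polii_effect)
    tracks <- list(tf = list(), polii = list())
    counts <- if (config$observation == "counts") list(tf = list(), polii = list()) else NULL
    for (r in seq_len(config$n_replicates)) {
      if (config$observation == "ratio") {
        tracks$tf[[r]] <- ratio_track(
          pk$effect + stats::rnorm(nrow(map), 0, config$noise_sd), map,
          sample_id = "tf", replicate = r)
        tracks$polii[[r]] <- ratio_track(
          pol_eff + stats::rnorm(nrow(map), 0, config$noise_sd), map,
          sample_id = "polii", replicate = r)
      } else {
        ctf <- sim_count_pair(map, pk$effect, config$noise_sd, config$depth,
                              config$nb_size, "tf", r)
        cpol <- sim_count_pair(map, pol_eff, config$noise_sd, config$depth,
                               config$nb_size, "polii", r)
        counts$tf[[r]] <- ctf
        counts$polii[[r]] <- cpol
        tracks$tf[[r]] <- normalize_ratio(ctf$fusion, ctf$dam, map,
                                          sample_id = "tf", replicate = r)
        tracks$polii[[r]] <- normalize_ratio(cpol$fusion, cpol$dam, map,
                                             sample_id = "polii", replicate = r)
      }
    }
    truth <- list(peaks = pk$peaks,
                  transcribed_genes = transcribed,
                  expected_targets = assign_targets_bruteforce(pk$peaks, genes),
                  config = unclass(config))
    structure(list(map = map, genes = genes, tracks = tracks, counts = counts,
                   truth = truth, config = config),
              class = "tada_simulation")
  })
}

#' Simulate a null TaDa experiment (no planted signal)
#'
#' Same generative model as [simulate_experiment()] with zero planted peaks
#' and no transcribed genes; the truth record is empty. Used for FDR
#' calibration.
#'
#' @param config A `simulation_config`; its `n_peaks` and
#'   `transcribed_fraction` are forced to zero.
#' @return A `tada_simulation` with empty truth.
#' @export
make_null_experiment <- function(config) {
  config$n_peaks <- 0L
  config$transcribed_fraction <- 0
  simulate_experiment(config)
}

#' @export
print.tada_simulation <- function(x, ...) {
  cat("Synthetic TaDa experiment: ", nrow(x$map), " fragments, ",
      nrow(x$genes), " genes, ", nrow(x$truth$peaks), " planted peaks, ",
      length(x$truth$transcribed_genes), " transcribed genes, ",
      x$config$n_replicates, " replicates (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write simulation outputs to a directory
#'
#' Emits the fragment map and ratio tracks as GFF, the annotation as GFF3,
#' counts (if simulated) as TSV, and the truth record as JSON.
#'
#' @param sim A `tada_simulation`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rtracklayer::export(map_to_granges(sim$map), file.path(dir, "fragment_map.gff"),
                      format = "gff2")
  write_annotation_gff3(sim$genes, file.path(dir, "annotation.gff3"))
  for (assay in names(sim$tracks)) {
    for (r in seq_along(sim$tracks[[assay]])) {
      write_ratio_gff(sim$tracks[[assay]][[r]], sim$map,
                      file.path(dir, sprintf("%s_rep%d.ratio.gff", assay, r)))
      if (!is.null(sim$counts)) {
        cp <- sim$counts[[assay]][[r]]
        for (cond in c("fusion", "dam")) {
          utils::write.table(
            data.frame(fragment = seq_len(nrow(sim$map)) - 1L,
                       count = cp[[cond]]$counts),
            file.path(dir, sprintf("%s_rep%d.%s.counts.tsv", assay, r, cond)),
            sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
  }
  truth <- sim$truth
  truth$expected_targets <- as.list(truth$expected_targets)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(dir)
}
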