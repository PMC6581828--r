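#' Read a fragment map from GFF
#'
#' Counterpart of the fragment-map GFF written by [write_simulation()]:
#' every record is one GATC fragment.
#'
#' @param path GFF path.
#' @return A `gatc_map`.
#' @export
read_fragment_map_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff")
  if (length(gr) == 0L) stop("'", path, "' contains no fragments")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), , drop = FALSE]
  ord <- unlist(lapply(split(seq_len(nrow(df)), factor(df$chrom, unique(df$chrom))),
                       seq_along), use.names = FALSE)
  df$ordinal <- ord - 1L
  arm_lengths <- vapply(split(df$end, factor(df$chrom, unique(df$chrom))),
                        max, numeric(1L))
  new_gatc_map(df, arm_lengths)
}

# score targets by their strongest supporting consensus peak
add_target_scores <- function(targets, peaks) {
  targets$max_peak_ratio <- vapply(targets$peak_ids, function(ids) {
    pk <- strsplit(ids, ",", fixed = TRUE)[[1L]]
    max(peaks$mean_ratio[match(pk, peaks$peak_id)])
  }, numeric(1L), USE.NAMES = FALSE)
  targets$min_peak_fdr <- vapply(targets$peak_ids, function(ids) {
    pk <- strsplit(ids, ",", fixed = TRUE)[[1L]]
    min(peaks$fdr[match(pk, peaks$peak_id)])
  }, numeric(1L), USE.NAMES = FALSE)
  targets
}

default_pipeline_config <- function() {
  list(seed = NULL,
       simulate = list(),
       inputs = NULL,
       qc = list(min_correlation = 0.6),
       peaks = list(n_shuffles = 100L, max_fdr = 0.01, min_mean_ratio = 0.3,
                    ratio_step = 0.05, seed_quantile = 0.95),
       targets = list(max_distance = 5000),
       polii = list(iterations = 10L, samples = 1000L, max_fdr = 0.01),
       integrate = list(top_n = 250L))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    for (f in c("fragment_map", "annotation")) {
      if (is.null(inp[[f]])) stop("config error: inputs$", f, " is required")
      if (!file.exists(inp[[f]])) stop("missing input file: ", inp[[f]])
    }
    map <- read_fragment_map_gff(inp$fragment_map)
    genes <- read_annotation_gff3(inp$annotation)
    read_set <- function(paths, assay) {
      lapply(seq_along(paths), function(r) {
        if (!file.exists(paths[[r]])) stop("missing input file: ", paths[[r]])
        read_ratio_gff(paths[[r]], map, sample_id = assay, replicate = r)
      })
    }
    list(map = map, genes = genes,
         tf = read_set(inp$tf, "tf"),
         polii = if (!is.null(inp$polii)) read_set(inp$polii, "polii") else list(),
         truth = NULL)
  } else {
    sim_args <- cfg$simulate
    sim_args$seed <- if (is.null(sim_args$seed)) cfg$seed else sim_args$seed
    sim <- simulate_experiment(do.call(simulation_config, sim_args))
    list(map = sim$map, genes = sim$genes, tf = sim$tracks$tf,
         polii = sim$tracks$polii, truth = sim$truth)
  }
}

#' Run the full TaDa analysis pipeline
#'
#' Sequences the stages normalize/simulate -> replicate QC -> per-replicate
#' peak calling -> consensus -> target assignment -> PolII transcription
#' calls -> bound/transcribed integration, writing stage outputs and a run
#' manifest (parameter echo, seed, output checksums) to `out_dir`. Reruns
#' with an identical config produce byte-identical outputs.
#'
#' @param config A config list, or the path to a YAML file with the same
#'   structure. Recognized sections: `seed` (required), `simulate`
#'   (arguments to [simulation_config()]) or `inputs` (`fragment_map`,
#'   `annotation`, `tf`, `polii` file paths), `qc`, `peaks`, `targets`,
#'   `polii`, `integrate`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the stage results (`qc`, `replicate_peaks`,
#'   `consensus`, `targets`, `transcript_calls`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  if (is.null(cfg$seed)) stop("config error: 'seed' is required")
  known <- names(default_pipeline_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("config error: unknown field(s): ", paste(unknown, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- load_pipeline_inputs(cfg)
  map <- dat$map

  # replicate QC (per assay, when there is more than one replicate)
  qc <- list()
  tf_tracks <- dat$tf
  if (length(tf_tracks) >= 2L) {
    qc$tf <- replicate_qc(tf_tracks, min_correlation = cfg$qc$min_correlation)
    tf_tracks <- keep_qc_passing(tf_tracks, qc$tf)
  }
  polii_tracks <- dat$polii
  if (length(polii_tracks) >= 2L) {
    qc$polii <- replicate_qc(polii_tracks, min_correlation = cfg$qc$min_correlation)
    polii_tracks <- keep_qc_passing(polii_tracks, qc$polii)
  }

  # per-replicate peak calls, then consensus
  pk <- call_peaks(tf_tracks, map, seed = cfg$seed + 100L,
                   n_shuffles = cfg$peaks$n_shuffles,
                   seed_quantile = cfg$peaks$seed_quantile,
                   max_fdr = cfg$peaks$max_fdr,
                   min_mean_ratio = cfg$peaks$min_mean_ratio,
                   ratio_step = cfg$peaks$ratio_step)
  rep_peaks <- pk$per_replicate
  for (r in seq_along(rep_peaks)) {
    write_peaks(rep_peaks[[r]], file.path(out_dir, sprintf("peaks_rep%d.gff", r)), "gff")
  }
  consensus <- pk$consensus
  write_peaks(consensus, file.path(out_dir, "peaks_consensus.gff"), "gff")
  write_peaks(consensus, file.path(out_dir, "peaks_consensus.bed"), "bed")

  # target genes
  targets <- assign_targets(consensus, dat$genes,
                            max_distance = cfg$targets$max_distance)
  if (nrow(targets)) targets <- add_target_scores(targets, consensus)
  write_targets_tsv(targets, file.path(out_dir, "target_genes.tsv"))

  # transcription state
  calls <- NULL
  summary <- NULL
  if (length(polii_tracks)) {
    calls <- call_transcribed_genes(polii_tracks, dat$genes, map,
                                    seed = cfg$seed + 200L,
                                    max_fdr = cfg$polii$max_fdr,
                                    iterations = cfg$polii$iterations,
                                    samples = cfg$polii$samples)
    utils::write.table(calls, file.path(out_dir, "transcript_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- summarize_bound_transcribed(targets, calls)
    if (nrow(targets)) {
      top <- top_n_bound(targets, n = cfg$integrate$top_n)
      write_gene_list(top, file.path(out_dir, "top_bound_genes.txt"))
    }
    jsonlite::write_json(
      list(n_bound = summary$n_bound,
           n_transcribed_bound = summary$n_transcribed_bound,
           fraction_transcribed = summary$fraction,
           percent_transcribed = summary$percent),
      file.path(out_dir, "bound_transcribed_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # run manifest: parameter echo + checksums of every stage output
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    tool = "tadacall",
    version = as.character(utils::packageVersion("tadacall")),
    seed = cfg$seed,
    parameters = cfg[c("qc", "peaks", "targets", "polii", "integrate")],
    simulate = if (is.null(cfg$inputs)) cfg$simulate else NULL,
    inputs = if (!is.null(cfg$inputs))
      lapply(cfg$inputs, function(p) unname(tools::md5sum(unlist(p)))) else NULL,
    qc_flagged = lapply(qc, function(q) q$flagged),
    outputs = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(qc = qc, replicate_peaks = rep_peaks, consensus = consensus,
                 targets = targets, transcript_calls = calls,
                 summary = summary, truth = dat$truth,
                 manifest = file.path(out_dir, "manifest.json")))
}
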