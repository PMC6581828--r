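#' Build a GATC fragment map from arm sequences
#'
#' Tiles each chromosome arm into the fragments DamID resolves: the intervals
#' between consecutive GATC motifs. A fragment boundary is placed at the
#' midpoint of each motif (between the GA and TC half-sites, where DpnI cuts
#' methylated GATC), so fragments are non-overlapping, contiguous, and jointly
#' cover the arm. Interior fragments are at least 4 bp by construction;
#' terminal fragments shorter than 4 bp (a motif within 2 bp of an arm end)
#' are merged into their neighbour. Runs of N are treated as ordinary
#' non-motif sequence.
#'
#' @param genome_sequences Named character vector or list, one nucleotide
#'   string (A/C/G/T/N) per chromosome arm.
#' @return A `gatc_map`: data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive bp) and `ordinal` (0-based fragment index within its
#'   arm), rows ordered by arm then position, with an `arm_lengths` attribute.
#'   An arm without any GATC motif becomes a single whole-arm fragment, with
#'   a warning.
#' @export
build_fragment_map <- function(genome_sequences) {
  genome_sequences <- as.list(genome_sequences)
  if (is.null(names(genome_sequences)) || anyNA(names(genome_sequences)) ||
      any(names(genome_sequences) == "")) {
    stop("genome_sequences must be named by chromosome arm")
  }
  pieces <- lapply(names(genome_sequences), function(arm) {
    seqstr <- toupper(as.character(genome_sequences[[arm]]))
    if (grepl("[^ACGTN]", seqstr)) {
      stop("arm '", arm, "' contains characters outside {A,C,G,T,N}")
    }
    len <- nchar(seqstr)
    hits <- gregexpr("GATC", seqstr, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) {
      warning("arm '", arm, "' has no GATC site; using one whole-arm fragment")
      starts <- 1L
      ends <- len
    } else {
      m <- as.integer(hits)
      # boundary between GA and TC: fragment ends at m+1, next starts at m+2
      starts <- c(1L, m + 2L)
      ends <- c(m + 1L, len)
      # only terminal fragments can be short; merge them inward
      repeat {
        n <- length(starts)
        if (n <= 1L) break
        if (ends[1L] - starts[1L] + 1L < 4L) {
          starts <- starts[-2L]; ends <- ends[-1L]; next
        }
        if (ends[n] - starts[n] + 1L < 4L) {
          starts <- starts[-n]; ends <- ends[-(n - 1L)]; next
        }
        break
      }
    }
    data.frame(chrom = arm, start = starts, end = ends,
               ordinal = seq_along(starts) - 1L,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, pieces)
  rownames(map) <- NULL
  arm_lengths <- vapply(genome_sequences, nchar, integer(1L))
  new_gatc_map(map, arm_lengths)
}

new_gatc_map <- function(df, arm_lengths) {
  stopifnot(all(c("chrom", "start", "end", "ordinal") %in% names(df)))
  structure(df, arm_lengths = arm_lengths,
            class = c("gatc_map", "data.frame"))
}

#' @export
print.gatc_map <- function(x, ...) {
  cat("GATC fragment map: ", nrow(x), " fragments over ",
      length(attr(x, "arm_lengths")), " arm(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# arm names in map order
map_arms <- function(map) unique(map$chrom)

# list of global row indices per arm
map_arm_rows <- function(map) split(seq_len(nrow(map)), factor(map$chrom, levels = map_arms(map)))

validate_track_on_map <- function(values, map) {
  if (length(values) != nrow(map)) {
    stop("track has ", length(values), " values but the fragment map has ",
         nrow(map), " fragments")
  }
  invisible(TRUE)
}

#' Construct a per-fragment log2 ratio track
#'
#' @param values Numeric vector of finite log2(Dam-fusion/Dam) values, one per
#'   fragment of `map`, in map row order.
#' @param map A `gatc_map`.
#' @param sample_id,replicate Identifiers carried through to outputs.
#' @return A `ratio_track` object.
#' @export
ratio_track <- function(values, map, sample_id = "sample", replicate = 1L) {
  validate_track_on_map(values, map)
  if (!all(is.finite(values))) stop("ratio values must be finite")
  structure(list(sample_id = sample_id, replicate = as.integer(replicate),
                 values = as.numeric(values)),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  cat("log2 ratio track '", x$sample_id, "' replicate ", x$replicate, ": ",
      length(x$values), " fragments, mean ", signif(mean(x$values), 3), "\n",
      sep = "")
  invisible(x)
}

#' Construct a per-fragment count track
#'
#' @param counts Non-negative integer read counts, one per fragment of `map`.
#' @param map A `gatc_map`.
#' @param library_id Library identifier.
#' @param condition `"dam_only"` or `"fusion"`.
#' @return A `count_track` with the library size (sum of counts) attached.
#' @export
count_track <- function(counts, map, library_id = "lib", condition = c("fusion", "dam_only")) {
  condition <- match.arg(condition)
  validate_track_on_map(counts, map)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(list(library_id = library_id, condition = condition,
                 counts = as.numeric(counts), lib_size = sum(counts)),
            class = "count_track")
}

map_to_granges <- function(map, score = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = map$chrom,
    ranges = IRanges::IRanges(start = map$start, end = map$end))
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- score
  gr
}

#' Write a ratio track to GFF
#'
#' One GFF record per GATC fragment with the log2 ratio in the score column,
#' the format the damidseq-style pipelines emit.
#'
#' @param track A `ratio_track`.
#' @param map The `gatc_map` the track is indexed on.
#' @param path Output file path.
#' @export
write_ratio_gff <- function(track, map, path) {
  gr <- map_to_granges(map, score = round(track$values, 6))
  S4Vectors::mcols(gr)$source <- "tadacall"
  S4Vectors::mcols(gr)$type <- "misc_feature"
  rtracklayer::export(gr, path, format = "gff2")
  invisible(path)
}

#' Read a ratio track from GFF
#'
#' Accepts any GFF whose intervals match the supplied fragment map exactly
#' (chrom, start, end); the score column carries the log2 ratio.
#'
#' @param path GFF file path.
#' @param map The `gatc_map` the file must match.
#' @param sample_id,replicate Identifiers for the returned track.
#' @return A `ratio_track`. An empty file yields an all-zero-length error-free
#'   empty track with a warning.
#' @export
read_ratio_gff <- function(path, map, sample_id = basename(path), replicate = 1L) {
  gr <- rtracklayer::import(path, format = "gff")
  if (length(gr) == 0L) {
    warning("'", path, "' contains no features; returning an empty track")
    return(structure(list(sample_id = sample_id, replicate = as.integer(replicate),
                          values = numeric(0)),
                     class = "ratio_track"))
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   score = as.numeric(S4Vectors::mcols(gr)$score),
                   stringsAsFactors = FALSE)
  key_map <- paste(map$chrom, map$start, map$end)
  key_gff <- paste(df$chrom, df$start, df$end)
  idx <- match(key_gff, key_map)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("GFF record ", bad, " (", key_gff[bad],
         ") does not match any fragment in the map")
  }
  if (length(idx) != nrow(map)) {
    stop("GFF covers ", length(idx), " fragments; map has ", nrow(map))
  }
  values <- numeric(nrow(map))
  values[idx] <- df$score
  ratio_track(values, map, sample_id = sample_id, replicate = replicate)
}

#' Read gene models from a GFF3 annotation
#'
#' Extracts features of type `gene` (configurable) with 1-based inclusive
#' coordinates, one record per gene.
#'
#' @param path GFF3 file path.
#' @param feature_type Feature type(s) to keep (default `"gene"`).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `size` (bp). Duplicate gene ids or a gene with `end < start`
#'   are errors.
#' @export
read_annotation_gff3 <- function(path, feature_type = "gene") {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 '", path, "': ",
                                          conditionMessage(e)))
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (length(gr) == 0L) stop("no '", paste(feature_type, collapse = "/"),
                             "' features found in '", path, "'")
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    nm <- S4Vectors::mcols(gr)$Name
    ids <- if (!is.null(nm)) nm else paste0("gene", seq_along(gr))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene ids in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genes <- data.frame(gene_id = as.character(ids),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if (any(genes$end < genes$start)) {
    bad <- genes$gene_id[genes$end < genes$start]
    stop("gene(s) with end < start: ", paste(bad, collapse = ", "))
  }
  genes$size <- genes$end - genes$start + 1L
  genes[order(genes$chrom, genes$start), , drop = FALSE]
}

#' Write gene models to GFF3
#'
#' @param genes data.frame as returned by [read_annotation_gff3()].
#' @param path Output path.
#' @export
write_annotation_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$source <- "tadacall"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
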