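test_that("fragment map splits arms at GATC midpoints", {
  # motifs at positions 3-6 and 9-12; boundaries between GA and TC
  m <- build_fragment_map(c(armA = "AAGATCCCGATCAA"))
  expect_equal(nrow(m), 3L)
  expect_equal(m$start, c(1L, 5L, 11L))
  expect_equal(m$end, c(4L, 10L, 14L))
  expect_equal(sum(m$end - m$start + 1L), 14L)
  expect_equal(m$ordinal, 0:2)
})

test_that("an arm without GATC becomes a single fragment with a warning", {
  expect_warning(m <- build_fragment_map(c(armA = "AAAACCCCTTTT")), "no GATC")
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1L, 12L))
})

test_that("adjacent motifs still yield fragments of at least 4 bp", {
  m <- build_fragment_map(c(armA = "GATCGATC"))
  expect_true(all(m$end - m$start + 1L >= 4L))
  expect_equal(sum(m$end - m$start + 1L), 8L)
  m2 <- build_fragment_map(c(armA = "GATCGATCGATCGATC"))
  expect_true(all(m2$end - m2$start + 1L >= 4L))
  expect_equal(sum(m2$end - m2$start + 1L), 16L)
})

test_that("fragment maps tile random genomes exactly", {
  withr::with_seed(7, {
    for (k in 1:20) {
      len <- sample(50:400, 1L)
      seqs <- c(a = paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                                 prob = c(.24, .24, .24, .24, .04)),
                          collapse = ""))
      m <- suppressWarnings(build_fragment_map(seqs))
      expect_equal(m$start[1L], 1L)
      expect_equal(m$end[nrow(m)], len)
      if (nrow(m) > 1L) {
        expect_true(all(m$start[-1L] == m$end[-nrow(m)] + 1L))
      }
      expect_true(all(m$end - m$start + 1L >= 4L))
      expect_equal(sum(m$end - m$start + 1L), len)
    }
  })
})

test_that("lowercase and invalid sequence characters are handled", {
  m <- build_fragment_map(c(armA = "aagatcccgatcaa"))
  expect_equal(nrow(m), 3L)
  expect_error(build_fragment_map(c(armA = "AAGRTC")), "outside")
})

test_that("ratio GFF round-trips coordinates and scores", {
  map <- uniform_map(8)
  tr <- ratio_track(round(rnorm(8), 4), map, sample_id = "s", replicate = 2L)
  path <- withr::local_tempfile(fileext = ".gff")
  write_ratio_gff(tr, map, path)
  back <- read_ratio_gff(path, map, sample_id = "s", replicate = 2L)
  expect_equal(back$values, tr$values, tolerance = 1e-6)
  expect_equal(back$replicate, 2L)
})

test_that("ratio GFF reader rejects fragments absent from the map", {
  map <- uniform_map(4)
  tr <- ratio_track(c(0.1, 0.2, 0.3, 0.4), map)
  path <- withr::local_tempfile(fileext = ".gff")
  write_ratio_gff(tr, map, path)
  other <- uniform_map(4, frag_len = 7L)
  expect_error(read_ratio_gff(path, other), "does not match")
})

test_that("empty ratio GFF yields an empty track with a warning", {
  path <- withr::local_tempfile(fileext = ".gff")
  writeLines("##gff-version 2", path)
  map <- uniform_map(3)
  expect_warning(tr <- read_ratio_gff(path, map), "no features")
  expect_length(tr$values, 0L)
})

test_that("GFF3 annotation round-trips gene records", {
  genes <- toy_genes(c("g1", "g2", "g3"), "chrA",
                     c(100L, 500L, 900L), c(300L, 750L, 1400L))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(genes, path)
  back <- read_annotation_gff3(path)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$size, genes$size)
})

test_that("malformed annotations are rejected", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrA\tsrc\tgene\t500\t300\t.\t+\t.\tID=bad1"), path)
  expect_error(read_annotation_gff3(path))
  writeLines(c("##gff-version 3",
               "chrA\tsrc\tgene\t100\t300\t.\t+\t.\tID=dup",
               "chrA\tsrc\tgene\t400\t600\t.\t+\t.\tID=dup"), path)
  expect_error(read_annotation_gff3(path), "duplicate")
})

test_that("tracks must align with their map", {
  map <- uniform_map(5)
  expect_error(ratio_track(1:4, map), "4 values")
  expect_error(ratio_track(c(1, 2, 3, 4, NaN), map), "finite")
  expect_error(count_track(c(1, -2, 3, 4, 5), map), "non-negative")
})
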