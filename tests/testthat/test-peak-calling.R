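test_that("candidate peaks are maximal positive runs of two or more fragments", {
  map <- uniform_map(4)
  tr <- ratio_track(c(0.5, 0.6, -0.1, 0.4), map)
  cand <- enumerate_candidate_peaks(tr, map)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$frag_first, 0L)
  expect_equal(cand$frag_last, 1L)
  expect_equal(cand$mean_ratio, 0.55)
  expect_equal(cand$start, 1L)
  expect_equal(cand$end, 20L)

  expect_equal(nrow(enumerate_candidate_peaks(
    ratio_track(c(-0.2, 0, -1, -0.5), map), map)), 0L)
  # single positive fragment flanked by negatives is too short
  expect_equal(nrow(enumerate_candidate_peaks(
    ratio_track(c(-0.2, 2.0, -1, -0.5), map), map)), 0L)
})

test_that("runs never cross arm boundaries", {
  map <- toy_map(a = rep(10L, 3), b = rep(10L, 3))
  tr <- ratio_track(rep(1, 6), map)
  cand <- enumerate_candidate_peaks(tr, map)
  expect_equal(cand$chrom, c("a", "b"))
  expect_equal(cand$n_fragments, c(3L, 3L))
})

test_that("candidate enumeration agrees with an exhaustive interval scan", {
  withr::with_seed(42, {
    for (k in 1:15) {
      n <- sample(5:200, 1L)
      map <- uniform_map(n)
      tr <- ratio_track(rnorm(n, 0, 1), map)
      cand <- enumerate_candidate_peaks(tr, map)
      oracle <- runs_bruteforce(tr$values)
      expect_equal(nrow(cand), length(oracle))
      if (length(oracle)) {
        om <- do.call(rbind, oracle)
        expect_equal(cand$frag_first, unname(om[, "first"]))
        expect_equal(cand$frag_last, unname(om[, "last"]))
        means <- vapply(oracle, function(o)
          mean(tr$values[(o["first"]:o["last"]) + 1L]), numeric(1L))
        expect_equal(cand$mean_ratio, unname(means))
      }
    }
  })
})

test_that("permutation FDR tables are deterministic given the seed", {
  map <- uniform_map(300)
  withr::with_seed(8, tr <- ratio_track(rnorm(300, 0, 0.3), map))
  cand <- enumerate_candidate_peaks(tr, map)
  t1 <- estimate_peak_fdr(tr, map, cand, n_shuffles = 5, seed = 99)
  t2 <- estimate_peak_fdr(tr, map, cand, n_shuffles = 5, seed = 99)
  expect_identical(t1, t2)
  t3 <- estimate_peak_fdr(tr, map, cand, n_shuffles = 5, seed = 100)
  expect_false(identical(t1$fdr, t3$fdr))
})

test_that("FDR is non-increasing in mean ratio and clipped to [0, 1]", {
  map <- uniform_map(2000)
  withr::with_seed(13, tr <- ratio_track(rnorm(2000, 0, 0.3), map))
  cand <- enumerate_candidate_peaks(tr, map)
  tab <- estimate_peak_fdr(tr, map, cand, n_shuffles = 20, seed = 4)
  expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))
  expect_true(all(apply(tab$fdr, 1L, function(row) all(diff(row) <= 1e-12))))
})

test_that("null tracks rarely yield low-FDR candidates", {
  map <- toy_map(a = rep(10L, 2500), b = rep(10L, 2500))
  withr::with_seed(17, tr <- ratio_track(rnorm(5000, 0, 0.3), map))
  cand <- enumerate_candidate_peaks(tr, map)
  tab <- estimate_peak_fdr(tr, map, cand, n_shuffles = 30, seed = 5)
  cand <- assign_peak_fdr(cand, tab)
  frac_low <- mean(cand$fdr < 0.01)
  expect_lte(frac_low, 0.01 + 3 * sqrt(0.01 / nrow(cand)))
})

test_that("a strong planted run reaches FDR below 1%", {
  map <- uniform_map(5000)
  withr::with_seed(23, {
    vals <- rnorm(5000, 0, 0.3)
    vals[1001:1010] <- vals[1001:1010] + 2
    tr <- ratio_track(vals, map)
  })
  cand <- enumerate_candidate_peaks(tr, map)
  tab <- estimate_peak_fdr(tr, map, cand, n_shuffles = 100, seed = 6)
  cand <- assign_peak_fdr(cand, tab)
  planted <- cand[cand$frag_first <= 1009 & cand$frag_last >= 1000, ]
  expect_gte(nrow(planted), 1L)
  expect_lt(min(planted$fdr), 0.01)
})

test_that("significance filtering applies both thresholds", {
  cand <- toy_peaks("a", c(1, 100, 200), c(50, 150, 250),
                    frag_first = c(0, 10, 20), frag_last = c(4, 14, 24),
                    mean_ratio = c(0.25, 1.0, 0.31),
                    fdr = c(0.005, 0.02, 0.004))
  out <- call_peaks_replicate(cand)
  expect_equal(out$peak_id, "p03")  # 0.25 fails ratio, 0.02 fails FDR
})

test_that("consensus keeps only regions supported in every replicate", {
  map <- uniform_map(30)
  r1 <- toy_peaks("chrA", 101, 151, frag_first = 10, frag_last = 15,
                  mean_ratio = 1.0, fdr = 0.002)
  r2 <- toy_peaks("chrA", 121, 181, frag_first = 12, frag_last = 18,
                  mean_ratio = 0.8, fdr = 0.004)
  cons <- consensus_peaks(list(r1, r2), map)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$frag_first, 12L)
  expect_equal(cons$frag_last, 15L)
  expect_equal(cons$mean_ratio, 0.9)
  expect_equal(cons$fdr, 0.004)  # conservative max over replicates

  # present in one replicate only: absent
  lone <- toy_peaks("chrA", 201, 231, frag_first = 20, frag_last = 22,
                    mean_ratio = 1, fdr = 0.001)
  r1b <- rbind(r1, lone)
  cons2 <- consensus_peaks(list(r1b, r2), map)
  expect_equal(nrow(cons2), 1L)
  expect_equal(cons2$frag_first, 12L)

  # identical replicate lists reproduce themselves
  cons3 <- consensus_peaks(list(r1, r1), map)
  expect_equal(cons3$frag_first, r1$frag_first)
  expect_equal(cons3$frag_last, r1$frag_last)
  expect_equal(cons3$mean_ratio, r1$mean_ratio)

  expect_error(consensus_peaks(list(), map), "no replicate")
})

test_that("consensus fragments are covered by significant peaks in all replicates", {
  cfg <- simulation_config(arms = c(a = 1.28e6), n_genes = 50, n_peaks = 20,
                           seed = 61)
  sim <- simulate_experiment(cfg)
  pk <- call_peaks(sim$tracks$tf, sim$map, seed = 610, n_shuffles = 30)
  cons_rows <- tadacall:::peak_fragment_rows(pk$consensus, sim$map)
  for (reps in pk$per_replicate) {
    rep_rows <- tadacall:::peak_fragment_rows(reps, sim$map)
    expect_true(all(cons_rows %in% rep_rows))
  }
})

test_that("peak export writes GFF and BED that round-trip coordinates", {
  pk <- toy_peaks("chrA", c(101, 301), c(200, 420),
                  frag_first = c(10, 30), frag_last = c(19, 41),
                  mean_ratio = c(0.8, 1.2), fdr = c(0.001, 0.005))
  gff <- withr::local_tempfile(fileext = ".gff")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_peaks(pk, gff, "gff")
  write_peaks(pk, bed, "bed")
  g <- rtracklayer::import(gff)
  expect_equal(GenomicRanges::start(g), pk$start)
  b <- rtracklayer::import(bed)  # BED is 0-based half-open on disk
  expect_equal(GenomicRanges::start(b), pk$start)
  expect_equal(GenomicRanges::end(b), pk$end)
  raw <- read.table(bed, sep = "\t")
  expect_equal(raw$V2, pk$start - 1L)
})
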