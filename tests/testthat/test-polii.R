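test_that("transcript mean ratio length-weights fragment overlaps", {
  # two equal fragments, gene covers both fully
  map <- toy_map(a = c(200L, 200L))
  tr <- ratio_track(c(0.2, 0.6), map)
  gene <- toy_genes("g", "a", 1, 400)
  expect_equal(transcript_mean_ratio(tr, gene, map), 0.4)

  # 100 bp of a ratio-1 fragment and 300 bp of a ratio-0 fragment
  map2 <- toy_map(a = c(200L, 400L))
  tr2 <- ratio_track(c(1, 0), map2)
  gene2 <- toy_genes("g", "a", 101, 500)
  expect_equal(transcript_mean_ratio(tr2, gene2, map2), 0.25)

  # constant track gives the constant for any gene span
  tr3 <- ratio_track(c(0.37, 0.37), map2)
  expect_equal(transcript_mean_ratio(tr3, toy_genes("g", "a", 57, 313), map2),
               0.37)
})

test_that("genes outside track coverage are errors", {
  map <- toy_map(a = c(100L, 100L))
  tr <- ratio_track(c(0, 0), map)
  expect_error(transcript_mean_ratio(tr, toy_genes("g", "b", 1, 50), map),
               "unmapped arm")
  expect_error(transcript_mean_ratio(tr, toy_genes("g", "a", 300, 400), map),
               "covers no")
})

test_that("null frequency tables are deterministic and well-shaped", {
  map <- uniform_map(2000, frag_len = 250L)
  withr::with_seed(71, tr <- ratio_track(rnorm(2000, 0, 0.3), map))
  t1 <- build_null_table(tr, map, iterations = 3, samples = 200, seed = 12)
  t2 <- build_null_table(tr, map, iterations = 3, samples = 200, seed = 12)
  expect_identical(t1, t2)
  # frequency non-increasing in the ratio threshold at every size
  expect_true(all(apply(t1$pooled, 1L, function(row) all(diff(row) <= 0))))
  expect_true(all(t1$pooled >= 0 & t1$pooled <= 1))
})

test_that("null frequencies reflect the symmetric ratio distribution", {
  map <- uniform_map(5000, frag_len = 100L)
  withr::with_seed(73, tr <- ratio_track(rnorm(5000, 0, 0.5), map))
  tab <- build_null_table(tr, map, iterations = 10, samples = 1000,
                          size_grid = c(100L, 400L), seed = 3)
  # at r = 0, about half of the sampled windows lie above zero
  expect_equal(tab$pooled["100", 1L], 0.5, tolerance = 0.05)
  # thresholds beyond the track maximum are never reached
  tab2 <- build_null_table(tr, map, iterations = 2, samples = 200,
                           size_grid = c(100L),
                           ratio_grid = c(0, max(tr$values) + 1), seed = 4)
  expect_equal(unname(tab2$pooled[1L, 2L]), 0)
})

test_that("window sizes exceeding an arm are skipped with a warning", {
  map <- toy_map(tiny = rep(50L, 4), big = rep(500L, 40))
  withr::with_seed(5, tr <- ratio_track(rnorm(44), map))
  expect_warning(
    tab <- build_null_table(tr, map, iterations = 2, samples = 50,
                            size_grid = c(100L, 1000L), seed = 9),
    "shorter")
  expect_true(is.na(tab$freq["tiny", "1000", 1L]))
  expect_false(is.na(tab$freq["big", "1000", 1L]))
})

test_that("the surface fit recovers a planted exponential law", {
  # frequencies generated exactly from f(r, s) = exp(-a r) * s^(-b)
  a <- 4.2; b <- 0.8
  size_grid <- round(exp(seq(log(250), log(2500), length.out = 8)))
  ratio_grid <- seq(0, 0.75, 0.05)
  f <- outer(size_grid, ratio_grid, function(s, r) exp(-a * r) * s^(-b))
  tab <- structure(list(pooled = f, size_grid = size_grid,
                        ratio_grid = ratio_grid),
                   class = "null_freq_table")
  surf <- fit_fdr_surface(tab)
  expect_equal(unname(surf$coef["b1"]), -a, tolerance = 0.1 * a)
  expect_equal(unname(surf$coef["b2"]), -b, tolerance = 0.1 * b)
  expect_lt(surf$rmse, 1e-6)
  # extrapolation stays monotone: far corner below the training-grid corner
  expect_lte(predict_fdr(surf, 2.0, 10000),
             predict_fdr(surf, 0.75, 2500))
  # predictions never leave [0, 1]
  expect_true(all(predict_fdr(surf, seq(-1, 3, 0.5), 1000) >= 0))
  expect_true(all(predict_fdr(surf, seq(-1, 3, 0.5), 1000) <= 1))
})

test_that("a degenerate all-zero table yields a zero surface with warning", {
  tab <- structure(list(pooled = matrix(0, 3, 4), size_grid = c(250, 500, 1000),
                        ratio_grid = c(0, 0.25, 0.5, 0.75)),
                   class = "null_freq_table")
  expect_warning(surf <- fit_fdr_surface(tab), "degenerate")
  expect_equal(predict_fdr(surf, 0.5, 1000), 0)
})

test_that("replicate combination takes the mean ratio and the worst FDR", {
  calls <- list(
    data.frame(gene_id = c("g1", "g2"), mean_ratio = c(0.4, 1.0),
               fdr = c(0.005, 0.5)),
    data.frame(gene_id = c("g2", "g1"), mean_ratio = c(0.8, 0.6),
               fdr = c(0.2, 0.02)))
  out <- call_transcribed(calls, max_fdr = 0.05)
  expect_equal(out$mean_ratio[out$gene_id == "g1"], 0.5)
  expect_equal(out$fdr[out$gene_id == "g1"], 0.02)
  expect_equal(out$fdr[out$gene_id == "g2"], 0.5)
  expect_equal(out$transcribed, c(TRUE, FALSE))
  # a single replicate combines to itself
  single <- call_transcribed(calls[1L])
  expect_equal(single$mean_ratio, calls[[1L]]$mean_ratio)
  expect_equal(single$fdr, calls[[1L]]$fdr)
})

test_that("combined FDR dominates every replicate FDR on random fixtures", {
  withr::with_seed(31, {
    for (k in 1:10) {
      n <- sample(3:40, 1L)
      ids <- sprintf("g%03d", seq_len(n))
      calls <- lapply(1:3, function(r)
        data.frame(gene_id = sample(ids), mean_ratio = rnorm(n),
                   fdr = runif(n)))
      out <- call_transcribed(calls)
      per_rep <- vapply(calls, function(rc) rc$fdr[match(out$gene_id, rc$gene_id)],
                        numeric(n))
      expect_equal(out$fdr, apply(per_rep, 1L, max))
      expect_true(all(out$fdr >= per_rep))
      expect_equal(out$mean_ratio, rowMeans(
        vapply(calls, function(rc) rc$mean_ratio[match(out$gene_id, rc$gene_id)],
               numeric(n))))
    }
  })
})

test_that("mismatched replicate gene sets are rejected", {
  expect_error(call_transcribed(list(
    data.frame(gene_id = "g1", mean_ratio = 1, fdr = 0.1),
    data.frame(gene_id = "g2", mean_ratio = 1, fdr = 0.1))),
    "different gene sets")
})
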