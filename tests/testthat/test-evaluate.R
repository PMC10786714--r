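test_that("matching requires reciprocal 50% overlap", {
  truth <- data.frame(start_cm = 10, end_cm = 14)            # 4 cM
  good <- data.frame(start_cm = 9.5, end_cm = 14.5)          # 5 cM, ov 4
  m <- match_segments(good, truth)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$length_error_cm, 1)
  # a 12 cM call covering the 4 cM truth fails the reciprocal criterion
  bloated <- data.frame(start_cm = 6, end_cm = 18)
  m2 <- match_segments(bloated, truth)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$fp_idx, 1L)
  expect_equal(m2$miss_idx, 1L)
})

test_that("greedy matching is one-to-one and prefers larger overlaps", {
  truth <- data.frame(start_cm = c(0, 20), end_cm = c(10, 30))
  called <- data.frame(start_cm = c(0.5, 1), end_cm = c(10.5, 9))
  m <- match_segments(called, truth)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$called, 1L)  # the better-overlapping call wins
  expect_equal(m$miss_idx, 2L)
  expect_equal(m$fp_idx, 2L)
})

test_that("segments on different chromosomes never match", {
  truth <- data.frame(chrom = "2", start_cm = 0, end_cm = 10)
  called <- data.frame(chromosome = "1", start_cm = 0, end_cm = 10)
  m <- match_segments(called, truth)
  expect_equal(nrow(m$pairs), 0L)
})

test_that("power and length bias are aggregated per true length class", {
  results <- list(
    list(truth = data.frame(start_cm = c(0, 20), end_cm = c(8, 32),
                            length_cm = c(8, 12)),
         called = data.frame(start_cm = 19.5, end_cm = 32.5)),
    list(truth = data.frame(start_cm = c(0, 20), end_cm = c(8, 32),
                            length_cm = c(8, 12)),
         called = data.frame(start_cm = c(0, 20), end_cm = c(8, 32)))
  )
  pb <- power_length_bias(results, lengths = c(8, 12))
  expect_equal(pb$power, c(0.5, 1))
  expect_equal(pb$n_truth, c(2L, 2L))
  expect_equal(pb$mean_length_error_cm[2], 0.5)  # (+1 + 0) / 2
})

test_that("false positive rates are binned per pair-chromosome", {
  fpr <- false_positive_rate(c(0.1, 0.3, 0.3, 8.2), n_pairs = 8,
                             bin_cm = 0.25, max_cm = 10)
  expect_equal(nrow(fpr), 40L)
  expect_equal(fpr$rate[1], 1 / 8)            # [0, 0.25)
  expect_equal(fpr$rate[2], 2 / 8)            # [0.25, 0.5)
  expect_equal(fpr$rate[fpr$bin_start_cm == 8], 1 / 8)
  expect_equal(sum(fpr$rate), 4 / 8)
})

test_that("expected segment density decreases with length and scales by pair basis", {
  d <- expected_ibd_constant_ne(500, c(4, 8, 12, 20))
  expect_true(all(diff(d) < 0))
  d2 <- expected_ibd_constant_ne(500, 8, basis = "diploid")
  expect_equal(d2, 4 * expected_ibd_constant_ne(500, 8))
  expect_equal(expected_ibd_constant_ne(500, 150, chrom_cm = 100), 0)
  expect_error(expected_ibd_constant_ne(-5, 8), "must be > 0")
})

test_that("the coalescent expectation matches a forward Wright-Fisher simulation", {
  # sparse-coalescence regime: recent common ancestry is rare, so maximal
  # founder-label runs coincide with single-coalescence IBD segments (in a
  # drift-heavy population, runs merge across re-coalescences and the two
  # objects diverge)
  set.seed(31)
  ne <- 120; n_gen <- 25; chrom_cm <- 100
  pop_means <- vapply(1:8, function(rep) {
    segs <- ibdscreen:::wf_ibd_segments(ne, n_gen, chrom_cm,
                                        n_samples = 20,
                                        basis = "haplotype")
    mean(vapply(segs, function(s) sum(s$length_cm >= 4), numeric(1)))
  }, numeric(1))
  # expected count of haplotype-pair segments >= 4 cM with ancestry
  # within n_gen: integrate the length density
  grid <- seq(4, chrom_cm, by = 0.5)
  dens <- expected_ibd_constant_ne(ne, grid, chrom_cm,
                                   basis = "haplotype", max_gen = n_gen)
  expected <- sum(dens) * 0.5
  se <- stats::sd(pop_means) / sqrt(length(pop_means))
  expect_lt(abs(mean(pop_means) - expected), 4 * se)
})

test_that("the grid search ranks a sensible cell above a broken one", {
  set.seed(32)
  cfg <- mosaic_config(chrom_length_cm = 40, n_panel = 60)
  panel <- simulate_panel(60, mosaic_sites(cfg))
  scenarios <- lapply(1:3, function(i) {
    sim <- simulate_ibd_pair(cfg, noise_config(tier = "1x"),
                             ibd = data.frame(start_cm = 10, length_cm = 15),
                             panel = panel)
    list(gm = sim$gm, sites = sim$sites, truth = sim$truth)
  })
  # the second cell's density floor exceeds the simulated marker density,
  # so it can never report a segment
  grid <- data.frame(ibd_in = c(0.01, 0.01),
                     ibd_out = c(5, 5),
                     post_threshold = c(0.5, 0.5),
                     density_min_snps_per_cm = c(75, 1e6))
  res <- grid_search_defaults(grid, scenarios)
  expect_equal(res$density_min_snps_per_cm[res$rank == 1], 75)
  expect_gt(res$recall[res$rank == 1], res$recall[res$rank == 2])
  expect_equal(res$recall[res$rank == 2], 0)
  expect_error(grid_search_defaults(grid[0, ], scenarios), "empty")
})
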