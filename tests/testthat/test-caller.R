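# helper: a fake posterior trace with a given non-IBD posterior vector
fake_trace <- function(g0, pos_cm) {
  gamma <- cbind(g0, (1 - g0) / 4, (1 - g0) / 4, (1 - g0) / 4, (1 - g0) / 4)
  structure(list(gamma = gamma, scale = rep(1, length(g0)),
                 loglik = 0, pos_cm = pos_cm),
            class = "posterior_trace")
}

even_sites <- function(n, step_cm = 0.1, chrom = "1") {
  site_table(chrom, seq_len(n), (seq_len(n) - 1L) * step_cm, freq = 0.5)
}

test_that("a posterior dip is called with 0-based half-open indices and SNP-to-SNP cM bounds", {
  g0 <- rep(0.99, 100)
  g0[31:70] <- 0.01
  sites <- even_sites(100)
  segs <- call_segments(fake_trace(g0, sites$pos_cm), sites,
                        caller_params(min_length_cm = 2))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start_idx, 30L)
  expect_equal(segs$end_idx, 70L)
  expect_equal(segs$n_snps, 40L)
  expect_equal(segs$start_cm, 3.0)
  expect_equal(segs$end_cm, 6.9)
  expect_equal(segs$length_cm, 3.9)
})

test_that("runs shorter than the candidate floor are not called", {
  g0 <- rep(0.99, 100)
  g0[41:55] <- 0.01   # 1.4 cM at 0.1 cM spacing
  sites <- even_sites(100)
  segs <- call_segments(fake_trace(g0, sites$pos_cm), sites,
                        caller_params(min_length_cm = 2))
  expect_equal(nrow(segs), 0L)
})

test_that("the posterior threshold boundary is exclusive", {
  g0 <- rep(0.5, 10)   # exactly at the default threshold: not below it
  sites <- even_sites(10)
  segs <- call_segments(fake_trace(g0, sites$pos_cm), sites)
  expect_equal(nrow(segs), 0L)
})

test_that("short well-flanked gaps are merged, long or poorly flanked gaps are not", {
  seg <- function(s_cm, e_cm, step = 0.1) data.frame(
    sample1 = "a", sample2 = "b", chromosome = "1",
    start_idx = as.integer(s_cm / step), end_idx = as.integer(e_cm / step) + 1L,
    start_cm = s_cm, end_cm = e_cm, length_cm = e_cm - s_cm,
    n_snps = as.integer((e_cm - s_cm) / step) + 1L,
    snps_per_cm = ((e_cm - s_cm) / step + 1) / (e_cm - s_cm),
    mean_post_nonibd = 0.05, stringsAsFactors = FALSE)
  p <- caller_params(merge_max_gap_cm = 0.5, merge_min_flank_cm = 2)
  # 0.4 cM gap between two 3 cM flanks: merged
  m <- merge_gaps(rbind(seg(10, 13), seg(13.4, 16.4)), p)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start_cm, 10)
  expect_equal(m$end_cm, 16.4)
  expect_equal(m$length_cm, 6.4)
  # 0.8 cM gap: kept apart
  m2 <- merge_gaps(rbind(seg(10, 13), seg(13.8, 16.8)), p)
  expect_equal(nrow(m2), 2L)
  # short flank (1 cM): kept apart even across a 0.3 cM gap
  m3 <- merge_gaps(rbind(seg(10, 11), seg(11.3, 14.3)), p)
  expect_equal(nrow(m3), 2L)
})

test_that("merging cascades left to right until a fixpoint", {
  seg <- function(s_cm, e_cm) data.frame(
    sample1 = "a", sample2 = "b", chromosome = "1",
    start_idx = as.integer(s_cm * 10), end_idx = as.integer(e_cm * 10) + 1L,
    start_cm = s_cm, end_cm = e_cm, length_cm = e_cm - s_cm,
    n_snps = as.integer((e_cm - s_cm) * 10) + 1L, snps_per_cm = 10,
    mean_post_nonibd = 0.05, stringsAsFactors = FALSE)
  p <- caller_params(merge_max_gap_cm = 0.5, merge_min_flank_cm = 2)
  m <- merge_gaps(rbind(seg(0, 3), seg(3.4, 6.4), seg(6.8, 9.8)), p)
  expect_equal(nrow(m), 1L)
  expect_equal(m$length_cm, 9.8)
})

test_that("marker-sparse segments are removed and the removal is counted", {
  d <- data.frame(sample1 = "a", sample2 = "b", chromosome = "1",
                  start_idx = c(0L, 100L), end_idx = c(50L, 200L),
                  start_cm = c(0, 50), end_cm = c(10, 60),
                  length_cm = c(10, 10), n_snps = c(50L, 2500L),
                  snps_per_cm = c(5, 250), mean_post_nonibd = 0.1,
                  stringsAsFactors = FALSE)
  out <- filter_density(d, caller_params(density_min_snps_per_cm = 220))
  expect_equal(nrow(out), 1L)
  expect_equal(out$snps_per_cm, 250)
  expect_equal(attr(out, "n_removed"), 1L)
})

test_that("segments mostly inside a mask are dropped, partial overlaps are truncated", {
  d <- data.frame(sample1 = "a", sample2 = "b", chromosome = "1",
                  start_idx = c(0L, 500L), end_idx = c(200L, 800L),
                  start_cm = c(0, 50), end_cm = c(20, 80),
                  length_cm = c(20, 30), n_snps = c(200L, 300L),
                  snps_per_cm = 10, mean_post_nonibd = 0.1,
                  stringsAsFactors = FALSE)
  # mask covers 60% of the first segment, 20% of the second (tail piece longest)
  masks <- mask_set(c("1", "1"), c(0, 50), c(12, 56))
  out <- apply_masks(d, masks, caller_params(mask_max_overlap = 0.5))
  expect_equal(nrow(out), 1L)
  expect_equal(out$start_cm, 56)
  expect_equal(out$end_cm, 80)
  expect_equal(out$length_cm, 24)
})

test_that("a truncated remnant below the output floor is discarded", {
  d <- data.frame(sample1 = "a", sample2 = "b", chromosome = "1",
                  start_idx = 0L, end_idx = 100L,
                  start_cm = 0, end_cm = 10, length_cm = 10, n_snps = 100L,
                  snps_per_cm = 10, mean_post_nonibd = 0.1,
                  stringsAsFactors = FALSE)
  # 30% masked, remnant 7 cM < 8 cM output floor
  masks <- mask_set("1", 7, 10)
  out <- apply_masks(d, masks, caller_params(mask_max_overlap = 0.5,
                                             output_min_length_cm = 8))
  expect_equal(nrow(out), 0L)
})

test_that("masks on other chromosomes and empty mask sets are no-ops", {
  d <- data.frame(sample1 = "a", sample2 = "b", chromosome = "1",
                  start_idx = 0L, end_idx = 100L,
                  start_cm = 0, end_cm = 10, length_cm = 10, n_snps = 100L,
                  snps_per_cm = 10, mean_post_nonibd = 0.1,
                  stringsAsFactors = FALSE)
  expect_equal(nrow(apply_masks(d, mask_set("2", 0, 100))), 1L)
  expect_equal(nrow(apply_masks(d, mask_set())), 1L)
  expect_equal(nrow(apply_masks(d, NULL)), 1L)
})

test_that("the full pipeline enforces the reporting length floor", {
  g0 <- rep(0.99, 2000)
  g0[101:700] <- 0.01    # ~6 cM at 0.01 cM spacing: candidate but below floor
  g0[1001:1901] <- 0.01  # 9 cM: reported
  sites <- even_sites(2000, step_cm = 0.01)
  segs <- postprocess_trace(fake_trace(g0, sites$pos_cm), sites,
                            caller_params(density_min_snps_per_cm = 50))
  expect_equal(nrow(segs), 1L)
  expect_gte(segs$length_cm, 8)
  expect_equal(segs$start_idx, 1000L)
})
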