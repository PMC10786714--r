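make_qc_gm <- function(frac_confident, n_sites = 100) {
  n_conf <- round(frac_confident * n_sites)
  gp <- array(NA_real_, dim = c(1, n_sites, 3))
  gp[1, , ] <- cbind(rep(c(0.995, 0.5), c(n_conf, n_sites - n_conf)),
                     rep(c(0.003, 0.3), c(n_conf, n_sites - n_conf)),
                     rep(c(0.002, 0.2), c(n_conf, n_sites - n_conf)))
  gt <- array(NA_integer_, dim = c(1, n_sites, 2))
  genotype_matrix("s1", gp, gt)
}

test_that("sample QC threshold on the confident-genotype fraction is inclusive", {
  qc <- qc_sample(make_qc_gm(0.70), "s1", threshold = 0.70)
  expect_equal(qc$frac_gp_confident, 0.70)
  expect_true(qc$pass)
  expect_false(qc_sample(make_qc_gm(0.69), "s1", threshold = 0.70)$pass)
  expect_true(qc_sample(make_qc_gm(0.90), "s1")$pass)
})

test_that("QC restricts to chromosome-3 sites when a site table is given", {
  gm <- make_qc_gm(0.5, n_sites = 100)  # 50 confident, sites 1..50
  sites <- site_table(rep(c("3", "7"), each = 50), 1:100, 1:100)
  qc <- qc_sample(gm, "s1", sites = sites)
  expect_equal(qc$frac_gp_confident, 1)  # all chr-3 sites are confident
  sites_no3 <- site_table("7", 1:100, 1:100)
  expect_error(qc_sample(gm, "s1", sites = sites_no3), "no chromosome-3")
})

test_that("batch bookkeeping counts every unordered pair exactly once", {
  for (n in c(2, 5, 50, 401, 997)) {
    for (bs in c(1L, 7L, 400L)) {
      expect_equal(count_pairs(n, bs), choose(n, 2))
    }
  }
})

test_that("pair summaries use strict length thresholds", {
  seg <- function(len) data.frame(
    sample1 = "a", sample2 = "b", chromosome = "1", start_idx = 0L,
    end_idx = 10L, start_cm = 0, end_cm = len, length_cm = len,
    n_snps = 10L, snps_per_cm = 1, mean_post_nonibd = 0.1,
    stringsAsFactors = FALSE)
  s <- summarize_pair(rbind(seg(12), seg(15), seg(25)))
  expect_equal(s$n_ibd_over_8, 3L)
  expect_equal(s$n_ibd_over_12, 2L)       # the exact-12 segment is excluded
  expect_equal(s$sum_ibd_over_12, 40)
  expect_equal(s$n_ibd_over_20, 1L)
  expect_equal(s$max_ibd_cm, 25)
  empty <- summarize_pair(NULL)
  expect_equal(empty$n_ibd_over_8, 0L)
  expect_equal(empty$max_ibd_cm, 0)
})

test_that("relationship annotation follows the documented heuristics", {
  G <- sum(autosome_lengths_cm)
  po <- list(sum_ibd_over_12 = 0.95 * G, n_ibd_over_12 = 22L,
             n_ibd_over_20 = 22L)
  expect_equal(annotate_relatives(po), "parent-offspring")
  sib <- list(sum_ibd_over_12 = 0.6 * G, n_ibd_over_12 = 50L,
              n_ibd_over_20 = 30L)
  expect_equal(annotate_relatives(sib), "1st-degree (sib)")
  second <- list(sum_ibd_over_12 = 0.25 * G, n_ibd_over_12 = 20L,
                 n_ibd_over_20 = 10L)
  expect_equal(annotate_relatives(second), "2nd-degree")
  distant <- list(sum_ibd_over_12 = 0.02 * G, n_ibd_over_12 = 3L,
                  n_ibd_over_20 = 3L)
  expect_equal(annotate_relatives(distant), "likely <=6th-degree")
  none <- list(sum_ibd_over_12 = 0, n_ibd_over_12 = 0L, n_ibd_over_20 = 0L)
  expect_equal(annotate_relatives(none), "unrelated/ambiguous")
})

test_that("screening a small cohort yields canonical pair ordering and QC exclusions", {
  cfg <- mosaic_config(chrom_length_cm = 20, n_panel = 40)
  set.seed(41)
  panel <- simulate_panel(40, mosaic_sites(cfg))
  mp1 <- make_mosaic_pair(panel, cfg)
  mp2 <- make_mosaic_pair(panel, cfg)
  genomes <- c(mp1$genomes, mp2$genomes)
  gm <- add_noise(genomes, panel$sites, noise_config(),
                  ids = c("delta", "alpha", "charlie", "bravo"))
  # break one sample's imputation quality so QC drops it
  gm$gp[1, , ] <- matrix(1 / 3, nrow = dim(gm$gp)[2], ncol = 3)
  res <- screen_pairs(gm, panel$sites, caller = caller_params(
    density_min_snps_per_cm = 75), batch_size = 2, qc_threshold = 0.7)
  expect_equal(res$excluded, "delta")
  expect_equal(nrow(res$summaries), choose(3, 2))
  expect_true(all(res$summaries$sample1 < res$summaries$sample2))
  expect_equal(res$summaries$sample1, c("alpha", "alpha", "bravo"))
  expect_equal(res$summaries$sample2, c("bravo", "charlie", "charlie"))
})

test_that("duplicate sample ids are rejected at screening", {
  gp <- array(1 / 3, dim = c(2, 10, 3))
  gt <- array(NA_integer_, dim = c(2, 10, 2))
  gm <- genotype_matrix(c("a", "b"), gp, gt)
  gm$sample_ids <- c("a", "a")
  sites <- site_table("3", 1:10, 1:10, freq = 0.5)
  expect_error(screen_pairs(gm, sites), "duplicate")
})
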