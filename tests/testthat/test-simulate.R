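test_that("simulated site tables are evenly spaced at the requested density", {
  cfg <- mosaic_config(chrom_length_cm = 10, snps_per_cm = 100)
  sites <- mosaic_sites(cfg)
  expect_equal(nrow(sites), 1000L)
  expect_equal(sites$pos_cm[1], 0)
  expect_equal(max(sites$pos_cm), 10)
  expect_equal(diff(range(diff(sites$pos_cm))), 0, tolerance = 1e-12)
})

test_that("panel haplotypes are binary with recorded generating frequencies", {
  cfg <- mosaic_config(chrom_length_cm = 5, n_panel = 30)
  set.seed(2)
  panel <- simulate_panel(30, mosaic_sites(cfg))
  expect_equal(dim(panel$haps), c(30L, 750L))
  expect_true(all(panel$haps %in% 0:1))
  expect_true(all(panel$sites$freq >= 1e-4 & panel$sites$freq <= 1 - 1e-4))
  # observed panel frequencies track the generating p
  expect_gt(cor(colMeans(panel$haps), panel$sites$freq), 0.8)
})

test_that("the copying process induces local LD between non-founder haplotypes", {
  cfg <- mosaic_config(chrom_length_cm = 20, n_panel = 60)
  set.seed(3)
  panel <- simulate_panel(60, mosaic_sites(cfg))
  # non-founders are long stretches copied from founders: a non-founder
  # must match a single founder over many consecutive sites somewhere
  founders <- panel$haps[1:20, , drop = FALSE]
  nf <- panel$haps[60, ]
  # in at least one 1-cM window no template switch occurred, so the
  # non-founder matches one founder exactly there
  best <- max(vapply(seq(1, 2851, by = 150), function(s) {
    w <- s:(s + 149)
    max(apply(founders[, w, drop = FALSE], 1L,
              function(f) mean(f == nf[w])))
  }, numeric(1)))
  expect_gt(best, 0.99)
})

test_that("copied-in segments create exactly matching haplotype stretches with recorded truth", {
  cfg <- mosaic_config(chrom_length_cm = 30, n_panel = 30)
  set.seed(4)
  panel <- simulate_panel(30, mosaic_sites(cfg))
  mp <- make_mosaic_pair(panel, cfg,
                         ibd = data.frame(start_cm = 10, length_cm = 8))
  expect_equal(mp$truth$start_cm, 10)
  expect_equal(mp$truth$end_cm, 18)
  sel <- mp$sites$pos_cm >= 10 & mp$sites$pos_cm < 18
  agree <- vapply(1:2, function(h1) vapply(1:2, function(h2) {
    all(mp$genomes[[1]][[h1]][sel] == mp$genomes[[2]][[h2]][sel])
  }, logical(1)), matrix(logical(2), 2))
  expect_true(any(agree))  # some haplotype pair is identical over the segment
})

test_that("invalid copied-in segment requests are rejected", {
  cfg <- mosaic_config(chrom_length_cm = 20, n_panel = 20)
  set.seed(5)
  panel <- simulate_panel(20, mosaic_sites(cfg))
  expect_error(make_mosaic_pair(panel, cfg,
                                data.frame(start_cm = 15, length_cm = 10)),
               "outside the chromosome")
  expect_error(make_mosaic_pair(panel, cfg,
                                data.frame(start_cm = c(2, 5),
                                           length_cm = c(6, 4))),
               "overlap")
})

test_that("noise tiers set decreasing GP quality and unknown tiers error", {
  concs <- vapply(c("2x", "1x", "0.5x", "0.25x"),
                  function(t) noise_config(tier = t)$gp_concentration,
                  numeric(1))
  expect_true(all(diff(concs) < 0))
  miscalls <- vapply(c("2x", "1x", "0.5x", "0.25x"),
                     function(t) noise_config(tier = t)$gp_miscall,
                     numeric(1))
  expect_true(all(diff(miscalls) > 0))
  expect_error(noise_config(tier = "30x"), "unknown tier")
})

test_that("infinite concentration and zero switch rate reproduce the truth exactly", {
  cfg <- mosaic_config(chrom_length_cm = 5, n_panel = 20)
  set.seed(6)
  panel <- simulate_panel(20, mosaic_sites(cfg))
  mp <- make_mosaic_pair(panel, cfg)
  gm <- add_noise(mp$genomes, mp$sites, noise_config())
  for (j in 1:2) {
    g_true <- mp$genomes[[j]][[1]] + mp$genomes[[j]][[2]]
    expect_equal(gm$gp[j, , 1], as.numeric(g_true == 0))
    expect_equal(gm$gp[j, , 2], as.numeric(g_true == 1))
    expect_equal(gm$gp[j, , 3], as.numeric(g_true == 2))
    expect_equal(gm$gt[j, , 1], mp$genomes[[j]][[1]])
    expect_equal(gm$gt[j, , 2], mp$genomes[[j]][[2]])
  }
})

test_that("finite concentration yields normalised GP triples centred on the truth", {
  cfg <- mosaic_config(chrom_length_cm = 5, n_panel = 20)
  set.seed(7)
  panel <- simulate_panel(20, mosaic_sites(cfg))
  mp <- make_mosaic_pair(panel, cfg)
  gm <- add_noise(mp$genomes, mp$sites, noise_config(gp_concentration = 100))
  s <- gm$gp[1, , 1] + gm$gp[1, , 2] + gm$gp[1, , 3]
  expect_equal(s, rep(1, length(s)), tolerance = 1e-9)
  g_true <- mp$genomes[[1]][[1]] + mp$genomes[[1]][[2]]
  argmax <- max.col(cbind(gm$gp[1, , 1], gm$gp[1, , 2], gm$gp[1, , 3])) - 1L
  expect_gt(mean(argmax == g_true), 0.95)
})

test_that("phase switch errors flip the reported haplotype order in parity blocks", {
  cfg <- mosaic_config(chrom_length_cm = 50, n_panel = 20)
  set.seed(8)
  panel <- simulate_panel(20, mosaic_sites(cfg))
  mp <- make_mosaic_pair(panel, cfg)
  gm <- add_noise(mp$genomes, mp$sites, noise_config(phase_switch_rate = 0.2))
  hA <- mp$genomes[[1]][[1]]; hB <- mp$genomes[[1]][[2]]
  straight <- gm$gt[1, , 1] == hA & gm$gt[1, , 2] == hB
  flipped <- gm$gt[1, , 1] == hB & gm$gt[1, , 2] == hA
  expect_true(all(straight | flipped))
  het <- hA != hB
  # with rate 0.2/cM over 50 cM, some het sites should be genuinely flipped
  expect_true(any(flipped[het] & !straight[het]))
})

test_that("pair simulation is reproducible from its seed", {
  a <- simulate_ibd_pair(mosaic_config(chrom_length_cm = 4, n_panel = 16),
                         noise_config(gp_concentration = 30),
                         ibd = data.frame(start_cm = 1, length_cm = 2),
                         seed = 99)
  b <- simulate_ibd_pair(mosaic_config(chrom_length_cm = 4, n_panel = 16),
                         noise_config(gp_concentration = 30),
                         ibd = data.frame(start_cm = 1, length_cm = 2),
                         seed = 99)
  expect_identical(a$gm$gp, b$gm$gp)
  expect_identical(a$gm$gt, b$gm$gt)
  expect_identical(a$truth, b$truth)
})
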