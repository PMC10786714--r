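#' Configuration of the mosaic-haplotype simulator
#'
#' Synthetic chromosomes are built by stitching short stretches
#' (`chunk_cm`) copied from a panel of source haplotypes. The stitching
#' destroys long-range haplotype sharing while keeping local allele
#' structure, so any long IBD between two mosaic genomes is only what the
#' simulation explicitly copies in.
#'
#' @param chunk_cm Length of each copied stretch (cM).
#' @param chrom_length_cm Simulated chromosome length (cM).
#' @param snps_per_cm Marker density (sites per cM).
#' @param chrom Chromosome label for the site table.
#' @param n_panel Number of panel haplotypes to draw chunks from.
#' @return An object of class `mosaic_config`.
#' @export
mosaic_config <- function(chunk_cm = 0.25, chrom_length_cm = 100,
                          snps_per_cm = 150, chrom = "3", n_panel = 200L) {
  stopifnot(chunk_cm > 0, chrom_length_cm > 0, snps_per_cm > 0,
            n_panel >= 4L)
  structure(as.list(environment()), class = "mosaic_config")
}

#' Site table for a simulated chromosome
#'
#' Markers are evenly spaced in genetic distance; physical positions are a
#' nominal 1 Mb/cM.
#' @param cfg A [mosaic_config()].
#' @return A [site_table()] with `pos_cm` filled (frequencies added by
#'   [simulate_panel()]).
#' @export
mosaic_sites <- function(cfg) {
  L <- round(cfg$chrom_length_cm * cfg$snps_per_cm)
  cm <- seq(0, cfg$chrom_length_cm, length.out = L)
  site_table(cfg$chrom, as.integer(round(cm * 1e6)) + 1L, cm)
}

#' Simulate a panel of source haplotypes
#'
#' Per-site alternative-allele frequencies are drawn from a beta-shaped
#' spectrum; a subset of "founder" haplotypes is drawn independently
#' Bernoulli(p) per site, and the remaining haplotypes are produced by a
#' copying process (template switches along the map) that induces local
#' linkage disequilibrium. The generating frequencies are recorded as the
#' truth `p` used by the emission model.
#'
#' @param n_haplotypes Panel size.
#' @param sites A [site_table()] with `pos_cm` filled.
#' @param switch_rate_per_cm Template switch rate of the copying process.
#' @return A list with `haps` (binary matrix `n_haplotypes x n_sites`) and
#'   `sites` (the site table with `freq` set to the generating p).
#' @export
simulate_panel <- function(n_haplotypes, sites, switch_rate_per_cm = 0.5) {
  L <- nrow(sites)
  if (L == 0L) {
    return(list(haps = matrix(integer(), max(n_haplotypes, 0L), 0L),
                sites = sites))
  }
  p <- clamp_freq(0.05 + 0.9 * stats::rbeta(L, 0.7, 0.7))
  sites$freq <- p
  n_founders <- max(8L, ceiling(n_haplotypes / 3))
  n_founders <- min(n_founders, n_haplotypes)
  haps <- matrix(0L, n_haplotypes, L)
  for (i in seq_len(n_founders)) {
    haps[i, ] <- stats::rbinom(L, 1L, p)
  }
  if (n_haplotypes > n_founders) {
    span <- max(sites$pos_cm) - min(sites$pos_cm)
    for (i in (n_founders + 1L):n_haplotypes) {
      n_sw <- stats::rpois(1L, switch_rate_per_cm * span)
      cuts <- sort(stats::runif(n_sw, min(sites$pos_cm), max(sites$pos_cm)))
      bounds <- c(min(sites$pos_cm) - 1, cuts, max(sites$pos_cm) + 1)
      for (b in seq_len(length(bounds) - 1L)) {
        sel <- sites$pos_cm >= bounds[b] & sites$pos_cm < bounds[b + 1L]
        tpl <- sample.int(n_founders, 1L)
        haps[i, sel] <- haps[tpl, sel]
      }
    }
  }
  list(haps = haps, sites = sites)
}

# one mosaic haplotype: chunk boundaries every chunk_cm, random panel donor
stitch_mosaic <- function(panel_haps, pos_cm, chunk_cm) {
  L <- length(pos_cm)
  hap <- integer(L)
  chunk <- findInterval(pos_cm, seq(0, max(pos_cm) + chunk_cm, by = chunk_cm))
  donors <- sample.int(nrow(panel_haps), max(chunk), replace = TRUE)
  for (cid in unique(chunk)) {
    sel <- chunk == cid
    hap[sel] <- panel_haps[donors[cid], sel]
  }
  hap
}

#' Build a pair of mosaic diploid genomes with copied-in IBD
#'
#' Both genomes are independent chunk mosaics; for every requested IBD
#' segment a freshly stitched donor stretch is copied onto one haplotype
#' of each individual over the same map interval, creating ground-truth
#' IBD of exactly known position and length.
#'
#' @param panel A [simulate_panel()] result.
#' @param cfg The [mosaic_config()] used to build the panel sites.
#' @param ibd Data.frame with columns `start_cm` and `length_cm` of
#'   segments to copy in (non-overlapping, inside the chromosome).
#' @return A list with `genomes` (list of two individuals, each a list of
#'   two 0/1 haplotype vectors), `truth` (data.frame of copied segments)
#'   and `sites`.
#' @export
make_mosaic_pair <- function(panel, cfg,
                             ibd = data.frame(start_cm = numeric(),
                                              length_cm = numeric())) {
  sites <- panel$sites
  pos <- sites$pos_cm
  if (nrow(ibd) > 0L) {
    ends <- ibd$start_cm + ibd$length_cm
    if (any(ibd$start_cm < 0) || any(ends > cfg$chrom_length_cm)) {
      stop("requested IBD segment outside the chromosome")
    }
    o <- order(ibd$start_cm)
    if (any(ibd$start_cm[o][-1L] < ends[o][-nrow(ibd)])) {
      stop("requested IBD segments overlap")
    }
  }
  genomes <- lapply(1:2, function(i) {
    lapply(1:2, function(h) stitch_mosaic(panel$haps, pos, cfg$chunk_cm))
  })
  truth <- list()
  for (k in seq_len(nrow(ibd))) {
    s <- ibd$start_cm[k]; e <- s + ibd$length_cm[k]
    sel <- pos >= s & pos < e
    donor <- stitch_mosaic(panel$haps, pos, cfg$chunk_cm)
    h1 <- sample.int(2L, 1L); h2 <- sample.int(2L, 1L)
    genomes[[1L]][[h1]][sel] <- donor[sel]
    genomes[[2L]][[h2]][sel] <- donor[sel]
    truth[[k]] <- data.frame(chrom = cfg$chrom, start_cm = s, end_cm = e,
                             length_cm = e - s, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(chrom = character(), start_cm = numeric(),
               end_cm = numeric(), length_cm = numeric(),
               stringsAsFactors = FALSE)
  }
  list(genomes = genomes, truth = truth, sites = sites)
}

#' Genotype-probability noise model
#'
#' A parametric stand-in for empirically matched imputation noise: at every
#' site the GP triple is drawn from a Dirichlet distribution centred on the
#' true diploid genotype with concentration `gp_concentration`
#' (`Inf` = noiseless one-hot GPs). Named coverage tiers bundle
#' concentrations loosely mimicking imputation quality at decreasing
#' coverage; they are calibration knobs, not measurements of any specific
#' dataset. Phase integrity is degraded separately: switch points are
#' placed as a Poisson process of `phase_switch_rate` per cM, and the
#' reported haplotype order flips at each point.
#'
#' @param gp_concentration Dirichlet concentration on the centred genotype;
#'   overridden by `tier` when given.
#' @param gp_miscall Probability that a site's GP triple centres on a wrong
#'   genotype (imputation miscall); overridden by `tier`.
#' @param phase_switch_rate Phase switch errors per cM.
#' @param tier One of `"2x"`, `"1x"`, `"0.5x"`, `"0.25x"` (concentration /
#'   miscall: 200 / 0.002, 60 / 0.01, 20 / 0.06, 8 / 0.15).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(gp_concentration = Inf, gp_miscall = 0,
                         phase_switch_rate = 0, tier = NULL) {
  tiers <- list("2x" = c(200, 0.002), "1x" = c(60, 0.01),
                "0.5x" = c(20, 0.06), "0.25x" = c(8, 0.15))
  if (!is.null(tier)) {
    if (!tier %in% names(tiers)) {
      stop("unknown tier; use one of ", paste(names(tiers), collapse = ", "))
    }
    gp_concentration <- tiers[[tier]][1L]
    gp_miscall <- tiers[[tier]][2L]
  }
  stopifnot(gp_concentration > 0, phase_switch_rate >= 0,
            gp_miscall >= 0, gp_miscall < 1)
  structure(list(gp_concentration = gp_concentration,
                 gp_miscall = gp_miscall,
                 phase_switch_rate = phase_switch_rate, tier = tier),
            class = "noise_config")
}

#' Turn true genomes into a noisy genotype matrix
#'
#' Emits GP triples concentrated on the true genotype and phased GT calls
#' whose haplotype order flips downstream of Poisson-placed phase switch
#' points, emulating imputed low-coverage output.
#'
#' @param genomes List of individuals, each a list of two 0/1 haplotype
#'   vectors (as from [make_mosaic_pair()]).
#' @param sites The matching [site_table()].
#' @param noise A [noise_config()].
#' @param ids Sample ids.
#' @return A [genotype_matrix()].
#' @export
add_noise <- function(genomes, sites, noise = noise_config(),
                      ids = paste0("ind", seq_along(genomes))) {
  L <- nrow(sites)
  nS <- length(genomes)
  gp <- array(NA_real_, dim = c(nS, L, 3L))
  gt <- array(NA_integer_, dim = c(nS, L, 2L))
  span <- max(sites$pos_cm) - min(sites$pos_cm)
  for (j in seq_len(nS)) {
    hA <- genomes[[j]][[1L]]; hB <- genomes[[j]][[2L]]
    g <- hA + hB
    if (noise$gp_miscall > 0) {
      bad <- stats::runif(L) < noise$gp_miscall
      shift <- sample(1:2, sum(bad), replace = TRUE)
      g[bad] <- (g[bad] + shift) %% 3L
    }
    if (is.finite(noise$gp_concentration)) {
      alpha <- matrix(0.3, L, 3L)
      alpha[cbind(seq_len(L), g + 1L)] <-
        alpha[cbind(seq_len(L), g + 1L)] + noise$gp_concentration
      draws <- matrix(stats::rgamma(3L * L, shape = alpha), L, 3L)
      gp[j, , ] <- draws / rowSums(draws)
    } else {
      onehot <- matrix(0, L, 3L)
      onehot[cbind(seq_len(L), g + 1L)] <- 1
      gp[j, , ] <- onehot
    }
    n_sw <- stats::rpois(1L, noise$phase_switch_rate * span)
    flip <- rep(FALSE, L)
    if (n_sw > 0L) {
      pts <- stats::runif(n_sw, min(sites$pos_cm), max(sites$pos_cm))
      flip <- (outer(sites$pos_cm, pts, ">") |> rowSums()) %% 2L == 1L
    }
    gt[j, , 1L] <- ifelse(flip, hB, hA)
    gt[j, , 2L] <- ifelse(flip, hA, hB)
  }
  genotype_matrix(ids, gp, gt)
}

#' One-call simulation of an imputed pair with known IBD
#'
#' Convenience wrapper: panel, mosaic pair with copied-in IBD, and noise,
#' reproducible from a seed.
#'
#' @param cfg A [mosaic_config()].
#' @param noise A [noise_config()].
#' @param ibd Data.frame of segments to copy in (`start_cm`, `length_cm`).
#' @param panel Optional pre-built [simulate_panel()] result to reuse
#'   across replicates.
#' @param seed Optional integer seed.
#' @return A list with `sites`, `gm` (samples `ind1`, `ind2`) and `truth`.
#' @export
simulate_ibd_pair <- function(cfg = mosaic_config(),
                              noise = noise_config(),
                              ibd = data.frame(start_cm = numeric(),
                                               length_cm = numeric()),
                              panel = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(panel)) panel <- simulate_panel(cfg$n_panel, mosaic_sites(cfg))
  mp <- make_mosaic_pair(panel, cfg, ibd)
  gm <- add_noise(mp$genomes, mp$sites, noise)
  list(sites = mp$sites, gm = gm, truth = mp$truth)
}
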