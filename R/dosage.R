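#' Haploid dosages from imputed genotype probabilities
#'
#' Converts per-site genotype posterior triples (GP) and phased genotype
#' calls (GT) into haploid dosages — the probability that each phased
#' haplotype carries the alternative allele. These four dosages per site
#' (1A, 1B, 2A, 2B for a pair of individuals) are the observed data of the
#' IBD HMM's emission model.
#'
#' For one individual with genotype posteriors `(p0, p1, p2)` the four
#' phased-genotype probabilities are approximated as `P00 = p0`,
#' `P11 = p2` and, for the heterozygote mass `p1`:
#' * if the GP argmax is the heterozygote and GT is a phased heterozygote,
#'   all of `p1` is assigned to the orientation GT reports (`P01 = p1` for
#'   `0|1`, `P10 = p1` for `1|0`);
#' * otherwise (homozygote argmax, unphased or missing GT, or an
#'   inconsistent record where GP says heterozygote but GT is homozygous)
#'   the mass is split: `P01 = P10 = p1 / 2`.
#'
#' The dosages are then `xA = P11 + P10`, `xB = P11 + P01`.
#'
#' @param gp Numeric matrix `n_sites x 3` of genotype posteriors (rows
#'   normalised).
#' @param gt Integer matrix `n_sites x 2` of phased haplotype alleles (0/1),
#'   `NA` for missing/unphased.
#' @return A list with `x` (`n_sites x 2` matrix of dosages for haplotypes
#'   A and B) and `n_inconsistent`, the count of records whose GP argmax was
#'   heterozygous while GT was homozygous.
#' @export
haploid_dosages <- function(gp, gt) {
  stopifnot(is.matrix(gp), ncol(gp) == 3L)
  n <- nrow(gp)
  if (is.null(gt)) gt <- matrix(NA_integer_, n, 2L)
  stopifnot(nrow(gt) == n, ncol(gt) == 2L)
  p1 <- gp[, 2L]
  amax <- max.col(gp, ties.method = "first")
  het_max <- amax == 2L
  gt_phased_het <- !is.na(gt[, 1L]) & !is.na(gt[, 2L]) & (gt[, 1L] != gt[, 2L])
  gt_hom <- !is.na(gt[, 1L]) & !is.na(gt[, 2L]) & (gt[, 1L] == gt[, 2L])
  inconsistent <- het_max & gt_hom

  P10 <- p1 / 2
  P01 <- p1 / 2
  use_phase <- het_max & gt_phased_het
  # GT a|b with a = first haplotype: 1|0 puts the alt allele on haplotype A
  is10 <- use_phase & gt[, 1L] == 1L
  is01 <- use_phase & gt[, 1L] == 0L
  P10[is10] <- p1[is10]; P01[is10] <- 0
  P01[is01] <- p1[is01]; P10[is01] <- 0

  P11 <- gp[, 3L]
  xA <- pmin(pmax(P11 + P10, 0), 1)
  xB <- pmin(pmax(P11 + P01, 0), 1)
  list(x = cbind(A = xA, B = xB), n_inconsistent = sum(inconsistent))
}

#' Haploid dosages for a pair of samples in a genotype matrix
#'
#' Sites with missing GP in either sample are dropped (the emission model is
#' undefined there); the kept-site index is returned for alignment with the
#' site table.
#'
#' @param gm A `genotype_matrix` (see [read_vcf()]).
#' @param pair Character or integer vector of length 2 naming the samples.
#' @return A list with `x` (`n_kept x 4` dosage matrix, columns 1A, 1B, 2A,
#'   2B), `kept` (integer site indices used), `n_dropped` and
#'   `n_inconsistent`.
#' @export
pair_dosages <- function(gm, pair) {
  idx <- sample_index(gm, pair)
  gp1 <- gm$gp[idx[1L], , ]; gp2 <- gm$gp[idx[2L], , ]
  ok <- stats::complete.cases(gp1) & stats::complete.cases(gp2)
  kept <- which(ok)
  gt1 <- matrix(gm$gt[idx[1L], kept, ], ncol = 2L)
  gt2 <- matrix(gm$gt[idx[2L], kept, ], ncol = 2L)
  d1 <- haploid_dosages(gp1[kept, , drop = FALSE], gt1)
  d2 <- haploid_dosages(gp2[kept, , drop = FALSE], gt2)
  list(x = cbind(`1A` = d1$x[, 1L], `1B` = d1$x[, 2L],
                 `2A` = d2$x[, 1L], `2B` = d2$x[, 2L]),
       kept = kept,
       n_dropped = sum(!ok),
       n_inconsistent = d1$n_inconsistent + d2$n_inconsistent)
}

sample_index <- function(gm, pair) {
  stopifnot(length(pair) == 2L)
  if (is.character(pair)) {
    idx <- match(pair, gm$sample_ids)
    if (anyNA(idx)) stop("sample(s) not found: ",
                         paste(pair[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(pair)
  }
  idx
}
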