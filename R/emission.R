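#' Emission likelihood ratios of the five HMM states
#'
#' Computes, for every site, the likelihood of the four haploid dosages
#' under each hidden state, expressed relative to the non-IBD state so that
#' the non-IBD column is identically 1. For the state sharing haplotypes
#' `h1` of individual 1 and `h2` of individual 2 the closed form is
#'
#' `e = x_h1 * x_h2 / p + (1 - x_h1) * (1 - x_h2) / (1 - p)`,
#'
#' where `p` is the population frequency of the alternative allele. This is
#' the collapsed form of a sum over the 16 latent phased genotype
#' combinations with Hardy-Weinberg priors, in which the shared haplotype
#' counts as a single draw from the population (see
#' [emission_bruteforce_oracle()]).
#'
#' @param x Numeric matrix `n_sites x 4`, haploid dosages in column order
#'   1A, 1B, 2A, 2B.
#' @param p Numeric vector of alternative-allele frequencies; clamped to
#'   `[1e-4, 1 - 1e-4]`.
#' @return Numeric matrix `n_sites x 5`; column 1 (non-IBD) is all ones,
#'   columns 2-5 correspond to shared pairs (1A,2A), (1A,2B), (1B,2A),
#'   (1B,2B).
#' @export
emission_likelihoods <- function(x, p) {
  stopifnot(is.matrix(x), ncol(x) == 4L, length(p) == nrow(x))
  p <- clamp_freq(p)
  e1 <- pair_state_lik(x[, 1L], x[, 3L], p)
  e2 <- pair_state_lik(x[, 1L], x[, 4L], p)
  e3 <- pair_state_lik(x[, 2L], x[, 3L], p)
  e4 <- pair_state_lik(x[, 2L], x[, 4L], p)
  e <- cbind(1, e1, e2, e3, e4)
  if (!all(is.finite(e))) {
    stop("non-finite emission at site(s) ",
         paste(utils::head(which(!stats::complete.cases(e)), 5L),
               collapse = ", "))
  }
  dimnames(e) <- NULL
  e
}

pair_state_lik <- function(xa, xb, p) {
  xa * xb / p + (1 - xa) * (1 - xb) / (1 - p)
}

clamp_freq <- function(p, eps = 1e-4) {
  pmin(pmax(p, eps), 1 - eps)
}

#' Brute-force emission likelihoods by latent-genotype enumeration
#'
#' Independent reference for [emission_likelihoods()] at a single site: sums
#' over all 16 latent phased genotype vectors `g = (g1A, g1B, g2A, g2B)` the
#' term `P(g | D) / P(g) * P(g | s)`, with `P(g | D)` a product of Bernoulli
#' haplotype terms from the dosages, `P(g)` the Hardy-Weinberg product of
#' four allele-frequency factors, and `P(g | s)` the Hardy-Weinberg prior
#' under the state: for an IBD state the two shared alleles are one draw
#' (three factors; combinations where the shared alleles differ have
#' probability zero). Used as the test oracle; the closed form must agree
#' to near machine precision.
#'
#' @param x Numeric vector of 4 haploid dosages (1A, 1B, 2A, 2B).
#' @param p Alternative-allele frequency (scalar), clamped as in
#'   [emission_likelihoods()].
#' @return Numeric vector of 5 state likelihood ratios.
#' @export
emission_bruteforce_oracle <- function(x, p) {
  stopifnot(length(x) == 4L, length(p) == 1L)
  p <- clamp_freq(p)
  g <- as.matrix(expand.grid(g1A = 0:1, g1B = 0:1, g2A = 0:1, g2B = 0:1))
  freq <- function(a) ifelse(a == 1, p, 1 - p)
  # P(g | D): product of per-haplotype Bernoulli terms
  pgd <- apply(g, 1L, function(gg) prod(gg * x + (1 - gg) * (1 - x)))
  pg <- apply(g, 1L, function(gg) prod(freq(gg)))
  shared <- list(NULL, c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L))
  vapply(seq_len(5L), function(s) {
    pgs <- apply(g, 1L, function(gg) {
      if (s == 1L) return(prod(freq(gg)))
      sh <- shared[[s]]
      if (gg[sh[1L]] != gg[sh[2L]]) return(0)
      prod(freq(gg[-sh[1L]]))
    })
    sum(pgd / pg * pgs)
  }, numeric(1L))
}
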