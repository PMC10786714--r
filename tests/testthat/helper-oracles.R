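# Independent reference implementations used as oracles in the tests.
# These deliberately avoid the package's own computational shortcuts:
# the forward-backward oracle works in log space with full 5x5 matrix
# products, and the matrix exponential oracle uses Matrix::expm on the
# dense generator.

# Log-space forward-backward over an explicit list of 5x5 transition
# matrices (one per interval). Returns the posterior state marginals.
log_space_posteriors <- function(e, trans_list, pi0) {
  n <- nrow(e)
  k <- ncol(e)
  log_e <- log(pmax(e, .Machine$double.xmin))
  log_pi <- log(pmax(pi0, .Machine$double.xmin))
  log_sum_exp <- function(v) {
    m <- max(v)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(v - m)))
  }
  la <- matrix(-Inf, n, k)
  la[1, ] <- log_pi + log_e[1, ]
  for (t in 2:n) {
    lA <- log(pmax(trans_list[[t - 1L]], .Machine$double.xmin))
    for (j in seq_len(k)) {
      la[t, j] <- log_sum_exp(la[t - 1L, ] + lA[, j]) + log_e[t, j]
    }
  }
  lb <- matrix(0, n, k)
  for (t in (n - 1L):1L) {
    lA <- log(pmax(trans_list[[t]], .Machine$double.xmin))
    for (i in seq_len(k)) {
      lb[t, i] <- log_sum_exp(lA[i, ] + log_e[t + 1L, ] + lb[t + 1L, ])
    }
  }
  lg <- la + lb
  gamma <- t(apply(lg, 1L, function(v) exp(v - log_sum_exp(v))))
  list(gamma = gamma, loglik = log_sum_exp(la[n, ]))
}

# Dense matrix exponential of the full 5x5 generator, via Matrix::expm.
dense_transition_oracle <- function(rates, r_morgan) {
  q <- rate_matrix(rates)
  as.matrix(Matrix::expm(q * r_morgan))
}
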