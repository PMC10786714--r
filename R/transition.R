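#' Transition rate parameters of the IBD hidden Markov model
#'
#' The chain has five states: state 0 is "non-IBD" and states 1-4 are the
#' four possible shared haplotype pairs (1A/2A, 1A/2B, 1B/2A, 1B/2B) between
#' two phased diploid genomes. Three rates, all per Morgan, define the
#' infinitesimal generator `Q`:
#' * `ibd_in` — rate of jumping from non-IBD into each of the four IBD states,
#' * `ibd_out` — rate of jumping from any IBD state back to non-IBD,
#' * `ibd_switch` — rate of jumping from one IBD state to each other IBD state
#'   (this models phase switch errors inside a true IBD segment: a switch
#'   changes which haplotype pair is shared).
#'
#' `initial_nonibd` is the probability mass the chain places on the non-IBD
#' state at the first marker of a chromosome; the remainder is split equally
#' across the four IBD states so that a segment overlapping the chromosome
#' start is reachable.
#'
#' Default values were frozen from the package's own grid-search calibration
#' harness (see [grid_search_defaults()] and the methods vignette).
#'
#' @param ibd_in,ibd_out,ibd_switch Non-negative rates per Morgan.
#' @param initial_nonibd Start-distribution mass on the non-IBD state,
#'   in (0, 1].
#' @return An object of class `ibd_rates`.
#' @export
ibd_rates <- function(ibd_in = 0.01, ibd_out = 5, ibd_switch = 7.5,
                      initial_nonibd = 0.999) {
  stopifnot(is.numeric(ibd_in), is.numeric(ibd_out), is.numeric(ibd_switch),
            length(ibd_in) == 1L, length(ibd_out) == 1L,
            length(ibd_switch) == 1L)
  if (!all(is.finite(c(ibd_in, ibd_out, ibd_switch))) ||
      any(c(ibd_in, ibd_out, ibd_switch) < 0)) {
    stop("rates must be finite and non-negative")
  }
  if (!is.numeric(initial_nonibd) || length(initial_nonibd) != 1L ||
      initial_nonibd <= 0 || initial_nonibd > 1) {
    stop("'initial_nonibd' must be in (0, 1]")
  }
  structure(list(ibd_in = ibd_in, ibd_out = ibd_out,
                 ibd_switch = ibd_switch,
                 initial_nonibd = initial_nonibd),
            class = "ibd_rates")
}

#' @export
print.ibd_rates <- function(x, ...) {
  cat("IBD HMM transition rates (per Morgan):\n")
  cat(sprintf("  ibd_in = %g, ibd_out = %g, ibd_switch = %g\n",
              x$ibd_in, x$ibd_out, x$ibd_switch))
  cat(sprintf("  start mass on non-IBD: %g\n", x$initial_nonibd))
  invisible(x)
}

#' Full 5x5 generator matrix
#'
#' Rows sum to zero. Row/column order: non-IBD, then the four IBD states.
#' @param rates An [ibd_rates()] object.
#' @return A 5x5 numeric matrix.
#' @export
rate_matrix <- function(rates) {
  i <- rates$ibd_in; o <- rates$ibd_out; w <- rates$ibd_switch
  Q <- matrix(w, 5, 5)
  Q[1, ] <- i
  Q[, 1] <- o
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# Collapsed 3-state generator seen from one focal IBD state:
# states (non-IBD, focal IBD, other-IBD pooled). The pooled state absorbs
# the three symmetric alternatives, so only 3x3 exponentials are needed.
collapsed_rate_matrix <- function(rates) {
  i <- rates$ibd_in; o <- rates$ibd_out; w <- rates$ibd_switch
  matrix(c(-4 * i,           i,            3 * i,
           o,      -(o + 3 * w),           3 * w,
           o,                 w,     -(o + w)),
         nrow = 3, byrow = TRUE)
}

# Eigen-decompose the collapsed generator once, so that exp(Q3 * r) for many
# distances r is a sum of three rank-one terms scaled by exp(lambda_k * r).
# Returns coefficient matrices C_k with exp(Q3 r) = sum_k C_k exp(lambda_k r),
# or NULL when the decomposition is too ill-conditioned (dense fallback).
collapsed_eigen <- function(rates) {
  Q3 <- collapsed_rate_matrix(rates)
  eg <- eigen(Q3)
  V <- eg$vectors
  kappa <- tryCatch(1 / rcond(Re(V)), error = function(e) Inf)
  if (!is.finite(kappa) || kappa > 1e10) return(NULL)
  Vinv <- solve(V)
  list(lambda = eg$values,
       coef = lapply(seq_len(3L), function(k) V[, k] %o% Vinv[k, ]))
}

# exp(Q3 * r) for a vector of distances r (Morgans).  Returns the five
# distinct entries of the expanded 5x5 transition matrix as columns:
#   a = P(0 -> 0), b = P(0 -> one given IBD state),
#   c = P(IBD -> 0), d = P(IBD -> same IBD), f = P(IBD -> one other IBD).
transition_components <- function(rates, r) {
  if (any(r < 0)) stop("genetic distances must be non-negative")
  dec <- collapsed_eigen(rates)
  n <- length(r)
  M <- array(0, dim = c(3, 3, n))
  if (!is.null(dec)) {
    # M[i,j,t] = sum_k C_k[i,j] * exp(lambda_k r_t)
    M <- array(0i, dim = c(3, 3, n))
    for (k in 1:3) {
      ek <- exp(dec$lambda[k] * r)
      Ck <- dec$coef[[k]]
      M <- M + outer(Ck, ek)
    }
    M <- Re(M)
  } else {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("ill-conditioned rate matrix and package 'Matrix' not available")
    }
    Q3 <- collapsed_rate_matrix(rates)
    for (t in seq_len(n)) {
      M[, , t] <- as.matrix(Matrix::expm(Q3 * r[t]))
    }
  }
  a <- pmin(pmax(M[1, 1, ], 0), 1)
  b <- pmin(pmax(M[1, 2, ], 0), 1)
  cc <- pmin(pmax(M[2, 1, ], 0), 1)
  d <- pmin(pmax(M[2, 2, ], 0), 1)
  f <- pmin(pmax(M[2, 3, ] / 3, 0), 1)
  cbind(a = a, b = b, c = cc, d = d, f = f)
}

#' Transition probability matrix over a genetic distance
#'
#' Computes `exp(Q * r)` for the five-state chain, where `Q` is the generator
#' implied by `rates` and `r` a genetic distance in Morgans. Internally the
#' three symmetric "other IBD" states are collapsed so only a 3x3 matrix is
#' exponentiated (by eigendecomposition); the 5x5 matrix is then rebuilt from
#' the symmetry.
#'
#' @param rates An [ibd_rates()] object.
#' @param r Genetic distance in Morgans (scalar, `>= 0`).
#' @return A row-stochastic 5x5 matrix.
#' @export
transition_matrix <- function(rates, r) {
  stopifnot(is.numeric(r), length(r) == 1L)
  if (!is.finite(r) || r < 0) stop("genetic distance 'r' must be >= 0")
  cmp <- transition_components(rates, r)
  a <- cmp[1, "a"]; b <- cmp[1, "b"]; cc <- cmp[1, "c"]
  d <- cmp[1, "d"]; f <- cmp[1, "f"]
  A <- matrix(f, 5, 5)
  A[1, 1] <- a
  A[1, 2:5] <- b
  A[2:5, 1] <- cc
  diag(A)[2:5] <- d
  A / rowSums(A)
}

# Start distribution implied by the rates object.
start_distribution <- function(rates) {
  c(rates$initial_nonibd, rep((1 - rates$initial_nonibd) / 4, 4))
}
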