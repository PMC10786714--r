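#' Rescaled forward-backward posterior decoding
#'
#' Runs the scaled (non-logarithmic) forward-backward algorithm over one
#' chromosome, returning per-site posterior state probabilities. Transition
#' matrices between adjacent sites are `exp(Q * r)` with `r` the map
#' distance in Morgans; distances are floored at `1e-8` Morgan so duplicate
#' map positions do not produce degenerate transitions.
#'
#' @param e Emission matrix from [emission_likelihoods()] (`L x 5`,
#'   strictly positive, finite).
#' @param pos_cm Numeric vector of site positions in centimorgans
#'   (non-decreasing), length `L >= 2`.
#' @param rates An [ibd_rates()] object.
#' @return An object of class `posterior_trace`: list with `gamma`
#'   (`L x 5`, rows sum to 1), `scale` (per-site scaling factors),
#'   `loglik` (sum of log scaling factors) and `pos_cm`.
#' @export
forward_backward <- function(e, pos_cm, rates) {
  stopifnot(is.matrix(e), ncol(e) == 5L)
  L <- nrow(e)
  if (L < 2L) stop("need at least 2 sites")
  if (length(pos_cm) != L) stop("'pos_cm' length must match emission rows")
  if (!all(is.finite(e))) {
    stop("non-finite emission at site(s) ",
         paste(utils::head(which(rowSums(!is.finite(e)) > 0), 5L),
               collapse = ", "))
  }
  r <- pmax(diff(pos_cm) / 100, 1e-8)
  trans <- transition_components(rates, r)
  res <- .fwd_bwd_cpp(e, trans, start_distribution(rates))
  structure(list(gamma = res$gamma, scale = res$scale,
                 loglik = sum(log(res$scale)), pos_cm = pos_cm),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat(sprintf("Posterior trace over %d sites (%.1f-%.1f cM)\n",
              nrow(x$gamma), min(x$pos_cm), max(x$pos_cm)))
  cat(sprintf("  mean P(non-IBD) = %.4f, min = %.4f\n",
              mean(x$gamma[, 1L]), min(x$gamma[, 1L])))
  invisible(x)
}
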