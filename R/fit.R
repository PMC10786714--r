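#' Fit the IBD hidden Markov model to a pair of individuals
#'
#' The central model-fitting function: for one pair of imputed, phased
#' diploid genomes it converts genotype probabilities to haploid dosages,
#' evaluates the five-state emission likelihoods, runs the rescaled
#' forward-backward algorithm along each chromosome, and postprocesses the
#' posterior into called IBD segments.
#'
#' @param gm A [genotype_matrix()] holding (at least) the two samples.
#' @param sites The matching [site_table()] with `pos_cm` and `freq`
#'   filled.
#' @param pair Character (or integer) vector of length 2 selecting the
#'   samples.
#' @param rates An [ibd_rates()] object (transition model).
#' @param caller A [caller_params()] object (postprocessing).
#' @param masks Optional [mask_set()].
#' @param keep_trace Keep per-site posteriors in the returned object
#'   (memory grows with site count).
#' @return An object of class `ibd_fit` with components `segments` (the
#'   called-segment data.frame), `traces` (per-chromosome
#'   `posterior_trace`s, if kept), `loglik`, `pair`, `rates`, `caller`,
#'   `dropped` (sites without usable GP in either sample) and
#'   `n_inconsistent` (GP/GT-contradictory records).
#' @examples
#' sim <- simulate_ibd_pair(ibd = data.frame(start_cm = 40, length_cm = 12),
#'                          seed = 1)
#' fit <- ibd_hmm(sim$gm, sim$sites, pair = c("ind1", "ind2"))
#' summary(fit)
#' @export
ibd_hmm <- function(gm, sites, pair, rates = ibd_rates(),
                    caller = caller_params(), masks = NULL,
                    keep_trace = TRUE) {
  stopifnot(inherits(sites, "site_table"), n_sites(gm) == nrow(sites))
  if (anyNA(sites$pos_cm)) stop("site table lacks genetic positions; ",
                                "run attach_genetic_map() first")
  if (anyNA(sites$freq)) stop("site table lacks allele frequencies; ",
                              "run attach_allele_freqs() first")
  idx <- sample_index(gm, pair)
  pair_ids <- gm$sample_ids[idx]
  if (pair_ids[1L] > pair_ids[2L]) {
    pair_ids <- rev(pair_ids); idx <- rev(idx)
  }
  dos <- pair_dosages(gm, idx)
  seg_list <- list()
  traces <- list()
  loglik <- 0
  for (ch in unique(sites$chrom)) {
    rows <- which(sites$chrom[dos$kept] == ch)
    if (length(rows) < 2L) next
    kept_ch <- dos$kept[rows]
    e <- emission_likelihoods(dos$x[rows, , drop = FALSE],
                              sites$freq[kept_ch])
    tr <- forward_backward(e, sites$pos_cm[kept_ch], rates)
    loglik <- loglik + tr$loglik
    segs <- postprocess_trace(tr, sites[kept_ch, , drop = FALSE],
                              caller, pair_ids, masks,
                              site_idx = kept_ch - 1L)
    seg_list[[ch]] <- segs
    if (keep_trace) traces[[ch]] <- tr
  }
  segments <- as_segment_table(
    if (length(seg_list)) do.call(rbind, seg_list) else NULL)
  rownames(segments) <- NULL
  structure(list(segments = segments,
                 traces = if (keep_trace) traces else NULL,
                 loglik = loglik, pair = pair_ids, rates = rates,
                 caller = caller, dropped = dos$n_dropped,
                 n_inconsistent = dos$n_inconsistent),
            class = "ibd_fit")
}

#' Extract called IBD segments from a fit
#' @param fit An `ibd_fit`.
#' @return The segment data.frame.
#' @export
ibd_segments <- function(fit) {
  stopifnot(inherits(fit, "ibd_fit"))
  fit$segments
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat(sprintf("IBD HMM fit: %s - %s\n", x$pair[1L], x$pair[2L]))
  cat(sprintf("  %d segment(s) called, total %.1f cM\n",
              nrow(x$segments), sum(x$segments$length_cm)))
  cat(sprintf("  log-likelihood (up to emission constant): %.2f\n",
              x$loglik))
  if (x$dropped > 0L) {
    cat(sprintf("  %d site(s) dropped (missing GP)\n", x$dropped))
  }
  invisible(x)
}

#' @export
summary.ibd_fit <- function(object, ...) {
  s <- object$segments
  out <- list(pair = object$pair, segments = s,
              pair_summary = summarize_pair(s),
              rates = object$rates,
              dropped = object$dropped,
              n_inconsistent = object$n_inconsistent)
  class(out) <- "summary.ibd_fit"
  out
}

#' @export
print.summary.ibd_fit <- function(x, ...) {
  cat(sprintf("Pair %s - %s\n", x$pair[1L], x$pair[2L]))
  if (nrow(x$segments) == 0L) {
    cat("  no IBD segments called\n")
  } else {
    print(x$segments[, c("chromosome", "start_cm", "end_cm", "length_cm",
                         "n_snps", "mean_post_nonibd")],
          row.names = FALSE, digits = 4)
  }
  ps <- x$pair_summary
  cat(sprintf("  IBD >8 cM: n = %d, sum = %.1f cM; >12 cM: n = %d, sum = %.1f cM; >20 cM: n = %d\n",
              ps$n_ibd_over_8, ps$sum_ibd_over_8, ps$n_ibd_over_12,
              ps$sum_ibd_over_12, ps$n_ibd_over_20))
  invisible(x)
}

#' @export
coef.ibd_fit <- function(object, ...) {
  unlist(object$rates)
}

#' Plot the non-IBD posterior along a chromosome
#'
#' Draws `P(non-IBD)` against genetic position, with called segments
#' shaded; requires the fit to have been run with `keep_trace = TRUE`.
#'
#' @param x An `ibd_fit`.
#' @param chrom Chromosome to plot (default: the first with a trace).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ibd_fit <- function(x, chrom = NULL, ...) {
  if (is.null(x$traces) || length(x$traces) == 0L) {
    stop("fit was run with keep_trace = FALSE")
  }
  if (is.null(chrom)) chrom <- names(x$traces)[1L]
  tr <- x$traces[[chrom]]
  graphics::plot(tr$pos_cm, tr$gamma[, 1L], type = "l",
                 xlab = "position (cM)", ylab = "P(non-IBD)",
                 ylim = c(0, 1),
                 main = sprintf("%s - %s, chr %s", x$pair[1L], x$pair[2L],
                                chrom), ...)
  segs <- x$segments[x$segments$chromosome == chrom, , drop = FALSE]
  if (nrow(segs) > 0L) {
    graphics::rect(segs$start_cm, -0.04, segs$end_cm, 1.04,
                   col = grDevices::adjustcolor("steelblue", 0.25),
                   border = NA)
  }
  graphics::abline(h = x$caller$post_threshold, lty = 2, col = "grey40")
  invisible(x)
}
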