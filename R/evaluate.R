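#' Match called segments to truth segments
#'
#' Greedy one-to-one matching by reciprocal overlap: a called and a truth
#' segment match when their cM overlap is at least `min_overlap_frac` of
#' both lengths; candidate matches are taken in decreasing overlap order.
#' Unmatched called segments are false positives, unmatched truth segments
#' misses.
#'
#' @param called Data.frame with `start_cm`, `end_cm` (and optionally
#'   `chrom`/`chromosome`).
#' @param truth Same shape.
#' @param min_overlap_frac Reciprocal overlap fraction required.
#' @return A list with `pairs` (data.frame of matched index pairs and the
#'   signed length error called - truth), `fp_idx` and `miss_idx`.
#' @export
match_segments <- function(called, truth, min_overlap_frac = 0.5) {
  chrom_of <- function(d) {
    if ("chromosome" %in% names(d)) d$chromosome
    else if ("chrom" %in% names(d)) d$chrom
    else rep("1", nrow(d))
  }
  nc <- nrow(called); nt <- nrow(truth)
  cand <- list()
  if (nc > 0L && nt > 0L) {
    cc <- chrom_of(called); tc <- chrom_of(truth)
    for (i in seq_len(nc)) for (j in seq_len(nt)) {
      if (cc[i] != tc[j]) next
      ov <- min(called$end_cm[i], truth$end_cm[j]) -
        max(called$start_cm[i], truth$start_cm[j])
      if (ov <= 0) next
      lc <- called$end_cm[i] - called$start_cm[i]
      lt <- truth$end_cm[j] - truth$start_cm[j]
      if (ov >= min_overlap_frac * lc && ov >= min_overlap_frac * lt) {
        cand[[length(cand) + 1L]] <- c(i, j, ov)
      }
    }
  }
  pairs <- data.frame(called = integer(), truth = integer(),
                      overlap_cm = numeric(), length_error_cm = numeric())
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, 3L]), , drop = FALSE]
    used_c <- logical(nc); used_t <- logical(nt)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      if (used_c[i] || used_t[j]) next
      used_c[i] <- TRUE; used_t[j] <- TRUE
      err <- (called$end_cm[i] - called$start_cm[i]) -
        (truth$end_cm[j] - truth$start_cm[j])
      pairs <- rbind(pairs, data.frame(called = i, truth = j,
                                       overlap_cm = cand[r, 3L],
                                       length_error_cm = err))
    }
  }
  list(pairs = pairs,
       fp_idx = setdiff(seq_len(nc), pairs$called),
       miss_idx = setdiff(seq_len(nt), pairs$truth))
}

#' Power and length bias by true segment length
#'
#' For simulation experiments with known copied-in segments: recall
#' (detection power) and the signed length-error distribution per true
#' length class.
#'
#' @param results List of per-replicate lists, each with `called` and
#'   `truth` segment data.frames.
#' @param lengths True length classes (cM).
#' @param min_overlap_frac Matching criterion, see [match_segments()].
#' @return A data.frame with one row per length class: `n_truth`,
#'   `n_detected`, `power`, `mean_length_error_cm`,
#'   `median_length_error_cm`.
#' @export
power_length_bias <- function(results, lengths = c(4, 8, 12, 16, 20),
                              min_overlap_frac = 0.5) {
  rows <- lapply(lengths, function(l) {
    n_truth <- 0L; n_det <- 0L; errs <- numeric()
    for (r in results) {
      tr <- r$truth
      sel <- abs(tr$length_cm - l) < 1e-6
      if (!any(sel)) next
      m <- match_segments(r$called, tr[sel, , drop = FALSE],
                          min_overlap_frac)
      n_truth <- n_truth + sum(sel)
      n_det <- n_det + nrow(m$pairs)
      errs <- c(errs, m$pairs$length_error_cm)
    }
    data.frame(true_length_cm = l, n_truth = n_truth, n_detected = n_det,
               power = if (n_truth) n_det / n_truth else NA_real_,
               mean_length_error_cm = if (length(errs)) mean(errs)
                 else NA_real_,
               median_length_error_cm = if (length(errs))
                 stats::median(errs) else NA_real_)
  })
  do.call(rbind, rows)
}

#' False-positive segment rate per length bin
#'
#' Mean number of called segments per pair-chromosome in bins of
#' `bin_cm`, computed on pairs simulated with no copied-in IBD (so every
#' call is false).
#'
#' @param called_lengths Vector of lengths (cM) of all segments called on
#'   IBD-free pairs.
#' @param n_pairs Number of pair-chromosomes screened.
#' @param bin_cm Bin width (cM).
#' @param max_cm Upper end of the binned range.
#' @return A data.frame with `bin_start_cm`, `bin_end_cm`, `rate`.
#' @export
false_positive_rate <- function(called_lengths, n_pairs, bin_cm = 0.25,
                                max_cm = 30) {
  breaks <- seq(0, max_cm, by = bin_cm)
  counts <- graphics::hist(pmin(called_lengths, max_cm - 1e-9),
                           breaks = breaks, plot = FALSE)$counts
  data.frame(bin_start_cm = breaks[-length(breaks)],
             bin_end_cm = breaks[-1L],
             rate = counts / n_pairs)
}

#' Expected IBD segment density under a constant population size
#'
#' Coalescent expectation for the density (per cM and per haplotype or
#' diploid pair) of IBD segments of length `l_cm` on a chromosome of
#' length `chrom_cm`, in a randomly mating population of constant diploid
#' effective size `ne`. Two haplotypes coalesce in generation `t` with
#' probability `(1/(2 Ne)) (1 - 1/(2 Ne))^(t-1)`; conditional on
#' coalescence at `t`, segment boundaries form a Poisson process of rate
#' `2 t` per Morgan, so a maximal segment of map length `u` Morgans
#' requires `exp(-2 t u)` interior survival with density factors for its
#' two ends (interior `(2t)^2 (G - u)`, plus `2 * 2t` for segments ending
#' at a chromosome edge). The series is truncated at `max_gen`.
#'
#' @param ne Constant diploid effective population size (> 0).
#' @param l_cm Segment length(s) in cM.
#' @param chrom_cm Chromosome map length in cM.
#' @param basis `"haplotype"` for one haplotype pair, `"diploid"` to count
#'   all four haplotype pairs of two diploid individuals.
#' @param max_gen Truncation of the generation sum (`Inf`-like defaults to
#'   `50 * ne`).
#' @return Expected segments per cM (per pair on the chosen basis), same
#'   length as `l_cm`.
#' @export
expected_ibd_constant_ne <- function(ne, l_cm, chrom_cm = 100,
                                     basis = c("haplotype", "diploid"),
                                     max_gen = NULL) {
  if (ne <= 0) stop("'ne' must be > 0")
  basis <- match.arg(basis)
  if (is.null(max_gen)) max_gen <- ceiling(50 * ne)
  t <- seq_len(max_gen)
  p_coal <- (1 / (2 * ne)) * (1 - 1 / (2 * ne))^(t - 1)
  G <- chrom_cm / 100
  vapply(l_cm, function(l) {
    u <- l / 100
    if (u > G) return(0)
    per_t <- p_coal * exp(-2 * t * u) *
      ((2 * t)^2 * (G - u) + 2 * (2 * t))
    dens_per_morgan <- sum(per_t)
    out <- dens_per_morgan / 100  # per cM of segment length
    if (basis == "diploid") out <- out * 4
    out
  }, numeric(1L))
}

# Forward Wright-Fisher simulation with recombination, used as the
# independent check of expected_ibd_constant_ne() on small populations:
# haplotypes carry unique labels at generation 0; after n_gen generations
# two distinct individuals are sampled and their shared-label segments
# collected (these are IBD segments with common ancestry within n_gen).
# basis = "diploid" reports the union of sharing over all four haplotype
# pairs (what a diploid screen sees); "haplotype" samples one haplotype
# from each individual, matching the analytic per-haplotype-pair density
# exactly (the diploid union merges overlapping segments and so
# undercounts relative to the summed analytic expectation).
wf_ibd_segments <- function(ne, n_gen, chrom_cm = 100, n_samples = 1L,
                            basis = c("diploid", "haplotype")) {
  basis <- match.arg(basis)
  pop <- lapply(seq_len(ne), function(i) {
    list(founder_hap(2L * i - 1L, chrom_cm),
         founder_hap(2L * i, chrom_cm))
  })
  for (g in seq_len(n_gen)) {
    pop <- lapply(seq_len(ne), function(i) {
      p1 <- pop[[sample.int(ne, 1L)]]
      p2 <- pop[[sample.int(ne, 1L)]]
      child_of(p1, p2, chrom_cm)
    })
  }
  out <- list()
  for (s in seq_len(n_samples)) {
    ij <- sample.int(ne, 2L)
    ind1 <- pop[[ij[1L]]]; ind2 <- pop[[ij[2L]]]
    if (basis == "haplotype") {
      h1 <- ind1[[sample.int(2L, 1L)]]
      h2 <- ind2[[sample.int(2L, 1L)]]
      ind1 <- list(h1, h1); ind2 <- list(h2, h2)
    }
    prof <- sharing_profile(ind1, ind2)
    out[[s]] <- profile_segments(prof, "1")$ibd
  }
  out
}

#' Grid search for default model and caller parameters
#'
#' Evaluates each cell of a Cartesian parameter grid on simulated
#' scenarios with known truth and ranks the cells. The scalarisation is
#' documented and simple: mean recall over true lengths >= 8 cM, with
#' cells whose false-positive count per pair exceeds `fp_ceiling`
#' excluded; mean absolute length error breaks ties.
#'
#' @param grid Data.frame whose columns are a subset of the [ibd_rates()]
#'   and [caller_params()] argument names; one row per cell.
#' @param scenarios List of simulated scenarios, each a list with `gm`,
#'   `sites`, `truth` (as from [simulate_ibd_pair()]).
#' @param fp_ceiling Maximum tolerated mean false-positive segments per
#'   scenario.
#' @param min_overlap_frac Matching criterion.
#' @return The grid with appended `recall`, `fp_per_pair`,
#'   `mean_abs_length_error` and `rank` (1 = chosen cell), sorted by rank.
#' @export
grid_search_defaults <- function(grid, scenarios, fp_ceiling = 0.5,
                                 min_overlap_frac = 0.5) {
  if (nrow(grid) == 0L) stop("empty parameter grid")
  rate_names <- setdiff(names(formals(ibd_rates)), "")
  caller_names <- setdiff(names(formals(caller_params)), "")
  res <- lapply(seq_len(nrow(grid)), function(r) {
    args_r <- as.list(grid[r, intersect(names(grid), rate_names),
                           drop = FALSE])
    args_c <- as.list(grid[r, intersect(names(grid), caller_names),
                           drop = FALSE])
    rates <- do.call(ibd_rates, args_r)
    caller <- do.call(caller_params, args_c)
    n_det <- 0L; n_truth <- 0L; n_fp <- 0L; errs <- numeric()
    for (sc in scenarios) {
      fit <- ibd_hmm(sc$gm, sc$sites, c(1L, 2L), rates, caller,
                     keep_trace = FALSE)
      m <- match_segments(fit$segments, sc$truth, min_overlap_frac)
      truth_long <- sc$truth$length_cm >= 8
      m8 <- match_segments(fit$segments,
                           sc$truth[truth_long, , drop = FALSE],
                           min_overlap_frac)
      n_truth <- n_truth + sum(truth_long)
      n_det <- n_det + nrow(m8$pairs)
      n_fp <- n_fp + length(m$fp_idx)
      errs <- c(errs, m$pairs$length_error_cm)
    }
    data.frame(recall = if (n_truth) n_det / n_truth else NA_real_,
               fp_per_pair = n_fp / length(scenarios),
               mean_abs_length_error = if (length(errs))
                 mean(abs(errs)) else NA_real_)
  })
  out <- cbind(grid, do.call(rbind, res))
  score <- ifelse(out$fp_per_pair > fp_ceiling, -Inf,
                  out$recall - 1e-3 * out$mean_abs_length_error)
  score[is.na(score)] <- -Inf
  out$rank <- rank(-score, ties.method = "first")
  out[order(out$rank), , drop = FALSE]
}
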