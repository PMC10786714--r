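#' Sample quality control from imputation confidence
#'
#' Low-coverage samples impute poorly; a robust proxy is the fraction of
#' chromosome-3 markers whose largest genotype posterior exceeds 0.99. A
#' sample passes when that fraction is at least `threshold` (boundary
#' inclusive).
#'
#' @param gm A [genotype_matrix()] restricted to chromosome-3 sites (or
#'   pass `sites` and the full matrix).
#' @param sample Sample id or index.
#' @param threshold Pass threshold on the confident fraction.
#' @param sites Optional [site_table()]; when given, only rows with
#'   `chrom == chrom3` are used.
#' @param chrom3 Chromosome label used for QC (default `"3"`).
#' @return A list with `sample_id`, `frac_gp_confident` and `pass`.
#' @export
qc_sample <- function(gm, sample, threshold = 0.70, sites = NULL,
                      chrom3 = "3") {
  idx <- sample_index(gm, c(sample, sample))[1L]
  gp <- gm$gp[idx, , , drop = TRUE]
  if (!is.null(sites)) {
    sel <- sites$chrom == chrom3
    if (!any(sel)) stop("no chromosome-", chrom3, " sites present")
    gp <- gp[sel, , drop = FALSE]
  }
  if (nrow(gp) == 0L) stop("no sites for QC")
  ok <- stats::complete.cases(gp)
  maxgp <- apply(gp, 1L, max)
  frac <- sum(ok & maxgp > 0.99, na.rm = TRUE) / nrow(gp)
  list(sample_id = gm$sample_ids[idx], frac_gp_confident = frac,
       pass = frac >= threshold)
}

# batch partition of sample indices
batch_split <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

#' Count the unordered pairs the batch screener will process
#'
#' Walks the same batch-pair loops as [screen_pairs()] (all pairs within
#' each batch plus all cross pairs between batches) and sums, without
#' materialising pairs; `n` samples always yield `n (n - 1) / 2`.
#'
#' @param n Number of samples.
#' @param batch_size Batch size.
#' @return Pair count (double, exact for the sizes in question).
#' @export
count_pairs <- function(n, batch_size = 400L) {
  batches <- batch_split(n, batch_size)
  total <- 0
  for (i in seq_along(batches)) {
    ni <- length(batches[[i]])
    total <- total + ni * (ni - 1) / 2
    if (i < length(batches)) for (j in (i + 1L):length(batches)) {
      total <- total + ni * length(batches[[j]])
    }
  }
  total
}

#' Screen all sample pairs for IBD in batches
#'
#' Processes every unordered pair of samples exactly once. Samples are
#' grouped into batches; all within-batch pairs and all cross-batch pairs
#' are run, so peak working data grows with `2 * batch_size` rather than
#' with the cohort size. Output is canonical (pairs ordered
#' lexicographically, deterministic row order) and therefore independent
#' of `batch_size`.
#'
#' @param gm A [genotype_matrix()] with all samples.
#' @param sites The matching [site_table()].
#' @param rates,caller,masks Model and postprocessing parameters, as in
#'   [ibd_hmm()].
#' @param batch_size Number of samples per batch.
#' @param qc_threshold If non-`NULL`, samples failing [qc_sample()] at this
#'   threshold are excluded (requires chromosome-3 sites; use `NULL` to
#'   bypass QC).
#' @return A list with `segments` (all called segments), `summaries` (one
#'   [summarize_pair()] row per pair) and `excluded` (samples failing QC).
#' @export
screen_pairs <- function(gm, sites, rates = ibd_rates(),
                         caller = caller_params(), masks = NULL,
                         batch_size = 400L, qc_threshold = NULL) {
  ids <- gm$sample_ids
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  excluded <- character()
  if (!is.null(qc_threshold)) {
    pass <- vapply(ids, function(s) {
      qc_sample(gm, s, threshold = qc_threshold, sites = sites)$pass
    }, logical(1L))
    excluded <- ids[!pass]
    ids <- ids[pass]
  }
  n <- length(ids)
  batches <- batch_split(n, batch_size)
  seg_list <- list()
  sum_list <- list()
  run_pair <- function(s1, s2) {
    fit <- ibd_hmm(gm, sites, c(s1, s2), rates, caller, masks,
                   keep_trace = FALSE)
    seg_list[[paste(fit$pair, collapse = "|")]] <<- fit$segments
    sum_list[[paste(fit$pair, collapse = "|")]] <<-
      cbind(data.frame(sample1 = fit$pair[1L], sample2 = fit$pair[2L],
                       stringsAsFactors = FALSE),
            as.data.frame(summarize_pair(fit$segments)))
  }
  for (i in seq_along(batches)) {
    bi <- ids[batches[[i]]]
    if (length(bi) > 1L) {
      cmb <- utils::combn(bi, 2L)
      for (k in seq_len(ncol(cmb))) run_pair(cmb[1L, k], cmb[2L, k])
    }
    if (i < length(batches)) for (j in (i + 1L):length(batches)) {
      bj <- ids[batches[[j]]]
      for (s1 in bi) for (s2 in bj) run_pair(s1, s2)
    }
  }
  ord <- order(names(seg_list))
  segments <- as_segment_table(do.call(rbind, seg_list[ord]))
  rownames(segments) <- NULL
  summaries <- do.call(rbind, sum_list[ord])
  if (is.null(summaries)) {
    summaries <- data.frame(sample1 = character(), sample2 = character())
  }
  rownames(summaries) <- NULL
  list(segments = segments, summaries = summaries, excluded = excluded)
}

#' Per-pair IBD sharing summary
#'
#' Counts and summed lengths of segments longer than each threshold
#' (strictly greater; a segment of exactly 12 cM does not count as
#' "> 12 cM").
#'
#' @param segments Segment data.frame for one pair.
#' @param thresholds Length thresholds in cM.
#' @return A named list: `n_ibd_over_*` and `sum_ibd_over_*` per
#'   threshold, plus `max_ibd_cm`.
#' @export
summarize_pair <- function(segments, thresholds = c(8, 12, 20)) {
  segments <- as_segment_table(segments)
  len <- segments$length_cm
  out <- list()
  for (th in thresholds) {
    sel <- len > th
    out[[paste0("n_ibd_over_", th)]] <- sum(sel)
    out[[paste0("sum_ibd_over_", th)]] <- sum(len[sel])
  }
  out$max_ibd_cm <- if (length(len)) max(len) else 0
  out
}

#' Heuristic relationship annotation from IBD sharing
#'
#' Coarse labels from total and count of long shared segments. A
#' parent-offspring pair shares each autosome fully in a single segment
#' (sum over ">12 cM" segments close to the genome length, count close to
#' the chromosome number); full siblings share about three quarters of the
#' genome in many segments; more distant but recent relatives retain a few
#' very long (>20 cM) segments. These cutoffs are heuristics, not a
#' probabilistic classifier.
#'
#' @param summary A [summarize_pair()] result.
#' @param genome_length_cm Total map length screened (default: sum of the
#'   bundled human-like autosome lengths).
#' @param n_chrom Number of chromosomes screened.
#' @return One of `"parent-offspring"`, `"1st-degree (sib)"`,
#'   `"2nd-degree"`, `"likely <=6th-degree"`, `"unrelated/ambiguous"`.
#' @export
annotate_relatives <- function(summary,
                               genome_length_cm = sum(autosome_lengths_cm),
                               n_chrom = 22L) {
  s12 <- summary$sum_ibd_over_12
  n12 <- summary$n_ibd_over_12
  n20 <- summary$n_ibd_over_20
  if (s12 >= 0.85 * genome_length_cm && n12 <= 1.5 * n_chrom) {
    return("parent-offspring")
  }
  if (s12 >= 0.55 * genome_length_cm) return("1st-degree (sib)")
  if (s12 >= 0.2 * genome_length_cm) return("2nd-degree")
  if (n20 >= 3L) return("likely <=6th-degree")
  "unrelated/ambiguous"
}
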