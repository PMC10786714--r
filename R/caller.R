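#' Postprocessing parameters for IBD segment calling
#'
#' @param post_threshold Ceiling on the non-IBD posterior inside a
#'   segment: a segment is a maximal run of sites with
#'   `P(non-IBD) < post_threshold`.
#' @param min_length_cm Minimum genetic length (cM) of a run to be recorded
#'   as a candidate segment (before merging).
#' @param merge_max_gap_cm Maximum gap (cM) between two candidate segments
#'   that may be merged into one.
#' @param merge_min_flank_cm Both flanking segments must be at least this
#'   long (cM) for their gap to be merged.
#' @param density_min_snps_per_cm Segments with fewer SNPs per cM are
#'   discarded (low-density regions generate false positives). The default
#'   of 220 is tuned to ~1.1M-site capture panels; scale it to the marker
#'   density of your input.
#' @param output_min_length_cm Minimum length (cM) of reported segments;
#'   detection below ~8 cM is unreliable for low-coverage ancient genomes.
#' @param mask_max_overlap Fraction of a segment's length that may overlap
#'   region masks before the whole segment is dropped; smaller overlaps
#'   truncate the segment to its longest unmasked part.
#' @return An object of class `caller_params`.
#' @export
caller_params <- function(post_threshold = 0.5,
                          min_length_cm = 2,
                          merge_max_gap_cm = 0.5,
                          merge_min_flank_cm = 2,
                          density_min_snps_per_cm = 220,
                          output_min_length_cm = 8,
                          mask_max_overlap = 0.5) {
  stopifnot(post_threshold > 0, post_threshold < 1,
            min_length_cm > 0, merge_max_gap_cm >= 0,
            merge_min_flank_cm >= 0, density_min_snps_per_cm >= 0,
            output_min_length_cm > 0,
            mask_max_overlap >= 0, mask_max_overlap <= 1)
  structure(as.list(environment()), class = "caller_params")
}

#' Call candidate IBD segments from a posterior trace
#'
#' Screens for maximal runs of consecutive markers whose posterior
#' probability of the non-IBD state stays below `post_threshold`. The
#' segment start is the first SNP below the threshold and the end the last
#' SNP before the posterior rises above it again; runs spanning less than
#' `min_length_cm` are discarded. Indices are 0-based and half-open in
#' site-index space; cM bounds are the positions of the first and last SNP
#' inside the run.
#'
#' @param trace A `posterior_trace` from [forward_backward()].
#' @param sites A [site_table()] aligned to the trace rows.
#' @param params A [caller_params()].
#' @param pair Character vector of the two sample names.
#' @param site_idx Optional integer vector mapping trace rows to 0-based
#'   indices in an original site table (defaults to `0:(L-1)`).
#' @return A segment data.frame (possibly empty).
#' @export
call_segments <- function(trace, sites, params = caller_params(),
                          pair = c("A", "B"), site_idx = NULL) {
  g0 <- trace$gamma[, 1L]
  L <- length(g0)
  if (is.null(site_idx)) site_idx <- seq_len(L) - 1L
  below <- g0 < params$post_threshold
  runs <- rle_runs(below)
  segs <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]  # inclusive trace-row indices
    len <- sites$pos_cm[e] - sites$pos_cm[s]
    if (len < params$min_length_cm) next
    segs[[length(segs) + 1L]] <- data.frame(
      sample1 = pair[1L], sample2 = pair[2L],
      chromosome = sites$chrom[s],
      start_idx = site_idx[s], end_idx = site_idx[e] + 1L,
      start_cm = sites$pos_cm[s], end_cm = sites$pos_cm[e],
      length_cm = len,
      n_snps = site_idx[e] + 1L - site_idx[s],
      snps_per_cm = (site_idx[e] + 1L - site_idx[s]) / max(len, 1e-12),
      mean_post_nonibd = mean(g0[s:e]),
      stringsAsFactors = FALSE)
  }
  as_segment_table(if (length(segs)) do.call(rbind, segs) else NULL)
}

rle_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Merge candidate segments separated by short gaps
#'
#' Spurious gaps inside one true IBD segment (sparse markers, sporadic
#' genotype errors) are removed by merging adjacent segments of the same
#' pair and chromosome when both flanks are at least `merge_min_flank_cm`
#' long and the gap is at most `merge_max_gap_cm`; merging is applied
#' left-to-right until a fixpoint.
#'
#' @param segments A segment data.frame (sorted or not).
#' @param params A [caller_params()].
#' @return The merged segment data.frame.
#' @export
merge_gaps <- function(segments, params = caller_params()) {
  segments <- as_segment_table(segments)
  if (nrow(segments) < 2L) return(segments)
  key <- paste(segments$sample1, segments$sample2, segments$chromosome)
  out <- lapply(split(segments, key), function(d) {
    d <- d[order(d$start_cm), , drop = FALSE]
    repeat {
      merged <- FALSE
      i <- 1L
      while (i < nrow(d)) {
        gap <- d$start_cm[i + 1L] - d$end_cm[i]
        if (gap <= params$merge_max_gap_cm &&
            d$length_cm[i] >= params$merge_min_flank_cm &&
            d$length_cm[i + 1L] >= params$merge_min_flank_cm) {
          d$end_idx[i] <- d$end_idx[i + 1L]
          d$end_cm[i] <- d$end_cm[i + 1L]
          d$length_cm[i] <- d$end_cm[i] - d$start_cm[i]
          d$n_snps[i] <- d$end_idx[i] - d$start_idx[i]
          d$snps_per_cm[i] <- d$n_snps[i] / max(d$length_cm[i], 1e-12)
          # weighted approximation: the gap's posterior is not retained
          w <- c(d$n_snps[i], d$n_snps[i + 1L])
          d$mean_post_nonibd[i] <-
            sum(d$mean_post_nonibd[i:(i + 1L)] * w) / sum(w)
          d <- d[-(i + 1L), , drop = FALSE]
          merged <- TRUE
        } else {
          i <- i + 1L
        }
      }
      if (!merged) break
    }
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  as_segment_table(out)
}

#' Remove segments in marker-sparse regions
#'
#' Low SNP density inflates false-positive IBD; segments whose average
#' density falls below `density_min_snps_per_cm` are discarded.
#'
#' @param segments A segment data.frame.
#' @param params A [caller_params()].
#' @return The filtered data.frame, with the removal count in
#'   `attr(, "n_removed")`.
#' @export
filter_density <- function(segments, params = caller_params()) {
  segments <- as_segment_table(segments)
  keep <- segments$snps_per_cm >= params$density_min_snps_per_cm
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Apply region masks to called segments
#'
#' Regions with systematically inflated IBD sharing (centromeres,
#' telomeres, ...) can be excluded. A segment whose total overlap with the
#' masks exceeds `mask_max_overlap` of its length is dropped; a smaller
#' overlap truncates the segment to its longest unmasked stretch, which is
#' then re-checked against `output_min_length_cm`. An empty mask set is a
#' no-op.
#'
#' @param segments A segment data.frame.
#' @param masks A [mask_set()].
#' @param params A [caller_params()].
#' @param sites Optional [site_table()] used to recompute site indices and
#'   SNP counts of truncated segments; without it counts are scaled
#'   proportionally.
#' @return The masked segment data.frame.
#' @export
apply_masks <- function(segments, masks, params = caller_params(),
                        sites = NULL) {
  segments <- as_segment_table(segments)
  if (is.null(masks) || nrow(masks) == 0L || nrow(segments) == 0L) {
    return(segments)
  }
  if (!inherits(masks, "mask_set")) {
    masks <- mask_set(masks[[1L]], masks[[2L]], masks[[3L]])
  }
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, , drop = FALSE]
    m <- masks[masks$chrom == seg$chromosome, , drop = FALSE]
    pieces <- subtract_intervals(seg$start_cm, seg$end_cm,
                                 m$start_cm, m$end_cm)
    unmasked <- sum(pieces$end - pieces$start)
    overlap_frac <- 1 - unmasked / seg$length_cm
    if (overlap_frac <= 0) { rows[[length(rows) + 1L]] <- seg; next }
    if (overlap_frac >= params$mask_max_overlap) next
    j <- which.max(pieces$end - pieces$start)
    new_start <- pieces$start[j]; new_end <- pieces$end[j]
    if (new_end - new_start < params$output_min_length_cm) next
    scale <- (new_end - new_start) / seg$length_cm
    if (!is.null(sites)) {
      in_seg <- sites$chrom == seg$chromosome &
        sites$pos_cm >= new_start & sites$pos_cm <= new_end
      idx <- which(in_seg)
      seg$start_idx <- idx[1L] - 1L
      seg$end_idx <- idx[length(idx)]
      seg$n_snps <- length(idx)
    } else {
      offset <- seg$start_idx
      seg$n_snps <- max(1L, as.integer(round(seg$n_snps * scale)))
      seg$start_idx <- offset
      seg$end_idx <- offset + seg$n_snps
    }
    seg$start_cm <- new_start; seg$end_cm <- new_end
    seg$length_cm <- new_end - new_start
    seg$snps_per_cm <- seg$n_snps / max(seg$length_cm, 1e-12)
    rows[[length(rows) + 1L]] <- seg
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  out <- as_segment_table(out)
  rownames(out) <- NULL
  out
}

# [lo, hi] minus a set of intervals; returns remaining pieces
subtract_intervals <- function(lo, hi, m_lo, m_hi) {
  pieces <- data.frame(start = lo, end = hi)
  for (k in seq_along(m_lo)) {
    nxt <- list()
    for (r in seq_len(nrow(pieces))) {
      s <- pieces$start[r]; e <- pieces$end[r]
      if (m_hi[k] <= s || m_lo[k] >= e) {
        nxt[[length(nxt) + 1L]] <- c(s, e)
      } else {
        if (m_lo[k] > s) nxt[[length(nxt) + 1L]] <- c(s, m_lo[k])
        if (m_hi[k] < e) nxt[[length(nxt) + 1L]] <- c(m_hi[k], e)
      }
    }
    pieces <- if (length(nxt)) {
      as.data.frame(do.call(rbind, nxt)) |> stats::setNames(c("start", "end"))
    } else data.frame(start = numeric(), end = numeric())
  }
  pieces
}

#' Full postprocessing pipeline from posterior trace to reported segments
#'
#' Candidate calling, gap merging, SNP-density filtering, optional masking
#' and the final report-length floor, in that order.
#'
#' @inheritParams call_segments
#' @param masks Optional [mask_set()].
#' @return The reported segment data.frame.
#' @export
postprocess_trace <- function(trace, sites, params = caller_params(),
                              pair = c("A", "B"), masks = NULL,
                              site_idx = NULL) {
  segs <- call_segments(trace, sites, params, pair, site_idx)
  segs <- merge_gaps(segs, params)
  segs <- filter_density(segs, params)
  segs <- apply_masks(segs, masks, params, sites)
  out <- segs[segs$length_cm >= params$output_min_length_cm, , drop = FALSE]
  rownames(out) <- NULL
  out
}
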