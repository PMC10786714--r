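#' Construct a site table
#'
#' The site table aligns all per-site data: physical and genetic positions,
#' alleles and the alternative-allele frequency `p` used by the emission
#' model. Frequencies are clamped away from 0 and 1 because the emission
#' likelihood divides by `p` and `1 - p`.
#'
#' @param chrom Chromosome labels.
#' @param pos_bp Physical positions (non-negative integers).
#' @param pos_cm Genetic positions in centimorgans (non-decreasing within a
#'   chromosome); may be `NA` before [attach_genetic_map()].
#' @param ref,alt Single-character alleles.
#' @param freq Alternative-allele frequencies in (0, 1); may be `NA` before
#'   [attach_allele_freqs()].
#' @return A `data.frame` with class `site_table`.
#' @export
site_table <- function(chrom, pos_bp, pos_cm = NA_real_, ref = "A",
                       alt = "G", freq = NA_real_) {
  df <- data.frame(chrom = as.character(chrom),
                   pos_bp = as.integer(pos_bp),
                   pos_cm = as.numeric(pos_cm),
                   ref = as.character(ref), alt = as.character(alt),
                   freq = as.numeric(freq),
                   stringsAsFactors = FALSE)
  if (any(df$pos_bp < 0, na.rm = TRUE)) stop("pos_bp must be >= 0")
  for (ch in unique(df$chrom)) {
    cm <- df$pos_cm[df$chrom == ch]
    if (!anyNA(cm) && is.unsorted(cm)) {
      stop("pos_cm must be non-decreasing within chromosome ", ch)
    }
  }
  if (!all(is.na(df$freq))) df$freq <- clamp_freq(df$freq)
  class(df) <- c("site_table", "data.frame")
  df
}

#' Read a genetic map
#'
#' Whitespace-separated columns (chromosome, position in bp, position in
#' cM); lines starting with `#` are comments.
#'
#' @param path Path to the map file.
#' @return A data.frame with columns `chrom`, `pos_bp`, `pos_cm`.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("chrom", "pos_bp", "pos_cm"),
                          colClasses = c("character", "integer", "numeric"))
  df[order(df$chrom, df$pos_bp), , drop = FALSE]
}

#' Interpolate genetic positions onto a site table
#'
#' Fills `pos_cm` by linear interpolation between map anchors; beyond the
#' outermost anchors of a chromosome the terminal recombination rate is
#' extrapolated. Output is forced non-decreasing by a cumulative maximum
#' (defensive against non-monotone input maps).
#'
#' @param sites A [site_table()].
#' @param map A genetic map data.frame (see [read_genetic_map()]) or a path
#'   to one.
#' @return The site table with `pos_cm` filled.
#' @export
attach_genetic_map <- function(sites, map) {
  if (is.character(map)) map <- read_genetic_map(map)
  out <- sites
  for (ch in unique(sites$chrom)) {
    anchors <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(anchors) == 0L) {
      stop("chromosome ", ch, " absent from genetic map")
    }
    sel <- sites$chrom == ch
    out$pos_cm[sel] <- interpolate_cm(sites$pos_bp[sel],
                                      anchors$pos_bp, anchors$pos_cm)
  }
  out
}

interpolate_cm <- function(bp, anchor_bp, anchor_cm) {
  o <- order(anchor_bp)
  anchor_bp <- anchor_bp[o]; anchor_cm <- anchor_cm[o]
  if (length(anchor_bp) == 1L) {
    cm <- rep(anchor_cm, length(bp))
  } else {
    cm <- stats::approx(anchor_bp, anchor_cm, xout = bp, rule = 1)$y
    # constant-rate extrapolation beyond the outer anchors
    n <- length(anchor_bp)
    lo <- bp < anchor_bp[1L]
    hi <- bp > anchor_bp[n]
    rate_lo <- (anchor_cm[2L] - anchor_cm[1L]) /
      (anchor_bp[2L] - anchor_bp[1L])
    rate_hi <- (anchor_cm[n] - anchor_cm[n - 1L]) /
      (anchor_bp[n] - anchor_bp[n - 1L])
    cm[lo] <- anchor_cm[1L] + (bp[lo] - anchor_bp[1L]) * rate_lo
    cm[hi] <- anchor_cm[n] + (bp[hi] - anchor_bp[n]) * rate_hi
  }
  cummax(pmax(cm, 0))
}

#' Attach alternative-allele frequencies to a site table
#'
#' Frequency source precedence: an explicit frequency table beats an `AF`
#' value carried from VCF INFO, which beats frequencies estimated from the
#' samples' own genotype probabilities (mean dosage / 2). The source used
#' is reported via `message()` and recorded in `attr(, "freq_source")`.
#'
#' @param sites A [site_table()].
#' @param freq Optional: a path to a TSV with columns (chrom, bp, alt_freq)
#'   or a data.frame of the same shape.
#' @param gm Optional `genotype_matrix` used as a last-resort frequency
#'   source.
#' @return The site table with `freq` filled (clamped to
#'   `[1e-4, 1 - 1e-4]`).
#' @export
attach_allele_freqs <- function(sites, freq = NULL, gm = NULL) {
  out <- sites
  if (!is.null(freq)) {
    if (is.character(freq)) {
      freq <- utils::read.table(freq, header = FALSE, comment.char = "#",
                                col.names = c("chrom", "pos_bp", "alt_freq"))
    }
    key_s <- paste(sites$chrom, sites$pos_bp)
    key_f <- paste(freq$chrom, freq$pos_bp)
    m <- match(key_s, key_f)
    out$freq <- clamp_freq(freq$alt_freq[m])
    source <- "explicit frequency table"
  } else if (!all(is.na(sites$freq))) {
    out$freq <- clamp_freq(sites$freq)
    source <- "VCF INFO/AF"
  } else if (!is.null(gm)) {
    dos <- apply(gm$gp, 2L, function(g) mean(g[, 2L] + 2 * g[, 3L],
                                             na.rm = TRUE))
    out$freq <- clamp_freq(dos / 2)
    source <- "mean sample dosage"
  } else {
    stop("no allele-frequency source available")
  }
  message("allele frequencies from: ", source)
  attr(out, "freq_source") <- source
  out
}

#' Construct or normalize a mask set
#'
#' Masks are genomic intervals, in centimorgans, excluded from IBD calls.
#' Intervals on the same chromosome are sorted and overlapping or abutting
#' ones merged.
#'
#' @param chrom Chromosome labels.
#' @param start_cm,end_cm Interval bounds in cM, `start_cm < end_cm`.
#' @return A data.frame with class `mask_set`.
#' @export
mask_set <- function(chrom = character(), start_cm = numeric(),
                     end_cm = numeric()) {
  df <- data.frame(chrom = as.character(chrom),
                   start_cm = as.numeric(start_cm),
                   end_cm = as.numeric(end_cm), stringsAsFactors = FALSE)
  if (any(!is.finite(df$start_cm)) || any(!is.finite(df$end_cm)) ||
      any(df$start_cm >= df$end_cm)) {
    stop("malformed mask interval: require finite start_cm < end_cm")
  }
  out <- do.call(rbind, lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start_cm), , drop = FALSE]
    if (nrow(d) > 1L) {
      keep <- list(d[1L, ])
      for (i in 2L:nrow(d)) {
        last <- keep[[length(keep)]]
        if (d$start_cm[i] <= last$end_cm) {
          keep[[length(keep)]]$end_cm <- max(last$end_cm, d$end_cm[i])
        } else {
          keep[[length(keep) + 1L]] <- d[i, ]
        }
      }
      d <- do.call(rbind, keep)
    }
    d
  }))
  if (is.null(out)) out <- df
  rownames(out) <- NULL
  class(out) <- c("mask_set", "data.frame")
  out
}

#' Read masks from BED or a cM interval table
#'
#' `.bed` files are 0-based half-open physical intervals and require a
#' genetic map (or a site table with `pos_cm`) to convert bounds to cM;
#' other files are read as TSV with columns (chrom, start_cm, end_cm).
#'
#' @param path Path to the mask file.
#' @param map Genetic map data.frame or path (required for BED input).
#' @return A [mask_set()].
#' @export
read_masks <- function(path, map = NULL) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    if (is.null(map)) stop("BED masks require a genetic map to convert to cM")
    if (is.character(map)) map <- read_genetic_map(map)
    bed <- utils::read.table(path, header = FALSE, comment.char = "#",
                             col.names = c("chrom", "start", "end"))
    start_cm <- end_cm <- numeric(nrow(bed))
    for (i in seq_len(nrow(bed))) {
      anchors <- map[map$chrom == bed$chrom[i], , drop = FALSE]
      if (nrow(anchors) == 0L) stop("chromosome ", bed$chrom[i],
                                    " absent from genetic map")
      start_cm[i] <- interpolate_cm(bed$start[i], anchors$pos_bp,
                                    anchors$pos_cm)
      end_cm[i] <- interpolate_cm(bed$end[i], anchors$pos_bp,
                                  anchors$pos_cm)
    }
    mask_set(bed$chrom, start_cm, end_cm)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    mask_set(df[[1L]], df[[2L]], df[[3L]])
  }
}
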