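#' Sex-averaged autosome map lengths (cM)
#'
#' Approximate human autosome genetic lengths used as the default map for
#' pedigree simulations and genome-wide expectations.
#' @format Named numeric vector, chromosomes "1".."22".
#' @export
autosome_lengths_cm <- stats::setNames(
  c(286.3, 268.6, 223.4, 214.6, 204.1, 192.0, 187.2, 168.0, 166.4, 181.1,
    158.2, 174.7, 125.9, 120.2, 141.9, 134.0, 128.5, 117.2, 107.9, 108.3,
    62.8, 74.1),
  as.character(1:22))

# A haplotype in descent tracking is a piecewise-constant map
# (start_cm, end_cm, founder-haplotype label).
founder_hap <- function(label, length_cm) {
  data.frame(start = 0, end = length_cm, label = label,
             stringsAsFactors = FALSE)
}

slice_hap <- function(hap, s, e) {
  sel <- hap$end > s & hap$start < e
  out <- hap[sel, , drop = FALSE]
  if (nrow(out) > 0L) {
    out$start <- pmax(out$start, s)
    out$end <- pmin(out$end, e)
  }
  out
}

#' Simulate one meiosis
#'
#' Crossovers form a Poisson process of one event per Morgan (no
#' interference); the gamete alternates between the two parental
#' haplotypes at the crossover points, starting from a fair-coin choice.
#'
#' @param hapA,hapB Parental haplotypes as (start, end, label)
#'   data.frames.
#' @param length_cm Chromosome map length.
#' @return A list with `gamete` (label mosaic data.frame) and `crossovers`
#'   (positions in cM).
#' @export
simulate_meiosis <- function(hapA, hapB, length_cm) {
  stopifnot(length_cm >= 0)
  n_co <- stats::rpois(1L, length_cm / 100)
  cuts <- sort(stats::runif(n_co, 0, length_cm))
  bounds <- c(0, cuts, length_cm)
  cur <- sample.int(2L, 1L)
  pieces <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    src <- if (cur == 1L) hapA else hapB
    pieces[[i]] <- slice_hap(src, bounds[i], bounds[i + 1L])
    cur <- 3L - cur
  }
  gamete <- do.call(rbind, pieces)
  # merge abutting pieces with identical labels
  if (nrow(gamete) > 1L) {
    keep <- c(TRUE, gamete$label[-1L] != gamete$label[-nrow(gamete)] |
                abs(gamete$start[-1L] - gamete$end[-nrow(gamete)]) > 1e-12)
    grp <- cumsum(keep)
    gamete <- data.frame(start = tapply(gamete$start, grp, min),
                         end = tapply(gamete$end, grp, max),
                         label = gamete$label[keep],
                         stringsAsFactors = FALSE)
  }
  rownames(gamete) <- NULL
  list(gamete = gamete, crossovers = cuts)
}

# individual = list(hap1, hap2) per chromosome handled by the caller
child_of <- function(parent1, parent2, length_cm) {
  list(simulate_meiosis(parent1[[1L]], parent1[[2L]], length_cm)$gamete,
       simulate_meiosis(parent2[[1L]], parent2[[2L]], length_cm)$gamete)
}

# IBD sharing profile between two individuals on one chromosome:
# piecewise count (0/1/2) of matched founder-haplotype labels
sharing_profile <- function(indX, indY) {
  bounds <- sort(unique(c(0,
                          indX[[1L]]$end, indX[[2L]]$end,
                          indY[[1L]]$end, indY[[2L]]$end,
                          indX[[1L]]$start, indX[[2L]]$start,
                          indY[[1L]]$start, indY[[2L]]$start)))
  label_at <- function(hap, pos) {
    hap$label[which(hap$start <= pos & hap$end > pos)[1L]]
  }
  n <- length(bounds) - 1L
  lev <- integer(n)
  for (i in seq_len(n)) {
    mid <- (bounds[i] + bounds[i + 1L]) / 2
    a1 <- label_at(indX[[1L]], mid); a2 <- label_at(indX[[2L]], mid)
    b1 <- label_at(indY[[1L]], mid); b2 <- label_at(indY[[2L]], mid)
    lev[i] <- if (a1 == b1) 1L + (a2 == b2) else if (a1 == b2) {
      1L + (a2 == b1)
    } else as.integer(a2 == b1 || a2 == b2)
  }
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L],
             level = lev)
}

# maximal runs with level >= 1 (IBD) and level == 2 (double IBD)
profile_segments <- function(profile, chrom) {
  seg_of <- function(flag) {
    runs <- rle_runs(flag)
    if (nrow(runs) == 0L) {
      return(data.frame(chrom = character(), start_cm = numeric(),
                        end_cm = numeric(), length_cm = numeric(),
                        stringsAsFactors = FALSE))
    }
    data.frame(chrom = chrom,
               start_cm = profile$start[runs$start],
               end_cm = profile$end[runs$end],
               length_cm = profile$end[runs$end] -
                 profile$start[runs$start],
               stringsAsFactors = FALSE)
  }
  list(ibd = seg_of(profile$level >= 1L),
       ibd2 = seg_of(profile$level == 2L))
}

#' Simulate true IBD sharing between relatives
#'
#' Tracks descent of founder haplotypes through an explicit pedigree over
#' the autosomes and reports, per replicate, the true IBD segments (any
#' haplotype pair shared) and double-IBD segments (both pairs shared)
#' between the target pair.
#'
#' @param relationship One of `"parent-offspring"`, `"full-sib"`,
#'   `"half-sib"`, `"grandparent"`, `"avuncular"`, `"1st-cousin"`,
#'   `"2nd-cousin"`, `"3rd-cousin"`.
#' @param n_replicates Number of independent replicates.
#' @param chrom_lengths Named vector of chromosome map lengths in cM.
#' @param seed Optional integer seed.
#' @return A list of replicates; each has `ibd` and `ibd2` segment
#'   data.frames (columns chrom, start_cm, end_cm, length_cm).
#' @export
simulate_relatives <- function(relationship, n_replicates = 100L,
                               chrom_lengths = autosome_lengths_cm,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  known <- c("parent-offspring", "full-sib", "half-sib", "grandparent",
             "avuncular", "1st-cousin", "2nd-cousin", "3rd-cousin")
  if (!relationship %in% known) {
    stop("unknown relationship '", relationship, "'; use one of ",
         paste(known, collapse = ", "))
  }
  replicate(n_replicates, simplify = FALSE, {
    ibd_all <- list(); ibd2_all <- list()
    for (ch in names(chrom_lengths)) {
      L <- chrom_lengths[[ch]]
      fid <- 0L
      founder <- function() {
        fid <<- fid + 2L
        list(founder_hap(fid - 1L, L), founder_hap(fid, L))
      }
      pair <- switch(relationship,
        "parent-offspring" = {
          f1 <- founder(); f2 <- founder()
          list(f1, child_of(f1, f2, L))
        },
        "full-sib" = {
          f1 <- founder(); f2 <- founder()
          list(child_of(f1, f2, L), child_of(f1, f2, L))
        },
        "half-sib" = {
          f1 <- founder(); f2 <- founder(); f3 <- founder()
          list(child_of(f1, f2, L), child_of(f1, f3, L))
        },
        "grandparent" = {
          f1 <- founder(); f2 <- founder(); f3 <- founder()
          c1 <- child_of(f1, f2, L)
          list(f1, child_of(c1, f3, L))
        },
        "avuncular" = {
          f1 <- founder(); f2 <- founder(); f3 <- founder()
          c1 <- child_of(f1, f2, L); c2 <- child_of(f1, f2, L)
          list(c1, child_of(c2, f3, L))
        },
        "1st-cousin" = {
          f1 <- founder(); f2 <- founder(); f3 <- founder()
          f4 <- founder()
          c1 <- child_of(f1, f2, L); c2 <- child_of(f1, f2, L)
          list(child_of(c1, f3, L), child_of(c2, f4, L))
        },
        "2nd-cousin" = {
          f1 <- founder(); f2 <- founder()
          c1 <- child_of(f1, f2, L); c2 <- child_of(f1, f2, L)
          d1 <- child_of(c1, founder(), L)
          d2 <- child_of(c2, founder(), L)
          list(child_of(d1, founder(), L), child_of(d2, founder(), L))
        },
        "3rd-cousin" = {
          f1 <- founder(); f2 <- founder()
          c1 <- child_of(f1, f2, L); c2 <- child_of(f1, f2, L)
          d1 <- child_of(c1, founder(), L)
          d2 <- child_of(c2, founder(), L)
          e1 <- child_of(d1, founder(), L)
          e2 <- child_of(d2, founder(), L)
          list(child_of(e1, founder(), L), child_of(e2, founder(), L))
        })
      segs <- profile_segments(sharing_profile(pair[[1L]], pair[[2L]]), ch)
      ibd_all[[ch]] <- segs$ibd
      ibd2_all[[ch]] <- segs$ibd2
    }
    list(ibd = do.call(rbind, ibd_all), ibd2 = do.call(rbind, ibd2_all))
  })
}

#' Summaries of simulated relative sharing
#'
#' Genome fractions in single and double IBD and segment counts per
#' replicate. "IBD1 fraction" is the genome fraction shared on exactly one
#' haplotype pair; "IBD2" on both.
#'
#' @param reps Output of [simulate_relatives()].
#' @param chrom_lengths Map lengths used in the simulation.
#' @return A data.frame with one row per replicate: `n_segments`,
#'   `frac_ibd1`, `frac_ibd2`.
#' @export
relative_ibd_summary <- function(reps,
                                 chrom_lengths = autosome_lengths_cm) {
  G <- sum(chrom_lengths)
  do.call(rbind, lapply(reps, function(r) {
    any_ibd <- sum(r$ibd$length_cm)
    dbl <- sum(r$ibd2$length_cm)
    data.frame(n_segments = nrow(r$ibd),
               frac_ibd1 = (any_ibd - dbl) / G,
               frac_ibd2 = dbl / G)
  }))
}

#' Probability that a segment survives crossovers over meioses
#'
#' Monte-Carlo estimate of the chance that no crossover falls inside a
#' segment of `length_cm` during `n_meioses` successive meioses — the
#' recombination clock by which long shared segments decay across
#' generations (for a pair separated by `t` generations on both sides,
#' `n_meioses = 2 t` and the survival probability is
#' `exp(-t * length_cm / 50)`).
#'
#' @param length_cm Segment length (cM).
#' @param n_meioses Number of meioses.
#' @param n_reps Monte-Carlo replicates.
#' @param chrom_length_cm Chromosome length containing the segment.
#' @return Estimated survival probability.
#' @export
segment_survival_prob <- function(length_cm, n_meioses, n_reps = 2000L,
                                  chrom_length_cm = 150) {
  stopifnot(length_cm <= chrom_length_cm)
  start <- (chrom_length_cm - length_cm) / 2
  hapA <- founder_hap(1L, chrom_length_cm)
  hapB <- founder_hap(2L, chrom_length_cm)
  hits <- vapply(seq_len(n_reps), function(i) {
    for (m in seq_len(n_meioses)) {
      co <- simulate_meiosis(hapA, hapB, chrom_length_cm)$crossovers
      if (any(co > start & co < start + length_cm)) return(FALSE)
    }
    TRUE
  }, logical(1L))
  mean(hits)
}
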