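#' Construct a genotype matrix
#'
#' Container aligning imputed genotype probabilities and phased genotype
#' calls for a set of samples on one chromosome (or a concatenation of
#' chromosomes sharing one site table).
#'
#' @param sample_ids Character vector of sample labels.
#' @param gp Array `n_samples x n_sites x 3` of genotype posteriors; each
#'   triple must sum to 1 within `1e-3` (renormalised otherwise).
#' @param gt Integer array `n_samples x n_sites x 2` of phased haplotype
#'   alleles (0/1); `NA` marks missing or unphased-heterozygote calls.
#' @return A list of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, gp, gt) {
  stopifnot(length(dim(gp)) == 3L, dim(gp)[3L] == 3L,
            length(dim(gt)) == 3L, dim(gt)[3L] == 2L,
            dim(gp)[1L] == length(sample_ids),
            all(dim(gp)[1:2] == dim(gt)[1:2]))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  s <- gp[, , 1L] + gp[, , 2L] + gp[, , 3L]
  bad <- is.finite(s) & abs(s - 1) > 1e-3
  if (any(bad)) {
    # silent renormalisation: VCF rounding
    for (k in 1:3) gp[, , k] <- gp[, , k] / s
  }
  structure(list(sample_ids = as.character(sample_ids),
                 gp = gp, gt = gt),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites\n",
              length(x$sample_ids), dim(x$gp)[2L]))
  invisible(x)
}

n_sites <- function(gm) dim(gm$gp)[2L]

#' Read an imputed VCF with GT and GP FORMAT fields
#'
#' Reads phased, imputed genotypes (the output format of low-coverage
#' imputation tools): the phased `GT` call and the three genotype posterior
#' probabilities `GP` per site. Only biallelic SNPs are kept; skipped
#' multi-allelic/indel records are counted in `message()` output. Records
#' without a GP value, and heterozygote GT calls that are unphased, are
#' flagged missing. An `AF` INFO tag, when present, is carried into the
#' site table's `freq` column.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param site_filter Optional integer vector of physical positions to
#'   keep, or a data.frame with columns `chrom`, `pos_bp`.
#' @return A list with elements `sites` (a [site_table()]) and `gm`
#'   (a [genotype_matrix()]).
#' @export
read_vcf <- function(path, site_filter = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  has_gp <- any(grepl("\\bGP\\b", v@gt[, "FORMAT"]))
  if (!has_gp) stop("VCF lacks the GP FORMAT field")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt)
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0L) {
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  }
  keep <- biallelic
  if (!is.null(site_filter)) {
    if (is.data.frame(site_filter)) {
      keep <- keep & paste(chrom, pos) %in%
        paste(site_filter$chrom, site_filter$pos_bp)
    } else {
      keep <- keep & pos %in% site_filter
    }
    if (!any(keep)) stop("no sites overlap the site filter")
  }
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  sites <- site_table(chrom[keep], pos[keep], NA_real_,
                      ref[keep], alt[keep], af[keep])

  gt_chr <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  gp_chr <- vcfR::extract.gt(v, element = "GP")[keep, , drop = FALSE]
  ids <- colnames(gt_chr)
  L <- sum(keep); nS <- length(ids)

  gp <- array(NA_real_, dim = c(nS, L, 3L))
  gt <- array(NA_integer_, dim = c(nS, L, 2L))
  for (j in seq_len(nS)) {
    trip <- strsplit(gp_chr[, j], ",", fixed = TRUE)
    len3 <- lengths(trip) == 3L
    m <- matrix(NA_real_, L, 3L)
    m[len3, ] <- matrix(as.numeric(unlist(trip[len3])), ncol = 3L,
                        byrow = TRUE)
    gp[j, , ] <- m
    g <- gt_chr[, j]
    phased <- grepl("|", g, fixed = TRUE)
    a1 <- suppressWarnings(as.integer(substr(g, 1L, 1L)))
    a2 <- suppressWarnings(as.integer(substr(g, 3L, 3L)))
    het <- !is.na(a1) & !is.na(a2) & a1 != a2
    # unphased heterozygotes carry no phase information: flag missing
    a1[het & !phased] <- NA_integer_
    a2[het & !phased] <- NA_integer_
    gt[j, , 1L] <- a1
    gt[j, , 2L] <- a2
  }
  list(sites = sites, gm = genotype_matrix(ids, gp, gt))
}

#' Write a genotype matrix as a VCF
#'
#' Emits a minimal VCF 4.2 with `GT:GP` FORMAT fields, the format the
#' reader and the simulator share.
#'
#' @param sites A [site_table()].
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @export
write_vcf <- function(sites, gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
               "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype posterior probabilities\">",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternative allele frequency\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", gm$sample_ids),
                     collapse = "\t")), con)
  L <- n_sites(gm)
  fields <- matrix("", L, length(gm$sample_ids))
  for (j in seq_along(gm$sample_ids)) {
    a1 <- gm$gt[j, , 1L]; a2 <- gm$gt[j, , 2L]
    gts <- ifelse(is.na(a1) | is.na(a2), "./.",
                  paste0(a1, "|", a2))
    gps <- paste(formatC(gm$gp[j, , 1L], format = "g", digits = 6),
                 formatC(gm$gp[j, , 2L], format = "g", digits = 6),
                 formatC(gm$gp[j, , 3L], format = "g", digits = 6),
                 sep = ",")
    gps[is.na(gm$gp[j, , 1L])] <- "."
    fields[, j] <- paste(gts, gps, sep = ":")
  }
  info <- if (all(is.na(sites$freq))) rep(".", L) else {
    paste0("AF=", formatC(sites$freq, format = "g", digits = 6))
  }
  body <- paste(sites$chrom, sites$pos_bp, ".", sites$ref, sites$alt,
                ".", "PASS", info, "GT:GP",
                apply(fields, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

segment_columns <- c("sample1", "sample2", "chromosome", "start_idx",
                     "end_idx", "start_cm", "end_cm", "length_cm",
                     "n_snps", "snps_per_cm", "mean_post_nonibd")

#' Write called IBD segments to a TSV
#'
#' Deterministic row order: (sample1, sample2, chromosome, start_cm).
#' An empty list yields a header-only file.
#'
#' @param segments A data.frame of IBD segments (see [call_segments()]).
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  segments <- as_segment_table(segments)
  o <- order(segments$sample1, segments$sample2, segments$chromosome,
             segments$start_cm)
  utils::write.table(segments[o, segment_columns, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a segment table written by [write_segments()]
#' @param path Path to the TSV.
#' @return A segment data.frame.
#' @export
read_segments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "character", "integer", "integer",
                                         rep("numeric", 3L), "integer",
                                         "numeric", "numeric"),
                          stringsAsFactors = FALSE)
  as_segment_table(df)
}

# canonical empty/complete segment data.frame
as_segment_table <- function(df) {
  if (is.null(df) || (is.data.frame(df) && nrow(df) == 0L) ||
      (is.list(df) && length(df) == 0L && !is.data.frame(df))) {
    df <- data.frame(sample1 = character(), sample2 = character(),
                     chromosome = character(), start_idx = integer(),
                     end_idx = integer(), start_cm = numeric(),
                     end_cm = numeric(), length_cm = numeric(),
                     n_snps = integer(), snps_per_cm = numeric(),
                     mean_post_nonibd = numeric(),
                     stringsAsFactors = FALSE)
  }
  stopifnot(all(segment_columns %in% names(df)))
  df[, segment_columns, drop = FALSE]
}
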