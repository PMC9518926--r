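# VCF input: biallelic SNP genotypes to per-locus derived-allele counts.

#' Read haplotypes from a VCF file
#'
#' Parses biallelic SNPs with vcfR and splits diploid (or haploid) GT fields
#' into haplotype columns; phase separators (`|` vs `/`) are ignored, only
#' allele counts are used downstream. Multiallelic records and indels are
#' skipped (they count as invariant). Polarization: with
#' `polarization = "AA-tag"` the ancestral allele is taken from the `AA`
#' INFO tag (sites lacking a usable tag are dropped, i.e. treated as
#' invariant); with `"ref-ancestral"` the REF allele is ancestral.
#'
#' @param path VCF file (plain or gzipped).
#' @param polarization `"ref-ancestral"` or `"AA-tag"`.
#' @param seq_start,seq_end Coordinates of the surveyed segment (1-based,
#'   inclusive); default to the first and last SNP position.
#' @return A `hap_data`: positions, a sites x haplotypes 0/1 matrix (NA for
#'   missing calls, 1 meaning derived), chromosome label, and the surveyed
#'   span.
#' @export
read_vcf_haplotypes <- function(path, polarization = c("ref-ancestral", "AA-tag"),
                                seq_start = NULL, seq_end = NULL) {
  polarization <- match.arg(polarization)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix)) fix <- t(as.matrix(fix))   # single-record VCF
  if (nrow(fix) == 0) stop("read_vcf_haplotypes: no records in ", path)
  chrom <- fix[1, "CHROM"]
  biall <- vcfR::is.biallelic(v) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    fix[, "REF"] %in% c("A", "C", "G", "T") & fix[, "ALT"] %in% c("A", "C", "G", "T")
  anc_is_alt <- rep(FALSE, nrow(fix))
  if (polarization == "AA-tag") {
    aa <- toupper(vcfR::extract.info(v, "AA"))
    usable <- !is.na(aa) & (aa == fix[, "REF"] | aa == fix[, "ALT"])
    anc_is_alt <- !is.na(aa) & aa == fix[, "ALT"]
    biall <- biall & usable
  }
  gt <- vcfR::extract.gt(v, "GT")
  keep <- which(biall)
  pos <- as.integer(fix[keep, "POS"])
  gt <- gt[keep, , drop = FALSE]
  anc_is_alt <- anc_is_alt[keep]
  # split GT strings into haplotype allele columns
  split_gt <- function(row) {
    parts <- strsplit(row, "[/|]")
    unlist(parts)
  }
  ploidies <- lengths(strsplit(gt[1, ], "[/|]"))
  hap <- matrix(NA_integer_, length(keep), sum(ploidies))
  col_names <- unlist(lapply(seq_along(ploidies), function(j) {
    paste0(colnames(gt)[j], "_", seq_len(ploidies[j]))
  }))
  colnames(hap) <- col_names
  for (r in seq_along(keep)) {
    alleles <- split_gt(gt[r, ])
    if (length(alleles) != ncol(hap)) {
      stop(sprintf("read_vcf_haplotypes: inconsistent ploidy at record %d", r))
    }
    a <- suppressWarnings(as.integer(alleles))
    hap[r, ] <- a
  }
  # derived = non-ancestral allele
  if (any(anc_is_alt)) {
    hap[anc_is_alt, ] <- 1L - hap[anc_is_alt, ]
  }
  ord <- order(pos)
  structure(list(chrom = chrom, pos = pos[ord],
                 hap = hap[ord, , drop = FALSE],
                 ploidy = ploidies,
                 seq_start = seq_start %||% min(pos),
                 seq_end = seq_end %||% max(pos)),
            class = "hap_data")
}

#' @export
print.hap_data <- function(x, ...) {
  cat(sprintf("<hap_data> chrom %s: %d sites x %d haplotypes, span %d-%d\n",
              x$chrom, nrow(x$hap), ncol(x$hap), x$seq_start, x$seq_end))
  invisible(x)
}

#' Derived-allele count observations for a haplotype subset
#'
#' Converts site-level haplotype data into the run-length encoded emission
#' sequence of the CHMM: for each usable site the derived count among the
#' subset's haplotypes, with the base-pair gaps between consecutive sites
#' contributing runs of `d = 0`. Sites with missing calls in the subset are
#' treated as invariant, as are sites where every subset haplotype carries
#' the derived allele (counts of `n` map to `d = 0`).
#'
#' @param hap A `hap_data`.
#' @param subset Haplotype column indices (default: all).
#' @param mask Optional two-column matrix or data frame of 0-based,
#'   half-open `[start, end)` intervals to excise; masked loci are removed
#'   from the sequence entirely.
#' @return A `chmm_obs`.
#' @export
observations_from_haplotypes <- function(hap, subset = NULL, mask = NULL) {
  stopifnot(inherits(hap, "hap_data"))
  if (is.null(subset)) subset <- seq_len(ncol(hap$hap))
  n <- length(subset)
  stopifnot(n >= 2)
  sub <- hap$hap[, subset, drop = FALSE]
  d <- rowSums(sub)
  d[is.na(d)] <- 0          # missing genotype in subset: treat as invariant
  d[d == n] <- 0            # all-derived maps to d = 0
  keep_pos <- hap$pos
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    in_mask_site <- rep(FALSE, length(keep_pos))
    for (r in seq_len(nrow(mask))) {
      in_mask_site <- in_mask_site |
        (keep_pos - 1 >= mask[r, 1] & keep_pos - 1 < mask[r, 2])
    }
    d <- d[!in_mask_site]
    keep_pos <- keep_pos[!in_mask_site]
  }
  span_start <- hap$seq_start
  span_end <- hap$seq_end
  masked_before <- function(p) {
    if (is.null(mask)) return(0)
    sum(pmax(0, pmin(mask[, 2], p) - pmax(mask[, 1], span_start - 1)))
  }
  # runs: gap of g bp between consecutive sites contributes g - 1 invariant
  # loci (masked loci are excised from the gap bookkeeping)
  pos_eff <- function(p) p - vapply(p, masked_before, 0)  # after excision
  pe <- pos_eff(c(span_start - 1, keep_pos, span_end))
  k <- length(keep_pos)
  gaps <- pe[1 + seq_len(k)] - pe[seq_len(k)] - 1     # invariant run before each site
  tail_gap <- pe[k + 2] - pe[k + 1]
  ds <- as.integer(rbind(0L, as.integer(d)))
  ls <- as.numeric(rbind(gaps, 1))
  keep_runs <- ls > 0
  ds <- c(ds[keep_runs], if (tail_gap > 0) 0L)
  ls <- c(ls[keep_runs], if (tail_gap > 0) tail_gap)
  if (length(ds) == 0) stop("observations_from_haplotypes: empty sequence")
  chmm_obs(ds, ls, n = n, chrom = hap$chrom)
}

#' VCF to observation sequence
#'
#' Convenience wrapper: [read_vcf_haplotypes()] followed by
#' [observations_from_haplotypes()].
#'
#' @inheritParams read_vcf_haplotypes
#' @inheritParams observations_from_haplotypes
#' @return A `chmm_obs`.
#' @export
vcf_to_observations <- function(path, subset = NULL,
                                polarization = c("ref-ancestral", "AA-tag"),
                                seq_start = NULL, seq_end = NULL, mask = NULL) {
  hap <- read_vcf_haplotypes(path, polarization, seq_start, seq_end)
  observations_from_haplotypes(hap, subset, mask)
}

#' Pseudo-haploidize diploid haplotype data
#'
#' For each individual (pair of haplotype columns) and site, keeps one of
#' the two alleles chosen uniformly at random, emulating pseudo-haploid
#' genotype calling from low-coverage data.
#'
#' @param hap A `hap_data` with an even number of haplotype columns (column
#'   `2i - 1` and `2i` form individual `i`).
#' @param seed RNG seed.
#' @return A `hap_data` with one pseudo-haploid column per individual.
#' @export
pseudo_haploidize <- function(hap, seed = 1) {
  stopifnot(inherits(hap, "hap_data"))
  n_hap <- ncol(hap$hap)
  if (n_hap %% 2 != 0) stop("pseudo_haploidize: need diploid input (even haplotype count)")
  n_ind <- n_hap / 2
  picks <- withr::with_seed(seed,
    matrix(runif(nrow(hap$hap) * n_ind) < 0.5, nrow(hap$hap), n_ind))
  out <- matrix(NA_integer_, nrow(hap$hap), n_ind)
  for (i in seq_len(n_ind)) {
    a <- hap$hap[, 2 * i - 1]
    b <- hap$hap[, 2 * i]
    out[, i] <- ifelse(picks[, i], a, b)
  }
  colnames(out) <- paste0("pseudo_", seq_len(n_ind))
  hap$hap <- out
  hap$ploidy <- rep(1L, n_ind)
  hap$pseudo <- TRUE
  hap
}
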