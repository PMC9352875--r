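## Nucleotide diversity within a population and absolute divergence from
## the linear backbone reference, computed locus-by-locus from diploid
## genotype calls.

#' Diploid population genotype matrix
#'
#' Container for per-sample, per-locus diploid allele assignments. Loci
#' are independent (no phasing structure is modelled); each locus carries
#' its full allele set with the reference allele first.
#'
#' @param samples Character vector of sample identifiers (length S).
#' @param loci Data frame with columns `contig`, `pos` (1-based) and a
#'   list-column `alleles` (character vectors, reference allele first).
#' @param calls Integer matrix of dimension L x 2S: allele index (1 =
#'   reference) for each haplotype; haplotypes `2s-1` and `2s` belong to
#'   sample `s`. `NA` marks a missing call and is excluded from allele
#'   totals at that locus.
#' @param strata Optional character vector of subpopulation labels per
#'   sample (used by homogeneous sample ordering).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, loci, calls, strata = NULL) {
  S <- length(samples)
  calls <- as.matrix(calls)
  if (ncol(calls) != 2L * S)
    stopf("calls must have 2 x %d columns (one per haplotype)", S)
  if (nrow(calls) != nrow(loci))
    stopf("calls must have one row per locus")
  if (!is.list(loci$alleles)) stopf("loci$alleles must be a list-column")
  nall <- lengths(loci$alleles)
  mx <- suppressWarnings(apply(calls, 1, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- 1L
  if (any(mx > nall))
    stopf("call references an allele not defined at its locus")
  if (any(calls < 1L, na.rm = TRUE)) stopf("allele indices are 1-based")
  if (!is.null(strata) && length(strata) != S)
    stopf("strata must have one label per sample")
  structure(list(samples = as.character(samples), loci = loci,
                 calls = calls, strata = strata),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d sample(s) (%d alleles), %d locus/loci>\n",
              length(x$samples), 2L * length(x$samples), nrow(x$loci)))
  invisible(x)
}

n_alleles_total <- function(gm) 2L * length(gm$samples)

#' Levenshtein edit distance between two allele strings
#'
#' The distance between alleles at a locus; symmetric, zero iff equal.
#' The shared VCF anchor base contributes nothing.
#'
#' @param a,b Non-empty allele strings.
#' @return Integer edit distance.
#' @examples
#' allele_edit_distance("ACGT", "AT")  # 2
#' @export
allele_edit_distance <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stopf("alleles must be non-empty")
  as.integer(adist(a, b))
}

## per-locus allele occurrence counts, excluding missing calls
locus_allele_counts <- function(gm, locus_idx, haplotype_cols = NULL) {
  x <- gm$calls[locus_idx, , drop = TRUE]
  if (!is.null(haplotype_cols)) x <- x[haplotype_cols]
  x <- x[!is.na(x)]
  tabulate(x, nbins = length(gm$loci$alleles[[locus_idx]]))
}

check_loci_in_region <- function(gm, region) {
  reflen <- nchar(vapply(gm$loci$alleles, `[`, "", 1L))
  s <- gm$loci$pos - 1L
  e <- s + reflen
  bad <- gm$loci$contig != region$contig | s < region$start | e > region$end
  if (any(bad))
    stopf("%d locus/loci fall outside the region", sum(bad))
}

#' Per-region nucleotide diversity and absolute divergence
#'
#' Diversity is the average per-bp edit distance between two haplotypes
#' drawn from the population, over all ordered pairs of distinct alleles:
#' for each variant locus the contribution is
#' sum over allele pairs i != j of |i| |j| d(i,j) / (N (N - 1)),
#' where |i| is the occurrence count of allele i, d the Levenshtein
#' distance between allele strings and N the total (non-missing) allele
#' count at the locus; the region value is the summed contribution divided
#' by the region width. Divergence compares each allele against the
#' reference allele instead:
#' sum over alleles i of |i| d(i, ref) / N, again divided by region width.
#'
#' Loci with fewer than two called alleles contribute nothing to
#' diversity. N is computed locus-wise so missing genotypes simply drop
#' out.
#'
#' @param gm A `genotype_matrix`; all loci must lie inside `region`.
#' @param region A `region`.
#' @return List of class `diversity_result` with elements `region`,
#'   `diversity`, `divergence` (both per-bp) and `per_locus` (data frame
#'   of per-locus contributions, before division by region width).
#' @export
diversity_result <- function(gm, region) {
  if (length(gm$samples) < 1) stopf("need at least one sample")
  check_loci_in_region(gm, region)
  L <- nrow(gm$loci)
  div_c <- num_c <- numeric(L)
  for (l in seq_len(L)) {
    alleles <- gm$loci$alleles[[l]]
    cnt <- locus_allele_counts(gm, l)
    N <- sum(cnt)
    present <- which(cnt > 0)
    if (N >= 1) {
      dref <- as.integer(adist(alleles[present], alleles[1L]))
      num_c[l] <- sum(cnt[present] * dref) / N
    }
    if (N >= 2 && length(present) >= 2) {
      d <- adist(alleles[present])
      cp <- cnt[present]
      div_c[l] <- sum(outer(cp, cp) * d) / (N * (N - 1))
    }
  }
  w <- region_width(region)
  structure(list(region = region,
                 diversity = sum(div_c) / w,
                 divergence = sum(num_c) / w,
                 per_locus = data.frame(contig = gm$loci$contig,
                                        pos = gm$loci$pos,
                                        diversity_contribution = div_c,
                                        divergence_contribution = num_c)),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("<diversity_result %s:%d-%d  diversity=%.6g  divergence=%.6g per bp>\n",
              x$region$contig, x$region$start, x$region$end,
              x$diversity, x$divergence))
  invisible(x)
}

#' @rdname diversity_result
#' @export
nucleotide_diversity <- function(gm, region) {
  if (n_alleles_total(gm) < 2)
    stopf("nucleotide diversity needs at least 2 alleles")
  diversity_result(gm, region)$diversity
}

#' @rdname diversity_result
#' @export
absolute_divergence <- function(gm, region) {
  diversity_result(gm, region)$divergence
}

#' Observed alternate-allele frequency per locus
#'
#' For biallelic loci: the fraction of called haplotypes carrying a
#' non-reference allele, computed over a subset of samples.
#'
#' @param gm A `genotype_matrix`.
#' @param samples Integer vector of sample indices (default all).
#' @return Numeric vector of length `nrow(gm$loci)`; `NaN` where no
#'   haplotype is called.
#' @export
observed_af <- function(gm, samples = seq_along(gm$samples)) {
  cols <- as.vector(rbind(2L * samples - 1L, 2L * samples))
  m <- gm$calls[, cols, drop = FALSE]
  alt <- m > 1L
  rowSums(alt, na.rm = TRUE) / rowSums(!is.na(m))
}
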