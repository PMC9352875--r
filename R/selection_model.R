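## Graph representativeness as a function of the number of construction
## samples: the binomial selection model (probability that a variant of
## true allele frequency f is observed at or above the cut-off in N
## diploid samples) and the empirical sample-accrual experiment.

#' Empirical allele-frequency density on (0, 1]
#'
#' Piecewise-constant (histogram) density of allele frequencies, the
#' weight p(f) of the theoretical TPR/FPR integrals. Constructed either
#' from observed frequencies or from explicit bin densities.
#'
#' @param af Numeric vector of allele frequencies in (0, 1].
#' @param nbins Number of equal-width bins on (0, 1] (default 512).
#' @param breaks,density Alternatively, explicit bin breaks (length B+1,
#'   from 0 to 1) and non-negative per-bin densities; they are
#'   renormalized to integrate to 1.
#' @return Object of class `af_density` with elements `breaks`, `mids`,
#'   `width`, `density`.
#' @export
af_density <- function(af = NULL, nbins = 512L, breaks = NULL, density = NULL) {
  if (is.null(breaks)) {
    breaks <- seq(0, 1, length.out = nbins + 1L)
    if (!is.null(af)) {
      if (any(af <= 0 | af > 1)) stopf("allele frequencies must lie in (0, 1]")
      h <- graphics::hist(af, breaks = breaks, plot = FALSE)
      density <- h$density
    } else stopf("supply af or (breaks, density)")
  }
  width <- diff(breaks)
  if (any(density < 0)) stopf("density must be non-negative")
  tot <- sum(density * width)
  if (tot <= 0) stopf("density has zero total mass")
  density <- density / tot
  structure(list(breaks = breaks, mids = (head(breaks, -1) + tail(breaks, -1)) / 2,
                 width = width, density = density),
            class = "af_density")
}

#' Allele-frequency density from a Beta shape
#'
#' Convenience constructor discretizing a Beta(a, b) profile onto the
#' histogram grid; useful as a smooth stand-in for empirical population
#' AF spectra (small `a` piles mass near zero, as real site-frequency
#' spectra do).
#'
#' @param shape1,shape2 Beta shape parameters.
#' @param nbins Number of bins.
#' @return An `af_density`.
#' @export
af_density_beta <- function(shape1, shape2, nbins = 512L) {
  breaks <- seq(0, 1, length.out = nbins + 1L)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  af_density(breaks = breaks, density = stats::dbeta(mids, shape1, shape2))
}

#' Draw allele frequencies from an AF density
#' @param p An `af_density`.
#' @param n Number of draws.
#' @return Numeric vector in (0, 1].
#' @export
sample_af <- function(p, n) {
  bin <- sample.int(length(p$density), n, replace = TRUE,
                    prob = p$density * p$width)
  pmin(1, pmax(1e-9, p$breaks[bin] + runif(n) * p$width[bin]))
}

## smallest included occurrence count for cut-off f_c over 2N alleles;
## an exact-integer boundary (k/2N == f_c) is included
min_count_for_cutoff <- function(f_c, n_samples) {
  as.integer(ceiling(round(2 * n_samples * f_c, 9)))
}

#' Probability a variant enters the graph
#'
#' A variant with true allele frequency `f` is added to a graph built
#' from `n_samples` diploid samples when its observed occurrence count k
#' among the 2N sampled alleles satisfies k / 2N >= f_c. Occurrences are
#' modelled as independent Bernoulli(f) draws, so k is Binomial(2N, f)
#' and the probability of addition is the binomial upper tail at
#' k = ceiling(2N f_c).
#'
#' @param f True allele frequency (vectorized, in \[0, 1\]).
#' @param f_c Allele-frequency cut-off in (0, 1].
#' @param n_samples Number of diploid samples N (>= 1).
#' @return Probability of addition, same length as `f`.
#' @examples
#' prob_added(0.5, f_c = 0.5, n_samples = 1)  # P(k >= 1 of 2) = 0.75
#' @export
prob_added <- function(f, f_c, n_samples) {
  stopifnot(n_samples >= 1, f_c > 0, f_c <= 1)
  kmin <- min_count_for_cutoff(f_c, n_samples)
  if (kmin <= 0) return(rep(1, length(f)))
  pbinom(kmin - 1L, size = 2L * n_samples, prob = f, lower.tail = FALSE)
}

integral_above <- function(p, f_c) sum(p$density * p$width * (p$mids >= f_c))

#' Theoretical TPR and FPR of graph construction
#'
#' Expected fraction of truly common variants (true AF >= f_c) captured
#' by a graph built from N samples, and the expected number of
#' falsely-included rare variants relative to the ideal graph size.
#' Both are midpoint-rule quadratures of the binomial addition
#' probability against the AF density:
#' TPR = int over f >= f_c of P(added | f) p(f) df / int over f >= f_c of p(f) df;
#' FPR integrates P(added | f) p(f) below the cut-off instead, with the
#' same denominator (so FPR can exceed 1 for densities overwhelmingly
#' concentrated below the cut-off).
#'
#' @param p An `af_density`.
#' @param f_c Allele-frequency cut-off.
#' @param n_samples Number of diploid samples.
#' @return Scalar rate.
#' @export
theoretical_tpr <- function(p, f_c, n_samples) {
  denom <- integral_above(p, f_c)
  if (denom <= 0) stopf("AF density has zero mass at or above the cut-off")
  above <- p$mids >= f_c
  sum(prob_added(p$mids[above], f_c, n_samples) *
        p$density[above] * p$width[above]) / denom
}

#' @rdname theoretical_tpr
#' @export
theoretical_fpr <- function(p, f_c, n_samples) {
  denom <- integral_above(p, f_c)
  if (denom <= 0) stopf("AF density has zero mass at or above the cut-off")
  below <- p$mids < f_c
  sum(prob_added(p$mids[below], f_c, n_samples) *
        p$density[below] * p$width[below]) / denom
}

#' Theoretical selection curve over a range of sample counts
#'
#' @param p An `af_density`.
#' @param f_c Allele-frequency cut-off.
#' @param n_values Integer vector of sample counts.
#' @return Data frame of class `selection_curve` (columns `n`, `tpr`,
#'   `fpr`) with attribute `f_c`.
#' @export
theoretical_curve <- function(p, f_c, n_values) {
  out <- data.frame(n = as.integer(n_values),
                    tpr = vapply(n_values, function(n) theoretical_tpr(p, f_c, n), 0),
                    fpr = vapply(n_values, function(n) theoretical_fpr(p, f_c, n), 0))
  attr(out, "f_c") <- f_c
  class(out) <- c("selection_curve", "data.frame")
  out
}

#' Empirical accrual of graph content, sample by sample
#'
#' Adds population samples one at a time in the given order and, at each
#' step n, builds the variant set of a graph from the first n samples
#' (observed AF >= f_c). Against the ideal set (AF >= f_c in the full
#' matrix) it labels graph variants as true (ideal AF >= f_c) or false
#' positives and reports TPR = |TP| / ideal size, FPR = |FP| / ideal
#' size.
#'
#' @param gm A `genotype_matrix` with biallelic loci.
#' @param order Integer permutation of sample indices (default input
#'   order).
#' @param f_c Allele-frequency cut-off (ties at exactly `f_c` are
#'   included).
#' @return A `selection_curve` data frame (columns `n`, `tpr`, `fpr`)
#'   with attributes `f_c` and `ideal_size`.
#' @export
empirical_accrual <- function(gm, order = seq_along(gm$samples), f_c = 0.05) {
  S <- length(gm$samples)
  stopifnot(length(order) >= 1, all(order %in% seq_len(S)),
            !anyDuplicated(order), f_c > 0, f_c < 1)
  cols <- as.vector(rbind(2L * order - 1L, 2L * order))
  m <- gm$calls[, cols, drop = FALSE]
  alt <- (m > 1L); alt[is.na(m)] <- 0L
  called <- !is.na(m)
  cum_alt <- t(apply(alt, 1, cumsum))
  cum_tot <- t(apply(called, 1, cumsum))
  ideal_af <- observed_af(gm)
  ideal <- !is.na(ideal_af) & ideal_af >= f_c
  ideal_n <- sum(ideal)
  if (ideal_n == 0) stopf("no variant reaches the cut-off in the full population")
  n_values <- seq_along(order)
  tpr <- fpr <- numeric(length(n_values))
  for (i in n_values) {
    tot <- cum_tot[, 2L * i]
    af <- ifelse(tot > 0, cum_alt[, 2L * i] / tot, 0)
    sel <- af >= f_c
    tpr[i] <- sum(sel & ideal) / ideal_n
    fpr[i] <- sum(sel & !ideal) / ideal_n
  }
  out <- data.frame(n = n_values, tpr = tpr, fpr = fpr)
  attr(out, "f_c") <- f_c
  attr(out, "ideal_size") <- ideal_n
  class(out) <- c("selection_curve", "data.frame")
  out
}

#' Sample orderings for the accrual experiment
#'
#' `random` is a seeded uniform shuffle. `homogeneous` walks round-robin
#' across subpopulation strata (in sorted label order), shuffling within
#' each stratum by the seed, so that consecutive samples are spread
#' evenly over subpopulations.
#'
#' @param gm A `genotype_matrix` (strata labels required for
#'   `homogeneous`).
#' @param strategy One of `"homogeneous"`, `"random"`.
#' @param seed Integer seed; fixed seed gives an identical ordering.
#' @return Integer permutation of sample indices.
#' @export
sample_orderings <- function(gm, strategy = c("homogeneous", "random"),
                             seed = 1L) {
  strategy <- match.arg(strategy)
  S <- length(gm$samples)
  if (strategy == "random" || (strategy == "homogeneous" &&
                               length(unique(gm$strata)) <= 1 &&
                               !is.null(gm$strata))) {
    return(with_seed(seed, sample.int(S)))
  }
  if (is.null(gm$strata))
    stopf("homogeneous ordering requires subpopulation labels (strata)")
  labs <- sort(unique(gm$strata))
  pools <- with_seed(seed, lapply(labs, function(l) {
    idx <- which(gm$strata == l)
    idx[sample.int(length(idx))]
  }))
  out <- integer(0)
  repeat {
    taken <- FALSE
    for (j in seq_along(pools)) {
      if (length(pools[[j]]) > 0) {
        out <- c(out, pools[[j]][1])
        pools[[j]] <- pools[[j]][-1]
        taken <- TRUE
      }
    }
    if (!taken) break
  }
  out
}
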