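# Independent oracles: deliberately brute-force / quadratic, sharing no
# code with the implementation paths they check.

# longest common substring by full dynamic programming (row-vectorized)
lcs_dp <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  prev <- integer(length(bv))
  best <- 0L
  for (i in seq_along(av)) {
    eq <- bv == av[i]
    cur <- ifelse(eq, c(0L, prev[-length(prev)]) + 1L, 0L)
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

# all-ordered-pairs diversity: total edit distance between every ordered
# pair of distinct haplotype columns (summed across loci via per-locus
# allele distance matrices), averaged and divided by |R|
diversity_brute <- function(gm, region) {
  H <- ncol(gm$calls)
  pairdist <- matrix(0, H, H)
  for (l in seq_len(nrow(gm$loci))) {
    D <- adist(gm$loci$alleles[[l]])
    pairdist <- pairdist + D[gm$calls[l, ], gm$calls[l, ]]
  }
  sum(pairdist[row(pairdist) != col(pairdist)]) / (H * (H - 1)) /
    (region$end - region$start)
}

# all-vs-reference divergence: mean per-locus distance of each haplotype
# to the reference allele, divided by |R|
divergence_brute <- function(gm, region) {
  H <- ncol(gm$calls)
  total <- 0
  for (l in seq_len(nrow(gm$loci))) {
    D <- adist(gm$loci$alleles[[l]])
    total <- total + sum(D[gm$calls[l, ], 1])
  }
  total / H / (region$end - region$start)
}

# random small genotype matrix with SNP/indel alleles, no missing calls
random_gm <- function(n_samples, n_loci, seed, contig = "chr1",
                      region_len = 500L) {
  set.seed(seed)
  pos <- sort(sample(seq(5L, region_len - 10L), n_loci))
  while (any(diff(pos) < 6L))
    pos <- sort(sample(seq(5L, region_len - 10L), n_loci))
  alleles <- lapply(seq_len(n_loci), function(l) {
    n_alt <- sample(1:3, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), TRUE),
                 collapse = "")
    alts <- replicate(n_alt, paste(sample(c("A", "C", "G", "T"),
                                          sample(1:4, 1), TRUE),
                                   collapse = ""))
    unique(c(ref, alts))
  })
  calls <- matrix(0L, n_loci, 2L * n_samples)
  for (l in seq_len(n_loci))
    calls[l, ] <- sample(seq_along(alleles[[l]]), 2L * n_samples,
                         replace = TRUE)
  loci <- data.frame(contig = contig, pos = pos, stringsAsFactors = FALSE)
  loci$alleles <- alleles
  genotype_matrix(sprintf("s%03d", seq_len(n_samples)), loci, calls)
}

# minimum hitting set by exhaustive search over subset sizes
hitting_set_brute <- function(sets) {
  cand <- sort(unique(unlist(sets)))
  if (length(sets) == 0) return(character(0))
  for (size in seq_along(cand)) {
    combs <- utils::combn(cand, size, simplify = FALSE)
    for (cm in combs) {
      if (all(vapply(sets, function(s) any(s %in% cm), TRUE)))
        return(cm)
    }
  }
  cand
}

# count of pairwise-compatible subsets by explicit 2^k enumeration
count_compatible_subsets <- function(starts, ends) {
  k <- length(starts)
  if (k == 0) return(1L)
  n <- 0L
  for (mask in 0:(2^k - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    ok <- TRUE
    if (length(sel) > 1) {
      for (i in seq_len(length(sel) - 1)) for (j in (i + 1):length(sel)) {
        if (starts[sel[i]] < ends[sel[j]] && starts[sel[j]] < ends[sel[i]]) {
          ok <- FALSE
        }
      }
    }
    if (ok) n <- n + 1L
  }
  n
}

# brute-force placement enumeration over a small graph: for every
# anchor, compatible variant subset and allele-internal offset, spell
# the full path to the contig end and take the L-prefix; returns the
# deduplicated (sequence, contig, anchor, offset) position table
placements_brute <- function(graph, L) {
  out <- list()
  for (ct in names(graph$backbone)) {
    seq <- graph$backbone[[ct]]
    clen <- nchar(seq)
    vt <- graph$variants[graph$variants$contig == ct, , drop = FALSE]
    vt <- vt[order(vt$pos, vt$ref, vt$alt), , drop = FALSE]
    k <- nrow(vt)
    st <- vt$pos - 1L
    en <- st + nchar(vt$ref)
    for (a in 0:(clen - 1L)) {
      for (mask in 0:(2^k - 1)) {
        sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0)
        if (length(sel) > 0 && any(st[sel] < a)) next
        ok <- TRUE
        if (length(sel) > 1) {
          o <- order(st[sel])
          ss <- st[sel][o]; ee <- en[sel][o]
          if (any(ss[-1] < ee[-length(ee)])) ok <- FALSE
        }
        if (!ok) next
        sub <- vt[sel[order(st[sel])], , drop = FALSE]
        # full path spelling from a to the contig end
        pieces <- character(0); cur <- a
        for (idx in seq_len(nrow(sub))) {
          vs <- sub$pos[idx] - 1L
          if (vs > cur) pieces <- c(pieces, substr(seq, cur + 1L, vs))
          pieces <- c(pieces, sub$alt[idx])
          cur <- vs + nchar(sub$ref[idx])
        }
        if (cur < clen) pieces <- c(pieces, substr(seq, cur + 1L, clen))
        path <- paste(pieces, collapse = "")
        skips <- 0L
        if (nrow(sub) > 0 && sub$pos[1] - 1L == a &&
            nchar(sub$alt[1]) > 1L)
          skips <- 0:(nchar(sub$alt[1]) - 1L)
        for (sk in skips) {
          readseq <- substr(path, sk + 1L, sk + L)
          if (nchar(readseq) < L) next
          out[[length(out) + 1L]] <- data.frame(sequence = readseq,
                                                contig = ct, anchor = a,
                                                offset = sk,
                                                stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  res[!duplicated(paste(res$sequence, res$contig, res$anchor, res$offset)), ]
}

# small multimap test instance: two near-identical blocks plus bridging
# SNPs that can recreate the identity, with a few unambiguous SNPs
multimap_instance <- function(seed, L = 60L, contig_len = 900L,
                              block_len = 150L, n_mm = 2L, n_extra = 2L) {
  set.seed(seed)
  repeat {
    bb <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
    src <- 50L
    dst <- contig_len - block_len - 50L
    blk <- bb[src:(src + block_len - 1L)]
    ## mismatch offsets spaced so no L-window of the copies is identical
    repeat {
      offs <- sort(sample(seq(5L, block_len - 5L), n_mm))
      gaps <- diff(c(0L, offs, block_len + 1L))
      if (all(gaps < L - 2L)) break
    }
    blk2 <- blk
    for (o in offs) blk2[o] <- sample(setdiff(c("A", "C", "G", "T"),
                                              blk[o]), 1)
    bb[dst:(dst + block_len - 1L)] <- blk2
    contig <- paste(bb, collapse = "")
    bridging <- data.frame(pos = dst + offs - 1L, ref = blk2[offs],
                           alt = blk[offs], stringsAsFactors = FALSE)
    ## unambiguous extra SNPs in the gap between the two block copies
    zone <- seq(src + block_len + 2L * L, dst - 2L * L)
    v <- bridging
    if (n_extra > 0) {
      extra_pos <- sample(zone, n_extra)
      refb <- substring(contig, extra_pos, extra_pos)
      v <- rbind(v, data.frame(pos = extra_pos, ref = refb,
                               alt = vapply(refb, function(r)
                                 sample(setdiff(c("A", "C", "G", "T"), r),
                                        1), ""),
                               stringsAsFactors = FALSE))
    }
    vt <- variant_table("chr1", v$pos, v$ref, v$alt,
                        af = round(runif(nrow(v), 0.05, 0.5), 3))
    g <- build_graph(c(chr1 = contig), vt)
    # the backbone copy itself must not be a perfect repeat at length L
    rep0 <- detect_ambiguity(build_graph(c(chr1 = contig)), L = L,
                             stride = 1L)
    if (n_edges(g) == nrow(v) && nrow(rep0$ambiguous) == 0) {
      attr(g, "bridging_keys") <- graphref:::variant_key(
        variant_table("chr1", bridging$pos, bridging$ref, bridging$alt))
      ev <- v[-seq_len(nrow(bridging)), , drop = FALSE]
      attr(g, "extra_keys") <- if (nrow(ev) > 0) graphref:::variant_key(
        variant_table("chr1", ev$pos, ev$ref, ev$alt)) else character(0)
      return(g)
    }
  }
}
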