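## Synthetic-data generators. Every stage of the package is testable
## against these: they emit standard FASTA/VCF/SAM plus truth tables so
## downstream results can be scored against known ground truth. Loci are
## statistically independent (no linkage or phasing structure), matching
## the independence assumption of the binomial selection model; this is
## a documented limitation relative to real populations.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Reference allele-frequency spectra for synthetic populations
#'
#' Three fixed Beta-shaped spectra spanning the qualitative range seen
#' across human super-populations: `high_diversity` is strongly
#' rare-skewed (most variants at low frequency, as in the most diverse
#' populations), `low_diversity` is common-skewed, `mid_diversity` sits
#' between. Paired with proportionally more loci for the rare-skewed
#' spectra, they reproduce the pattern that more diverse populations
#' carry both more variant sites and a larger rare fraction.
#'
#' @return Named list of `af_density` objects.
#' @export
af_spectrum_presets <- function() {
  list(high_diversity = af_density_beta(0.3, 1.5),
       mid_diversity = af_density_beta(0.5, 1.0),
       low_diversity = af_density_beta(0.8, 0.8))
}

#' Generate a synthetic multi-contig reference
#'
#' I.i.d. uniform ACGT contigs, optionally with decoy contigs and
#' planted (near-)duplications whose coordinates are returned for
#' multimap tests.
#'
#' @param n_contigs Number of primary contigs.
#' @param lengths Integer vector of contig lengths (recycled).
#' @param n_decoys Number of decoy contigs (appended, named `decoyN`).
#' @param decoy_length Length of each decoy contig.
#' @param seed Integer seed; output is fully reproducible.
#' @param dup Optional planted duplication spec:
#'   `list(length =, n = 1, mismatches = 0)`. Each duplication copies a
#'   window of contig 1 to a non-overlapping position (of contig 1),
#'   with `mismatches` random substitutions applied to the copy.
#' @return List with `backbone` (named character), `decoys` (names) and
#'   `dups` (data frame: contig, src_start, dst_start, length,
#'   mismatch_offsets — 1-based, comma-joined offsets within the copy).
#' @export
make_reference <- function(n_contigs = 1L, lengths = 10000L, n_decoys = 0L,
                           decoy_length = 2000L, seed = 1L, dup = NULL) {
  lengths <- rep_len(as.integer(lengths), n_contigs)
  with_seed(seed, {
    backbone <- setNames(vapply(lengths, random_dna, ""),
                         paste0("chr", seq_len(n_contigs)))
    decoys <- character(0)
    if (n_decoys > 0) {
      dseq <- setNames(vapply(rep_len(decoy_length, n_decoys), random_dna, ""),
                       paste0("decoy", seq_len(n_decoys)))
      decoys <- names(dseq)
      backbone <- c(backbone, dseq)
    }
    dups <- data.frame(contig = character(), src_start = integer(),
                       dst_start = integer(), length = integer(),
                       mismatch_offsets = character(),
                       stringsAsFactors = FALSE)
    if (!is.null(dup)) {
      len <- dup$length
      n <- dup$n %||% 1L
      mm <- dup$mismatches %||% 0L
      clen <- lengths[1]
      for (i in seq_len(n)) {
        src <- sample.int(clen %/% 2L - len, 1L)
        dst <- clen %/% 2L + sample.int(clen %/% 2L - len, 1L)
        piece <- substr(backbone[[1]], src, src + len - 1L)
        offs <- integer(0)
        if (mm > 0) {
          offs <- sort(sample.int(len, mm))
          pb <- strsplit(piece, "")[[1]]
          for (o in offs)
            pb[o] <- sample(setdiff(c("A", "C", "G", "T"), pb[o]), 1L)
          piece <- paste(pb, collapse = "")
        }
        substr(backbone[[1]], dst, dst + len - 1L) <- piece
        dups <- rbind(dups, data.frame(contig = names(backbone)[1],
                                       src_start = src, dst_start = dst,
                                       length = len,
                                       mismatch_offsets = paste(offs,
                                                                collapse = ","),
                                       stringsAsFactors = FALSE))
      }
    }
    list(backbone = backbone, decoys = decoys, dups = dups)
  })
}

#' Simulate a diploid population from an allele-frequency density
#'
#' Places variant loci uniformly along a contig, draws each locus's true
#' allele frequency from `af_density`, and assigns each of the 2N
#' haplotypes the alternate allele independently with probability equal
#' to that frequency — exactly the independence structure the binomial
#' selection model assumes. A fraction of loci are small indels instead
#' of SNPs; optional strata labels split the samples into equal
#' subpopulations (labels only; the allele model is shared).
#'
#' @param backbone Named character vector (loci go on the first contig).
#' @param n_samples Number of diploid samples.
#' @param n_loci Number of variant loci.
#' @param density An `af_density` supplying true allele frequencies.
#' @param indel_fraction Fraction of loci that are 1-3 bp indels.
#' @param n_strata Number of equal subpopulation labels (0 for none).
#' @param seed Integer seed.
#' @return List with `gm` (a `genotype_matrix`), `variants` (a
#'   `variant_table` of the alt alleles with observed AF/AC/AN) and
#'   `truth` (data frame: contig, pos, ref, alt, true_af).
#' @export
make_population <- function(backbone, n_samples, n_loci, density,
                            indel_fraction = 0.1, n_strata = 0L, seed = 1L) {
  ct <- names(backbone)[1]
  seq <- backbone[[ct]]
  clen <- nchar(seq)
  with_seed(seed, {
    ## uniform, well-separated locus positions (room for small indels)
    pos <- sort(sample.int(clen - 10L, n_loci))
    keep <- c(TRUE, diff(pos) >= 6L)
    while (!all(keep)) {
      pos <- pos[keep]
      extra <- sort(sample.int(clen - 10L, n_loci - length(pos)))
      pos <- sort(unique(c(pos, extra)))
      keep <- c(TRUE, diff(pos) >= 6L)
    }
    n_loci <- length(pos)
    f <- sample_af(density, n_loci)
    is_indel <- runif(n_loci) < indel_fraction
    ref <- substr(rep(seq, n_loci), pos, pos)
    alt <- character(n_loci)
    for (l in seq_len(n_loci)) {
      if (is_indel[l]) {
        if (runif(1) < 0.5) {           # insertion of 1-3 bp
          alt[l] <- paste0(ref[l], random_dna(sample.int(3L, 1L)))
        } else {                        # deletion of 1-3 bp
          d <- sample.int(3L, 1L)
          ref[l] <- substr(seq, pos[l], pos[l] + d)
          alt[l] <- substr(seq, pos[l], pos[l])
        }
      } else {
        alt[l] <- sample(setdiff(c("A", "C", "G", "T"), ref[l]), 1L)
      }
    }
    calls <- matrix(1L + (runif(n_loci * 2L * n_samples) <
                            rep(f, 2L * n_samples)),
                    nrow = n_loci)
    samples <- sprintf("S%04d", seq_len(n_samples))
    strata <- if (n_strata > 0)
      paste0("P", rep_len(seq_len(n_strata), n_samples)) else NULL
    loci <- data.frame(contig = ct, pos = pos, stringsAsFactors = FALSE)
    loci$alleles <- mapply(c, ref, alt, SIMPLIFY = FALSE, USE.NAMES = FALSE)
    gm <- genotype_matrix(samples, loci, calls, strata = strata)
    ac <- as.integer(rowSums(calls > 1L))
    an <- 2L * n_samples
    vt <- variant_table(contig = ct, pos = pos, ref = ref, alt = alt,
                        af = ac / an, ac = ac, an = an, source = "simulated")
    truth <- data.frame(contig = ct, pos = pos, ref = ref, alt = alt,
                        true_af = f, stringsAsFactors = FALSE)
    list(gm = gm, variants = vt, truth = truth)
  })
}

#' Generate a structural-variant call set with controlled similarity
#'
#' Plants insertion/deletion SVs (> 50 bp) on a backbone for exercising
#' the SV filter: clean random insertions, insertions embedding a
#' verbatim copy of a backbone window (reference-duplicating), pairs of
#' insertions sharing a long exact substring (near-duplicates), and
#' insertions embedding a decoy window (decoy-matching).
#'
#' @param backbone Named character vector.
#' @param decoys Decoy contig names.
#' @param n_clean,n_ref_copy,n_pairs,n_decoy_copy Counts per category.
#' @param ins_len Length of inserted sequence.
#' @param shared_len Length of the planted shared substring (>= the
#'   filter's read length to trigger it).
#' @param n_del Number of deletion SVs (length `ins_len`).
#' @param af Allele frequency stamped on the records.
#' @param seed Integer seed.
#' @return List with `variants` (a `variant_table`) and `truth` (data
#'   frame: pos, category).
#' @export
make_sv_set <- function(backbone, decoys = character(), n_clean = 2L,
                        n_ref_copy = 1L, n_pairs = 1L, n_decoy_copy = 1L,
                        ins_len = 200L, shared_len = 160L, n_del = 1L,
                        af = 0.2, seed = 1L) {
  ct <- setdiff(names(backbone), decoys)[1]
  seq <- backbone[[ct]]
  clen <- nchar(seq)
  with_seed(seed, {
    total <- n_clean + n_ref_copy + 2L * n_pairs + n_decoy_copy + n_del
    pos <- sort(sample.int(clen - 2L * ins_len - 10L, total))
    ## keep SV loci far enough apart that deletions never overlap
    while (any(diff(pos) < ins_len + 10L)) {
      pos <- sort(sample.int(clen - 2L * ins_len - 10L, total))
    }
    rows <- list(); truth <- list(); pi <- 1L
    add <- function(p, ref, alt, category) {
      rows[[length(rows) + 1L]] <<- data.frame(contig = ct, pos = p,
                                               ref = ref, alt = alt,
                                               stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <<- data.frame(pos = p,
                                                 category = category,
                                                 stringsAsFactors = FALSE)
    }
    anchor <- function(p) substr(seq, p, p)
    for (i in seq_len(n_clean)) {
      add(pos[pi], anchor(pos[pi]),
          paste0(anchor(pos[pi]), random_dna(ins_len)), "clean_insertion")
      pi <- pi + 1L
    }
    for (i in seq_len(n_ref_copy)) {
      src <- sample.int(clen - shared_len, 1L)
      ins <- paste0(random_dna((ins_len - shared_len) %/% 2L),
                    substr(seq, src, src + shared_len - 1L),
                    random_dna(ins_len - shared_len -
                                 (ins_len - shared_len) %/% 2L))
      add(pos[pi], anchor(pos[pi]), paste0(anchor(pos[pi]), ins), "ref_copy")
      pi <- pi + 1L
    }
    for (i in seq_len(n_pairs)) {
      shared <- random_dna(shared_len)
      long <- paste0(random_dna(ins_len - shared_len), shared,
                     random_dna(60L))
      short <- paste0(shared, random_dna(ins_len - shared_len))
      add(pos[pi], anchor(pos[pi]), paste0(anchor(pos[pi]), long),
          "pair_long")
      pi <- pi + 1L
      add(pos[pi], anchor(pos[pi]), paste0(anchor(pos[pi]), short),
          "pair_short")
      pi <- pi + 1L
    }
    for (i in seq_len(n_decoy_copy)) {
      dc <- decoys[1]
      src <- sample.int(nchar(backbone[[dc]]) - shared_len, 1L)
      ins <- paste0(random_dna(ins_len - shared_len),
                    substr(backbone[[dc]], src, src + shared_len - 1L))
      add(pos[pi], anchor(pos[pi]), paste0(anchor(pos[pi]), ins),
          "decoy_copy")
      pi <- pi + 1L
    }
    for (i in seq_len(n_del)) {
      p <- pos[pi]
      add(p, substr(seq, p, p + ins_len), anchor(p), "deletion")
      pi <- pi + 1L
    }
    df <- do.call(rbind, rows)
    list(variants = variant_table(contig = df$contig, pos = df$pos,
                                  ref = df$ref, alt = df$alt, af = af,
                                  source = "sv_fixture"),
         truth = do.call(rbind, truth))
  })
}

#' Generate a synthetic alt contig with its SAM alignment
#'
#' Mutates a window of the backbone with a known edit script (SNPs,
#' insertions, deletions) and returns the alt contig sequence together
#' with a SAM alignment line whose CIGAR uses base-level =/X/I/D
#' operations — input for alt-contig decomposition, with the truth edits
#' retained for round-trip checks.
#'
#' @param backbone Named character vector.
#' @param contig Primary contig to derive from.
#' @param start,end 0-based half-open window on the primary contig.
#' @param n_snp,n_ins,n_del Edit counts; indel lengths are drawn from
#'   `2:ins_max`.
#' @param ins_max Maximum indel length.
#' @param name Alt contig name.
#' @param seed Integer seed.
#' @return List with `name`, `sequence`, `sam_line` (alignment record),
#'   `sq_line` (`@SQ` header for the primary contig), `edits` (truth
#'   data frame) and `span` (the `region` aligned).
#' @export
make_alt_contig <- function(backbone, contig = names(backbone)[1],
                            start, end, n_snp = 3L, n_ins = 1L, n_del = 1L,
                            ins_max = 8L, name = "alt1", seed = 1L) {
  refwin <- substr(backbone[[contig]], start + 1L, end)
  w <- nchar(refwin)
  with_seed(seed, {
    ## choose well-separated edit anchors inside the window
    total <- n_snp + n_ins + n_del
    anchors <- sort(sample(seq(10L, w - ins_max - 10L), total))
    while (any(diff(anchors) < 2L * ins_max))
      anchors <- sort(sample(seq(10L, w - ins_max - 10L), total))
    kind <- sample(c(rep("X", n_snp), rep("I", n_ins), rep("D", n_del)))
    cig <- character(0); qparts <- character(0)
    edits <- list()
    cur <- 1L
    for (e in seq_len(total)) {
      at <- anchors[e]
      if (at > cur) {
        cig <- c(cig, sprintf("%d=", at - cur))
        qparts <- c(qparts, substr(refwin, cur, at - 1L))
      }
      if (kind[e] == "X") {
        rb <- substr(refwin, at, at)
        qb <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
        cig <- c(cig, "1X"); qparts <- c(qparts, qb)
        edits[[length(edits) + 1L]] <- data.frame(type = "X", ref_at = at,
                                                  len = 1L)
        cur <- at + 1L
      } else if (kind[e] == "I") {
        len <- sample(2:ins_max, 1L)
        ins <- random_dna(len)
        cig <- c(cig, sprintf("%dI", len)); qparts <- c(qparts, ins)
        edits[[length(edits) + 1L]] <- data.frame(type = "I", ref_at = at,
                                                  len = len)
        cur <- at
      } else {
        len <- sample(2:ins_max, 1L)
        cig <- c(cig, sprintf("%dD", len))
        edits[[length(edits) + 1L]] <- data.frame(type = "D", ref_at = at,
                                                  len = len)
        cur <- at + len
      }
    }
    if (cur <= w) {
      cig <- c(cig, sprintf("%d=", w - cur + 1L))
      qparts <- c(qparts, substr(refwin, cur, w))
    }
    qseq <- paste(qparts, collapse = "")
    cigar <- paste(cig, collapse = "")
    sam_line <- paste(name, 0L, contig, start + 1L, 60L, cigar, "*", 0L, 0L,
                      qseq, "*", sep = "\t")
    sq_line <- sprintf("@SQ\tSN:%s\tLN:%d", contig,
                       nchar(backbone[[contig]]))
    list(name = name, sequence = qseq, sam_line = sam_line,
         sq_line = sq_line, edits = do.call(rbind, edits),
         span = region(contig, start, end))
  })
}

#' Write alt-contig alignments to a SAM file
#' @param alts List of objects from [make_alt_contig()].
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_alt_sam <- function(alts, path) {
  sq <- unique(vapply(alts, `[[`, "", "sq_line"))
  lines <- c("@HD\tVN:1.6\tSO:unsorted", sq,
             vapply(alts, `[[`, "", "sam_line"))
  writeLines(lines, path)
  invisible(path)
}
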