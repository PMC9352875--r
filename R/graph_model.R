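## Core data structures: regions, variant tables, the backbone+paths genome
## graph, haplotype spelling and local path enumeration.
##
## Coordinate conventions: variant `pos` is 1-based (VCF); regions and all
## internal interval arithmetic are 0-based half-open. Conversion happens
## only at I/O boundaries.

SV_LENGTH_THRESHOLD <- 50L

#' Genomic region (0-based, half-open)
#'
#' @param contig Contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; `end - start` is the region width in bp.
#' @return An object of class `region`.
#' @examples
#' region("chr1", 0, 100)
#' @export
region <- function(contig, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(contig) != 1 || length(start) != 1 || length(end) != 1)
    stopf("region() takes scalar arguments")
  if (is.na(start) || is.na(end) || start < 0 || end <= start)
    stopf("invalid region: need 0 <= start < end (got [%s, %s))", start, end)
  structure(list(contig = as.character(contig), start = start, end = end),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region %s:%d-%d (%d bp)>\n", x$contig, x$start, x$end,
              region_width(x)))
  invisible(x)
}

#' Width of a region in bp
#' @param r A `region`.
#' @return Integer width.
#' @export
region_width <- function(r) r$end - r$start

#' Classify variants by allele length
#'
#' A variant is an SV when the longer of its two alleles exceeds 50 bp;
#' otherwise it is a SNP (equal-length single-base alleles) or an indel.
#'
#' @param ref,alt Allele strings (vectorized).
#' @return Character vector in `c("SNP", "INDEL", "SV")`.
#' @export
classify_variant <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  out <- ifelse(pmax(lr, la) > SV_LENGTH_THRESHOLD, "SV",
                ifelse(lr == 1L & la == 1L, "SNP", "INDEL"))
  out
}

#' Build a table of biallelic variant records
#'
#' The unit record of the graph: one contig/position/ref/alt with optional
#' allele frequency (`af`), allele count (`ac`), total allele number (`an`)
#' and a provenance tag. When both `ac` and `an` are present, `af` must
#' equal `ac / an`.
#'
#' @param contig,pos,ref,alt Record fields; `pos` is 1-based.
#' @param af,ac,an Optional frequency annotations (NA when absent).
#' @param source Provenance tag.
#' @param iter Iteration index of first addition (pipeline bookkeeping).
#' @return A `data.frame` of class `variant_table` with a `var_class` column.
#' @export
variant_table <- function(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          af = NA_real_, ac = NA_integer_, an = NA_integer_,
                          source = NA_character_, iter = NA_integer_) {
  n <- max(length(contig), length(pos), length(ref), length(alt))
  if (length(pos) == 0) n <- 0L
  vt <- data.frame(contig = rep_len(as.character(contig), n),
                   pos = rep_len(as.integer(pos), n),
                   ref = rep_len(toupper(as.character(ref)), n),
                   alt = rep_len(toupper(as.character(alt)), n),
                   af = rep_len(as.numeric(af), n),
                   ac = rep_len(as.integer(ac), n),
                   an = rep_len(as.integer(an), n),
                   source = rep_len(as.character(source), n),
                   iter = rep_len(as.integer(iter), n),
                   stringsAsFactors = FALSE)
  if (n > 0) {
    if (any(nchar(vt$ref) == 0) || any(nchar(vt$alt) == 0))
      stopf("ref and alt alleles must be non-empty")
    ## when counts are present they are the source of truth: af must agree
    ## (up to serialization rounding) and is stored as the exact ratio
    hascnt <- !is.na(vt$ac) & !is.na(vt$an) & vt$an > 0L
    bad <- hascnt & !is.na(vt$af) & abs(vt$af - vt$ac / vt$an) > 1e-5
    if (any(bad))
      stopf("af inconsistent with ac/an for %d record(s)", sum(bad))
    vt$af[hascnt] <- vt$ac[hascnt] / vt$an[hascnt]
    vt$var_class <- classify_variant(vt$ref, vt$alt)
  } else {
    vt$var_class <- character()
  }
  class(vt) <- c("variant_table", "data.frame")
  vt
}

as_variant_table <- function(df) {
  variant_table(contig = df$contig, pos = df$pos, ref = df$ref, alt = df$alt,
                af = df$af %||% NA_real_, ac = df$ac %||% NA_integer_,
                an = df$an %||% NA_integer_,
                source = df$source %||% NA_character_,
                iter = df$iter %||% NA_integer_)
}

## 0-based half-open backbone interval occupied by each record's ref allele
variant_interval <- function(vt) {
  data.frame(start = vt$pos - 1L, end = vt$pos - 1L + nchar(vt$ref))
}

variant_key <- function(vt) paste(vt$contig, vt$pos, vt$ref, vt$alt, sep = "\r")

## the canonical column set, dropping helper columns (e.g. norm_flagged)
vt_core <- function(vt) {
  cols <- c("contig", "pos", "ref", "alt", "af", "ac", "an", "source",
            "iter", "var_class")
  vt[, cols, drop = FALSE]
}

sort_variants <- function(vt) {
  if (nrow(vt) == 0) return(vt)
  vt[order(vt$contig, vt$pos, vt$ref, vt$alt), , drop = FALSE]
}

#' Assemble a genome graph from a backbone and variant records
#'
#' The graph is a linear backbone (one DNA string per contig, stored
#' uppercase) plus a deduplicated set of biallelic variant records
#' interpreted as alternate paths. Records whose ref allele disagrees with
#' the backbone, that run past a contig end, or that touch N-bases are
#' rejected into a log rather than raising an error.
#'
#' @param backbone Named character vector (or `DNAStringSet`) of contig
#'   sequences.
#' @param variants A `variant_table` (may be empty).
#' @param decoys Character vector naming decoy contigs.
#' @return An object of class `genome_graph` with elements `backbone`,
#'   `variants` (sorted, deduplicated), `decoys` and `rejections` (log
#'   data frame).
#' @examples
#' g <- build_graph(c(chr1 = "ACGTACGT"),
#'                  variant_table("chr1", 2, "C", "G"))
#' n_edges(g)
#' @export
build_graph <- function(backbone, variants = variant_table(),
                        decoys = character()) {
  if (methods::is(backbone, "DNAStringSet"))
    backbone <- setNames(as.character(backbone), names(backbone))
  if (is.null(names(backbone)) || any(!nzchar(names(backbone))))
    stopf("backbone contigs must be named")
  backbone <- toupper(backbone)
  stopifnot(all(decoys %in% names(backbone)))
  vt <- as_variant_table(variants)
  rej <- empty_log()
  if (nrow(vt) > 0) {
    ok <- rep(TRUE, nrow(vt))
    reason <- character(nrow(vt))
    known <- vt$contig %in% names(backbone)
    reason[!known] <- "unknown contig"
    ok <- ok & known
    iv <- variant_interval(vt)
    clen <- nchar(backbone)[vt$contig]
    inb <- ok & !is.na(clen) & iv$end <= clen & vt$pos >= 1L
    reason[ok & !inb] <- "outside contig bounds"
    ok <- inb
    if (any(ok)) {
      obs <- substr(backbone[vt$contig[ok]], vt$pos[ok], iv$end[ok])
      mism <- obs != vt$ref[ok]
      reason[which(ok)[mism]] <- "ref mismatch against backbone"
      ok[which(ok)[mism]] <- FALSE
    }
    hasn <- ok & (grepl("[^ACGT]", vt$ref) | grepl("[^ACGT]", vt$alt))
    reason[hasn] <- "non-ACGT allele"
    ok <- ok & !hasn
    rej <- log_entry(vt[!ok, , drop = FALSE], reason[!ok])
    vt <- vt[ok, , drop = FALSE]
    vt <- vt[!duplicated(variant_key(vt)), , drop = FALSE]
    vt <- sort_variants(vt)
    rownames(vt) <- NULL
  }
  structure(list(backbone = backbone, variants = vt, decoys = decoys,
                 rejections = rej),
            class = "genome_graph")
}

#' @export
print.genome_graph <- function(x, ...) {
  cat(sprintf("<genome_graph: %d contig(s), %d bp backbone, %d edge(s), %d decoy(s)>\n",
              length(x$backbone), sum(nchar(x$backbone)), nrow(x$variants),
              length(x$decoys)))
  if (nrow(x$variants) > 0)
    print(table(x$variants$var_class))
  invisible(x)
}

#' Number of variant edges in a graph
#' @param graph A `genome_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(graph) nrow(graph$variants)

## check pairwise compatibility: ref intervals must not intersect
check_non_overlapping <- function(vt) {
  if (nrow(vt) < 2) return(invisible(TRUE))
  iv <- variant_interval(vt)
  o <- order(vt$contig, iv$start, iv$end)
  for (i in seq_len(nrow(vt) - 1)) {
    a <- o[i]; b <- o[i + 1]
    if (vt$contig[a] == vt$contig[b] &&
        intervals_overlap(iv$start[a], iv$end[a], iv$start[b], iv$end[b]))
      stopf("overlapping variants cannot be applied together: %s:%d %s>%s clashes with %s:%d %s>%s",
            vt$contig[a], vt$pos[a], vt$ref[a], vt$alt[a],
            vt$contig[b], vt$pos[b], vt$ref[b], vt$alt[b])
  }
  invisible(TRUE)
}

#' Spell the haplotype of a region with a set of variants applied
#'
#' Returns the backbone sequence of `region` with the given
#' (pairwise non-overlapping, fully contained) variant records applied
#' left-to-right. With no variants this is exactly the backbone substring.
#'
#' @param graph A `genome_graph` (or named character backbone vector).
#' @param region A `region`.
#' @param included A `variant_table` subset to apply (default none).
#' @return DNA string; its length is the region width minus the net
#'   deleted bases of the applied records.
#' @export
spell_haplotype <- function(graph, region, included = NULL) {
  backbone <- if (inherits(graph, "genome_graph")) graph$backbone else graph
  seq <- backbone[[region$contig]]
  if (region$end > nchar(seq)) stopf("region extends past contig end")
  if (is.null(included) || nrow(included) == 0)
    return(substr(seq, region$start + 1L, region$end))
  vt <- included[included$contig == region$contig, , drop = FALSE]
  if (nrow(vt) != nrow(included)) stopf("included variants on wrong contig")
  iv <- variant_interval(vt)
  if (any(iv$start < region$start | iv$end > region$end))
    stopf("included variants must lie fully inside the region")
  check_non_overlapping(vt)
  o <- order(iv$start)
  vt <- vt[o, , drop = FALSE]; iv <- iv[o, , drop = FALSE]
  pieces <- character(0)
  cur <- region$start   # 0-based cursor
  for (i in seq_len(nrow(vt))) {
    if (iv$start[i] > cur)
      pieces <- c(pieces, substr(seq, cur + 1L, iv$start[i]))
    pieces <- c(pieces, vt$alt[i])
    cur <- iv$end[i]
  }
  if (cur < region$end)
    pieces <- c(pieces, substr(seq, cur + 1L, region$end))
  paste0(pieces, collapse = "")
}

## Enumerate pairwise-compatible subsets of variants (given their 0-based
## intervals), as a list of integer index vectors, in deterministic order:
## empty set, then singles in input order, then larger subsets.  `af` breaks
## the fill order when the enumeration must be truncated (higher AF first).
compatible_subsets <- function(starts, ends, max_n = Inf, af = NULL) {
  k <- length(starts)
  out <- list(integer(0))
  if (k == 0) return(out)
  ## the reference path and every single-variant path are always emitted,
  ## even when that alone exceeds max_n
  for (i in seq_len(k)) out[[length(out) + 1L]] <- i
  if (length(out) >= max_n) {
    attr(out, "truncated") <- TRUE
    return(out)
  }
  ## grow breadth-first by size; within a size level, order frontier by
  ## decreasing summed AF (NA treated as 0), then lexicographically
  afv <- if (is.null(af)) rep(0, k) else ifelse(is.na(af), 0, af)
  frontier <- as.list(seq_len(k))
  truncated <- FALSE
  repeat {
    nxt <- list()
    for (s in frontier) {
      last <- s[length(s)]
      if (last >= k) next
      for (j in (last + 1L):k) {
        if (!any(intervals_overlap(starts[s], ends[s], starts[j], ends[j])))
          nxt[[length(nxt) + 1L]] <- c(s, j)
      }
    }
    if (length(nxt) == 0) break
    keyaf <- vapply(nxt, function(s) sum(afv[s]), 0)
    keylex <- vapply(nxt, function(s) paste(sprintf("%06d", s), collapse = ","), "")
    ord <- order(-keyaf, keylex)
    nxt <- nxt[ord]
    for (s in nxt) {
      if (length(out) >= max_n) { truncated <- TRUE; break }
      out[[length(out) + 1L]] <- s
    }
    if (truncated) break
    frontier <- nxt
  }
  attr(out, "truncated") <- truncated
  out
}

#' Enumerate local haplotype paths through a window
#'
#' Spells every subset of mutually compatible (non-overlapping) variants
#' fully contained in the window. If the subset count exceeds `max_paths`
#' the reference-only path and every single-variant path are guaranteed,
#' remaining slots are filled deterministically preferring high-AF
#' combinations, and the result is flagged as truncated.
#'
#' @param graph A `genome_graph`.
#' @param window A `region`.
#' @param max_paths Maximum number of paths to return.
#' @return List of `local_path` objects (fields `window`, `included`,
#'   `sequence`), with attribute `truncated`.
#' @export
enumerate_local_paths <- function(graph, window, max_paths = Inf) {
  stopifnot(region_width(window) >= 1)
  vt <- graph$variants
  iv <- variant_interval(vt)
  inw <- vt$contig == window$contig & iv$start >= window$start &
    iv$end <= window$end
  vt <- vt[inw, , drop = FALSE]; iv <- iv[inw, , drop = FALSE]
  subs <- compatible_subsets(iv$start, iv$end, max_n = max_paths, af = vt$af)
  paths <- lapply(subs, function(s) {
    inc <- vt[s, , drop = FALSE]
    structure(list(window = window, included = inc,
                   sequence = spell_haplotype(graph, window, inc)),
              class = "local_path")
  })
  attr(paths, "truncated") <- isTRUE(attr(subs, "truncated"))
  paths
}
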