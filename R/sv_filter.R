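## Structural-variant ambiguity filtering: insertion sequences that
## duplicate reference sequence, SV pairs that duplicate each other, and
## SV matches on decoy contigs (masked with N), plus a length cap.
## "Similarity" is operationalized as an exact common substring of at
## least read length: exact L-mer sharing is precisely what makes
## read-length fragments multi-map.

#' SV filter configuration
#'
#' @param read_len Read length L in bp (default 150); exact matches of
#'   at least this length trigger filtering.
#' @param max_sv_len Maximum SV allele length in bp (default 10000); the
#'   published method caps SV length without stating a value, so this is
#'   a configurable package default.
#' @return List of class `sv_filter_config`.
#' @export
sv_filter_config <- function(read_len = 150L, max_sv_len = 10000L) {
  stopifnot(read_len >= 20, max_sv_len > read_len)
  structure(list(read_len = as.integer(read_len),
                 max_sv_len = as.integer(max_sv_len)),
            class = "sv_filter_config")
}

kmers_of <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1L), k:n)
}

#' All maximal exact matches between two sequences
#'
#' k-mer anchoring: every shared k-mer is located with a Biostrings
#' dictionary match, and consecutive seeds on the same alignment
#' diagonal are coalesced into maximal exact matches. Complete for
#' matches of length >= k; shorter common substrings are not reported.
#'
#' @param a,b DNA strings (`a` supplies the k-mer dictionary).
#' @param k Seed length; shrunk to `min(nchar(a), nchar(b))` if needed.
#' @return Data frame with columns `len`, `a_start`, `b_start`
#'   (1-based), one row per maximal match of length >= k.
#' @export
shared_matches <- function(a, b, k = 31L) {
  none <- data.frame(len = integer(), a_start = integer(),
                     b_start = integer())
  k <- min(k, nchar(a), nchar(b))
  if (k < 1) return(none)
  km_a <- kmers_of(a, k)
  km_b <- kmers_of(b, k)
  ## vectorized hash join on k-mers; seeds containing non-ACGT (N masks)
  ## are excluded so masked sequence can never match
  ok_a <- !grepl("[^ACGT]", km_a)
  ua <- unique(km_a[ok_a])
  if (length(ua) == 0) return(none)
  amap <- split(which(ok_a), factor(km_a[ok_a], levels = ua))
  hit <- match(km_b, ua)
  jb <- which(!is.na(hit))
  if (length(jb) == 0) return(none)
  alist <- amap[hit[jb]]
  seeds <- data.frame(a_start = unlist(alist, use.names = FALSE),
                      b_start = rep.int(jb, lengths(alist)))
  seeds$diag <- seeds$b_start - seeds$a_start
  seeds <- seeds[order(seeds$diag, seeds$a_start), ]
  ## coalesce runs of consecutive seeds per diagonal: a maximal match of
  ## length m contributes m - k + 1 consecutive seeds
  newrun <- c(TRUE, diff(seeds$diag) != 0 | diff(seeds$a_start) != 1L)
  run <- cumsum(newrun)
  first <- !duplicated(run)
  runlen <- as.integer(table(run))
  data.frame(len = runlen + k - 1L,
             a_start = seeds$a_start[first],
             b_start = seeds$b_start[first])
}

#' Longest common exact substring of two sequences
#'
#' Seed length defaults to `min(31, floor(read_len / 2))`, shrunk to the
#' shorter input when necessary; the result is exact whenever the true
#' longest common substring is at least the seed length, and 0
#' otherwise.
#'
#' @param a,b Non-empty DNA strings.
#' @param k Seed length.
#' @return List with `length` and, when positive, 1-based witness
#'   positions `a_start`, `b_start`.
#' @examples
#' longest_common_exact_substring("ACGT", "TACGTA")$length  # 4
#' @export
longest_common_exact_substring <- function(a, b, k = 31L) {
  stopifnot(nzchar(a), nzchar(b))
  m <- shared_matches(a, b, k = k)
  if (nrow(m) == 0) return(list(length = 0L, a_start = NA_integer_,
                                b_start = NA_integer_))
  i <- which.max(m$len)
  list(length = m$len[i], a_start = m$a_start[i], b_start = m$b_start[i])
}

is_insertion_sv <- function(vt) {
  vt$var_class == "SV" & nchar(vt$alt) > nchar(vt$ref)
}

#' Filter insertion SVs that duplicate reference sequence
#'
#' An insertion whose alt sequence shares an exact substring of at least
#' read length with any non-decoy backbone contig is removed: reads from
#' it could not be placed unambiguously.
#'
#' @param svs A `variant_table` (non-SV records pass through untouched).
#' @param backbone Named character vector of contig sequences.
#' @param decoys Decoy contig names (not screened here).
#' @param cfg An `sv_filter_config`.
#' @return List with `kept`, `removed` (log including witness length).
#' @export
filter_sv_vs_reference <- function(svs, backbone, decoys = character(),
                                   cfg = sv_filter_config()) {
  L <- cfg$read_len
  targets <- setdiff(names(backbone), decoys)
  cand <- which(is_insertion_sv(svs) & nchar(svs$alt) >= L)
  drop <- logical(nrow(svs))
  why <- character(nrow(svs))
  for (i in cand) {
    for (ct in targets) {
      hit <- longest_common_exact_substring(svs$alt[i], backbone[[ct]],
                                            k = min(31L, L %/% 2L))
      if (hit$length >= L) {
        drop[i] <- TRUE
        why[i] <- sprintf("shares %d bp with reference contig %s at %d",
                          hit$length, ct, hit$b_start)
        break
      }
    }
  }
  list(kept = svs[!drop, , drop = FALSE],
       removed = log_entry(svs[drop, , drop = FALSE], why[drop]))
}

#' Filter SV pairs that duplicate each other
#'
#' For every pair of insertion SVs sharing an exact common substring of
#' at least read length, the record with the shorter alt allele is
#' removed (ties keep the record at the lexicographically smaller
#' coordinate). Pairs are processed in deterministic sorted order until
#' a fixpoint, so the result does not depend on input record order.
#'
#' @inheritParams filter_sv_vs_reference
#' @return List with `kept`, `removed`.
#' @export
filter_sv_vs_sv <- function(svs, cfg = sv_filter_config()) {
  L <- cfg$read_len
  svs <- sort_variants(svs)
  cand <- which(is_insertion_sv(svs) & nchar(svs$alt) >= L)
  drop <- logical(nrow(svs))
  why <- character(nrow(svs))
  k <- min(31L, L %/% 2L)
  repeat {
    changed <- FALSE
    live <- cand[!drop[cand]]
    if (length(live) >= 2) {
      for (ii in seq_len(length(live) - 1)) {
        i <- live[ii]
        if (drop[i]) next
        for (jj in (ii + 1):length(live)) {
          j <- live[jj]
          if (drop[i] || drop[j]) next
          hit <- longest_common_exact_substring(svs$alt[i], svs$alt[j], k = k)
          if (hit$length >= L) {
            ## remove the shorter alt; on ties the later coordinate goes
            loser <- if (nchar(svs$alt[i]) < nchar(svs$alt[j])) i
            else if (nchar(svs$alt[j]) < nchar(svs$alt[i])) j
            else j   # svs sorted: j has the larger (contig, pos, ref, alt)
            winner <- if (loser == i) j else i
            drop[loser] <- TRUE
            why[loser] <- sprintf("shares %d bp with kept SV %s:%d",
                                  hit$length, svs$contig[winner],
                                  svs$pos[winner])
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  list(kept = svs[!drop, , drop = FALSE],
       removed = log_entry(svs[drop, , drop = FALSE], why[drop]))
}

#' Mask decoy sequence matched by kept SVs
#'
#' Every maximal exact match of at least read length between a kept SV
#' alt sequence and a decoy contig is replaced by N bases on the decoy,
#' so the decoy cannot absorb reads that belong on the SV path. The SV
#' set itself is unchanged; overlapping match intervals are masked as
#' their union.
#'
#' @inheritParams filter_sv_vs_reference
#' @return List with `backbone` (modified), `mask_log` (data frame of
#'   masked intervals, 1-based inclusive).
#' @export
mask_decoys <- function(svs, backbone, decoys, cfg = sv_filter_config()) {
  L <- cfg$read_len
  k <- min(31L, L %/% 2L)
  cand <- which(is_insertion_sv(svs) & nchar(svs$alt) >= L)
  mask_log <- data.frame(decoy = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  for (dc in decoys) {
    ivs <- list()
    for (i in cand) {
      m <- shared_matches(svs$alt[i], backbone[[dc]], k = k)
      m <- m[m$len >= L, , drop = FALSE]
      if (nrow(m))
        ivs[[length(ivs) + 1L]] <- IRanges::IRanges(start = m$b_start,
                                                    width = m$len)
    }
    if (length(ivs) == 0) next
    merged <- IRanges::reduce(do.call(c, ivs))
    seq <- backbone[[dc]]
    for (j in seq_along(merged)) {
      s <- IRanges::start(merged)[j]; e <- IRanges::end(merged)[j]
      substr(seq, s, e) <- strrep("N", e - s + 1L)
      mask_log <- rbind(mask_log,
                        data.frame(decoy = dc, start = s, end = e,
                                   stringsAsFactors = FALSE))
    }
    backbone[[dc]] <- seq
  }
  list(backbone = backbone, mask_log = mask_log)
}

#' Cap SV allele length
#'
#' Removes records whose longer allele exceeds `max_sv_len`; very long
#' SV paths are disproportionately costly downstream.
#'
#' @inheritParams filter_sv_vs_reference
#' @return List with `kept`, `removed`.
#' @export
cap_sv_length <- function(svs, cfg = sv_filter_config()) {
  too_long <- pmax(nchar(svs$ref), nchar(svs$alt)) > cfg$max_sv_len
  list(kept = svs[!too_long, , drop = FALSE],
       removed = log_entry(svs[too_long, , drop = FALSE],
                           sprintf("allele longer than %d bp cap",
                                   cfg$max_sv_len)))
}

#' Full SV filter chain
#'
#' Runs, in order: insertion-vs-reference filtering, SV-vs-SV
#' deduplication, decoy masking, and the length cap. Only insertion alts
#' are screened against sequence; deletions participate in the length
#' cap only.
#'
#' @param vt A `variant_table` (all classes; non-SVs pass through).
#' @param backbone Named character vector including decoys.
#' @param decoys Decoy contig names.
#' @param cfg An `sv_filter_config`.
#' @return List with `kept`, `removed` (log with stage column),
#'   `backbone` (decoy-masked), `mask_log`.
#' @export
sv_filter <- function(vt, backbone, decoys = character(),
                      cfg = sv_filter_config()) {
  s1 <- filter_sv_vs_reference(vt, backbone, decoys, cfg)
  s2 <- filter_sv_vs_sv(s1$kept, cfg)
  s3 <- mask_decoys(s2$kept, backbone, decoys, cfg)
  s4 <- cap_sv_length(s2$kept, cfg)
  removed <- rbind(cbind(s1$removed, stage = rep_len("sv_vs_reference", nrow(s1$removed))),
                   cbind(s2$removed, stage = rep_len("sv_vs_sv", nrow(s2$removed))),
                   cbind(s4$removed, stage = rep_len("length_cap", nrow(s4$removed))))
  list(kept = s4$kept, removed = removed, backbone = s3$backbone,
       mask_log = s3$mask_log)
}
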