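## Variant-source preparation: quality filtering, multiallelic splitting,
## left normalization, alt-contig decomposition, source merging with
## allele-frequency recalculation, and the AF cut-off filter.

#' Quality-control filter on raw VCF records
#'
#' Default rule: keep records whose FILTER is PASS or missing. A custom
#' predicate on the raw record data frame can replace the rule.
#'
#' @param records Raw records from [read_site_vcf()].
#' @param predicate Function taking the data frame and returning a
#'   logical keep vector, or `NULL` for the default.
#' @return List with `kept` (records) and `removed` (log data frame).
#' @export
qc_filter <- function(records, predicate = NULL) {
  if (nrow(records) == 0) return(list(kept = records, removed = empty_log()))
  keep <- if (is.null(predicate)) {
    records$filter %in% c("PASS", ".", "") | is.na(records$filter)
  } else predicate(records)
  list(kept = records[keep, , drop = FALSE],
       removed = log_entry(records[!keep, , drop = FALSE], "failed QC filter"))
}

#' Split multiallelic records into biallelic variant records
#'
#' Each alternate allele becomes its own record carrying its per-allele
#' AC/AF; positions are unchanged (normalization happens separately).
#' Records whose per-allele annotations cannot be aligned with their
#' alts are rejected to the log.
#'
#' @param records Raw records from [read_site_vcf()], or a data frame
#'   with `alt` as comma-joined alleles and list-columns `af`, `ac`.
#' @return List with `kept` (a `variant_table`) and `removed` (log).
#' @export
split_multiallelic <- function(records) {
  removed <- empty_log()
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    alts <- strsplit(records$alt[i], ",", fixed = TRUE)[[1]]
    m <- length(alts)
    af <- if (is.list(records$af)) records$af[[i]] else records$af[i]
    ac <- if (is.list(records$ac)) records$ac[[i]] else records$ac[i]
    if (length(af) == 0 || all(is.na(af))) af <- rep(NA_real_, m)
    if (length(ac) == 0 || all(is.na(ac))) ac <- rep(NA_integer_, m)
    if (m == 0 || !nzchar(records$ref[i]) ||
        length(af) != m || length(ac) != m) {
      removed <- rbind(removed,
                       data.frame(contig = records$contig[i],
                                  pos = records$pos[i], ref = records$ref[i],
                                  alt = records$alt[i],
                                  reason = "malformed record",
                                  stringsAsFactors = FALSE))
      next
    }
    rows[[i]] <- data.frame(contig = records$contig[i], pos = records$pos[i],
                            ref = records$ref[i], alt = alts, af = af,
                            ac = as.integer(ac),
                            an = records$an[i] %||% NA_integer_,
                            source = records$source[i] %||% NA_character_,
                            stringsAsFactors = FALSE)
  }
  kept <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(kept))
    kept <- variant_table()
  else
    kept <- variant_table(contig = kept$contig, pos = kept$pos, ref = kept$ref,
                          alt = kept$alt, af = kept$af, ac = kept$ac,
                          an = kept$an, source = kept$source)
  list(kept = kept, removed = removed)
}

## scalar left-normalization; returns list(pos, ref, alt, flagged)
normalize_one <- function(pos, ref, alt, seq) {
  flagged <- FALSE
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (substr(ref, lr, lr) != substr(alt, la, la)) break
    if (lr > 1 && la > 1) {
      ref <- substr(ref, 1, lr - 1); alt <- substr(alt, 1, la - 1)
    } else if (pos > 1) {
      b <- substr(seq, pos - 1, pos - 1)
      ref <- paste0(b, substr(ref, 1, lr - 1))
      alt <- paste0(b, substr(alt, 1, la - 1))
      pos <- pos - 1L
    } else { flagged <- TRUE; break }   # cannot extend past contig start
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt, flagged = flagged)
}

#' Left-normalize variant records against the backbone
#'
#' Standard parsimony/left-shift normalization: while ref and alt share
#' their last base, trim it (left-extending with the preceding backbone
#' base when an allele would become empty), then trim shared leading
#' bases keeping at least one. Idempotent; records that would walk off
#' the contig start are kept at position 1 and flagged.
#'
#' @param vt A `variant_table` whose refs are consistent with `backbone`.
#' @param backbone Named character vector of contig sequences.
#' @return The normalized `variant_table` with a logical `norm_flagged`
#'   column.
#' @export
left_normalize <- function(vt, backbone) {
  if (nrow(vt) == 0) { vt$norm_flagged <- logical(0); return(vt) }
  out <- vt
  flg <- logical(nrow(vt))
  for (i in seq_len(nrow(vt))) {
    r <- normalize_one(vt$pos[i], vt$ref[i], vt$alt[i],
                       backbone[[vt$contig[i]]])
    out$pos[i] <- r$pos; out$ref[i] <- r$ref; out$alt[i] <- r$alt
    flg[i] <- r$flagged
  }
  out$var_class <- classify_variant(out$ref, out$alt)
  out$norm_flagged <- flg
  out
}

## ---- alt-contig decomposition -------------------------------------------

parse_cigar <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  data.frame(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
             op = sub("^\\d+", "", toks), stringsAsFactors = FALSE)
}

## walk one alignment, emitting raw (unnormalized) variant records by
## direct comparison of the query against the backbone
decompose_alignment <- function(qname, rname, pos, cigar, seq, backbone) {
  ref <- backbone[[rname]]
  cg <- parse_cigar(cigar)
  rpos <- pos          # 1-based ref cursor
  qpos <- 1L           # 1-based query cursor
  recs <- list()
  emit <- function(p, r, a) recs[[length(recs) + 1L]] <<-
    data.frame(contig = rname, pos = p, ref = r, alt = a,
               stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cg))) {
    len <- cg$len[i]; op <- cg$op[i]
    if (op %in% c("M", "=", "X")) {
      qseg <- substr(seq, qpos, qpos + len - 1L)
      rseg <- substr(ref, rpos, rpos + len - 1L)
      if (qseg != rseg) {
        qb <- strsplit(qseg, "")[[1]]; rb <- strsplit(rseg, "")[[1]]
        for (j in which(qb != rb)) emit(rpos + j - 1L, rb[j], qb[j])
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "I") {
      ins <- substr(seq, qpos, qpos + len - 1L)
      if (rpos > 1L) {
        b <- substr(ref, rpos - 1L, rpos - 1L)
        emit(rpos - 1L, b, paste0(b, ins))
      } else {
        b <- substr(ref, rpos, rpos)
        emit(rpos, b, paste0(ins, b))
      }
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      del <- substr(ref, rpos, rpos + len - 1L)
      if (rpos > 1L) {
        b <- substr(ref, rpos - 1L, rpos - 1L)
        emit(rpos - 1L, paste0(b, del), b)
      } else {
        b <- substr(ref, rpos + len, rpos + len)
        emit(rpos, paste0(del, b), b)
      }
      rpos <- rpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    } # H, P consume nothing we track
  }
  vt <- if (length(recs)) do.call(rbind, recs) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  list(variants = vt, ref_span = c(pos - 1L, rpos - 1L))  # 0-based half-open
}

#' Decompose alt contigs into variant paths on the primary assembly
#'
#' Removes ALT/NOVEL contigs from the assembly and converts each one's
#' alignment to its primary region into left-normalized SNP, insertion
#' and deletion records, so alternate haplotypes become graph paths
#' instead of separate sequences. The round trip holds: applying the
#' emitted records to the primary region reconstructs the aligned
#' portion of the alt contig.
#'
#' @param assembly List as from [read_backbone_fasta()] (elements
#'   `backbone`, `decoys`, `alt_contigs`), or a named character vector
#'   plus an `alt_contigs` argument.
#' @param alignments List as from [read_alt_alignments()], or a path to
#'   a SAM file.
#' @param alt_contigs Contig names to treat as alternate haplotypes
#'   (defaults to `assembly$alt_contigs`).
#' @param source Provenance tag for the emitted records.
#' @return List with `primary` (backbone without alt contigs),
#'   `variants` (normalized `variant_table`), `spans` (per alt contig,
#'   the 0-based half-open primary region covered) and `dropped`
#'   (names of unaligned alt contigs).
#' @export
decompose_alt_contigs <- function(assembly, alignments,
                                  alt_contigs = NULL,
                                  source = "altcontig") {
  if (is.character(assembly))
    assembly <- list(backbone = toupper(assembly), decoys = character(),
                     alt_contigs = character())
  alt_contigs <- alt_contigs %||% assembly$alt_contigs
  if (is.character(alignments) && length(alignments) == 1)
    alignments <- read_alt_alignments(alignments)
  aln <- alignments$alignments
  aln <- aln[aln$qname %in% alt_contigs, , drop = FALSE]
  dropped <- union(alignments$unmapped,
                   setdiff(alt_contigs, aln$qname))
  primary <- assembly$backbone[setdiff(names(assembly$backbone), alt_contigs)]
  all_vt <- list(); spans <- list()
  for (i in seq_len(nrow(aln))) {
    d <- decompose_alignment(aln$qname[i], aln$rname[i], aln$pos[i],
                             aln$cigar[i], toupper(aln$seq[i]), primary)
    spans[[aln$qname[i]]] <- region(aln$rname[i], d$ref_span[1], d$ref_span[2])
    if (nrow(d$variants)) {
      vt <- variant_table(contig = d$variants$contig, pos = d$variants$pos,
                          ref = d$variants$ref, alt = d$variants$alt,
                          source = paste0(source, ":", aln$qname[i]))
      all_vt[[length(all_vt) + 1L]] <- left_normalize(vt, primary)
    }
  }
  variants <- if (length(all_vt)) {
    v <- do.call(rbind, lapply(all_vt, function(x) x[names(all_vt[[1]])]))
    v <- v[!duplicated(variant_key(v)), , drop = FALSE]
    sort_variants(v)
  } else variant_table()
  list(primary = primary, variants = variants, spans = spans,
       dropped = dropped)
}

## ---- merging and AF filtering -------------------------------------------

#' Merge harmonized variant sources and recalculate allele frequencies
#'
#' Records are keyed by (contig, pos, ref, alt). When every source
#' carrying a record provides AC and AN, the merged frequency is
#' sum(AC) / sum(AN); otherwise it is the sample-count-weighted mean of
#' the available per-source AFs. Provenance tags are concatenated.
#' Order-independent: permuting the sources yields identical output.
#'
#' @param sources List of sources, each a list with elements `variants`
#'   (a normalized biallelic `variant_table`), `n_samples` (weight) and
#'   optionally `name`.
#' @return A merged, sorted `variant_table`.
#' @export
merge_sources <- function(sources) {
  if (length(sources) == 0) return(variant_table())
  parts <- lapply(sources, function(s) {
    vt <- s$variants
    vt$weight <- rep_len(as.numeric(s$n_samples %||% 1), nrow(vt))
    if (!is.null(s$name)) vt$source <- rep_len(s$name, nrow(vt))
    vt
  })
  all <- do.call(rbind, lapply(parts, function(p)
    p[, c("contig", "pos", "ref", "alt", "af", "ac", "an", "source",
          "weight"), drop = FALSE]))
  key <- variant_key(all)
  groups <- split(seq_len(nrow(all)), key)
  ## deterministic output order regardless of source order
  rows <- lapply(groups, function(idx) {
    g <- all[idx, , drop = FALSE]
    if (all(!is.na(g$ac)) && all(!is.na(g$an))) {
      ac <- sum(g$ac); an <- sum(g$an); af <- ac / an
    } else {
      ac <- NA_integer_; an <- NA_integer_
      ok <- !is.na(g$af)
      af <- if (any(ok)) sum(g$af[ok] * g$weight[ok]) / sum(g$weight[ok])
      else NA_real_
    }
    data.frame(contig = g$contig[1], pos = g$pos[1], ref = g$ref[1],
               alt = g$alt[1], af = af, ac = as.integer(ac),
               an = as.integer(an),
               source = paste(sort(unique(g$source[!is.na(g$source)])),
                              collapse = ","),
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, rows)
  m$source[m$source == ""] <- NA_character_
  sort_variants(variant_table(contig = m$contig, pos = m$pos, ref = m$ref,
                              alt = m$alt, af = m$af, ac = m$ac, an = m$an,
                              source = m$source))
}

#' Allele-frequency filter
#'
#' Keeps records whose merged AF is at or above the cut-off (ties
#' included). Records with no AF are dropped and logged.
#'
#' @param vt A `variant_table` with merged AFs.
#' @param f_c Allele-frequency cut-off (default 0.05).
#' @return List with `kept` and `removed` (log with reasons).
#' @export
af_filter <- function(vt, f_c = 0.05) {
  if (nrow(vt) == 0) return(list(kept = vt, removed = empty_log()))
  missing <- is.na(vt$af)
  low <- !missing & vt$af < f_c
  removed <- rbind(log_entry(vt[missing, , drop = FALSE], "missing AF"),
                   log_entry(vt[low, , drop = FALSE], "AF below cut-off"))
  list(kept = vt[!missing & !low, , drop = FALSE], removed = removed)
}
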