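## End-to-end graph construction: harmonize sources, decompose alt
## contigs, merge with AF recalculation, AF-filter, SV-filter, build,
## multimap-prune — with per-stage record accounting, plus the iterative
## augmentation loop that folds cohort calls back into the graph.

default_config <- function() {
  list(version = 1L, f_c = 0.05, read_len = 150L, max_sv_len = 10000L,
       stride = 1L, seed = 1L, max_paths_per_anchor = 64L)
}

#' Load a graph construction config
#'
#' @param x A YAML file path or a named list; missing keys take package
#'   defaults (`f_c` 0.05, `read_len` 150, `max_sv_len` 10000, `stride`
#'   1, `seed` 1).
#' @return Normalized config list.
#' @export
load_config <- function(x) {
  if (is.character(x) && length(x) == 1) x <- yaml::read_yaml(x)
  cfg <- utils::modifyList(default_config(), x)
  if (!is.null(cfg$version) && cfg$version != 1L)
    stopf("unsupported config schema version %s", cfg$version)
  cfg
}

stage_log <- function(input, kept, removed) {
  list(input = input, kept = kept, removed = removed)
}

## harmonize one source into a normalized biallelic variant table
prepare_source <- function(src, backbone) {
  raw <- if (!is.null(src$variants)) {
    v <- src$variants
    if (inherits(v, "variant_table")) {
      ## already biallelic records; route through the same log structure
      data.frame(contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
                 filter = "PASS", an = v$an, source = src$name %||% v$source,
                 af = I(as.list(v$af)), ac = I(as.list(v$ac)),
                 stringsAsFactors = FALSE)
    } else v
  } else read_site_vcf(src$vcf, source = src$name %||% basename(src$vcf))
  qc <- qc_filter(raw, src$qc_predicate %||% NULL)
  sp <- split_multiallelic(qc$kept)
  norm <- left_normalize(sp$kept, backbone)
  list(variants = norm,
       log = stage_log(nrow(raw),
                       nrow(norm),
                       rbind(qc$removed, sp$removed)))
}

#' Construct a genome graph from a configuration
#'
#' Runs the full construction pipeline deterministically: per-source
#' QC + multiallelic splitting + left normalization, optional
#' alt-contig decomposition, merging with allele-frequency
#' recalculation, the AF cut-off filter, the SV ambiguity filter
#' (including decoy masking) and multimap pruning. Alt-contig-derived
#' records carry no population AF and are added alongside the
#' AF-filtered merged set rather than being discarded by it.
#'
#' @param config A config list or YAML path (see [load_config()]).
#'   Recognized keys: `backbone_fasta` (or `backbone` + `decoy_contigs`
#'   + `alt_contigs` in-memory), `alt_alignments` (SAM), `sources`
#'   (list of `name`/`vcf`-or-`variants`/`n_samples`), `f_c`,
#'   `read_len`, `max_sv_len`, `stride`, `seed`.
#' @return List of class `graph_build`: `graph` (the final
#'   `genome_graph`), `stage_logs` (per-stage input/kept/removed
#'   accounting), `mask_log`, `multimap` (pruning result) and
#'   `summary` (as [graph_summary()], plus pruning counters).
#' @export
construct_graph <- function(config) {
  cfg <- load_config(config)
  if (!is.null(cfg$backbone_fasta)) {
    bb <- read_backbone_fasta(cfg$backbone_fasta)
  } else {
    bb <- list(backbone = toupper(cfg$backbone),
               decoys = cfg$decoy_contigs %||% character(),
               alt_contigs = cfg$alt_contigs %||% character())
  }
  svcfg <- sv_filter_config(read_len = cfg$read_len,
                            max_sv_len = cfg$max_sv_len)
  logs <- list()

  ## alt-contig decomposition (before source harmonization: sources are
  ## expressed against the primary contigs)
  backbone <- bb$backbone
  alt_vt <- variant_table()
  if (length(bb$alt_contigs) > 0 && !is.null(cfg$alt_alignments)) {
    dec <- decompose_alt_contigs(bb, cfg$alt_alignments)
    backbone <- dec$primary
    alt_vt <- dec$variants
    alt_vt$iter <- rep_len(1L, nrow(alt_vt))
    logs$alt_contigs <- stage_log(length(bb$alt_contigs),
                                  length(bb$alt_contigs) -
                                    length(dec$dropped),
                                  data.frame(contig = dec$dropped,
                                             reason = rep_len("unaligned alt contig",
                                                              length(dec$dropped))))
  } else {
    backbone <- backbone[setdiff(names(backbone), bb$alt_contigs)]
  }

  ## per-source harmonization
  prepped <- lapply(cfg$sources %||% list(), prepare_source,
                    backbone = backbone)
  for (i in seq_along(prepped))
    logs[[paste0("source_", cfg$sources[[i]]$name %||% i)]] <- prepped[[i]]$log

  ## merge + AF recalculation
  merged <- merge_sources(lapply(seq_along(prepped), function(i)
    list(variants = prepped[[i]]$variants,
         n_samples = cfg$sources[[i]]$n_samples %||% 1,
         name = cfg$sources[[i]]$name %||% NULL)))
  logs$merge <- stage_log(sum(vapply(prepped, function(p)
    nrow(p$variants), 0L)), nrow(merged), empty_log())

  ## AF cut-off
  aff <- af_filter(merged, f_c = cfg$f_c)
  logs$af_filter <- stage_log(nrow(merged), nrow(aff$kept), aff$removed)

  ## union with alt-contig paths (exempt from the AF filter)
  pool <- rbind(vt_core(aff$kept), vt_core(alt_vt))
  pool <- pool[!duplicated(variant_key(pool)), , drop = FALSE]
  pool$iter[is.na(pool$iter)] <- 1L

  ## SV ambiguity filter + decoy masking
  svf <- sv_filter(pool, backbone, decoys = bb$decoys, cfg = svcfg)
  logs$sv_filter <- stage_log(nrow(pool), nrow(svf$kept), svf$removed)
  backbone <- svf$backbone

  ## assemble and multimap-prune
  graph <- build_graph(backbone, svf$kept, decoys = bb$decoys)
  logs$build <- stage_log(nrow(svf$kept), n_edges(graph), graph$rejections)
  mm <- multimap_prune(graph, L = cfg$read_len, stride = cfg$stride,
                       objective = cfg$objective %||% "count",
                       max_paths_per_anchor = cfg$max_paths_per_anchor)
  logs$multimap <- stage_log(n_edges(graph), n_edges(mm$graph),
                             data.frame(key = mm$removed,
                                        reason = rep_len("multimap pruning",
                                                         length(mm$removed))))
  summ <- graph_summary(mm$graph)
  summ$multimap_removed <- length(mm$removed)
  summ$multimap_bp_removed <- mm$bp_removed
  structure(list(graph = mm$graph, stage_logs = logs,
                 mask_log = svf$mask_log, multimap = mm, summary = summ,
                 config = cfg),
            class = "graph_build")
}

#' @export
print.graph_build <- function(x, ...) {
  cat("<graph_build>\n")
  print(x$graph)
  for (nm in names(x$stage_logs)) {
    lg <- x$stage_logs[[nm]]
    cat(sprintf("  %-18s in=%d kept=%d removed=%d\n", nm, lg$input, lg$kept,
                if (is.data.frame(lg$removed)) nrow(lg$removed) else 0L))
  }
  invisible(x)
}

#' Augment a graph with a new cohort's variant calls
#'
#' The iterative construction loop: variant calls from a cohort analyzed
#' against the current graph are AF-filtered at the cut-off and merged
#' into the graph's variant set as a new source, then the SV filter and
#' multimap filter are re-run over the union. Existing edges are never
#' removed by AF re-filtering — only the multimap stage may prune them.
#' Newly added edges carry the next iteration index.
#'
#' @param prior A `graph_build` or `genome_graph`.
#' @param cohort A `variant_table` (normalized against the same
#'   backbone) or path to a site VCF of cohort calls with AF/AC/AN.
#' @param f_c Allele-frequency cut-off for the new calls.
#' @param read_len,stride,max_sv_len,max_paths_per_anchor As in
#'   [construct_graph()].
#' @return A `graph_build` for the augmented graph.
#' @export
augment_graph <- function(prior, cohort, f_c = 0.05, read_len = 150L,
                          stride = 1L, max_sv_len = 10000L,
                          max_paths_per_anchor = 64L) {
  graph <- if (inherits(prior, "graph_build")) prior$graph else prior
  if (is.character(cohort) && length(cohort) == 1) {
    sp <- split_multiallelic(read_site_vcf(cohort, source = "cohort"))
    cohort <- left_normalize(sp$kept, graph$backbone)
  }
  bad <- !(cohort$contig %in% names(graph$backbone))
  if (any(bad)) stopf("cohort calls on contig(s) absent from the backbone: %s",
                      paste(unique(cohort$contig[bad]), collapse = ", "))
  logs <- list()
  aff <- af_filter(cohort, f_c = f_c)
  logs$af_filter <- stage_log(nrow(cohort), nrow(aff$kept), aff$removed)
  prev_iter <- suppressWarnings(max(graph$variants$iter, na.rm = TRUE))
  if (!is.finite(prev_iter)) prev_iter <- 1L
  new <- aff$kept
  novel <- !(variant_key(new) %in% variant_key(graph$variants))
  new$iter <- rep_len(prev_iter + 1L, nrow(new))
  prior_vt <- graph$variants
  pool <- rbind(prior_vt[, names(prior_vt), drop = FALSE],
                new[novel, names(prior_vt), drop = FALSE])
  logs$union <- stage_log(nrow(prior_vt) + nrow(new), nrow(pool),
                          log_entry(new[!novel, , drop = FALSE],
                                    "already present in graph"))
  svcfg <- sv_filter_config(read_len = read_len, max_sv_len = max_sv_len)
  svf <- sv_filter(pool, graph$backbone, decoys = graph$decoys, cfg = svcfg)
  logs$sv_filter <- stage_log(nrow(pool), nrow(svf$kept), svf$removed)
  g2 <- build_graph(svf$backbone, svf$kept, decoys = graph$decoys)
  logs$build <- stage_log(nrow(svf$kept), n_edges(g2), g2$rejections)
  mm <- multimap_prune(g2, L = read_len, stride = stride,
                       max_paths_per_anchor = max_paths_per_anchor)
  logs$multimap <- stage_log(n_edges(g2), n_edges(mm$graph),
                             data.frame(key = mm$removed,
                                        reason = rep_len("multimap pruning",
                                                         length(mm$removed))))
  summ <- graph_summary(mm$graph)
  summ$multimap_removed <- length(mm$removed)
  summ$multimap_bp_removed <- mm$bp_removed
  structure(list(graph = mm$graph, stage_logs = logs,
                 mask_log = svf$mask_log, multimap = mm, summary = summ),
            class = "graph_build")
}
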