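## Graph-induced reference ambiguity: simulate reads over every local
## path of the graph, find reads whose exact sequence is spelled at more
## than one placement, and prune a minimal variant set that resolves the
## ambiguity. Ambiguity here means exact full-length duplicate
## spellings; mismatch-tolerant multi-mapping is out of scope, which
## keeps the filter deterministic and auditable.

## spell the L-prefix of the path starting at 0-based backbone position
## `a` with the given (sorted, compatible) variant rows applied; returns
## NULL if fewer than L path bases are available before the contig ends.
## `effective` marks variants whose first differing path character falls
## within the read.
spell_from <- function(seq, clen, a, pos, ref, alt, lr, la, L, skip = 0L) {
  nv <- length(pos)
  out <- character(0)
  plen <- 0L          # path chars emitted so far
  cur <- a            # 0-based backbone cursor
  eff <- logical(nv)
  i <- 1L
  if (skip > 0L) {
    ## read starts inside the first variant's alt allele (offset `skip`)
    stopifnot(nv >= 1L, pos[1L] - 1L == a, skip < la[1L])
    eff[1L] <- TRUE
    take <- min(la[1L] - skip, L)
    out <- substr(alt[1L], skip + 1L, skip + take)
    plen <- take
    cur <- a + lr[1L]
    i <- 2L
  }
  while (plen < L) {
    vs <- if (i <= nv) pos[i] - 1L else clen
    if (cur < vs) {
      take <- min(vs - cur, L - plen)
      out <- c(out, substr(seq, cur + 1L, cur + take))
      plen <- plen + take; cur <- cur + take
      if (plen >= L) break
    } else if (i <= nv) {
      ## apply variant i starting at path position plen; its first path
      ## character that can differ from the reference sits after the
      ## common prefix of the two alleles (the anchor base for a
      ## left-normalized indel)
      cp <- 0L
      m <- min(lr[i], la[i])
      while (cp < m &&
             substr(ref[i], cp + 1L, cp + 1L) ==
             substr(alt[i], cp + 1L, cp + 1L)) cp <- cp + 1L
      if (plen + cp < L) eff[i] <- TRUE
      take <- min(la[i], L - plen)
      out <- c(out, substr(alt[i], 1L, take))
      plen <- plen + take
      cur <- cur + lr[i]
      i <- i + 1L
    } else {
      return(NULL)    # backbone exhausted before L path bases
    }
    if (plen < L && cur >= clen && i > nv) return(NULL)
  }
  list(sequence = paste0(out, collapse = ""), effective = eff)
}

#' Simulate reads traversing every local path of the graph
#'
#' For every backbone anchor (every `stride`-th position of every
#' non-decoy contig) and every compatible subset of nearby variants,
#' emits the exact L-mer a read starting at that anchor on that path
#' would have. Origins are canonicalized to the variants that actually
#' alter the read, and deduplicated. At `stride = 1` every variant edge
#' is covered at every offset (subject to the per-anchor path cap, which
#' always retains the reference path and all single-variant paths).
#'
#' @param graph A `genome_graph`.
#' @param L Read length (>= 20).
#' @param stride Anchor spacing in bp (>= 1).
#' @param max_paths_per_anchor Path cap per anchor (default 64).
#' @param include_decoys Simulate from decoy contigs too (default FALSE).
#' @return Data frame with columns `sequence`, `contig`, `anchor`
#'   (0-based backbone position of the read start), `offset` (0 for
#'   backbone-anchored reads; k > 0 for a read starting k characters
#'   into the alt allele of the variant at the anchor) and `subset`
#'   (comma-joined keys of the variants the read observes; `""` for
#'   backbone-only reads).
#' @export
simulate_reads <- function(graph, L = 150L, stride = 1L,
                           max_paths_per_anchor = 64L,
                           include_decoys = FALSE) {
  stopifnot(L >= 20, stride >= 1)
  contigs <- names(graph$backbone)
  if (!include_decoys) contigs <- setdiff(contigs, graph$decoys)
  acc_seq <- character(0); acc_ct <- character(0)
  acc_a <- integer(0); acc_sub <- character(0); acc_of <- integer(0)
  for (ct in contigs) {
    seq <- graph$backbone[[ct]]
    clen <- nchar(seq)
    if (clen < L) next
    vt <- graph$variants[graph$variants$contig == ct, , drop = FALSE]
    vt <- vt[order(vt$pos, vt$ref, vt$alt), , drop = FALSE]
    vpos <- vt$pos; vref <- vt$ref; valt <- vt$alt
    vlr <- nchar(vref); vla <- nchar(valt)
    vstart <- vpos - 1L; vend <- vstart + vlr
    keys <- variant_key(vt)
    vaf <- vt$af
    anchors <- seq.int(0L, clen - 1L, by = stride)
    deln <- pmax(0L, vlr - vla)
    ## anchors with no variant starting within reach of a read
    touched <- rep(FALSE, length(anchors))
    if (length(vpos) > 0) {
      maxreach <- L + sum(deln)
      for (v in seq_along(vpos))
        touched <- touched |
          (anchors > vstart[v] - maxreach & anchors <= vstart[v])
    }
    plain <- anchors[!touched]
    plain <- plain[plain + L <= clen]
    if (length(plain) > 0) {
      acc_seq <- c(acc_seq, substring(seq, plain + 1L, plain + L))
      acc_ct <- c(acc_ct, rep(ct, length(plain)))
      acc_a <- c(acc_a, plain)
      acc_sub <- c(acc_sub, rep("", length(plain)))
      acc_of <- c(acc_of, rep(0L, length(plain)))
    }
    ## per-anchor enumeration near variants, collected in blocks
    bs <- bc <- ba <- bsub <- bof <- vector("list", sum(touched))
    bi <- 0L
    for (a in anchors[touched]) {
      ## iterate reach to capture deletions pulling later variants into range
      reach <- a + L
      repeat {
        cand <- which(vstart >= a & vstart < reach)
        r2 <- a + L + sum(deln[cand])
        if (r2 == reach) break
        reach <- r2
      }
      if (length(cand) == 0) {
        if (a + L <= clen) {
          bi <- bi + 1L
          bs[[bi]] <- substr(seq, a + 1L, a + L)
          bc[[bi]] <- ct; ba[[bi]] <- a; bsub[[bi]] <- ""; bof[[bi]] <- 0L
        }
        next
      }
      subs <- compatible_subsets(vstart[cand], vend[cand],
                                 max_n = max_paths_per_anchor,
                                 af = vaf[cand])
      seen <- character(0)
      sqs <- character(0); sbs <- character(0); sof <- integer(0)
      for (s in subs) {
        ci <- cand[s]
        ## reads anchored at the backbone position itself, plus — when the
        ## path enters a variant allele exactly at this anchor — reads
        ## starting at every internal offset of that allele
        skips <- 0L
        if (length(ci) > 0 && vstart[ci[1L]] == a && vla[ci[1L]] > 1L)
          skips <- c(0L, seq_len(vla[ci[1L]] - 1L))
        for (sk in skips) {
          sp <- spell_from(seq, clen, a, vpos[ci], vref[ci], valt[ci],
                           vlr[ci], vla[ci], L, skip = sk)
          if (is.null(sp)) next
          kk <- paste(sort(keys[ci][sp$effective]), collapse = ",")
          dk <- paste(sk, kk)
          if (dk %in% seen) next
          seen <- c(seen, dk)
          sqs <- c(sqs, sp$sequence); sbs <- c(sbs, kk)
          sof <- c(sof, sk)
        }
      }
      if (length(sqs)) {
        bi <- bi + 1L
        bs[[bi]] <- sqs; bc[[bi]] <- rep(ct, length(sqs))
        ba[[bi]] <- rep(a, length(sqs)); bsub[[bi]] <- sbs
        bof[[bi]] <- sof
      }
    }
    if (bi > 0) {
      acc_seq <- c(acc_seq, unlist(bs[seq_len(bi)]))
      acc_ct <- c(acc_ct, unlist(bc[seq_len(bi)]))
      acc_a <- c(acc_a, unlist(ba[seq_len(bi)]))
      acc_sub <- c(acc_sub, unlist(bsub[seq_len(bi)]))
      acc_of <- c(acc_of, unlist(bof[seq_len(bi)]))
    }
  }
  data.frame(sequence = acc_seq, contig = acc_ct, anchor = acc_a,
             offset = acc_of, subset = acc_sub, stringsAsFactors = FALSE)
}

#' Index all spelled read placements of a graph
#'
#' Builds a hash from every distinct L-mer the graph can spell to its
#' placements, by exhausting the same enumeration as [simulate_reads()]
#' at stride 1 — placement lookup is therefore complete for exact
#' matches by construction.
#'
#' @inheritParams simulate_reads
#' @return Environment mapping sequence to a data frame of placements.
#' @export
build_placement_index <- function(graph, L = 150L,
                                  max_paths_per_anchor = 64L,
                                  include_decoys = TRUE) {
  reads <- simulate_reads(graph, L = L, stride = 1L,
                          max_paths_per_anchor = max_paths_per_anchor,
                          include_decoys = include_decoys)
  idx <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(reads) == 0) return(idx)
  groups <- split(seq_len(nrow(reads)), reads$sequence)
  for (sq in names(groups))
    assign(sq, reads[groups[[sq]], c("contig", "anchor", "offset", "subset"),
                     drop = FALSE],
           envir = idx)
  idx
}

#' Find all exact placements of a read in the graph
#'
#' @param read DNA string of length L.
#' @param index Placement index from [build_placement_index()].
#' @return Data frame of placements (`contig`, `anchor`, `offset`,
#'   `subset`); zero rows when the read does not occur.
#' @export
find_placements <- function(read, index) {
  if (exists(read, envir = index, inherits = FALSE))
    get(read, envir = index)
  else data.frame(contig = character(), anchor = integer(),
                  offset = integer(), subset = character(),
                  stringsAsFactors = FALSE)
}

#' Detect multi-mapping ambiguity introduced by graph variants
#'
#' Simulates all reads, groups identical sequences, and reports every
#' read that is spelled at two or more distinct genomic positions — a
#' position being (contig, backbone anchor, offset into a variant
#' allele). Alternate paths spelling the same read at a single position
#' are not multi-mapping: the read still has one unambiguous location.
#' A read is *pruneable* when removing variants can leave it at a single
#' position, i.e. at most one of its positions is reachable through the
#' plain backbone; pure backbone repeats are reported but cannot be
#' pruned, since the backbone is immutable.
#'
#' @inheritParams simulate_reads
#' @return List of class `multimap_report`: `ambiguous` (data frame with
#'   `sequence`, `n_placements`, `n_backbone`, `pruneable`,
#'   `implicated` comma-joined variant keys), `placements` (list of
#'   placement data frames, parallel to `ambiguous`), `n_reads`,
#'   `read_len`, `stride`.
#' @export
detect_ambiguity <- function(graph, L = 150L, stride = 1L,
                             max_paths_per_anchor = 64L) {
  reads <- simulate_reads(graph, L = L, stride = stride,
                          max_paths_per_anchor = max_paths_per_anchor,
                          include_decoys = TRUE)
  amb <- list(); plc <- list()
  if (nrow(reads) > 0) {
    groups <- split(seq_len(nrow(reads)), reads$sequence)
    groups <- groups[lengths(groups) >= 2L]   # unique spellings can't clash
    for (sq in names(groups)) {
      g <- reads[groups[[sq]], , drop = FALSE]
      key <- paste(g$contig, g$anchor, g$offset, g$subset, sep = "\r")
      g <- g[!duplicated(key), , drop = FALSE]
      poskey <- paste(g$contig, g$anchor, g$offset, sep = "\r")
      npos <- length(unique(poskey))
      if (npos < 2) next
      ## positions reachable through the plain backbone cannot be pruned
      nb <- length(unique(poskey[g$subset == ""]))
      prn <- nb <= 1
      impl <- sort(unique(unlist(strsplit(g$subset[g$subset != ""], ",",
                                          fixed = TRUE))))
      amb[[length(amb) + 1L]] <-
        data.frame(sequence = sq, n_placements = npos, n_backbone = nb,
                   pruneable = prn,
                   implicated = paste(impl, collapse = ","),
                   stringsAsFactors = FALSE)
      plc[[length(plc) + 1L]] <- g[, c("contig", "anchor", "offset",
                                       "subset")]
    }
  }
  ambiguous <- if (length(amb)) do.call(rbind, amb) else
    data.frame(sequence = character(), n_placements = integer(),
               n_backbone = integer(), pruneable = logical(),
               implicated = character(), stringsAsFactors = FALSE)
  structure(list(ambiguous = ambiguous, placements = plc,
                 n_reads = nrow(reads), read_len = L, stride = stride),
            class = "multimap_report")
}

#' @export
print.multimap_report <- function(x, ...) {
  cat(sprintf("<multimap_report: %d read(s) simulated, %d ambiguous (%d pruneable)>\n",
              x$n_reads, nrow(x$ambiguous), sum(x$ambiguous$pruneable)))
  invisible(x)
}

## exact minimum-weight hitting set by branch and bound over candidate
## elements; sets is a list of character vectors, w a named weight vector
hitting_set_exact <- function(sets, w) {
  best <- names(w)          # trivial solution: everything
  bestw <- sum(w)
  recurse <- function(sets, chosen, cw) {
    if (length(sets) == 0) {
      if (cw < bestw) { best <<- chosen; bestw <<- cw }
      return()
    }
    if (cw >= bestw) return()
    ## branch on the smallest unhit set
    sizes <- lengths(sets)
    s <- sets[[which.min(sizes)]]
    for (e in s) {
      rest <- sets[!vapply(sets, function(x) e %in% x, TRUE)]
      recurse(rest, c(chosen, e), cw + w[[e]])
    }
  }
  recurse(sets, character(0), 0)
  best
}

hitting_set_greedy <- function(sets, w, af, coord) {
  chosen <- character(0)
  while (length(sets) > 0) {
    cand <- unique(unlist(sets))
    hits <- vapply(cand, function(e)
      sum(vapply(sets, function(x) e %in% x, TRUE)), 0L)
    score <- hits / w[cand]
    o <- order(-score, af[cand], coord[cand])
    e <- cand[o[1]]
    chosen <- c(chosen, e)
    sets <- sets[!vapply(sets, function(x) e %in% x, TRUE)]
  }
  chosen
}

#' Smallest variant set resolving the pruneable ambiguity
#'
#' Hitting set over the per-read implicated variant sets of all
#' pruneable ambiguous reads: exact (branch and bound) when at most
#' `max_exact` candidate variants are implicated, greedy otherwise
#' (most-implicated first; ties by lowest AF, then coordinate). The
#' objective is set cardinality by default; `objective = "bp"` instead
#' minimizes the total base pairs removed, weighting each variant by its
#' longer allele.
#'
#' @param report A `multimap_report`.
#' @param graph The `genome_graph` the report came from (for AF and
#'   length tie-breaks/weights).
#' @param objective `"count"` or `"bp"`.
#' @param max_exact Candidate-count threshold for the exact solver.
#' @return Character vector of variant keys to remove (may be empty).
#' @export
minimal_pruning_set <- function(report, graph, objective = c("count", "bp"),
                                max_exact = 20L) {
  objective <- match.arg(objective)
  prn <- report$ambiguous[report$ambiguous$pruneable, , drop = FALSE]
  if (nrow(prn) == 0) return(character(0))
  sets <- unique(lapply(strsplit(prn$implicated, ",", fixed = TRUE), sort))
  cand <- unique(unlist(sets))
  keys <- variant_key(graph$variants)
  sel <- match(cand, keys)
  if (anyNA(sel)) stopf("report references variants absent from the graph")
  bp <- pmax(nchar(graph$variants$ref[sel]), nchar(graph$variants$alt[sel]))
  w <- if (objective == "bp") setNames(as.numeric(bp), cand)
  else setNames(rep(1, length(cand)), cand)
  af <- setNames(ifelse(is.na(graph$variants$af[sel]), 0,
                        graph$variants$af[sel]), cand)
  coord <- setNames(cand, cand)
  if (length(cand) <= max_exact) hitting_set_exact(sets, w)
  else hitting_set_greedy(sets, w, af, coord)
}

#' Remove a variant set from the graph
#'
#' @param graph A `genome_graph`.
#' @param keys Character vector of variant keys (as produced internally,
#'   `contig\rpos\rref\ralt`) or a `variant_table` subset.
#' @return The pruned `genome_graph`, with attribute `bp_removed` (sum
#'   of the longer allele length over removed records).
#' @export
prune <- function(graph, keys) {
  if (inherits(keys, "data.frame")) keys <- variant_key(keys)
  gk <- variant_key(graph$variants)
  if (!all(keys %in% gk)) stopf("cannot prune variant(s) not in the graph")
  sel <- gk %in% keys
  bp <- sum(pmax(nchar(graph$variants$ref[sel]),
                 nchar(graph$variants$alt[sel])))
  graph$variants <- graph$variants[!sel, , drop = FALSE]
  rownames(graph$variants) <- NULL
  attr(graph, "bp_removed") <- bp
  graph
}

#' Iterated multimap pruning to a fixpoint
#'
#' Runs [detect_ambiguity()], removes the [minimal_pruning_set()], and
#' repeats until no pruneable ambiguity remains (pruning only deletes
#' spellings, so the loop terminates).
#'
#' @inheritParams simulate_reads
#' @param objective Passed to [minimal_pruning_set()].
#' @param max_iter Safety bound on iterations.
#' @return List with `graph` (pruned), `removed` (variant keys),
#'   `bp_removed`, `iterations` and `report` (final `multimap_report`).
#' @export
multimap_prune <- function(graph, L = 150L, stride = 1L,
                           objective = "count", max_iter = 20L,
                           max_paths_per_anchor = 64L) {
  removed <- character(0); bp <- 0L
  for (it in seq_len(max_iter)) {
    rep <- detect_ambiguity(graph, L = L, stride = stride,
                            max_paths_per_anchor = max_paths_per_anchor)
    if (!any(rep$ambiguous$pruneable))
      return(list(graph = graph, removed = removed, bp_removed = bp,
                  iterations = it - 1L, report = rep))
    ks <- minimal_pruning_set(rep, graph, objective = objective)
    graph <- prune(graph, ks)
    bp <- bp + attr(graph, "bp_removed")
    removed <- c(removed, ks)
  }
  warning("multimap pruning did not reach a fixpoint within max_iter")
  list(graph = graph, removed = removed, bp_removed = bp,
       iterations = max_iter,
       report = detect_ambiguity(graph, L = L, stride = stride,
                                 max_paths_per_anchor = max_paths_per_anchor))
}
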