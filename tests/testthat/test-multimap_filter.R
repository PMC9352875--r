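test_that("read simulation covers a variant-free contig exhaustively", {
  set.seed(101)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  g <- build_graph(c(chr1 = seq))
  reads <- simulate_reads(g, L = 150, stride = 1)
  expect_identical(nrow(reads), 851L)   # contig_len - L + 1
  expect_false(any(duplicated(paste(reads$contig, reads$anchor))))
  expect_true(all(nchar(reads$sequence) == 150L))
  expect_true(all(reads$subset == ""))
})

test_that("a single SNP doubles the reads of windows that observe it", {
  set.seed(102)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  rb <- substr(seq, 200, 200)
  g <- build_graph(c(chr1 = seq),
                   variant_table("chr1", 200, rb,
                                 setdiff(c("A", "C", "G", "T"), rb)[1]))
  L <- 50L
  reads <- simulate_reads(g, L = L, stride = 1)
  per_anchor <- table(reads$anchor)
  covering <- as.integer(names(per_anchor)) <= 199 &
    as.integer(names(per_anchor)) >= 199 - (L - 1)
  expect_true(all(per_anchor[covering] == 2L))
  expect_true(all(per_anchor[!covering] == 1L))
})

test_that("placement search is complete against brute-force spelling enumeration", {
  for (seed in c(201, 202, 203)) {
    set.seed(seed)
    seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    k <- 3L
    pos <- sort(sample(seq(30, 270, by = 12), k))
    ref <- vapply(pos, function(p) substr(seq, p, p + sample(0:2, 1)), "")
    alt <- vapply(seq_along(pos), function(i) {
      if (nchar(ref[i]) == 1 && runif(1) < 0.5)
        paste0(ref[i], paste(sample(c("A", "C", "G", "T"), 2, TRUE),
                             collapse = ""))
      else chartr("ACGT", "TGCA", substr(ref[i], 1, 1))
    }, "")
    g <- build_graph(c(chr1 = seq), variant_table("chr1", pos, ref, alt))
    L <- 40L
    idx <- build_placement_index(g, L = L)
    brute <- placements_brute(g, L)
    ## every brute-force spelling is found at exactly the same positions
    poskey <- function(d) sort(unique(paste(d$contig, d$anchor, d$offset)))
    for (sq in unique(brute$sequence)) {
      want <- brute[brute$sequence == sq, , drop = FALSE]
      got <- find_placements(sq, idx)
      expect_identical(poskey(got), poskey(want))
    }
    ## and the index holds nothing the brute force does not
    sim <- simulate_reads(g, L = L, stride = 1)
    expect_identical(sort(unique(paste(sim$sequence, sim$contig,
                                       sim$anchor, sim$offset))),
                     sort(unique(paste(brute$sequence, brute$contig,
                                       brute$anchor, brute$offset))))
    ## a read absent from the graph has no placement
    expect_identical(nrow(find_placements(strrep("A", L), idx)), 0L)
  }
})

test_that("ambiguity detection separates pruneable from backbone repeats", {
  ## variant-free unique contig: nothing to report
  set.seed(105)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  g0 <- build_graph(c(chr1 = seq))
  rep0 <- detect_ambiguity(g0, L = 60, stride = 1)
  expect_identical(nrow(rep0$ambiguous), 0L)
  ## a perfect backbone duplication is ambiguous but not pruneable
  dup <- paste0(seq, substr(seq, 101, 200), "ACGT")
  g1 <- build_graph(c(chr1 = dup))
  rep1 <- detect_ambiguity(g1, L = 60, stride = 1)
  expect_gt(nrow(rep1$ambiguous), 0L)
  expect_false(any(rep1$ambiguous$pruneable))
  ## SNPs recreating a near-duplicate: implicated and pruneable
  g2 <- multimap_instance(seed = 106, L = 60)
  rep2 <- detect_ambiguity(g2, L = 60, stride = 1)
  expect_gt(sum(rep2$ambiguous$pruneable), 0L)
  impl <- unique(unlist(strsplit(rep2$ambiguous$implicated[
    rep2$ambiguous$pruneable], ",")))
  expect_setequal(impl, attr(g2, "bridging_keys"))
})

test_that("identical SV insertions implicate both edges", {
  set.seed(107)
  seq <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  ins <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  a1 <- substr(seq, 150, 150); a2 <- substr(seq, 600, 600)
  g <- build_graph(c(chr1 = seq),
                   variant_table("chr1", c(150, 600), c(a1, a2),
                                 c(paste0(a1, ins), paste0(a2, ins)),
                                 af = c(0.3, 0.2)))
  rep <- detect_ambiguity(g, L = 60, stride = 1)
  expect_gt(sum(rep$ambiguous$pruneable), 0)
  impl <- unique(unlist(strsplit(rep$ambiguous$implicated[
    rep$ambiguous$pruneable], ",")))
  expect_setequal(impl, graphref:::variant_key(g$variants))
})

test_that("minimal pruning sets equal the brute-force minimum hitting set", {
  for (seed in 301:312) {
    g <- multimap_instance(seed = seed, L = 60,
                           n_mm = sample(2:3, 1), n_extra = sample(0:3, 1))
    rep <- detect_ambiguity(g, L = 60, stride = 1)
    ks <- minimal_pruning_set(rep, g)
    prn <- rep$ambiguous[rep$ambiguous$pruneable, , drop = FALSE]
    sets <- unique(lapply(strsplit(prn$implicated, ","), sort))
    expect_identical(length(ks), length(hitting_set_brute(sets)))
    ## the returned set actually hits every pruneable read
    expect_true(all(vapply(sets, function(s) any(s %in% ks), TRUE)))
  }
})

test_that("hand-built hitting-set instances recover known minima", {
  ## one read implicating one SNP -> that SNP
  set.seed(108)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  rb <- substr(seq, 100, 100)
  g <- build_graph(c(chr1 = seq), variant_table(
    "chr1", 100, rb, setdiff(c("A", "C", "G", "T"), rb)[1], af = 0.2))
  fake_rep <- list(ambiguous = data.frame(
    sequence = "x", n_placements = 2L, n_backbone = 1L, pruneable = TRUE,
    implicated = graphref:::variant_key(g$variants),
    stringsAsFactors = FALSE))
  expect_identical(minimal_pruning_set(fake_rep, g),
                   graphref:::variant_key(g$variants))
  ## two reads sharing variant v plus one private variant each -> {v}
  pos <- c(100, 200, 300)
  rb <- substring(seq, pos, pos)
  g3 <- build_graph(c(chr1 = seq), variant_table(
    "chr1", pos, rb, vapply(rb, function(r)
      setdiff(c("A", "C", "G", "T"), r)[1], ""), af = 0.2))
  keys <- graphref:::variant_key(g3$variants)
  fake3 <- list(ambiguous = data.frame(
    sequence = c("r1", "r2"), n_placements = 2L, n_backbone = 1L,
    pruneable = TRUE,
    implicated = c(paste(sort(keys[c(1, 2)]), collapse = ","),
                   paste(sort(keys[c(2, 3)]), collapse = ",")),
    stringsAsFactors = FALSE))
  expect_identical(minimal_pruning_set(fake3, g3), keys[2])
})

test_that("pruning reaches a fixpoint without touching the backbone", {
  g <- multimap_instance(seed = 401, L = 60)
  before <- g$backbone
  mm <- multimap_prune(g, L = 60, stride = 1)
  expect_identical(mm$graph$backbone, before)
  expect_identical(sum(mm$report$ambiguous$pruneable), 0L)
  expect_identical(n_edges(mm$graph) + length(mm$removed), n_edges(g))
  expect_identical(mm$bp_removed,
                   sum(pmax(nchar(g$variants$ref),
                            nchar(g$variants$alt))[
                     graphref:::variant_key(g$variants) %in% mm$removed]))
  ## pruning never introduces new ambiguity: re-detect on the pruned
  ## graph finds nothing pruneable at the same parameters
  rep2 <- detect_ambiguity(mm$graph, L = 60, stride = 1)
  expect_identical(sum(rep2$ambiguous$pruneable), 0L)
  ## prune() edge cases
  expect_identical(n_edges(prune(g, character(0))), n_edges(g))
  expect_identical(n_edges(prune(g, g$variants)), 0L)
  expect_error(prune(g, "chrX\r1\rA\rG"), "not in the graph")
})
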