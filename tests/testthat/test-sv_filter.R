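test_that("longest common exact substring agrees with the DP oracle", {
  expect_identical(longest_common_exact_substring("ACGT", "ACGT")$length, 4L)
  expect_identical(longest_common_exact_substring("AAAA", "CCCC")$length, 0L)
  ## planted shared 200-mer in random 1 kb strings
  set.seed(81)
  a <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  b <- paste0(substr(b, 1, 300), substr(a, 401, 600), substr(b, 501, 1000))
  r <- longest_common_exact_substring(a, b)
  expect_identical(r$length, lcs_dp(a, b))
  expect_identical(r$length, 200L)
  expect_identical(substr(a, r$a_start, r$a_start + r$length - 1L),
                   substr(b, r$b_start, r$b_start + r$length - 1L))
  ## random planted lengths >= seed size match DP exactly
  for (i in 1:10) {
    la <- sample(120:300, 1); lb <- sample(200:400, 1)
    m <- sample(35:100, 1)
    a <- paste(sample(c("A", "C", "G", "T"), la, TRUE), collapse = "")
    b0 <- paste(sample(c("A", "C", "G", "T"), lb, TRUE), collapse = "")
    p <- sample(1:(la - m), 1); q <- sample(1:(lb - m), 1)
    b <- paste0(substr(b0, 1, q - 1), substr(a, p, p + m - 1),
                substr(b0, q + m, lb))
    expect_identical(longest_common_exact_substring(a, b)$length,
                     lcs_dp(a, b))
  }
})

test_that("insertions duplicating reference sequence are filtered", {
  ref <- make_reference(lengths = 6000, n_decoys = 1, seed = 90)
  cfg <- sv_filter_config(read_len = 150)
  seq <- ref$backbone[[1]]
  anchor <- substr(seq, 1000, 1000)
  set.seed(91)
  rnd200 <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  svs <- variant_table("chr1", c(1000, 2000, 3000),
                       c(anchor, substr(seq, 2000, 2000),
                         substr(seq, 3000, 3000)),
                       c(paste0(anchor, rnd200),
                         paste0(substr(seq, 2000, 2000),
                                paste0(substr(seq, 4000, 4149), "ACGTAC",
                                       strrep("A", 60))),
                         paste0(substr(seq, 3000, 3000), strrep("ACG", 20))),
                       af = 0.2)
  res <- filter_sv_vs_reference(svs, ref$backbone, ref$decoys, cfg)
  ## random 200 bp insertion kept (verify with the DP oracle)
  expect_lt(lcs_dp(rnd200, seq), 150L)
  expect_true(1000 %in% res$kept$pos)
  ## insertion embedding a verbatim 150 bp backbone window removed
  expect_true(2000 %in% res$removed$pos)
  ## 60 bp insertion cannot contain a 150-mer: kept regardless
  expect_true(3000 %in% res$kept$pos)
})

test_that("SV-vs-SV filtering removes the shorter of similar pairs deterministically", {
  ref <- make_reference(lengths = 5000, seed = 92)
  cfg <- sv_filter_config(read_len = 150)
  seq <- ref$backbone[[1]]
  set.seed(93)
  shared <- paste(sample(c("A", "C", "G", "T"), 160, TRUE), collapse = "")
  tail40 <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  a300 <- paste0(shared, paste(sample(c("A", "C", "G", "T"), 140, TRUE),
                               collapse = ""))
  b200 <- paste0(tail40, shared)
  ident <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  anch <- function(p) substr(seq, p, p)
  svs <- variant_table("chr1", c(500, 1500, 2500, 3500),
                       c(anch(500), anch(1500), anch(2500), anch(3500)),
                       c(paste0(anch(500), a300), paste0(anch(1500), b200),
                         paste0(anch(2500), ident), paste0(anch(3500), ident)),
                       af = 0.2)
  res <- filter_sv_vs_sv(svs, cfg)
  ## 300 vs 200 bp sharing a 160-mer: the 200 bp record goes
  expect_true(1500 %in% res$removed$pos)
  expect_true(500 %in% res$kept$pos)
  ## identical insertions at two loci: the smaller coordinate is kept
  expect_true(2500 %in% res$kept$pos)
  expect_true(3500 %in% res$removed$pos)
  ## input order does not matter
  res2 <- filter_sv_vs_sv(svs[c(3, 1, 4, 2), ], cfg)
  expect_identical(sort(res2$removed$pos), sort(res$removed$pos))
  ## pairs sharing < L survive
  res3 <- filter_sv_vs_sv(svs[1:2, ][integer(0), ], cfg)
  expect_identical(nrow(res3$removed), 0L)
})

test_that("decoy masking replaces matched windows with N and nothing else", {
  ref <- make_reference(lengths = 4000, n_decoys = 1, seed = 94)
  cfg <- sv_filter_config(read_len = 150)
  dc <- ref$decoys[1]
  dseq <- ref$backbone[[dc]]
  anchor <- substr(ref$backbone[[1]], 700, 700)
  ## two SVs hitting overlapping decoy windows: union interval masked
  sv1 <- paste0(anchor, substr(dseq, 301, 480))
  sv2 <- paste0(substr(ref$backbone[[1]], 900, 900), substr(dseq, 401, 580))
  svs <- variant_table("chr1", c(700, 900),
                       c(anchor, substr(ref$backbone[[1]], 900, 900)),
                       c(sv1, sv2), af = 0.3)
  res <- mask_decoys(svs, ref$backbone, ref$decoys, cfg)
  expect_identical(nrow(res$mask_log), 1L)
  expect_identical(res$mask_log$start, 301L)
  expect_identical(res$mask_log$end, 580L)
  masked <- res$backbone[[dc]]
  expect_identical(substr(masked, 301, 580), strrep("N", 280))
  ## everything outside the union, and all other contigs, untouched
  expect_identical(substr(masked, 1, 300), substr(dseq, 1, 300))
  expect_identical(substr(masked, 581, nchar(dseq)),
                   substr(dseq, 581, nchar(dseq)))
  expect_identical(res$backbone[["chr1"]], ref$backbone[["chr1"]])
  ## no matches: backbone unchanged
  clean <- variant_table("chr1", 700, anchor,
                         paste0(anchor, strrep("ACGTT", 40)), af = 0.3)
  res0 <- mask_decoys(clean, ref$backbone, ref$decoys, cfg)
  expect_identical(res0$backbone, ref$backbone)
})

test_that("the SV length cap removes only over-length records", {
  cfg <- sv_filter_config(read_len = 150, max_sv_len = 10000)
  mk <- function(n) variant_table("chr1", 1, "A",
                                  paste0("A", strrep("C", n)), af = 0.1)
  expect_identical(nrow(cap_sv_length(mk(9999), cfg)$removed), 0L)
  expect_identical(nrow(cap_sv_length(mk(10001), cfg)$removed), 1L)
  huge <- sv_filter_config(read_len = 150, max_sv_len = .Machine$integer.max)
  expect_identical(nrow(cap_sv_length(mk(10001), huge)$removed), 0L)
})

test_that("the full chain leaves no kept sequence sharing >= L with reference or peers", {
  ref <- make_reference(lengths = 6000, n_decoys = 1, seed = 95)
  svs <- make_sv_set(ref$backbone, ref$decoys, n_clean = 2, n_ref_copy = 1,
                     n_pairs = 1, n_decoy_copy = 1, seed = 96)
  cfg <- sv_filter_config(read_len = 150)
  res <- sv_filter(svs$variants, ref$backbone, ref$decoys, cfg)
  ## conservation: every record is kept or removed exactly once
  expect_identical(nrow(res$kept) + nrow(res$removed), nrow(svs$variants))
  ## audit with the quadratic DP oracle
  ins <- res$kept[graphref:::is_insertion_sv(res$kept), , drop = FALSE]
  for (i in seq_len(nrow(ins))) {
    for (ct in setdiff(names(ref$backbone), ref$decoys))
      expect_lt(lcs_dp(ins$alt[i], ref$backbone[[ct]]), 150L)
    if (i > 1) for (j in seq_len(i - 1))
      expect_lt(lcs_dp(ins$alt[i], ins$alt[j]), 150L)
  }
})
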