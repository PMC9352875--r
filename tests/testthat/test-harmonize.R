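test_that("multiallelic records split into aligned biallelic records", {
  rec <- data.frame(contig = "chr1", pos = 5L, ref = "A", alt = "G,T",
                    filter = "PASS", an = 200L, source = "db",
                    stringsAsFactors = FALSE)
  rec$af <- list(c(0.1, 0.2)); rec$ac <- list(c(20L, 40L))
  sp <- split_multiallelic(rec)
  expect_identical(nrow(sp$kept), 2L)
  expect_identical(sp$kept$alt, c("G", "T"))
  expect_equal(sp$kept$af, c(0.1, 0.2))
  expect_identical(sp$kept$ac, c(20L, 40L))
  ## biallelic record is unchanged
  rec2 <- data.frame(contig = "chr1", pos = 5L, ref = "A", alt = "G",
                     filter = "PASS", an = 10L, source = "db",
                     stringsAsFactors = FALSE)
  rec2$af <- list(0.3); rec2$ac <- list(3L)
  sp2 <- split_multiallelic(rec2)
  expect_identical(nrow(sp2$kept), 1L)
  expect_equal(sp2$kept$af, 0.3)
  ## mis-aligned per-allele annotations are rejected to the log
  rec3 <- rec; rec3$af <- list(c(0.1))
  sp3 <- split_multiallelic(rec3)
  expect_identical(nrow(sp3$kept), 0L)
  expect_identical(sp3$removed$reason, "malformed record")
})

test_that("left normalization is canonical, haplotype-preserving, idempotent", {
  bb <- c(chr1 = "GCACACAT")
  ## two representations of deleting one CA unit from the repeat
  v1 <- variant_table("chr1", 3, "ACA", "A")
  v2 <- variant_table("chr1", 5, "ACA", "A")
  n1 <- left_normalize(v1, bb); n2 <- left_normalize(v2, bb)
  expect_identical(graphref:::variant_key(graphref:::vt_core(n1)),
                   graphref:::variant_key(graphref:::vt_core(n2)))
  ## both spell the same haplotype as the original representation
  r <- region("chr1", 0, 8)
  expect_identical(spell_haplotype(bb, r, n1), spell_haplotype(bb, r, v1))
  expect_identical(spell_haplotype(bb, r, n2), spell_haplotype(bb, r, v2))
  ## SNPs are untouched; normalization is idempotent
  snp <- variant_table("chr1", 4, "C", "T")
  expect_identical(left_normalize(snp, bb)$pos, 4L)
  nn <- left_normalize(n1, bb)
  expect_identical(graphref:::vt_core(nn), graphref:::vt_core(n1))
  ## walking off the contig start keeps pos 1 and flags
  bb2 <- c(chr1 = "AAAT")
  v3 <- variant_table("chr1", 1, "AA", "A")
  n3 <- left_normalize(v3, bb2)
  expect_identical(n3$pos, 1L)
  expect_true(n3$norm_flagged)
})

test_that("random indel representations normalize to a spelled-equivalent canonical form", {
  set.seed(20)
  seq <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  bb <- c(chr1 = seq)
  for (i in 1:60) {
    p <- sample(60:500, 1)
    len <- sample(1:6, 1)
    if (runif(1) < 0.5) {  # deletion, represented with a redundant suffix
      ref <- substr(seq, p, p + len)
      alt <- substr(seq, p, p)
      sfx <- substr(seq, p + len + 1, p + len + 3)
      v_pad <- variant_table("chr1", p, paste0(ref, sfx), paste0(alt, sfx))
    } else {               # insertion with a redundant shared suffix
      ins <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
      ref <- substr(seq, p, p)
      sfx <- substr(seq, p + 1, p + 2)
      v_pad <- variant_table("chr1", p, paste0(ref, sfx),
                             paste0(ref, ins, sfx))
    }
    nv <- left_normalize(v_pad, bb)
    w <- region("chr1", max(0, p - 55), min(600, p + 55))
    expect_identical(spell_haplotype(bb, w, nv), spell_haplotype(bb, w, v_pad))
    nn <- left_normalize(nv, bb)
    expect_identical(graphref:::vt_core(nn), graphref:::vt_core(nv))
  }
})

test_that("merge_sources pools AC/AN, falls back to weighted AF, is order-independent", {
  mk <- function(af = NA, ac = NA, an = NA, src = "a")
    variant_table("chr1", 10, "A", "G", af = af, ac = ac, an = an,
                  source = src)
  ## single source: identity
  m1 <- merge_sources(list(list(variants = mk(af = 0.1), n_samples = 5)))
  expect_identical(nrow(m1), 1L)
  expect_equal(m1$af, 0.1)
  ## AC/AN pooling: 3/100 + 7/100 = 0.05
  m2 <- merge_sources(list(
    list(variants = mk(af = 0.03, ac = 3, an = 100, src = "a"), n_samples = 50),
    list(variants = mk(af = 0.07, ac = 7, an = 100, src = "b"), n_samples = 50)))
  expect_equal(m2$af, 0.05)
  expect_identical(m2$ac, 10L)
  expect_identical(m2$an, 200L)
  expect_identical(m2$source, "a,b")
  ## AF-only weighted mean: 0.10 (n=100), 0.40 (n=300) -> 0.325
  s3 <- list(list(variants = mk(af = 0.10, src = "a"), n_samples = 100),
             list(variants = mk(af = 0.40, src = "b"), n_samples = 300))
  m3 <- merge_sources(s3)
  expect_equal(m3$af, 0.325)
  ## permuting sources yields identical output
  m3r <- merge_sources(rev(s3))
  expect_identical(m3, m3r)
})

test_that("the AF filter keeps the boundary and logs missing frequencies", {
  vt <- variant_table("chr1", c(10, 20, 30), c("A", "C", "G"),
                      c("G", "T", "A"), af = c(0.05, 0.049, NA))
  res <- af_filter(vt, f_c = 0.05)
  expect_identical(res$kept$pos, 10L)
  expect_setequal(res$removed$reason, c("AF below cut-off", "missing AF"))
  empty <- af_filter(variant_table(), 0.05)
  expect_identical(nrow(empty$kept), 0L)
})

test_that("qc_filter defaults to PASS-or-missing and accepts predicates", {
  rec <- data.frame(contig = "chr1", pos = c(1L, 2L, 3L, 4L),
                    ref = "A", alt = "G",
                    filter = c("PASS", ".", "LowQual", NA),
                    stringsAsFactors = FALSE)
  res <- qc_filter(rec)
  expect_identical(res$kept$pos, c(1L, 2L, 4L))
  res2 <- qc_filter(rec, predicate = function(df) df$pos > 2)
  expect_identical(res2$kept$pos, c(3L, 4L))
})

test_that("alt contigs decompose into variants that reconstruct them exactly", {
  ref <- make_reference(n_contigs = 1, lengths = 4000, seed = 33)
  bbfull <- ref$backbone
  ## identical alt contig: zero variants
  same <- list(name = "altA", sequence = substr(bbfull[[1]], 501, 1500),
               sam_line = paste("altA", 0, "chr1", 501, 60, "1000=", "*",
                                0, 0, substr(bbfull[[1]], 501, 1500), "*",
                                sep = "\t"),
               sq_line = sprintf("@SQ\tSN:chr1\tLN:%d", nchar(bbfull[[1]])))
  ## one substitution
  subseq <- substr(bbfull[[1]], 2001, 2600)
  sb <- strsplit(subseq, "")[[1]]
  sb[300] <- setdiff(c("A", "C", "G", "T"), sb[300])[1]
  snpseq <- paste(sb, collapse = "")
  snp <- list(name = "altB", sequence = snpseq,
              sam_line = paste("altB", 0, "chr1", 2001, 60,
                               "299=1X300=", "*", 0, 0, snpseq, "*",
                               sep = "\t"),
              sq_line = same$sq_line)
  ## 60 bp novel insertion -> one SV-class record
  set.seed(44)
  ins60 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  insseq <- paste0(substr(bbfull[[1]], 3001, 3200), ins60,
                   substr(bbfull[[1]], 3201, 3400))
  insal <- list(name = "altC", sequence = insseq,
                sam_line = paste("altC", 0, "chr1", 3001, 60,
                                 "200=60I200=", "*", 0, 0, insseq, "*",
                                 sep = "\t"),
                sq_line = same$sq_line)
  sam <- tempfile(fileext = ".sam")
  write_alt_sam(list(same, snp, insal), sam)
  asm <- list(backbone = c(bbfull,
                           altA = same$sequence, altB = snp$sequence,
                           altC = insal$sequence),
              decoys = character(),
              alt_contigs = c("altA", "altB", "altC"))
  dec <- decompose_alt_contigs(asm, sam)
  expect_identical(names(dec$primary), "chr1")
  byq <- split(dec$variants, sub("^altcontig:", "", dec$variants$source))
  expect_false("altA" %in% names(byq))
  expect_identical(nrow(byq$altB), 1L)
  expect_identical(byq$altB$var_class, "SNP")
  expect_identical(byq$altB$alt, sb[300])
  expect_identical(nrow(byq$altC), 1L)
  expect_identical(byq$altC$var_class, "SV")
  ## round trips
  expect_identical(spell_haplotype(dec$primary, dec$spans$altB,
                                   byq$altB), snpseq)
  expect_identical(spell_haplotype(dec$primary, dec$spans$altC,
                                   byq$altC), insseq)
})

test_that("randomized alt contigs round-trip through decomposition", {
  ref <- make_reference(n_contigs = 1, lengths = 6000, seed = 55)
  for (i in 1:5) {
    alt <- make_alt_contig(ref$backbone, "chr1", 500 + 400 * i,
                           2300 + 400 * i, n_snp = 3, n_ins = 2, n_del = 2,
                           name = paste0("alt", i), seed = 60 + i)
    sam <- tempfile(fileext = ".sam")
    write_alt_sam(list(alt), sam)
    asm <- list(backbone = c(ref$backbone,
                             setNames(alt$sequence, alt$name)),
                decoys = character(), alt_contigs = alt$name)
    dec <- decompose_alt_contigs(asm, sam)
    expect_identical(spell_haplotype(dec$primary, dec$spans[[alt$name]],
                                     dec$variants),
                     alt$sequence)
  }
})

test_that("unaligned alt contigs are reported and dropped", {
  ref <- make_reference(n_contigs = 1, lengths = 3000, seed = 70)
  alt <- make_alt_contig(ref$backbone, "chr1", 200, 1200, seed = 71)
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", alt$sq_line,
               alt$sam_line,
               paste("altZ", 4, "*", 0, 0, "*", "*", 0, 0,
                     "ACGTACGTACGT", "*", sep = "\t")), sam)
  asm <- list(backbone = c(ref$backbone, alt1 = alt$sequence,
                           altZ = "ACGTACGTACGT"),
              decoys = character(), alt_contigs = c("alt1", "altZ"))
  dec <- decompose_alt_contigs(asm, sam)
  expect_identical(dec$dropped, "altZ")
  expect_identical(sort(names(dec$primary)), "chr1")
})
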