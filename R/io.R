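## File-format boundaries: FASTA backbones, VCF 4.2 variant sets and
## multi-sample genotypes, BED regions. All coordinates are converted to
## the internal conventions (0-based regions, 1-based variant pos) here
## and nowhere else.

#' Read a backbone FASTA, classifying decoy and alt contigs
#'
#' Contig roles are taken from the FASTA description line: a token
#' `decoy` flags a decoy contig, tokens `ALT` or `NOVEL` flag an
#' alternate-haplotype contig. The first whitespace-delimited word is the
#' contig name.
#'
#' @param path FASTA file.
#' @return List with `backbone` (named uppercase character vector),
#'   `decoys` and `alt_contigs` (character vectors of contig names).
#' @export
read_backbone_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  full <- names(ss)
  nm <- sub("\\s.*$", "", full)
  desc <- sub("^\\S+\\s*", "", full)
  backbone <- setNames(toupper(as.character(ss)), nm)
  list(backbone = backbone,
       decoys = nm[grepl("\\bdecoy\\b", desc, ignore.case = TRUE)],
       alt_contigs = nm[grepl("\\b(ALT|NOVEL)\\b", desc)])
}

#' Write a backbone FASTA
#'
#' @param backbone Named character vector of contig sequences.
#' @param path Output file.
#' @param decoys,alt_contigs Contig names to tag in the description.
#' @return `path`, invisibly.
#' @export
write_backbone_fasta <- function(backbone, path, decoys = character(),
                                 alt_contigs = character()) {
  tags <- ifelse(names(backbone) %in% decoys, " decoy",
                 ifelse(names(backbone) %in% alt_contigs, " ALT", ""))
  ss <- Biostrings::DNAStringSet(backbone)
  names(ss) <- paste0(names(backbone), tags)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read regions from a BED file
#' @param path BED file (0-based half-open, as BED is defined).
#' @return List of `region` objects.
#' @export
read_bed_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lapply(seq_along(gr), function(i)
    region(as.character(GenomicRanges::seqnames(gr)[i]),
           GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i]))
}

fmt_af <- function(af) ifelse(is.na(af), NA, signif(af, 6))

#' Write a variant table as a sorted VCF 4.2 site file
#'
#' Emits contig header lines for the backbone, one biallelic record per
#' row, and INFO keys AF (6 significant digits), AC, AN, SRC (provenance)
#' and ITER (iteration of first addition) where present. Output is
#' coordinate-sorted and byte-deterministic.
#'
#' @param vt A `variant_table`.
#' @param path Output file.
#' @param backbone Named character vector (for contig header lines).
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(vt, path, backbone = NULL) {
  vt <- sort_variants(vt)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=graphref")
  if (!is.null(backbone))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(backbone),
                          nchar(backbone)))
  hdr <- c(hdr,
           '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
           '##INFO=<ID=AC,Number=A,Type=Integer,Description="Allele count">',
           '##INFO=<ID=AN,Number=1,Type=Integer,Description="Total allele number">',
           '##INFO=<ID=SRC,Number=.,Type=String,Description="Source provenance">',
           '##INFO=<ID=VC,Number=1,Type=String,Description="Variant class">',
           '##INFO=<ID=ITER,Number=1,Type=Integer,Description="Construction iteration of first addition">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 sep = "\t"))
  info <- vapply(seq_len(nrow(vt)), function(i) {
    parts <- character(0)
    if (!is.na(vt$af[i])) parts <- c(parts, paste0("AF=", fmt_af(vt$af[i])))
    if (!is.na(vt$ac[i])) parts <- c(parts, paste0("AC=", vt$ac[i]))
    if (!is.na(vt$an[i])) parts <- c(parts, paste0("AN=", vt$an[i]))
    if (!is.na(vt$source[i])) parts <- c(parts, paste0("SRC=", vt$source[i]))
    parts <- c(parts, paste0("VC=", vt$var_class[i]))
    if (!is.na(vt$iter[i])) parts <- c(parts, paste0("ITER=", vt$iter[i]))
    paste(parts, collapse = ";")
  }, "")
  body <- if (nrow(vt) == 0) character(0) else
    paste(vt$contig, vt$pos, ".", vt$ref, vt$alt, ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

info_field_num <- function(vcf, key) {
  x <- vcfR::extract.info(vcf, element = key)
  suppressWarnings(lapply(strsplit(ifelse(is.na(x), "", x), ","), as.numeric))
}

#' Read a site VCF into raw (possibly multiallelic) records
#'
#' Per-allele AF/AC and site AN are pulled from INFO; comma-separated
#' per-allele values are kept aligned with their alt alleles for
#' downstream multiallelic splitting.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param source Provenance tag to stamp on the records.
#' @return Data frame with columns `contig`, `pos`, `ref`, `alt`
#'   (comma-joined alts), `filter`, and list-columns `af`, `ac`, plus
#'   `an`, `source`.
#' @export
read_site_vcf <- function(path, source = basename(path)) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  af <- info_field_num(vcf, "AF")
  ac <- info_field_num(vcf, "AC")
  an <- vapply(info_field_num(vcf, "AN"), function(x) x[1] %||% NA_real_, 0)
  out <- data.frame(contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    ref = toupper(fix[, "REF"]), alt = toupper(fix[, "ALT"]),
                    filter = fix[, "FILTER"], an = as.integer(an),
                    source = rep_len(source, n), stringsAsFactors = FALSE)
  out$af <- af
  out$ac <- lapply(ac, as.integer)
  out
}

#' Read a multi-sample genotype VCF into a genotype matrix
#'
#' @param path VCF with GT fields.
#' @param strata Optional named vector (sample -> subpopulation label) or
#'   unnamed vector in sample order.
#' @return A `genotype_matrix`.
#' @export
read_population_vcf <- function(path, strata = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  a1 <- suppressWarnings(matrix(as.integer(sub("/.*$", "", gt)), nrow = nrow(gt)))
  a2 <- suppressWarnings(matrix(as.integer(sub("^.*/", "", gt)), nrow = nrow(gt)))
  S <- length(samples)
  calls <- matrix(NA_integer_, nrow(gt), 2L * S)
  calls[, seq(1, 2 * S, by = 2)] <- a1 + 1L
  calls[, seq(2, 2 * S, by = 2)] <- a2 + 1L
  alleles <- mapply(function(r, a) c(r, strsplit(a, ",", fixed = TRUE)[[1]]),
                    toupper(fix[, "REF"]), toupper(fix[, "ALT"]),
                    SIMPLIFY = FALSE, USE.NAMES = FALSE)
  loci <- data.frame(contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     stringsAsFactors = FALSE)
  loci$alleles <- alleles
  if (!is.null(strata) && !is.null(names(strata)))
    strata <- unname(strata[samples])
  genotype_matrix(samples, loci, calls, strata = strata)
}

#' Write a genotype matrix as a multi-sample VCF
#'
#' @param gm A `genotype_matrix`.
#' @param path Output file.
#' @param backbone Optional named character vector for contig headers.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(gm, path, backbone = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=graphref")
  if (!is.null(backbone))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(backbone),
                          nchar(backbone)))
  hdr <- c(hdr,
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  S <- length(gm$samples)
  o <- order(gm$loci$contig, gm$loci$pos)
  body <- vapply(o, function(l) {
    alleles <- gm$loci$alleles[[l]]
    a1 <- gm$calls[l, seq(1, 2 * S, by = 2)] - 1L
    a2 <- gm$calls[l, seq(2, 2 * S, by = 2)] - 1L
    gts <- paste(ifelse(is.na(a1), ".", a1), ifelse(is.na(a2), ".", a2),
                 sep = "/")
    paste(c(gm$loci$contig[l], gm$loci$pos[l], ".", alleles[1],
            paste(alleles[-1], collapse = ","), ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alt-contig alignments from a SAM file
#'
#' The SAM is converted to BAM with Rsamtools and scanned for name,
#' flag, target, position, CIGAR and query sequence. Alignments must
#' carry a base-level path (a real CIGAR and sequence); unmapped records
#' are returned under `unmapped`.
#'
#' @param sam_path SAM file with `@SQ` headers.
#' @return List with `alignments` (data frame: qname, rname, pos, cigar,
#'   seq) and `unmapped` (character vector of query names).
#' @export
read_alt_alignments <- function(sam_path) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq")))[[1]]
  unmapped <- res$qname[bitwAnd(res$flag, 4L) != 0]
  keep <- bitwAnd(res$flag, 4L) == 0
  aln <- data.frame(qname = res$qname[keep],
                    rname = as.character(res$rname[keep]),
                    pos = res$pos[keep], cigar = res$cigar[keep],
                    seq = as.character(res$seq[keep]),
                    stringsAsFactors = FALSE)
  bad <- is.na(aln$cigar) | aln$cigar == "*" | aln$seq == "" | is.na(aln$seq)
  if (any(bad))
    stopf("alignment(s) without base-level edit script (need CIGAR and SEQ, e.g. minimap2 --eqx output): %s",
          paste(aln$qname[bad], collapse = ", "))
  list(alignments = aln, unmapped = unmapped)
}

#' Serialize a genome graph
#'
#' Writes the backbone FASTA, the sorted variant VCF and a JSON sidecar
#' of summary statistics (edge counts by class, mean AF).
#'
#' @param graph A `genome_graph`.
#' @param prefix Output path prefix; files `<prefix>.fa`, `<prefix>.vcf`
#'   and `<prefix>.summary.json` are written.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_graph <- function(graph, prefix) {
  fa <- paste0(prefix, ".fa"); vcf <- paste0(prefix, ".vcf")
  js <- paste0(prefix, ".summary.json")
  write_backbone_fasta(graph$backbone, fa, decoys = graph$decoys)
  write_variant_vcf(graph$variants, vcf, backbone = graph$backbone)
  jsonlite::write_json(graph_summary(graph), js, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(fasta = fa, vcf = vcf, summary = js))
}

#' Load a genome graph from FASTA + VCF
#'
#' @param fasta_path Backbone FASTA (decoys tagged in descriptions).
#' @param vcf_path Variant VCF as written by [write_variant_vcf()].
#' @return A `genome_graph`.
#' @export
read_graph <- function(fasta_path, vcf_path) {
  bb <- read_backbone_fasta(fasta_path)
  raw <- read_site_vcf(vcf_path, source = NA_character_)
  src <- vcfR::extract.info(vcfR::read.vcfR(vcf_path, verbose = FALSE), "SRC")
  it <- suppressWarnings(as.integer(
    vcfR::extract.info(vcfR::read.vcfR(vcf_path, verbose = FALSE), "ITER")))
  vt <- variant_table(contig = raw$contig, pos = raw$pos, ref = raw$ref,
                      alt = raw$alt,
                      af = vapply(raw$af, function(x) x[1] %||% NA_real_, 0),
                      ac = vapply(raw$ac, function(x) x[1] %||% NA_integer_, 1L),
                      an = raw$an, source = src,
                      iter = if (length(it)) it else NA_integer_)
  build_graph(bb$backbone, vt, decoys = bb$decoys)
}

#' Summary statistics of a genome graph
#'
#' Edge counts by variant class, mean allele frequency, and counts per
#' construction iteration — the headline numbers used to characterize a
#' constructed graph.
#'
#' @param graph A `genome_graph`.
#' @return Named list.
#' @export
graph_summary <- function(graph) {
  vt <- graph$variants
  cls <- c(SNP = 0L, INDEL = 0L, SV = 0L)
  tab <- table(vt$var_class)
  cls[names(tab)] <- as.integer(tab)
  by_iter <- if (nrow(vt) && any(!is.na(vt$iter)))
    as.list(table(vt$iter)) else NULL
  list(n_edges = nrow(vt),
       n_contigs = length(graph$backbone),
       backbone_bp = sum(nchar(graph$backbone)),
       n_decoys = length(graph$decoys),
       edges_by_class = as.list(cls),
       mean_af = if (nrow(vt) && any(!is.na(vt$af)))
         mean(vt$af, na.rm = TRUE) else NA,
       edges_by_iteration = by_iter)
}
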