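# I/O layer: FASTA references, BED panel regions, per-individual VCFs.
#
# Coordinate conventions are confined here: variants and GRanges are
# 1-based inclusive, BED files on disk are 0-based half-open (handled by
# rtracklayer on both read and write).

#' Read a reference sequence from FASTA
#'
#' @param path FASTA file.
#' @return named character vector, one element per sequence.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a reference sequence to FASTA
#'
#' @param reference named character vector of sequences.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  ss <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read panel regions from BED
#'
#' Intervals are merged and sorted. The on-disk 0-based half-open BED
#' convention is converted to 1-based inclusive `GRanges` coordinates.
#'
#' @param path BED file.
#' @return a merged, sorted `GRanges`.
#' @export
read_panel <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Write panel regions to BED
#'
#' @param panel a `GRanges`.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  rtracklayer::export(panel, path, format = "BED")
  invisible(path)
}

#' Make panel regions from coordinates
#'
#' @param chrom,start,end vectors of 1-based inclusive interval bounds.
#' @return a merged, sorted `GRanges`.
#' @export
panel_regions <- function(chrom, start, end) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Which positions fall inside a panel
#'
#' @param chrom,pos position vectors (1-based).
#' @param panel a `GRanges`.
#' @return logical vector.
#' @export
in_panel <- function(chrom, pos, panel) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(q, panel) > 0L
}

# parse one diploid GT string into allele indices (integer vector of 2),
# NA for missing alleles, NULL for malformed
.parse_gt <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(c(NA_integer_, NA_integer_))
  parts <- strsplit(gt, "[/|]")[[1]]
  if (length(parts) != 2L) return(NULL)
  suppressWarnings(idx <- as.integer(ifelse(parts == ".", NA, parts)))
  if (any(is.na(idx) & parts != ".")) return(NULL)
  idx
}

#' Read a single-sample VCF into call records
#'
#' Multi-allelic records are decomposed into biallelic call records; for
#' each decomposed alternate, `alt_copies` counts how many of the two
#' genotype alleles equal that alternate. Depth is taken from FORMAT/DP
#' with an AD-sum fallback (recorded in `depth_source`). A per-caller
#' adapter maps dialects: `caller = "varscan"` reads VarScan-style
#' FORMAT/RD (reference depth) + FORMAT/AD (alternate depth scalar);
#' the default reads the usual FORMAT/AD vector.
#'
#' @param path uncompressed VCF file, one sample.
#' @param caller dialect adapter: `"generic"` (GATK-style AD vector; also
#'   fits Strelka2 realigned AD, VarDict, DNAscope) or `"varscan"`.
#' @param sample_id sample name; defaults to the VCF sample column.
#' @return `data.table` with columns `sample`, `chrom`, `pos`, `ref`,
#'   `alt`, `filter`, `gt`, `alt_copies`, `ref_depth`, `alt_depth`,
#'   `depth`, `depth_source`, `malformed_gt`.
#' @export
read_sample_vcf <- function(path, caller = c("generic", "varscan"),
                            sample_id = NULL) {
  caller <- match.arg(caller)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (is.null(sample_id)) {
    sn <- colnames(vcf)
    sample_id <- if (length(sn) >= 1L) sn[1L] else "sample"
  }
  if (n == 0L) {
    return(data.table::data.table(
      sample = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), filter = character(),
      gt = character(), alt_copies = integer(), ref_depth = integer(),
      alt_depth = integer(), depth = integer(), depth_source = character(),
      malformed_gt = logical()))
  }
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt_flat <- as.character(BiocGenerics::unlist(rr$ALT))
  nalt0 <- S4Vectors::elementNROWS(rr$ALT)
  filt <- VariantAnnotation::filt(vcf)
  g <- VariantAnnotation::geno(vcf)
  gt_str <- if ("GT" %in% names(g)) as.character(g$GT[, 1L])
            else rep(NA_character_, n)
  dp <- if ("DP" %in% names(g)) suppressWarnings(as.integer(g$DP[, 1L]))
        else rep(NA_integer_, n)
  ad_list <- if ("AD" %in% names(g)) {
    ad <- g$AD
    if (is.list(ad)) lapply(seq_len(n), function(i) ad[[i, 1L]])
    else if (length(dim(ad)) == 3L) lapply(seq_len(n), function(i) ad[i, 1L, ])
    else lapply(seq_len(n), function(i) ad[i, 1L])
  } else NULL
  rd <- if ("RD" %in% names(g)) suppressWarnings(as.integer(g$RD[, 1L]))
        else rep(NA_integer_, n)

  # parsed genotype allele indices (n x 2); malformed rows flagged
  gtp <- strsplit(ifelse(is.na(gt_str), ".", gt_str), "[/|]")
  malformed <- lengths(gtp) != 2L & !(gt_str %in% c(".", NA))
  a1 <- suppressWarnings(as.integer(vapply(gtp, `[`, "", 1L)))
  a2 <- suppressWarnings(as.integer(vapply(gtp, function(x)
    if (length(x) >= 2L) x[2L] else NA_character_, "")))
  bad_tok <- function(k) {
    tok <- vapply(gtp, function(x) if (length(x) >= k) x[k] else ".", "")
    !is.na(tok) & tok != "." & is.na(suppressWarnings(as.integer(tok)))
  }
  malformed <- malformed | bad_tok(1L) | bad_tok(2L)

  # decompose multi-allelic records: one output row per alternate
  row_of <- rep(seq_len(n), nalt0)
  within <- sequence(nalt0)
  ok <- nzchar(alt_flat) & alt_flat != "."
  ridx <- row_of[ok]
  aidx <- within[ok]
  alt <- alt_flat[ok]

  alt_copies <- ifelse(is.na(a1[ridx]) & is.na(a2[ridx]), NA_integer_,
                       (a1[ridx] == aidx & !is.na(a1[ridx])) +
                       (a2[ridx] == aidx & !is.na(a2[ridx])))
  if (caller == "varscan") {
    ref_depth <- rd[ridx]
    alt_depth <- if (is.null(ad_list)) rep(NA_integer_, length(ridx))
                 else suppressWarnings(as.integer(
                   vapply(ad_list, function(x) as.numeric(x[1L]), 0)))[ridx]
  } else {
    ref_depth <- if (is.null(ad_list)) rep(NA_integer_, length(ridx))
                 else suppressWarnings(as.integer(
                   vapply(ad_list, function(x) as.numeric(x[1L]), 0)))[ridx]
    alt_depth <- if (is.null(ad_list)) rep(NA_integer_, length(ridx))
                 else suppressWarnings(as.integer(mapply(
                   function(i, j) {
                     x <- ad_list[[i]]
                     if (length(x) >= j + 1L) as.numeric(x[j + 1L]) else NA_real_
                   }, ridx, aidx)))
  }
  depth <- dp[ridx]
  dsource <- ifelse(is.na(depth), "AD-sum", "DP")
  ad_sum <- ifelse(is.na(ref_depth) & is.na(alt_depth), NA_integer_,
                   as.integer(ifelse(is.na(ref_depth), 0L, ref_depth) +
                              ifelse(is.na(alt_depth), 0L, alt_depth)))
  depth <- ifelse(is.na(depth), ad_sum, depth)

  data.table::data.table(
    sample = sample_id, chrom = chrom[ridx], pos = pos[ridx],
    ref = ref[ridx], alt = alt, filter = filt[ridx], gt = gt_str[ridx],
    alt_copies = as.integer(alt_copies),
    ref_depth = ref_depth, alt_depth = alt_depth,
    depth = depth, depth_source = dsource,
    malformed_gt = malformed[ridx])
}

#' Write a simple single-sample VCF
#'
#' Emits the fixture dialect: FORMAT `GT:AD:DP`, FILTER `PASS` unless
#' overridden. Used by the synthetic-cohort generator.
#'
#' @param calls `data.table`/data.frame with columns `chrom`, `pos`,
#'   `ref`, `alt`, `gt`, `ref_depth`, `alt_depth`, `depth` and optionally
#'   `filter`.
#' @param sample_id sample column name.
#' @param path output file.
#' @param reference optional named character vector used to emit contig
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(calls, sample_id, path, reference = NULL) {
  calls <- data.table::as.data.table(calls)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=varconcord-fixtures",
    '##FILTER=<ID=PASS,Description="All filters passed">',
    '##FILTER=<ID=LowQual,Description="Low quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(reference))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(reference), nchar(reference)))
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                       sample_id))
  filt <- if ("filter" %in% names(calls)) calls$filter else rep("PASS", nrow(calls))
  body <- if (nrow(calls) == 0L) character() else {
    o <- order(calls$chrom, calls$pos)
    with(calls[o], sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT:AD:DP\t%s:%d,%d:%d",
                           chrom, pos, ref, alt, filt[o], gt,
                           ref_depth, alt_depth, depth))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
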