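# Transcript models, genomic-to-cDNA coordinate mapping and main
# transcript selection.
#
# Transcript models come from a small tab-delimited file: one row per
# transcript with comma-separated exon bounds and genomic CDS bounds.
# Full HGVS string grammar is out of scope; the mapping exposes a coding
# position plus a signed intronic offset, which together with the
# right-shifted alleles determines the coding-DNA name.

#' Construct a transcript model
#'
#' @param id transcript accession.
#' @param gene gene symbol.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of 1-based inclusive exon
#'   bounds, sorted by genomic position, non-overlapping.
#' @param cds_start,cds_end genomic bounds of the coding region (inside
#'   the exon span). For `-` strand transcripts the CDS still uses genomic
#'   bounds; translation begins at `cds_end`.
#' @param is_lrg_first does the transcript match the first LRG transcript
#'   of the gene?
#' @param is_canonical flagged canonical by the annotator?
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(id, gene, strand, exon_starts, exon_ends,
                             cds_start, cds_end,
                             is_lrg_first = FALSE, is_canonical = FALSE) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            all(exon_starts <= exon_ends))
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o]); exon_ends <- as.integer(exon_ends[o])
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] <= exon_ends[-length(exon_ends)]))
    .stopf("exons of %s overlap", id)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_start < exon_starts[1L] || cds_end > exon_ends[length(exon_ends)] ||
      cds_start > cds_end)
    .stopf("CDS bounds of %s outside exon span", id)
  structure(list(id = id, gene = gene, strand = strand,
                 exon_starts = exon_starts, exon_ends = exon_ends,
                 cds_start = cds_start, cds_end = cds_end,
                 is_lrg_first = isTRUE(is_lrg_first),
                 is_canonical = isTRUE(is_canonical)),
            class = "transcript_model")
}

#' Read transcript models from a tab-delimited file
#'
#' Columns: `id`, `gene`, `strand`, `exon_starts`, `exon_ends`
#' (comma-separated), `cds_start`, `cds_end`, `lrg_first`, `canonical`.
#'
#' @param path file path.
#' @return named list of `transcript_model` objects.
#' @export
read_transcripts <- function(path) {
  tab <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("id", "gene", "strand", "exon_starts", "exon_ends")))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i]
    transcript_model(
      r$id, r$gene, r$strand,
      as.integer(strsplit(r$exon_starts, ",")[[1]]),
      as.integer(strsplit(r$exon_ends, ",")[[1]]),
      r$cds_start, r$cds_end,
      as.logical(r$lrg_first), as.logical(r$canonical))
  })
  names(out) <- tab$id
  out
}

# exonic genomic positions in transcript (5'->3') order
.tx_positions <- function(t) {
  g <- unlist(mapply(seq.int, t$exon_starts, t$exon_ends, SIMPLIFY = FALSE))
  if (t$strand == "-") rev(g) else g
}

# cDNA coordinate of an exonic genomic position: integer relative to the
# translation start; 1..n within CDS, negative in the 5' UTR, and
# past-the-stop counts returned with region "utr3"
.cdna_of_exonic <- function(g, t, txpos) {
  idx <- match(g, txpos)
  cds_first <- match(if (t$strand == "+") t$cds_start else t$cds_end, txpos)
  cds_last  <- match(if (t$strand == "+") t$cds_end else t$cds_start, txpos)
  if (idx < cds_first) list(cpos = idx - cds_first, region = "utr5")
  else if (idx > cds_last) list(cpos = idx - cds_last, region = "utr3")
  else list(cpos = idx - cds_first + 1L, region = "cds")
}

#' Map a genomic position to cDNA coordinates
#'
#' Exonic positions are counted in coding bases from the translation
#' start (negative in the 5' UTR; `region = "utr3"` positions count past
#' the stop). Intronic positions are expressed as the cDNA coordinate of
#' the nearest exon boundary plus a signed offset (positive downstream of
#' a donor, negative upstream of an acceptor; ties go to the donor side).
#' Reverse-strand transcripts count along the antisense direction.
#'
#' @param v a `gvariant` or a single genomic position. For indels the
#'   variant should be right-normalized with respect to transcript
#'   direction before mapping.
#' @param t a `transcript_model`.
#' @return list with `cpos` (integer), `offset` (integer, 0 for exonic)
#'   and `region` (`"cds"`, `"utr5"`, `"utr3"`).
#' @export
map_to_cdna <- function(v, t) {
  g <- if (inherits(v, "gvariant")) v$pos else as.integer(v)
  n_ex <- length(t$exon_starts)
  if (g < t$exon_starts[1L] || g > t$exon_ends[n_ex])
    .stopf("position %d outside transcript span of %s", g, t$id)
  txpos <- .tx_positions(t)
  in_exon <- any(g >= t$exon_starts & g <= t$exon_ends)
  if (in_exon) {
    r <- .cdna_of_exonic(g, t, txpos)
    return(list(cpos = r$cpos, offset = 0L, region = r$region))
  }
  # intronic: flanking exon boundaries in genomic coordinates
  i <- max(which(t$exon_ends < g))            # exon genomically left
  left_b <- t$exon_ends[i]; right_b <- t$exon_starts[i + 1L]
  d_left <- g - left_b; d_right <- right_b - g
  if (t$strand == "+") {
    donor_b <- left_b; acceptor_b <- right_b
    d_donor <- d_left; d_acceptor <- d_right
  } else {
    donor_b <- right_b; acceptor_b <- left_b
    d_donor <- d_right; d_acceptor <- d_left
  }
  if (d_donor <= d_acceptor) {
    anchor <- .cdna_of_exonic(donor_b, t, txpos)
    list(cpos = anchor$cpos, offset = d_donor, region = anchor$region)
  } else {
    anchor <- .cdna_of_exonic(acceptor_b, t, txpos)
    list(cpos = anchor$cpos, offset = -d_acceptor, region = anchor$region)
  }
}

#' Default consequence severity ranking
#'
#' Configurable total order over consequence terms, most severe first,
#' following the ordering commonly published by variant-effect
#' annotators. Used by [select_main_transcript()].
#'
#' @return character vector of consequence terms.
#' @export
default_consequence_ranking <- function() {
  c("transcript_ablation", "splice_acceptor_variant", "splice_donor_variant",
    "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
    "transcript_amplification", "inframe_insertion", "inframe_deletion",
    "missense_variant", "protein_altering_variant",
    "splice_donor_5th_base_variant", "splice_region_variant",
    "splice_donor_region_variant", "splice_polypyrimidine_tract_variant",
    "incomplete_terminal_codon_variant", "start_retained_variant",
    "stop_retained_variant", "synonymous_variant",
    "coding_sequence_variant", "mature_miRNA_variant",
    "5_prime_UTR_variant", "3_prime_UTR_variant",
    "non_coding_transcript_exon_variant", "intron_variant",
    "non_coding_transcript_variant", "upstream_gene_variant",
    "downstream_gene_variant", "intergenic_variant")
}

#' Select the main transcript for display
#'
#' Within each gene the candidate is the transcript matching the first
#' LRG transcript of the gene if one exists, otherwise the one flagged
#' canonical (falling back to the first candidate by transcript id when
#' neither flag is present). When candidates span several genes, the
#' per-gene candidates compete on consequence severity; ties are broken
#' by transcript id.
#'
#' @param annotations data.frame with columns `transcript_id`, `gene`,
#'   `consequence`, `is_lrg_first`, `is_canonical`.
#' @param ranking character vector of consequence terms from most to
#'   least severe; defaults to [default_consequence_ranking()].
#' @return the selected transcript id.
#' @export
select_main_transcript <- function(annotations,
                                   ranking = default_consequence_ranking()) {
  ann <- data.table::as.data.table(annotations)
  if (nrow(ann) == 0L) .stopf("no candidate transcript")
  if (anyDuplicated(ranking)) .stopf("ranking contains duplicate terms")
  sev <- match(ann$consequence, ranking)
  if (anyNA(sev))
    .stopf("consequence term(s) absent from ranking: %s",
           paste(unique(ann$consequence[is.na(sev)]), collapse = ", "))
  ann$.sev <- sev
  pick_in_gene <- function(d) {
    if (any(d$is_lrg_first)) d <- d[d$is_lrg_first == TRUE]
    else if (any(d$is_canonical)) d <- d[d$is_canonical == TRUE]
    d[order(d$transcript_id)][1L]
  }
  picks <- ann[, pick_in_gene(.SD), by = "gene"]
  picks <- picks[order(picks$.sev, picks$transcript_id)]
  picks$transcript_id[1L]
}
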